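#' Eyring plot of a rate panel fit
#'
#' Linearized Eyring plot: `ln(kcat/T)` against `1000/T` with the fitted
#' line.
#'
#' @param object An `eyring_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eyring_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data,
                      inv_T = 1000 / celsius_to_kelvin(.data$temp_C),
                      y = log(.data$kcat_per_s /
                                celsius_to_kelvin(.data$temp_C)))
  grid <- tibble::tibble(
    temp_K = seq(min(celsius_to_kelvin(df$temp_C)),
                 max(celsius_to_kelvin(df$temp_C)), length.out = 100)
  )
  grid$inv_T <- 1000 / grid$temp_K
  grid$y <- log(eyring_kcat(object$dH_act, object$dS_act, grid$temp_K) /
                  grid$temp_K)
  ggplot2::ggplot(df, ggplot2::aes(.data$inv_T, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::labs(x = "1000 / T (1/K)", y = "ln(kcat / T)",
                  title = sprintf("Eyring fit (%s)", object$condition),
                  subtitle = sprintf(
                    "dH = %.0f cal/mol, dS = %.2f cal/(mol K)",
                    object$dH_act, object$dS_act)) +
    ggplot2::theme_minimal()
}

#' Bootstrap distributions of the allosteric energetics
#'
#' Histograms of the paired bootstrap draws of `ddH`, `T*ddS` and `ddG`.
#'
#' @param object An `allostery_energetics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allostery_energetics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$boot[, c("ddH", "TddS", "ddG")],
    dplyr::everything(), names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", color = NA) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = "cal/mol", y = "bootstrap draws",
                  title = sprintf("Lit-minus-dark energetics at %.1f K",
                                  object$T_ref)) +
    ggplot2::theme_minimal()
}

#' Melt curve with its two-state fit
#'
#' CD data inside and outside the fit window, the fitted two-state curve,
#' and the fitted melting temperature.
#'
#' @param object A `melt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melt_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(temp_C = seq(object$window$t_start,
                                      object$window$t_end,
                                      length.out = 200))
  grid$cd <- two_state_model(grid$temp_C, object$dH_fold, object$Tm,
                             object$F, object$Cf, object$U, object$CU)
  ggplot2::ggplot(df, ggplot2::aes(.data$temp_C, .data$cd_mdeg)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$cd),
                       color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$Tm, linetype = 2) +
    ggplot2::labs(x = "Temperature (°C)", y = "Ellipticity (mdeg)",
                  title = sprintf("Two-state melt fit: Tm = %.1f °C",
                                  object$Tm),
                  subtitle = if (object$accepted) NULL else
                    paste("FLAGGED:", object$flag)) +
    ggplot2::theme_minimal()
}

#' Raw melt curve channels
#'
#' CD and HT channels of a (raw or cleaned) melt curve against
#' temperature.
#'
#' @param object A `melt_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melt_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df[, c("temp_C", "cd_mdeg", "ht_v")],
                              c("cd_mdeg", "ht_v"),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$temp_C, .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Temperature (°C)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Enthalpy-entropy tradeoff plot
#'
#' Variants placed at `(T_ref * ddS, ddH)` with the `x = y` diagonal of
#' exact compensation; the vertical offset from the line is the allosteric
#' free-energy gain.
#'
#' @param records A list of `variant_record`s or a [variant_panel()]
#'   tibble.
#' @param T_ref Reference temperature (K), passed to
#'   [tradeoff_coordinates()].
#' @return A ggplot object.
#' @export
plot_tradeoff <- function(records, T_ref = NULL) {
  df <- tradeoff_coordinates(records, T_ref = T_ref)
  rng <- range(c(df$x_TddS, df$y_ddH))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_TddS, .data$y_ddH)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$variant),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal(xlim = rng, ylim = rng) +
    ggplot2::labs(x = "T · ddS (cal/mol)", y = "ddH (cal/mol)",
                  title = "Enthalpy-entropy tradeoff of light activation") +
    ggplot2::theme_minimal()
}

#' Temperature profiles of the allosteric fold change
#'
#' One line (with bootstrap ribbon) per variant.
#'
#' @param records A list of `variant_record` objects.
#' @param temps_K Temperatures (K) to evaluate.
#' @return A ggplot object.
#' @export
plot_temperature_profiles <- function(records,
                                      temps_K = seq(278.15, 313.15, 1)) {
  df <- purrr::map_dfr(records, temperature_profile, temps_K = temps_K)
  ggplot2::ggplot(df, ggplot2::aes(.data$temp_C, .data$fold,
                                   color = .data$variant,
                                   fill = .data$variant)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "Predicted lit/dark kcat ratio") +
    ggplot2::theme_minimal()
}

#' Stability-activity correlation plot
#'
#' Scatter of `dTm` against `ddG` with the best-fit line computed on the
#' non-excluded records; excluded variants are circled.
#'
#' @param panel A [variant_panel()] tibble.
#' @param exclude Variant labels omitted from the fitted line.
#' @return A ggplot object.
#' @export
plot_stability_activity <- function(panel, exclude = character(0)) {
  res <- stability_activity_correlation(panel, exclude = exclude)
  panel$excluded <- panel$variant %in% exclude
  ggplot2::ggplot(panel, ggplot2::aes(.data$ddG, .data$dTm)) +
    ggplot2::geom_abline(slope = res$slope, intercept = res$intercept,
                         color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2) +
    ggplot2::geom_point(data = panel[panel$excluded, , drop = FALSE],
                        shape = 1, size = 4, color = "firebrick") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "ddG lit-dark (cal/mol)", y = "dTm lit-dark (°C)",
                  subtitle = sprintf("Pearson r = %.2f (n = %d)",
                                     res$pearson_r, res$n_used)) +
    ggplot2::theme_minimal()
}
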