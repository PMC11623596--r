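#' Initial reaction velocity from an absorbance trace
#'
#' Fits a straight line to the first `window_s` seconds of the progress
#' curve and converts the slope to a molar velocity via Beer's law:
#' `v0 = -slope / (epsilon * pathlength)` with the result expressed in M/s.
#' A negative velocity (rising absorbance) is flagged, not clamped, so
#' pathological traces remain visible downstream.
#'
#' @param trace A `kinetic_trace` tibble (columns `time_s`, `absorbance`)
#'   such as produced by [simulate_absorbance_trace()] or
#'   [read_trace_csv()].
#' @param window_s Length of the initial-velocity window in seconds.
#' @param epsilon_mM_cm,pathlength_cm Overrides for the trace metadata.
#'
#' @return A one-row tibble: `temp_C`, `condition`, `slope_AU_s`,
#'   `velocity_M_s`, `n_points`, `r_squared`, `flagged`.
#' @examples
#' tr <- simulate_absorbance_trace(0.58, 1e-7, noise_sd = 0)
#' initial_velocity(tr)
#' @export
initial_velocity <- function(trace, window_s = 15,
                             epsilon_mM_cm = NULL, pathlength_cm = NULL) {
  epsilon_mM_cm <- epsilon_mM_cm %||% attr(trace, "epsilon_mM_cm")
  pathlength_cm <- pathlength_cm %||% attr(trace, "pathlength_cm")
  if (is.null(epsilon_mM_cm) || is.null(pathlength_cm) ||
      !isTRUE(epsilon_mM_cm > 0) || !isTRUE(pathlength_cm > 0)) {
    abort("Positive `epsilon_mM_cm` and `pathlength_cm` are required.",
          class = "litdark_bad_params")
  }
  sub <- dplyr::filter(tibble::as_tibble(trace),
                       .data$time_s >= 0, .data$time_s <= window_s)
  if (nrow(sub) < 5) {
    abort(sprintf("Need >= 5 samples in the first %g s; got %d.",
                  window_s, nrow(sub)),
          class = "litdark_too_few_points")
  }
  fit <- lm(absorbance ~ time_s, data = sub)
  slope <- unname(coef(fit)[["time_s"]])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((sub$absorbance - mean(sub$absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  v0 <- -slope / (epsilon_mM_cm * pathlength_cm * 1000)
  tibble::tibble(
    temp_C = attr(trace, "temp_C") %||% NA_real_,
    condition = attr(trace, "condition") %||% NA_character_,
    slope_AU_s = slope,
    velocity_M_s = v0,
    n_points = nrow(sub),
    r_squared = r2,
    flagged = v0 < 0
  )
}

#' Turnover number from an initial velocity
#'
#' Under saturating substrate and cofactor, `kcat = v0 / [E]`.
#'
#' @param velocity_M_s Initial velocity in M/s.
#' @param enzyme_conc_M Enzyme concentration in M; must be positive.
#' @return kcat in 1/s.
#' @export
kcat_from_velocity <- function(velocity_M_s, enzyme_conc_M) {
  if (!isTRUE(all(enzyme_conc_M > 0))) {
    abort("`enzyme_conc_M` must be positive.", class = "litdark_bad_params")
  }
  velocity_M_s / enzyme_conc_M
}

#' Turnover number straight from a trace
#'
#' Convenience wrapper chaining [initial_velocity()] and
#' [kcat_from_velocity()] using the enzyme concentration stored on the
#' trace.
#'
#' @inheritParams initial_velocity
#' @return The tibble from [initial_velocity()] with an extra
#'   `kcat_per_s` column.
#' @export
trace_to_kcat <- function(trace, window_s = 15) {
  enz <- attr(trace, "enzyme_conc_M")
  v <- initial_velocity(trace, window_s = window_s)
  dplyr::mutate(v, kcat_per_s = kcat_from_velocity(.data$velocity_M_s, enz))
}

#' One-phase association fit of a relaxation trace
#'
#' Nonlinear least-squares fit of `A(t) = plateau + (A0 - plateau) *
#' exp(-k * t)`, the single-exponential recovery of the dark-state
#' chromophore absorbance after illumination. Starting values come from the
#' trace endpoints and a log-linearized slope; the rate is constrained
#' positive.
#'
#' @param trace A `kinetic_trace` tibble with columns `time_s`,
#'   `absorbance`.
#' @return An object of class `relaxation_fit` with elements `k_rel`, `A0`,
#'   `plateau`, `rms`, `converged` and the data.
#' @examples
#' tr <- simulate_relaxation_trace(k_rel = 0.02, noise_sd = 0)
#' fit_one_phase_association(tr)$k_rel
#' @export
fit_one_phase_association <- function(trace) {
  df <- tibble::as_tibble(trace)[, c("time_s", "absorbance")]
  if (nrow(df) < 4) {
    abort("Need >= 4 samples.", class = "litdark_too_few_points")
  }
  rng <- diff(range(df$absorbance))
  if (rng <= .Machine$double.eps^0.5 * max(1, abs(df$absorbance[1]))) {
    abort("Constant trace: A0 = plateau, rate unidentifiable.",
          class = "litdark_degenerate_fit")
  }
  A0_0 <- df$absorbance[1]
  plateau_0 <- mean(tail(df$absorbance, max(3L, nrow(df) %/% 10)))
  span <- diff(range(df$time_s))
  dev <- abs(df$absorbance - plateau_0)
  usable <- dev > 0.05 * max(dev)
  k0 <- if (sum(usable) >= 2) {
    sl <- unname(coef(lm(log(dev[usable]) ~ df$time_s[usable]))[2])
    if (is.finite(sl) && sl < 0) -sl else 1 / span
  } else {
    1 / span
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      absorbance ~ plateau + (A0 - plateau) * exp(-k * time_s),
      data = df,
      start = list(A0 = A0_0, plateau = plateau_0, k = k0),
      lower = c(A0 = -Inf, plateau = -Inf, k = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    abort(paste0("One-phase association fit failed: ",
                 conditionMessage(fit)),
          class = "litdark_fit_failure")
  }
  cf <- coef(fit)
  structure(
    list(k_rel = unname(cf[["k"]]), A0 = unname(cf[["A0"]]),
         plateau = unname(cf[["plateau"]]),
         rms = sqrt(mean(stats::residuals(fit)^2)),
         converged = fit$convInfo$isConv %||% TRUE,
         n_points = nrow(df), data = df),
    class = "relaxation_fit"
  )
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat("One-phase association fit\n")
  cat(sprintf("  k_rel   = %.4g /s (half-time %.4g s)\n",
              x$k_rel, log(2) / x$k_rel))
  cat(sprintf("  A0      = %.4g\n  plateau = %.4g\n  rms     = %.3g (n = %d)\n",
              x$A0, x$plateau, x$rms, x$n_points))
  invisible(x)
}
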