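#' Tidy an Eyring fit
#'
#' @param x An `eyring_fit`.
#' @param ... Unused.
#' @return A tibble with one row per transition-state parameter:
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.eyring_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dH_act", "dS_act"),
    estimate = c(x$dH_act, x$dS_act),
    std.error = c(x$se_dH %||% NA_real_, x$se_dS %||% NA_real_),
    conf.low = c(x$ci_dH[1] %||% NA_real_, x$ci_dS[1] %||% NA_real_),
    conf.high = c(x$ci_dH[2] %||% NA_real_, x$ci_dS[2] %||% NA_real_)
  )
}

#' @rdname tidy.eyring_fit
#' @export
glance.eyring_fit <- function(x, ...) {
  tibble::tibble(condition = x$condition, n_points = x$n_points,
                 n_excluded = x$n_excluded, t_max = x$t_max,
                 r.squared = x$r_squared, n_boot = x$n_boot,
                 n_redrawn = x$n_redrawn,
                 seed = x$seed %||% NA_integer_)
}

#' Tidy lit-minus-dark allosteric energetics
#'
#' @param x An `allostery_energetics` object.
#' @param ... Unused.
#' @return A tibble with one row per derived quantity (`ddH`, `ddS`,
#'   `TddS_at_ref`, `ddG_at_ref`, `fold_change_at_ref`) and its paired
#'   bootstrap interval.
#' @export
tidy.allostery_energetics <- function(x, ...) {
  est <- c(x$ddH, x$ddS, x$TddS_at_ref, x$ddG_at_ref, x$fold_change_at_ref)
  dplyr::mutate(x$ci, estimate = est, .after = "quantity")
}

#' @rdname tidy.allostery_energetics
#' @export
glance.allostery_energetics <- function(x, ...) {
  tibble::tibble(T_ref = x$T_ref, n_boot = x$n_boot,
                 ddG_at_ref = x$ddG_at_ref,
                 fold_change_at_ref = x$fold_change_at_ref)
}

#' Tidy a two-state melt fit
#'
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter.
#' @export
tidy.melt_fit <- function(x, ...) {
  terms <- c("Tm", "dH_fold", "F", "Cf", "U", "CU")
  tibble::tibble(
    term = terms,
    estimate = c(x$Tm, x$dH_fold, x$F, x$Cf, x$U, x$CU),
    std.error = unname(x$se[c("Tm", "dH", "F", "Cf", "U", "CU")])
  )
}

#' @rdname tidy.melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, condition = x$condition,
                 t_start = x$window$t_start, t_end = x$window$t_end,
                 full_window = x$window$full_window,
                 n_points = x$n_points, rms = x$rms,
                 converged = x$converged, accepted = x$accepted,
                 flag = x$flag)
}

#' Tidy a one-phase association fit
#'
#' @param x A `relaxation_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k_rel`, `A0`, `plateau`).
#' @export
tidy.relaxation_fit <- function(x, ...) {
  tibble::tibble(term = c("k_rel", "A0", "plateau"),
                 estimate = c(x$k_rel, x$A0, x$plateau))
}

#' @rdname tidy.relaxation_fit
#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, n_points = x$n_points,
                 converged = x$converged,
                 half_time_s = log(2) / x$k_rel)
}

#' Tidy a variant record
#'
#' @param x A `variant_record`.
#' @param ... Unused.
#' @return The one-row panel representation of the record (see
#'   [variant_panel()]).
#' @export
tidy.variant_record <- function(x, ...) {
  variant_panel(list(x), reference_variant = NULL)
}

#' Tidy a stability-activity correlation
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return A tibble of the regression coefficients for both fitting
#'   directions.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope", "reverse_intercept", "reverse_slope"),
    estimate = c(x$intercept, x$slope, x$reverse_intercept, x$reverse_slope)
  )
}

#' @rdname tidy.correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, n_used = x$n_used,
                 n_excluded = length(x$excluded))
}
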