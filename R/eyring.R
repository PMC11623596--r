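#' Eyring rate law
#'
#' Transition-state-theory turnover number
#' `kcat = (kB*T/h) * exp(-dH_act/(R*T)) * exp(dS_act/R)` with
#' `R = 1.987 cal/(mol K)` and temperatures in kelvin.
#'
#' @param dH_act Activation enthalpy (cal/mol).
#' @param dS_act Activation entropy (cal/(mol K)).
#' @param temp_K Absolute temperature (K); vectorized.
#' @return kcat in 1/s.
#' @examples
#' eyring_kcat(14000, -12.5, 298.15)
#' @export
eyring_kcat <- function(dH_act, dS_act, temp_K) {
  if (any(temp_K <= 0)) {
    abort("`temp_K` must be positive.", class = "litdark_bad_params")
  }
  KB_OVER_H * temp_K * exp(-dH_act / (R_CAL * temp_K)) * exp(dS_act / R_CAL)
}

new_eyring_fit <- function(dH_act, dS_act, data, n_excluded, condition,
                           t_max, r_squared, boot = NULL, seed = NULL,
                           n_redrawn = 0L, stratified = FALSE) {
  out <- list(
    dH_act = dH_act, dS_act = dS_act, n_points = nrow(data),
    n_excluded = n_excluded, condition = condition, t_max = t_max,
    r_squared = r_squared, data = data,
    boot = boot, n_boot = if (is.null(boot)) 0L else nrow(boot),
    seed = seed, n_redrawn = n_redrawn, stratified = stratified
  )
  if (!is.null(boot)) {
    out$se_dH <- sd(boot$dH_act)
    out$se_dS <- sd(boot$dS_act)
    out$ci_dH <- unname(quantile(boot$dH_act, c(0.025, 0.975)))
    out$ci_dS <- unname(quantile(boot$dS_act, c(0.025, 0.975)))
  }
  structure(out, class = "eyring_fit")
}

eyring_design <- function(measurements, t_max) {
  req <- c("temp_C", "kcat_per_s")
  if (!all(req %in% names(measurements))) {
    abort("`measurements` needs columns `temp_C` and `kcat_per_s`.",
          class = "litdark_bad_params")
  }
  keep <- dplyr::filter(tibble::as_tibble(measurements),
                        .data$temp_C <= t_max)
  if (any(keep$kcat_per_s <= 0)) {
    abort("All kcat values must be positive for the linearized fit.",
          class = "litdark_bad_params")
  }
  if (dplyr::n_distinct(keep$temp_C) < 2) {
    abort("Need >= 2 distinct temperatures at or below `t_max`.",
          class = "litdark_degenerate_design")
  }
  keep
}

## Closed-form OLS on the linearized Eyring form:
## ln(kcat/T) = [ln(kB/h) + dS/R] - (dH/R) * (1/T)
eyring_ols <- function(temp_K, kcat) {
  x <- 1 / temp_K
  y <- log(kcat / temp_K)
  mx <- mean(x); my <- mean(y)
  sxx <- mean(x * x) - mx^2
  sxy <- mean(x * y) - mx * my
  slope <- sxy / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  list(dH_act = -slope * R_CAL,
       dS_act = (intercept - log(KB_OVER_H)) * R_CAL,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Eyring fit of a rate panel (point estimates)
#'
#' Ordinary least squares on the linearized Eyring form
#' `ln(kcat/T) = [ln(kB/h) + dS_act/R] - (dH_act/R) * (1/T)`. Measurements
#' above `t_max` are excluded before fitting (the high-temperature points
#' sit above the protein's melting temperature, where activity no longer
#' follows the transition-state model).
#'
#' @param measurements A tibble of rate measurements with columns `temp_C`
#'   and `kcat_per_s` (see [simulate_kcat_dataset()] / [read_rate_csv()]).
#' @param t_max Upper temperature bound (degrees C) of the analysis window.
#' @return An object of class `eyring_fit` carrying `dH_act` (cal/mol),
#'   `dS_act` (cal/(mol K)), the filtered data, `n_points` and
#'   `n_excluded`.
#' @examples
#' rates <- simulate_kcat_dataset(true_params(kcat_cv = 0), seed = 1)
#' fit_eyring(rates)
#' @export
fit_eyring <- function(measurements, t_max = 35) {
  keep <- eyring_design(measurements, t_max)
  est <- eyring_ols(celsius_to_kelvin(keep$temp_C), keep$kcat_per_s)
  cond <- if ("condition" %in% names(keep)) {
    paste(unique(keep$condition), collapse = "+")
  } else {
    NA_character_
  }
  new_eyring_fit(est$dH_act, est$dS_act, data = keep,
                 n_excluded = nrow(measurements) - nrow(keep),
                 condition = cond, t_max = t_max,
                 r_squared = est$r_squared)
}

#' Bootstrap Eyring fit
#'
#' Point estimates from the full filtered dataset plus a nonparametric
#' bootstrap of the transition-state parameters: each iteration resamples
#' the pooled (temperature, kcat) pairs with replacement and refits the
#' linearized form. Draws with fewer than two distinct temperatures cannot
#' be fit and are redrawn (the count is recorded in `n_redrawn`). Standard
#' errors are bootstrap standard deviations; 95% intervals are the 2.5/97.5
#' percentiles.
#'
#' @inheritParams fit_eyring
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed making the bootstrap reproducible.
#' @param stratified If `TRUE`, resample replicates within each temperature
#'   instead of pooling all pairs.
#' @return An `eyring_fit` whose `boot` element is a tibble with columns
#'   `iteration`, `dH_act`, `dS_act`, plus `se_dH`, `se_dS`, `ci_dH`,
#'   `ci_dS`.
#' @examples
#' rates <- simulate_kcat_dataset(true_params(kcat_cv = 0.05), seed = 1)
#' fit <- bootstrap_eyring(rates, n_boot = 200, seed = 2)
#' fit$ci_dH
#' @export
bootstrap_eyring <- function(measurements, n_boot = 5000, seed = 1L,
                             t_max = 35, stratified = FALSE) {
  keep <- eyring_design(measurements, t_max)
  n <- nrow(keep)
  temp_K <- celsius_to_kelvin(keep$temp_C)
  x <- 1 / temp_K
  y <- log(keep$kcat_per_s / temp_K)
  est <- eyring_ols(temp_K, keep$kcat_per_s)

  draw_idx <- function(m) {
    if (stratified) {
      groups <- split(seq_len(n), keep$temp_C)
      idx <- lapply(groups, function(g) {
        matrix(g[sample.int(length(g), length(g) * m, replace = TRUE)],
               nrow = m)
      })
      do.call(cbind, idx)
    } else {
      matrix(sample.int(n, n * m, replace = TRUE), nrow = m)
    }
  }

  n_redrawn <- 0L
  boot <- withr::with_seed(seed, {
    idx <- draw_idx(n_boot)
    repeat {
      xm <- matrix(x[idx], nrow = nrow(idx))
      ym <- matrix(y[idx], nrow = nrow(idx))
      mx <- rowMeans(xm); my <- rowMeans(ym)
      sxx <- rowMeans(xm * xm) - mx^2
      bad <- sxx <= 0
      if (!any(bad)) {
        slope <- (rowMeans(xm * ym) - mx * my) / sxx
        intercept <- my - slope * mx
        break
      }
      n_redrawn <- n_redrawn + sum(bad)
      idx[bad, ] <- draw_idx(sum(bad))
    }
    tibble::tibble(iteration = seq_len(n_boot),
                   dH_act = -slope * R_CAL,
                   dS_act = (intercept - log(KB_OVER_H)) * R_CAL)
  })

  cond <- if ("condition" %in% names(keep)) {
    paste(unique(keep$condition), collapse = "+")
  } else {
    NA_character_
  }
  new_eyring_fit(est$dH_act, est$dS_act, data = keep,
                 n_excluded = nrow(measurements) - nrow(keep),
                 condition = cond, t_max = t_max,
                 r_squared = est$r_squared, boot = boot, seed = seed,
                 n_redrawn = n_redrawn, stratified = stratified)
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("Eyring fit (%s), %d points (%d excluded above %g C)\n",
              x$condition %||% "?", x$n_points, x$n_excluded, x$t_max))
  cat(sprintf("  dH_act = %.0f cal/mol\n  dS_act = %.2f cal/(mol K)\n",
              x$dH_act, x$dS_act))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap (n = %d, seed = %s): se(dH) = %.0f, se(dS) = %.2f\n",
                x$n_boot, format(x$seed), x$se_dH, x$se_dS))
    cat(sprintf("  95%% CI dH: [%.0f, %.0f]  dS: [%.2f, %.2f]\n",
                x$ci_dH[1], x$ci_dH[2], x$ci_dS[1], x$ci_dS[2]))
  }
  invisible(x)
}

#' Lit-minus-dark allosteric energetics
#'
#' Differences the transition-state parameters of a lit and a dark Eyring
#' fit: `ddH = dH_lit - dH_dark`, `ddS = dS_lit - dS_dark`,
#' `ddG(T_ref) = ddH - T_ref * ddS`, and the catalytic fold change
#' `exp(-ddG/(R*T_ref))`. Confidence intervals come from pairing iteration
#' i of the lit bootstrap stream with iteration i of the (independent) dark
#' stream. The entropic term is exposed both as `ddS` (cal/(mol K)) and as
#' the energy `TddS_at_ref = T_ref * ddS` (cal/mol), the form in which an
#' entropic penalty at a stated temperature is usually quoted.
#'
#' @param lit,dark `eyring_fit` objects with bootstrap distributions of
#'   equal size (see [bootstrap_eyring()]).
#' @param T_ref Reference temperature in kelvin (default 30 degrees C).
#' @return An object of class `allostery_energetics` with point estimates,
#'   a `ci` tibble and the per-iteration paired bootstrap tibble `boot`.
#' @examples
#' p_dark <- true_params(dH_act = 14000, dS_act = -12.5, kcat_cv = 0.05)
#' p_lit <- true_params(dH_act = 12335, dS_act = -17.6, kcat_cv = 0.05)
#' lit <- bootstrap_eyring(simulate_kcat_dataset(p_lit, condition = "lit",
#'                                               seed = 11),
#'                         n_boot = 200, seed = 1)
#' dark <- bootstrap_eyring(simulate_kcat_dataset(p_dark, seed = 12),
#'                          n_boot = 200, seed = 2)
#' allostery_energetics(lit, dark)
#' @export
allostery_energetics <- function(lit, dark, T_ref = 303.15) {
  stopifnot(inherits(lit, "eyring_fit"), inherits(dark, "eyring_fit"))
  if (lit$n_boot == 0 || dark$n_boot == 0) {
    abort("Both fits must carry bootstrap distributions.",
          class = "litdark_bad_params")
  }
  if (lit$n_boot != dark$n_boot) {
    abort("Bootstrap sizes differ between the lit and dark fits.",
          class = "litdark_bad_params")
  }
  ddH <- lit$dH_act - dark$dH_act
  ddS <- lit$dS_act - dark$dS_act
  ddG <- ddH - T_ref * ddS
  boot <- tibble::tibble(
    iteration = lit$boot$iteration,
    ddH = lit$boot$dH_act - dark$boot$dH_act,
    ddS = lit$boot$dS_act - dark$boot$dS_act
  )
  boot$TddS <- T_ref * boot$ddS
  boot$ddG <- boot$ddH - boot$TddS
  boot$fold <- exp(-boot$ddG / (R_CAL * T_ref))
  ci_of <- function(v) unname(quantile(v, c(0.025, 0.975)))
  ci <- tibble::tibble(
    quantity = c("ddH", "ddS", "TddS_at_ref", "ddG_at_ref",
                 "fold_change_at_ref"),
    lower = c(ci_of(boot$ddH)[1], ci_of(boot$ddS)[1], ci_of(boot$TddS)[1],
              ci_of(boot$ddG)[1], ci_of(boot$fold)[1]),
    upper = c(ci_of(boot$ddH)[2], ci_of(boot$ddS)[2], ci_of(boot$TddS)[2],
              ci_of(boot$ddG)[2], ci_of(boot$fold)[2])
  )
  structure(
    list(ddH = ddH, ddS = ddS, TddS_at_ref = T_ref * ddS,
         ddG_at_ref = ddG,
         fold_change_at_ref = exp(-ddG / (R_CAL * T_ref)),
         T_ref = T_ref, ci = ci, boot = boot, n_boot = lit$n_boot,
         lit = list(dH_act = lit$dH_act, dS_act = lit$dS_act),
         dark = list(dH_act = dark$dH_act, dS_act = dark$dS_act)),
    class = "allostery_energetics"
  )
}

#' @export
print.allostery_energetics <- function(x, ...) {
  cat(sprintf("Lit-minus-dark allosteric energetics at T_ref = %.2f K\n",
              x$T_ref))
  cat(sprintf("  ddH          = %8.0f cal/mol\n", x$ddH))
  cat(sprintf("  T*ddS        = %8.0f cal/mol (ddS = %.2f cal/(mol K))\n",
              x$TddS_at_ref, x$ddS))
  cat(sprintf("  ddG          = %8.0f cal/mol\n", x$ddG_at_ref))
  cat(sprintf("  fold change  = %8.3f\n", x$fold_change_at_ref))
  cat(sprintf("  (paired bootstrap, n = %d)\n", x$n_boot))
  invisible(x)
}

#' Predicted lit/dark fold change at a temperature
#'
#' Evaluates `exp(-(ddH - T*ddS)/(R*T))`, the temperature profile of the
#' allosteric activation implied by the fitted energetics. For `ddH < 0`
#' the profile decreases with temperature: the enthalpic benefit dominates
#' in the cold and the entropic penalty erodes it as T rises.
#'
#' @param energetics An [allostery_energetics()] object.
#' @param temp_K Temperature(s) in kelvin.
#' @param with_ci If `TRUE`, return a tibble with percentile bootstrap
#'   intervals instead of a bare numeric vector.
#' @return A numeric vector of fold changes, or a tibble with columns
#'   `temp_K`, `fold`, `lower`, `upper` when `with_ci = TRUE`.
#' @export
predicted_fold_change <- function(energetics, temp_K, with_ci = FALSE) {
  stopifnot(inherits(energetics, "allostery_energetics"))
  if (any(temp_K <= 0)) {
    abort("`temp_K` must be positive.", class = "litdark_bad_params")
  }
  fold_at <- function(ddH, ddS, T) exp(-(ddH - T * ddS) / (R_CAL * T))
  fold <- fold_at(energetics$ddH, energetics$ddS, temp_K)
  if (!with_ci) {
    return(fold)
  }
  qs <- vapply(temp_K, function(T) {
    quantile(fold_at(energetics$boot$ddH, energetics$boot$ddS, T),
             c(0.025, 0.975))
  }, numeric(2))
  tibble::tibble(temp_K = temp_K, fold = fold,
                 lower = qs[1, ], upper = qs[2, ])
}
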