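#' Detect light-pulse artifacts in an HT voltage series
#'
#' Samples acquired while the excitation LED fires show a steep transient
#' drop in the photomultiplier (HT) voltage. A sample opens a candidate
#' artifact run when the drop from the preceding level exceeds `k_mad`
#' robust scale units (MAD of the successive HT differences); the run may
#' extend over up to `max_run` consecutive depressed samples and is
#' confirmed only if the signal then recovers by at least the same
#' threshold. The recovery requirement distinguishes a transient pulse hit
#' from a genuine monotone decline (e.g. the HT decay that accompanies
#' aggregation), which is never flagged. A pulse coinciding with the very
#' first or last sample leaves no observable drop-and-recovery and cannot
#' be detected.
#'
#' @param ht Numeric HT voltage series in acquisition order.
#' @param k_mad Threshold in units of the MAD of successive differences.
#' @param max_run Maximum number of consecutive pulse-affected samples.
#' @return Integer indices of flagged samples (empty on clean data).
#' @examples
#' detect_light_pulses(c(300, 300.1, 270, 300.2, 300.3))
#' @export
detect_light_pulses <- function(ht, k_mad = 5, max_run = 3) {
  n <- length(ht)
  if (n < 5) {
    abort("Need >= 5 samples.", class = "litdark_too_few_points")
  }
  d <- diff(ht)
  thr <- median(d) - k_mad * mad(d)
  if (thr >= 0) thr <- -.Machine$double.eps # guard: a drop must be a drop
  flagged <- logical(n)
  i <- 2L
  while (i <= n) {
    if (ht[i] - ht[i - 1] < thr) {
      level <- ht[i - 1]
      j <- i
      while (j <= n && ht[j] - level < thr && (j - i) < max_run) {
        j <- j + 1L
      }
      recovered <- j <= n && ht[j] - min(ht[i:(j - 1)]) > -thr
      if (recovered) {
        flagged[i:(j - 1)] <- TRUE
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  which(flagged)
}

#' Clean a raw melt curve
#'
#' Removes pulse-affected samples (per wavelength channel, via
#' [detect_light_pulses()]) and averages the dual 222/222.1 nm channels
#' onto a single temperature grid. Channels are paired by
#' nearest-temperature clustering: temperatures closer than `pair_tol`
#' (default half the median grid step) are treated as one acquisition
#' point. Where a pulse removed one channel's sample, the remaining
#' channel's value is used alone.
#'
#' @param curve A `melt_curve` tibble with columns `temp_C`,
#'   `wavelength_nm`, `cd_mdeg`, `ht_v` (plus optional `variant`,
#'   `condition`).
#' @param k_mad Pulse-detection threshold, see [detect_light_pulses()].
#' @param pair_tol Maximum temperature separation (degrees C) for two rows
#'   to be averaged together.
#' @return A single-channel `melt_curve` tibble (`temp_C`, `cd_mdeg`,
#'   `ht_v`, `n_obs`) with attributes `removed_rows` (indices into the
#'   input) and `n_removed`.
#' @export
clean_melt <- function(curve, k_mad = 5, pair_tol = NULL) {
  df <- tibble::as_tibble(curve)
  req <- c("temp_C", "wavelength_nm", "cd_mdeg", "ht_v")
  if (!all(req %in% names(df))) {
    abort(sprintf("`curve` needs columns %s.", paste(req, collapse = ", ")),
          class = "litdark_bad_params")
  }
  wls <- unique(df$wavelength_nm)
  if (length(wls) > 2) {
    abort("At most two wavelength channels are supported.",
          class = "litdark_bad_params")
  }
  df$.row <- seq_len(nrow(df))
  removed <- integer(0)
  for (w in wls) {
    rows <- df$.row[df$wavelength_nm == w]
    if (length(rows) >= 5) {
      hit <- detect_light_pulses(df$ht_v[rows], k_mad = k_mad)
      removed <- c(removed, rows[hit])
    }
  }
  kept <- df[!df$.row %in% removed, ]

  temps <- sort(kept$temp_C)
  gaps <- diff(unique(temps))
  step <- if (length(gaps)) median(gaps[gaps > 0]) else 1
  if (is.null(pair_tol)) pair_tol <- step / 2

  ord <- order(kept$temp_C)
  kept <- kept[ord, ]
  cluster <- cumsum(c(1, as.integer(diff(kept$temp_C) > pair_tol)))
  kept$.cluster <- cluster
  dup <- dplyr::summarise(dplyr::group_by(kept, .data$.cluster),
                          dup = anyDuplicated(.data$wavelength_nm) > 0,
                          .groups = "drop")
  if (any(dup$dup)) {
    abort("Wavelength channels could not be paired within the tolerance.",
          class = "litdark_pairing_failure")
  }
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$.cluster),
    variant = if ("variant" %in% names(kept)) .data$variant[1] else NA_character_,
    condition = if ("condition" %in% names(kept)) .data$condition[1] else NA_character_,
    temp_C = mean(.data$temp_C),
    cd_mdeg = mean(.data$cd_mdeg),
    ht_v = mean(.data$ht_v),
    n_obs = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(dplyr::select(out, -".cluster"), .data$temp_C)
  attr(out, "removed_rows") <- sort(removed)
  attr(out, "n_removed") <- length(removed)
  class(out) <- c("melt_curve", class(out))
  out
}

#' Aggregate replicate melt scans
#'
#' Melts are recorded as repeated scans of the same ramp; the instrument
#' protocol aggregates them before fitting. Raw scans (still carrying a
#' `wavelength_nm` column) are cleaned individually with [clean_melt()]
#' first, then all scans are averaged per temperature (nearest-temperature
#' clustering, weighted by the number of surviving observations).
#'
#' @param curves A list of `melt_curve` tibbles (raw or cleaned).
#' @param k_mad Pulse-detection threshold used when cleaning raw scans.
#' @param pair_tol Temperature clustering tolerance (degrees C); defaults
#'   to half the median grid step.
#' @return A single-channel `melt_curve` tibble.
#' @export
aggregate_melt_scans <- function(curves, k_mad = 5, pair_tol = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1)
  cleaned <- lapply(curves, function(cv) {
    if ("wavelength_nm" %in% names(cv)) clean_melt(cv, k_mad = k_mad) else
      tibble::as_tibble(cv)
  })
  df <- dplyr::bind_rows(cleaned)
  if (!"n_obs" %in% names(df)) df$n_obs <- 1L
  df <- dplyr::arrange(df, .data$temp_C)
  gaps <- diff(unique(df$temp_C))
  step <- if (length(gaps)) median(gaps[gaps > 0]) else 1
  if (is.null(pair_tol)) pair_tol <- step / 2
  df$.cluster <- cumsum(c(1, as.integer(diff(df$temp_C) > pair_tol)))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$.cluster),
    variant = if ("variant" %in% names(df)) .data$variant[1] else NA_character_,
    condition = if ("condition" %in% names(df)) .data$condition[1] else NA_character_,
    temp_C = stats::weighted.mean(.data$temp_C, .data$n_obs),
    cd_mdeg = stats::weighted.mean(.data$cd_mdeg, .data$n_obs),
    ht_v = stats::weighted.mean(.data$ht_v, .data$n_obs),
    n_obs = sum(.data$n_obs),
    .groups = "drop"
  )
  out <- dplyr::arrange(dplyr::select(out, -".cluster"), .data$temp_C)
  class(out) <- c("melt_curve", class(out))
  out
}

#' Convert ellipticity in millidegrees to mean residue ellipticity
#'
#' `MRE = theta_mdeg / (10 * pathlength_cm * molar_conc_M * n_residues)`,
#' in deg cm^2 dmol^-1. This is the single conversion convention used
#' throughout the package (the 0.001 deg/mdeg and the per-decimole factors
#' combine into the 1/10).
#'
#' @param theta_mdeg Ellipticity in millidegrees.
#' @param molar_conc_M Protein concentration (M).
#' @param pathlength_cm Cuvette path length (cm).
#' @param n_residues Number of residues per chain.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
mdeg_to_mre <- function(theta_mdeg, molar_conc_M, pathlength_cm, n_residues) {
  if (!isTRUE(molar_conc_M > 0) || !isTRUE(pathlength_cm > 0) ||
      !isTRUE(n_residues > 0)) {
    abort("Concentration, path length and residue count must be positive.",
          class = "litdark_bad_params")
  }
  theta_mdeg / (10 * pathlength_cm * molar_conc_M * n_residues)
}

#' @rdname mdeg_to_mre
#' @param mre Mean residue ellipticity to convert back to millidegrees.
#' @export
mre_to_mdeg <- function(mre, molar_conc_M, pathlength_cm, n_residues) {
  if (!isTRUE(molar_conc_M > 0) || !isTRUE(pathlength_cm > 0) ||
      !isTRUE(n_residues > 0)) {
    abort("Concentration, path length and residue count must be positive.",
          class = "litdark_bad_params")
  }
  mre * 10 * pathlength_cm * molar_conc_M * n_residues
}

#' Aggregation-aware fit window for a melt curve
#'
#' The fit starts at the lowest measured temperature. When the HT channel
#' shows an aggregation signature (a substantial decline after its
#' maximum), the endpoint is the midpoint between the temperature of the
#' CD maximum and the temperature of the HT maximum, which places the
#' boundary between completed unfolding and the aggregation artifact.
#' Without an aggregation signature, or when the midpoint would leave less
#' than 10 degrees of data, the full temperature range is used and the
#' fallback is recorded in `reason`.
#'
#' @param curve A cleaned single-channel melt curve (see [clean_melt()]).
#' @return A one-row tibble: `t_start`, `t_end`, `t_cd_max`, `t_ht_max`,
#'   `full_window`, `reason`.
#' @export
fit_window <- function(curve) {
  df <- tibble::as_tibble(curve)
  t_start <- min(df$temp_C)
  t_max_grid <- max(df$temp_C)
  t_cd_max <- df$temp_C[which.max(df$cd_mdeg)]
  t_ht_max <- df$temp_C[which.max(df$ht_v)]
  ht_span <- diff(range(df$ht_v))
  ht_drop_after_max <- max(df$ht_v) - df$ht_v[which.max(df$temp_C)]
  has_aggregation <- ht_span > 0 && ht_drop_after_max > 0.25 * ht_span

  if (!has_aggregation) {
    t_end <- t_max_grid
    full <- TRUE
    reason <- "no aggregation signature in the HT channel"
  } else {
    t_end <- (t_cd_max + t_ht_max) / 2
    full <- FALSE
    reason <- "midpoint of CD-max and HT-max temperatures"
    if (t_end <= t_start + 10) {
      t_end <- t_max_grid
      full <- TRUE
      reason <- "midpoint left < 10 C of data; full window fallback"
    }
  }
  tibble::tibble(t_start = t_start, t_end = t_end, t_cd_max = t_cd_max,
                 t_ht_max = t_ht_max, full_window = full, reason = reason)
}

## Equilibrium constant of the two-state transition, overflow-guarded.
two_state_K <- function(temp_C, dH_fold, Tm) {
  T_K <- celsius_to_kelvin(temp_C)
  Tm_K <- celsius_to_kelvin(Tm)
  expo <- (dH_fold / (R_CAL * T_K)) * (T_K / Tm_K - 1)
  exp(pmin(pmax(expo, -700), 700))
}

two_state_fraction_folded <- function(temp_C, dH_fold, Tm) {
  K <- two_state_K(temp_C, dH_fold, Tm)
  K / (1 + K)
}

#' Two-state unfolding model with sloping baselines
#'
#' Predicted ellipticity of a monomer in equilibrium between folded and
#' unfolded forms, each with a temperature-linear baseline:
#' `f = K/(1+K) * ((F + Cf*T) - (U + CU*T)) + (U + CU*T)` with
#' `K = exp[(dH_fold/(R*T_K)) * (T_K/Tm_K - 1)]`, temperatures converted
#' as `T_K = T + 273.15`, and `R = 1.987 cal/(mol K)`. At `T = Tm` the
#' population is half folded and the prediction is the midpoint of the two
#' baselines; for negative `dH_fold` the folded baseline is approached far
#' below `Tm` and the unfolded baseline far above. The exponent is clipped
#' at +/-700 to avoid overflow.
#'
#' @param temp_C Temperature (degrees C); vectorized.
#' @param dH_fold Folding enthalpy (cal/mol), negative.
#' @param Tm Melting temperature (degrees C).
#' @param F,Cf Folded baseline intercept (mdeg) and slope (mdeg/degree C).
#' @param U,CU Unfolded baseline intercept and slope.
#' @return Predicted ellipticity (mdeg).
#' @examples
#' two_state_model(33.9, -60000, 33.9, -11, 0.02, -3, 0.02)
#' @export
two_state_model <- function(temp_C, dH_fold, Tm, F, Cf, U, CU) {
  K <- two_state_K(temp_C, dH_fold, Tm)
  folded <- F + Cf * temp_C
  unfolded <- U + CU * temp_C
  K / (1 + K) * (folded - unfolded) + unfolded
}

#' Fit the two-state unfolding model to a melt curve
#'
#' Nonlinear least squares over `(dH_fold, Tm, F, Cf, U, CU)` inside the
#' fit window. Initialization: `Tm` from the extremum of the derivative of
#' a 5-point moving-average smoothed CD trace, baselines from linear fits
#' to the outer 20% temperature segments, `dH_fold` from `dH_init`. The
#' folding enthalpy is constrained negative. A fit that fails to converge,
#' lands `Tm` on the window boundary, or has a transition amplitude
#' indistinguishable from the residual noise is returned flagged
#' (`accepted = FALSE` with a `flag` message), never as a silent number.
#'
#' @param curve A cleaned single-channel melt curve (see [clean_melt()]).
#' @param window A one-row tibble from [fit_window()], or `NULL` to
#'   compute it from the curve. A numeric length-2 vector `c(t_start,
#'   t_end)` is also accepted.
#' @param dH_init Starting value for the folding enthalpy (cal/mol).
#' @param smooth_n Moving-average width for the Tm initialization.
#' @return An object of class `melt_fit`: the six parameters, `window`,
#'   `rms`, `n_points`, `converged`, `accepted`, `flag` and the windowed
#'   data.
#' @examples
#' curve <- simulate_melt_curve(true_params(Tm_true = 33.9), noise_sd = 0,
#'                              ht_noise_sd = 0, condition = "lit")
#' fit <- fit_two_state(clean_melt(curve))
#' fit$Tm
#' @export
fit_two_state <- function(curve, window = NULL, dH_init = -50000,
                          smooth_n = 5) {
  df <- tibble::as_tibble(curve)
  if (is.null(window)) window <- fit_window(df)
  if (is.numeric(window) && length(window) == 2) {
    window <- tibble::tibble(t_start = window[1], t_end = window[2],
                             t_cd_max = NA_real_, t_ht_max = NA_real_,
                             full_window = NA, reason = "user-specified")
  }
  sub <- dplyr::filter(df, .data$temp_C >= window$t_start,
                       .data$temp_C <= window$t_end)
  if (nrow(sub) < 10) {
    abort("Need >= 10 points inside the fit window.",
          class = "litdark_too_few_points")
  }
  sub <- dplyr::arrange(sub, .data$temp_C)

  ## Tm init: extremum of the smoothed derivative
  sm <- stats::filter(sub$cd_mdeg, rep(1 / smooth_n, smooth_n), sides = 2)
  sm <- as.numeric(sm)
  ok <- which(!is.na(sm))
  dcd <- diff(sm[ok]) / diff(sub$temp_C[ok])
  Tm0 <- sub$temp_C[ok][which.max(abs(dcd))]

  ## baselines from the outer 20% temperature segments
  t_lo <- stats::quantile(sub$temp_C, 0.2)
  t_hi <- stats::quantile(sub$temp_C, 0.8)
  lo <- sub[sub$temp_C <= t_lo, ]
  hi <- sub[sub$temp_C >= t_hi, ]
  cf_lo <- coef(lm(cd_mdeg ~ temp_C, data = lo))
  cf_hi <- coef(lm(cd_mdeg ~ temp_C, data = hi))

  start <- list(dH = dH_init, Tm = Tm0,
                F = unname(cf_lo[1]), Cf = unname(cf_lo[2]),
                U = unname(cf_hi[1]), CU = unname(cf_hi[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cd_mdeg ~ two_state_model(temp_C, dH, Tm, F, Cf, U, CU),
      data = sub, start = start,
      lower = c(dH = -1e7, Tm = window$t_start, F = -1e5, Cf = -1e3,
                U = -1e5, CU = -1e3),
      upper = c(dH = -1, Tm = window$t_end, F = 1e5, Cf = 1e3,
                U = 1e5, CU = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )

  failed <- inherits(fit, "error")
  if (failed) {
    pars <- setNames(rep(NA_real_, 6), c("dH", "Tm", "F", "Cf", "U", "CU"))
    rms <- NA_real_
    converged <- FALSE
    se <- setNames(rep(NA_real_, 6), names(pars))
  } else {
    pars <- coef(fit)
    rms <- sqrt(mean(stats::residuals(fit)^2))
    converged <- isTRUE(fit$convInfo$isConv)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) setNames(rep(NA_real_, 6), names(pars)))
  }

  flag <- NULL
  if (failed) {
    flag <- paste("optimizer error:", conditionMessage(fit))
  } else if (!converged) {
    flag <- "optimizer did not converge"
  } else {
    amp <- abs((pars[["F"]] + pars[["Cf"]] * pars[["Tm"]]) -
                 (pars[["U"]] + pars[["CU"]] * pars[["Tm"]]))
    margin <- 1e-6 * max(1, abs(window$t_end - window$t_start))
    if (pars[["Tm"]] <= window$t_start + margin ||
        pars[["Tm"]] >= window$t_end - margin) {
      flag <- "Tm on the window boundary"
    } else if (amp < 2 * rms) {
      flag <- "transition amplitude indistinguishable from noise"
    }
  }

  structure(
    list(Tm = unname(pars[["Tm"]]), dH_fold = unname(pars[["dH"]]),
         F = unname(pars[["F"]]), Cf = unname(pars[["Cf"]]),
         U = unname(pars[["U"]]), CU = unname(pars[["CU"]]),
         se = se, window = window, rms = rms, n_points = nrow(sub),
         converged = converged, accepted = is.null(flag),
         flag = flag %||% NA_character_,
         variant = if ("variant" %in% names(sub)) sub$variant[1] else NA_character_,
         condition = if ("condition" %in% names(sub)) sub$condition[1] else NA_character_,
         data = sub),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit (%s/%s), window [%.1f, %.1f] C, %d points\n",
              x$variant %||% "?", x$condition %||% "?",
              x$window$t_start, x$window$t_end, x$n_points))
  if (!x$accepted) {
    cat("  FLAGGED:", x$flag, "\n")
  }
  cat(sprintf("  Tm      = %.2f C\n  dH_fold = %.0f cal/mol\n  rms = %.3g mdeg\n",
              x$Tm, x$dH_fold, x$rms))
  invisible(x)
}

#' Clean, window and fit a raw melt curve in one call
#'
#' Convenience pipeline: [clean_melt()] then [fit_window()] then
#' [fit_two_state()].
#'
#' @inheritParams clean_melt
#' @inheritParams fit_two_state
#' @return A `melt_fit` object; the cleaning summary is attached as
#'   attributes `n_removed` / `removed_rows` of its `data` element's
#'   source curve are reflected in `n_cleaned`.
#' @export
fit_melt <- function(curve, k_mad = 5, window = NULL, dH_init = -50000) {
  cleaned <- clean_melt(curve, k_mad = k_mad)
  fit <- fit_two_state(cleaned, window = window, dH_init = dH_init)
  fit$n_cleaned <- attr(cleaned, "n_removed")
  fit
}

#' Fraction of protein folded at a temperature
#'
#' `K/(1+K)` from an accepted two-state fit; equals 0.5 at `Tm` and is
#' monotone decreasing in temperature for a negative folding enthalpy.
#'
#' @param fit An accepted `melt_fit`.
#' @param temp_C Temperature(s) in degrees C.
#' @return Fraction folded in `[0, 1]`.
#' @export
fraction_folded <- function(fit, temp_C) {
  stopifnot(inherits(fit, "melt_fit"))
  if (!isTRUE(fit$accepted)) {
    abort(paste("Refusing to evaluate a flagged fit:", fit$flag),
          class = "litdark_flagged_fit")
  }
  two_state_fraction_folded(temp_C, fit$dH_fold, fit$Tm)
}
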