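#' Generating parameters for a synthetic lit/dark experiment
#'
#' Bundles the "true" thermodynamic parameters from which synthetic rate
#' panels and melt curves are drawn, so that downstream fitters can be tested
#' against a known ground truth. One `true_params` object describes one
#' illumination condition of one variant.
#'
#' @param dH_act Activation enthalpy (cal/mol) of the catalytic transition
#'   state used by [simulate_kcat_dataset()].
#' @param dS_act Activation entropy (cal/(mol K)).
#' @param Tm_true Melting temperature (degrees C) of the two-state unfolding
#'   transition used by [simulate_melt_curve()].
#' @param dH_fold Folding enthalpy (cal/mol). Must be negative: folding is
#'   exothermic in this parameterization, which makes the folded state
#'   populated below `Tm_true`.
#' @param F,Cf Intercept (mdeg) and slope (mdeg/degree C) of the folded-state
#'   ellipticity baseline.
#' @param U,CU Intercept and slope of the unfolded-state baseline.
#' @param kcat_cv Coefficient of variation of replicate turnover
#'   measurements. Rate noise is multiplicative lognormal with
#'   `sigma = log(1 + kcat_cv)`: rates are strictly positive and replicate
#'   scatter in kinetic assays scales with the rate itself.
#' @param seed Integer seed; generators that take a `true_params` object use
#'   it by default so identical parameters reproduce identical data.
#'
#' @return A list of class `true_params`.
#' @examples
#' p <- true_params(dH_act = 14000, dS_act = -12.5, Tm_true = 33.9)
#' @export
true_params <- function(dH_act = 14000, dS_act = -12.5, Tm_true = 33.9,
                        dH_fold = -60000, F = -11, Cf = 0.02,
                        U = -3, CU = 0.02, kcat_cv = 0.05, seed = 1L) {
  if (dH_fold >= 0) {
    abort("`dH_fold` must be negative (folding is exothermic).",
          class = "litdark_bad_params")
  }
  if (kcat_cv < 0) {
    abort("`kcat_cv` must be >= 0.", class = "litdark_bad_params")
  }
  structure(
    list(dH_act = dH_act, dS_act = dS_act, Tm_true = Tm_true,
         dH_fold = dH_fold, F = F, Cf = Cf, U = U, CU = CU,
         kcat_cv = kcat_cv, seed = as.integer(seed)),
    class = "true_params"
  )
}

#' Light-pulse schedule of the CD instrument
#'
#' Describes the periodic blue-LED excitation pulses delivered while a melt
#' is recorded. Measurements acquired while a pulse fires show a sharp
#' transient drop in the photomultiplier (HT) voltage; [simulate_melt_curve()]
#' injects these artifacts and [detect_light_pulses()] removes them.
#'
#' @param period_s Seconds from the start of one pulse to the start of the
#'   next. The default corresponds to a 250 ms pulse followed by a 10 s gap.
#' @param pulse_duration_s Pulse length in seconds.
#' @param ht_drop Magnitude (volts) of the HT dip on an affected sample.
#' @param cd_artifact Stray-light offset (mdeg) corrupting the CD reading
#'   of an affected sample; this is why pulse-coincident measurements must
#'   be removed before fitting.
#' @param phase_s Offset (seconds) of the first pulse relative to the first
#'   measurement.
#'
#' @return A list of class `pulse_schedule`.
#' @export
pulse_schedule <- function(period_s = 10.25, pulse_duration_s = 0.25,
                           ht_drop = 30, cd_artifact = 5, phase_s = 5) {
  if (!(period_s > pulse_duration_s && pulse_duration_s > 0)) {
    abort("Need `period_s` > `pulse_duration_s` > 0.",
          class = "litdark_bad_params")
  }
  structure(list(period_s = period_s, pulse_duration_s = pulse_duration_s,
                 ht_drop = ht_drop, cd_artifact = cd_artifact,
                 phase_s = phase_s),
            class = "pulse_schedule")
}

#' Aggregation signature for dark-state melts
#'
#' Above an onset temperature the dark-state protein aggregates: the CD
#' signal rises rapidly while the HT voltage decays. The artifact is
#' modeled piecewise: two-state behavior below `t_onset`; above it, an
#' exponential HT decay toward `ht_floor` and a transient CD surge - a
#' second, sharp transition peaking at `cd_surge_max` mdeg a few degrees
#' above the onset (at `t_onset + cd_surge_max / cd_surge_rate`) and then
#' settling as the precipitate falls out of the beam. The bounded, peaked
#' shape is what makes the temperature of the CD maximum a usable landmark
#' for the aggregation-aware fit window.
#'
#' @param t_onset Onset temperature (degrees C).
#' @param cd_surge_rate Surge steepness scale (mdeg/degree C); together
#'   with `cd_surge_max` it sets the peak position.
#' @param ht_decay_rate Exponential decay rate of the HT voltage (1/degree C).
#' @param cd_surge_max Peak surge amplitude (mdeg) above the two-state curve.
#' @param ht_floor Asymptotic HT voltage (volts) once aggregation completes.
#'
#' @return A list of class `aggregation_signature`.
#' @export
aggregation_signature <- function(t_onset = 50, cd_surge_rate = 3,
                                  ht_decay_rate = 0.05, cd_surge_max = 9,
                                  ht_floor = 250) {
  if (cd_surge_rate <= 0 || ht_decay_rate <= 0 || cd_surge_max <= 0) {
    abort("Aggregation rates and amplitude must be positive.",
          class = "litdark_bad_params")
  }
  structure(list(t_onset = t_onset, cd_surge_rate = cd_surge_rate,
                 ht_decay_rate = ht_decay_rate, cd_surge_max = cd_surge_max,
                 ht_floor = ht_floor),
            class = "aggregation_signature")
}

new_kinetic_trace <- function(df, temp_C, condition, enzyme_conc_M,
                              epsilon_mM_cm, pathlength_cm, wavelength_nm) {
  out <- tibble::as_tibble(df)
  attr(out, "temp_C") <- temp_C
  attr(out, "condition") <- condition
  attr(out, "enzyme_conc_M") <- enzyme_conc_M
  attr(out, "epsilon_mM_cm") <- epsilon_mM_cm
  attr(out, "pathlength_cm") <- pathlength_cm
  attr(out, "wavelength_nm") <- wavelength_nm
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Metadata of a kinetic trace
#'
#' @param trace A `kinetic_trace` tibble.
#' @return A named list of the trace's instrument metadata.
#' @export
trace_meta <- function(trace) {
  nm <- c("temp_C", "condition", "enzyme_conc_M", "epsilon_mM_cm",
          "pathlength_cm", "wavelength_nm")
  setNames(lapply(nm, function(x) attr(trace, x)), nm)
}

#' Simulate a zero-order NADPH-depletion absorbance trace
#'
#' Under saturating substrate and cofactor the reaction is zero order, so the
#' 340 nm absorbance falls linearly at `epsilon * pathlength * [E] * kcat`
#' until the limiting reactant is exhausted, after which the trace floors.
#' Gaussian instrument noise is added on top.
#'
#' @param kcat_true Turnover number (1/s) used to generate the trace.
#' @param enzyme_conc_M Enzyme concentration (M).
#' @param epsilon_mM_cm Extinction coefficient of the chromophore
#'   (mM^-1 cm^-1); 13.2 for NADPH at 340 nm.
#' @param pathlength_cm Cuvette path length (cm).
#' @param duration_s,dt_s Trace length and sampling interval (s).
#' @param noise_sd Gaussian noise standard deviation (AU).
#' @param substrate_conc_M,cofactor_conc_M Initial substrate (DHF) and
#'   cofactor (NADPH) concentrations (M); depletion floors at their minimum.
#' @param temp_C,condition Metadata recorded on the trace.
#' @param A0 Starting absorbance (AU); defaults to the absorbance of the
#'   full cofactor pool.
#' @param seed Integer seed for the noise stream.
#'
#' @return A `kinetic_trace` tibble with columns `time_s`, `absorbance`.
#' @examples
#' tr <- simulate_absorbance_trace(kcat_true = 0.58, enzyme_conc_M = 1e-7,
#'                                 noise_sd = 0)
#' head(tr)
#' @export
simulate_absorbance_trace <- function(kcat_true, enzyme_conc_M,
                                      epsilon_mM_cm = 13.2,
                                      pathlength_cm = 1,
                                      duration_s = 60, dt_s = 0.1,
                                      noise_sd = 0,
                                      substrate_conc_M = 25e-6,
                                      cofactor_conc_M = 90e-6,
                                      temp_C = 25, condition = "dark",
                                      A0 = NULL, seed = 1L) {
  if (dt_s <= 0 || duration_s <= 0) {
    abort("`dt_s` and `duration_s` must be positive.",
          class = "litdark_bad_params")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "litdark_bad_params")
  }
  if (enzyme_conc_M <= 0 || substrate_conc_M <= 0 || cofactor_conc_M <= 0 ||
      epsilon_mM_cm <= 0 || pathlength_cm <= 0) {
    abort("Concentrations, epsilon and path length must be positive.",
          class = "litdark_bad_params")
  }
  time_s <- seq(0, duration_s, by = dt_s)
  if (is.null(A0)) {
    A0 <- epsilon_mM_cm * pathlength_cm * cofactor_conc_M * 1000
  }
  consumed_M <- pmin(kcat_true * enzyme_conc_M * time_s,
                     min(substrate_conc_M, cofactor_conc_M))
  absorbance <- A0 - epsilon_mM_cm * pathlength_cm * 1000 * consumed_M
  if (noise_sd > 0) {
    absorbance <- absorbance +
      withr::with_seed(seed, rnorm(length(time_s), 0, noise_sd))
  }
  new_kinetic_trace(tibble::tibble(time_s = time_s, absorbance = absorbance),
                    temp_C = temp_C, condition = condition,
                    enzyme_conc_M = enzyme_conc_M,
                    epsilon_mM_cm = epsilon_mM_cm,
                    pathlength_cm = pathlength_cm, wavelength_nm = 340)
}

#' Simulate a panel of turnover measurements across temperatures
#'
#' Draws replicate kcat values at each temperature from the Eyring model
#' defined by `params`, with multiplicative lognormal replicate noise
#' (`sigma = log(1 + kcat_cv)`). The default design matches the study
#' layout: seven temperatures from 5 to 35 degrees C in triplicate,
#' 21 measurements per condition.
#'
#' @param params A [true_params()] object.
#' @param temps_C Temperatures (degrees C) at which kcat is measured.
#' @param reps Replicates per temperature.
#' @param condition Illumination condition label (`"lit"` or `"dark"`).
#' @param variant Construct label.
#' @param seed Integer seed; defaults to `params$seed`.
#'
#' @return A tibble with columns `variant`, `condition`, `temp_C`,
#'   `replicate`, `kcat_per_s`.
#' @examples
#' rates <- simulate_kcat_dataset(true_params(kcat_cv = 0.05), seed = 7)
#' nrow(rates) # 7 temperatures x 3 replicates
#' @export
simulate_kcat_dataset <- function(params, temps_C = seq(5, 35, by = 5),
                                  reps = 3, condition = "dark",
                                  variant = "DL121", seed = params$seed) {
  stopifnot(inherits(params, "true_params"))
  if (reps < 1) abort("`reps` must be >= 1.", class = "litdark_bad_params")
  if (length(temps_C) == 0) {
    abort("`temps_C` must be non-empty.", class = "litdark_bad_params")
  }
  grid <- tidyr::expand_grid(temp_C = temps_C, replicate = seq_len(reps))
  mu <- eyring_kcat(params$dH_act, params$dS_act,
                    celsius_to_kelvin(grid$temp_C))
  sigma <- log1p(params$kcat_cv)
  noise <- if (sigma > 0) {
    withr::with_seed(seed, rnorm(nrow(grid), 0, sigma))
  } else {
    rep(0, nrow(grid))
  }
  tibble::tibble(variant = variant, condition = condition,
                 temp_C = grid$temp_C, replicate = grid$replicate,
                 kcat_per_s = mu * exp(noise))
}

#' Simulate a dual-wavelength CD thermal melt
#'
#' Generates the raw melt table the CD instrument would produce during a
#' temperature ramp: ellipticity following the two-state unfolding model of
#' [two_state_model()] plus Gaussian noise, recorded at both 222 and
#' 222.1 nm at every grid temperature (the instrument's dual-wavelength
#' protocol), together with a photomultiplier (HT) channel that rises
#' smoothly as the protein unfolds. Optionally injects the two artifacts the
#' cleaning pipeline must handle: transient HT dips on samples that coincide
#' with LED light pulses (mapped onto the ramp via the measurement times),
#' and an aggregation signature (bounded CD surge plus exponential HT decay)
#' above an onset temperature.
#'
#' @param params A [true_params()] object supplying `Tm_true`, `dH_fold` and
#'   the four baseline coefficients.
#' @param temps_C Strictly increasing temperature grid (degrees C).
#' @param noise_sd Gaussian noise on the CD channel (mdeg).
#' @param pulses A [pulse_schedule()] or `NULL` for no pulse artifacts.
#' @param aggregation An [aggregation_signature()] or `NULL`.
#' @param condition,variant Labels carried through to the output.
#' @param ht_base,ht_slope HT baseline intercept (V) and slope (V/degree C).
#' @param ht_unfold_amp HT rise (V) accompanying complete unfolding.
#' @param ht_noise_sd Gaussian noise on the HT channel (V).
#' @param ramp_rate_C_min Temperature ramp rate used to map grid
#'   temperatures to measurement times (degrees C per minute).
#' @param dit_s Detector integration time per sample (s); the second
#'   wavelength is acquired `dit_s` after the first.
#' @param wavelengths The two recorded wavelengths (nm).
#' @param seed Integer seed; defaults to `params$seed`.
#'
#' @return A `melt_curve` tibble with columns `variant`, `condition`,
#'   `temp_C`, `wavelength_nm`, `cd_mdeg`, `ht_v`, ordered by acquisition
#'   time. The indices of pulse-affected rows are stored in
#'   `attr(, "pulse_rows")` and the generating parameters in
#'   `attr(, "true_params")`.
#' @examples
#' curve <- simulate_melt_curve(true_params(Tm_true = 33.9), noise_sd = 0)
#' @export
simulate_melt_curve <- function(params, temps_C = seq(5, 90, by = 0.5),
                                noise_sd = 0.2, pulses = NULL,
                                aggregation = NULL, condition = "dark",
                                variant = "DL121",
                                ht_base = 300, ht_slope = 0.2,
                                ht_unfold_amp = 40, ht_noise_sd = 0.3,
                                ramp_rate_C_min = 0.5, dit_s = 1,
                                wavelengths = c(222, 222.1),
                                seed = params$seed) {
  stopifnot(inherits(params, "true_params"))
  if (any(diff(temps_C) <= 0)) {
    abort("`temps_C` must be strictly increasing.",
          class = "litdark_bad_params")
  }
  if (!is.null(pulses)) stopifnot(inherits(pulses, "pulse_schedule"))
  if (!is.null(aggregation)) {
    stopifnot(inherits(aggregation, "aggregation_signature"))
  }

  n_t <- length(temps_C)
  n_w <- length(wavelengths)
  temp <- rep(temps_C, each = n_w)
  wl <- rep(wavelengths, times = n_t)
  chan <- rep(seq_len(n_w), times = n_t)
  time_s <- (temp - temps_C[1]) / ramp_rate_C_min * 60 + (chan - 1) * dit_s

  cd <- two_state_model(temp, params$dH_fold, params$Tm_true,
                        params$F, params$Cf, params$U, params$CU)
  frac_unfolded <- 1 - two_state_fraction_folded(temp, params$dH_fold,
                                                 params$Tm_true)
  ht <- ht_base + ht_slope * temp + ht_unfold_amp * frac_unfolded

  if (!is.null(aggregation)) {
    dT <- pmax(temp - aggregation$t_onset, 0)
    above <- dT > 0
    t_peak <- aggregation$t_onset +
      aggregation$cd_surge_max / aggregation$cd_surge_rate
    w <- (t_peak - aggregation$t_onset) / 6
    cd[above] <- cd[above] + aggregation$cd_surge_max *
      exp(-(temp[above] - t_peak)^2 / (2 * w^2))
    ht[above] <- aggregation$ht_floor +
      (ht[above] - aggregation$ht_floor) *
      exp(-aggregation$ht_decay_rate * dT[above])
  }

  pulse_rows <- integer(0)
  if (!is.null(pulses)) {
    phase <- (time_s + pulses$phase_s) %% pulses$period_s
    hit <- phase < pulses$pulse_duration_s |
      phase + dit_s > pulses$period_s
    ht[hit] <- ht[hit] - pulses$ht_drop
    cd[hit] <- cd[hit] + pulses$cd_artifact
    pulse_rows <- which(hit)
  }

  n <- n_t * n_w
  noise <- withr::with_seed(seed, list(
    cd = if (noise_sd > 0) rnorm(n, 0, noise_sd) else rep(0, n),
    ht = if (ht_noise_sd > 0) rnorm(n, 0, ht_noise_sd) else rep(0, n)
  ))

  out <- tibble::tibble(variant = variant, condition = condition,
                        temp_C = temp, wavelength_nm = wl,
                        cd_mdeg = cd + noise$cd, ht_v = ht + noise$ht)
  attr(out, "pulse_rows") <- pulse_rows
  attr(out, "true_params") <- params
  class(out) <- c("melt_curve", class(out))
  out
}

#' Simulate a chromophore relaxation trace
#'
#' One-phase association toward a plateau: after the excitation light is
#' switched off, the lit-state chromophore absorbance at 447 nm recovers as
#' `A(t) = plateau + (A0 - plateau) * exp(-k_rel * t)`.
#'
#' @param k_rel Relaxation rate constant (1/s); must be positive.
#' @param A0 Absorbance at time zero.
#' @param plateau Asymptotic absorbance.
#' @param duration_s,dt_s Trace length and sampling interval (s).
#' @param noise_sd Gaussian noise standard deviation (AU).
#' @param seed Integer seed.
#'
#' @return A `kinetic_trace` tibble with columns `time_s`, `absorbance`.
#' @export
simulate_relaxation_trace <- function(k_rel, A0 = 0.2, plateau = 0.6,
                                      duration_s = 300, dt_s = 1,
                                      noise_sd = 0, seed = 1L) {
  if (k_rel <= 0) abort("`k_rel` must be positive.",
                        class = "litdark_bad_params")
  if (dt_s <= 0 || duration_s <= 0) {
    abort("`dt_s` and `duration_s` must be positive.",
          class = "litdark_bad_params")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.",
                          class = "litdark_bad_params")
  time_s <- seq(0, duration_s, by = dt_s)
  absorbance <- plateau + (A0 - plateau) * exp(-k_rel * time_s)
  if (noise_sd > 0) {
    absorbance <- absorbance +
      withr::with_seed(seed, rnorm(length(time_s), 0, noise_sd))
  }
  new_kinetic_trace(tibble::tibble(time_s = time_s, absorbance = absorbance),
                    temp_C = 25, condition = "dark", enzyme_conc_M = NA_real_,
                    epsilon_mM_cm = NA_real_, pathlength_cm = 1,
                    wavelength_nm = 447)
}
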