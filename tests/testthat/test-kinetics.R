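test_that("initial velocity converts the 15 s slope to molar units", {
  # exact line A(t) = 0.5 - 0.001 t: slope -0.001 AU/s, v0 = 0.001/13.2 mM/s
  t <- seq(0, 30, by = 1)
  tr <- manual_trace(t, 0.5 - 0.001 * t)
  v <- initial_velocity(tr)
  expect_equal(v$slope_AU_s, -0.001, tolerance = 1e-12)
  expect_equal(v$velocity_M_s, 0.001 / 13.2 / 1000, tolerance = 1e-12)
  expect_equal(v$n_points, 16L)
  expect_false(v$flagged)

  # flat trace: zero velocity
  flat <- initial_velocity(manual_trace(t, rep(0.5, length(t))))
  expect_equal(flat$velocity_M_s, 0)

  # rising absorbance is flagged, not clamped
  up <- initial_velocity(manual_trace(t, 0.5 + 0.001 * t))
  expect_true(up$flagged)
  expect_lt(up$velocity_M_s, 0)
})

test_that("velocity and kcat plumbing validate their inputs", {
  t <- seq(0, 30, by = 5)
  expect_error(initial_velocity(manual_trace(t, 0.5 - 0.001 * t),
                                window_s = 12),
               class = "litdark_too_few_points")
  tr <- manual_trace(seq(0, 30), 0.5 - 0.001 * seq(0, 30))
  expect_error(initial_velocity(tr, epsilon_mM_cm = 0),
               class = "litdark_bad_params")
  expect_error(kcat_from_velocity(1e-8, 0), class = "litdark_bad_params")
  expect_equal(kcat_from_velocity(7.576e-8, 1e-7), 0.7576)
  expect_equal(kcat_from_velocity(0, 1e-7), 0)
})

test_that("trace -> velocity -> kcat round-trips the generating rate", {
  for (kcat_true in c(0.1, 0.58, 2)) {
    tr <- simulate_absorbance_trace(kcat_true, enzyme_conc_M = 1e-7,
                                    noise_sd = 0)
    out <- trace_to_kcat(tr)
    expect_equal(out$kcat_per_s, kcat_true, tolerance = 1e-10)
    expect_equal(out$velocity_M_s, 1e-7 * kcat_true, tolerance = 1e-10)
  }
})

test_that("the Eyring rate law matches its closed form and limits", {
  # zero barriers: kcat = kB*T/h, evaluated independently from CODATA values
  kbt_h <- 1.380649e-23 * 298.15 / 6.62607015e-34
  expect_equal(eyring_kcat(0, 0, 298.15), kbt_h, tolerance = 1e-12)
  # infinite enthalpy barrier kills the rate
  expect_equal(eyring_kcat(1e9, 0, 298.15), 0)
  # monotone increasing in T for a positive enthalpy barrier
  grid <- seq(274, 320, by = 0.5)
  expect_true(all(diff(eyring_kcat(14000, -12, grid)) > 0))
  expect_error(eyring_kcat(14000, -12, -5), class = "litdark_bad_params")
})

test_that("the linearized Eyring fit is exact on noiseless data", {
  p <- true_params(dH_act = 12000, dS_act = -20, kcat_cv = 0)
  rates <- simulate_kcat_dataset(p, seed = 1L)
  fit <- fit_eyring(rates)
  expect_equal(fit$dH_act, 12000, tolerance = 1e-8)
  expect_equal(fit$dS_act, -20, tolerance = 1e-8)
  expect_equal(fit$n_points, 21L)

  # agrees with a direct nonlinear least-squares fit of ln(kcat)
  df <- dplyr::mutate(rates, T_K = temp_C + 273.15, y = log(kcat_per_s))
  nl <- minpack.lm::nlsLM(
    y ~ log(1.380649e-23 / 6.62607015e-34 * T_K) - dH / (1.987 * T_K) +
      dS / 1.987,
    data = df, start = list(dH = 10000, dS = -10)
  )
  expect_equal(fit$dH_act, unname(coef(nl)[["dH"]]), tolerance = 1e-6)
  expect_equal(fit$dS_act, unname(coef(nl)[["dS"]]), tolerance = 1e-6)
})

test_that("the Eyring fit matches an independent grid-search oracle on noisy data", {
  p <- true_params(dH_act = 14000, dS_act = -12, kcat_cv = 0.15)
  rates <- simulate_kcat_dataset(p, temps_C = c(10, 20, 30), reps = 3,
                                 seed = 7L)
  fit <- fit_eyring(rates)
  oracle <- eyring_grid_oracle(rates$temp_C, rates$kcat_per_s)
  expect_lt(abs(fit$dH_act - oracle$dH_act), 1)     # grid refined to 1 cal/mol
  expect_lt(abs(fit$dS_act - oracle$dS_act), 0.01)
})

test_that("measurements above the temperature cutoff are excluded before fitting", {
  p <- dark_truth(cv = 0)
  rates <- simulate_kcat_dataset(p, temps_C = seq(5, 40, by = 5), seed = 1L)
  expect_equal(nrow(rates), 24L)
  fit <- fit_eyring(rates, t_max = 35)
  expect_equal(fit$n_points, 21L)
  expect_equal(fit$n_excluded, 3L)
  expect_true(all(fit$data$temp_C <= 35))
  # the bootstrap resamples only the filtered pool
  bf <- bootstrap_eyring(rates, n_boot = 50, seed = 1L, t_max = 35)
  expect_equal(bf$n_points, 21L)
  expect_equal(bf$n_excluded, 3L)

  # degenerate designs are refused
  one_T <- simulate_kcat_dataset(p, temps_C = 25, seed = 1L)
  expect_error(fit_eyring(one_T), class = "litdark_degenerate_design")
  bad <- rates
  bad$kcat_per_s[1] <- -1
  expect_error(fit_eyring(bad), class = "litdark_bad_params")
})

test_that("the bootstrap collapses at zero noise and is seed-reproducible", {
  p <- dark_truth(cv = 0)
  rates <- simulate_kcat_dataset(p, seed = 1L)
  bf <- bootstrap_eyring(rates, n_boot = 100, seed = 9L)
  # every resample refits the same exact line (up to float roundoff)
  expect_lt(bf$se_dH, 1e-6)
  expect_lt(bf$se_dS, 1e-9)
  expect_equal(unique(round(bf$boot$dH_act, 6)), round(bf$dH_act, 6))

  pn <- dark_truth(cv = 0.05)
  rn <- simulate_kcat_dataset(pn, seed = 2L)
  b1 <- bootstrap_eyring(rn, n_boot = 500, seed = 31L)
  b2 <- bootstrap_eyring(rn, n_boot = 500, seed = 31L)
  expect_identical(b1$boot, b2$boot)

  # bootstrap mean is consistent with the point estimate (Monte-Carlo
  # error of the bootstrap mean is se/sqrt(n_boot))
  expect_lt(abs(mean(b1$boot$dH_act) - b1$dH_act), 3 * b1$se_dH / sqrt(500))

  # stratified resampling keeps the per-temperature design
  bs <- bootstrap_eyring(rn, n_boot = 50, seed = 4L, stratified = TRUE)
  expect_equal(bs$n_points, 21L)
  expect_true(bs$se_dH > 0)
})

test_that("allosteric energetics obey their defining identities", {
  dark <- bootstrap_eyring(simulate_kcat_dataset(dark_truth(), seed = 3L),
                           n_boot = 400, seed = 5L)
  lit <- bootstrap_eyring(
    simulate_kcat_dataset(lit_truth(), condition = "lit", seed = 4L),
    n_boot = 400, seed = 6L
  )
  ae <- allostery_energetics(lit, dark)
  # exact identities, machine precision
  expect_identical(ae$ddG_at_ref, ae$ddH - ae$T_ref * ae$ddS)
  expect_identical(ae$fold_change_at_ref,
                   exp(-ae$ddG_at_ref / (1.987 * ae$T_ref)))
  expect_equal(ae$boot$ddG, ae$boot$ddH - ae$T_ref * ae$boot$ddS)
  expect_equal(ae$boot$fold, exp(-ae$boot$ddG / (1.987 * ae$T_ref)))

  # identical lit and dark fits: every difference is exactly zero
  same <- allostery_energetics(dark, dark)
  expect_identical(same$ddH, 0)
  expect_identical(same$ddS, 0)
  expect_identical(same$fold_change_at_ref, 1)

  # mismatched bootstrap sizes are refused
  short <- bootstrap_eyring(simulate_kcat_dataset(dark_truth(), seed = 3L),
                            n_boot = 100, seed = 5L)
  expect_error(allostery_energetics(lit, short),
               class = "litdark_bad_params")
  plain <- fit_eyring(simulate_kcat_dataset(dark_truth(), seed = 3L))
  expect_error(allostery_energetics(plain, dark),
               class = "litdark_bad_params")
})

test_that("the printed enthalpy/entropy pair implies ddG = -129 cal/mol and a 1.24-fold change", {
  # noiseless panels generated at ddH = -1665, T*ddS = -1536 at 303.15 K
  dark <- bootstrap_eyring(
    simulate_kcat_dataset(dark_truth(cv = 0), seed = 1L),
    n_boot = 50, seed = 1L
  )
  lit <- bootstrap_eyring(
    simulate_kcat_dataset(lit_truth(cv = 0), condition = "lit", seed = 1L),
    n_boot = 50, seed = 2L
  )
  ae <- allostery_energetics(lit, dark, T_ref = 303.15)
  expect_equal(ae$ddH, -1665, tolerance = 1e-6)
  expect_equal(ae$TddS_at_ref, -1536, tolerance = 1e-6)
  expect_equal(ae$ddG_at_ref, -129, tolerance = 1e-4)
  expect_equal(ae$fold_change_at_ref,
               exp(129 / (1.987 * 303.15)), tolerance = 1e-6)
  expect_equal(ae$fold_change_at_ref, 1.24, tolerance = 0.002)
})

test_that("the predicted fold change is monotone decreasing for enthalpy-driven allostery", {
  dark <- bootstrap_eyring(
    simulate_kcat_dataset(dark_truth(cv = 0), seed = 1L),
    n_boot = 20, seed = 1L
  )
  lit <- bootstrap_eyring(
    simulate_kcat_dataset(lit_truth(cv = 0), condition = "lit", seed = 1L),
    n_boot = 20, seed = 2L
  )
  ae <- allostery_energetics(lit, dark)
  temps <- seq(275, 315, by = 1)
  prof <- predicted_fold_change(ae, temps)
  expect_true(all(diff(prof) < 0)) # ddH < 0: stronger activation when cold
  expect_gt(predicted_fold_change(ae, 278), predicted_fold_change(ae, 308))

  # zero energetics: flat profile at 1
  same <- allostery_energetics(dark, dark)
  expect_equal(predicted_fold_change(same, temps), rep(1, length(temps)))

  # exact compensation temperature: ratio is 1 where ddH = T * ddS
  t_comp <- ae$ddH / ae$ddS
  expect_equal(predicted_fold_change(ae, t_comp), 1, tolerance = 1e-12)

  # CI version brackets the point estimate
  ci <- predicted_fold_change(ae, c(280, 300), with_ci = TRUE)
  expect_true(all(ci$lower <= ci$fold & ci$fold <= ci$upper))
})

test_that("one-phase association fitting recovers rates and rejects degenerate traces", {
  tr <- simulate_relaxation_trace(k_rel = 0.02, A0 = 0.2, plateau = 0.6,
                                  duration_s = 400, dt_s = 1, noise_sd = 0)
  fit <- fit_one_phase_association(tr)
  expect_equal(fit$k_rel, 0.02, tolerance = 1e-6)
  expect_equal(fit$A0, 0.2, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.6, tolerance = 1e-6)

  # constant trace: unidentifiable
  const <- manual_trace(0:20, rep(0.5, 21))
  expect_error(fit_one_phase_association(const),
               class = "litdark_degenerate_fit")
  expect_error(fit_one_phase_association(manual_trace(0:2, c(1, 2, 3))),
               class = "litdark_too_few_points")
})

test_that("one-phase fit matches a profile-likelihood oracle on noisy data", {
  tr <- simulate_relaxation_trace(k_rel = 0.015, A0 = 0.25, plateau = 0.55,
                                  duration_s = 400, dt_s = 1,
                                  noise_sd = 0.005, seed = 21L)
  fit <- fit_one_phase_association(tr)
  # oracle: 1-D scan over k with the analytic linear sub-fit of (A0, plateau)
  ks <- seq(0.005, 0.05, by = 1e-5)
  rss <- vapply(ks, function(k) {
    basis <- exp(-k * tr$time_s)
    sum(lm(tr$absorbance ~ basis)$residuals^2)
  }, numeric(1))
  k_oracle <- ks[which.min(rss)]
  expect_lt(abs(fit$k_rel - k_oracle), 2e-5)
})

test_that("tidy and glance summarize fit objects in broom style", {
  rates <- simulate_kcat_dataset(dark_truth(), seed = 2L)
  bf <- bootstrap_eyring(rates, n_boot = 200, seed = 3L)
  td <- tidy(bf)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high"))
  expect_equal(td$term, c("dH_act", "dS_act"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(bf)
  expect_equal(gl$n_points, 21L)
  expect_equal(gl$n_boot, 200L)

  lit <- bootstrap_eyring(
    simulate_kcat_dataset(lit_truth(), condition = "lit", seed = 5L),
    n_boot = 200, seed = 4L
  )
  ae <- allostery_energetics(lit, bf)
  tae <- tidy(ae)
  expect_true(all(c("quantity", "estimate", "lower", "upper") %in%
                    names(tae)))
  expect_equal(nrow(tae), 5L)
})
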