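# build a variant_record from generating parameters; melt fits are made
# from noiseless lit-state-style curves at the requested Tm values
make_record <- function(variant, ddH = -1665, TddS = -1536,
                        Tm_lit = 31.3, Tm_dark = 33.9, cv = 0.05,
                        seed = 1L, n_boot = 200) {
  dark <- bootstrap_eyring(
    simulate_kcat_dataset(dark_truth(cv), variant = variant,
                          seed = seed),
    n_boot = n_boot, seed = seed + 1L
  )
  lit <- bootstrap_eyring(
    simulate_kcat_dataset(lit_truth(ddH = ddH, TddS = TddS, cv = cv),
                          condition = "lit", variant = variant,
                          seed = seed + 2L),
    n_boot = n_boot, seed = seed + 3L
  )
  melt_of <- function(Tm, condition) {
    cv_m <- simulate_melt_curve(true_params(Tm_true = Tm), noise_sd = 0,
                                ht_noise_sd = 0, pulses = NULL,
                                condition = condition, variant = variant)
    fit_two_state(clean_melt(cv_m))
  }
  build_variant_record(lit, dark, melt_of(Tm_lit, "lit"),
                       melt_of(Tm_dark, "dark"), variant = variant)
}

test_that("variant records join kinetics and melt results exactly", {
  rec <- make_record("DL121", seed = 10L)
  expect_identical(rec$dTm, rec$Tm_lit - rec$Tm_dark)
  expect_equal(rec$dTm, 31.3 - 33.9, tolerance = 1e-4) # -2.6 C
  expect_length(rec$missing, 0)
  expect_s3_class(rec$energetics, "allostery_energetics")

  # identical lit/dark kinetics: no allosteric effect
  dark <- bootstrap_eyring(simulate_kcat_dataset(dark_truth(), seed = 1L),
                           n_boot = 100, seed = 2L)
  m <- fit_two_state(clean_melt(simulate_melt_curve(
    true_params(Tm_true = 33), noise_sd = 0, ht_noise_sd = 0,
    pulses = NULL, condition = "lit")))
  same <- build_variant_record(dark, dark, m, m, variant = "null")
  expect_identical(same$dTm, 0)
  expect_identical(same$fold_change_at_ref, 1)

  # missing inputs give explicit markers, not errors
  partial <- build_variant_record(NULL, dark, m, NULL, variant = "p")
  expect_setequal(partial$missing, c("energetics", "Tm_dark"))
  expect_true(is.na(partial$fold_change_at_ref))
})

test_that("a study-sized panel classifies variants against the reference", {
  # DL121-like reference plus an enhancer and a disruptor with clearly
  # separated fold changes, and low-noise kinetics so the CIs separate
  recs <- list(
    make_record("DL121", seed = 20L, cv = 0.01),
    make_record("D127W", ddH = -2600, TddS = -1800, seed = 30L, cv = 0.01),
    make_record("M16P", ddH = -2000, TddS = -2000, seed = 40L, cv = 0.01)
  )
  panel <- variant_panel(recs, reference_variant = "DL121")
  expect_equal(nrow(panel), 3L)
  expect_equal(panel$classification[panel$variant == "DL121"], "neutral")
  expect_equal(panel$classification[panel$variant == "D127W"], "enhancing")
  expect_equal(panel$classification[panel$variant == "M16P"], "disrupting")

  # the zero-effect record is neutral against itself whatever its CI width
  self_class <- classify_variant(recs[[1]], recs[[1]])
  expect_equal(self_class, "neutral")
})

test_that("the study design yields a ten-construct panel", {
  # DL121 plus the nine characterized mutants
  labels <- c("DL121", "A9N", "M16A", "M16P", "G86K", "D87A", "R98M",
              "D116M", "H124Q", "D127W")
  m <- fit_two_state(clean_melt(simulate_melt_curve(
    true_params(Tm_true = 33), noise_sd = 0, ht_noise_sd = 0,
    pulses = NULL, condition = "lit")))
  recs <- lapply(seq_along(labels), function(i) {
    dark <- bootstrap_eyring(
      simulate_kcat_dataset(dark_truth(cv = 0), variant = labels[i],
                            seed = 200L + i),
      n_boot = 50, seed = 300L + i
    )
    lit <- bootstrap_eyring(
      simulate_kcat_dataset(lit_truth(cv = 0), condition = "lit",
                            variant = labels[i], seed = 400L + i),
      n_boot = 50, seed = 500L + i
    )
    build_variant_record(lit, dark, m, m, variant = labels[i])
  })
  panel <- variant_panel(recs)
  expect_equal(nrow(panel), 10L)
  expect_setequal(panel$variant, labels)
})

test_that("tradeoff coordinates measure the off-diagonal free-energy gain", {
  recs <- list(
    make_record("DL121", ddH = -1665, TddS = -1536, cv = 0, seed = 50L),
    make_record("M16P", ddH = -2000, TddS = -2000, cv = 0, seed = 60L)
  )
  co <- tradeoff_coordinates(recs)
  dl <- co[co$variant == "DL121", ]
  expect_equal(dl$x_TddS, -1536, tolerance = 1e-6)
  expect_equal(dl$y_ddH, -1665, tolerance = 1e-6)
  expect_equal(dl$gain, 129, tolerance = 1e-4) # = -ddG

  # exact compensation sits on the x = y diagonal with zero gain
  m16p <- co[co$variant == "M16P", ]
  expect_equal(m16p$gain, 0, tolerance = 1e-4)
  expect_equal(m16p$x_TddS, m16p$y_ddH, tolerance = 1e-6)

  # translation along the diagonal leaves the gain unchanged
  shifted <- make_record("S", ddH = -1665 + 500, TddS = -1536 + 500,
                         cv = 0, seed = 70L)
  co2 <- tradeoff_coordinates(list(shifted))
  expect_equal(co2$gain, dl$gain, tolerance = 1e-4)

  # panel-tibble input gives the same point coordinates
  co3 <- tradeoff_coordinates(variant_panel(recs, NULL))
  expect_equal(co3$gain, co$gain, tolerance = 1e-9)
})

test_that("temperature profiles are flat, crossing, or steep as the energetics dictate", {
  temps <- seq(278.15, 313.15, by = 5)
  # ddH = 0 (and ddS = 0): flat profile at 1
  null_rec <- make_record("null", ddH = 0, TddS = 0, cv = 0, seed = 80L)
  prof0 <- temperature_profile(null_rec, temps)
  expect_equal(prof0$fold, rep(1, length(temps)), tolerance = 1e-9)

  # two records with equal ddG at 303.15 K but different ddH cross there
  a <- make_record("a", ddH = -1665, TddS = -1536, cv = 0, seed = 90L)
  b <- make_record("b", ddH = -800, TddS = -671, cv = 0, seed = 100L)
  fa <- predicted_fold_change(a$energetics, 303.15)
  fb <- predicted_fold_change(b$energetics, 303.15)
  expect_equal(fa, fb, tolerance = 1e-6)
  # the more negative-ddH record has the steeper profile
  pa <- temperature_profile(a, temps)$fold
  pb <- temperature_profile(b, temps)$fold
  expect_gt(pa[1], pb[1])                       # stronger in the cold
  expect_lt(pa[length(pa)], pb[length(pb)])     # weaker in the warm
  expect_true(all(diff(pa) < 0))
})

test_that("the stability-activity correlation respects exclusions and ordering", {
  # collinear synthetic panel: perfect correlation
  lin <- tibble::tibble(variant = paste0("v", 1:5),
                        ddG = c(-400, -200, 0, 200, 400),
                        dTm = -0.005 * c(-400, -200, 0, 200, 400) + 1)
  res <- stability_activity_correlation(lin)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  expect_equal(res$slope, -0.005, tolerance = 1e-12)
  expect_equal(res$n_used, 5L)

  # unknown exclusion labels are an error
  expect_error(stability_activity_correlation(lin, exclude = "nope"),
               class = "litdark_bad_params")
  expect_error(stability_activity_correlation(lin[1:2, ]),
               class = "litdark_too_few_points")

  # a negative dTm-ddG trend (stronger light activation goes with stronger
  # light destabilization) plus three stabilized off-trend points: the
  # generating slope sign is recovered only once the off-trend labels are
  # excluded
  on_trend <- tibble::tibble(variant = paste0("t", 1:6),
                             ddG = seq(-600, -100, by = 100))
  on_trend$dTm <- -3 - 0.004 * on_trend$ddG
  # stabilized in the light yet with a near-reference allosteric effect:
  # small-|ddG| points with positive dTm, off the common trend
  off_trend <- tibble::tibble(variant = c("A9N", "H124Q", "R98M"),
                              ddG = c(-150, -120, -100),
                              dTm = c(2.5, 3.0, 2.8))
  panel <- dplyr::bind_rows(on_trend, off_trend)
  with_all <- stability_activity_correlation(panel)
  with_excl <- stability_activity_correlation(
    panel, exclude = c("A9N", "H124Q", "R98M"))
  expect_equal(with_excl$n_used, 6L)
  expect_equal(with_excl$slope, -0.004, tolerance = 1e-9)
  expect_gt(with_all$slope, 0)           # sign flipped by the off-trend set
  # record ordering does not matter
  shuffled <- panel[sample(nrow(panel)), ]
  res_shuf <- stability_activity_correlation(
    shuffled, exclude = c("A9N", "H124Q", "R98M"))
  expect_equal(res_shuf$slope, with_excl$slope, tolerance = 1e-12)
  expect_equal(res_shuf$pearson_r, with_excl$pearson_r, tolerance = 1e-12)
})

test_that("aggregation is idempotent: derived panels are exact functions of the records", {
  recs <- list(make_record("DL121", seed = 110L),
               make_record("M16A", ddH = -2200, TddS = -1900, seed = 120L))
  p1 <- variant_panel(recs)
  p2 <- variant_panel(recs)
  expect_identical(p1, p2)
  expect_identical(p1$ddG, p1$ddH - p1$TddS)
})
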