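test_that("compound sampling respects size, mixture and invariants", {
  one <- sample_compound_truths(1, seed = 0)
  expect_equal(nrow(one), 1L)
  expect_true(is.finite(one$s0_log_molar))
  expect_true(all(one$amorphous_prob >= 0 & one$amorphous_prob <= 1))

  neutral_only <- sample_compound_truths(50, mix = c(0, 0, 1), seed = 0)
  expect_true(all(neutral_only$ion_class == "neutral"))
  expect_true(all(is.na(neutral_only$pKa)))

  mixed <- sample_compound_truths(200, seed = 0)
  expect_true(all(!is.na(mixed$pKa[mixed$ion_class != "neutral"])))
  expect_true(all(is.na(mixed$pKa[mixed$ion_class == "neutral"])))
  expect_equal(ncol(mixed$latent), 8L)

  expect_error(sample_compound_truths(0), "positive")
  expect_error(sample_compound_truths(5, mix = c(1, 1, 1)), "mix")
})

test_that("compound sampling is deterministic under a seed", {
  a <- sample_compound_truths(100, seed = 42)
  b <- sample_compound_truths(100, seed = 42)
  expect_identical(a, b)
})

test_that("intrinsic solubility distribution is right-skewed with the bulk below 100 uM", {
  cmp <- sample_compound_truths(5000, seed = 0)
  uM <- log_s_to_uM(cmp$s0_log_molar)
  frac_low <- mean(uM > 0 & uM <= 100)
  expect_gt(frac_low, 0.60)
  expect_lt(frac_low, 0.75)
  # right skew on the linear scale: mean far above the median
  expect_gt(mean(uM), 2 * median(uM))
})

test_that("logd_curve matches the closed monoprotic forms", {
  expect_equal(logd_curve(2.0, "neutral", NA, 7.4), 2.0)
  expect_equal(logd_curve(3.0, "acid", 4.0, 4.0), 3.0 - log10(2))
  # frozen from an independent evaluation of logP - log10(1 + 10^(pKa-pH))
  expect_equal(logd_curve(3.0, "base", 9.0, 7.0), 0.99567863, tolerance = 1e-8)
  expect_error(logd_curve(3.0, "acid", NA, 7), "pKa")
})

test_that("logd_curve is monotone in pH and shift-equivariant in logP", {
  pH <- seq(0, 14, by = 0.5)
  acid <- logd_curve(2, "acid", 6, pH)
  base <- logd_curve(2, "base", 6, pH)
  expect_true(all(diff(acid) <= 0))   # acids ionize (logD falls) as pH rises
  expect_true(all(diff(base) >= 0))
  expect_equal(logd_curve(2 + 1.3, "acid", 6, pH), acid + 1.3)
})

test_that("ph_solubility matches closed forms and never drops below S0", {
  expect_equal(ph_solubility(-5, "neutral", NA, 2), -5)
  expect_equal(ph_solubility(-5, "neutral", NA, 7), -5)
  expect_equal(ph_solubility(-5, "acid", 4, 4), -5 + log10(2))
  # frozen from an independent evaluation of s0 + log10(1 + 10^(pKa-pH))
  expect_equal(ph_solubility(-6, "base", 9, 2), 1.0000000434,
               tolerance = 1e-8)
  for (cls in c("acid", "base", "neutral")) {
    s <- ph_solubility(-5, cls, 6, seq(0, 14, 0.25))
    expect_true(all(s >= -5))
  }
})

test_that("noiseless assay is an exact unit conversion of ph_solubility", {
  cmp <- sample_compound_truths(200, seed = 3, amorphous_prob = 0)
  assay <- simulate_assay(cmp, noiseless_config(), seed = 4)
  joined <- dplyr::inner_join(assay, cmp, by = "compound_id")
  truth <- ph_solubility(joined$s0_log_molar, joined$ion_class,
                         joined$pKa, joined$pH)
  ok <- joined$qualifier == "none"
  expect_equal(joined$solubility_uM[ok], log_s_to_uM(truth[ok]),
               tolerance = 1e-12)
  # censored records carry a qualifier instead of a value
  expect_true(all(is.na(joined$solubility_uM[!ok])))
  expect_true(all(log_s_to_uM(truth[joined$qualifier == "above_range"]) > 600))
  expect_true(all(log_s_to_uM(truth[joined$qualifier == "below_range"]) < 0.1))
})

test_that("a compound with true pH-2 solubility 1e-2 M censors above range", {
  cmp <- sample_compound_truths(1, mix = c(0, 0, 1), seed = 1,
                                amorphous_prob = 0)
  cmp$s0_log_molar <- -2
  assay <- simulate_assay(cmp, noiseless_config(), seed = 1)
  expect_true(all(assay$qualifier == "above_range"))
})

test_that("amorphous shift averages to its configured mean", {
  cmp <- sample_compound_truths(1000, seed = 5, amorphous_prob = 1)
  # censor limits widened so large shifts are not selectively lost to the
  # dynamic range, which would bias the recorded mean downward
  noise <- noise_config(analytical_sigma = 0, analytical_sigma_high = 0,
                        cond_sigma = 0, gross_prob = 0,
                        amorphous_shift_mean = 0.7, amorphous_shift_sd = 0.25,
                        frac_no_residue = 0, censor_limits = c(1e-4, 1e8))
  assay <- simulate_assay(cmp, noise, seed = 0)
  joined <- dplyr::inner_join(assay, cmp, by = "compound_id")
  truth <- ph_solubility(joined$s0_log_molar, joined$ion_class,
                         joined$pKa, joined$pH)
  ok <- joined$qualifier == "none"
  shift <- uM_to_log_s(joined$solubility_uM[ok]) - truth[ok]
  expect_true(all(shift >= 0))            # one-sided positive bias
  expect_equal(mean(shift), 0.7, tolerance = 0.05)  # MC at ~1800 records
  expect_true(all(joined$solid_state %in% c("amorphous")))
})

test_that("assay replicate and no-residue fractions follow the config", {
  cmp <- sample_compound_truths(2000, seed = 6)
  noise <- noise_config(frac_duplicates = 0.25, frac_no_residue = 0.1)
  assay <- simulate_assay(cmp, noise, seed = 7)
  per_pair <- dplyr::count(assay, compound_id, pH)
  expect_equal(mean(per_pair$n == 2), 0.25, tolerance = 0.03)
  expect_equal(mean(assay$solid_state == "no_residue"), 0.1, tolerance = 0.03)
  expect_identical(assay, simulate_assay(cmp, noise, seed = 7))
})

test_that("log D simulation hits its calibration anchors", {
  cmp <- sample_compound_truths(2000, seed = 8)
  noise <- noise_config()
  ld <- simulate_logd(cmp, noise, seed = 9)
  expect_equal(nrow(ld$predicted), 2000L)
  expect_equal(nrow(ld$measured), 2000 * noise$frac_measured_logd,
               tolerance = 0.1)
  true_d74 <- logd_curve(cmp$logP, cmp$ion_class, cmp$pKa, 7.4)
  rmse <- sqrt(mean((ld$predicted$d74 - true_d74)^2))
  expect_equal(rmse, noise$pred_logd_sigma[2], tolerance = 0.05)

  # zero-sigma prediction reproduces the true curve; zero measured fraction
  ld0 <- simulate_logd(cmp, noise_config(pred_logd_sigma = 0,
                                         frac_measured_logd = 0), seed = 9)
  expect_equal(ld0$predicted$d74, true_d74, tolerance = 1e-12)
  expect_equal(nrow(ld0$measured), 0L)
})

test_that("descriptor simulation plants recoverable structure", {
  cmp <- sample_compound_truths(1000, seed = 10, k = 4)
  # identity limit: p = k, no noise, no redundancy
  d0 <- simulate_descriptors(cmp, p = 4, redundancy = 0, noise_sd = 0,
                             seed = 1)
  expect_equal(unname(as.matrix(d0[, -1])), unname(cmp$latent))

  d <- simulate_descriptors(cmp, p = 12, redundancy = 3, seed = 2)
  expect_equal(ncol(d) - 1L, 15L)
  dup_cols <- grep("_r", names(d), value = TRUE)
  expect_length(dup_cols, 3L)
  for (dc in dup_cols) {
    src <- sub("_r.*$", "", dc)
    expect_gt(abs(cor(d[[dc]], d[[src]])), 0.9)  # planted pair
  }
  expect_error(simulate_descriptors(cmp, p = 2), "p must be")
})

test_that("library simulation is reproducible end to end", {
  a <- simulate_library(150, seed = 11)
  b <- simulate_library(150, seed = 11)
  expect_identical(a$assay, b$assay)
  expect_identical(a$descriptors, b$descriptors)
  expect_identical(a$logd$predicted, b$logd$predicted)
})
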