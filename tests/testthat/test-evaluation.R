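test_that("outer folds partition the data", {
  withr::with_seed(81, {
    X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(4)
  })
  cv <- nested_cv(X, y, outer = 2, inner = 2, grid = NULL, threshold = NULL,
                  seed = 5)
  expect_equal(nrow(cv$per_fold), 2L)
  expect_error(nested_cv(X, y, outer = 10, seed = 5), "too small")
})

test_that("nested CV is deterministic and learns the noiseless signal", {
  cmp <- sample_compound_truths(600, seed = 82, resid_sd = 0)
  X <- cmp$latent
  colnames(X) <- sprintf("z%d", seq_len(ncol(X)))
  y <- cmp$s0_log_molar
  cv1 <- nested_cv(X, y, outer = 3, inner = 2, seed = 6)
  cv2 <- nested_cv(X, y, outer = 3, inner = 2, seed = 6)
  expect_identical(cv1$per_fold, cv2$per_fold)
  # looser bound than the plain fit check: each fold trains on ~400 points
  expect_lt(cv1$summary$rmse_mean, 0.35 * sd(y))
})

test_that("clean test sets never leak into any training set", {
  lib <- simulate_library(800, seed = 83)
  builds <- build_datasets(lib, seed = 84)
  rte <- refined_test_experiment(builds, n_test_sets = 3, seed = 85)
  # reconstruct each repetition's test ids from the stored predictions
  for (r in unique(rte$predictions$rep)) {
    test_ids <- unique(rte$predictions$compound_id[rte$predictions$rep == r])
    n_clean <- rte$metrics$n_train[rte$metrics$dataset == "Clean" &
                                     rte$metrics$rep == r]
    expect_equal(n_clean, nrow(builds$Clean$data) - length(test_ids))
  }
  expect_equal(nrow(rte$metrics), 3L * length(builds))
})

test_that("a duplicate of Clean scores identically to Clean", {
  lib <- simulate_library(500, seed = 86)
  builds <- build_datasets(lib, seed = 87)
  builds$CleanCopy <- builds$Clean
  builds$CleanCopy$name <- "CleanCopy"
  rte <- refined_test_experiment(builds, n_test_sets = 2, seed = 88)
  s <- rte$summary
  expect_equal(s$rmse_mean[s$dataset == "CleanCopy"],
               s$rmse_mean[s$dataset == "Clean"])
})

test_that("identical groups give ANOVA and Tukey p-values near 1", {
  g <- c(0.5, 0.52, 0.48, 0.51)
  cmp <- compare_rmse(list(a = g, b = g, c = g))
  expect_gt(cmp$anova_p, 0.99)
  expect_true(all(cmp$tukey$p_adj > 0.99))
})

test_that("well-separated groups are flagged at p < 0.05", {
  withr::with_seed(91, {
    a <- rnorm(10, 0, 0.1)
    b <- rnorm(10, 1, 0.1)   # shifted by 10 sd
  })
  cmp <- compare_rmse(list(a = a, b = b))
  expect_lt(cmp$anova_p, 0.05)
  expect_true(all(cmp$tukey$significant))
  expect_error(compare_rmse(list(a = 1, b = 2)), "groups")
})

test_that("Tukey flags agree with a permutation oracle on three groups", {
  withr::with_seed(92, {
    groups <- list(g1 = rnorm(10, 0, 1), g2 = rnorm(10, 0, 1),
                   g3 = rnorm(10, 2, 1))
  })
  cmp <- compare_rmse(groups)
  flagged <- cmp$tukey$pair[cmp$tukey$significant]
  expect_setequal(flagged, c("g3-g1", "g3-g2"))

  # permutation oracle: max |pairwise mean difference| null distribution,
  # 1e4 shuffles, family-wise by the max statistic
  x <- unlist(groups)
  lab <- rep(names(groups), each = 10)
  obs <- abs(outer(tapply(x, lab, mean), tapply(x, lab, mean), "-"))
  withr::with_seed(93, {
    null_max <- replicate(1e4, {
      sh <- sample(lab)
      m <- tapply(x, sh, mean)
      max(abs(outer(m, m, "-")))
    })
  })
  perm_p <- sapply(c("g2-g1" = obs["g2", "g1"], "g3-g1" = obs["g3", "g1"],
                     "g3-g2" = obs["g3", "g2"]),
                   function(d) mean(null_max >= d))
  expect_setequal(names(perm_p)[perm_p < 0.05], flagged)
})

test_that("bias analysis reproduces the hand-binned example", {
  b <- bias_analysis(c(-7, -6, -5, -4), c(-6.2, -6.0, -5.8, -4.0), n_bins = 2)
  expect_equal(b$over, c(1L, 0L))
  expect_equal(b$under, c(0L, 1L))
  expect_equal(b$within, c(1L, 1L))
  expect_equal(sum(b$n), 4L)
})

test_that("bias analysis handles perfect and shifted predictions", {
  withr::with_seed(94, y <- rnorm(200, -5))
  perfect <- bias_analysis(y, y)
  expect_equal(sum(perfect$over), 0L)
  expect_equal(sum(perfect$under), 0L)
  expect_equal(sum(perfect$within), 200L)
  expect_equal(nrow(perfect), 6L)

  shifted <- bias_analysis(y, y + 1.0)
  expect_equal(sum(shifted$over), 200L)
  expect_equal(sum(shifted$n), 200L)
  # degenerate single-value range collapses to one bin
  expect_equal(nrow(bias_analysis(c(-5, -5), c(-5, -5))), 1L)
})

test_that("amorphous bias check compares matched prediction sets", {
  withr::with_seed(95, {
    base <- tibble::tibble(rep = rep(1:2, each = 50),
                           compound_id = rep(sprintf("c%02d", 1:50), 2),
                           y_true = rnorm(100, -5))
  })
  ref <- dplyr::mutate(base, y_pred = y_true + rnorm(100, 0, 0.1))
  same <- amorphous_bias_check(ref, ref)
  expect_false(same$positive_bias)
  expect_equal(same$mean_error_ref, same$mean_error_ac)

  ac <- dplyr::mutate(base, y_pred = y_true + rnorm(100, 0.8, 0.2))
  biased <- amorphous_bias_check(ref, ac)
  expect_true(biased$positive_bias)
  expect_gt(biased$over_ac, biased$under_ac)

  expect_error(amorphous_bias_check(ref, ac[-1, ]), "identical")
})
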