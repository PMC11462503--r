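# Evaluation experiments -----------------------------------------------------
#
# Experiment 1: nested cross-validation (outer folds estimate
#   generalization, inner folds pick hyperparameters) on one dataset.
# Experiment 2: repeated clean test sets — random 20% splits of Clean are
#   held out, their compounds removed from every training variant, and all
#   variants are scored on the same clean labels. RMSE samples are compared
#   by one-way ANOVA + Tukey HSD; prediction bias is profiled by binning.

balanced_folds <- function(n, k) {
  if (n < k) stop(sprintf("dataset of %d rows is too small for %d folds",
                          n, k), call. = FALSE)
  sample(rep_len(seq_len(k), n))
}

# columns of a build's data that are descriptors (numeric, non-meta)
descriptor_cols <- function(data) {
  meta <- c("compound_id", "intrinsic_log_s", "assignment", "logd_source",
            "solid_state_used", "s2_uM", "s7_uM", "qc_passed")
  cols <- setdiff(names(data), meta)
  cols[vapply(data[cols], is.numeric, TRUE)]
}

#' Nested cross-validation of a solubility model
#'
#' Outer folds partition the data; on each outer training split an inner
#' k-fold cross-validation selects the hyperparameter combination from
#' `grid` with the lowest mean inner RMSE, a model is refit on the whole
#' outer training split with the selected combination, and metrics are
#' computed on the held-out outer fold. The descriptor decorrelation
#' filter, when enabled, is fit on the outer training split only (no
#' leakage into the outer test fold).
#'
#' @param X numeric descriptor matrix (pre-decorrelation).
#' @param y numeric target (log S).
#' @param spec a [model_spec()]; the grid search applies to
#'   `random_forest` only.
#' @param outer,inner fold counts (defaults 10 and 5).
#' @param grid hyperparameter grid (tibble, one column per
#'   hyperparameter), or `NULL` to skip inner selection and use `spec`'s
#'   hyperparameters as-is.
#' @param threshold decorrelation |Pearson| ceiling applied per outer
#'   training split; `NULL` disables the filter.
#' @param seed integer seed (fold assignment and fits).
#' @return object of class `nested_cv_result`: `per_fold` tibble (fold,
#'   selected hyperparameters, metric columns), `summary` (mean and sd per
#'   metric), `outer`, `inner`, `seed`.
#' @examples
#' lib <- simulate_library(300, seed = 3)
#' prep <- prepare_features(build_dataset(lib, dataset_spec("Clean")),
#'                          threshold = NULL)
#' cv <- nested_cv(prep$X, prep$y, outer = 3, inner = 2, seed = 1)
#' cv$summary
#' @export
nested_cv <- function(X, y, spec = model_spec(), outer = 10L, inner = 5L,
                      grid = default_rf_grid(), threshold = 0.9, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (!is.null(grid) && spec$algorithm != "random_forest") grid <- NULL

  withr::with_seed(as.integer(seed), {
    fold_id <- balanced_folds(length(y), outer)
    per_fold <- purrr::map_dfr(seq_len(outer), function(f) {
      tr <- fold_id != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      kept <- if (is.null(threshold)) colnames(Xtr)
              else suppressWarnings(decorrelate(Xtr, ytr, threshold))
      Xtr <- Xtr[, kept, drop = FALSE]
      Xte <- X[!tr, kept, drop = FALSE]

      hp <- spec$hyperparameters
      if (!is.null(grid) && nrow(grid) > 1) {
        inner_id <- balanced_folds(length(ytr), inner)
        inner_rmse <- vapply(seq_len(nrow(grid)), function(g) {
          hp_g <- utils::modifyList(hp, as.list(grid[g, ]))
          mean(vapply(seq_len(inner), function(i) {
            itr <- inner_id != i
            m <- fit_model(Xtr[itr, , drop = FALSE], ytr[itr],
                           model_spec(spec$algorithm, hp_g, spec$seed))
            sqrt(mean((predict(m, Xtr[!itr, , drop = FALSE]) - ytr[!itr])^2))
          }, 0))
        }, 0)
        hp <- utils::modifyList(hp, as.list(grid[which.min(inner_rmse), ]))
      }
      m <- fit_model(Xtr, ytr, model_spec(spec$algorithm, hp, spec$seed))
      met <- solubility_metrics(y[!tr], predict(m, Xte))
      row <- tibble::tibble(fold = f)
      if (length(hp) > 0) row <- dplyr::bind_cols(row, tibble::as_tibble(hp))
      dplyr::bind_cols(row, met)
    })
  })
  metric_cols <- intersect(names(per_fold),
                           c("rmse", "r2", grep("^pct_within",
                                                names(per_fold), value = TRUE)))
  summary <- per_fold %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   list(mean = mean, sd = sd)))
  structure(list(per_fold = per_fold, summary = summary,
                 outer = outer, inner = inner, seed = as.integer(seed)),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %d outer x %d inner folds\n",
              x$outer, x$inner))
  cat(sprintf("  RMSE %.3f (%.3f), R2 %.3f\n",
              x$summary$rmse_mean, x$summary$rmse_sd, x$summary$r2_mean))
  invisible(x)
}

#' Repeated clean-test-set experiment over dataset variants
#'
#' For each of `n_test_sets` repetitions: a random `test_frac` of the
#' Clean build is held out as the test set; its compounds are removed from
#' the training data of *every* variant; one model per variant is trained
#' on what remains (decorrelation fit on each training set) and scored on
#' the same clean test labels. Variants therefore differ only in their
#' training data, and the per-variant RMSE samples feed [compare_rmse()].
#'
#' @param builds named list of `dataset_build` objects including `Clean`
#'   (e.g. from [build_datasets()]).
#' @param spec a [model_spec()] used for every fit (fixed hyperparameters;
#'   the comparison is between datasets, not tuners).
#' @param n_test_sets number of repetitions (default 10); test sets are
#'   drawn independently per repetition.
#' @param test_frac fraction of Clean held out per repetition (default
#'   0.2).
#' @param threshold decorrelation ceiling per training set; `NULL`
#'   disables.
#' @param seed integer seed.
#' @return object of class `refined_test_result`: `metrics` (tibble:
#'   `dataset`, `rep`, `n_train`, metric columns, `mean_error`),
#'   `predictions` (tibble: `dataset`, `rep`, `compound_id`, `y_true`,
#'   `y_pred`), `summary` (per-dataset mean/sd of each metric).
#' @export
refined_test_experiment <- function(builds, spec = model_spec(),
                                    n_test_sets = 10L, test_frac = 0.2,
                                    threshold = 0.9, seed = 1L) {
  stopifnot("Clean" %in% names(builds))
  clean <- builds$Clean$data
  if (nrow(clean) == 0) stop("Clean build is empty", call. = FALSE)
  desc <- descriptor_cols(clean)
  n_test <- max(1L, round(test_frac * nrow(clean)))

  rep_seeds <- derive_seeds(seed, n_test_sets)
  res <- purrr::map_dfr(seq_len(n_test_sets), function(r) {
    test <- withr::with_seed(rep_seeds[r],
                             dplyr::slice_sample(clean, n = n_test))
    X_test <- as.matrix(test[desc])
    purrr::map_dfr(names(builds), function(nm) {
      train <- dplyr::anti_join(builds[[nm]]$data, test["compound_id"],
                                by = "compound_id")
      if (nrow(train) == 0)
        stop(sprintf("training build '%s' empty after test-set removal", nm),
             call. = FALSE)
      Xtr <- as.matrix(train[desc])
      kept <- if (is.null(threshold)) desc
              else suppressWarnings(decorrelate(Xtr, train$intrinsic_log_s,
                                                threshold))
      m <- fit_model(Xtr[, kept, drop = FALSE], train$intrinsic_log_s,
                     model_spec(spec$algorithm, spec$hyperparameters,
                                seed = rep_seeds[r]))
      y_pred <- predict(m, X_test[, kept, drop = FALSE])
      met <- solubility_metrics(test$intrinsic_log_s, y_pred)
      dplyr::bind_cols(
        tibble::tibble(dataset = nm, rep = r, n_train = nrow(train)),
        met,
        tibble::tibble(
          mean_error = mean(y_pred - test$intrinsic_log_s),
          predictions = list(tibble::tibble(
            compound_id = test$compound_id,
            y_true = test$intrinsic_log_s,
            y_pred = y_pred))))
    })
  })

  predictions <- res %>%
    dplyr::select("dataset", "rep", "predictions") %>%
    tidyr::unnest("predictions")
  metrics <- dplyr::select(res, -"predictions")
  metric_cols <- intersect(names(metrics),
                           c("rmse", "r2", "mean_error",
                             grep("^pct_within", names(metrics), value = TRUE)))
  summary <- metrics %>%
    dplyr::group_by(.data$dataset) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   list(mean = mean, sd = sd)),
                     .groups = "drop")
  structure(list(metrics = metrics, predictions = predictions,
                 summary = summary, n_test_sets = n_test_sets,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "refined_test_result")
}

#' @export
print.refined_test_result <- function(x, ...) {
  cat(sprintf("<refined_test_result> %d clean test sets (%.0f%% of Clean)\n",
              x$n_test_sets, 100 * x$test_frac))
  print(x$summary[, c("dataset", "rmse_mean", "rmse_sd")], n = Inf)
  invisible(x)
}

#' Compare per-dataset RMSE samples by ANOVA and Tukey HSD
#'
#' One-way ANOVA over the RMSE values grouped by dataset, followed by
#' Tukey honestly-significant-difference pairwise comparisons
#' (studentized-range procedure).
#'
#' @param metrics tibble with columns `dataset` and `rmse` (e.g.
#'   `refined_test_result$metrics`), or a named list of numeric RMSE
#'   vectors.
#' @param alpha significance level annotated on the pairwise table.
#' @return list: `anova_p` (F-test p-value), `tukey` (tibble: `pair`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `significant`), `fit` (the `aov`
#'   object).
#' @examples
#' compare_rmse(list(a = c(0.5, 0.52, 0.48), b = c(0.9, 0.88, 0.91)))$anova_p
#' @export
compare_rmse <- function(metrics, alpha = 0.05) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- purrr::map_dfr(names(metrics), function(nm)
      tibble::tibble(dataset = nm, rmse = metrics[[nm]]))
  }
  stopifnot(all(c("dataset", "rmse") %in% names(metrics)))
  counts <- table(metrics$dataset)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >= 2 groups with >= 2 RMSE values each", call. = FALSE)

  df <- data.frame(dataset = factor(metrics$dataset), rmse = metrics$rmse)
  fit <- aov(rmse ~ dataset, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$dataset
  tukey <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  list(anova_p = anova_p, tukey = tukey, fit = fit)
}

#' Over/under-prediction bias profile by true-solubility bin
#'
#' True log S values are split into `n_bins` equal-width bins over their
#' observed range; within each bin, compounds are counted as overpredicted
#' (`y_pred - y_true > threshold`, strictly), underpredicted (`< -threshold`)
#' or within tolerance. Counts across bins sum to `length(y_true)`.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 1), log S.
#' @param n_bins number of equal-width bins (default 6).
#' @param threshold log10 error threshold (default 0.7, i.e. 5-fold).
#' @return tibble: `bin`, `lo`, `hi`, `n`, `over`, `under`, `within`.
#' @examples
#' bias_analysis(c(-7, -6, -5, -4), c(-6.2, -6, -5.8, -4), n_bins = 2)
#' @export
bias_analysis <- function(y_true, y_pred, n_bins = 6L, threshold = 0.7) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  stopifnot(length(y_true) >= 1, n_bins >= 1)
  rng <- range(y_true)
  if (diff(rng) == 0) {
    bin <- rep(1L, length(y_true))
    edges <- c(rng[1], rng[2])
    n_bins <- 1L
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(y_true, edges, rightmost.closed = TRUE)
  }
  err <- y_pred - y_true
  purrr::map_dfr(seq_len(n_bins), function(b) {
    i <- bin == b
    tibble::tibble(
      bin = b, lo = edges[b], hi = edges[b + 1], n = sum(i),
      over = sum(err[i] > threshold),
      under = sum(err[i] < -threshold),
      within = sum(abs(err[i]) <= threshold)
    )
  })
}

#' Check for amorphous-training-data prediction bias
#'
#' Compares two models evaluated on identical test sets (typically the
#' Clean-trained and Clean_ac-trained models from
#' [refined_test_experiment()]). Training data containing amorphous-residue
#' measurements carries a one-sided positive solubility bias; a model
#' inheriting it shows a positive mean signed error and more over- than
#' under-predictions on clean test labels.
#'
#' @param pred_ref,pred_ac prediction tibbles with columns `rep`,
#'   `compound_id`, `y_true`, `y_pred`, on identical test sets.
#' @param threshold log10 error threshold for over/under counting.
#' @return list: `mean_error_ref`, `mean_error_ac`, `over_ref`,
#'   `under_ref`, `over_ac`, `under_ac`, and `positive_bias` — `TRUE` when
#'   the amorphous-trained model both over-counts (`over_ac > under_ac`)
#'   and has a larger mean signed error than the reference.
#' @export
amorphous_bias_check <- function(pred_ref, pred_ac, threshold = 0.7) {
  key <- function(p) paste(p$rep, p$compound_id)
  if (!setequal(key(pred_ref), key(pred_ac)))
    stop("prediction sets are not on identical test sets", call. = FALSE)
  err_ref <- pred_ref$y_pred - pred_ref$y_true
  err_ac <- pred_ac$y_pred - pred_ac$y_true
  out <- list(
    mean_error_ref = mean(err_ref),
    mean_error_ac = mean(err_ac),
    over_ref = sum(err_ref > threshold),
    under_ref = sum(err_ref < -threshold),
    over_ac = sum(err_ac > threshold),
    under_ac = sum(err_ac < -threshold)
  )
  out$positive_bias <- out$over_ac > out$under_ac &&
    out$mean_error_ac > out$mean_error_ref
  out
}
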