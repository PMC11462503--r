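# Regressor abstraction and metric suite ------------------------------------

#' Model specification
#'
#' Random forest is the default and the reference algorithm; lasso,
#' support-vector regression and gradient boosting are available behind
#' the same interface when the corresponding package is installed.
#'
#' @param algorithm one of `random_forest`, `lasso`, `svr`,
#'   `gradient_boosting`.
#' @param hyperparameters named list; unset entries use per-algorithm
#'   defaults (random forest: `num_trees = 300`, `mtry_frac = 1`,
#'   `min_node = 2` — the defaults of the reference implementation most
#'   widely used for QSPR regression: all features considered per split,
#'   near-singleton leaves).
#' @param seed integer seed used at fit time.
#' @return object of class `model_spec`.
#' @examples
#' model_spec()
#' model_spec("random_forest", list(mtry_frac = 0.5), seed = 3)
#' @export
model_spec <- function(algorithm = "random_forest",
                       hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm,
                         c("random_forest", "lasso", "svr",
                           "gradient_boosting"))
  structure(list(algorithm = algorithm,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters) == 0) "defaults"
        else paste(names(x$hyperparameters), unlist(x$hyperparameters),
                   sep = "=", collapse = ", ")
  cat(sprintf("<model_spec> %s (%s), seed %d\n", x$algorithm, hp, x$seed))
  invisible(x)
}

#' Default random-forest hyperparameter grid for inner-loop selection
#'
#' A small fixed grid over the fraction of descriptors tried per split and
#' the minimum node size, searched by the inner loop of [nested_cv()].
#'
#' @return tibble with columns `mtry_frac`, `min_node`.
#' @export
default_rf_grid <- function() {
  tidyr::expand_grid(mtry_frac = c(1 / 3, 1), min_node = c(2, 8))
}

hp_default <- function(hp, name, default) {
  if (is.null(hp[[name]])) default else hp[[name]]
}

#' Fit a solubility regressor
#'
#' @param X numeric descriptor matrix.
#' @param y numeric target (log S, log10 mol/L).
#' @param spec a [model_spec()].
#' @return object of class `sol_model` with a [predict][predict.sol_model]
#'   method.
#' @examples
#' prep <- prepare_features(build_dataset(simulate_library(300, seed = 3),
#'                                        dataset_spec("Clean")))
#' m <- fit_model(prep$X, prep$y, model_spec(seed = 1))
#' head(predict(m, prep$X))
#' @export
fit_model <- function(X, y, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"),
            nrow(X) == length(y), length(y) >= 2)
  hp <- spec$hyperparameters
  fitted <- switch(
    spec$algorithm,
    random_forest = {
      mtry <- max(1L, floor(hp_default(hp, "mtry_frac", 1) * ncol(X)))
      ranger::ranger(
        x = as.data.frame(X), y = y,
        num.trees = hp_default(hp, "num_trees", 300L),
        mtry = min(mtry, ncol(X)),
        min.node.size = hp_default(hp, "min_node", 2L),
        seed = spec$seed, num.threads = 1L
      )
    },
    lasso = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("lasso requires the glmnet package", call. = FALSE)
      withr::with_seed(spec$seed,
        glmnet::cv.glmnet(X, y, alpha = 1,
                          nfolds = hp_default(hp, "nfolds", 5L)))
    },
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("svr requires the e1071 package", call. = FALSE)
      e1071::svm(X, y, type = "eps-regression",
                 cost = hp_default(hp, "cost", 1),
                 gamma = hp_default(hp, "gamma", 1 / ncol(X)))
    },
    gradient_boosting = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("gradient_boosting requires the xgboost package", call. = FALSE)
      xgboost::xgboost(
        x = X, y = y,
        nrounds = hp_default(hp, "nrounds", 200L),
        max_depth = hp_default(hp, "max_depth", 5L),
        learning_rate = hp_default(hp, "learning_rate", 0.1),
        nthreads = 1L, verbosity = 0L,
        seed = spec$seed)
    }
  )
  structure(list(fitted = fitted, spec = spec, features = colnames(X)),
            class = "sol_model")
}

#' Predict from a fitted solubility model
#'
#' @param object a `sol_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predicted log S.
#' @export
predict.sol_model <- function(object, newdata, ...) {
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  switch(
    object$spec$algorithm,
    random_forest = predict(object$fitted, data = as.data.frame(newdata),
                            num.threads = 1L)$predictions,
    lasso = drop(predict(object$fitted, newx = as.matrix(newdata),
                         s = "lambda.min")),
    svr = unname(predict(object$fitted, newdata)),
    gradient_boosting = predict(object$fitted, newdata)
  )
}

#' Regression metric bundle for solubility models
#'
#' RMSE, coefficient of determination and the percentage of compounds
#' predicted within each absolute log10 tolerance (`%log S +/- t`;
#' non-strict comparison). The default 0.7 log-unit tolerance corresponds
#' to a 5-fold solubility ratio, the typical error of the assay itself.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 1).
#' @param tolerances log10 tolerances for the percent-within metrics.
#' @return one-row tibble: `rmse`, `r2` (NA with a warning when `y_true`
#'   is constant), `pct_within_0_7`, `pct_within_0_5` (one column per
#'   tolerance, named by its value).
#' @examples
#' solubility_metrics(c(0, 0, 0, 0), c(1, 0, 0, 0))
#' @export
solubility_metrics <- function(y_true, y_pred, tolerances = c(0.7, 0.5)) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  stopifnot(length(y_true) >= 1)
  err <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("y_true is constant; R^2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  out <- tibble::tibble(rmse = sqrt(mean(err^2)), r2 = r2)
  for (t in tolerances)
    out[[sprintf("pct_within_%s", gsub("\\.", "_", format(t)))]] <-
      100 * mean(abs(err) <= t)
  out
}
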