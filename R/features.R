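# Descriptor handling and the correlation filter ----------------------------

#' Decorrelate a descriptor matrix against a solubility target
#'
#' Multicollinearity filter: among descriptor pairs correlated above
#' `threshold` (|Pearson|), only the descriptor more correlated with the
#' solubility target survives. Implemented as a deterministic greedy scan:
#' columns are ranked by decreasing `|cor(x, y)|` (ties broken by column
#' name, ascending); a column is kept iff its absolute correlation with
#' every already-kept column is `<= threshold`. Zero-variance columns are
#' excluded before ranking. The result is invariant to column order of
#' `X`, and the kept set satisfies `max |cor|` pairwise `<= threshold` by
#' construction.
#'
#' @param X numeric matrix or data frame of descriptors (rows aligned with
#'   `y`; a `compound_id` column, if present, is ignored).
#' @param y numeric target (log S), same length as `nrow(X)`.
#' @param threshold pairwise |Pearson| ceiling (default 0.9).
#' @return character vector of kept column names, in the original column
#'   order of `X`; attribute `"dropped_zero_variance"` lists excluded
#'   constant columns.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' X <- cbind(X, a2 = X[, "a"] + rnorm(100, 0, 0.05))  # planted duplicate
#' y <- X[, "a"] + rnorm(100, 0, 0.2)
#' decorrelate(X, y)
#' @export
decorrelate <- function(X, y, threshold = 0.9) {
  if (is.data.frame(X)) {
    X <- X[setdiff(names(X), "compound_id")]
    X <- as.matrix(X)
  }
  stopifnot(is.numeric(y), nrow(X) == length(y), nrow(X) >= 2)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))

  sds <- apply(X, 2, sd)
  zero_var <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(zero_var) > 0) {
    warning("excluding zero-variance column(s): ",
            paste(zero_var, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (ncol(X) == 0) {
    out <- character()
    attr(out, "dropped_zero_variance") <- zero_var
    return(out)
  }

  target_cor <- abs(drop(cor(X, y)))
  ord <- order(-target_cor, colnames(X))
  C <- abs(cor(X))
  kept_idx <- integer()
  for (j in ord) {
    if (all(C[j, kept_idx] <= threshold)) kept_idx <- c(kept_idx, j)
  }
  out <- colnames(X)[sort(kept_idx)]
  attr(out, "dropped_zero_variance") <- zero_var
  out
}

#' Prepare a model-ready feature matrix and target from a dataset build
#'
#' Joins a build's curated records with descriptors (already joined by
#' [build_dataset()]; a `provider` function or external descriptor tibble
#' may replace them), drops rows with missing descriptor values, applies
#' [decorrelate()] and returns aligned `(X, y)`.
#'
#' @param build a `dataset_build`, or any tibble carrying
#'   `compound_id`, `intrinsic_log_s` and descriptor columns.
#' @param provider optional descriptor source: either a tibble keyed by
#'   `compound_id`, or a function `compounds_tbl -> tibble` (descriptor
#'   provider contract). `NULL` (default) uses the descriptor columns
#'   already present in the build.
#' @param threshold passed to [decorrelate()]; `NULL` skips the filter.
#' @return list: `X` (numeric matrix), `y` (numeric), `compound_id`,
#'   `kept` (column names), `n_dropped_incomplete`.
#' @export
prepare_features <- function(build, provider = NULL, threshold = 0.9) {
  data <- if (inherits(build, "dataset_build")) build$data else build
  meta_cols <- c("compound_id", "intrinsic_log_s", "assignment",
                 "logd_source", "solid_state_used", "s2_uM", "s7_uM",
                 "qc_passed")
  if (!is.null(provider)) {
    desc <- if (is.function(provider)) provider(data["compound_id"]) else provider
    data <- dplyr::inner_join(data[intersect(meta_cols, names(data))], desc,
                              by = "compound_id")
  }
  if (nrow(data) == 0) {
    return(list(X = matrix(numeric(), 0, 0), y = numeric(),
                compound_id = character(), kept = character(),
                n_dropped_incomplete = 0L))
  }
  desc_cols <- setdiff(names(data), meta_cols)
  desc_cols <- desc_cols[vapply(data[desc_cols], is.numeric, TRUE)]
  complete <- complete.cases(data[desc_cols]) & !is.na(data$intrinsic_log_s)
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]

  X <- as.matrix(data[desc_cols])
  y <- data$intrinsic_log_s
  kept <- if (is.null(threshold) || nrow(X) < 2) colnames(X)
          else suppressWarnings(decorrelate(X, y, threshold))
  list(X = X[, kept, drop = FALSE], y = y,
       compound_id = data$compound_id, kept = as.character(kept),
       n_dropped_incomplete = n_dropped)
}
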