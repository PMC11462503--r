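# Independent oracles and small fixture builders used across the suite.

# Literal scalar transcription of the ionization-assignment rules, written
# directly from their verbal statement and kept deliberately independent of
# classify_ionization()'s vectorized implementation:
#   1. neutral if the absolute difference among the three log D values is
#      less than 0.5;
#   2. intrinsic at pH 2: first drop compounds with maximum log D at pH
#      10.5, then select |d(2.6) - d(7.4)| < 0.25;
#   3. intrinsic at pH 7: first drop compounds with maximum log D at pH
#      2.6, then select |d(7.4) - d(10.5)| < 0.25;
#   4. otherwise excluded. Ties never count as a maximum "at" a pH.
oracle_classify <- function(d26, d74, d105,
                            neutral_tol = 0.5, intrinsic_tol = 0.25) {
  d <- c(d26, d74, d105)
  if (max(d) - min(d) < neutral_tol) return("neutral")
  maximum_at_105 <- d105 > d26 && d105 > d74
  if (!maximum_at_105 && abs(d26 - d74) < intrinsic_tol)
    return("intrinsic_pH2")
  maximum_at_26 <- d26 > d74 && d26 > d105
  if (!maximum_at_26 && abs(d74 - d105) < intrinsic_tol)
    return("intrinsic_pH7")
  "excluded"
}

# Exhaustive-subset oracle for the decorrelation filter on <= 10 columns:
# enumerate every subset satisfying the pairwise |Pearson| <= threshold
# constraint and pick the one whose membership vector, read in preference
# order (decreasing |cor(x, y)|, ties by ascending name), is
# lexicographically maximal — i.e. prefer including the most
# target-correlated columns first. That subset is automatically maximal
# (appending any still-compatible column improves the key), so it is the
# unique solution a preference-respecting filter must return.
oracle_decorrelate <- function(X, y, threshold = 0.9) {
  stopifnot(ncol(X) <= 10)
  p <- ncol(X)
  C <- abs(cor(X))
  target <- abs(drop(cor(X, y)))
  pref <- order(-target, colnames(X))   # columns in preference order
  best_member <- NULL
  best_idx <- NULL
  for (m in 0:(2^p - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) > 1 &&
        any(C[idx, idx][upper.tri(C[idx, idx])] > threshold)) next
    member <- as.integer(pref %in% idx)   # membership in preference order
    if (is.null(best_member) || first_diff(member, best_member) > 0) {
      best_member <- member
      best_idx <- idx
    }
  }
  colnames(X)[sort(best_idx)]
}

first_diff <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (length(nz) == 0) 0 else sign(d[nz[1]])
}

# noiseless assay configuration: every stochastic corruption off
noiseless_config <- function(...) {
  noise_config(analytical_sigma = 0, analytical_sigma_high = 0,
               cond_sigma = 0, gross_prob = 0,
               measured_logd_sigma = 0, pred_logd_sigma = 0,
               frac_no_residue = 0, ...)
}

# small deterministic assay table exercising each filtering rule once
toy_assay <- function() {
  tibble::tibble(
    compound_id = c("ok", "amo", "nores", "cens", "salt", "stereo"),
    pH = 2,
    solubility_uM = c(10, 10, 10, NA, 10, 10),
    qualifier = factor(
      c("none", "none", "none", "above_range", "none", "none"),
      levels = c("none", "below_range", "above_range")),
    solid_state = factor(
      c("crystalline", "amorphous", "no_residue", "crystalline",
        "crystalline", "crystalline"),
      levels = c("crystalline", "amorphous", "no_residue")),
    replicate = 1L
  )
}

toy_compounds <- function() {
  tibble::tibble(
    compound_id = c("ok", "amo", "nores", "cens", "salt", "stereo"),
    is_salt = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    is_stereoisomer = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# pre-QC intrinsic record with chosen paired solubilities
qc_record <- function(assignment, s2, s7) {
  tibble::tibble(
    compound_id = "x",
    intrinsic_log_s = -5,
    assignment = factor(assignment,
                        levels = c("neutral", "intrinsic_pH2",
                                   "intrinsic_pH7")),
    logd_source = "measured",
    solid_state_used = factor("crystalline",
                              levels = c("crystalline", "amorphous")),
    s2_uM = s2,
    s7_uM = s7
  )
}
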