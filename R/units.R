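#' Convert between micromolar solubility and log10 molar log S
#'
#' The assay reports solubility in uM; models and curated records work in
#' log10 mol/L ("log S"). `uM_to_log_s(600)` is -3.22 to two decimals, the
#' upper bound imposed by the assay dynamic range; `uM_to_log_s(0.1)` is -7.
#'
#' @param uM solubility in micromol/L, positive.
#' @param log_s solubility as log10 mol/L.
#' @return `uM_to_log_s`: log10 mol/L; `log_s_to_uM`: uM.
#' @examples
#' uM_to_log_s(600)   # -3.22
#' log_s_to_uM(-5)    # 10 uM
#' @export
uM_to_log_s <- function(uM) {
  stopifnot(is.numeric(uM), all(uM > 0, na.rm = TRUE))
  log10(uM) - 6
}

#' @rdname uM_to_log_s
#' @export
log_s_to_uM <- function(log_s) {
  stopifnot(is.numeric(log_s))
  10^(log_s + 6)
}

#' Fold-change equivalent of a log10 error tolerance
#'
#' A tolerance of 0.7 log10 units corresponds to a 5-fold ratio in molar
#' solubility (10^0.7 rounds to 5), the typical run-to-run error of a
#' discovery solubility assay.
#'
#' @param tol tolerance in log10 units.
#' @return linear fold-change, `10^tol`.
#' @examples
#' log_tol_to_fold(0.7)  # ~5
#' @export
log_tol_to_fold <- function(tol) {
  stopifnot(is.numeric(tol), all(tol >= 0))
  10^tol
}

# deterministic expansion of one user seed into per-stage seeds; keeps every
# stage independently re-runnable with the same stream it saw in a full run
derive_seeds <- function(seed, n, offset = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), {
    s <- sample.int(.Machine$integer.max - 1L, n + offset)
  })
  s[(offset + 1L):(offset + n)]
}
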