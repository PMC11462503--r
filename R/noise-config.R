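#' Calibrate the analytical noise s.d. from a duplicate-agreement rate
#'
#' The assay's run-to-run variability is multiplicative in concentration,
#' i.e. additive Gaussian in log10 units with s.d. `sigma`. Two replicates
#' of the same sample then differ by N(0, sigma * sqrt(2)), so the fraction
#' of duplicate pairs agreeing within a given fold-change pins down sigma:
#'
#'   P(|diff| < log10(fold)) = target  =>
#'   sigma = log10(fold) / (sqrt(2) * qnorm((1 + target) / 2))
#'
#' The default reproduces the observed behaviour of low-solubility duplicate
#' measurements, 76% of which agree within 5-fold, giving sigma ~ 0.42.
#'
#' @param target fraction of duplicate pairs within `fold` of each other.
#' @param fold linear fold-change defining agreement (default 5).
#' @return analytical s.d. in log10 units.
#' @examples
#' calibrate_analytical_sigma()            # ~0.4206
#' calibrate_analytical_sigma(0.95, 10)    # tighter assay
#' @export
calibrate_analytical_sigma <- function(target = 0.76, fold = 5) {
  stopifnot(target > 0, target < 1, fold > 1)
  log10(fold) / (sqrt(2) * qnorm((1 + target) / 2))
}

#' Assay noise configuration
#'
#' Bundles every noise/nuisance parameter of the synthetic assay:
#'
#' * `analytical_sigma` — log10 s.d. of per-replicate measurement noise
#'   for low-solubility samples (true concentration <= 10 uM), calibrated
#'   by default so 76% of low-solubility duplicate pairs agree within
#'   5-fold (see [calibrate_analytical_sigma()]).
#' * `analytical_sigma_high` — replicate s.d. for high-solubility samples
#'   (>= 100 uM); quantification far from the detection limit is more
#'   precise. The s.d. interpolates linearly in log-concentration between
#'   10 and 100 uM.
#' * `cond_sigma`, `gross_prob`, `gross_sigma` — a per-(compound, pH)
#'   "condition" error shared by replicates of the same sample: benign
#'   N(0, `cond_sigma`) variation with probability `1 - gross_prob`, a
#'   gross N(0, `gross_sigma`) discrepancy (solid-form change,
#'   degradation, handling error) otherwise. Duplicates of one sample
#'   agree to replicate noise, yet the pH 2/pH 7 pair of a compound can
#'   disagree grossly — which is what the 3-fold quality check exists to
#'   catch, and why it removes far more compounds than replicate noise
#'   alone would explain.
#' * `amorphous_shift_mean`, `amorphous_shift_sd` — a positive log10 shift
#'   (Normal truncated at 0) added when the residual solid is amorphous;
#'   amorphicity increases apparent solubility, a one-sided bias.
#' * `pred_logd_sigma` — s.d. of predicted log D error, one value per assay
#'   pH (2.6, 7.4, 10.5); defaults match an RMSE of 0.17/0.15/0.15.
#' * `measured_logd_sigma` — small zero-mean error of chromatographic log D.
#' * `frac_measured_logd` — fraction of compounds with measured triplets.
#' * `frac_duplicates` — fraction of compound x pH measurements run twice.
#' * `frac_no_residue` — fraction of measurements with no solid residue
#'   recovered (these cannot be solid-state verified and are later removed).
#' * `censor_limits` — assay dynamic range in uM; readings outside it are
#'   reported only as "<" / ">" bounds.
#'
#' @param analytical_sigma,analytical_sigma_high log10 units, >= 0.
#' @param cond_sigma,gross_sigma log10 units, >= 0.
#' @param gross_prob probability of a gross condition error.
#' @param amorphous_shift_mean,amorphous_shift_sd log10 units; mean must be
#'   > 0 (the bias is one-sided positive).
#' @param pred_logd_sigma length 1 or 3, recycled to (pH 2.6, 7.4, 10.5).
#' @param measured_logd_sigma log10 units, >= 0.
#' @param frac_measured_logd,frac_duplicates,frac_no_residue probabilities.
#' @param censor_limits length-2 numeric, uM, increasing.
#' @return an object of class `noise_config` (a named list).
#' @examples
#' noise_config()
#' noise_config(analytical_sigma = 0)  # noiseless assay
#' @export
noise_config <- function(analytical_sigma = calibrate_analytical_sigma(),
                         analytical_sigma_high = 0.18,
                         cond_sigma = 0.2,
                         gross_prob = 0.3,
                         gross_sigma = 1.5,
                         amorphous_shift_mean = 0.7,
                         amorphous_shift_sd = 0.25,
                         pred_logd_sigma = c(0.17, 0.15, 0.15),
                         measured_logd_sigma = 0.05,
                         frac_measured_logd = 0.65,
                         frac_duplicates = 0.10,
                         frac_no_residue = 0.05,
                         censor_limits = c(0.1, 600)) {
  pred_logd_sigma <- rep_len(pred_logd_sigma, 3L)
  cfg <- list(
    analytical_sigma = analytical_sigma,
    analytical_sigma_high = analytical_sigma_high,
    cond_sigma = cond_sigma,
    gross_prob = gross_prob,
    gross_sigma = gross_sigma,
    amorphous_shift_mean = amorphous_shift_mean,
    amorphous_shift_sd = amorphous_shift_sd,
    pred_logd_sigma = pred_logd_sigma,
    measured_logd_sigma = measured_logd_sigma,
    frac_measured_logd = frac_measured_logd,
    frac_duplicates = frac_duplicates,
    frac_no_residue = frac_no_residue,
    censor_limits = censor_limits
  )
  validate_noise_config(cfg)
  structure(cfg, class = "noise_config")
}

validate_noise_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(analytical_sigma) || analytical_sigma < 0 ||
        analytical_sigma_high < 0)
      stop("analytical sigmas must be >= 0", call. = FALSE)
    if (cond_sigma < 0 || gross_sigma < 0)
      stop("condition-error sigmas must be >= 0", call. = FALSE)
    if (gross_prob < 0 || gross_prob > 1)
      stop("gross_prob must lie in [0, 1]", call. = FALSE)
    if (amorphous_shift_mean <= 0)
      stop("amorphous_shift_mean must be > 0 (one-sided positive bias)",
           call. = FALSE)
    if (amorphous_shift_sd < 0) stop("amorphous_shift_sd must be >= 0", call. = FALSE)
    if (any(pred_logd_sigma < 0) || measured_logd_sigma < 0)
      stop("log D sigmas must be >= 0", call. = FALSE)
    probs <- c(frac_measured_logd, frac_duplicates, frac_no_residue)
    if (any(probs < 0 | probs > 1))
      stop("fractions must lie in [0, 1]", call. = FALSE)
    if (length(censor_limits) != 2L || censor_limits[1] <= 0 ||
        diff(censor_limits) <= 0)
      stop("censor_limits must be two increasing positive values (uM)",
           call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.noise_config <- function(x, ...) {
  cat("<noise_config>\n")
  cat(sprintf("  analytical sigma      : %.4f (low) / %.2f (high solubility)\n",
              x$analytical_sigma, x$analytical_sigma_high))
  cat(sprintf("  condition error       : %.2f benign / %.2f gross (p = %.2f)\n",
              x$cond_sigma, x$gross_sigma, x$gross_prob))
  cat(sprintf("  amorphous shift       : +%.2f (sd %.2f) log10 units\n",
              x$amorphous_shift_mean, x$amorphous_shift_sd))
  cat(sprintf("  predicted logD sigma  : %s (pH 2.6/7.4/10.5)\n",
              paste(format(x$pred_logd_sigma), collapse = "/")))
  cat(sprintf("  measured logD sigma   : %.3f; measured fraction %.2f\n",
              x$measured_logd_sigma, x$frac_measured_logd))
  cat(sprintf("  duplicates %.2f; no-residue %.2f; range %g-%g uM\n",
              x$frac_duplicates, x$frac_no_residue,
              x$censor_limits[1], x$censor_limits[2]))
  invisible(x)
}
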