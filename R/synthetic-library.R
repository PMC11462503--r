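# Synthetic discovery-solubility library ------------------------------------
#
# Ground truth is a monoprotic compound: ionization class (acid/base/neutral),
# pKa, logP, intrinsic solubility S0 (log10 mol/L) and a latent feature
# vector that carries the learnable structure-property signal. The assay
# simulator then produces what a high-throughput solubility platform would
# report: apparent solubility at pH 2 and pH 7 in uM, censored to the
# 0.1-600 uM dynamic range, with analytical noise, amorphous solid-state
# bias, occasional missing residue and duplicate measurements.

# per-term variances of the latent signal g(z); constants are the analytic
# Var of each term under z ~ N(0,1): Var(sin(1.5 z)) = (1 - exp(-4.5))/2,
# Var(tanh(z)) ~ 0.39429 (high-precision quadrature, frozen)
.signal_terms <- list(
  list(fn = function(z) z,             w = 1.0, v = 1.0),
  list(fn = function(z) z,             w = 0.8, v = 0.64),
  list(fn = function(z) sin(1.5 * z),  w = 0.6, v = 0.36 * 0.4944455),
  list(fn = function(z) tanh(z),       w = 0.4, v = 0.16 * 0.3942919)
)

# smooth structure-property signal: weighted sum over the first <=4 latent
# dims, rescaled analytically to unit variance (no data-dependent scaling,
# so the mapping is identical at any n)
latent_signal <- function(latent) {
  k <- ncol(latent)
  terms <- .signal_terms[seq_len(min(4L, k))]
  g <- numeric(nrow(latent))
  for (i in seq_along(terms))
    g <- g + terms[[i]]$w * terms[[i]]$fn(latent[, i])
  g / sqrt(sum(vapply(terms, function(t) t$v, 0)))
}

#' Sample ground-truth compounds
#'
#' Draws a synthetic compound library. Intrinsic solubility in log10 mol/L
#' is a fixed smooth function of an i.i.d. standard-normal latent vector
#' plus a Gaussian residual, centred and scaled so the uM distribution is
#' right-skewed with the configured majority of compounds below 100 uM
#' (defaults give ~70% in (0, 100] uM, within the 60-75% band typical of
#' discovery libraries).
#'
#' Ionizable compounds are monoprotic. pKa values are drawn from two
#' sub-populations per class: acids from carboxylic-like (3.5-5.5) or
#' phenol-like (9.3-10.4) ranges, bases from weakly basic heteroaromatic
#' (3.2-4.2) or aliphatic-amine (8.5-10.5) ranges, with configurable weak
#' sub-population fractions (drug-like bases are predominantly aliphatic
#' or alicyclic amines, hence the smaller default weak fraction for
#' bases). Only the weak sub-populations are neutral at an assay pH and
#' therefore survive the log D extraction step; the strong ones are
#' realistically excluded.
#'
#' @param n number of compounds (>= 1).
#' @param k latent dimension (>= 2).
#' @param mix length-3 probability vector (acid, base, neutral); must sum
#'   to 1.
#' @param seed integer seed; draws are deterministic given `(args, seed)`.
#' @param s0_mean,signal_sd,resid_sd location and scale of intrinsic log S:
#'   `s0 = s0_mean + signal_sd * g(latent) + N(0, resid_sd)` with g
#'   standardized.
#' @param acid_weak_frac,base_weak_frac fraction of each ionizable class
#'   drawn from its weak (assay-pH-neutral) sub-population.
#' @param frac_salt,frac_stereoisomer fractions flagged as salt forms /
#'   stereoisomers (the assay cannot resolve these; curation drops them).
#' @param amorphous_prob either `NULL` (per-compound Beta(2, 3.7) draw,
#'   mean 0.35) or a value in \[0, 1\] recycled to all compounds.
#' @return tibble with one row per compound: `compound_id`, `ion_class`,
#'   `pKa` (NA for neutral), `logP`, `s0_log_molar`, `is_salt`,
#'   `is_stereoisomer`, `amorphous_prob`, and a `latent` matrix column.
#' @examples
#' cmp <- sample_compound_truths(100, seed = 1)
#' mean(log_s_to_uM(cmp$s0_log_molar) <= 100)
#' @export
sample_compound_truths <- function(n, k = 8L,
                                   mix = c(acid = 0.25, base = 0.45, neutral = 0.30),
                                   seed = 1L,
                                   s0_mean = -4.6, signal_sd = 0.95,
                                   resid_sd = 0.30,
                                   acid_weak_frac = 0.5, base_weak_frac = 0.35,
                                   frac_salt = 0.03, frac_stereoisomer = 0.02,
                                   amorphous_prob = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (k < 2) stop("latent dimension k must be >= 2", call. = FALSE)
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix must be 3 non-negative probabilities summing to 1", call. = FALSE)
  if (!is.null(amorphous_prob) &&
      any(amorphous_prob < 0 | amorphous_prob > 1))
    stop("amorphous_prob must lie in [0, 1]", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    latent <- matrix(rnorm(n * k), nrow = n, ncol = k)
    classes <- sample(c("acid", "base", "neutral"), n, replace = TRUE,
                      prob = mix)
    # weak sub-population = neutral at one assay pH (retained downstream)
    u_weak <- runif(n)
    pKa <- rep(NA_real_, n)
    ai <- classes == "acid"
    bi <- classes == "base"
    pKa[ai] <- ifelse(u_weak[ai] < acid_weak_frac,
                      runif(sum(ai), 9.3, 10.4), runif(sum(ai), 3.5, 5.5))
    pKa[bi] <- ifelse(u_weak[bi] < base_weak_frac,
                      runif(sum(bi), 3.2, 4.2), runif(sum(bi), 8.5, 10.5))
    s0 <- s0_mean + signal_sd * latent_signal(latent) + rnorm(n, 0, resid_sd)
    amo <- if (is.null(amorphous_prob)) rbeta(n, 2, 3.7)
           else rep_len(amorphous_prob, n)
    out <- tibble::tibble(
      compound_id = sprintf("CPD%06d", seq_len(n)),
      ion_class = factor(classes, levels = c("acid", "base", "neutral")),
      pKa = pKa,
      logP = rnorm(n, 2.5, 1.2),
      s0_log_molar = s0,
      is_salt = runif(n) < frac_salt,
      is_stereoisomer = runif(n) < frac_stereoisomer,
      amorphous_prob = amo
    )
    out$latent <- latent
    out
  })
}

#' Henderson-Hasselbalch log D curve for a monoprotic compound
#'
#' log D equals log P where the compound is uncharged and decreases as the
#' ionized fraction grows: for an acid by `log10(1 + 10^(pH - pKa))`, for a
#' base by `log10(1 + 10^(pKa - pH))`; a neutral compound has log D = log P
#' at every pH.
#'
#' @param logP partition coefficient of the neutral species.
#' @param ion_class `"acid"`, `"base"` or `"neutral"` (vectorized).
#' @param pKa dissociation constant; required unless neutral.
#' @param pH measurement pH.
#' @return log D, dimensionless; vectorized over the inputs.
#' @examples
#' logd_curve(3, "acid", 4, 4)        # logP - log10(2)
#' logd_curve(2, "neutral", NA, 7.4)  # 2
#' @export
logd_curve <- function(logP, ion_class, pKa, pH) {
  ion_class <- as.character(ion_class)
  if (any(ion_class != "neutral" & is.na(pKa)))
    stop("pKa required for ionizable compounds", call. = FALSE)
  penalty <- ifelse(ion_class == "acid", log1p(10^(pH - pKa)) / log(10),
             ifelse(ion_class == "base", log1p(10^(pKa - pH)) / log(10), 0))
  logP - penalty
}

#' pH-dependent apparent solubility of a monoprotic compound
#'
#' Ionization adds the charged species to the dissolved pool, so apparent
#' solubility is never below the intrinsic value S0: for an acid
#' `S(pH) = S0 + log10(1 + 10^(pH - pKa))` (log10 molar), mirrored for a
#' base; a neutral compound shows no pH dependence.
#'
#' @param s0_log_molar intrinsic solubility, log10 mol/L.
#' @inheritParams logd_curve
#' @return apparent solubility, log10 mol/L; always `>= s0_log_molar`.
#' @examples
#' ph_solubility(-5, "acid", 4, 4)  # -5 + log10(2)
#' @export
ph_solubility <- function(s0_log_molar, ion_class, pKa, pH) {
  ion_class <- as.character(ion_class)
  if (any(ion_class != "neutral" & is.na(pKa)))
    stop("pKa required for ionizable compounds", call. = FALSE)
  boost <- ifelse(ion_class == "acid", log1p(10^(pH - pKa)) / log(10),
           ifelse(ion_class == "base", log1p(10^(pKa - pH)) / log(10), 0))
  s0_log_molar + boost
}

# positive truncated-normal draw via inverse CDF (truncation at 0)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Simulate the high-throughput solubility assay
#'
#' For every compound and each of pH 2 and pH 7, computes the true
#' pH-dependent solubility, then applies in order: (i) solid-state
#' assignment — the residual solid is amorphous with the compound's
#' `amorphous_prob` (one draw per compound: amorphicity is a property of
#' the molecule's crystallization behaviour, shared by its pH 2 and pH 7
#' samples), and independently each measurement reports no residue with
#' probability `frac_no_residue`; (ii) a positive amorphous shift
#' (truncated Normal, log10 units) per amorphous record; (iii) a
#' per-(compound, pH) condition error shared by replicates of that sample
#' — benign N(0, `cond_sigma`), or gross N(0, `gross_sigma`) with
#' probability `gross_prob`; (iv) additive heteroscedastic replicate noise
#' — s.d. `analytical_sigma` up to 10 uM, falling linearly in
#' log-concentration to `analytical_sigma_high` at 100 uM and above;
#' (v) dynamic-range censoring — readings outside `censor_limits` become
#' qualifier-only records carrying the bound. A fraction
#' `frac_duplicates` of compound x pH measurements is run in duplicate
#' with independent replicate noise (the condition error belongs to the
#' sample, so duplicates share it: duplicate pairs agree to replicate
#' noise while a compound's pH 2/pH 7 pair can disagree grossly).
#'
#' @param truths compound tibble from [sample_compound_truths()].
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @return tibble of assay records: `compound_id`, `pH` (2 or 7),
#'   `solubility_uM` (NA when censored), `qualifier` (`none`,
#'   `below_range`, `above_range`), `solid_state`, `replicate`.
#' @examples
#' cmp <- sample_compound_truths(50, seed = 1, amorphous_prob = 0)
#' a <- simulate_assay(cmp, noise_config(analytical_sigma = 0), seed = 2)
#' @export
simulate_assay <- function(truths, noise = noise_config(), seed = 1L) {
  stopifnot(nrow(truths) >= 1)
  validate_noise_config(noise)

  withr::with_seed(as.integer(seed), {
    cmp <- truths[c("compound_id", "ion_class", "pKa", "s0_log_molar",
                    "amorphous_prob")]
    cmp$is_amorphous <- runif(nrow(cmp)) < cmp$amorphous_prob
    base <- tidyr::expand_grid(cmp, pH = c(2, 7))
    m <- nrow(base)
    no_res <- runif(m) < noise$frac_no_residue
    base$solid_state <- factor(
      ifelse(no_res, "no_residue",
             ifelse(base$is_amorphous, "amorphous", "crystalline")),
      levels = c("crystalline", "amorphous", "no_residue")
    )
    is_gross <- runif(m) < noise$gross_prob
    base$cond_err <- rnorm(m, 0, ifelse(is_gross, noise$gross_sigma,
                                        noise$cond_sigma))
    base$n_rep <- 1L + as.integer(runif(m) < noise$frac_duplicates)
    rec <- tidyr::uncount(base, weights = .data$n_rep, .id = "replicate")
    true_log <- ph_solubility(rec$s0_log_molar, rec$ion_class, rec$pKa, rec$pH)
    shift <- numeric(nrow(rec))
    ia <- rec$solid_state == "amorphous"
    shift[ia] <- rtruncnorm_pos(sum(ia), noise$amorphous_shift_mean,
                                noise$amorphous_shift_sd)
    # replicate noise shrinks with concentration: interpolate sigma in
    # log10 uM between the 10 uM (low) and 100 uM (high) anchors
    w <- pmin(1, pmax(0, (true_log + shift + rec$cond_err + 6) - 1))
    rep_sigma <- noise$analytical_sigma * (1 - w) +
      noise$analytical_sigma_high * w
    obs_log <- true_log + shift + rec$cond_err +
      rnorm(nrow(rec), 0, rep_sigma)
    uM <- log_s_to_uM(obs_log)
    qualifier <- factor(
      ifelse(uM < noise$censor_limits[1], "below_range",
      ifelse(uM > noise$censor_limits[2], "above_range", "none")),
      levels = c("none", "below_range", "above_range")
    )
    tibble::tibble(
      compound_id = rec$compound_id,
      pH = rec$pH,
      solubility_uM = ifelse(qualifier == "none", uM, NA_real_),
      qualifier = qualifier,
      solid_state = rec$solid_state,
      replicate = as.integer(rec$replicate)
    )
  })
}

#' Simulate measured and predicted log D triplets
#'
#' True log D at pH 2.6, 7.4 and 10.5 follows [logd_curve()].
#' Chromatographically measured triplets exist for a `frac_measured_logd`
#' subset (small zero-mean error, s.d. `measured_logd_sigma`); predicted
#' triplets exist for every compound with per-pH error s.d.
#' `pred_logd_sigma`, emulating an in-silico log D model with RMSE ~
#' 0.15-0.17 against measurement.
#'
#' @inheritParams simulate_assay
#' @return list with tibbles `measured` and `predicted`, columns
#'   `compound_id`, `source`, `d26`, `d74`, `d105`.
#' @export
simulate_logd <- function(truths, noise = noise_config(), seed = 1L) {
  stopifnot(nrow(truths) >= 1)
  validate_noise_config(noise)
  ph <- c(2.6, 7.4, 10.5)
  true_d <- vapply(ph, function(p)
    logd_curve(truths$logP, truths$ion_class, truths$pKa, p),
    numeric(nrow(truths)))

  withr::with_seed(as.integer(seed), {
    n <- nrow(truths)
    pred_err <- vapply(1:3, function(j) rnorm(n, 0, noise$pred_logd_sigma[j]),
                       numeric(n))
    predicted <- tibble::tibble(
      compound_id = truths$compound_id,
      source = "predicted",
      d26 = true_d[, 1] + pred_err[, 1],
      d74 = true_d[, 2] + pred_err[, 2],
      d105 = true_d[, 3] + pred_err[, 3]
    )
    has_meas <- runif(n) < noise$frac_measured_logd
    meas_err <- vapply(1:3, function(j) rnorm(n, 0, noise$measured_logd_sigma),
                       numeric(n))
    measured <- tibble::tibble(
      compound_id = truths$compound_id,
      source = "measured",
      d26 = true_d[, 1] + meas_err[, 1],
      d74 = true_d[, 2] + meas_err[, 2],
      d105 = true_d[, 3] + meas_err[, 3]
    )[has_meas, ]
    list(measured = measured, predicted = predicted)
  })
}

#' Simulate a molecular descriptor matrix
#'
#' Stands in for a computed descriptor set. The observed columns are noisy
#' views of the latent structure vector: the first `k` columns copy the
#' latent dimensions, further columns are nonlinear transforms of random
#' latent projections or pure noise, and `redundancy` extra columns are
#' near-duplicates of earlier signal columns planted to exercise the
#' correlation filter (pairwise Pearson > 0.9 by construction).
#'
#' @param truths compound tibble with a `latent` matrix column.
#' @param p number of base descriptor columns, `p >= k`.
#' @param redundancy number of planted near-duplicate columns (appended, so
#'   the matrix has `p + redundancy` columns).
#' @param noise_sd s.d. of additive descriptor noise.
#' @param seed integer seed.
#' @return tibble keyed by `compound_id` with `p + redundancy` numeric
#'   descriptor columns named `d001`, `d002`, ... (duplicates `*_r`).
#' @export
simulate_descriptors <- function(truths, p = 24L, redundancy = 4L,
                                 noise_sd = 0.1, seed = 1L) {
  latent <- truths$latent
  stopifnot(!is.null(latent), is.matrix(latent))
  k <- ncol(latent)
  if (p < k) stop("p must be >= latent dimension k", call. = FALSE)
  if (redundancy < 0) stop("redundancy must be >= 0", call. = FALSE)
  n <- nrow(latent)

  withr::with_seed(as.integer(seed), {
    X <- matrix(0, n, p)
    X[, seq_len(k)] <- latent
    extra <- p - k
    if (extra > 0) {
      n_trans <- ceiling(extra / 2)
      for (j in seq_len(extra)) {
        if (j <= n_trans) {
          w <- rnorm(k)
          proj <- drop(latent %*% (w / sqrt(sum(w^2))))
          X[, k + j] <- if (j %% 2 == 0) tanh(proj) else sin(proj)
        } else {
          X[, k + j] <- rnorm(n)  # pure-noise descriptor
        }
      }
    }
    X <- X + matrix(rnorm(n * p, 0, noise_sd), n, p)
    colnames(X) <- sprintf("d%03d", seq_len(p))
    if (redundancy > 0) {
      n_signal <- k + if (extra > 0) ceiling(extra / 2) else 0L
      src <- sample(seq_len(n_signal), redundancy,
                    replace = redundancy > n_signal)
      dup <- vapply(src, function(j)
        X[, j] + rnorm(n, 0, 0.2 * max(sd(X[, j]), 1e-12)), numeric(n))
      colnames(dup) <- sprintf("%s_r", colnames(X)[src])
      colnames(dup) <- make.unique(colnames(dup), sep = "")
      X <- cbind(X, dup)
    }
    out <- tibble::as_tibble(X)
    out <- dplyr::bind_cols(
      tibble::tibble(compound_id = truths$compound_id), out)
    out
  })
}

#' Simulate a complete discovery-solubility library
#'
#' Convenience wrapper: samples ground-truth compounds, runs the assay at
#' pH 2 and pH 7, generates measured/predicted log D triplets and a
#' descriptor matrix, all from one seed (expanded deterministically into
#' per-stage seeds).
#'
#' @inheritParams sample_compound_truths
#' @inheritParams simulate_descriptors
#' @param noise a [noise_config()].
#' @param ... passed on to [sample_compound_truths()].
#' @return object of class `solubility_library`: list with `compounds`,
#'   `assay`, `logd` (list of `measured`/`predicted`), `descriptors`,
#'   `noise`, `seed`.
#' @examples
#' lib <- simulate_library(200, seed = 7)
#' lib
#' @export
simulate_library <- function(n, k = 8L,
                             mix = c(acid = 0.25, base = 0.45, neutral = 0.30),
                             noise = noise_config(), seed = 1L,
                             p = 24L, redundancy = 4L, noise_sd = 0.1, ...) {
  seeds <- derive_seeds(seed, 4L)
  compounds <- sample_compound_truths(n, k = k, mix = mix, seed = seeds[1], ...)
  structure(list(
    compounds = compounds,
    assay = simulate_assay(compounds, noise, seed = seeds[2]),
    logd = simulate_logd(compounds, noise, seed = seeds[3]),
    descriptors = simulate_descriptors(compounds, p = p,
                                       redundancy = redundancy,
                                       noise_sd = noise_sd, seed = seeds[4]),
    noise = noise,
    seed = as.integer(seed)
  ), class = "solubility_library")
}

#' @export
print.solubility_library <- function(x, ...) {
  cat("<solubility_library>\n")
  cat(sprintf("  %d compounds, %d assay records (pH 2/7), %d measured logD triplets\n",
              nrow(x$compounds), nrow(x$assay), nrow(x$logd$measured)))
  cat(sprintf("  %d descriptor columns; seed %d\n",
              ncol(x$descriptors) - 1L, x$seed))
  invisible(x)
}
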