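# End-to-end workflow, configuration and persistence -------------------------

#' Pipeline run configuration
#'
#' One object fully determines every output of [run_pipeline()]: library
#' size and noise, the six dataset presets (fixed), model, evaluation
#' parameters and a single global seed (expanded deterministically into
#' per-stage seeds, so stages can be re-run in isolation).
#'
#' @param n library size (number of compounds).
#' @param k latent dimension.
#' @param mix ionization class mix (acid, base, neutral).
#' @param noise a [noise_config()].
#' @param model a [model_spec()].
#' @param outer,inner nested-CV fold counts.
#' @param n_test_sets,test_frac repeated clean-test-set parameters.
#' @param decorrelate_threshold descriptor |Pearson| ceiling (`NULL`
#'   disables the filter).
#' @param seed global integer seed.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   persists builds, metrics and a hashed JSON manifest there.
#' @param ... passed to [sample_compound_truths()] (e.g.
#'   `amorphous_prob`).
#' @return object of class `run_config`.
#' @export
run_config <- function(n = 5000L, k = 8L,
                       mix = c(acid = 0.25, base = 0.45, neutral = 0.30),
                       noise = noise_config(), model = model_spec(),
                       outer = 10L, inner = 5L,
                       n_test_sets = 10L, test_frac = 0.2,
                       decorrelate_threshold = 0.9,
                       seed = 1L, out_dir = NULL, ...) {
  validate_noise_config(noise)
  stopifnot(inherits(model, "model_spec"), n >= 1, outer >= 2, inner >= 2,
            n_test_sets >= 1, test_frac > 0, test_frac < 1)
  structure(list(n = as.integer(n), k = as.integer(k), mix = mix,
                 noise = noise, model = model,
                 outer = as.integer(outer), inner = as.integer(inner),
                 n_test_sets = as.integer(n_test_sets),
                 test_frac = test_frac,
                 decorrelate_threshold = decorrelate_threshold,
                 seed = as.integer(seed), out_dir = out_dir,
                 truth_args = list(...)),
            class = "run_config")
}

#' Run the complete pipeline
#'
#' simulate -> curate into six dataset variants -> summarize -> nested CV
#' on Clean -> repeated clean-test-set experiment over all variants ->
#' ANOVA/Tukey comparison -> bias analyses. When `config$out_dir` is set,
#' intermediates are written as CSV and a JSON manifest records the
#' configuration, per-stage counts and an MD5 hash of every artifact
#' (identical config + seed reproduces identical hashes).
#'
#' @param config a [run_config()].
#' @return object of class `solubility_run`: `library`, `builds`,
#'   `dataset_summary`, `nested` (nested-CV result on Clean), `refined`
#'   (refined-test result), `comparison` (ANOVA/Tukey), `bias` (per-model
#'   bin profiles for Clean/Noisy/Clean_ac), `amorphous` (bias check),
#'   `manifest`.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(n = 400, outer = 2, inner = 2,
#'                                n_test_sets = 2, seed = 1))
#' run$refined$summary
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 4L)

  lib <- do.call(simulate_library,
                 c(list(n = config$n, k = config$k, mix = config$mix,
                        noise = config$noise, seed = seeds[1]),
                   config$truth_args))
  builds <- build_datasets(lib, seed = seeds[2])
  dataset_summary <- summarize_datasets(builds)

  prep <- prepare_features(builds$Clean, threshold = NULL)
  nested <- nested_cv(prep$X, prep$y, config$model,
                      outer = config$outer, inner = config$inner,
                      threshold = config$decorrelate_threshold,
                      seed = seeds[3])
  refined <- refined_test_experiment(builds, config$model,
                                     n_test_sets = config$n_test_sets,
                                     test_frac = config$test_frac,
                                     threshold = config$decorrelate_threshold,
                                     seed = seeds[4])
  comparison <- compare_rmse(refined$metrics)

  bias <- lapply(intersect(c("Clean", "Noisy", "Clean_ac"), names(builds)),
                 function(nm) {
                   p <- dplyr::filter(refined$predictions, .data$dataset == nm)
                   bias_analysis(p$y_true, p$y_pred)
                 })
  names(bias) <- intersect(c("Clean", "Noisy", "Clean_ac"), names(builds))
  amorphous <- amorphous_bias_check(
    dplyr::filter(refined$predictions, .data$dataset == "Clean"),
    dplyr::filter(refined$predictions, .data$dataset == "Clean_ac"))

  run <- structure(list(library = lib, builds = builds,
                        dataset_summary = dataset_summary,
                        nested = nested, refined = refined,
                        comparison = comparison, bias = bias,
                        amorphous = amorphous, config = config,
                        manifest = NULL),
                   class = "solubility_run")
  if (!is.null(config$out_dir)) run$manifest <- write_run(run, config$out_dir)
  run
}

#' @export
print.solubility_run <- function(x, ...) {
  cat("<solubility_run>\n")
  cat(sprintf("  library: %d compounds (seed %d)\n", x$config$n,
              x$config$seed))
  print(x$dataset_summary[, c("name", "n", "mean_log_s", "frac_amorphous")],
        n = Inf)
  cat(sprintf("  nested CV on Clean: RMSE %.3f (%.3f)\n",
              x$nested$summary$rmse_mean, x$nested$summary$rmse_sd))
  cat(sprintf("  ANOVA over test-set RMSE: p = %.3g\n", x$comparison$anova_p))
  cat(sprintf("  amorphous positive bias: %s (over %d vs under %d)\n",
              x$amorphous$positive_bias, x$amorphous$over_ac,
              x$amorphous$under_ac))
  invisible(x)
}

# ---- persistence ------------------------------------------------------------

#' Write an assay table to CSV, serializing censored records as bounds
#'
#' Censored records are written with their dynamic-range bound prefixed by
#' `<` or `>` in the `solubility` column, the format a discovery database
#' export would use; [read_assay_csv()] parses them back.
#'
#' @param assay assay record tibble.
#' @param path output CSV path.
#' @param censor_limits assay bounds in uM used for censored rows.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(assay, path, censor_limits = c(0.1, 600)) {
  out <- assay
  out$solubility <- dplyr::case_when(
    out$qualifier == "below_range" ~ paste0("<", format(censor_limits[1])),
    out$qualifier == "above_range" ~ paste0(">", format(censor_limits[2])),
    TRUE ~ format(out$solubility_uM, digits = 17, trim = TRUE,
                  scientific = FALSE)
  )
  out <- out[c("compound_id", "pH", "solubility", "solid_state", "replicate")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an assay table written by [write_assay_csv()] or a compatible
#' export
#'
#' @param path CSV with columns `compound_id`, `pH`, `solubility`
#'   (numeric, or `<`/`>`-prefixed bound), `solid_state`, `replicate`.
#' @return assay record tibble in the package schema (uM solubility,
#'   `qualifier` factor).
#' @export
read_assay_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    pH = readr::col_double(),
    solubility = readr::col_character(),
    solid_state = readr::col_character(),
    replicate = readr::col_integer()
  ))
  s <- trimws(raw$solubility)
  qualifier <- factor(
    ifelse(startsWith(s, "<"), "below_range",
    ifelse(startsWith(s, ">"), "above_range", "none")),
    levels = c("none", "below_range", "above_range"))
  value <- suppressWarnings(as.numeric(sub("^[<>]", "", s)))
  bad <- is.na(value) & !is.na(s)
  if (any(bad))
    stop("unparseable solubility value(s) at row(s): ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  tibble::tibble(
    compound_id = raw$compound_id,
    pH = raw$pH,
    solubility_uM = ifelse(qualifier == "none", value, NA_real_),
    qualifier = qualifier,
    solid_state = factor(raw$solid_state,
                         levels = c("crystalline", "amorphous", "no_residue")),
    replicate = raw$replicate
  )
}

#' Ingest an external wide-format solubility CSV
#'
#' Real-data entry point. Expected columns (units documented): \describe{
#'   \item{compound_id}{identifier (required)}
#'   \item{smiles}{optional, carried through}
#'   \item{solubility_pH2, solubility_pH7}{uM; numeric or `<`/`>`-prefixed
#'     bound strings for out-of-range readings}
#'   \item{solid_state_pH2, solid_state_pH7}{`crystalline`, `amorphous` or
#'     `no_residue` (optional; default `crystalline`)}
#'   \item{is_salt, is_stereoisomer}{optional logical flags}
#'   \item{logd_pH2.6, logd_pH7.4, logd_pH10.5}{dimensionless log D}
#' }
#'
#' @param path CSV path.
#' @return list with `assay` (long record tibble), `triplets` (log D
#'   tibble), `compounds` (flags tibble) and `missingness` (per-column NA
#'   counts).
#' @export
ingest_external <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!"compound_id" %in% names(raw))
    stop("external CSV must have a compound_id column", call. = FALSE)

  parse_sol <- function(s) {
    s <- trimws(s)
    qualifier <- ifelse(is.na(s), NA_character_,
                 ifelse(startsWith(s, "<"), "below_range",
                 ifelse(startsWith(s, ">"), "above_range", "none")))
    value <- suppressWarnings(as.numeric(sub("^[<>]", "", s)))
    bad <- which(!is.na(s) & is.na(value))
    if (length(bad) > 0)
      stop("unparseable solubility at row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    list(value = ifelse(qualifier == "none", value, NA_real_),
         qualifier = qualifier)
  }
  get_state <- function(col) {
    if (col %in% names(raw)) raw[[col]] else rep("crystalline", nrow(raw))
  }
  assay <- purrr::map_dfr(c(2, 7), function(ph) {
    sol <- parse_sol(raw[[sprintf("solubility_pH%d", ph)]])
    tibble::tibble(
      compound_id = raw$compound_id, pH = ph,
      solubility_uM = sol$value,
      qualifier = factor(sol$qualifier,
                         levels = c("none", "below_range", "above_range")),
      solid_state = factor(get_state(sprintf("solid_state_pH%d", ph)),
                           levels = c("crystalline", "amorphous",
                                      "no_residue")),
      replicate = 1L
    )
  })
  assay <- assay[!is.na(assay$qualifier), , drop = FALSE]

  num <- function(col) if (col %in% names(raw))
    suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, nrow(raw))
  triplets <- tibble::tibble(
    compound_id = raw$compound_id, source = "measured",
    d26 = num("logd_pH2.6"), d74 = num("logd_pH7.4"), d105 = num("logd_pH10.5"))
  triplets <- triplets[complete.cases(triplets[c("d26", "d74", "d105")]), ]

  lgl <- function(col) if (col %in% names(raw))
    !is.na(raw[[col]]) & tolower(raw[[col]]) %in% c("true", "1", "yes")
    else rep(FALSE, nrow(raw))
  compounds <- tibble::tibble(
    compound_id = raw$compound_id,
    smiles = if ("smiles" %in% names(raw)) raw$smiles else NA_character_,
    is_salt = lgl("is_salt"), is_stereoisomer = lgl("is_stereoisomer"))

  list(assay = assay, triplets = triplets, compounds = compounds,
       missingness = vapply(raw, function(x) sum(is.na(x)), 0L))
}

# write the run's artifacts and return a manifest (config + counts + hashes)
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  p <- file.path(dir, "assay.csv")
  write_assay_csv(run$library$assay, p,
                  censor_limits = run$config$noise$censor_limits)
  paths <- c(paths, p)
  for (nm in names(run$builds)) {
    p <- file.path(dir, sprintf("dataset_%s.csv", nm))
    d <- run$builds[[nm]]$data
    readr::write_csv(d[setdiff(names(d), "latent")], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "dataset_summary.csv")
  readr::write_csv(run$dataset_summary, p)
  paths <- c(paths, p)
  p <- file.path(dir, "nested_cv_metrics.csv")
  readr::write_csv(run$nested$per_fold, p)
  paths <- c(paths, p)
  p <- file.path(dir, "test_set_metrics.csv")
  readr::write_csv(run$refined$metrics, p)
  paths <- c(paths, p)
  p <- file.path(dir, "tukey.csv")
  readr::write_csv(run$comparison$tukey, p)
  paths <- c(paths, p)

  manifest <- list(
    config = list(n = run$config$n, k = run$config$k,
                  seed = run$config$seed,
                  analytical_sigma = run$config$noise$analytical_sigma,
                  algorithm = run$config$model$algorithm),
    counts = lapply(run$builds, function(b) nrow(b$data)),
    anova_p = run$comparison$anova_p,
    amorphous_positive_bias = run$amorphous$positive_bias,
    files = setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
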