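# Six dataset variants -------------------------------------------------------
#
# Each variant toggles one curation choice against the reference build:
#   Clean       exclude amorphous, measured log D, QC on   (most refined)
#   Pred_logD   exclude amorphous, predicted log D, QC on
#   Noisy       exclude amorphous, measured log D, QC off
#   Noisy_small Noisy subsampled to |Clean| (size-matched noise)
#   Clean_ac    include amorphous, measured log D, QC on
#   Noisy_ac    include amorphous, measured log D, QC off  (largest)

dataset_names <- c("Clean", "Pred_logD", "Noisy", "Noisy_small",
                   "Clean_ac", "Noisy_ac")

#' Dataset variant specification
#'
#' @param name one of `Clean`, `Pred_logD`, `Noisy`, `Noisy_small`,
#'   `Clean_ac`, `Noisy_ac`. The preset mapping of curation toggles is
#'   fixed (see Details) and cannot be overridden — variants are defined
#'   by their toggles.
#' @param subsample_to target size for `Noisy_small` (normally supplied by
#'   [build_datasets()] as the size of the Clean build).
#' @param seed seed for the `Noisy_small` subsample.
#' @details Preset toggles:
#'
#' | name        | amorphous | log D     | quality check | subsample |
#' |-------------|-----------|-----------|---------------|-----------|
#' | Clean       | exclude   | measured  | on            | --        |
#' | Pred_logD   | exclude   | predicted | on            | --        |
#' | Noisy       | exclude   | measured  | off           | --        |
#' | Noisy_small | exclude   | measured  | off           | to |Clean| |
#' | Clean_ac    | include   | measured  | on            | --        |
#' | Noisy_ac    | include   | measured  | off           | --        |
#'
#' `Pred_logD` substitutes predicted triplets for *all* compounds, keeping
#' the substitution experiment clean.
#' @return object of class `dataset_spec`.
#' @examples
#' dataset_spec("Noisy")
#' @export
dataset_spec <- function(name, subsample_to = NULL, seed = 1L) {
  name <- match.arg(name, dataset_names)
  presets <- list(
    Clean       = list(include_amorphous = FALSE, logd_source = "measured",
                       quality_check = TRUE),
    Pred_logD   = list(include_amorphous = FALSE, logd_source = "predicted",
                       quality_check = TRUE),
    Noisy       = list(include_amorphous = FALSE, logd_source = "measured",
                       quality_check = FALSE),
    Noisy_small = list(include_amorphous = FALSE, logd_source = "measured",
                       quality_check = FALSE),
    Clean_ac    = list(include_amorphous = TRUE, logd_source = "measured",
                       quality_check = TRUE),
    Noisy_ac    = list(include_amorphous = TRUE, logd_source = "measured",
                       quality_check = FALSE)
  )
  structure(c(list(name = name), presets[[name]],
              list(subsample_to = subsample_to, seed = as.integer(seed))),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf("<dataset_spec> %s: amorphous %s, logD %s, QC %s%s\n",
              x$name,
              if (x$include_amorphous) "included" else "excluded",
              x$logd_source,
              if (x$quality_check) "on" else "off",
              if (!is.null(x$subsample_to))
                sprintf(", subsampled to %d", x$subsample_to) else ""))
  invisible(x)
}

#' Build one curated dataset variant
#'
#' Applies the curation workflow with the spec's toggles to a simulated
#' (or ingested) library and joins the curated intrinsic records with the
#' descriptor matrix on `compound_id`. For `Noisy_small` the full Noisy
#' build is subsampled uniformly at random (seeded) to `spec$subsample_to`
#' rows — uniform sampling preserves the noise composition in expectation.
#'
#' @param library a `solubility_library` (or a list with the same
#'   `compounds`, `assay`, `logd`, `descriptors` elements).
#' @param spec a [dataset_spec()].
#' @return list of class `dataset_build`: `name`, `spec`, `data` (tibble of
#'   intrinsic records + descriptor columns), `report` (curation counts).
#' @examples
#' lib <- simulate_library(300, seed = 3)
#' b <- build_dataset(lib, dataset_spec("Clean"))
#' nrow(b$data)
#' @export
build_dataset <- function(library, spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  triplets <- library$logd[[spec$logd_source]]
  cur <- curate(library$assay, library$compounds, triplets,
                include_amorphous = spec$include_amorphous,
                logd_source = spec$logd_source,
                run_quality_check = spec$quality_check)
  data <- dplyr::inner_join(cur$records, library$descriptors,
                            by = "compound_id")
  if (!is.null(spec$subsample_to)) {
    if (spec$subsample_to > nrow(data))
      stop(sprintf("cannot subsample %d rows from %d", spec$subsample_to,
                   nrow(data)), call. = FALSE)
    data <- withr::with_seed(spec$seed,
                             dplyr::slice_sample(data, n = spec$subsample_to))
  }
  structure(list(name = spec$name, spec = spec, data = data,
                 report = cur$report),
            class = "dataset_build")
}

#' @export
print.dataset_build <- function(x, ...) {
  cat(sprintf("<dataset_build> %s: %d compounds\n", x$name, nrow(x$data)))
  invisible(x)
}

#' Build all six dataset variants
#'
#' Builds `Clean` first (its size defines the `Noisy_small` target), then
#' the remaining five variants.
#'
#' @param library a `solubility_library`.
#' @param seed seed for the `Noisy_small` subsample.
#' @return named list of six `dataset_build` objects.
#' @examples
#' lib <- simulate_library(400, seed = 5)
#' builds <- build_datasets(lib)
#' sapply(builds, function(b) nrow(b$data))
#' @export
build_datasets <- function(library, seed = 1L) {
  builds <- list()
  builds$Clean <- build_dataset(library, dataset_spec("Clean"))
  for (nm in c("Pred_logD", "Noisy", "Clean_ac", "Noisy_ac"))
    builds[[nm]] <- build_dataset(library, dataset_spec(nm))
  builds$Noisy_small <- build_dataset(
    library, dataset_spec("Noisy_small",
                          subsample_to = nrow(builds$Clean$data),
                          seed = seed))
  builds[dataset_names]
}

#' Summarize dataset builds
#'
#' One row per build: size, intrinsic log S distribution statistics and
#' the fraction of records whose assigned measurement came from an
#' amorphous residue.
#'
#' @param builds list of `dataset_build` objects (at least one).
#' @return tibble with columns `name`, `n`, `min_log_s`, `median_log_s`,
#'   `mean_log_s`, `max_log_s`, `sd_log_s`, `frac_amorphous`.
#' @export
summarize_datasets <- function(builds) {
  stopifnot(length(builds) >= 1)
  purrr::map_dfr(builds, function(b) {
    d <- b$data
    if (nrow(d) == 0) {
      return(tibble::tibble(name = b$name, n = 0L, min_log_s = NA_real_,
                            median_log_s = NA_real_, mean_log_s = NA_real_,
                            max_log_s = NA_real_, sd_log_s = NA_real_,
                            frac_amorphous = NA_real_))
    }
    tibble::tibble(
      name = b$name,
      n = nrow(d),
      min_log_s = min(d$intrinsic_log_s),
      median_log_s = stats::median(d$intrinsic_log_s),
      mean_log_s = mean(d$intrinsic_log_s),
      max_log_s = max(d$intrinsic_log_s),
      sd_log_s = sd(d$intrinsic_log_s),
      frac_amorphous = mean(d$solid_state_used == "amorphous")
    )
  })
}
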