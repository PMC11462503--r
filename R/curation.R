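# Three-step curation workflow ----------------------------------------------
#
# 1. filter_records():   remove records that cannot carry a crystalline
#                        intrinsic measurement (no residue, amorphous unless
#                        requested, out-of-range qualifiers, salts,
#                        stereoisomers).
# 2. extract_intrinsic(): use the log D triplet at pH 2.6/7.4/10.5 to find
#                        the pH at which the compound is neutral, and take
#                        the solubility measured there as intrinsic.
# 3. quality_check():    drop compounds whose paired pH 2/pH 7 solubilities
#                        contradict their ionization assignment by more than
#                        3-fold.

#' Filter assay records ahead of intrinsic-solubility extraction
#'
#' Removes, in a single pass: records with no solid residue (solid state
#' unverifiable); amorphous-residue records unless `include_amorphous`;
#' records censored outside the assay dynamic range (reported only as
#' "<"/">" bounds); and all records of compounds flagged as salt forms or
#' stereoisomers. The rules are a pure conjunction, so ordering does not
#' affect the survivors; per-rule counts report how many records each rule
#' alone would remove (a record can fall under several rules).
#'
#' @param assay assay record tibble (see [simulate_assay()]).
#' @param compounds compound tibble carrying `is_salt` and
#'   `is_stereoisomer` flags; records of unknown compounds are kept.
#' @param include_amorphous keep amorphous-residue records? Default `FALSE`.
#' @return list with `records` (the surviving tibble) and `removed`, a
#'   named integer vector of per-rule counts plus `total` (distinct records
#'   removed).
#' @examples
#' cmp <- sample_compound_truths(20, seed = 1)
#' a <- simulate_assay(cmp, seed = 2)
#' filter_records(a, cmp)$removed
#' @export
filter_records <- function(assay, compounds, include_amorphous = FALSE) {
  required <- c("compound_id", "pH", "solubility_uM", "qualifier",
                "solid_state", "replicate")
  missing_cols <- setdiff(required, names(assay))
  if (length(missing_cols) > 0)
    stop("assay table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  flags <- compounds[c("compound_id", "is_salt", "is_stereoisomer")]
  x <- dplyr::left_join(assay, flags, by = "compound_id")
  x$is_salt[is.na(x$is_salt)] <- FALSE
  x$is_stereoisomer[is.na(x$is_stereoisomer)] <- FALSE

  drop_no_residue <- x$solid_state == "no_residue"
  drop_amorphous <- !include_amorphous & x$solid_state == "amorphous"
  drop_qualifier <- x$qualifier != "none"
  drop_salt <- x$is_salt
  drop_stereo <- x$is_stereoisomer
  drop_any <- drop_no_residue | drop_amorphous | drop_qualifier |
    drop_salt | drop_stereo

  list(
    records = assay[!drop_any, , drop = FALSE],
    removed = c(
      no_residue = sum(drop_no_residue),
      amorphous = sum(drop_amorphous),
      qualifier = sum(drop_qualifier),
      salt = sum(drop_salt),
      stereoisomer = sum(drop_stereo),
      total = sum(drop_any)
    )
  )
}

#' Classify ionization state from a log D triplet
#'
#' log D is maximal where a compound is uncharged, so the triplet at pH
#' 2.6, 7.4 and 10.5 locates the neutral window. Rules, applied in order:
#'
#' 1. **neutral** if the spread `max(d) - min(d)` is below `neutral_tol`
#'    (uncharged across pH 2.6-10.5);
#' 2. **intrinsic_pH2** if the maximum is *not* at pH 10.5 and
#'    `|d26 - d74| < intrinsic_tol` (uncharged at low pH — the pH 2
#'    measurement is intrinsic);
#' 3. **intrinsic_pH7** if the maximum is *not* at pH 2.6 and
#'    `|d74 - d105| < intrinsic_tol` (uncharged at neutral-to-high pH);
#' 4. otherwise **excluded** (e.g. amphoteric or strongly ionized across
#'    the window).
#'
#' "Maximum at a pH" means strictly greater than both other values; a tie
#' does not count as evidence for exclusion. All comparisons are strict.
#' The classification depends only on differences, so adding a constant to
#' all three values never changes it.
#'
#' @param d26,d74,d105 log D at pH 2.6, 7.4, 10.5 (vectorized, no NAs).
#' @param neutral_tol spread below which the compound is neutral
#'   throughout (default 0.5).
#' @param intrinsic_tol pairwise tolerance for the one-sided rules
#'   (default 0.25).
#' @return factor with levels `neutral`, `intrinsic_pH2`, `intrinsic_pH7`,
#'   `excluded`.
#' @examples
#' classify_ionization(2, 2, 2)          # neutral
#' classify_ionization(3, 2.9, 1)        # intrinsic_pH2
#' classify_ionization(0, 2, 2.1)        # intrinsic_pH7
#' classify_ionization(0, 1, 2.1)        # excluded
#' @export
classify_ionization <- function(d26, d74, d105,
                                neutral_tol = 0.5, intrinsic_tol = 0.25) {
  n <- length(d26)
  stopifnot(length(d74) == n, length(d105) == n)
  if (anyNA(d26) || anyNA(d74) || anyNA(d105))
    stop("log D triplet components must all be present", call. = FALSE)

  spread <- pmax(d26, d74, d105) - pmin(d26, d74, d105)
  max_at_105 <- d105 > d26 & d105 > d74   # strict: tie is not evidence
  max_at_26 <- d26 > d74 & d26 > d105

  cls <- ifelse(spread < neutral_tol, "neutral",
         ifelse(!max_at_105 & abs(d26 - d74) < intrinsic_tol, "intrinsic_pH2",
         ifelse(!max_at_26 & abs(d74 - d105) < intrinsic_tol, "intrinsic_pH7",
                "excluded")))
  factor(cls, levels = c("neutral", "intrinsic_pH2", "intrinsic_pH7",
                         "excluded"))
}

# replicate-averaged (log10-mean) solubility per compound x pH, wide form
pair_ph_solubility <- function(records) {
  records %>%
    dplyr::filter(.data$qualifier == "none") %>%
    dplyr::group_by(.data$compound_id, .data$pH) %>%
    dplyr::summarise(
      log_uM = mean(log10(.data$solubility_uM)),
      any_amorphous = any(.data$solid_state == "amorphous"),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "pH", values_from = c("log_uM", "any_amorphous"),
                       names_prefix = "pH") %>%
    ensure_pair_cols()
}

ensure_pair_cols <- function(wide) {
  for (col in c("log_uM_pH2", "log_uM_pH7"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  for (col in c("any_amorphous_pH2", "any_amorphous_pH7"))
    if (!col %in% names(wide)) wide[[col]] <- NA
  wide
}

#' Extract intrinsic solubility from filtered assay records
#'
#' Replicates are first averaged in log10 space per compound and pH. Each
#' compound is classified from its log D triplet ([classify_ionization()]);
#' the intrinsic value is the pH 2 measurement for `intrinsic_pH2`, the
#' pH 7 measurement for `intrinsic_pH7`, and the geometric mean of the two
#' (equivalently the mean in log10 space) for `neutral` compounds, whose
#' solubility is theoretically pH-independent. Values are converted from
#' uM to log10 mol/L. Compounds without a triplet from the requested
#' source, classified `excluded`, or lacking a surviving record at their
#' assigned pH are dropped with logged counts.
#'
#' @param records filtered assay tibble (output `records` of
#'   [filter_records()]).
#' @param triplets log D triplet tibble (`compound_id`, `d26`, `d74`,
#'   `d105`), e.g. one element of [simulate_logd()]'s output.
#' @param logd_source label recorded on each output row (`"measured"` or
#'   `"predicted"`); purely provenance, the data come from `triplets`.
#' @param neutral_tol,intrinsic_tol passed to [classify_ionization()].
#' @return list with `records` — tibble of pre-QC intrinsic records
#'   (`compound_id`, `intrinsic_log_s`, `assignment`, `logd_source`,
#'   `solid_state_used`, plus paired `s2_uM`/`s7_uM` used later by the
#'   quality check) — and `dropped`, named counts (`no_triplet`,
#'   `excluded_class`, `missing_assigned_ph`).
#' @export
extract_intrinsic <- function(records, triplets, logd_source = "measured",
                              neutral_tol = 0.5, intrinsic_tol = 0.25) {
  if (nrow(records) == 0) {
    return(list(records = empty_intrinsic_tbl(),
                dropped = c(no_triplet = 0L, excluded_class = 0L,
                            missing_assigned_ph = 0L)))
  }
  wide <- pair_ph_solubility(records)

  n_no_triplet <- sum(!wide$compound_id %in% triplets$compound_id)
  x <- dplyr::inner_join(wide, triplets[c("compound_id", "d26", "d74", "d105")],
                         by = "compound_id")
  x$assignment <- classify_ionization(x$d26, x$d74, x$d105,
                                      neutral_tol, intrinsic_tol)
  n_excluded <- sum(x$assignment == "excluded")
  x <- x[x$assignment != "excluded", , drop = FALSE]

  # intrinsic value in log10 uM at the assigned pH
  log_uM <- dplyr::case_when(
    x$assignment == "intrinsic_pH2" ~ x$log_uM_pH2,
    x$assignment == "intrinsic_pH7" ~ x$log_uM_pH7,
    TRUE ~ dplyr::coalesce((x$log_uM_pH2 + x$log_uM_pH7) / 2,
                           x$log_uM_pH2, x$log_uM_pH7)
  )
  used_amorphous <- dplyr::case_when(
    x$assignment == "intrinsic_pH2" ~ x$any_amorphous_pH2,
    x$assignment == "intrinsic_pH7" ~ x$any_amorphous_pH7,
    TRUE ~ dplyr::coalesce(x$any_amorphous_pH2, FALSE) |
           dplyr::coalesce(x$any_amorphous_pH7, FALSE)
  )
  keep <- !is.na(log_uM)
  n_missing_ph <- sum(!keep)

  out <- tibble::tibble(
    compound_id = x$compound_id[keep],
    intrinsic_log_s = log_uM[keep] - 6,   # uM -> log10 mol/L
    assignment = factor(as.character(x$assignment[keep]),
                        levels = c("neutral", "intrinsic_pH2", "intrinsic_pH7")),
    logd_source = logd_source,
    solid_state_used = factor(
      ifelse(dplyr::coalesce(used_amorphous[keep], FALSE),
             "amorphous", "crystalline"),
      levels = c("crystalline", "amorphous")),
    s2_uM = 10^x$log_uM_pH2[keep],
    s7_uM = 10^x$log_uM_pH7[keep]
  )
  list(records = out,
       dropped = c(no_triplet = n_no_triplet,
                   excluded_class = n_excluded,
                   missing_assigned_ph = n_missing_ph))
}

empty_intrinsic_tbl <- function() {
  tibble::tibble(
    compound_id = character(),
    intrinsic_log_s = numeric(),
    assignment = factor(character(),
                        levels = c("neutral", "intrinsic_pH2", "intrinsic_pH7")),
    logd_source = character(),
    solid_state_used = factor(character(),
                              levels = c("crystalline", "amorphous")),
    s2_uM = numeric(),
    s7_uM = numeric(),
    qc_passed = logical()
  )
}

#' Quality-check intrinsic records against their paired pH measurements
#'
#' A neutral compound should dissolve identically at pH 2 and pH 7, so a
#' pair differing by more than `fold` (strictly) is discarded. An
#' `intrinsic_pH7` compound (a base, more soluble at low pH) is discarded
#' when its pH 2 solubility is more than `fold` *less* than at pH 7 — the
#' wrong direction for a base; symmetrically for `intrinsic_pH2`. Ratios
#' are taken on the linear uM scale. Records missing the partner pH skip
#' the check (`qc_passed = NA`) and are kept, with a logged count.
#'
#' @param records pre-QC intrinsic tibble from [extract_intrinsic()] (must
#'   carry `s2_uM` and `s7_uM`).
#' @param fold linear fold-difference threshold (default 3).
#' @return list with `records` (failures removed, `qc_passed` column set)
#'   and `dropped`, named counts (`neutral_inconsistent`,
#'   `ph7_contradicted`, `ph2_contradicted`, `skipped_missing_pair`).
#' @examples
#' # a neutral pair exactly 3-fold apart is kept (strictly greater fails)
#' r <- tibble::tibble(compound_id = "a", intrinsic_log_s = -5,
#'                     assignment = factor("neutral",
#'                       levels = c("neutral", "intrinsic_pH2", "intrinsic_pH7")),
#'                     logd_source = "measured",
#'                     solid_state_used = factor("crystalline",
#'                       levels = c("crystalline", "amorphous")),
#'                     s2_uM = 10, s7_uM = 30)
#' quality_check(r)$records$qc_passed
#' @export
quality_check <- function(records, fold = 3) {
  if (nrow(records) == 0) {
    out <- records
    out$qc_passed <- logical(0)
    return(list(records = out,
                dropped = c(neutral_inconsistent = 0L, ph7_contradicted = 0L,
                            ph2_contradicted = 0L, skipped_missing_pair = 0L)))
  }
  s2 <- records$s2_uM
  s7 <- records$s7_uM
  if (any(s2 <= 0 | s7 <= 0, na.rm = TRUE))
    stop("solubilities must be positive", call. = FALSE)
  have_pair <- !is.na(s2) & !is.na(s7)

  ratio <- pmax(s2, s7) / pmin(s2, s7)
  fail_neutral <- have_pair & records$assignment == "neutral" & ratio > fold
  fail_ph7 <- have_pair & records$assignment == "intrinsic_pH7" &
    s2 < s7 / fold
  fail_ph2 <- have_pair & records$assignment == "intrinsic_pH2" &
    s7 < s2 / fold
  fail <- fail_neutral | fail_ph7 | fail_ph2

  out <- records
  out$qc_passed <- ifelse(have_pair, !fail, NA)
  out <- out[!fail, , drop = FALSE]
  list(records = out,
       dropped = c(neutral_inconsistent = sum(fail_neutral),
                   ph7_contradicted = sum(fail_ph7),
                   ph2_contradicted = sum(fail_ph2),
                   skipped_missing_pair = sum(!have_pair)))
}

#' Run the full three-step curation workflow
#'
#' Convenience wrapper chaining [filter_records()], [extract_intrinsic()]
#' and (optionally) [quality_check()], collecting per-rule removal counts
#' into a curation report.
#'
#' @param assay assay record tibble.
#' @param compounds compound tibble (for salt/stereoisomer flags).
#' @param triplets log D triplet tibble.
#' @param include_amorphous keep amorphous-residue records?
#' @param logd_source provenance label for the triplets used.
#' @param run_quality_check apply the 3-fold consistency check?
#' @param fold quality-check fold threshold.
#' @return list with `records` (curated intrinsic tibble) and `report`
#'   (nested list of removal counts per stage).
#' @examples
#' lib <- simulate_library(300, seed = 3)
#' cur <- curate(lib$assay, lib$compounds, lib$logd$measured)
#' cur$report
#' @export
curate <- function(assay, compounds, triplets,
                   include_amorphous = FALSE, logd_source = "measured",
                   run_quality_check = TRUE, fold = 3) {
  filt <- filter_records(assay, compounds, include_amorphous)
  extr <- extract_intrinsic(filt$records, triplets, logd_source)
  if (run_quality_check) {
    qc <- quality_check(extr$records, fold = fold)
  } else {
    recs <- extr$records
    recs$qc_passed <- NA
    qc <- list(records = recs, dropped = c(quality_check = "off"))
  }
  list(
    records = qc$records,
    report = list(
      filtering = as.list(filt$removed),
      extraction = as.list(extr$dropped),
      quality_check = as.list(qc$dropped),
      n_curated = nrow(qc$records)
    )
  )
}
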