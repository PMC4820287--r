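# The deterministic classification cascade: case Types 1-3, four exclusion
# rules, and the control definition, applied in a fixed priority order.
#
# Rule order (first match wins):
#   1. any phenocopy diagnosis                     -> EXCLUDED / PHENOCOPY
#   2. age at reference date outside [min, max]    -> EXCLUDED / AGE
#   3. earliest AAA evidence at age <= min_age     -> EXCLUDED / AAA_ONSET_AT_OR_UNDER_MIN_AGE
#   4. any AAA-repair procedure                    -> CASE type 1
#   5. ruptured-AAA dx at a specialty clinic       -> CASE type 2
#   6. >= 2 distinct specialty AAA-dx dates        -> CASE type 3
#   7. any remaining 441.* diagnosis               -> EXCLUDED / UNCONFIRMED_AAA_CODE
#   8. latest event beyond the lookback window     -> EXCLUDED / NO_RECENT_ENCOUNTER
#   9. otherwise                                   -> CONTROL
#
# Phenocopies and out-of-age subjects are removed before case typing; the
# unconfirmed-code and recency filters apply only to would-be controls.

EXCLUSION_REASONS <- c("PHENOCOPY", "AGE", "AAA_ONSET_AT_OR_UNDER_MIN_AGE",
                       "UNCONFIRMED_AAA_CODE", "NO_RECENT_ENCOUNTER")

DAYS_PER_YEAR <- 365.25

#' Engine configuration
#'
#' @param specialty_clinics Character vector of clinic names counted as
#'   specialty clinics for case Types 2 and 3 (compared after trimming and
#'   case-folding). Site-specific: vascular surgery at the primary site;
#'   elsewhere possibly cardiology or interventional radiology.
#' @param min_age,max_age Inclusive age bounds at the reference date
#'   (defaults 40 and 89: subjects younger than 40 or older than 89 are
#'   excluded). `min_age` doubles as the onset bound: any subject whose
#'   earliest AAA evidence occurred at or under this age is excluded.
#' @param lookback_years Encounter-recency window in years (default 5): a
#'   would-be control whose latest event is older than this is excluded.
#' @param reference_date A `Date`, an ISO date string, or `"auto"` (default):
#'   the anchor for age and recency. `"auto"` resolves to the latest event
#'   date in the data.
#' @param min_type3_dates Minimum number of distinct specialty-clinic AAA
#'   diagnosis dates for a Type 3 case (default 2).
#' @param require_specialty_type2 Whether a Type 2 ruptured-AAA encounter must
#'   be at a specialty clinic (default TRUE).
#' @param registry A `code_set_registry` ([default_registry()] by default).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(specialty_clinics = "vascular surgery",
                          min_age = 40L, max_age = 89L,
                          lookback_years = 5, reference_date = "auto",
                          min_type3_dates = 2L,
                          require_specialty_type2 = TRUE,
                          registry = default_registry()) {
  min_age <- as.integer(min_age); max_age <- as.integer(max_age)
  stopifnot(min_age < max_age, lookback_years > 0, min_type3_dates >= 2L)
  if (!identical(reference_date, "auto")) {
    reference_date <- as.Date(reference_date)
    if (is.na(reference_date)) stop("unparseable reference_date", call. = FALSE)
  }
  if (!inherits(registry, "code_set_registry")) {
    stop("registry must be a code_set_registry", call. = FALSE)
  }
  structure(list(
    specialty_clinics = normalize_clinic(specialty_clinics),
    min_age = min_age, max_age = max_age,
    lookback_years = as.numeric(lookback_years),
    reference_date = reference_date,
    min_type3_dates = as.integer(min_type3_dates),
    require_specialty_type2 = isTRUE(require_specialty_type2),
    registry = registry
  ), class = "engine_config")
}

#' Resolve the reference date for age and recency rules
#'
#' The source algorithm evaluated "within the past 5 years" relative to its
#' execution time; for reproducibility this package anchors both the age and
#' the recency rule to an explicit reference date, defaulting to the latest
#' event date observed in either stream.
#'
#' @param dx,px Diagnosis and procedure event tibbles.
#' @param config An [engine_config()].
#' @return A `Date`.
#' @export
resolve_reference_date <- function(dx, px, config) {
  if (!identical(config$reference_date, "auto")) return(config$reference_date)
  dates <- c(dx$event_date, px$event_date)
  if (length(dates) == 0L) {
    stop("reference_date = 'auto' requires at least one event", call. = FALSE)
  }
  max(dates)
}

specialty_hit <- function(clinics, config) {
  normalize_clinic(clinics) %in% config$specialty_clinics
}

#' Case Type 1: AAA repair procedure
#'
#' @param px Procedure events of one subject.
#' @param registry A `code_set_registry`.
#' @return A list with `hit` (logical) and `evidence` (the triggering rows).
#' @export
is_type1 <- function(px, registry) {
  hit <- matches_any(px$cpt_code, registry$aaa_repair_px$members)
  list(hit = any(hit), evidence = px[hit, , drop = FALSE])
}

#' Case Type 2: ruptured-AAA diagnosis at a specialty clinic
#'
#' @param dx Diagnosis events of one subject.
#' @param registry A `code_set_registry`.
#' @param config An [engine_config()].
#' @return A list with `hit` and `evidence`.
#' @export
is_type2 <- function(dx, registry, config) {
  hit <- matches_any(dx$icd9_code, registry$aaa_ruptured_dx$members)
  if (config$require_specialty_type2) {
    hit <- hit & specialty_hit(dx$clinic, config)
  }
  list(hit = any(hit), evidence = dx[hit, , drop = FALSE])
}

#' Case Type 3: AAA diagnoses on distinct dates at specialty clinics
#'
#' True when the subject carries an AAA diagnosis code at a configured
#' specialty clinic on at least `min_type3_dates` distinct calendar dates.
#' Repeat codes on the same day count once: the rule requires codes assigned
#' on different visits, so a confirmed diagnosis is distinguished from a
#' single working or referral diagnosis.
#'
#' @inheritParams is_type2
#' @return A list with `hit`, `evidence`, and `n_distinct_dates`.
#' @export
is_type3 <- function(dx, registry, config) {
  hit <- matches_any(dx$icd9_code, registry$aaa_dx$members) &
    specialty_hit(dx$clinic, config)
  ev <- dx[hit, , drop = FALSE]
  n_dates <- length(unique(ev$event_date))
  list(hit = n_dates >= config$min_type3_dates, evidence = ev,
       n_distinct_dates = n_dates)
}

# Age at the reference date, reconstructed from the subject's latest event:
# its recorded age plus whole elapsed years. The input contract carries
# age-at-event, not birth date. NA when the subject has no events.
age_at_reference <- function(dx, px, reference_date) {
  dates <- c(dx$event_date, px$event_date)
  if (length(dates) == 0L) return(NA_integer_)
  ages <- c(dx$age_at_event, px$age_at_event)
  latest <- max(dates)
  at_latest <- ages[dates == latest]
  age_latest <- max(at_latest)
  elapsed <- floor(as.numeric(reference_date - latest) / DAYS_PER_YEAR)
  as.integer(age_latest + elapsed)
}

#' Classify one subject through the rule cascade
#'
#' Applies the rules in the fixed priority order documented for
#' `classify_cohort()` and stops at the first match.
#'
#' @param subject_id Subject identifier.
#' @param dx,px This subject's diagnosis and procedure events.
#' @param config An [engine_config()].
#' @param reference_date Resolved reference `Date`.
#' @return A list (class `classification`) with `subject_id`, `label`
#'   (`"CASE"`, `"CONTROL"` or `"EXCLUDED"`), `case_type` (1, 2, 3 or `NA`),
#'   `exclusion_reason` (or `NA`), and `evidence` (tibble of triggering
#'   events, with a `stream` column).
#' @export
classify_subject <- function(subject_id, dx, px, config, reference_date) {
  reg <- config$registry
  result <- function(label, case_type = NA_integer_,
                     reason = NA_character_, evidence = NULL) {
    structure(list(subject_id = subject_id, label = label,
                   case_type = case_type, exclusion_reason = reason,
                   evidence = evidence), class = "classification")
  }
  dx_ev <- function(rows) {
    if (nrow(rows) > 0L) rows$stream <- "dx"
    rows
  }
  px_ev <- function(rows) {
    if (nrow(rows) > 0L) rows$stream <- "px"
    rows
  }

  # 1. phenocopy: rare heritable disorders with aortic manifestation,
  #    thoracic aneurysms, dissections
  pheno <- matches_any(dx$icd9_code, reg$phenocopy_exclusion_dx$members)
  if (any(pheno)) {
    return(result("EXCLUDED", reason = "PHENOCOPY",
                  evidence = dx_ev(dx[pheno, , drop = FALSE])))
  }

  # 2. age bounds at the reference date
  age_ref <- age_at_reference(dx, px, reference_date)
  if (!is.na(age_ref) && (age_ref < config$min_age || age_ref > config$max_age)) {
    return(result("EXCLUDED", reason = "AGE"))
  }

  # 3. AAA onset at or under min_age (likely traumatic or unrecognized
  #    syndromic aneurysm)
  aaa_dx_hit <- matches_any(dx$icd9_code, reg$aaa_dx$members)
  repair_hit <- matches_any(px$cpt_code, reg$aaa_repair_px$members)
  aaa_dates <- c(dx$event_date[aaa_dx_hit], px$event_date[repair_hit])
  if (length(aaa_dates) > 0L) {
    aaa_ages <- c(dx$age_at_event[aaa_dx_hit], px$age_at_event[repair_hit])
    first_age <- min(aaa_ages[aaa_dates == min(aaa_dates)])
    if (first_age <= config$min_age) {
      first_dx <- dx[aaa_dx_hit & dx$event_date == min(aaa_dates), , drop = FALSE]
      first_px <- px[repair_hit & px$event_date == min(aaa_dates), , drop = FALSE]
      ev <- dplyr::bind_rows(dx_ev(first_dx), px_ev(first_px))
      return(result("EXCLUDED", reason = "AAA_ONSET_AT_OR_UNDER_MIN_AGE",
                    evidence = ev))
    }
  }

  # 4-6. case types in order of decreasing certainty
  t1 <- is_type1(px, reg)
  if (t1$hit) return(result("CASE", case_type = 1L, evidence = px_ev(t1$evidence)))
  t2 <- is_type2(dx, reg, config)
  if (t2$hit) return(result("CASE", case_type = 2L, evidence = dx_ev(t2$evidence)))
  t3 <- is_type3(dx, reg, config)
  if (t3$hit) return(result("CASE", case_type = 3L, evidence = dx_ev(t3$evidence)))

  # 7. unconfirmed AAA code: any 441.* on record bars control status
  unconf <- matches_any(dx$icd9_code, reg$control_exclusion_dx$members)
  if (any(unconf)) {
    return(result("EXCLUDED", reason = "UNCONFIRMED_AAA_CODE",
                  evidence = dx_ev(dx[unconf, , drop = FALSE])))
  }

  # 8. encounter recency: controls need a visit within the lookback window
  dates <- c(dx$event_date, px$event_date)
  if (length(dates) == 0L ||
      as.numeric(reference_date - max(dates)) >
        config$lookback_years * DAYS_PER_YEAR) {
    return(result("EXCLUDED", reason = "NO_RECENT_ENCOUNTER"))
  }

  # 9. control
  result("CONTROL")
}

#' Classify a whole cohort
#'
#' Runs [classify_subject()] for every subject in the identifier table and
#' assembles the per-subject results and the cohort summary. Events whose
#' subject identifier is not in `subjects` are ignored.
#'
#' @param subjects Tibble with a `subject_id` column (unique, non-empty).
#' @param dx,px Diagnosis and procedure event tibbles.
#' @param config An [engine_config()].
#' @return An object of class `aaa_classification`: a list with
#'   * `results` — tibble of `subject_id`, `label`, `case_type`,
#'     `exclusion_reason`, `n_evidence_events`;
#'   * `evidence` — named list of evidence tibbles per subject;
#'   * `summary` — counts per label, per case type, per exclusion reason;
#'   * `reference_date`, `config`.
#' @export
classify_cohort <- function(subjects, dx, px, config = engine_config()) {
  ids <- as.character(subjects$subject_id)
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  if (length(ids) == 0L) stop("empty subject table", call. = FALSE)
  dx <- dx[dx$subject_id %in% ids, , drop = FALSE]
  px <- px[px$subject_id %in% ids, , drop = FALSE]
  reference_date <- resolve_reference_date(dx, px, config)
  dx_by <- split(seq_len(nrow(dx)), factor(dx$subject_id, levels = ids))
  px_by <- split(seq_len(nrow(px)), factor(px$subject_id, levels = ids))
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    res[[i]] <- classify_subject(
      ids[[i]],
      dx[dx_by[[i]], , drop = FALSE],
      px[px_by[[i]], , drop = FALSE],
      config, reference_date
    )
  }
  n_ev <- vapply(res, function(r) {
    if (is.null(r$evidence)) 0L else nrow(r$evidence)
  }, integer(1))
  results <- tibble::tibble(
    subject_id = ids,
    label = vapply(res, `[[`, character(1), "label"),
    case_type = vapply(res, `[[`, integer(1), "case_type"),
    exclusion_reason = vapply(res, `[[`, character(1), "exclusion_reason"),
    n_evidence_events = n_ev
  )
  evidence <- lapply(res, `[[`, "evidence")
  names(evidence) <- ids
  summary <- list(
    n_subjects = length(ids),
    n_cases = sum(results$label == "CASE"),
    n_controls = sum(results$label == "CONTROL"),
    n_excluded = sum(results$label == "EXCLUDED"),
    by_case_type = as.list(table(factor(results$case_type, levels = 1:3))),
    by_exclusion_reason = as.list(
      table(factor(results$exclusion_reason, levels = EXCLUSION_REASONS))
    )
  )
  stopifnot(summary$n_cases + summary$n_controls + summary$n_excluded ==
              summary$n_subjects)
  structure(list(results = results, evidence = evidence, summary = summary,
                 reference_date = reference_date, config = config),
            class = "aaa_classification")
}

#' @export
print.aaa_classification <- function(x, ...) {
  s <- x$summary
  cat("<aaa_classification> ", s$n_subjects, " subjects (reference date ",
      format(x$reference_date), ")\n", sep = "")
  cat("  cases:    ", s$n_cases, " (type 1: ", s$by_case_type[["1"]],
      ", type 2: ", s$by_case_type[["2"]], ", type 3: ",
      s$by_case_type[["3"]], ")\n", sep = "")
  cat("  controls: ", s$n_controls, "\n", sep = "")
  cat("  excluded: ", s$n_excluded, "\n", sep = "")
  for (r in names(s$by_exclusion_reason)) {
    if (s$by_exclusion_reason[[r]] > 0L) {
      cat("    ", r, ": ", s$by_exclusion_reason[[r]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Case-type distribution table
#'
#' Tabulates classified cases by type with percentages of all cases, as in
#' published multi-site case-type breakdowns.
#'
#' @param x Either an `aaa_classification` (or its `results` tibble), or a
#'   numeric vector of three counts (Types 1, 2, 3).
#' @return A tibble with `case_type` (`"1"`, `"2"`, `"3"`, `"All"`), `count`,
#'   and `percent` (of all cases, rounded to 1 decimal). With zero cases the
#'   `percent` column is `NA` (no division by zero).
#' @examples
#' case_type_distribution(c(295, 16, 388))
#' @export
case_type_distribution <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 3L, all(x >= 0))
    counts <- as.integer(x)
  } else {
    results <- if (inherits(x, "aaa_classification")) x$results else x
    counts <- as.integer(table(factor(results$case_type, levels = 1:3)))
  }
  total <- sum(counts)
  percent <- if (total > 0L) round(100 * counts / total, 1) else
    rep(NA_real_, 3L)
  tibble::tibble(
    case_type = c("1", "2", "3", "All"),
    count = c(counts, total),
    percent = c(percent, if (total > 0L) 100 else NA_real_)
  )
}

#' Write classification outputs
#'
#' Writes the per-subject results CSV and a JSON summary (counts, config echo,
#' reference date).
#'
#' @param classification An `aaa_classification`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_classification <- function(classification, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  results_path <- file.path(dir, "results.csv")
  summary_path <- file.path(dir, "summary.json")
  readr::write_csv(classification$results, results_path)
  cfg <- classification$config
  summary <- c(classification$summary, list(
    reference_date = format(classification$reference_date),
    config = list(
      specialty_clinics = cfg$specialty_clinics,
      min_age = cfg$min_age, max_age = cfg$max_age,
      lookback_years = cfg$lookback_years,
      min_type3_dates = cfg$min_type3_dates,
      require_specialty_type2 = cfg$require_specialty_type2,
      code_sets = lapply(unclass(cfg$registry), function(s) {
        list(system = s$system, members = s$members)
      })
    )
  ))
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results = results_path, summary = summary_path))
}
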