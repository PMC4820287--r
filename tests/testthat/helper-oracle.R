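# Independent oracles, written before and apart from the implementations
# they check.
#
# oracle_classify evaluates all rule predicates unordered with its own
# plain-loop code matching, then applies the documented priority.
# cp_bisect inverts the binomial tail sums by bisection instead of using
# beta quantiles.

oracle_code_in <- function(code, patterns) {
  for (p in patterns) {
    if (endsWith(p, ".*")) {
      stem <- substr(p, 1L, nchar(p) - 2L)
      if (identical(code, stem)) return(TRUE)
      if (startsWith(code, paste0(stem, "."))) {
        suffix <- substring(code, nchar(stem) + 2L)
        if (nchar(suffix) >= 1L && nchar(suffix) <= 2L &&
            grepl("^[0-9]+$", suffix)) return(TRUE)
      }
    } else if (identical(code, p)) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_any_code <- function(codes, patterns) {
  for (cd in codes) if (oracle_code_in(cd, patterns)) return(TRUE)
  FALSE
}

oracle_classify <- function(subject_id, dx, px, config, reference_date) {
  reg <- config$registry
  clinic_ok <- function(cl) {
    tolower(trimws(cl)) %in% config$specialty_clinics
  }

  # every predicate, evaluated unconditionally
  p_phenocopy <- oracle_any_code(dx$icd9_code, reg$phenocopy_exclusion_dx$members)

  dates <- c(dx$event_date, px$event_date)
  ages <- c(dx$age_at_event, px$age_at_event)
  age_ref <- NA_integer_
  if (length(dates) > 0L) {
    latest <- max(dates)
    age_ref <- max(ages[dates == latest]) +
      floor(as.numeric(reference_date - latest) / 365.25)
  }
  p_age <- !is.na(age_ref) && (age_ref < config$min_age || age_ref > config$max_age)

  aaa_flag_dx <- vapply(dx$icd9_code, oracle_code_in, logical(1),
                        patterns = reg$aaa_dx$members)
  rep_flag_px <- vapply(px$cpt_code, oracle_code_in, logical(1),
                        patterns = reg$aaa_repair_px$members)
  ev_dates <- c(dx$event_date[aaa_flag_dx], px$event_date[rep_flag_px])
  ev_ages <- c(dx$age_at_event[aaa_flag_dx], px$age_at_event[rep_flag_px])
  p_onset <- length(ev_dates) > 0L &&
    min(ev_ages[ev_dates == min(ev_dates)]) <= config$min_age

  p_t1 <- any(rep_flag_px)

  rupt_flag <- vapply(dx$icd9_code, oracle_code_in, logical(1),
                      patterns = reg$aaa_ruptured_dx$members)
  spec_flag <- vapply(dx$clinic, clinic_ok, logical(1), USE.NAMES = FALSE)
  if (length(spec_flag) == 0L) spec_flag <- logical(0)
  p_t2 <- if (config$require_specialty_type2) any(rupt_flag & spec_flag)
    else any(rupt_flag)

  t3_dates <- unique(dx$event_date[aaa_flag_dx & spec_flag])
  p_t3 <- length(t3_dates) >= config$min_type3_dates

  p_unconfirmed <- oracle_any_code(dx$icd9_code,
                                   reg$control_exclusion_dx$members)

  p_stale <- length(dates) == 0L ||
    as.numeric(reference_date - max(dates)) > config$lookback_years * 365.25

  # documented priority
  if (p_phenocopy) return(list(label = "EXCLUDED", case_type = NA_integer_,
                               reason = "PHENOCOPY"))
  if (p_age) return(list(label = "EXCLUDED", case_type = NA_integer_,
                         reason = "AGE"))
  if (p_onset) return(list(label = "EXCLUDED", case_type = NA_integer_,
                           reason = "AAA_ONSET_AT_OR_UNDER_MIN_AGE"))
  if (p_t1) return(list(label = "CASE", case_type = 1L, reason = NA_character_))
  if (p_t2) return(list(label = "CASE", case_type = 2L, reason = NA_character_))
  if (p_t3) return(list(label = "CASE", case_type = 3L, reason = NA_character_))
  if (p_unconfirmed) return(list(label = "EXCLUDED", case_type = NA_integer_,
                                 reason = "UNCONFIRMED_AAA_CODE"))
  if (p_stale) return(list(label = "EXCLUDED", case_type = NA_integer_,
                           reason = "NO_RECENT_ENCOUNTER"))
  list(label = "CONTROL", case_type = NA_integer_, reason = NA_character_)
}

# Random raw cohorts for adversarial oracle comparison: codes, clinics,
# dates and ages drawn freely (no archetype structure) so rule interactions
# and boundary ages are exercised.
random_raw_cohort <- function(n_subjects, seed) {
  set.seed(seed)
  dx_codes <- c("441.3", "441.4", "441", "441.2", "441.02", "441.9",
                "759.82", "756.83", "437.5", "447.8",
                "442.4", "401.9", "250.00", "496", "724.2")
  px_codes <- c("34800", "34802", "35081", "35102", "99213", "93000")
  clinics <- c("vascular surgery", "Vascular Surgery ", "family practice",
               "cardiology clinic", "")
  ids <- sprintf("R%04d", seq_len(n_subjects))
  mk_events <- function(id, k, code_pool, code_col) {
    if (k == 0L) return(NULL)
    tb <- tibble::tibble(
      subject_id = id,
      event_date = as.Date("2004-01-01") +
        sample.int(3300L, k, replace = TRUE),
      clinic = sample(clinics, k, replace = TRUE),
      age_at_event = sample(30:95, k, replace = TRUE)
    )
    tb[[code_col]] <- sample(code_pool, k, replace = TRUE)
    tb
  }
  dx <- dplyr::bind_rows(lapply(ids, function(id) {
    mk_events(id, stats::rpois(1L, 3), dx_codes, "icd9_code")
  }))
  px <- dplyr::bind_rows(lapply(ids, function(id) {
    mk_events(id, stats::rpois(1L, 0.7), px_codes, "cpt_code")
  }))
  if (is.null(dx) || nrow(dx) == 0L) {
    dx <- tibble::tibble(subject_id = ids[1],
                         event_date = as.Date("2012-06-01"),
                         clinic = "family practice", age_at_event = 60L,
                         icd9_code = "401.9")
  }
  list(subjects = tibble::tibble(subject_id = ids),
       dx = dx[c("subject_id", "event_date", "icd9_code", "clinic",
                 "age_at_event")],
       px = if (is.null(px) || nrow(px) == 0L) {
         tibble::tibble(subject_id = character(0),
                        event_date = as.Date(character(0)),
                        cpt_code = character(0), clinic = character(0),
                        age_at_event = integer(0))
       } else {
         px[c("subject_id", "event_date", "cpt_code", "clinic",
              "age_at_event")]
       })
}

# Clopper-Pearson by bisecting the binomial tail sums.
cp_bisect <- function(x, n, alpha = 0.05, tol = 1e-9) {
  bisect <- function(f, lo, hi) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) sum(stats::dbinom(x:n, n, p)) - alpha / 2, 0, 1)
  upper <- if (x == n) 1 else
    bisect(function(p) alpha / 2 - sum(stats::dbinom(0:x, n, p)), 0, 1)
  c(lower = lower, upper = upper)
}

# Hand-built six-subject toy cohort: one archetype each of type 1/2/3 case,
# phenocopy, single unconfirmed code, clean control.
toy_cohort <- function() {
  d <- function(x) as.Date(x)
  dx <- tibble::tibble(
    subject_id = c("T3", "T3", "T2", "PH", "PH", "SC", "CC"),
    event_date = d(c("2012-01-05", "2012-06-07", "2012-03-01", "2012-02-01",
                     "2012-02-15", "2012-04-01", "2012-05-01")),
    icd9_code = c("441.4", "441.4", "441.3", "759.82", "441.4", "441.4",
                  "401.9"),
    clinic = c("vascular surgery", "vascular surgery", "vascular surgery",
               "family practice", "vascular surgery", "vascular surgery",
               "family practice"),
    age_at_event = c(70L, 70L, 72L, 60L, 60L, 65L, 55L)
  )
  px <- tibble::tibble(
    subject_id = "T1",
    event_date = d("2012-02-20"),
    cpt_code = "34800",
    clinic = "vascular surgery",
    age_at_event = 68L
  )
  list(subjects = tibble::tibble(subject_id = c("T1", "T2", "T3", "PH",
                                                "SC", "CC")),
       dx = dx, px = px)
}
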