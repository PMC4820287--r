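# Synthetic coded-EHR generator. Each subject is drawn from an archetype
# whose event recipe deterministically triggers exactly one engine rule under
# the default configuration, so the generated ground truth is exact. Ages are
# kept arithmetically consistent with event dates through one latent birth
# date per subject, because the engine reconstructs reference-date age from
# age-at-event fields.

ARCHETYPES <- c("TYPE1_CASE", "TYPE2_CASE", "TYPE3_CASE", "PHENOCOPY",
                "YOUNG_AAA", "SINGLE_CODE_AAA", "NONSPECIALTY_AAA",
                "STALE_RECORD", "CLEAN_CONTROL", "NOISY_CONTROL")

# benign (non-aortic) ICD-9 codes used as encounter filler
BENIGN_DX <- c("401.9", "250.00", "272.4", "414.01", "496", "285.9",
               "530.81", "715.90", "724.2", "780.79", "300.00", "311")

archetype_expectations <- function() {
  tibble::tibble(
    archetype = ARCHETYPES,
    expected_label = c("CASE", "CASE", "CASE", "EXCLUDED", "EXCLUDED",
                       "EXCLUDED", "EXCLUDED", "EXCLUDED", "CONTROL",
                       "CONTROL"),
    expected_case_type = c(1L, 2L, 3L, NA, NA, NA, NA, NA, NA, NA),
    expected_exclusion_reason = c(NA, NA, NA, "PHENOCOPY",
                                  "AAA_ONSET_AT_OR_UNDER_MIN_AGE",
                                  "UNCONFIRMED_AAA_CODE",
                                  "UNCONFIRMED_AAA_CODE",
                                  "NO_RECENT_ENCOUNTER", NA, NA)
  )
}

#' Simulation configuration for the synthetic-EHR generator
#'
#' @param n_subjects Total number of subjects.
#' @param mixture Named vector over archetypes, either exact integer counts
#'   summing to `n_subjects` or proportions summing to 1 (proportions are
#'   rounded to counts with the remainder given to the largest shares).
#'   Default: equal counts over all ten archetypes.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param date_window Length-2 `Date` (or ISO string) vector: events are
#'   drawn inside this window (default 2008-01-01 to 2012-12-31, a five-year
#'   observation window).
#' @param specialty_clinics,other_clinics Clinic-name pools.
#' @param noise_rate Expected number of extraneous benign diagnosis events
#'   per subject (Poisson; default 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 100L,
                       mixture = NULL,
                       seed = 1L,
                       date_window = c("2008-01-01", "2012-12-31"),
                       specialty_clinics = "vascular surgery",
                       other_clinics = c("family practice", "cardiology clinic",
                                         "internal medicine", "urgent care"),
                       noise_rate = 2) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 1L)
  date_window <- as.Date(date_window)
  if (length(date_window) != 2L || anyNA(date_window) ||
      date_window[1] >= date_window[2]) {
    stop("date_window must be two increasing dates", call. = FALSE)
  }
  if (is.null(mixture)) {
    base <- n_subjects %/% length(ARCHETYPES)
    counts <- stats::setNames(rep(base, length(ARCHETYPES)), ARCHETYPES)
    rem <- n_subjects - sum(counts)
    if (rem > 0L) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  } else {
    unknown <- setdiff(names(mixture), ARCHETYPES)
    if (length(unknown) > 0L) {
      stop("unknown archetype(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    counts <- stats::setNames(rep(0, length(ARCHETYPES)), ARCHETYPES)
    counts[names(mixture)] <- mixture
    if (all(counts == floor(counts)) && sum(counts) == n_subjects) {
      counts <- stats::setNames(as.integer(counts), ARCHETYPES)
    } else if (abs(sum(counts) - 1) < 1e-8) {
      raw <- counts * n_subjects
      base <- floor(raw)
      rem <- n_subjects - sum(base)
      if (rem > 0L) {
        top <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[top] <- base[top] + 1
      }
      counts <- stats::setNames(as.integer(base), ARCHETYPES)
    } else {
      stop("mixture must be exact counts summing to n_subjects or ",
           "proportions summing to 1", call. = FALSE)
    }
  }
  structure(list(n_subjects = n_subjects, counts = counts,
                 seed = as.integer(seed), date_window = date_window,
                 specialty_clinics = as.character(specialty_clinics),
                 other_clinics = as.character(other_clinics),
                 noise_rate = as.numeric(noise_rate)),
            class = "sim_config")
}

rand_date <- function(n, from, to) {
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

# age consistent with event dates via the subject's latent birth date
age_on <- function(dates, birth_date) {
  as.integer(floor(as.numeric(dates - birth_date) / DAYS_PER_YEAR))
}

#' Generate a synthetic cohort with ground-truth labels
#'
#' Emits the three coded-EHR streams (subjects, ICD-9 diagnoses, CPT
#' procedures) plus a per-subject truth table. Every archetype's recipe is
#' constructed so the default-configured engine assigns exactly the expected
#' label:
#' * `TYPE1_CASE` — an AAA-repair CPT plus supporting diagnoses;
#' * `TYPE2_CASE` — a ruptured-AAA diagnosis (441.3) at a specialty clinic;
#' * `TYPE3_CASE` — unruptured-AAA diagnoses (441.4) at a specialty clinic on
#'   two or more distinct dates;
#' * `PHENOCOPY` — a heritable-disease/dissection code;
#' * `YOUNG_AAA` — first AAA evidence at age 40 or under;
#' * `SINGLE_CODE_AAA` — a single specialty 441.4 encounter;
#' * `NONSPECIALTY_AAA` — repeated 441.4 but never at a specialty clinic;
#' * `STALE_RECORD` — benign history ending before the lookback window;
#' * `CLEAN_CONTROL` / `NOISY_CONTROL` — benign recent history (the noisy
#'   variant with extra random benign codes).
#'
#' @param config A [sim_config()].
#' @param registry A `code_set_registry` supplying the codes the recipes draw
#'   from (default [default_registry()]).
#' @return A list with tibbles `subjects`, `dx`, `px`, `truth` (columns
#'   `subject_id`, `archetype`, `expected_label`, `expected_case_type`,
#'   `expected_exclusion_reason`, `true_case`) and the `config`.
#' @export
generate_cohort <- function(config = sim_config(),
                            registry = default_registry()) {
  stopifnot(inherits(config, "sim_config"))
  win_start <- config$date_window[1]
  win_end <- config$date_window[2]
  lookback_days <- round(5 * DAYS_PER_YEAR)
  recent_start <- max(win_start, win_end - 365L)
  exp_tab <- archetype_expectations()

  with_local_seed(config$seed, {
    arche <- rep(ARCHETYPES, config$counts)
    n <- length(arche)
    ids <- sprintf("S%05d", seq_len(n))
    dx_list <- vector("list", n)
    px_list <- vector("list", n)
    literal <- function(set) set$members[!endsWith(set$members, ".*")]
    repair_codes <- literal(registry$aaa_repair_px)
    ruptured <- literal(registry$aaa_ruptured_dx)
    unruptured <- literal(registry$aaa_unruptured_dx)
    pheno_codes <- literal(registry$phenocopy_exclusion_dx)
    spec_clinic <- function(k) sample(config$specialty_clinics, k, replace = TRUE)
    other_clinic <- function(k) sample(config$other_clinics, k, replace = TRUE)

    for (i in seq_len(n)) {
      a <- arche[[i]]
      # anchor: age at window end, chosen inside the archetype's window
      anchor_age <- switch(
        a,
        TYPE1_CASE = ,
        TYPE2_CASE = ,
        TYPE3_CASE = sample(55:85, 1L),
        PHENOCOPY = sample(45:80, 1L),
        # YOUNG_AAA: onset at <= 40 must fit in the window while the subject
        # is over 40 at the reference date, so the anchor sits just past 40
        YOUNG_AAA = NA_integer_,  # set in its branch
        STALE_RECORD = sample(50:80, 1L),
        sample(45:85, 1L)
      )
      if (a == "YOUNG_AAA") {
        onset_age <- sample(37:40, 1L)
        gaps <- max(41L - onset_age, 1L):4L
        gap <- gaps[sample.int(length(gaps), 1L)]  # safe when length 1
        anchor_age <- onset_age + gap
      }
      birth <- win_end - round(anchor_age * DAYS_PER_YEAR) -
        sample.int(300L, 1L)
      dx <- px <- NULL
      add_dx <- function(dates, codes, clinics) {
        tibble::tibble(subject_id = ids[[i]], event_date = dates,
                       icd9_code = codes, clinic = clinics,
                       age_at_event = age_on(dates, birth))
      }
      add_px <- function(dates, codes, clinics) {
        tibble::tibble(subject_id = ids[[i]], event_date = dates,
                       cpt_code = codes, clinic = clinics,
                       age_at_event = age_on(dates, birth))
      }
      if (a == "TYPE1_CASE") {
        d_rep <- rand_date(1L, recent_start, win_end)
        px <- add_px(d_rep, sample(repair_codes, 1L), spec_clinic(1L))
        d_dx <- sort(rand_date(2L, recent_start, win_end))
        dx <- add_dx(d_dx, sample(unruptured, 2L, replace = TRUE),
                     spec_clinic(2L))
      } else if (a == "TYPE2_CASE") {
        d <- rand_date(1L, recent_start, win_end)
        dx <- add_dx(d, sample(ruptured, 1L), spec_clinic(1L))
      } else if (a == "TYPE3_CASE") {
        k <- sample(2:4, 1L)
        d <- rand_date(k, recent_start, win_end)
        while (length(unique(d)) < 2L) d <- rand_date(k, recent_start, win_end)
        dx <- add_dx(d, sample(unruptured, k, replace = TRUE), spec_clinic(k))
      } else if (a == "PHENOCOPY") {
        d <- rand_date(2L, recent_start, win_end)
        dx <- add_dx(d, c(sample(pheno_codes, 1L),
                          sample(unruptured, 1L)),
                     c(other_clinic(1L), spec_clinic(1L)))
      } else if (a == "YOUNG_AAA") {
        # first AAA code at age <= 40; a later benign visit carries the
        # subject past 40 at the reference date
        d_onset <- birth + round(onset_age * DAYS_PER_YEAR) + 30L
        d_recent <- rand_date(1L, recent_start, win_end)
        dx <- add_dx(c(d_onset, d_recent),
                     c(sample(unruptured, 1L), sample(BENIGN_DX, 1L)),
                     c(spec_clinic(1L), other_clinic(1L)))
      } else if (a == "SINGLE_CODE_AAA") {
        d_aaa <- rand_date(1L, recent_start, win_end)
        d_ben <- rand_date(1L, recent_start, win_end)
        dx <- add_dx(c(d_aaa, d_ben),
                     c(sample(unruptured, 1L), sample(BENIGN_DX, 1L)),
                     c(spec_clinic(1L), other_clinic(1L)))
      } else if (a == "NONSPECIALTY_AAA") {
        d <- rand_date(3L, recent_start, win_end)
        while (length(unique(d)) < 2L) d <- rand_date(3L, recent_start, win_end)
        dx <- add_dx(d, sample(unruptured, 3L, replace = TRUE),
                     other_clinic(3L))
      } else if (a == "STALE_RECORD") {
        # latest event more than the lookback before the window end
        stale_end <- win_end - lookback_days - 400L
        stale_start <- min(stale_end - 700L, stale_end)
        d <- sort(rand_date(2L, stale_start, stale_end))
        dx <- add_dx(d, sample(BENIGN_DX, 2L, replace = TRUE),
                     other_clinic(2L))
      } else {  # CLEAN_CONTROL, NOISY_CONTROL
        d <- c(rand_date(1L, recent_start, win_end),
               rand_date(2L, win_start, win_end))
        dx <- add_dx(d, sample(BENIGN_DX, 3L, replace = TRUE),
                     other_clinic(3L))
      }
      # extraneous benign noise; never for STALE_RECORD (noise inside the
      # window would defeat the staleness) and never dated after the
      # subject's own span for YOUNG_AAA onset integrity
      if (a %in% c("NOISY_CONTROL") ||
          (config$noise_rate > 0 &&
           a %in% c("TYPE1_CASE", "TYPE2_CASE", "TYPE3_CASE", "PHENOCOPY",
                    "SINGLE_CODE_AAA", "NONSPECIALTY_AAA", "CLEAN_CONTROL",
                    "NOISY_CONTROL"))) {
        k <- stats::rpois(1L, config$noise_rate) +
          if (a == "NOISY_CONTROL") 2L else 0L
        if (k > 0L) {
          d <- rand_date(k, win_start, win_end)
          dx <- dplyr::bind_rows(
            dx, add_dx(d, sample(BENIGN_DX, k, replace = TRUE),
                       other_clinic(k))
          )
        }
      }
      dx_list[[i]] <- dx
      px_list[[i]] <- px
    }
    truth <- tibble::tibble(subject_id = ids, archetype = arche)
    truth <- dplyr::left_join(truth, exp_tab, by = "archetype")
    truth$true_case <- truth$expected_label == "CASE"
    dx_proto <- tibble::tibble(
      subject_id = character(0), event_date = as.Date(character(0)),
      icd9_code = character(0), clinic = character(0),
      age_at_event = integer(0))
    px_proto <- dx_proto
    names(px_proto)[3] <- "cpt_code"
    list(
      subjects = tibble::tibble(subject_id = ids),
      dx = dplyr::bind_rows(c(list(dx_proto), dx_list)),
      px = dplyr::bind_rows(c(list(px_proto), px_list)),
      truth = truth,
      config = config
    )
  })
}

#' Plant engine-visible false positives among clean controls
#'
#' Gives `k` randomly chosen `CLEAN_CONTROL` subjects the code pattern of a
#' Type 3 case (two specialty-clinic AAA diagnoses on distinct recent dates)
#' while leaving their ground truth as non-case. This mimics the documented
#' failure mode of coded-data phenotyping — e.g. pre-aneurysmal aortic
#' ectasia coded as AAA — and yields a cohort whose true case PPV is known
#' analytically: `(n_cases_predicted - k) / n_cases_predicted`.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param k Number of false positives to plant (`k = 0` allowed).
#' @param seed Integer seed for choosing the subjects and dates.
#' @return The cohort with augmented `dx` and updated `truth` (planted
#'   subjects get `archetype = "PLANTED_FALSE_POSITIVE"`,
#'   `expected_label = "CASE"`, `expected_case_type = 3`,
#'   `true_case = FALSE`).
#' @export
perturb_to_false_positive <- function(cohort, k, seed) {
  stopifnot(k >= 0)
  if (k == 0L) return(cohort)
  pool <- cohort$truth$subject_id[cohort$truth$archetype == "CLEAN_CONTROL"]
  if (length(pool) < k) {
    stop("need at least ", k, " CLEAN_CONTROL subjects; have ", length(pool),
         call. = FALSE)
  }
  cfg <- cohort$config
  win_end <- cfg$date_window[2]
  recent_start <- max(cfg$date_window[1], win_end - 365L)
  codes <- "441.4"
  with_local_seed(seed, {
    chosen <- sample(pool, k)
    extra <- vector("list", k)
    for (j in seq_along(chosen)) {
      id <- chosen[[j]]
      sub_dx <- cohort$dx[cohort$dx$subject_id == id, , drop = FALSE]
      # reuse the subject's own age/date relationship
      ref_row <- which.max(sub_dx$event_date)
      base_date <- sub_dx$event_date[ref_row]
      base_age <- sub_dx$age_at_event[ref_row]
      d1 <- min(base_date + 10L, win_end)
      d2 <- min(base_date + 40L, win_end)
      if (d1 == d2) d1 <- d2 - 30L
      extra[[j]] <- tibble::tibble(
        subject_id = id,
        event_date = c(d1, d2),
        icd9_code = codes,
        clinic = sample(cfg$specialty_clinics, 2L, replace = TRUE),
        age_at_event = base_age + as.integer(
          floor(as.numeric(c(d1, d2) - base_date) / DAYS_PER_YEAR))
      )
    }
    cohort$dx <- dplyr::bind_rows(cohort$dx, dplyr::bind_rows(extra))
    hit <- cohort$truth$subject_id %in% chosen
    cohort$truth$archetype[hit] <- "PLANTED_FALSE_POSITIVE"
    cohort$truth$expected_label[hit] <- "CASE"
    cohort$truth$expected_case_type[hit] <- 3L
    cohort$truth$true_case[hit] <- FALSE
    cohort
  })
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the same CSV dialect [load_streams()] reads, plus `truth.csv`.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- write_streams(cohort, dir)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(cohort$truth, truth_path)
  invisible(c(paths, truth = truth_path))
}
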