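cfg_default <- engine_config()

test_that("reference date resolves explicitly or from the latest event", {
  dx <- tibble::tibble(subject_id = "A",
                       event_date = as.Date(c("2010-05-01", "2012-03-02")),
                       icd9_code = "401.9", clinic = "x", age_at_event = 60L)
  px <- dx[0, ]; names(px)[3] <- "cpt_code"
  expect_equal(resolve_reference_date(dx, px, cfg_default),
               as.Date("2012-03-02"))
  cfg <- engine_config(reference_date = "2013-01-01")
  expect_equal(resolve_reference_date(dx, px, cfg), as.Date("2013-01-01"))
  expect_error(resolve_reference_date(dx[0, ], px, cfg_default),
               "at least one event")
})

test_that("case-type predicates follow their code-set and clinic rules", {
  reg <- default_registry()
  px1 <- tibble::tibble(subject_id = "A", event_date = as.Date("2011-01-01"),
                        cpt_code = "34800", clinic = "vascular surgery",
                        age_at_event = 65L)
  expect_true(is_type1(px1, reg)$hit)
  px2 <- px1; px2$cpt_code <- "99213"
  expect_false(is_type1(px2, reg)$hit)
  two_rep <- rbind(px1, px1)
  t1 <- is_type1(two_rep, reg)
  expect_true(t1$hit)
  expect_equal(nrow(t1$evidence), 2)

  mk_dx <- function(code, clinic, dates = "2011-05-01") {
    tibble::tibble(subject_id = "A", event_date = as.Date(dates),
                   icd9_code = code, clinic = clinic, age_at_event = 70L)
  }
  expect_true(is_type2(mk_dx("441.3", "vascular surgery"), reg, cfg_default)$hit)
  expect_false(is_type2(mk_dx("441.3", "family practice"), reg, cfg_default)$hit)
  expect_false(is_type2(mk_dx("441.4", "vascular surgery"), reg, cfg_default)$hit)
  # clinic requirement is configurable for ruptured-AAA encounters
  relaxed <- engine_config(require_specialty_type2 = FALSE)
  expect_true(is_type2(mk_dx("441.3", "family practice"), reg, relaxed)$hit)

  expect_true(is_type3(mk_dx(c("441.4", "441.4"), "vascular surgery",
                             c("2010-01-05", "2010-06-07")),
                       reg, cfg_default)$hit)
  # same calendar day counts once
  expect_false(is_type3(mk_dx(c("441.4", "441.4"), "vascular surgery",
                              c("2010-01-05", "2010-01-05")),
                        reg, cfg_default)$hit)
  # one specialty + one non-specialty encounter is not enough
  expect_false(is_type3(mk_dx(c("441.4", "441.4"),
                              c("vascular surgery", "family practice"),
                              c("2010-01-05", "2010-06-07")),
                        reg, cfg_default)$hit)
  # clinic comparison is trim/case-insensitive
  expect_true(is_type3(mk_dx(c("441.4", "441.4"),
                             c(" Vascular Surgery", "VASCULAR SURGERY "),
                             c("2010-01-05", "2010-06-07")),
                       reg, cfg_default)$hit)
})

test_that("the cascade stops at the first matching rule", {
  ref <- as.Date("2012-12-31")
  dx0 <- tibble::tibble(subject_id = character(0),
                        event_date = as.Date(character(0)),
                        icd9_code = character(0), clinic = character(0),
                        age_at_event = integer(0))
  px0 <- dx0; names(px0)[3] <- "cpt_code"
  mk_dx <- function(codes, clinics, dates, ages = 70L) {
    tibble::tibble(subject_id = "A", event_date = as.Date(dates),
                   icd9_code = codes, clinic = clinics,
                   age_at_event = as.integer(ages))
  }

  # phenocopy beats an otherwise perfect Type 3 pattern
  r <- classify_subject("A",
    mk_dx(c("759.82", "441.4", "441.4"),
          c("family practice", "vascular surgery", "vascular surgery"),
          c("2012-01-01", "2012-02-01", "2012-03-01")),
    px0, cfg_default, ref)
  expect_equal(r$label, "EXCLUDED")
  expect_equal(r$exclusion_reason, "PHENOCOPY")

  # a repair procedure beats Type 3 evidence ("decreasing certainty")
  px_rep <- tibble::tibble(subject_id = "A",
                           event_date = as.Date("2012-04-01"),
                           cpt_code = "34800", clinic = "vascular surgery",
                           age_at_event = 70L)
  r <- classify_subject("A",
    mk_dx(c("441.4", "441.4", "441.4"), "vascular surgery",
          c("2012-01-01", "2012-02-01", "2012-03-01")),
    px_rep, cfg_default, ref)
  expect_equal(r$label, "CASE")
  expect_equal(r$case_type, 1L)

  # ruptured specialty encounter beats Type 3
  r <- classify_subject("A",
    mk_dx(c("441.3", "441.4", "441.4"), "vascular surgery",
          c("2012-01-01", "2012-02-01", "2012-03-01")),
    px0, cfg_default, ref)
  expect_equal(r$case_type, 2L)

  # a single unconfirmed AAA code excludes a would-be control
  r <- classify_subject("A",
    mk_dx(c("441.4", "401.9"), c("vascular surgery", "family practice"),
          c("2012-04-01", "2012-05-01"), c(65L, 65L)),
    px0, cfg_default, ref)
  expect_equal(r$exclusion_reason, "UNCONFIRMED_AAA_CODE")

  # age bounds at the reference date
  r <- classify_subject("A",
    mk_dx("401.9", "family practice", "2012-06-01", 35L),
    px0, cfg_default, ref)
  expect_equal(r$exclusion_reason, "AGE")
  r <- classify_subject("A",
    mk_dx("401.9", "family practice", "2012-06-01", 92L),
    px0, cfg_default, ref)
  expect_equal(r$exclusion_reason, "AGE")

  # onset at or under 40 excludes even a current 60-year-old with repair
  r <- classify_subject("A",
    mk_dx(c("441.4", "401.9"), c("vascular surgery", "family practice"),
          c("1992-06-01", "2012-06-01"), c(40L, 60L)),
    px0, cfg_default, ref)
  expect_equal(r$exclusion_reason, "AAA_ONSET_AT_OR_UNDER_MIN_AGE")

  # stale record: last visit beyond the lookback window
  r <- classify_subject("A",
    mk_dx("401.9", "family practice", "2005-06-01", 60L),
    px0, cfg_default, ref)
  expect_equal(r$exclusion_reason, "NO_RECENT_ENCOUNTER")
  # no events at all
  r <- classify_subject("A", dx0, px0, cfg_default, ref)
  expect_equal(r$exclusion_reason, "NO_RECENT_ENCOUNTER")

  # clean recent history within age bounds -> control
  r <- classify_subject("A",
    mk_dx("401.9", "family practice", "2012-06-01", 60L),
    px0, cfg_default, ref)
  expect_equal(r$label, "CONTROL")
})

test_that("hand-evaluated six-subject toy cohort classifies as derived", {
  toy <- toy_cohort()
  cl <- classify_cohort(toy$subjects, toy$dx, toy$px, cfg_default)
  expect_equal(cl$summary$n_cases, 3)
  expect_equal(cl$summary$n_controls, 1)
  expect_equal(cl$summary$n_excluded, 2)
  res <- cl$results
  lab <- function(id) res[res$subject_id == id, ]
  expect_equal(lab("T1")$case_type, 1L)
  expect_equal(lab("T2")$case_type, 2L)
  expect_equal(lab("T3")$case_type, 3L)
  expect_equal(lab("PH")$exclusion_reason, "PHENOCOPY")
  expect_equal(lab("SC")$exclusion_reason, "UNCONFIRMED_AAA_CODE")
  expect_equal(lab("CC")$label, "CONTROL")
})

test_that("classify_cohort enforces the partition invariant and rejects bad input", {
  co <- generate_cohort(sim_config(n_subjects = 80, seed = 3))
  cl <- classify_cohort(co$subjects, co$dx, co$px, cfg_default)
  s <- cl$summary
  expect_equal(s$n_cases + s$n_controls + s$n_excluded, s$n_subjects)
  expect_equal(nrow(cl$results), nrow(co$subjects))
  expect_false(anyNA(cl$results$label))
  # case_type set iff CASE; exclusion_reason set iff EXCLUDED
  expect_true(all(is.na(cl$results$case_type) !=
                    (cl$results$label == "CASE")))
  expect_true(all(is.na(cl$results$exclusion_reason) !=
                    (cl$results$label == "EXCLUDED")))

  dup <- tibble::tibble(subject_id = c("A", "A"))
  expect_error(classify_cohort(dup, co$dx, co$px, cfg_default), "duplicate")
  two <- tibble::tibble(subject_id = c("A", "B"))
  expect_error(classify_cohort(two, co$dx[0, ], co$px[0, ], cfg_default),
               "at least one event")
})

test_that("no control carries any 441.* diagnosis (control purity)", {
  for (s in c(2, 9)) {
    co <- generate_cohort(sim_config(n_subjects = 120, seed = s))
    cl <- classify_cohort(co$subjects, co$dx, co$px, cfg_default)
    controls <- cl$results$subject_id[cl$results$label == "CONTROL"]
    hits <- matches_any(co$dx$icd9_code, "441.*")
    expect_length(intersect(controls, unique(co$dx$subject_id[hits])), 0)
  }
})

test_that("Type 3 case evidence holds enough distinct specialty dates", {
  co <- generate_cohort(sim_config(n_subjects = 120, seed = 4))
  cl <- classify_cohort(co$subjects, co$dx, co$px, cfg_default)
  t3 <- cl$results$subject_id[!is.na(cl$results$case_type) &
                                cl$results$case_type == 3L]
  expect_gt(length(t3), 0)
  for (id in t3) {
    ev <- cl$evidence[[id]]
    expect_gte(length(unique(ev$event_date)), cfg_default$min_type3_dates)
    expect_true(all(tolower(trimws(ev$clinic)) %in%
                      cfg_default$specialty_clinics))
  }
})

test_that("adding a phenocopy code never yields a case or control", {
  co <- generate_cohort(sim_config(n_subjects = 60, seed = 8))
  ref <- as.Date("2012-12-31")
  ids <- sample(co$subjects$subject_id, 20)
  for (id in ids) {
    dx <- co$dx[co$dx$subject_id == id, ]
    px <- co$px[co$px$subject_id == id, ]
    extra <- tibble::tibble(subject_id = id, event_date = as.Date("2011-06-01"),
                            icd9_code = "759.82", clinic = "family practice",
                            age_at_event = if (nrow(dx) > 0)
                              dx$age_at_event[1] else 60L)
    r <- classify_subject(id, rbind(dx, extra), px, cfg_default, ref)
    expect_equal(r$label, "EXCLUDED")
    expect_equal(r$exclusion_reason, "PHENOCOPY")
  }
})

test_that("the cascade agrees with the unordered-predicate oracle", {
  cfg <- engine_config()
  for (s in 1:25) {
    raw <- random_raw_cohort(50, seed = 1000 + s)
    ref <- resolve_reference_date(raw$dx, raw$px, cfg)
    cl <- classify_cohort(raw$subjects, raw$dx, raw$px, cfg)
    for (i in seq_len(nrow(raw$subjects))) {
      id <- raw$subjects$subject_id[[i]]
      want <- oracle_classify(id, raw$dx[raw$dx$subject_id == id, ],
                              raw$px[raw$px$subject_id == id, ], cfg, ref)
      got <- cl$results[cl$results$subject_id == id, ]
      expect_equal(got$label, want$label, info = paste("seed", s, "id", id))
      expect_equal(got$case_type, want$case_type,
                   info = paste("seed", s, "id", id))
      expect_equal(got$exclusion_reason, want$reason,
                   info = paste("seed", s, "id", id))
    }
  }
})

test_that("classification is deterministic and serializes byte-identically", {
  co <- generate_cohort(sim_config(n_subjects = 60, seed = 12))
  cl1 <- classify_cohort(co$subjects, co$dx, co$px, cfg_default)
  cl2 <- classify_cohort(co$subjects, co$dx, co$px, cfg_default)
  expect_identical(cl1$results, cl2$results)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_classification(cl1, d1)
  write_classification(cl2, d2)
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
})

test_that("case_type_distribution reports counts and rounded percentages", {
  expect_equal(case_type_distribution(c(295, 16, 388))$percent,
               c(42.2, 2.3, 55.5, 100))
  expect_equal(case_type_distribution(c(0, 7, 249))$percent,
               c(0, 2.7, 97.3, 100))
  d <- case_type_distribution(c(72, 0, 106))
  expect_equal(d$count, c(72, 0, 106, 178))
  expect_equal(d$percent[1:2], c(40.4, 0))
  # zero cases: counts reported, no division
  d0 <- case_type_distribution(c(0, 0, 0))
  expect_equal(d0$count, c(0, 0, 0, 0))
  expect_true(all(is.na(d0$percent)))
  # from a classification object
  toy <- toy_cohort()
  cl <- classify_cohort(toy$subjects, toy$dx, toy$px, cfg_default)
  expect_equal(case_type_distribution(cl)$count, c(1, 1, 1, 3))
})
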