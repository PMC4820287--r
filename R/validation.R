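# Blinded chart-review sampling and algorithm-performance statistics:
# positive predictive value (PPV), exact binomial confidence intervals,
# multi-site pooling, and the false-positive breakdown by case type.

#' Positive predictive value, in percent
#'
#' The standard formula: confirmed positives over algorithm-predicted
#' positives, with chart review (expert opinion) as the gold standard.
#'
#' @param true_positive Number of predicted positives confirmed by review.
#' @param predicted_positive Number of predicted positives reviewed (>= 1).
#' @return PPV as a percentage.
#' @examples
#' ppv(47, 50)  # 94
#' @export
ppv <- function(true_positive, predicted_positive) {
  stopifnot(length(true_positive) == length(predicted_positive))
  if (any(predicted_positive < 1)) {
    stop("PPV undefined: no predicted positives reviewed", call. = FALSE)
  }
  if (any(true_positive < 0 | true_positive > predicted_positive)) {
    stop("true_positive must be between 0 and predicted_positive",
         call. = FALSE)
  }
  100 * true_positive / predicted_positive
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval via beta quantiles:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). Always
#' contains the point estimate `x/n` and is conservative (coverage at least
#' the nominal level).
#'
#' @param successes Number of successes `x` (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param alpha Two-sided error rate in (0, 1); default 0.05.
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @examples
#' clopper_pearson_ci(116, 125)  # c(0.868..., 0.967...)
#' @export
clopper_pearson_ci <- function(successes, n, alpha = 0.05) {
  stopifnot(length(successes) == 1L, length(n) == 1L, length(alpha) == 1L)
  if (!(n >= 1 && successes >= 0 && successes <= n)) {
    stop("require 0 <= successes <= n and n >= 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Wilson score interval (alternative to the exact interval)
#'
#' @inheritParams clopper_pearson_ci
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @export
wilson_ci <- function(successes, n, alpha = 0.05) {
  stopifnot(n >= 1, successes >= 0, successes <= n, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

binom_ci <- function(successes, n, alpha = 0.05,
                     method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  switch(method,
         "clopper-pearson" = clopper_pearson_ci(successes, n, alpha),
         "wilson" = wilson_ci(successes, n, alpha))
}

#' Draw a blinded chart-review sample
#'
#' Samples `n_per_stratum` predicted cases and `n_per_stratum` predicted
#' controls uniformly at random without replacement (capped, with a warning,
#' at the stratum size). The `sample` element omits the predicted label so
#' the review is blinded; the `key` element maps identifiers back to labels
#' and is meant to be sealed until review is complete.
#'
#' @param classification An `aaa_classification` (or its `results` tibble).
#' @param n_per_stratum Number of subjects per stratum (>= 1).
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A list of class `review_sample` with `sample` (tibble of
#'   `subject_id` only, shuffled), `key` (tibble of `subject_id`,
#'   `predicted_label`), and `seed`.
#' @export
sample_for_review <- function(classification, n_per_stratum, seed) {
  results <- if (inherits(classification, "aaa_classification"))
    classification$results else classification
  stopifnot(n_per_stratum >= 1)
  cases <- results$subject_id[results$label == "CASE"]
  controls <- results$subject_id[results$label == "CONTROL"]
  if (length(cases) == 0L) stop("no predicted cases to sample", call. = FALSE)
  if (length(controls) == 0L) stop("no predicted controls to sample",
                                   call. = FALSE)
  n_cases <- min(n_per_stratum, length(cases))
  n_controls <- min(n_per_stratum, length(controls))
  if (n_cases < n_per_stratum) {
    warning("only ", n_cases, " predicted cases available; stratum capped",
            call. = FALSE)
  }
  if (n_controls < n_per_stratum) {
    warning("only ", n_controls, " predicted controls available; stratum capped",
            call. = FALSE)
  }
  drawn <- with_local_seed(seed, {
    picked_cases <- sample(cases, n_cases)
    picked_controls <- sample(controls, n_controls)
    ids <- c(picked_cases, picked_controls)
    list(ids = sample(ids, length(ids)),  # shuffle so order leaks no label
         key = tibble::tibble(
           subject_id = c(picked_cases, picked_controls),
           predicted_label = rep(c("CASE", "CONTROL"), c(n_cases, n_controls))
         ))
  })
  structure(list(sample = tibble::tibble(subject_id = drawn$ids),
                 key = drawn$key, seed = as.integer(seed)),
            class = "review_sample")
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Per-site and pooled PPV report with exact confidence intervals
#'
#' Pooling sums confirmed and reviewed counts across sites per stratum (it
#' does not average site PPVs), so the pooled PPV is the reviewed-count-
#' weighted mean of the site PPVs.
#'
#' @param site_counts Data frame with one row per site and columns `site`,
#'   `cases_reviewed`, `cases_confirmed`, `controls_reviewed`,
#'   `controls_confirmed`. Reviewed counts of 0 are allowed (that stratum's
#'   PPV is `NA` for the site).
#' @param alpha Two-sided error rate for the intervals (default 0.05).
#' @param sites Optional character vector: restrict the report (and the pool)
#'   to these sites.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return A tibble with one row per site plus a `"Pooled"` row; PPVs and CI
#'   bounds in percent.
#' @export
pooled_ppv_report <- function(site_counts, alpha = 0.05, sites = NULL,
                              ci_method = "clopper-pearson") {
  needed <- c("site", "cases_reviewed", "cases_confirmed",
              "controls_reviewed", "controls_confirmed")
  missing <- setdiff(needed, names(site_counts))
  if (length(missing) > 0L) {
    stop("site_counts missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(sites)) {
    unknown <- setdiff(sites, site_counts$site)
    if (length(unknown) > 0L) {
      stop("unknown site(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    site_counts <- site_counts[site_counts$site %in% sites, , drop = FALSE]
  }
  if (nrow(site_counts) == 0L) stop("no sites to report", call. = FALSE)
  bad <- with(site_counts, cases_confirmed > cases_reviewed |
                controls_confirmed > controls_reviewed |
                cases_confirmed < 0 | controls_confirmed < 0)
  if (any(bad)) {
    stop("confirmed counts must be between 0 and the reviewed counts",
         call. = FALSE)
  }
  pooled <- tibble::tibble(
    site = "Pooled",
    cases_reviewed = sum(site_counts$cases_reviewed),
    cases_confirmed = sum(site_counts$cases_confirmed),
    controls_reviewed = sum(site_counts$controls_reviewed),
    controls_confirmed = sum(site_counts$controls_confirmed)
  )
  all_rows <- dplyr::bind_rows(
    tibble::as_tibble(site_counts[needed]), pooled
  )
  stat_row <- function(x, n) {
    if (n < 1) return(c(NA_real_, NA_real_, NA_real_))
    ci <- binom_ci(x, n, alpha, method = ci_method)
    c(100 * x / n, 100 * ci[["lower"]], 100 * ci[["upper"]])
  }
  case_stats <- t(mapply(stat_row, all_rows$cases_confirmed,
                         all_rows$cases_reviewed))
  control_stats <- t(mapply(stat_row, all_rows$controls_confirmed,
                            all_rows$controls_reviewed))
  all_rows$case_ppv <- case_stats[, 1]
  all_rows$case_ci_lower <- case_stats[, 2]
  all_rows$case_ci_upper <- case_stats[, 3]
  all_rows$control_ppv <- control_stats[, 1]
  all_rows$control_ci_lower <- control_stats[, 2]
  all_rows$control_ci_upper <- control_stats[, 3]
  all_rows
}

#' Format a PPV report as a text table
#'
#' @param report A tibble from [pooled_ppv_report()].
#' @return A character vector of lines (also printed with `cat` style by the
#'   CLI); PPVs and CI bounds rounded to 1 decimal.
#' @export
format_ppv_report <- function(report) {
  fmt <- function(x) ifelse(is.na(x), "-", formatC(round(x, 1), format = "fg"))
  lines <- sprintf(
    "%-12s cases %3d/%3d PPV %5s%% (CI %s-%s)  controls %3d/%3d PPV %5s%% (CI %s-%s)",
    report$site,
    report$cases_confirmed, report$cases_reviewed, fmt(report$case_ppv),
    fmt(report$case_ci_lower), fmt(report$case_ci_upper),
    report$controls_confirmed, report$controls_reviewed,
    fmt(report$control_ppv),
    fmt(report$control_ci_lower), fmt(report$control_ci_upper)
  )
  lines
}

#' False-positive breakdown by assigned case type and site
#'
#' Cross-tabulates reviewed predicted cases that chart review judged to be
#' non-cases, by the case type the algorithm assigned and by site, with row
#' and column totals.
#'
#' @param review_outcomes Data frame with columns `subject_id`, `site`, and
#'   `reviewer_judgment` (`"case"`, `"control"` or `"unsure"`); one row per
#'   reviewed predicted case. A judgment other than `"case"` counts as a
#'   false positive.
#' @param classification An `aaa_classification` (or its `results` tibble)
#'   containing every reviewed subject as a predicted case.
#' @return A tibble with rows for case types 1-3 and `"All"`, one column per
#'   site plus `Total`.
#' @export
false_positive_breakdown <- function(review_outcomes, classification) {
  results <- if (inherits(classification, "aaa_classification"))
    classification$results else classification
  needed <- c("subject_id", "site", "reviewer_judgment")
  missing <- setdiff(needed, names(review_outcomes))
  if (length(missing) > 0L) {
    stop("review_outcomes missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(review_outcomes$subject_id, results$subject_id)
  if (anyNA(idx)) {
    stop("review outcome for unknown subject id: ",
         review_outcomes$subject_id[which(is.na(idx))[1]], call. = FALSE)
  }
  if (any(results$label[idx] != "CASE")) {
    stop("review outcome for a subject not predicted as case: ",
         review_outcomes$subject_id[which(results$label[idx] != "CASE")[1]],
         call. = FALSE)
  }
  fp <- review_outcomes$reviewer_judgment != "case"
  sites <- sort(unique(review_outcomes$site))
  type <- factor(results$case_type[idx], levels = 1:3)
  tab <- table(type[fp], factor(review_outcomes$site[fp], levels = sites))
  out <- tibble::tibble(case_type = c("1", "2", "3", "All"))
  for (s in sites) {
    col <- as.integer(tab[, s])
    out[[s]] <- c(col, sum(col))
  }
  totals <- as.integer(rowSums(tab))
  out$Total <- c(totals, sum(totals))
  out
}
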