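# Domain model for coded-EHR extracts: ICD-9 diagnosis events, CPT procedure
# events, code normalization and wildcard matching, and delimited-file I/O.

#' Normalize ICD-9 codes to canonical dotted form
#'
#' Real EHR extracts mix dotted ("441.4") and undotted ("4414") ICD-9 dialects.
#' All matching in this package is exact string matching on the canonical
#' dotted form: a 3-character category (three digits, `V` plus two digits, or
#' `E` plus three digits), followed by a dot and one or two digits when a
#' subcode is present. Normalization is idempotent.
#'
#' @param raw Character vector of raw ICD-9 codes (dotted or undotted).
#' @return Character vector of normalized codes.
#' @examples
#' normalize_icd9(c("441.4", "4414", " 759.82 ", "V10.3"))
#' @export
normalize_icd9 <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- toupper(trimws(as.character(raw)))
  bad <- function(v) {
    stop("malformed ICD-9 code: ", deparse(v), call. = FALSE)
  }
  vapply(seq_along(x), function(i) {
    v <- x[[i]]
    if (is.na(v) || !nzchar(v)) bad(raw[[i]])
    if (grepl(".", v, fixed = TRUE)) {
      parts <- strsplit(v, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L) bad(v)
      cat3 <- parts[[1]]
      sub <- parts[[2]]
      if (!grepl("^[0-9]{1,2}$", sub)) bad(v)
    } else {
      # undotted: split category / subcode by coding-system prefix
      if (grepl("^E", v)) {
        if (!grepl("^E[0-9]{3,5}$", v)) bad(v)
        cat3 <- substr(v, 1L, 4L)
        sub <- substring(v, 5L)
      } else if (grepl("^V", v)) {
        if (!grepl("^V[0-9]{2,4}$", v)) bad(v)
        cat3 <- substr(v, 1L, 3L)
        sub <- substring(v, 4L)
      } else {
        if (!grepl("^[0-9]{3,5}$", v)) bad(v)
        cat3 <- substr(v, 1L, 3L)
        sub <- substring(v, 4L)
      }
    }
    ok_cat <- grepl("^[0-9]{3}$", cat3) || grepl("^V[0-9]{2}$", cat3) ||
      grepl("^E[0-9]{3}$", cat3)
    if (!ok_cat) bad(v)
    if (nzchar(sub)) paste0(cat3, ".", sub) else cat3
  }, character(1))
}

#' Normalize CPT codes
#'
#' Trims whitespace and upper-cases. Standard CPT codes are 5 characters
#' (5 digits, or 4 digits plus a letter for category II/III codes); other
#' non-empty alphanumeric tokens are accepted unchanged so that site-local
#' procedure vocabularies survive ingestion.
#'
#' @param raw Character vector of raw CPT codes.
#' @return Character vector of normalized codes.
#' @export
normalize_cpt <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- toupper(trimws(as.character(raw)))
  ok <- !is.na(x) & grepl("^[0-9A-Z]+$", x)
  if (!all(ok)) {
    stop("malformed CPT code: ", deparse(raw[which(!ok)[1]]), call. = FALSE)
  }
  x
}

#' Match normalized codes against literal or wildcard patterns
#'
#' A pattern is either a literal normalized code, matched by string equality,
#' or a category wildcard written `"P.*"` (e.g. `"441.*"`), which matches the
#' bare category `"P"` and any 1- or 2-digit subcode `"P.d"` / `"P.dd"`, and
#' never a different category. The bare-category match is deliberate: a
#' miscoded bare `441` must never let a subject into the control group.
#'
#' @param pattern A single pattern string.
#' @param code Character vector of normalized codes.
#' @return Logical vector, one element per code.
#' @examples
#' code_matches("441.*", c("441.4", "441.02", "441", "442.4"))
#' code_matches("441.3", c("441.3", "441.4"))
#' @export
code_matches <- function(pattern, code) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  if (endsWith(pattern, ".*")) {
    stem <- substr(pattern, 1L, nchar(pattern) - 2L)
    if (!nzchar(stem) || grepl("*", stem, fixed = TRUE)) {
      stop("malformed wildcard pattern: ", deparse(pattern), call. = FALSE)
    }
    code == stem | grepl(paste0("^", stem, "\\.[0-9]{1,2}$"), code)
  } else {
    if (grepl("*", pattern, fixed = TRUE)) {
      stop("malformed pattern (wildcard must be a single trailing '.*'): ",
           deparse(pattern), call. = FALSE)
    }
    code == pattern
  }
}

#' Match codes against any of several patterns
#'
#' @param codes Character vector of normalized codes.
#' @param patterns Character vector of literal/wildcard patterns.
#' @return Logical vector, TRUE where the code matches at least one pattern.
#' @export
matches_any <- function(codes, patterns) {
  if (length(codes) == 0L) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in patterns) hit <- hit | code_matches(p, codes)
  hit
}

# canonicalize clinic names for comparison: trim + case-fold; NA -> ""
normalize_clinic <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  x
}

default_column_map <- function() {
  list(
    subjects = c(subject_id = "subject_id"),
    dx = c(subject_id = "subject_id", event_date = "event_date",
           code = "icd9_code", clinic = "clinic", age_at_event = "age_at_event"),
    px = c(subject_id = "subject_id", event_date = "event_date",
           code = "cpt_code", clinic = "clinic", age_at_event = "age_at_event")
  )
}

read_delim_auto <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delimiter <- if (grepl("\t", first)) "\t" else ","
  }
  readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE)
}

require_columns <- function(df, wanted, what) {
  missing <- setdiff(unname(wanted), names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

parse_event_table <- function(df, map, system, what) {
  require_columns(df, map, what)
  out <- tibble::tibble(
    subject_id = as.character(df[[map[["subject_id"]]]]),
    event_date = suppressWarnings(
      readr::parse_date(df[[map[["event_date"]]]], format = "")
    ),
    code = as.character(df[[map[["code"]]]]),
    clinic = as.character(df[[map[["clinic"]]]]),
    age_at_event = suppressWarnings(as.integer(df[[map[["age_at_event"]]]]))
  )
  bad_date <- which(is.na(out$event_date))
  if (length(bad_date) > 0L) {
    stop("unparseable event_date in ", what, " at row(s): ",
         paste(utils::head(bad_date, 5), collapse = ", "), call. = FALSE)
  }
  bad_age <- which(is.na(out$age_at_event) | out$age_at_event < 0L |
                     out$age_at_event > 150L)
  if (length(bad_age) > 0L) {
    stop("invalid age_at_event in ", what, " at row(s): ",
         paste(utils::head(bad_age, 5), collapse = ", "), call. = FALSE)
  }
  out$clinic[is.na(out$clinic)] <- ""
  if (system == "ICD9") {
    out$icd9_code <- normalize_icd9(out$code)
  } else {
    out$cpt_code <- normalize_cpt(out$code)
  }
  out$code <- NULL
  cols <- c("subject_id", "event_date",
            if (system == "ICD9") "icd9_code" else "cpt_code",
            "clinic", "age_at_event")
  out[cols]
}

#' Load the three coded-EHR input streams
#'
#' Reads the subject-identifier table, the ICD-9 diagnosis stream and the CPT
#' procedure stream from delimited files, normalizes all codes, parses dates,
#' and drops (with a message) any event whose subject identifier is absent
#' from the subject table — the extract-filtering step of the source workflow.
#'
#' @param subjects_path,dx_path,px_path Paths to delimited files with headers.
#' @param column_map Optional list with elements `subjects`, `dx`, `px`, each a
#'   named character vector mapping canonical field names to file column names
#'   (see `aaapheno:::default_column_map()` for the defaults).
#' @param delimiter Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line of each file.
#' @return A list with tibbles `subjects`, `dx`, `px` and a named integer
#'   `dropped` recording how many events were discarded per stream for having
#'   an unknown subject identifier.
#' @export
load_streams <- function(subjects_path, dx_path, px_path,
                         column_map = NULL, delimiter = NULL) {
  map <- default_column_map()
  if (!is.null(column_map)) {
    for (nm in intersect(names(column_map), names(map))) {
      user <- column_map[[nm]]
      map[[nm]][names(user)] <- unname(user)
    }
  }
  subj_raw <- read_delim_auto(subjects_path, delimiter)
  require_columns(subj_raw, map$subjects, "subjects")
  subjects <- tibble::tibble(
    subject_id = as.character(subj_raw[[map$subjects[["subject_id"]]]])
  )
  subjects <- subjects[nzchar(subjects$subject_id) & !is.na(subjects$subject_id), ,
                       drop = FALSE]
  if (nrow(subjects) == 0L) stop("empty subject table", call. = FALSE)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in subject table", call. = FALSE)
  }
  dx <- parse_event_table(read_delim_auto(dx_path, delimiter), map$dx, "ICD9", "dx")
  px <- parse_event_table(read_delim_auto(px_path, delimiter), map$px, "CPT", "px")
  keep_dx <- dx$subject_id %in% subjects$subject_id
  keep_px <- px$subject_id %in% subjects$subject_id
  dropped <- c(dx = sum(!keep_dx), px = sum(!keep_px))
  if (any(dropped > 0L)) {
    message("dropped ", dropped[["dx"]], " dx and ", dropped[["px"]],
            " px events with subject ids absent from the subject table")
  }
  list(subjects = subjects, dx = dx[keep_dx, , drop = FALSE],
       px = px[keep_px, , drop = FALSE], dropped = dropped)
}

#' Write the three event streams back to CSV
#'
#' @param streams A list as returned by [load_streams()] or
#'   [generate_cohort()] (elements `subjects`, `dx`, `px`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_streams <- function(streams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    dx = file.path(dir, "diagnoses.csv"),
    px = file.path(dir, "procedures.csv")
  )
  readr::write_csv(streams$subjects, paths[["subjects"]])
  readr::write_csv(streams$dx, paths[["dx"]])
  readr::write_csv(streams$px, paths[["px"]])
  invisible(paths)
}
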