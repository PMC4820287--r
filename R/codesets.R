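# Named code sets and the six-role registry driving the classification rules.
# The published algorithm keeps its full code lists in a supplementary file
# that is not reproduced in the article body; the defaults here are
# reconstructed from the codes the article prints and are site-configurable.

CODESET_ROLES <- c("aaa_dx", "aaa_ruptured_dx", "aaa_unruptured_dx",
                   "aaa_repair_px", "phenocopy_exclusion_dx",
                   "control_exclusion_dx")

#' Construct a named code set
#'
#' @param name Set name (one of the registry roles, or any label).
#' @param system Coding system, `"ICD9"` or `"CPT"`.
#' @param members Character vector of literal codes and/or trailing-`.*`
#'   wildcard patterns. ICD-9 literals are normalized on construction.
#' @return An object of class `code_set`.
#' @export
code_set <- function(name, system = c("ICD9", "CPT"), members) {
  system <- match.arg(system)
  members <- as.character(members)
  if (length(members) == 0L) {
    stop("code set '", name, "' has an empty member list", call. = FALSE)
  }
  is_wild <- endsWith(members, ".*")
  if (any(is_wild)) {
    stems <- substr(members[is_wild], 1L, nchar(members[is_wild]) - 2L)
    if (any(!nzchar(stems) | grepl("\\*|\\.", stems))) {
      stop("code set '", name, "': wildcard must be a category followed by '.*'",
           call. = FALSE)
    }
  }
  if (any(grepl("\\*", members[!is_wild]))) {
    stop("code set '", name, "': '*' only allowed as a trailing '.*'",
         call. = FALSE)
  }
  if (system == "ICD9") {
    members[!is_wild] <- normalize_icd9(members[!is_wild])
  } else {
    members[!is_wild] <- normalize_cpt(members[!is_wild])
  }
  structure(list(name = name, system = system,
                 members = sort(unique(members))),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set> ", x$name, " [", x$system, "]: ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default AAA code-set registry
#'
#' Reconstructs the algorithm's code sets from the codes printed in the source
#' article:
#' * `aaa_dx` — AAA diagnoses 441.3 (ruptured) and 441.4 (without rupture);
#' * `aaa_ruptured_dx` / `aaa_unruptured_dx` — the two partitions of `aaa_dx`;
#' * `phenocopy_exclusion_dx` — Marfan syndrome (759.82), Ehlers-Danlos
#'   syndrome (756.83), Moyamoya disease (437.5), fibromuscular dysplasia
#'   (447.8), plus the thoracic/thoracoabdominal aneurysm and aortic
#'   dissection family (441.0x, 441.1, 441.2, 441.5-441.7, 441.9);
#' * `control_exclusion_dx` — the `441.*` wildcard: a control must never have
#'   carried any aortic-aneurysm code;
#' * `aaa_repair_px` — a default list of standard open and endovascular
#'   AAA-repair CPT codes. This list is a documented placeholder for the
#'   site-maintained procedure list and should be confirmed against the
#'   deployment site's vocabulary (the engine's logic is independent of its
#'   contents).
#'
#' @return A `code_set_registry`: a named list of six [code_set()] objects.
#' @examples
#' reg <- default_registry()
#' reg$aaa_dx$members
#' @export
default_registry <- function() {
  sets <- list(
    aaa_dx = code_set("aaa_dx", "ICD9", c("441.3", "441.4")),
    aaa_ruptured_dx = code_set("aaa_ruptured_dx", "ICD9", "441.3"),
    aaa_unruptured_dx = code_set("aaa_unruptured_dx", "ICD9", "441.4"),
    aaa_repair_px = code_set("aaa_repair_px", "CPT", c(
      # endovascular repair (EVAR) and open repair of infrarenal AAA
      "34800", "34802", "34803", "34804", "34805", "34830", "34831", "34832",
      "35081", "35082", "35091", "35092", "35102", "35103"
    )),
    phenocopy_exclusion_dx = code_set("phenocopy_exclusion_dx", "ICD9", c(
      "759.82",  # Marfan syndrome
      "756.83",  # Ehlers-Danlos syndrome
      "437.5",   # Moyamoya disease
      "447.8",   # fibromuscular dysplasia (other specified arterial disease)
      # dissection of aorta and non-abdominal aortic aneurysms
      "441.00", "441.01", "441.02", "441.03",
      "441.1", "441.2", "441.5", "441.6", "441.7", "441.9"
    )),
    control_exclusion_dx = code_set("control_exclusion_dx", "ICD9", "441.*")
  )
  new_registry(sets)
}

new_registry <- function(sets) {
  missing <- setdiff(CODESET_ROLES, names(sets))
  if (length(missing) > 0L) {
    stop("registry is missing role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(sets), CODESET_ROLES)
  if (length(extra) > 0L) {
    stop("unknown code-set role(s): ", paste(extra, collapse = ", "),
         "; valid roles are: ", paste(CODESET_ROLES, collapse = ", "),
         call. = FALSE)
  }
  expected_system <- c(aaa_dx = "ICD9", aaa_ruptured_dx = "ICD9",
                       aaa_unruptured_dx = "ICD9", aaa_repair_px = "CPT",
                       phenocopy_exclusion_dx = "ICD9",
                       control_exclusion_dx = "ICD9")
  for (role in CODESET_ROLES) {
    if (!inherits(sets[[role]], "code_set")) {
      stop("role '", role, "' is not a code_set", call. = FALSE)
    }
    if (sets[[role]]$system != expected_system[[role]]) {
      stop("system mismatch for role '", role, "': expected ",
           expected_system[[role]], ", got ", sets[[role]]$system,
           call. = FALSE)
    }
  }
  both <- sort(unique(c(sets$aaa_ruptured_dx$members,
                        sets$aaa_unruptured_dx$members)))
  if (!identical(both, sets$aaa_dx$members)) {
    stop("registry invariant violated: aaa_ruptured_dx + aaa_unruptured_dx ",
         "must equal aaa_dx", call. = FALSE)
  }
  literal_aaa <- sets$aaa_dx$members[!endsWith(sets$aaa_dx$members, ".*")]
  if (!all(matches_any(literal_aaa, sets$control_exclusion_dx$members))) {
    stop("registry invariant violated: every aaa_dx code must be matched by ",
         "control_exclusion_dx (controls may never carry an AAA code)",
         call. = FALSE)
  }
  structure(sets[CODESET_ROLES], class = "code_set_registry")
}

#' @export
print.code_set_registry <- function(x, ...) {
  cat("<code_set_registry> with", length(x), "roles\n")
  for (s in x) print(s)
  invisible(x)
}

#' Load a code-set registry from a YAML or JSON configuration file
#'
#' The configuration overrides the defaults role by role; roles not mentioned
#' keep their [default_registry()] members. Each overriding block must give
#' `system` and `members`, e.g.
#'
#' ```yaml
#' code_sets:
#'   aaa_repair_px:
#'     system: CPT
#'     members: ["34800", "34802"]
#' ```
#'
#' A top-level `code_sets:` block is used when present; otherwise the roles
#' may sit at the top level of the file.
#'
#' @param config_path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated `code_set_registry`.
#' @export
load_registry <- function(config_path) {
  cfg <- read_config_file(config_path)
  block <- if (!is.null(cfg$code_sets)) cfg$code_sets else cfg
  block <- block[intersect(names(block), c(CODESET_ROLES, character(0)))]
  sets <- unclass(default_registry())
  if (!is.null(cfg$code_sets)) {
    unknown <- setdiff(names(cfg$code_sets), CODESET_ROLES)
    if (length(unknown) > 0L) {
      stop("unknown code-set role(s) in config: ",
           paste(unknown, collapse = ", "), "; valid roles are: ",
           paste(CODESET_ROLES, collapse = ", "), call. = FALSE)
    }
  }
  for (role in names(block)) {
    spec <- block[[role]]
    if (length(spec$members) == 0L) {
      stop("config role '", role, "' must provide a non-empty 'members' list",
           call. = FALSE)
    }
    system <- if (!is.null(spec$system)) spec$system else sets[[role]]$system
    sets[[role]] <- code_set(role, system, unlist(spec$members))
  }
  new_registry(sets)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}
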