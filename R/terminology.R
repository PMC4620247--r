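# Fixture-scale terminology service.  Research-side schema items are
# bound to MedDRA preferred terms while warehouse condition entries are
# coded in ICD-9-CM; value matching bridges the two through a concept
# map queried symmetrically, one hop only (multi-hop chaining across
# terminologies silently broadens clinical meaning and is deliberately
# not performed).

#' Load a terminology store from CSV fixtures
#'
#' @param concepts_csv CSV with columns `system,code,display`.
#' @param map_csv CSV with columns `system_a,code_a,system_b,code_b`
#'   (pairs are stored once, queried symmetrically). `NULL` for no map.
#' @return An object of class `terminology`.
#' @examples
#' term <- load_terminology(
#'   system.file("extdata", "concepts.csv", package = "cdelink"),
#'   system.file("extdata", "concept_map.csv", package = "cdelink"))
#' lookup_concept(term, "MedDRA", "10007559")$display
#' @export
load_terminology <- function(concepts_csv, map_csv = NULL) {
  concepts <- utils::read.csv(concepts_csv, colClasses = "character")
  stopifnot(all(c("system", "code", "display") %in% names(concepts)))
  if (!all(nzchar(concepts$code))) {
    abort_cdelink("concept with empty code in terminology fixture",
                  "cdelink_load_error")
  }
  if (anyDuplicated(concepts[, c("system", "code")])) {
    abort_cdelink("duplicate (system, code) in terminology fixture",
                  "cdelink_load_error")
  }
  map <- if (is.null(map_csv)) {
    data.frame(system_a = character(0), code_a = character(0),
               system_b = character(0), code_b = character(0))
  } else {
    utils::read.csv(map_csv, colClasses = "character")
  }
  stopifnot(all(c("system_a", "code_a", "system_b", "code_b") %in% names(map)))
  structure(list(concepts = concepts, map = map), class = "terminology")
}

#' @export
print.terminology <- function(x, ...) {
  cat(sprintf("<terminology> %d concepts in %d systems, %d map pairs\n",
              nrow(x$concepts), length(unique(x$concepts$system)), nrow(x$map)))
  invisible(x)
}

#' Look up a concept by code
#'
#' @param term A `terminology`.
#' @param system_id Code system id (`"MedDRA"`, `"ICD9CM"`, ...).
#' @param code Code string.
#' @return A list with `system`, `code`, `display`.
#' @export
lookup_concept <- function(term, system_id, code) {
  hit <- term$concepts[term$concepts$system == system_id & term$concepts$code == code, ]
  if (!nrow(hit)) {
    abort_cdelink(sprintf("concept %s|%s not found", system_id, code),
                  "cdelink_not_found_error")
  }
  as.list(hit[1, ])
}

#' Type-ahead prefix search over concept displays
#'
#' Case-insensitive prefix match on the display name, returned in
#' alphabetical order of display.
#'
#' @param term A `terminology`.
#' @param prefix Search prefix.
#' @param system_id Code system to search in.
#' @return Data frame of matching concepts (possibly empty).
#' @export
search_concepts <- function(term, prefix, system_id) {
  pool <- term$concepts[term$concepts$system == system_id, , drop = FALSE]
  hit <- pool[startsWith(tolower(pool$display), tolower(prefix)), , drop = FALSE]
  hit <- hit[order(hit$display), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Map a code into another code system
#'
#' Returns every mapped target (one-to-many fan-out is normal: a MedDRA
#' preferred term typically covers several ICD-9-CM codes). Mapping is
#' symmetric: if `b` is among `map_code(a)` then `a` is among
#' `map_code(b)`. One hop only.
#'
#' @param term A `terminology`.
#' @param code Source code.
#' @param from_system Source code system.
#' @param to_system Target code system.
#' @return Character vector of target codes (possibly empty), sorted.
#' @export
map_code <- function(term, code, from_system, to_system) {
  m <- term$map
  fwd <- m$code_b[m$system_a == from_system & m$code_a == code & m$system_b == to_system]
  rev <- m$code_a[m$system_b == from_system & m$code_b == code & m$system_a == to_system]
  sort(unique(c(fwd, rev)))
}

#' Do two codes denote the same concept?
#'
#' True iff same system and same code, or a concept-map pair links them
#' directly (one hop). Symmetric and reflexive.
#'
#' @param term A `terminology`.
#' @param code_a,system_a First code and its system.
#' @param code_b,system_b Second code and its system.
#' @return Logical scalar.
#' @export
codes_match <- function(term, code_a, system_a, code_b, system_b) {
  if (identical(system_a, system_b)) return(identical(code_a, code_b))
  code_b %in% map_code(term, code_a, system_a, system_b)
}

# Expand a set of (system, code) bindings with all their one-hop mapped
# equivalents in `to_systems`; used to vectorize matching over large
# condition tables.
expand_code_set <- function(term, codes, system, to_systems) {
  out <- data.frame(system = rep(system, length(codes)), code = codes)
  for (ts in to_systems) {
    for (cd in codes) {
      mapped <- map_code(term, cd, system, ts)
      if (length(mapped)) out <- rbind(out, data.frame(system = ts, code = mapped))
    }
  }
  unique(out)
}
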