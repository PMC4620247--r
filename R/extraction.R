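# Execute extraction specifications against patient summaries in either
# content model and return typed, entry-grouped values.  The entry is the
# anchor of every specification: a schema item that pairs a code with a
# date needs both to come from the SAME clinical entry, so results carry
# the id of the entry they were taken from and are joined on it.

#' Construct an XML patient summary
#'
#' @param doc An `xml2::xml_document` in the package's CCD-like dialect
#'   (sections of entries holding coded acts/observations), or a string
#'   / file path parseable by [xml2::read_xml()].
#' @return An object of class `xml_summary`.
#' @export
xml_summary <- function(doc) {
  if (!inherits(doc, "xml_document")) doc <- xml2::read_xml(doc)
  pid <- xml2::xml_attr(xml2::xml_root(doc), "patientId")
  structure(list(doc = doc, patient_id = pid), class = "xml_summary")
}

#' @export
print.xml_summary <- function(x, ...) {
  cat(sprintf("<xml_summary> patient %s, %d entries\n", x$patient_id,
              length(xml2::xml_find_all(x$doc, "//entry"))))
  invisible(x)
}

empty_extracted <- function() {
  data.frame(entry_id = character(0), value = character(0),
             code_system = character(0), stringsAsFactors = FALSE)
}

#' Execute a path (XPath) extraction specification on an XML summary
#'
#' The script must address an attribute (`.../@code`, `.../@value`).
#' One result row is produced per matched node, in document order; the
#' entry id is taken from the nearest ancestor `entry` node (or
#' `"document"` for patient-level facts outside any entry). When the
#' addressed attribute is `code` and the carrying element also has a
#' `codeSystem` attribute, the code system is captured alongside.
#'
#' Zero matches yield an empty result, not an error: sparsely structured
#' sources legitimately produce empty columns.
#'
#' @param doc An `xml_summary`.
#' @param spec An extraction specification with `dialect = "path"`.
#' @return Data frame with columns `entry_id`, `value`, `code_system`.
#' @export
execute_path_spec <- function(doc, spec) {
  stopifnot(inherits(doc, "xml_summary"))
  if (!identical(spec$dialect, "path")) {
    abort_cdelink("execute_path_spec requires a spec with dialect 'path'",
                  "cdelink_spec_error")
  }
  script <- trimws(spec$script)
  m <- regmatches(script, regexec("^(.*)/@([A-Za-z][A-Za-z0-9_]*)$", script))[[1]]
  if (length(m) != 3) {
    abort_cdelink(sprintf("path script must select an attribute: '%s'", script),
                  "cdelink_spec_error")
  }
  nodes <- tryCatch(xml2::xml_find_all(doc$doc, m[2]),
                    error = function(e) abort_cdelink(
                      sprintf("malformed path script '%s': %s", script, conditionMessage(e)),
                      "cdelink_spec_error"),
                    warning = function(w) abort_cdelink(
                      sprintf("malformed path script '%s': %s", script, conditionMessage(w)),
                      "cdelink_spec_error"))
  if (!length(nodes)) return(empty_extracted())
  value <- xml2::xml_attr(nodes, m[3])
  keep <- !is.na(value)
  nodes <- nodes[keep]; value <- value[keep]
  if (!length(nodes)) return(empty_extracted())
  entry_id <- vapply(nodes, function(nd) {
    anc <- xml2::xml_find_first(nd, "ancestor::entry")
    if (inherits(anc, "xml_missing")) "document" else xml2::xml_attr(anc, "id")
  }, "")
  code_system <- if (m[3] == "code") xml2::xml_attr(nodes, "codeSystem") else
    rep(NA_character_, length(nodes))
  data.frame(entry_id = entry_id, value = value, code_system = code_system,
             stringsAsFactors = FALSE)
}

# parsed-query cache, keyed by script text (scripts come from the registry
# and are reused across every patient of a cohort)
.graph_query_cache <- new.env(parent = emptyenv())

#' Execute a graph-pattern extraction specification on a graph summary
#'
#' The script is a SPARQL SELECT restricted to a basic graph pattern and
#' FILTER equality, projecting `?entry` and `?value` (and optionally
#' `?system` for coded values). One result row per solution binding.
#'
#' @param graph A `graph_summary`.
#' @param spec An extraction specification with `dialect = "graph_pattern"`.
#' @return Data frame with columns `entry_id`, `value`, `code_system`.
#' @export
execute_graph_spec <- function(graph, spec) {
  stopifnot(inherits(graph, "graph_summary"))
  if (!identical(spec$dialect, "graph_pattern")) {
    abort_cdelink("execute_graph_spec requires a spec with dialect 'graph_pattern'",
                  "cdelink_spec_error")
  }
  key <- spec$script
  q <- .graph_query_cache[[key]]
  if (is.null(q)) {
    q <- parse_graph_pattern(spec$script)
    if (!all(c("?entry", "?value") %in% q$vars)) {
      abort_cdelink("graph-pattern script must project ?entry and ?value",
                    "cdelink_spec_error")
    }
    assign(key, q, envir = .graph_query_cache)
  }
  sol <- match_bgp(graph$triples, q)
  if (!nrow(sol)) return(empty_extracted())
  strip <- function(x) ifelse(is_lit(x), lit_value(x), local_name(x))
  data.frame(
    entry_id = strip(sol$entry),
    value = strip(sol$value),
    code_system = if ("system" %in% names(sol)) strip(sol$system) else NA_character_,
    stringsAsFactors = FALSE)
}

coerce_extracted <- function(df, element) {
  dt <- element$value_domain$datatype
  raw <- df$value
  out <- switch(dt,
    date = {
      d <- suppressWarnings(as.Date(raw, format = "%Y-%m-%d"))
      if (anyNA(d)) {
        bad <- df$entry_id[is.na(d)]
        abort_cdelink(sprintf("element %s: value not an ISO-8601 date (entry %s)",
                              element$id, paste(bad, collapse = ", ")),
                      "cdelink_data_quality_error")
      }
      d
    },
    quantity = {
      q <- suppressWarnings(as.numeric(raw))
      if (anyNA(q)) {
        bad <- df$entry_id[is.na(q)]
        abort_cdelink(sprintf("element %s: value not numeric (entry %s)",
                              element$id, paste(bad, collapse = ", ")),
                      "cdelink_data_quality_error")
      }
      q
    },
    boolean = {
      ok <- raw %in% c("true", "false", "Y", "N")
      if (!all(ok)) {
        abort_cdelink(sprintf("element %s: value not boolean (entry %s)",
                              element$id, paste(df$entry_id[!ok], collapse = ", ")),
                      "cdelink_data_quality_error")
      }
      raw %in% c("true", "Y")
    },
    raw)
  df$value <- out
  df
}

summary_model_ok <- function(summary, dialect) {
  (inherits(summary, "graph_summary") && dialect == "graph_pattern") ||
  (inherits(summary, "xml_summary") && dialect == "path")
}

#' Extract a data element's values from a patient summary
#'
#' Resolves the extraction specification for the requested content model
#' over the semantic link chain, dispatches on the spec's dialect, and
#' coerces results to the element's value-domain datatype. The caller
#' never needs to know which concrete content model (or dialect) served
#' the request.
#'
#' @param registry A `cde_registry`.
#' @param element_id Data element id (typically an SDTM variable).
#' @param summary An `xml_summary` or `graph_summary`.
#' @param content_model_id Content model the summary conforms to.
#' @return Data frame with columns `entry_id`, `value` (typed per the
#'   element's value domain), `code_system`, plus attribute `element_id`.
#' @export
extract <- function(registry, element_id, summary, content_model_id) {
  el <- get_data_element(registry, element_id)
  res <- resolve_extraction_spec(registry, element_id, content_model_id)
  if (!summary_model_ok(summary, res$spec$dialect)) {
    abort_cdelink(sprintf(
      "summary class %s does not match dialect '%s' of content model '%s'",
      class(summary)[1], res$spec$dialect, content_model_id), "cdelink_spec_error")
  }
  df <- if (res$spec$dialect == "path") execute_path_spec(summary, res$spec)
        else execute_graph_spec(summary, res$spec)
  df <- coerce_extracted(df, el)
  attr(df, "element_id") <- element_id
  attr(df, "chain") <- res$chain
  df
}

#' Extract several elements of one object class as entry-joined rows
#'
#' A schema item frequently needs the code AND the date of the same
#' clinical entry (e.g. a medical-history problem code plus its start
#' date). This performs a per-entry outer join of the elements' values
#' on the entry id; entries missing one element get a null in that
#' slot. Values of different entries are never cross-joined.
#'
#' @param registry A `cde_registry`.
#' @param object_class_id Object class all elements must belong to.
#' @param element_ids Character vector of element ids.
#' @param summary An `xml_summary` or `graph_summary`.
#' @param content_model_id Content model the summary conforms to.
#' @return Data frame with one row per entry: `entry_id`, one (typed)
#'   column per element id, and `<element id>.system` columns carrying
#'   code systems for coded elements.
#' @export
extract_entries <- function(registry, object_class_id, element_ids, summary,
                            content_model_id) {
  for (eid in element_ids) {
    el <- get_data_element(registry, eid)
    if (!identical(el$object_class, object_class_id)) {
      abort_cdelink(sprintf("element '%s' does not belong to object class '%s'",
                            eid, object_class_id), "cdelink_engine_error")
    }
  }
  parts <- lapply(element_ids, function(eid)
    extract(registry, eid, summary, content_model_id))
  entry_order <- unique(unlist(lapply(parts, function(p) p$entry_id)))
  out <- data.frame(entry_id = entry_order, stringsAsFactors = FALSE)
  for (k in seq_along(element_ids)) {
    eid <- element_ids[k]
    p <- parts[[k]]
    # one value per entry per element: identical duplicates collapse,
    # conflicting values within one entry are a data-quality problem
    p <- p[!duplicated(p[, c("entry_id", "value")]), , drop = FALSE]
    if (anyDuplicated(p$entry_id)) {
      bad <- unique(p$entry_id[duplicated(p$entry_id)])
      abort_cdelink(sprintf(
        "element %s: conflicting values within entry %s",
        eid, paste(bad, collapse = ", ")), "cdelink_data_quality_error")
    }
    idx <- match(out$entry_id, p$entry_id)
    out[[eid]] <- p$value[idx]
    el <- get_data_element(registry, eid)
    if (el$value_domain$datatype == "code") {
      out[[paste0(eid, ".system")]] <- p$code_system[idx]
    }
  }
  out
}
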