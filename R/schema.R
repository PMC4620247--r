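# Data-collection-set schemas: named columns (schema items) annotated
# with data elements and fixed code values, each produced by a derivation
# over the entries extracted for one patient.  Items may reference other
# items (a windowed mean needs the index event's date), so evaluation is
# dependency-ordered; the engine derives the order itself.

DERIVATION_FNS <- c("VALUE", "FIRST_DATE", "LAST_VALUE_BEFORE", "MEAN_IN_WINDOW",
                    "EXISTS_BEFORE", "EXISTS_AFTER", "DATE_OFFSET", "MIN_DATE")
FNS_NEEDING_INDEX <- c("LAST_VALUE_BEFORE", "MEAN_IN_WINDOW",
                       "EXISTS_BEFORE", "EXISTS_AFTER")

#' Read a data-collection-set schema definition
#'
#' The config (YAML or JSON) lists schema items; each item names the
#' data elements it is built from (optionally with a fixed code value,
#' e.g. a MedDRA preferred term), and a derivation function with its
#' parameters. Dependencies between items are derived automatically
#' from index/candidate references.
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON schema config.
#' @param registry A `cde_registry` used to validate element references
#'   and bound values.
#' @return An object of class `dcs_schema`.
#' @examples
#' reg <- load_registry(system.file("extdata", "registry.json", package = "cdelink"))
#' sch <- read_schema(system.file("extdata", "schema-table1.yaml", package = "cdelink"), reg)
#' validate_schema(sch)
#' @export
read_schema <- function(path, registry) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  items <- lapply(cfg$items, function(it) {
    drv <- it$derivation %||% list(fn = "VALUE")
    if (!(drv$fn %in% DERIVATION_FNS)) {
      abort_cdelink(sprintf("item '%s': unknown derivation function '%s'",
                            it$name, drv$fn), "cdelink_validation_error")
    }
    bindings <- lapply(it$elements %||% list(), function(b) {
      el <- get_data_element(registry, b$element)
      out <- list(element = b$element,
                  value = b$value,
                  system = b$system %||% el$value_domain$code_system)
      if (!is.null(out$value)) {
        pv <- el$value_domain$permissible_values
        if (!is.null(pv) && !(out$value %in% pv)) {
          abort_cdelink(sprintf(
            "item '%s': bound value '%s' not permissible for element %s",
            it$name, out$value, b$element), "cdelink_validation_error")
        }
      }
      out
    })
    list(name = it$name, bindings = bindings,
         derivation = list(
           fn = drv$fn,
           index = drv$index,
           window_days = drv$window_days,
           offset_days = drv$offset_days,
           index_offset_days = drv$index_offset_days %||% 0L,
           date = drv$date,
           candidates = unlist(drv$candidates) %||% character(0),
           constants = unlist(drv$constants) %||% character(0)))
  })
  structure(list(items = items, content_model = cfg$content_model %||% "CIM-RDF"),
            class = "dcs_schema")
}

item_depends_on <- function(item, item_names) {
  deps <- character(0)
  d <- item$derivation
  if (!is.null(d$index)) deps <- c(deps, d$index)
  deps <- c(deps, intersect(d$candidates, item_names))
  unique(deps)
}

#' Validate a schema and produce its evaluation plan
#'
#' Checks name uniqueness, that index-requiring derivations carry an
#' index reference, that every dependency names an existing item, and
#' that the dependency graph is acyclic. Returns a topological order of
#' item names, stable among valid orders (ties broken by declaration
#' order).
#'
#' @param schema A `dcs_schema`.
#' @return Character vector of item names in evaluation order.
#' @export
validate_schema <- function(schema) {
  names_ <- vapply(schema$items, function(it) it$name, "")
  if (anyDuplicated(names_)) {
    abort_cdelink(sprintf("duplicate schema item name(s): %s",
                          paste(unique(names_[duplicated(names_)]), collapse = ", ")),
                  "cdelink_validation_error")
  }
  deps <- lapply(schema$items, item_depends_on, item_names = names_)
  names(deps) <- names_
  for (it in schema$items) {
    d <- it$derivation
    if (d$fn %in% FNS_NEEDING_INDEX && is.null(d$index)) {
      abort_cdelink(sprintf("item '%s': derivation %s requires an index item reference",
                            it$name, d$fn), "cdelink_validation_error")
    }
    if (identical(d$fn, "DATE_OFFSET") && is.null(d$index) && is.null(d$date)) {
      abort_cdelink(sprintf("item '%s': DATE_OFFSET needs an index item or a constant date",
                            it$name), "cdelink_validation_error")
    }
    unknown <- setdiff(deps[[it$name]], names_)
    # index references must resolve; non-item candidates were filtered out
    if (!is.null(d$index) && !(d$index %in% names_)) {
      abort_cdelink(sprintf("item '%s': unknown dependency '%s'", it$name, d$index),
                    "cdelink_validation_error")
    }
    if (length(unknown)) {
      abort_cdelink(sprintf("item '%s': unknown dependency '%s'",
                            it$name, paste(unknown, collapse = ", ")),
                    "cdelink_validation_error")
    }
  }
  # Kahn's algorithm, always taking the earliest declared ready item
  plan <- character(0)
  remaining <- names_
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm)
      all(deps[[nm]] %in% plan), TRUE)]
    if (!length(ready)) {
      abort_cdelink(sprintf("dependency cycle among schema items: %s",
                            paste(remaining, collapse = " -> ")),
                    "cdelink_validation_error")
    }
    nxt <- remaining[remaining %in% ready][1]  # declaration order
    plan <- c(plan, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  plan
}

#' Applicable derivation functions for a data element
#'
#' Determined from the element's value domain, so a schema editor can
#' offer only calculations that make sense: dates get first-occurrence
#' and offset arithmetic, quantities get windowed means and last-value
#' lookups, coded elements get existence flags.
#'
#' @param registry A `cde_registry`.
#' @param element_id Element id.
#' @return Character vector of derivation function names.
#' @export
calculation_options <- function(registry, element_id) {
  el <- get_data_element(registry, element_id)
  switch(el$value_domain$datatype,
    date = c("FIRST_DATE", "DATE_OFFSET", "MIN_DATE", "VALUE"),
    quantity = c("MEAN_IN_WINDOW", "LAST_VALUE_BEFORE", "VALUE"),
    code = c("VALUE", "EXISTS_BEFORE", "EXISTS_AFTER"),
    c("VALUE"))
}

binding_by_datatype <- function(item, registry, types) {
  for (b in item$bindings) {
    el <- get_data_element(registry, b$element)
    if (el$value_domain$datatype %in% types) return(b)
  }
  NULL
}

# entries for an item: per-entry join of its bound elements, filtered on
# any fixed code binding through the terminology service (unmatched
# warehouse codes simply fail to match; never an error)
item_entries <- function(item, summary, registry, term, content_model, cache) {
  eids <- vapply(item$bindings, function(b) b$element, "")
  if (!length(eids)) return(NULL)
  oc <- get_data_element(registry, eids[1])$object_class
  key <- paste(oc, paste(sort(eids), collapse = "|"), sep = "::")
  ent <- cache[[key]]
  if (is.null(ent)) {
    ent <- extract_entries(registry, oc, eids, summary, content_model)
    cache[[key]] <- ent
  }
  for (b in item$bindings) {
    if (is.null(b$value)) next
    syscol <- paste0(b$element, ".system")
    codes <- ent[[b$element]]
    systems <- if (syscol %in% names(ent)) ent[[syscol]] else rep(NA_character_, nrow(ent))
    keep <- vapply(seq_along(codes), function(i) {
      if (is.na(codes[i])) return(FALSE)
      si <- if (is.na(systems[i])) b$system else systems[i]
      codes_match(term, b$value, b$system, codes[i], si)
    }, TRUE)
    ent <- ent[keep, , drop = FALSE]
  }
  ent
}

index_date_for <- function(item, context) {
  d <- item$derivation
  if (is.null(d$index)) return(NULL)
  if (!(d$index %in% names(context))) {
    abort_cdelink(sprintf("item '%s': dependency '%s' missing from evaluation context",
                          item$name, d$index), "cdelink_engine_error")
  }
  idx <- context[[d$index]]
  if (is.null(idx) || length(idx) == 0 || is.na(idx)) return(NA)
  as_date_strict(idx, sprintf("index of item '%s'", item$name)) +
    as.integer(d$index_offset_days %||% 0L)
}

#' Evaluate a single schema item for one patient
#'
#' Applies the item's derivation to its entry-joined, code-filtered
#' extracted entries. A derivation over zero qualifying entries yields
#' `NA`, never an error: missing data flows through as explicit nulls.
#'
#' @param item A schema item (an element of `dcs_schema$items`).
#' @param summary Patient summary (`xml_summary` or `graph_summary`).
#' @param context Named list of already-evaluated item values for the
#'   same patient.
#' @param registry A `cde_registry`.
#' @param term A `terminology`.
#' @param content_model Content model id of `summary`.
#' @param cache Optional environment reused across items of one patient
#'   to avoid re-extracting shared element sets.
#' @return A typed scalar cell (`Date`, numeric, or character), `NA` if
#'   no qualifying data.
#' @export
evaluate_item <- function(item, summary, context, registry, term,
                          content_model, cache = new.env(parent = emptyenv())) {
  d <- item$derivation
  fn <- d$fn

  if (fn == "DATE_OFFSET") {
    base <- if (!is.null(d$index)) index_date_for(item, context)
            else as_date_strict(d$date, "DATE_OFFSET constant")
    if (is.null(base) || is.na(base)) return(as.Date(NA))
    return(base + as.integer(d$offset_days %||% 0L))
  }
  if (fn == "MIN_DATE") {
    vals <- as.Date(character(0))
    for (cand in d$candidates) {
      if (!(cand %in% names(context))) {
        abort_cdelink(sprintf("item '%s': dependency '%s' missing from evaluation context",
                              item$name, cand), "cdelink_engine_error")
      }
      v <- context[[cand]]
      if (!is.null(v) && length(v) && !is.na(v)) vals <- c(vals, as_date_strict(v))
    }
    for (cst in d$constants) vals <- c(vals, as_date_strict(cst, "MIN_DATE constant"))
    if (!length(vals)) return(as.Date(NA))
    return(min(vals))
  }

  ent <- item_entries(item, summary, registry, term, content_model, cache)
  datecol <- binding_by_datatype(item, registry, "date")
  dates <- if (!is.null(datecol) && !is.null(ent)) ent[[datecol$element]] else NULL

  if (fn == "VALUE") {
    b <- item$bindings[[1]]
    # the value element is the first binding without a fixed code filter,
    # falling back to the first binding
    for (bb in item$bindings) if (is.null(bb$value)) { b <- bb; break }
    v <- ent[[b$element]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      el <- get_data_element(registry, b$element)
      return(switch(el$value_domain$datatype, date = as.Date(NA),
                    quantity = NA_real_, NA_character_))
    }
    u <- unique(v)
    if (length(u) > 1) {
      abort_cdelink(sprintf("item '%s': conflicting duplicate values (%s)",
                            item$name, paste(u, collapse = ", ")),
                    "cdelink_data_quality_error")
    }
    return(u)
  }

  if (fn == "FIRST_DATE") {
    dd <- dates[!is.na(dates)]
    if (!is.null(d$index)) {
      idx <- index_date_for(item, context)
      if (is.na(idx)) return(as.Date(NA))
      dd <- dd[dd >= idx]
    }
    if (!length(dd)) return(as.Date(NA))
    return(min(dd))
  }

  idx <- index_date_for(item, context)
  if (is.null(idx) || is.na(idx)) {
    return(if (fn %in% c("EXISTS_BEFORE", "EXISTS_AFTER")) NA_character_ else NA_real_)
  }

  if (fn == "EXISTS_BEFORE") {
    return(if (any(!is.na(dates) & dates < idx)) "Y" else "N")
  }
  if (fn == "EXISTS_AFTER") {
    return(if (any(!is.na(dates) & dates >= idx)) "Y" else "N")
  }

  qb <- binding_by_datatype(item, registry, c("quantity", "code", "text"))
  vals <- if (!is.null(qb) && !is.null(ent)) ent[[qb$element]] else NULL
  ok <- !is.na(vals) & !is.na(dates)

  if (fn == "MEAN_IN_WINDOW") {
    w <- as.integer(d$window_days %||% DAYS_PER_YEAR)
    # half-open window (index - w, index]: avoids double counting at
    # the boundary between adjacent windows
    inw <- ok & dates > (idx - w) & dates <= idx
    if (!any(inw)) return(NA_real_)
    return(mean(vals[inw]))
  }
  if (fn == "LAST_VALUE_BEFORE") {
    before <- ok & dates <= idx
    if (!any(before)) return(NA_real_)
    cand <- which(before)
    cand <- cand[order(dates[cand], cand)]  # maximal date; ties -> last entry
    return(vals[cand[length(cand)]])
  }
  abort_cdelink(sprintf("unhandled derivation '%s'", fn), "cdelink_engine_error")
}

item_output_class <- function(item, registry) {
  d <- item$derivation
  if (d$fn %in% c("FIRST_DATE", "DATE_OFFSET", "MIN_DATE")) return("Date")
  if (d$fn %in% c("EXISTS_BEFORE", "EXISTS_AFTER")) return("character")
  if (d$fn %in% c("MEAN_IN_WINDOW", "LAST_VALUE_BEFORE")) return("numeric")
  # VALUE: type of the (first unfixed) bound element
  b <- item$bindings[[1]]
  for (bb in item$bindings) if (is.null(bb$value)) { b <- bb; break }
  el <- get_data_element(registry, b$element)
  switch(el$value_domain$datatype, date = "Date", quantity = "numeric", "character")
}

na_of <- function(cls) switch(cls, Date = as.Date(NA), numeric = NA_real_, NA_character_)

#' Populate a data collection set
#'
#' Runs the schema's evaluation plan for every patient and assembles
#' the analysis-ready table: one row per patient, one typed column per
#' schema item, explicit `NA` for missing data (empty columns are a
#' legitimate outcome on sparsely structured sources). Patients are
#' rendered into the requested content model on the fly when canonical
#' records are supplied; the result is identical whichever content
#' model is used.
#'
#' @param schema A `dcs_schema`.
#' @param cohort List of patients: canonical `patient_record`s (rendered
#'   internally) or pre-rendered `xml_summary`/`graph_summary` objects.
#' @param registry A `cde_registry`.
#' @param term A `terminology`.
#' @param content_model_id Content model to execute against; defaults
#'   to the schema's.
#' @return A data frame (`patient_id` plus one column per item) with
#'   attribute `element_bindings` mapping columns to element ids.
#' @export
populate <- function(schema, cohort, registry, term,
                     content_model_id = schema$content_model) {
  plan <- validate_schema(schema)
  items <- schema$items
  names(items) <- vapply(items, function(it) it$name, "")
  cls <- vapply(items, item_output_class, "", registry = registry)
  cols <- lapply(cls, function(cl) rep(na_of(cl), length(cohort)))
  pid <- character(length(cohort))

  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    summary <- if (inherits(p, "patient_record")) {
      if (content_model_id == "CCD-XML") render_xml(p) else render_graph(p)
    } else p
    pid[i] <- summary$patient_id
    cache <- new.env(parent = emptyenv())
    context <- list()
    for (nm in plan) {
      cell <- tryCatch(
        evaluate_item(items[[nm]], summary, context, registry, term,
                      content_model_id, cache),
        cdelink_error = function(e) {
          abort_cdelink(sprintf("patient %s, item '%s': %s",
                                summary$patient_id, nm, conditionMessage(e)),
                        class(e)[1])
        })
      context[[nm]] <- cell
      if (!is.na(cell)) cols[[nm]][i] <- cell
    }
  }
  out <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
  for (nm in names(items)) out[[nm]] <- cols[[nm]]
  attr(out, "element_bindings") <- lapply(items, function(it)
    vapply(it$bindings, function(b) b$element, ""))
  out
}

#' Write a data collection set to CSV (with a column-metadata sidecar)
#'
#' RFC 4180 CSV, one row per patient, nulls as empty fields; the
#' optional sidecar JSON maps each column to the data element ids that
#' defined it.
#'
#' @param dcs A populated data collection set.
#' @param path Output CSV path.
#' @param sidecar Whether to also write `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_dcs <- function(dcs, path, sidecar = TRUE) {
  utils::write.csv(dcs, path, row.names = FALSE, na = "")
  if (sidecar) {
    meta <- attr(dcs, "element_bindings")
    if (!is.null(meta)) {
      jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = FALSE)
    }
  }
  invisible(path)
}
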