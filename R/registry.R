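# In-process semantic metadata registry: ISO/IEC 11179-style data element
# definitions (object class, value domain), SKOS links between element sets
# maintained by different organisations (SDTM variables, an RDF common
# information model, a CCD-bound data dictionary), and the extraction
# specifications attached to them.  Retrieval follows the metadata
# source/consumer contract: element id in, full definition plus extraction
# spec out.  Peer registries are loaded into one federated in-memory store.

VALID_DATATYPES <- c("code", "date", "quantity", "text", "boolean")
VALID_PREDICATES <- c("exactMatch", "notation")
VALID_DIALECTS <- c("graph_pattern", "path")
VALID_ANCHORS <- c("entry", "document")

#' Load a metadata registry dump
#'
#' Reads a registry dump (JSON) holding one or more peer registries of
#' common data element definitions and merges them into a single
#' federated in-memory store. Every element carries its object class,
#' value domain, extraction specifications (XPath or graph-pattern
#' scripts bound to a content model) and semantic links to elements of
#' peer registries.
#'
#' All structural invariants are validated at load time: element ids
#' must be globally unique, every semantic link target must resolve
#' within the loaded registries, coded value domains must name their
#' code system, and an element may carry at most one extraction
#' specification per content model.
#'
#' @param source Path to a registry dump JSON file, or an already-parsed
#'   list with the same structure.
#' @return An object of class `cde_registry`.
#' @examples
#' reg <- load_registry(system.file("extdata", "registry.json", package = "cdelink"))
#' get_data_element(reg, "SDTM:MH.MHPTCD")$value_domain$datatype
#' @export
load_registry <- function(source) {
  dump <- if (is.character(source)) {
    jsonlite::read_json(source, simplifyVector = FALSE)
  } else {
    source
  }
  if (is.null(dump$registries)) {
    # single-registry shorthand {elements: [...]}
    dump <- list(registries = list(list(
      registry_id = dump$registry_id %||% "default",
      elements = dump$elements %||% list()
    )))
  }

  content_models <- list()
  for (cm in dump$content_models %||% list()) {
    content_models[[cm$id]] <- list(id = cm$id, payload = cm$payload %||% "document")
  }

  elements <- list()
  element_registry <- character(0)
  registries <- character(0)
  for (r in dump$registries) {
    rid <- r$registry_id
    registries <- c(registries, rid)
    for (e in r$elements %||% list()) {
      el <- normalize_element(e)
      if (!is.null(elements[[el$id]])) {
        abort_cdelink(sprintf("duplicate element id '%s'", el$id),
                      "cdelink_load_error")
      }
      elements[[el$id]] <- el
      element_registry[el$id] <- rid
    }
  }

  # dangling link targets
  ids <- names(elements)
  dangling <- character(0)
  for (el in elements) {
    for (lk in el$links) {
      if (!(lk$target %in% ids)) dangling <- c(dangling, lk$target)
    }
  }
  if (length(dangling)) {
    abort_cdelink(sprintf("semantic link target(s) not found in any loaded registry: %s",
                          paste(sort(unique(dangling)), collapse = ", ")),
                  "cdelink_load_error")
  }

  # dialect / content-model payload compatibility (when models declared)
  if (length(content_models)) {
    for (el in elements) {
      for (sp in el$extraction_specs) {
        cm <- content_models[[sp$content_model]]
        if (is.null(cm)) next
        ok <- (sp$dialect == "graph_pattern" && cm$payload == "graph") ||
              (sp$dialect == "path" && cm$payload == "document")
        if (!ok) {
          abort_cdelink(sprintf(
            "element '%s': dialect '%s' incompatible with content model '%s' (payload '%s')",
            el$id, sp$dialect, sp$content_model, cm$payload), "cdelink_load_error")
        }
      }
    }
  }

  # object classes derived from elements
  ocs <- list()
  for (el in elements) {
    oc <- el$object_class
    if (is.null(ocs[[oc]])) {
      ocs[[oc]] <- list(id = oc, name = sub("^[^:]*:", "", oc), element_ids = character(0))
    }
    ocs[[oc]]$element_ids <- c(ocs[[oc]]$element_ids, el$id)
  }
  for (oc in names(ocs)) ocs[[oc]]$element_ids <- sort(ocs[[oc]]$element_ids)

  structure(list(
    registries = unique(registries),
    elements = elements,
    element_registry = element_registry,
    object_classes = ocs,
    content_models = content_models
  ), class = "cde_registry")
}

normalize_element <- function(e) {
  if (is.null(e$id) || !nzchar(e$id)) {
    abort_cdelink("element without id in registry dump", "cdelink_load_error")
  }
  vd <- e$value_domain %||% list(datatype = "text")
  if (!(vd$datatype %in% VALID_DATATYPES)) {
    abort_cdelink(sprintf("element '%s': unknown datatype '%s'", e$id, vd$datatype),
                  "cdelink_load_error")
  }
  if (identical(vd$datatype, "code") && is.null(vd$code_system)) {
    abort_cdelink(sprintf("element '%s': coded value domain without code_system", e$id),
                  "cdelink_load_error")
  }
  specs <- list()
  for (sp in e$extraction_specs %||% list()) {
    if (!(sp$dialect %in% VALID_DIALECTS)) {
      abort_cdelink(sprintf("element '%s': unknown dialect '%s'", e$id, sp$dialect),
                    "cdelink_load_error")
    }
    if (!is.null(specs[[sp$content_model]])) {
      abort_cdelink(sprintf("element '%s': more than one extraction spec for content model '%s'",
                            e$id, sp$content_model), "cdelink_load_error")
    }
    specs[[sp$content_model]] <- list(
      content_model = sp$content_model,
      dialect = sp$dialect,
      script = sp$script,
      anchor = if (!is.null(sp$anchor) && sp$anchor %in% VALID_ANCHORS) sp$anchor else "entry"
    )
  }
  links <- lapply(e$links %||% list(), function(lk) {
    if (!(lk$predicate %in% VALID_PREDICATES)) {
      abort_cdelink(sprintf("element '%s': unknown link predicate '%s'", e$id, lk$predicate),
                    "cdelink_load_error")
    }
    list(predicate = lk$predicate, target = lk$target)
  })
  list(
    id = e$id,
    name = e$name %||% e$id,
    definition = e$definition %||% "",
    object_class = e$object_class %||% sub("\\.[^.]*$", "", e$id),
    value_domain = list(
      datatype = vd$datatype,
      code_system = vd$code_system,
      unit = vd$unit,
      permissible_values = unlist(vd$permissible_values) %||% NULL
    ),
    extraction_specs = specs,
    links = links
  )
}

#' Dump a registry back to its JSON dialect
#'
#' Inverse of [load_registry()]: writing a loaded registry and loading
#' the written file reproduces the same store (round trip is idempotent;
#' elements are emitted sorted by id).
#'
#' @param registry A `cde_registry`.
#' @param path Output file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly), or the JSON string when `path` is `NULL`.
#' @export
dump_registry <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "cde_registry"))
  regs <- lapply(sort(registry$registries), function(rid) {
    ids <- sort(names(registry$element_registry)[registry$element_registry == rid])
    list(
      registry_id = rid,
      elements = lapply(ids, function(id) {
        el <- registry$elements[[id]]
        vd <- el$value_domain
        out <- list(id = el$id, name = el$name, definition = el$definition,
                    object_class = el$object_class,
                    value_domain = Filter(Negate(is.null), list(
                      datatype = vd$datatype, code_system = vd$code_system,
                      unit = vd$unit,
                      permissible_values = as.list(vd$permissible_values)
                    )))
        if (!length(out$value_domain$permissible_values)) {
          out$value_domain$permissible_values <- NULL
        }
        sps <- el$extraction_specs
        if (length(sps)) sps <- sps[order(names(sps))]
        out$extraction_specs <- unname(lapply(sps, function(sp) {
          list(content_model = sp$content_model, dialect = sp$dialect,
               script = sp$script, anchor = sp$anchor)
        }))
        out$links <- lapply(el$links, function(lk) {
          list(predicate = lk$predicate, target = lk$target)
        })
        out
      })
    )
  })
  cms <- unname(lapply(registry$content_models[order(names(registry$content_models))],
                       function(cm) list(id = cm$id, payload = cm$payload)))
  obj <- list(content_models = cms, registries = regs)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Retrieve a full data element definition
#'
#' The in-process metadata-source contract: given an element id, return
#' the complete definition including value domain, semantic links and
#' extraction specifications.
#'
#' @param registry A `cde_registry`.
#' @param element_id Element id, e.g. `"SDTM:MH.MHPTCD"`.
#' @return A list describing the element.
#' @export
get_data_element <- function(registry, element_id) {
  el <- registry$elements[[element_id]]
  if (is.null(el)) {
    abort_cdelink(sprintf("data element '%s' not found", element_id),
                  "cdelink_not_found_error")
  }
  el
}

#' List the object classes (domains) of a registry
#'
#' Object classes give the top-down browsing entry point: SDTM domains
#' (DM, MH, ...) on the research side, Patient/Condition/Observation on
#' the EHR side.
#'
#' @param registry A `cde_registry`.
#' @param registry_id Which peer registry to list, e.g. `"SDTM"`.
#' @return A list of object classes, sorted by id.
#' @export
list_object_classes <- function(registry, registry_id) {
  if (!(registry_id %in% registry$registries)) {
    abort_cdelink(sprintf("registry '%s' not loaded", registry_id),
                  "cdelink_not_found_error")
  }
  ids <- names(registry$element_registry)[registry$element_registry == registry_id]
  ocs <- unique(vapply(registry$elements[ids], function(e) e$object_class, ""))
  registry$object_classes[sort(ocs)]
}

#' List the data elements of an object class
#'
#' @param registry A `cde_registry`.
#' @param object_class_id Object class id, e.g. `"SDTM:MH"`.
#' @return A list of elements, sorted by id.
#' @export
list_elements <- function(registry, object_class_id) {
  oc <- registry$object_classes[[object_class_id]]
  if (is.null(oc)) {
    abort_cdelink(sprintf("object class '%s' not found", object_class_id),
                  "cdelink_not_found_error")
  }
  registry$elements[oc$element_ids]
}

# Symmetric exactMatch adjacency (skos:exactMatch is symmetric by
# definition; links are stored directionally but traversed both ways).
exact_match_adjacency <- function(registry) {
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- unique(c(adj[[a]], b))
    adj[[b]] <<- unique(c(adj[[b]], a))
  }
  for (el in registry$elements) {
    for (lk in el$links) {
      if (lk$predicate == "exactMatch") add(el$id, lk$target)
    }
  }
  adj
}

#' Resolve the extraction specification for a content model
#'
#' Breadth-first traversal over the symmetric exactMatch link chain
#' starting at `element_id`, stopping at the first element that carries
#' an extraction specification for `content_model_id` (shortest chain;
#' ties among equally short chains broken by lexicographic element-id
#' order, for determinism). A chain of length 1 means the element
#' itself carries the specification.
#'
#' @param registry A `cde_registry`.
#' @param element_id Starting element id.
#' @param content_model_id Content model, e.g. `"CIM-RDF"` or `"CCD-XML"`.
#' @return A list with `spec` (the extraction specification), `holder`
#'   (id of the element carrying it) and `chain` (element ids from the
#'   start to the holder, inclusive).
#' @export
resolve_extraction_spec <- function(registry, element_id, content_model_id) {
  get_data_element(registry, element_id)  # not-found check
  adj <- exact_match_adjacency(registry)
  parent <- structure(NA_character_, names = element_id)
  visited <- element_id
  frontier <- element_id
  repeat {
    frontier <- sort(frontier)
    for (id in frontier) {
      sp <- registry$elements[[id]]$extraction_specs[[content_model_id]]
      if (!is.null(sp)) {
        chain <- id
        while (!is.na(parent[[chain[1]]])) chain <- c(parent[[chain[1]]], chain)
        return(list(spec = sp, holder = id, chain = chain))
      }
    }
    nxt <- character(0)
    for (id in frontier) {
      for (nb in adj[[id]] %||% character(0)) {
        if (!(nb %in% visited)) {
          visited <- c(visited, nb)
          parent[nb] <- id
          nxt <- c(nxt, nb)
        }
      }
    }
    if (!length(nxt)) {
      abort_cdelink(sprintf(
        "no extraction spec for content model '%s' reachable from '%s' (searched: %s)",
        content_model_id, element_id, paste(sort(visited), collapse = ", ")),
        "cdelink_resolution_error")
    }
    frontier <- nxt
  }
}

#' Transitive exactMatch closure of an element
#'
#' All elements reachable from `element_id` over exactMatch links,
#' treated as symmetric and transitive (the connected component),
#' excluding the element itself.
#'
#' @param registry A `cde_registry`.
#' @param element_id Element id.
#' @return A sorted character vector of element ids (possibly empty).
#' @export
transitive_matches <- function(registry, element_id) {
  get_data_element(registry, element_id)
  adj <- exact_match_adjacency(registry)
  seen <- element_id
  frontier <- element_id
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, function(id) adj[[id]]))), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(seen, element_id))
}

#' @export
print.cde_registry <- function(x, ...) {
  cat(sprintf("<cde_registry> %d peer registr%s (%s), %d elements, %d object classes\n",
              length(x$registries), if (length(x$registries) == 1) "y" else "ies",
              paste(x$registries, collapse = ", "),
              length(x$elements), length(x$object_classes)))
  invisible(x)
}
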