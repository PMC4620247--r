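# End-to-end orchestration of the study data flow: schema definition ->
# metadata retrieval -> cohort eligibility -> extraction -> derivation ->
# populated data collection set -> incidence report.

#' Shipped reference registry, terminology and schema configurations
#'
#' Convenience loaders for the fixtures installed with the package: the
#' three-peer registry (SDTM variables, the RDF common-information-model
#' element set with graph-pattern extraction specs, and the CCD-bound
#' data dictionary with XPath specs), the toy MedDRA/ICD-9-CM
#' terminology with its concept map, and the study schema configs.
#'
#' @return [default_registry()] a `cde_registry`; [default_terminology()]
#'   a `terminology`.
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "registry.json", package = "cdelink"))
}

#' @rdname default_registry
#' @export
default_terminology <- function() {
  load_terminology(system.file("extdata", "concepts.csv", package = "cdelink"),
                   system.file("extdata", "concept_map.csv", package = "cdelink"))
}

#' Path to a shipped schema config
#' @param which `"table1"` (the six-item core schema) or `"study"` (the
#'   full schema with follow-up dates and windowed calculations).
#' @return File path.
#' @export
schema_fixture <- function(which = c("study", "table1")) {
  which <- match.arg(which)
  system.file("extdata", paste0("schema-", which, ".yaml"), package = "cdelink")
}

age_group <- function(age, breaks = c(18, 50, 65, Inf),
                      labels = c("18-49", "50-64", "65+")) {
  as.character(cut(age, breaks = breaks, labels = labels, right = FALSE))
}

#' Cohort study table from canonical records
#'
#' The scalable evaluation path: derives the per-member study columns
#' (demographics, index dates, CHF flags and first post-ACS CHF date,
#' death) directly from canonical patient records, using the same
#' eligibility rules and terminology matching as the semantic
#' extraction path. [populate()] over either content-model rendering
#' reproduces these columns cell for cell (a tested invariant); this
#' path simply skips the serialization round trip, which matters when
#' simulating tens of thousands of patients.
#'
#' @param patients List of `patient_record`s.
#' @param criteria An `eligibility_criteria`.
#' @param term A `terminology`.
#' @param chf_code,chf_code_system Code identifying congestive heart
#'   failure on the research side.
#' @return A list with `members` data frame (SEX, AGE, AGEGRP, ACS_DATE,
#'   STARTDATE, LASTDATE, CHF_BEFORE_ACS, CHF_AFTER_ACS, CHF_AFTER_DATE,
#'   DIED) and `exclusions` counts.
#' @export
study_table <- function(patients, criteria = eligibility_criteria(),
                        term = default_terminology(),
                        chf_code = "10007559", chf_code_system = "MedDRA") {
  elig <- apply_eligibility(patients, criteria, term)
  m <- elig$members
  chf_set <- expand_code_set(term, chf_code, chf_code_system, "ICD9CM")
  idx <- match(m$patient_id, vapply(patients, function(p) p$patient_id, ""))
  chf_before <- character(nrow(m))
  chf_after <- character(nrow(m))
  chf_after_date <- rep(as.Date(NA), nrow(m))
  for (k in seq_len(nrow(m))) {
    p <- patients[[idx[k]]]
    hit <- condition_matches(p$conditions, chf_set)
    dates <- p$conditions$start_date[hit]
    chf_before[k] <- if (any(dates < m$acs_date[k])) "Y" else "N"
    after <- dates[dates >= m$start_date[k]]
    chf_after[k] <- if (length(after)) "Y" else "N"
    if (length(after)) chf_after_date[k] <- min(after)
  }
  members <- data.frame(
    patient_id = m$patient_id,
    SEX = m$sex,
    AGE = m$age_at_acs,
    AGEGRP = age_group(m$age_at_acs),
    ACS_DATE = m$acs_date,
    STARTDATE = m$start_date,
    LASTDATE = m$last_date,
    CHF_BEFORE_ACS = chf_before,
    CHF_AFTER_ACS = chf_after,
    CHF_AFTER_DATE = chf_after_date,
    DIED = ifelse(is.na(m$death_date), "N", "Y"),
    stringsAsFactors = FALSE)
  list(members = members, exclusions = elig$exclusions)
}

step_log <- function(verbose, n, msg) {
  if (verbose) message(sprintf("[step %s] %s", n, msg))
}

#' Run the full study pipeline
#'
#' Executes the complete data flow on a set of canonical patient
#' records: (1) schema definition read, (2) element definitions
#' retrieved from the registry, (3) value bindings checked against the
#' terminology, (4) evaluation plan derived, (5) cohort eligibility
#' applied, (6) extraction specifications resolved over the semantic
#' links and executed on each member's summary in the chosen content
#' model, (7) the data collection set populated, (8) the incidence
#' report computed. Steps are logged to standard error.
#'
#' @param patients List of `patient_record`s (e.g. from [generate()]).
#' @param schema A `dcs_schema` or path to a schema config.
#' @param registry A `cde_registry`.
#' @param term A `terminology`.
#' @param criteria An `eligibility_criteria`.
#' @param content_model_id `"CIM-RDF"` or `"CCD-XML"`.
#' @param event_column Event date column for the incidence report.
#' @param strata Stratification columns for the report.
#' @param verbose Log data-flow steps to standard error.
#' @return A list with `dcs` (populated set, cohort members only),
#'   `members`, `exclusions`, and `report` (stratified incidence rates,
#'   with an `overall` attribute row).
#' @export
run_study <- function(patients, schema, registry = default_registry(),
                      term = default_terminology(),
                      criteria = eligibility_criteria(),
                      content_model_id = NULL,
                      event_column = "CHF_AFTER_DATE",
                      strata = c("SEX"),
                      verbose = TRUE) {
  step_log(verbose, 1, "reading data collection set schema definition")
  if (is.character(schema)) schema <- read_schema(schema, registry)
  cm <- content_model_id %||% schema$content_model
  step_log(verbose, 2, sprintf("retrieving %d data element definitions from the registry",
                               length(unique(unlist(lapply(schema$items, function(it)
                                 vapply(it$bindings, function(b) b$element, "")))))))
  step_log(verbose, 3, "validating fixed value bindings against the terminology")
  plan <- validate_schema(schema)
  step_log(verbose, 4, sprintf("evaluation plan: %s", paste(plan, collapse = " -> ")))
  step_log(verbose, 5, sprintf("applying eligibility criteria to %d patients", length(patients)))
  elig <- apply_eligibility(patients, criteria, term)
  members <- elig$members
  step_log(verbose, 6, sprintf(
    "resolving extraction specs for content model %s and extracting %d cohort members",
    cm, nrow(members)))
  cohort <- patients[match(members$patient_id,
                           vapply(patients, function(p) p$patient_id, ""))]
  step_log(verbose, 7, "populating the data collection set")
  dcs <- populate(schema, cohort, registry, term, content_model_id = cm)
  # follow-up dates for the report come from the schema itself when it
  # defines them, otherwise from the eligibility output
  colmap <- c(STARTDATE = "start_date", LASTDATE = "last_date")
  for (col in names(colmap)) {
    if (!(col %in% names(dcs))) dcs[[col]] <- members[[colmap[[col]]]]
  }
  if (!("AGEGRP" %in% names(dcs))) dcs$AGEGRP <- age_group(members$age_at_acs)
  step_log(verbose, 8, "computing stratified incidence report")
  report <- if (event_column %in% names(dcs)) {
    incidence_rate(dcs, event_column, strata = strata, zero_follow_up = "drop")
  } else NULL
  overall <- if (event_column %in% names(dcs)) {
    incidence_rate(dcs, event_column, zero_follow_up = "drop")
  } else NULL
  list(dcs = dcs, members = members, exclusions = elig$exclusions,
       report = report, overall = overall)
}

#' Describe a data element: metadata, mappings, calculation options
#'
#' Prints the element's definition and value domain, its transitive
#' exactMatch mappings, the resolution chain and dialect used for each
#' known content model, and the derivation functions applicable to its
#' value domain.
#'
#' @param element_id Element id.
#' @param registry A `cde_registry`.
#' @return The assembled description, invisibly (a list).
#' @export
describe_element <- function(element_id, registry = default_registry()) {
  el <- get_data_element(registry, element_id)
  cat(sprintf("%s  (%s)\n", el$id, el$name))
  if (nzchar(el$definition)) cat(sprintf("  definition: %s\n", el$definition))
  cat(sprintf("  object class: %s\n", el$object_class))
  vd <- el$value_domain
  cat(sprintf("  value domain: %s%s%s\n", vd$datatype,
              if (!is.null(vd$code_system)) paste0(", code system ", vd$code_system) else "",
              if (!is.null(vd$unit)) paste0(", unit ", vd$unit) else ""))
  tm <- transitive_matches(registry, element_id)
  cat(sprintf("  exactMatch closure: %s\n",
              if (length(tm)) paste(tm, collapse = ", ") else "(none)"))
  chains <- list()
  for (cmid in names(registry$content_models)) {
    res <- tryCatch(resolve_extraction_spec(registry, element_id, cmid),
                    cdelink_resolution_error = function(e) NULL)
    if (!is.null(res)) {
      chains[[cmid]] <- res
      cat(sprintf("  %s: %s spec held by %s via chain %s\n", cmid,
                  res$spec$dialect, res$holder, paste(res$chain, collapse = " -> ")))
    } else {
      cat(sprintf("  %s: no extraction spec reachable\n", cmid))
    }
  }
  opts <- calculation_options(registry, element_id)
  cat(sprintf("  calculation options: %s\n", paste(opts, collapse = ", ")))
  invisible(list(element = el, matches = tm, chains = chains, options = opts))
}
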