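# Twin renderings of the canonical patient record: a Turtle triple graph
# over the toy common-information-model vocabulary, and a CCD-like XML
# document (sections of entries holding coded acts/observations).  Both
# derive from the same canonical record and are lossless for every field
# the extraction specifications touch, so a schema populated from either
# rendering must agree cell for cell.

cim_iri <- function(local) iri(paste0(CIM_NS, local))

fmt_quantity <- function(x) sprintf("%.1f", x)

#' Render a patient record as an RDF graph summary
#'
#' @param patient A `patient_record`.
#' @return A `graph_summary`. Rendering is pure: the same record always
#'   yields the identical triple set.
#' @export
render_graph <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  pid <- patient$patient_id
  pat <- cim_iri(paste0("pat_", pid))
  s <- p <- o <- character(0)
  add <- function(su, pr, ob) {
    s <<- c(s, su); p <<- c(p, pr); o <<- c(o, ob)
  }
  add(pat, RDF_TYPE, cim_iri("Patient"))
  add(pat, cim_iri("patientId"), lit(pid))
  add(pat, cim_iri("gender"), lit(patient$sex))
  add(pat, cim_iri("birthDate"), lit(format(patient$birth_date)))
  add(pat, cim_iri("registrationDate"), lit(format(patient$registration_date)))
  if (!is.na(patient$death_date)) {
    add(pat, cim_iri("deathDate"), lit(format(patient$death_date)))
  }
  if (!is.na(patient$transfer_date)) {
    add(pat, cim_iri("transferDate"), lit(format(patient$transfer_date)))
  }
  cd <- patient$conditions
  for (k in seq_len(nrow(cd))) {
    node <- cim_iri(paste0(pid, "_", cd$entry_id[k]))
    add(node, RDF_TYPE, cim_iri("Condition"))
    add(node, cim_iri("ofPatient"), pat)
    add(node, cim_iri("code"), lit(cd$code[k]))
    add(node, cim_iri("codeSystem"), lit(cd$code_system[k]))
    add(node, cim_iri("startDate"), lit(format(cd$start_date[k])))
  }
  ob <- patient$observations
  for (k in seq_len(nrow(ob))) {
    node <- cim_iri(paste0(pid, "_", ob$entry_id[k]))
    add(node, RDF_TYPE, cim_iri("Observation"))
    add(node, cim_iri("ofPatient"), pat)
    add(node, cim_iri("code"), lit(ob$code[k]))
    add(node, cim_iri("codeSystem"), lit(ob$code_system[k]))
    add(node, cim_iri("value"), lit(fmt_quantity(ob$value[k])))
    add(node, cim_iri("unit"), lit(ob$unit[k]))
    add(node, cim_iri("date"), lit(format(ob$date[k])))
  }
  graph_summary(data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE), pat, pid)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Render a patient record as a CCD-like XML summary
#'
#' Document layout mirrors the component/structuredBody/section/entry
#' nesting of continuity-of-care documents: a `conditions` section of
#' coded acts with effective times, and an `observations` section of
#' coded observations with values, units and effective times. Every
#' coded node carries `code` and `codeSystem`; every dated node carries
#' an ISO-8601 `value`.
#'
#' @param patient A `patient_record`.
#' @return An `xml_summary`.
#' @export
render_xml <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  xml_summary(xml2::read_xml(render_xml_string(patient)))
}

#' Serialize a patient record to the XML dialect
#' @param patient A `patient_record`.
#' @return A single XML string (deterministic for a given record).
#' @export
render_xml_string <- function(patient) {
  lines <- c(
    sprintf("<ClinicalDocument patientId=\"%s\">", xml_escape(patient$patient_id)),
    "  <recordTarget>",
    "    <patient>",
    sprintf("      <gender code=\"%s\" codeSystem=\"HL7-AdministrativeGender\"/>",
            xml_escape(patient$sex)),
    sprintf("      <birthTime value=\"%s\"/>", format(patient$birth_date)),
    sprintf("      <registrationTime value=\"%s\"/>", format(patient$registration_date)))
  if (!is.na(patient$death_date)) {
    lines <- c(lines, sprintf("      <deathTime value=\"%s\"/>", format(patient$death_date)))
  }
  if (!is.na(patient$transfer_date)) {
    lines <- c(lines, sprintf("      <transferTime value=\"%s\"/>", format(patient$transfer_date)))
  }
  lines <- c(lines,
    "    </patient>",
    "  </recordTarget>",
    "  <component>",
    "    <structuredBody>",
    "      <component>",
    "        <section code=\"conditions\">")
  cd <- patient$conditions
  for (k in seq_len(nrow(cd))) {
    lines <- c(lines,
      sprintf("          <entry id=\"%s\">", cd$entry_id[k]),
      "            <act>",
      sprintf("              <code code=\"%s\" codeSystem=\"%s\"/>",
              xml_escape(cd$code[k]), xml_escape(cd$code_system[k])),
      sprintf("              <effectiveTime value=\"%s\"/>", format(cd$start_date[k])),
      "            </act>",
      "          </entry>")
  }
  lines <- c(lines,
    "        </section>",
    "      </component>",
    "      <component>",
    "        <section code=\"observations\">")
  ob <- patient$observations
  for (k in seq_len(nrow(ob))) {
    lines <- c(lines,
      sprintf("          <entry id=\"%s\">", ob$entry_id[k]),
      "            <observation>",
      sprintf("              <code code=\"%s\" codeSystem=\"%s\"/>",
              xml_escape(ob$code[k]), xml_escape(ob$code_system[k])),
      sprintf("              <value value=\"%s\" unit=\"%s\"/>",
              fmt_quantity(ob$value[k]), xml_escape(ob$unit[k])),
      sprintf("              <effectiveTime value=\"%s\"/>", format(ob$date[k])),
      "            </observation>",
      "          </entry>")
  }
  lines <- c(lines,
    "        </section>",
    "      </component>",
    "    </structuredBody>",
    "  </component>",
    "</ClinicalDocument>")
  paste(lines, collapse = "\n")
}

#' Write a generated population to disk
#'
#' One Turtle and one XML file per patient plus the ground truth as
#' JSON -- the on-disk form of the synthetic warehouse extract.
#'
#' @param population Result of [generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in population$patients) {
    writeLines(write_turtle(render_graph(p)),
               file.path(dir, paste0(p$patient_id, ".ttl")))
    writeLines(render_xml_string(p),
               file.path(dir, paste0(p$patient_id, ".xml")))
  }
  gt <- population$ground_truth
  for (col in names(gt)) if (inherits(gt[[col]], "Date")) gt[[col]] <- format(gt[[col]])
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(dir)
}
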