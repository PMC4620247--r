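Package: cdelink
Title: Common Data Element Driven Extraction of Analysis-Ready Data
    Collection Sets from Heterogeneous EHR Patient Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A semantic metadata registry of ISO/IEC 11179-style common
    data elements (CDEs) with SKOS exactMatch link traversal lets a
    clinical researcher define a data-collection-set schema in research
    vocabulary (SDTM variables) and have it executed against electronic
    health record patient summaries in whichever content model the
    source exposes: a CCD-like XML document dialect queried with XPath,
    or an RDF triple dialect (Turtle) queried with a SPARQL basic graph
    pattern subset. Includes a fixture-scale terminology service for
    MedDRA to ICD-9-CM value matching, a dependency-ordered derivation
    engine for time-windowed calculations (window means, first/last
    values, existence flags, date offsets), pharmacoepidemiological
    cohort selection with person-time incidence-rate reporting, and a
    seeded synthetic longitudinal patient generator with recorded
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
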