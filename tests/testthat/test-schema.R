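write_schema_yaml <- function(items_yaml) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(c("content_model: CIM-RDF", "items:", items_yaml), path)
  path
}

test_that("the evaluation plan is a stable topological order of the dependencies", {
  reg <- fixture_registry()
  sch <- read_schema(schema_fixture("study"), reg)
  plan <- validate_schema(sch)
  expect_lt(match("ACS_DATE", plan), match("CHF_BEFORE_ACS", plan))
  expect_lt(match("ACS_DATE", plan), match("STARTDATE", plan))
  # CHF_AFTER_DATE is declared before STARTDATE but depends on it
  expect_lt(match("STARTDATE", plan), match("CHF_AFTER_DATE", plan))
  expect_lt(match("DEATH_DATE", plan), match("LASTDATE", plan))

  # independent items keep declaration order
  t1 <- read_schema(schema_fixture("table1"), reg)
  expect_equal(validate_schema(t1)[1:2], c("SEX", "ACS_DATE"))
})

test_that("cycles and unknown dependencies are rejected with named errors", {
  reg <- fixture_registry()
  cyc <- write_schema_yaml(c(
    "  - name: A",
    "    elements: [{element: 'SDTM:MH.MHPTCD', value: '10007559'}, {element: 'SDTM:MH.MHSTDTC'}]",
    "    derivation: {fn: EXISTS_BEFORE, index: B}",
    "  - name: B",
    "    elements: [{element: 'SDTM:MH.MHPTCD', value: '10007559'}, {element: 'SDTM:MH.MHSTDTC'}]",
    "    derivation: {fn: EXISTS_BEFORE, index: A}"))
  expect_error(validate_schema(read_schema(cyc, reg)), "A -> B",
               class = "cdelink_validation_error")

  unk <- write_schema_yaml(c(
    "  - name: A",
    "    elements: [{element: 'SDTM:MH.MHPTCD', value: '10007559'}, {element: 'SDTM:MH.MHSTDTC'}]",
    "    derivation: {fn: EXISTS_BEFORE, index: NOPE}"))
  expect_error(validate_schema(read_schema(unk, reg)), "NOPE",
               class = "cdelink_validation_error")

  dup <- write_schema_yaml(c(
    "  - name: A",
    "    elements: [{element: 'SDTM:DM.DMSEX'}]",
    "    derivation: {fn: VALUE}",
    "  - name: A",
    "    elements: [{element: 'SDTM:DM.DMSEX'}]",
    "    derivation: {fn: VALUE}"))
  expect_error(validate_schema(read_schema(dup, reg)),
               class = "cdelink_validation_error")

  # a bound value must be permissible for the element's value domain
  badval <- write_schema_yaml(c(
    "  - name: A",
    "    elements: [{element: 'SDTM:DM.DMSEX', value: 'X'}]",
    "    derivation: {fn: VALUE}"))
  expect_error(read_schema(badval, reg), class = "cdelink_validation_error")
})

test_that("calculation options follow the element's value domain", {
  reg <- fixture_registry()
  expect_true("FIRST_DATE" %in% calculation_options(reg, "SDTM:MH.MHSTDTC"))
  expect_true("MEAN_IN_WINDOW" %in% calculation_options(reg, "SDTM:VS.SYSBP"))
  expect_true("EXISTS_BEFORE" %in% calculation_options(reg, "SDTM:MH.MHPTCD"))
  expect_false("MEAN_IN_WINDOW" %in% calculation_options(reg, "SDTM:MH.MHPTCD"))
  expect_error(calculation_options(reg, "SDTM:XX.NOPE"),
               class = "cdelink_not_found_error")
})

test_that("derivations implement the windowed calculations on hand fixtures", {
  reg <- fixture_registry()
  term <- fixture_term()
  sch <- read_schema(schema_fixture("study"), reg)
  items <- sch$items
  names(items) <- vapply(items, function(it) it$name, "")
  idx <- as.Date("2007-07-05")

  # a 30-day stabilization offset lands on 4 August 2007
  start <- evaluate_item(items$STARTDATE, render_graph(make_patient(id = "PX")),
                         list(ACS_DATE = idx), reg, term, "CIM-RDF")
  expect_equal(start, as.Date("2007-08-04"))

  # mean over the one-year window keeps only in-window measurements
  p <- make_patient(id = "PBP", observations = data.frame(
    code = "SBP", value = c(120, 130, 140),
    date = as.character(c(idx - 100, idx - 200, idx - 400))))
  m <- evaluate_item(items$SBP_MEAN_1Y_BEFORE_ACS, render_graph(p),
                     list(ACS_DATE = idx), reg, term, "CIM-RDF")
  expect_equal(m, 125.0)
  # on the XML rendering too
  expect_equal(evaluate_item(items$SBP_MEAN_1Y_BEFORE_ACS, render_xml(p),
                             list(ACS_DATE = idx), reg, term, "CCD-XML"), 125.0)

  # zero qualifying entries yield nulls, never errors
  none <- render_graph(make_patient(id = "PZ"))
  expect_equal(evaluate_item(items$CHF_BEFORE_ACS, none,
                             list(ACS_DATE = idx), reg, term, "CIM-RDF"), "N")
  expect_true(is.na(evaluate_item(items$SBP_MEAN_1Y_BEFORE_ACS, none,
                                  list(ACS_DATE = idx), reg, term, "CIM-RDF")))

  # last value before the index takes the maximal date <= index
  pw <- make_patient(id = "PW", observations = data.frame(
    code = "WEIGHT", value = c(80, 75, 90),
    date = as.character(c(idx - 50, idx - 300, idx + 10)), unit = "kg"))
  w <- evaluate_item(items$LAST_WEIGHT_BEFORE_ACS, render_graph(pw),
                     list(ACS_DATE = idx), reg, term, "CIM-RDF")
  expect_equal(w, 80)

  # boundary convention: window is half-open (index - w, index]
  pb <- make_patient(id = "PB", observations = data.frame(
    code = "SBP", value = c(100, 200),
    date = as.character(c(idx - 365, idx))))
  mb <- evaluate_item(items$SBP_MEAN_1Y_BEFORE_ACS, render_graph(pb),
                      list(ACS_DATE = idx), reg, term, "CIM-RDF")
  expect_equal(mb, 200)  # the measurement exactly one window ago is out

  # a null index propagates null
  expect_true(is.na(evaluate_item(items$CHF_BEFORE_ACS, none,
                                  list(ACS_DATE = as.Date(NA)), reg, term, "CIM-RDF")))
  # a missing dependency is an engine error
  expect_error(evaluate_item(items$CHF_BEFORE_ACS, none, list(), reg, term, "CIM-RDF"),
               class = "cdelink_engine_error")
})

test_that("VALUE with conflicting duplicates is a data-quality error", {
  reg <- fixture_registry()
  term <- fixture_term()
  sch <- read_schema(schema_fixture("table1"), reg)
  sex_item <- sch$items[[1]]
  pat <- "<http://cdelink.example.org/cim#pat_PD>"
  gs <- graph_summary(data.frame(
    s = rep(pat, 4),
    p = c("<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>",
          "<http://cdelink.example.org/cim#patientId>",
          rep("<http://cdelink.example.org/cim#gender>", 2)),
    o = c("<http://cdelink.example.org/cim#Patient>", "\"PD\"", "\"F\"", "\"M\""),
    stringsAsFactors = FALSE), pat, "PD")
  expect_error(evaluate_item(sex_item, gs, list(), reg, term, "CIM-RDF"),
               class = "cdelink_data_quality_error")
})

test_that("populate recovers the generator's ground truth on both renderings", {
  reg <- fixture_registry()
  term <- fixture_term()
  pop <- fixture_pop(50, 42)
  st <- study_table(pop$patients)
  cohort <- cohort_of(pop, st$members)
  sch <- read_schema(schema_fixture("study"), reg)

  dcs <- populate(sch, cohort, reg, term, "CIM-RDF")
  expect_equal(nrow(dcs), nrow(st$members))
  expect_setequal(setdiff(names(dcs), "patient_id"),
                  vapply(sch$items, function(it) it$name, ""))

  gt <- pop$ground_truth[match(st$members$patient_id, pop$ground_truth$patient_id), ]
  expect_equal(dcs$SEX, gt$sex)
  expect_equal(dcs$ACS_DATE, gt$acs_date)
  expect_equal(dcs$STARTDATE, gt$start_date)
  expect_equal(dcs$LASTDATE, gt$last_date)
  expect_equal(dcs$CHF_BEFORE_ACS, ifelse(gt$chf_before, "Y", "N"))
  expect_equal(dcs$CHF_AFTER_ACS, ifelse(!is.na(gt$chf_after_date), "Y", "N"))
  expect_equal(dcs$CHF_AFTER_DATE, gt$chf_after_date)
  expect_equal(dcs$SBP_MEAN_1Y_BEFORE_ACS, gt$sbp_mean_1y, tolerance = 1e-9)
  expect_equal(dcs$LAST_WEIGHT_BEFORE_ACS, gt$last_weight_before)
  expect_equal(dcs$DEATH_DATE, gt$death_date)

  dcs_x <- populate(sch, cohort, reg, term, "CCD-XML")
  expect_equal(dcs_x, dcs, ignore_attr = TRUE)
})

test_that("any valid evaluation order gives the identical table, and adding an item changes nothing", {
  reg <- fixture_registry()
  term <- fixture_term()
  pop <- fixture_pop(50, 42)
  st <- study_table(pop$patients)
  cohort <- cohort_of(pop, st$members)[1:8]
  sch <- read_schema(schema_fixture("study"), reg)
  base <- populate(sch, cohort, reg, term, "CIM-RDF")

  set.seed(7)
  for (k in 1:3) {
    shuffled <- sch
    shuffled$items <- sample(sch$items)
    got <- populate(shuffled, cohort, reg, term, "CIM-RDF")
    expect_equal(got[names(base)], base, ignore_attr = TRUE)
  }

  extra <- sch
  extra$items <- c(sch$items, list(list(
    name = "DBP_MEAN_1Y_BEFORE_ACS",
    bindings = list(list(element = "SDTM:VS.DIABP", value = NULL, system = NULL),
                    list(element = "SDTM:VS.VSDTC", value = NULL, system = NULL)),
    derivation = list(fn = "MEAN_IN_WINDOW", index = "ACS_DATE",
                      window_days = 365, offset_days = NULL,
                      index_offset_days = 0L, date = NULL,
                      candidates = character(0), constants = character(0)))))
  got <- populate(extra, cohort, reg, term, "CIM-RDF")
  expect_equal(got[names(base)], base, ignore_attr = TRUE)
})

test_that("an empty cohort yields a zero-row set with the full header, written as valid CSV", {
  reg <- fixture_registry()
  term <- fixture_term()
  sch <- read_schema(schema_fixture("table1"), reg)
  dcs <- populate(sch, list(), reg, term, "CIM-RDF")
  expect_equal(nrow(dcs), 0)
  expect_equal(names(dcs), c("patient_id", "SEX", "ACS_DATE", "MI_DATE", "UA_DATE",
                             "CHF_BEFORE_ACS", "CHF_AFTER_ACS"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dcs(dcs, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), names(dcs))
  expect_true(file.exists(paste0(path, ".meta.json")))
})
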