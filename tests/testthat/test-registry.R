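test_that("the shipped registry resolves the study elements with their value domains and links", {
  reg <- fixture_registry()
  el <- get_data_element(reg, "SDTM:MH.MHPTCD")
  expect_equal(el$value_domain$datatype, "code")
  expect_equal(el$value_domain$code_system, "MedDRA")
  expect_true(any(vapply(el$links, function(l)
    l$predicate == "exactMatch" && l$target == "SALUS:Condition.ProblemCode.CD", TRUE)))

  sex <- get_data_element(reg, "SDTM:DM.DMSEX")
  expect_true(any(vapply(sex$links, function(l)
    l$target == "SALUS:Patient.Gender.CD", TRUE)))

  expect_error(get_data_element(reg, "SDTM:XX.BOGUS"),
               class = "cdelink_not_found_error")
})

test_that("object class browsing lists domains and their elements deterministically", {
  reg <- fixture_registry()
  ocs <- list_object_classes(reg, "SDTM")
  expect_true(all(c("SDTM:DM", "SDTM:MH") %in% names(ocs)))
  els <- list_elements(reg, "SDTM:MH")
  expect_setequal(names(els), c("SDTM:MH.MHPTCD", "SDTM:MH.MHSTDTC"))
  expect_equal(names(els), sort(names(els)))
  expect_error(list_elements(reg, "SDTM:NOPE"), class = "cdelink_not_found_error")
  expect_error(list_object_classes(reg, "NOPE"), class = "cdelink_not_found_error")
})

test_that("load errors identify duplicate ids and dangling link targets", {
  mk <- function(id, links = list()) {
    list(id = id, name = id, object_class = "R:C",
         value_domain = list(datatype = "text"),
         extraction_specs = list(), links = links)
  }
  expect_error(
    load_registry(list(registries = list(list(registry_id = "R",
      elements = list(mk("R:A"), mk("R:A")))))),
    "R:A", class = "cdelink_load_error")
  expect_error(
    load_registry(list(registries = list(list(registry_id = "R",
      elements = list(mk("R:A", links = list(list(predicate = "exactMatch",
                                                  target = "SALUS:Nonexistent")))))))),
    "SALUS:Nonexistent", class = "cdelink_load_error")
  # empty dump is the identity case
  empty <- load_registry(list(elements = list()))
  expect_length(empty$elements, 0)
  # coded value domain requires a code system
  bad_vd <- mk("R:A"); bad_vd$value_domain <- list(datatype = "code")
  expect_error(load_registry(list(registries = list(list(registry_id = "R",
    elements = list(bad_vd))))), class = "cdelink_load_error")
})

test_that("extraction specs resolve over the shortest exactMatch chain per content model", {
  reg <- fixture_registry()
  r <- resolve_extraction_spec(reg, "SDTM:MH.MHPTCD", "CIM-RDF")
  expect_equal(r$holder, "SALUS:Condition.ProblemCode.CD")
  expect_equal(r$chain, c("SDTM:MH.MHPTCD", "SALUS:Condition.ProblemCode.CD"))
  expect_equal(r$spec$dialect, "graph_pattern")

  r2 <- resolve_extraction_spec(reg, "SDTM:MH.MHPTCD", "CCD-XML")
  expect_equal(r2$holder, "HITSP:7.04")
  expect_equal(r2$chain, c("SDTM:MH.MHPTCD", "SALUS:Condition.ProblemCode.CD",
                           "HITSP:7.04"))
  expect_equal(r2$spec$dialect, "path")

  # zero-hop: the element itself carries the spec
  r3 <- resolve_extraction_spec(reg, "SALUS:Condition.ProblemCode.CD", "CIM-RDF")
  expect_equal(r3$chain, "SALUS:Condition.ProblemCode.CD")

  expect_error(resolve_extraction_spec(reg, "SDTM:MH.MHPTCD", "NO-SUCH-MODEL"),
               class = "cdelink_resolution_error")
})

test_that("transitive exactMatch closure matches the study mappings and a brute-force oracle", {
  reg <- fixture_registry()
  expect_setequal(transitive_matches(reg, "SDTM:MH.MHSTDTC"),
                  c("SALUS:Condition.TimeInterval.IVLTS", "HITSP:7.01"))
  # isolated element
  iso <- load_registry(list(registries = list(list(registry_id = "R", elements = list(
    list(id = "R:A", name = "A", object_class = "R:C",
         value_domain = list(datatype = "text"),
         extraction_specs = list(), links = list()))))))
  expect_length(transitive_matches(iso, "R:A"), 0)

  for (seed in 1:8) {
    rr <- random_registry(sample(5:20, 1), seed = seed)
    for (id in names(rr$elements)) {
      expect_equal(transitive_matches(rr, id), bf_closure(rr, id),
                   info = sprintf("seed %d, element %s", seed, id))
    }
  }
})

test_that("closure is symmetric: b in matches(a) iff a in matches(b)", {
  rr <- random_registry(15, seed = 99)
  ids <- names(rr$elements)
  for (a in ids) {
    for (b in transitive_matches(rr, a)) {
      expect_true(a %in% transitive_matches(rr, b))
    }
  }
})

test_that("resolution chains are minimal among all paths reaching a spec (enumeration oracle)", {
  # literal all-simple-paths enumeration is only feasible on tiny registries
  for (seed in 31:40) {
    rr <- random_registry(sample(4:8, 1), seed = seed)
    for (id in names(rr$elements)) {
      want <- bf_min_chain_length_enum(rr, id, "CM-T")
      got <- tryCatch(resolve_extraction_spec(rr, id, "CM-T"),
                      cdelink_resolution_error = function(e) NULL)
      if (is.na(want)) {
        expect_null(got, info = sprintf("seed %d %s", seed, id))
      } else {
        expect_equal(length(got$chain), want, info = sprintf("seed %d %s", seed, id))
      }
    }
  }
  # matrix-distance oracle scales to the full 20-element registries
  for (seed in 11:25) {
    rr <- random_registry(sample(5:20, 1), seed = seed)
    for (id in names(rr$elements)) {
      want <- bf_min_chain_length(rr, id, "CM-T")
      got <- tryCatch(resolve_extraction_spec(rr, id, "CM-T"),
                      cdelink_resolution_error = function(e) NULL)
      if (is.na(want)) {
        expect_null(got, info = sprintf("seed %d %s", seed, id))
      } else {
        expect_equal(length(got$chain), want, info = sprintf("seed %d %s", seed, id))
        # the chain is a real path ending at a spec carrier
        expect_equal(got$chain[1], id)
        expect_false(is.null(rr$elements[[got$holder]]$extraction_specs[["CM-T"]]))
      }
    }
  }
})

test_that("equally short chains break ties lexicographically", {
  mk <- function(id, targets = character(0), spec = FALSE) {
    list(id = id, name = id, object_class = "R:C",
         value_domain = list(datatype = "text"),
         extraction_specs = if (spec)
           list(list(content_model = "CM-T", dialect = "path",
                     script = paste0("/", id, "/@v"), anchor = "entry")) else list(),
         links = lapply(targets, function(t) list(predicate = "exactMatch", target = t)))
  }
  rr <- load_registry(list(registries = list(list(registry_id = "R", elements = list(
    mk("R:A", c("R:B", "R:Z")),
    mk("R:B", spec = TRUE),
    mk("R:Z", spec = TRUE))))))
  r <- resolve_extraction_spec(rr, "R:A", "CM-T")
  expect_equal(r$holder, "R:B")
})

test_that("dump -> load -> dump is idempotent and preserves all element fields", {
  reg <- fixture_registry()
  json1 <- dump_registry(reg)
  reg2 <- load_registry(jsonlite::parse_json(json1))
  json2 <- dump_registry(reg2)
  expect_identical(json1, json2)
  # elements are re-emitted sorted by id; every field survives the trip
  ids <- sort(names(reg$elements))
  expect_identical(reg2$elements[ids], reg$elements[ids])
  expect_identical(sort(reg2$registries), sort(reg$registries))
})
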