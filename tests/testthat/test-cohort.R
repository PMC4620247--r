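test_that("first ACS event detection honors the accrual window and first-event rule", {
  term <- fixture_term()
  crit <- eligibility_criteria()
  mi <- make_patient(conditions = data.frame(code = "410.0", start_date = "2007-07-05"))
  expect_equal(first_acs_event(mi, crit, term), as.Date("2007-07-05"))

  none <- make_patient(conditions = data.frame(code = "401.9", start_date = "2007-07-05"))
  expect_true(is.na(first_acs_event(none, crit, term)))
  expect_true(is.na(first_acs_event(make_patient(), crit, term)))

  # a first-ever MI before the window disqualifies: the 2007 event is a recurrence
  recur <- make_patient(conditions = data.frame(
    code = c("410.0", "410.0"), start_date = c("2003-05-01", "2007-07-05")))
  expect_true(is.na(first_acs_event(recur, crit, term)))
  # ... unless the config switch says otherwise
  crit2 <- eligibility_criteria(pre_window_disqualifies = FALSE)
  expect_equal(first_acs_event(recur, crit2, term), as.Date("2007-07-05"))

  # unstable angina qualifies through the concept map
  ua <- make_patient(conditions = data.frame(code = "411.1", start_date = "2006-02-03"))
  expect_equal(first_acs_event(ua, crit, term), as.Date("2006-02-03"))
})

test_that("each exclusion is attributed to the first failing filter, in protocol order", {
  term <- fixture_term()
  crit <- eligibility_criteria()
  early_death <- make_patient(id = "D10",
    conditions = data.frame(code = "410.0", start_date = "2007-07-05"),
    death = "2007-07-15")
  minor <- make_patient(id = "A17", birth = "1990-01-01",
    registration = "2000-06-01",
    conditions = data.frame(code = "410.0", start_date = "2007-07-05"))
  short_hist <- make_patient(id = "H01", registration = "2007-01-01",
    conditions = data.frame(code = "410.0", start_date = "2007-07-05"))
  ok <- make_patient(id = "OK1",
    conditions = data.frame(code = "410.0", start_date = "2007-07-05"))

  res <- apply_eligibility(list(early_death, minor, short_hist, ok), crit, term)
  expect_equal(unname(res$exclusions["death_within_30_days"]), 1L)
  expect_equal(unname(res$exclusions["under_min_age"]), 1L)
  expect_equal(unname(res$exclusions["insufficient_history"]), 1L)
  expect_equal(res$members$patient_id, "OK1")
  expect_equal(res$members$start_date, as.Date("2007-08-04"))
  expect_equal(res$members$last_date, as.Date("2011-12-31"))

  # a patient failing several filters counts only under the first
  dead_minor <- make_patient(id = "DM1", birth = "1995-01-01",
    conditions = data.frame(code = "410.0", start_date = "2007-07-05"),
    death = "2007-07-10")
  res2 <- apply_eligibility(list(dead_minor), crit, term)
  expect_equal(unname(res2$exclusions["death_within_30_days"]), 1L)
  expect_equal(unname(res2$exclusions["under_min_age"]), 0L)
})

test_that("eligibility agrees with a brute-force re-application on a large simulated population", {
  term <- fixture_term()
  pop <- fixture_pop(2000, 1)
  res <- apply_eligibility(pop$patients, eligibility_criteria(), term)
  verdict <- bf_eligibility(pop$patients)
  expect_equal(nrow(res$members), sum(verdict == "member"))
  for (f in names(res$exclusions)) {
    expect_equal(unname(res$exclusions[f]), sum(verdict == f), info = f)
  }
  expect_setequal(res$members$patient_id,
                  vapply(pop$patients, function(p) p$patient_id, "")[verdict == "member"])
  # and with the generator's own ground truth
  gt <- pop$ground_truth
  expect_equal(sort(res$members$patient_id), sort(gt$patient_id[gt$eligible]))
})

test_that("filters commute with patient order", {
  term <- fixture_term()
  pop <- fixture_pop(200, 8)
  a <- apply_eligibility(pop$patients, eligibility_criteria(), term)
  set.seed(3)
  b <- apply_eligibility(sample(pop$patients), eligibility_criteria(), term)
  expect_equal(a$exclusions, b$exclusions)
  expect_setequal(a$members$patient_id, b$members$patient_id)
  expect_equal(sorted_rows(a$members), sorted_rows(b$members))
})

test_that("incidence rates follow the person-time arithmetic identity", {
  # four members, 250 person-years each, two events inside follow-up
  start <- as.Date("2005-01-31")
  mk <- function(id, event = NA) data.frame(
    patient_id = id, STARTDATE = start, LASTDATE = start + 250 * 365,
    EVT = as.Date(event), stringsAsFactors = FALSE)
  dcs <- rbind(mk("a", "2010-01-01"), mk("b", "2020-01-01"), mk("c"), mk("d"))
  # events before LASTDATE cut person-time at the event
  r <- incidence_rate(dcs, "EVT")
  expect_equal(r$events, 2)
  py <- sum(as.numeric(as.Date(c("2010-01-01", "2020-01-01")) - start) / 365) + 2 * 250
  expect_equal(r$person_years, py)
  expect_equal(r$rate_per_1000py, 1000 * 2 / py)

  # exact identity: 2 events over 1000 person-years = 2.0 per 1000 PY
  dcs2 <- rbind(mk("a", as.character(start + 250 * 365)),
                mk("b", as.character(start + 250 * 365)), mk("c"), mk("d"))
  r2 <- incidence_rate(dcs2, "EVT")
  expect_equal(r2$events, 2)
  expect_equal(r2$person_years, 1000)
  expect_equal(r2$rate_per_1000py, 2.0)

  expect_equal(nrow(incidence_rate(dcs[0, ], "EVT")), 0)

  neg <- mk("x"); neg$LASTDATE <- start - 10
  expect_error(incidence_rate(rbind(dcs, neg), "EVT"),
               "x", class = "cdelink_data_quality_error")
  dropped <- incidence_rate(rbind(dcs, neg), "EVT", zero_follow_up = "drop")
  expect_equal(dropped$events, r$events)
  expect_equal(dropped$person_years, r$person_years)
})

test_that("person-time is non-negative and bounded by the study window for every member", {
  pop <- fixture_pop(2000, 1)
  st <- study_table(pop$patients)
  m <- st$members
  keep <- m$LASTDATE >= m$STARTDATE
  pt <- as.numeric(m$LASTDATE[keep] - m$STARTDATE[keep])
  expect_true(all(pt >= 0))
  expect_true(all(pt <= as.numeric(as.Date("2011-12-31") - m$STARTDATE[keep])))
})

test_that("proportions match direct counts over the ground truth", {
  pop <- fixture_pop(200, 8)
  st <- study_table(pop$patients)
  gt <- pop$ground_truth
  frac <- proportion(st$members, "SEX", "F")
  want <- mean(gt$sex[gt$eligible] == "F")
  expect_equal(frac, want)

  toy <- data.frame(SEX = c("F", "F", NA))
  expect_equal(proportion(toy, "SEX", "F"), 1.0)
  expect_true(is.na(proportion(data.frame(SEX = c(NA, NA)), "SEX", "F")))
  expect_error(proportion(toy, "NOPE", "F"), class = "cdelink_validation_error")
  # terminology-mediated comparison bridges code systems
  term <- fixture_term()
  coded <- data.frame(CODE = c("428.0", "410.0"))
  expect_equal(proportion(coded, "CODE", "10007559", term = term,
                          system = "ICD9CM", value_system = "MedDRA"), 0.5)
})
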