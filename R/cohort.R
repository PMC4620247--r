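# Cohort selection and reporting for the post-ACS safety study: first
# acute-coronary-syndrome event identification, eligibility filtering in
# the protocol's stated order, STARTDATE/LASTDATE derivation, and
# stratified person-time incidence rates on the populated table.

#' Eligibility criteria for the ACS cohort
#'
#' Defaults encode the study protocol: first ACS event (acute myocardial
#' infarction or unstable angina, as MedDRA preferred terms) during
#' 2005--2011, at least one year of history before the event, alive 30
#' days after it, aged 18 or over at the event; follow-up starts 30 days
#' after the ACS (stabilization delay) and ends at the earliest of
#' death, transfer out of the system, or the study end (2011-12-31).
#'
#' @param acs_codes MedDRA codes defining an ACS event.
#' @param acs_code_system Code system of `acs_codes`.
#' @param accrual_start,accrual_end First-event accrual window.
#' @param min_history_days Minimum pre-event history required.
#' @param death_exclusion_days Post-event survival required.
#' @param min_age_years Minimum age at the event, in completed years.
#' @param start_offset_days Follow-up start offset after the event.
#' @param study_end Administrative end of follow-up.
#' @param pre_window_disqualifies If `TRUE` (default) a first-ever ACS
#'   before the accrual window disqualifies the patient entirely (the
#'   in-window event would not be a *first* event); if `FALSE` the
#'   earliest in-window event is used.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(acs_codes = c("10000891", "10002388"),
                                 acs_code_system = "MedDRA",
                                 accrual_start = "2005-01-01",
                                 accrual_end = "2011-12-31",
                                 min_history_days = 365L,
                                 death_exclusion_days = 30L,
                                 min_age_years = 18L,
                                 start_offset_days = 30L,
                                 study_end = "2011-12-31",
                                 pre_window_disqualifies = TRUE) {
  accrual_start <- as_date_strict(accrual_start)
  accrual_end <- as_date_strict(accrual_end)
  if (accrual_start > accrual_end) {
    abort_cdelink("accrual window start must not be after its end",
                  "cdelink_validation_error")
  }
  stopifnot(min_history_days > 0, death_exclusion_days > 0, min_age_years > 0)
  structure(list(acs_codes = acs_codes, acs_code_system = acs_code_system,
                 accrual_start = accrual_start, accrual_end = accrual_end,
                 min_history_days = as.integer(min_history_days),
                 death_exclusion_days = as.integer(death_exclusion_days),
                 min_age_years = as.integer(min_age_years),
                 start_offset_days = as.integer(start_offset_days),
                 study_end = as_date_strict(study_end),
                 pre_window_disqualifies = isTRUE(pre_window_disqualifies)),
            class = "eligibility_criteria")
}

#' Read eligibility criteria from a YAML/JSON config
#' @param path Config file path; keys as in [eligibility_criteria()].
#' @return An `eligibility_criteria` object.
#' @export
read_criteria <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(eligibility_criteria, cfg)
}

acs_warehouse_codes <- function(criteria, term, systems = "ICD9CM") {
  expand_code_set(term, criteria$acs_codes, criteria$acs_code_system, systems)
}

condition_matches <- function(conds, code_set) {
  paste(conds$code_system, conds$code) %in% paste(code_set$system, code_set$code)
}

#' First qualifying ACS event of a patient
#'
#' Scans the patient's condition entries for codes matching the ACS code
#' set (through the terminology concept map, so ICD-9-CM warehouse codes
#' match the MedDRA bindings) and returns the date of the first matching
#' event if it falls inside the accrual window. A first-ever event
#' before the window disqualifies by default (the in-window events are
#' recurrences, not a first event).
#'
#' @param patient A `patient_record`.
#' @param criteria An `eligibility_criteria`.
#' @param term A `terminology`.
#' @return A `Date`, or `NA` if the patient has no qualifying first event.
#' @export
first_acs_event <- function(patient, criteria, term) {
  code_set <- acs_warehouse_codes(criteria, term)
  conds <- patient$conditions
  hit <- condition_matches(conds, code_set)
  if (!any(hit)) return(as.Date(NA))
  first <- min(conds$start_date[hit])
  if (first < criteria$accrual_start) {
    if (criteria$pre_window_disqualifies) return(as.Date(NA))
    inw <- hit & conds$start_date >= criteria$accrual_start &
      conds$start_date <= criteria$accrual_end
    if (!any(inw)) return(as.Date(NA))
    return(min(conds$start_date[inw]))
  }
  if (first > criteria$accrual_end) return(as.Date(NA))
  first
}

age_in_years <- function(birth, at) {
  # completed years at `at` (standard epidemiological convention)
  by <- as.integer(format(birth, "%Y")); ay <- as.integer(format(at, "%Y"))
  had_birthday <- format(at, "%m-%d") >= format(birth, "%m-%d")
  ay - by - ifelse(had_birthday, 0L, 1L)
}

#' Apply the eligibility filters and derive follow-up dates
#'
#' Filters are applied in the protocol's stated order -- qualifying
#' first ACS event, minimum history, 30-day survival, minimum age --
#' and every exclusion is attributed to the first failing filter, so
#' the exclusion counts are deterministic. Survivors get STARTDATE
#' (event + 30 days) and LASTDATE (min of death, transfer-out, study
#' end).
#'
#' @param patients List of `patient_record`s.
#' @param criteria An `eligibility_criteria`.
#' @param term A `terminology`.
#' @return A list with `members` (data frame: patient_id, acs_date,
#'   start_date, last_date, age_at_acs, sex, death_date, transfer_date)
#'   and `exclusions` (named integer vector of per-filter counts).
#' @export
apply_eligibility <- function(patients, criteria, term) {
  filters <- c("no_first_acs_in_window", "insufficient_history",
               "death_within_30_days", "under_min_age")
  excl <- stats::setNames(integer(length(filters)), filters)
  rows <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    acs <- first_acs_event(p, criteria, term)
    if (is.na(acs)) { excl["no_first_acs_in_window"] <- excl["no_first_acs_in_window"] + 1L; next }
    if (p$registration_date > acs - criteria$min_history_days) {
      excl["insufficient_history"] <- excl["insufficient_history"] + 1L; next
    }
    if (!is.na(p$death_date) &&
        p$death_date <= acs + criteria$death_exclusion_days) {
      excl["death_within_30_days"] <- excl["death_within_30_days"] + 1L; next
    }
    age <- age_in_years(p$birth_date, acs)
    if (age < criteria$min_age_years) {
      excl["under_min_age"] <- excl["under_min_age"] + 1L; next
    }
    start <- acs + criteria$start_offset_days
    last <- min(c(p$death_date, p$transfer_date, criteria$study_end), na.rm = TRUE)
    rows[[i]] <- data.frame(
      patient_id = p$patient_id, acs_date = acs, start_date = start,
      last_date = last, age_at_acs = age, sex = p$sex,
      death_date = p$death_date, transfer_date = p$transfer_date,
      stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(members)) {
    members <- data.frame(patient_id = character(0), acs_date = as.Date(character(0)),
                          start_date = as.Date(character(0)), last_date = as.Date(character(0)),
                          age_at_acs = integer(0), sex = character(0),
                          death_date = as.Date(character(0)), transfer_date = as.Date(character(0)))
  }
  rownames(members) <- NULL
  list(members = members, exclusions = excl)
}

#' Stratified person-time incidence rates
#'
#' Person-time per patient runs from STARTDATE to the event date or
#' LASTDATE, whichever is earlier, in years of 365 days; events are
#' counted when the event date falls in (STARTDATE, LASTDATE]. The rate
#' is reported per 1000 person-years. Strata are formed on exact values
#' of the requested columns.
#'
#' @param dcs Data frame containing `STARTDATE`, `LASTDATE`, and the
#'   event date column (any extra columns are carried for stratification).
#' @param event_column Name of the event date column.
#' @param strata Character vector of stratification columns (optional).
#' @param zero_follow_up Members accrued so close to the administrative
#'   study end that LASTDATE precedes STARTDATE have no observable
#'   follow-up: `"error"` (default) reports them as a data-quality
#'   problem, `"drop"` removes them (they can contribute neither events
#'   nor person-time).
#' @return Data frame: stratum columns, `events`, `person_years`,
#'   `rate_per_1000py`, plus a normal-approximation standard error.
#' @export
incidence_rate <- function(dcs, event_column, strata = NULL,
                           zero_follow_up = c("error", "drop")) {
  zero_follow_up <- match.arg(zero_follow_up)
  needed <- c("STARTDATE", "LASTDATE", event_column)
  missing <- setdiff(needed, names(dcs))
  if (length(missing)) {
    abort_cdelink(sprintf("data collection set lacks column(s): %s",
                          paste(missing, collapse = ", ")),
                  "cdelink_validation_error")
  }
  if (!nrow(dcs)) {
    out <- data.frame(events = integer(0), person_years = numeric(0),
                      rate_per_1000py = numeric(0), se_rate = numeric(0))
    return(out)
  }
  if (zero_follow_up == "drop") {
    keep <- is.na(dcs$LASTDATE) | is.na(dcs$STARTDATE) |
      as_date_strict(dcs$LASTDATE) >= as_date_strict(dcs$STARTDATE)
    dcs <- dcs[keep, , drop = FALSE]
  }
  start <- as_date_strict(dcs$STARTDATE)
  last <- as_date_strict(dcs$LASTDATE)
  event <- as_date_strict(dcs[[event_column]])
  stopi <- as.integer(last)
  has_ev <- !is.na(event)
  stopi[has_ev] <- pmin(as.integer(event[has_ev]), stopi[has_ev])
  ptime_days <- stopi - as.integer(start)
  if (any(ptime_days < 0, na.rm = TRUE)) {
    bad <- dcs$patient_id[which(ptime_days < 0)]
    abort_cdelink(sprintf("negative person-time for patient(s): %s",
                          paste(bad, collapse = ", ")),
                  "cdelink_data_quality_error")
  }
  py <- ptime_days / DAYS_PER_YEAR
  is_event <- !is.na(event) & event > start & event <= last

  grp <- if (length(strata)) {
    interaction(dcs[, strata, drop = FALSE], drop = TRUE, sep = "\r")
  } else {
    factor(rep("all", nrow(dcs)))
  }
  agg <- lapply(levels(grp), function(g) {
    sel <- grp == g
    ev <- sum(is_event[sel])
    pt <- sum(py[sel])
    data.frame(.group = g, events = ev, person_years = pt,
               rate_per_1000py = if (pt > 0) 1000 * ev / pt else NA_real_,
               se_rate = if (pt > 0 && ev > 0) 1000 * sqrt(ev) / pt else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  if (length(strata)) {
    parts <- do.call(rbind, strsplit(out$.group, "\r", fixed = TRUE))
    colnames(parts) <- strata
    out <- cbind(as.data.frame(parts, stringsAsFactors = FALSE),
                 out[, c("events", "person_years", "rate_per_1000py", "se_rate")])
  } else {
    out$.group <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Share of a column equal to a value
#'
#' Fraction of non-null cells equal to `value`; used for the validity
#' checks that compare the populated table against direct queries of
#' the source (e.g. the female share of the cohort).
#'
#' @param dcs Data frame.
#' @param column Column name.
#' @param value Value to match.
#' @param term Optional `terminology`; when given together with
#'   `system`/`value_system`, cells are compared through [codes_match()].
#' @param system Code system of the column's cells.
#' @param value_system Code system of `value`.
#' @return Fraction in `[0, 1]`, or `NA` if the column is entirely null.
#' @export
proportion <- function(dcs, column, value, term = NULL,
                       system = NULL, value_system = NULL) {
  if (!(column %in% names(dcs))) {
    abort_cdelink(sprintf("column '%s' not present", column),
                  "cdelink_validation_error")
  }
  x <- dcs[[column]]
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (!is.null(term) && !is.null(system) && !is.null(value_system)) {
    hits <- vapply(as.character(x), function(cell)
      codes_match(term, value, value_system, cell, system), TRUE)
    mean(hits)
  } else {
    mean(x == value)
  }
}
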