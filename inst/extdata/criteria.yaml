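# Eligibility criteria of the reference study: first ACS event (acute
# myocardial infarction or unstable angina) during 2005-2011, >= 1 year
# of history, alive 30 days after the event, aged >= 18 at the event.
acs_codes: ["10000891", "10002388"]
acs_code_system: MedDRA
accrual_start: "2005-01-01"
accrual_end: "2011-12-31"
min_history_days: 365
death_exclusion_days: 30
min_age_years: 18
start_offset_days: 30
study_end: "2011-12-31"
pre_window_disqualifies: true
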