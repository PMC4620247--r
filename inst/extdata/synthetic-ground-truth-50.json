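{
  "patient_id": ["P00001", "P00002", "P00003", "P00004", "P00005", "P00006", "P00007", "P00008", "P00009", "P00010", "P00011", "P00012", "P00013", "P00014", "P00015", "P00016", "P00017", "P00018", "P00019", "P00020", "P00021", "P00022", "P00023", "P00024", "P00025", "P00026", "P00027", "P00028", "P00029", "P00030", "P00031", "P00032", "P00033", "P00034", "P00035", "P00036", "P00037", "P00038", "P00039", "P00040", "P00041", "P00042", "P00043", "P00044", "P00045", "P00046", "P00047", "P00048", "P00049", "P00050"],
  "sex": ["M", "M", "F", "F", "M", "F", "F", "M", "M", "M", "M", "M", "M", "M", "M", "F", "F", "M", "F", "F", "F", "M", "M", "M", "M", "F", "M", "M", "M", "M", "F", "M", "M", "M", "M", "F", "M", "F", "M", "F", "M", "M", "M", "F", "M", "M", "F", "M", "M", "M"],
  "birth_date": ["1987-03-01", "1959-11-21", "1986-10-05", "1959-06-13", "1969-08-28", "1939-06-03", "1937-08-10", "1970-12-01", "1950-12-10", "1948-03-27", "1968-04-07", "1974-11-22", "1975-07-22", "1948-01-13", "1976-01-10", "1981-09-10", "1982-11-27", "1933-05-03", "1936-12-29", "1978-11-09", "1951-01-25", "1977-11-22", "1987-08-24", "1970-05-12", "1934-12-07", "1987-08-06", "1957-06-13", "1934-11-20", "1989-06-11", "1976-07-15", "1974-09-28", "1986-02-05", "1964-03-29", "1933-04-09", "1936-02-09", "1951-06-18", "1940-06-02", "1973-01-27", "1946-06-18", "1956-11-19", "1980-05-12", "1989-01-04", "1931-09-08", "1968-06-22", "1966-03-21", "1942-04-10", "1933-02-24", "1938-01-12", "1954-02-23", "1986-09-09"],
  "registration_date": ["1997-11-11", "1996-09-18", "1997-12-20", "2004-10-16", "2004-03-19", "1997-08-31", "2002-04-13", "1995-03-19", "1997-06-12", "2003-09-05", "1995-09-24", "2002-07-09", "2001-04-24", "1996-10-24", "2001-08-12", "2004-03-10", "2004-12-16", "2003-09-05", "1995-08-22", "1996-12-25", "2001-03-22", "2004-03-06", "1995-03-15", "1999-02-27", "1996-01-02", "1999-06-18", "1999-06-19", "1998-02-27", "2002-06-13", "2001-05-28", "1996-06-28", "1998-06-30", "1996-05-03", "2001-03-31", "2002-01-27", "1999-08-15", "2000-08-07", "1995-01-16", "1995-02-08", "2003-02-10", "2001-10-02", "1997-02-20", "1995-12-29", "2004-05-16", "2001-01-30", "1996-05-15", "2000-09-21", "2002-02-15", "2000-08-19", "1996-08-27"],
  "death_date": ["2011-04-09", null, null, null, null, null, null, null, null, null, null, "2007-11-30", null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, "2005-09-28", null, "2008-03-11", "2007-12-29", "2011-01-12", null, "2009-11-01", null, "2009-09-23", "2006-02-19", "2009-05-12", "2003-08-09", null, null, null, null, null, null, "2010-11-16", null, "2009-08-26", "2009-02-02"],
  "transfer_date": [null, null, null, null, null, null, null, null, null, null, "2011-04-24", null, null, null, "2010-04-29", null, "2009-02-08", null, "2006-10-21", "2009-03-17", null, null, null, null, null, null, null, null, null, null, "2007-08-14", null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null],
  "acs_date": ["2006-09-14", "2004-10-14", "2005-07-09", "2006-07-30", "2008-04-23", "2008-02-25", "2004-10-27", "2005-02-18", "2004-10-11", null, "2008-04-16", "2007-11-29", null, "2006-04-26", "2006-04-09", null, "2004-12-24", "2006-08-26", "2006-07-15", "2005-08-11", "2010-05-31", "2006-05-13", "2008-10-02", "2011-08-08", "2006-08-04", "2004-10-11", "2006-01-12", "2006-04-06", "2004-12-29", "2006-08-14", "2005-11-10", "2006-06-12", "2010-03-14", "2006-04-26", "2004-10-18", "2004-08-01", "2004-12-24", "2006-01-29", "2007-11-24", null, "2008-08-18", "2008-10-03", "2007-04-05", null, "2006-12-28", "2005-07-14", "2005-06-17", "2005-12-14", "2004-10-09", "2006-09-14"],
  "eligible": [true, false, true, true, true, true, false, true, false, false, true, false, false, true, true, false, false, true, true, true, true, true, true, true, true, false, true, true, false, true, true, true, true, true, false, false, false, false, true, false, true, true, true, false, true, true, true, true, false, true],
  "failing_filter": [null, "no_first_acs_in_window", null, null, null, null, "no_first_acs_in_window", null, "no_first_acs_in_window", "no_first_acs_in_window", null, "death_within_30_days", "no_first_acs_in_window", null, null, "no_first_acs_in_window", "no_first_acs_in_window", null, null, null, null, null, null, null, null, "no_first_acs_in_window", null, null, "no_first_acs_in_window", null, null, null, null, null, "no_first_acs_in_window", "no_first_acs_in_window", "no_first_acs_in_window", "death_within_30_days", null, "no_first_acs_in_window", null, null, null, "no_first_acs_in_window", null, null, null, null, "no_first_acs_in_window", null],
  "start_date": ["2006-10-14", null, "2005-08-08", "2006-08-29", "2008-05-23", "2008-03-26", null, "2005-03-20", null, null, "2008-05-16", null, null, "2006-05-26", "2006-05-09", null, null, "2006-09-25", "2006-08-14", "2005-09-10", "2010-06-30", "2006-06-12", "2008-11-01", "2011-09-07", "2006-09-03", null, "2006-02-11", "2006-05-06", null, "2006-09-13", "2005-12-10", "2006-07-12", "2010-04-13", "2006-05-26", null, null, null, null, "2007-12-24", null, "2008-09-17", "2008-11-02", "2007-05-05", null, "2007-01-27", "2005-08-13", "2005-07-17", "2006-01-13", null, "2006-10-14"],
  "last_date": ["2011-04-09", null, "2011-12-31", "2011-12-31", "2011-12-31", "2011-12-31", null, "2011-12-31", null, null, "2011-04-24", null, null, "2011-12-31", "2010-04-29", null, null, "2011-12-31", "2006-10-21", "2009-03-17", "2011-12-31", "2011-12-31", "2011-12-31", "2011-12-31", "2011-12-31", null, "2011-12-31", "2011-12-31", null, "2011-12-31", "2007-08-14", "2007-12-29", "2011-01-12", "2011-12-31", null, null, null, null, "2009-05-12", null, "2011-12-31", "2011-12-31", "2011-12-31", null, "2011-12-31", "2011-12-31", "2010-11-16", "2011-12-31", null, "2009-02-02"],
  "age_at_acs": [19, null, 18, 47, 38, 68, null, 34, null, null, 40, null, null, 58, 30, null, null, 73, 69, 26, 59, 28, 21, 41, 71, null, 48, 71, null, 30, 31, 20, 45, 73, null, null, null, null, 61, null, 28, 19, 75, null, 40, 63, 72, 67, null, 20],
  "chf_before": [false, false, false, false, true, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, true, false, false, false, false, false, true, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false],
  "chf_after_date": [null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null],
  "sbp_mean_1y": [169.3, null, null, null, null, null, null, null, null, null, 135, null, null, null, 132.5, null, null, 146.2, null, 120.2, 149.8, null, 136.5, null, null, null, null, 130.2, null, null, null, 127.9, null, null, null, null, null, 120.8, 145.2, null, 128.5, 125.5, 150.1, null, null, null, 122.85, null, null, 143.4],
  "last_weight_before": [62.2, null, 94.4, null, 80.7, 91, null, 69.8, null, null, null, null, null, 63.3, null, null, null, null, 107.8, 85.7, 66.2, 88, 99.3, 85, 87.9, null, null, 77.5, null, null, 91.1, 86.1, 80.8, null, null, null, null, 87.2, 54.2, null, 52, 91.1, 72.4, null, 58.4, 58.2, 70.3, null, null, null],
  "t2d": [false, true, false, false, false, true, false, false, true, false, false, false, false, false, false, false, true, false, false, false, false, false, true, true, true, true, false, false, false, true, true, true, true, false, false, false, true, true, false, true, true, true, true, true, false, false, false, false, true, false]
}
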