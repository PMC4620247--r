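#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions: every user-facing failure carries a class under
# "cdelink_error" so callers (and the CLI) can attribute the stage.
abort_cdelink <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cdelink_error")))
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  if (any(is.na(d) & !is.na(x))) {
    abort_cdelink(sprintf("cannot parse %s as ISO-8601 calendar date: %s",
                          what, paste(x[is.na(d) & !is.na(x)], collapse = ", ")),
                  "cdelink_data_quality_error")
  }
  d
}

# days in one study year; "12 months" is fixed at 365 days throughout
DAYS_PER_YEAR <- 365
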