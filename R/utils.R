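#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr %>%
NULL

# Far-future sentinel standing in for an open-ended spell; only used inside
# half-open interval joins, never written to disk.
.FAR_FUTURE <- as.Date("9999-12-31")

#' Number of days in the month containing `date`
#' @param date a Date vector
#' @return integer vector
#' @keywords internal
days_in_month_of <- function(date) {
  as.integer(lubridate::days_in_month(date))
}

# TRUE where `date` lies in the half-open interval [start, end); an NA end
# means the spell is still open.
in_spell <- function(date, start, end) {
  end <- dplyr::coalesce(end, .FAR_FUTURE)
  !is.na(date) & !is.na(start) & date >= start & date < end
}

# Missing-field predicate for raw event columns: NA or empty/whitespace string.
is_blank <- function(x) {
  if (inherits(x, "Date")) return(is.na(x))
  is.na(x) | !nzchar(trimws(as.character(x)))
}

# Deterministic per-stage seed derived from a root seed; keeps every stage's
# stream independent while remaining reproducible from one integer.
stage_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 11L, codes = 23L, events = 37L, corrupt = 53L,
    panel = 67L, series = 79L
  )
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# Stop with a configuration error naming the offending field.
abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field '%s' %s", field, msg),
        class = "rrda_config_error")
}

utils::globalVariables(".")
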