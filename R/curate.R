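#' Step 1: drop records with missing identifying fields
#'
#' A raw event is kept only if person id (`alf`), `event_dt` and
#' `practice_id` are all present. Drop reasons partition the removals: a row
#' missing several fields is counted once, under the first missing field in
#' the order alf, date, practice.
#'
#' @param events data frame of raw events (`source_row_id`, `alf`,
#'   `event_dt`, `practice_id`, `code`, `value`, `value_unit`)
#' @return list with `events` (kept rows, as a tibble) and `dropped`, a
#'   tibble of per-reason counts (`MISSING_ALF`, `MISSING_DATE`,
#'   `MISSING_PRACTICE`)
#' @export
drop_incomplete <- function(events) {
  events <- tibble::as_tibble(events)
  reason <- dplyr::case_when(
    is_blank(events$alf) ~ "MISSING_ALF",
    is_blank(events$event_dt) ~ "MISSING_DATE",
    is_blank(events$practice_id) ~ "MISSING_PRACTICE",
    TRUE ~ NA_character_
  )
  dropped <- tibble::tibble(reason = c("MISSING_ALF", "MISSING_DATE", "MISSING_PRACTICE")) %>%
    dplyr::left_join(
      tibble::tibble(reason = reason[!is.na(reason)]) %>% dplyr::count(.data$reason),
      by = "reason"
    ) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  list(events = events[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Practice actively registered for a person on a date
#'
#' Registration spells are half-open `[start_dt, end_dt)`: an event dated on
#' the start date falls inside the spell, one dated on the end date does
#' not; a missing `end_dt` means the spell is still open. When several
#' spells cover the date, the spell with the latest start wins, ties broken
#' by the lexicographically smallest practice id.
#'
#' @param registrations data frame with `alf`, `practice_id`, `start_dt`,
#'   `end_dt`
#' @param alf person id vector
#' @param date Date vector (recycled against `alf`)
#' @return character vector of practice ids, `NA` where no spell covers the
#'   date
#' @export
active_registration <- function(registrations, alf, date) {
  keys <- tibble::tibble(alf = alf, date = as.Date(date)) %>%
    dplyr::mutate(.k = dplyr::row_number())
  hits <- keys %>%
    dplyr::inner_join(tibble::as_tibble(registrations), by = "alf",
                      relationship = "many-to-many") %>%
    dplyr::filter(in_spell(.data$date, .data$start_dt, .data$end_dt)) %>%
    dplyr::arrange(.data$.k, dplyr::desc(.data$start_dt), .data$practice_id) %>%
    dplyr::distinct(.data$.k, .keep_all = TRUE)
  out <- rep(NA_character_, nrow(keys))
  out[hits$.k] <- hits$practice_id
  out
}

#' Step 2: registration-based validation and practice-id annotation
#'
#' Events whose person had no active GP registration on the event date are
#' excluded. Surviving events are annotated with `canonical_practice_id`,
#' the practice the registration history says the person was registered with
#' on that date; the recorded `practice_id` is kept unchanged so that the
#' GP-to-GP de-duplication step can still compare the two.
#'
#' @param events complete events (after [drop_incomplete()])
#' @param registrations registration spell table
#' @return list with `events` (annotated tibble) and `n_excluded`
#' @export
validate_and_annotate <- function(events, registrations) {
  events <- tibble::as_tibble(events)
  canonical <- active_registration(registrations, events$alf, events$event_dt)
  keep <- !is.na(canonical)
  events$canonical_practice_id <- canonical
  list(events = events[keep, , drop = FALSE], n_excluded = sum(!keep))
}

# Clinical values are compared as trimmed strings so that de-duplication is
# exact and free of float-tolerance ambiguity.
value_key <- function(x) {
  x <- trimws(as.character(x))
  dplyr::coalesce(x, "")
}

#' Step 3: remove exact duplicates
#'
#' One representative is kept per group of rows identical on
#' (`alf`, `event_dt`, `practice_id`, `code`, `value`, `value_unit`); the
#' representative is the row with the smallest `source_row_id`.
#'
#' @param events event tibble
#' @return tibble of unique events
#' @export
dedup_exact <- function(events) {
  tibble::as_tibble(events) %>%
    dplyr::mutate(.vk = value_key(.data$value), .uk = value_key(.data$value_unit),
                  .ck = value_key(.data$code)) %>%
    dplyr::arrange(.data$source_row_id) %>%
    dplyr::distinct(.data$alf, .data$event_dt, .data$practice_id,
                    .data$.ck, .data$.vk, .data$.uk, .keep_all = TRUE) %>%
    dplyr::select(-".vk", -".uk", -".ck") %>%
    dplyr::arrange(.data$source_row_id)
}

#' Step 4: de-duplicate GP-to-GP transferred records
#'
#' Rows identical on (`alf`, `event_dt`, `code`, `value`, `value_unit`) but
#' differing in recorded practice id are treated as copies of one event
#' carried over by a practice transfer. Within such a group the row whose
#' recorded practice equals the registration-derived
#' `canonical_practice_id` is retained; if none matches, the row with the
#' smallest recorded practice id is kept. After this step the canonical
#' practice becomes the output practice for every event, and a final exact
#' pass removes any residual identical rows.
#'
#' @param events annotated events (after [validate_and_annotate()] and
#'   [dedup_exact()])
#' @return tibble of de-duplicated events with `practice_id` set to the
#'   canonical practice
#' @export
dedup_gp2gp <- function(events) {
  out <- tibble::as_tibble(events) %>%
    dplyr::mutate(.vk = value_key(.data$value), .uk = value_key(.data$value_unit),
                  .ck = value_key(.data$code),
                  .match = .data$practice_id == .data$canonical_practice_id) %>%
    dplyr::arrange(dplyr::desc(.data$.match), .data$practice_id, .data$source_row_id) %>%
    dplyr::distinct(.data$alf, .data$event_dt, .data$.ck, .data$.vk, .data$.uk,
                    .keep_all = TRUE) %>%
    dplyr::mutate(practice_id = .data$canonical_practice_id) %>%
    dplyr::select(-".vk", -".uk", -".ck", -".match") %>%
    dplyr::arrange(.data$source_row_id)
  dedup_exact(out)
}

#' Step 6: normalise events into the three-table RRDA
#'
#' Builds the person-day table (one row per distinct person/date/practice,
#' with dense integer `event_id` assigned by sorting on alf, date, practice)
#' and the clinical-event table (one row per event, carrying `code_id` and
#' the clinical value). Codes are resolved through [resolve_code()], which
#' may extend the look-up with supplementary entries; joining the three
#' tables back reproduces the input events exactly.
#'
#' @param events de-duplicated events (practice id already canonical)
#' @param lookup code look-up from [build_lookup()]
#' @return list with `person_day`, `clinical_events` and the (possibly
#'   extended) `lookup`
#' @export
normalize_rrda <- function(events, lookup) {
  events <- tibble::as_tibble(events)
  res <- resolve_code(lookup, events$code)
  events$code_id <- res$code_id
  person_day <- events %>%
    dplyr::distinct(.data$alf, .data$event_dt, .data$practice_id) %>%
    dplyr::arrange(.data$alf, .data$event_dt, .data$practice_id) %>%
    dplyr::mutate(event_id = dplyr::row_number()) %>%
    dplyr::select("event_id", "alf", "event_dt", "practice_id")
  clinical <- events %>%
    dplyr::left_join(person_day, by = c("alf", "event_dt", "practice_id")) %>%
    dplyr::arrange(.data$event_id, .data$code_id, .data$source_row_id) %>%
    dplyr::select("event_id", "code_id", "value", "value_unit")
  list(person_day = person_day, clinical_events = clinical, lookup = res$lookup)
}

#' Reconstruct the event table from the normalised RRDA
#'
#' Inverse of [normalize_rrda()] up to `source_row_id` (which is
#' regenerated): joining person-day, clinical-event and look-up tables back
#' into one flat event table.
#'
#' @param person_day,clinical_events,lookup the three RRDA tables
#' @return flat event tibble
#' @export
denormalize_rrda <- function(person_day, clinical_events, lookup) {
  clinical_events %>%
    dplyr::left_join(person_day, by = "event_id") %>%
    dplyr::left_join(dplyr::select(lookup, "code_id", "code_key"), by = "code_id") %>%
    dplyr::transmute(
      source_row_id = dplyr::row_number(),
      alf = .data$alf, event_dt = .data$event_dt, practice_id = .data$practice_id,
      code = .data$code_key, value = .data$value, value_unit = .data$value_unit
    )
}

#' Yearly data-retention report
#'
#' Per event year: raw and retained record counts with record retention %,
#' and raw and retained distinct-person counts with person retention %. Raw
#' rows with a missing event date are reported in a separate `"undated"`
#' bucket.
#'
#' @param raw_events the raw input batch
#' @param person_day,clinical_events the final RRDA tables from the same run
#' @return tibble with one row per year plus an `"undated"` row when raw
#'   undated records exist
#' @export
retention_report <- function(raw_events, person_day, clinical_events) {
  raw <- tibble::as_tibble(raw_events) %>%
    dplyr::mutate(year = dplyr::if_else(is_blank(.data$event_dt), "undated",
                                        format(.data$event_dt, "%Y")))
  raw_tab <- raw %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      n_raw = dplyr::n(),
      persons_raw = dplyr::n_distinct(.data$alf[!is_blank(.data$alf)]),
      .groups = "drop"
    )
  final <- clinical_events %>%
    dplyr::left_join(person_day, by = "event_id") %>%
    dplyr::mutate(year = format(.data$event_dt, "%Y")) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      n_retained = dplyr::n(),
      persons_retained = dplyr::n_distinct(.data$alf),
      .groups = "drop"
    )
  raw_tab %>%
    dplyr::left_join(final, by = "year") %>%
    dplyr::mutate(
      n_retained = dplyr::coalesce(.data$n_retained, 0L),
      persons_retained = dplyr::coalesce(.data$persons_retained, 0L),
      record_retention_pct = 100 * .data$n_retained / .data$n_raw,
      person_retention_pct = dplyr::if_else(.data$persons_raw > 0,
                                            100 * .data$persons_retained / .data$persons_raw,
                                            NA_real_)
    ) %>%
    dplyr::arrange(.data$year != "undated", .data$year)
}

#' Run the full curation pipeline
#'
#' Executes the curation steps in order — cleaning, registration validation
#' and practice-id annotation, exact de-duplication, GP-to-GP
#' de-duplication, code resolution and normalisation — and reports per-step
#' kept/dropped counts (the consort table) plus the yearly retention report.
#'
#' @param events raw event table
#' @param registrations registration spell table
#' @param code_sources code source table for [build_lookup()], or an
#'   already-built look-up
#' @return list with `person_day`, `clinical_events`, `lookup`, `retention`,
#'   and `consort` (tibble of step, n_in, n_kept, n_dropped)
#' @export
build_rrda <- function(events, registrations, code_sources) {
  events <- tibble::as_tibble(events)
  lookup <- if (!is.null(code_sources$code_id)) code_sources else build_lookup(code_sources)

  s1 <- drop_incomplete(events)
  s2 <- validate_and_annotate(s1$events, registrations)
  s3 <- dedup_exact(s2$events)
  s4 <- dedup_gp2gp(s3)
  norm <- normalize_rrda(s4, lookup)

  consort <- tibble::tibble(
    step = c("1_clean", "2_registration_validation", "3_exact_dedup",
             "4_gp2gp_dedup", "6_normalise"),
    n_in = c(nrow(events), nrow(s1$events), nrow(s2$events), nrow(s3), nrow(s4)),
    n_kept = c(nrow(s1$events), nrow(s2$events), nrow(s3), nrow(s4),
               nrow(norm$clinical_events))
  ) %>%
    dplyr::mutate(n_dropped = .data$n_in - .data$n_kept)

  list(
    person_day = norm$person_day,
    clinical_events = norm$clinical_events,
    lookup = norm$lookup,
    retention = retention_report(events, norm$person_day, norm$clinical_events),
    consort = consort,
    drop_reasons = s1$dropped
  )
}
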