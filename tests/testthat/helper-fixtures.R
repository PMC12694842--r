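# Small configurations and brute-force oracles shared across tests.

tiny_config <- function(n_persons = 150, years = c(2018, 2020), seed = 20240101,
                        corruption = list(missing_field_frac = 0, exact_dup_frac = 0,
                                          gp2gp_dup_frac = 0, out_of_registration_frac = 0,
                                          invalid_code_frac = 0, unknown_code_frac = 0),
                        ...) {
  sim_config(
    n_persons = n_persons, n_practices = 10,
    date_span = as.Date(sprintf(c("%d-01-01", "%d-12-31"), years)),
    corruption = corruption, seed = seed, ...
  )
}

toy_sources <- function() {
  tibble::tibble(
    source = c("readish", "readish", "emisish", "emisish", "visionish"),
    code_type = c("READ_V2", "READ_V2", "EMIS_UKB", "EMIS_UKB", "VISION_LOCAL"),
    code = c("H33", "A1B2.", "H33..", "EM001", "A1B2"),
    description = c("asthma read", "read thing", "asthma emis", "emis thing", "vision thing")
  )
}

# random raw batches designed to collide often, for de-duplication oracles;
# the canonical practice is registration-derived, so it is constant within a
# person-day (as validate_and_annotate guarantees)
random_batch <- function(seed, n = NULL) {
  set.seed(seed)
  n <- n %||% sample(20:1000, 1)
  practices <- sprintf("P%02d", 1:3)
  b <- tibble::tibble(
    source_row_id = seq_len(n),
    alf = sample(1:20, n, replace = TRUE),
    event_dt = as.Date("2020-06-01") + sample(0:4, n, replace = TRUE),
    practice_id = sample(practices, n, replace = TRUE),
    code = sample(c("Cd001", "Rx001", "Ad001", "Fe001"), n, replace = TRUE),
    value = sample(c(NA, 1, 2), n, replace = TRUE),
    value_unit = ifelse(is.na(value), NA_character_, "u")
  )
  canon <- b %>%
    dplyr::distinct(alf, event_dt) %>%
    dplyr::mutate(canonical_practice_id = sample(practices, dplyr::n(), replace = TRUE))
  dplyr::left_join(b, canon, by = c("alf", "event_dt"))
}

# Brute-force exact de-duplication: full string keys, first occurrence by
# source_row_id wins.
oracle_dedup_exact <- function(events) {
  ord <- order(events$source_row_id)
  ev <- events[ord, ]
  key <- paste(ev$alf, ev$event_dt, ev$practice_id, trimws(as.character(ev$code)),
               trimws(as.character(ev$value)), trimws(as.character(ev$value_unit)),
               sep = "\r")
  ev[match(unique(key), key), ]
}

# Brute-force GP-to-GP de-duplication over exact-deduped input: per group
# ignoring practice, keep canonical-matching row else smallest practice id,
# set practice to canonical, then a final exact pass.
oracle_dedup_gp2gp <- function(events) {
  key <- paste(events$alf, events$event_dt, trimws(as.character(events$code)),
               trimws(as.character(events$value)), trimws(as.character(events$value_unit)),
               sep = "\r")
  pick <- unlist(lapply(unique(key), function(k) {
    idx <- which(key == k)
    hit <- idx[events$practice_id[idx] == events$canonical_practice_id[idx]]
    if (length(hit)) hit[which.min(events$source_row_id[hit])]
    else idx[order(events$practice_id[idx], events$source_row_id[idx])[1]]
  }))
  out <- events[sort(pick), ]
  out$practice_id <- out$canonical_practice_id
  oracle_dedup_exact(out)
}

expect_same_events <- function(a, b) {
  cols <- c("source_row_id", "alf", "event_dt", "practice_id", "code", "value", "value_unit")
  expect_equal(
    as.data.frame(dplyr::arrange(a[cols], source_row_id)),
    as.data.frame(dplyr::arrange(b[cols], source_row_id))
  )
}
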