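# Month grid for a set of registration spells clipped to the study window:
# one row per (spell, month) with the covered day range inside that month.
spell_month_grid <- function(registrations, span) {
  spells <- registrations %>%
    dplyr::mutate(
      s = pmax(.data$start_dt, span[1]),
      e = pmin(dplyr::coalesce(.data$end_dt, .FAR_FUTURE) - 1, span[2])
    ) %>%
    dplyr::filter(.data$s <= .data$e)
  if (nrow(spells) == 0) {
    return(tibble::tibble(alf = integer(), practice_id = character(),
                          month_start = as.Date(character()), first_day = as.Date(character()),
                          covered_days = integer(), frac = numeric()))
  }
  spells %>%
    dplyr::mutate(
      m0 = lubridate::floor_date(.data$s, "month"),
      m1 = lubridate::floor_date(.data$e, "month"),
      n_months = lubridate::interval(.data$m0, .data$m1) %/% months(1) + 1
    ) %>%
    tidyr::uncount(.data$n_months, .id = ".m") %>%
    dplyr::mutate(
      month_start = .data$m0 %m+% months(.data$.m - 1),
      first_day = pmax(.data$s, .data$month_start),
      last_day = pmin(.data$e, .data$month_start %m+% months(1) - 1),
      covered_days = as.integer(.data$last_day - .data$first_day) + 1L,
      frac = .data$covered_days / days_in_month_of(.data$month_start)
    ) %>%
    dplyr::select("alf", "practice_id", "month_start", "first_day",
                  "covered_days", "frac")
}

#' @importFrom lubridate %m+%
NULL

# log-scale intensity multiplier for one category over a vector of months
category_log_rate <- function(config, category, month_start) {
  yrs <- as.numeric(month_start - config$date_span[1]) / 365.25
  m <- as.integer(format(month_start, "%m"))
  amp <- config$seasonal_amplitude[[category]]
  peak <- config$seasonal_peak[[category]]
  slope <- config$trend_slope[[category]]
  lp <- log(config$category_intensity[[category]] / 12) +
    slope * yrs + amp * cos(2 * pi * (m - peak) / 12)
  pw <- config$pandemic_windows[[category]]
  if (!is.null(pw)) {
    mid <- month_start + 14
    inside <- mid >= pw$start & mid <= pw$end
    lp[inside] <- lp[inside] + log(pw$multiplier)
  }
  lp
}

#' Generate clean synthetic GP events with ground truth
#'
#' Draws per-category person-day activity bundles from a log-linear Poisson
#' model (baseline intensity, linear trend, cosine seasonality, pandemic
#' multiplier windows), dates each bundle uniformly over the registered days
#' of its month, and expands bundles into one or more coded events drawn
#' from the category's code pools. A share of consultation bundles is a
#' remote-prescription pair (prescription code plus phone-contact code). All
#' events fall inside a registration spell of their person by construction.
#'
#' The returned ground truth records the true activity-category set of every
#' person-day, derived from the known per-code assignments with a direct
#' implementation of the category definitions, kept separate from the
#' rules-engine classification path.
#'
#' @param cohort output of [generate_cohort()]
#' @param code_universe output of [generate_code_universe()]
#' @param config the shared [sim_config()]
#' @return list with `events` (clean raw-event tibble) and `truth`
#'   (`person_day` truth sets, per-code assignments, bundle table)
#' @export
generate_events <- function(cohort, code_universe, config) {
  set.seed(stage_seed(config$seed, "events"))
  grid <- spell_month_grid(cohort$registrations, config$date_span)
  if (nrow(grid) == 0) {
    warn("empty cohort or no registration time in the study window; no events generated")
    empty <- empty_events()
    return(list(events = empty, truth = truth_from_events(empty, code_universe)))
  }

  codes_by_pool <- split(code_universe$truth$code_key,
                         substr(code_universe$truth$code_key, 1, 2))

  bundles <- purrr::map_dfr(activity_categories(), function(cat) {
    lam <- exp(category_log_rate(config, cat, grid$month_start)) * grid$frac
    n <- stats::rpois(nrow(grid), lam)
    keep <- n > 0
    if (!any(keep)) return(NULL)
    grid[keep, ] %>%
      dplyr::mutate(n = n[keep], category = cat) %>%
      tidyr::uncount(.data$n) %>%
      dplyr::mutate(event_dt = .data$first_day +
                      floor(stats::runif(dplyr::n()) * .data$covered_days))
  })
  if (nrow(bundles) == 0) {
    empty <- empty_events()
    return(list(events = empty, truth = truth_from_events(empty, code_universe)))
  }
  # distinct person-day per category (two bundles of one category on the same
  # day collapse; different categories may share a day)
  bundles <- bundles %>%
    dplyr::distinct(.data$alf, .data$event_dt, .data$practice_id, .data$category) %>%
    dplyr::mutate(bundle_id = dplyr::row_number())

  # expand bundles into events
  remote_rx <- bundles$category == "CONSULTATION" & stats::runif(nrow(bundles)) < 0.15
  n_codes <- ifelse(remote_rx, 2L, 1L + stats::rpois(nrow(bundles), 0.4))
  ev <- bundles %>%
    dplyr::mutate(n_codes = n_codes, remote_rx = remote_rx) %>%
    tidyr::uncount(.data$n_codes, .id = ".j")
  draw_pool <- character(nrow(ev))
  for (cat in unique(ev$category)) {
    rows <- which(ev$category == cat)
    p <- .CATEGORY_POOLS[[cat]]
    draw_pool[rows] <- sample(names(p), length(rows), replace = TRUE, prob = p)
  }
  # remote-prescription pairs: one prescription code + one phone code
  draw_pool[ev$remote_rx & ev$.j == 1L] <- "Rx"
  draw_pool[ev$remote_rx & ev$.j == 2L] <- "Ph"
  code <- character(nrow(ev))
  for (pl in unique(draw_pool)) {
    rows <- which(draw_pool == pl)
    code[rows] <- sample(codes_by_pool[[pl]], length(rows), replace = TRUE)
  }
  ev$code <- code

  is_lab <- startsWith(ev$code, "Cl")
  ev$value <- ifelse(is_lab, round(stats::rnorm(nrow(ev), 5, 1), 1), NA_real_)
  ev$value_unit <- ifelse(is_lab, "mmol/L", NA_character_)

  # within a person-day, identical (code, value) rows would be indistinguishable
  # from injected duplicates; keep events unique by construction
  events <- ev %>%
    dplyr::distinct(.data$alf, .data$event_dt, .data$practice_id, .data$code,
                    .data$value, .data$value_unit) %>%
    dplyr::arrange(.data$alf, .data$event_dt, .data$practice_id, .data$code) %>%
    dplyr::mutate(source_row_id = dplyr::row_number()) %>%
    dplyr::select("source_row_id", "alf", "event_dt", "practice_id",
                  "code", "value", "value_unit")

  list(events = events, truth = truth_from_events(events, code_universe))
}

empty_events <- function() {
  tibble::tibble(
    source_row_id = integer(), alf = integer(), event_dt = as.Date(character()),
    practice_id = character(), code = character(), value = numeric(),
    value_unit = character()
  )
}

# Ground-truth activity categories per person-day, computed directly from the
# generator's known per-code assignments. This is a deliberate second
# implementation of the category definitions, independent of the
# rules-engine path in classify.R.
truth_from_events <- function(events, code_universe) {
  truth_map <- code_universe$truth
  if (nrow(events) == 0) {
    return(list(
      person_day = tibble::tibble(alf = integer(), event_dt = as.Date(character()),
                                  categories = character()),
      code_assignments = truth_map
    ))
  }
  consult_details <- c("EXAMINATION_SIGN", "HISTORY_SYMPTOM", "OBSERVATION",
                       "DIAGNOSIS", "LAB_PROCEDURE", "LAB_REQUEST_RESULT",
                       "SCREENING_ASSESSMENT", "CHRONIC_MONITORING",
                       "PATIENT_MONITORING", "REVIEW_PREVENTION",
                       "THERAPEUTIC_PROCEDURE", "CERTIFICATE", "MATERNAL_CHILD",
                       "COUNSELLING_EDUCATION", "REFERRAL")
  pd <- events %>%
    dplyr::left_join(truth_map, by = c(code = "code_key")) %>%
    dplyr::group_by(.data$alf, .data$event_dt) %>%
    dplyr::summarise(
      primary = any(.data$provider == "PRIMARY_CARE"),
      consultation = any(.data$detail %in% consult_details) |
        (any(.data$detail == "DRUG_PRESCRIPTION") &
           (any(.data$access_mode == "REMOTE") |
              any(.data$interaction_type %in% c("IN_PRACTICE_VISIT", "HOME_VISIT")))),
      prescription_only = all(.data$detail == "DRUG_PRESCRIPTION"),
      vaccination = any(.data$interaction_type == "IMMUNISATION") &
        !any(.data$interaction_type %in% c("PHARMACY", "DENTAL")) &
        !any(.data$detail == "FAILED_ENCOUNTER"),
      admin_only = all(.data$access_mode == "ADMIN") & !all(.data$detail == "FAILED_ENCOUNTER"),
      certificate = any(.data$detail == "CERTIFICATE"),
      review = any(.data$detail %in% c("CHRONIC_MONITORING", "PATIENT_MONITORING",
                                       "REVIEW_PREVENTION")),
      screening = any(.data$detail == "SCREENING_ASSESSMENT"),
      failed = all(.data$detail == "FAILED_ENCOUNTER"),
      .groups = "drop"
    )
  cat_cols <- c(ADMIN_ONLY = "admin_only", CERTIFICATE = "certificate",
                CONSULTATION = "consultation", FAILED_ENCOUNTER = "failed",
                PRESCRIPTION_ONLY = "prescription_only", REVIEW_MONITORING = "review",
                SCREENING_ASSESSMENT = "screening", VACCINATION = "vaccination")
  m <- as.matrix(pd[, cat_cols]) & pd$primary
  colnames(m) <- names(cat_cols)
  person_day <- pd %>%
    dplyr::transmute(
      .data$alf, .data$event_dt,
      categories = apply(m, 1L, function(r) paste(sort(colnames(m)[r]), collapse = "|"))
    )
  list(person_day = person_day, code_assignments = truth_map)
}

#' Inject corruption into a clean event stream
#'
#' Applies each corruption kind to a disjoint random sample of clean rows
#' (sampled without replacement from one permutation, so the ledger
#' partitions the injections): blanking one identifying field, appending an
#' exact copy, appending a GP-to-GP copy under a different practice id,
#' re-dating a row before the person's first registration spell, and
#' swapping the code for a malformed or an undocumented-but-well-formed
#' string. Every injection is recorded in the corruption ledger.
#'
#' @param clean_events clean events from [generate_events()]
#' @param cohort the cohort the events were generated from
#' @param config the shared [sim_config()]
#' @return list with `events` (the corrupted raw table) and `ledger`
#'   (tibble of `source_row_id`, `corruption_kind`, `clean_row_id`)
#' @export
corrupt_events <- function(clean_events, cohort, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "corrupt"))
  fr <- config$corruption
  n <- nrow(clean_events)
  events <- tibble::as_tibble(clean_events)
  ledger <- tibble::tibble(source_row_id = integer(), corruption_kind = character(),
                           clean_row_id = integer())
  if (n == 0 || sum(unlist(fr)) == 0) {
    return(list(events = events, ledger = ledger))
  }

  kinds <- c(MISSING_FIELD = fr$missing_field_frac, EXACT_DUP = fr$exact_dup_frac,
             GP2GP_DUP = fr$gp2gp_dup_frac, OUT_OF_REGISTRATION = fr$out_of_registration_frac,
             INVALID_CODE = fr$invalid_code_frac, UNKNOWN_CODE = fr$unknown_code_frac)
  counts <- stats::rbinom(length(kinds), n, unname(kinds))
  names(counts) <- names(kinds)
  if (sum(counts) > n) counts <- floor(counts * n / sum(counts))
  perm <- sample.int(n)
  idx <- split(perm[seq_len(sum(counts))], rep(names(kinds), counts))

  add_ledger <- function(kind, source_id, clean_id) {
    ledger <<- dplyr::bind_rows(ledger, tibble::tibble(
      source_row_id = source_id, corruption_kind = kind, clean_row_id = clean_id
    ))
  }

  # in-place: blank one identifying field (cycled over the three fields)
  i <- idx$MISSING_FIELD
  if (length(i)) {
    which_field <- seq_along(i) %% 3L
    events$alf[i[which_field == 0L]] <- NA_integer_
    events$event_dt[i[which_field == 1L]] <- as.Date(NA)
    events$practice_id[i[which_field == 2L]] <- NA_character_
    add_ledger("MISSING_FIELD", events$source_row_id[i], events$source_row_id[i])
  }

  # in-place: move the event before the person's first registration spell
  i <- idx$OUT_OF_REGISTRATION
  if (length(i)) {
    first_start <- cohort$registrations %>%
      dplyr::group_by(.data$alf) %>%
      dplyr::summarise(first_start = min(.data$start_dt), .groups = "drop")
    new_dt <- events[i, ] %>%
      dplyr::left_join(first_start, by = "alf") %>%
      dplyr::pull("first_start")
    events$event_dt[i] <- new_dt - sample(30:400, length(i), replace = TRUE)
    add_ledger("OUT_OF_REGISTRATION", events$source_row_id[i], events$source_row_id[i])
  }

  # in-place code swaps; each injection gets a distinct string so that two
  # same-day rows can never be collapsed into one by the swap itself
  i <- idx$INVALID_CODE
  if (length(i)) {
    events$code[i] <- sprintf("#%05d", sample.int(99999, length(i)))
    add_ledger("INVALID_CODE", events$source_row_id[i], events$source_row_id[i])
  }
  i <- idx$UNKNOWN_CODE
  if (length(i)) {
    events$code[i] <- sprintf("Q%04d", sample.int(9999, length(i)))
    add_ledger("UNKNOWN_CODE", events$source_row_id[i], events$source_row_id[i])
  }

  next_id <- max(events$source_row_id) + 1L

  # appended: exact copies
  i <- idx$EXACT_DUP
  if (length(i)) {
    dup <- events[i, ]
    dup$source_row_id <- seq(next_id, length.out = length(i))
    next_id <- next_id + length(i)
    add_ledger("EXACT_DUP", dup$source_row_id, events$source_row_id[i])
    events <- dplyr::bind_rows(events, dup)
  }

  # appended: GP-to-GP copies under a different recorded practice
  i <- idx$GP2GP_DUP
  if (length(i)) {
    dup <- events[i, ]
    other <- vapply(dup$practice_id, function(p) {
      pool <- setdiff(cohort$practices$practice_id, p)
      if (length(pool)) sample(pool, 1L) else p
    }, character(1))
    dup$practice_id <- unname(other)
    dup$source_row_id <- seq(next_id, length.out = length(i))
    add_ledger("GP2GP_DUP", dup$source_row_id, events$source_row_id[i])
    events <- dplyr::bind_rows(events, dup)
  }

  list(events = dplyr::arrange(events, .data$source_row_id),
       ledger = dplyr::arrange(ledger, .data$source_row_id))
}
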