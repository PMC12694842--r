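#' Simulation configuration for the synthetic GP-data generator
#'
#' Defines the synthetic study universe: cohort size, practice network and
#' data-sharing fraction, the study window, per-category person-day
#' intensities with seasonal/trend/pandemic modulation, and the corruption
#' fractions injected into the clean event stream. Defaults describe a
#' ten-year demonstration cohort with activity magnitudes in the range seen
#' in UK primary care (a handful of consultation and prescription days per
#' person-year, October-peaked vaccination).
#'
#' @param n_persons,n_practices cohort and practice-network size
#' @param sharing_fraction proportion of practices sharing data
#' @param date_span length-2 Date vector, start and end of the study window
#' @param category_intensity named numeric, mean person-day bundles per
#'   person-year for each activity category
#' @param seasonal_amplitude named numeric, multiplicative log-scale cosine
#'   amplitude per category (0 = no seasonality)
#' @param seasonal_peak named integer, calendar month of the seasonal peak
#' @param trend_slope named numeric, log-rate change per year
#' @param pandemic_windows named list per category of
#'   `list(start =, end =, multiplier =)` applied to months inside the window
#' @param corruption named list of fractions
#'   (`missing_field_frac`, `exact_dup_frac`, `gp2gp_dup_frac`,
#'   `out_of_registration_frac`, `invalid_code_frac`, `unknown_code_frac`)
#' @param seed root seed; every generator stage derives its stream from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_persons = 2000,
                       n_practices = 40,
                       sharing_fraction = 0.8,
                       date_span = as.Date(c("2015-01-01", "2024-12-31")),
                       category_intensity = c(
                         CONSULTATION = 5, PRESCRIPTION_ONLY = 6, VACCINATION = 0.7,
                         ADMIN_ONLY = 1.5, CERTIFICATE = 0.25, REVIEW_MONITORING = 1.2,
                         SCREENING_ASSESSMENT = 0.5, FAILED_ENCOUNTER = 0.3
                       ),
                       seasonal_amplitude = c(
                         CONSULTATION = 0.10, PRESCRIPTION_ONLY = 0.05, VACCINATION = 2.5,
                         ADMIN_ONLY = 0, CERTIFICATE = 0, REVIEW_MONITORING = 0,
                         SCREENING_ASSESSMENT = 0, FAILED_ENCOUNTER = 0
                       ),
                       seasonal_peak = c(
                         CONSULTATION = 1, PRESCRIPTION_ONLY = 1, VACCINATION = 10,
                         ADMIN_ONLY = 1, CERTIFICATE = 1, REVIEW_MONITORING = 1,
                         SCREENING_ASSESSMENT = 1, FAILED_ENCOUNTER = 1
                       ),
                       trend_slope = c(
                         CONSULTATION = 0.026, PRESCRIPTION_ONLY = 0.029, VACCINATION = 0.018,
                         ADMIN_ONLY = 0, CERTIFICATE = 0, REVIEW_MONITORING = 0.01,
                         SCREENING_ASSESSMENT = 0, FAILED_ENCOUNTER = 0
                       ),
                       pandemic_windows = list(
                         CONSULTATION = list(start = as.Date("2020-03-01"),
                                             end = as.Date("2021-03-31"), multiplier = 0.6),
                         VACCINATION = list(start = as.Date("2021-01-01"),
                                            end = as.Date("2022-12-31"), multiplier = 3)
                       ),
                       corruption = list(
                         missing_field_frac = 0.02, exact_dup_frac = 0.03,
                         gp2gp_dup_frac = 0.02, out_of_registration_frac = 0.02,
                         invalid_code_frac = 0.01, unknown_code_frac = 0.01
                       ),
                       seed = 20240101) {
  cats <- activity_categories()
  fill <- function(x, default = 0) {
    out <- stats::setNames(rep(default, length(cats)), cats)
    out[names(x)] <- x
    out
  }
  cfg <- list(
    n_persons = n_persons, n_practices = n_practices,
    sharing_fraction = sharing_fraction,
    date_span = as.Date(date_span),
    category_intensity = fill(category_intensity),
    seasonal_amplitude = fill(seasonal_amplitude),
    seasonal_peak = fill(seasonal_peak, 1),
    trend_slope = fill(trend_slope),
    pandemic_windows = pandemic_windows,
    corruption = corruption,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 0) abort_config("n_persons", "must be a non-negative count")
  if (!is.numeric(cfg$n_practices) || cfg$n_practices < 1) abort_config("n_practices", "must be a positive count")
  if (is.na(cfg$sharing_fraction) || cfg$sharing_fraction < 0 || cfg$sharing_fraction > 1) {
    abort_config("sharing_fraction", "must lie in [0, 1]")
  }
  if (length(cfg$date_span) != 2 || any(is.na(cfg$date_span)) ||
      cfg$date_span[1] > cfg$date_span[2]) {
    abort_config("date_span", "must be a non-empty (start, end) date range")
  }
  if (any(cfg$category_intensity < 0)) abort_config("category_intensity", "must be >= 0")
  if (any(cfg$seasonal_amplitude < 0)) abort_config("seasonal_amplitude", "must be >= 0")
  needed <- c("missing_field_frac", "exact_dup_frac", "gp2gp_dup_frac",
              "out_of_registration_frac", "invalid_code_frac", "unknown_code_frac")
  missing_fracs <- setdiff(needed, names(cfg$corruption))
  if (length(missing_fracs)) abort_config("corruption", paste("lacks", paste(missing_fracs, collapse = ", ")))
  fr <- unlist(cfg$corruption[needed])
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1)) {
    abort_config("corruption", "fractions must lie in [0, 1]")
  }
  if (sum(fr) > 1) {
    abort_config("corruption", "fractions must sum to <= 1 (kinds are applied to disjoint row samples)")
  }
  if (!is.numeric(cfg$seed) || is.na(cfg$seed)) abort_config("seed", "must be an integer")
  invisible(cfg)
}

.HEALTH_BOARDS <- c(
  "Betsi Cadwaladr", "Powys", "Hywel Dda", "Swansea Bay",
  "Cwm Taf Morgannwg", "Aneurin Bevan", "Cardiff & Vale"
)

#' Generate the synthetic cohort
#'
#' Creates persons (sex, birth date, deprivation quintile, health board),
#' their residence histories (mostly stable Welsh residence, with a minority
#' moving in and out of Wales), their GP registration histories (possibly
#' several spells with different practices, non-overlapping, half-open
#' `[start, end)`), and the practice network with data-sharing flags drawn
#' at the configured fraction.
#'
#' @param config a [sim_config()]
#' @return list of tibbles: `persons`, `residence`, `registrations`,
#'   `practices`
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "cohort"))
  span <- config$date_span
  n <- config$n_persons

  practices <- tibble::tibble(
    practice_id = sprintf("P%03d", seq_len(config$n_practices)),
    health_board = sample(.HEALTH_BOARDS, config$n_practices, replace = TRUE),
    shares_data = stats::runif(config$n_practices) < config$sharing_fraction
  )

  persons <- tibble::tibble(
    alf = seq_len(n),
    sex = sample(c("M", "F"), n, replace = TRUE),
    birth_dt = span[1] - round(stats::runif(n, 0, 90 * 365.25)),
    wimd_quintile = sample(1:5, n, replace = TRUE),
    health_board = sample(.HEALTH_BOARDS, n, replace = TRUE)
  )
  if (n == 0) {
    return(list(
      persons = persons,
      residence = tibble::tibble(alf = integer(), lsoa = character(),
                                 start_dt = as.Date(character()), end_dt = as.Date(character())),
      registrations = tibble::tibble(alf = integer(), practice_id = character(),
                                     start_dt = as.Date(character()), end_dt = as.Date(character())),
      practices = practices
    ))
  }

  # Residence: ~90% have one open-ended Welsh spell from max(birth, pre-span);
  # movers get a gap (out of Wales) splitting their residence, some with an
  # English spell in between.
  res_start <- pmax(persons$birth_dt, span[1] - round(stats::runif(n, 365, 5 * 365)))
  mover <- stats::runif(n) < 0.10
  gap_start <- res_start + round(stats::runif(n, 200, as.numeric(span[2] - res_start) * 0.8))
  gap_len <- round(stats::runif(n, 90, 720))
  welsh_lsoa <- function(k) sprintf("W0%07d", sample.int(2e6, k, replace = TRUE))
  english_lsoa <- function(k) sprintf("E0%07d", sample.int(2e6, k, replace = TRUE))

  stay <- tibble::tibble(alf = persons$alf[!mover], lsoa = welsh_lsoa(sum(!mover)),
                         start_dt = res_start[!mover], end_dt = as.Date(NA))
  mv <- which(mover)
  moved <- dplyr::bind_rows(
    tibble::tibble(alf = persons$alf[mv], lsoa = welsh_lsoa(length(mv)),
                   start_dt = res_start[mv], end_dt = gap_start[mv]),
    tibble::tibble(alf = persons$alf[mv], lsoa = english_lsoa(length(mv)),
                   start_dt = gap_start[mv], end_dt = gap_start[mv] + gap_len[mv]),
    tibble::tibble(alf = persons$alf[mv], lsoa = welsh_lsoa(length(mv)),
                   start_dt = gap_start[mv] + gap_len[mv], end_dt = as.Date(NA))
  )
  residence <- dplyr::bind_rows(stay, moved) %>% dplyr::arrange(.data$alf, .data$start_dt)

  # Registrations: within each Welsh residence spell, 1-3 consecutive spells
  # with randomly drawn practices; a short unregistered lead-in sometimes.
  welsh <- residence %>%
    dplyr::filter(startsWith(.data$lsoa, "W")) %>%
    dplyr::mutate(.spell = dplyr::row_number(),
                  end_eff = dplyr::coalesce(.data$end_dt, span[2] + 1))
  nseg <- sample(1:3, nrow(welsh), replace = TRUE, prob = c(0.6, 0.3, 0.1))
  lead_in <- round(stats::runif(nrow(welsh), 0, 45))
  regs <- welsh %>%
    dplyr::mutate(n_seg = nseg, reg_start = .data$start_dt + lead_in) %>%
    dplyr::filter(.data$reg_start < .data$end_eff) %>%
    tidyr::uncount(.data$n_seg, .id = "seg") %>%
    dplyr::group_by(.data$.spell) %>%
    dplyr::mutate(
      .len = as.numeric(.data$end_eff - .data$reg_start),
      .cut = round(.data$.len * (.data$seg / dplyr::n())),
      start_dt = .data$reg_start + c(0, utils::head(.data$.cut, -1)),
      end_dt = dplyr::if_else(.data$seg == dplyr::n(), .data$end_dt,
                              .data$reg_start + .data$.cut)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(practice_id = sample(practices$practice_id, dplyr::n(), replace = TRUE)) %>%
    dplyr::filter(is.na(.data$end_dt) | .data$start_dt < .data$end_dt) %>%
    dplyr::select("alf", "practice_id", "start_dt", "end_dt") %>%
    dplyr::arrange(.data$alf, .data$start_dt)

  list(persons = persons, residence = residence,
       registrations = regs, practices = practices)
}
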