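# ---- IO helpers -----------------------------------------------------------

write_tbl <- function(x, path) {
  readr::write_csv(x, path, na = "")
  path
}

.RAW_EVENT_COLS <- readr::cols(
  source_row_id = readr::col_integer(), alf = readr::col_integer(),
  event_dt = readr::col_date(), practice_id = readr::col_character(),
  code = readr::col_character(), value = readr::col_double(),
  value_unit = readr::col_character()
)

#' Read a raw event CSV
#'
#' Empty strings are missing values; dates are ISO-8601.
#'
#' @param path CSV path with columns `source_row_id`, `alf`, `event_dt`,
#'   `practice_id`, `code`, `value`, `value_unit`
#' @return tibble of raw events
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = .RAW_EVENT_COLS, na = "")
}

#' Read a registration or residence spell CSV
#' @param path CSV with `alf`, `practice_id` or `lsoa`, `start_dt`, `end_dt`
#' @return tibble
#' @export
read_spells <- function(path) {
  readr::read_csv(path, na = "", col_types = readr::cols(
    alf = readr::col_integer(), start_dt = readr::col_date(),
    end_dt = readr::col_date(), .default = readr::col_character()
  ))
}

# ---- run configuration ----------------------------------------------------

#' Default end-to-end run configuration
#'
#' @param out_dir output directory
#' @param seed root seed
#' @param n_persons,n_practices cohort size
#' @param years length-2 integer vector, first and last study year
#' @param categories activity categories to run the trend analyses for
#' @return a nested configuration list accepted by [run_all()]
#' @export
default_run_config <- function(out_dir = tempfile("rrda_run_"), seed = 20240101,
                               n_persons = 2000, n_practices = 40,
                               years = c(2015, 2024),
                               categories = c("CONSULTATION", "PRESCRIPTION_ONLY")) {
  list(
    out_dir = out_dir, seed = seed,
    simulate = list(n_persons = n_persons, n_practices = n_practices,
                    sharing_fraction = 0.8, years = years),
    analysis = list(
      categories = categories,
      ref_year = max(years[1] + 1, min(2019, years[2] - 1)),
      exclude_years = intersect(2020:2021, seq(years[1], years[2])),
      vaccination_exclude_years = intersect(2021:2022, seq(years[1], years[2]))
    )
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  base <- default_run_config()
  config <- utils::modifyList(base, config)
  if (is.null(config$out_dir)) abort_config("out_dir", "is required")
  config
}

# ---- stages ---------------------------------------------------------------

stage_simulate <- function(config) {
  sim <- config$simulate
  span <- as.Date(sprintf(c("%d-01-01", "%d-12-31"), sim$years))
  cfg <- sim_config(
    n_persons = sim$n_persons, n_practices = sim$n_practices,
    sharing_fraction = sim$sharing_fraction %||% 0.8,
    date_span = span, seed = config$seed
  )
  cohort <- generate_cohort(cfg)
  universe <- generate_code_universe(cfg)
  gen <- generate_events(cohort, universe, cfg)
  cor <- corrupt_events(gen$events, cohort, cfg)
  out <- config$out_dir
  dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "codes"), showWarnings = FALSE)
  write_tbl(cohort$persons, file.path(out, "persons.csv"))
  write_tbl(cohort$residence, file.path(out, "residence.csv"))
  write_tbl(cohort$registrations, file.path(out, "registrations.csv"))
  write_tbl(cohort$practices, file.path(out, "practices.csv"))
  write_tbl(cor$events, file.path(out, "events_raw.csv"))
  for (src in unique(universe$sources$source)) {
    write_tbl(dplyr::filter(universe$sources, .data$source == src),
              file.path(out, "codes", paste0(src, ".csv")))
  }
  yaml::write_yaml(purrr::transpose(as.list(universe$rules)),
                   file.path(out, "rules.yaml"))
  write_tbl(cor$ledger, file.path(out, "truth", "corruption_ledger.csv"))
  write_tbl(gen$truth$person_day, file.path(out, "truth", "person_day_categories.csv"))
  write_tbl(gen$truth$code_assignments, file.path(out, "truth", "code_assignments.csv"))
  invisible(config)
}

stage_build_lookup <- function(config) {
  out <- config$out_dir
  files <- list.files(file.path(out, "codes"), full.names = TRUE)
  sources <- purrr::map_dfr(files, ~ readr::read_csv(.x, na = "", col_types = readr::cols(
    .default = readr::col_character()
  )))
  lookup <- build_lookup(sources)
  write_tbl(lookup, file.path(out, "code_lookup.csv"))
  invisible(config)
}

stage_curate <- function(config) {
  out <- config$out_dir
  events <- read_events(file.path(out, "events_raw.csv"))
  regs <- read_spells(file.path(out, "registrations.csv"))
  lookup <- readr::read_csv(file.path(out, "code_lookup.csv"), na = "",
                            col_types = readr::cols(code_id = readr::col_integer(),
                                                    .default = readr::col_character()))
  rrda <- build_rrda(events, regs, lookup)
  write_tbl(rrda$person_day, file.path(out, "person_day.csv"))
  write_tbl(rrda$clinical_events, file.path(out, "clinical_event.csv"))
  write_tbl(rrda$lookup, file.path(out, "code_lookup.csv"))
  write_tbl(rrda$retention, file.path(out, "retention.csv"))
  jsonlite::write_json(rrda$consort, file.path(out, "consort.json"), digits = NA)
  ev_resolved <- rrda$clinical_events %>%
    dplyr::left_join(rrda$person_day, by = "event_id")
  write_tbl(usage_summary(ev_resolved, rrda$lookup), file.path(out, "usage_summary.csv"))
  invisible(config)
}

stage_classify <- function(config) {
  out <- config$out_dir
  person_day <- readr::read_csv(file.path(out, "person_day.csv"), na = "",
                                col_types = readr::cols(event_id = readr::col_integer(),
                                                        alf = readr::col_integer(),
                                                        event_dt = readr::col_date(),
                                                        practice_id = readr::col_character()))
  clinical <- readr::read_csv(file.path(out, "clinical_event.csv"), na = "",
                              col_types = readr::cols(event_id = readr::col_integer(),
                                                      code_id = readr::col_integer(),
                                                      value = readr::col_double(),
                                                      value_unit = readr::col_character()))
  lookup <- readr::read_csv(file.path(out, "code_lookup.csv"), na = "",
                            col_types = readr::cols(code_id = readr::col_integer(),
                                                    .default = readr::col_character()))
  rules <- compile_rules(file.path(out, "rules.yaml"))
  activity <- categorize_all(person_day, clinical, lookup, rules)
  write_tbl(activity, file.path(out, "activity.csv"))
  invisible(config)
}

stage_coverage <- function(config) {
  out <- config$out_dir
  persons <- readr::read_csv(file.path(out, "persons.csv"), na = "",
                             col_types = readr::cols(alf = readr::col_integer(),
                                                     birth_dt = readr::col_date(),
                                                     wimd_quintile = readr::col_integer(),
                                                     .default = readr::col_character()))
  residence <- read_spells(file.path(out, "residence.csv"))
  regs <- read_spells(file.path(out, "registrations.csv"))
  practices <- readr::read_csv(file.path(out, "practices.csv"), na = "",
                               col_types = readr::cols(shares_data = readr::col_logical(),
                                                       .default = readr::col_character()))
  years <- seq(config$simulate$years[1], config$simulate$years[2])
  panel <- build_panel(persons, residence, regs, practices, years)
  write_tbl(panel, file.path(out, "panel.csv"))
  fit <- fit_coverage_gamm(panel, adjusted = TRUE)
  jsonlite::write_json(
    list(or_table = fit$or_table, rho = fit$rho, ar_sd = fit$ar_sd,
         adjusted = fit$adjusted, covariates = fit$covariates),
    file.path(out, "coverage_fit.json"), digits = 10, auto_unbox = TRUE
  )
  invisible(config)
}

stage_trends <- function(config) {
  out <- config$out_dir
  activity <- readr::read_csv(file.path(out, "activity.csv"), na = "",
                              col_types = readr::cols(event_id = readr::col_integer(),
                                                      categories = readr::col_character())) %>%
    dplyr::mutate(categories = dplyr::coalesce(.data$categories, ""))
  person_day <- readr::read_csv(file.path(out, "person_day.csv"), na = "",
                                col_types = readr::cols(event_id = readr::col_integer(),
                                                        alf = readr::col_integer(),
                                                        event_dt = readr::col_date(),
                                                        practice_id = readr::col_character()))
  panel <- readr::read_csv(file.path(out, "panel.csv"), na = "",
                           col_types = readr::cols(year = readr::col_integer(),
                                                   n_resident = readr::col_integer(),
                                                   n_covered = readr::col_integer(),
                                                   .default = readr::col_character()))
  annual <- panel %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(population = sum(.data$n_covered), .groups = "drop")
  years <- seq(config$simulate$years[1], config$simulate$years[2])
  population <- monthly_population(annual, years)
  ana <- config$analysis
  for (cat in ana$categories) {
    excl <- if (cat == "VACCINATION") ana$vaccination_exclude_years else ana$exclude_years
    series <- monthly_series(activity, person_day, population, cat)
    write_tbl(series, file.path(out, sprintf("monthly_%s.csv", tolower(cat))))
    fit <- fit_trend_gamm(series, exclude_years = excl)
    dev <- predict_expected(fit)
    write_tbl(dev, file.path(out, sprintf("deviations_%s.csv", tolower(cat))))
    jsonlite::write_json(
      list(theta = fit$theta, rho = fit$rho, exclude_years = excl,
           fitted_months = sum(!series$year %in% excl)),
      file.path(out, sprintf("trend_fit_%s.json", tolower(cat))),
      digits = 10, auto_unbox = TRUE
    )
    if (ana$ref_year %in% series$year) {
      rr <- fit_year_rr(series, ref_year = ana$ref_year)
      jsonlite::write_json(
        list(ref_year = rr$ref_year, theta = rr$theta, rho = rr$rho,
             rr_table = rr$rr_table),
        file.path(out, sprintf("year_rr_%s.json", tolower(cat))),
        digits = 10, auto_unbox = TRUE
      )
    }
  }
  invisible(config)
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes, in order: synthetic-data generation, look-up construction,
#' curation into the three-table RRDA, person-day activity classification,
#' the coverage panel and binomial GAMM, and the monthly trend analyses.
#' All outputs are written under `config$out_dir`; the returned manifest
#' lists every file with its row count (for tabular outputs) and MD5 hash,
#' plus a hash of the effective configuration. Identical configuration and
#' seed yield identical manifests.
#'
#' @param config configuration list or YAML path; see
#'   [default_run_config()]
#' @param seed optional seed override
#' @param out_dir optional output-directory override
#' @param stages subset of stages to run (default all, in order)
#' @return manifest tibble (invisibly reachable via attribute
#'   `config_hash`)
#' @export
run_all <- function(config = default_run_config(), seed = NULL, out_dir = NULL,
                    stages = c("simulate", "build_lookup", "curate", "classify",
                               "coverage", "trends")) {
  config <- load_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(simulate = stage_simulate, build_lookup = stage_build_lookup,
                  curate = stage_curate, classify = stage_classify,
                  coverage = stage_coverage, trends = stage_trends)
  for (st in stages) {
    message(sprintf("[%s] running", st))
    tryCatch(runners[[st]](config),
             error = function(e) {
               abort(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
                     class = "rrda_stage_error")
             })
  }
  files <- sort(list.files(config$out_dir, recursive = TRUE, full.names = TRUE))
  manifest <- tibble::tibble(
    file = sub(paste0("^", config$out_dir, "/?"), "", files),
    rows = vapply(files, function(f) {
      if (grepl("\\.csv$", f)) length(readr::read_lines(f)) - 1L else NA_integer_
    }, integer(1)),
    md5 = unname(tools::md5sum(files))
  )
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], cfg_file,
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "config_hash") <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  manifest
}
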