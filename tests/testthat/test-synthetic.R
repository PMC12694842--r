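test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(sharing_fraction = 1.2), "sharing_fraction")
  expect_error(sim_config(date_span = as.Date(c("2020-01-01", "2019-01-01"))),
               "date_span")
  expect_error(sim_config(category_intensity = c(CONSULTATION = -1)),
               "category_intensity")
  expect_error(sim_config(corruption = list(missing_field_frac = 0.6,
                                            exact_dup_frac = 0.6,
                                            gp2gp_dup_frac = 0,
                                            out_of_registration_frac = 0,
                                            invalid_code_frac = 0,
                                            unknown_code_frac = 0)),
               "sum")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config(n_persons = 60)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a, b)
  ua <- generate_code_universe(cfg); ub <- generate_code_universe(cfg)
  expect_identical(ua, ub)
  ea <- generate_events(a, ua, cfg); eb <- generate_events(b, ub, cfg)
  expect_identical(ea, eb)
  cfg2 <- tiny_config(n_persons = 60, seed = 999,
                      corruption = list(missing_field_frac = 0.1, exact_dup_frac = 0.1,
                                        gp2gp_dup_frac = 0, out_of_registration_frac = 0,
                                        invalid_code_frac = 0, unknown_code_frac = 0))
  ca <- corrupt_events(ea$events, a, cfg2); cb <- corrupt_events(eb$events, b, cfg2)
  expect_identical(ca, cb)
})

test_that("practice sharing matches the configured fraction", {
  none <- generate_cohort(tiny_config(n_persons = 20, sharing_fraction = 0))
  expect_false(any(none$practices$shares_data))
  cfg <- sim_config(n_persons = 1000, n_practices = 200, sharing_fraction = 0.8,
                    date_span = as.Date(c("2019-01-01", "2020-12-31")))
  cohort <- generate_cohort(cfg)
  n_shared <- sum(cohort$practices$shares_data)
  bounds <- stats::qbinom(c(0.005, 0.995), 200, 0.8)
  expect_gte(n_shared, bounds[1])
  expect_lte(n_shared, bounds[2])
})

test_that("cohort spells are well-formed", {
  cohort <- generate_cohort(tiny_config(n_persons = 150))
  for (tbl in list(cohort$residence, cohort$registrations)) {
    closed <- tbl[!is.na(tbl$end_dt), ]
    expect_true(all(closed$start_dt < closed$end_dt))
    # no overlap within person under the half-open convention
    per <- split(tbl, tbl$alf)
    overlap <- vapply(per, function(s) {
      s <- s[order(s$start_dt), ]
      if (nrow(s) < 2) return(FALSE)
      any(utils::head(dplyr::coalesce(s$end_dt, as.Date("9999-12-31")), -1) >
            utils::tail(s$start_dt, -1))
    }, logical(1))
    expect_false(any(overlap))
  }
})

test_that("the code universe carries full truth and the designed overlap", {
  uni <- generate_code_universe(tiny_config())
  non_snomed <- uni$sources[uni$sources$code_type != "SNOMED_CT", ]
  # official-style codes standardise to themselves
  expect_equal(standardize_code(non_snomed$code), non_snomed$code)
  # truth covers every non-SNOMED code
  expect_true(all(non_snomed$code %in% uni$truth$code_key))
  # at least six source lists and the overlap present in both lists
  expect_gte(dplyr::n_distinct(uni$sources$source), 6)
  read_codes <- uni$sources$code[uni$sources$source == "read_v2"]
  ukb_codes <- uni$sources$code[uni$sources$source == "emis_ukb"]
  expect_true(all(uni$overlap %in% read_codes))
  expect_true(all(uni$overlap %in% ukb_codes))
  # truth assignments are layer-consistent
  expect_true(all(layer_consistency(uni$truth)))
})

test_that("clean events land inside registration spells and track intensities", {
  cfg <- tiny_config(n_persons = 120)
  cohort <- generate_cohort(cfg)
  uni <- generate_code_universe(cfg)
  gen <- generate_events(cohort, uni, cfg)
  inside <- active_registration(cohort$registrations, gen$events$alf, gen$events$event_dt)
  expect_false(anyNA(inside))
  expect_equal(inside, gen$events$practice_id)

  # zero intensity produces zero events (and a warning for the empty stream)
  cfg0 <- tiny_config(n_persons = 30,
                      category_intensity = stats::setNames(rep(0, 8), activity_categories()))
  gen0 <- generate_events(generate_cohort(cfg0), generate_code_universe(cfg0), cfg0)
  expect_equal(nrow(gen0$events), 0)

  # an empty cohort yields an empty stream with a warning
  cfg_e <- tiny_config(n_persons = 0)
  expect_warning(gen_e <- generate_events(generate_cohort(cfg_e),
                                          generate_code_universe(cfg_e), cfg_e))
  expect_equal(nrow(gen_e$events), 0)
})

test_that("flat configuration yields Poisson-dispersed monthly counts", {
  cfg <- tiny_config(
    n_persons = 400, years = c(2016, 2023),
    category_intensity = c(CONSULTATION = 6),
    seasonal_amplitude = stats::setNames(rep(0, 8), activity_categories()),
    trend_slope = stats::setNames(rep(0, 8), activity_categories()),
    pandemic_windows = list()
  )
  cohort <- generate_cohort(cfg)
  gen <- generate_events(cohort, generate_code_universe(cfg), cfg)
  monthly <- gen$truth$person_day %>%
    dplyr::filter(grepl("CONSULTATION", categories)) %>%
    dplyr::count(ym = format(event_dt, "%Y-%m"))
  # variance/mean of flat Poisson-ish counts near 1 (person-time varies a bit)
  disp <- stats::var(monthly$n) / mean(monthly$n)
  expect_gt(disp, 0.5)
  expect_lt(disp, 2.5)
})

test_that("October-peaked vaccination has its annual maximum in October", {
  cfg <- tiny_config(n_persons = 600, years = c(2016, 2023),
                     pandemic_windows = list())
  cohort <- generate_cohort(cfg)
  gen <- generate_events(cohort, generate_code_universe(cfg), cfg)
  vac <- gen$truth$person_day %>%
    dplyr::filter(grepl("VACCINATION", categories)) %>%
    dplyr::mutate(year = format(event_dt, "%Y"), month = as.integer(format(event_dt, "%m"))) %>%
    dplyr::count(year, month)
  peak <- vac %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(peak_month = month[which.max(n)])
  expect_gte(mean(peak$peak_month == 10), 0.9)
})

test_that("corruption injection is exactly ledgered", {
  cfg <- tiny_config(n_persons = 150)
  cohort <- generate_cohort(cfg)
  gen <- generate_events(cohort, generate_code_universe(cfg), cfg)

  # zero fractions: identity, empty ledger
  c0 <- corrupt_events(gen$events, cohort, cfg)
  expect_identical(c0$events, gen$events)
  expect_equal(nrow(c0$ledger), 0)

  cfg2 <- tiny_config(n_persons = 150,
                      corruption = list(missing_field_frac = 0.05, exact_dup_frac = 0.1,
                                        gp2gp_dup_frac = 0.05, out_of_registration_frac = 0.03,
                                        invalid_code_frac = 0.02, unknown_code_frac = 0.02))
  c2 <- corrupt_events(gen$events, cohort, cfg2)
  # multiset accounting: raw rows = clean rows + appended duplicates
  n_appended <- sum(c2$ledger$corruption_kind %in% c("EXACT_DUP", "GP2GP_DUP"))
  expect_equal(nrow(c2$events), nrow(gen$events) + n_appended)
  # every ledger entry points at an emitted raw row and kinds partition rows
  expect_true(all(c2$ledger$source_row_id %in% c2$events$source_row_id))
  expect_false(anyDuplicated(c2$ledger$source_row_id) > 0)
  # injected exact-duplicate count within binomial 99.9% bounds
  n_dup <- sum(c2$ledger$corruption_kind == "EXACT_DUP")
  bounds <- stats::qbinom(c(0.0005, 0.9995), nrow(gen$events), 0.1)
  expect_gte(n_dup, bounds[1]); expect_lte(n_dup, bounds[2])
  # GP-to-GP copies differ from their clean twin only in practice id
  g2g <- c2$ledger[c2$ledger$corruption_kind == "GP2GP_DUP", ]
  twin <- dplyr::left_join(g2g, c2$events, by = "source_row_id") %>%
    dplyr::left_join(gen$events, by = c(clean_row_id = "source_row_id"),
                     suffix = c("", ".clean"))
  expect_true(all(twin$practice_id != twin$practice_id.clean))
  expect_true(all(twin$alf == twin$alf.clean & twin$event_dt == twin$event_dt.clean &
                    twin$code == twin$code.clean))
})
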