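make_events <- function(...) {
  tibble::tibble(...)
}

regs1 <- tibble::tibble(
  alf = c(1L, 1L, 2L),
  practice_id = c("P01", "P02", "P01"),
  start_dt = as.Date(c("2019-01-01", "2020-01-01", "2019-06-01")),
  end_dt = as.Date(c("2020-01-01", NA, "2019-12-01"))
)

test_that("records missing person, date or practice are dropped with partitioned reasons", {
  ev <- make_events(
    source_row_id = 1:4,
    alf = c(NA, 2L, 3L, 4L),
    event_dt = as.Date(c("2020-01-01", NA, "2020-01-01", "2020-01-01")),
    practice_id = c("P01", "P01", NA, "P01"),
    code = "Cd001", value = NA_real_, value_unit = NA_character_
  )
  out <- drop_incomplete(ev)
  expect_equal(out$events$source_row_id, 4L)
  expect_equal(out$dropped$n[out$dropped$reason == "MISSING_ALF"], 1L)
  expect_equal(out$dropped$n[out$dropped$reason == "MISSING_DATE"], 1L)
  expect_equal(out$dropped$n[out$dropped$reason == "MISSING_PRACTICE"], 1L)
  # complete batch is the identity
  out2 <- drop_incomplete(out$events)
  expect_equal(out2$events, out$events)
  expect_equal(sum(out2$dropped$n), 0L)
})

test_that("active registration respects the half-open convention and tie-breaks", {
  # strictly inside
  expect_equal(active_registration(regs1, 1L, as.Date("2019-06-15")), "P01")
  # on the start date: inside; on the end date: outside (next spell takes over)
  expect_equal(active_registration(regs1, 1L, as.Date("2019-01-01")), "P01")
  expect_equal(active_registration(regs1, 1L, as.Date("2020-01-01")), "P02")
  # no covering spell
  expect_true(is.na(active_registration(regs1, 2L, as.Date("2020-06-01"))))
  # overlapping spells: latest start wins, then smallest practice id
  regs2 <- tibble::tibble(
    alf = 1L, practice_id = c("P09", "P03", "P05"),
    start_dt = as.Date(c("2019-01-01", "2019-06-01", "2019-06-01")),
    end_dt = as.Date(NA)
  )
  expect_equal(active_registration(regs2, 1L, as.Date("2019-07-01")), "P03")

  # brute-force oracle over random overlapping spells
  for (seed in 1:20) {
    set.seed(seed)
    spells <- tibble::tibble(
      alf = 1L,
      practice_id = sprintf("P%02d", sample(1:9, 6, replace = TRUE)),
      start_dt = as.Date("2020-01-01") + sample(0:100, 6),
      end_dt = as.Date("2020-01-01") + sample(50:300, 6)
    )
    d <- as.Date("2020-01-01") + sample(0:250, 1)
    covering <- spells[!is.na(spells$start_dt) & spells$start_dt <= d & d < spells$end_dt, ]
    expected <- if (nrow(covering) == 0) NA_character_ else {
      covering <- covering[order(covering$start_dt, decreasing = TRUE), ]
      covering <- covering[covering$start_dt == covering$start_dt[1], ]
      min(covering$practice_id)
    }
    expect_equal(active_registration(spells, 1L, d), expected)
  }
})

test_that("registration validation excludes uncovered events and annotates the canonical practice", {
  ev <- make_events(
    source_row_id = 1:3, alf = c(1L, 1L, 2L),
    event_dt = as.Date(c("2019-06-15", "2021-06-15", "2020-06-01")),
    practice_id = c("P09", "P09", "P01"),
    code = "Cd001", value = NA_real_, value_unit = NA_character_
  )
  out <- validate_and_annotate(ev, regs1)
  expect_equal(out$n_excluded, 1L)  # person 2 unregistered mid-2020
  expect_equal(out$events$canonical_practice_id, c("P01", "P02"))
  # recorded practice is kept for the GP-to-GP comparison
  expect_equal(out$events$practice_id, c("P09", "P09"))
})

test_that("exact de-duplication keeps the smallest source row per identical group", {
  base <- make_events(
    source_row_id = 1:5, alf = 1L, event_dt = as.Date("2020-01-01"),
    practice_id = "P01", code = c("A", "A", "A", "B", "B"),
    value = c(1, 1, 1, NA, NA), value_unit = c("u", "u", "u", NA, NA)
  )
  out <- dedup_exact(base)
  expect_equal(out$source_row_id, c(1L, 4L))
  # all-distinct batch is untouched and agrees with the oracle
  for (seed in 1:5) {
    b <- random_batch(seed, n = 200)
    expect_same_events(dedup_exact(b), oracle_dedup_exact(b))
  }
})

test_that("GP-to-GP twins collapse onto the registration-backed practice", {
  twin <- make_events(
    source_row_id = 1:2, alf = 1L, event_dt = as.Date("2020-02-01"),
    practice_id = c("P02", "P07"), code = "A", value = NA_real_,
    value_unit = NA_character_, canonical_practice_id = "P02"
  )
  out <- dedup_gp2gp(twin)
  expect_equal(nrow(out), 1L)
  expect_equal(out$source_row_id, 1L)
  expect_equal(out$practice_id, "P02")

  # neither twin matches: deterministic smallest-practice pick, in both orders
  twin2 <- dplyr::mutate(twin, canonical_practice_id = "P01")
  out2a <- dedup_gp2gp(twin2)
  out2b <- dedup_gp2gp(twin2[2:1, ])
  expect_equal(out2a$source_row_id, 1L)  # P02 < P07
  expect_equal(out2b$source_row_id, 1L)
  expect_equal(out2a$practice_id, "P01")

  # rows differing in code are not a GP-to-GP group
  two <- dplyr::mutate(twin, code = c("A", "B"))
  expect_equal(nrow(dedup_gp2gp(two)), 2L)
})

test_that("normalisation is lossless and keys are dense", {
  lk <- build_lookup(tibble::tibble(source = "r", code_type = "READ_V2",
                                    code = c("A1111", "B2222"),
                                    description = c("a", "b")))
  ev <- make_events(
    source_row_id = 1:3, alf = c(1L, 1L, 2L),
    event_dt = as.Date(c("2020-01-01", "2020-01-01", "2020-01-02")),
    practice_id = c("P01", "P01", "P02"),
    code = c("A1111", "B2222", "A1111"),
    value = c(1, NA, NA), value_unit = c("u", NA, NA)
  )
  norm <- normalize_rrda(ev, lk)
  expect_equal(nrow(norm$person_day), 2L)          # k events -> 1 person-day
  expect_equal(nrow(norm$clinical_events), 3L)
  expect_equal(norm$person_day$event_id, 1:2)
  back <- denormalize_rrda(norm$person_day, norm$clinical_events, norm$lookup)
  cols <- c("alf", "event_dt", "practice_id", "code", "value", "value_unit")
  expect_equal(
    dplyr::arrange(back[cols], alf, event_dt, code),
    dplyr::arrange(dplyr::mutate(ev[cols], code = standardize_code(code)),
                   alf, event_dt, code)
  )
  # empty input
  norm0 <- normalize_rrda(ev[0, ], lk)
  expect_equal(nrow(norm0$person_day), 0L)
  expect_equal(nrow(norm0$clinical_events), 0L)
})

test_that("curation drops nothing on clean data, is idempotent and monotone", {
  cfg <- tiny_config(n_persons = 80)
  cohort <- generate_cohort(cfg)
  uni <- generate_code_universe(cfg)
  gen <- generate_events(cohort, uni, cfg)
  lk <- build_lookup(uni$sources)
  rrda1 <- build_rrda(gen$events, cohort$registrations, lk)
  expect_true(all(rrda1$consort$n_dropped == 0))
  expect_true(all(rrda1$retention$record_retention_pct == 100))
  expect_true(all(rrda1$retention$person_retention_pct == 100))
  # monotone record counts
  expect_true(all(diff(rrda1$consort$n_kept) <= 0))
  # fixed point: curating the curated output changes nothing
  back <- denormalize_rrda(rrda1$person_day, rrda1$clinical_events, rrda1$lookup)
  rrda2 <- build_rrda(back, cohort$registrations, lk)
  expect_true(all(rrda2$consort$n_dropped == 0))
  expect_equal(nrow(rrda2$clinical_events), nrow(rrda1$clinical_events))
  expect_equal(nrow(rrda2$person_day), nrow(rrda1$person_day))
})

test_that("yearly retention accounts for injected losses exactly", {
  cfg <- tiny_config(
    n_persons = 120,
    corruption = list(missing_field_frac = 0.05, exact_dup_frac = 0,
                      gp2gp_dup_frac = 0, out_of_registration_frac = 0,
                      invalid_code_frac = 0, unknown_code_frac = 0)
  )
  cohort <- generate_cohort(cfg)
  uni <- generate_code_universe(cfg)
  gen <- generate_events(cohort, uni, cfg)
  cor <- corrupt_events(gen$events, cohort, cfg)
  rrda <- build_rrda(cor$events, cohort$registrations, build_lookup(uni$sources))
  ret <- rrda$retention
  # per-year: raw - retained equals the ledgered losses dated in that year
  lost <- cor$events %>%
    dplyr::semi_join(cor$ledger, by = "source_row_id") %>%
    dplyr::mutate(year = dplyr::if_else(is.na(event_dt), "undated",
                                        format(event_dt, "%Y"))) %>%
    dplyr::count(year)
  for (i in seq_len(nrow(lost))) {
    row <- ret[ret$year == lost$year[i], ]
    expect_equal(row$n_raw - row$n_retained, lost$n[i])
  }
})
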