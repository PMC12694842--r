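rule_row <- function(rule_id, match, pattern, provider = "PRIMARY_CARE",
                     access_mode = "CLINICAL_UNMATCHED",
                     interaction_type = "CLINICAL_ACTIVITY", detail = "DIAGNOSIS") {
  tibble::tibble(rule_id = rule_id, match = match, pattern = pattern,
                 provider = provider, access_mode = access_mode,
                 interaction_type = interaction_type, detail = detail)
}

entry_row <- function(code_key, code_type = "READ_V2", description = "desc") {
  tibble::tibble(code_key = code_key, code_type = code_type, description = description)
}

assign_row <- function(provider = "PRIMARY_CARE", access_mode = "CLINICAL_UNMATCHED",
                       interaction_type = "CLINICAL_ACTIVITY", detail = "DIAGNOSIS",
                       n = 1) {
  tibble::tibble(provider = rep(provider, n), access_mode = rep(access_mode, n),
                 interaction_type = rep(interaction_type, n), detail = rep(detail, n))
}

test_that("rule compilation validates ids, match kinds and layer consistency", {
  empty <- compile_rules(tibble::tibble())
  expect_equal(nrow(empty), 0)
  expect_error(compile_rules(dplyr::bind_rows(rule_row("a", "EXACT_CODE", "X"),
                                              rule_row("a", "KEYWORD", "y"))),
               "duplicate")
  # a prescription detail outside CLINICAL_UNMATCHED access is inconsistent
  expect_error(compile_rules(rule_row("bad", "EXACT_CODE", "X", access_mode = "REMOTE",
                                      interaction_type = "PHONE_CALL",
                                      detail = "DRUG_PRESCRIPTION")),
               class = "rrda_rules_error")
  # non-primary providers may carry no lower layers
  expect_error(compile_rules(rule_row("bad2", "EXACT_CODE", "X",
                                      provider = "SECONDARY_CARE")),
               class = "rrda_rules_error")
  ok <- compile_rules(rule_row("ok", "EXACT_CODE", "X", provider = "SECONDARY_CARE",
                               access_mode = "UNASSIGNED",
                               interaction_type = "UNASSIGNED", detail = "NONE"))
  expect_equal(nrow(ok), 1)
})

test_that("matching precedence is exact, then longest prefix, then keyword", {
  rules <- compile_rules(dplyr::bind_rows(
    rule_row("kw", "KEYWORD", "asthma", detail = "HISTORY_SYMPTOM"),
    rule_row("p1", "CODE_PREFIX", "H", detail = "OBSERVATION",
             access_mode = "FACE_TO_FACE", interaction_type = "IN_PRACTICE_VISIT"),
    rule_row("p3", "CODE_PREFIX", "H33", detail = "DIAGNOSIS"),
    rule_row("ex", "EXACT_CODE", "H33..", detail = "REFERRAL")
  ))
  entries <- entry_row(c("H33..", "H3310", "H9999", "Z1111"),
                       description = c("x", "x", "asthma care", "asthma care"))
  out <- classify_code(rules, entries)
  expect_equal(out$rule_id, c("ex", "p3", "p1", "kw"))
  # enumeration oracle: every rule fires on its own code set
  expect_equal(out$detail, c("REFERRAL", "DIAGNOSIS", "OBSERVATION", "HISTORY_SYMPTOM"))
})

test_that("SNOMED and unmatched codes stay unassigned", {
  rules <- compile_rules(rule_row("p", "CODE_PREFIX", "H"))
  out <- classify_code(rules, dplyr::bind_rows(
    entry_row("H3300"),
    entry_row("12345678901", code_type = "SNOMED_CT", description = "H code words"),
    entry_row("Z9999")
  ))
  expect_equal(out$provider, c("PRIMARY_CARE", "UNASSIGNED", "UNASSIGNED"))
  expect_equal(out$detail, c("DIAGNOSIS", "NONE", "NONE"))
  # prescription rule fixture
  rx <- compile_rules(rule_row("rx", "CODE_PREFIX", "Rx", detail = "DRUG_PRESCRIPTION"))
  out_rx <- classify_code(rx, entry_row("Rx001"))
  expect_equal(unlist(out_rx[, c("provider", "access_mode", "interaction_type", "detail")],
                      use.names = FALSE),
               c("PRIMARY_CARE", "CLINICAL_UNMATCHED", "CLINICAL_ACTIVITY",
                 "DRUG_PRESCRIPTION"))
})

test_that("person-day categories follow the activity definitions", {
  rx <- assign_row(detail = "DRUG_PRESCRIPTION")
  diag <- assign_row(detail = "DIAGNOSIS")
  phone <- assign_row(access_mode = "REMOTE", interaction_type = "PHONE_CALL",
                      detail = "NONE")
  imm <- assign_row(access_mode = "FACE_TO_FACE", interaction_type = "IMMUNISATION",
                    detail = "NONE")
  pharm <- assign_row(access_mode = "FACE_TO_FACE", interaction_type = "PHARMACY",
                      detail = "NONE")
  cert <- assign_row(access_mode = "ADMIN", interaction_type = "PATIENT_ADMIN",
                     detail = "CERTIFICATE")
  monit <- assign_row(detail = "CHRONIC_MONITORING")
  adminreg <- assign_row(access_mode = "ADMIN", interaction_type = "PATIENT_ADMIN",
                         detail = "SOCIODEMO_REGISTRATION")
  failed <- assign_row(access_mode = "ADMIN", interaction_type = "PATIENT_ADMIN",
                       detail = "FAILED_ENCOUNTER")

  expect_equal(classify_person_day(rbind(rx, rx)), "PRESCRIPTION_ONLY")
  expect_equal(classify_person_day(diag), "CONSULTATION")
  expect_true("CONSULTATION" %in% classify_person_day(rbind(rx, phone)))
  expect_false("PRESCRIPTION_ONLY" %in% classify_person_day(rbind(rx, phone)))
  expect_false("VACCINATION" %in% classify_person_day(rbind(imm, pharm)))
  expect_equal(classify_person_day(imm), "VACCINATION")
  expect_equal(classify_person_day(rbind(cert, monit)),
               c("CERTIFICATE", "CONSULTATION", "REVIEW_MONITORING"))
  expect_equal(classify_person_day(adminreg), "ADMIN_ONLY")
  # a certificate-only day is admin, certificate and consultation at once
  expect_equal(classify_person_day(cert),
               c("ADMIN_ONLY", "CERTIFICATE", "CONSULTATION"))
  # failed encounters are exclusive
  expect_equal(classify_person_day(rbind(failed, failed)), "FAILED_ENCOUNTER")
  # without any primary-care event the set is empty
  sec <- assign_row(provider = "SECONDARY_CARE", access_mode = "UNASSIGNED",
                    interaction_type = "UNASSIGNED", detail = "NONE")
  expect_equal(classify_person_day(sec), character(0))
  expect_error(classify_person_day(rx[0, ]), class = "rrda_contract_error")
})

test_that("category sets are order-invariant and respect exclusivity invariants", {
  cfg <- tiny_config(n_persons = 120)
  cohort <- generate_cohort(cfg)
  uni <- generate_code_universe(cfg)
  gen <- generate_events(cohort, uni, cfg)
  lk <- build_lookup(uni$sources)
  rrda <- build_rrda(gen$events, cohort$registrations, lk)
  rules <- compile_rules(uni$rules)
  act <- categorize_all(rrda$person_day, rrda$clinical_events, rrda$lookup, rules)
  sets <- strsplit(act$categories, "|", fixed = TRUE)
  has <- function(cat) vapply(sets, function(s) cat %in% s, logical(1))
  expect_false(any(has("PRESCRIPTION_ONLY") & has("CONSULTATION")))
  expect_false(any(has("FAILED_ENCOUNTER") & lengths(sets) > 1))
  # shuffling the clinical-event rows changes nothing
  set.seed(9)
  shuffled <- rrda$clinical_events[sample(nrow(rrda$clinical_events)), ]
  act2 <- categorize_all(rrda$person_day, shuffled, rrda$lookup, rules)
  expect_equal(dplyr::arrange(act2, event_id), dplyr::arrange(act, event_id))
})

test_that("categorize_all handles degenerate inputs", {
  rules <- compile_rules(rule_row("rx", "CODE_PREFIX", "Rx", detail = "DRUG_PRESCRIPTION"))
  lk <- build_lookup(tibble::tibble(source = "r", code_type = "READ_V2",
                                    code = "Rx001", description = "rx"))
  pd <- tibble::tibble(event_id = 1L, alf = 1L, event_dt = as.Date("2020-01-01"),
                       practice_id = "P01")
  ce <- tibble::tibble(event_id = 1L, code_id = lk$code_id[1],
                       value = NA_real_, value_unit = NA_character_)
  expect_equal(categorize_all(pd, ce, lk, rules)$categories, "PRESCRIPTION_ONLY")
  expect_equal(nrow(categorize_all(pd[0, ], ce[0, ], lk, rules)), 0)
  bad <- dplyr::mutate(ce, event_id = 99L)
  expect_error(categorize_all(pd, bad, lk, rules), class = "rrda_integrity_error")
})
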