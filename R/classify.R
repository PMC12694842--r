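#' Four-layer classification vocabulary
#'
#' Levels of the hierarchical patient-practice interaction classification:
#' care provider, access mode, interaction type and interaction detail.
#' `layer_consistency()` encodes which combinations the hierarchy admits.
#'
#' @name four_layer
NULL

providers <- function() c("PRIMARY_CARE", "SECONDARY_CARE", "COMMUNITY_CARE", "UNASSIGNED")

access_modes <- function() c("FACE_TO_FACE", "REMOTE", "CLINICAL_UNMATCHED", "ADMIN", "UNASSIGNED")

interaction_types <- function() {
  c("IN_PRACTICE_VISIT", "IMMUNISATION", "DENTAL", "PHARMACY", "HOME_VISIT",
    "PHONE_CALL", "TEXT_EMAIL_LETTER", "OTHER_REMOTE", "CLINICAL_ACTIVITY",
    "PATIENT_ADMIN", "OTHER_ADMIN", "UNASSIGNED")
}

interaction_details <- function() {
  c("EXAMINATION_SIGN", "OBSERVATION", "SCREENING_ASSESSMENT", "LAB_PROCEDURE",
    "THERAPEUTIC_PROCEDURE", "OTHER_F2F", "DRUG_PRESCRIPTION",
    "LAB_REQUEST_RESULT", "CHRONIC_MONITORING", "PATIENT_MONITORING",
    "MATERNAL_CHILD", "DIAGNOSIS", "HISTORY_SYMPTOM", "REFERRAL",
    "COUNSELLING_EDUCATION", "REVIEW_PREVENTION", "OTHER_CLINICAL",
    "SOCIODEMO_REGISTRATION", "CERTIFICATE", "FAILED_ENCOUNTER",
    "OTHER_PATIENT_ADMIN", "NONE")
}

#' Activity categories for person-day events
#' @export
activity_categories <- function() {
  c("ADMIN_ONLY", "CERTIFICATE", "CONSULTATION", "FAILED_ENCOUNTER",
    "PRESCRIPTION_ONLY", "REVIEW_MONITORING", "SCREENING_ASSESSMENT",
    "VACCINATION")
}

# types admissible under each access mode
.TYPES_BY_MODE <- list(
  FACE_TO_FACE = c("IN_PRACTICE_VISIT", "IMMUNISATION", "DENTAL", "PHARMACY", "HOME_VISIT"),
  REMOTE = c("PHONE_CALL", "TEXT_EMAIL_LETTER", "OTHER_REMOTE"),
  CLINICAL_UNMATCHED = "CLINICAL_ACTIVITY",
  ADMIN = c("PATIENT_ADMIN", "OTHER_ADMIN"),
  UNASSIGNED = "UNASSIGNED"
)

# details admissible under each interaction type; types absent here admit
# only NONE
.DETAILS_BY_TYPE <- list(
  IN_PRACTICE_VISIT = c("EXAMINATION_SIGN", "OBSERVATION", "SCREENING_ASSESSMENT",
                        "LAB_PROCEDURE", "THERAPEUTIC_PROCEDURE", "OTHER_F2F"),
  CLINICAL_ACTIVITY = c("DRUG_PRESCRIPTION", "LAB_REQUEST_RESULT", "CHRONIC_MONITORING",
                        "PATIENT_MONITORING", "MATERNAL_CHILD", "DIAGNOSIS",
                        "HISTORY_SYMPTOM", "REFERRAL", "COUNSELLING_EDUCATION",
                        "REVIEW_PREVENTION", "OTHER_CLINICAL"),
  PATIENT_ADMIN = c("SOCIODEMO_REGISTRATION", "CERTIFICATE", "FAILED_ENCOUNTER",
                    "OTHER_PATIENT_ADMIN")
)

#' Check four-layer assignments for hierarchy consistency
#'
#' @param assignment data frame with columns `provider`, `access_mode`,
#'   `interaction_type`, `detail`
#' @return logical vector, TRUE where the assignment is admissible
#' @export
layer_consistency <- function(assignment) {
  with(assignment, {
    ok <- provider %in% providers() & access_mode %in% access_modes() &
      interaction_type %in% interaction_types() & detail %in% interaction_details()
    non_primary <- provider != "PRIMARY_CARE"
    ok <- ok & (!non_primary | (access_mode == "UNASSIGNED" &
                                  interaction_type == "UNASSIGNED" & detail == "NONE"))
    mode_ok <- mapply(function(m, t) t %in% .TYPES_BY_MODE[[m]], access_mode, interaction_type)
    det_ok <- mapply(function(t, d) {
      allowed <- .DETAILS_BY_TYPE[[t]]
      if (is.null(allowed)) d == "NONE" else d %in% c(allowed, "NONE")
    }, interaction_type, detail)
    ok & (non_primary | (mode_ok & det_ok))
  })
}

#' Compile an ordered classification rule set
#'
#' Rules map clinical codes to four-layer assignments. Matching precedence
#' is: exact code match, then longest matching code prefix, then keyword
#' match against the code description in file order. Every rule's
#' assignment must be hierarchy-consistent, and rule ids must be unique.
#'
#' @param rules a data frame with columns `rule_id`, `match`
#'   (`EXACT_CODE`/`CODE_PREFIX`/`KEYWORD`), `pattern`, `provider`,
#'   `access_mode`, `interaction_type`, `detail` — or the path of a YAML
#'   file holding an ordered list of such records
#' @return a `rrda_rules` tibble, ordered by file position
#' @export
compile_rules <- function(rules) {
  if (is.character(rules) && length(rules) == 1) {
    raw <- yaml::read_yaml(rules)
    rules <- purrr::map_dfr(raw, tibble::as_tibble)
  }
  rules <- tibble::as_tibble(rules)
  if (nrow(rules) == 0) {
    out <- tibble::tibble(rule_id = character(), match = character(),
                          pattern = character(), provider = character(),
                          access_mode = character(), interaction_type = character(),
                          detail = character(), .order = integer())
    class(out) <- c("rrda_rules", class(out))
    return(out)
  }
  if (anyDuplicated(rules$rule_id)) {
    abort(paste("duplicate rule_id:",
                paste(unique(rules$rule_id[duplicated(rules$rule_id)]), collapse = ", ")),
          class = "rrda_rules_error")
  }
  bad_match <- setdiff(unique(rules$match), c("EXACT_CODE", "CODE_PREFIX", "KEYWORD"))
  if (length(bad_match)) {
    abort(paste("unknown match kind:", paste(bad_match, collapse = ", ")),
          class = "rrda_rules_error")
  }
  if (any(!nzchar(trimws(rules$pattern)))) {
    abort("rule patterns must be non-empty", class = "rrda_rules_error")
  }
  bad <- !layer_consistency(rules)
  if (any(bad)) {
    abort(paste("layer-inconsistent assignment in rule(s):",
                paste(rules$rule_id[bad], collapse = ", ")),
          class = "rrda_rules_error")
  }
  out <- dplyr::mutate(rules, .order = dplyr::row_number())
  class(out) <- c("rrda_rules", class(out))
  out
}

.UNASSIGNED <- tibble::tibble(
  provider = "UNASSIGNED", access_mode = "UNASSIGNED",
  interaction_type = "UNASSIGNED", detail = "NONE"
)

#' Classify look-up entries with the rules engine
#'
#' SNOMED-CT entries are excluded from classification and receive the
#' all-unassigned assignment; so does any entry matched by no rule. For
#' other entries the highest-precedence matching rule decides: exact code
#' match beats prefix match (longest prefix first), which beats keyword
#' match (case-insensitive, against the description, in rule order).
#'
#' @param rules compiled rules from [compile_rules()]
#' @param entries look-up rows (`code_key`, `code_type`, `description`)
#' @return tibble of `entries` with `provider`, `access_mode`,
#'   `interaction_type`, `detail` and the matched `rule_id` (NA when
#'   unmatched) appended
#' @export
classify_code <- function(rules, entries) {
  entries <- tibble::as_tibble(entries)
  n <- nrow(entries)
  assign <- .UNASSIGNED[rep(1L, max(n, 1L)), ][seq_len(n), ]
  assign$rule_id <- NA_character_
  if (n == 0) return(dplyr::bind_cols(entries, assign))

  classifiable <- !(entries$code_type %in% c("SNOMED_CT"))
  key <- dplyr::coalesce(entries$code_key, "")
  # score: lower is stronger. exact = 0; prefix = 1000 - pattern length
  # (longer prefix first, then file order); keyword = 2000 + file order.
  best_score <- rep(Inf, n)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    hit <- switch(r$match,
      EXACT_CODE = key == r$pattern,
      CODE_PREFIX = startsWith(key, r$pattern),
      KEYWORD = stringr::str_detect(
        tolower(dplyr::coalesce(entries$description, "")),
        stringr::fixed(tolower(r$pattern))
      )
    )
    score <- switch(r$match,
      EXACT_CODE = 0 + i * 1e-6,
      CODE_PREFIX = 1000 - nchar(r$pattern) + i * 1e-6,
      KEYWORD = 2000 + i * 1e-6
    )
    take <- classifiable & hit & score < best_score
    if (any(take)) {
      best_score[take] <- score
      assign$provider[take] <- r$provider
      assign$access_mode[take] <- r$access_mode
      assign$interaction_type[take] <- r$interaction_type
      assign$detail[take] <- r$detail
      assign$rule_id[take] <- r$rule_id
    }
  }
  dplyr::bind_cols(entries, assign)
}

.CONSULT_DETAILS <- c(
  "EXAMINATION_SIGN", "HISTORY_SYMPTOM", "OBSERVATION", "DIAGNOSIS",
  "LAB_PROCEDURE", "LAB_REQUEST_RESULT", "SCREENING_ASSESSMENT",
  "CHRONIC_MONITORING", "PATIENT_MONITORING", "REVIEW_PREVENTION",
  "THERAPEUTIC_PROCEDURE", "CERTIFICATE", "MATERNAL_CHILD",
  "COUNSELLING_EDUCATION", "REFERRAL"
)

# Vectorised day-level category logic over per-day aggregates. `flags` has
# one row per person-day with the logical aggregates listed below.
day_categories <- function(flags) {
  with(flags, {
    consult <- any_consult_detail |
      (any_prescription & (any_remote | any_visit_type))
    tibble::tibble(
      ADMIN_ONLY = all_admin & !all_failed,
      CERTIFICATE = any_certificate,
      CONSULTATION = consult,
      FAILED_ENCOUNTER = all_failed,
      PRESCRIPTION_ONLY = all_prescription,
      REVIEW_MONITORING = any_review,
      SCREENING_ASSESSMENT = any_screening,
      VACCINATION = any_immunisation & !any_pharmacy_dental & !any_failed
    ) %>%
      dplyr::mutate(dplyr::across(dplyr::everything(), ~ .x & flags$any_primary))
  })
}

day_flags <- function(assignments) {
  dplyr::summarise(
    assignments,
    any_primary = any(.data$provider == "PRIMARY_CARE"),
    any_consult_detail = any(.data$detail %in% .CONSULT_DETAILS),
    any_prescription = any(.data$detail == "DRUG_PRESCRIPTION"),
    all_prescription = all(.data$detail == "DRUG_PRESCRIPTION"),
    any_remote = any(.data$access_mode == "REMOTE"),
    any_visit_type = any(.data$interaction_type %in% c("IN_PRACTICE_VISIT", "HOME_VISIT")),
    any_immunisation = any(.data$interaction_type == "IMMUNISATION"),
    any_pharmacy_dental = any(.data$interaction_type %in% c("PHARMACY", "DENTAL")),
    any_failed = any(.data$detail == "FAILED_ENCOUNTER"),
    all_failed = all(.data$detail == "FAILED_ENCOUNTER"),
    all_admin = all(.data$access_mode == "ADMIN"),
    any_certificate = any(.data$detail == "CERTIFICATE"),
    any_review = any(.data$detail %in% c("CHRONIC_MONITORING", "PATIENT_MONITORING",
                                         "REVIEW_PREVENTION")),
    any_screening = any(.data$detail == "SCREENING_ASSESSMENT"),
    .groups = "drop"
  )
}

#' Categorise one person-day of classified events
#'
#' Applies the eight activity-type definitions to the four-layer
#' assignments of a single person-day. Categories are only evaluated when
#' the day includes at least one primary-care event; otherwise the set is
#' empty. The result is a set — categories are not mutually exclusive —
#' except that a day consisting solely of failed encounters belongs to
#' `FAILED_ENCOUNTER` alone (such a day is not counted as
#' administrative-only).
#'
#' @param assignments data frame of the day's events with columns
#'   `provider`, `access_mode`, `interaction_type`, `detail`
#' @return sorted character vector of activity categories (possibly empty)
#' @export
classify_person_day <- function(assignments) {
  assignments <- tibble::as_tibble(assignments)
  if (nrow(assignments) == 0) {
    abort("classify_person_day() requires at least one event", class = "rrda_contract_error")
  }
  cats <- day_categories(day_flags(assignments))
  sort(names(cats)[unlist(cats[1, ])])
}

#' Categorise every person-day in an RRDA
#'
#' Joins the clinical-event table to the look-up, classifies each distinct
#' code once with the rules engine, and applies the activity-type
#' definitions to every person-day. Person-days with no primary-care event
#' are emitted with an empty category set.
#'
#' @param person_day,clinical_events,lookup the RRDA tables
#' @param rules compiled rules from [compile_rules()]
#' @return tibble with `event_id` and `categories` (pipe-separated set,
#'   `""` when empty)
#' @export
categorize_all <- function(person_day, clinical_events, lookup, rules) {
  if (nrow(person_day) == 0) {
    return(tibble::tibble(event_id = integer(), categories = character()))
  }
  if (!all(clinical_events$event_id %in% person_day$event_id) ||
      !all(clinical_events$code_id %in% lookup$code_id)) {
    abort("dangling foreign key between RRDA tables", class = "rrda_integrity_error")
  }
  code_assign <- classify_code(rules, lookup[lookup$code_id %in% clinical_events$code_id, ])
  flags <- clinical_events %>%
    dplyr::left_join(
      dplyr::select(code_assign, "code_id", "provider", "access_mode",
                    "interaction_type", "detail"),
      by = "code_id"
    ) %>%
    dplyr::group_by(.data$event_id) %>%
    day_flags()
  cats <- day_categories(flags)
  cat_names <- names(cats)
  m <- as.matrix(cats)
  categories <- apply(m, 1L, function(row) paste(sort(cat_names[row]), collapse = "|"))
  person_day %>%
    dplyr::select("event_id") %>%
    dplyr::left_join(tibble::tibble(event_id = flags$event_id, categories = categories),
                     by = "event_id") %>%
    dplyr::mutate(categories = dplyr::coalesce(.data$categories, ""))
}
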