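# Synthetic code universe.
#
# Codes are 5 characters: a 2-character pool prefix plus 3 digits. Each pool
# carries one four-layer assignment, so the classification truth of any
# generated code is known by construction. The pools cover every activity
# category, a remote-contact pool (phone calls, used to build
# remote-prescription consultation days), and a secondary-care pool that the
# person-day categoriser must ignore.
.CODE_POOLS <- tibble::tibble(
  prefix = c("Cd", "Ch", "Cl", "Fx", "Rx", "Vc", "Ad", "Ao", "Ct",
             "Rm", "Rp", "Sc", "Fe", "Ph", "Vi", "Em", "Av", "Eu", "Xs"),
  provider = c(rep("PRIMARY_CARE", 18), "SECONDARY_CARE"),
  access_mode = c("CLINICAL_UNMATCHED", "CLINICAL_UNMATCHED", "CLINICAL_UNMATCHED",
                  "FACE_TO_FACE", "CLINICAL_UNMATCHED", "FACE_TO_FACE",
                  "ADMIN", "ADMIN", "ADMIN",
                  "CLINICAL_UNMATCHED", "CLINICAL_UNMATCHED", "FACE_TO_FACE",
                  "ADMIN", "REMOTE", "ADMIN", "CLINICAL_UNMATCHED",
                  "CLINICAL_UNMATCHED", "CLINICAL_UNMATCHED", "UNASSIGNED"),
  interaction_type = c("CLINICAL_ACTIVITY", "CLINICAL_ACTIVITY", "CLINICAL_ACTIVITY",
                       "IN_PRACTICE_VISIT", "CLINICAL_ACTIVITY", "IMMUNISATION",
                       "PATIENT_ADMIN", "OTHER_ADMIN", "PATIENT_ADMIN",
                       "CLINICAL_ACTIVITY", "CLINICAL_ACTIVITY", "IN_PRACTICE_VISIT",
                       "PATIENT_ADMIN", "PHONE_CALL", "PATIENT_ADMIN",
                       "CLINICAL_ACTIVITY", "CLINICAL_ACTIVITY", "CLINICAL_ACTIVITY",
                       "UNASSIGNED"),
  detail = c("DIAGNOSIS", "HISTORY_SYMPTOM", "LAB_REQUEST_RESULT",
             "EXAMINATION_SIGN", "DRUG_PRESCRIPTION", "NONE",
             "SOCIODEMO_REGISTRATION", "NONE", "CERTIFICATE",
             "CHRONIC_MONITORING", "PATIENT_MONITORING", "SCREENING_ASSESSMENT",
             "FAILED_ENCOUNTER", "NONE", "OTHER_PATIENT_ADMIN",
             "DRUG_PRESCRIPTION", "REVIEW_PREVENTION", "COUNSELLING_EDUCATION",
             "NONE"),
  source = c(rep("read_v2", 14), "vision_local", "emis_local",
             "read_vision_additional", "emis_ukb", "read_v2"),
  description_stem = c(
    "diagnosis of condition", "history or symptom record", "laboratory result",
    "physical examination", "drug prescription issued", "vaccination given",
    "patient registration detail", "practice administration note",
    "fitness certificate issued", "chronic disease monitoring",
    "patient monitoring record", "screening assessment performed",
    "did not attend appointment", "telephone consultation",
    "supplier administrative marker", "supplier prescription marker",
    "structured review of patient", "lifestyle counselling session",
    "secondary care letter")
)

.SOURCE_TYPES <- c(
  read_v2 = "READ_V2", snomed_ct = "SNOMED_CT", vision_local = "VISION_LOCAL",
  emis_local = "EMIS_LOCAL", read_vision_additional = "READ_VISION_ADDITIONAL",
  emis_ukb = "EMIS_UKB"
)

# Codes each activity category's event bundles draw from, with draw weights.
.CATEGORY_POOLS <- list(
  CONSULTATION = c(Cd = 0.35, Ch = 0.25, Cl = 0.2, Fx = 0.15, Eu = 0.05),
  PRESCRIPTION_ONLY = c(Rx = 0.9, Em = 0.1),
  VACCINATION = c(Vc = 1),
  ADMIN_ONLY = c(Ad = 0.5, Ao = 0.3, Vi = 0.2),
  CERTIFICATE = c(Ct = 1),
  REVIEW_MONITORING = c(Rm = 0.5, Rp = 0.4, Av = 0.1),
  SCREENING_ASSESSMENT = c(Sc = 1),
  FAILED_ENCOUNTER = c(Fe = 1)
)

#' Generate the synthetic clinical-code universe
#'
#' Emits six code source lists mirroring the real code-type landscape
#' (official Read-like, SNOMED-like, supplier-local Vision and EMIS,
#' additional Read/Vision, additional EMIS), a designated overlap set
#' present in both the Read-like and additional-EMIS lists, the matching
#' classification rules (prefix rules for most pools, keyword rules for the
#' additional sources, one exact-code rule to exercise precedence), the
#' ground-truth four-layer assignment of every non-SNOMED code, and
#' reserved pools of malformed and of well-formed-but-undocumented codes
#' used by the corruption injector.
#'
#' @param config a [sim_config()]
#' @param codes_per_pool codes generated per pool prefix
#' @return list with `sources`, `rules`, `truth`, `overlap`,
#'   `invalid_pool`, `unknown_pool`
#' @export
generate_code_universe <- function(config, codes_per_pool = 8) {
  set.seed(stage_seed(config$seed, "codes"))
  pools <- .CODE_POOLS
  codes <- pools %>%
    tidyr::uncount(codes_per_pool, .id = ".i") %>%
    dplyr::mutate(
      code = sprintf("%s%03d", .data$prefix, .data$.i),
      description = paste(.data$description_stem, .data$.i)
    )
  sources <- codes %>%
    dplyr::transmute(
      source = .data$source,
      code_type = .SOURCE_TYPES[.data$source],
      code = .data$code,
      description = .data$description,
      category = NA_character_
    )
  # SNOMED-like numeric identifiers (excluded from classification)
  snomed <- tibble::tibble(
    source = "snomed_ct", code_type = "SNOMED_CT",
    code = sprintf("%d000%04d", sample(10:99, 20, replace = TRUE), seq_len(20)),
    description = paste("snomed concept", seq_len(20)),
    category = NA_character_
  )
  # overlap set: first codes of the Cd pool also appear in the EMIS UK-Biobank
  # list; the look-up must retain them as Read codes
  overlap <- codes$code[codes$prefix == "Cd"][1:3]
  overlap_rows <- tibble::tibble(
    source = "emis_ukb", code_type = "EMIS_UKB", code = overlap,
    description = paste("duplicate emis description", seq_along(overlap)),
    category = NA_character_
  )
  sources <- dplyr::bind_rows(sources, snomed, overlap_rows) %>%
    dplyr::arrange(match(.data$source, names(.SOURCE_TYPES)))

  truth <- codes %>%
    dplyr::transmute(code_key = .data$code, .data$provider, .data$access_mode,
                     .data$interaction_type, .data$detail)

  # prefix rules for all pools except the additional sources, which are
  # matched through keywords in their descriptions; one exact rule overrides
  # (consistently) the first examination code
  prefix_pools <- pools %>% dplyr::filter(!.data$prefix %in% c("Av", "Eu"))
  rules <- dplyr::bind_rows(
    tibble::tibble(
      rule_id = "exact_fx001", match = "EXACT_CODE", pattern = "Fx001",
      provider = "PRIMARY_CARE", access_mode = "FACE_TO_FACE",
      interaction_type = "IN_PRACTICE_VISIT", detail = "EXAMINATION_SIGN"
    ),
    prefix_pools %>%
      dplyr::transmute(
        rule_id = paste0("prefix_", tolower(.data$prefix)), match = "CODE_PREFIX",
        pattern = .data$prefix, .data$provider, .data$access_mode,
        .data$interaction_type, .data$detail
      ),
    tibble::tibble(
      rule_id = c("kw_review", "kw_counselling"), match = "KEYWORD",
      pattern = c("structured review", "lifestyle counselling"),
      provider = "PRIMARY_CARE", access_mode = "CLINICAL_UNMATCHED",
      interaction_type = "CLINICAL_ACTIVITY",
      detail = c("REVIEW_PREVENTION", "COUNSELLING_EDUCATION")
    )
  )

  list(
    sources = sources,
    rules = rules,
    truth = truth,
    overlap = overlap,
    invalid_pool = c("", "  ", "A?B", "#bad#", "longcode9", "a b.c", ">>>"),
    unknown_pool = sprintf("Q9%03d", 1:40)
  )
}
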