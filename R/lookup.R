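#' Clinical code types, in priority order
#'
#' When the same standardised code key appears in more than one source list,
#' the entry whose type comes first in this vector is retained: official
#' Read V2 first, then official SNOMED-CT, supplier-local Vision and EMIS
#' codes, additional Read/Vision codes, additional EMIS codes, and finally
#' the two supplementary categories for codes that are blank/malformed or
#' structurally valid but undocumented.
#'
#' @export
code_types <- function() {
  c("READ_V2", "SNOMED_CT", "VISION_LOCAL", "EMIS_LOCAL",
    "READ_VISION_ADDITIONAL", "EMIS_UKB", "BLANK_INVALID", "UNKNOWN")
}

code_type_rank <- function(type) {
  match(type, code_types())
}

# Characters accepted by basic format validation. Anything else (or an empty
# string, or more than 7 characters before standardisation) is blank/invalid.
.CODE_ALPHABET_RE <- "^[A-Za-z0-9._%-]+$"

#' Standardise a clinical code to the 5-character level
#'
#' Codes longer than five characters are truncated; shorter codes are
#' right-padded with `"."`. Case is preserved throughout (Read V2 is
#' case-sensitive). The operation is idempotent.
#'
#' @param code character vector of raw codes (non-empty after trimming)
#' @return character vector of 5-character code keys
#' @examples
#' standardize_code(c("H33", "1234567", "A1B2."))
#' @export
standardize_code <- function(code) {
  code <- trimws(as.character(code))
  if (any(!nzchar(code) | is.na(code))) {
    abort("standardize_code() requires non-empty codes; route blank codes to BLANK_INVALID instead",
          class = "rrda_format_error")
  }
  key <- substr(code, 1L, 5L)
  short <- nchar(key) < 5L
  key[short] <- stringr::str_pad(key[short], 5L, side = "right", pad = ".")
  key
}

#' Basic format validation of a raw clinical code
#'
#' @param code character vector
#' @return character vector, `"VALID"` or `"BLANK_INVALID"`
#' @export
validate_code <- function(code) {
  code <- trimws(as.character(code))
  bad <- is.na(code) | !nzchar(code) | nchar(code) > 7L |
    !grepl(.CODE_ALPHABET_RE, code)
  ifelse(bad, "BLANK_INVALID", "VALID")
}

#' Build the comprehensive clinical-code look-up
#'
#' Takes code entries from an ordered set of sources, standardises all
#' non-SNOMED codes to the 5-character key, collapses within-source
#' duplicates (first occurrence wins) and resolves cross-source duplicates
#' by code-type priority (see [code_types()]), not input order. In
#' particular, a code present in both a Read V2 and an EMIS list is retained
#' as a Read code. Retained entries get deterministic integer ids by sorting
#' on (type priority, code key).
#'
#' @param sources data frame with columns `source` (label), `code_type`
#'   (one of [code_types()]), `code`, `description` and optionally
#'   `category`; row order within a source is the source's own order.
#' @return a tibble with columns `code_id`, `code_key`, `code_type`,
#'   `description`, `source`, `category`; dropped duplicates are attached as
#'   the `"collisions"` attribute.
#' @export
build_lookup <- function(sources) {
  if (nrow(sources) == 0) {
    out <- tibble::tibble(
      code_id = integer(), code_key = character(), code_type = character(),
      description = character(), source = character(), category = character()
    )
    attr(out, "collisions") <- out
    return(out)
  }
  bad_type <- setdiff(unique(sources$code_type), code_types())
  if (length(bad_type)) {
    abort_config("code_type", paste("has unknown level(s):", paste(bad_type, collapse = ", ")))
  }
  entries <- sources %>%
    tibble::as_tibble() %>%
    dplyr::mutate(
      category = if ("category" %in% names(sources)) .data$category else NA_character_,
      .input_order = dplyr::row_number()
    )
  # SNOMED identifiers bypass 5-character standardisation and are stored
  # verbatim; everything else is validated then standardised.
  entries <- entries %>%
    dplyr::mutate(
      .valid = validate_code(.data$code),
      code_type = dplyr::if_else(.data$code_type != "SNOMED_CT" & .data$.valid == "BLANK_INVALID",
                                 "BLANK_INVALID", .data$code_type),
      code_key = dplyr::case_when(
        .data$code_type == "SNOMED_CT" ~ trimws(.data$code),
        .data$code_type == "BLANK_INVALID" ~ trimws(.data$code),
        TRUE ~ standardize_code(ifelse(.data$.valid == "VALID", .data$code, "X"))
      ),
      .rank = code_type_rank(.data$code_type)
    )
  deduped <- entries %>%
    dplyr::arrange(.data$.rank, .data$.input_order) %>%
    dplyr::distinct(.data$code_key, .keep_all = TRUE)
  collisions <- entries %>%
    dplyr::anti_join(deduped, by = ".input_order") %>%
    dplyr::select("code_key", "code_type", "description", "source", "category")
  out <- deduped %>%
    dplyr::arrange(.data$.rank, .data$code_key) %>%
    dplyr::mutate(code_id = dplyr::row_number()) %>%
    dplyr::select("code_id", "code_key", "code_type", "description", "source", "category")
  attr(out, "collisions") <- collisions
  out
}

#' Resolve raw codes against the look-up
#'
#' Resolution is total: every raw code maps to a `code_id`. Valid codes found
#' in the look-up map to their entry; structurally valid but unlisted codes
#' get a new `UNKNOWN` entry per distinct key; blank or malformed codes get a
#' shared `BLANK_INVALID` entry per distinct trimmed form.
#'
#' @param lookup a look-up table from [build_lookup()]
#' @param code character vector of raw codes
#' @return a list with `code_id` (integer vector parallel to `code`) and
#'   `lookup` (the look-up, extended with any new supplementary entries)
#' @export
resolve_code <- function(lookup, code) {
  code <- as.character(code)
  valid <- validate_code(code)
  key <- character(length(code))
  key[valid == "VALID"] <- standardize_code(code[valid == "VALID"])
  key[valid == "BLANK_INVALID"] <- trimws(ifelse(is.na(code[valid == "BLANK_INVALID"]), "",
                                                 code[valid == "BLANK_INVALID"]))
  # SNOMED-style numeric identifiers longer than 7 characters would fail the
  # 5-char validation; look them up verbatim first so official SNOMED entries
  # resolve to themselves rather than to BLANK_INVALID.
  verbatim <- trimws(ifelse(is.na(code), "", code))
  is_snomed <- verbatim %in% lookup$code_key[lookup$code_type == "SNOMED_CT"]
  key[is_snomed] <- verbatim[is_snomed]
  valid[is_snomed] <- "VALID"

  found <- match(key, lookup$code_key)
  miss <- is.na(found)
  if (any(miss)) {
    new_entries <- tibble::tibble(
      code_key = key[miss],
      code_type = ifelse(valid[miss] == "VALID", "UNKNOWN", "BLANK_INVALID")
    ) %>%
      dplyr::distinct() %>%
      dplyr::arrange(code_type_rank(.data$code_type), .data$code_key) %>%
      dplyr::mutate(
        code_id = max(lookup$code_id, 0L) + dplyr::row_number(),
        description = dplyr::if_else(.data$code_type == "UNKNOWN",
                                     "unknown code (no known description)",
                                     "blank or invalid code"),
        source = "resolver",
        category = NA_character_
      ) %>%
      dplyr::select("code_id", "code_key", "code_type", "description", "source", "category")
    collisions <- attr(lookup, "collisions")
    lookup <- dplyr::bind_rows(lookup, new_entries)
    attr(lookup, "collisions") <- collisions
    found <- match(key, lookup$code_key)
  }
  list(code_id = lookup$code_id[found], lookup = lookup)
}

#' Yearly usage of clinical code types
#'
#' For each calendar year with events, the share of distinct code keys and of
#' records falling to each code type. Shares are percentages and sum to 100
#' within a year across all types including `READ_V2`.
#'
#' @param events data frame with columns `event_dt` (Date) and `code_id`
#' @param lookup look-up table containing every `code_id` used
#' @return tibble with columns `year`, `code_type`, `n_distinct`, `n_records`,
#'   `distinct_pct`, `record_pct`
#' @export
usage_summary <- function(events, lookup) {
  events %>%
    dplyr::filter(!is.na(.data$event_dt)) %>%
    dplyr::mutate(year = as.integer(format(.data$event_dt, "%Y"))) %>%
    dplyr::left_join(dplyr::select(lookup, "code_id", "code_type", "code_key"),
                     by = "code_id") %>%
    dplyr::group_by(.data$year, .data$code_type) %>%
    dplyr::summarise(
      n_distinct = dplyr::n_distinct(.data$code_key),
      n_records = dplyr::n(),
      .groups = "drop_last"
    ) %>%
    dplyr::mutate(
      distinct_pct = 100 * .data$n_distinct / sum(.data$n_distinct),
      record_pct = 100 * .data$n_records / sum(.data$n_records)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$year, code_type_rank(.data$code_type))
}
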