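#' Welsh residence on a snapshot date
#'
#' A person counts as living in Wales on the snapshot date if a Welsh
#' residence spell (LSOA starting `"W"`) covers the date, and either their
#' Welsh spells cover the preceding three calendar months without a gap
#' (back-to-back spells count as gap-free under the half-open convention)
#' or the person was born within those three months.
#'
#' @param residence residence spell table (`alf`, `lsoa`, `start_dt`,
#'   `end_dt`)
#' @param persons person table carrying `alf` and `birth_dt`
#' @param alf person id vector
#' @param date snapshot Date (scalar, or vector recycled against `alf`)
#' @return logical vector parallel to `alf`
#' @export
resident_on <- function(residence, persons, alf, date) {
  keys <- tibble::tibble(alf = alf, date = as.Date(date)) %>%
    dplyr::mutate(.k = dplyr::row_number(),
                  win_start = .data$date %m-% months(3))
  welsh <- residence %>%
    dplyr::filter(startsWith(.data$lsoa, "W")) %>%
    dplyr::mutate(end_eff = dplyr::coalesce(.data$end_dt, .FAR_FUTURE))
  joined <- keys %>%
    dplyr::inner_join(welsh, by = "alf", relationship = "many-to-many") %>%
    dplyr::filter(.data$end_eff > .data$win_start, .data$start_dt <= .data$date)
  # walk the person's Welsh spells across the window; gap-free iff the merged
  # coverage spans [win_start, date]: the first clipped spell starts at the
  # window start, no spell starts after the running furthest end reached so
  # far, and the furthest end passes the snapshot date
  cov <- joined %>%
    dplyr::arrange(.data$.k, .data$start_dt) %>%
    dplyr::group_by(.data$.k) %>%
    dplyr::mutate(
      s = pmax(.data$start_dt, .data$win_start),
      reach_before = dplyr::lag(cummax(as.numeric(.data$end_eff)),
                                default = as.numeric(.data$win_start[1]))
    ) %>%
    dplyr::summarise(
      covers_date = any(in_spell(.data$date, .data$start_dt, .data$end_dt)),
      gap_free = all(as.numeric(.data$s) <= .data$reach_before) &
        max(.data$end_eff) > .data$date[1],
      .groups = "drop"
    )
  birth <- persons$birth_dt[match(keys$alf, persons$alf)]
  newborn <- !is.na(birth) & birth >= keys$win_start
  out <- rep(FALSE, nrow(keys))
  hit <- match(seq_len(nrow(keys)), cov$.k)
  covers <- !is.na(hit) & cov$covers_date[hit]
  gapfree <- !is.na(hit) & cov$gap_free[hit]
  out <- covers & (gapfree | newborn)
  out
}

#' GP-record coverage on a snapshot date
#'
#' A person's GP records are available if the practice they are actively
#' registered with on the date shares data, or if any later registration
#' spell (starting on or after the date) is with a sharing practice — the
#' latter captures historical records added when a future GP starts
#' sharing.
#'
#' @param registrations registration spell table
#' @param practices practice table with `practice_id`, `shares_data`
#' @param alf person id vector
#' @param date snapshot Date
#' @return logical vector parallel to `alf`
#' @export
covered_on <- function(registrations, practices, alf, date) {
  keys <- tibble::tibble(alf = alf, date = as.Date(date)) %>%
    dplyr::mutate(.k = dplyr::row_number())
  regs <- registrations %>%
    dplyr::left_join(dplyr::select(practices, "practice_id", "shares_data"),
                     by = "practice_id")
  hits <- keys %>%
    dplyr::inner_join(regs, by = "alf", relationship = "many-to-many") %>%
    dplyr::group_by(.data$.k) %>%
    dplyr::summarise(
      covered = any(.data$shares_data & in_spell(.data$date, .data$start_dt, .data$end_dt)) ||
        any(.data$shares_data & .data$start_dt >= .data$date),
      .groups = "drop"
    )
  out <- rep(FALSE, nrow(keys))
  out[hits$.k] <- hits$covered
  out
}

.AGE_BREAKS <- c(0, 16, 35, 50, 65, 111)
.AGE_LABELS <- c("0-15", "16-34", "35-49", "50-64", "65-110")

#' Build the annual coverage panel
#'
#' For each year, residents on 1 July are counted and cross-classified by
#' sex, age group, deprivation quintile and health board, together with the
#' number whose GP records are covered. Persons with missing demographics
#' are excluded (count attached as attribute `n_excluded`).
#'
#' @param persons,residence,registrations,practices cohort tables
#' @param years integer vector of snapshot years
#' @return `CoveragePanel` tibble: `year`, `sex`, `age_group`,
#'   `wimd_quintile`, `health_board`, `n_resident`, `n_covered`
#' @export
build_panel <- function(persons, residence, registrations, practices, years) {
  complete <- !is.na(persons$sex) & !is.na(persons$birth_dt) &
    !is.na(persons$wimd_quintile) & !is.na(persons$health_board)
  n_excluded <- sum(!complete)
  persons <- persons[complete, , drop = FALSE]
  panel <- purrr::map_dfr(years, function(y) {
    snap <- as.Date(sprintf("%d-07-01", y))
    res <- resident_on(residence, persons, persons$alf, snap)
    if (!any(res)) return(NULL)
    p <- persons[res, , drop = FALSE]
    cov <- covered_on(registrations, practices, p$alf, snap)
    age <- floor(lubridate::interval(p$birth_dt, snap) / lubridate::years(1))
    tibble::tibble(
      year = y, sex = p$sex,
      age_group = cut(age, .AGE_BREAKS, labels = .AGE_LABELS, right = FALSE),
      wimd_quintile = factor(p$wimd_quintile, levels = 1:5),
      health_board = p$health_board, covered = cov
    ) %>%
      dplyr::filter(!is.na(.data$age_group)) %>%
      dplyr::group_by(.data$year, .data$sex, .data$age_group,
                      .data$wimd_quintile, .data$health_board) %>%
      dplyr::summarise(n_resident = dplyr::n(), n_covered = sum(.data$covered),
                       .groups = "drop")
  })
  attr(panel, "n_excluded") <- n_excluded
  panel
}

# factor setup with the package's reference levels
panel_factors <- function(panel) {
  out <- panel
  if ("sex" %in% names(out)) {
    out$sex <- stats::relevel(factor(out$sex), ref = "M")
  }
  if ("age_group" %in% names(out)) {
    out$age_group <- droplevels(factor(out$age_group, levels = .AGE_LABELS))
  }
  if ("wimd_quintile" %in% names(out)) {
    out$wimd_quintile <- stats::relevel(factor(out$wimd_quintile), ref = "1")
  }
  if ("health_board" %in% names(out)) {
    hb <- unique(as.character(out$health_board))
    ref <- if ("Betsi Cadwaladr" %in% hb) "Betsi Cadwaladr" else sort(hb)[1]
    out$health_board <- stats::relevel(factor(out$health_board), ref = ref)
  }
  out
}

#' Fit the longitudinal binomial coverage GAMM
#'
#' Models the number of covered residents out of residents per stratum-year
#' with a logit link, a penalized thin-plate spline over year capturing the
#' common trend, fixed effects for the requested covariates (one when
#' unadjusted, all when adjusted), and an AR(1) correlation between
#' year-on-year observations nested within strata. Estimation is by maximum
#' (Laplace) likelihood with the AR(1) process as a latent stratum-level
#' series. Odds ratios use Wald 95% intervals.
#'
#' @param panel a coverage panel (from [build_panel()] or
#'   [simulate_coverage_panel()])
#' @param covariates character vector of covariate column names; default all
#'   of sex, age group, deprivation quintile, health board that vary
#' @param adjusted if `FALSE`, each fit uses only the first covariate
#' @param k_year year-spline basis dimension
#' @return object of class `coverage_gamm` with elements `model`,
#'   `or_table`, `rho`, `ar_sd`, `covariates`, `adjusted`
#' @export
fit_coverage_gamm <- function(panel, covariates = NULL, adjusted = TRUE, k_year = 10) {
  if (dplyr::n_distinct(panel$year) < 2) {
    abort("coverage panel must span at least two years", class = "rrda_fit_error")
  }
  all_covs <- c("sex", "age_group", "wimd_quintile", "health_board")
  present <- intersect(all_covs, names(panel))
  varying <- present[vapply(present, function(v) dplyr::n_distinct(panel[[v]]) > 1, logical(1))]
  covariates <- covariates %||% varying
  if (!adjusted) covariates <- covariates[1]
  if (!length(covariates)) abort("no varying covariate to model", class = "rrda_fit_error")

  dat <- panel_factors(panel) %>%
    dplyr::mutate(
      yc = .data$year - mean(.data$year),
      ftime = factor(.data$yc),
      stratum = interaction(!!!rlang::syms(intersect(all_covs, names(panel))), drop = TRUE)
    )
  k_year <- min(k_year, dplyr::n_distinct(dat$yc) - 1)
  fo <- stats::as.formula(paste(
    "cbind(n_covered, n_resident - n_covered) ~",
    paste(c(sprintf("s(yc, k = %d)", k_year), covariates,
            "ar1(0 + ftime | stratum)"), collapse = " + ")
  ))
  fit <- suppressWarnings(glmmTMB::glmmTMB(fo, family = stats::binomial(), data = dat))
  if (is.na(fit$fit$objective) || !is.finite(fit$fit$objective)) {
    abort("coverage GAMM failed to converge", class = "rrda_fit_error")
  }

  vc <- glmmTMB::VarCorr(fit)$cond$stratum
  rho <- attr(vc, "correlation")[1, 2]
  ar_sd <- attr(vc, "stddev")[1]
  beta <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(stats::vcov(fit)$cond))
  keep <- !grepl("^s\\(yc", names(beta)) & names(beta) != "(Intercept)"
  or_table <- purrr::map_dfr(covariates, function(v) {
    levs <- levels(dat[[v]])
    terms <- paste0(v, levs)
    tibble::tibble(
      covariate = v, level = levs,
      or = c(1, exp(unname(beta[terms[-1]]))),
      conf_low = c(1, exp(unname(beta[terms[-1]] - 1.96 * se[terms[-1]]))),
      conf_high = c(1, exp(unname(beta[terms[-1]] + 1.96 * se[terms[-1]]))),
      reference = levs == levs[1]
    )
  })
  structure(
    list(model = fit, or_table = or_table, rho = unname(rho), ar_sd = unname(ar_sd),
         covariates = covariates, adjusted = adjusted, n_obs = nrow(dat)),
    class = "coverage_gamm"
  )
}

#' @export
print.coverage_gamm <- function(x, ...) {
  cat(sprintf("Binomial coverage GAMM (%s; %d stratum-years)\n",
              if (x$adjusted) "adjusted" else "unadjusted", x$n_obs))
  cat(sprintf("AR(1) rho = %.3f (sd %.3f)\n", x$rho, x$ar_sd))
  print(x$or_table, n = 20)
  invisible(x)
}

#' Simulate stratified coverage panels for recovery studies
#'
#' Generates a stratum-by-year binomial panel whose logit-scale coverage
#' follows a smooth common trend, a sex effect of known odds ratio, and a
#' latent AR(1) series per stratum — the data-generating model the coverage
#' GAMM assumes. Used to verify parameter recovery.
#'
#' @param n_years panel length in years (annual snapshots)
#' @param or_sex true covariate odds ratio (female vs male)
#' @param rho,ar_sd AR(1) parameter and stationary standard deviation
#' @param n_age age strata per sex
#' @param n_resident residents per stratum-year
#' @param base_p baseline coverage probability
#' @param trend logit-scale linear trend per year
#' @param seed RNG seed
#' @return a coverage-panel tibble
#' @export
simulate_coverage_panel <- function(n_years = 35, or_sex = 1.10, rho = 0.5,
                                    ar_sd = 0.1, n_age = 5, n_resident = 20000,
                                    base_p = 0.8, trend = 0.02, seed = 1) {
  set.seed(seed)
  years <- seq(1990, length.out = n_years)
  panel <- tidyr::expand_grid(
    year = years, sex = c("M", "F"), age_group = .AGE_LABELS[seq_len(n_age)]
  ) %>% dplyr::arrange(.data$sex, .data$age_group, .data$year)
  n_strat <- 2 * n_age
  ar <- as.numeric(vapply(seq_len(n_strat), function(i) {
    as.numeric(stats::arima.sim(list(ar = rho), n = n_years,
                                sd = ar_sd * sqrt(1 - rho^2)))
  }, numeric(n_years)))
  eta <- stats::qlogis(base_p) + trend * (panel$year - stats::median(years)) +
    log(or_sex) * (panel$sex == "F") + ar
  panel %>%
    dplyr::mutate(
      n_resident = n_resident,
      n_covered = stats::rbinom(dplyr::n(), n_resident, stats::plogis(eta))
    )
}

#' @importFrom lubridate %m-%
NULL
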