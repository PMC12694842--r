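#' Monthly averaged daily activity rates per 100,000
#'
#' Counts categorised person-days per calendar month for one activity
#' category and converts them to the analysis outcome: the average daily
#' number of person-days that month per 100,000 of the GP-registered covered
#' population, `rate = (n / days_in_month) / population * 1e5`.
#'
#' @param activity person-day category table from [categorize_all()]
#' @param person_day the RRDA person-day table (for event dates)
#' @param population tibble with `year`, `month`, `population` covering
#'   every month with events
#' @param category one activity category label
#' @return a `monthly_series` tibble: `year`, `month`, `category`,
#'   `n_person_days`, `days_in_month`, `population`, `rate` — including
#'   zero-count rows for covered months without events
#' @export
monthly_series <- function(activity, person_day, population, category) {
  counts <- activity %>%
    dplyr::filter(stringr::str_detect(.data$categories,
                                      stringr::fixed(category))) %>%
    dplyr::left_join(person_day, by = "event_id") %>%
    dplyr::mutate(year = as.integer(format(.data$event_dt, "%Y")),
                  month = as.integer(format(.data$event_dt, "%m"))) %>%
    dplyr::count(.data$year, .data$month, name = "n_person_days")
  out <- population %>%
    dplyr::left_join(counts, by = c("year", "month")) %>%
    dplyr::mutate(
      category = category,
      n_person_days = dplyr::coalesce(.data$n_person_days, 0L),
      days_in_month = days_in_month_of(as.Date(sprintf("%d-%02d-01", .data$year, .data$month)))
    )
  if (any(is.na(out$population) | out$population <= 0)) {
    abort("population series must be positive for every month", class = "rrda_input_error")
  }
  missing_pop <- counts %>% dplyr::anti_join(population, by = c("year", "month"))
  if (nrow(missing_pop) > 0) {
    abort("population series does not cover all months with events",
          class = "rrda_input_error")
  }
  out %>%
    dplyr::mutate(rate = (.data$n_person_days / .data$days_in_month) /
                    .data$population * 1e5) %>%
    dplyr::select("year", "month", "category", "n_person_days",
                  "days_in_month", "population", "rate") %>%
    dplyr::arrange(.data$year, .data$month)
}

#' Interpolate annual mid-year population to a monthly series
#'
#' Linear interpolation between 1-July snapshots; ends are carried flat.
#'
#' @param annual tibble with `year` and `population` (mid-year count)
#' @param years years the monthly series should span (default the annual
#'   range)
#' @return tibble with `year`, `month`, `population`
#' @export
monthly_population <- function(annual, years = NULL) {
  years <- years %||% seq(min(annual$year), max(annual$year))
  grid <- tidyr::expand_grid(year = years, month = 1:12) %>%
    dplyr::mutate(t = .data$year + (.data$month - 0.5) / 12)
  interp <- stats::approx(annual$year + 0.5, annual$population, xout = grid$t,
                          rule = 2)
  dplyr::mutate(grid, population = interp$y) %>% dplyr::select(-"t")
}

series_data <- function(series, exclude_years) {
  series %>%
    dplyr::mutate(
      t = (.data$year - min(.data$year)) * 12 + .data$month,
      offset = log(.data$population / 1e5 * .data$days_in_month),
      excluded = .data$year %in% exclude_years
    )
}

#' Fit the seasonal-trend negative-binomial GAMM to a monthly series
#'
#' Negative-binomial model of monthly person-day counts with log link and
#' `log(population / 1e5 * days_in_month)` offset (so the linear predictor
#' is the log daily rate per 100,000), a cyclic penalized cubic regression
#' spline over calendar month (period 12), a penalized thin-plate spline
#' over continuous time for the long-run trend, and AR(1) correlation
#' between consecutive months. The dispersion is estimated by restricted
#' maximum likelihood in a working independence fit, then held fixed while
#' the correlated-error model is estimated by penalized quasi-likelihood.
#' Months in `exclude_years` are omitted from fitting entirely.
#'
#' @param series a `monthly_series` tibble
#' @param exclude_years years excluded from fitting (pandemic disruption);
#'   default 2020-2021, the convention for most categories — use 2021-2022
#'   for vaccination
#' @param k_season,k_trend basis dimensions of the seasonal and trend
#'   splines
#' @return object of class `trend_gamm`
#' @export
fit_trend_gamm <- function(series, exclude_years = c(2020, 2021),
                           k_season = 8, k_trend = 20) {
  dat <- series_data(series, exclude_years)
  fitdat <- dat[!dat$excluded, , drop = FALSE]
  if (nrow(fitdat) < 36) {
    abort("at least 36 non-excluded months are required", class = "rrda_fit_error")
  }
  k_trend <- min(k_trend, dplyr::n_distinct(fitdat$t) - k_season - 2)
  knots <- list(month = c(0.5, 12.5))
  g0 <- mgcv::gam(
    n_person_days ~ s(month, bs = "cc", k = k_season) + s(t, k = k_trend) +
      offset(offset),
    family = mgcv::nb(), data = fitdat, knots = knots, method = "REML"
  )
  theta <- g0$family$getTheta(TRUE)
  fit <- tryCatch(
    mgcv::gamm(
      n_person_days ~ s(month, bs = "cc", k = k_season) + s(t, k = k_trend) +
        offset(offset),
      family = mgcv::negbin(theta), data = fitdat, knots = knots,
      correlation = nlme::corAR1(form = ~t), verbose = FALSE
    ),
    error = function(e) abort(paste("trend GAMM failed to converge:", conditionMessage(e)),
                              class = "rrda_fit_error")
  )
  rho <- unname(stats::coef(fit$lme$modelStruct$corStruct, unconstrained = FALSE))
  structure(
    list(gam = fit$gam, lme = fit$lme, theta = theta, rho = rho,
         exclude_years = exclude_years, series = series,
         k_season = k_season, k_trend = k_trend),
    class = "trend_gamm"
  )
}

#' @export
print.trend_gamm <- function(x, ...) {
  cat(sprintf("Negative-binomial trend GAMM: %s, %d months fitted (excluding %s)\n",
              x$series$category[1], sum(!x$series$year %in% x$exclude_years),
              paste(x$exclude_years, collapse = ", ")))
  cat(sprintf("theta = %.1f, AR(1) rho = %.3f\n", x$theta, x$rho))
  invisible(x)
}

#' Expected rates and observed-vs-expected deviations
#'
#' Predicts the model-based expected daily rate per 100,000 for the given
#' months (default: the whole series, including excluded years) and the
#' percentage deviation of the observed rate from it.
#'
#' @param fit a `trend_gamm` from [fit_trend_gamm()]
#' @param months optional subset tibble with `year` and `month`
#' @return tibble with `year`, `month`, `observed_rate`, `expected_rate`,
#'   `deviation_pct`
#' @export
predict_expected <- function(fit, months = NULL) {
  dat <- series_data(fit$series, fit$exclude_years)
  if (!is.null(months)) {
    dat <- dplyr::semi_join(dat, months, by = intersect(c("year", "month"), names(months)))
  }
  eta <- as.numeric(stats::predict(fit$gam, newdata = dat, type = "link"))
  expected_count <- exp(eta)  # offset included by predict via `offset` column
  dat %>%
    dplyr::mutate(
      expected_rate = expected_count / .data$days_in_month / .data$population * 1e5,
      observed_rate = .data$rate,
      deviation_pct = 100 * (.data$observed_rate - .data$expected_rate) / .data$expected_rate
    ) %>%
    dplyr::select("year", "month", "observed_rate", "expected_rate", "deviation_pct")
}

# ---- AR(1)-plus-noise working covariance for year contrasts ---------------
#
# The year-categorical model absorbs each year's mean, so the lag-1
# autocorrelation of its residuals is biased far towards zero (classic
# demeaning bias at block length 12). Instead of estimating the AR(1)
# parameter from those residuals naively, we fit (AR variance, rho, white
# variance) by matching the empirical autocovariances of the year-demeaned
# log-scale residuals to their closed-form expectations under within-block
# demeaning, then propagate the fitted covariance into the year-contrast
# standard errors. Months sit in regular 12-month blocks, so the expected
# demeaned autocovariance at lag k has a closed form over block positions.

theo_demeaned_acov <- function(s2a, rho, s2n, K) {
  G <- function(d) s2a * rho^abs(d) + s2n * (d == 0)
  gbar1 <- function(x) mean(G(x - 1:12))
  gbar2 <- function(x) mean(G(x - 13:24))
  bb11 <- mean(outer(1:12, 1:12, function(i, j) G(i - j)))
  bb12 <- mean(outer(1:12, 13:24, function(i, j) G(i - j)))
  vapply(0:K, function(k) {
    same <- if (k <= 11) {
      p <- 1:(12 - k); q <- p + k
      mean(G(k) - vapply(p, gbar1, numeric(1)) - vapply(q, gbar1, numeric(1)) + bb11)
    } else 0
    cross <- if (k >= 1) {
      p <- (13 - k):12; q <- p + k
      mean(G(k) - vapply(p, gbar2, numeric(1)) - vapply(q, gbar1, numeric(1)) + bb12)
    } else 0
    ((12 - k) * same + k * cross) / 12
  }, numeric(1))
}

fit_ar_noise <- function(r, t, K = 6) {
  n <- length(r)
  c_emp <- vapply(0:K, function(k) {
    idx <- seq_len(n - k)
    keep <- (t[idx + k] - t[idx]) == k
    mean(r[idx][keep] * r[idx + k][keep])
  }, numeric(1))
  obj <- function(p) {
    sum((theo_demeaned_acov(exp(p[1]), tanh(p[2]), exp(p[3]), K) - c_emp)^2)
  }
  v0 <- max(c_emp[1], 1e-8)
  opt <- stats::optim(c(log(v0 / 2), atanh(0.3), log(v0 / 2)), obj,
                      method = "Nelder-Mead", control = list(maxit = 500))
  list(s2a = exp(opt$par[1]), rho = tanh(opt$par[2]), s2n = exp(opt$par[3]))
}

ar_contrast_var <- function(pars, t_y, t_ref) {
  G <- function(d) pars$s2a * pars$rho^abs(d) + pars$s2n * (d == 0)
  S <- function(ta, tb) sum(outer(ta, tb, function(x, y) G(x - y)))
  m1 <- length(t_y); m2 <- length(t_ref)
  S(t_y, t_y) / m1^2 + S(t_ref, t_ref) / m2^2 - 2 * S(t_y, t_ref) / (m1 * m2)
}

#' Fit the year-categorical rate-ratio model
#'
#' Same specification as [fit_trend_gamm()] but with the trend spline
#' replaced by calendar year as a categorical covariate (reference 2019),
#' yielding rate ratios of every other year versus the reference with Wald
#' 95% intervals. Point estimates come from the restricted-maximum-likelihood
#' negative-binomial fit; the interval standard errors propagate an
#' AR(1)-plus-white-noise working covariance whose parameters are fitted by
#' matching the residual autocovariances to their closed-form expectations
#' under year-demeaning (the naive residual autocorrelation of a
#' year-factor model is severely biased towards zero).
#'
#' @param series a `monthly_series` tibble
#' @param ref_year reference year (must be present in the series)
#' @param exclude_years years omitted from fitting (default none: the
#'   rate-ratio model provides estimates for all years)
#' @param k_season seasonal spline basis dimension
#' @return object of class `year_rr` with an `rr_table`
#' @export
fit_year_rr <- function(series, ref_year = 2019, exclude_years = integer(),
                        k_season = 8) {
  if (!ref_year %in% series$year) {
    abort(sprintf("reference year %d absent from series", ref_year),
          class = "rrda_fit_error")
  }
  dat <- series_data(series, exclude_years)
  fitdat <- dat[!dat$excluded, , drop = FALSE] %>%
    dplyr::mutate(fyear = stats::relevel(factor(.data$year), ref = as.character(ref_year)))
  knots <- list(month = c(0.5, 12.5))
  g0 <- tryCatch(
    mgcv::gam(
      n_person_days ~ s(month, bs = "cc", k = k_season) + fyear + offset(offset),
      family = mgcv::nb(), data = fitdat, knots = knots, method = "REML"
    ),
    error = function(e) abort(paste("rate-ratio model failed to converge:",
                                    conditionMessage(e)),
                              class = "rrda_fit_error")
  )
  theta <- g0$family$getTheta(TRUE)
  resid_log <- log(pmax(fitdat$n_person_days, 0.5)) -
    as.numeric(stats::predict(g0, type = "link"))
  pars <- fit_ar_noise(resid_log, fitdat$t)
  beta <- stats::coef(g0)
  yr_terms <- grep("^fyear", names(beta), value = TRUE)
  yrs <- as.integer(sub("^fyear", "", yr_terms))
  se <- vapply(yrs, function(y) {
    sqrt(ar_contrast_var(pars, fitdat$t[fitdat$year == y],
                         fitdat$t[fitdat$year == ref_year]))
  }, numeric(1))
  rr_table <- tibble::tibble(
    year = c(ref_year, yrs),
    rate_ratio = c(1, exp(unname(beta[yr_terms]))),
    conf_low = c(1, exp(unname(beta[yr_terms] - 1.96 * se))),
    conf_high = c(1, exp(unname(beta[yr_terms] + 1.96 * se))),
    reference = c(TRUE, rep(FALSE, length(yrs)))
  ) %>% dplyr::arrange(.data$year)
  structure(
    list(gam = g0, rr_table = rr_table, theta = theta, rho = pars$rho,
         ar_sd = sqrt(pars$s2a), noise_sd = sqrt(pars$s2n),
         ref_year = ref_year, exclude_years = exclude_years, series = series),
    class = "year_rr"
  )
}

#' @export
print.year_rr <- function(x, ...) {
  cat(sprintf("Year rate-ratio NB GAMM vs %d (theta %.1f, rho %.3f)\n",
              x$ref_year, x$theta, x$rho))
  print(x$rr_table, n = 30)
  invisible(x)
}

#' Percent change and ratio between two endpoint rates
#'
#' @param rate_a,rate_b rates at the two endpoints (`rate_a` > 0)
#' @return tibble with `percent` (nearest integer) and `ratio` (1 decimal)
#' @examples
#' endpoint_change(18560, 35192)  # +90%, ratio 1.9
#' @export
endpoint_change <- function(rate_a, rate_b) {
  if (any(rate_a <= 0)) {
    abort("rate_a must be positive", class = "rrda_input_error")
  }
  tibble::tibble(
    percent = round(100 * (rate_b - rate_a) / rate_a),
    ratio = round(rate_b / rate_a, 1)
  )
}

#' Autocorrelation diagnostics with approximate 95% bands
#'
#' @param residuals numeric residual series (at least `max_lag + 2` values)
#' @param max_lag largest lag
#' @return tibble with `lag` (0..max_lag), `acf`, `conf_low`, `conf_high`
#' @export
acf_diagnostics <- function(residuals, max_lag = 24) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < max_lag + 2) {
    abort("need at least max_lag + 2 observations", class = "rrda_input_error")
  }
  a <- stats::acf(residuals, lag.max = max_lag, plot = FALSE)
  band <- 1.96 / sqrt(length(residuals))
  tibble::tibble(
    lag = drop(a$lag), acf = drop(a$acf),
    conf_low = -band, conf_high = band
  )
}

#' Simulate a monthly activity-count series
#'
#' Negative-binomial monthly counts around a log-linear rate with cosine
#' seasonality, optional long-run trend, optional per-year multiplicative
#' level shifts, and a latent AR(1) process — the generating model the
#' trend GAMMs assume. Count magnitudes default to the scale of national
#' consultation rates (tens of thousands per 100,000 per day).
#'
#' @param n_years series length (from `start_year`)
#' @param start_year first calendar year
#' @param base_rate baseline daily rate per 100,000
#' @param seasonal_amp cosine amplitude on the log scale
#' @param peak_month month of the seasonal peak
#' @param trend log-rate change per year
#' @param year_shifts named numeric, log-scale level shift per year
#'   (e.g. `c("2024" = log(1.08))`)
#' @param month_shocks optional tibble (`year`, `month`, `log_mult`) of
#'   single-month shocks
#' @param rho,ar_sd latent AR(1) parameter and stationary sd
#' @param theta negative-binomial dispersion
#' @param population constant GP-registered population
#' @param seed RNG seed
#' @return a `monthly_series`-shaped tibble (category `"SIMULATED"`)
#' @export
simulate_monthly_series <- function(n_years = 25, start_year = 2000,
                                    base_rate = 20000, seasonal_amp = 0.3,
                                    peak_month = 10, trend = 0,
                                    year_shifts = NULL, month_shocks = NULL,
                                    rho = 0.5, ar_sd = 0.08, theta = 80,
                                    population = 3e6, seed = 1) {
  set.seed(seed)
  n <- n_years * 12
  grid <- tidyr::expand_grid(year = seq(start_year, length.out = n_years),
                             month = 1:12)
  ar <- if (rho == 0) stats::rnorm(n, 0, ar_sd) else
    as.numeric(stats::arima.sim(list(ar = rho), n = n, sd = ar_sd * sqrt(1 - rho^2)))
  shift <- rep(0, n)
  if (!is.null(year_shifts)) {
    hit <- match(as.character(grid$year), names(year_shifts))
    shift <- ifelse(is.na(hit), 0, year_shifts[hit])
  }
  if (!is.null(month_shocks)) {
    key <- paste(grid$year, grid$month)
    hit <- match(key, paste(month_shocks$year, month_shocks$month))
    shift <- shift + ifelse(is.na(hit), 0, month_shocks$log_mult[hit])
  }
  yrs <- (seq_len(n) - 1) / 12
  grid %>%
    dplyr::mutate(
      category = "SIMULATED",
      days_in_month = days_in_month_of(as.Date(sprintf("%d-%02d-01", .data$year, .data$month))),
      population = population,
      .mu = base_rate * exp(seasonal_amp * cos(2 * pi * (.data$month - peak_month) / 12) +
                              trend * yrs + shift + ar) *
        .data$days_in_month * population / 1e5,
      n_person_days = stats::rnbinom(n, size = theta, mu = .data$.mu),
      rate = (.data$n_person_days / .data$days_in_month) / population * 1e5
    ) %>%
    dplyr::select("year", "month", "category", "n_person_days",
                  "days_in_month", "population", "rate")
}
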