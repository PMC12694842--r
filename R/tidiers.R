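#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a coverage GAMM fit
#'
#' @param x a `coverage_gamm`
#' @param ... unused
#' @return tibble of odds ratios with 95% Wald intervals, one row per
#'   covariate level (reference rows have OR 1)
#' @method tidy coverage_gamm
#' @export
tidy.coverage_gamm <- function(x, ...) {
  x$or_table
}

#' @rdname tidy.coverage_gamm
#' @method glance coverage_gamm
#' @export
glance.coverage_gamm <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, ar_sd = x$ar_sd, adjusted = x$adjusted,
    n_obs = x$n_obs, logLik = as.numeric(stats::logLik(x$model))
  )
}

#' Tidy a year rate-ratio fit
#'
#' @param x a `year_rr`
#' @param ... unused
#' @return tibble of rate ratios vs the reference year
#' @method tidy year_rr
#' @export
tidy.year_rr <- function(x, ...) {
  x$rr_table
}

#' @rdname tidy.year_rr
#' @method glance year_rr
#' @export
glance.year_rr <- function(x, ...) {
  tibble::tibble(ref_year = x$ref_year, theta = x$theta, rho = x$rho,
                 n_months = nrow(x$gam$model))
}

#' Tidy a seasonal-trend GAMM fit
#'
#' @param x a `trend_gamm`
#' @param ... unused
#' @return per-month observed/expected table from [predict_expected()]
#' @method tidy trend_gamm
#' @export
tidy.trend_gamm <- function(x, ...) {
  predict_expected(x)
}

#' @rdname tidy.trend_gamm
#' @method glance trend_gamm
#' @export
glance.trend_gamm <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, rho = x$rho,
    exclude_years = paste(x$exclude_years, collapse = ","),
    n_months_fitted = nrow(x$gam$model),
    edf_seasonal = sum(x$gam$edf[grepl("s\\(month\\)", names(x$gam$edf))]),
    edf_trend = sum(x$gam$edf[grepl("s\\(t\\)", names(x$gam$edf))])
  )
}
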