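# Monetization of DALYs and the descriptive arithmetic reported on top of the
# resulting burden tables: percent change, share of total, GDP share,
# quintile maps.

#' Monetize a DALY table with VSLY values
#'
#' Each DALY lost is priced at one VSLY. Money dated after the base year is
#' discounted back at the configured rate; money dated before it is inflated
#' with the CPI when a \code{cpi} column is supplied in \code{econ_cpi}.
#' Uncertainty bounds propagate the DALY interval only (VSLY fixed); the
#' combined VSLY uncertainty lives in \code{\link{bootstrap_burden}}.
#'
#' @param dalys GBD-dialect data frame (see \code{\link{gen_daly_table}} /
#'   \code{\link{read_gbd_csv}}) with columns \code{location}, \code{year},
#'   \code{cause}, \code{val}, \code{lower}, \code{upper}.
#' @param vsly VSLY table from \code{\link{build_vsly_table}}.
#' @param params A \code{\link{vsl_params}}.
#' @param econ_cpi Optional data frame (\code{country}, \code{year},
#'   \code{cpi}) used to inflate pre-base-year money; if omitted, pre-base
#'   money is left in nominal terms (the common case when VSLY is already
#'   expressed in base-year dollars for every year).
#' @return Burden table: data frame (\code{country}, \code{year},
#'   \code{cause}, \code{burden}, \code{lower}, \code{upper}) in base-year
#'   international dollars, one row per country-year-cause (ages summed).
#' @export
monetize <- function(dalys, vsly, params = vsl_params(), econ_cpi = NULL) {
  need <- c("location", "year", "cause", "val", "lower", "upper")
  if (!all(need %in% names(dalys)))
    stop("dalys must have columns ", paste(need, collapse = ", "))
  agg <- stats::aggregate(cbind(val, lower, upper) ~ location + year + cause,
                          data = dalys, FUN = sum)
  key_v <- paste(vsly$country, vsly$year)
  idx <- match(paste(agg$location, agg$year), key_v)
  if (anyNA(idx)) {
    miss <- unique(paste(agg$location, agg$year)[is.na(idx)])
    stop("missing VSLY rows for: ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) " ..." else "")
  }
  v <- vsly$vsly[idx]
  adj <- rep(1, nrow(agg))
  post <- agg$year > params$base_year
  adj[post] <- 1 / (1 + params$discount_rate)^(agg$year[post] - params$base_year)
  if (!is.null(econ_cpi)) {
    pre <- agg$year < params$base_year
    if (any(pre)) {
      ck <- paste(econ_cpi$country, econ_cpi$year)
      ci <- match(paste(agg$location, agg$year)[pre], ck)
      cb <- match(paste(agg$location, params$base_year)[pre], ck)
      if (anyNA(ci) || anyNA(cb))
        stop("econ_cpi must cover every pre-base country-year and the base year")
      adj[pre] <- econ_cpi$cpi[cb] / econ_cpi$cpi[ci]
    }
  }
  out <- data.frame(country = agg$location, year = agg$year,
                    cause = agg$cause,
                    burden = agg$val * v * adj,
                    lower = agg$lower * v * adj,
                    upper = agg$upper * v * adj,
                    stringsAsFactors = FALSE)
  attr(out, "units") <- sprintf("%d international dollars", params$base_year)
  out[order(out$country, out$year, out$cause), , drop = FALSE]
}

#' Aggregate a burden table
#'
#' Exact sums of burden over rows, grouped by country, cause, income group or
#' globally, optionally restricted to one year. Income-group aggregation
#' needs an economic panel carrying the classification.
#'
#' @param burden Burden table from \code{\link{monetize}}.
#' @param by One of \code{"country"}, \code{"cause"}, \code{"income_group"},
#'   \code{"global"}.
#' @param year Optional year filter.
#' @param econ Economic panel with \code{country}, \code{year},
#'   \code{income_group}; required for \code{by = "income_group"}.
#' @return Data frame with the grouping column(s), \code{year} when filtered,
#'   and \code{burden}.
#' @export
aggregate_burden <- function(burden, by = c("global", "country", "cause",
                                            "income_group"),
                             year = NULL, econ = NULL) {
  by <- match.arg(by)
  b <- burden
  if (!is.null(year)) b <- b[b$year %in% year, , drop = FALSE]
  if (by == "income_group") {
    if (is.null(econ)) stop("income-group aggregation needs the econ panel")
    idx <- match(paste(b$country, b$year), paste(econ$country, econ$year))
    if (anyNA(idx)) stop("econ panel does not cover all burden country-years")
    b$income_group <- econ$income_group[idx]
  }
  if (by == "global")
    return(data.frame(group = "global", burden = sum(b$burden)))
  f <- stats::as.formula(paste("burden ~", by))
  out <- stats::aggregate(f, data = b, FUN = sum)
  out[order(out[[by]]), , drop = FALSE]
}

#' Percent change between two values
#'
#' @param v0 Baseline value (> 0).
#' @param v1 Comparison value.
#' @return Signed percent change \code{100 * (v1 - v0) / v0}.
#' @examples
#' percent_change(992, 1516)   # 52.8
#' @export
percent_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("baseline value must be positive")
  100 * (v1 - v0) / v0
}

#' Share of a total, in percent
#'
#' @param part Component value.
#' @param total Total (> 0).
#' @return \code{100 * part / total}.
#' @export
share_of_total <- function(part, total) {
  if (any(total <= 0)) stop("total must be positive")
  100 * part / total
}

#' Burden as a fraction of GDP
#'
#' @param burden Money.
#' @param gdp Money (> 0).
#' @return Fraction \code{burden / gdp} (multiply by 100 for percent).
#' @export
gdp_share <- function(burden, gdp) {
  if (any(gdp <= 0)) stop("gdp must be positive")
  burden / gdp
}

#' Quintile bins of country values
#'
#' Splits countries into five bins at the empirical 20/40/60/80 percentiles
#' (inclusive linear interpolation). Ties are broken by the stable order of
#' the input names.
#'
#' @param values Named numeric vector, one value per country; needs at least
#'   5 distinct values.
#' @return Named integer vector of bins 1 (lowest) to 5 (highest).
#' @export
quintile_bins <- function(values) {
  if (length(values) < 5) stop("need at least 5 countries")
  if (length(unique(values)) < 5)
    stop("fewer than 5 distinct values; quintiles are degenerate")
  r <- rank(values, ties.method = "first")
  bins <- as.integer(ceiling(5 * r / length(values)))
  names(bins) <- names(values)
  bins
}
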