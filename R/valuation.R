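#' Valuation parameters for VSL benefit transfer
#'
#' Bundles the constants of the value-of-statistical-life (VSL) benefit
#' transfer: the reference US VSL, the US GNI per capita it is anchored to,
#' the income elasticities applied to high-income versus other countries, the
#' VSL floor expressed as a multiple of GNI per capita, the discount rate used
#' to bring post-base-year money back to the base year, and the base year
#' itself.
#'
#' @param vsl_us Reference VSL in base-year US dollars. Default
#'   \code{11.23e6} (the 2015 HHS estimate of $9.4M inflated to 2021).
#' @param gnipc_us US GNI per capita (PPP, current international dollars) in
#'   the transfer reference year. Default \code{66060} (2019).
#' @param elasticity_hic Income elasticity applied to high-income countries.
#' @param elasticity_non_hic Income elasticity applied to upper-middle-,
#'   lower-middle- and low-income countries.
#' @param floor_multiple Minimum VSL as a multiple of GNI per capita.
#' @param discount_rate Annual discount rate for money after \code{base_year}.
#' @param base_year Calendar year money is expressed in.
#' @param reference_year Year of the GNI-per-capita values used in the
#'   transfer ratio.
#' @return An object of class \code{"vsl_params"} (a named list).
#' @examples
#' p <- vsl_params()
#' transfer_vsl(p$gnipc_us / 2, p, income_group = "HIC")
#' @export
vsl_params <- function(vsl_us = 11.23e6,
                       gnipc_us = 66060,
                       elasticity_hic = 1.0,
                       elasticity_non_hic = 1.5,
                       floor_multiple = 20,
                       discount_rate = 0.03,
                       base_year = 2021,
                       reference_year = 2019) {
  stopifnot(vsl_us > 0, gnipc_us > 0, elasticity_hic > 0,
            floor_multiple > 0)
  if (elasticity_non_hic < elasticity_hic)
    stop("elasticity_non_hic must be >= elasticity_hic")
  if (discount_rate < 0 || discount_rate >= 1)
    stop("discount_rate must lie in [0, 1)")
  structure(list(vsl_us = vsl_us, gnipc_us = gnipc_us,
                 elasticity_hic = elasticity_hic,
                 elasticity_non_hic = elasticity_non_hic,
                 floor_multiple = floor_multiple,
                 discount_rate = discount_rate,
                 base_year = base_year,
                 reference_year = reference_year),
            class = "vsl_params")
}

#' @export
print.vsl_params <- function(x, ...) {
  cat("VSL benefit-transfer parameters\n")
  cat(sprintf("  US VSL: $%.4g (%d dollars), US GNIpc (PPP): $%.6g\n",
              x$vsl_us, x$base_year, x$gnipc_us))
  cat(sprintf("  elasticity: HIC %.2f, non-HIC %.2f; floor: %g x GNIpc\n",
              x$elasticity_hic, x$elasticity_non_hic, x$floor_multiple))
  cat(sprintf("  discount rate %.1f%% after %d\n",
              100 * x$discount_rate, x$base_year))
  invisible(x)
}

#' Transfer the US VSL to another country
#'
#' Benefit transfer by income ratio: \deqn{VSL_x = VSL_{US} \times
#' (GNIPC_x / GNIPC_{US})^E}{VSL_x = VSL_US * (GNIPC_x/GNIPC_US)^E}
#' where the elasticity \eqn{E} is 1 for high-income countries and 1.5
#' otherwise (defaults in \code{\link{vsl_params}}). No floor is applied
#' here; see \code{\link{apply_vsl_floor}}.
#'
#' @param gnipc_target Target-country GNI per capita (PPP), same reference
#'   year as \code{params$gnipc_us}. Vectorised.
#' @param params A \code{\link{vsl_params}} object.
#' @param income_group Character vector in \code{c("HIC","UMIC","LMIC","LIC")},
#'   recycled against \code{gnipc_target}.
#' @return Transferred VSL in base-year dollars.
#' @export
transfer_vsl <- function(gnipc_target, params = vsl_params(),
                         income_group = "HIC") {
  stopifnot(inherits(params, "vsl_params"))
  if (any(!is.finite(gnipc_target)) || any(gnipc_target <= 0))
    stop("gnipc_target must be positive and finite")
  income_group <- match_income_group(income_group)
  e <- ifelse(income_group == "HIC",
              params$elasticity_hic, params$elasticity_non_hic)
  params$vsl_us * (gnipc_target / params$gnipc_us)^e
}

#' Apply the VSL floor
#'
#' Raises a transferred VSL to a minimum multiple of GNI per capita
#' (default 20x), leaving larger values untouched.
#'
#' @param vsl Transferred VSL (vectorised).
#' @param gnipc GNI per capita for the same country-years.
#' @param floor_multiple Floor expressed as a multiple of \code{gnipc}.
#' @return \code{pmax(vsl, floor_multiple * gnipc)}.
#' @export
apply_vsl_floor <- function(vsl, gnipc, floor_multiple = 20) {
  stopifnot(all(vsl > 0), all(gnipc > 0), floor_multiple > 0)
  pmax(vsl, floor_multiple * gnipc)
}

#' VSLY from VSL and remaining life expectancy
#'
#' Spreads the VSL evenly (undiscounted) over the remaining life years of the
#' population, taken as period life expectancy at the population median age.
#'
#' @param vsl VSL in base-year dollars (vectorised).
#' @param le_at_median_age Remaining life years at the median age; must be
#'   positive.
#' @return VSLY = \code{vsl / le_at_median_age}, dollars per life year.
#' @export
vsly_from_vsl <- function(vsl, le_at_median_age) {
  if (any(!is.finite(le_at_median_age)) || any(le_at_median_age <= 0))
    stop("le_at_median_age must be positive")
  vsl / le_at_median_age
}

#' Average annual GNI-per-capita growth over a window
#'
#' Geometric-mean annual growth between the window endpoints:
#' \code{(value[end]/value[start])^(1/(end-start)) - 1}. Used to project VSLY
#' beyond the base year from observed 2011-2020 income growth.
#'
#' @param gnipc_series Named numeric vector (names are years) or a data frame
#'   with columns \code{year} and \code{value}.
#' @param window Length-2 integer vector, inclusive start and end year.
#' @return Annual growth rate (e.g. 0.03 for 3\%/yr).
#' @export
gni_growth_rate <- function(gnipc_series, window = c(2011, 2020)) {
  if (is.data.frame(gnipc_series)) {
    v <- gnipc_series$value
    names(v) <- gnipc_series$year
    gnipc_series <- v
  }
  yrs <- as.integer(names(gnipc_series))
  if (anyNA(yrs)) stop("gnipc_series must be named by year")
  i0 <- match(window[1], yrs); i1 <- match(window[2], yrs)
  if (is.na(i0) || is.na(i1) ||
      is.na(gnipc_series[i0]) || is.na(gnipc_series[i1]))
    stop(sprintf("series must cover window endpoints %d and %d",
                 window[1], window[2]))
  v0 <- gnipc_series[[i0]]; v1 <- gnipc_series[[i1]]
  if (v0 <= 0 || v1 <= 0) stop("GNI per capita must be positive")
  (v1 / v0)^(1 / (window[2] - window[1])) - 1
}

#' Project VSLY forward with income growth
#'
#' @param vsly_base VSLY in the base year.
#' @param growth Annual growth rate from \code{\link{gni_growth_rate}}.
#' @param target_year Year at or after \code{base_year}.
#' @param base_year Anchor year of \code{vsly_base}.
#' @return \code{vsly_base * (1 + growth)^(target_year - base_year)}.
#' @export
project_vsly <- function(vsly_base, growth, target_year, base_year = 2021) {
  if (any(target_year < base_year))
    stop("target_year must not precede the base year")
  vsly_base * (1 + growth)^(target_year - base_year)
}

#' Inflate money to the base year with a CPI ratio
#'
#' For amounts dated before the base year: multiplies by
#' \code{cpi_base / cpi_source}.
#'
#' @param amount Money in source-year dollars.
#' @param cpi_source CPI index value in the source year.
#' @param cpi_base CPI index value in the base year.
#' @return Amount in base-year dollars.
#' @export
cpi_adjust <- function(amount, cpi_source, cpi_base) {
  if (any(cpi_source <= 0) || any(cpi_base <= 0))
    stop("CPI values must be positive")
  amount * cpi_base / cpi_source
}

#' Discount money after the base year back to the base year
#'
#' @param amount Money in year-\code{year} dollars.
#' @param year Calendar year; must be at or after \code{params$base_year}
#'   (use \code{\link{cpi_adjust}} for earlier years).
#' @param params A \code{\link{vsl_params}} object.
#' @return \code{amount / (1 + discount_rate)^(year - base_year)}.
#' @export
discount_to_base <- function(amount, year, params = vsl_params()) {
  stopifnot(inherits(params, "vsl_params"))
  if (any(year < params$base_year))
    stop("year precedes base year; use cpi_adjust for pre-base-year money")
  amount / (1 + params$discount_rate)^(year - params$base_year)
}

#' Build the country-year VSLY table
#'
#' Composes the valuation chain per country-year: transfer the US VSL by the
#' income ratio at the reference year, apply the floor, then divide by
#' remaining life years (period life expectancy at the median age).
#'
#' @param econ Economic panel: data frame with columns \code{country},
#'   \code{year}, \code{gnipc}, \code{income_group} (and optionally more).
#' @param demog Demography panel: data frame with columns \code{country},
#'   \code{year}, \code{median_age}, \code{le_at_median_age}.
#' @param params A \code{\link{vsl_params}} object.
#' @return Data frame (\code{country}, \code{year}, \code{vsl},
#'   \code{remaining_life_years}, \code{vsly}); money in base-year
#'   international dollars. Attribute \code{units} records the currency label.
#' @export
build_vsly_table <- function(econ, demog, params = vsl_params()) {
  need <- c("country", "year", "gnipc", "income_group")
  if (!all(need %in% names(econ)))
    stop("econ must have columns ", paste(need, collapse = ", "))
  key_e <- paste(econ$country, econ$year)
  key_d <- paste(demog$country, demog$year)
  miss <- setdiff(key_e, key_d)
  if (length(miss))
    stop("missing demography for country-years: ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) " ..." else "")
  d <- demog[match(key_e, key_d), ]
  vsl <- transfer_vsl(econ$gnipc, params, econ$income_group)
  vsl <- apply_vsl_floor(vsl, econ$gnipc, params$floor_multiple)
  out <- data.frame(country = econ$country, year = econ$year,
                    vsl = vsl,
                    remaining_life_years = d$le_at_median_age,
                    vsly = vsly_from_vsl(vsl, d$le_at_median_age),
                    stringsAsFactors = FALSE)
  attr(out, "units") <- sprintf("%d international dollars", params$base_year)
  out
}

# Canonicalise income-group labels; errors on anything unknown.
match_income_group <- function(x) {
  x <- toupper(as.character(x))
  ok <- x %in% c("HIC", "UMIC", "LMIC", "LIC")
  if (!all(ok))
    stop("unknown income group(s): ", paste(unique(x[!ok]), collapse = ", "))
  x
}
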