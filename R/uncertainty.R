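# Bootstrap uncertainty for the monetized burden: normal resampling of DALYs
# within their uncertainty intervals (truncated at zero), +/-20% VSLY
# perturbation, percentile intervals per income-group stratum.

#' Bootstrap configuration
#'
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param vsly_halfwidth VSLY perturbation half-width as a fraction
#'   (default 0.20, i.e. +/-20\%).
#' @param ci_level Nominal coverage of the percentile interval.
#' @param seed Integer seed.
#' @param vsly_mode \code{"uniform"}: VSLY drawn uniformly on
#'   \code{[1-h, 1+h] * vsly}; \code{"endpoints"}: the two-point sensitivity
#'   variant drawing only the interval ends.
#' @return Object of class \code{"bootstrap_config"}.
#' @export
bootstrap_config <- function(n_reps = 1000, vsly_halfwidth = 0.20,
                             ci_level = 0.95, seed = 1L,
                             vsly_mode = c("uniform", "endpoints")) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (vsly_halfwidth < 0 || vsly_halfwidth >= 1)
    stop("vsly_halfwidth must lie in [0, 1)")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(list(n_reps = as.integer(n_reps),
                 vsly_halfwidth = vsly_halfwidth, ci_level = ci_level,
                 seed = as.integer(seed),
                 vsly_mode = match.arg(vsly_mode)),
            class = "bootstrap_config")
}

#' Standard deviation implied by a 95\% uncertainty interval
#'
#' Under a normal model, a symmetric 95\% interval has half-width
#' \code{1.959964 * sd}, so \code{sd = (upper - lower) / (2 * 1.959964)}.
#'
#' @param point,lower,upper Point estimate and interval bounds
#'   (\code{lower <= point <= upper}); vectorised.
#' @return Implied standard deviation.
#' @export
daly_sd_from_ui <- function(point, lower, upper) {
  if (any(lower > point + 1e-12) || any(point > upper + 1e-12))
    stop("need lower <= point <= upper")
  (upper - lower) / (2 * stats::qnorm(0.975))
}

#' Percentile confidence interval
#'
#' Empirical quantiles at \code{(1 - level)/2} and \code{1 - (1 - level)/2},
#' inclusive linear interpolation (quantile type 7).
#'
#' @param samples Numeric vector of at least 2 replicate values.
#' @param level Nominal coverage in (0, 1).
#' @return Named numeric vector \code{c(lower =, upper =)}.
#' @export
ci_percentile <- function(samples, level = 0.95) {
  if (length(samples) < 2) stop("need at least 2 samples")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Bootstrap the monetized burden by income group
#'
#' Per replicate, every DALY cell is redrawn independently from a normal
#' distribution centred at its point estimate with the SD implied by its
#' uncertainty interval (truncated at zero), and every country-year VSLY is
#' perturbed within +/- \code{vsly_halfwidth} (one draw per country-year,
#' shared by that country-year's cells, since VSLY is a country-year
#' quantity); the stratum burden is the sum of draws times draws.
#' Confidence intervals are percentile intervals over replicates.
#' Deterministic given the config seed.
#'
#' @param dalys GBD-dialect DALY table with \code{val}, \code{lower},
#'   \code{upper}.
#' @param vsly VSLY table (\code{country}, \code{year}, \code{vsly}).
#' @param cfg A \code{\link{bootstrap_config}}.
#' @param strata Named character vector mapping country to stratum (e.g.
#'   income group); countries not named form their own stratum. Default: one
#'   global stratum.
#' @param year Optional year filter.
#' @return Data frame (\code{stratum}, \code{estimate}, \code{ci_lower},
#'   \code{ci_upper}, \code{n_reps}, \code{seed}).
#' @export
bootstrap_burden <- function(dalys, vsly, cfg = bootstrap_config(),
                             strata = NULL, year = NULL) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  d <- dalys
  if (!is.null(year)) d <- d[d$year %in% year, , drop = FALSE]
  if (!nrow(d)) stop("no DALY rows selected")
  idx <- match(paste(d$location, d$year), paste(vsly$country, vsly$year))
  if (anyNA(idx)) stop("VSLY table does not cover all DALY country-years")
  v <- vsly$vsly[idx]
  sdv <- daly_sd_from_ui(d$val, d$lower, d$upper)
  st <- if (is.null(strata)) rep("global", nrow(d)) else {
    s <- strata[d$location]
    s[is.na(s)] <- d$location[is.na(s)]
    unname(s)
  }
  st_f <- factor(st)
  if (any(tabulate(st_f) == 0)) stop("empty stratum")
  point <- as.vector(tapply(d$val * v, st_f, sum))
  h <- cfg$vsly_halfwidth
  n <- nrow(d)
  cy <- factor(paste(d$location, d$year))   # VSLY draw shared within these
  n_cy <- nlevels(cy)
  with_seed(cfg$seed, {
    reps <- matrix(0, cfg$n_reps, nlevels(st_f))
    for (r in seq_len(cfg$n_reps)) {
      daly_draw <- pmax(stats::rnorm(n, d$val, sdv), 0)
      u_cy <- if (cfg$vsly_mode == "uniform")
        stats::runif(n_cy, 1 - h, 1 + h)
      else (1 - h) + 2 * h * (stats::runif(n_cy) < 0.5)
      u <- u_cy[as.integer(cy)]
      reps[r, ] <- tapply(daly_draw * v * u, st_f, sum)
    }
    ci <- apply(reps, 2, ci_percentile, level = cfg$ci_level)
    data.frame(stratum = levels(st_f), estimate = point,
               ci_lower = ci["lower", ], ci_upper = ci["upper", ],
               n_reps = cfg$n_reps, seed = cfg$seed,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Coverage calibration experiment for the burden bootstrap
#'
#' Generates replicate synthetic worlds exactly under the assumed
#' uncertainty model -- observed DALYs normally distributed around a true
#' value with the SD encoded in their 95\% interval, observed VSLY a uniform
#' +/- \code{vsly_halfwidth} perturbation of a true country value -- runs
#' \code{\link{bootstrap_burden}} on each, and reports how often the nominal
#' interval covers the true total burden.
#'
#' @param n_worlds Number of replicate worlds.
#' @param n_reps Bootstrap replicates per world.
#' @param n_countries Countries per world (two age cells each).
#' @param ui_sd_frac True DALY SD as a fraction of the true value.
#' @param vsly_halfwidth VSLY perturbation half-width.
#' @param seed Integer seed; world w uses \code{seed + w}.
#' @return List with \code{coverage} (fraction of worlds covered) and
#'   \code{n_worlds}.
#' @export
coverage_experiment <- function(n_worlds = 500, n_reps = 200,
                                n_countries = 10, ui_sd_frac = 0.10,
                                vsly_halfwidth = 0.20, seed = 2024L) {
  z <- stats::qnorm(0.975)
  covered <- logical(n_worlds)
  for (w in seq_len(n_worlds)) {
    ages <- c("0-49", "50+")
    co <- sprintf("C%02d", seq_len(n_countries))
    world <- with_seed(seed + w, {
      d0 <- stats::runif(n_countries * 2, 500, 2000)
      v0 <- stats::runif(n_countries, 3e4, 8e4)
      list(d0 = d0, sd = ui_sd_frac * d0,
           val = stats::rnorm(n_countries * 2, d0, ui_sd_frac * d0),
           v0 = v0,
           v_obs = v0 * stats::runif(n_countries, 1 - vsly_halfwidth,
                                     1 + vsly_halfwidth))
    })
    truth <- sum(world$d0 * rep(world$v0, each = 2))
    d <- data.frame(measure = "DALYs (Disability-Adjusted Life Years)",
                    location = rep(co, each = 2), sex = "Both",
                    age = rep(ages, n_countries), cause = "HM",
                    metric = "Number", year = 2021, val = world$val,
                    upper = world$val + z * world$sd,
                    lower = world$val - z * world$sd,
                    stringsAsFactors = FALSE)
    v <- data.frame(country = co, year = 2021, vsl = world$v_obs,
                    remaining_life_years = 1, vsly = world$v_obs,
                    stringsAsFactors = FALSE)
    cfg <- bootstrap_config(n_reps = n_reps,
                            vsly_halfwidth = vsly_halfwidth,
                            seed = seed + w)
    out <- bootstrap_burden(d, v, cfg)
    covered[w] <- out$ci_lower <= truth && truth <= out$ci_upper
  }
  list(coverage = mean(covered), n_worlds = n_worlds)
}
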