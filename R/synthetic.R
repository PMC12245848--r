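# Synthetic worlds: countries with World Bank-style economies, evolving age
# pyramids, and DALY rates generated from a known log-linear age-period-cohort
# structure. Everything downstream is testable against this planted truth.

# Default GBD-style 5-year age bands with an open-ended top band.
default_age_groups <- function(n = 20) {
  lo <- seq(0, by = 5, length.out = n)
  labels <- c(paste(lo[-n], lo[-n] + 4, sep = "-"), paste0(lo[n], "+"))
  mid <- lo + 2.5
  data.frame(age = labels, midpoint = mid, stringsAsFactors = FALSE)
}

# World Bank-style GNI-per-capita classification thresholds (2021 scheme).
.income_thresholds <- c(LIC = 0, LMIC = 1046, UMIC = 4096, HIC = 12696)

#' Assign World Bank-style income groups from GNI per capita
#'
#' Monotone step function of GNI per capita using the 2021-style thresholds
#' (LIC below $1,046; LMIC to $4,095; UMIC to $12,695; HIC above).
#'
#' @param gnipc GNI per capita (vectorised, positive).
#' @return Character vector in \code{c("LIC","LMIC","UMIC","HIC")}.
#' @export
income_group_from_gni <- function(gnipc) {
  stopifnot(all(gnipc > 0))
  names(.income_thresholds)[
    findInterval(gnipc, .income_thresholds)]
}

#' Configuration of a synthetic world
#'
#' @param n_countries Number of countries (>= 1).
#' @param years Length-2 inclusive year range, e.g. \code{c(1990, 2021)}.
#' @param age_groups Data frame with columns \code{age} (band label) and
#'   \code{midpoint} (representative age in years), ordered and
#'   non-overlapping. Default: twenty 5-year GBD-style bands, open-ended top.
#' @param income_group_mix Named fractions over HIC/UMIC/LMIC/LIC summing
#'   to 1; the starting composition of the world.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return An object of class \code{"world_config"}.
#' @export
world_config <- function(n_countries = 40,
                         years = c(1990, 2021),
                         age_groups = default_age_groups(),
                         income_group_mix = c(HIC = 0.30, UMIC = 0.27,
                                              LMIC = 0.26, LIC = 0.17),
                         seed = 1L) {
  if (n_countries < 1) stop("n_countries must be >= 1")
  if (length(years) != 2 || years[2] <= years[1])
    stop("years must be an inclusive range spanning >= 2 years")
  if (!all(c("age", "midpoint") %in% names(age_groups)))
    stop("age_groups needs columns 'age' and 'midpoint'")
  if (is.unsorted(age_groups$midpoint, strictly = TRUE))
    stop("age bands must be ordered and non-overlapping")
  grp <- c("HIC", "UMIC", "LMIC", "LIC")
  if (!all(grp %in% names(income_group_mix)))
    stop("income_group_mix must name HIC, UMIC, LMIC, LIC")
  income_group_mix <- income_group_mix[grp]
  if (abs(sum(income_group_mix) - 1) > 1e-9)
    stop("income_group_mix fractions must sum to 1")
  structure(list(n_countries = as.integer(n_countries),
                 years = as.integer(years),
                 age_groups = age_groups,
                 income_group_mix = income_group_mix,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Age-period-cohort ground truth
#'
#' Holds the log-linear rate structure
#' \eqn{\log \lambda_{ij} = \mu + \alpha_i + \beta_j + \gamma_k}
#' with the standard cohort index \eqn{k = (n_{age} - i) + j}. Constrained
#' effect vectors are centred to sum to zero.
#'
#' @param mu Intercept on the log-rate scale.
#' @param alpha,beta,gamma Age, period and cohort effect vectors;
#'   \code{length(gamma)} must equal
#'   \code{length(alpha) + length(beta) - 1}.
#' @param center Logical flags (recycled to 3) choosing which of
#'   alpha/beta/gamma are centred to sum to zero. Default all.
#' @return An object of class \code{"apc_truth"}.
#' @export
apc_truth <- function(mu, alpha, beta, gamma = NULL, center = TRUE) {
  na <- length(alpha); np <- length(beta)
  if (is.null(gamma)) gamma <- numeric(na + np - 1)
  if (length(gamma) != na + np - 1)
    stop("length(gamma) must equal n_age + n_period - 1")
  center <- rep_len(center, 3)
  if (center[1]) alpha <- alpha - mean(alpha)
  if (center[2]) beta <- beta - mean(beta)
  if (center[3]) gamma <- gamma - mean(gamma)
  structure(list(mu = mu, alpha = alpha, beta = beta, gamma = gamma,
                 centered = center),
            class = "apc_truth")
}

# Log-rate grid (age x period) implied by an apc_truth.
apc_log_rate_grid <- function(truth) {
  na <- length(truth$alpha); np <- length(truth$beta)
  k <- outer(seq_len(na), seq_len(np), function(i, j) (na - i) + j)
  truth$mu + outer(truth$alpha, truth$beta, "+") +
    matrix(truth$gamma[k], na, np)
}

# Run code with a private RNG stream; global random state is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Poisson draw that stays exact for small means and switches to the normal
# approximation where rpois would overflow integer storage.
rpois_safe <- function(n, lambda) {
  out <- numeric(n)
  big <- lambda > 1e7
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big))
    out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                           sqrt(lambda[big]))))
  out
}

# Smooth random effect vector: cumulated-noise random walk, centred, with an
# amplitude cap so synthetic rates stay in a plausible range.
smooth_effect <- function(n, sd_step, detrend = FALSE) {
  if (n == 1) return(0)
  x <- cumsum(stats::rnorm(n, 0, sd_step))
  if (detrend) {
    t <- seq_len(n)
    x <- stats::resid(stats::lm.fit(cbind(1, t), x))
  }
  x - mean(x)
}

#' Generate a synthetic world
#'
#' Builds the economic panel (GNI per capita with country-specific geometric
#' growth, GDP, CPI, threshold-based income classification), the demography
#' panel (population with growth, an age pyramid that ages smoothly via a
#' per-country drift, median age and remaining life expectancy at that age),
#' and per-country, per-cause age-period-cohort rate truths.
#'
#' @param config A \code{\link{world_config}}.
#' @param causes Character vector of cause labels to plant rate truths for.
#' @param growth_range Range of annual GNI-per-capita growth rates countries
#'   are drawn from.
#' @return An object of class \code{"synthetic_world"}: list with elements
#'   \code{econ}, \code{demog} (data frames), \code{pop_age} (long data frame
#'   of population by age band), \code{truth} (nested list
#'   \code{[[country]][[cause]]} of \code{\link{apc_truth}}), \code{config}.
#' @export
gen_world <- function(config = world_config(),
                      causes = c("Leukemia", "Non-Hodgkin lymphoma",
                                 "Multiple myeloma", "Hodgkin lymphoma"),
                      growth_range = c(-0.01, 0.06)) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, {
    nc <- config$n_countries
    yrs <- seq(config$years[1], config$years[2])
    ny <- length(yrs)
    ages <- config$age_groups
    na <- nrow(ages)
    country <- sprintf("C%03d", seq_len(nc))

    # starting income groups honour the configured mix
    grp_n <- diff(round(cumsum(c(0, config$income_group_mix)) * nc))
    grp_n[1] <- grp_n[1] + (nc - sum(grp_n))   # rounding remainder to HIC
    grp0 <- rep(names(config$income_group_mix), grp_n)

    # start-of-window GNI pc drawn inside each group's threshold band
    band_lo <- c(HIC = 12696, UMIC = 4096, LMIC = 1046, LIC = 250)
    band_hi <- c(HIC = 90000, UMIC = 12695, LMIC = 4095, LIC = 1045)
    gnipc0 <- exp(stats::runif(nc, log(band_lo[grp0]), log(band_hi[grp0])))
    growth <- stats::runif(nc, growth_range[1], growth_range[2])

    pop0 <- exp(stats::rnorm(nc, log(1e7), 0.9))
    pop_growth <- stats::rnorm(nc, 0.012, 0.008)
    # pyramid steepness: larger d = younger population; d shrinks over time
    d0 <- stats::runif(nc, 0.02, 0.06)
    aging_drift <- stats::runif(nc, 0, 0.015)
    e0 <- stats::runif(nc, 62, 84)             # life expectancy at birth

    econ <- demog <- vector("list", nc)
    pop_age <- vector("list", nc)
    truth <- vector("list", nc); names(truth) <- country
    for (c_i in seq_len(nc)) {
      t_rel <- yrs - yrs[1]
      gnipc <- gnipc0[c_i] * (1 + growth[c_i])^t_rel
      pop <- pop0[c_i] * exp(pop_growth[c_i] * t_rel)
      cpi <- 100 * 1.02^(yrs - 2021)
      d_t <- pmax(d0[c_i] * exp(-aging_drift[c_i] * t_rel), 0.005)
      shares <- vapply(d_t, function(d) {
        w <- exp(-d * ages$midpoint); w / sum(w)
      }, numeric(na))                          # na x ny
      med_age <- apply(shares, 2, function(s) {
        cum <- cumsum(s)
        i <- which(cum >= 0.5)[1]
        lo <- ages$midpoint[i] - 2.5
        lo + 5 * (0.5 - c(0, cum)[i]) / s[i]
      })
      le_med <- pmax(e0[c_i] + 0.02 * t_rel - 0.72 * med_age, 3)
      econ[[c_i]] <- data.frame(
        country = country[c_i], year = yrs, gnipc = gnipc,
        gdp = gnipc * pop, cpi = cpi,
        income_group = income_group_from_gni(gnipc),
        stringsAsFactors = FALSE)
      demog[[c_i]] <- data.frame(
        country = country[c_i], year = yrs, population = pop,
        median_age = med_age, le_at_median_age = le_med,
        stringsAsFactors = FALSE)
      pop_age[[c_i]] <- data.frame(
        country = country[c_i],
        year = rep(yrs, each = na),
        age = rep(ages$age, ny),
        population = as.vector(shares) * rep(pop, each = na),
        stringsAsFactors = FALSE)
      tr <- vector("list", length(causes)); names(tr) <- causes
      for (cause in causes) {
        # baseline log DALY rate per person-year, age-increasing profile
        mu <- stats::rnorm(1, log(2e-3), 0.5)
        alpha <- 0.045 * (ages$midpoint - mean(ages$midpoint)) +
          smooth_effect(na, 0.05)
        beta <- smooth_effect(ny, 0.01)
        gamma <- smooth_effect(na + ny - 1, 0.01, detrend = TRUE)
        tr[[cause]] <- apc_truth(mu, alpha, beta, gamma)
      }
      truth[[c_i]] <- tr
    }
    structure(list(econ = do.call(rbind, econ),
                   demog = do.call(rbind, demog),
                   pop_age = do.call(rbind, pop_age),
                   truth = truth,
                   config = config),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d countries, %d-%d, %d age bands\n",
              x$config$n_countries, x$config$years[1], x$config$years[2],
              nrow(x$config$age_groups)))
  cat("  income groups at start:",
      paste(names(table(x$econ$income_group[x$econ$year == x$config$years[1]])),
            table(x$econ$income_group[x$econ$year == x$config$years[1]]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sample an age x period count grid from an APC truth
#'
#' Independent Poisson draws with mean \code{exposure * exp(log-rate)}.
#'
#' @param truth An \code{\link{apc_truth}}.
#' @param exposure Positive matrix of person-years, dimensions
#'   \code{n_age x n_period}.
#' @param seed Integer seed.
#' @return Integer-valued matrix of counts, same dimensions as
#'   \code{exposure}.
#' @export
gen_apc_counts <- function(truth, exposure, seed = 1L) {
  stopifnot(inherits(truth, "apc_truth"))
  lr <- apc_log_rate_grid(truth)
  if (!all(dim(exposure) == dim(lr)))
    stop(sprintf("exposure must be %d x %d to match the truth grid",
                 nrow(lr), ncol(lr)))
  if (any(exposure <= 0)) stop("exposure must be strictly positive")
  mu <- exposure * exp(lr)
  with_seed(seed,
    matrix(rpois_safe(length(mu), as.vector(mu)), nrow(mu), ncol(mu),
           dimnames = dimnames(exposure)))
}

#' Generate a GBD-results-style DALY table for one cause
#'
#' Age-specific expected DALYs are \code{population x exp(mu + alpha + beta +
#' gamma)} from the world's planted truth, sampled with Poisson noise;
#' uncertainty bounds are a symmetric multiplicative band around the draw.
#'
#' @param world A \code{\link{gen_world}} result.
#' @param cause Cause label present in the world's truth.
#' @param ui_halfwidth_frac Half-width of the uncertainty interval as a
#'   fraction of the point estimate (default 0.1).
#' @param seed Integer seed (default: derived from the world config seed).
#' @return Data frame in the GBD results dialect: columns \code{measure},
#'   \code{location}, \code{sex}, \code{age}, \code{cause}, \code{metric},
#'   \code{year}, \code{val}, \code{upper}, \code{lower}.
#' @export
gen_daly_table <- function(world, cause, ui_halfwidth_frac = 0.1,
                           seed = world$config$seed + 1000L) {
  stopifnot(inherits(world, "synthetic_world"))
  if (ui_halfwidth_frac < 0 || ui_halfwidth_frac >= 1)
    stop("ui_halfwidth_frac must lie in [0, 1)")
  countries <- names(world$truth)
  if (!cause %in% names(world$truth[[1]]))
    stop("unknown cause: ", cause)
  yrs <- seq(world$config$years[1], world$config$years[2])
  ages <- world$config$age_groups
  na <- nrow(ages); ny <- length(yrs)
  with_seed(seed, {
    out <- vector("list", length(countries))
    for (ci in seq_along(countries)) {
      co <- countries[ci]
      pa <- world$pop_age[world$pop_age$country == co, ]
      # pop_age rows are ordered year-major, age within year
      pop <- matrix(pa$population[order(match(pa$year, yrs),
                                        match(pa$age, ages$age))],
                    na, ny)
      lambda <- pop * exp(apc_log_rate_grid(world$truth[[co]][[cause]]))
      val <- rpois_safe(length(lambda), as.vector(lambda))
      out[[ci]] <- data.frame(
        measure = "DALYs (Disability-Adjusted Life Years)",
        location = co, sex = "Both",
        age = rep(ages$age, ny), cause = cause, metric = "Number",
        year = rep(yrs, each = na),
        val = val,
        upper = val * (1 + ui_halfwidth_frac),
        lower = val * (1 - ui_halfwidth_frac),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
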