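# Deterministic scenario projection of DALY rates, and projection of the
# monetized burden to future years. The scenario engine and the Bayesian APC
# engine (see bapc()) are alternatives, never combined.

#' Projection scenario
#'
#' The three reference scenarios: \code{baseline} holds age-specific rates
#' constant at anchor-year levels; \code{negative} raises them 1\% per year;
#' \code{positive} lowers them 1\% per year.
#'
#' @param name One of \code{"baseline"}, \code{"negative"},
#'   \code{"positive"}.
#' @param anchor_year Year the scenario is anchored to (default 2021).
#' @return Object of class \code{"scenario_spec"} with fields \code{name},
#'   \code{multiplier} (1.00 / 1.01 / 0.99) and \code{anchor_year}.
#' @export
scenario_spec <- function(name = c("baseline", "negative", "positive"),
                          anchor_year = 2021) {
  name <- match.arg(name)
  mult <- c(baseline = 1.00, negative = 1.01, positive = 0.99)[[name]]
  structure(list(name = name, multiplier = mult,
                 anchor_year = as.integer(anchor_year)),
            class = "scenario_spec")
}

#' Project age-specific rates under a scenario
#'
#' @param rates_anchor Age-rate vector at the anchor year.
#' @param spec A \code{\link{scenario_spec}}.
#' @param year Target year (>= anchor year); vectorisation is over ages,
#'   not years.
#' @return \code{rates_anchor * multiplier^(year - anchor_year)}.
#' @export
scenario_rates <- function(rates_anchor, spec, year) {
  stopifnot(inherits(spec, "scenario_spec"), length(year) == 1)
  if (year < spec$anchor_year)
    stop("year must not precede the scenario anchor year")
  rates_anchor * spec$multiplier^(year - spec$anchor_year)
}

#' Project monetized burden to future years
#'
#' Combines projected age-specific DALY rates, a population projection and
#' projected VSLY values into discounted burden:
#' \deqn{DALY_t = \sum_a pop_{a,t} \, rate_{a,t}, \qquad
#'   burden_t = DALY_t \times VSLY_t / (1 + d)^{t - base}.}
#'
#' @param rates_by_year Data frame (\code{year}, \code{age}, \code{rate}).
#' @param population_projection Data frame (\code{year}, \code{age},
#'   \code{population}).
#' @param vsly_by_year Data frame (\code{year}, \code{vsly}); VSLY in
#'   nominal (undiscounted) year-\code{t} dollars.
#' @param params A \code{\link{vsl_params}} supplying the discount rate and
#'   base year.
#' @param years Projection years to report (default 2030, 2040, 2050).
#' @return Data frame (\code{year}, \code{dalys}, \code{burden}) with burden
#'   discounted to base-year dollars.
#' @export
project_burden <- function(rates_by_year, population_projection,
                           vsly_by_year, params = vsl_params(),
                           years = c(2030, 2040, 2050)) {
  out <- lapply(years, function(t) {
    r <- rates_by_year[rates_by_year$year == t, ]
    p <- population_projection[population_projection$year == t, ]
    v <- vsly_by_year$vsly[vsly_by_year$year == t]
    if (!nrow(r) || !nrow(p) || length(v) != 1)
      stop("missing projection inputs for year ", t)
    idx <- match(r$age, p$age)
    if (anyNA(idx)) stop("age bands of rates and population disagree in ", t)
    dal <- sum(p$population[idx] * r$rate)
    data.frame(year = t, dalys = dal,
               burden = discount_to_base(dal * v, t, params))
  })
  do.call(rbind, out)
}
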