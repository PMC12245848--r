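# Shapley decomposition of the change in monetized burden between two years
# into VSLY change, population growth, population aging and epidemiological
# (rate) change, using the burden identity C = sum_a P * s_a * r_a * V.

#' Factor state for burden decomposition
#'
#' One country's burden at one point in time, factored as total population
#' \code{P}, age-structure shares \code{s} (summing to 1), age-specific DALY
#' rates \code{r} (DALYs per person-year) and VSLY \code{V}, so that burden
#' is \eqn{C = \sum_a P s_a r_a V}.
#'
#' @param P Total population (> 0).
#' @param s Age-structure fractions, summing to 1.
#' @param r Age-specific DALY rates (>= 0), same length as \code{s}.
#' @param V VSLY in base-year dollars (> 0).
#' @return An object of class \code{"factor_state"}.
#' @export
factor_state <- function(P, s, r, V) {
  if (length(s) != length(r))
    stop("age-structure s and rate vector r must have equal length")
  if (abs(sum(s) - 1) > 1e-9) stop("age-structure fractions must sum to 1")
  if (P <= 0 || V <= 0 || any(r < 0))
    stop("need P > 0, V > 0, r >= 0")
  structure(list(P = P, s = s, r = r, V = V), class = "factor_state")
}

#' Burden implied by a factor state
#'
#' @param state A \code{\link{factor_state}}.
#' @return Money: \code{sum(P * s * r * V)}.
#' @export
burden_from_factors <- function(state) {
  stopifnot(inherits(state, "factor_state"))
  sum(state$P * state$s * state$r * state$V)
}

# Human-readable factor labels used in results.
.factor_labels <- c(V = "VSLY", P = "Population growth",
                    s = "Population aging", r = "Epidemiological change")

#' Exact Shapley decomposition of a burden change
#'
#' Attributes the change in burden between two factor states to each factor
#' as its marginal contribution averaged over all orderings in which factors
#' flip from the first state to the second. Computed by exact subset
#' enumeration (2^m cost evaluations with Shapley weights), equivalent to
#' averaging over all m! orderings; additive and order-independent by
#' construction.
#'
#' @param state_0,state_1 \code{\link{factor_state}} objects for the start
#'   and end points.
#' @param factors Character subset of \code{c("V","P","s","r")} to decompose
#'   over; factors omitted are held at \code{state_0}. Default all four.
#' @return An object of class \code{"decomposition_result"}: list with
#'   \code{table} (data frame: factor, absolute, percent), \code{grouped}
#'   (VSLY vs DALYs rollup), \code{total_change}, \code{degenerate} (TRUE
#'   when the total change is numerically zero so percentages are undefined).
#' @examples
#' s0 <- factor_state(1e6, 1, 0.001, 50000)
#' s1 <- factor_state(2e6, 1, 0.001, 50000)
#' shapley_decompose(s0, s1)   # all change attributed to population growth
#' @export
shapley_decompose <- function(state_0, state_1,
                              factors = c("V", "P", "s", "r")) {
  stopifnot(inherits(state_0, "factor_state"),
            inherits(state_1, "factor_state"))
  factors <- match.arg(factors, several.ok = TRUE)
  if (length(state_0$s) != length(state_1$s))
    stop("states must share the age grid")
  m <- length(factors)
  if (m > 6) stop("exact enumeration supports at most 6 factors")

  cost_of <- function(mask) {                 # mask: logical over factors
    st <- state_0
    for (i in which(mask)) st[[factors[i]]] <- state_1[[factors[i]]]
    sum(st$P * st$s * st$r * st$V)
  }
  n_sub <- 2^m
  costs <- vapply(seq_len(n_sub) - 1L, function(code) {
    cost_of(as.logical(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0))
  }, numeric(1))

  fact <- factorial(0:m)
  contrib <- numeric(m); names(contrib) <- factors
  for (f in seq_len(m)) {
    bit_f <- 2^(f - 1L)
    for (code in seq_len(n_sub) - 1L) {
      if (bitwAnd(code, bit_f) > 0) next     # subsets not containing f
      size <- sum(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0)
      w <- fact[size + 1L] * fact[m - size] / fact[m + 1L]
      contrib[f] <- contrib[f] +
        w * (costs[code + bit_f + 1L] - costs[code + 1L])
    }
  }
  total <- costs[n_sub] - costs[1L]
  degenerate <- abs(total) <= 1e-9 * max(abs(costs[1L]), abs(costs[n_sub]), 1)
  pct <- if (degenerate) rep(NA_real_, m) else 100 * contrib / total
  tab <- data.frame(factor = unname(.factor_labels[factors]),
                    absolute = unname(contrib), percent = unname(pct),
                    stringsAsFactors = FALSE)
  daly_f <- intersect(factors, c("P", "s", "r"))
  grouped <- data.frame(
    group = c("VSLY", "DALYs"),
    absolute = c(if ("V" %in% factors) contrib[["V"]] else 0,
                 sum(contrib[daly_f])),
    stringsAsFactors = FALSE)
  grouped$percent <- if (degenerate) NA_real_ else
    100 * grouped$absolute / total
  structure(list(table = tab, grouped = grouped, total_change = total,
                 degenerate = degenerate),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, digits = 2, ...) {
  cat("Shapley decomposition of burden change\n")
  cat(sprintf("  Total cost change: %.6g%s\n", x$total_change,
              if (x$degenerate) "  (degenerate: ~0, percentages undefined)"
              else ""))
  tab <- x$table
  tab$absolute <- signif(tab$absolute, 6)
  tab$percent <- round(tab$percent, digits)
  print(tab, row.names = FALSE)
  cat("Grouped rollup:\n")
  g <- x$grouped
  g$absolute <- signif(g$absolute, 6); g$percent <- round(g$percent, digits)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Aggregate per-country decompositions globally
#'
#' Sums absolute contributions across countries; global percentages are the
#' summed contributions over the summed total change.
#'
#' @param results Non-empty list of \code{\link{shapley_decompose}} results
#'   sharing the same factor set.
#' @return A \code{decomposition_result} for the aggregate.
#' @export
aggregate_decomposition <- function(results) {
  if (!length(results)) stop("empty list of decomposition results")
  stopifnot(all(vapply(results, inherits, logical(1),
                       "decomposition_result")))
  fac <- results[[1]]$table$factor
  if (!all(vapply(results, function(r) identical(r$table$factor, fac),
                  logical(1))))
    stop("all results must share the same factor set")
  absolute <- Reduce(`+`, lapply(results, function(r) r$table$absolute))
  g_abs <- Reduce(`+`, lapply(results, function(r) r$grouped$absolute))
  total <- sum(vapply(results, `[[`, numeric(1), "total_change"))
  scale0 <- max(vapply(results, function(r) abs(r$total_change), numeric(1)), 1)
  degenerate <- abs(total) <= 1e-9 * scale0
  tab <- data.frame(factor = fac, absolute = absolute,
                    percent = if (degenerate) NA_real_ else
                      100 * absolute / total,
                    stringsAsFactors = FALSE)
  grouped <- data.frame(group = results[[1]]$grouped$group,
                        absolute = g_abs,
                        percent = if (degenerate) NA_real_ else
                          100 * g_abs / total,
                        stringsAsFactors = FALSE)
  structure(list(table = tab, grouped = grouped, total_change = total,
                 degenerate = degenerate),
            class = "decomposition_result")
}

#' Factor states for a country from pipeline tables
#'
#' Convenience constructor: extracts P, s, r, V for one country and year from
#' the age-resolved population table, a DALY table and a VSLY table. Rates
#' are observed DALYs per person-year by age band.
#'
#' @param country Country/location label.
#' @param year Year.
#' @param pop_age Data frame (\code{country}, \code{year}, \code{age},
#'   \code{population}).
#' @param dalys GBD-dialect DALY table (summed within age bands if repeated).
#' @param vsly VSLY table.
#' @param cause Optional cause filter for \code{dalys}.
#' @return A \code{\link{factor_state}}.
#' @export
factor_state_from_tables <- function(country, year, pop_age, dalys, vsly,
                                     cause = NULL) {
  pa <- pop_age[pop_age$country == country & pop_age$year == year, ]
  if (!nrow(pa)) stop("no population rows for ", country, " ", year)
  d <- dalys[dalys$location == country & dalys$year == year, ]
  if (!is.null(cause)) d <- d[d$cause == cause, ]
  if (!nrow(d)) stop("no DALY rows for ", country, " ", year)
  dal <- tapply(d$val, d$age, sum)[pa$age]
  dal[is.na(dal)] <- 0
  v <- vsly$vsly[vsly$country == country & vsly$year == year]
  if (length(v) != 1) stop("need exactly one VSLY row for ", country, " ", year)
  P <- sum(pa$population)
  factor_state(P = P, s = pa$population / P,
               r = as.numeric(dal) / pa$population, V = v)
}
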