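# Shared fixture builders: tiny synthetic worlds and APC truths used across
# the suite. Everything is built in code at test time.

tiny_world <- function(n_countries = 4, years = c(2010, 2021), seed = 42,
                       n_age = 6, ...) {
  gen_world(world_config(n_countries = n_countries, years = years,
                         age_groups = hemecon:::default_age_groups(n_age),
                         seed = seed), ...)
}

# Smooth APC truth on an n_age x n_period grid: linear-plus-curvature age
# profile, mild period drift, detrended sinusoid cohort effect.
smooth_truth <- function(n_age = 10, n_period = 20, mu = -7) {
  i <- seq_len(n_age); j <- seq_len(n_period)
  alpha <- 0.3 * (i - mean(i)) / n_age + 0.02 * ((i - mean(i)) / n_age)^2
  beta <- 0.015 * (j - mean(j))
  K <- n_age + n_period - 1
  g <- 0.1 * sin(seq(0, 3, length.out = K))
  g <- stats::residuals(stats::lm(g ~ seq_len(K)))
  apc_truth(mu, alpha, beta, g)
}

# Brute-force Shapley oracle: average marginal contribution over all m!
# orderings, computed directly from the burden identity. Independent of the
# subset-enumeration implementation.
shapley_oracle <- function(state_0, state_1, factors = c("V", "P", "s", "r")) {
  m <- length(factors)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  cost <- function(flipped) {
    st <- state_0
    for (f in flipped) st[[f]] <- state_1[[f]]
    sum(st$P * st$s * st$r * st$V)
  }
  contrib <- stats::setNames(numeric(m), factors)
  all_p <- perms(factors)
  for (p in all_p) {
    for (pos in seq_len(m)) {
      before <- p[seq_len(pos - 1)]
      contrib[p[pos]] <- contrib[p[pos]] +
        (cost(c(before, p[pos])) - cost(before))
    }
  }
  contrib / length(all_p)
}

random_factor_state <- function(n_age = 3) {
  s <- stats::runif(n_age); s <- s / sum(s)
  factor_state(P = stats::runif(1, 1e5, 1e7), s = s,
               r = stats::runif(n_age, 1e-4, 1e-2),
               V = stats::runif(1, 1e4, 1e6))
}
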