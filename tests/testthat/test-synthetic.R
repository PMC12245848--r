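test_that("world generation is deterministic given the seed and respects config", {
  w1 <- tiny_world(seed = 7)
  w2 <- tiny_world(seed = 7)
  expect_identical(w1$econ, w2$econ)
  expect_identical(w1$demog, w2$demog)
  expect_identical(w1$truth, w2$truth)
  w3 <- tiny_world(seed = 8)
  expect_false(identical(w1$econ$gnipc, w3$econ$gnipc))

  # every econ country-year has demography; positive quantities
  expect_setequal(paste(w1$econ$country, w1$econ$year),
                  paste(w1$demog$country, w1$demog$year))
  expect_true(all(w1$econ$gnipc > 0))
  expect_true(all(w1$econ$gdp > 0))
  expect_true(all(w1$demog$population > 0))
})

test_that("zero growth yields constant GNI series", {
  w <- tiny_world(n_countries = 3, growth_range = c(0, 0))
  for (co in unique(w$econ$country)) {
    g <- w$econ$gnipc[w$econ$country == co]
    expect_equal(g, rep(g[1], length(g)))
  }
})

test_that("income-group assignment is a monotone step function of GNI", {
  g <- c(500, 1045, 1046, 4095, 4096, 12695, 12696, 60000)
  expect_equal(income_group_from_gni(g),
               c("LIC", "LIC", "LMIC", "LMIC", "UMIC", "UMIC", "HIC", "HIC"))
  x <- sort(exp(runif(100, log(200), log(1e5))))
  grp <- factor(income_group_from_gni(x),
                levels = c("LIC", "LMIC", "UMIC", "HIC"), ordered = TRUE)
  expect_true(!is.unsorted(grp))
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_countries = 0), "n_countries")
  expect_error(world_config(years = c(2020, 2020)), "years")
  expect_error(world_config(income_group_mix = c(HIC = 0.5, UMIC = 0.5,
                                                 LMIC = 0.2, LIC = 0.1)),
               "sum to 1")
  w <- tiny_world()
  expect_error(gen_daly_table(w, "NoSuchCause"), "unknown cause")
})

test_that("DALY table UI bounds bracket the point and degenerate UI collapses", {
  w <- tiny_world()
  d <- gen_daly_table(w, "Leukemia", ui_halfwidth_frac = 0.1)
  expect_true(all(d$lower <= d$val & d$val <= d$upper))
  expect_true(all(d$val >= 0))
  d0 <- gen_daly_table(w, "Leukemia", ui_halfwidth_frac = 0)
  expect_equal(d0$lower, d0$val)
  expect_equal(d0$upper, d0$val)
})

test_that("null APC truth gives expected DALYs = rate x population", {
  # all effects 0, mu = log r: empirical mean over replicate draws must sit
  # within 3 standard errors of r x population
  w <- tiny_world(n_countries = 1, years = c(2018, 2021), n_age = 4)
  r <- 1e-3
  w$truth[["C001"]] <- list(flat = apc_truth(log(r),
                                             numeric(4), numeric(4)))
  total_pop <- sum(w$pop_age$population)
  expected <- r * total_pop
  tot <- vapply(1:200, function(s)
    sum(gen_daly_table(w, "flat", seed = s)$val), numeric(1))
  se <- sqrt(expected / 200)   # Poisson variance of the per-replicate total
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("APC count grids are Poisson with mean exposure x rate", {
  tr <- apc_truth(log(0.01), numeric(5), numeric(10))
  ex <- matrix(1000, 5, 10)
  cnt <- gen_apc_counts(tr, ex, seed = 1)
  expect_identical(cnt, gen_apc_counts(tr, ex, seed = 1))  # reproducible
  expect_true(all(cnt >= 0))

  # mean count over many cells ~ 10 with sd sqrt(10/n)
  tr2 <- apc_truth(log(0.01), numeric(20), numeric(50))
  big <- gen_apc_counts(tr2, matrix(1000, 20, 50), seed = 2)
  expect_lt(abs(mean(big) - 10), 1)

  # doubling exposure doubles the expected count
  m1 <- mean(gen_apc_counts(tr2, matrix(1000, 20, 50), seed = 3))
  m2 <- mean(gen_apc_counts(tr2, matrix(2000, 20, 50), seed = 3))
  expect_lt(abs(m2 / m1 - 2), 0.1)

  # vanishing exposure drives counts to zero
  tiny <- gen_apc_counts(tr2, matrix(1e-8, 20, 50), seed = 4)
  expect_true(all(tiny == 0))

  expect_error(gen_apc_counts(tr, matrix(1, 3, 3)), "exposure must be")
  expect_error(gen_apc_counts(tr, matrix(0, 5, 10)), "positive")
})

test_that("constrained truth effects are centred and cohort length matches", {
  tr <- apc_truth(1, rnorm(6), rnorm(9), rnorm(14))
  expect_equal(sum(tr$alpha), 0, tolerance = 1e-9)
  expect_equal(sum(tr$beta), 0, tolerance = 1e-9)
  expect_equal(sum(tr$gamma), 0, tolerance = 1e-9)
  expect_error(apc_truth(1, rnorm(6), rnorm(9), rnorm(10)), "n_age")
})
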