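p <- vsl_params()

make_daly_row <- function(country, year, val, cause = "HM",
                          frac = 0) {
  data.frame(measure = "DALYs (Disability-Adjusted Life Years)",
             location = country, sex = "Both", age = "All ages",
             cause = cause, metric = "Number", year = year, val = val,
             upper = val * (1 + frac), lower = val * (1 - frac),
             stringsAsFactors = FALSE)
}

make_vsly_row <- function(country, year, vsly) {
  data.frame(country = country, year = year, vsl = vsly * 40,
             remaining_life_years = 40, vsly = vsly,
             stringsAsFactors = FALSE)
}

test_that("monetization prices one DALY at one VSLY with discounting", {
  d <- make_daly_row("A", 2021, 1000)
  v <- make_vsly_row("A", 2021, 50000)
  expect_equal(monetize(d, v, p)$burden, 5e7)
  expect_equal(monetize(make_daly_row("A", 2021, 0), v, p)$burden, 0)
  d22 <- make_daly_row("A", 2022, 1000)
  v22 <- make_vsly_row("A", 2022, 50000)
  expect_equal(monetize(d22, v22, p)$burden, 5e7 / 1.03)
  expect_error(monetize(d, make_vsly_row("B", 2021, 1), p), "missing VSLY")
})

test_that("monetization propagates DALY uncertainty bounds multiplicatively", {
  d <- make_daly_row("A", 2021, 1000, frac = 0.2)
  b <- monetize(d, make_vsly_row("A", 2021, 50000), p)
  expect_equal(b$lower, 0.8 * b$burden)
  expect_equal(b$upper, 1.2 * b$burden)
})

test_that("monetization is bilinear: scaling DALYs scales burden, shares invariant", {
  w <- tiny_world()
  d <- gen_daly_table(w, "Leukemia")
  v <- build_vsly_table(w$econ, w$demog, p)
  b1 <- monetize(d, v, p)
  d3 <- d; d3$val <- 3 * d3$val; d3$lower <- 3 * d3$lower
  d3$upper <- 3 * d3$upper
  b3 <- monetize(d3, v, p)
  expect_equal(b3$burden, 3 * b1$burden)
  g1 <- aggregate_burden(b1, "country", year = 2021)
  g3 <- aggregate_burden(b3, "country", year = 2021)
  expect_equal(share_of_total(g3$burden, sum(g3$burden)),
               share_of_total(g1$burden, sum(g1$burden)))
})

test_that("aggregation is additive over exhaustive partitions", {
  w <- tiny_world()
  d <- gen_daly_table(w, "Leukemia")
  v <- build_vsly_table(w$econ, w$demog, p)
  b <- monetize(d, v, p)
  glob <- aggregate_burden(b, "global", year = 2021)$burden
  by_c <- aggregate_burden(b, "country", year = 2021)
  by_g <- aggregate_burden(b, "income_group", year = 2021, econ = w$econ)
  expect_equal(sum(by_c$burden), glob)
  expect_equal(sum(by_g$burden), glob)
  expect_equal(sum(share_of_total(by_g$burden, glob)), 100, tolerance = 0.1)
})

test_that("planted group totals are recovered exactly", {
  # four countries, one per income group, with preset burdens
  d <- do.call(rbind, lapply(1:4, function(i)
    make_daly_row(paste0("C", i), 2021, i * 100)))
  v <- do.call(rbind, lapply(1:4, function(i)
    make_vsly_row(paste0("C", i), 2021, 1000)))
  econ <- data.frame(country = paste0("C", 1:4), year = 2021,
                     income_group = c("HIC", "UMIC", "LMIC", "LIC"))
  b <- monetize(d, v, p)
  got <- aggregate_burden(b, "income_group", year = 2021, econ = econ)
  expect_equal(got$burden[match(c("HIC", "UMIC", "LMIC", "LIC"),
                                got$income_group)],
               c(1, 2, 3, 4) * 1e5)
  one <- aggregate_burden(b[b$country == "C1", ], "global")
  expect_equal(one$burden,
               aggregate_burden(b[b$country == "C1", ], "country")$burden)
})

test_that("percent change and shares are plain signed arithmetic", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 50), -50)
  expect_equal(share_of_total(50, 50), 100)
  expect_error(percent_change(0, 10), "positive")
  expect_error(share_of_total(10, 0), "positive")
})

test_that("GDP share is the plain ratio", {
  expect_equal(gdp_share(5, 5), 1)
  expect_equal(gdp_share(0, 5), 0)
  expect_error(gdp_share(1, 0), "positive")
  # planted world: burden one percent of GDP
  gdp <- 3e12
  expect_equal(gdp_share(0.01 * gdp, gdp), 0.01)
})

test_that("quintile bins split at the empirical quintiles", {
  v <- setNames(1:10, paste0("c", 1:10))
  expect_equal(unname(quintile_bins(v)), rep(1:5, each = 2))
  expect_error(quintile_bins(setNames(rep(1, 6), paste0("c", 1:6))),
               "distinct")
  expect_error(quintile_bins(setNames(1:4, paste0("c", 1:4))), "at least 5")
  set.seed(9)
  big <- setNames(rnorm(204), paste0("c", 1:204))
  sizes <- table(quintile_bins(big))
  expect_true(all(sizes >= 40 & sizes <= 41))
})
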