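test_that("normal SD implied by a symmetric 95% interval", {
  expect_equal(daly_sd_from_ui(100, 100, 100), 0)
  expect_equal(daly_sd_from_ui(100, 80.4, 119.6), 39.2 / (2 * qnorm(0.975)))
  expect_equal(daly_sd_from_ui(100, 80.4, 119.6), 10, tolerance = 1e-4)
  expect_equal(daly_sd_from_ui(100, 60.8, 139.2),
               2 * daly_sd_from_ui(100, 80.4, 119.6))
  expect_error(daly_sd_from_ui(100, 120, 80), "lower <= point")
})

test_that("percentile interval uses inclusive linear interpolation", {
  expect_equal(ci_percentile(1:1000, 0.95),
               c(lower = 25.975, upper = 975.025))
  expect_equal(unname(diff(ci_percentile(rep(7, 10), 0.95))), 0)
  s <- rnorm(500)
  w90 <- diff(ci_percentile(s, 0.90))
  w99 <- diff(ci_percentile(s, 0.99))
  expect_gte(w99, w90)
  expect_error(ci_percentile(1, 0.95), "at least 2")
})

boot_fixture <- function(n_countries = 3, frac = 0.2, vsly = 5e4) {
  co <- paste0("C", seq_len(n_countries))
  d <- data.frame(measure = "DALYs (Disability-Adjusted Life Years)",
                  location = rep(co, each = 2), sex = "Both",
                  age = rep(c("0-49", "50+"), n_countries), cause = "HM",
                  metric = "Number", year = 2021,
                  val = rep(c(1000, 2000), n_countries),
                  stringsAsFactors = FALSE)
  d$upper <- d$val * (1 + frac); d$lower <- d$val * (1 - frac)
  v <- data.frame(country = co, year = 2021, vsl = vsly * 40,
                  remaining_life_years = 40, vsly = vsly)
  list(d = d, v = v)
}

test_that("degenerate bootstrap collapses to the point estimate", {
  f <- boot_fixture(frac = 0)
  cfg <- bootstrap_config(n_reps = 50, vsly_halfwidth = 0, seed = 3)
  out <- bootstrap_burden(f$d, f$v, cfg)
  expect_equal(out$ci_lower, out$estimate)
  expect_equal(out$ci_upper, out$estimate)
  expect_equal(out$estimate, 3 * 3000 * 5e4)
})

test_that("bootstrap is reproducible and scale-equivariant", {
  f <- boot_fixture()
  cfg <- bootstrap_config(n_reps = 200, seed = 11)
  a <- bootstrap_burden(f$d, f$v, cfg)
  b <- bootstrap_burden(f$d, f$v, cfg)
  expect_identical(a, b)
  v2 <- f$v; v2$vsly <- 2 * v2$vsly
  dbl <- bootstrap_burden(f$d, v2, cfg)
  expect_equal(dbl$estimate, 2 * a$estimate)
  expect_equal(dbl$ci_lower, 2 * a$ci_lower)
  expect_equal(dbl$ci_upper, 2 * a$ci_upper)
})

test_that("interval width grows with both uncertainty sources", {
  f <- boot_fixture()
  width <- function(h, frac = 0.2) {
    d <- f$d; d$upper <- d$val * (1 + frac); d$lower <- d$val * (1 - frac)
    cfg <- bootstrap_config(n_reps = 400, vsly_halfwidth = h, seed = 17)
    out <- bootstrap_burden(d, f$v, cfg)
    out$ci_upper - out$ci_lower
  }
  expect_gt(width(0.2), width(0.05))     # VSLY half-width
  expect_gt(width(0, 0.3), width(0, 0.1))  # DALY UI width
})

test_that("strata split the burden and empty strata are impossible", {
  f <- boot_fixture(n_countries = 4)
  strata <- setNames(c("HIC", "HIC", "LIC", "LIC"), paste0("C", 1:4))
  cfg <- bootstrap_config(n_reps = 100, seed = 5)
  out <- bootstrap_burden(f$d, f$v, cfg, strata = strata)
  expect_setequal(out$stratum, c("HIC", "LIC"))
  expect_equal(sum(out$estimate), 4 * 3000 * 5e4)
  expect_true(all(out$ci_lower <= out$estimate &
                    out$estimate <= out$ci_upper))
})

test_that("bootstrap intervals bracket the point estimate across worlds", {
  set.seed(23)
  ok <- vapply(1:50, function(i) {
    f <- boot_fixture(frac = runif(1, 0.05, 0.3))
    cfg <- bootstrap_config(n_reps = 200, seed = i)
    out <- bootstrap_burden(f$d, f$v, cfg)
    out$ci_lower <= out$estimate && out$estimate <= out$ci_upper
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("configuration invariants are enforced", {
  expect_error(bootstrap_config(n_reps = 1), "n_reps")
  expect_error(bootstrap_config(vsly_halfwidth = 1), "halfwidth")
  expect_error(bootstrap_config(ci_level = 1), "ci_level")
})
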