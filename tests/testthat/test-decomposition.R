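test_that("burden identity evaluates the factor product", {
  expect_equal(burden_from_factors(factor_state(1e6, 1, 0.001, 50000)), 5e7)
  expect_equal(burden_from_factors(factor_state(1e6, 1, 0, 50000)), 0)
  # collapsing two age groups with the matched aggregate rate preserves cost
  s2 <- factor_state(1e6, c(0.6, 0.4), c(0.002, 0.005), 3e4)
  r_agg <- 0.6 * 0.002 + 0.4 * 0.005
  s1 <- factor_state(1e6, 1, r_agg, 3e4)
  expect_equal(burden_from_factors(s2), burden_from_factors(s1))
  expect_error(factor_state(1e6, c(0.5, 0.5), 0.001, 5e4), "equal length")
  expect_error(factor_state(1e6, c(0.7, 0.4), c(0, 0), 5e4), "sum to 1")
})

test_that("two-factor toy matches the hand-enumerated Shapley values", {
  # C = D x V with D: 10 -> 20 and V: 5 -> 8; orderings give (50+80)/2 = 65
  # for D and (30+60)/2 = 45 for V
  s0 <- factor_state(10, 1, 1, 5)
  s1 <- factor_state(20, 1, 1, 8)
  res <- shapley_decompose(s0, s1, factors = c("P", "V"))
  expect_equal(res$total_change, 110)
  expect_equal(res$table$absolute[res$table$factor == "Population growth"], 65)
  expect_equal(res$table$absolute[res$table$factor == "VSLY"], 45)
})

test_that("an unchanged factor receives zero contribution (dummy property)", {
  s0 <- factor_state(1e6, c(0.5, 0.5), c(0.001, 0.002), 5e4)
  s1 <- factor_state(2e6, c(0.5, 0.5), c(0.001, 0.002), 5e4)
  res <- shapley_decompose(s0, s1)
  tab <- res$table
  expect_equal(tab$percent[tab$factor == "Population growth"], 100)
  others <- tab$factor != "Population growth"
  expect_equal(tab$absolute[others], rep(0, 3))

  same <- shapley_decompose(s0, s0)
  expect_true(same$degenerate)
  expect_equal(same$table$absolute, rep(0, 4))
})

test_that("efficient decomposition equals the brute-force ordering oracle", {
  set.seed(31)
  for (rep in 1:100) {
    s0 <- random_factor_state()
    s1 <- random_factor_state()
    res <- shapley_decompose(s0, s1)
    oracle <- shapley_oracle(s0, s1)
    expect_equal(unname(res$table$absolute), unname(oracle),
                 tolerance = 1e-9)
    dC <- burden_from_factors(s1) - burden_from_factors(s0)
    expect_lt(abs(sum(res$table$absolute) - dC) / max(abs(dC), 1), 1e-9)
  }
})

test_that("result is invariant under permutation of the factor list", {
  set.seed(5)
  s0 <- random_factor_state(); s1 <- random_factor_state()
  a <- shapley_decompose(s0, s1, factors = c("V", "P", "s", "r"))
  b <- shapley_decompose(s0, s1, factors = c("r", "s", "P", "V"))
  expect_equal(a$table$absolute[order(a$table$factor)],
               b$table$absolute[order(b$table$factor)])
})

test_that("grouped rollup reproduces the VSLY vs DALYs structure", {
  set.seed(6)
  s0 <- random_factor_state(); s1 <- random_factor_state()
  res <- shapley_decompose(s0, s1)
  g <- res$grouped
  expect_equal(sum(g$percent), 100, tolerance = 0.01)
  daly_pct <- sum(res$table$percent[res$table$factor != "VSLY"])
  expect_equal(g$percent[g$group == "DALYs"], daly_pct, tolerance = 0.01)
  expect_equal(sum(res$table$percent), 100, tolerance = 0.01)
})

test_that("global aggregation sums absolutes and recomputes percentages", {
  set.seed(7)
  states <- replicate(3, list(s0 = random_factor_state(),
                              s1 = random_factor_state()),
                      simplify = FALSE)
  per <- lapply(states, function(st) shapley_decompose(st$s0, st$s1))
  agg <- aggregate_decomposition(per)
  expect_equal(agg$table$absolute,
               Reduce(`+`, lapply(per, function(r) r$table$absolute)))
  expect_equal(agg$total_change,
               sum(vapply(per, `[[`, numeric(1), "total_change")))
  expect_equal(sum(agg$table$percent), 100, tolerance = 0.01)

  expect_equal(aggregate_decomposition(per[1])$table, per[[1]]$table)
  expect_error(aggregate_decomposition(list()), "empty")

  # equal and opposite country changes: global percentages undefined
  s0 <- factor_state(10, 1, 1, 5); s1 <- factor_state(20, 1, 1, 5)
  up <- shapley_decompose(s0, s1); down <- shapley_decompose(s1, s0)
  both <- aggregate_decomposition(list(up, down))
  expect_true(both$degenerate)
  expect_true(all(is.na(both$table$percent)))
})

test_that("a world where only VSLY changes attributes 100% to VSLY", {
  set.seed(8)
  per <- lapply(1:4, function(i) {
    s0 <- random_factor_state()
    s1 <- s0; s1$V <- s0$V * runif(1, 1.2, 2)
    shapley_decompose(s0, s1)
  })
  agg <- aggregate_decomposition(per)
  expect_equal(agg$table$percent[agg$table$factor == "VSLY"], 100)
  expect_equal(agg$grouped$percent, c(100, 0))
})
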