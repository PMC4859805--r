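test_that("composition distribution is the scaled binomial", {
  p <- composition_distribution(4, 2, 0.5)
  expect_equal(unname(p), c(0.25, 0, 0.5, 0, 0.25))
  expect_equal(sum(p), 1)

  # u = 1 equals brute-force enumeration over the 2^4 subunit assignments
  grid <- expand.grid(rep(list(0:1), 4))
  brute <- table(factor(rowSums(grid), levels = 0:4)) / 16
  expect_equal(unname(composition_distribution(4, 1, 0.5)),
               as.vector(brute))

  expect_equal(unname(composition_distribution(6, 2, 0)),
               c(1, rep(0, 6)))
  expect_error(composition_distribution(5, 2, 0.5), "divide")
  for (n in c(4, 6, 12)) for (u in c(1, 2)) for (f in c(0.2, 0.5, 0.9))
    expect_equal(sum(composition_distribution(n, u, f)), 1)
})

test_that("parity fraction separates dimer from monomer exchange", {
  expect_equal(parity_fraction(c(`0` = 5, `2` = 10, `4` = 5)), 1)
  p1 <- composition_distribution(4, 1, 0.5)
  expect_equal(parity_fraction(p1 * 1000), 0.5)
  expect_equal(parity_fraction(c(`1` = 7)), 0)
  expect_error(parity_fraction(c(`0` = 0, `1` = 0)), "zero")
  # under u = 2 from even pools, odd counts have probability exactly 0
  for (f in c(0.1, 0.5, 0.8)) for (n in c(4, 12, 14))
    expect_equal(parity_fraction(composition_distribution(n, 2, f)), 1)
})

test_that("likelihood ratio identifies the generating exchange unit", {
  g2 <- gen_exchange_populations(1000, n = 4, u = 2, f = 0.5, seed = 21)
  r2 <- infer_exchange_unit(g2$counts)
  expect_gt(r2$log_ratio, 0); expect_equal(r2$unit, 2L)

  g1 <- gen_exchange_populations(1000, n = 4, u = 1, f = 0.5, seed = 21)
  r1 <- infer_exchange_unit(g1$counts)
  expect_lt(r1$log_ratio, 0); expect_equal(r1$unit, 1L)

  # decision accuracy >= 95% over 100 seeded datasets for each unit
  correct <- vapply(1:100, function(s) {
    c(infer_exchange_unit(gen_exchange_populations(
        1000, 4, 2, 0.5, seed = s)$counts)$unit == 2L,
      infer_exchange_unit(gen_exchange_populations(
        1000, 4, 1, 0.5, seed = 5000 + s)$counts)$unit == 1L)
  }, logical(2))
  expect_gte(mean(correct[1, ]), 0.95)
  expect_gte(mean(correct[2, ]), 0.95)
})

test_that("dodecamer/tetradecamer interconversion moves by one dimer", {
  expect_equal(interconversion_step(12, "gain_dimer"), 14L)
  expect_equal(interconversion_step(14, "lose_dimer"), 12L)
  expect_error(interconversion_step(12, "lose_dimer"), "closed-ring")
  expect_error(interconversion_step(14, "gain_dimer"), "closed-ring")
  expect_equal(interconversion_step(6, "gain_dimer", mode = "open"), 8L)
  expect_error(interconversion_step(2, "lose_dimer", mode = "open"),
               "single-dimer")
  expect_error(interconversion_step(13, "gain_dimer", mode = "open"), "even")
})

test_that("swap simulation conserves units and converges to the binomial law", {
  pop <- oligomer_population(c(rep(2, 250), rep(0, 250)), n = 4, u = 2)
  total_long <- sum(pop$long_units)

  s0 <- simulate_exchange(pop, swaps = 0, seed = 1)
  expect_equal(s0$population$long_units, pop$long_units)

  sim <- simulate_exchange(pop, swaps = 1e5, seed = 42, record_every = 2e4)
  expect_equal(sum(sim$population$long_units), total_long)
  for (snap in sim$snapshots) {
    k <- as.integer(names(snap))
    expect_equal(sum(snap * k) / pop$u, total_long)  # long subunits / u
    expect_equal(sum(snap), 500)
  }
  # equilibrium composition ~ Binomial(2, 1/2) scaled by u = 2
  final <- composition_counts(sim$population)
  expect_equal(unname(final[c("1", "3")]), c(0L, 0L))  # parity preserved
  chi <- chisq.test(final[c("0", "2", "4")], p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})
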