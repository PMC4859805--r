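test_that("m/z series follows the electrospray relation", {
  expect_equal(mz_series(240000, 24), 10001.00728, tolerance = 1e-9)
  expect_equal(mz_series(5000, 1), 5001.00728)
  z <- 10:30
  expect_true(all(diff(mz_series(240000, z)) < 0))
  # linearity: (m/z - proton) * z is the mass
  expect_equal((mz_series(480000, 17) - 1.00728) * 17, 480000)
  expect_error(mz_series(240000, 0), "positive")
})

test_that("charge inference recovers generated envelopes and leaves
           isolated peaks unassigned", {
  sp <- data.frame(mz = mz_series(240000, 23:25), intensity = c(1, 2, 1))
  out <- infer_charges(sp, tol_ppm = 10)
  expect_equal(sort(out$charge), 23:25)
  expect_equal(out$mass, rep(240000, 3), tolerance = 1e-6)
  expect_equal(length(unique(out$species)), 1L)

  single <- data.frame(mz = 5000, intensity = 1)
  expect_true(all(is.na(infer_charges(single)$species)))
})

test_that("interleaved envelopes are separated, agreeing with brute-force
           charge enumeration", {
  sp <- gen_mass_spectrum(c(209000, 244000), c(1, 0.8), c(24, 26), seed = 5)
  dec <- deconvolve(sp, tol_ppm = 10)
  expect_equal(nrow(dec), 2L)
  expect_equal(dec$mass, c(209000, 244000), tolerance = 1e-6)
  oracle <- brute_force_species(sp, tol_ppm = 10)
  top2 <- sort(oracle$mass[1:2])
  expect_equal(dec$mass, top2, tolerance = 1e-6)
})

test_that("deconvolution round-trips the generator", {
  # noiseless: masses to < 1 ppm, equal abundances to ~1%
  sp0 <- gen_mass_spectrum(c(180000, 210000), c(1, 1), c(24, 26))
  d0 <- deconvolve(sp0, tol_ppm = 10)
  expect_equal(nrow(d0), 2L)
  expect_lt(abs(d0$mass[1] - 180000) / 180000, 1e-6)
  expect_lt(abs(d0$mass[2] - 210000) / 210000, 1e-6)
  expect_equal(d0$intensity[1] / d0$intensity[2], 1, tolerance = 0.02)

  # pure species: single assignment within tolerance
  pure <- gen_mass_spectrum(240000, 1, 24)
  dp <- deconvolve(pure, tol_ppm = 10)
  expect_equal(nrow(dp), 1L)
  expect_lt(abs(dp$mass - 240000), 1)

  # empty spectrum
  expect_equal(nrow(deconvolve(data.frame(mz = numeric(),
                                          intensity = numeric()))), 0L)
})

test_that("noisy 55:45 mixtures give the expected abundance ratio", {
  ratios <- vapply(1:15, function(s) {
    sp <- gen_mass_spectrum(c(180000, 210000), c(0.55, 0.45), c(24, 26),
                            mz_noise_ppm = 20, intensity_noise = 0.05,
                            seed = 200 + s)
    st <- ms_stoichiometry(sp, m_subunit = 15000, tol_ppm = 100)
    abundance_ratio(st, 12, 14)
  }, numeric(1))
  expect_equal(median(ratios), 55 / 45, tolerance = 0.05)
})

test_that("stoichiometry assignment resolves subunit and missing-tag counts", {
  m_sub <- 17419.5; m_tag <- 2014
  expect_equal(assign_stoichiometry(2 * m_sub, m_sub, m_tag, tol = 5)[
    , c("n", "t")], data.frame(n = 2L, t = 0L))
  a <- assign_stoichiometry(32825, m_sub, m_tag, tol = 5)
  expect_equal(a$n, 2L); expect_equal(a$t, 1L)
  expect_lt(a$residual, 1)
  far <- assign_stoichiometry(9999, m_sub, m_tag, tol = 5)
  expect_false(far$assigned)
})

test_that("a three-species tagged mixture is fully resolved", {
  m_sub <- 17419.5; m_tag <- 2014
  masses <- c(2 * m_sub, 2 * m_sub - m_tag, 14 * m_sub - 2 * m_tag)
  sp <- gen_mass_spectrum(masses, c(1, 0.6, 0.8), c(10, 10, 25),
                          z_width = 1.5, seed = 11)
  st <- ms_stoichiometry(sp, m_subunit = m_sub, m_tag = m_tag, tol = 5,
                         tol_ppm = 10)
  st <- st[order(st$mass), ]
  expect_equal(st$n, c(2L, 2L, 14L))
  expect_equal(st$t, c(1L, 0L, 2L))
  expect_true(all(st$assigned))
})

test_that("CID of a hub oligomer ejects one monomer", {
  expect_equal(cid_products(12), c(ejected = 1L, residual = 11L))
  expect_equal(cid_products(14), c(ejected = 1L, residual = 13L))
  expect_equal(cid_products(2), c(ejected = 1L, residual = 1L))
  expect_error(cid_products(1), "n >= 2")
})

test_that("abundance ratio handles equal, unequal and missing species", {
  asg <- data.frame(n = c(12, 14), intensity = c(2, 2))
  expect_equal(abundance_ratio(asg, 12, 14), 1)
  asg2 <- data.frame(n = c(12, 14), intensity = c(5.5, 4.5))
  expect_equal(abundance_ratio(asg2, 12, 14), 55 / 45)
  expect_error(abundance_ratio(asg, 12, 16), "absent")
})
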