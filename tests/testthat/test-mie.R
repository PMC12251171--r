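test_that("Mie phase tables are normalized with monotone CDFs", {
  for (wl in c(520, 637, 940)) {
    tab <- mie_phase_table(wl)
    expect_identical(tab$cdf[1], 0)
    expect_equal(tab$cdf[length(tab$cdf)], 1)
    expect_true(all(diff(tab$cdf) >= 0))
    expect_true(all(tab$pdf >= 0))
    expect_equal(pracma::trapz(tab$cos_theta, tab$pdf), 1,
                 tolerance = 1e-6)
    expect_gt(tab$g, 0)  # forward-scattering sphere
    expect_lt(tab$g, 1)
  }
})

test_that("inverse-CDF draws reproduce the table anisotropy", {
  tab <- mie_phase_table(520)
  n <- 1e6
  set.seed(7)
  x <- sample_table(tab, runif(n))
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - tab$g), max(3 * se, 1e-3))
})

test_that("small spheres approach the Rayleigh limit", {
  tab <- mie_phase_table(520, particle_diameter = 1)
  expect_lt(abs(tab$g), 1e-2)
  # shape proportional to 1 + cos^2(theta): value at +/-1 is twice that at 0
  p <- stats::approx(tab$cos_theta, tab$pdf, xout = c(-1, 0, 1))$y
  expect_equal(p[1] / p[2], 2, tolerance = 0.02)
  expect_equal(p[3] / p[2], 2, tolerance = 0.02)
  # against the analytic Rayleigh density (3/8)(1 + mu^2)
  mu <- seq(-1, 1, by = 0.05)
  pr <- stats::approx(tab$cos_theta, tab$pdf, xout = mu)$y
  expect_equal(pr, 3 / 8 * (1 + mu^2), tolerance = 0.02)
})

test_that("scatterer spec validation and DeVore dispersion", {
  expect_gt(tio2_index(520), tio2_index(940))  # normal dispersion
  expect_equal(tio2_index(520), sqrt(5.913 + 0.2441 / (0.52^2 - 0.0803)),
               tolerance = 1e-12)
  expect_error(mie_phase_table(520, n_nodes = 256))
  expect_error(mie_phase_table(520, particle_diameter = -5))
  expect_error(mie_phase_table(520, n_particle = 0.5))
  tab <- mie_phase_table(940)
  expect_equal(tab$metadata$size_parameter,
               pi * 0.25 * phantom_properties(940)$n / 0.94,
               tolerance = 1e-12)
})
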