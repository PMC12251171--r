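test_that("characterised optical parameters round-trip exactly", {
  # phantom: mu_a, mu_s', n at each wavelength (g shared)
  p520 <- phantom_properties(520)
  expect_identical(c(p520$mu_a, p520$mu_s_reduced, p520$n, p520$g),
                   c(0.093, 1.719, 1.561, 0.550))
  p637 <- phantom_properties(637)
  expect_identical(c(p637$mu_a, p637$mu_s_reduced, p637$n, p637$g),
                   c(0.019, 1.376, 1.552, 0.550))
  p940 <- phantom_properties(940)
  expect_identical(c(p940$mu_a, p940$mu_s_reduced, p940$n, p940$g),
                   c(0.016, 0.793, 1.543, 0.550))
  # glass: mu_a per wavelength, shared index
  expect_identical(vapply(c(520, 637, 940),
                          function(w) glass_properties(w)$mu_a, 0),
                   c(0.004, 0.005, 0.029))
  expect_identical(glass_properties(637)$n, 1.520)
})

test_that("uncharacterised wavelengths are rejected explicitly", {
  expect_error(phantom_properties(600),
               class = "ppgmc_unsupported_wavelength")
  expect_error(glass_properties(800),
               class = "ppgmc_unsupported_wavelength")
})

test_that("similarity relation mu_s = mu_s' / (1 - g)", {
  # 1.719 / 0.45 evaluated independently
  expect_equal(derive_mu_s(1.719, g = 0.550), 3.82, tolerance = 1e-4)
  expect_equal(derive_mu_s(0.793, g = 0), 0.793)       # isotropic identity
  expect_equal(derive_mu_s(0, g = 0.550), 0)           # non-scattering limit
  expect_equal(derive_mu_s(phantom_properties(520)), 1.719 / 0.45)
  expect_error(derive_mu_s(1, g = 1),
               class = "ppgmc_degenerate_anisotropy")
})

test_that("optical property invariants are validated", {
  expect_error(optical_properties(-0.1, 1, 0.5, 1.5))
  expect_error(optical_properties(0.1, -1, 0.5, 1.5))
  expect_error(optical_properties(0.1, 1, 1, 1.5))
  expect_error(optical_properties(0.1, 1, 0.5, 0.9))
  p <- optical_properties(0.1, 1, 0.5, 1.5)
  expect_s3_class(p, "optical_properties")
  expect_true(is.finite(derive_mu_s(p)) && derive_mu_s(p) >= 0)
})
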