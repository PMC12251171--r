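test_that("Lambert-Beer oracle", {
  expect_identical(beer_lambert(0, 5), 1)
  expect_equal(beer_lambert(0.029, 1), exp(-0.029))
  expect_equal(beer_lambert(0.029, 1), 0.97142, tolerance = 1e-5)
  expect_equal(beer_lambert(0.093, 10), 0.39455, tolerance = 1e-5)
  expect_error(beer_lambert(-1, 1))
})

test_that("unpolarized Fresnel reflectance", {
  expect_equal(fresnel_reflectance(1, 1, 0.3), 0, tolerance = 1e-15)
  # normal incidence: ((n2 - n1)/(n2 + n1))^2 evaluated independently
  expect_equal(fresnel_reflectance(1, 1.561, 1), (0.561 / 2.561)^2,
               tolerance = 1e-12)
  # beyond the critical angle going into the rarer medium
  crit <- asin(1 / 1.561)
  expect_identical(fresnel_reflectance(1.561, 1, cos(crit + 0.1)), 1)
  expect_lt(fresnel_reflectance(1.561, 1, cos(crit - 0.1)), 1)
  # grazing incidence approaches total reflection
  expect_gt(fresnel_reflectance(1, 1.5, 0.01), 0.9)
})

test_that("Snell angle and total internal reflection", {
  expect_equal(snell_angle(1, 1.561, 45),
               asin(sin(45 * pi / 180) / 1.561) * 180 / pi)
  expect_equal(snell_angle(1, 1.561, 45), 26.93, tolerance = 1e-3)
  expect_equal(snell_angle(1.4, 1.4, 33.3), 33.3)
  expect_error(snell_angle(1.561, 1, 50),
               class = "ppgmc_total_internal_reflection")
  # critical angle itself is just below the TIR region
  expect_equal(snell_angle(1.561, 1, asin(1 / 1.561) * 180 / pi - 1e-6),
               90, tolerance = 1e-2)
})

test_that("diffusion reflectance limits", {
  hi <- optical_properties(1e-9, 1, 0, 1)    # transport albedo -> 1
  expect_equal(diffusion_reflectance(hi), 1, tolerance = 1e-3)
  lo <- optical_properties(10, 1e-9, 0, 1)   # transport albedo -> 0
  expect_lt(diffusion_reflectance(lo), 1e-3)
  mid <- diffusion_reflectance(phantom_properties(940))
  expect_gt(mid, 0)
  expect_lt(mid, 1)
})

test_that("oracle report flags agreement between analytic and MC values", {
  rep <- oracle_report(n_photons = 5e4, seed = 3)
  expect_true(all(c("oracle", "analytic", "simulated", "tolerance",
                    "pass") %in% names(rep)))
  expect_true(all(rep$pass == (abs(rep$analytic - rep$simulated) <=
                                 rep$tolerance)))
  expect_true(all(rep$pass))
})
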