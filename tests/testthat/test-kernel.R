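test_that("pure absorbers follow Lambert-Beer and DPF = 1", {
  # glass-like absorber, 1 mm chord at the 940 nm glass absorption
  tr <- nonscattering_transmission(0.029, 1, n_photons = 4e4, seed = 5)
  expect_equal(tr$transmission, exp(-0.029), tolerance = 1e-6)
  expect_equal(tr$dpf, 1, tolerance = 1e-6)
  # thicker, stronger absorber
  tr2 <- nonscattering_transmission(0.093, 10, n_photons = 4e4, seed = 5)
  expect_equal(tr2$transmission, 0.39455, tolerance = 1e-4)
  expect_equal(tr2$dpf, 1, tolerance = 1e-6)
})

test_that("launched weight is fully accounted for", {
  for (wl in c(520, 940)) {
    sc <- build_scene(wl)
    r <- mc_run(sc, source_config(15, 2), detector_config(25, 2),
                3e5, seed = 2, stream = 9)
    audit <- energy_audit(r)
    expect_lt(abs(audit$rel_error), 0.005)
    # roulette is unbiased: net weight adjustment is small
    expect_lt(abs(r$roulette_killed_w - r$roulette_boost_w) / r$n_photons,
              0.005)
    expect_gt(r$deposited_w, 0)
    expect_gt(r$escaped_w, 0)
  }
})

test_that("identical seed and configuration give bitwise-identical output", {
  sc <- build_scene(637)
  src <- source_config(35, 3)
  det <- detector_config(35, 3)
  r1 <- mc_run(sc, src, det, 5e4, seed = 42, stream = 3)
  r2 <- mc_run(sc, src, det, 5e4, seed = 42, stream = 3)
  expect_identical(r1, r2)
  r3 <- mc_run(sc, src, det, 5e4, seed = 43, stream = 3)
  expect_false(identical(r1$detected_w, r3$detected_w))
})

test_that("total diffuse reflectance follows the albedo ordering", {
  refl <- vapply(c(520, 940), function(wl) {
    sc <- build_scene(wl, slides = FALSE, barrier = FALSE)
    total_diffuse_reflectance(sc, n_photons = 4e4, seed = 8)
  }, 0)
  expect_gt(refl[2], refl[1])  # 940 nm brighter than 520 nm
})

test_that("diffuse reflectance agrees with diffusion theory within 30%", {
  for (wl in c(520, 940)) {
    sc <- build_scene(wl, slides = FALSE, barrier = FALSE)
    mc <- total_diffuse_reflectance(sc, n_photons = 6e4, seed = 4)
    est <- diffusion_reflectance(phantom_properties(wl))
    expect_lt(abs(mc - est) / est, 0.30)
  }
})

test_that("detected photons stay inside the phantom and DPF >= 1", {
  r <- run_configuration(520, 2, 15, 25,
                         control = run_control(photons_base = 2e5,
                                               n_seeds = 2))
  expect_gt(r$n_detected, 0)
  expect_gte(r$dpf, 1)
  expect_lt(r$mean_max_depth, 50)
  expect_gt(r$mean_max_depth, 0)
})

test_that("the barrier is a perfect absorber", {
  sc <- build_scene(520)
  r <- mc_run(sc, source_config(15, 2), detector_config(25, 2),
              1e5, seed = 6, stream = 2)
  expect_gt(r$barrier_w, 0)  # cross-talk weight is intercepted
  # a barrier raised above the slides occludes an oblique negative-angle
  # beam completely: photons die on entry, none are detected
  sc_tall <- build_scene(520, barrier_height_above = 10)
  rt <- mc_run(sc_tall, source_config(-55, 2), detector_config(-55, 2),
               2e4, seed = 6, stream = 2)
  expect_equal(rt$detected_w, 0)
  expect_gt(rt$barrier_w / rt$n_photons, 0.9)
})
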