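test_that("source spot geometry follows the imaging optics", {
  src <- source_config(0, 2)
  expect_equal(src$spot_diameter, 0.61)
  expect_equal(src$spot_center, c(-1, 0))
  expect_error(source_config(95, 2), class = "ppgmc_geometry_error")
})

test_that("launch samples the projected elliptical footprint", {
  sc <- build_scene(520)
  # normal incidence: circular footprint of diameter 0.610 mm
  l0 <- launch(source_config(0, 2), sc, n = 2e4, seed = 3)
  expect_true(all(abs(l0$dz - cos(0)) < 1e-12))
  r <- sqrt((l0$fx + 1)^2 + l0$fy^2)
  expect_lte(max(r), 0.305 + 1e-12)
  expect_gt(max(r), 0.30)  # sampler fills the disc
  # oblique: major axis stretched to 0.610 / cos(55 deg) along x
  l55 <- launch(source_config(55, 2), sc, n = 2e4, seed = 3)
  a <- 0.305 / cos(55 * pi / 180)
  expect_true(all(((l55$fx + 1) / a)^2 + (l55$fy / 0.305)^2 <= 1 + 1e-9))
  expect_gt(max(abs(l55$fx + 1)), 0.9 * a)
  expect_true(all(abs(l55$dx - sin(55 * pi / 180)) < 1e-12))
  # photons start in ambient air above the slide stack
  expect_true(all(l55$z < -1))
  expect_true(all(material_at(sc, as.matrix(l55[, c("x", "y", "z")])) ==
                    "ambient"))
})

test_that("angle changes do not move the spot centres", {
  sc <- build_scene(940)
  centres <- vapply(c(-55, -15, 0, 15, 55), function(ts) {
    mean(launch(source_config(ts, 4), sc, n = 2e4, seed = 9)$fx)
  }, 0)
  expect_true(all(abs(centres - (-2)) < 0.01))
  dets <- vapply(c(-55, 0, 55), function(td)
    detector_config(td, 4)$spot_center[1], 0)
  expect_true(all(dets == 2))
})

test_that("detector acceptance combines spot ellipse and cone", {
  det <- detector_config(25, 2, acceptance_half_angle = 15)
  thd <- 25 * pi / 180
  axis <- c(sin(thd), 0, -cos(thd))
  # exit at spot centre along the detector axis
  expect_true(detector_accepts(det, 1, 0, axis[1], axis[2], axis[3]))
  # 5 mm away from the spot centre
  expect_false(detector_accepts(det, 6, 0, axis[1], axis[2], axis[3]))
  # inside the spot but almost orthogonal to the axis
  off <- c(cos(thd), 0, sin(thd))  # 90 degrees off axis
  expect_false(detector_accepts(det, 1, 0, off[1], off[2], off[3]))
  # straight up is outside a 15 degree cone tilted at 25 degrees
  expect_false(detector_accepts(det, 1, 0, 0, 0, -1))
  expect_true(detector_accepts(detector_config(0, 2), 1, 0, 0, 0, -1))
  expect_error(detector_config(90, 2), class = "ppgmc_geometry_error")
})

test_that("enlarging the acceptance cone never loses detected weight", {
  sc <- build_scene(520)
  src <- source_config(15, 2)
  w <- vapply(c(5, 15, 30, 60), function(alpha) {
    det <- detector_config(25, 2, acceptance_half_angle = alpha)
    # same stream: identical trajectories, acceptance is a superset
    mc_run(sc, src, det, 1e5, seed = 11, stream = 4)$detected_w
  }, 0)
  expect_true(all(diff(w) >= 0))
})
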