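test_that("point-to-material lookup matches the scene geometry", {
  sc <- build_scene(940)
  # below the surface: phantom inside the cylinder, ambient outside
  expect_identical(material_at(sc, 0, 0, 0.5), "phantom")
  expect_identical(material_at(sc, 26, 0, 10), "ambient")
  expect_identical(material_at(sc, 0, 0, 60), "ambient")
  # barrier midplane just above the surface
  expect_identical(material_at(sc, 0, 0, -0.005), "barrier")
  # air gap and glass on either side of the barrier
  expect_identical(material_at(sc, 2, 0, -0.01), "air")
  expect_identical(material_at(sc, 2, 0, -0.5), "glass")
  expect_identical(material_at(sc, -2, 0, -0.5), "glass")
  # well above everything
  expect_identical(material_at(sc, 0, 0, -10), "ambient")
})

test_that("every point maps to exactly one material, deterministically", {
  sc <- build_scene(520)
  set.seed(11)
  n <- 1e5
  x <- runif(n, -30, 30); y <- runif(n, -30, 30); z <- runif(n, -10, 60)
  m1 <- material_at(sc, x, y, z)
  m2 <- material_at(sc, x, y, z)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c("ambient", "phantom", "glass", "air",
                            "barrier")))
  expect_length(m1, n)
})

test_that("voxel volumes match analytic slab and barrier volumes", {
  sc <- build_scene(637)
  ve <- 0.1
  g <- scene_voxel_grid(sc, xlim = c(-3, 3), ylim = c(-3, 3),
                        zlim = c(-1.1, 0), voxel_edge = ve)
  vol <- ve^3
  counts <- table(factor(attr(g, "levels")[g + 1L],
                         levels = attr(g, "levels")))
  # barrier: 0.5 mm x 6 mm x (1.02 mm up to the zlim cut)
  barrier_analytic <- 0.5 * 6 * min(1.02, 1.1)
  # glass: (6 x 6 - 0.5 x 6 barrier cut) x 1 mm
  glass_analytic <- (6 * 6 - 0.5 * 6) * 1
  # one voxel layer of slack per bounding face
  slack_barrier <- vol * (2 * (0.5 / ve) * (6 / ve) +
                            2 * (6 / ve) * (1.1 / ve) +
                            2 * (0.5 / ve) * (1.1 / ve))
  slack_glass <- vol * (2 * (6 / ve)^2 + 4 * (6 / ve) * (1 / ve))
  expect_lt(abs(counts[["barrier"]] * vol - barrier_analytic),
            slack_barrier)
  expect_lt(abs(counts[["glass"]] * vol - glass_analytic), slack_glass)
})

test_that("voxel resolution must resolve the barrier", {
  expect_error(build_scene(520, voxel_edge = 0.6),
               class = "ppgmc_resolution_error")
  sc <- build_scene(520)
  expect_error(scene_voxel_grid(sc, voxel_edge = 0.7),
               class = "ppgmc_resolution_error")
})

test_that("scene summary exports every configuration field as JSON", {
  sc <- build_scene(940, air_gap_thickness = 0.05)
  f <- tempfile(fileext = ".json")
  scene_summary(sc, f)
  s <- jsonlite::read_json(f)
  expect_equal(s$wavelength, 940)
  expect_equal(s$air_gap_thickness, 0.05)
  expect_equal(s$phantom$mu_a, 0.016)
  expect_equal(s$phantom_radius, 25)
  unlink(f)
})
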