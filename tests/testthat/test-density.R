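ctl_dens <- function() run_control(photons_base = 3e5, n_seeds = 2,
                                   seed = 21)

test_that("density maps accumulate detected-photon segments", {
  m <- run_density_map(520, 2, 15, 25, control = ctl_dens(),
                       nx = 100, nz = 60, zlim = c(0, 6))
  expect_s3_class(m, "ppg_density")
  expect_true(all(m$map >= 0))
  expect_gt(sum(m$map), 0)
  expect_gt(m$n_detected, 0)
  # support concentrated between/around the spots, near the surface
  col_mass <- colSums(m$map)
  expect_gt(sum(col_mass[m$x > -2 & m$x < 2]), 0.5 * sum(col_mass))
  row_mass <- rowSums(m$map)
  expect_gt(sum(row_mass[m$z < 3]), 0.5 * sum(row_mass))
})

test_that("normalization sets the reference maximum to one", {
  m <- run_density_map(520, 2, 15, 25, control = ctl_dens(),
                       nx = 60, nz = 40, zlim = c(0, 5))
  n1 <- normalize_density(m)
  expect_equal(max(n1$map), 1)
  # normalizing against a brighter reference keeps values below 1
  ref <- m; ref$map <- m$map * 2
  n2 <- normalize_density(m, ref)
  expect_equal(max(n2$map), 0.5)
})

test_that("empty maps raise an explicit error", {
  ctl <- run_control(photons_base = 50, n_seeds = 2, seed = 1)
  m <- suppressWarnings(run_density_map(520, 5, -55, -55, control = ctl,
                                        nx = 20, nz = 20))
  expect_error(normalize_density(m), class = "ppgmc_empty_map")
})

test_that("the banana deepens with source-detector distance", {
  m2 <- run_density_map(520, 2, 15, 25, control = ctl_dens(),
                        nx = 80, nz = 60, zlim = c(0, 8))
  m5 <- run_density_map(520, 5, 15, 25, control = ctl_dens(),
                        nx = 80, nz = 60, zlim = c(0, 8))
  expect_gt(density_mean_depth(m5), density_mean_depth(m2))
})
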