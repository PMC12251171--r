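test_that("run_configuration is deterministic and order-independent", {
  ctl <- run_control(photons_base = 4e4, n_seeds = 2, seed = 7)
  a <- run_configuration(520, 2, 15, 25, control = ctl)
  b <- run_configuration(520, 2, 15, 25, control = ctl)
  expect_identical(a[setdiff(names(a), "per_seed")],
                   b[setdiff(names(b), "per_seed")])
  expect_identical(a$per_seed, b$per_seed)
})

test_that("photon budget scales linearly with distance", {
  ctl <- run_control(photons_base = 1e4, n_seeds = 2, seed = 1)
  r2 <- suppressWarnings(run_configuration(520, 2, 15, 25, control = ctl))
  r5 <- suppressWarnings(run_configuration(520, 5, 15, 25, control = ctl))
  expect_equal(r2$n_photons, 1e4)
  expect_equal(r5$n_photons, 2.5e4)  # N(d) = N0 * d / d_min
})

test_that("zero detections are flagged, not silently zero", {
  ctl <- run_control(photons_base = 200, n_seeds = 2, seed = 3)
  expect_warning(r <- run_configuration(520, 5, -55, -55, control = ctl),
                 "no photons detected")
  expect_true(r$zero_detected)
  expect_true(is.na(r$dpf))
})

test_that("normalization divides each branch by its reference row", {
  tab <- data.frame(
    wavelength = 520, distance = 2,
    theta_s = c(15, 35, 55, -15, -35),
    theta_d = c(25, 35, 55, -25, -35),
    S_bar = c(2, 4, 8, 1, 0.5))
  out <- normalize_sweep(tab)
  expect_identical(out$S_bar_prime, c(1, 2, 4, 1, 0.5))
  # missing reference row is a named error
  bad <- tab[tab$theta_s != 15, ]
  expect_error(normalize_sweep(bad), class = "ppgmc_normalization_error")
  expect_error(normalize_sweep(bad), "theta_s=15")
})

test_that("normalization references both branches per (wavelength, d)", {
  tab <- expand.grid(theta_s = c(15, -15), distance = c(2, 5),
                     wavelength = c(520, 940))
  tab$theta_d <- ifelse(tab$theta_s > 0, 25, -25)
  tab$S_bar <- seq_len(nrow(tab)) * 0.1
  out <- normalize_sweep(tab)
  expect_true(all(out$S_bar_prime == 1))
})

test_that("distance attenuation averages matched angle configurations", {
  tab <- data.frame(
    wavelength = 940,
    distance = rep(c(2, 5), each = 2),
    theta_s = c(15, 35, 15, 35),
    theta_d = c(25, 35, 25, 35),
    S_bar = c(10, 20, 1, 4))
  # hand-computed mean of (1/10, 4/20)
  expect_equal(distance_attenuation(tab, 940), mean(c(0.1, 0.2)))
  expect_error(distance_attenuation(tab, 520), "lacks")
})

test_that("sweeps cross the grids and carry metadata", {
  cfg <- sweep_config(wavelengths = 520, distances = 2,
                      theta_s = c(15, 25), theta_d = c(25, 35),
                      control = run_control(photons_base = 2e4,
                                            n_seeds = 2, seed = 5))
  sw <- run_sweep(cfg)
  expect_s3_class(sw, "ppg_sweep")
  expect_equal(nrow(sw), 4)
  expect_setequal(paste(sw$theta_s, sw$theta_d),
                  c("15 25", "15 35", "25 25", "25 35"))
  expect_true(all(sw$n_photons == 2e4))
  expect_identical(attr(sw, "control")$seed, 5L)
})

test_that("the Mie backend runs and uses the Mie anisotropy", {
  ctl <- run_control(photons_base = 4e4, n_seeds = 2, seed = 2,
                     phase = "mie")
  r <- run_configuration(520, 2, 15, 25, control = ctl)
  expect_gt(r$n_detected, 0)
  expect_identical(r$phase, "mie")
  # conversion anisotropy differs from the HG table value
  tab <- mie_phase_table(520)
  expect_false(isTRUE(all.equal(tab$g, 0.55, tolerance = 1e-3)))
})
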