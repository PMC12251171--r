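# Shared helpers for the test suite.

# one-sided comparison with a statistical tolerance of 3 standard errors
expect_gt_stat <- function(a, b, se, label = NULL) {
  se[is.na(se)] <- 0
  expect_true(a - b > -3 * se, label = label %||%
                sprintf("%g > %g within 3 se (%g)", a, b, se))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Cached reduced-grid sweep shared by the acceptance tests.  Built once per
# test run; every block reads from it instead of re-simulating.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function() {
  if (!is.null(.acceptance_cache$sweep)) return(.acceptance_cache$sweep)
  ctl <- run_control(photons_base = 6e5, n_seeds = 5, seed = 424242)
  configs <- rbind(
    # ratio grid (both distances)
    expand.grid(distance = c(2, 5),
                angle = I(list(c(15, 25), c(35, 35), c(55, 55)))),
    # angle-response grid at d = 2 mm
    expand.grid(distance = 2,
                angle = I(list(c(35, 25), c(55, 25), c(15, 35), c(15, 55),
                               c(0, 0), c(-15, -25), c(-35, -35),
                               c(-55, -55)))))
  rows <- list()
  for (wl in c(520, 637, 940)) {
    scene <- build_scene(wl)
    for (k in seq_len(nrow(configs))) {
      a <- configs$angle[[k]]
      r <- run_configuration(wl, configs$distance[k], a[1], a[2],
                             scene = scene, control = ctl)
      rows[[length(rows) + 1]] <- data.frame(
        wavelength = wl, distance = configs$distance[k],
        theta_s = a[1], theta_d = a[2],
        S_bar = r$S_bar, S_se = r$S_se, S_bar_prime = NA_real_,
        dpf = r$dpf, dpf_se = r$dpf_se,
        mean_max_depth = r$mean_max_depth, depth_se = r$depth_se,
        n_detected = r$n_detected, n_photons = r$n_photons)
    }
  }
  sweep <- do.call(rbind, rows)
  class(sweep) <- c("ppg_sweep", "data.frame")
  .acceptance_cache$sweep <- sweep
  sweep
}

sweep_row <- function(sweep, wl, d, ts, td) {
  r <- sweep[sweep$wavelength == wl & sweep$distance == d &
               sweep$theta_s == ts & sweep$theta_d == td, ]
  stopifnot(nrow(r) == 1)
  r
}
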