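#' Simulation control parameters
#'
#' @param photons_base per-configuration photon budget N0 at the reference
#'   distance \code{d_min}; the budget grows linearly with source-detector
#'   distance, N(d) = N0 * d / d_min, and is split evenly over the seeds
#' @param d_min reference distance for the budget scaling, mm
#' @param n_seeds number of independent replicate seeds averaged per
#'   configuration
#' @param seed base RNG seed; every configuration derives its replicate
#'   streams deterministically from this value and its own parameters, so
#'   results do not depend on sweep order
#' @param phase phase-function backend, \code{"hg"} or \code{"mie"}
#' @param acceptance_half_angle detector acceptance-cone half-angle,
#'   degrees
#' @param roulette_threshold packet weight below which Russian roulette is
#'   played
#' @param roulette_m roulette survival factor (survive with probability
#'   1/m, weight multiplied by m)
#' @param max_events per-photon event cap (guards against pathological
#'   trajectories; capped photons are booked as absorbed and counted)
#' @return A list of class \code{ppg_control}.
#' @export
run_control <- function(photons_base = 2e6, d_min = 2, n_seeds = 5,
                        seed = 1, phase = c("hg", "mie"),
                        acceptance_half_angle = 15,
                        roulette_threshold = 1e-4, roulette_m = 10,
                        max_events = 1e6) {
  phase <- match.arg(phase)
  stopifnot(photons_base >= 1, n_seeds >= 1, d_min > 0,
            roulette_threshold > 0, roulette_m > 1)
  structure(list(photons_base = photons_base, d_min = d_min,
                 n_seeds = as.integer(n_seeds), seed = as.integer(seed),
                 phase = phase,
                 acceptance_half_angle = acceptance_half_angle,
                 roulette_threshold = roulette_threshold,
                 roulette_m = roulette_m, max_events = max_events),
            class = "ppg_control")
}

# deterministic per-configuration stream id (order-independent seeding)
config_stream <- function(...) {
  key <- paste(vapply(list(...), function(v) sprintf("%.10g", as.numeric(v)),
                      character(1)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

phase_cpp_params <- function(control, scene) {
  if (control$phase == "hg") {
    list(type = 0L, g = scene$phantom$g)
  } else {
    tab <- mie_phase_table(scene$wavelength, n_host = scene$phantom$n)
    list(type = 1L, g = tab$g, cos_grid = tab$cos_theta, cdf = tab$cdf)
  }
}

#' Low-level single-seed kernel run
#'
#' Runs one photon batch through the transport kernel and returns the raw
#' accumulators (detected/escaped/side/deposited weights, path-length and
#' depth sums, counts).  Most users want \code{\link{run_configuration}};
#' this entry point exists for kernel physics tests and density maps.
#'
#' @param scene a \code{\link{build_scene}} object
#' @param source a \code{\link{source_config}}
#' @param detector a \code{\link{detector_config}}
#' @param n_photons photons to launch
#' @param seed,stream RNG stream identifiers
#' @param control a \code{\link{run_control}} (roulette/phase settings)
#' @param density_grid optional density-map spec
#'   \code{c(x0, x1, z0, z1, nx, nz)}; when given the returned list has a
#'   \code{density} matrix (nz x nx) accumulating detected-photon path
#'   segments weighted by packet weight
#' @return A list of kernel accumulators.
#' @export
mc_run <- function(scene, source, detector, n_photons, seed = 1L,
                   stream = 0L, control = run_control(),
                   density_grid = NULL) {
  stopifnot(inherits(scene, "ppg_scene"), inherits(source, "ppg_source"),
            inherits(detector, "ppg_detector"))
  ph <- phase_cpp_params(control, scene)
  ctl <- list(n_photons = as.integer(n_photons), seed = as.integer(seed),
              stream = as.integer(stream),
              roulette_threshold = control$roulette_threshold,
              roulette_m = control$roulette_m,
              max_events = control$max_events,
              record_density = !is.null(density_grid),
              density_grid = if (is.null(density_grid)) numeric(6)
                             else as.numeric(density_grid))
  .mc_run_cpp(scene_cpp_params(scene, g_for_mu_s = ph$g),
              source_cpp_params(source), detector_cpp_params(detector),
              ph, ctl)
}

#' Energy audit of a kernel run
#'
#' Detected + escaped + side-exit + deposited + barrier-absorbed weight,
#' with the net Russian-roulette weight adjustment, must equal the launched
#' weight in expectation.
#'
#' @param res a \code{\link{mc_run}} result
#' @return A list with \code{launched}, \code{accounted} and the relative
#'   error \code{rel_error}.
#' @export
energy_audit <- function(res) {
  accounted <- res$detected_w + res$escaped_w + res$side_w +
    res$deposited_w + res$barrier_w + res$roulette_killed_w -
    res$roulette_boost_w
  list(launched = res$n_photons, accounted = accounted,
       rel_error = (accounted - res$n_photons) / res$n_photons)
}

#' Simulate one sensor configuration
#'
#' Runs \code{n_seeds} independent replicates of a (wavelength, distance,
#' source angle, detector angle) configuration and reports the detected DC
#' level S-bar (mean detected packet weight per launched photon), the
#' differential pathlength factor DPF (weight-averaged detected optical
#' path length in the phantom divided by d), and the weight-averaged mean
#' maximum penetration depth.
#'
#' @param wavelength vacuum wavelength, nm (520, 637 or 940)
#' @param distance source-detector distance d, mm
#' @param theta_s signed source angle, degrees
#' @param theta_d signed detector angle, degrees
#' @param scene optional \code{\link{build_scene}} object (defaults to the
#'   laboratory scene at \code{wavelength})
#' @param control a \code{\link{run_control}}
#' @param n_photons optional per-configuration photon total, overriding
#'   the control's distance-scaled budget
#' @return An object of class \code{ppg_result}.
#' @export
run_configuration <- function(wavelength, distance, theta_s, theta_d,
                              scene = NULL, control = run_control(),
                              n_photons = NULL) {
  if (is.null(scene)) scene <- build_scene(wavelength)
  stopifnot(inherits(scene, "ppg_scene"))
  if (scene$wavelength != wavelength)
    stop("scene was built for a different wavelength")
  if (is.null(n_photons))
    n_photons <- control$photons_base * distance / control$d_min
  per_seed <- as.integer(ceiling(n_photons / control$n_seeds))
  src <- source_config(theta_s, distance)
  det <- detector_config(theta_d, distance,
                         acceptance_half_angle = control$acceptance_half_angle)
  base_stream <- config_stream(wavelength, distance, theta_s, theta_d)

  per <- vector("list", control$n_seeds)
  for (i in seq_len(control$n_seeds)) {
    res <- mc_run(scene, src, det, per_seed, seed = control$seed,
                  stream = (base_stream + i) %% 2147483647L,
                  control = control)
    per[[i]] <- data.frame(
      seed_index = i,
      n_photons = per_seed,
      S = res$detected_w / per_seed,
      n_detected = res$n_detected,
      sum_wl = res$sum_wl,
      sum_wdepth = res$sum_wdepth,
      detected_w = res$detected_w)
  }
  per <- do.call(rbind, per)
  tot_w <- sum(per$detected_w)
  S_bar <- mean(per$S)
  S_se <- stats::sd(per$S) / sqrt(control$n_seeds)
  zero <- tot_w <= 0
  if (zero) {
    warning(sprintf(
      "no photons detected at (%g nm, d=%g, theta_s=%g, theta_d=%g); DPF undefined",
      wavelength, distance, theta_s, theta_d))
    dpf <- NA_real_; depth <- NA_real_
    dpf_se <- NA_real_; depth_se <- NA_real_
  } else {
    dpf <- sum(per$sum_wl) / tot_w / distance
    depth <- sum(per$sum_wdepth) / tot_w
    ok <- per$detected_w > 0
    dpf_i <- ifelse(ok, per$sum_wl / per$detected_w / distance, NA)
    depth_i <- ifelse(ok, per$sum_wdepth / per$detected_w, NA)
    dpf_se <- stats::sd(dpf_i, na.rm = TRUE) / sqrt(sum(ok))
    depth_se <- stats::sd(depth_i, na.rm = TRUE) / sqrt(sum(ok))
  }
  structure(list(wavelength = wavelength, distance = distance,
                 theta_s = theta_s, theta_d = theta_d,
                 phase = control$phase,
                 n_photons = per_seed * control$n_seeds,
                 n_seeds = control$n_seeds,
                 S_bar = S_bar, S_se = S_se,
                 dpf = dpf, dpf_se = dpf_se,
                 mean_max_depth = depth, depth_se = depth_se,
                 n_detected = sum(per$n_detected),
                 zero_detected = zero,
                 per_seed = per),
            class = "ppg_result")
}

#' @export
print.ppg_result <- function(x, ...) {
  cat(sprintf(
    "PPG MC configuration: %g nm, d = %g mm, theta_s = %g, theta_d = %g (%s)\n",
    x$wavelength, x$distance, x$theta_s, x$theta_d, x$phase))
  cat(sprintf("  photons: %g over %d seeds; detected packets: %g\n",
              x$n_photons, x$n_seeds, x$n_detected))
  cat(sprintf("  DC level S-bar = %.4g (se %.2g)\n", x$S_bar, x$S_se))
  cat(sprintf("  DPF = %.3f, mean max depth = %.3f mm\n",
              x$dpf, x$mean_max_depth))
  invisible(x)
}

#' Sweep configuration
#'
#' @param wavelengths subset of c(520, 637, 940), nm
#' @param distances source-detector distances, mm
#' @param theta_s,theta_d signed angle grids in degrees; every combination
#'   is simulated
#' @param control a \code{\link{run_control}}
#' @param scene_args list of extra arguments passed to
#'   \code{\link{build_scene}} for each wavelength
#' @return A list of class \code{ppg_sweep_config}.
#' @export
sweep_config <- function(wavelengths = c(520, 637, 940),
                         distances = c(2, 3, 4, 5),
                         theta_s = c(0, 15, 25, 35, 45, 55),
                         theta_d = c(0, 25, 35, 45, 55),
                         control = run_control(),
                         scene_args = list()) {
  structure(list(wavelengths = wavelengths, distances = distances,
                 theta_s = theta_s, theta_d = theta_d, control = control,
                 scene_args = scene_args),
            class = "ppg_sweep_config")
}

#' Run a sensor-geometry sweep
#'
#' Simulates every (wavelength, distance, theta_s, theta_d) combination of
#' the sweep grid, scaling the photon budget linearly with distance and
#' averaging over replicate seeds.
#'
#' @param config a \code{\link{sweep_config}}
#' @param verbose print per-configuration progress
#' @return A data frame of class \code{ppg_sweep} with one row per
#'   configuration: \code{S_bar}, \code{S_se}, \code{dpf},
#'   \code{mean_max_depth}, \code{n_detected}, \code{n_photons}.
#'   \code{S_bar_prime} is added by \code{\link{normalize_sweep}}.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ppg_sweep_config"))
  grid <- expand.grid(theta_d = config$theta_d, theta_s = config$theta_s,
                      distance = config$distances,
                      wavelength = config$wavelengths,
                      KEEP.OUT.ATTRS = FALSE)
  scenes <- lapply(stats::setNames(nm = config$wavelengths), function(wl)
    do.call(build_scene, c(list(wavelength = wl), config$scene_args)))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    if (verbose)
      message(sprintf("[%d/%d] %g nm d=%g ts=%g td=%g", k, nrow(grid),
                      g$wavelength, g$distance, g$theta_s, g$theta_d))
    r <- run_configuration(g$wavelength, g$distance, g$theta_s, g$theta_d,
                           scene = scenes[[as.character(g$wavelength)]],
                           control = config$control)
    rows[[k]] <- data.frame(
      wavelength = g$wavelength, distance = g$distance,
      theta_s = g$theta_s, theta_d = g$theta_d,
      S_bar = r$S_bar, S_se = r$S_se, S_bar_prime = NA_real_,
      dpf = r$dpf, dpf_se = r$dpf_se,
      mean_max_depth = r$mean_max_depth, depth_se = r$depth_se,
      n_detected = r$n_detected, n_photons = r$n_photons)
  }
  out <- do.call(rbind, rows)
  attr(out, "control") <- config$control
  attr(out, "config") <- config
  class(out) <- c("ppg_sweep", "data.frame")
  out
}

#' Normalize DC levels within a sweep
#'
#' Divides every row's DC level by the reference configuration of its
#' (wavelength, distance) cell: (theta_s, theta_d) = (15, 25) degrees for
#' the positive-angle branch and (-15, -25) degrees for the negative
#' branch, giving S-bar-prime = 1 exactly at the reference.
#'
#' @param table a \code{ppg_sweep} data frame
#' @return The table with \code{S_bar_prime} filled in.
#' @export
normalize_sweep <- function(table) {
  stopifnot(is.data.frame(table))
  branch <- ifelse(table$theta_s < 0 | table$theta_d < 0,
                   "negative", "positive")
  refs <- list(positive = c(15, 25), negative = c(-15, -25))
  table$S_bar_prime <- NA_real_
  for (wl in unique(table$wavelength)) {
    for (d in unique(table$distance[table$wavelength == wl])) {
      cell <- table$wavelength == wl & table$distance == d
      for (br in unique(branch[cell])) {
        sel <- cell & branch == br
        ref <- refs[[br]]
        iref <- which(sel & table$theta_s == ref[1] &
                        table$theta_d == ref[2])
        if (length(iref) != 1) {
          stop(errorCondition(sprintf(
            "missing normalization reference (theta_s=%g, theta_d=%g) for %g nm, d=%g mm",
            ref[1], ref[2], wl, d),
            class = c("ppgmc_normalization_error", "error", "condition")))
        }
        table$S_bar_prime[sel] <- table$S_bar[sel] / table$S_bar[iref]
      }
    }
  }
  table
}

#' Distance-attenuation factor of the DC level
#'
#' Mean over positive-angle configurations of the ratio of the detected DC
#' level at the far distance to the near distance,
#' mean(S(d_far) / S(d_near)).
#'
#' @param table a \code{ppg_sweep} data frame containing both distances
#' @param wavelength wavelength to evaluate, nm
#' @param d_far,d_near distances forming the ratio, mm
#' @return The scalar mean ratio.
#' @export
distance_attenuation <- function(table, wavelength, d_far = 5, d_near = 2) {
  sel <- table$wavelength == wavelength & table$theta_s > 0 &
    table$theta_d > 0
  far <- table[sel & table$distance == d_far, ]
  near <- table[sel & table$distance == d_near, ]
  if (nrow(far) == 0 || nrow(near) == 0)
    stop(sprintf("table lacks positive-angle rows at d=%g and d=%g for %g nm",
                 d_far, d_near, wavelength))
  key <- function(df) paste(df$theta_s, df$theta_d)
  common <- intersect(key(far), key(near))
  if (length(common) == 0)
    stop("no matching angle configurations between the two distances")
  far <- far[match(common, key(far)), ]
  near <- near[match(common, key(near)), ]
  mean(far$S_bar / near$S_bar)
}
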