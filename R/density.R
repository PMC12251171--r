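#' Photon-density ("banana") map of detected photons
#'
#' Accumulates the in-phantom path segments of detected photons onto an
#' (x, z) grid, each segment weighted by the packet's detected weight times
#' its path length in the cell.  The characteristic arc between source and
#' detector spots (the "banana" region) emerges after normalization.
#'
#' @inheritParams run_configuration
#' @param xlim lateral extent of the map in mm (default -5 to +5 around
#'   the sensor midline)
#' @param zlim depth extent in mm
#' @param nx,nz grid resolution
#' @return An object of class \code{ppg_density}: a list with the raw
#'   accumulation matrix \code{map} (nz x nx, rows indexed by depth),
#'   cell-centre coordinates \code{x} and \code{z}, and the run metadata.
#' @export
run_density_map <- function(wavelength, distance, theta_s, theta_d,
                            scene = NULL, control = run_control(),
                            n_photons = NULL,
                            xlim = c(-5, 5), zlim = c(0, 5),
                            nx = 200, nz = 100) {
  if (is.null(scene)) scene <- build_scene(wavelength)
  if (is.null(n_photons))
    n_photons <- control$photons_base * distance / control$d_min
  per_seed <- as.integer(ceiling(n_photons / control$n_seeds))
  src <- source_config(theta_s, distance)
  det <- detector_config(theta_d, distance,
                         acceptance_half_angle = control$acceptance_half_angle)
  base_stream <- config_stream(wavelength, distance, theta_s, theta_d)
  grid <- c(xlim[1], xlim[2], zlim[1], zlim[2], nx, nz)
  map <- matrix(0, nz, nx)
  n_detected <- 0
  for (i in seq_len(control$n_seeds)) {
    res <- mc_run(scene, src, det, per_seed, seed = control$seed,
                  stream = (base_stream + i) %% 2147483647L,
                  control = control, density_grid = grid)
    map <- map + res$density
    n_detected <- n_detected + res$n_detected
  }
  structure(list(map = map,
                 x = seq(xlim[1], xlim[2], length.out = nx + 1)[-1] -
                   diff(xlim) / (2 * nx),
                 z = seq(zlim[1], zlim[2], length.out = nz + 1)[-1] -
                   diff(zlim) / (2 * nz),
                 wavelength = wavelength, distance = distance,
                 theta_s = theta_s, theta_d = theta_d,
                 n_photons = per_seed * control$n_seeds,
                 n_detected = n_detected),
            class = "ppg_density")
}

#' Normalize a density map
#'
#' Scales the map so that the maximum cell of the designated reference map
#' equals 1 (the reference defaults to the map itself, matching the
#' convention of normalizing to the maximum of the visualised data).
#'
#' @param map a \code{\link{run_density_map}} object
#' @param reference optional \code{ppg_density} whose maximum defines the
#'   normalization constant
#' @return The map with \code{map$map} scaled and field
#'   \code{normalization} recording the constant used.
#' @export
normalize_density <- function(map, reference = NULL) {
  stopifnot(inherits(map, "ppg_density"))
  ref <- if (is.null(reference)) map else reference
  m <- max(ref$map)
  if (m <= 0) {
    stop(errorCondition("empty density map: no detected photons accumulated",
                        class = c("ppgmc_empty_map", "error", "condition")))
  }
  map$map <- map$map / m
  map$normalization <- m
  map
}

#' Weighted mean depth of a density map
#'
#' Depth centroid of the accumulated photon density; increases with
#' source-detector distance as the banana region deepens.
#'
#' @param map a \code{\link{run_density_map}} object
#' @return Depth in mm.
#' @export
density_mean_depth <- function(map) {
  stopifnot(inherits(map, "ppg_density"))
  rowsum <- rowSums(map$map)
  sum(rowsum * map$z) / sum(rowsum)
}

#' @export
print.ppg_density <- function(x, ...) {
  cat(sprintf(
    "Photon density map: %g nm, d = %g mm, theta_s = %g, theta_d = %g\n",
    x$wavelength, x$distance, x$theta_s, x$theta_d))
  cat(sprintf("  grid %d x %d over x [%g, %g] mm, z [%g, %g] mm; %g detected packets\n",
              ncol(x$map), nrow(x$map), min(x$x), max(x$x), min(x$z),
              max(x$z), x$n_detected))
  invisible(x)
}

#' Plot a density map
#'
#' @param x a \code{\link{run_density_map}} object
#' @param log logical; plot log10 of the normalized density
#' @param ... passed to \code{image}
#' @export
plot.ppg_density <- function(x, log = TRUE, ...) {
  m <- t(x$map) / max(x$map)
  if (log) m <- log10(m + 1e-6)
  graphics::image(x$x, x$z, m, ylim = rev(range(x$z)),
                  xlab = "x [mm]", ylab = "depth z [mm]",
                  main = sprintf("%g nm, d=%g mm, ts=%g, td=%g",
                                 x$wavelength, x$distance, x$theta_s,
                                 x$theta_d), ...)
  invisible(x)
}
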