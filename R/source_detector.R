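#' Collimated source configuration
#'
#' The laboratory emitter is a collimated beam imaged onto the phantom:
#' facet diameter 0.2 mm magnified by 3.05, giving a 0.610 mm spot.  The
#' source spot centre sits at x = -d/2 on the surface; the signed source
#' angle theta_s tilts the beam axis in the x-z plane, positive toward the
#' detector (over the barrier) and negative away from it.  Angle changes do
#' not move the spot centre, so the designated source-detector distance is
#' preserved.
#'
#' @param theta_s signed source angle in degrees, |theta_s| < 90
#' @param distance source-detector distance d in mm
#' @param facet_diameter emitter facet diameter, mm
#' @param magnification source imaging magnification
#' @return An object of class \code{ppg_source}.
#' @export
source_config <- function(theta_s, distance, facet_diameter = 0.2,
                          magnification = 3.05) {
  if (abs(theta_s) >= 90) {
    stop(errorCondition("|theta_s| must be < 90 degrees",
                        class = c("ppgmc_geometry_error", "error",
                                  "condition")))
  }
  stopifnot(distance > 0)
  spot_diameter <- facet_diameter * magnification
  structure(list(theta_s = theta_s, distance = distance,
                 spot_center = c(-distance / 2, 0),
                 facet_diameter = facet_diameter,
                 magnification = magnification,
                 spot_diameter = spot_diameter),
            class = "ppg_source")
}

#' Detector configuration
#'
#' The detector is modelled at the phantom surface as a 0.55 mm spot (the
#' fibre image) plus an acceptance cone about the detector axis; the lens,
#' fibre and magnification values are carried as metadata.  The signed
#' detector angle theta_d tilts the optical axis in the x-z plane:
#' positive theta_d points the detector's view toward the source over the
#' barrier (the convergent arrangement, with the housing leaning away from
#' the source), so accepted photons leave the surface travelling away from
#' the source; negative theta_d points the view away from the source.  The
#' acceptance half-angle is not derivable from the published optics and is
#' an explicit parameter.
#'
#' @param theta_d signed detector angle in degrees, |theta_d| < 90
#' @param distance source-detector distance d in mm
#' @param spot_diameter detector spot diameter on the phantom, mm
#' @param lens_diameter collection lens diameter, mm (metadata)
#' @param fibre_diameter detector fibre diameter, mm (metadata)
#' @param magnification detector imaging magnification (metadata)
#' @param acceptance_half_angle acceptance-cone half-angle in degrees
#' @return An object of class \code{ppg_detector}.
#' @export
detector_config <- function(theta_d, distance, spot_diameter = 0.55,
                            lens_diameter = 10.9, fibre_diameter = 0.2,
                            magnification = 2.76,
                            acceptance_half_angle = 15) {
  if (abs(theta_d) >= 90) {
    stop(errorCondition("|theta_d| must be < 90 degrees",
                        class = c("ppgmc_geometry_error", "error",
                                  "condition")))
  }
  stopifnot(distance > 0, acceptance_half_angle > 0,
            acceptance_half_angle <= 90)
  structure(list(theta_d = theta_d, distance = distance,
                 spot_center = c(distance / 2, 0),
                 spot_diameter = spot_diameter,
                 lens_diameter = lens_diameter,
                 fibre_diameter = fibre_diameter,
                 magnification = magnification,
                 acceptance_half_angle = acceptance_half_angle),
            class = "ppg_detector")
}

# kernel parameter blocks ---------------------------------------------------

source_cpp_params <- function(source) {
  list(theta_s = source$theta_s,
       spot_x = source$spot_center[1],
       beam_radius = source$spot_diameter / 2)
}

detector_cpp_params <- function(det) {
  thd <- det$theta_d * pi / 180
  # positive theta_d: the detector's viewing axis points down toward the
  # source side (convergent arrangement, housing leaning away from the
  # source); accepted photons travel anti-parallel to the view, i.e. up
  # and away from the source (+x component).
  list(spot_x = det$spot_center[1],
       semi_x = det$spot_diameter / 2 / cos(thd),
       semi_y = det$spot_diameter / 2,
       axis_x = sin(thd),
       axis_z = -cos(thd),
       cos_alpha = cos(det$acceptance_half_angle * pi / 180))
}

#' Sample launched photon states
#'
#' Draws initial photon states for a source configuration: a uniform sample
#' over the beam cross-section projected onto the phantom surface (the
#' elliptical footprint, major axis 1/cos(theta_s) along x), and the
#' collimated direction.  Photons start in ambient air 0.5 mm above the
#' scene entry plane; the chief ray is aimed so that, after refraction
#' through the glass slide and air gap, it lands on the designated spot
#' centre.  This is the same sampler the transport kernel uses.
#'
#' @param source a \code{\link{source_config}}
#' @param scene a \code{\link{build_scene}} object
#' @param n number of photons
#' @param seed RNG seed
#' @return A data frame with the surface footprint sample (\code{fx},
#'   \code{fy}), starting position (\code{x}, \code{y}, \code{z}),
#'   direction (\code{dx}, \code{dy}, \code{dz}) and packet weight
#'   \code{w}.
#' @export
launch <- function(source, scene, n = 1000, seed = 1) {
  stopifnot(inherits(source, "ppg_source"), inherits(scene, "ppg_scene"))
  m <- .mc_launch_cpp(scene_cpp_params(scene), source_cpp_params(source),
                      as.integer(n), as.integer(seed), 0L)
  out <- as.data.frame(m)
  out$w <- 1
  out
}

#' Detector acceptance predicate
#'
#' A top-surface exit is accepted when its phantom-surface exit position
#' lies inside the detector spot ellipse (the spot disc projected at
#' theta_d) and its exit direction lies within the acceptance cone about
#' the detector axis.
#'
#' @param det a \code{\link{detector_config}}
#' @param exit_x,exit_y exit position on the phantom surface, mm
#' @param dir_x,dir_y,dir_z exit direction (unit vector, dir_z < 0 means
#'   travelling away from the phantom)
#' @return Logical vector of acceptance decisions.
#' @export
detector_accepts <- function(det, exit_x, exit_y, dir_x, dir_y, dir_z) {
  stopifnot(inherits(det, "ppg_detector"))
  p <- detector_cpp_params(det)
  rx <- (exit_x - p$spot_x) / p$semi_x
  ry <- exit_y / p$semi_y
  inside <- rx^2 + ry^2 <= 1
  along <- dir_x * p$axis_x + dir_z * p$axis_z
  inside & (along >= p$cos_alpha)
}

#' @export
print.ppg_source <- function(x, ...) {
  cat(sprintf("Source: theta_s = %g deg, spot centre (%g, 0) mm, spot %g mm\n",
              x$theta_s, x$spot_center[1], x$spot_diameter))
  invisible(x)
}

#' @export
print.ppg_detector <- function(x, ...) {
  cat(sprintf(
    "Detector: theta_d = %g deg, spot centre (%g, 0) mm, spot %g mm, cone %g deg\n",
    x$theta_d, x$spot_center[1], x$spot_diameter, x$acceptance_half_angle))
  invisible(x)
}
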