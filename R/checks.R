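#' Non-scattering limit check
#'
#' Degenerate test scene: an index-matched, purely absorbing slab (the
#' phantom with mu_s = 0, n = 1, no slides, no barrier) illuminated at
#' normal incidence.  Photons traverse in a straight line, so the
#' transmitted fraction must equal the Lambert-Beer value
#' exp(-mu_a * thickness), the optical path equals the geometric path, and
#' the differential pathlength factor is exactly 1.
#'
#' @param mu_a absorption coefficient of the slab, 1/mm
#' @param thickness slab thickness, mm
#' @param n_photons photon budget
#' @param seed RNG seed
#' @return A list with \code{transmission}, \code{dpf} (mean transmitted
#'   optical path divided by thickness) and the raw kernel result.
#' @export
nonscattering_transmission <- function(mu_a, thickness, n_photons = 1e5,
                                       seed = 1) {
  props <- optical_properties(mu_a = mu_a, mu_s_reduced = 0, g = 0, n = 1)
  sc <- build_scene(940, slides = FALSE, barrier = FALSE,
                    phantom = props, phantom_height = thickness,
                    phantom_radius = 50)
  src <- source_config(0, distance = 1e-3)
  det <- detector_config(0, distance = 1e-3)
  res <- mc_run(sc, src, det, n_photons, seed = seed)
  if (res$side_w <= 0) stop("no photons transmitted")
  list(transmission = res$side_w / res$n_photons,
       dpf = res$side_sum_wl / res$side_w / thickness,
       result = res)
}

#' Total diffuse reflectance of the bare phantom
#'
#' Runs the kernel on a semi-infinite-like homogeneous scene (no slides,
#' gap or barrier) at normal incidence and returns the total diffusely
#' reflected weight fraction, with the analytic specular reflection of the
#' collimated beam removed.  Comparable (within the diffusion
#' approximation's accuracy) to \code{\link{diffusion_reflectance}}.
#'
#' @param scene a bare-surface \code{\link{build_scene}} object
#' @param n_photons photon budget
#' @param seed RNG seed
#' @param control a \code{\link{run_control}}
#' @return Diffuse reflectance fraction.
#' @export
total_diffuse_reflectance <- function(scene, n_photons = 2e5, seed = 1,
                                      control = run_control()) {
  stopifnot(inherits(scene, "ppg_scene"), !scene$slides, !scene$barrier)
  src <- source_config(0, distance = 1e-3)
  det <- detector_config(0, distance = 1e-3)
  res <- mc_run(scene, src, det, n_photons, seed = seed, control = control)
  r_spec <- fresnel_reflectance(1, scene$phantom$n, 1)
  (res$escaped_w + res$detected_w) / res$n_photons - r_spec
}
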