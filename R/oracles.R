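#' Lambert-Beer transmission
#'
#' @param mu_a absorption coefficient, 1/mm
#' @param thickness path length, mm
#' @return Transmitted fraction exp(-mu_a * thickness).
#' @export
beer_lambert <- function(mu_a, thickness) {
  stopifnot(all(mu_a >= 0), all(thickness >= 0))
  exp(-mu_a * thickness)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized power reflectances at a planar
#' interface; returns 1 beyond the critical angle when n1 > n2.
#'
#' @param n1,n2 refractive indices on the incident and far side
#' @param cos_incident cosine of the incidence angle, in (0, 1]
#' @return Reflectance in [0, 1].
#' @examples
#' fresnel_reflectance(1, 1.561, 1)  # normal incidence on the phantom
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  stopifnot(all(n1 >= 1), all(n2 >= 1),
            all(cos_incident > 0), all(cos_incident <= 1))
  sin2t <- (n1 / n2)^2 * (1 - cos_incident^2)
  r <- ifelse(sin2t >= 1, 1, {
    cost <- sqrt(pmax(0, 1 - sin2t))
    rs <- (n1 * cos_incident - n2 * cost) / (n1 * cos_incident + n2 * cost)
    rp <- (n1 * cost - n2 * cos_incident) / (n1 * cost + n2 * cos_incident)
    (rs^2 + rp^2) / 2
  })
  as.numeric(r)
}

#' Snell refraction angle
#'
#' @param n1,n2 refractive indices on the incident and far side
#' @param theta_in incidence angle in degrees
#' @return Refraction angle in degrees.  Beyond the critical angle a
#'   condition of class \code{ppgmc_total_internal_reflection} is raised.
#' @export
snell_angle <- function(n1, n2, theta_in) {
  s <- n1 * sin(theta_in * pi / 180) / n2
  if (any(abs(s) > 1)) {
    stop(errorCondition(
      sprintf("total internal reflection: critical angle is %.2f degrees",
              asin(min(n2 / n1, 1)) * 180 / pi),
      class = c("ppgmc_total_internal_reflection", "error", "condition")))
  }
  asin(s) * 180 / pi
}

#' Diffusion-theory estimate of total diffuse reflectance
#'
#' Closed-form semi-infinite diffuse reflectance in the diffusion
#' approximation, parameterized by the transport albedo
#' a' = mu_s' / (mu_s' + mu_a) and the refractive-index mismatch through
#' the internal-reflection parameter A (Groenhuis-style polynomial fit for
#' the internally reflected fraction).  It is a coarse order-of-magnitude
#' cross-check for the Monte Carlo kernel, not a benchmark: the real scene
#' (glass, air gap, finite cylinder) departs from the half-space
#' idealization.
#'
#' @param props an \code{\link{optical_properties}} object with
#'   \code{mu_s_reduced > 0}
#' @return Estimated total diffuse reflectance in [0, 1].
#' @export
diffusion_reflectance <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  ap <- props$mu_s_reduced / (props$mu_s_reduced + props$mu_a)
  nr <- props$n  # relative index vs air
  rd <- -1.440 / nr^2 + 0.710 / nr + 0.668 + 0.0636 * nr
  A <- (1 + rd) / (1 - rd)
  ap / (1 + 2 * A * (1 - ap) + (1 + 2 * A / 3) * sqrt(3 * (1 - ap)))
}

#' Oracle cross-check report
#'
#' Compares closed-form reference values with kernel output on small test
#' problems: Lambert-Beer transmission through a pure absorber, Fresnel
#' normal-incidence reflectance, the Henyey-Greenstein first moment, and
#' the diffusion estimate of semi-infinite diffuse reflectance.
#'
#' @param n_photons photon budget for the Monte Carlo entries
#' @param seed RNG seed
#' @return A data frame with columns \code{oracle}, \code{analytic},
#'   \code{simulated}, \code{tolerance}, \code{pass}.
#' @export
oracle_report <- function(n_photons = 2e5, seed = 1) {
  rows <- list()

  tr <- nonscattering_transmission(mu_a = 0.093, thickness = 10,
                                   n_photons = n_photons, seed = seed)
  rows$beer <- data.frame(oracle = "lambert_beer_transmission",
                          analytic = beer_lambert(0.093, 10),
                          simulated = tr$transmission,
                          tolerance = 1e-3)

  rows$dpf1 <- data.frame(oracle = "nonscattering_dpf",
                          analytic = 1,
                          simulated = tr$dpf,
                          tolerance = 1e-3)

  u <- (seq_len(1e5) - 0.5) / 1e5
  rows$hg <- data.frame(oracle = "hg_mean_cosine",
                        analytic = 0.55,
                        simulated = mean(sample_hg(0.55, u)),
                        tolerance = 0.002)

  props <- phantom_properties(940)
  sc <- build_scene(940, slides = FALSE, barrier = FALSE)
  res <- total_diffuse_reflectance(sc, n_photons = n_photons, seed = seed)
  rows$diff <- data.frame(oracle = "diffusion_reflectance_940",
                          analytic = diffusion_reflectance(props),
                          simulated = res,
                          tolerance = 0.3 * diffusion_reflectance(props))

  out <- do.call(rbind, rows)
  out$pass <- abs(out$analytic - out$simulated) <= out$tolerance
  rownames(out) <- NULL
  out
}
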