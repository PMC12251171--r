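#' Build the laboratory scene
#'
#' Assembles the composite scene: a homogeneous scattering half-cylinder
#' phantom (radius 25 mm, height 50 mm) below the surface plane, covered by
#' an optional thin air gap, a 1 mm microscope-slide glass layer, and an
#' opaque optical barrier centred between the source and detector spots.
#'
#' Coordinates are in mm with the origin at the phantom surface midpoint
#' between the source and detector spots, +z pointing into the phantom and
#' +x from the source spot toward the detector spot.  The phantom below the
#' surface is represented analytically (layered model); the slide/gap/
#' barrier superstructure is describable both analytically (used by the
#' transport kernel, which needs exact interface normals) and as a voxel
#' grid (see \code{\link{scene_voxel_grid}}).
#'
#' @param wavelength vacuum wavelength in nm (520, 637 or 940)
#' @param phantom_radius phantom cylinder radius, mm
#' @param phantom_height phantom cylinder height, mm
#' @param slides logical; include the microscope slides and air gap
#' @param slide_thickness glass slide thickness, mm
#' @param air_gap_thickness air gap between slides and phantom, mm
#' @param barrier logical; include the optical barrier
#' @param barrier_thickness barrier thickness along x, mm
#' @param barrier_height_above barrier extension above the slide top, mm
#'   (the barrier always spans from the phantom surface to the slide top)
#' @param voxel_edge default voxel edge length for
#'   \code{\link{scene_voxel_grid}}, mm; must not exceed the barrier
#'   thickness so that the barrier is representable
#' @param phantom optional \code{\link{optical_properties}} override for
#'   the phantom (defaults to the characterised values at
#'   \code{wavelength})
#' @param glass optional \code{\link{optical_properties}} override for the
#'   glass
#' @return An object of class \code{ppg_scene}.
#' @examples
#' sc <- build_scene(940)
#' material_at(sc, 0, 0, 0.5)   # inside the phantom
#' @export
build_scene <- function(wavelength = 940,
                        phantom_radius = 25,
                        phantom_height = 50,
                        slides = TRUE,
                        slide_thickness = 1,
                        air_gap_thickness = 0.02,
                        barrier = TRUE,
                        barrier_thickness = 0.5,
                        barrier_height_above = 0,
                        voxel_edge = 0.1,
                        phantom = NULL,
                        glass = NULL) {
  if (voxel_edge <= 0) stop("voxel_edge must be > 0")
  if (barrier && voxel_edge > barrier_thickness) {
    stop(errorCondition(
      sprintf("voxel_edge (%g mm) exceeds barrier_thickness (%g mm); the barrier would not be representable",
              voxel_edge, barrier_thickness),
      class = c("ppgmc_resolution_error", "error", "condition")))
  }
  if (is.null(phantom)) phantom <- phantom_properties(wavelength)
  if (is.null(glass)) {
    glass <- if (slides) glass_properties(wavelength)
             else optical_properties(0, 0, 0, 1, wavelength)
  }
  if (!slides) {
    slide_thickness <- 0
    air_gap_thickness <- 0
  }
  structure(list(
    wavelength = wavelength,
    phantom_radius = phantom_radius,
    phantom_height = phantom_height,
    slides = slides,
    slide_thickness = slide_thickness,
    air_gap_thickness = air_gap_thickness,
    barrier = barrier,
    barrier_thickness = barrier_thickness,
    barrier_height_above = barrier_height_above,
    voxel_edge = voxel_edge,
    phantom = phantom,
    glass = glass),
    class = "ppg_scene")
}

# material index codes used by the C++ kernel
.mat_levels <- c("ambient", "phantom", "glass", "air", "barrier")

# parameter list consumed by the C++ kernel; mu_s via the similarity
# relation, with an optional anisotropy override (Mie backend)
scene_cpp_params <- function(scene, g_for_mu_s = NULL) {
  p <- scene$phantom
  g <- if (is.null(g_for_mu_s)) p$g else g_for_mu_s
  list(
    gap_t = scene$air_gap_thickness,
    glass_t = scene$slide_thickness,
    barrier_on = isTRUE(scene$barrier),
    barrier_half = scene$barrier_thickness / 2,
    barrier_above = scene$barrier_height_above,
    radius = scene$phantom_radius,
    height = scene$phantom_height,
    n_phantom = p$n,
    n_glass = scene$glass$n,
    n_gap = 1.0,
    mua_phantom = p$mu_a,
    mua_glass = scene$glass$mu_a,
    mus_phantom = if (p$mu_s_reduced > 0) derive_mu_s(p$mu_s_reduced, g) else 0)
}

#' Material lookup at spatial points
#'
#' Deterministic point-to-material mapping.  The phantom below the surface
#' plane is an analytic homogeneous half-cylinder; above the surface the
#' slide/gap/barrier stack applies; everything else is ambient air
#' (out-of-bounds points return \code{"ambient"}).
#'
#' @param scene a \code{\link{build_scene}} object
#' @param x,y,z point coordinates in mm (vectorized); alternatively
#'   \code{x} may be a 3-column matrix
#' @return Character vector of material names (\code{"ambient"},
#'   \code{"phantom"}, \code{"glass"}, \code{"air"}, \code{"barrier"}).
#' @export
material_at <- function(scene, x, y = NULL, z = NULL) {
  stopifnot(inherits(scene, "ppg_scene"))
  if (is.matrix(x)) {
    z <- x[, 3]; y <- x[, 2]; x <- x[, 1]
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(z)))
  idx <- .material_at_cpp(scene_cpp_params(scene),
                          as.numeric(x), as.numeric(y), as.numeric(z))
  .mat_levels[idx + 1L]
}

#' Voxelized superstructure grid
#'
#' Samples the scene's material map on a regular voxel grid covering the
#' slide/gap/barrier region above the phantom surface (and optionally part
#' of the phantom).  Each voxel takes the material at its centre.
#'
#' @param scene a \code{\link{build_scene}} object
#' @param xlim,ylim lateral extent in mm (default +/- 6 mm around the
#'   sensor midline)
#' @param zlim depth extent in mm; defaults to the full superstructure
#'   above the surface plus 1 mm of phantom
#' @param voxel_edge voxel edge length in mm (default from the scene)
#' @return A 3-D integer array of material indices (0 = ambient,
#'   1 = phantom, 2 = glass, 3 = air, 4 = barrier) with attributes
#'   \code{x}, \code{y}, \code{z} (voxel-centre coordinates),
#'   \code{voxel_edge} and \code{levels}.
#' @export
scene_voxel_grid <- function(scene, xlim = c(-6, 6), ylim = c(-6, 6),
                             zlim = NULL, voxel_edge = scene$voxel_edge) {
  stopifnot(inherits(scene, "ppg_scene"))
  if (voxel_edge <= 0) stop("voxel_edge must be > 0")
  if (scene$barrier && voxel_edge > scene$barrier_thickness) {
    stop(errorCondition(
      "voxel_edge exceeds barrier thickness; the barrier would not be representable",
      class = c("ppgmc_resolution_error", "error", "condition")))
  }
  top <- -(scene$air_gap_thickness + scene$slide_thickness +
             scene$barrier_height_above)
  if (is.null(zlim)) zlim <- c(top, 1)
  cx <- seq(xlim[1] + voxel_edge / 2, xlim[2] - voxel_edge / 2, by = voxel_edge)
  cy <- seq(ylim[1] + voxel_edge / 2, ylim[2] - voxel_edge / 2, by = voxel_edge)
  cz <- seq(zlim[1] + voxel_edge / 2, zlim[2] - voxel_edge / 2, by = voxel_edge)
  pts <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  idx <- .material_at_cpp(scene_cpp_params(scene), pts$x, pts$y, pts$z)
  arr <- array(as.integer(idx), dim = c(length(cx), length(cy), length(cz)))
  attr(arr, "x") <- cx
  attr(arr, "y") <- cy
  attr(arr, "z") <- cz
  attr(arr, "voxel_edge") <- voxel_edge
  attr(arr, "levels") <- .mat_levels
  arr
}

#' Scene summary for provenance export
#'
#' @param scene a \code{\link{build_scene}} object
#' @param file optional path; when given the summary is written as JSON
#' @return A list of all scene fields (invisibly when written to file).
#' @export
scene_summary <- function(scene, file = NULL) {
  stopifnot(inherits(scene, "ppg_scene"))
  s <- lapply(unclass(scene), function(f) {
    if (inherits(f, "optical_properties")) unclass(f) else f
  })
  if (!is.null(file)) {
    jsonlite::write_json(s, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(s))
  }
  s
}

#' @export
print.ppg_scene <- function(x, ...) {
  cat(sprintf("Reflective-PPG phantom scene (%g nm)\n", x$wavelength))
  cat(sprintf("  phantom: radius %g mm, height %g mm; mu_a %g, mu_s' %g, g %g, n %g\n",
              x$phantom_radius, x$phantom_height, x$phantom$mu_a,
              x$phantom$mu_s_reduced, x$phantom$g, x$phantom$n))
  if (x$slides)
    cat(sprintf("  slides: %g mm glass (n %g, mu_a %g) over %g mm air gap\n",
                x$slide_thickness, x$glass$n, x$glass$mu_a,
                x$air_gap_thickness))
  else cat("  bare surface (no slides)\n")
  if (x$barrier)
    cat(sprintf("  barrier: %g mm thick, absorbing, up to %g mm above slide top\n",
                x$barrier_thickness, x$barrier_height_above))
  invisible(x)
}
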