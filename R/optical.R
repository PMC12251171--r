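#' Optical parameters of the measurement scene
#'
#' Characterised optical parameters of the porcine-skin phantom and the
#' microscope-slide glass at the three laboratory wavelengths (520, 637 and
#' 940 nm).  The phantom is the only scattering medium; glass and the air
#' gap are traversed with Lambert-Beer attenuation only.
#'
#' @format A data frame with one row per (material, wavelength):
#' \describe{
#'   \item{material}{\code{"phantom"}, \code{"glass"} or \code{"air"}}
#'   \item{wavelength}{vacuum wavelength in nm}
#'   \item{mu_a}{absorption coefficient, 1/mm}
#'   \item{mu_s_reduced}{reduced scattering coefficient, 1/mm (NA for
#'     non-scattering media)}
#'   \item{n}{refractive index}
#'   \item{g}{scattering anisotropy factor (NA for non-scattering media)}
#' }
#' @export
optical_table <- data.frame(
  material     = c(rep("phantom", 3), rep("glass", 3), "air"),
  wavelength   = c(520, 637, 940, 520, 637, 940, NA),
  mu_a         = c(0.093, 0.019, 0.016, 0.004, 0.005, 0.029, 0),
  mu_s_reduced = c(1.719, 1.376, 0.793, NA, NA, NA, NA),
  n            = c(1.561, 1.552, 1.543, 1.520, 1.520, 1.520, 1.000),
  g            = c(0.550, 0.550, 0.550, NA, NA, NA, NA),
  stringsAsFactors = FALSE
)

#' Construct a set of optical properties
#'
#' @param mu_a absorption coefficient, 1/mm (>= 0)
#' @param mu_s_reduced reduced scattering coefficient, 1/mm (>= 0)
#' @param g anisotropy factor, -1 < g < 1
#' @param n refractive index, >= 1
#' @param wavelength optional vacuum wavelength in nm (metadata)
#' @return An object of class \code{optical_properties}.
#' @export
optical_properties <- function(mu_a, mu_s_reduced, g, n, wavelength = NA_real_) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s_reduced), is.numeric(g),
            is.numeric(n))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s_reduced < 0) stop("mu_s_reduced must be >= 0")
  if (g <= -1 || g >= 1) stop("anisotropy g must satisfy -1 < g < 1")
  if (n < 1) stop("refractive index n must be >= 1")
  structure(list(mu_a = mu_a, mu_s_reduced = mu_s_reduced, g = g, n = n,
                 wavelength = wavelength),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties%s: mu_a = %g /mm, mu_s' = %g /mm, g = %g, n = %g\n",
    if (is.na(x$wavelength)) "" else sprintf(" (%g nm)", x$wavelength),
    x$mu_a, x$mu_s_reduced, x$g, x$n))
  invisible(x)
}

stop_unsupported_wavelength <- function(wavelength) {
  stop(errorCondition(
    sprintf("unsupported wavelength %g nm; characterised wavelengths are 520, 637, 940 nm",
            wavelength),
    class = c("ppgmc_unsupported_wavelength", "error", "condition")))
}

#' Phantom optical properties at a characterised wavelength
#'
#' @param wavelength one of 520, 637 or 940 (nm)
#' @return An \code{\link{optical_properties}} object for the porcine-skin
#'   phantom.
#' @export
phantom_properties <- function(wavelength) {
  row <- optical_table[optical_table$material == "phantom" &
                         !is.na(optical_table$wavelength) &
                         optical_table$wavelength == wavelength, ]
  if (nrow(row) != 1) stop_unsupported_wavelength(wavelength)
  optical_properties(row$mu_a, row$mu_s_reduced, row$g, row$n, wavelength)
}

#' Microscope-slide glass optical properties at a characterised wavelength
#'
#' Glass is non-scattering: \code{mu_s_reduced = 0} and \code{g = 0}.
#'
#' @inheritParams phantom_properties
#' @return An \code{\link{optical_properties}} object.
#' @export
glass_properties <- function(wavelength) {
  row <- optical_table[optical_table$material == "glass" &
                         !is.na(optical_table$wavelength) &
                         optical_table$wavelength == wavelength, ]
  if (nrow(row) != 1) stop_unsupported_wavelength(wavelength)
  optical_properties(row$mu_a, 0, 0, row$n, wavelength)
}

#' Scattering coefficient from the similarity relation
#'
#' The characterisation lists the reduced scattering coefficient mu_s' and
#' the anisotropy g; the transport kernel needs the scattering coefficient
#' mu_s = mu_s' / (1 - g).
#'
#' @param props an \code{\link{optical_properties}} object, or a numeric
#'   mu_s_reduced when \code{g} is given
#' @param g anisotropy, used when \code{props} is numeric
#' @return mu_s in 1/mm.
#' @export
derive_mu_s <- function(props, g = NULL) {
  if (inherits(props, "optical_properties")) {
    msr <- props$mu_s_reduced
    g <- props$g
  } else {
    msr <- props
    if (is.null(g)) stop("g must be supplied when props is numeric")
  }
  if (any(g >= 1)) {
    stop(errorCondition("degenerate anisotropy: g = 1 gives infinite mu_s",
                        class = c("ppgmc_degenerate_anisotropy", "error",
                                  "condition")))
  }
  msr / (1 - g)
}
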