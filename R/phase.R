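#' Sample the Henyey-Greenstein scattering angle
#'
#' Closed-form inverse-CDF sampling of the deflection-angle cosine for the
#' one-parameter Henyey-Greenstein phase function.  For g = 0 the mapping
#' reduces to cos(theta) = 2u - 1.
#'
#' @param g anisotropy factor, |g| < 1
#' @param u uniform random numbers in [0, 1)
#' @return cos(theta) values in [-1, 1].
#' @examples
#' sample_hg(0.55, 0.5)
#' @export
sample_hg <- function(g, u) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  .sample_hg_cpp(g, as.numeric(u))
}

#' TiO2 refractive index (DeVore dispersion)
#'
#' Ordinary-ray refractive index of rutile TiO2 after DeVore's dispersion
#' fit, n^2 = 5.913 + 0.2441 / (lambda^2 - 0.0803) with lambda in
#' micrometres.  The phantom's scatterers are 250 nm TiO2 particles; no
#' comparable published single-term dispersion exists for anatase, so a
#' user-supplied particle index can be passed to
#' \code{\link{mie_phase_table}} instead.
#'
#' @param wavelength vacuum wavelength in nm
#' @return Refractive index (real).
#' @export
tio2_index <- function(wavelength) {
  lum <- wavelength / 1000
  n2 <- 5.913 + 0.2441 / (lum^2 - 0.0803)
  if (any(n2 <= 0)) stop("DeVore dispersion not valid at this wavelength")
  sqrt(n2)
}

# Mie scattering coefficients a_n, b_n for a homogeneous sphere
# (Bohren & Huffman recurrences; real relative index).  For very small
# size parameters the recurrences cancel catastrophically (b_1 is
# O(x^5) from the difference of O(x) terms), so a small-sphere series
# takes over below x = 0.1, which reproduces the Rayleigh dipole limit.
mie_ab <- function(x, m) {
  if (x < 0.1) {
    a1 <- -2i * x^3 / 3 * (m^2 - 1) / (m^2 + 2)
    b1 <- -1i * x^5 / 45 * (m^2 - 1)
    a2 <- -1i * x^5 / 15 * (m^2 - 1) / (2 * m^2 + 3)
    return(list(a = c(a1, a2), b = c(b1, 0), nmax = 2L))
  }
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- nmax + 15
  mx <- m * x
  # logarithmic derivative D_n(mx) by downward recurrence
  D <- numeric(nmx + 1)
  for (n in nmx:1) D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  # Riccati-Bessel psi, chi by upward recurrence
  psi <- numeric(nmax + 1)  # psi[n+1] = psi_n
  chi <- numeric(nmax + 1)
  psi0 <- cos(x); psi1 <- sin(x)   # psi_{-1}, psi_0
  chi0 <- -sin(x); chi1 <- cos(x)  # chi_{-1}, chi_0
  psi[1] <- psi1; chi[1] <- chi1
  pm1 <- psi0; cm1 <- chi0
  for (n in 1:nmax) {
    pn <- (2 * n - 1) / x * psi[n] - pm1
    cn <- (2 * n - 1) / x * chi[n] - cm1
    pm1 <- psi[n]; cm1 <- chi[n]
    psi[n + 1] <- pn; chi[n + 1] <- cn
  }
  n <- seq_len(nmax)
  xi <- complex(real = psi, imaginary = -chi)
  da <- D[n] / m + n / x
  db <- D[n] * m + n / x
  psin <- psi[n + 1]; psinm1 <- psi[n]
  xin <- xi[n + 1]; xinm1 <- xi[n]
  a <- (da * psin - psinm1) / (da * xin - xinm1)
  b <- (db * psin - psinm1) / (db * xin - xinm1)
  list(a = a, b = b, nmax = nmax)
}

# scattering amplitudes S1, S2 at cos(theta) values mu (vectorized over mu)
mie_S12 <- function(ab, mu) {
  nmax <- ab$nmax
  nmu <- length(mu)
  S1 <- complex(length.out = nmu)
  S2 <- complex(length.out = nmu)
  pi_nm1 <- rep(0, nmu)  # pi_0
  pi_n <- rep(1, nmu)    # pi_1
  for (n in 1:nmax) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (ab$a[n] * pi_n + ab$b[n] * tau_n)
    S2 <- S2 + fac * (ab$a[n] * tau_n + ab$b[n] * pi_n)
    pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
    pi_nm1 <- pi_n
    pi_n <- pi_np1
  }
  list(S1 = S1, S2 = S2)
}

#' Tabulated Mie phase function for the phantom's TiO2 scatterers
#'
#' Computes the unpolarized single-scattering phase function of a
#' homogeneous sphere from the Mie series and tabulates its inverse CDF for
#' sampling.  The size parameter is x = pi * D * n_host / lambda_vacuum.
#' Grid nodes are Gauss-Legendre points over cos(theta) in [-1, 1]
#' (augmented by the exact endpoints), dense near the forward peak.
#'
#' @param wavelength vacuum wavelength in nm
#' @param particle_diameter particle diameter in nm (default 250 nm TiO2)
#' @param n_host refractive index of the host medium; defaults to the
#'   phantom index at \code{wavelength}
#' @param n_particle particle refractive index; defaults to the DeVore
#'   rutile value at \code{wavelength} (see \code{\link{tio2_index}})
#' @param n_nodes number of interior grid nodes (>= 512)
#' @return An object of class \code{phase_table} with fields
#'   \code{cos_theta} (ascending grid in [-1, 1]), \code{pdf} (normalized
#'   so that the integral over cos(theta) is 1), \code{cdf} (0 to 1),
#'   \code{g} (anisotropy, the first moment of the table) and metadata.
#' @export
mie_phase_table <- function(wavelength, particle_diameter = 250,
                            n_host = NULL, n_particle = NULL,
                            n_nodes = 2048) {
  if (n_nodes < 512) stop("n_nodes must be >= 512")
  if (particle_diameter <= 0) stop("particle_diameter must be > 0")
  if (is.null(n_host)) n_host <- phantom_properties(wavelength)$n
  if (is.null(n_particle)) n_particle <- tio2_index(wavelength)
  if (n_host < 1 || n_particle < 1)
    stop("refractive indices must be >= 1")
  x <- pi * (particle_diameter / 1000) * n_host / (wavelength / 1000)
  m <- n_particle / n_host
  ab <- mie_ab(x, m)
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  mu <- c(-1, gl$x, 1)
  s <- mie_S12(ab, mu)
  intensity <- (Mod(s$S1)^2 + Mod(s$S2)^2) / 2
  # normalize by trapezoidal quadrature on the (dense) grid
  total <- pracma::trapz(mu, intensity)
  pdf <- intensity / total
  cdf <- pracma::cumtrapz(mu, pdf)[, 1]
  cdf <- cdf / cdf[length(cdf)]
  cdf[1] <- 0
  g <- pracma::trapz(mu, mu * pdf)
  phase_table(mu, pdf, cdf = cdf,
              metadata = list(wavelength = wavelength,
                              particle_diameter = particle_diameter,
                              host_index = n_host,
                              particle_index = n_particle,
                              size_parameter = x,
                              g = g))
}

#' Construct a tabulated phase function
#'
#' @param cos_theta ascending grid in [-1, 1]
#' @param pdf phase-function values on the grid (will be normalized so the
#'   integral over cos(theta) is 1)
#' @param cdf optional matching CDF; computed by trapezoid when missing
#' @param metadata list of provenance fields
#' @return An object of class \code{phase_table}.
#' @export
phase_table <- function(cos_theta, pdf, cdf = NULL, metadata = list()) {
  stopifnot(length(cos_theta) == length(pdf), all(diff(cos_theta) > 0),
            all(pdf >= 0))
  total <- pracma::trapz(cos_theta, pdf)
  pdf <- pdf / total
  if (is.null(cdf)) {
    cdf <- pracma::cumtrapz(cos_theta, pdf)[, 1]
    cdf <- cdf / cdf[length(cdf)]
    cdf[1] <- 0
  }
  if (any(diff(cdf) < 0)) stop("cdf must be monotone non-decreasing")
  g <- pracma::trapz(cos_theta, cos_theta * pdf)
  md <- metadata
  if (is.null(md$g)) md$g <- g
  structure(list(cos_theta = cos_theta, pdf = pdf, cdf = cdf, g = g,
                 metadata = md),
            class = "phase_table")
}

#' Sample a tabulated phase function
#'
#' Inverse-CDF lookup with linear interpolation between grid nodes; the
#' same sampler the transport kernel uses.
#'
#' @param table a \code{\link{phase_table}}
#' @param u uniform random numbers in [0, 1)
#' @return cos(theta) values.
#' @export
sample_table <- function(table, u) {
  stopifnot(inherits(table, "phase_table"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  .sample_table_cpp(table$cos_theta, table$cdf, as.numeric(u))
}

#' @export
print.phase_table <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Tabulated phase function: %d nodes, anisotropy <cos> = %.4f\n",
              length(x$cos_theta), x$g))
  if (!is.null(md$size_parameter))
    cat(sprintf("  Mie sphere: D = %g nm, x = %.3f, m = %.4f\n",
                md$particle_diameter, md$size_parameter,
                md$particle_index / md$host_index))
  invisible(x)
}

#' Export a phase table as CSV
#'
#' @param table a \code{\link{phase_table}}
#' @param file output path
#' @export
write_phase_table <- function(table, file) {
  stopifnot(inherits(table, "phase_table"))
  utils::write.csv(data.frame(cos_theta = table$cos_theta, pdf = table$pdf,
                              cdf = table$cdf),
                   file, row.names = FALSE)
  invisible(file)
}
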