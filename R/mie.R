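#' Mie cross-sections of a homogeneous sphere in a host medium
#'
#' Computes the scattering and absorption cross-sections and the scattering
#' anisotropy factor (mean deflection cosine) of a single spherical particle
#' from the Lorenz-Mie series, with the standard Bohren-Huffman downward
#' recurrence for the logarithmic derivative and the conventional
#' `x + 4 x^(1/3) + 2` truncation. The host medium is assumed transparent;
#' the relative index m = m_particle / n_host and the medium wavelength
#' lambda / n_host enter the series through the size parameter
#' x = pi d n_host / lambda.
#'
#' @param diameter particle diameter, nm (> 0).
#' @param wavelength vacuum wavelength, nm (> 0).
#' @param m_particle complex refractive index of the particle material.
#' @param n_host real refractive index of the host medium (> 0).
#' @return Named list: `C_sca`, `C_abs` (nm^2), `g` (dimensionless, in
#'   \[-1, 1\]), plus the size parameter `x` and the number of series terms.
#' @examples
#' mie_single(100, 550, complex(real = 4.08, imaginary = 0.029), 1.33)
#' @export
mie_single <- function(diameter, wavelength, m_particle, n_host) {
  stopifnot(diameter > 0, wavelength > 0, n_host > 0)
  m_particle <- as.complex(m_particle)
  if (Im(m_particle) < 0) stop("Im(m_particle) must be >= 0")
  x <- pi * diameter * n_host / wavelength
  geom <- pi * (diameter / 2)^2
  m <- m_particle / n_host
  if (m == as.complex(1))  # index-matched: no optical contrast
    return(list(C_sca = 0, C_abs = 0, g = 0, x = x, n_terms = 0L))
  if (x > 1000)
    stop(sprintf("size parameter x = %.1f too large for the series truncation",
                 x))
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  n <- seq_len(nmax)

  # logarithmic derivative D_n(mx) by downward recurrence
  mx <- m * x
  nstart <- max(nmax, ceiling(Mod(mx))) + 16L
  D <- complex(nstart + 1L)
  for (j in nstart:1) {
    r <- (j + 1) / mx
    D[j] <- r - 1 / (D[j + 1L] + r)
  }
  D <- D[n]

  # Riccati-Bessel psi_n(x), xi_n(x) by upward recurrence
  psi <- numeric(nmax); chi <- numeric(nmax)
  psim1 <- cos(x); psi0 <- sin(x)
  chim1 <- -sin(x); chi0 <- cos(x)
  for (j in n) {
    fac <- (2 * j - 1) / x
    psi[j] <- fac * psi0 - psim1
    chi[j] <- fac * chi0 - chim1
    psim1 <- psi0; psi0 <- psi[j]
    chim1 <- chi0; chi0 <- chi[j]
  }
  if (any(!is.finite(psi)) || any(!is.finite(chi)))
    stop("Riccati-Bessel recurrence overflow: series not convergent")
  xi <- complex(real = psi, imaginary = -chi)
  psi_nm1 <- c(sin(x), psi[-nmax])
  xi_nm1 <- complex(real = psi_nm1, imaginary = -c(cos(x), chi[-nmax]))

  ta <- D / m + n / x
  tb <- D * m + n / x
  a <- (ta * psi - psi_nm1) / (ta * xi - xi_nm1)
  b <- (tb * psi - psi_nm1) / (tb * xi - xi_nm1)

  w <- 2 * n + 1
  qsca_terms <- w * (Mod(a)^2 + Mod(b)^2)
  qsca <- (2 / x^2) * sum(qsca_terms)
  qext <- (2 / x^2) * sum(w * Re(a + b))
  if (qsca > 0 && qsca_terms[nmax] / sum(qsca_terms) > 1e-10)
    stop("Mie series did not converge within the truncation order")

  gq <- 0
  if (nmax >= 2) {
    j <- seq_len(nmax - 1)
    gq <- gq + sum(j * (j + 2) / (j + 1) *
                     Re(a[j] * Conj(a[j + 1]) + b[j] * Conj(b[j + 1])))
  }
  gq <- gq + sum(w / (n * (n + 1)) * Re(a * Conj(b)))
  gq <- (4 / x^2) * gq
  g <- if (qsca > 0) gq / qsca else 0
  g <- max(-1, min(1, g))

  C_sca <- qsca * geom
  C_abs <- max(0, (qext - qsca) * geom)
  list(C_sca = C_sca, C_abs = C_abs, g = g, x = x, n_terms = nmax)
}

#' Rayleigh scattering cross-section
#'
#' Closed-form small-particle (dipole) limit of the Mie scattering
#' cross-section for a sphere in a transparent host:
#' `C_sca = (2 pi^5 / 3) d^6 / lambda_m^4 |(m^2 - 1)/(m^2 + 2)|^2`,
#' with the medium wavelength `lambda_m = lambda / n_host` and the relative
#' index `m = m_particle / n_host`. Valid for `d / lambda` small; the caller
#' is responsible for staying in the Rayleigh regime.
#'
#' @inheritParams mie_single
#' @return Scattering cross-section, nm^2.
#' @export
rayleigh_cross_section <- function(diameter, wavelength, m_particle, n_host) {
  stopifnot(diameter > 0, wavelength > 0, n_host > 0)
  m <- as.complex(m_particle) / n_host
  lambda_m <- wavelength / n_host
  (2 * pi^5 / 3) * diameter^6 / lambda_m^4 * Mod((m^2 - 1) / (m^2 + 2))^2
}

#' Suspension description
#'
#' A polydisperse particle ensemble plus the physical parameters needed to
#' convert a mass concentration into a number density: spherical particles
#' of bulk material density in a host liquid.
#'
#' @param distribution a [size_distribution()].
#' @param concentration mass concentration, mg/mL (>= 0; default 0.5).
#' @param host a [host_medium()] or its name (`"water"`, `"ethanol"`).
#' @param particle_density bulk particle density, g/cm^3 (silicon 2.33).
#' @return An object of class `suspension`.
#' @export
suspension <- function(distribution, concentration = 0.5,
                       host = "water", particle_density = 2.33) {
  stopifnot(inherits(distribution, "size_distribution"),
            concentration >= 0, particle_density > 0)
  if (is.character(host)) host <- host_medium(host)
  stopifnot(inherits(host, "host_medium"))
  structure(list(distribution = distribution, concentration = concentration,
                 host = host, particle_density = particle_density),
            class = "suspension")
}

#' @export
print.suspension <- function(x, ...) {
  cat(sprintf("Suspension: %.3g mg/mL in %s (particle density %.2f g/cm^3)\n",
              x$concentration, x$host$name, x$particle_density))
  print(x$distribution)
  invisible(x)
}

#' Optical-property spectrum
#'
#' Per-wavelength (mu_a, mu_s, g) triple — the quantity the inversion
#' reconstructs and the forward model predicts.
#'
#' @param wavelength_nm wavelengths, nm.
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param g scattering anisotropy factor, in \[-1, 1\].
#' @return Object of class `optical_spectrum` (a data frame).
#' @export
optical_spectrum <- function(wavelength_nm, mu_a, mu_s, g) {
  wavelength_nm <- as.numeric(wavelength_nm)
  mu_a <- as.numeric(mu_a); mu_s <- as.numeric(mu_s); g <- as.numeric(g)
  stopifnot(length(mu_a) == length(wavelength_nm),
            length(mu_s) == length(wavelength_nm),
            length(g) == length(wavelength_nm),
            all(is.finite(mu_a)), all(mu_a >= 0),
            all(is.finite(mu_s)), all(mu_s >= 0),
            all(g >= -1), all(g <= 1))
  structure(data.frame(wavelength_nm = wavelength_nm, mu_a = mu_a,
                       mu_s = mu_s, g = g),
            class = c("optical_spectrum", "data.frame"))
}

#' Ensemble optical properties of a polydisperse suspension
#'
#' Averages single-particle Mie cross-sections over the size distribution by
#' Gauss-Legendre quadrature and converts to bulk coefficients:
#' `mu_s = N <C_sca>`, `mu_a = N <C_abs> + mu_a_host`,
#' `g = <g C_sca> / <C_sca>`, with the number density N derived from the
#' mass concentration assuming spherical particles of bulk density
#' (`N = f / <V>`, volume fraction `f = c / rho`).
#'
#' @param susp a [suspension()].
#' @param wavelengths wavelengths, nm, within the index table's support.
#' @param index_table particle-material [ri_table()]; crystalline silicon by
#'   default.
#' @param quadrature_points Gauss-Legendre nodes per distribution component
#'   (>= 16; default 64).
#' @return An [optical_spectrum()] (mm^-1 units).
#' @examples
#' s <- suspension(size_distribution(14, 10), 0.5, "water")
#' ensemble_properties(s, c(500, 700, 900))
#' @export
ensemble_properties <- function(susp, wavelengths, index_table = ri_silicon(),
                                quadrature_points = 64) {
  stopifnot(inherits(susp, "suspension"), all(wavelengths > 0))
  q <- size_quadrature(susp$distribution, quadrature_points)
  wq <- q$w / sum(q$w)

  # number density in nm^-3 from the mass concentration
  f_vol <- susp$concentration * 1e-3 / susp$particle_density
  mean_vol <- sum(wq * (pi / 6) * q$d^3)       # nm^3
  N <- f_vol / mean_vol                        # nm^-3
  nm_to_mm <- 1e6                              # nm^-1 -> mm^-1

  m_part <- ri_eval(index_table, wavelengths)
  n_host <- susp$host$n
  mu_a <- mu_s <- gg <- numeric(length(wavelengths))
  for (i in seq_along(wavelengths)) {
    cs <- ca <- gc <- 0
    for (j in seq_along(q$d)) {
      one <- mie_single(q$d[j], wavelengths[i], m_part[i], n_host)
      cs <- cs + wq[j] * one$C_sca
      ca <- ca + wq[j] * one$C_abs
      gc <- gc + wq[j] * one$g * one$C_sca
    }
    mu_s[i] <- N * cs * nm_to_mm
    mu_a[i] <- N * ca * nm_to_mm + susp$host$mu_a(wavelengths[i])
    gg[i] <- if (cs > 0) gc / cs else 0
  }
  optical_spectrum(wavelengths, mu_a, mu_s, pmin(1, pmax(-1, gg)))
}
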