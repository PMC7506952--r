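# Independent oracles used across the suite. These deliberately re-derive
# quantities by different routes than the package code.

# Rayleigh scattering cross-section, coded directly from the dipole formula
# (independent of rayleigh_cross_section()).
oracle_rayleigh <- function(d, wl, m_particle, n_host) {
  m <- m_particle / n_host
  lam <- wl / n_host
  pol <- (m^2 - 1) / (m^2 + 2)
  (2 * pi^5 / 3) * d^6 / lam^4 * Mod(pol)^2
}

# Incoherent (etalon) transmission/reflection of a stack of elements, each a
# list(T, Rf, Rb). Interfaces and absorbers compose by the standard
# multiple-reflection summation.
stack_combine <- function(e1, e2) {
  denom <- 1 - e1$Rb * e2$Rf
  list(T = e1$T * e2$T / denom,
       Rf = e1$Rf + e1$T^2 * e2$Rf / denom,
       Rb = e2$Rb + e2$T^2 * e1$Rb / denom)
}

stack_element_interface <- function(R) list(T = 1 - R, Rf = R, Rb = R)
stack_element_absorber <- function(t_int) list(T = t_int, Rf = 0, Rb = 0)

# Closed-form collimated transmittance of the cuvette at mu_s = 0:
# Beer-Lambert through the suspension x Fresnel at the four interfaces,
# including all incoherent multiple reflections.
oracle_tc_no_scatter <- function(mu_a, geom) {
  Rn <- function(n1, n2) ((n1 - n2) / (n1 + n2))^2
  els <- list(
    stack_element_interface(Rn(geom$n_outside, geom$n_wall)),
    stack_element_interface(Rn(geom$n_wall, geom$n_suspension)),
    stack_element_absorber(exp(-mu_a * geom$suspension_thickness)),
    stack_element_interface(Rn(geom$n_suspension, geom$n_wall)),
    stack_element_interface(Rn(geom$n_wall, geom$n_outside)))
  Reduce(stack_combine, els)$T
}

# One small shared lookup table, built lazily and cached for the whole run.
shared_cache <- new.env(parent = emptyenv())

shared_geom <- function() cuvette_geometry()

shared_lut <- function() {
  if (is.null(shared_cache$lut)) {
    shared_cache$lut <- lut_build(
      shared_geom(),
      lut_grid(mu_a = seq(0, 0.2, by = 0.05),
               mu_s = seq(0, 0.6, by = 0.15),
               g = seq(0, 0.9, by = 0.3)),
      sim_config(n_photons = 2e4, seed = 42))
  }
  shared_cache$lut
}
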