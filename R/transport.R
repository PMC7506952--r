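#' Cuvette measurement geometry
#'
#' Layered slab seen by the beam: air | quartz wall | suspension | quartz
#' wall | air, with a normally incident pencil beam along z and z = 0 at the
#' front air|wall interface. Photons that have never been scattered and leave
#' the rear face within `collimated_half_angle` of the axis are collimated
#' transmittance; any other rear-hemisphere exit is diffuse transmittance and
#' any front-hemisphere exit is diffuse reflectance. Photons drifting beyond
#' `half_width` laterally are counted as side loss.
#'
#' @param suspension_thickness suspension layer thickness, mm (default 5).
#' @param wall_thickness cuvette wall thickness, mm (default 1.25).
#' @param n_wall wall refractive index (fused quartz, default 1.45).
#' @param n_suspension host-liquid refractive index (default 1.33, water).
#' @param n_outside surrounding-medium index (air, 1.0).
#' @param collimated_half_angle detector acceptance half-angle for the
#'   collimated channel, degrees (default 5).
#' @param half_width lateral half-width of the cuvette, mm (default 5, i.e.
#'   a 10 mm wide cuvette).
#' @return Object of class `cuvette_geometry`.
#' @export
cuvette_geometry <- function(suspension_thickness = 5, wall_thickness = 1.25,
                             n_wall = 1.45, n_suspension = 1.33,
                             n_outside = 1.0, collimated_half_angle = 5,
                             half_width = 5) {
  stopifnot(suspension_thickness > 0, wall_thickness > 0,
            n_wall >= 1, n_suspension >= 1, n_outside >= 1,
            collimated_half_angle > 0, collimated_half_angle < 90,
            half_width > 0)
  structure(list(suspension_thickness = suspension_thickness,
                 wall_thickness = wall_thickness, n_wall = n_wall,
                 n_suspension = n_suspension, n_outside = n_outside,
                 collimated_half_angle = collimated_half_angle,
                 half_width = half_width),
            class = "cuvette_geometry")
}

#' @export
print.cuvette_geometry <- function(x, ...) {
  cat(sprintf(
    "Cuvette: %.3g mm suspension (n = %.3f) between %.3g mm walls (n = %.3f)\n",
    x$suspension_thickness, x$n_suspension, x$wall_thickness, x$n_wall))
  cat(sprintf("  collimated acceptance %.1f deg, half-width %.1f mm\n",
              x$collimated_half_angle, x$half_width))
  invisible(x)
}

#' Monte-Carlo simulation settings
#'
#' @param n_photons photons to launch (>= 1).
#' @param seed integer RNG seed; the run is bit-reproducible given the seed.
#' @param weight_threshold photon weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival roulette survival probability (default 0.1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 1e5, seed = 1,
                       weight_threshold = 1e-4, roulette_survival = 0.1) {
  stopifnot(n_photons >= 1, weight_threshold > 0, weight_threshold < 1,
            roulette_survival > 0, roulette_survival <= 1)
  structure(list(n_photons = as.numeric(n_photons), seed = as.numeric(seed),
                 weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival),
            class = "sim_config")
}

#' Measurement triple constructor
#'
#' The observable of one spectrophotometric measurement at one wavelength:
#' collimated transmittance, diffuse transmittance and diffuse reflectance,
#' optionally with the absorbed fraction and Monte-Carlo standard errors.
#'
#' @param T_C,T_D,R_D channel fractions in \[0, 1\].
#' @param A_medium absorbed fraction (default `NA`).
#' @param side_loss fraction lost through the cuvette sides (default `NA`).
#' @param se_T_C,se_T_D,se_R_D Monte-Carlo standard errors (default 0).
#' @return Object of class `measurement_triple` (a named list).
#' @export
measurement_triple <- function(T_C, T_D, R_D, A_medium = NA_real_,
                               side_loss = NA_real_,
                               se_T_C = 0, se_T_D = 0, se_R_D = 0) {
  ch <- c(T_C, T_D, R_D)
  stopifnot(all(is.finite(ch)), all(ch >= 0), all(ch <= 1),
            se_T_C >= 0, se_T_D >= 0, se_R_D >= 0)
  structure(list(T_C = T_C, T_D = T_D, R_D = R_D, A_medium = A_medium,
                 side_loss = side_loss, se_T_C = se_T_C, se_T_D = se_T_D,
                 se_R_D = se_R_D),
            class = "measurement_triple")
}

#' @export
print.measurement_triple <- function(x, ...) {
  cat(sprintf("T_C = %.5f (SE %.1e)  T_D = %.5f (SE %.1e)  R_D = %.5f (SE %.1e)\n",
              x$T_C, x$se_T_C, x$T_D, x$se_T_D, x$R_D, x$se_R_D))
  if (is.finite(x$A_medium))
    cat(sprintf("A_medium = %.5f  side_loss = %.5f\n", x$A_medium, x$side_loss))
  invisible(x)
}

#' Simulate a cuvette measurement
#'
#' Weighted-photon (implicit capture) Monte-Carlo random walk through the
#' cuvette: exponential free paths with mu_t = mu_a + mu_s in the suspension,
#' weight attenuation by the single-scattering albedo at each event,
#' Henyey-Greenstein deflection, unpolarised Fresnel reflection/refraction at
#' all four interfaces, Russian roulette below the weight threshold. The
#' roulette kill/boost ledger is folded into the medium-absorption tally
#' (zero expectation), so the per-run weight ledger
#' `T_C + T_D + R_D + A_medium + side_loss = 1` holds to rounding error.
#'
#' @param geometry a [cuvette_geometry()].
#' @param mu_a absorption coefficient of the suspension, mm^-1 (>= 0).
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param g Henyey-Greenstein anisotropy factor, in \[-1, 1\].
#' @param config a [sim_config()].
#' @return A [measurement_triple()] with absorbed fraction, side loss and
#'   Monte-Carlo standard errors filled in; the seed and photon count used
#'   are attached as attributes `seed` and `n_photons`.
#' @examples
#' geom <- cuvette_geometry()
#' mc_simulate(geom, mu_a = 0.05, mu_s = 0.3, g = 0.7,
#'             config = sim_config(n_photons = 1e4, seed = 7))
#' @export
mc_simulate <- function(geometry, mu_a, mu_s, g, config = sim_config()) {
  stopifnot(inherits(geometry, "cuvette_geometry"),
            inherits(config, "sim_config"),
            is.finite(mu_a), mu_a >= 0, is.finite(mu_s), mu_s >= 0,
            g >= -1, g <= 1)
  res <- mc_cuvette_cpp(
    mu_a, mu_s, g,
    geometry$wall_thickness, geometry$suspension_thickness,
    geometry$n_outside, geometry$n_wall, geometry$n_suspension,
    geometry$half_width, cos(geometry$collimated_half_angle * pi / 180),
    config$n_photons, config$weight_threshold, config$roulette_survival,
    config$seed)
  out <- measurement_triple(res$T_C, res$T_D, res$R_D,
                            A_medium = res$A_medium,
                            side_loss = res$side_loss,
                            se_T_C = res$se_T_C, se_T_D = res$se_T_D,
                            se_R_D = res$se_R_D)
  attr(out, "seed") <- config$seed
  attr(out, "n_photons") <- config$n_photons
  out
}

#' Henyey-Greenstein deflection-cosine sampling
#'
#' Inverse-CDF transform of a uniform deviate into the cosine of the
#' Henyey-Greenstein scattering angle; `g = 0` reduces to the isotropic
#' branch `2 u - 1`. The sample mean over many draws converges to g, the
#' distribution's first moment.
#'
#' @param g anisotropy factor, -1 < g < 1.
#' @param u uniform deviates in \[0, 1\] (vectorised).
#' @return Deflection cosines in \[-1, 1\].
#' @export
hg_sample <- function(g, u) {
  stopifnot(g > -1, g < 1, all(u >= 0), all(u <= 1))
  if (abs(g) < 1e-12) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
}

#' Unpolarised Fresnel reflectance
#'
#' Average of the s- and p-polarised Fresnel power reflectances for a ray
#' crossing a planar interface between transparent media; returns 1 beyond
#' the critical angle.
#'
#' @param n1 index on the incidence side (>= 1).
#' @param n2 index on the far side (>= 1).
#' @param cos_incident cosine of the incidence angle, in \[0, 1\]
#'   (vectorised).
#' @return Reflectance fraction(s) in \[0, 1\].
#' @export
fresnel_unpolarized <- function(n1, n2, cos_incident) {
  stopifnot(n1 >= 1, n2 >= 1,
            all(cos_incident >= 0), all(cos_incident <= 1))
  if (n1 == n2) return(rep(0, length(cos_incident)))
  sint2 <- (n1 / n2)^2 * (1 - cos_incident^2)
  cost <- sqrt(pmax(0, 1 - sint2))
  rs <- (n1 * cos_incident - n2 * cost) / (n1 * cos_incident + n2 * cost)
  rp <- (n1 * cost - n2 * cos_incident) / (n1 * cost + n2 * cos_incident)
  ifelse(sint2 >= 1, 1, 0.5 * (rs^2 + rp^2))
}
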