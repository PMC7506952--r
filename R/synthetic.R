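#' Built-in suspension scenarios
#'
#' The eight laser-ablated silicon nanoparticle suspension scenarios the
#' generator emulates: four nanostructured targets (micro- and mesoporous
#' silicon, low- and heavily-doped silicon nanowires), each ablated in water
#' or ethanol, with AFM-derived mean diameter and SD of the resulting
#' particle ensembles. The microporous-silicon-in-water ensemble is bimodal
#' and is modelled as an equal-weight two-lognormal mixture whose overall
#' mean and SD reproduce the tabulated values.
#'
#' @return Data frame with columns `label`, `target`, `host`, `mean_nm`,
#'   `sd_nm`, `bimodal`.
#' @export
sinp_scenarios <- function() {
  data.frame(
    label = c("microporous_water", "microporous_ethanol",
              "mesoporous_water", "mesoporous_ethanol",
              "lowdoped_sinw_water", "lowdoped_sinw_ethanol",
              "heavilydoped_sinw_water", "heavilydoped_sinw_ethanol"),
    target = rep(c("microporous silicon", "mesoporous silicon",
                   "low-doped SiNWs", "heavily-doped SiNWs"), each = 2),
    host = rep(c("water", "ethanol"), 4),
    mean_nm = c(65, 28, 14, 25, 42, 24, 45, 28),
    sd_nm = c(22, 22, 10, 13, 24, 9, 20, 9),
    bimodal = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

#' Synthetic suspension scenario
#'
#' Assembles a fully specified synthetic measurement scenario: a particle
#' size distribution (defaults per the built-in scenario table), host
#' liquid, mass concentration, spectrophotometer noise model and seed.
#'
#' @param label one of `sinp_scenarios()$label`.
#' @param concentration mass concentration, mg/mL (default 0.5).
#' @param multiplicative_sd relative Gaussian channel noise (default 0.02).
#' @param additive_sd additive Gaussian noise, fraction of full scale
#'   (default 0.002).
#' @param seed integer seed for all of the scenario's randomness.
#' @param kind size-distribution family for the default distribution;
#'   `"truncnorm"` (default) keeps the bounded right tail seen in the AFM
#'   histograms, `"lognormal"` is available for heavier-tailed ensembles.
#' @param distribution optional [size_distribution()] overriding the
#'   label's default.
#' @return Object of class `sinp_scenario`.
#' @examples
#' sc <- sinp_scenario("mesoporous_water", seed = 1)
#' mean(sample_sizes(sc, 1e4))
#' @export
sinp_scenario <- function(label, concentration = 0.5,
                          multiplicative_sd = 0.02, additive_sd = 0.002,
                          seed = 1, kind = c("truncnorm", "lognormal"),
                          distribution = NULL) {
  kind <- match.arg(kind)
  tab <- sinp_scenarios()
  row <- tab[tab$label == label, ]
  if (nrow(row) != 1)
    stop("unknown scenario label; see sinp_scenarios()$label")
  stopifnot(multiplicative_sd >= 0, additive_sd >= 0, concentration >= 0)
  if (is.null(distribution)) {
    distribution <- if (row$bimodal)
      bimodal_from_moments(row$mean_nm, row$sd_nm, kind = kind)
    else size_distribution(row$mean_nm, row$sd_nm, kind = kind)
  }
  structure(list(label = label, target = row$target, host = row$host,
                 distribution = distribution, concentration = concentration,
                 multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = seed),
            class = "sinp_scenario")
}

# equal-weight two-lognormal mixture with prescribed overall mean/SD:
# modes at mean -+ delta, component SDs absorbing the remaining variance
bimodal_from_moments <- function(mean_nm, sd_nm, delta = 20,
                                 kind = "truncnorm") {
  within_var <- sd_nm^2 - delta^2
  if (within_var <= 0) stop("component separation too large for target SD")
  s <- sqrt(within_var)
  size_mixture(size_distribution(mean_nm - delta, s, kind),
               size_distribution(mean_nm + delta, s, kind),
               weights = c(0.5, 0.5))
}

#' @export
print.sinp_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: %s ablated in %s, %.3g mg/mL (seed %g)\n",
              x$label, x$target, x$host, x$concentration, x$seed))
  print(x$distribution)
  cat(sprintf("  noise: %.1f%% multiplicative + %.2f%% additive\n",
              100 * x$multiplicative_sd, 100 * x$additive_sd))
  invisible(x)
}

#' @export
sample_sizes.sinp_scenario <- function(x, n, ...) {
  set.seed(x$seed)
  sample_sizes(x$distribution, n)
}

#' Suspension object for a scenario
#'
#' @param scenario a [sinp_scenario()].
#' @return The corresponding [suspension()].
#' @export
as_suspension <- function(scenario) {
  stopifnot(inherits(scenario, "sinp_scenario"))
  suspension(scenario$distribution, scenario$concentration,
             host_medium(scenario$host))
}

#' Generate synthetic measured spectra with ground truth
#'
#' The full forward chain: polydisperse Mie ensemble properties per
#' wavelength, Monte-Carlo simulation of the cuvette measurement at each
#' wavelength (per-wavelength seeds derived deterministically from the
#' config seed), then channel-wise measurement noise (multiplicative
#' Gaussian + additive floor, clamped to \[0, 1\]). The noise RNG is seeded
#' from the scenario seed, so the whole generation is reproducible.
#'
#' @param scenario a [sinp_scenario()].
#' @param wavelengths wavelengths, nm (default 400-1000 nm in 25 nm steps).
#' @param geometry a [cuvette_geometry()]; defaults to the standard cuvette
#'   with the scenario host's refractive index.
#' @param config a [sim_config()] for the per-wavelength simulations.
#' @param index_table particle-material [ri_table()] (crystalline silicon).
#' @return List of class `synthetic_run`: `spectra` (noisy
#'   [measured_spectra()]), `clean` (noise-free spectra),
#'   `ground_truth` (the forward-model [optical_spectrum()]), `scenario`,
#'   `geometry`, `config`, and a `manifest` recording seeds and versions.
#' @export
synthesize_spectra <- function(scenario,
                               wavelengths = seq(400, 1000, by = 25),
                               geometry = NULL,
                               config = sim_config(),
                               index_table = ri_silicon()) {
  stopifnot(inherits(scenario, "sinp_scenario"))
  host <- host_medium(scenario$host)
  if (is.null(geometry))
    geometry <- cuvette_geometry(n_suspension = host$n)
  susp <- as_suspension(scenario)
  truth <- ensemble_properties(susp, wavelengths, index_table)

  nch <- length(wavelengths)
  T_C <- T_D <- R_D <- numeric(nch)
  for (i in seq_len(nch)) {
    cfg <- config
    cfg$seed <- node_seed(config$seed, i)
    tr <- mc_simulate(geometry, truth$mu_a[i], truth$mu_s[i], truth$g[i], cfg)
    T_C[i] <- tr$T_C; T_D[i] <- tr$T_D; R_D[i] <- tr$R_D
  }
  clean <- measured_spectra(wavelengths, T_C, T_D, R_D)

  set.seed(scenario$seed)
  noisy <- lapply(clean[c("T_C", "T_D", "R_D")], function(v) {
    out <- v * (1 + stats::rnorm(nch, 0, scenario$multiplicative_sd)) +
      stats::rnorm(nch, 0, scenario$additive_sd)
    pmin(1, pmax(0, out))
  })
  spectra <- measured_spectra(wavelengths, noisy$T_C, noisy$T_D, noisy$R_D)

  manifest <- list(scenario_label = scenario$label,
                   scenario_seed = scenario$seed,
                   mc_base_seed = config$seed,
                   n_photons = config$n_photons,
                   wavelengths = wavelengths,
                   version = as.character(utils::packageVersion("imcspect")))
  structure(list(spectra = spectra, clean = clean, ground_truth = truth,
                 scenario = scenario, geometry = geometry, config = config,
                 manifest = manifest),
            class = "synthetic_run")
}

#' Read and write scenario files
#'
#' A scenario serialises to a small YAML document (label, concentration,
#' noise model, seed and, when it overrides the label's default, the size
#' distribution). Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return `read_scenario` returns a [sinp_scenario()];
#'   `write_scenario` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for scenario files")
  y <- yaml::read_yaml(path)
  known <- c("label", "concentration", "multiplicative_sd", "additive_sd",
             "seed", "kind", "distribution")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$distribution)) {
    comps <- lapply(y$distribution, function(cc)
      size_distribution(cc$mean, cc$sd, cc$kind))
    y$distribution <- if (length(comps) == 1) comps[[1]]
      else do.call(size_mixture,
                   c(comps, list(weights = vapply(y$distribution, `[[`,
                                                  numeric(1), "weight"))))
  }
  do.call(sinp_scenario, y)
}

#' @param scenario a [sinp_scenario()].
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sinp_scenario"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for scenario files")
  comps <- lapply(scenario$distribution$components, function(cc)
    list(kind = cc$kind, mean = cc$mean, sd = cc$sd, weight = cc$weight))
  yaml::write_yaml(list(label = scenario$label,
                        concentration = scenario$concentration,
                        multiplicative_sd = scenario$multiplicative_sd,
                        additive_sd = scenario$additive_sd,
                        seed = scenario$seed,
                        distribution = comps), path,
                   precision = 17)  # doubles round-trip losslessly
  invisible(path)
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat(sprintf("Synthetic run: %s, %d wavelengths (%g-%g nm), %g photons/lambda\n",
              x$scenario$label, nrow(x$spectra),
              min(x$spectra$wavelength_nm), max(x$spectra$wavelength_nm),
              x$config$n_photons))
  invisible(x)
}
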