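#' Measured spectra container
#'
#' Per-wavelength (T_C, T_D, R_D) triples as measured (or synthesised) by an
#' integrating-sphere spectrophotometer.
#'
#' @param wavelength_nm strictly increasing wavelengths, nm.
#' @param T_C,T_D,R_D channel fractions in \[0, 1\].
#' @return Object of class `measured_spectra` (a data frame).
#' @export
measured_spectra <- function(wavelength_nm, T_C, T_D, R_D) {
  wavelength_nm <- as.numeric(wavelength_nm)
  T_C <- as.numeric(T_C); T_D <- as.numeric(T_D); R_D <- as.numeric(R_D)
  stopifnot(length(T_C) == length(wavelength_nm),
            length(T_D) == length(wavelength_nm),
            length(R_D) == length(wavelength_nm))
  if (any(duplicated(wavelength_nm)))
    stop("duplicate wavelength rows")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  for (nm in c("T_C", "T_D", "R_D")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("channel ", nm, " outside [0, 1]")
  }
  structure(data.frame(wavelength_nm = wavelength_nm, T_C = T_C,
                       T_D = T_D, R_D = R_D),
            class = c("measured_spectra", "data.frame"))
}

#' Reconstruct optical properties from measured spectra
#'
#' The inverse Monte-Carlo fit: each wavelength's measured
#' (T_C, T_D, R_D) triple is inverted independently against a Monte-Carlo
#' lookup table by exhaustive minimisation of the relative least-squares
#' functional ([functional_f()]), returning the per-wavelength
#' (mu_a, mu_s, g) spectrum.
#'
#' @param spectra a [measured_spectra()] data frame (`wavelength_nm`,
#'   `T_C`, `T_D`, `R_D`; all channels positive).
#' @param lut a lookup table from [lut_build()] or [lut_read()].
#' @param refine logical; trilinear interpolation refinement around the
#'   argmin node (off by default: the table argmin is the canonical
#'   estimator, refinement is a convenience).
#' @param subdiv subdivisions per axis when `refine = TRUE`.
#' @return Object of class `imc_fit` with components `coefficients`
#'   (matrix: columns `mu_a`, `mu_s`, `g`; rows per wavelength),
#'   `diagnostics` (per-wavelength `F_min`, `runner_up_F`, `node_index`,
#'   `interpolated`), `fitted.values` (table channels at the estimates),
#'   `spectra`, and the `lut` used. Supported methods: `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' geom <- cuvette_geometry()
#' lut <- lut_build(geom, lut_grid(mu_a = seq(0, 0.2, 0.05),
#'                                 mu_s = seq(0, 0.6, 0.1),
#'                                 g = seq(0, 0.9, 0.3)),
#'                  sim_config(n_photons = 2e3, seed = 1))
#' tr <- mc_simulate(geom, 0.05, 0.3, 0.6, sim_config(2e4, seed = 2))
#' sp <- measured_spectra(550, tr$T_C, tr$T_D, tr$R_D)
#' fit <- imc_fit(sp, lut)
#' coef(fit)
#' }
#' @export
imc_fit <- function(spectra, lut, refine = FALSE, subdiv = 10) {
  stopifnot(inherits(lut, "mc_lut"))
  if (!inherits(spectra, "measured_spectra"))
    spectra <- measured_spectra(spectra$wavelength_nm, spectra$T_C,
                                spectra$T_D, spectra$R_D)
  nw <- nrow(spectra)
  if (nw == 0) stop("no wavelengths to invert")
  coefs <- matrix(NA_real_, nw, 3,
                  dimnames = list(NULL, c("mu_a", "mu_s", "g")))
  diag <- data.frame(wavelength_nm = spectra$wavelength_nm,
                     F_min = NA_real_, runner_up_F = NA_real_,
                     node_index = NA_integer_, interpolated = FALSE)
  for (i in seq_len(nw)) {
    res <- tryCatch(
      lut_invert(lut, c(spectra$T_C[i], spectra$T_D[i], spectra$R_D[i]),
                 refine = refine, subdiv = subdiv),
      error = function(e)
        stop(sprintf("inversion failed at %g nm: %s",
                     spectra$wavelength_nm[i], conditionMessage(e)),
             call. = FALSE))
    coefs[i, ] <- c(res$mu_a, res$mu_s, res$g)
    diag$F_min[i] <- res$F_min
    diag$runner_up_F[i] <- res$runner_up_F
    diag$node_index[i] <- res$node_index
    diag$interpolated[i] <- res$interpolated
  }
  fitted <- lut_interpolate(lut, coefs[, "mu_a"], coefs[, "mu_s"],
                            coefs[, "g"])
  fitted <- data.frame(wavelength_nm = spectra$wavelength_nm,
                       T_C = fitted$T_C, T_D = fitted$T_D, R_D = fitted$R_D)
  structure(list(coefficients = coefs, diagnostics = diag,
                 fitted.values = fitted, spectra = spectra, lut = lut,
                 call = match.call()),
            class = "imc_fit")
}

#' @export
print.imc_fit <- function(x, ...) {
  cat("Inverse Monte-Carlo optical-property fit\n")
  cat(sprintf("  %d wavelength(s), table of %d nodes\n",
              nrow(x$spectra), nrow(x$lut$nodes)))
  cat(sprintf("  mu_a in [%.4g, %.4g] mm^-1, mu_s in [%.4g, %.4g] mm^-1, g in [%.3g, %.3g]\n",
              min(x$coefficients[, "mu_a"]), max(x$coefficients[, "mu_a"]),
              min(x$coefficients[, "mu_s"]), max(x$coefficients[, "mu_s"]),
              min(x$coefficients[, "g"]), max(x$coefficients[, "g"])))
  cat(sprintf("  median F_min = %.3g\n", stats::median(x$diagnostics$F_min)))
  invisible(x)
}

#' @export
summary.imc_fit <- function(object, ...) {
  co <- object$coefficients
  out <- list(
    call = object$call,
    n_wavelengths = nrow(object$spectra),
    coef_summary = apply(co, 2, stats::quantile,
                         probs = c(0, 0.25, 0.5, 0.75, 1)),
    F_min_summary = stats::quantile(object$diagnostics$F_min,
                                    probs = c(0, 0.5, 0.9, 1)),
    n_interpolated = sum(object$diagnostics$interpolated),
    residual_rms = sqrt(colMeans(residuals.imc_fit(object)[-1]^2)))
  class(out) <- "summary.imc_fit"
  out
}

#' @export
print.summary.imc_fit <- function(x, ...) {
  cat("Inverse Monte-Carlo fit summary\n")
  cat(sprintf("  wavelengths: %d (refined: %d)\n",
              x$n_wavelengths, x$n_interpolated))
  cat("  reconstructed coefficients (quantiles):\n")
  print(signif(x$coef_summary, 4))
  cat("  functional minimum F_min (quantiles):\n")
  print(signif(x$F_min_summary, 3))
  cat("  channel residual RMS:\n")
  print(signif(x$residual_rms, 3))
  invisible(x)
}

#' @export
coef.imc_fit <- function(object, ...) object$coefficients

#' Reconstructed spectrum of an inverse fit
#'
#' @param fit an [imc_fit()].
#' @return The per-wavelength estimates as an [optical_spectrum()].
#' @export
as_optical_spectrum <- function(fit) {
  stopifnot(inherits(fit, "imc_fit"))
  optical_spectrum(fit$spectra$wavelength_nm,
                   fit$coefficients[, "mu_a"],
                   fit$coefficients[, "mu_s"],
                   fit$coefficients[, "g"])
}

#' @export
fitted.imc_fit <- function(object, ...) object$fitted.values

#' @export
residuals.imc_fit <- function(object, ...) {
  data.frame(wavelength_nm = object$spectra$wavelength_nm,
             T_C = object$spectra$T_C - object$fitted.values$T_C,
             T_D = object$spectra$T_D - object$fitted.values$T_D,
             R_D = object$spectra$R_D - object$fitted.values$R_D)
}

#' Predict measurement triples from optical properties
#'
#' Forward prediction through the fitted lookup table: trilinear
#' interpolation of the table channels at arbitrary (mu_a, mu_s, g)
#' coordinates.
#'
#' @param object an [imc_fit()].
#' @param newdata data frame with columns `mu_a`, `mu_s`, `g`; defaults to
#'   the fitted coefficients.
#' @param ... unused.
#' @return Data frame of predicted `T_C`, `T_D`, `R_D`.
#' @export
predict.imc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- as.data.frame(object$coefficients)
  stopifnot(all(c("mu_a", "mu_s", "g") %in% names(newdata)))
  ch <- lut_interpolate(object$lut, newdata$mu_a, newdata$mu_s, newdata$g)
  data.frame(T_C = ch$T_C, T_D = ch$T_D, R_D = ch$R_D)
}

#' Simulate replicate measured spectra from a fit
#'
#' Draws noisy replicates of the fitted channel triples under the
#' spectrophotometer noise model (multiplicative Gaussian per channel plus
#' an additive full-scale floor), clamped to \[0, 1\].
#'
#' @param object an [imc_fit()].
#' @param nsim number of replicate spectra.
#' @param seed optional seed passed to [set.seed()].
#' @param multiplicative_sd relative channel noise (default 0.02).
#' @param additive_sd additive noise as a fraction of full scale
#'   (default 0.002).
#' @param ... unused.
#' @return List of `nsim` [measured_spectra()] objects.
#' @export
simulate.imc_fit <- function(object, nsim = 1, seed = NULL,
                             multiplicative_sd = 0.02, additive_sd = 0.002,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$fitted.values
  replicate(nsim, {
    noisy <- lapply(base[c("T_C", "T_D", "R_D")], function(v) {
      out <- v * (1 + stats::rnorm(length(v), 0, multiplicative_sd)) +
        stats::rnorm(length(v), 0, additive_sd)
      pmin(1, pmax(0, out))
    })
    measured_spectra(base$wavelength_nm, noisy$T_C, noisy$T_D, noisy$R_D)
  }, simplify = FALSE)
}

#' Plot a reconstructed optical-property spectrum
#'
#' Draws mu_a and mu_s versus wavelength on a common panel (left axis) and
#' g on a secondary panel.
#'
#' @param x an [imc_fit()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.imc_fit <- function(x, ...) {
  sp <- as_optical_spectrum(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(sp$wavelength_nm, cbind(sp$mu_a, sp$mu_s),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "red"),
                    xlab = "wavelength (nm)",
                    ylab = expression(mu ~ (mm^-1)), ...)
  graphics::legend("topright", legend = c(expression(mu[a]),
                                          expression(mu[s])),
                   col = c("black", "red"), lty = 1, lwd = 2, bty = "n")
  graphics::plot(sp$wavelength_nm, sp$g, type = "l", lwd = 2,
                 xlab = "wavelength (nm)", ylab = "anisotropy g",
                 ylim = c(-1, 1))
  invisible(x)
}
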