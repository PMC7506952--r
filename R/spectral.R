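#' Power-law fit of a scattering spectrum
#'
#' Fits `mu_s(lambda) = c * lambda^p` by least squares in log-log space over
#' a wavelength window; the exponent `p` (signed) is the log-log slope.
#' Used to quantify how close a suspension's scattering spectrum is to the
#' Rayleigh `lambda^-4` limit versus the flatter Mie regime.
#'
#' @param wavelength_nm wavelengths, nm.
#' @param mu_s scattering coefficients, mm^-1 (> 0 within the fit range).
#' @param fit_range length-2 numeric window in nm (default `c(800, 1000)`,
#'   the near-infrared tail where the small-particle regime dominates).
#' @return Object of class `power_law_fit`: `exponent`, `prefactor`
#'   (mm^-1 nm^-exponent), `fit_range`, `r_squared`, `n_points`.
#' @examples
#' wl <- seq(800, 1000, 25)
#' fit_power_law(wl, 2e7 * wl^-3.3)
#' @export
fit_power_law <- function(wavelength_nm, mu_s, fit_range = c(800, 1000)) {
  stopifnot(length(mu_s) == length(wavelength_nm), length(fit_range) == 2,
            fit_range[1] < fit_range[2])
  sel <- wavelength_nm >= fit_range[1] & wavelength_nm <= fit_range[2]
  if (sum(sel) < 4) stop("need at least 4 points inside the fit range")
  if (any(mu_s[sel] <= 0))
    stop("non-positive mu_s inside the fit range: log-log fit undefined")
  lx <- log(wavelength_nm[sel]); ly <- log(mu_s[sel])
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 fit_range = fit_range,
                 r_squared = max(0, min(1, r2)),
                 n_points = sum(sel)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit over %g-%g nm (%d points):\n",
              x$fit_range[1], x$fit_range[2], x$n_points))
  cat(sprintf("  mu_s ~ lambda^%.4g   (r^2 = %.6f)\n", x$exponent,
              x$r_squared))
  invisible(x)
}

#' Upper Rayleigh diameter at a transition wavelength
#'
#' The Rayleigh-scattering condition `d / lambda <~ 1/15` turned around:
#' given the wavelength where a suspension's spectrum transitions from the
#' Mie to the Rayleigh regime, the largest particle diameter still
#' scattering in the Rayleigh regime is `d = lambda / 15`.
#'
#' @param transition_wavelength_nm wavelength(s), nm (> 0).
#' @return Data frame with `d_exact_nm` and `d_rounded_nm` (nearest nm).
#' @examples
#' rayleigh_upper_diameter(550)   # 36.67 nm exact, 37 nm rounded
#' @export
rayleigh_upper_diameter <- function(transition_wavelength_nm) {
  stopifnot(all(transition_wavelength_nm > 0))
  d <- transition_wavelength_nm / 15
  data.frame(transition_wavelength_nm = transition_wavelength_nm,
             d_exact_nm = d, d_rounded_nm = round(d))
}

#' Detect a local absorption peak
#'
#' Searches an absorption spectrum for a local maximum inside a wavelength
#' window, with the prominence measured against a linear baseline through
#' the window edges. Designed to pick up the host-liquid absorption band
#' (the ~970 nm water overtone) in reconstructed or forward-modelled mu_a
#' spectra of aqueous suspensions.
#'
#' @param spectrum an [optical_spectrum()] (or data frame with
#'   `wavelength_nm` and `mu_a`).
#' @param window length-2 numeric search window, nm (default
#'   `c(930, 1010)`).
#' @param prominence_threshold minimum baseline-subtracted prominence, mm^-1
#'   (default 0.005), for the peak to count as found.
#' @return List: `found` (logical), `peak_wavelength_nm`, `prominence_mm`
#'   (both `NA` when no interior local maximum exists).
#' @export
detect_absorption_peak <- function(spectrum, window = c(930, 1010),
                                   prominence_threshold = 0.005) {
  stopifnot(all(c("wavelength_nm", "mu_a") %in% names(spectrum)),
            length(window) == 2, window[1] < window[2])
  wl <- spectrum$wavelength_nm
  if (window[1] < min(wl) || window[2] > max(wl))
    stop("search window outside the spectrum support")
  sel <- wl >= window[1] & wl <= window[2]
  if (sum(sel) < 5) stop("need at least 5 points inside the window")
  x <- wl[sel]; y <- spectrum$mu_a[sel]
  n <- length(x)
  # interior local maxima
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  if (!any(is_peak))
    return(list(found = FALSE, peak_wavelength_nm = NA_real_,
                prominence_mm = NA_real_))
  baseline <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  prom <- y - baseline
  best <- which(is_peak)[which.max(prom[is_peak])]
  list(found = prom[best] > prominence_threshold,
       peak_wavelength_nm = x[best],
       prominence_mm = prom[best])
}

#' Spectral analysis report
#'
#' Bundles the power-law exponent fit of mu_s, the Rayleigh transition
#' diameter and the host-absorption peak search into one report, optionally
#' written as JSON.
#'
#' @param spectrum an [optical_spectrum()].
#' @param fit_range power-law fit window, nm.
#' @param transition_wavelength_nm assumed Mie/Rayleigh transition
#'   wavelength (default 550 nm).
#' @param peak_window absorption-peak search window, nm.
#' @param path optional path; if given, the report is written there as JSON.
#' @return List with elements `power_law`, `rayleigh_diameter`,
#'   `absorption_peak`.
#' @export
spectral_report <- function(spectrum, fit_range = c(800, 1000),
                            transition_wavelength_nm = 550,
                            peak_window = c(930, 1010), path = NULL) {
  pl <- fit_power_law(spectrum$wavelength_nm, spectrum$mu_s, fit_range)
  rd <- rayleigh_upper_diameter(transition_wavelength_nm)
  pk <- detect_absorption_peak(spectrum, peak_window)
  rep <- list(power_law = unclass(pl),
              rayleigh_diameter = as.list(rd),
              absorption_peak = pk)
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  rep
}
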