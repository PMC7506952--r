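#' Refractive-index table
#'
#' Container for tabulated complex refractive indices n(lambda) + i k(lambda),
#' with linear interpolation in wavelength. Used for the particle material
#' (crystalline silicon by default) and, where needed, host liquids.
#'
#' @param wavelength_nm numeric, strictly increasing wavelengths in nm.
#' @param n numeric, real part of the refractive index (> 0).
#' @param k numeric, imaginary part (extinction coefficient, >= 0). Defaults
#'   to zero (transparent material).
#' @return An object of class `ri_table`: a data frame with columns
#'   `wavelength_nm`, `n`, `k`.
#' @seealso [ri_eval()], [ri_silicon()]
#' @export
ri_table <- function(wavelength_nm, n, k = rep(0, length(wavelength_nm))) {
  wavelength_nm <- as.numeric(wavelength_nm)
  n <- as.numeric(n)
  k <- as.numeric(k)
  if (length(wavelength_nm) < 2L)
    stop("ri_table needs at least two wavelengths")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(n) != length(wavelength_nm) || length(k) != length(wavelength_nm))
    stop("n and k must match the wavelength grid length")
  if (any(!is.finite(n)) || any(n <= 0)) stop("n must be finite and > 0")
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0")
  structure(
    data.frame(wavelength_nm = wavelength_nm, n = n, k = k),
    class = c("ri_table", "data.frame"))
}

#' Interpolate a refractive-index table
#'
#' @param table an [ri_table()].
#' @param wavelength_nm wavelengths (nm) at which to evaluate; must lie within
#'   the table's support.
#' @return Complex vector n + i k at the requested wavelengths.
#' @export
ri_eval <- function(table, wavelength_nm) {
  stopifnot(inherits(table, "ri_table"))
  rng <- range(table$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside table support [%g, %g] nm", rng[1], rng[2]))
  n <- stats::approx(table$wavelength_nm, table$n, xout = wavelength_nm)$y
  k <- stats::approx(table$wavelength_nm, table$k, xout = wavelength_nm)$y
  complex(real = n, imaginary = k)
}

#' Crystalline-silicon optical constants
#'
#' Embedded tabulation of the complex refractive index of crystalline silicon
#' over 400-1000 nm, interpolated from the standard room-temperature
#' dispersion data for intrinsic c-Si (n falls from ~5.6 at 400 nm to ~3.6 in
#' the near infrared; k from ~0.3 to below 1e-3). Override with your own
#' [ri_table()] (e.g. read via [read_ri_table()]) where a different material
#' model is needed.
#'
#' @return An [ri_table()] covering 400-1100 nm.
#' @export
ri_silicon <- function() {
  ri_table(
    wavelength_nm = c(400, 420, 440, 460, 480, 500, 550, 600, 650, 700,
                      750, 800, 850, 900, 950, 1000, 1050, 1100),
    n = c(5.57, 5.12, 4.82, 4.62, 4.47, 4.29, 4.08, 3.94, 3.85, 3.78,
          3.73, 3.69, 3.66, 3.64, 3.62, 3.60, 3.59, 3.57),
    k = c(0.303, 0.179, 0.118, 0.0880, 0.0668, 0.0442, 0.0293, 0.0198,
          0.0145, 0.0106, 0.00776, 0.00541, 0.00362, 0.00219, 0.00098,
          0.00051, 0.00028, 0.00012))
}

# Pure-water absorption coefficient, mm^-1, 400-1000 nm; interpolated from
# the standard pure-water absorption tabulations (visible minimum near
# 420-500 nm, overtone shoulder near 750 nm, local maximum near 970 nm).
water_absorption_table <- function() {
  data.frame(
    wavelength_nm = c(400, 450, 500, 550, 600, 650, 700, 725, 750, 775,
                      800, 825, 850, 875, 900, 920, 940, 960, 970, 980,
                      1000, 1050, 1100),
    mu_a_mm = c(6.6e-6, 9.2e-6, 2.04e-5, 5.65e-5, 2.224e-4, 3.40e-4,
                6.24e-4, 1.60e-3, 2.72e-3, 2.40e-3, 2.07e-3, 2.80e-3,
                4.33e-3, 5.33e-3, 6.79e-3, 1.10e-2, 2.67e-2, 4.20e-2,
                4.52e-2, 4.30e-2, 3.64e-2, 1.65e-2, 1.80e-2))
}

#' Host-liquid optical model
#'
#' Refractive index and absorption spectrum of the suspension host liquid.
#' Water carries the embedded pure-water absorption table (whose local
#' maximum near 970 nm shows up in forward-modelled mu_a of aqueous
#' suspensions); ethanol defaults to negligible absorption over 400-1000 nm.
#' Both can be overridden.
#'
#' @param name `"water"` or `"ethanol"`.
#' @param n real refractive index; defaults 1.33 (water) / 1.36 (ethanol).
#'   Dispersion across 400-1000 nm is below 1% and is neglected.
#' @param absorption optional data frame `wavelength_nm`, `mu_a_mm` replacing
#'   the built-in host absorption spectrum.
#' @return An object of class `host_medium` with elements `name`, `n` and
#'   `mu_a(wavelength_nm)`, a vectorised absorption function (mm^-1).
#' @export
host_medium <- function(name = c("water", "ethanol"), n = NULL,
                        absorption = NULL) {
  name <- match.arg(name)
  if (is.null(n)) n <- if (name == "water") 1.33 else 1.36
  stopifnot(is.numeric(n), n >= 1)
  if (is.null(absorption)) {
    absorption <- if (name == "water") water_absorption_table()
                  else data.frame(wavelength_nm = c(400, 1100), mu_a_mm = c(0, 0))
  }
  stopifnot(all(c("wavelength_nm", "mu_a_mm") %in% names(absorption)),
            all(absorption$mu_a_mm >= 0))
  abs_tab <- absorption
  mu_a <- function(wavelength_nm) {
    stats::approx(abs_tab$wavelength_nm, abs_tab$mu_a_mm,
                  xout = wavelength_nm, rule = 2)$y
  }
  structure(list(name = name, n = n, mu_a = mu_a, absorption = abs_tab),
            class = "host_medium")
}

#' @export
print.host_medium <- function(x, ...) {
  cat(sprintf("Host medium: %s (n = %.3f)\n", x$name, x$n))
  cat(sprintf("  absorption table: %d points, %g-%g nm\n",
              nrow(x$absorption), min(x$absorption$wavelength_nm),
              max(x$absorption$wavelength_nm)))
  invisible(x)
}
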