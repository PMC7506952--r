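#' Read and write measured spectra
#'
#' CSV dialect `wavelength_nm,T_C,T_D,R_D`. Reading validates the header,
#' strictly increasing non-duplicated wavelengths and channel values in
#' \[0, 1\]; writing uses 17 significant digits so finite doubles round-trip
#' losslessly.
#'
#' @param path CSV file path.
#' @return `read_spectra` returns a [measured_spectra()];
#'   `write_spectra` returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expected <- c("wavelength_nm", "T_C", "T_D", "R_D")
  if (!identical(trimws(header), expected))
    stop("malformed header: expected 'wavelength_nm,T_C,T_D,R_D'")
  df <- utils::read.csv(path)
  measured_spectra(df$wavelength_nm, df$T_C, df$T_D, df$R_D)
}

#' @param spectra a [measured_spectra()].
#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "measured_spectra"))
  write_csv17(as.data.frame(spectra), path)
}

#' Read and write optical-property spectra
#'
#' CSV dialect `wavelength_nm,mu_a_mm,mu_s_mm,g`.
#'
#' @param path CSV file path.
#' @return `read_optical_spectrum` returns an [optical_spectrum()];
#'   `write_optical_spectrum` returns `path` invisibly.
#' @export
read_optical_spectrum <- function(path) {
  df <- utils::read.csv(path)
  expected <- c("wavelength_nm", "mu_a_mm", "mu_s_mm", "g")
  if (!identical(names(df), expected))
    stop("malformed header: expected 'wavelength_nm,mu_a_mm,mu_s_mm,g'")
  optical_spectrum(df$wavelength_nm, df$mu_a_mm, df$mu_s_mm, df$g)
}

#' @param spectrum an [optical_spectrum()].
#' @rdname read_optical_spectrum
#' @export
write_optical_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "optical_spectrum"))
  df <- data.frame(wavelength_nm = spectrum$wavelength_nm,
                   mu_a_mm = spectrum$mu_a, mu_s_mm = spectrum$mu_s,
                   g = spectrum$g)
  write_csv17(df, path)
}

#' Read a refractive-index table
#'
#' CSV `wavelength_nm,n[,k]`; a missing `k` column means a transparent
#' material.
#'
#' @param path CSV file path.
#' @return An [ri_table()].
#' @export
read_ri_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "n") %in% names(df)))
    stop("malformed header: expected 'wavelength_nm,n[,k]'")
  if (is.null(df$k)) df$k <- 0
  ri_table(df$wavelength_nm, df$n, df$k)
}

# full-precision CSV writer (doubles round-trip through %.17g)
write_csv17 <- function(df, path) {
  txt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1)
  writeLines(c(paste(names(df), collapse = ","),
               apply(txt, 1, paste, collapse = ",")), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Serialises the provenance record of a synthetic run (scenario, seeds,
#' photon counts, wavelengths, package version) as JSON so outputs can be
#' regenerated exactly.
#'
#' @param run a `synthetic_run` from [synthesize_spectra()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  stopifnot(inherits(run, "synthetic_run"))
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Regenerate a synthetic run from its manifest
#'
#' @param path manifest JSON path.
#' @return A `synthetic_run` identical to the one the manifest records
#'   (same scenario defaults, seeds and wavelength grid).
#' @export
rerun_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- sinp_scenario(man$scenario_label, seed = man$scenario_seed)
  synthesize_spectra(scenario, wavelengths = man$wavelengths,
                     config = sim_config(n_photons = man$n_photons,
                                         seed = man$mc_base_seed))
}
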