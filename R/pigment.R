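# Chlorophyll-a quantification: fitted absorption -> volumetric molar and
# mass concentration -> areal density over the attenuation-fit window.

#' Analytic chlorophyll-a-like absorption shape
#'
#' A documented analytic stand-in for the chlorophyll-a (in methanol)
#' absorption spectrum over the visible band: a Gaussian red (Qy) band at
#' 660 nm, a vibronic satellite near 615 nm, and the long-wavelength tail of
#' the Soret band. Max-normalized over 520-720 nm, peaking at 660 nm. This
#' is the shape shipped in the packaged synthetic reference fixture
#' (`inst/extdata/chla_synthetic_methanol.tsv`); a digitized measured
#' spectrum can be swapped in via the same fixture format.
#'
#' @param lambda Wavelengths in nm.
#' @return Relative absorption in \[0, 1\].
#' @export
chla_shape_synthetic <- function(lambda) {
  s <- exp(-(lambda - 660)^2 / (2 * 11.9^2)) +
    0.20 * exp(-(lambda - 615)^2 / (2 * 12.7^2)) +
    1.10 * exp(-(lambda - 430)^2 / (2 * 34^2))
  s / max(exp(-(0)^2))  # peak of the red band dominates in 520-720
}

#' Load a pigment reference spectrum
#'
#' Reads a two-column tab-separated fixture (wavelength nm, relative
#' absorption) with a `#`-prefixed metadata block recording the extinction
#' convention (decadic or natural), the peak decadic molar extinction
#' coefficient, the solvent and the source. The default is the packaged
#' synthetic chlorophyll-a (methanol-like) reference.
#'
#' @param path Fixture path; default is the packaged chlorophyll-a fixture.
#' @return An object of class `pigment_spectrum`: `lambda` (nm),
#'   `mu_a_star` (max-normalized shape), `peak_lambda` (nm),
#'   `epsilon_peak` (decadic molar extinction, 1/(M cm)), `molar_mass`
#'   (g/mol), `convention`, `source`.
#' @export
pigment_reference <- function(path = system.file("extdata",
                                                 "chla_synthetic_methanol.tsv",
                                                 package = "isoct")) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    if (grepl(":", kv)) {
      k <- trimws(sub(":.*$", "", kv))
      v <- trimws(sub("^[^:]*:", "", kv))
      meta[[k]] <- v
    }
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  stopifnot(all(c("wavelength_nm", "relative_absorption") %in% names(tab)))
  shape <- tab$relative_absorption / max(tab$relative_absorption)
  pk <- tab$wavelength_nm[which.max(shape)]
  if (pk < 655 || pk > 665)
    stop("pigment reference peak must lie within 655-665 nm")
  structure(list(lambda = tab$wavelength_nm, mu_a_star = shape,
                 peak_lambda = pk,
                 epsilon_peak = as.numeric(meta[["epsilon_peak_M_cm"]]),
                 molar_mass = as.numeric(meta[["molar_mass_g_mol"]]),
                 convention = meta[["extinction_convention"]],
                 source = meta[["source"]]),
            class = "pigment_spectrum")
}

#' @export
print.pigment_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<pigment_spectrum> peak %g nm, epsilon_peak %g 1/(M cm)",
                     " (%s), %d wavelengths\n"),
              x$peak_lambda, x$epsilon_peak, x$convention, length(x$lambda)))
  invisible(x)
}

# Interpolate the normalized absorption shape onto arbitrary wavelengths.
pigment_shape_at <- function(spectrum, lambda) {
  stats::approx(spectrum$lambda, spectrum$mu_a_star, xout = lambda,
                rule = 2)$y
}

# Absorption shape as seen through Gaussian spectral bands of the given
# FWHM: spectra measured band-wise average the narrow pigment peak over the
# window, so the reference used in the decomposition must be blurred to the
# same spectral resolution (fwhm = 0 returns the raw shape).
pigment_shape_banded <- function(spectrum, band_centers, band_fwhm = 0) {
  if (band_fwhm <= 0) return(pigment_shape_at(spectrum, band_centers))
  sigma <- band_fwhm / (2 * sqrt(2 * log(2)))
  lam <- seq(min(band_centers) - 3 * band_fwhm,
             max(band_centers) + 3 * band_fwhm, by = 0.5)
  sh <- pigment_shape_at(spectrum, lam)
  vapply(band_centers, function(c0) {
    w <- exp(-(lam - c0)^2 / (2 * sigma^2))
    sum(w * sh) / sum(w)
  }, numeric(1))
}

#' Chlorophyll-a volumetric concentration from absorption
#'
#' Divides the absorption coefficient at the red peak by the molar
#' extinction coefficient. The packaged extinction coefficient is decadic
#' (base-10, as absorbance spectra are tabulated), while `mu_a` is a
#' natural-log (Beer-Lambert, base-e) coefficient, so the conversion is
#' `C = mu_a(peak) / (ln(10) * epsilon_peak)`. The fixture's
#' `extinction_convention` field is the single source of truth; a
#' natural-log fixture would drop the `ln(10)` factor.
#'
#' @param mu_a_peak Absorption coefficient at the pigment peak, 1/cm
#'   (natural-log convention), `>= 0`.
#' @param spectrum A [pigment_reference()] object.
#' @return A list with `molar` (mol/L) and `mg_cm3` (mg/cm^3).
#' @export
chl_volumetric <- function(mu_a_peak, spectrum = pigment_reference()) {
  if (any(mu_a_peak < 0, na.rm = TRUE))
    stop("`mu_a_peak` must be >= 0")
  fac <- if (identical(spectrum$convention, "natural")) 1 else log(10)
  molar <- mu_a_peak / (fac * spectrum$epsilon_peak)
  list(molar = molar, mg_cm3 = molar * spectrum$molar_mass)
}

#' Forward absorption spectrum from a chlorophyll-a concentration
#'
#' Inverse of [chl_volumetric()]: builds `mu_a(lambda)` (natural-log, 1/cm)
#' from a mass concentration, used by the phantom builder.
#'
#' @param conc_mg_cm3 Mass concentration in mg/cm^3 (`>= 0`).
#' @param lambda Wavelengths in nm.
#' @param spectrum A [pigment_reference()] object.
#' @return `mu_a(lambda)` in 1/cm.
#' @export
chl_mu_a <- function(conc_mg_cm3, lambda, spectrum = pigment_reference()) {
  stopifnot(conc_mg_cm3 >= 0)
  molar <- conc_mg_cm3 / spectrum$molar_mass
  fac <- if (identical(spectrum$convention, "natural")) 1 else log(10)
  fac * spectrum$epsilon_peak * molar * pigment_shape_at(spectrum, lambda)
}

#' Chlorophyll-a areal density over the fit window
#'
#' Integrates the volumetric concentration over the attenuation-fit
#' thickness under the constant-concentration assumption:
#' `areal = volumetric * thickness`.
#'
#' @param volumetric_mg_cm3 Volumetric concentration, mg/cm^3.
#' @param thickness_um Window thickness in micrometers (default 90).
#' @return Areal density in micrograms per cm^2.
#' @export
chl_areal_density <- function(volumetric_mg_cm3, thickness_um = 90) {
  stopifnot(thickness_um > 0)
  # mg/cm^3 * um = mg/cm^3 * 1e-4 cm * 1000 ug/mg = 0.1 * ug/cm^2 per um
  volumetric_mg_cm3 * thickness_um * 0.1
}
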