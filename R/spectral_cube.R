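# Short-time Fourier transform of raw fringes into the 4-D spectrally
# resolved OCT cube I_b(band, x, y, z), plus calibration against a
# Rayleigh-scattering reference standard. Windows are Gaussian in the
# acquisition (wavenumber) domain, centered at k = 2 pi / lambda_c with the
# stated wavelength FWHM mapped to k at each center; depth is reported in
# optical path and intensity is magnitude squared, so Beer-Lambert slopes
# downstream are -2 mu_t.

new_spectral_cube <- function(intensity, band_centers, band_fwhm, z_grid,
                              acq, provenance = list()) {
  stopifnot(length(dim(intensity)) == 4L,
            dim(intensity)[1] == length(band_centers),
            dim(intensity)[4] == length(z_grid),
            all(diff(band_centers) > 0))
  structure(list(intensity = intensity, band_centers = band_centers,
                 band_fwhm = band_fwhm, z_grid = z_grid,
                 acquisition = acq, provenance = provenance),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(paste0("<spectral_cube> %d bands (%g-%g nm, FWHM %g nm) x ",
                     "%d x %d columns x %d depths (%.2f um/px, optical)\n"),
              d[1], min(x$band_centers), max(x$band_centers), x$band_fwhm,
              d[2], d[3], d[4], mean(diff(x$z_grid))))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, paste, character(1),
                                      collapse = " "), collapse = "; "),
        "\n")
  invisible(x)
}

#' Default spectral band centers
#'
#' 22 Gaussian bands of 20 nm FWHM, uniformly spaced in wavelength across
#' the acquired spectrum with a 1.5-FWHM margin at each edge, so every
#' window is fully supported by the acquisition (a clipped window tail
#' produces point-spread-function sidelobes that leak bright surface
#' signal into depth and bias edge-band attenuation fits).
#'
#' @param acq An [oct_acquisition()] (or a list with `lambda_min`,
#'   `lambda_max`).
#' @param n_bands Number of bands (default 22).
#' @param band_fwhm Band FWHM in nm (default 20).
#' @return Band center wavelengths in nm.
#' @export
default_band_centers <- function(acq, n_bands = 22L, band_fwhm = 20) {
  seq(acq$lambda_min + 1.5 * band_fwhm, acq$lambda_max - 1.5 * band_fwhm,
      length.out = n_bands)
}

# Optical-path depth grid (um) of the STFT output.
stft_z_grid <- function(acq, z_max_um = NULL, z_decim = 1L) {
  k <- acq_k_grid(acq)
  dk <- (k[length(k)] - k[1]) / (length(k) - 1)
  m <- seq_len(acq$n_k %/% 2L) - 1L
  z <- pi * m / (acq$n_k * dk) / 1000  # nm -> um
  if (z_decim > 1L) {
    nz <- (length(z) %/% z_decim) * z_decim
    z <- colMeans(matrix(z[seq_len(nz)], z_decim))
  }
  if (!is.null(z_max_um)) z <- z[z <= z_max_um]
  z
}

#' Short-time Fourier transform of a raw scan into a spectral cube
#'
#' For each band, the fringe spectrum is multiplied by a Gaussian window in
#' k (centered at `2 pi / lambda_c`, FWHM `2 pi fwhm / lambda_c^2`) and
#' Fourier transformed to depth; the magnitude squared is stored as band
#' intensity. Depth is optical path (um).
#'
#' @param raw A [simulate_volume()] / [mirror_raw_scan()] style `raw_scan`
#'   with a uniform, strictly increasing k grid.
#' @param band_centers Band center wavelengths (nm); default 22 bands.
#' @param band_fwhm Band FWHM in nm (default 20). A band whose
#'   `center +/- 1.5 fwhm` extends beyond the acquired spectrum is an
#'   error.
#' @param z_max_um Optional crop of the depth axis (optical um).
#' @param z_decim Optional integer depth decimation (bin averaging).
#' @return A `spectral_cube`: `intensity` (band x x x y x z, >= 0),
#'   `band_centers`, `band_fwhm`, `z_grid` (optical um), `acquisition`,
#'   `provenance`.
#' @export
stft_cube <- function(raw, band_centers = default_band_centers(
                        raw$acquisition),
                      band_fwhm = 20, z_max_um = NULL, z_decim = 1L) {
  stopifnot(inherits(raw, "raw_scan"))
  acq <- raw$acquisition
  if (any(band_centers - 1.5 * band_fwhm < acq$lambda_min) ||
      any(band_centers + 1.5 * band_fwhm > acq$lambda_max))
    stop("band extends beyond the acquired spectrum")
  k <- raw$k_grid
  stopifnot(all(diff(k) > 0))
  nk <- length(k)
  d <- dim(raw$fringes)
  fr <- matrix(raw$fringes, nk, d[2] * d[3])
  fr <- sweep(fr, 2L, colMeans(fr))  # remove DC
  zg <- stft_z_grid(acq, z_max_um, z_decim)
  n_keep <- length(zg) * z_decim
  nb <- length(band_centers)
  inten <- array(0, c(nb, d[2], d[3], length(zg)))
  for (b in seq_len(nb)) {
    kc <- 2 * pi / band_centers[b]
    dkw <- 2 * pi * band_fwhm / band_centers[b]^2
    w <- exp(-4 * log(2) * (k - kc)^2 / dkw^2)
    w <- w / sqrt(sum(w^2))  # unit-energy window: uniform band gain
    A <- stats::mvfft(fr * w)[seq_len(n_keep), , drop = FALSE]
    I <- Mod(A)^2 / nk
    if (z_decim > 1L) {
      dim(I) <- c(z_decim, length(zg), ncol(I))
      I <- colMeans(I)
    } else {
      I <- t(I)
      dim(I) <- c(ncol(fr), length(zg))
      inten[b, , , ] <- I
      next
    }
    inten[b, , , ] <- aperm(I, c(2, 1))
  }
  new_spectral_cube(inten, band_centers, band_fwhm, zg, acq,
                    provenance = list(source = "stft",
                                      n_bands = nb, fwhm_nm = band_fwhm))
}

#' Full-band (non-spectroscopic) intensity volume
#'
#' The conventional OCT image: magnitude-squared Fourier transform of the
#' unwindowed fringes. Its axial point-spread function is the full-bandwidth
#' one, finer than any band image.
#'
#' @inheritParams stft_cube
#' @return A list with `intensity` (x, y, z) and `z_grid` (optical um).
#' @export
full_band_intensity <- function(raw, z_max_um = NULL) {
  acq <- raw$acquisition
  nk <- length(raw$k_grid)
  d <- dim(raw$fringes)
  fr <- matrix(raw$fringes, nk, d[2] * d[3])
  fr <- sweep(fr, 2L, colMeans(fr))
  zg <- stft_z_grid(acq, z_max_um)
  A <- stats::mvfft(fr)[seq_along(zg), , drop = FALSE]
  I <- t(Mod(A)^2 / nk)
  dim(I) <- c(d[2], d[3], length(zg))
  list(intensity = I, z_grid = zg)
}

#' Compensate the spectrometer sensitivity roll-off
#'
#' Divides each voxel by the known depth sensitivity profile
#' `rolloff(z)^2` recorded in the acquisition metadata (intensity dB/mm of
#' optical path), so that residual depth decay reflects sample attenuation
#' only.
#'
#' @param cube A `spectral_cube`.
#' @return The compensated cube (provenance updated).
#' @export
compensate_rolloff <- function(cube) {
  r2 <- rolloff_amplitude(cube$z_grid,
                          cube$acquisition$rolloff_db_per_mm)^2
  cube$intensity <- sweep(cube$intensity, 4L, r2, "/")
  cube$provenance <- c(cube$provenance, list(rolloff_compensated = TRUE))
  cube
}

#' Calibrate band spectra against a Rayleigh-scattering reference
#'
#' Divides each band by the reference band spectrum, expressing sample
#' spectra relative to the bead standard (whose known backscatter model,
#' `lambda^-4` for Rayleigh-regime spheres, restores absolute shape and
#' scale downstream via [mu_b_spectrum()]'s calibration vector). With
#' `reference = NULL` the analytic Rayleigh stand-in is used: each band is
#' divided by the `(lambda/lambda_ref)^-4` model factor only.
#'
#' @param cube A `spectral_cube`.
#' @param reference Either a per-band numeric vector of reference
#'   intensities (e.g. the depth-averaged, attenuation-compensated spectrum
#'   of a bead-standard scan), a reference `spectral_cube` (its voxelwise
#'   mean spectrum is used), or `NULL` for the analytic model.
#' @param min_rel Bands whose reference value is below `min_rel` times the
#'   reference maximum are masked (set `NA`), never divided.
#' @return The calibrated cube; masked bands recorded in provenance.
#' @export
reference_calibrate <- function(cube, reference = NULL, min_rel = 1e-8) {
  nb <- length(cube$band_centers)
  if (is.null(reference)) {
    ref <- (cube$band_centers / cube$band_centers[1])^-4
    mode <- "analytic rayleigh"
  } else if (inherits(reference, "spectral_cube")) {
    stopifnot(length(reference$band_centers) == nb)
    ref <- apply(reference$intensity, 1L, mean)
    mode <- "reference cube"
  } else {
    stopifnot(is.numeric(reference), length(reference) == nb)
    ref <- reference
    mode <- "reference spectrum"
  }
  bad <- !is.finite(ref) | ref < min_rel * max(ref, na.rm = TRUE)
  ref[bad] <- NA_real_
  cube$intensity <- sweep(cube$intensity, 1L, ref, "/")
  cube$provenance <- c(cube$provenance,
                       list(calibration = mode,
                            masked_bands = which(bad)))
  cube
}

#' Read/write spectral cubes and raw scans
#'
#' Containers are stored as self-describing serialized R objects with named
#' components (`intensity`/`fringes`, grids, acquisition metadata,
#' provenance); round-trips are bit-exact.
#'
#' @param x A `spectral_cube` or `raw_scan`.
#' @param path File path.
#' @return Readers return the object; writers return `path` invisibly.
#' @export
write_cube <- function(x, path) {
  stopifnot(inherits(x, "spectral_cube"))
  saveRDS(x, path); invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  x <- readRDS(path); stopifnot(inherits(x, "spectral_cube")); x
}

#' @rdname write_cube
#' @export
write_raw_scan <- function(x, path) {
  stopifnot(inherits(x, "raw_scan"))
  saveRDS(x, path); invisible(path)
}

#' @rdname write_cube
#' @export
read_raw_scan <- function(path) {
  x <- readRDS(path); stopifnot(inherits(x, "raw_scan")); x
}
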