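# Forward simulator of spectral-domain OCT volumes. The signal model is the
# one the inversion assumes: per-voxel backscatter amplitude
#   A(z, k) = sqrt(mu_b(k, z) dz) * exp(-integral_0^z mu_t(k, z') dz')
#             * rolloff(z),
# summed over depth with round-trip phase 2 k n z and, in speckle mode, a
# complex circular-Gaussian per-voxel reflectivity (variance proportional to
# mu_b), which produces fully developed speckle with a Rayleigh envelope.
# Detected band *intensity* (magnitude squared) then decays as
# exp(-2 mu_t z): the factor-2 convention shared with the attenuation
# fitter and guarded externally by the Mie standards.

#' Acquisition settings for simulated spectral-domain OCT
#'
#' @param lambda_min,lambda_max Spectral band edges in nm (defaults 520/720).
#' @param n_k Number of wavenumber samples (>= 512).
#' @param nx,ny Lateral raster size (overridden by the phantom when
#'   simulating a volume).
#' @param pixel_pitch_um Lateral pitch in micrometers.
#' @param rolloff_db_per_mm Depth sensitivity roll-off of the spectrometer,
#'   dB of *intensity* per mm of optical path (negative; default -10).
#' @param noise_rel Additive detector noise standard deviation relative to
#'   the RMS fringe amplitude; `10^(-SNR_dB/20)` for a target SNR.
#' @param medium_index Refractive index used for the optical-path phase.
#' @param rng_seed Integer seed; mandatory, all stochastic generation is
#'   reproducible from (phantom, acquisition, seed).
#' @return An object of class `oct_acquisition`.
#' @export
oct_acquisition <- function(lambda_min = 520, lambda_max = 720,
                            n_k = 1024L, nx = 64L, ny = 64L,
                            pixel_pitch_um = 5, rolloff_db_per_mm = -10,
                            noise_rel = 0, medium_index = 1.35,
                            rng_seed) {
  if (missing(rng_seed) || !is.numeric(rng_seed))
    stop("`rng_seed` is mandatory: stochastic generation must be seeded")
  if (lambda_min >= lambda_max) stop("`lambda_min` must be < `lambda_max`")
  if (n_k < 512L) stop("`n_k` must be >= 512")
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max,
                 n_k = as.integer(n_k), nx = as.integer(nx),
                 ny = as.integer(ny), pixel_pitch_um = pixel_pitch_um,
                 rolloff_db_per_mm = rolloff_db_per_mm,
                 noise_rel = noise_rel, medium_index = medium_index,
                 rng_seed = as.integer(rng_seed)),
            class = "oct_acquisition")
}

# Uniform wavenumber grid (1/nm), strictly increasing.
acq_k_grid <- function(acq) {
  seq(2 * pi / acq$lambda_max, 2 * pi / acq$lambda_min,
      length.out = acq$n_k)
}

# Spectrometer sensitivity amplitude factor at optical depth z (um).
rolloff_amplitude <- function(z_opt_um, rolloff_db_per_mm) {
  10^(rolloff_db_per_mm * (z_opt_um / 1000) / 20)
}

# Complex per-(k, z) transfer matrix of one column profile: amplitude x
# round-trip phase, on the geometric voxel grid z_geom (um).
column_transfer <- function(phantom, region, surface_um, z_geom, k_grid,
                            rolloff_db_per_mm) {
  lam_k <- 2 * pi / k_grid
  sp <- region_spectra_at(phantom, region, lam_k)  # [n_k x n_layer]
  lay <- column_layers(phantom, region, surface_um, z_geom)
  n_k <- length(k_grid); n_z <- length(z_geom)
  dz_cm <- phantom$dz_um * 1e-4
  mu_t <- matrix(0, n_k, n_z); mu_b <- matrix(0, n_k, n_z)
  inside <- lay > 0L
  if (any(inside)) {
    mu_t[, inside] <- sp$mu_t[, lay[inside], drop = FALSE]
    mu_b[, inside] <- sp$mu_b[, lay[inside], drop = FALSE]
  }
  od <- t(apply(mu_t * dz_cm, 1L, cumsum)) - mu_t * dz_cm / 2
  n_med <- phantom$medium_index
  z_opt_um <- z_geom * n_med
  roll <- rolloff_amplitude(z_opt_um, rolloff_db_per_mm)
  amp <- sqrt(mu_b * dz_cm) * exp(-od) *
    matrix(roll, n_k, n_z, byrow = TRUE)
  phase <- exp(1i * 2 * outer(k_grid, z_opt_um * 1000))  # z in nm
  amp * phase
}

#' Simulate a full OCT volume from a phantom
#'
#' Rasterizes the column-wise signal model over (x, y). Columns sharing a
#' surface-voxel depth and region reuse one transfer matrix; speckle draws
#' are independent per column and voxel. Bit-identical output is guaranteed
#' for a fixed (phantom, acquisition, seed).
#'
#' @param phantom A [make_phantom()] object.
#' @param acq An [oct_acquisition()]; its `nx`, `ny` are taken from the
#'   phantom.
#' @param speckle Draw complex circular-Gaussian per-voxel reflectivities
#'   (`TRUE`, fully developed speckle) or use the deterministic mean
#'   amplitude (`FALSE`, speckle-free mode).
#' @return An object of class `raw_scan`: `fringes` (n_k x nx x ny array of
#'   real-valued interferogram spectra), `k_grid` (1/nm), `acquisition`,
#'   `ground_truth` (the phantom), `speckle`.
#' @export
simulate_volume <- function(phantom, acq, speckle = TRUE) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "oct_acquisition"))
  acq$nx <- phantom$nx; acq$ny <- phantom$ny
  set.seed(acq$rng_seed)
  k_grid <- acq_k_grid(acq)
  z_geom <- seq(phantom$dz_um / 2, phantom$depth_um, by = phantom$dz_um)
  n_cols <- phantom$nx * phantom$ny
  surf_bin <- round(phantom$surface_um / phantom$dz_um)
  key <- paste(as.vector(phantom$region_map), as.vector(surf_bin))
  groups <- split(seq_len(n_cols), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]  # deterministic
  fr <- matrix(0, acq$n_k, n_cols)
  for (gi in seq_along(groups)) {
    cols <- groups[[gi]]
    region <- as.vector(phantom$region_map)[cols[1]]
    s_um <- surf_bin[cols[1]] * phantom$dz_um
    keep <- z_geom >= s_um - phantom$dz_um  # drop empty rows above surface
    W <- column_transfer(phantom, region, s_um, z_geom[keep], k_grid,
                         acq$rolloff_db_per_mm)
    n_z <- sum(keep)
    if (speckle) {
      R <- matrix(complex(real = stats::rnorm(n_z * length(cols)),
                          imaginary = stats::rnorm(n_z * length(cols))) /
                    sqrt(2), n_z, length(cols))
      fr[, cols] <- Re(W %*% R)
    } else {
      fr[, cols] <- Re(rowSums(W))
    }
  }
  if (acq$noise_rel > 0) {
    sigma <- acq$noise_rel * sqrt(mean(fr^2))
    fr <- fr + stats::rnorm(length(fr), sd = sigma)
  }
  structure(list(fringes = array(fr, c(acq$n_k, phantom$nx, phantom$ny)),
                 k_grid = k_grid, acquisition = acq,
                 ground_truth = phantom, speckle = speckle),
            class = "raw_scan")
}

#' Simulate a single A-line
#'
#' One-column convenience wrapper around the volume engine.
#'
#' @inheritParams simulate_volume
#' @param x,y Column indices into the phantom raster.
#' @return Numeric fringe spectrum of length `acq$n_k`.
#' @export
simulate_aline <- function(phantom, acq, x = 1L, y = 1L, speckle = TRUE) {
  sub <- phantom
  sub$nx <- 1L; sub$ny <- 1L
  sub$region_map <- phantom$region_map[x, y, drop = FALSE]
  sub$surface_um <- phantom$surface_um[x, y, drop = FALSE]
  simulate_volume(sub, acq, speckle = speckle)$fringes[, 1L, 1L]
}

#' Ideal-mirror raw scan
#'
#' A single specular reflector at geometric depth `z0_um` in the medium:
#' `S(k) = cos(2 k n z0)` for every column. Used for point-spread-function
#' and depth-calibration checks.
#'
#' @param z0_um Mirror depth, geometric micrometers.
#' @param acq An [oct_acquisition()].
#' @return A `raw_scan` (with `ground_truth = NULL`).
#' @export
mirror_raw_scan <- function(z0_um, acq) {
  k_grid <- acq_k_grid(acq)
  z_nm <- z0_um * acq$medium_index * 1000
  fr <- matrix(cos(2 * k_grid * z_nm), acq$n_k, acq$nx * acq$ny)
  structure(list(fringes = array(fr, c(acq$n_k, acq$nx, acq$ny)),
                 k_grid = k_grid, acquisition = acq, ground_truth = NULL,
                 speckle = FALSE),
            class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  d <- dim(x$fringes)
  cat(sprintf("<raw_scan> %d k-samples x %d x %d columns (%s%s)\n",
              d[1], d[2], d[3],
              if (x$speckle) "speckle" else "speckle-free",
              if (is.null(x$ground_truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Analytic noiseless band-intensity cube of a phantom
#'
#' Evaluates the simulator's signal-model *intensity* directly on the STFT
#' depth grid, bypassing fringe synthesis and transform:
#' `I(band, x, y, z) = mu_b dz exp(-2 OD) rolloff^2` below the surface.
#' This is the exact Beer-Lambert contract of the simulator and serves as
#' the strict reference for fitting and compensation tests.
#'
#' @inheritParams simulate_volume
#' @param band_centers,band_fwhm Spectral bands as in [stft_cube()].
#' @return A `spectral_cube` (see [stft_cube()]) with analytic provenance.
#' @export
model_cube <- function(phantom, acq,
                       band_centers = default_band_centers(acq),
                       band_fwhm = 20) {
  acq$nx <- phantom$nx; acq$ny <- phantom$ny
  zg <- stft_z_grid(acq)          # optical um
  n_med <- phantom$medium_index
  z_geom <- zg / n_med
  nb <- length(band_centers)
  dz_cm <- mean(diff(z_geom)) * 1e-4
  roll2 <- rolloff_amplitude(zg, acq$rolloff_db_per_mm)^2
  surf_bin <- round(phantom$surface_um / phantom$dz_um)
  key <- paste(as.vector(phantom$region_map), as.vector(surf_bin))
  groups <- split(seq_len(phantom$nx * phantom$ny), key)
  inten <- array(0, c(nb, phantom$nx, phantom$ny, length(zg)))
  flat <- matrix(0, nb * phantom$nx * phantom$ny, length(zg))
  dim(inten) <- c(nb, phantom$nx * phantom$ny, length(zg))
  for (cols in groups) {
    region <- as.vector(phantom$region_map)[cols[1]]
    s_um <- surf_bin[cols[1]] * phantom$dz_um
    sp <- region_spectra_at(phantom, region, band_centers)
    lay <- column_layers(phantom, region, s_um, z_geom)
    inside <- lay > 0L
    mu_t <- matrix(0, nb, length(zg)); mu_b <- matrix(0, nb, length(zg))
    if (any(inside)) {
      mu_t[, inside] <- sp$mu_t[, lay[inside], drop = FALSE]
      mu_b[, inside] <- sp$mu_b[, lay[inside], drop = FALSE]
    }
    od <- t(apply(mu_t * dz_cm, 1L, cumsum)) - mu_t * dz_cm / 2
    I <- mu_b * dz_cm * exp(-2 * od) *
      matrix(roll2, nb, length(zg), byrow = TRUE)
    for (cc in cols) inten[, cc, ] <- I
  }
  dim(inten) <- c(nb, phantom$nx, phantom$ny, length(zg))
  new_spectral_cube(inten, band_centers, band_fwhm, zg, acq,
                    provenance = list(source = "analytic signal model"))
}
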