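# Wavelength-resolved total attenuation: weighted linear regression of
# log band intensity against optical depth over a fixed window below the
# detected surface. Intensity is magnitude squared, so mu_t = -slope/2
# (converted from optical to geometric path by the medium index); the
# simulator shares the same convention and the Mie bead standards guard the
# factor of 2 externally.

#' Subtract the per-band detector noise floor from a cube
#'
#' Estimates the noise floor of each band as the median intensity over the
#' empty region above the shallowest detected surface (excluding the lowest
#' depth bins where transform leakage lives) and subtracts it, clamping at
#' zero. The flat noise floor otherwise tilts weak bands and biases both
#' the Beer-Lambert slope and the backscatter spectral slope; subtraction
#' must happen before attenuation compensation, which amplifies the floor
#' depth-dependently. A no-op (with a provenance note) when no empty
#' region is available.
#'
#' @param cube A `spectral_cube`.
#' @param surface A `surface_map` locating the empty region.
#' @param margin_um Keep-out margin above the shallowest surface (optical
#'   um).
#' @param z_min_um Shallow cutoff excluding transform-leakage bins.
#' @return The floor-subtracted cube.
#' @export
subtract_noise_floor <- function(cube, surface, margin_um = 15,
                                 z_min_um = 8) {
  zg <- cube$z_grid
  zs_min <- suppressWarnings(min(surface$z_um[surface$valid]))
  sel <- is.finite(zs_min) & zg > z_min_um & zg < zs_min - margin_um
  if (sum(sel) < 5L) {
    cube$provenance <- c(cube$provenance,
                         list(noise_floor = "no empty region; skipped"))
    return(cube)
  }
  nb <- dim(cube$intensity)[1]
  v <- cube$intensity
  dim(v) <- c(nb, prod(dim(cube$intensity)[2:3]),
              dim(cube$intensity)[4])
  floor_b <- apply(v[, , sel, drop = FALSE], 1L, stats::median)
  cube$intensity <- pmax(sweep(cube$intensity, 1L, floor_b), 0)
  cube$provenance <- c(cube$provenance,
                       list(noise_floor_subtracted = TRUE))
  cube
}

# 2-D lateral box smoothing of the cube along (x, y), all bands/depths.
smooth_cube_lateral <- function(intensity, k = 3L) {
  if (k <= 1L) return(intensity)
  d <- dim(intensity)
  half <- (k - 1L) %/% 2L
  sm <- array(0, d); cnt <- array(0, d)
  for (dx in -half:half) {
    xi <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    for (dy in -half:half) {
      yi <- pmin(pmax(seq_len(d[3]) + dy, 1L), d[3])
      sm <- sm + intensity[, xi, yi, , drop = FALSE]
      cnt <- cnt + 1
    }
  }
  sm / cnt
}

#' Fit the total attenuation coefficient below the surface
#'
#' For every valid lateral position and every band, performs a linear
#' regression of `log(intensity)` against optical depth over
#' `[z_surface, z_surface + depth_window]`, optionally weighted by
#' intensity (de-emphasizing noise-floor voxels) and preceded by lateral
#' speckle averaging. The geometric-path attenuation coefficient is
#' `mu_t = -slope * medium_index / 2` (1/cm). Negative fits are floored at
#' zero and flagged; columns with fewer than `min_samples` depth samples
#' are invalid.
#'
#' @param cube A `spectral_cube` (roll-off compensated).
#' @param surface A `surface_map` (optical-path depths).
#' @param depth_window_um Fit window in optical-path micrometers
#'   (default 90).
#' @param lateral_kernel Lateral box-averaging kernel width in columns
#'   (default 3; 0 or 1 disables).
#' @param min_samples Minimum depth samples required in the window.
#' @param weighted Intensity-weight the regression?
#' @param z_offset_um Start of the fit below the detected surface (optical
#'   um), skipping the point-spread-function ramp at the surface onset.
#' @return An object of class `attenuation_maps`: `mu_t` (band x nx x ny,
#'   1/cm geometric), `r2`, `clipped`, `valid`, `band_centers`,
#'   `depth_window_um`.
#' @export
fit_mu_t <- function(cube, surface, depth_window_um = 90,
                     lateral_kernel = 3L, min_samples = 5L,
                     weighted = TRUE, z_offset_um = 4) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(surface, "surface_map"))
  I <- smooth_cube_lateral(cube$intensity, lateral_kernel)
  zg <- cube$z_grid
  nb <- dim(I)[1]; nx <- dim(I)[2]; ny <- dim(I)[3]
  n_med <- cube$acquisition$medium_index
  mu <- matrix(NA_real_, nb, nx * ny)
  r2 <- matrix(NA_real_, nb, nx * ny)
  clip <- matrix(FALSE, nb, nx * ny)
  valid <- surface$valid
  cols <- which(valid)
  if (length(cols)) {
    i0 <- findInterval(surface$z_um[cols] + z_offset_um - 1e-9, zg) + 1L
    groups <- split(seq_along(cols), i0)
    dim(I) <- c(nb, nx * ny, length(zg))
    for (gk in names(groups)) {
      g0 <- as.integer(gk)
      gi <- groups[[gk]]
      ccols <- cols[gi]
      i1 <- max(which(zg <= zg[g0] + depth_window_um - z_offset_um))
      if (i1 - g0 + 1L < min_samples) { valid[ccols] <- FALSE; next }
      zw <- zg[g0:i1]
      for (b in seq_len(nb)) {
        Y <- I[b, ccols, g0:i1, drop = FALSE]
        dim(Y) <- c(length(ccols), length(zw))
        W <- if (weighted) pmax(Y, 0) else matrix(1, nrow(Y), ncol(Y))
        L <- log(pmax(Y, 1e-300))
        sw <- rowSums(W)
        xb <- (W %*% zw) / sw
        yb <- rowSums(W * L) / sw
        xc <- outer(rep(1, length(ccols)), zw) - as.vector(xb)
        sxx <- rowSums(W * xc^2)
        sxy <- rowSums(W * xc * L)
        slope <- sxy / sxx               # per optical um
        ybar <- yb
        res <- L - ybar - xc * slope
        sst <- rowSums(W * (L - ybar)^2)
        rr <- 1 - rowSums(W * res^2) / pmax(sst, 1e-300)
        m <- -slope / 2 * n_med * 1e4    # 1/cm geometric
        cl <- m < 0
        m[cl] <- 0
        mu[b, ccols] <- m
        r2[b, ccols] <- rr
        clip[b, ccols] <- cl
      }
    }
  }
  dim(mu) <- c(nb, nx, ny); dim(r2) <- c(nb, nx, ny)
  dim(clip) <- c(nb, nx, ny)
  structure(list(mu_t = mu, r2 = r2, clipped = clip, valid = valid,
                 band_centers = cube$band_centers,
                 depth_window_um = depth_window_um,
                 lateral_kernel = lateral_kernel),
            class = "attenuation_maps")
}

#' @export
print.attenuation_maps <- function(x, ...) {
  cat(sprintf(paste0("<attenuation_maps> %d bands x %d x %d, window %g um,",
                     " median mu_t %.1f 1/cm\n"),
              dim(x$mu_t)[1], dim(x$mu_t)[2], dim(x$mu_t)[3],
              x$depth_window_um, stats::median(x$mu_t, na.rm = TRUE)))
  invisible(x)
}

#' Compensate band intensities for overlying attenuation
#'
#' Divides every voxel below the surface by
#' `exp(-2 mu_t(band) (z - z_surface))` using that column's fitted
#' attenuation, so the residual depth profile reflects backscatter only.
#'
#' @param cube A `spectral_cube`.
#' @param atten An [fit_mu_t()] result.
#' @param surface The `surface_map` used for the fit.
#' @return The compensated cube (provenance updated).
#' @export
compensate_attenuation <- function(cube, atten, surface) {
  zg <- cube$z_grid
  n_med <- cube$acquisition$medium_index
  nb <- dim(cube$intensity)[1]
  dims <- dim(cube$intensity)
  I <- cube$intensity
  dim(I) <- c(nb, dims[2] * dims[3], dims[4])
  amu <- atten$mu_t
  dim(amu) <- c(nb, dims[2] * dims[3])
  for (ci in which(surface$valid & atten$valid)) {
    zs <- surface$z_um[ci]
    mu_opt <- amu[, ci] / (n_med * 1e4)  # per optical um
    dz <- pmax(zg - zs, 0)
    fac <- exp(2 * outer(mu_opt, dz))
    I[, ci, ] <- I[, ci, ] * fac
  }
  dim(I) <- dims
  cube$intensity <- I
  cube$provenance <- c(cube$provenance,
                       list(attenuation_compensated = TRUE))
  cube
}

#' Backscattering spectrum from the compensated cube
#'
#' Per column and band, the mean compensated intensity over the first
#' `depth_window_um` (optical path) below the surface, converted to the
#' backscattering coefficient via the bead-standard calibration vector.
#' Returned in both conventions: `mu_b` is the amplitude-convention
#' spectrum (square root of calibrated power; its log-log wavelength slope
#' is `D/2 - 2` and it is the input to [fit_D_from_mub()]), and
#' `mu_b_power` the power convention (1/cm) used for the albedo.
#'
#' @param cube A compensated `spectral_cube`.
#' @param surface A `surface_map`.
#' @param depth_window_um Averaging window (optical um, default 90).
#' @param calibration Per-band amplitude calibration vector
#'   `sqrt(mu_b_ref_power / I_ref)` from a reference standard; default 1
#'   (uncalibrated, arbitrary units).
#' @param lateral_kernel Lateral box averaging (columns) before extraction.
#' @return An object of class `mu_b_maps`: `mu_b`, `mu_b_power`
#'   (band x nx x ny), `band_centers`, `valid`.
#' @export
mu_b_spectrum <- function(cube, surface, depth_window_um = 90,
                          calibration = NULL, lateral_kernel = 3L) {
  zg <- cube$z_grid
  I <- smooth_cube_lateral(cube$intensity, lateral_kernel)
  nb <- dim(I)[1]; nx <- dim(I)[2]; ny <- dim(I)[3]
  if (is.null(calibration)) calibration <- rep(1, nb)
  stopifnot(length(calibration) == nb)
  M <- matrix(NA_real_, nb, nx * ny)
  dim(I) <- c(nb, nx * ny, length(zg))
  for (ci in which(surface$valid)) {
    zs <- surface$z_um[ci]
    sel <- zg >= zs & zg <= zs + depth_window_um
    if (!any(sel)) next
    M[, ci] <- rowMeans(I[, ci, sel, drop = FALSE])
  }
  vall <- surface$valid & is.finite(matrix(M[1, ], nx, ny))
  dim(M) <- c(nb, nx, ny)
  amp <- sweep(sqrt(pmax(M, 0)), 1L, calibration, "*")
  structure(list(mu_b = amp, mu_b_power = amp^2,
                 band_centers = cube$band_centers,
                 valid = vall),
            class = "mu_b_maps")
}
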