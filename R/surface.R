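# Surface detection per B-scan: contrast normalization, extended-maxima
# binarization (h-maxima by grayscale geodesic reconstruction), binary
# morphological cleanup, then the first above-threshold voxel per column.
# Detected surfaces are stitched over B-scans into a per-(x, y) SurfaceMap
# whose validity mask gates every downstream fit.

# 8-neighborhood shift with constant padding.
shift_pad <- function(M, di, dj, fill = -Inf) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(fill, n, m)
  si <- seq_len(n) - di; sj <- seq_len(m) - dj
  ok_i <- si >= 1 & si <= n; ok_j <- sj >= 1 & sj <= m
  out[ok_i, ok_j] <- M[si[ok_i], sj[ok_j]]
  out
}

# Grayscale reconstruction of `marker` under `mask` by sequential
# directional sweeps (each sweep propagates fully along its direction, so
# a handful of passes converge).
gray_reconstruct <- function(marker, mask, max_pass = 64L, tol = 1e-10) {
  J <- pmin(marker, mask)
  nz <- nrow(J); nx <- ncol(J)
  lat <- function(r) pmax(r, c(r[1], r[-nx]), c(r[-1], r[nx]))
  for (p in seq_len(max_pass)) {
    old <- J
    for (z in 2:nz) J[z, ] <- pmin(pmax(lat(J[z - 1L, ]), J[z, ]),
                                   mask[z, ])
    for (z in (nz - 1L):1L) J[z, ] <- pmin(pmax(lat(J[z + 1L, ]), J[z, ]),
                                           mask[z, ])
    latz <- function(r) pmax(r, c(r[1], r[-nz]), c(r[-1], r[nz]))
    for (x in 2:nx) J[, x] <- pmin(pmax(latz(J[, x - 1L]), J[, x]),
                                   mask[, x])
    for (x in (nx - 1L):1L) J[, x] <- pmin(pmax(latz(J[, x + 1L]), J[, x]),
                                           mask[, x])
    if (max(abs(J - old)) < tol) break
  }
  J
}

# Extended-maxima binarization: regions whose dome height exceeds h.
extended_maxima <- function(I, h) {
  J <- gray_reconstruct(I - h, I)
  (I - J) >= h * (1 - 1e-6)
}

# Binary reconstruction of `marker` within `mask` via the grayscale sweeps.
binary_reconstruct <- function(marker, mask) {
  gray_reconstruct((marker & mask) * 1, mask * 1) > 0.5
}

# 3x3 binary morphology with edge replication (no boundary shrink).
shift_clamp <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  si <- pmin(pmax(seq_len(n) - di, 1L), n)
  sj <- pmin(pmax(seq_len(m) - dj, 1L), m)
  M[si, sj, drop = FALSE]
}

binary_erode3 <- function(B) {
  out <- B
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out & shift_clamp(B, di, dj)
  }
  out
}

binary_dilate3 <- function(B) {
  out <- B
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out | shift_clamp(B, di, dj)
  }
  out
}

#' Detect the sample surface in a spectral cube
#'
#' Two-stage detection on the band-summed intensity. First, the sample
#' region of each B-scan (a depth-by-x image) is delineated: intensities
#' are speckle-averaged and contrast-normalized, an extended-maxima
#' transform (dome height `h`) marks confidently bright sample structure,
#' and the full sample band is recovered by binary morphological
#' reconstruction of those markers within the above-background mask,
#' followed by closing/opening cleanup and a minimum-object-size filter
#' (noise-floor blobs contain no marker and are discarded). Second, the
#' surface depth of each column is refined at full axial resolution as the
#' first half-maximum crossing of the laterally speckle-averaged (axially
#' unsmoothed) intensity profile near the top of the detected region.
#' Columns with no detected region are flagged invalid
#' (`reason = "no-edge"`), never an error.
#'
#' The `h` parameter and morphology sizes have defaults tuned on the
#' package's simulated phantom suite and are exposed in the processing
#' configuration.
#'
#' @param cube A `spectral_cube` (or a list with `intensity` (x, y, z) and
#'   `z_grid` as returned by [full_band_intensity()]).
#' @param h Extended-maxima dome height, relative to the contrast-
#'   normalized B-scan.
#' @param min_object_px Minimum connected-component size kept (pixels).
#' @param lateral_kernel Lateral speckle-averaging kernel (columns) for the
#'   onset refinement profile.
#' @param onset_frac Fraction of the local plateau intensity defining the
#'   surface onset.
#' @param mask_level Above-background level (relative intensity) bounding
#'   the reconstruction of the sample band.
#' @return An object of class `surface_map`: `z_um` (optical-path surface
#'   depth, NA where invalid), `valid`, `reason` (""/"no-edge"), `method`.
#' @export
detect_surface <- function(cube, h = 0.1, min_object_px = 30L,
                           lateral_kernel = 9L, onset_frac = 0.5,
                           mask_level = 0.02) {
  if (inherits(cube, "spectral_cube")) {
    vol <- apply(cube$intensity, c(2, 3, 4), sum)
    zg <- cube$z_grid
  } else {
    vol <- cube$intensity; zg <- cube$z_grid
  }
  if (any(vol < 0)) stop("B-scan intensity must be nonnegative")
  nx <- dim(vol)[1]; ny <- dim(vol)[2]; nz <- dim(vol)[3]
  sm <- vol
  dim(sm) <- c(1L, nx, ny, nz)
  sm <- smooth_cube_lateral(sm, lateral_kernel)
  dim(sm) <- c(nx, ny, nz)
  z_um <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) {
    P <- t(sm[, j, ])  # z x x, laterally speckle-averaged
    q <- stats::quantile(P, 0.999)
    if (q <= 0) next  # fully dark B-scan: all columns invalid
    I <- pmin(P / q, 1)
    # light axial smoothing for the region image only
    I <- (I + shift_pad(I, 1, 0, fill = 0) +
            shift_pad(I, -1, 0, fill = 0)) / 3
    markers <- extended_maxima(I, h)
    B <- binary_reconstruct(markers, I > mask_level)
    B <- binary_erode3(binary_dilate3(B))   # closing
    B <- binary_dilate3(binary_erode3(B))   # opening
    if (any(B)) {
      lab <- EBImage::bwlabel(EBImage::Image(B * 1))
      sizes <- table(lab[lab > 0])
      small <- as.integer(names(sizes)[sizes < min_object_px])
      B[matrix(as.integer(lab), nrow(B)) %in% small] <- FALSE
    }
    for (i in seq_len(nx)) {
      reg <- which(B[, i])
      if (!length(reg)) next
      i0 <- reg[1]
      top <- min(nz, i0 + 30L)
      plateau <- stats::quantile(P[i0:top, i], 0.9, names = FALSE)
      lo <- max(1L, i0 - 10L)
      thr <- onset_frac * plateau
      onset <- which(P[lo:top, i] >= thr)[1]
      if (is.na(onset)) next
      k <- lo + onset - 1L
      # sub-pixel linear interpolation of the threshold crossing
      if (k > 1L && P[k, i] > P[k - 1L, i] && P[k - 1L, i] < thr) {
        fr <- (thr - P[k - 1L, i]) / (P[k, i] - P[k - 1L, i])
        z_um[i, j] <- zg[k - 1L] + fr * (zg[k] - zg[k - 1L])
      } else {
        z_um[i, j] <- zg[k]
      }
    }
  }
  z_um <- median_filter_na(z_um)
  valid <- is.finite(z_um)
  reason <- matrix(ifelse(valid, "", "no-edge"), nx, ny)
  structure(list(z_um = z_um, valid = valid, reason = reason,
                 method = "detected"),
            class = "surface_map")
}

# NA-aware 3x3 median filter for surface-map cleanup: each detected depth
# is replaced by the median of the valid values in its neighborhood (the
# surface is laterally smooth at the pixel scale, so this suppresses
# per-column speckle outliers without moving ramps).
median_filter_na <- function(z) {
  nx <- nrow(z); ny <- ncol(z)
  out <- z
  stack <- array(NA_real_, c(nx, ny, 9L))
  s <- 1L
  for (di in -1:1) for (dj in -1:1) {
    xi <- pmin(pmax(seq_len(nx) + di, 1L), nx)
    yi <- pmin(pmax(seq_len(ny) + dj, 1L), ny)
    stack[, , s] <- z[xi, yi]
    s <- s + 1L
  }
  med <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  out[is.finite(z)] <- med[is.finite(z)]
  out
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d x %d columns, %.1f%% valid (%s)\n",
              nrow(x$z_um), ncol(x$z_um), 100 * mean(x$valid), x$method))
  invisible(x)
}

#' Load a manual surface segmentation
#'
#' Reads a single-channel image mask (TIFF or PNG) whose nonzero pixels
#' override detection: the pixel value encodes the surface depth in
#' optical-path micrometers (scaled by `depth_scale` for integer-valued
#' formats). Dimensions must match the scan raster.
#'
#' @param path Mask file, or a numeric matrix given directly.
#' @param dims Expected `c(nx, ny)` raster size.
#' @param depth_scale Multiplier from stored pixel value to micrometers.
#' @return A `surface_map` with `method = "manual"`; zero-valued pixels are
#'   invalid (no override).
#' @export
load_manual_surface <- function(path, dims, depth_scale = 1) {
  m <- if (is.matrix(path)) path else {
    img <- if (grepl("\\.png$", path, ignore.case = TRUE))
      png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    t(img)  # image row = y; store as (x, y)
  }
  if (!all(dim(m) == dims))
    stop(sprintf("manual mask is %d x %d but scan is %d x %d",
                 nrow(m), ncol(m), dims[1], dims[2]))
  z <- m * depth_scale
  valid <- is.finite(z) & z > 0
  z[!valid] <- NA_real_
  structure(list(z_um = z, valid = valid,
                 reason = matrix(ifelse(valid, "", "no-edge"), dims[1],
                                 dims[2]),
                 method = "manual"),
            class = "surface_map")
}

#' Merge manual and detected surfaces
#'
#' Manual segmentation overrides detection wherever both exist; detection
#' fills the rest. The downstream contract is identical for either source.
#'
#' @param detected,manual `surface_map` objects of equal size.
#' @return A merged `surface_map` (`method = "detected+manual"`).
#' @export
merge_surfaces <- function(detected, manual) {
  stopifnot(all(dim(detected$z_um) == dim(manual$z_um)))
  out <- detected
  take <- manual$valid
  out$z_um[take] <- manual$z_um[take]
  out$valid <- out$valid | take
  out$reason[take] <- ""
  out$method <- "detected+manual"
  out
}

#' Apply roll-off and specular validity filters
#'
#' Invalidates columns whose surface lies deeper than the configured
#' sensitivity budget allows (predicted roll-off loss
#' `|rolloff_db_per_mm| * z` exceeding `rolloff_limit_db`), and columns
#' whose surface-voxel intensity exceeds `specular_threshold` times the
#' median surface intensity (saturated mirror-like reflections). Thresholds
#' of `Inf` leave the mask unchanged.
#'
#' @param surface A `surface_map`.
#' @param cube The `spectral_cube` the surface was detected in.
#' @param rolloff_limit_db Maximum tolerated predicted sensitivity loss, dB.
#' @param specular_threshold Relative surface-intensity threshold.
#' @return The filtered `surface_map` with updated `reason` codes
#'   (`"roll-off"`, `"specular"`).
#' @export
apply_validity_filters <- function(surface, cube, rolloff_limit_db = Inf,
                                   specular_threshold = Inf) {
  z <- surface$z_um
  acq <- cube$acquisition
  if (is.finite(rolloff_limit_db)) {
    loss_db <- abs(acq$rolloff_db_per_mm) * z / 1000
    bad <- surface$valid & is.finite(loss_db) & loss_db > rolloff_limit_db
    surface$valid[bad] <- FALSE
    surface$reason[bad] <- "roll-off"
  }
  if (is.finite(specular_threshold)) {
    vol <- apply(cube$intensity, c(2, 3, 4), sum)
    zi <- matrix(NA_integer_, nrow(z), ncol(z))
    zi[surface$valid] <- vapply(which(surface$valid), function(i) {
      which.min(abs(cube$z_grid - z[i]))
    }, integer(1))
    si <- matrix(NA_real_, nrow(z), ncol(z))
    for (i in which(surface$valid)) {
      xy <- arrayInd(i, dim(z))
      si[i] <- vol[xy[1], xy[2], zi[i]]
    }
    med <- stats::median(si[surface$valid], na.rm = TRUE)
    bad <- surface$valid & is.finite(si) & si > specular_threshold * med
    surface$valid[bad] <- FALSE
    surface$reason[bad] <- "specular"
  }
  surface
}

#' Write / read a surface map
#'
#' Exported as 32-bit float TIFF (depth in um, NaN where invalid) plus a
#' CSV of (x, y, z_um, valid, reason); reading restores the map losslessly
#' from the CSV.
#'
#' @param surface A `surface_map`.
#' @param path_prefix Output path without extension.
#' @return `write_surface_map` returns the paths invisibly;
#'   `read_surface_map` returns the `surface_map`.
#' @export
write_surface_map <- function(surface, path_prefix) {
  z <- surface$z_um
  z[!surface$valid] <- NA_real_
  tif <- paste0(path_prefix, ".tif")
  csv <- paste0(path_prefix, ".csv")
  write_float_tiff(z, tif)
  df <- data.frame(x = as.vector(row(z)), y = as.vector(col(z)),
                   z_um = as.vector(z), valid = as.vector(surface$valid),
                   reason = as.vector(surface$reason),
                   method = surface$method)
  utils::write.csv(df, csv, row.names = FALSE)
  invisible(c(tif, csv))
}

#' @rdname write_surface_map
#' @export
read_surface_map <- function(path_prefix) {
  df <- utils::read.csv(paste0(path_prefix, ".csv"),
                        colClasses = c(reason = "character"))
  nx <- max(df$x); ny <- max(df$y)
  df$reason[is.na(df$reason)] <- ""
  structure(list(z_um = matrix(df$z_um, nx, ny),
                 valid = matrix(df$valid, nx, ny),
                 reason = matrix(df$reason, nx, ny),
                 method = df$method[1]),
            class = "surface_map")
}
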