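# Anisotropy lookup: within the Born model, at fixed wavelength, both the
# reflection albedo alpha = mu_b/mu_s and the anisotropy g are functions of
# (D, Ln) only (An cancels in both ratios). Sweeping Ln therefore traces a
# curve (alpha(Ln), g(Ln)) for each D, which is resampled to a regular
# (albedo, D) -> g table used to invert measured albedos.

#' Build the g(albedo, D) lookup table
#'
#' For each `D` on `D_grid`, sweeps an internal geometric grid of correlation
#' lengths, computes the albedo `alpha = mu_b / mu_s` (power convention) and
#' the anisotropy `g` by quadrature, and resamples `g` onto `albedo_grid` by
#' monotone interpolation in `log(alpha)`. Albedos outside the range
#' achievable at a given `D` yield `NA` (mask), never extrapolation.
#'
#' @param D_grid Strictly increasing shape-parameter grid.
#' @param albedo_grid Strictly increasing albedo grid (dimensionless).
#' @param wavelength Vacuum wavelength in nm at which the table is computed.
#' @param medium_index Medium refractive index.
#' @param solid_angle Collection solid angle (sr) defining `mu_b`; must match
#'   the calibration convention of the measured albedo.
#' @param Ln_grid Internal correlation-length sweep in nm.
#' @return An object of class `g_lookup`: list with matrix `g`
#'   (`length(albedo_grid)` x `length(D_grid)`), the grids, and generation
#'   metadata.
#' @export
build_g_lookup <- function(D_grid = seq(1.2, 6, by = 0.1),
                           albedo_grid = 10^seq(-7, -0.5, length.out = 90),
                           wavelength = 620, medium_index = 1.35,
                           solid_angle = 0.01,
                           Ln_grid = 10^seq(log10(5), log10(20000),
                                            length.out = 80)) {
  stopifnot(all(diff(D_grid) > 0), all(diff(albedo_grid) > 0),
            all(diff(Ln_grid) > 0), length(wavelength) == 1L)
  G <- matrix(NA_real_, nrow = length(albedo_grid), ncol = length(D_grid),
              dimnames = list(albedo = NULL, D = NULL))
  for (j in seq_along(D_grid)) {
    a <- g <- numeric(length(Ln_grid))
    for (i in seq_along(Ln_grid)) {
      p <- wm_params(1, Ln_grid[i], D_grid[j])
      mus <- mu_s_spectrum(p, wavelength, medium_index)$mu_s
      mub <- wm_mu_b(p, wavelength, medium_index, solid_angle, "power")
      a[i] <- mub / mus
      g[i] <- anisotropy_g(p, wavelength, medium_index)
    }
    # alpha decreases with Ln (more forward-peaked scattering); keep the
    # strictly monotone branch for interpolation
    o <- order(a)
    a <- a[o]; g <- g[o]
    keep <- c(TRUE, diff(a) > 0)
    a <- a[keep]; g <- g[keep]
    inside <- albedo_grid >= min(a) & albedo_grid <= max(a)
    if (any(inside)) {
      G[inside, j] <- stats::approx(log(a), g, xout =
                                      log(albedo_grid[inside]))$y
    }
  }
  structure(list(g = G, albedo_grid = albedo_grid, D_grid = D_grid,
                 wavelength = wavelength, medium_index = medium_index,
                 solid_angle = solid_angle, Ln_grid = Ln_grid,
                 version = as.character(utils::packageVersion("isoct"))),
            class = "g_lookup")
}

#' @export
print.g_lookup <- function(x, ...) {
  cat(sprintf(paste0("<g_lookup> %d albedo x %d D values at %g nm ",
                     "(n = %g, dOmega = %g sr)\n"),
              length(x$albedo_grid), length(x$D_grid), x$wavelength,
              x$medium_index, x$solid_angle))
  invisible(x)
}

#' Interpolate g from the lookup table
#'
#' Bilinear interpolation in (`log(albedo)`, `D`). Queries outside the table
#' support, or falling in masked (unachievable-albedo) cells, return `NA`;
#' there is no extrapolation.
#'
#' @param lookup A [build_g_lookup()] table.
#' @param albedo Measured albedo value(s).
#' @param D Shape-parameter value(s), recycled against `albedo`.
#' @return Anisotropy value(s) with `NA` where out of support.
#' @export
g_lookup_interp <- function(lookup, albedo, D) {
  stopifnot(inherits(lookup, "g_lookup"))
  n <- max(length(albedo), length(D))
  albedo <- rep_len(albedo, n); D <- rep_len(D, n)
  la <- log(lookup$albedo_grid)
  Dg <- lookup$D_grid
  out <- rep(NA_real_, n)
  ok <- is.finite(albedo) & is.finite(D) & albedo > 0 &
    albedo >= lookup$albedo_grid[1] &
    albedo <= lookup$albedo_grid[length(la)] &
    D >= Dg[1] & D <= Dg[length(Dg)]
  if (!any(ok)) return(out)
  x <- log(albedo[ok]); y <- D[ok]
  ix <- pmin(pmax(findInterval(x, la), 1L), length(la) - 1L)
  iy <- pmin(pmax(findInterval(y, Dg), 1L), length(Dg) - 1L)
  tx <- (x - la[ix]) / (la[ix + 1L] - la[ix])
  ty <- (y - Dg[iy]) / (Dg[iy + 1L] - Dg[iy])
  g00 <- lookup$g[cbind(ix, iy)]
  g10 <- lookup$g[cbind(ix + 1L, iy)]
  g01 <- lookup$g[cbind(ix, iy + 1L)]
  g11 <- lookup$g[cbind(ix + 1L, iy + 1L)]
  v <- (1 - tx) * (1 - ty) * g00 + tx * (1 - ty) * g10 +
    (1 - tx) * ty * g01 + tx * ty * g11
  out[ok] <- v  # NA propagates from masked cells
  out
}

#' Serialize / read a g lookup table
#'
#' The table is stored as a self-describing container: the `g` matrix with
#' named axes plus an attribute block carrying the wavelength, medium index,
#' generation grids and code version. Round-trips losslessly.
#'
#' @param lookup A `g_lookup` object.
#' @param path File path.
#' @return `read_g_lookup` returns the `g_lookup`; `write_g_lookup` returns
#'   `path` invisibly.
#' @export
write_g_lookup <- function(lookup, path) {
  stopifnot(inherits(lookup, "g_lookup"))
  saveRDS(lookup, path)
  invisible(path)
}

#' @rdname write_g_lookup
#' @export
read_g_lookup <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "g_lookup"))
  x
}
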