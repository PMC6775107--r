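# Layered phantoms with known ground-truth optical properties. Each layer is
# either a Whittle-Matern medium (spectra derived from the model plus an
# optional chlorophyll-a load) or a tabulated set of spectra (used for bead
# standards and power-law test media). Phantoms emulate tissue over skeleton:
# an absorbing, moderately scattering layer above a non-absorbing strongly
# scattering one.

#' Specify one phantom layer
#'
#' @param thickness_um Layer thickness in micrometers (> 0).
#' @param wm A [wm_params()] object describing the layer ultrastructure, or
#'   `NULL` when `optical` is given.
#' @param chl_mg_cm3 Chlorophyll-a mass concentration in mg/cm^3 (>= 0).
#'   Skeleton-type layers are non-absorbing and must use 0.
#' @param backscatter_scale Dimensionless reflectivity multiplier applied to
#'   the layer's backscattering coefficient.
#' @param optical Optional tabulated spectra: a list with `lambda` (nm) and
#'   `mu_s`, `mu_a`, `mu_b` (1/cm; `mu_b` in power convention), overriding
#'   the Whittle-Matern route.
#' @param name Layer label.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(thickness_um, wm = NULL, chl_mg_cm3 = 0,
                       backscatter_scale = 1, optical = NULL,
                       name = "layer") {
  if (!is.numeric(thickness_um) || thickness_um <= 0)
    stop("`thickness_um` must be > 0 (negative or overlapping layers are ",
         "not representable)")
  if (chl_mg_cm3 < 0) stop("`chl_mg_cm3` must be >= 0")
  if (is.null(wm) && is.null(optical))
    stop("give either `wm` parameters or tabulated `optical` spectra")
  if (!is.null(wm)) wm <- as_wm_params(wm)
  if (!is.null(optical))
    stopifnot(all(c("lambda", "mu_s", "mu_a", "mu_b") %in% names(optical)))
  structure(list(thickness_um = thickness_um, wm = wm,
                 chl_mg_cm3 = chl_mg_cm3,
                 backscatter_scale = backscatter_scale,
                 optical = optical, name = name),
            class = "layer_spec")
}

# Evaluate a layer's (mu_s, mu_a, mu_b) on a wavelength grid.
layer_spectra <- function(layer, lambda_grid, medium_index, solid_angle,
                          pigment) {
  if (!is.null(layer$optical)) {
    o <- layer$optical
    interp <- function(v) stats::spline(o$lambda, v, xout = lambda_grid)$y
    mu_s <- interp(o$mu_s); mu_a <- interp(o$mu_a); mu_b <- interp(o$mu_b)
  } else {
    mu_s <- mu_s_spectrum(layer$wm, lambda_grid, medium_index)$mu_s
    mu_b <- wm_mu_b(layer$wm, lambda_grid, medium_index, solid_angle,
                    "power")
    mu_a <- if (layer$chl_mg_cm3 > 0)
      chl_mu_a(layer$chl_mg_cm3, lambda_grid, pigment)
    else rep(0, length(lambda_grid))
  }
  list(lambda = lambda_grid, mu_s = pmax(mu_s, 0), mu_a = pmax(mu_a, 0),
       mu_b = pmax(mu_b, 0) * layer$backscatter_scale,
       mu_t = pmax(mu_s, 0) + pmax(mu_a, 0))
}

#' Build a layered phantom volume
#'
#' Assigns wavelength-resolved optical properties (`mu_s`, `mu_a`, `mu_b`)
#' to a laterally sampled volume. Each lateral position belongs to a region
#' (an ordered layer stack, surface down); the surface height field sets
#' where the first layer begins. Spectra are precomputed per layer on
#' `lambda_grid` and interpolated where finer sampling is needed.
#'
#' @param stacks Either a list of [layer_spec()] objects (a single stack) or
#'   a list of such lists (one stack per region).
#' @param nx,ny Lateral raster size.
#' @param pixel_pitch_um Lateral pixel pitch in micrometers.
#' @param surface_um Surface depth below the probe in geometric micrometers:
#'   a scalar (flat surface) or an `nx` x `ny` matrix height field.
#' @param region_map `nx` x `ny` integer matrix of region (stack) indices;
#'   default all 1.
#' @param dz_um Axial voxel pitch of the scatterer grid (geometric um).
#' @param depth_um Total simulated depth extent (geometric um).
#' @param lambda_grid Wavelength grid (nm) for spectra precomputation.
#' @param medium_index Embedding/tissue refractive index.
#' @param solid_angle Collection solid angle (sr) for `mu_b`.
#' @param pigment A [pigment_reference()] used for chlorophyll absorption.
#' @return An object of class `phantom`.
#' @export
make_phantom <- function(stacks, nx, ny, pixel_pitch_um = 5,
                         surface_um = 150, region_map = NULL, dz_um = 2,
                         depth_um = 600,
                         lambda_grid = seq(500, 740, by = 5),
                         medium_index = 1.35, solid_angle = 0.01,
                         pigment = pigment_reference()) {
  if (inherits(stacks[[1]], "layer_spec")) stacks <- list(stacks)
  lapply(stacks, function(st) {
    if (!length(st) || !all(vapply(st, inherits, TRUE, "layer_spec")))
      stop("each stack must be a non-empty list of `layer_spec`s")
  })
  if (is.null(region_map)) region_map <- matrix(1L, nx, ny)
  stopifnot(all(dim(region_map) == c(nx, ny)),
            all(region_map %in% seq_along(stacks)))
  if (length(surface_um) == 1L) surface_um <- matrix(surface_um, nx, ny)
  stopifnot(all(dim(surface_um) == c(nx, ny)), all(is.finite(surface_um)),
            all(surface_um >= 0))
  spectra <- lapply(stacks, function(st)
    lapply(st, layer_spectra, lambda_grid = lambda_grid,
           medium_index = medium_index, solid_angle = solid_angle,
           pigment = pigment))
  structure(list(stacks = stacks, spectra = spectra,
                 region_map = region_map, surface_um = surface_um,
                 nx = nx, ny = ny, pixel_pitch_um = pixel_pitch_um,
                 dz_um = dz_um, depth_um = depth_um,
                 lambda_grid = lambda_grid, medium_index = medium_index,
                 solid_angle = solid_angle),
            class = "phantom")
}

#' Single-layer flat-surface phantom
#'
#' Convenience constructor for calibration and contract tests.
#'
#' @param layer A [layer_spec()].
#' @inheritParams make_phantom
#' @param ... Passed to [make_phantom()].
#' @return A `phantom`.
#' @export
flat_phantom <- function(layer, nx = 16, ny = 16, surface_um = 150, ...) {
  make_phantom(list(list(layer)), nx = nx, ny = ny,
               surface_um = surface_um, ...)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d columns, %d region(s), depth %g um\n",
              x$nx, x$ny, length(x$stacks), x$depth_um))
  for (i in seq_along(x$stacks)) {
    cat(sprintf("  region %d: %s\n", i,
                paste(vapply(x$stacks[[i]], function(l)
                  sprintf("%s (%g um)", l$name, l$thickness_um),
                  character(1)), collapse = " / ")))
  }
  invisible(x)
}

# Per-region layer assignment on the geometric z voxel grid for a given
# surface depth: 0 = above surface (no scatterers), else layer index.
column_layers <- function(phantom, region, surface_um, z_geom) {
  st <- phantom$stacks[[region]]
  bounds <- surface_um + cumsum(c(0, vapply(st, `[[`, numeric(1),
                                            "thickness_um")))
  idx <- findInterval(z_geom, bounds)
  idx[idx > length(st)] <- 0L  # below the deepest layer: empty
  idx
}

# Interpolate a region's per-layer spectra onto arbitrary wavelengths;
# returns list of matrices [length(lambda) x n_layer] for mu_t and mu_b.
region_spectra_at <- function(phantom, region, lambda) {
  sp <- phantom$spectra[[region]]
  mu_t <- vapply(sp, function(s)
    pmax(stats::spline(s$lambda, s$mu_t, xout = lambda)$y, 0),
    numeric(length(lambda)))
  mu_b <- vapply(sp, function(s)
    pmax(stats::spline(s$lambda, s$mu_b, xout = lambda)$y, 0),
    numeric(length(lambda)))
  mu_a <- vapply(sp, function(s)
    pmax(stats::spline(s$lambda, s$mu_a, xout = lambda)$y, 0),
    numeric(length(lambda)))
  mu_s <- vapply(sp, function(s)
    pmax(stats::spline(s$lambda, s$mu_s, xout = lambda)$y, 0),
    numeric(length(lambda)))
  list(mu_t = rbind(mu_t), mu_b = rbind(mu_b), mu_a = rbind(mu_a),
       mu_s = rbind(mu_s))
}

#' Ground truth summary of a phantom
#'
#' Per-region, per-layer optical truth evaluated at the requested
#' wavelengths, plus the structural truth (`D`, `Ln`, anisotropy at a
#' reference wavelength) and the chlorophyll-a areal density over a window.
#'
#' @param phantom A [make_phantom()] object.
#' @param lambda Wavelengths (nm) at which coefficients are reported.
#' @param lambda_ref Reference wavelength for the anisotropy (nm).
#' @param window_um Window for areal chlorophyll density (um).
#' @return A nested list `truth[[region]][[layer]]` with elements `mu_s`,
#'   `mu_a`, `mu_b`, `mu_t`, `D`, `Ln`, `g`, `chl_mg_cm3`,
#'   `chl_areal_ug_cm2`.
#' @export
phantom_truth <- function(phantom, lambda, lambda_ref = 620,
                          window_um = 90) {
  lapply(seq_along(phantom$stacks), function(r) {
    sp <- region_spectra_at(phantom, r, lambda)
    lapply(seq_along(phantom$stacks[[r]]), function(l) {
      ly <- phantom$stacks[[r]][[l]]
      g <- if (!is.null(ly$wm))
        anisotropy_g(ly$wm, lambda_ref, phantom$medium_index) else NA_real_
      list(lambda = lambda, mu_s = sp$mu_s[, l], mu_a = sp$mu_a[, l],
           mu_b = sp$mu_b[, l], mu_t = sp$mu_t[, l],
           D = if (!is.null(ly$wm)) ly$wm$D else NA_real_,
           Ln = if (!is.null(ly$wm)) ly$wm$Ln else NA_real_,
           g = g, chl_mg_cm3 = ly$chl_mg_cm3,
           chl_areal_ug_cm2 = chl_areal_density(ly$chl_mg_cm3, window_um))
    })
  })
}
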