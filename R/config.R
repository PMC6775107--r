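# Run configuration: one structured file drives both simulation and
# processing, so simulate -> process closure tests are a two-command
# script. Defaults mirror the instrument and analysis settings of the
# visible-band system modeled here: 520-720 nm, 22 bands of 20 nm FWHM,
# 90 um fit window, -10 dB/mm roll-off.

#' Default run configuration
#'
#' @param rng_seed Seed recorded into the acquisition section.
#' @return A nested list with sections `acquisition`, `phantom`, `stft`,
#'   `surface`, `fit`, `lookup`, `pigment`, `reference`.
#' @export
default_run_config <- function(rng_seed = 1L) {
  list(
    acquisition = list(lambda_min = 520, lambda_max = 720, n_k = 1024L,
                       pixel_pitch_um = 5, rolloff_db_per_mm = -10,
                       noise_rel = 0.0316, medium_index = 1.35,
                       rng_seed = as.integer(rng_seed)),
    phantom = list(
      nx = 64L, ny = 64L, dz_um = 2, depth_um = 420, surface_um = 60,
      solid_angle = 0.01,
      region_split = NULL,  # set to a fraction for left/right regions
      # coenosarc-like tissue (moderately scattering, chlorophyll-a
      # absorbing) over a strongly scattering non-absorbing skeleton
      regions = list(list(name = "tissue_over_skeleton", layers = list(
        list(name = "tissue", thickness_um = 150, D = 2.5, Ln = 600,
             mu_s_600 = 100, chl_mg_cm3 = 0.3, backscatter_scale = 1),
        list(name = "skeleton", thickness_um = 200, D = 3.5, Ln = 800,
             mu_s_600 = 200, chl_mg_cm3 = 0, backscatter_scale = 1))))),
    stft = list(n_bands = 22L, band_fwhm = 20, z_max_um = NULL),
    surface = list(h = 0.1, min_object_px = 30L,
                   rolloff_limit_db = 1e9, specular_threshold = 1e9),
    fit = list(depth_window_um = 90, lateral_kernel = 3L, block = 8L,
               seed = 1L),
    lookup = list(path = NULL, lambda_ref = 620),
    pigment = list(fixture = NULL),
    reference = list(simulate = TRUE, bead_diameter_nm = 80,
                     volume_fraction = 0.02, surface_um = 60)
  )
}

# Field-level schema validation with named error messages.
validate_run_config <- function(config) {
  need <- function(section, fields) {
    if (is.null(config[[section]]))
      stop(sprintf("config: missing required section `%s`", section),
           call. = FALSE)
    for (f in fields)
      if (is.null(config[[section]][[f]]))
        stop(sprintf("config: missing required field `%s.%s`", section, f),
             call. = FALSE)
  }
  need("acquisition", c("lambda_min", "lambda_max", "n_k", "rng_seed",
                        "medium_index", "rolloff_db_per_mm", "noise_rel"))
  need("phantom", c("nx", "ny", "regions", "surface_um", "dz_um",
                    "depth_um"))
  need("stft", c("n_bands", "band_fwhm"))
  need("fit", c("depth_window_um"))
  with(config$acquisition, {
    if (lambda_min >= lambda_max)
      stop("config: acquisition.lambda_min must be < lambda_max",
           call. = FALSE)
  })
  invisible(config)
}

#' Read a run configuration file
#'
#' YAML; missing optional fields are filled from [default_run_config()],
#' then the schema is validated with field-level messages.
#'
#' @param path YAML file path, or a config list passed through.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  config <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- default_run_config()
  merge2 <- function(d, u) {
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(u[[nm]]) && is.list(d[[nm]]) &&
                     !is.null(names(u[[nm]])))
        merge2(d[[nm]], u[[nm]]) else u[[nm]]
    }
    d
  }
  validate_run_config(merge2(def, config))
}

# Build acquisition / phantom objects from a config.
config_acquisition <- function(config) {
  a <- config$acquisition
  p <- config$phantom
  oct_acquisition(lambda_min = a$lambda_min, lambda_max = a$lambda_max,
                  n_k = a$n_k, nx = p$nx, ny = p$ny,
                  pixel_pitch_um = a$pixel_pitch_um,
                  rolloff_db_per_mm = a$rolloff_db_per_mm,
                  noise_rel = a$noise_rel, medium_index = a$medium_index,
                  rng_seed = a$rng_seed)
}

config_pigment <- function(config) {
  fx <- config$pigment$fixture
  if (is.null(fx)) pigment_reference() else pigment_reference(fx)
}

config_layer <- function(ly, medium_index, pigment) {
  wm <- wm_params(An = if (is.null(ly$An)) 1 else ly$An,
                  Ln = ly$Ln, D = ly$D)
  if (!is.null(ly$mu_s_600))
    wm <- wm_scale_to_mu_s(wm, ly$mu_s_600, 600, medium_index)
  layer_spec(thickness_um = ly$thickness_um, wm = wm,
             chl_mg_cm3 = if (is.null(ly$chl_mg_cm3)) 0 else ly$chl_mg_cm3,
             backscatter_scale = if (is.null(ly$backscatter_scale)) 1
             else ly$backscatter_scale,
             name = if (is.null(ly$name)) "layer" else ly$name)
}

config_phantom <- function(config) {
  p <- config$phantom
  pig <- config_pigment(config)
  n_med <- config$acquisition$medium_index
  stacks <- lapply(p$regions, function(rg)
    lapply(rg$layers, config_layer, medium_index = n_med, pigment = pig))
  region_map <- matrix(1L, p$nx, p$ny)
  if (!is.null(p$region_split) && length(stacks) > 1L) {
    cut <- max(1L, round(p$nx * p$region_split))
    region_map[(cut + 1L):p$nx, ] <- 2L
  }
  make_phantom(stacks, nx = p$nx, ny = p$ny,
               pixel_pitch_um = config$acquisition$pixel_pitch_um,
               surface_um = p$surface_um, region_map = region_map,
               dz_um = p$dz_um, depth_um = p$depth_um,
               medium_index = n_med, solid_angle = p$solid_angle,
               pigment = pig)
}

#' Derive the tissue-removed (skeleton-exposed) configuration
#'
#' Emulates the rescan after tissue removal: every region keeps only its
#' deepest (skeleton) layer, exposed at the original surface height, and a
#' distinct seed offset keeps the rescan's speckle independent. Processed
#' with `skeleton_mode = TRUE`, this is the second scan of the
#' tissue/skeleton pair.
#'
#' @param config A run configuration (list or YAML path).
#' @return The modified configuration list.
#' @export
skeleton_exposed_config <- function(config) {
  config <- read_run_config(config)
  config$phantom$regions <- lapply(config$phantom$regions, function(rg) {
    rg$layers <- rg$layers[length(rg$layers)]
    rg
  })
  config$acquisition$rng_seed <- config$acquisition$rng_seed + 500009L
  config
}

# Reference bead phantom matching the sample scan geometry.
config_reference_phantom <- function(config) {
  r <- config$reference
  p <- config$phantom
  a <- config$acquisition
  lam <- seq(a$lambda_min - 20, a$lambda_max + 20, by = 10)
  mu_t <- mie_mu_t(r$bead_diameter_nm, lam, r$volume_fraction)
  mu_b <- rayleigh_mu_b(r$bead_diameter_nm, lam, r$volume_fraction,
                        solid_angle = p$solid_angle)
  ly <- layer_spec(p$depth_um, optical = list(lambda = lam, mu_s = mu_t,
                                              mu_a = 0 * lam, mu_b = mu_b),
                   name = "bead standard")
  make_phantom(list(list(ly)), nx = p$nx, ny = p$ny,
               pixel_pitch_um = a$pixel_pitch_um,
               surface_um = r$surface_um, dz_um = p$dz_um,
               depth_um = p$depth_um, medium_index = a$medium_index,
               solid_angle = p$solid_angle)
}
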