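# Shared fixtures, all generated in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

test_acq <- function(seed, nx = 16L, ny = 16L, noise_rel = 0.0316,
                     rolloff = -10, n_k = 1024L) {
  oct_acquisition(n_k = n_k, nx = nx, ny = ny, noise_rel = noise_rel,
                  rolloff_db_per_mm = rolloff, rng_seed = seed)
}

tissue_wm <- function(mu_s600 = 100, D = 2.5, Ln = 600) {
  wm_scale_to_mu_s(wm_params(1, Ln, D), mu_s600, 600)
}

tissue_layer <- function(thickness = 150, mu_s600 = 100, D = 2.5,
                         Ln = 600, chl = 0.3) {
  layer_spec(thickness, wm = tissue_wm(mu_s600, D, Ln),
             chl_mg_cm3 = chl, name = "tissue")
}

# wavelength-flat tabulated layer: mu_s, mu_a in 1/cm; mu_b power units
const_layer <- function(thickness = 250, mu_s = 100, mu_a = 0,
                        mu_b = 1e-3) {
  lam <- c(500, 740)
  layer_spec(thickness, optical = list(lambda = lam, mu_s = rep(mu_s, 2),
                                       mu_a = rep(mu_a, 2),
                                       mu_b = rep(mu_b, 2)))
}

# one shared speckled tissue scan (16 x 16, 30 dB) + its processed stages
tissue_scan <- function() cached("tissue_scan", {
  ph <- flat_phantom(tissue_layer(), nx = 16, ny = 16, surface_um = 60,
                     depth_um = 300)
  raw <- simulate_volume(ph, test_acq(101), speckle = TRUE)
  cube <- compensate_rolloff(stft_cube(raw))
  surf <- detect_surface(cube)
  list(phantom = ph, raw = raw, cube = cube, surface = surf)
})

# small anisotropy lookup shared by lookup/inversion tests
small_lookup <- function() cached("small_lookup", {
  build_g_lookup(D_grid = seq(2, 4, by = 0.25),
                 albedo_grid = 10^seq(-7, -1, length.out = 50),
                 Ln_grid = 10^seq(log10(20), log10(10000),
                                  length.out = 40))
})

default_bands <- function() default_band_centers(list(lambda_min = 520,
                                                      lambda_max = 720))
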