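# Beer-Lambert attenuation fitting, compensation and backscatter spectra.

# analytic speckle-free cube for strict contract checks
flat_model_cube <- function(mu_s = 100, mu_a = 0, mu_b = 1e-3,
                            surface_um = 100, nx = 2, ny = 2) {
  ph <- flat_phantom(const_layer(320, mu_s, mu_a, mu_b), nx = nx, ny = ny,
                     surface_um = surface_um, depth_um = 420)
  acq <- test_acq(41, nx = nx, ny = ny, noise_rel = 0, rolloff = 0)
  list(cube = model_cube(ph, acq), phantom = ph, acq = acq)
}

flat_surface_map <- function(z_opt_um, nx, ny) {
  structure(list(z_um = matrix(z_opt_um, nx, ny),
                 valid = matrix(TRUE, nx, ny),
                 reason = matrix("", nx, ny), method = "manual"),
            class = "surface_map")
}

test_that("noiseless exponential decay fits to 1e-6 relative", {
  fm <- flat_model_cube(mu_s = 100)
  surf <- flat_surface_map(100 * 1.35, 2, 2)
  at <- fit_mu_t(fm$cube, surf, lateral_kernel = 0)
  expect_equal(as.vector(at$mu_t), rep(100, length(at$mu_t)),
               tolerance = 1e-6)
  expect_true(all(at$r2 > 1 - 1e-9))
})

test_that("mu_t adds scattering and absorption contributions", {
  fm <- flat_model_cube(mu_s = 80, mu_a = 40)
  surf <- flat_surface_map(100 * 1.35, 2, 2)
  at <- fit_mu_t(fm$cube, surf, lateral_kernel = 0)
  expect_equal(as.vector(at$mu_t), rep(120, length(at$mu_t)),
               tolerance = 1e-6)
})

test_that("speckled attenuation recovers after lateral averaging", {
  ph <- flat_phantom(const_layer(300, mu_s = 150, mu_b = 1e-3),
                     nx = 10, ny = 10, surface_um = 60, depth_um = 380)
  acq <- test_acq(42, nx = 10, ny = 10, noise_rel = 0, rolloff = 0)
  raw <- simulate_volume(ph, acq, speckle = TRUE)
  cube <- stft_cube(raw)
  surf <- flat_surface_map(60 * 1.35, 10, 10)
  at <- fit_mu_t(cube, surf, lateral_kernel = 9)  # ~10x10 average
  med <- median(at$mu_t, na.rm = TRUE)
  expect_equal(med, 150, tolerance = 0.10)
})

test_that("pipeline mu_t matches Mie theory for a bead suspension", {
  lam <- seq(500, 740, by = 10)
  mu_t_mie <- mie_mu_t(200, lam, 0.01)
  ly <- layer_spec(300, optical = list(
    lambda = lam, mu_s = mu_t_mie, mu_a = 0 * lam,
    mu_b = 1e-3 * (lam / 600)^-1))
  ph <- make_phantom(list(list(ly)), nx = 48, ny = 48, surface_um = 60,
                     depth_um = 380)
  acq <- test_acq(43, nx = 48, ny = 48, noise_rel = 0, rolloff = 0)
  raw <- simulate_volume(ph, acq, speckle = TRUE)
  cube <- stft_cube(raw)
  # homogeneous standard: fit the speckle-averaged (ensemble mean) profile
  Im <- apply(cube$intensity, c(1, 4), mean)
  cube$intensity <- array(Im, c(22, 1, 1, dim(Im)[2]))
  surf <- flat_surface_map(60 * 1.35, 1, 1)
  at <- fit_mu_t(cube, surf, lateral_kernel = 0)
  fitted <- as.vector(at$mu_t)
  truth <- mie_mu_t(200, cube$band_centers, 0.01)
  expect_true(all(abs(fitted / truth - 1) < 0.10))
})

test_that("compensation flattens the profile and then refits to zero", {
  fm <- flat_model_cube(mu_s = 100)
  surf <- flat_surface_map(100 * 1.35, 2, 2)
  at <- fit_mu_t(fm$cube, surf, lateral_kernel = 0)
  comp <- compensate_attenuation(fm$cube, at, surf)
  z <- comp$z_grid
  sel <- z > 100 * 1.35 + 10 & z < 100 * 1.35 + 80
  sl <- stats::coef(stats::lm(log(comp$intensity[11, 1, 1, sel]) ~
                                z[sel]))[[2]]
  expect_lt(abs(sl), 1e-6)
  at2 <- fit_mu_t(comp, surf, lateral_kernel = 0)
  expect_lt(max(abs(at2$mu_t)), 1)
})

test_that("zero attenuation compensation is the identity", {
  fm <- flat_model_cube(mu_s = 100)
  surf <- flat_surface_map(100 * 1.35, 2, 2)
  at <- fit_mu_t(fm$cube, surf, lateral_kernel = 0)
  at$mu_t[] <- 0
  comp <- compensate_attenuation(fm$cube, at, surf)
  expect_identical(comp$intensity, fm$cube$intensity)
})

test_that("constant intensity with unit calibration returns itself", {
  ts <- tissue_scan()
  cube <- ts$cube
  cube$intensity[] <- 3.7
  surf <- flat_surface_map(100, 16, 16)
  mb <- mu_b_spectrum(cube, surf, calibration = rep(1, 22),
                      lateral_kernel = 0)
  expect_equal(as.vector(mb$mu_b_power),
               rep(3.7, length(mb$mu_b_power)), tolerance = 1e-12)
  expect_equal(as.vector(mb$mu_b), rep(sqrt(3.7), length(mb$mu_b)),
               tolerance = 1e-12)
})

test_that("a lambda^-0.5 backscatter phantom measures slope -0.5", {
  lam <- c(500, 560, 620, 680, 740)
  ly <- layer_spec(300, optical = list(
    lambda = lam, mu_s = rep(100, 5), mu_a = rep(0, 5),
    mu_b = 1e-3 * (lam / 600)^-0.5))
  ph <- make_phantom(list(list(ly)), nx = 24, ny = 24, surface_um = 60,
                     depth_um = 380)
  acq <- test_acq(44, nx = 24, ny = 24, noise_rel = 0, rolloff = 0)
  raw <- simulate_volume(ph, acq, speckle = TRUE)
  cube <- stft_cube(raw)
  surf <- detect_surface(cube)
  at <- fit_mu_t(cube, surf)
  # homogeneous phantom: compensate with the per-band median attenuation
  at$mu_t <- array(apply(at$mu_t, 1L, median, na.rm = TRUE),
                   dim(at$mu_t))
  comp <- compensate_attenuation(cube, at, surf)
  mb <- mu_b_spectrum(comp, surf)
  spec <- apply(mb$mu_b_power, 1L, median, na.rm = TRUE)
  sl <- stats::coef(stats::lm(log(spec) ~ log(cube$band_centers)))[[2]]
  expect_lt(abs(sl - (-0.5)), 0.05)
})

test_that("doubling the backscatter scale doubles measured mu_b", {
  mk <- function(scale) {
    ly <- layer_spec(300, optical = list(lambda = c(500, 740),
                                         mu_s = c(100, 100),
                                         mu_a = c(0, 0),
                                         mu_b = c(1e-3, 1e-3)),
                     backscatter_scale = scale)
    ph <- make_phantom(list(list(ly)), nx = 8, ny = 8, surface_um = 60,
                       depth_um = 380)
    raw <- simulate_volume(ph, test_acq(45, nx = 8, ny = 8,
                                        noise_rel = 0, rolloff = 0))
    cube <- stft_cube(raw)
    surf <- detect_surface(cube)
    at <- fit_mu_t(cube, surf)
    comp <- compensate_attenuation(cube, at, surf)
    mb <- mu_b_spectrum(comp, surf)
    median(mb$mu_b_power, na.rm = TRUE)
  }
  expect_equal(mk(2) / mk(1), 2, tolerance = 0.02)
})
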