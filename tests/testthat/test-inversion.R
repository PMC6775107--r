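# Spectral decomposition, D fitting, albedo lookup and the map
# orchestrator.

bands22 <- function() default_bands()

test_that("decomposition recovers a known mixture", {
  pig <- pigment_reference()
  bands <- bands22()
  a_star <- isoct:::pigment_shape_at(pig, bands)
  a_star <- a_star / max(a_star)
  s_star <- isoct:::mu_s_star_model(bands, 3, 500)
  t_star <- 0.5 * a_star + 0.5 * s_star
  dec <- decompose_mu_t(t_star, bands, pig, normalized = TRUE, seed = 7)
  expect_equal(unname(dec$par["c_a"]), 0.5, tolerance = 0.02)
  expect_equal(unname(dec$par["c_s"]), 0.5, tolerance = 0.02)
  expect_equal(unname(dec$c_a), 0.5, tolerance = 0.02)
  expect_equal(unname(dec$c_s), 0.5, tolerance = 0.02)
  expect_equal(dec$D, 3, tolerance = 0.1)
  expect_true(dec$converged)
  # reported cost equals an independent recomputation
  expect_lt(abs(dec$cost - decomposition_cost(dec)), 1e-10)
})

test_that("pure scattering yields no absorption contribution", {
  pig <- pigment_reference()
  bands <- bands22()
  s_star <- isoct:::mu_s_star_model(bands, 2.5, 300)
  dec <- decompose_mu_t(s_star, bands, pig, normalized = TRUE, seed = 3)
  expect_lt(dec$c_a, 0.02)
})

test_that("contributions never exceed the 1/2 bound and clip with a flag", {
  pig <- pigment_reference()
  bands <- bands22()
  # a real (unnormalized) attenuation spectrum whose scattering fraction
  # exceeds the bound
  mu_s <- 100 * isoct:::mu_s_star_model(bands, 2.5, 600)
  mu_a <- chl_mu_a(0.3, bands, pig)
  dec <- decompose_mu_t(mu_s + mu_a, bands, pig, seed = 5)
  expect_lte(dec$c_a, 0.5)
  expect_lte(dec$c_s, 0.5)
  expect_true(dec$clipped["c_s"])
  # the absolute coefficients remain scale-consistent: mu_a + mu_s
  # reproduces mu_t at the spectrum maximum
  i_max <- which.max(mu_s + mu_a)
  expect_equal(dec$mu_a[i_max] + dec$mu_s[i_max],
               (mu_s + mu_a)[i_max], tolerance = 0.02 * max(mu_s + mu_a))
})

test_that("skeleton mode matches the full fit on a no-absorber spectrum", {
  pig <- pigment_reference()
  bands <- bands22()
  mu_s <- 200 * isoct:::mu_s_star_model(bands, 3.5, 800)
  full <- decompose_mu_t(mu_s, bands, pig, seed = 9)
  skel <- decompose_mu_t(mu_s, bands, pig, seed = 9, skeleton = TRUE)
  expect_equal(skel$mu_s, full$mu_s, tolerance = 0.01 * max(mu_s))
  expect_identical(unname(skel$par["c_a"]), 0)
})

test_that("decomposition identifiability needs the red absorption peak", {
  pig <- pigment_reference()
  bands <- bands22()
  a_star <- isoct:::pigment_shape_at(pig, bands)
  a_star <- a_star / max(a_star)
  s_star <- isoct:::mu_s_star_model(bands, 3, 500)
  t_star <- 0.5 * a_star + 0.5 * s_star
  with_peak <- decompose_mu_t(t_star, bands, pig, normalized = TRUE,
                              seed = 11)
  # remove the spectral feature: a featureless flat "pigment"
  flat_pig <- pig
  flat_pig$mu_a_star <- rep(1, length(pig$lambda))
  t_flat <- 0.5 * 1 + 0.5 * s_star
  no_peak <- decompose_mu_t(t_flat, bands, flat_pig, normalized = TRUE,
                            seed = 11)
  expect_lt(with_peak$start_dispersion, 0.02)
  expect_gt(no_peak$start_dispersion, 5 * with_peak$start_dispersion)
})

test_that("D inverts exactly from noiseless power-law spectra", {
  bands <- bands22()
  f <- fit_D_from_mub(bands^-0.5, bands)
  expect_equal(f$D, 3, tolerance = 1e-9)
  expect_equal(fit_D_from_mub(rep(2, 22), bands)$D, 4, tolerance = 1e-12)
  expect_equal(fit_D_from_mub(bands^-1.25, bands)$D, 1.5,
               tolerance = 1e-9)
})

test_that("D fit equals a 0.001-step grid search on random spectra", {
  bands <- bands22()
  grid_D <- seq(1.2, 6, by = 0.001)
  lx <- log(bands); lxc <- lx - mean(lx)
  set.seed(123)
  for (i in 1:100) {
    D_true <- runif(1, 1.2, 6)
    amp <- runif(1, 0.5, 2)
    mb <- amp * bands^(D_true / 2 - 2)
    fast <- fit_D_from_mub(mb, bands)$D
    # brute force: squared log-residual after profiling out the intercept
    y <- log(mb); yc <- y - mean(y)
    rss <- vapply(grid_D, function(D)
      sum((yc - (D / 2 - 2) * lxc)^2), numeric(1))
    brute <- grid_D[which.min(rss)]
    expect_lt(abs(fast - brute), 0.002)
    expect_lt(abs(fast - D_true), 1e-6)
  }
})

test_that("nonpositive bands are dropped and sparse spectra are invalid", {
  bands <- bands22()
  mb <- bands^-0.5
  mb[c(3, 7)] <- 0
  expect_equal(fit_D_from_mub(mb, bands)$D, 3, tolerance = 1e-9)
  mb[1:18] <- 0
  expect_true(is.na(fit_D_from_mub(mb, bands)$D))
})

test_that("albedo lookup inversion respects masks and monotonicity", {
  lk <- small_lookup()
  expect_true(is.na(g_from_albedo(1e-4, 0, 3, lk)))
  expect_true(is.na(g_from_albedo(1e-4, NA, 3, lk)))
  g1 <- g_from_albedo(1e-4, 1, 3, lk)
  g2 <- g_from_albedo(2e-4, 1, 3, lk)
  expect_lt(g2, g1)  # doubling the albedo moves g down the table
})

test_that("two-region phantom maps separate low and high D", {
  stacks <- list(
    list(layer_spec(250, wm = tissue_wm(100, 2, 400))),
    list(layer_spec(250, wm = tissue_wm(100, 4, 400))))
  rm <- matrix(1L, 24, 12); rm[13:24, ] <- 2L
  ph <- make_phantom(stacks, nx = 24, ny = 12, surface_um = 60,
                     region_map = rm, depth_um = 330)
  raw <- simulate_volume(ph, test_acq(51, nx = 24, ny = 12,
                                      noise_rel = 0))
  cube <- compensate_rolloff(stft_cube(raw))
  surf <- detect_surface(cube)
  maps <- build_property_maps(cube, surf, lookup = NULL,
                              skeleton_mode = TRUE, block = 6L)
  d_lo <- median(maps$D[1:12, ], na.rm = TRUE)
  d_hi <- median(maps$D[13:24, ], na.rm = TRUE)
  expect_gt(d_hi - d_lo, 1.5)
})

test_that("an all-invalid surface yields empty maps, not errors", {
  ts <- tissue_scan()
  surf <- ts$surface
  surf$valid[] <- FALSE
  maps <- build_property_maps(ts$cube, surf, lookup = NULL)
  expect_true(all(is.na(maps$D)))
  expect_true(all(is.na(maps$chl_areal_ug_cm2)))
  expect_false(any(maps$valid))
})

test_that("map histograms are normalized per-pixel frequencies", {
  m <- matrix(rnorm(400, 3), 20, 20)
  h <- map_histogram(m)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
  expect_true(all(c("bin_center", "frequency") %in% names(h)))
})
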