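# STFT spectral cube: band layout, depth mapping, energy bookkeeping,
# phase invariance, calibration and container round-trips.

test_that("default configuration yields exactly 22 bands", {
  ts <- tissue_scan()
  expect_identical(dim(ts$cube$intensity)[1], 22L)
  expect_true(all(diff(ts$cube$band_centers) > 0))
  expect_true(all(ts$cube$intensity >= 0))
  expect_equal(ts$cube$band_fwhm, 20)
})

test_that("bands beyond the acquired spectrum are rejected", {
  ts <- tissue_scan()
  expect_error(stft_cube(ts$raw, band_centers = c(530, 600, 700)),
               "beyond the acquired spectrum")
  expect_error(stft_cube(ts$raw, band_centers = c(600, 710)),
               "beyond the acquired spectrum")
})

test_that("every band localizes a mirror at the same depth", {
  acq <- test_acq(21, nx = 1, ny = 1, noise_rel = 0, rolloff = 0)
  cube <- stft_cube(mirror_raw_scan(150, acq))
  px <- mean(diff(cube$z_grid))
  peaks <- vapply(seq_len(22), function(b)
    cube$z_grid[which.max(cube$intensity[b, 1, 1, ])], numeric(1))
  expect_true(all(abs(peaks - 150 * acq$medium_index) <= px))
})

test_that("band intensities sum to the full-band profile", {
  # Parseval-type bookkeeping: the ratio of summed band intensity to the
  # full-band intensity is a window-overlap constant, flat over depth
  # sub-resolution scatterer pitch so the full-band image resolves a
  # continuum, not the discrete scatterer comb
  ph <- flat_phantom(const_layer(250, mu_s = 60), nx = 10, ny = 10,
                     surface_um = 60, depth_um = 330, dz_um = 0.4)
  acq <- test_acq(22, nx = 10, ny = 10, noise_rel = 0, rolloff = 0)
  raw <- simulate_volume(ph, acq, speckle = TRUE)
  cube <- stft_cube(raw)
  fb <- full_band_intensity(raw)
  zg <- cube$z_grid
  sel <- zg > 60 * 1.35 + 15 & zg < 60 * 1.35 + 150
  band_sum <- apply(cube$intensity[, , , sel], 4, mean)
  # bands are unit-energy normalized; undo for the energy comparison
  k <- raw$k_grid
  wsum <- vapply(seq_len(22), function(b) {
    kc <- 2 * pi / cube$band_centers[b]
    dkw <- 2 * pi * 20 / cube$band_centers[b]^2
    sum(exp(-4 * log(2) * (k - kc)^2 / dkw^2)^2)
  }, numeric(1))
  band_sum_raw <- apply(sweep(cube$intensity[, , , sel], 1, wsum, "*"),
                        4, mean)
  full <- apply(fb$intensity[, , sel], 3, mean)
  # compare at matched axial resolution: the full-band profile resolves
  # the discrete scatterer comb that band images smooth over
  boxcar <- function(v) as.vector(stats::filter(v, rep(1 / 15, 15)))
  ratio <- boxcar(band_sum_raw) / boxcar(full)
  ratio <- ratio[is.finite(ratio)]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.02)
})

test_that("band intensities are invariant to a global fringe phase", {
  acq <- test_acq(23, nx = 1, ny = 1, noise_rel = 0, rolloff = 0)
  k <- isoct:::acq_k_grid(acq)
  z_nm <- 150 * acq$medium_index * 1000
  mk <- function(phi) {
    fr <- array(cos(2 * k * z_nm + phi), c(acq$n_k, 1, 1))
    structure(list(fringes = fr, k_grid = k, acquisition = acq,
                   ground_truth = NULL, speckle = FALSE),
              class = "raw_scan")
  }
  c0 <- stft_cube(mk(0)); c1 <- stft_cube(mk(pi / 3))
  for (b in c(1, 11, 22)) {
    p0 <- c0$intensity[b, 1, 1, ]; p1 <- c1$intensity[b, 1, 1, ]
    expect_identical(which.max(p0), which.max(p1))
    expect_equal(max(p1), max(p0), tolerance = 0.01)
  }
})

test_that("band images trade axial resolution for spectral resolution", {
  acq <- test_acq(24, nx = 1, ny = 1, noise_rel = 0, rolloff = 0)
  raw <- mirror_raw_scan(150, acq)
  cube <- stft_cube(raw)
  fb <- full_band_intensity(raw)
  fwhm <- function(z, p) {
    p <- p / max(p)
    f <- stats::approxfun(z, p - 0.5)
    pk <- z[which.max(p)]
    lo <- stats::uniroot(f, c(pk - 30, pk))$root
    hi <- stats::uniroot(f, c(pk, pk + 30))$root
    hi - lo
  }
  w_band <- fwhm(cube$z_grid, cube$intensity[11, 1, 1, ])
  w_full <- fwhm(fb$z_grid, fb$intensity[1, 1, ])
  expect_gt(w_band, w_full)
})

test_that("reference calibration removes the system response", {
  ts <- tissue_scan()
  cube <- ts$cube
  nb <- 22L
  # self-calibration: flat output per band
  ref_spec <- apply(cube$intensity, 1L, mean)
  cal <- reference_calibrate(cube, ref_spec)
  out <- apply(cal$intensity, 1L, mean)
  expect_lt(max(abs(out - out[1])), 1e-10 * out[1])
  # synthetic response round-trip
  resp <- 1 + 0.5 * sin(seq(0, pi, length.out = nb))
  warped <- cube
  warped$intensity <- sweep(cube$intensity, 1L, resp, "*")
  fixed <- reference_calibrate(warped, ref_spec * resp)
  expect_equal(apply(fixed$intensity, 1L, mean), out, tolerance = 0.005)
  # analytic mode: output differs from input by the lambda^-4 factor only
  an <- reference_calibrate(cube, NULL)
  model <- (cube$band_centers / cube$band_centers[1])^-4
  expect_equal(apply(an$intensity, 1L, mean), ref_spec / model,
               tolerance = 1e-12)
  # near-zero reference band is masked
  ref0 <- ref_spec; ref0[5] <- 0
  masked <- reference_calibrate(cube, ref0)
  expect_true(all(is.na(masked$intensity[5, , , ])))
  expect_true(5L %in% masked$provenance$masked_bands)
})

test_that("cube and raw-scan containers round-trip bit-exactly", {
  ts <- tissue_scan()
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  write_cube(ts$cube, p1)
  expect_identical(read_cube(p1), ts$cube)
  write_raw_scan(ts$raw, p2)
  expect_identical(read_raw_scan(p2), ts$raw)
})
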