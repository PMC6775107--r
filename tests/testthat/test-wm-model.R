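# Whittle-Matern model: autocorrelation, spectrum, phase function,
# anisotropy, scattering spectra and the backscatter spectral exponent.

test_that("D = 4 autocorrelation is exactly exponential", {
  p <- wm_params(An = 1, Ln = 137, D = 4)
  r <- c(10, 137, 500, 1000)
  ratio <- bn_autocorr(p, r) / bn_autocorr(p, 0)
  expect_equal(ratio, exp(-r / 137), tolerance = 1e-9)
})

test_that("autocorrelation origin behavior follows the shape parameter", {
  # divergence for D <= 3: error at r = 0, growth without bound as r -> 0
  p <- wm_params(1, 100, 3.0001)
  expect_error(bn_autocorr(wm_params(1, 100, 3), 0), "diverges")
  expect_error(bn_autocorr(wm_params(1, 100, 2.2), 0), "diverges")
  v <- bn_autocorr(p, 10^seq(-1, -6, by = -1))
  expect_true(all(diff(v) > 0))     # grows as r shrinks (log divergence)
  expect_gt(v[6], 2 * v[1])  # logarithmic growth
  # negative separation is a domain error
  expect_error(bn_autocorr(p, -1), ">= 0")
  # finite origin value above D = 3 matches the K_nu small-argument limit
  p4 <- wm_params(2.5, 100, 4.4)
  nu <- (4.4 - 3) / 2
  expect_equal(bn_autocorr(p4, 0), 2.5 * 2^(nu - 1) * gamma(nu),
               tolerance = 1e-12)
})

test_that("autocorrelation matches an independent Bessel evaluation", {
  # oracle: scipy.special.kv(0.25, 1) (independent K_nu implementation);
  # B_n(100; D = 2.5, Ln = 100, An = 1) = K_{-0.25}(1) = K_{0.25}(1)
  expect_equal(bn_autocorr(wm_params(1, 100, 2.5), 100),
               0.4307397744485814, tolerance = 1e-12)
})

test_that("power spectrum has the model form and fixed normalization", {
  p <- wm_params(1, 100, 3)
  expect_equal(wm_power_spectrum(p, 1 / 100) / wm_power_spectrum(p, 0),
               2^(-3 / 2), tolerance = 1e-12)
  # Phi(0) is the maximum; monotone nonincreasing
  q <- seq(0, 0.2, length.out = 200)
  v <- wm_power_spectrum(wm_params(0.7, 310, 2.2), q)
  expect_true(all(diff(v) <= 0))
  expect_error(wm_power_spectrum(p, -0.1), ">= 0")
})

test_that("power spectrum is the 3-D Fourier transform of B_n", {
  # oracle: numerical radial Fourier transform of the autocorrelation
  p <- wm_params(1, 100, 2.5)
  phinum <- function(q) {
    f <- function(r) bn_autocorr(p, r) * r * sin(q * r)
    stats::integrate(f, 0, 50 * p$Ln, subdivisions = 20000L,
                     rel.tol = 1e-10)$value / (2 * pi^2 * q)
  }
  for (q in c(1e-4, 1e-3, 1e-2, 1e-1)) {
    expect_equal(phinum(q), wm_power_spectrum(p, q), tolerance = 1e-2)
  }
})

test_that("phase function is a normalized density over solid angle", {
  cases <- list(c(2, 50), c(2.5, 600), c(3, 300), c(4, 1000), c(5, 2000))
  for (cs in cases) {
    pf <- phase_function(wm_params(1, cs[2], cs[1]), 600)
    tot <- stats::integrate(function(th) pf$density(th) * 2 * pi * sin(th),
                            0, pi, rel.tol = 1e-9,
                            subdivisions = 500L)$value
    expect_equal(tot, 1, tolerance = 1e-6)
    expect_true(all(pf$p >= 0))
  }
})

test_that("small-particle limit is isotropic", {
  # k Ln = 1e-3 at 600 nm
  Ln <- 1e-3 / wm_k(600)
  expect_lt(abs(anisotropy_g(wm_params(1, Ln, 3), 600)), 1e-3)
})

test_that("D = 3 phase function is Henyey-Greenstein after g matching", {
  p <- wm_params(1, 300, 3)
  g <- anisotropy_g(p, 600)
  pf <- phase_function(p, 600)
  th <- seq(0, pi, length.out = 2001)
  expect_lt(max(abs(pf$density(th) - henyey_greenstein(th, g))), 1e-6)
  # and at a bisected g = 0.9
  p9 <- wm_params_for_g(3, 0.9)
  expect_equal(anisotropy_g(p9, 600), 0.9, tolerance = 1e-8)
  pf9 <- phase_function(p9, 600)
  expect_lt(max(abs(pf9$density(th) - henyey_greenstein(th, 0.9))), 1e-6)
})

test_that("anisotropy is nondecreasing in the correlation length", {
  Lns <- 10^seq(1, log10(2000), length.out = 12)
  gs <- vapply(Lns, function(L) anisotropy_g(wm_params(1, L, 3), 600),
               numeric(1))
  expect_true(all(diff(gs) > -1e-10))
  expect_true(all(gs > -1 & gs < 1))
})

test_that("forward-lobe mass grows with the forward-peaking parameters", {
  lobe <- function(D, Ln) {
    pf <- phase_function(wm_params(1, Ln, D), 600)
    stats::integrate(function(th) pf$density(th) * 2 * pi * sin(th),
                     0, 10 * pi / 180, rel.tol = 1e-9)$value
  }
  kLn10 <- 10 / wm_k(600)
  expect_gt(lobe(5, kLn10), lobe(3, kLn10 / 10))
})

test_that("mu_s spectra are smooth, monotone in lambda and linear in An", {
  lam <- seq(520, 720, by = 10)
  for (D in c(2, 3, 4, 5)) for (Ln in c(50, 300, 1000)) {
    mus <- mu_s_spectrum(wm_params(1, Ln, D), lam)$mu_s
    d1 <- diff(mus)
    expect_true(all(d1 < 0) || all(d1 > 0))  # monotone, no pigment peak
    d2 <- diff(log(mus))
    expect_lt(max(abs(diff(d2))), 0.05 * max(abs(d2)) + 1e-12)  # smooth
  }
  p <- wm_params(1, 300, 2.5)
  p2 <- wm_params(2, 300, 2.5)
  expect_equal(mu_s_spectrum(p2, lam)$mu_s, 2 * mu_s_spectrum(p, lam)$mu_s,
               tolerance = 1e-12)
})

test_that("mu_s depends on D at fixed amplitude and correlation length", {
  v <- vapply(c(2, 3, 4), function(D)
    mu_s_spectrum(wm_params(1, 300, D), 600)$mu_s, numeric(1))
  expect_gt(diff(range(v)) / max(v), 0.1)
})

test_that("closed-form and quadrature mu_s agree", {
  lam <- c(520, 600, 720)
  for (D in c(1.5, 2, 2.5, 3.7)) {
    a <- mu_s_spectrum(wm_params(1, 400, D), lam)$mu_s
    q <- mu_s_spectrum(wm_params(1, 400, D), lam,
                       method = "quadrature")$mu_s
    expect_equal(a, q, tolerance = 1e-8)
  }
})

test_that("backscatter spectral exponent is D/2 - 2", {
  expect_identical(mub_exponent(4), 0)
  expect_identical(mub_exponent(3), -0.5)
  expect_identical(mub_exponent(1.5), -1.25)
  # log-log slope of the model amplitude spectrum reaches D/2 - 2 when
  # Ln >> lambda, and stays within a small bias band at moderate Ln
  lam <- seq(520, 720, length.out = 22)
  for (D in c(2, 2.5, 3.5, 5)) {
    mb <- wm_mu_b(wm_params(1, 20000, D), lam, convention = "amplitude")
    sl <- stats::coef(stats::lm(log(mb) ~ log(lam)))[[2]]
    expect_equal(sl, mub_exponent(D), tolerance = 0.05)
    mb2 <- wm_mu_b(wm_params(1, 600, D), lam, convention = "amplitude")
    sl2 <- stats::coef(stats::lm(log(mb2) ~ log(lam)))[[2]]
    expect_equal(sl2, mub_exponent(D), tolerance = 0.12)  # moderate Ln
  }
})

test_that("reduced scattering obeys mu_s' = mu_s (1 - g)", {
  os <- optical_spectra(wm_params(1, 500, 2.8), c(540, 620, 700))
  expect_equal(os$mu_s_prime, os$mu_s * (1 - os$g), tolerance = 1e-12)
  expect_true(all(os$albedo > 0))
  expect_true(all(os$g >= 0 & os$g < 1))
})

test_that("large-D autocorrelation approaches a Gaussian", {
  # D = 50 is outside the supported inversion range; evaluate the raw model
  nu <- (50 - 3) / 2
  r <- seq(1, 4000, length.out = 400)
  b <- (r / 1000)^nu * besselK(r / 1000, nu)
  fit <- stats::lm(log(b) ~ I(r^2))
  expect_gt(stats::cor(log(b), stats::fitted(fit)), 0.999)
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(wm_params(1, -5, 3), "Ln")
  expect_error(wm_params(0, 5, 3), "An")
  expect_error(wm_params(1, 5, 1.1), "supported range")
  expect_error(wm_params(1, 5, 6.5), "supported range")
})
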