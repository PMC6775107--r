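# Whittle-Matern continuous random medium optics under the first-order Born
# approximation. The medium's refractive-index autocorrelation is
#   B_n(r) = A_n (r/L_n)^((D-3)/2) K_((D-3)/2)(r/L_n),
# whose 3-D spectral density is proportional to (1 + q^2 L_n^2)^(-D/2).
# All single-scattering quantities (p(theta), g, mu_s, mu_b) follow from it.

#' Whittle-Matern structural parameters
#'
#' Bundle the three parameters of the Whittle-Matern refractive-index
#' autocorrelation model for one medium: the amplitude `An` (proportional to
#' the refractive-index variance), the correlation length `Ln` and the shape
#' parameter `D`. `D < 3` corresponds to a mass-fractal medium with fractal
#' dimension `D`, `3 < D < 4` to a stretched-exponential autocorrelation,
#' `D = 4` to an exponential one, and large `D` approaches a Gaussian.
#'
#' The supported range is `D` in \[1.2, 6\]: it covers the mass-fractal to
#' near-Gaussian regimes that occur in soft tissue and biomineral, while the
#' Born integrals and the spectral-exponent mapping used downstream degrade
#' outside it.
#'
#' @param An Correlation amplitude (dimensionless, > 0).
#' @param Ln Correlation length in nm (> 0).
#' @param D Shape / mass-fractal parameter (in \[1.2, 6\]).
#' @return An object of class `wm_params`.
#' @examples
#' wm_params(An = 1, Ln = 500, D = 2.5)
#' @export
wm_params <- function(An = 1, Ln, D) {
  stopifnot(is.numeric(An), is.numeric(Ln), is.numeric(D),
            length(An) == 1L, length(Ln) == 1L, length(D) == 1L)
  if (!is.finite(An) || An <= 0) stop("`An` must be finite and > 0")
  if (!is.finite(Ln) || Ln <= 0) stop("`Ln` must be finite and > 0 (nm)")
  if (!is.finite(D) || D < wm_D_range()[1] || D > wm_D_range()[2])
    stop(sprintf("`D` must lie in the supported range [%g, %g]",
                 wm_D_range()[1], wm_D_range()[2]))
  structure(list(An = An, Ln = Ln, D = D), class = "wm_params")
}

#' @export
print.wm_params <- function(x, ...) {
  cat(sprintf("<wm_params> An = %g, Ln = %g nm, D = %g\n", x$An, x$Ln, x$D))
  invisible(x)
}

#' Supported range of the shape parameter D
#' @return Numeric vector `c(min, max)`.
#' @export
wm_D_range <- function() c(1.2, 6)

as_wm_params <- function(params) {
  if (inherits(params, "wm_params")) return(params)
  if (is.list(params) && all(c("An", "Ln", "D") %in% names(params)))
    return(wm_params(params$An, params$Ln, params$D))
  stop("`params` must be a `wm_params` object")
}

#' Whittle-Matern refractive-index autocorrelation
#'
#' Evaluates `B_n(r) = An (r/Ln)^((D-3)/2) K_((D-3)/2)(r/Ln)`. For `D > 3`
#' the `r = 0` limit is finite, `An 2^((D-5)/2) Gamma((D-3)/2)`; for
#' `D <= 3` the autocorrelation diverges at the origin and requesting
#' `r = 0` is an error.
#'
#' @param params A [wm_params()] object.
#' @param r Separation distance(s) in nm, `>= 0`.
#' @return Autocorrelation value(s), same length as `r`.
#' @export
bn_autocorr <- function(params, r) {
  params <- as_wm_params(params)
  if (any(!is.finite(r)) || any(r < 0)) stop("`r` must be finite and >= 0")
  nu <- (params$D - 3) / 2
  out <- numeric(length(r))
  zero <- r == 0
  if (any(zero)) {
    if (params$D <= 3)
      stop("B_n(0) diverges for D <= 3 (origin is singular); use r > 0")
    out[zero] <- params$An * 2^(nu - 1) * gamma(nu)
  }
  x <- r[!zero] / params$Ln
  out[!zero] <- params$An * x^nu * besselK(x, nu)
  out
}

# Closed-form prefactor of the 3-D spectral density: the inverse Fourier
# transform of N * (1 + q^2 Ln^2)^(-D/2) reproduces B_n with amplitude An.
wm_spectrum_norm <- function(params) {
  params$An * params$Ln^3 * 2^((params$D - 5) / 2) * gamma(params$D / 2) /
    pi^1.5
}

#' Whittle-Matern power spectral density
#'
#' The 3-D spectral density of the refractive-index fluctuations,
#' `Phi(q) = N (1 + q^2 Ln^2)^(-D/2)`, with the closed-form prefactor
#' `N = An Ln^3 2^((D-5)/2) Gamma(D/2) / pi^(3/2)` fixed so that the inverse
#' Fourier transform reproduces [bn_autocorr()] with amplitude `An` (this is
#' verified numerically in the package tests against a radial Fourier
#' transform of the autocorrelation). Monotonically nonincreasing in `q`.
#'
#' @param params A [wm_params()] object.
#' @param q Spatial frequency(ies) in 1/nm, `>= 0`.
#' @return Spectral density value(s) in nm^3.
#' @export
wm_power_spectrum <- function(params, q) {
  params <- as_wm_params(params)
  if (any(!is.finite(q)) || any(q < 0)) stop("`q` must be finite and >= 0")
  wm_spectrum_norm(params) * (1 + q^2 * params$Ln^2)^(-params$D / 2)
}

#' Optical wavenumber in the medium
#' @param wavelength Vacuum wavelength in nm.
#' @param medium_index Refractive index of the embedding medium.
#' @return Wavenumber `2 pi medium_index / wavelength` in 1/nm.
#' @export
wm_k <- function(wavelength, medium_index = 1.35) {
  stopifnot(all(wavelength > 0), medium_index > 0)
  2 * pi * medium_index / wavelength
}

# Differential scattering cross-section per unit volume [1/(nm sr)] under the
# scalar-wave Born approximation; `dipole = TRUE` enables the EM dipole factor
# (1 + cos^2 theta)/2 for sensitivity checks.
born_diff_xsec <- function(params, theta, wavelength, medium_index = 1.35,
                           dipole = FALSE) {
  k <- wm_k(wavelength, medium_index)
  q <- 2 * k * sin(theta / 2)
  v <- 2 * pi * k^4 * wm_power_spectrum(params, q)
  if (dipole) v <- v * (1 + cos(theta)^2) / 2
  v
}

# Integration breakpoints that resolve the forward-scattering lobe.
theta_breaks <- function(kL) {
  w <- 1 / (1 + 2 * kL)
  unique(sort(pmin(pi, c(0, w, 5 * w, 25 * w, pi / 2, pi))))
}

# Adaptive quadrature of f(theta) over [0, pi] split at forward-lobe scales.
quad_theta <- function(f, kL, rel.tol = 1e-10) {
  br <- theta_breaks(kL)
  tot <- 0
  for (i in seq_len(length(br) - 1L)) {
    tot <- tot + stats::integrate(f, br[i], br[i + 1L], rel.tol = rel.tol,
                                  subdivisions = 400L)$value
  }
  tot
}

#' Single-scattering phase function
#'
#' The angular probability density of single scattering,
#' `p(theta) ∝ Phi(q = 2 k sin(theta/2))`, normalized to unit integral
#' over solid angle (`integral p(theta) 2 pi sin(theta) dtheta = 1`). For
#' `D = 3` this family reduces exactly to the Henyey-Greenstein phase
#' function.
#'
#' @inheritParams bn_autocorr
#' @param wavelength Vacuum wavelength in nm (one value).
#' @param medium_index Medium refractive index (default 1.35,
#'   seawater/tissue-like).
#' @param n_theta Number of angle samples returned (denser near theta = 0).
#' @param dipole Include the dipole factor `(1 + cos^2)/2`?
#' @return An object of class `phase_function` with fields `theta_grid`, `p`
#'   (density over solid angle, 1/sr), and `density`, a vectorized function
#'   of theta usable for quadrature.
#' @export
phase_function <- function(params, wavelength, medium_index = 1.35,
                           n_theta = 1001L, dipole = FALSE) {
  params <- as_wm_params(params)
  stopifnot(length(wavelength) == 1L, wavelength > 0)
  k <- wm_k(wavelength, medium_index)
  kL <- k * params$Ln
  norm <- quad_theta(function(th) {
    born_diff_xsec(params, th, wavelength, medium_index, dipole) *
      2 * pi * sin(th)
  }, kL)
  dens <- function(theta) {
    born_diff_xsec(params, theta, wavelength, medium_index, dipole) / norm
  }
  # log-spaced angles through the forward lobe, linear beyond
  w <- 1 / (1 + 2 * kL)
  n1 <- floor(n_theta / 2)
  th <- unique(sort(c(0,
                      exp(seq(log(w * 1e-3), log(min(pi, 10 * w)),
                              length.out = n1)),
                      seq(0, pi, length.out = n_theta - n1))))
  structure(list(theta_grid = th, p = dens(th), density = dens,
                 wavelength = wavelength, medium_index = medium_index,
                 params = params, dipole = dipole),
            class = "phase_function")
}

#' Scattering anisotropy factor g
#'
#' The average cosine of the phase function, computed by adaptive quadrature
#' with refinement in the forward lobe. `g` lies in (-1, 1); for this model
#' family it is nonnegative and approaches 0 in the small-particle
#' (`k Ln -> 0`) limit.
#'
#' @inheritParams phase_function
#' @return The anisotropy factor (dimensionless).
#' @export
anisotropy_g <- function(params, wavelength, medium_index = 1.35,
                         dipole = FALSE) {
  params <- as_wm_params(params)
  k <- wm_k(wavelength, medium_index)
  kL <- k * params$Ln
  num <- quad_theta(function(th) {
    cos(th) * born_diff_xsec(params, th, wavelength, medium_index, dipole) *
      sin(th)
  }, kL)
  den <- quad_theta(function(th) {
    born_diff_xsec(params, th, wavelength, medium_index, dipole) * sin(th)
  }, kL)
  num / den
}

# Closed-form mu_s [1/nm] for the scalar Born cross-section (no dipole term):
# mu_s = 8 pi^2 k^4 N [(1+x)^(1-D/2) - 1] / (x (1 - D/2)),  x = 4 k^2 Ln^2.
wm_mu_s_closed <- function(params, k) {
  N <- wm_spectrum_norm(params)
  x <- 4 * k^2 * params$Ln^2
  D <- params$D
  if (abs(D - 2) < 1e-9) {
    f <- log1p(x) / x
  } else {
    f <- ((1 + x)^(1 - D / 2) - 1) / (x * (1 - D / 2))
  }
  8 * pi^2 * k^4 * N * f
}

#' Scattering coefficient spectrum mu_s(lambda)
#'
#' Integrates the Born-approximation differential cross-section per unit
#' volume over all solid angle at each wavelength. The scalar-wave integral
#' has a closed form which is used by default; `method = "quadrature"`
#' evaluates the same integral by adaptive quadrature (the two agree to the
#' quadrature tolerance and are cross-checked in the package tests).
#' `mu_s` is linear in `An`.
#'
#' @inheritParams phase_function
#' @param lambda_grid Vacuum wavelengths in nm.
#' @param method `"analytic"` (closed form) or `"quadrature"`.
#' @return A list with `lambda` (nm), `mu_s` (1/cm) and `mu_s_star`
#'   (max-normalized spectrum).
#' @export
mu_s_spectrum <- function(params, lambda_grid, medium_index = 1.35,
                          method = c("analytic", "quadrature"),
                          dipole = FALSE) {
  params <- as_wm_params(params)
  method <- match.arg(method)
  stopifnot(all(lambda_grid > 0))
  k <- wm_k(lambda_grid, medium_index)
  if (method == "analytic" && !dipole) {
    mu_nm <- vapply(k, function(ki) wm_mu_s_closed(params, ki), numeric(1))
  } else {
    mu_nm <- vapply(seq_along(k), function(i) {
      quad_theta(function(th) {
        born_diff_xsec(params, th, lambda_grid[i], medium_index, dipole) *
          2 * pi * sin(th)
      }, k[i] * params$Ln, rel.tol = 1e-8)
    }, numeric(1))
  }
  if (any(!is.finite(mu_nm)))
    stop("Born scattering integral did not converge for these parameters")
  mu_cm <- mu_nm * 1e7  # 1/nm -> 1/cm
  list(lambda = lambda_grid, mu_s = mu_cm, mu_s_star = mu_cm / max(mu_cm))
}

#' Spectral exponent of the OCT backscatter spectrum
#'
#' For a Whittle-Matern medium with `Ln` much larger than the wavelength,
#' the wavelength-resolved OCT backscatter amplitude spectrum follows a
#' power law `lambda^(D/2 - 2)`; this returns that exponent. Inverting it
#' is how the mass-fractal dimension is estimated from measured spectra
#' (see [fit_D_from_mub()]).
#'
#' @param D Shape parameter(s).
#' @return `D/2 - 2`.
#' @export
mub_exponent <- function(D) D / 2 - 2

#' Backscattering coefficient of the model medium
#'
#' The backscattering cross-section per unit volume over the collection solid
#' angle of the system: the theta = pi differential value times
#' `solid_angle`. Only the spectral shape is model-critical downstream (the
#' absolute scale of measured spectra is set by a bead-standard calibration);
#' the solid angle fixes the absolute albedo convention shared with
#' [build_g_lookup()].
#'
#' Two conventions are offered: `"power"` is the physical backscattering
#' coefficient in 1/cm (proportional to detected OCT band *intensity*);
#' `"amplitude"` is its square root, the convention of the OCT backscatter
#' *amplitude* spectrum whose log-log slope against wavelength is
#' `D/2 - 2` (see [mub_exponent()]).
#'
#' @inheritParams phase_function
#' @param lambda Vacuum wavelength(s) in nm.
#' @param solid_angle Collection solid angle in sr.
#' @param convention `"power"` (1/cm) or `"amplitude"` (sqrt of power).
#' @return Backscattering coefficient(s).
#' @export
wm_mu_b <- function(params, lambda, medium_index = 1.35, solid_angle = 0.01,
                    convention = c("power", "amplitude"), dipole = FALSE) {
  params <- as_wm_params(params)
  convention <- match.arg(convention)
  v <- born_diff_xsec(params, pi, lambda, medium_index, dipole) *
    solid_angle * 1e7  # 1/nm -> 1/cm
  if (convention == "amplitude") sqrt(v) else v
}

#' Full set of single-scattering optical spectra for a medium
#'
#' Computes `mu_s`, `mu_b` (power convention), `g`,
#' `mu_s_prime = mu_s (1 - g)` and the reflection albedo
#' `alpha = mu_b / mu_s` on a wavelength grid.
#'
#' @inheritParams mu_s_spectrum
#' @inheritParams wm_mu_b
#' @return An object of class `optical_spectra`: a list of numeric vectors
#'   `lambda`, `mu_s`, `mu_b`, `g`, `mu_s_prime`, `albedo`.
#' @export
optical_spectra <- function(params, lambda_grid, medium_index = 1.35,
                            solid_angle = 0.01, dipole = FALSE) {
  params <- as_wm_params(params)
  mus <- mu_s_spectrum(params, lambda_grid, medium_index,
                       method = if (dipole) "quadrature" else "analytic",
                       dipole = dipole)$mu_s
  mub <- wm_mu_b(params, lambda_grid, medium_index, solid_angle,
                 convention = "power", dipole = dipole)
  g <- vapply(lambda_grid, function(l)
    anisotropy_g(params, l, medium_index, dipole), numeric(1))
  structure(list(lambda = lambda_grid, mu_s = mus, mu_b = mub, g = g,
                 mu_s_prime = mus * (1 - g), albedo = mub / mus,
                 medium_index = medium_index, solid_angle = solid_angle),
            class = "optical_spectra")
}

#' Scale the correlation amplitude to reach a target mu_s
#'
#' `mu_s` is linear in `An`, so a single evaluation fixes the scale.
#'
#' @inheritParams phase_function
#' @param mu_s_target Target scattering coefficient (1/cm) at `lambda0`.
#' @param lambda0 Anchor wavelength in nm.
#' @return A new `wm_params` with `An` rescaled.
#' @export
wm_scale_to_mu_s <- function(params, mu_s_target, lambda0 = 600,
                             medium_index = 1.35) {
  params <- as_wm_params(params)
  cur <- mu_s_spectrum(params, lambda0, medium_index)$mu_s
  wm_params(An = params$An * mu_s_target / cur, Ln = params$Ln, D = params$D)
}

#' Henyey-Greenstein phase function
#'
#' Closed-form reference density over solid angle, used as the independent
#' oracle for the `D = 3` special case of the Whittle-Matern family.
#'
#' @param theta Scattering angle(s), radians.
#' @param g Asymmetry parameter in (-1, 1).
#' @return Density value(s), 1/sr.
#' @export
henyey_greenstein <- function(theta, g) {
  (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos(theta))^1.5)
}

#' Find Ln giving a target anisotropy at fixed D
#'
#' Bisection on `log(Ln)`; `g` is monotone increasing in `Ln` at fixed `D`
#' over the supported range.
#'
#' @param D Shape parameter.
#' @param g_target Target anisotropy in (0, 1).
#' @param wavelength,medium_index As in [anisotropy_g()].
#' @param interval Search interval for `Ln` in nm.
#' @return A `wm_params` object (with `An = 1`) achieving `g_target`.
#' @export
wm_params_for_g <- function(D, g_target, wavelength = 600,
                            medium_index = 1.35,
                            interval = c(5, 50000)) {
  f <- function(lnL) {
    anisotropy_g(wm_params(1, exp(lnL), D), wavelength, medium_index) -
      g_target
  }
  r <- stats::uniroot(f, log(interval), tol = 1e-10)
  wm_params(An = 1, Ln = exp(r$root), D = D)
}
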