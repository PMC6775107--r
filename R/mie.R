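# Mie-theory standards for validating the attenuation fit: polystyrene
# microsphere suspensions with known mu_t provide external physics against
# which the pipeline's Beer-Lambert conventions (including the factor of 2)
# are checked.

#' Refractive index of polystyrene (visible band)
#'
#' One-term Sellmeier dispersion fit,
#' `n^2 = 1 + 1.4435 lambda^2 / (lambda^2 - 0.020216)` with `lambda` in
#' micrometers; accurate to ~1e-3 over 400-800 nm.
#'
#' @param lambda Vacuum wavelength(s) in nm.
#' @return Refractive index.
#' @export
polystyrene_index <- function(lambda) {
  lum2 <- (lambda / 1000)^2
  sqrt(1 + 1.4435 * lum2 / (lum2 - 0.020216))
}

#' Refractive index of water (visible band)
#'
#' Empirical Cauchy-type fit `n = 1.31279 + 15.762/l - 4382/l^2 + 1.1455e6/l^3`
#' with `l` in nm (room temperature).
#'
#' @inheritParams polystyrene_index
#' @return Refractive index.
#' @export
water_index <- function(lambda) {
  1.31279 + 15.762 / lambda - 4382 / lambda^2 + 1.1455e6 / lambda^3
}

#' Mie scattering and extinction efficiencies of a homogeneous sphere
#'
#' Standard Lorenz-Mie series with the logarithmic-derivative downward
#' recurrence for the internal field and upward Riccati-Bessel recurrences
#' for the external field.
#'
#' @param x Size parameter `pi * diameter * n_medium / lambda`.
#' @param m Relative refractive index `n_sphere / n_medium` (real).
#' @return A list with `Qsca` and `Qext`.
#' @export
mie_efficiencies <- function(x, m) {
  stopifnot(x > 0, m > 0)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- max(nmax, ceiling(abs(m * x))) + 16L
  Dlog <- rep(0 + 0i, nmx + 1L)
  for (n in nmx:1) Dlog[n] <- (n + 1) / (m * x) - 1 / (Dlog[n + 1L] +
                                                         (n + 1) / (m * x))
  psi <- numeric(nmax + 1L); chi <- numeric(nmax + 1L)
  psi[1L] <- sin(x); chi[1L] <- cos(x)
  psim1 <- cos(x); chim1 <- -sin(x)  # order -1
  an <- bn <- complex(nmax)
  for (n in 1:nmax) {
    psi_n <- (2 * n - 1) / x * psi[n] - psim1
    chi_n <- (2 * n - 1) / x * chi[n] - chim1
    psim1 <- psi[n]; chim1 <- chi[n]
    psi[n + 1L] <- psi_n; chi[n + 1L] <- chi_n
    xi_n <- psi_n - 1i * chi_n
    xi_nm1 <- psi[n] - 1i * chi[n]
    Dn <- Dlog[n]
    an[n] <- ((Dn / m + n / x) * psi_n - psi[n]) /
      ((Dn / m + n / x) * xi_n - xi_nm1)
    bn[n] <- ((Dn * m + n / x) * psi_n - psi[n]) /
      ((Dn * m + n / x) * xi_n - xi_nm1)
  }
  n <- 1:nmax
  list(Qsca = 2 / x^2 * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)),
       Qext = 2 / x^2 * sum((2 * n + 1) * Re(an + bn)))
}

#' Mie scattering cross-section of a sphere
#'
#' @param diameter Sphere diameter in nm.
#' @param lambda Vacuum wavelength in nm.
#' @param n_sphere Sphere refractive index; default polystyrene dispersion.
#' @param n_medium Medium refractive index; default water dispersion.
#' @return Cross-section in cm^2.
#' @export
mie_cross_section <- function(diameter, lambda,
                              n_sphere = polystyrene_index(lambda),
                              n_medium = water_index(lambda)) {
  x <- pi * diameter * n_medium / lambda
  q <- mie_efficiencies(x, n_sphere / n_medium)$Qsca
  q * pi * (diameter / 2)^2 * 1e-14  # nm^2 -> cm^2
}

#' Rayleigh-limit scattering cross-section of a small sphere
#'
#' Closed form `sigma = (8/3) x^4 ((m^2-1)/(m^2+2))^2 * pi a^2`, the
#' small-particle limit of the Mie series.
#'
#' @inheritParams mie_cross_section
#' @return Cross-section in cm^2.
#' @export
rayleigh_cross_section <- function(diameter, lambda,
                                   n_sphere = polystyrene_index(lambda),
                                   n_medium = water_index(lambda)) {
  x <- pi * diameter * n_medium / lambda
  m <- n_sphere / n_medium
  q <- 8 / 3 * x^4 * ((m^2 - 1) / (m^2 + 2))^2
  q * pi * (diameter / 2)^2 * 1e-14
}

#' Total attenuation coefficient of a dilute sphere suspension
#'
#' Independent-scattering estimate `mu_t = number density x Mie extinction
#' cross-section` (non-absorbing spheres, so extinction = scattering). Warns
#' above 5% volume fraction where dependent-scattering corrections matter.
#'
#' @inheritParams mie_cross_section
#' @param volume_fraction Sphere volume fraction (dimensionless, << 1).
#' @return `mu_t` in 1/cm (vectorized over `lambda`).
#' @export
mie_mu_t <- function(diameter, lambda, volume_fraction,
                     n_sphere = polystyrene_index(lambda),
                     n_medium = water_index(lambda)) {
  stopifnot(volume_fraction > 0, diameter > 0)
  if (volume_fraction > 0.05)
    warning("volume fraction > 0.05: dependent scattering not modeled")
  n_sphere <- rep_len(n_sphere, length(lambda))
  n_medium <- rep_len(n_medium, length(lambda))
  sigma <- vapply(seq_along(lambda), function(i)
    mie_cross_section(diameter, lambda[i], n_sphere[i], n_medium[i]),
    numeric(1))
  vol_nm3 <- pi / 6 * diameter^3          # sphere volume, nm^3
  rho_cm3 <- volume_fraction / vol_nm3 * 1e21  # number density, 1/cm^3
  rho_cm3 * sigma
}

#' Rayleigh backscattering coefficient of a small-sphere suspension
#'
#' Differential Rayleigh cross-section at 180 degrees,
#' `dsigma/dOmega = k^4 a^6 ((m^2-1)/(m^2+2))^2`, times number density and
#' the collection solid angle. Used as the known backscatter spectrum of the
#' bead calibration standard (power convention, proportional to detected
#' band intensity).
#'
#' @inheritParams mie_mu_t
#' @param solid_angle Collection solid angle in sr.
#' @return `mu_b` in 1/cm (power convention), vectorized over `lambda`.
#' @export
rayleigh_mu_b <- function(diameter, lambda, volume_fraction,
                          solid_angle = 0.01,
                          n_sphere = polystyrene_index(lambda),
                          n_medium = water_index(lambda)) {
  k <- 2 * pi * n_medium / lambda  # 1/nm in medium
  a <- diameter / 2
  m <- n_sphere / n_medium
  dsig <- k^4 * a^6 * ((m^2 - 1) / (m^2 + 2))^2  # nm^2/sr
  vol_nm3 <- pi / 6 * diameter^3
  rho_cm3 <- volume_fraction / vol_nm3 * 1e21
  rho_cm3 * dsig * 1e-14 * solid_angle
}
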