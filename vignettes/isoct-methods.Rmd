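---
title: "Inverse spectroscopic OCT: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse spectroscopic OCT: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This package implements an inverse spectroscopic OCT (ISOCT) processing
chain for visible-band (520–720 nm) spectral-domain OCT of strongly
scattering, pigmented samples — the motivating system is living
reef-building coral, whose thin absorbing tissue covers a strongly
scattering aragonite skeleton — together with a forward simulator that
makes every inversion stage testable by parameter recovery against known
ground truth. This vignette explains the model, the estimation procedure,
the tunable parameters, and the design choices that were genuinely open.

## The light-scattering model

Light transport in a weakly scattering continuous random medium is
determined by the spatial statistics of its refractive index. We model the
index autocorrelation with the three-parameter Whittle–Matérn family

$$B_n(r) = A_n \left(\frac{r}{L_n}\right)^{(D-3)/2}
           K_{(D-3)/2}\!\left(\frac{r}{L_n}\right),$$

where $A_n$ is proportional to the index variance, $L_n$ is a correlation
length (nm), $D$ is the shape parameter, and $K_\nu$ is the modified
Bessel function of the second kind. For $D<3$ the autocorrelation is an
inverse power law — the signature of a mass fractal with fractal dimension
$D$; $D = 4$ gives an exponential; $D \to \infty$ a Gaussian. The package
supports $D \in [1.2, 6]$, which covers the mass-fractal to near-Gaussian
regimes observed in soft tissue and biomineral; outside this range the
Born integrals and the spectral-exponent mapping used for inversion
degrade, so out-of-range values are an error rather than a silent
extrapolation.

Under the first-order Born approximation the differential scattering
cross-section per unit volume is proportional to the 3-D power spectral
density of the index fluctuations evaluated at the momentum transfer
$q = 2k\sin(\theta/2)$:

$$\Phi(q) = \frac{A_n L_n^3\, 2^{(D-5)/2}\,\Gamma(D/2)}{\pi^{3/2}}
            \,(1 + q^2 L_n^2)^{-D/2},$$

with the prefactor fixed so that the inverse transform reproduces $B_n$
with amplitude $A_n$ (verified numerically in the test suite against a
radial Fourier transform of `bn_autocorr()`). From $\Phi$ follow all
single-scattering quantities: the phase function
$p(\theta) \propto \Phi(2k\sin(\theta/2))$ normalized over solid angle,
its average cosine $g$, the scattering coefficient $\mu_s$ (the scalar
Born integral has a closed form, used by default and cross-checked against
adaptive quadrature), the reduced scattering coefficient
$\mu_s' = \mu_s(1-g)$, and the backscattering coefficient $\mu_b$, taken
as the $\theta = \pi$ differential value times a configured collection
solid angle (0.01 sr by default). For $D = 3$ the family reduces exactly
to the Henyey–Greenstein phase function, which the tests verify to
$10^{-6}$ after matching $g$; for $D \ne 3$ the two differ, which is the
reason to measure $D$ rather than assume it.

The scalar-wave Born form is used (no dipole $(1+\cos^2\theta)/2$ factor),
matching the convention of the ISOCT literature this analysis follows; the
dipole factor can be enabled (`dipole = TRUE`) for sensitivity checks.

### Backscatter spectral conventions

Two conventions coexist and are kept explicit throughout. The physical
(power) backscattering coefficient $\mu_b$ [1/cm] is proportional to
detected band *intensity* and scales as $\lambda^{D-4}$ for
$L_n \gg \lambda$. The OCT backscatter *amplitude* spectrum — the square
root of intensity — scales as $\lambda^{D/2-2}$, and that is the spectrum
whose log–log slope the inversion fits (`fit_D_from_mub()`,
$D = 2(\mathrm{slope}+2)$). `mu_b_spectrum()` returns both: `mu_b`
(amplitude, for the $D$ fit) and `mu_b_power` (1/cm, for the albedo).
The albedo $\alpha = \mu_b/\mu_s$ and the $g(\alpha, D)$ lookup table are
defined in the power convention, so the measured albedo and the
model-generated table are directly comparable.

## The processing pipeline

1. **STFT.** Raw interferograms on a uniform wavenumber grid are windowed
   with 22 Gaussian windows of 20 nm FWHM (widths stated in wavelength and
   mapped to k at each center, since the transform operates in the
   acquisition domain) and transformed to depth; magnitude squared is
   stored, so depth decay is $e^{-2\mu_t z}$ and depths are optical path.
   Windows are normalized to unit energy: their k-space width scales as
   $1/\lambda_c^2$, and without normalization this instrumental gain tilts
   every spectrum by $\lambda^{-2}$ (a $\Delta D \approx -2$ bias). Band
   centers keep a 1.5-FWHM margin from the spectrum edges because a
   clipped window tail produces point-spread-function sidelobes that leak
   bright surface signal into depth and bias edge-band attenuation fits.
2. **Roll-off compensation and noise floor.** The known spectrometer
   sensitivity decay (dB/mm of optical path, −10 dB/mm default) is divided
   out. The per-band detector noise floor is estimated from the empty
   region above the shallowest surface and subtracted before any
   compensation — a flat floor otherwise tilts weak bands and biases both
   the Beer–Lambert slope and the backscatter spectral slope, and
   attenuation compensation would amplify it depth-dependently.
3. **Calibration.** Spectra are calibrated against a scan of a dilute
   80 nm polystyrene bead suspension, a near-Rayleigh standard with known
   backscatter. The reference is pushed through the same pipeline; because
   it is homogeneous by construction it is compensated with its per-band
   median attenuation (per-column attenuation noise would otherwise bias
   the compensated spectrum through the exponential). The calibration
   vector $\sqrt{\mu_b^{\mathrm{model}}/I_{\mathrm{ref}}}$ cancels all
   system spectral gains and sets the absolute $\mu_b$ scale.
4. **Surface detection.** Per B-scan: speckle-averaged, contrast-
   normalized intensity is binarized by an extended-maxima transform
   (dome height `h = 0.1` of the normalized image) whose markers are
   grown by binary morphological reconstruction within the
   above-background mask, then cleaned by closing/opening and a minimum
   object size (30 px). The per-column surface is then refined at full
   axial resolution as the sub-pixel half-maximum crossing of the
   laterally averaged profile, and the surface map is median-filtered
   (3×3). The refinement stage exists because the first-true-voxel of the
   binarized region alone is not repeatable to ±1 axial pixel under fully
   developed speckle; with it, detection on the simulated flat phantom at
   30 dB SNR is within ±1 pixel for over 99% of columns. Validity filters
   mask columns whose surface sits beyond the roll-off sensitivity budget
   or shows specular (saturated) reflection; manual segmentation masks
   override detection where provided.
5. **Attenuation.** Per band and column, weighted linear regression of
   log intensity over a 90 µm (optical path) window below the surface,
   starting 4 µm below the detected onset to skip the PSF ramp;
   $\mu_t = -\mathrm{slope}\cdot n/2$ converts to geometric path (the
   medium index defaults to 1.35, seawater/tissue-like). A 3×3 lateral
   speckle-averaging kernel precedes the fit. Negative fits are floored at
   zero and flagged. The factor-of-2 (intensity) convention is shared with
   the simulator and guarded externally by the Mie-theory bead standards.
6. **Decomposition.** The max-normalized attenuation spectrum is fit as
   $c_a\,\mu_a^*(\lambda) + c_s\,\mu_s^*(\lambda; D, L_n)$ by multi-start
   Nelder–Mead (8 Latin-hypercube starts, fixed seed, ties toward smaller
   $D$), with the chlorophyll-a reference supplying $\mu_a^*$ and the
   Whittle–Matérn model $\mu_s^*$. The optimizer fits unconstrained
   nonnegative amplitudes; reported fractional contributions are clipped
   to $[0, \tfrac12]$ with a flag, while the absolute coefficients use the
   raw amplitudes so that $\mu_a + \mu_s$ reproduces $\mu_t$ at the
   spectrum maximum. (The raw optimum necessarily has $c_a + c_s \ge 1$
   for any max-normalized spectrum, so a hard $\tfrac12$ box would forbid
   the scale consistency that the absolute coefficients require; keeping
   the box on the reported fractions and the scale on the absolute
   coefficients satisfies both conventions simultaneously.) The pigment
   reference is blurred to the 20 nm band resolution before fitting —
   band-wise measurement averages the narrow 660 nm peak over the window,
   reducing its apparent amplitude by ~18% — and the fitted amplitude is
   converted back to the physical peak for concentration. In skeleton
   mode the absorption term is disabled (skeletal absorption is ignored)
   and the fit reduces to $(c_s, D, L_n)$. Identifiability rests on the
   660 nm feature: with a featureless reference the absorption and
   scattering fractions become degenerate, which the tests demonstrate via
   multi-start dispersion.
7. **D, albedo, g.** After attenuation compensation, the mean compensated
   intensity over the same 90 µm window gives the backscatter spectrum
   per pixel; its log–log slope gives the per-pixel $D$ map (this
   $\mu_b$-derived $D$ is used for maps and the $g$ lookup; the
   decomposition's $D$ is reported separately). The albedo at a reference
   band near 620 nm — chosen away from the 660 nm absorption peak because
   the albedo is a scattering quantity — is inverted to $g$ by bilinear
   interpolation in a precomputed $g(\alpha, D)$ table (quadrature over an
   internal $(D, L_n)$ grid; out-of-support albedos are masked, never
   extrapolated).
8. **Chlorophyll-a.** The fitted peak absorption is divided by the
   decadic molar extinction coefficient ($C = \mu_a(660)/(\ln 10\,
   \varepsilon)$; the packaged fixture records its convention, and a
   natural-log fixture would drop the $\ln 10$), converted to mass
   concentration via the 893.5 g/mol molar mass, and integrated over the
   90 µm window to areal density (µg/cm²) under a constant-concentration
   assumption. The decomposition runs on 8×8-column super-pixels (a
   22-band spectrum needs lateral speckle averaging to be stable) while
   $D$ and $g$ stay at pixel resolution.

```{r pipeline, eval = FALSE}
library(isoct)
cfg <- default_run_config(rng_seed = 1)
isoct_simulate(cfg, "scan.rds")
maps <- isoct_process("scan.rds", cfg, "out/")
isoct_report("out/")
```

## The forward simulator

The simulator realizes exactly the signal model the inversion assumes:
per-voxel backscatter amplitude
$\sqrt{\mu_b(\lambda, z)\,dz}\;e^{-\int_0^z \mu_t\,dz'}\,
\mathrm{rolloff}(z)$, summed over depth with round-trip phase $2 k n z$
(optical path; the convention is explicit and symmetric between simulator
and inversion, and fitted slopes are converted back to geometric path with
the same index). Speckle is a complex circular-Gaussian per-voxel
reflectivity with variance proportional to $\mu_b$, which produces fully
developed speckle with a Rayleigh amplitude envelope — the statistics the
pipeline's averaging assumes, verified by a Kolmogorov–Smirnov test.
Additive detector noise is white in the fringe domain with standard
deviation `noise_rel` relative to the RMS fringe amplitude;
`noise_rel` $= 10^{-\mathrm{SNR_{dB}}/20}$ defines the quoted SNR (30 dB
in the standard conditions). All stochastic output is reproducible from
(phantom, acquisition, seed), and a speckle-free mode plus an analytic
`model_cube()` provide exact references for the strict contract tests.

Phantoms are ordered layer stacks over a surface height field; layers are
either Whittle–Matérn media (with optional chlorophyll-a load, forward
absorption built through the same pigment module the inversion uses —
closure by construction) or tabulated spectra (used for bead standards and
power-law test media). The standard study phantom is 64×64 columns of
coenosarc-like tissue (150 µm, $D = 2.5$, $L_n = 600$ nm,
$\mu_s(600) = 100$ /cm, chlorophyll-a 0.3 mg/cm³ — areal truth
2.7 µg/cm² over the 90 µm window) over skeleton (200 µm, $D = 3.5$,
$L_n = 800$ nm, $\mu_s(600) = 200$ /cm, no absorption), surface at 60 µm,
2 µm scatterer pitch, 1024 wavenumber samples. The skeleton is measured
from a second, tissue-removed scan (`skeleton_exposed_config()`), mirroring
the tissue-stripping rescan protocol, because the surface-referenced 90 µm
window of the tissue scan sees only tissue. The scattering scales and
correlation lengths were chosen once as realistic for weakly pigmented
coral tissue over aragonite ($g$ near 0.8–0.96, $\mu_s'$ of a few 1/cm)
and are part of the package's fixed study conditions.

### What the simulator does and does not emulate

It emulates layered media with model-exact spectra, Beer–Lambert depth
decay, fully developed speckle, spectrometer roll-off, detector noise and
surface topography. It does not model beam focusing/confocal gating,
dispersion mismatch, k-linearization errors, multiple scattering,
polarization/birefringence (relevant for aragonite), lateral speckle
correlation (columns are independent), or within-layer heterogeneity.
Passing recovery tests therefore demonstrates that the inversion is
consistent and unbiased under its own assumptions at realistic SNR — not
that those assumptions hold in any particular real sample.

## Numerical choices

- Quadratures on $\theta\in[0,\pi]$ are adaptive with explicit breakpoints
  through the forward lobe (width $\sim 1/(kL_n)$), relative tolerance
  1e−8 or better; phase-function normalization holds to 1e−6 across the
  supported parameter space.
- The closed-form scalar Born $\mu_s$ (and the $\mu_s^*$ shape inside the
  decomposition's objective) agrees with quadrature to machine precision
  and keeps the per-super-pixel fit fast.
- The attenuation regression is linear in log intensity — equivalent to a
  nonlinear exponential fit in the noiseless limit, robust and fast —
  weighted by intensity to de-emphasize noise-floor voxels.
- Degenerate inputs produce masks, not errors: dark B-scans, columns with
  no detected edge, out-of-support albedos, nonpositive backscatter bands
  (dropped; fewer than 6 surviving bands invalidates the pixel), and
  negative attenuation slopes (floored, flagged).
- The g lookup interpolates bilinearly in $(\log\alpha, D)$ on a
  49×90 grid built from an 80-point geometric $L_n$ sweep; table cells
  outside the albedo range achievable at a given $D$ stay masked.
- Problem sizes in the tests and the acceptance script (64×64 columns,
  1024 wavenumber samples, 48×48 columns for the Mie standard, 8-start
  decompositions on 8×8 blocks) were chosen so the whole suite exercises
  every stage at full fidelity in minutes on one CPU; recovery tolerances
  are quoted at these sizes.

## Known limitations

- The $[0, \tfrac12]$ box on the reported fractional contributions is a
  reporting convention (see above); consumers needing absolute optics
  should use `mu_a`/`mu_s` or the raw `par`, not `c_a`/`c_s`.
- $D$ estimated from a 140 nm wavelength lever arm has a small negative
  bias (≈0.05 under the standard conditions) from residual
  compensation/floor coupling; it is well inside the ±0.3 recovery band
  but visible in the acceptance numbers.
- The packaged chlorophyll-a reference is a documented analytic stand-in
  (Gaussian Qy band at 660 nm, vibronic satellite at 615 nm, Soret tail),
  with the peak decadic extinction of chlorophyll-a in methanol; a
  digitized measured spectrum can be swapped in via the same fixture
  format, and the closure tests make the pipeline self-consistent for
  whichever fixture ships. No solvent-to-in-vivo spectral shift is
  applied.
- At the aqueous bead-standard condition (80 nm spheres, size parameter
  ≈0.56) the true Mie cross-section sits ≈6.5% below the Rayleigh closed
  form; the standard's *spectral shape* is still Rayleigh-like to well
  within the calibration's needs, and the Rayleigh-limit unit check is
  run at small size parameter where the closed form applies.
- Multi-pigment unmixing is out of scope: the decomposition assumes
  chlorophyll-a is the dominant absorber. The pigment fixture interface
  is the hook for additional spectra, but none ship.
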