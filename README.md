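# isoct

Inverse spectroscopic optical coherence tomography (ISOCT) processing for
visible-band (520–720 nm) spectral-domain OCT of strongly scattering,
pigmented samples — built for living reef-building corals, whose thin
chlorophyll-bearing tissue covers a strongly scattering aragonite
skeleton, and applicable to any layered turbid medium in the same regime.

Conventional OCT intensity mixes backscattering, total attenuation and
pigment absorption into one number per voxel. ISOCT resolves the OCT
signal in wavelength and inverts it: the package converts raw
interferogram volumes into a 4-D spectral cube `I_b(λ, x, y, z)`, detects
the sample surface, fits the wavelength-resolved total attenuation
coefficient `μ_t(λ)` by Beer–Lambert regression over a 90 µm window, and
decomposes it under a Whittle–Matérn continuous-random-medium model into

- the scattering coefficient `μ_s(λ)` and absorption coefficient
  `μ_a(λ)` (1/cm), with `μ_a` converted to chlorophyll-a volumetric and
  areal density (µg/cm²);
- the mass-fractal dimension `D` of the sub-resolution refractive-index
  correlations, from the power law `μ_b(λ) ∝ λ^(D/2−2)` of the
  attenuation-compensated backscatter spectrum;
- the scattering anisotropy `g` (and `μ_s′ = μ_s(1−g)`), from the
  reflection albedo `α = μ_b/μ_s` through a precomputed `g(α, D)` lookup
  table.

The refractive-index autocorrelation model is
`B_n(r) = A_n (r/L_n)^((D−3)/2) K_((D−3)/2)(r/L_n)`; its `D = 3` special
case is exactly the Henyey–Greenstein phase function, and measuring `D`
removes the need for that assumption. All single-scattering quantities
(phase function, `g`, `μ_s`, `μ_b`) are computed from the model under the
first-order Born approximation.

Because real coral datasets of this kind are not publicly deposited, the
package ships a first-class forward simulator: layered phantoms with known
ground-truth optics (Whittle–Matérn layers with chlorophyll-a loads, or
tabulated bead standards), fully developed speckle, spectrometer roll-off
and detector noise. Every inversion stage is tested by parameter recovery,
and the attenuation convention is validated externally against Mie theory
for polystyrene microsphere suspensions.

## Worked example

A packaged demo configuration simulates a small two-layer phantom —
coenosarc-like tissue (`D = 2.5`, `μ_s(600) = 100` /cm, chlorophyll-a
0.3 mg/cm³, areal truth 2.7 µg/cm² over the 90 µm window) over skeleton
(`D = 3.5`, `μ_s(600) = 200` /cm, no absorption) — and runs the full
pipeline:

```r
library(isoct)
cfg <- system.file("extdata", "demo_config.yaml", package = "isoct")
isoct_simulate(cfg, "demo_scan.rds")
maps <- isoct_process("demo_scan.rds", cfg, "demo_out")
```

prints

```
wrote demo_scan.rds (24 x 24 columns, 1024 k-samples, seed 1)
  region 1 layer 1: D = 2.50, g(620) = 0.792, mu_t(620) = 103.6 1/cm, chl = 0.30 mg/cm^3
  region 1 layer 2: D = 3.50, g(620) = 0.958, mu_t(620) = 187.2 1/cm, chl = 0.00 mg/cm^3
wrote reference demo_scan_reference.rds
stft: 22 bands
calibrating against reference: demo_scan_reference.rds
surface detection
building g(albedo, D) lookup table
fitting maps
<property_maps> 24 x 24, 100.0% valid; median D = 2.37, median g = 0.78, median chl = 3.02 ug/cm^2
```

The first three lines are the simulator's ground truth; the last line is
the recovery on this small raster: median `D` 2.37 against a true 2.5,
median `g` 0.78 against 0.792 at 620 nm, and chlorophyll-a areal density
3.0 µg/cm² against 2.7 (the tissue layer is measured through the first
90 µm of optical path below the detected surface). `demo_out/` then holds
the en-face maps (32-bit float TIFF with scale sidecars plus CSV), the
surface map, histograms, the serialized `g(α, D)` lookup and a provenance
record; `isoct_report("demo_out")` renders labeled map and histogram
images. The same two commands are available from a shell as
`exec/isoct simulate|process|report`. Skeleton scans (after tissue
removal) are processed with `skeleton_mode = TRUE`, which disables
absorption fitting and omits the chlorophyll output.

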