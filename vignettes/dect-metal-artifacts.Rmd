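---
title: "Simulating and quantifying metal artifacts in dual-energy CT virtual monochromatic imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying metal artifacts in dual-energy CT virtual monochromatic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metallic hip stems produce two families of streak artifact in CT. Beam
hardening: as a polychromatic beam crosses dense, high-Z metal, its soft
photons are absorbed preferentially, the surviving beam is "harder" than the
calibration assumed, and the reconstruction books the deficit as spurious
dark bands around the implant. Photon starvation: behind enough metal almost
no photons reach the detector, the log-normalized projections become wildly
noisy or clipped, and the filtered back projection smears that error into
bright streaks. Dual-energy CT (DECT) attacks the first mechanism: from two
acquisitions at different tube voltages (here sequential scans at 80 kVp and
140 kVp) one can synthesize *virtual monochromatic spectral* (VMS) images at
a chosen photon energy, and at high energies the hardening contrast largely
vanishes.

`dectlab` rebuilds that experiment end to end at desk scale: a water-gel box
phantom holding one femoral stem — titanium alloy (Ti-6Al-7Nb), chrome-cobalt
(CoCrMo) or stainless steel (CrNi) — surrounded by six calcium
hydroxyapatite calibration pellets; a polychromatic parallel-beam CT
simulator; image-domain two-material decomposition with VMS synthesis at
40/50/70/100/120/140/190 keV; and the measurement stack (artifact volumetry
in fixed Hounsfield intervals, pellet ROI density and deviation,
signal-to-noise ratios, paired comparisons of monochromatic versus
polychromatic stations).

## Attenuation model

Elemental mass attenuation coefficients ship as plain-text tables on a
30–200 keV grid (no packaged element has an absorption edge above 30 keV).
Between grid points the lookup interpolates log–log, because attenuation is
close to a power law between edges; on grid points the tabulated value is
returned exactly. Compounds and alloys use the weight-fraction mixture rule

$$ (\mu/\rho)_{\text{mix}}(E) \;=\; \sum_i w_i \,(\mu/\rho)_i(E),
\qquad \mu = \rho \,(\mu/\rho)_{\text{mix}}, $$

which is linear in the weights (a mixture of mixtures equals the direct
mixture). The stem alloys are not published with exact weight fractions, so
the package uses standard orthopaedic compositions, stored as editable YAML
so users can refine them:

| material          | composition (weight)                       | density (g/cm³) |
|-------------------|--------------------------------------------|-----------------|
| titanium_alloy    | Ti 0.87, Al 0.06, Nb 0.07                  | 4.52            |
| chrome_cobalt     | Co 0.60, Cr 0.27, Ni 0.07, Mo 0.06         | 8.30            |
| stainless_steel   | Fe 0.63, Cr 0.20, Ni 0.15, Mo 0.02         | 7.95            |
| ha_pellet         | 200 mg/cm³ hydroxyapatite in water matrix  | 1.13            |
| water             | H 0.1119, O 0.8881                         | 1.00            |

The 5% gelatin of the physical gel box shifts water attenuation by well
under 1% in this energy range and is modeled as pure water. These choices
give the orderings that drive everything downstream: at every energy in
40–190 keV, LAC(HA) < LAC(Ti alloy) < LAC(steel) < LAC(CoCr), and at 50 keV
the metal ordering follows the atomic number of the dominant element
(photoelectric absorption roughly ∝ Z³/E³).

## Phantom geometry

The box is 400 × 335 × 170 mm. The stem is a truncated cone (length 150 mm,
radius tapering 8 mm proximally to 3 mm distally — commercial stems are
specified only qualitatively, so these are declared defaults, overridable in
`phantom_config()`). The stem lies along the scan axis, so reconstructed
slices are transverse to it and contain its circular cross-section. This
orientation is the one consistent with the reported measurements: transverse
mid-stem slices show radial streaks around the stem profile with the
reference pellet visible in the image corner, the most affected pellets are
the ones beside the *thick* proximal cross-section, and the pellet below the
distal tip stays clean. Pellet cylinders (30 mm × 20 mm ⌀) stand parallel
to the stem: zones 2/6 lateral/medial at the proximal third, zones 3/5 at
the distal third, zone 4 vertically below the distal tip, all at a 5 mm
surface gap (taken against the largest stem radius over the pellet's axial
extent); the reference pellet P1 sits near a box corner at mid-stem level.
Voxelization includes a voxel when its center lies inside the solid, with
half-open axial spans so lattice-aligned boundaries never double-count a
slice; halving the spacing moves each solid's volume by under 2%. Spacing
must be ≤ 2.5 mm so the 5 mm gap stays resolved.

```{r}
library(dectlab)
ph <- build_phantom(phantom_config(spacing_mm = 2.1))
ph
```

## Scanner model

**Spectra.** Kramers bremsstrahlung as seen by an energy-integrating
detector — effective fluence ∝ (kVp − E) — filtered by aluminum and
renormalized. Characteristic lines are omitted; the analysis needs spectral
hardening, not spectroscopic fidelity, and the model is swappable. Defaults:
6 mm Al total filtration (typical body-protocol inherent plus flat
filtration) and a reference fluence of 2 × 10⁷ photons per detector element
at the 140 kVp station's 91 mAs — a conservative figure for ~3 mm² detector
cells, chosen once so that reconstructed noise and reference-pellet SNR sit
in the range the protocol describes ("similar noise levels of both scans",
SNR peaking at 70 keV). The 80 kVp station is scaled by its tube
current–time product, 265/91 × that fluence.

**Projection.** A distance-driven parallel-beam projector: per view, each
voxel's projected top-hat footprint (width `spacing·(|cos θ|+|sin θ|)`) is
overlapped with the detector cells it covers, accumulating per-label path
lengths. The splat is mass-conserving and a partition of unity across the
detector row, so uniform regions project without pitch/voxel moiré and
axis-aligned slabs project exactly; a noiseless flat water box reconstructs
within a few HU of zero. Detected counts follow the spectrally integrated
Beer–Lambert law; Poisson noise is drawn per bin with per-slice seeds
derived from the master seed by fixed offsets, under a private RNG stream so
package randomness never disturbs the caller's.

**Starvation and log step.** `p = −ln(max(counts, floor)/flat)` with a floor
of one count: fully absorbed rays stay finite but wrong, which is exactly
the mechanism that becomes bright streaks after filtering.

**Water precorrection.** A calibration table of polychromatic `p` versus
water thickness (direct spectral integration, 1024 thickness samples to
60 cm) is inverted to map each line integral to `μ_w(E_ref)·L`; `E_ref`
defaults to the spectrum's effective energy, defined as the monochromatic
energy whose water attenuation equals the fluence-weighted polychromatic
value — which makes water reconstruct flat at 0 HU by construction. Line
integrals beyond the water calibration range (every ray through metal) are
extended linearly; that is the intended extended-scale behaviour, not an
error.

**Reconstruction.** Classical filtered back projection with the band-limited
Ram–Lak kernel (Shepp-Logan and cosine windows available), FFT convolution,
linear-interpolation backprojection, on the phantom's in-plane grid. A
noiseless analytic disk reconstructs its interior attenuation to about 0.2%.
The scanner's iterative reconstruction and proprietary kernel are explicitly
out of scope; FBP with a configurable filter stands in. HU conversion uses
the fluence-weighted effective water attenuation and clamps at the
extended-scale floor of −1042 HU.

## VMS synthesis

Per voxel, measured HU pairs are converted back to effective attenuation and
the 2 × 2 system `μ_i = a·μ_i(water) + b·μ_i(HA)` is solved exactly — the
algebraic inverse, no regularization, no smoothing, no noise-balancing blend
(the vendor's "monoenergetic application" internals are unknowable; the
plain two-basis method is the declared stand-in). The virtual monochromatic
image at energy E is then `μ(E) = a·μ_water(E) + b·μ_HA(E)` in HU at that
energy, clamped to the extended scale [−1042, 3071].

One modelling subtlety matters: a reconstructed, water-precorrected image
expresses material contrast under the spectrum *inside* the object, not at
the entrance. `calibrate_basis()` therefore hardens each spectrum through a
representative water depth (default 12 cm, about the mean half-chord of the
335 × 170 mm section) before fluence weighting — the scan-to-scan analogue
of calibrating a decomposition empirically on phantom measurements. Depth 0
recovers the entrance-spectrum convention; monochromatic spectra are
unaffected, which is why the self-consistency oracle (decompose two
noiseless monochromatic scans, synthesize back at an input energy,
reproduce it within 1 HU) holds exactly.

Basis choice: water and the hydroxyapatite pellet material, matching the
phantom's constituents, rather than photoelectric/Compton — configurable.

## Measurement stack

Dark artifacts are voxels in [−1042, −200] HU; bright artifacts are voxels
in [400, 2500] HU *outside* the implant mask (the prosthesis volume is
subtracted so metal itself is not booked as artifact); both intervals are
closed, volumes are voxel counts × voxel volume. The fixed intervals
replace the semiautomatic workflow of the original study; the ground-truth
implant mask from the phantom replaces its unstated prosthesis delineation.
A diagnostic (`background_range()`) reports the central HU quantiles of a
metal-free region of the noisiest station, the rationale from which such
fixed intervals are justified — but the operational thresholds stay fixed.
ROI density uses a 16 mm circle centered on each 20 mm pellet over eight
contiguous slices; "density deviation" is the sample SD (n − 1). SNR is the
reference-pellet mean over its SD. Monochromatic-versus-polychromatic
comparisons (70 keV vs 80 kVp, 140 keV vs 140 kVp) use the classical paired
t on the six per-pellet deviations; p-values are reported raw, flagged at
p < 0.01, with no multiplicity correction — deliberately mirroring the
original analysis.

```{r}
cfg <- experiment_config(seed = 17)
bundle <- run_experiment(cfg, verbose = TRUE)
summary(bundle)
plot(bundle)
write_bundle(bundle, "results", save_volumes = FALSE)
```

## Problem sizes and determinism

The default experiment uses the full-size phantom at 2.1 mm isotropic
voxels (≈ 160 × 81 transverse grid), 180 angles over 180°, 256 detectors
covering the grid diagonal, and reconstructs the ≈ 190 mm axial slab that
contains the stem and every pellet — about 90 slices per scan, two scans
plus seven synthesized energies per alloy, roughly three minutes per alloy
on one core. The unit-test suite exercises the same geometry down-scaled
(a 200 × 170 × 60 mm box with a shorter stem) so every geometric feature
survives. End-to-end determinism is part of the contract: the experiment
bundle's manifest carries an MD5 of the configuration, every stochastic
stage derives its seed from the master seed by fixed offsets, and the CSV
serialization pins floating-point formatting, so a fixed config and seed
reproduce every byte.

## What the simulator does and does not emulate

It emulates: energy-dependent attenuation of the real alloy/pellet
chemistry; spectral beam hardening and its first-order (water)
precorrection; photon starvation behind metal with tube-current-scaled
Poisson noise; scan-to-scan DECT with image-domain monochromatic synthesis;
and the full measurement protocol. It does not emulate: helical/cone-beam
geometry, scatter, detector afterglow, iterative reconstruction, vendor
monochromatic blending, or commercial metal-artifact-reduction algorithms.
Consequences worth knowing before comparing with scanner data:

* **The VMS artifact-volume curve is V-shaped, not hyperbolic.** The
  synthesis is an affine recombination of the two polychromatic images; near
  70 keV the weight on the artifact-heavy 80 kVp image passes through zero,
  so artifacts nearly cancel, and extrapolating beyond the high station
  re-amplifies both inputs' residuals. On real scanners the 140 kVp image is
  itself heavily corrupted and vendor blending suppresses the extrapolation
  tail, so published curves decline monotonically. The low-energy side
  (40 → 70 keV) and the alloy ordering reproduce as published.
* **High-keV pellet density keeps declining.** A 200 mg/cm³ HA insert
  retains a calcium photoelectric component at 100 keV; its monochromatic
  HU genuinely falls another ~25% from 100 to 190 keV before flattening
  toward the electron-density limit. Reports of a stable plateau above
  100 keV reflect vendor VMS behaviour rather than the underlying
  attenuation curve.
* **Chrome-cobalt sits at the starvation knife-edge.** At desk scale its
  proximal cross-section fully starves the 80 kVp beam, so bright streaks
  can offset the dark halo right at the proximal pellets, where the steel
  phantom shows the published dark-dominated zone pattern.
* Low-keV VMS noise amplification is expected and intentional — no
  noise-balancing is applied across energies.

## Numerical choices

Log–log interpolation with exact grid passthrough; spectra binned at 24
energies from 30 keV to the kVp; the starvation floor at 1 count; the FBP
pad length at the next power of two ≥ twice the detector count; the
precorrection table at 1024 thicknesses with linear extension beyond; ties
in voxelization broken by half-open axial intervals; the HU floor −1042
matching the lower dark-artifact bound and the VMS ceiling 3071 keeping the
bright interval meaningful; degenerate inputs rejected early (zero-variance
paired tests, empty ROIs, rank-deficient calibrations, sub-90-angle FBP).

## Known limitations

Parallel-beam 2-D slices instead of helical cone-beam; no scatter, so
bright-artifact volumes run lower than scanner data; ideal flat fields and
an ideal water precorrection; alloy compositions are nominal rather than
vendor-certified; the desk-scale grid (≥ 2 mm voxels against the scanner's
sub-millimeter reconstruction) quantizes the 5 mm pellet gap to two to
three voxels. All of these trade fidelity for a fully inspectable,
reproducible pipeline at interactive cost.
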