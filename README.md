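# dectlab

Desk-scale simulation and quantification of metal artifacts around
orthopaedic hip-stem alloys in dual-energy CT (DECT) virtual monochromatic
spectral (VMS) imaging.

Metallic femoral stems corrupt CT images through beam hardening (dark
streaks: the polychromatic beam loses its soft photons inside high-Z metal)
and photon starvation (bright streaks: almost no photons survive the metal,
so log-normalized projections are clipped and noisy). DECT acquires the same
object at two tube voltages (80 and 140 kVp, scan-to-scan) and synthesizes
virtual monochromatic images at a chosen energy E; at high keV the
hardening contrast largely vanishes, and how much artifact remains depends
strongly on the alloy. `dectlab` is for medical-physics and image-analysis
work that needs that whole chain as inspectable, reproducible code: phantom
in, artifact volumes and ROI statistics out.

## What is inside

* **materials** — elemental mass attenuation tables (30–200 keV, plain
  text), the weight-fraction mixture rule
  (μ/ρ)ₘᵢₓ(E) = Σᵢ wᵢ (μ/ρ)ᵢ(E), LAC curves μ(E) = ρ·(μ/ρ)(E) for
  Ti-6Al-7Nb, CoCrMo, CrNi steel, a 200 mg/cm³ hydroxyapatite pellet and
  water.
* **phantom** — a voxelized 400 × 335 × 170 mm gel box with a cone-tapered
  stem along the scan axis and six 30 × 20 mm pellets: five at a 5 mm
  surface gap in Gruen zones 2–6, one remote reference near a box corner.
* **scanner** — filtered-Kramers spectra, a distance-driven parallel-beam
  projector with spectral Beer–Lambert detection
  N = N₀ Σ_E S(E) exp(−Σ μ(E)·L), Poisson noise with mAs scaling
  (265/91 between the stations), a photon-starvation floor, water
  precorrection, filtered back projection, extended-scale HU conversion.
* **vms** — image-domain two-material decomposition (water/HA basis,
  exact 2 × 2 inverse) and monochromatic synthesis at
  40/50/70/100/120/140/190 keV.
* **quantify** — artifact volumetry (dark [−1042, −200] HU; bright
  [400, 2500] HU with the prosthesis subtracted), pellet ROI mean/SD over
  the 8-slice 16 mm-circle protocol, SNR, paired t tests, reduction and
  fold ratios.
* **pipeline** — the full three-alloy experiment with fixed-seed
  determinism, CSV/JSON outputs, and a thin CLI
  (`inst/cli/dectlab.R run|lac|quantify`).

## Worked example

```r
library(dectlab)

cfg    <- experiment_config(seed = 17)   # full phantom, 3 alloys, ~9 min
bundle <- run_experiment(cfg)
summary(bundle)
```

```
titanium_alloy: dark 34.3 -> 2.3 cm^3 (40 -> 190 keV, reduction 93.3%)
chrome_cobalt: dark 1173.9 -> 250.7 cm^3 (40 -> 190 keV, reduction 78.6%)
stainless_steel: dark 893.0 -> 190.3 cm^3 (40 -> 190 keV, reduction 78.7%)
```

Those three lines are the headline physics: every alloy's dark-artifact
volume collapses as the monochromatic energy rises, and titanium — the
alloy with the lowest linear attenuation — ends more than an order of
magnitude cleaner than chrome-cobalt or steel. The bundle also carries the
per-pellet ROI table (`bundle$roi`), where the proximal-zone pellets 2/6
next to the thick stem section read lower HU than distal 3/5 for steel,
and the reference pellet's density falls from ≈ 587 HU at 40 keV to
≈ 134 HU at 100 keV; the SNR table (`bundle$snr_table`), peaking at 70 keV
(e.g. 11.9 for the titanium experiment); and the paired
monochromatic-versus-polychromatic statistics (`bundle$stats`), where
70 keV beats 80 kVp on density deviation for all three alloys
(titanium p ≈ 0.009).

Smaller building blocks work standalone:

```r
m <- default_materials()
lac_curve(m$titanium_alloy, c(40, 70, 100, 190))
#   energy_kev   lac_cm1
# 1         40 12.610
# 2         70  2.999      # steel: 6.85, chrome-cobalt: 7.88 at 70 keV
# 3        100  1.423
# 4        190  0.658

ph  <- build_phantom(phantom_config(spacing_mm = 2.1, stem_material = "stainless_steel"))
ct  <- simulate_scan(crop_slices(ph, central_slices(ph, 8)),
                     m, kvp = 80, seed = 1)
rep <- segment_artifacts(ct, implant_mask(crop_slices(ph, central_slices(ph, 8))))
```

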