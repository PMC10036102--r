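---
title: "Methods: Monte Carlo scatter dosimetry for perforated shields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo scatter dosimetry for perforated shields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fluoroshield)
```

## The problem

During fluoroscopy-guided structural-heart procedures (TAVR, TEER) the
anesthesiologist stands at the patient's head and is irradiated almost
entirely by Compton-scattered photons from the patient, table and floor. A
freestanding protective board at the head side blocks that scatter but also
blocks access to the airway; a *perforated* board with work apertures on the
echocardiographer's and anesthesiologist's sides trades a little shielding
for workability. `fluoroshield` simulates that trade-off: it transports
diagnostic-energy photons through a voxelized operating room containing an
undertable x-ray source, a supine patient phantom, a standing staff phantom
and the shield in four configurations (no shield, large apertures, small
apertures, solid panel), and reports body-surface dose rates and air
dose-rate maps at operator-relevant heights.

## Transport model

The engine is a photon-only Monte Carlo with the standard simplifications
used for fast dose estimation in the diagnostic range (5-150 keV):

* **Kerma approximation.** Electron transport is suppressed: all energy
  transferred to electrons deposits in the interaction voxel. At these
  energies secondary-electron ranges are at most a few millimetres in tissue,
  below or near the voxel sizes used. No fluorescence photons are emitted;
  the K edge of lead (88 keV) lies above the 80 kVp endpoint of the study
  beam, and the L fluorescence (10-15 keV) is absorbed within a fraction of a
  millimetre of lead, so the approximation mainly smooths sub-voxel detail.
* **Free-electron Klein-Nishina Compton scattering**, sampled with Kahn's
  composition-rejection method; the electron binding (incoherent scattering
  function) and Doppler broadening are neglected. **Thomson angular law**
  (no form factors) for coherent scattering. Both simplifications change the
  scatter-field shape by at most a few percent here and keep every sampler
  verifiable against closed forms.
* **5 keV cut-off**: photons falling below it deposit locally and terminate.
* **Woodcock (delta) tracking** so that no per-voxel boundary crossings are
  needed on multimillion-voxel grids. A single global majorant would be
  hopeless in these scenes: 1 mm of lead implies a majorant free path of a
  fraction of a millimetre, and photons crossing metres of air would undergo
  tens of thousands of virtual collisions. The engine therefore partitions
  the grid into macro cells (8^3 voxels by default), records which materials
  occur in each cell, and uses the per-cell majorant evaluated exactly at the
  flight energy. In air-only cells the majorant is the air attenuation and
  flights jump cell to cell; delta tracking with a local majorant is
  statistically identical to the global-majorant scheme.
* **Dual estimators.** Energy deposition is scored analog per fine voxel
  (body dose); simultaneously every flight segment contributes a track-length
  collision-kerma estimate `w E (mu_en/rho)_air l` to a coarse co-registered
  air grid (5 cm default). The track-length estimator has orders of magnitude
  lower variance in air, where analog collisions are rare.
* **Reproducibility.** Batch `b` of a run draws from an independent
  `mt19937_64` stream seeded by `splitmix64(seed, b)`; results depend only on
  the seed and configuration. Histories are capped at 10^4 interactions
  (and a generous internal step guard); a capped or non-finite history is
  dropped and counted as corrupted, and its residual energy is tracked so the
  per-batch ledger `emitted = deposited + escaped + corrupted` closes to
  1e-6 relative.

## Cross sections

Attenuation data are packaged as plain-text tables (`inst/extdata/xs/`), one
per element and one per registry material, on a log grid over 5-150 keV with
explicit rows at the absorption edges in range (Pb L1/L2/L3 and K, Cu K,
Fe K). The construction mirrors the engine's physics so that tables and
samplers are mutually consistent: the incoherent partial *is* the
free-electron Klein-Nishina cross section; the coherent partial is Thomson
scattering with Thomas-Fermi-Moliere form factors; the photoelectric partial
is anchored so that the total matches published reference compilations for
the materials that matter most (water, air, aluminum, copper, lead, bone),
with minor elements interpolated in log Z. `mu_en` is computed as
photoelectric plus incoherent times the mean Klein-Nishina energy-transfer
fraction, again with no fluorescence escape - i.e. it is the energy-absorption
coefficient *of this engine's physics*, a few percent from reference values
for air. Partial-sum consistency is exact by construction; totals for the
anchored materials reproduce the references to well within the 2% the tests
demand. Lookup is log-log interpolation, exact at grid nodes.

## Source model

The tube spectrum is Kramers bremsstrahlung `N(E) ~ (kVp - E)/E` filtered by
the inherent aluminum (1.0 mm default, 12 degree anode recorded as metadata),
with tungsten K lines added above the 69.5 keV K edge at a small
semi-empirical fraction. The clinical beam is 80 kVp with added
2.5 mmAl + 0.4 mmCu + 1.0 mmAl. Beam-quality checks are done on two beams
for a reason: the *mean energy* band (40-55 keV) is checked on the fully
filtered clinical beam, while the *aluminum HVL* plausibility band
(2.5-4.5 mm) is checked on the aluminum-filtered beam without the copper -
copper hardening pushes the HVL of the full stack to roughly 7 mm Al, which
is expected physics, not a spectral-model defect.

`photons_per_mAs` is set from a nominal tube output (30 uGy air kerma per
mAs at 1 m into the collimated field). This constant is deliberately not a
physics claim: absolute dose rates are anchored by the measured-versus-
simulated scaling factor (below), and all shielding conclusions are ratios.

## Scene model

* Room: 8.1 x 7.3 x 3.4 m interior with 20 cm ordinary-concrete walls, floor
  and ceiling; z = 0 at the floor, patient along +x, head towards the shield.
* Source: point focal spot under the table, SSD 60 cm, SID 100 cm, ideal
  rectangular collimation to a 156.5 mm square field *at the receptor* (the
  field-definition plane is not otherwise constrained; the receptor at SID
  is assumed). Projections: PA (axis +z), Cusp-overlap (RAO 9, CAU 1),
  Perpendicular (LAO 16, CRA 13); RAO/LAO rotates about the patient's
  longitudinal axis, CRA/CAU about the lateral axis, in that order.
* Phantoms are stylized stacked elliptical-cylinder bodies (legs, trunk,
  neck, head) of water with a one-voxel skin shell, a bone core and eye-lens
  patches, standing in for licensed reference voxel phantoms. The staff
  phantom is 160.8 cm tall at 45 degrees to the patient axis; ROI height
  bands (lens 145-150, neck/thyroid 130-135, chest 110-130, waist/ovary
  80-85 cm) scale linearly with height, and "surface dose" means the
  mass-weighted mean over skin-shell voxels on the source-facing side.
  What passing tests show is therefore about scatter fields and shielding
  geometry, not about organ-level anatomical dosimetry.
* Sub-voxel slabs are homogenized: a 1 mm lead panel or 2 cm tabletop inside
  a 5 cm voxel layer is assigned its material with density scaled so the
  areal density (hence transmission along any chord) is preserved.
* Shield: 1.0 m wide, 1.8 m tall panel, lower edge on the floor, 30 cm
  beyond the patient's head plane. Aperture bands from the floor: large -
  echo side 100-140 cm, anesthetic side 90-130 cm; small - 105-125 cm and
  95-115 cm; widths 35 cm (large) and 25 cm (small) per side, centred on
  each worker's station. Width, placement and aperture geometry are
  configurable; the defaults are declared choices where no published value
  exists (the panel is "about 10 cm wider than commercial boards", whose
  width is unstated).
* The staff phantom stands 95 cm beyond the head plane, 65 cm behind the
  shield - far enough that the panel column and the phantom never share a
  voxel; overlaps elsewhere resolve by the fixed priority
  shield > staff > patient > table > walls > air.

## Calibration: the factor of scaling on dose conversion

The simulator produces relative dose (per photon, per-mAs normalization).
Absolute dose rates use a zero-intercept regression of measured against
simulated doses over a 12-condition design - SSD 60/65/70 cm crossed with
depth 0/5/10/15 cm in a water phantom (the published description fixes the
count and the ranges; the 3 x 4 grid is this package's declared choice).
`fit_zero_intercept()` uses the closed form `slope = sum(xy)/sum(x^2)`;
`r_squared` is reported as the square of Pearson's correlation, which is how
the source measurements were summarized (the through-origin R^2 variant is
also returned). No physical dosimeter data ship with the package: the
synthetic generator `make_noisy_calibration()` produces
`measured = slope * simulated * (1 + eps)` with `eps ~ N(0, cv^2)`, cv 5% by
default, and the clinical default scaling factor is the published 1.10. The
dosimeter's energy response is not modelled.

The default dose-rate conversion treats the listed tube current (3.0 mA) as
time-averaged, so mAs/h = 3.0 x 3600; the pulse rate (3.75 fps) is carried
as metadata only, since no pulse width is available to do better. Both are
configurable in `dose_conversion()`.

## Synthetic data and problem sizes

The fixtures module generates every input the analyses need: analytic slab
and point-source scenes for the Beer-Lambert, inverse-square and estimator
oracles; noisy calibration datasets; and scaled operating-room scenes.
`make_scaled_or_scene(scale)` shrinks the room laterally while keeping SSD,
SID, field size, shield placement, stance and ROI heights at full scale, so
shielding ratios stay comparable while the air volume (and voxel count)
drops. The study configuration used throughout the tests and the
reproduction script is scale 0.5 at 5 cm voxels (about 550k voxels) with
1-6 x 10^6 histories per scene and 10 batches - sizes chosen so a full
four-pattern comparison runs in minutes on a single core while leaving the
ordering and shadow contrasts many standard errors wide. Closer walls in the
scaled room return somewhat more backscatter than the full room, which makes
shielded-to-unshielded ratios conservative (slightly high). A full-scale,
2 mm, 10^12-history run is a configuration change, not a code change.

## Numerical choices

* Engine energy grid: 0.25 keV uniform over 5-150 keV, linear interpolation
  (tables themselves are log-log interpolated onto it); spectra use 1 keV
  bins, inverse-CDF sampled, uniform within a bin.
* Voxels are half-open boxes `[o + i s, o + (i+1) s)`; material is decided at
  the voxel centre; a 5 cm grid from the floor puts the 145-150 cm band in
  exactly one layer.
* HVL is found by bracketed root search on the air-kerma-weighted
  transmission to 0.01 mm; an absorber that cannot halve the beam within
  100 mm raises a diagnostic error rather than extrapolating.
* ROI uncertainties are standard errors over 10 independent batches;
  ratio uncertainties use first-order propagation (cross-checked against a
  batch bootstrap in the tests).
* Degenerate inputs fail loudly: all-zero simulated doses in the fit, empty
  ROI masks, zero-mass voxels, out-of-range energies, apertures outside the
  panel, angulations beyond 45 degrees.

## Known limitations

Stylized phantoms without internal organs or articulated posture; no C-arm
hardware, monitors or second staff member; free-electron scattering physics;
no personal protective equipment or operational quantities (Hp(10), Hp(3));
absolute output anchored by one scaling constant rather than tube physics;
air maps score collision kerma, which at these energies is numerically close
to absorbed dose in air but not identical inside solid objects.
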