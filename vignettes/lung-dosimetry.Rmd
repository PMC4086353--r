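---
title: "Personalized lung dosimetry for Y-90 radioembolization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized lung dosimetry for Y-90 radioembolization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y90lung)
```

# The dosimetric model

Yttrium-90 is a pure beta emitter whose energy is deposited locally, so the
mean absorbed dose to an organ containing a known activity is simply the
emitted energy divided by the organ mass. For ⁹⁰Y distributed uniformly,
1 GBq through 1 kg of tissue delivers 49.67 Gy, giving the MIRD lung mean
dose

$$D_\mathrm{mean} = \frac{49.67 \times \mathrm{LSF} \times A\,[\mathrm{GBq}]}{m_\mathrm{lung}\,[\mathrm{kg}]},$$

where the lung shunt fraction (LSF) is the fraction of injected particles
reaching the lung,

$$\mathrm{LSF} = \frac{\text{total lung counts}}{\text{total lung counts} + \text{total counts in all target hepatic arterial territories}},$$

measured on ⁹⁹ᵐTc MAA imaging before treatment. A single treatment is
planned to keep $D_\mathrm{mean} \le 25$ Gy (`lung_mean_dose()` uses an
inclusive boundary: exactly 25 Gy passes, a convention this package fixes
explicitly because the limit is usually quoted without boundary semantics).
`max_activity_for_limit()` inverts the formula for planning; it refuses
`LSF = 0` rather than returning an infinite activity.

Two of the three quantities in the formula are where methods diverge:

* **Planar methodology**: LSF from anterior/posterior planar scintigraphy
  and an assumed standard lung mass of 1,000 g.
* **SPECT/CT methodology**: LSF from quantitative SPECT/CT and a
  patient-specific lung parenchyma mass from CT densitovolumetry of the
  SPECT/CT's own CT.
* **Reference combination**: SPECT/CT LSF with the mass from diagnostic
  breath-hold CT — the best available stand-in for truth, since no gold
  standard for the in-vivo lung mass exists.

`methodology_comparison()` evaluates all three pairings on one treatment.

# Lung mass by CT densitovolumetry

Within the lung range, CT numbers are approximately linear in physical
density, anchored at air (−1000 HU, 0 g/cm³) and water (0 HU, 1 g/cm³):

$$\rho\,[\mathrm{g/cm^3}] = \frac{\mathrm{CT\ number} + 1000}{1000}.$$

The linearity is validated for CT numbers ≤ 0 HU; `hu_to_density()` accepts
positive values (lung ROIs deliberately include dependent atelectasis and
vessels, and a water phantom can legitimately read a few HU above zero) but
warns. The mass convention is **mean-then-convert**: the conversion is
applied to the ROI's *mean* CT number and multiplied by the ROI volume.
Because the conversion is affine this is algebraically identical to summing
per-voxel masses; `region_densitovolumetry()` reports the per-voxel sum as
`mass_voxelwise_g` so the identity can be audited on any dataset.
`water_phantom_qa()` closes the QA loop by expressing a measured water VOI
as a signed percent density error against 1 g/cm³.

## Segmentation conventions

`segment_lungs()` reproduces a slice-wise threshold region-growing
workflow. The lower threshold is fixed at −1000 HU; the upper threshold
defaults to −400 HU within the clinically used range [−600, −150]. The
interactive step of visually tuning the upper threshold per slice cannot be
reproduced faithfully in batch code; an optional per-slice search
(`upper_search = TRUE`) picks from {−600, −500, −400, −300, −150} the value
maximising in-band area after discarding components that touch the image
border, as a documented stand-in for operator judgement, not a
reconstruction of it.

Other conventions, all of which were genuinely open design choices:

* **Seeds**: automatic — the two largest in-band 3-D components with
  centroids on opposite sides of the body midline become the lungs; a
  single component spanning the midline (anterior junction merge) is split
  at the midline plane; anything else is an error with diagnostics. Manual
  seed arrays are accepted.
* **Trachea / proximal bronchi**: the in-band components intersecting the
  most superior in-band slice within a 25 mm half-width midline corridor
  are removed (this also removes air outside the body). Hilar vessels are
  soft-tissue density and are excluded by the threshold itself. This rule
  assumes the central airway is not threshold-connected to the lungs at the
  acquired resolution; at sub-millimetre resolutions a real bronchial tree
  would connect, and the rule would need an airway-aware replacement.
* **Pleural sliver**: for free-breathing SPECT/CT, margins are dilated
  in-plane by at most 1 mm (`segmentation_preset("spectct")`), mirroring
  the empirical observation that slightly generous SPECT/CT margins
  reproduce breath-hold masses. Dilation never crosses into the other lung;
  the known tendency to over-include the left mediastinal border has no
  principled correction, so the cap is the only guard.
* **Dependent atelectasis** is soft-tissue density and cannot be captured
  by any air-side threshold; it is merged from an explicit flagged mask
  (operator- or phantom-supplied), matching the manual inclusion practice.
* **Coordinates**: axial slices along z, z increasing toward the head;
  physical position of 1-based voxel `k` is `origin + (k−1)·spacing`
  (voxel-center).

Per-lung volumes follow the stacked-ROI convention, slice area × slice
thickness. An alternative `"interpolate"` mode integrates a
piecewise-linear area profile with half-slice tapered end caps (a surrogate
for contour interpolation at partial-volume apex/base slices); on smooth
convex regions the two agree within ~2%, and the default is the plain sum.

# Lung shunt fraction

## Planar

`planar_lsf_from_images()` applies, per view, background correction by
count-density subtraction (background ROI counts per pixel, scaled to the
target ROI area — the simplest published style of planar background
correction; the exact historical ROI geometry is not reproducible, so a
user-supplied rectangle lateral to the liver is the documented choice),
then the geometric mean $\sqrt{\Sigma A \cdot \Sigma P}$ across views, then
the lung fraction. No attenuation or scatter correction, by construction —
that *is* the conventional method. Negative corrected counts clamp to zero
with a warning. Lung ROIs exclude a 25 mm midline corridor (mediastinum).

## SPECT/CT

Free-breathing SPECT mis-registers liver-dome activity into the lung
bases. The quantification therefore:

1. locates each diaphragm apex (`find_diaphragm_apex()`): per in-plane
   column, the inferior-most lung voxel; the apex is the most superior such
   base over the **central two-thirds of the lung footprint** (elliptical
   fraction about the footprint centroid). Restricting to the core keeps
   costophrenic recesses from dragging the estimate down and keeps columns
   grazing the anterior/posterior lung rim — whose inferior boundary is
   chest wall, not diaphragm — from pushing it up. On phantoms whose dome
   barely indents the lung base the estimate can still land on the rim and
   read high by up to ~10 mm; an explicit `apex_z` override always wins,
   and a high apex only enlarges the excluded zone (conservative for
   mis-registration);
2. excludes all lung counts at or below a cut-off 1.5 cm above each apex
   (`apply_exclusion_zone()`; the 1.5 cm default reflects the measured
   cranio-caudal diaphragm excursion of ~2.7 ± 1 cm during free breathing —
   there is no per-patient adaptation rule, so the margin is a parameter).
   "Above" means voxel-center z strictly greater than the cut-off, an
   unambiguous half-open convention; cut-offs may differ per side;
3. estimates the blood-pool/soft-tissue background count density
   (counts/cm³) in a cylindrical VOI along the left erector spinae
   (`background_voi_cylinder()`, validated to lie in soft tissue,
   CT ∈ [−100, 200] HU);
4. subtracts lung background as density × lung *tissue* volume, where
   tissue volume = parenchyma mass above the zone / 1.04 g/cm³ — aerated
   lung is mostly air by volume, so its blood-pool background scales with
   its tissue content, not its CT volume. The mass above the zone comes
   from densitovolumetry of the co-registered SPECT/CT CT restricted to the
   retained mask (the only CT aligned with the counts; whether the original
   workflow used this or the diagnostic CT is not stated, so this choice is
   documented rather than asserted);
5. divides by the CT lung volume above the zone to get the
   background-corrected lung mean count density, assumed representative of
   the whole lung, and multiplies by the total CT lung volume
   (`corrected_lung_counts()`). For spatially uniform lung activity this
   extrapolation equals the direct whole-lung sum exactly; for
   basally-weighted mis-registered activity it is smaller — which is the
   intended effect;
6. forms the LSF against the supplied territory counts (`spectct_lsf()`).
   Deriving the background-corrected hepatic territory counts belongs to
   the liver dosimetry workflow and is accepted here as an input.

`spect_lsf_pipeline()` runs the chain and returns every intermediate for
audit. `margin_mm = NULL` disables the exclusion zone (naive whole-lung
quantification) for comparison studies.

# Agreement statistics

`bland_altman()` takes differences first-minus-second, bias = mean
difference, 95% limits of agreement = bias ± 1.96 × sample SD (n − 1).
`summarize_cohort()` uses the normal-theory CI `mean ± 1.96·sd/√n`: with
the 1.96 multiplier the published cohort tables this package is validated
against are reproduced from their printed means and SDs to printed
precision on most rows (mass, dose, planar-LSF rows exactly; a few rows
differ by one unit in the last printed digit because the source computed
from unrounded moments), whereas the t-quantile (2.045 at n = 30) does
not reproduce them. No multiple-testing correction is applied anywhere,
matching the validated workflow. `paired_t_test()` wraps `stats::t.test()`
and pins the degenerate cases: all-zero differences give t = 0, p = 1;
zero variance with non-zero mean is flagged with p = 0.

# The digital thorax phantom

No public dataset pairs CT, SPECT and ground-truth shunt fractions, so
`generate_phantom()` builds one analytically: elliptical-cylinder body
(40 HU), two ellipsoidal lungs, spherical-cap diaphragm domes whose apex
heights are known in closed form, a dome-topped liver under the right lung,
a midline trachea (−1000 HU), an erector-spinae background VOI, and
optional basal dependent atelectasis (soft tissue, labelled separately).
Voxelisation is by center-inclusion, so the manifest ground truth (masses,
volumes, per-region counts) is obtained by direct summation over the same
voxel field every estimator sees.

Default study conditions mirror the validated cohort: lung CT number
−784 HU (density 0.216 g/cm³) and ~4 L total lung volume at inspiratory
breath-hold; the free-breathing preset scales lung volume down ~30%
(matching the observed 3,967 → 2,749 cm³ shift), raises the lung CT number
to −701 HU (0.299 g/cm³), adds 3% basal atelectasis, and turns on 15 mm
mis-registration. The default true LSF is 0.0596 and the injected-activity
example is 1.65 GBq — the cohort means. Primary counts (3 × 10⁶ total,
a realistic MAA SPECT magnitude) are split `true_lsf` : `1 − true_lsf`
between lungs and liver, uniformly within each compartment.

Two generator choices matter for interpretation:

* **Background is laid down per unit tissue volume**: each voxel receives
  `bg_density × voxel_volume × ρ(HU)/1.04` counts. This is exactly the
  model behind the mass/1.04 background correction, so on phantoms the
  correction is unbiased *by construction*. Passing tests therefore show
  the chain is implemented correctly, not that the tissue-volume model is
  right for real pertechnetate biodistributions.
* **Mis-registration relocates counts** from the top 15 mm of the liver
  into lung voxels within 15 mm above the diaphragm apices, leaving the
  manifest's true LSF untouched — it is an imaging artifact, not a real
  shunt. The exclusion zone must therefore reduce the error of the naive
  whole-lung estimate, and the suite asserts exactly that, as a direction,
  not a magnitude.

`project_planar()` produces the anterior/posterior pair by summation along
the antero-posterior axis, optionally with exponential attenuation whose
per-voxel coefficient scales with density (`μ = μ_water × ρ`, with
μ_water ≈ 0.0153 mm⁻¹ at the 140 keV of ⁹⁹ᵐTc). A single
density-scaled μ is enough to reproduce the *sign* of the planar-vs-SPECT/CT
LSF bias (liver counts are attenuated more than lung counts, so planar
overestimates the LSF); it does not model scatter, collimation or detector
response, so the magnitude of that bias is not meaningful and is never
asserted.

What the phantom deliberately does not emulate: anthropomorphic anatomy,
scanner point-spread and collimator effects, scatter, reconstruction
artifacts, respiratory motion blur (mis-registration is modelled as a
static count shift), and heterogeneous lung density. Recovery results on
phantoms bound algorithmic correctness, not clinical accuracy.

# Numerical choices and problem sizes

* Region growing and connected components use a vectorised frontier flood
  fill (in-plane 4- or 8-connectivity, optional inter-slice adjacency);
  tests compare it against an independently written queue-based BFS.
* Ties and degenerate inputs are errors, not guesses: empty masks, grid
  mismatches, seeds outside the threshold band (named in the message),
  exclusion zones that would swallow an entire lung, a background VOI
  outside soft tissue.
* Negative background-corrected counts clamp to zero with a warning, in
  both planar and SPECT/CT paths; over-subtraction has no defined
  semantics in the source workflow.
* The test suite exercises the default anatomy at 8 mm voxels
  (48 × 48 × 42), where a full segmentation runs in ~2 s and the
  end-to-end noiseless pipeline recovers mass and LSF to better than 1%
  relative; the 4 mm native grid (96 × 96 × 84) is used once to check
  resolution stability of the voxelised mass. Twenty seeded Poisson
  replicates bound estimator bias at two standard errors.

# Known limitations

* The operator-in-the-loop steps (per-slice threshold adjustment, manual
  ROI refinement, visual apex placement) are replaced by fixed, documented
  heuristics; on real data the package's automatic segmentation should be
  reviewed, and every automatic estimate accepts an explicit override.
* The Cheng-style linearity of CT number vs density is assumed transferable
  across scanners; no lung-density phantom calibration is applied because
  none is derivable from the validated workflow.
* Hepatic territory counts are an input, not a computation — the liver
  partition-model workflow is out of scope.
* SPECT voxel dosimetry and dose-volume histograms are out of scope; only
  the mean lung dose is computed.
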