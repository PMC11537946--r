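---
title: "Characterizing paired OCTA projection maps: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing paired OCTA projection maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(octamorph)
```

## The problem

OCT angiography (OCTA) renders retinal blood flow as en-face projection
maps. When a second arm of images exists for the same eyes — a
GAN-translated reconstruction, a different device, a re-scan — the
scientific question is whether the comparison arm (here called TR)
preserves the vascular biomarkers measured on the reference arm (GT).
`octamorph` implements that characterization: four vascular morphometry
features per image, three image-quality metrics per pair or cohort, and
the cohort-level statistics that compare arms per patient group and
field of view (FoV).

Because clinical OCTA cohorts cannot ship with a package, `octamorph`
also includes a seeded synthetic generator of paired OCTA-like maps.
Every claim the test suite makes is made on synthetic instances whose
ground truth is known by construction.

## Morphometry model

All features are computed from a binarized vessel mask and pixel-based
units; for a mask $M$ with vessel area $A$ (pixels), skeleton length
$L$ (pixels), and boundary contour length $P$ (pixels):

* **BVD** (blood vessel density) $= A / \text{total area}$, in $[0,1]$.
* **BVC** (blood vessel caliber) $= A / L$, pixels — an average-width
  proxy.
* **BVT** (blood vessel tortuosity) $= \frac{1}{n}\sum_{b=1}^{n}
  \frac{\text{geodesic}_b}{\text{euclidean}_b}$ over the $n$ retained
  centerline branches; 1 means perfectly straight.
* **VPI** (vessel perimeter index) $= P / A$, 1/pixels.

The pipeline behind them is: binarization (global Otsu by default,
method and threshold recorded), Zhang–Suen thinning to a 1-px
8-connected centerline, branch decomposition at junction pixels, and
sub-pixel 0.5-level contour extraction for the perimeter.

### Numerical choices that matter

**Junction detection.** A junction is a skeleton pixel whose circular
*crossing number* (number of background-to-foreground transitions
around its 8-neighbour ring) is at least 3. The naive neighbour count
misclassifies L-corners of thinned staircases as junctions and shatters
smooth curves into fragments; the crossing number does not. Junction
pixels are clustered (8-connected) into junction nodes, so a plus-shaped
crossing reports one junction and four branches. A diagonal step
between two non-junction pixels that both touch the same junction pixel
is treated as a corner cut and blocked, so arms meeting at a junction
do not short-circuit around it.

**Branch geodesic length.** Raw 8-connected chain length (1 per axial
step, $\sqrt2$ per diagonal) overestimates the arc length of smooth
digitized curves by about 5–8% depending on orientation, which would
bias BVT far beyond its rasterization tolerance. The package therefore
measures geodesic length on the corner-cut resampled path (every 5th
pixel plus the endpoint, Euclidean segment sums); the raw chain length
is retained per branch as `chain_len_px` for audit. On a rasterized
quarter circle of radius 80 px this reproduces the analytic
arc-to-chord ratio $\pi/(2\sqrt2) \approx 1.1107$ to within 0.002.

**Free-end extension.** Thinning retracts the centerline by roughly
half the vessel width at every free end. Branch ends that terminate in
an endpoint (not a junction) are extended along the local tangent by
the mask's Euclidean distance-transform value at the tip. Without this,
BVC of a 5-px-wide, 100-px-long bar measures ~5.3; with it, 5.0.

**Perimeter.** The boundary is the 0.5-level iso-contour of the mask
(marching squares), holes included, with the same corner-cut
resampling: the raw contour polygon overestimates a digitized disc's
perimeter by ~6%, the resampled one is within 0.5%.

**Degenerate inputs** never abort a cohort run: a blank image gives
BVD 0 and `NaN` sentinels (with warnings) for BVC/BVT/VPI; closed loops
and branches whose endpoint chord is shorter than `bvt_eps` (default
1 px) are excluded from the BVT mean and counted in
`n_loops_excluded`; spur branches shorter than `min_branch_len`
(default 3 px) are pruned and counted.

**Units.** Features are reported exactly as the definitions above in
pixel-based units (BVD is a fraction in $[0,1]$). Published tables in
this literature sometimes print density and perimeter-index values on
other, unstated scales; `run_config(report_scale = ...)` exposes an
explicit per-feature multiplier for such conventions but defaults to 1
everywhere, and no attempt is made to guess anyone else's units.

## Quality metrics

**SSIM** uses the canonical constants: 11-px Gaussian window
($\sigma = 1.5$), $k_1 = 0.01$, $k_2 = 0.03$, dynamic range 1 for
$[0,1]$ maps, valid-region filtering. It matches scikit-image's
implementation to $10^{-9}$ on a fixture.

**PCQI** scores each 11-px patch (stride 4) as the product of a
contrast-change term $\frac{4}{\pi}\arctan\frac{\sigma_{ab}+c}
{\sigma_a^2+c}$, a patch-similarity term
$\frac{\sigma_{ab}+c}{\sigma_a \sigma_b + c}$, and a mean-luminance
term $e^{-|\mu_a-\mu_b|/L}$, averaged over patches; identical inputs
score exactly 1, and the per-term means are returned for audit.

**Fréchet distance** between arms fits a Gaussian to embedded image
sets: $\|\mu_A-\mu_B\|^2 + \mathrm{Tr}(\Sigma_A+\Sigma_B -
2(\Sigma_A\Sigma_B)^{1/2})$, covariances ridged by $10^{-6}I$, the
matrix square root via the symmetric factorization
$\sqrt{\Sigma_A}\,\Sigma_B\sqrt{\Sigma_A}$. The conventional embedding
for this distance is a pretrained Inception network; a deterministic
19-dimensional image descriptor (intensity quantiles, mean/SD,
gradient-magnitude statistics, six radially averaged log-power bins) is
the default extractor so the distance is computable with no downloaded
weights and bit-reproducibly. Absolute values are therefore not
comparable to published Inception-based FID scores; orderings under
increasing degradation are, and that is what the tests assert.

## The synthetic cohort generator

`generate_network()` grows each vessel as a stochastic branching random
walk: unit-pixel steps, per-step heading perturbation
$\mathcal N(0, \texttt{tortuosity\_amp}^2)$, bifurcation with
probability `branch_prob` per step (child headings split symmetrically,
radii scaled by `caliber_decay`). The walk gives each measured feature
its own independent knob: `n_seeds` drives BVD, `caliber_root_px`
drives BVC, `tortuosity_amp` drives BVT. Rasterization stamps hard
discs of the branch radius (no anti-aliasing), so the binary mask and
the recorded polylines/radii are exact ground truth; the grayscale arm
adds only a thin Gaussian edge profile ($\sigma = 0.6$ px). The `"6mm"`
FoV label halves vessel radii on the same 256-px canvas, mimicking the
coarser px/mm sampling of wide-field scans — no other physics is
intended.

`degrade()` models translation artifacts parametrically: dropout of the
smallest-caliber branches, multiplicative caliber jitter and bias
(`caliber_scale < 1` thins systematically), Gaussian blur, contrast
gain, pixel noise. The all-identity spec returns the GT map
bit-for-bit, which is what makes the paired-test null exact.

Default severities are calibration choices, not facts about any
particular translation model: the defaults used by `run_pipeline()`
(blur 1 px, 15% dropout, 10% caliber jitter, 2% noise) produce mean
SSIM around 0.5–0.8 on the demo cohort, in the range reported for
GAN-translated OCTA.

What the generator does **not** emulate: capillary-scale texture and
flow-signal speckle, the foveal avascular zone, layer-resolved plexuses,
vessel-density gradients across the macula, and pathology-specific
lesion morphology. Passing tests therefore demonstrate that the
measurement and statistics machinery is correct and calibrated on
vascular-network-like images — not that any particular clinical effect
size will be detected on real scans.

## Statistics

`summarize_features()` reports per (group, arm, FoV, feature) n, mean
and sample SD (denominator $n-1$), excluding sentinel values listwise
per feature with counts. `ttest_tr_vs_gt()` defaults to the unpaired
Welch test; because TR/GT values are per-subject pairs, the paired test
is also computed and both appear in every report. No multiple-testing
correction is applied; the report carries the number of tests so users
can correct downstream. Zero-variance degenerate inputs return
$t = 0, p = 1$ (equal means) rather than erroring.

**Calibration.** On null cohorts (TR drawn independently from the same
spec), the pooled fraction of (feature, replicate) Welch tests with
$p < 0.05$ sits within the 95% binomial band of 0.05 (observed
0.035–0.041 across 200-replicate studies of 6–20 subjects per arm).
Feature-wise, BVD, BVC and VPI are close to nominal while BVT is
conservative (rejection rate 0.01–0.035): subject-level BVT is
heavy-tailed, since one hairpin branch whose endpoint chord is barely
above the 1-px exclusion threshold can contribute a per-branch ratio an
order of magnitude above the median. This is a property of applying a
t-test to a heavy-tailed statistic at small n, documented rather than
patched; the calibration study uses 200 replicate cohorts of 6 subjects
per arm on 96-px, 3-seed maps, sizes chosen to keep the full check
under two minutes while leaving the binomial band informative.

**Power direction.** A `caliber_scale = 0.7` degradation (systematic
thinning) moves TR BVC below GT BVC and is detected by the paired test
at $n = 12$ in the test suite — a sanity direction check, not a power
claim.

## A worked run

```{r demo, eval = FALSE}
out <- file.path(tempdir(), "demo")
report <- run_pipeline(out, config = run_config(master_seed = 1L))
glance(report)
tidy(report)
autoplot(quantify_cohort(read_manifest(file.path(out, "manifest.csv"))))
```

`run_pipeline()` writes `features.csv`, `quality.csv`, `fid.csv`,
`means.csv`, `ttests.csv` and `report.json`, each stamped with the
package version, the configuration hash and the master seed; reruns
with the same seed are byte-identical.

## Known limitations

* Branch decomposition depends on the thinning topology; in dense
  networks, rasterization overlaps create junctions that the generator's
  geometry record does not know about, so branch counts are only
  comparable on sparse networks.
* BVT is sensitive to the `bvt_eps` chord threshold on hairpin
  branches (see the calibration note above).
* The default embedding makes Fréchet distances internally comparable
  but not comparable to Inception-based FID values.
* The synthetic generator is a measurement testbed, not a retina model;
  effect sizes on it do not transfer to clinical cohorts.
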