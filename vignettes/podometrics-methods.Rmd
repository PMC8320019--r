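---
title: "Podometric quantification from multiplexed immunofluorescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Podometric quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podoquant)
```

## The problem

Podocytes are terminally differentiated epithelial cells of the renal
glomerulus; their loss drives glomerulosclerosis and correlates with the
progression of diabetic nephropathy. Because podocytes do not divide,
their *volumetric density* in the glomerular tuft — podocytes per unit
tuft volume — is a clinically meaningful quantity. It cannot be read
directly from a single histologic section: a section shows 2D *profiles*
of 3D nuclei, and thicker sections catch more nuclei per unit area.
Podometrics is the set of stereological corrections that convert what a
section shows into the 3D quantities of interest.

podoquant implements the full image-to-density chain for multiplexed
immunofluorescence of kidney sections: GLEPP1 (a membrane marker of the
glomerular tuft) delineates regions of interest, Hoechst/DAPI provides
nuclear profiles, TLE4 (a podocyte-specific nuclear marker) classifies
profiles as podocytes, and YAP — a Hippo-pathway mechanosensor whose
nuclear localization signals activity — is scored per nucleus or, for
cultured cells, per nuclear/cytoplasmic compartment pair.

## The slab-projection forward model

The stereological core treats a nucleus as a sphere of caliper diameter
$D$ and the section as a slab of thickness $T$ imaged by full-thickness
projection. A nucleus is visible whenever any part of it intersects the
slab, i.e. when its centre lies within $(D+T)/2$ of the slab mid-plane.
A nucleus whose equator lies inside the slab projects at its full
diameter $D$; one centred a distance $\delta$ beyond a slab face shows a
cap circle of diameter $2\sqrt{(D/2)^2 - \delta^2}$. Averaging over a
uniform centre position gives the expected apparent profile diameter

$$\bar d = \frac{D\,(T + \pi D/4)}{D + T},$$

with the classical thin-section limit $\bar d = \pi D / 4$ at $T = 0$
and $\bar d \to D$ for thick slabs. `expected_profile_diameter()`
implements this closed form; the test suite checks it against an
independent Monte-Carlo simulation of the same geometry (uniform centre
offsets, projection rule applied per draw) to within 0.2% at $10^6$
samples.

Inverting the model gives the caliper diameter from a measured mean
profile diameter: $D$ solves $(\pi/4)D^2 + (T-\bar d)D - \bar d T = 0$,
taken at the positive root with a numerically stable quadratic solver
(`estimate_caliper_diameter()`; round-trip accurate to $10^{-9}$
relative over $D \in [4,16]$, $T \in [0,10]$).

Counting uses the same geometry: profiles per tuft area $N_A = n/A$
over-count nuclei by the factor $D + T$, so the Abercrombie-type
correction

$$N_V = \frac{n/A}{D + T} \times 10^6$$

yields nuclei per $10^6\,\mu m^3$ (`nuclear_density()`). Tuft volume
follows the Weibel–Gomez estimator under the spherical-tuft assumption,
$V = (\beta/k)\,A^{3/2}$ with $\beta = 1.38$ (sphere) and $k = 1.01$
(`tuft_volume()`). Derived figures are podocytes per tuft
($N_V V / 10^6$) and tuft volume per podocyte ($10^6/N_V$).

### Detection-floor truncation

Real measurements cannot see arbitrarily small cap profiles. With a
minimum detectable profile diameter $h$, profiles are lost when the
centre lies more than $\delta_c = \sqrt{(D/2)^2 - (h/2)^2}$ beyond a
face, so the effective counting depth shrinks from $D+T$ to
$T + 2\delta_c$, and the visible-profile mean diameter rises to

$$\bar d_h = \frac{TD + 2\left(\tfrac{h}{2}\delta_c + (D/2)^2
  \arcsin\tfrac{\delta_c}{D/2}\right)}{T + 2\delta_c}.$$

All three stereology operations accept `min_detectable = h`; the
default is $h = 0$ (no correction), matching the convention of
published podometric protocols that state none. The truncated forward
model is also verified against the Monte-Carlo oracle. The effect is
not negligible: at $D = 8$, $T = 3$ and $h = 2\,\mu m$, ignoring the
floor biases $N_V$ by about $-4\%$.

## Segmentation and classification

The commercial pipeline this package mirrors used a trained
tissue-classifier; only its marker logic is specified, and every
downstream metric depends solely on masks and counts. podoquant
therefore uses transparent classical segmentation:

* **Glomeruli** (`segment_glomeruli()`): GLEPP1 threshold (default 100
  on the 8-bit scale) → morphological closing (disc radius 5 µm,
  roughly the intra-tuft capillary gap scale) → hole filling →
  connected components → size filter (default 2,000 µm², rejecting
  capsular/tubular staining). Manual ROI correction is supported as a
  label-mask override rather than interactive editing.
* **Nuclei** (`segment_nuclei()`): DNA threshold (default 100) →
  optional distance-transform watershed for touching nuclei → size
  filter (default 10 µm² in tissue mode, removing optical debris; see
  below for phantom work). A nucleus belongs to the ROI containing its
  centroid and is kept in full even when it touches the ROI boundary.
* **Classification** (`classify_podocytes()`, `classify_nuclear_yap()`):
  a nucleus is a podocyte iff its *mean* TLE4 intensity over the
  nuclear mask is at or above 115, and nuclear-YAP positive iff mean
  nuclear YAP ≥ 75. These thresholds are fixed 8-bit constants from the
  published analysis settings; ties count positive everywhere, a
  deterministic rule stated once and applied consistently (display
  binning of TLE4 into low/medium/high uses the same right-closed
  convention and never enters any metric). The mean was chosen as the
  per-object statistic because the published description applies "an
  intensity threshold per marker" to objects without naming another
  statistic; alternative statistics would be a config extension.

Intensities are never rescaled: data are assumed 8-bit because the
printed thresholds (75, 115) only make sense on that scale, and
`bit_depth` is configurable for other acquisitions.

## YAP metrics

In tissue mode the per-glomerulus score is the count quotient
`n(podocyte & nuclear-YAP+) / n(podocyte)` — undefined (flagged `NA`)
for tufts without podocytes rather than zero or infinite. In culture
mode, where the published scoring was visual, podoquant substitutes a
documented surrogate: the cytoplasmic compartment is a fixed-width ring
(3 µm) around the nuclear mask, and a cell is nuclear-localized when
the nuclear/cytoplasmic mean ratio is ≥ 1.2. The 1.2 value is a
calibration knob, not a published constant; with the ≥2× contrasts of
clear translocation states the call is insensitive to it, which the
phantom tests demonstrate (100% accuracy at 3× contrast, noise SD 2).

## The phantom generator

`generate_tissue_phantom()` renders what the estimators assume:
circular GLEPP1-bright tuft cross-sections; nuclear profiles whose
diameters are drawn from the slab-projection model at a known true
density; TLE4 and nuclear-YAP assignments drawn at known fractions;
Gaussian blur (σ = 1 px) and additive Gaussian noise. Every rendered
object is listed in a ground-truth manifest. Defaults were chosen once
as the study conditions: 0.5 µm/px (a 20× whole-slide scan), 8-bit,
$D = 8$ µm podocyte nuclei, $T = 3$ µm sections, 60 µm tuft radius,
$N_V = 226$ per $10^6$ µm³ (an early-grade value), 40% TLE4⁺ among
glomerular nuclei, 50% nuclear-YAP⁺ among podocytes, noise SD 2.

Two generator choices deserve comment:

* **Detection floor.** Profiles below 2 µm diameter are not rendered
  (a 2 µm cap is at the resolution limit of the simulated optics) and
  are absent from the manifest. Phantom analyses therefore pass
  `min_detectable = 2` to the stereology and use
  `min_nucleus_area = 2` µm² so the analysis floor matches the
  rendering floor. The tissue default of 10 µm² would itself truncate
  ~4% of slab-model profiles — a property of that floor, not of the
  estimator.
* **Density-recovery phantoms render only the podocyte population**
  (`frac_tle4 = 1`). At the top of the tested density range (400 per
  $10^6$ µm³) a 40% TLE4 fraction would imply 1,000 total nuclei per
  $10^6$ µm³, which cannot be placed without profile overlap in a
  60 µm tuft; and the recovery experiment tests the density estimator,
  while the classifier is exercised by separate mixed-population
  phantoms.

What the phantoms do *not* emulate: tissue autofluorescence, uneven
illumination, sclerotic (GLEPP1-low) glomeruli, non-spherical or
clumped nuclei, and out-of-focus light. Passing phantom recovery
therefore validates the estimator chain and the segmentation logic on
well-behaved input; it does not certify segmentation accuracy on
degraded clinical material, where the ROI override mechanism exists.

## Statistics

Cohort analysis mirrors the published surface: unpaired Student
t-tests (Welch by flag), ordinary least-squares regression against
clinical parameters, and a grade-stratified report (early I/II vs late
III/IV) with group means ± SD, pairwise tests, equal-weight pooled
means and the late/early percentage ratio. No multiple-testing
adjustment is applied anywhere, matching the source analysis.
`t_test_from_summary()` computes the identical test from printed
group summaries (sufficiency verified to $10^{-12}$), and supports
reading the dispersion column as either SD or SEM — the published
table is ambiguous on this point, and the one significant contrast
(proteinuria) is significant under both readings. A seeded null
simulation (10,000 replicates, $n = 7$ per group) checks the type-I
error rate stays within (0.04, 0.06) at $\alpha = 0.05$.

Two numbers from the source deserve explicit care. First, the reported
"55% decrease" in density from early to late grade describes means of
226 and 124.5 per $10^6$ µm³ whose ratio is 55.1% *remaining* (a 45%
decrease); podoquant reports the ratio and labels it
`ratio_late_over_early_pct`. Second, the reported regression of
nuclear-YAP ratio on proteinuria ($r^2 = 0.48$, $p \approx 0.02$) is
internally inconsistent with $n = 14$ under OLS; the effective sample
size is unknowable from the text, so no test asserts it.

## Problem sizes and numerical choices

Validation experiments are sized to run on a laptop: density recovery
uses 100 single-section tufts per density (about 2,500–5,000 nuclei),
the Monte-Carlo oracle $10^6$ draws, the null simulation 10,000
replicates, and culture-mode recovery 3 replicates × 100 cells.
Quadratic inversion uses the stable root pair $q/a$, $c/q$; the
truncated inversion uses `uniroot` on $[\bar d, 4\bar d]$ at tolerance
$10^{-12}$. Zero-podocyte tufts produce density 0 with flagged-missing
volume-per-podocyte; zero-variance t-tests resolve to $p = 1$ when
means agree. All randomness flows through explicit seeds; a fixed seed
makes phantoms bit-identical and pipeline outputs byte-identical.

## Limitations

Per-tuft caliper-diameter estimation from few profiles is noisy; a
pooled per-case diameter can be supplied via `caliper_diameter` in
`derive_metrics()`. The spherical-nucleus and spherical-tuft
assumptions are inherited from the published method, along with its
single-section design — no disector or serial-section stereology is
attempted. Grade IV glomeruli with lost GLEPP1 signal cannot be
segmented by thresholding at all; they require the ROI override path.
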