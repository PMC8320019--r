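# podoquant

Automated podometrics from multiplexed immunofluorescence images of
kidney biopsy sections.

Podocyte loss drives glomerular disease, and podocyte *density* —
cells per unit glomerular tuft volume — is the quantity that tracks
disease severity. A single stained section only shows 2D profiles of
3D nuclei, so density estimation needs stereology. podoquant
implements the complete chain for GLEPP1 / TLE4 / YAP / DNA
multiplexed immunofluorescence:

1. **Segmentation** — glomerular tuft ROIs from the GLEPP1 channel
   (threshold → closing → hole filling → size filter), nuclear
   profiles from the DNA channel (threshold → optional watershed).
2. **Classification** — fixed intensity thresholds on per-nucleus mean
   intensities: TLE4 ≥ 115 ⇒ podocyte, nuclear YAP ≥ 75 ⇒
   nuclear-YAP positive (8-bit scale, ties count positive).
3. **Podometry** — for each tuft with area $A$, apparent podocyte
   count $n$, mean profile diameter $\bar d$ and section thickness
   $T$: caliper diameter $D$ from the slab-projection model
   $\bar d = D(T+\pi D/4)/(D+T)$; Abercrombie-corrected density
   $N_V = (n/A)/(D+T)\times 10^6$ per $10^6\ \mu m^3$; Weibel–Gomez
   tuft volume $V = (\beta/k) A^{3/2}$ ($\beta = 1.38$, $k = 1.01$);
   podocytes per tuft $N_V V/10^6$ and volume per podocyte $10^6/N_V$.
4. **YAP metrics** — per-glomerulus nuclear-YAP ratio among podocytes;
   nuclear/cytoplasmic translocation scoring for cultured cells.
5. **Cohort statistics** — grade-stratified (I/II vs III/IV) report
   with Student t-tests, OLS regressions against clinical parameters,
   and summary-statistics t-tests for printed tables.
6. **Phantoms** — a synthetic tissue/cell generator with ground-truth
   manifests, so every stage is testable without clinical data.

See `vignettes/podometrics-methods.Rmd` for the models, assumptions
and design choices.

## Worked example

Generate a six-glomerulus phantom at a known podocyte density of 226
per 10⁶ µm³ and run the full chain:

```r
library(podoquant)

ph  <- generate_tissue_phantom(phantom_spec(n_tufts = 6, seed = 42))
g   <- segment_glomeruli(ph$image)
nuc <- segment_nuclei(ph$image, g, min_nucleus_area = 2)
nuc <- classify_nuclear_yap(classify_podocytes(nuc))
m   <- derive_metrics(g, nuc, min_detectable = 2)
aggregate_case(m, case_id = "phantom-42")
```

The per-glomerulus table (`m`) contains the estimator chain per tuft:

```
  roi_id tuft_area_um2 n_podocytes caliper_diameter_um nuclear_density_per_1e6um3 podocytes_per_tuft
1      1         11311          38                7.68                     322.61             530.25
2      2         11311          19                7.90                     157.81             259.38
3      3         11311          39                7.55                     335.27             551.06
...
case phantom-42: 6 glomeruli, qc_pass=TRUE, mean density 221.2 per 1e6 um^3
```

The per-case mean density (221.2) recovers the generator's true 226
within the sampling noise of six tufts; the QC flag records that the
minimum of 6 evaluated glomeruli was met. Comparing clinical groups
from printed summary statistics:

```r
t_test_from_summary(0.96, 0.31, 7, 2.11, 0.35, 7,
                    group_labels = c("grade I/II", "grade III/IV"))
#> grade I/II vs grade III/IV: 0.96 +/- 0.31 (n=7) vs 2.11 +/- 0.35 (n=7)
#> student t = -6.508, df = 12, p = 2.904e-05
```

A command-line front end for batch use (`quantify`, `report`,
`phantom`, `yap-cells` subcommands) ships in `inst/cli/podoquant.R`.

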