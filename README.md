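# ifishtrial

Correlative-science and design computations for a single-arm phase II trial
of a JAK1/2 inhibitor (ruxolitinib) in metastatic triple-negative breast
cancer, packaged as a reusable, fully tested pipeline. It is aimed at
translational biostatisticians and imaging scientists who need the whole
chain — biomarker screening, exact trial design, single-cell immuno-FISH
image analysis, intratumor-diversity statistics, transcriptional
pharmacodynamics, and clinical endpoint summaries — runnable end to end on
synthetic data with known ground truth.

## What it computes

- **pSTAT3 IHC T-score** (`tscore`, `is_eligible`, `funnel_summary`): an
  Allred-style additive score, intensity *I* ∈ {0..3} plus proportion
  *P* ∈ {0..5} binned at 0, 1, 10, 33, 66, 100%; total 0 = negative,
  3–4 = weak/equivocal, 5–6 = moderate, ≥7 = high; eligibility at
  total ≥ 5.
- **Two-stage single-arm binomial design** (`two_stage_design`,
  `reject_probability`, `operating_characteristics`): exact
  P(deem worthy) = Σ_{x₁=r₁}^{n₁} B(x₁; n₁, p) · P(X₂ ≥ r − x₁),
  X₂ ~ B(n − n₁, p), plus PET and E[N] under the null — no Monte Carlo.
- **Immuno-FISH image analysis** (`segment_nuclei`, `count_spots`,
  `call_cells`, `analyze_slide`): nucleus segmentation (Gaussian smoothing,
  Otsu, connected components, area filter), difference-of-Gaussians spot
  detection for *JAK2* and CEP9, per-cell pSTAT3 positivity (per-slide
  Otsu) and *JAK2* amplification (JAK2/max(CEP9, 2) ≥ 2).
- **Intratumor diversity** (`summarize_slide`, `compare_fractions`,
  `compare_pooled_counts`, `diversity_cd8_regression`, `topology_map`):
  four populations pSTAT3± × JAK2 amp/noamp, Shannon entropy
  H = −Σ pᵢ ln pᵢ, exact small-sample Wilcoxon tests (midranks,
  enumeration by dynamic programming), 2×4 chi-square, OLS of CD8
  infiltrate on diversity with a 95% band, and binned topology maps.
- **Expression pharmacodynamics** (`qc_filter`, `to_tpm`, `gene_test`,
  `signature_score`, `signature_test`, `gene_set_enrichment`): tumor-content
  QC (< 20% excluded), TPM, t-tests on log₂(TPM+1), mean-z signature
  scores, hypergeometric over-representation with BH adjustment.
- **Clinical endpoints** (`response_summary`, `km_estimate`, `ae_table`):
  ORR/SD/CBR (CR + PR + SD > 24 weeks), Kaplan–Meier medians with log–log
  CIs, max-grade adverse-event tables.
- **Synthetic data** (`slide_spec`/`generate_slide_image`/
  `generate_cell_table`, `cohort_spec`/`generate_cohort`,
  `expression_spec`/`generate_expression`, `generate_slide_set`): every
  input above with known ground truth, all randomness derived from one
  seed.

## Worked example

```r
library(ifishtrial)

d <- two_stage_design(n1 = 21, r1 = 2, n_total = 41, r = 5,
                      p0 = 0.05, p1 = 0.20)
operating_characteristics(d)
#> Two-stage design: continue if >= 2/21, worthy if >= 5/41
#>   alpha (p = 0.05): 0.0457
#>   power (p = 0.20): 0.9017
#>   PET(p0): 0.7170   E[N | p0]: 26.66
```

The design needs at least 2 responses in the first 21 patients to continue
and 5 of 41 overall to call the agent worthy; the exact type I error at a
true 5% response rate is 0.046 and power at 20% is 0.90.

```r
sp <- slide_spec(n_cells = 100, width = 640, height = 640,
                 fractions = c(0.4, 0.3, 0.2, 0.1), seed = 7)
slide <- generate_slide_image(sp)          # 4-channel image + ground truth
calls <- analyze_slide(slide$image)        # segment, count spots, call cells
summarize_slide(calls, slide_id = "demo", timepoint = "baseline")
#> Slide demo (baseline): 100 cells, Shannon 1.3073 nats
#> pSTAT3-/JAK2noamp pSTAT3+/JAK2noamp   pSTAT3-/JAK2amp   pSTAT3+/JAK2amp
#>              0.38              0.26              0.25              0.11
```

All 100 planted nuclei are recovered; the called population fractions sit
near the specified (0.4, 0.3, 0.2, 0.1) mixture and the Shannon index
(maximum ln 4 ≈ 1.386 nats) quantifies the slide's diversity.

```r
tscore(80, 3)
#> pSTAT3 T-score: 8 (intensity 3 + proportion 5) -> high
funnel_summary(rep(c("moderate", "weak/equivocal", "negative"),
                   c(67, 71, 33)), 217)
#> Screened 217 consented; 171 with result: 67 moderate/high (39.2%),
#> 71 weak, 33 negative
```

## Command line

```sh
Rscript inst/cli/ifishtrial.R trial-oc --n1 21 --r1 2 --n 41 --r 5 \
    --p0 0.05 --p1 0.20 --outdir out
Rscript inst/cli/ifishtrial.R all --seed 1 --outdir out   # full pipeline
```

Exit codes: 0 ok, 2 missing input, 3 schema violation.

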