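---
title: "Models, conventions and limitations of ifishtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and limitations of ifishtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifishtrial)
```

`ifishtrial` packages the correlative analyses around a single-arm phase II
trial of a JAK1/2 inhibitor in metastatic triple-negative breast cancer:
biomarker screening by pSTAT3 immunohistochemistry, the exact two-stage
design, single-cell immuno-FISH readouts of *JAK2* copy number and pSTAT3
phenotype, intratumor-diversity statistics, transcriptional
pharmacodynamics, and endpoint summaries. This vignette documents the
models behind each stage, the conventions adopted where the underlying
study protocol left choices open, and what the synthetic-data generator
does and does not establish.

## The two-stage design

Stage 1 enrolls $n_1$ patients and the study continues only if at least
$r_1$ responses are observed; the agent is deemed worthy if at least $r$
responses accrue among $n$ total patients (stage-1 responses count toward
the total). The probability of deeming the agent worthy at true response
rate $p$ is computed exactly:

$$\Pr(\text{worthy}\mid p) \;=\; \sum_{x_1=r_1}^{n_1} \binom{n_1}{x_1}
p^{x_1}(1-p)^{n_1-x_1}\; \Pr\!\big(X_2 \ge \max(0, r-x_1)\big),\qquad
X_2 \sim \mathrm{Bin}(n-n_1,\,p).$$

For the implemented trial's design ($n_1=21$, $r_1=2$, $n=41$, $r=5$) this
yields type I error 0.0457 at $p_0=0.05$ and power 0.9017 at $p_1=0.20$
(0.046 and 0.90 at the precisions conventionally reported). Binomial terms
come from R's exact `dbinom`/`pbinom`; the summation is validated in the
test suite against exhaustive enumeration of all $2^n$ outcome sequences
for $n \le 12$ and against a $10^6$-replicate Monte-Carlo oracle. The
interpretation that stage-1 responses count toward the total of 41 is the
one that reproduces both published operating characteristics.

## T-score

The T-score formula itself is not in the public record, but its printed
interpretation anchors (0 negative; 3–4 weak/equivocal; 5 moderate; >6
high) match the standard Allred-style additive convention: intensity 0–3
plus a proportion score binning percent positive cells at 0, 1, 10, 33,
66, 100%, giving totals 0 and 2–8. We adopt that convention with
configurable bin edges. A total of 1 is unreachable; percent > 0 with
intensity 0 is scored 0 with a warning, since zero intensity means no
staining. Eligibility defaults to total $\ge 5$ ("moderate or high"),
reconciling the record's inconsistent ">5" and "5 or higher" phrasings in
favor of the interpretive anchors; the threshold is a parameter.

## Immuno-FISH image analysis

Images are numeric matrices (rows = y, columns = x, 0-based pixel
coordinates), four channels in fixed order DAPI, JAK2, CEP9, pSTAT3. No
image-analysis package exists in the offline dependency stack, so the
primitives are implemented in-package and unit-tested directly: separable
Gaussian convolution with replicate padding, Otsu thresholding on a
256-bin histogram, 8-connected component labeling by iterative min-label
propagation, and difference-of-Gaussians band-pass spot detection.

* **Segmentation**: smooth ($\sigma$ = 1.5 px), threshold (Otsu per image
  by default; fixed override), label, filter components to
  [`min_nucleus_area`, `max_nucleus_area`] (defaults 100–2000 px²,
  bracketing the generator's radius-12 disks). No watershed declumping is
  applied: the generator guarantees non-touching nuclei, and the
  segmentation method used in the original study is unstated.
* **Spot counting**: local maxima of DoG($\sigma$ 1–2.5 px) above a
  prominence of 15, assigned to the enclosing nucleus; spots outside
  nuclei are discarded.
* **Calling**: pSTAT3 positivity thresholds the per-nucleus mean intensity
  by Otsu computed per slide (staining batches vary; a fixed threshold is
  available). *JAK2* amplification uses the conventional FISH ratio
  criterion JAK2/CEP9 $\ge 2$ — with the reference floored at 2, its
  diploid expectation. Flooring at 1 (sometimes seen) makes the call
  fragile: a single dropped CEP9 hybridization halves the denominator and
  miscalls a substantial fraction of diploid cells as amplified; fewer
  than two observed reference signals is evidence of dropout, not
  monosomy. `cep9_floor = 1` and an absolute rule (`jak2_spots >= 4`) are
  provided. Cells with zero CEP9 spots are retained and flagged.

## Diversity and spatial statistics

Cells are cross-classified as pSTAT3±/JAK2amp-or-noamp (four populations,
fixed order). Per-slide diversity is Shannon entropy
$H = -\sum_i p_i \ln p_i$ over the four fractions (natural log by
default — the upstream reference does not fix a base; base 2 available;
$0\ln 0 = 0$ by the limit convention), so $0 \le H \le \ln 4$.

Group comparisons use the Wilcoxon rank-sum (unpaired) or signed-rank
(paired) test with *exact* conditional p-values under ties: midranks are
doubled to integers and the permutation distribution is built by dynamic
programming, up to 40 total observations (rank-sum) or 25 pairs
(signed-rank), beyond which tie-corrected normal approximations take
over. The phrase "paired Wilcoxon rank-sum test" in the study record is
internally contradictory; we implement the signed-rank test and offer the
paired t-test alongside, because on three pairs an exact rank test's
smallest two-sided p is 0.25 and the study's reported p = 0.029 on three
pairs can only have come from a t-type test. Both are reported; no
attempt is made to force agreement. Pooled population counts are compared
by a 2×4 chi-square test of homogeneity (df 3; populations empty in both
groups are collapsed with a warning).

The CD8 association is ordinary least squares of per-montage CD8 counts
on $H$ with the two-sided slope t-test and a pointwise 95% confidence
band. Topology maps bin the slide into squares and report per-bin
population counts and the dominant label (ties to the lower population
index; empty bins are explicit `NA`s) — visualization-level spatial
summaries only, matching the source study's use; no Ripley-K-style
inference is attempted.

## Expression pharmacodynamics

Samples below 20% tumor content are excluded (strict `<`; the boundary is
retained). TPM is
$\mathrm{tpm}_{gs} = (c_{gs}/\ell_g)\big/\sum_g (c_{gs}/\ell_g) \times
10^6$ with lengths in kb, so columns sum to $10^6$ exactly. Single-gene
contrasts are Welch t-tests on $\log_2(\mathrm{TPM}+1)$ (pseudocount
configurable); unpaired is the default, matching the "Student's t-test"
language of the source, with a paired mode. The published analysis used
DESeq2 for genome-wide discovery; this package deliberately substitutes
the documented per-gene t-test and does not re-implement shrinkage
estimation. Signature scores are the mean over signature genes of
per-gene z-scores of $\log_2(\mathrm{TPM}+1)$ across samples
(zero-variance genes contribute 0; scores are undefined below 50% gene
coverage). The two bundled STAT3 signature lists are synthetic
placeholders (plausible JAK–STAT members, shipped as a GMT file and
marked synthetic); users should substitute the published lists. Gene-set
analysis is a generic one-sided hypergeometric over-representation test
with Benjamini–Hochberg adjustment — the commercial ontology used
upstream is out of scope.

## Clinical endpoints

ORR is (CR+PR)/n over all treated patients, unevaluable patients staying
in the denominator; the clinical benefit rate adds SD lasting more than
24 weeks. Display percentages round half-to-even to integers, and exact
fractions are always retained (the source's own rounding is internally
inconsistent). Kaplan–Meier estimation is delegated to the `survival`
package with `conf.type = "log-log"` as the default CI (the transform
actually used upstream is unstated; log and plain are options); the
median is the first time the curve reaches 0.5. Adverse events are
tabulated at each patient's maximum grade per event, filtered to
incidence ≥ 10% or any grade ≥ 3.

## The synthetic-data generator

The generator emulates, with controllable ground truth: (a) slides
carrying a four-population mixture with optional parent/offspring spatial
clustering; (b) CD8/GZMB infiltrate flags whose rate falls with the
slide's realized diversity (logistic link, default slope −1.5 per nat);
(c) pre/post negative-binomial count matrices in which named
STAT3-induced genes shift by a target log2 fold-change after treatment
(and repressed genes shift oppositely); (d) single-arm cohorts with
Bernoulli response, exponential PFS/OS at stated medians under
independent exponential censoring, and per-grade adverse-event profiles.
All randomness flows from one integer seed through a documented splitting
scheme (`derive_seed(seed, stream)`, a 31-bit multiplicative hash), so
outputs are bit-identical across runs and adding a stream never perturbs
another.

Defaults state the assumed world: 512×512 px slides, radius-12 nuclei
kept at least one diameter plus a 5-px guard band apart (without the
band, pre-threshold smoothing bridges 1-px gaps and merges neighbors —
the study gives no segmentation detail, so the generator stays in the
regime its pipeline models); *JAK2*/CEP9 copies 2/2 (non-amplified) and
6/2 (amplified); pSTAT3 nuclear intensity Gaussians at 30 (negative) and
160 (positive) with SD 15 on an 8-bit scale; background noise SD 5;
FISH puncta at least 5 px apart within a nucleus (distinct chromosome
territories). Spot counts default to a *detection* model —
Binomial(copies, 0.95) + Poisson(0.05) background — rather than the naive
Poisson(mean) convention: Poisson counts at mean 2 would make the
conventional ratio-2 criterion misclassify roughly a quarter of diploid
cells, i.e. the naive convention contradicts the very separability the
populations are defined by. `spot_model = "poisson"` restores the literal
convention for sensitivity analyses. Expression defaults: 1,000 genes,
baseline log2 means uniform on [3, 9], NB dispersion 0.2, library sizes
±30%, gene lengths gamma with mean 2 kb — typical bulk RNA-seq biopsy
scales. No distributional facts about any of these quantities are in the
public record; they are conventions, chosen once.

What a green test establishes — and what it does not: the generator
renders clean, well-separated, in-focus nuclei. End-to-end recovery of
≥95% of population labels on such slides validates the *software chain*
(segmentation → counting → calling → statistics), not performance on real
FFPE tissue with touching nuclei, z-structure, autofluorescence and
sectioning artifacts, which the generator deliberately does not model.
Likewise the power figures measured on synthetic expression data reflect
the assumed dispersion, not any property of the trial's actual biopsies.
At the chosen dispersion (0.2), the true power of the unpaired t-test to
detect a 2-fold repression at n = 10/arm is about 0.75–0.79; the test
suite checks the pipeline's detection rate against an independent
Monte-Carlo power oracle rather than asserting a round nominal figure.

## Numerical choices

Exact binomial tails via `pbinom`; exact Wilcoxon distributions via
integer dynamic programming on doubled midranks (no floating-point
accumulation error); Otsu on 256 bins; reported-value tolerance for the
design operating characteristics 5e-4; chi-square without continuity
correction (matching the df-3 homogeneity test); TPM conservation checked
to 1e-6 relative; entropy validated against brute force at 1e-12.
Degenerate inputs are flags, not errors, where a study could genuinely
produce them: empty slides, all-censored cohorts, zero-total expression
columns, constant regression predictors.

## Known limitations

No watershed separation of touching nuclei is exercised; chromogenic
FISH, 3-D stacks and out-of-focus modeling are out of scope. The
screening funnel and AE tables reproduce printed aggregate values, but
patient-level survival and figure-level results of the source study are
not reproducible from published material and are not claimed. The
gene-signature fixtures are placeholders, and DESeq2-class inference is
intentionally not replicated.
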