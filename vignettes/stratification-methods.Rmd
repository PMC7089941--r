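---
title: "Two-axis stratification of high-grade serous ovarian cancer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-axis stratification of HGSOC: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgsocstrat)
```

High-grade serous ovarian carcinoma (HGSOC) is routinely stratified along two
largely independent molecular axes. The first is genomic: homologous
recombination deficiency (HRD), read from the scar it leaves on the tumour's
absolute copy-number profile, predicts sensitivity to platinum salts and PARP
inhibitors. The second is transcriptomic: a mesenchymal/fibrotic expression
programme — called C1, Fibrosis, Angiogenic or Mesenchymal depending on the
signature — consistently marks the poor-prognosis subgroup across cohorts.
`hgsocstrat` implements both callers, combines them into four prognostic
strata, and provides the association and survival statistics used to evaluate
such stratifications, together with a synthetic cohort generator that plants
known truth for every stage.

This vignette records the model behind each stage, the tunable parameters and
their defaults, the numerical choices made where the procedure was genuinely
open, and what the synthetic generator does and does not emulate.

## The LST caller

The genomic axis counts **large-scale state transitions (LST)**: chromosomal
breakpoints — a change in total copy number or major allele count between two
adjacent genomic regions — where both flanking regions span at least 10 Mb,
counted genome-wide after variant regions shorter than 3 Mb have been smoothed
away. High counts indicate the fragmented, HRD-type genome.

The caller consumes absolute copy-number segments (1-based closed
coordinates, SEG convention; segment length is `end - start + 1`) and
composes four steps:

1. **DNA index.** The segment-length-weighted mean total copy number divided
   by two, so a uniform diploid genome scores 1.0:
   \(\mathrm{DI} = \sum_i \ell_i c_i / (2\sum_i \ell_i)\). The source
   procedure says only "averaged copy number" but thresholds at 1.3, which
   separates diploid from tetraploid genomes only on this conventional
   (flow-cytometry) scale — a raw mean copy number of 1.3 would be a heavily
   deleted genome, not a ploidy boundary. We therefore divide by two and
   expose `raw = TRUE` for the literal reading.
2. **Ploidy class.** Near-diploid below a DNA index of 1.3, near-tetraploid
   at or above it; the boundary value is tetraploid.
3. **Smoothing and filtering** (`min_variant_mb = 3`). Adjacent same-state
   segments merge; then sub-3 Mb segments are deleted iteratively, shortest
   first with ties broken by genomic position, re-merging the neighbours when
   their states agree. The deletion-order rule makes the fixed point
   deterministic and independent of input row order, and it is idempotent.
   When a deleted segment's neighbours disagree, the freed interval is
   absorbed by the left neighbour (the right one for a leading segment); a
   chromosome consisting of a single sub-3 Mb segment is dropped as a variant
   region. Only the bridged case was specified upstream; the gap rule is this
   package's choice and only affects breakpoint positions by under 3 Mb,
   never the transition count between retained ≥ 10 Mb regions.
4. **Counting and classification** (`min_region_mb = 10`). Transitions are
   counted between consecutive retained segments of one chromosome;
   chromosome boundaries never count. The original LST method counted within
   chromosome arms; the procedure reproduced here says only "chromosomal
   breakpoint", so counting is per-chromosome by default and per-arm when a
   centromere interval table is supplied (`arm_boundaries`, BED via
   `read_centromeres_bed()`). Cut-offs are ploidy-specific — 15 LST per
   genome for near-diploid, 20 for near-tetraploid — and inclusive: a tumour
   at the cut-off is `LST_high` (HRD).

Profiles lacking major allele counts fall back to a total-copy-number
breakpoint predicate with one warning per call; allele-balanced events then
become invisible, so counts are conservative.

## The transcriptomic classifier

Samples are classified under a gene-signature scheme by unsupervised
hierarchical clustering, reproducing the published procedure: restrict the
log-expression matrix to the signature's genes, standardize each gene,
cluster samples with Ward's agglomeration, cut the tree into `k` groups
(k = 2 for Fibrosis/non-Fibrosis, C1/C2–C6, M1/M2–M4; k = 4 for D-I-M-P), and
name the clusters.

Numerical choices, each of which the source left open:

* **Standardization** uses the population SD (divide by the root mean squared
  deviation), so a row `(1, 2, 3)` maps to `(-1.2247, 0, 1.2247)`. Sample-SD
  scaling differs only by the constant \(\sqrt{(n-1)/n}\) applied to every
  row, so clustering and PCA are unaffected by the choice. Heatmap
  conventions imply centering; scaling is assumed so that no single
  high-variance gene dominates the Euclidean distance. Zero-variance genes
  are dropped with a warning.
* **Distance.** The methods text says Euclidean, the corresponding figure
  legend says Pearson, for the same clustering. Euclidean is the default;
  `distance = "pearson"` (d = 1 − r) is supported and both are tested. On
  standardized rows the two usually agree.
* **Ward variant.** `ward.D2`, the Lance–Williams update equivalent to
  Ward's minimum-variance criterion on squared Euclidean distances. R ships
  two Ward variants with different merge costs; `ward.D2` is the one that
  matches the textbook criterion, so it is fixed here and documented.
* **Cluster naming.** The source never states how dendrogram branches were
  mapped to subtype names. Each cluster is scored by the mean standardized
  expression of each label's up-gene set and labels are assigned by greedy
  maximum-score matching (ties broken by gene-set order and logged; an
  all-tie score matrix aborts and asks for a manual mapping). The rule is
  deterministic and auditable, and planted-truth simulations recover the
  generator's labels exactly.
* **Canonical cluster ids.** Raw `cutree` ids depend on input order, so they
  are relabelled by decreasing cluster size (first-sample id breaking ties),
  making `classify()` invariant to column permutations.
* **Gene matching.** Signature genes absent from the matrix are dropped with
  a logged match fraction; below 50% the run aborts unless `force = TRUE`.
  Identifiers are opaque strings — no probe/symbol harmonization is
  attempted, matching is exact.

Cross-scheme agreement is quantified by `concordance()` (cross-tabulation
with row percentages), and `pca_subgroup_association()` tests, per principal
component of the standardized signature submatrix, whether component scores
differ between two groups. The source reports these p-values without naming
the test; its `p < 2.2e-16` floor is typical of rank or t statistics in R, so
a two-sided Mann–Whitney test is the default (rank-based, robust to the
heavy tails of expression scores) with Welch's t as an option. Median
dichotomization (`dichotomize_by_median()`) assigns ties to `low`,
deterministically.

## Survival and association statistics

* `fisher_exact()` — two-sided Fisher's exact test. For 2×2 tables the
  point-probability convention (sum of hypergeometric point probabilities at
  most that of the observed table), not tail doubling; larger tables use the
  exact network algorithm up to a total count of 1000 and a seeded
  Monte-Carlo estimate (10^6 draws, seed recorded in the `method` field)
  beyond. Zero margins are rejected: the test is undefined.
* `km_curve()`, `logrank()` — product-limit estimate and k-group log-rank
  chi-square (df = k − 1). Both administratively censor follow-up at
  `horizon_months = 120` by default so that curves and tests match the
  10-year analyses; whether the source truncated its tests or only its
  plots is not stated, so `Inf` disables the horizon.
* `pairwise_logrank_bh()` — all pairwise log-rank tests, Benjamini-Hochberg
  adjusted over the pairs of this one analysis only (6 pairs for 4 strata),
  the `pairwise_survdiff` convention. `bh_adjust()` is the classic step-up
  with cumulative minima from the largest rank and clipping at 1. Note BH
  adjustment is not idempotent — adjusted vectors are not fixed points — so
  no such property is claimed or tested.
* `cox_fit()` — proportional-hazards partial likelihood with **Efron** tie
  handling (the default of the R `survival` stack the source used);
  categorical covariates with explicit reference levels; Wald 95% intervals
  `exp(beta ± 1.96 se)`. One covariate gives the univariate model, several
  the joint model. Non-convergence and complete separation abort rather than
  returning unstable estimates.

Missing clinical values are never imputed: each association or model drops
them pairwise and reports its own denominator, which is why published
association tables show different totals per variable.

## The synthetic cohort generator

`gen_cohort()` plants ground truth for every pipeline stage. Its defaults are
the package's stated world and were fixed before any acceptance result was
measured:

| Parameter | Default | Rationale |
|---|---|---|
| cohort size `n` | 200 | four strata of 50, a mid-sized cohort |
| strata | equal four-way split | balanced design |
| baseline hazard | 0.0154 / month | median OS ≈ 45 months, typical HGSOC |
| planted HRs | 1 / 1.5 / 2 / 3 | Fibrosis ≈ 1.5, LST_low ≈ 2, jointly 3; mirrors the published ordering (LST-high/non-Fibrosis best, LST-low/Fibrosis worst) |
| censoring | 30% exponential + 120-month horizon | typical follow-up loss |
| LST counts | ≈ 22 (high) vs ≈ 5 (low), Poisson | clearly across the diploid cut-off of 15 |
| genome | 22 chromosomes × 130 Mb | coarse human autosome scale |
| small variants | 5 per profile, 0.2–2.9 Mb | filtering workload |
| expression shift | 3 × noise SD on up-genes | strong but noisy subtype separation |
| background genes | 200 | unstructured dimensions |
| stage / debulking frequencies | 98%/93% advanced, 84%/76% partial by Fibrosis status | group-dependent covariates at published magnitudes |

Mechanics worth knowing:

* `gen_cn_profile()` places exactly `n_lst` breakpoints with every flank
  ≥ 10 Mb (segment lengths are 10 Mb plus a random split of the slack) and
  alternates copy number between the baseline and baseline + 1. Sub-3 Mb
  variants are inserted strictly inside host segments with both residual
  flanks ≥ 3 Mb, so no deletion order can erode a planted flank: filtering
  provably restores the planted geometry and `count_lst()` returns exactly
  `n_lst` for any number of variants. Infeasible requests abort with the
  capacity.
* `gen_survival()` draws exponential event times with hazard
  \(\lambda_i = \lambda_0 e^{\beta_{g(i)}}\) and an independent exponential
  censoring clock with rate \(\mu_i = \lambda_i c/(1-c)\), which censors a
  fraction *c* of subjects among pre-horizon resolutions; the administrative
  horizon adds its own censoring on top (about 5 further points at the
  default hazard). Exponential rather than Weibull because it is the minimal
  proportional-hazards generator; the calibration identity would not be
  closed-form otherwise.
* All randomness flows through one master seed; each generator uses a
  deterministic sub-seed (kept below 2^31), so a cohort is byte-identical
  across runs and machines, and generators never leak RNG state.

What the generator does **not** emulate: microarray probe effects, batch or
platform differences, correlated gene-gene structure within signatures,
subclonal or fractional copy numbers, genome-position-dependent breakpoint
rates, or the marginal distributions of any real cohort. A green planted-truth
test therefore establishes that the algorithms implement their definitions —
not that the signatures have the published effect sizes in real tumours;
those claims are checked only where the published contingency tables allow
exact recomputation.

## Pipeline and configuration

`run_pipeline()` chains the stages (LST calling → classification →
combination → association report → KM / log-rank / pairwise-BH → univariate
and multivariate Cox) with stage-tagged error reporting, and optionally
writes TSV/JSON artifacts. The configuration is an R list or a JSON file;
JSON (via `jsonlite`) stands in for the YAML configuration a command-line
tool would use, since no YAML parser is available in the supported
dependency set. There is no separate command-line binary: the exported
functions are the interface, and `scripts/acceptance.R` shows the package
driven non-interactively.

## Known limitations

* The LST caller consumes absolute copy-number segments; it does not
  re-estimate allele-specific copy number from raw SNP-array data, and no
  other HRD scores (TAI, HRD-LOH) are provided.
* Gene identifiers are matched exactly; cross-platform probe/symbol
  harmonization is the caller's responsibility.
* `classify()` clusters all provided samples; it has no notion of the
  "not applicable" exclusions real cohorts apply upstream.
* No proportional-hazards diagnostics, time-varying covariates or competing
  risks; no GO-enrichment stage (an external web-service analysis upstream).
* Published patient-level results (hazard-ratio tables, pairwise p-value
  tables, survival curves) require the original cohorts and are out of
  reach; the package reproduces their *procedures* and checks them on
  planted truth, and reproduces exactly those published numbers whose full
  contingency tables are printed.

## A worked example

```{r example, message = FALSE, warning = FALSE}
cohort <- gen_cohort(seed = 1)
report <- run_pipeline(list(
  segments = cohort$segments, expr = cohort$expr,
  signatures = cohort$signature, clinical = cohort$clinical
))
report
tidy(report$cox_multivariate)
as.matrix(report$pairwise_logrank)
```

The recomputation of the published association tables needs no simulation at
all — the printed counts ship with the package:

```{r fisher}
counts <- tcga_association_counts()
association_fisher(counts, "fibrosis", "stage")    # printed p = 0.01
association_fisher(counts, "dimp", "ploidy")       # printed p = 4.6e-5
association_fisher(counts, "lst", "brca_mutation") # printed p = 2.0e-15
```
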