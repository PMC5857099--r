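---
title: "Methods: screening RBPs and calling their stabilized targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening RBPs and calling their stabilized targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpscreen)
```

This vignette is the package's own account of the models it implements, the
choices made where the underlying procedures were ambiguous, and what the
synthetic-data generators do and do not establish.

# The analysis design

An RBP (RNA-binding protein) suspected of suppressing metastasis through
transcript stabilization leaves three computable footprints: (i) its gene is
recurrently down-regulated in aggressive-disease expression comparisons (and,
for a genetic cause, deleted in a fraction of tumors); (ii) its direct
target transcripts are enriched in RIP-seq immunoprecipitates relative to
input and IgG controls, with binding sites concentrated in 3'UTRs near stop
codons; (iii) those targets decay faster when the RBP is depleted — visible
both transcriptome-wide (retention after transcription inhibition) and in
per-gene inhibitor time courses. Downstream, expression of the RBP and its
secreted targets can be related to immune-marker co-expression and survival
in a tumor cohort. `rbpscreen` implements each footprint as a separate module
with plain data-frame/matrix interfaces.

# Screening

Each dataset is a genes-by-samples log2-intensity matrix with two groups.
Rows are median-centered over **all** samples, and Student's pooled-variance
t-test (two-sided) compares the groups; Welch's correction sits behind
`var_equal = FALSE`. The ranking metric is the signed log2 fold change —
"most down-regulated" — not the t statistic, which enters only through the
`p < 0.05` gate.

**Percentile denominator.** "Top 10% of the most down-regulated RBP genes"
admits two readings: rank over the RBP genes that pass the gate, or rank over
the RBP census present in the dataset. The package defaults to the census
denominator (`denominator = "rbp_total"`). The gate-passing denominator
(available as `"ranked"`) makes recovery of consistently planted genes
structurally impossible whenever the passing pool is dominated by true
positives — at most 10% of that pool can sit in its own top 10% — which
contradicts the design's purpose of retaining reproducible hits. With the
census denominator, "top 10%" means the most down-regulated tenth of all RBP
genes under consideration, independent of how many clear the gate.

Ties in fold change are broken by smaller p, then gene id; the percentile
convention makes the selection a permutation-consistent function of the
input. The three category rules (all-three at &le; 10%, any-one at &le; 5%,
any-two at &le; 10%) are a union with per-rule provenance. The deletion
filter is a strict inequality (`fraction_deleted > 0.05`).

# Target calling

* **Bound set.** Enrichment is `log2((IP_cpm + 0.5) / (ctrl_cpm + 0.5))`
  against input and IgG separately; both must reach `log2(2)`, and input CPM
  must reach 1. These thresholds are explicit stand-ins — the source
  procedure reports a bound-set size without stating its cutoffs — and are
  exposed as arguments. Without an IgG library the call degrades to
  input-only with a warning.
* **Steady-state down.** Linear fold `mean(ctrl CPM)/mean(kd CPM)` with
  pseudocount 0.5, strictly greater than 1.1, plus Benjamini-Hochberg
  `q < 0.05` from a pooled t-test on log2 CPM. "Fold change down > 1.1" is
  interpreted on the linear scale with strict inequality; the log-scale
  reading differs only in the third decimal at this threshold but the choice
  is documented and tested at the exact boundary (11/10 is excluded).
* **Destabilized.** The stability measure is
  `delta = logFC(9 h) - logFC(0 h)` of knockdown vs control; selection is
  `delta < -log2(1.1)`, strict. An equivalent formulation — the log ratio of
  per-condition retention fractions — is algebraically identical.
  Notably this rule carries no significance gate (matching the published
  set sizes, where roughly a quarter of all transcripts qualify); its false
  positives are controlled downstream by the triple intersection.
* **Peak annotation.** Midpoint membership with priority
  3'UTR &gt; 5'UTR &gt; CDS &gt; intron across overlapping transcripts,
  reflecting the 3'UTR-centric biology of stability-regulating RBPs; the
  priority vector is an argument. Coordinates are 0-based half-open
  throughout; BED passes through untouched, GTF is converted on read/write.
  `distance_to_stop` is the signed genomic distance from the peak midpoint to
  the last CDS base in transcript orientation (negative = upstream), and is
  strand-consistent under coordinate mirroring.

# Decay kinetics

The source procedure says half-lives came from "nonlinear regression" of
data "on a semilog scale" — internally contradictory, since the best-fit
line on a semilog plot *is* ordinary least squares of `ln(abundance)` on
time. The package makes the log-linear OLS slope the primary estimator
(`k = -slope`, `t_1/2 = ln 2 / k`, exactly, by construction), with true
nonlinear least squares on `a e^{-kt}` behind `method = "nls"`, initialized
from the log-linear fit. Replicates are pooled into one regression by
default (preserving degrees of freedom); averaging first is a flag. A
non-negative slope yields `k = 0`, `t_half = Inf`, and a `decaying = FALSE`
flag rather than a negative half-life; comparisons against a non-decaying
fit return a not-applicable result instead of an exception. Condition
comparison uses the time-by-condition interaction of a joint log-linear
model. ΔΔCt quantification averages technical replicates on the Ct scale
before exponentiation, so the calibrator maps to exactly 1.

# Co-expression and survival

Counts become log2-CPM with the voom offset
(`log2((c + 0.5)/(N + 1) * 1e6)`). Composite groups intersect top/bottom
`floor(q n)` sample sets; the quantile `q` has no canonical default beyond
0.30 (published panels mix 20%, 30% and 50%), so it is a plain argument.
An empty intersection (e.g. anti-correlated gene pairs) raises an explicit
error. The moderated linear model of the original workflow is replaced by
Welch t-tests with BH adjustment: with roughly a hundred samples per
composite group, variance moderation is immaterial, and the substitution
keeps the module dependency-free. "0.75 fold change" is taken as
`|log2 FC| >= 0.75`, consistent with the phrase "log fold change 0.75" in
the source description; a linear-scale reading is a flag. Whether the 0.01
significance gate was raw or adjusted is unstated; the raw p gates, and the
BH q is always reported alongside. Z-scores use the population sd
(divisor n). Kaplan-Meier and log-rank follow the textbook estimators
(censoring processed after events at tied times). "Autoselect best cutoff"
— an external web tool's behavior — is realized as a quantile-grid
(0.10-0.90, step 0.05) minimum-p scan with the feasibility constraint that
each group keeps at least 10% of samples; because the scan is
anti-conservative, a grid-size Bonferroni p accompanies the raw minimum in
every report. Cox modeling and hazard ratios are out of scope.

# The synthetic world

The generators state one fixed world; their defaults are not tuned to test
outcomes.

* **Sizes** mirror the design where printed: three screening datasets with
  10 samples per group; a 354-sample cohort; stability contrasts at 0 and
  9 h with two replicates; DRB-style time courses at 0/2/4/6/8 h with three
  replicates; 200-subject survival tables.
* **Screening plant.** 1000 genes, 100 RBPs, and 10 RBP genes planted
  down-regulated (log2 FC -1) in all three datasets, Gaussian noise sd 0.5 on
  the log2 scale. Ten reproducible hits against a null background reflects
  the funnel shape of such screens, which end at a handful of validated
  candidates. The copy-number table gives those ten deterministic deletion
  fractions alternating above/below the 5% threshold, so the deletion-filter
  output is decidable by construction; background genes draw from Beta(1, 20).
* **Counts** are negative binomial with dispersion 0.01 (biological CV 0.1),
  the conventional value for replicates of genetically identical cell lines —
  the knockdown experiments emulated here are cell-line assays, not patient
  tissues. Baseline means span roughly 64-2048 counts (expressed genes).
* **Stability normalization.** Reported library sizes are anchored at the
  common expected time-zero total, emulating spike-in depth normalization.
  With per-library totals instead, global RNA loss in the knockdown would
  shift the composition and bias every stability contrast toward zero; the
  anchored convention makes the planted contrast (knockdown half-life 4.5 h
  vs control 9 h at 9 h, i.e. delta of exactly -1) recoverable.
* **Time courses** multiply `e^{-kt}` by `1 + eps`, `eps ~ N(0, 0.10)`
  (floored far in the tail to keep abundances positive).
* **Cohorts** draw a latent Gaussian log2 level with requested correlations
  (single-factor structure against the index gene, or a user correlation
  matrix validated for positive semi-definiteness) and NB counts around
  `2^latent`. Observed log-CPM correlations are attenuated relative to the
  latent target (about -0.5 observed for -0.6 latent at these depths).
* **Survival** uses exponential event times with hazard
  `lambda0 exp(beta z)`, `lambda0 = ln 2 / 24` months, and independent
  exponential censoring at rate `lambda0 c/(1 - c)`, giving expected
  censoring fraction `c` under the null. A `"threshold"` effect mode plants
  a step at the median for cutoff-selection checks.
* One global seed expands to per-generator substreams (a deterministic hash
  of seed and stream name), so adding a generator never perturbs another's
  draws, and a fixed config is byte-identical across calls.

**What a green test establishes.** That the implementations compute their
stated quantities correctly (closed forms, independent oracles, boundary
behavior) and that planted effects of the stated sizes are recovered at the
frozen pilot rates. The world omits batch effects, normalization artifacts,
alignment noise, probe-level microarray structure, and copy-number
segmentation; green tests say nothing about robustness to those.

# Known limitations and one red criterion

* With three replicates, 2-fold planted steady-state changes, and BCV 0.1,
  BH-gated recovery is about 46% — an honest reflection of the design's
  power, not a defect; the pilot-frozen assertion is a lower bound of 0.40.
* The decay-recovery acceptance criterion requires that over 200 simulations
  at `k` in {0.05, 0.1, 0.2, 0.4}/h with 10% noise, 80% of estimates fall
  within ±10% of truth. Analytically, the pooled-OLS slope standard error in
  this world is about 0.0091/h (error sd 0.1 over a time design with
  `Sxx = 120`), so the ±10% band covers at roughly 42% for `k = 0.05`, 73%
  for 0.1, 97% for 0.2 and ~100% for 0.4 — an expected average near 78.5%.
  At the pre-registered seed the suite measures 79%, and the criterion is
  left red rather than met by widening the band, changing the noise model,
  or shopping for a seed. The median-bias half of the criterion (< 5%)
  passes with two orders of magnitude to spare.
* `best_cutoff`'s Bonferroni adjustment treats the grid points as
  independent; they are positively correlated, so the adjusted test is
  conservative in principle. At the pre-registered seed its null rejection
  rate (9/200) still falls inside the 95% binomial band of the nominal 5%.
* The RBP census, secreted-protein list, and immune-factor list are plain
  input files; no annotation databases are bundled (a small example immune
  list ships in `inst/extdata/`).
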