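---
title: "Classifying translational regulation from polysome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying translational regulation from polysome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystate)
```

## The measurement and the question

Polysome profiling separates a cytoplasmic lysate on a sucrose gradient into
fractions that report how heavily each mRNA is engaged by ribosomes: free
mRNA, the 40S-60S-80S (monosome) region, and the polysome region where
multiple ribosomes translate a message at once. Sequencing the unfractionated
*input* (total RNA) alongside the pooled *monosome* and *polysome* fractions
at two developmental stages lets one ask, per transcript isoform, whether a
change in polysome association between the stages reflects translational
control rather than a change in transcription or mRNA stability.

`polystate` classifies each isoform by combining three per-fraction stage
contrasts:

* **transcription_up / transcription_down** — total (input) abundance changes;
  whatever happens in the gradient fractions is confounded by transcription
  or stability, so these isoforms are excluded from the translational classes.
* **repressed** — input unchanged, polysome association goes down from the
  earlier to the later stage.
* **derepressed** — input unchanged, polysome association goes up.
* **monosome_shift** — only the monosome fraction changes; recorded
  explicitly because isoforms whose monosome association moves while input
  and polysome hold still do not fit the other categories.
* **steady** — nothing changes.

The rules are applied in that order, so a transcriptional call always takes
precedence over a translational one: the repressed/derepressed sets are by
construction isoforms with steady total abundance. Isoforms undetected in
input remain eligible for the polysome rules — detection of low-abundance
mRNAs is more sensitive in the polysome fraction than in total RNA — and the
summary reports how many derepressed calls fall below the input detection
threshold.

## The per-isoform contrast

Each fraction is tested separately with a two-sided test on
`log2(abundance + pseudocount)` across replicates, comparing stage B (later)
to stage A (earlier). The log2 fold change reported is
`log2((mean_B + pseudocount) / (mean_A + pseudocount))` on the raw scale, and
q-values are Benjamini–Hochberg adjusted within the fraction (the three
fractions are three separate testing families; a single family across all
contrasts can be assembled by the caller from the returned p-values if
wanted). A direction (`up`/`down`) is assigned when `q <= alpha`, with
`alpha = 0.05` as the default level.

Two statistics are available:

* `method = "moderated"` (default): limma's empirical-Bayes moderated t with
  a mean–variance trend, fitted to the log2 values. With the 2–3 replicates
  per stage that polysome-profiling studies typically have, a per-isoform
  variance estimate carries only ~4 degrees of freedom; sharing variance
  information across isoforms is the standard remedy and is what makes
  fold-4 effects recoverable after FDR control at this replication level.
* `method = "welch"`: textbook Welch's t with Welch–Satterthwaite degrees of
  freedom, per isoform, no information sharing. It is fully self-contained
  and is the statistic used for the fraction-profile comparisons below; as a
  genome-wide screen at n = 3 it is substantially underpowered, which is the
  reason it is not the default.

Degenerate rows (zero variance in both groups) follow a fixed convention:
equal means give `t = 0, p = 1`; separated constant groups give `p = 0`
under `"welch"`; both are flagged in the `degenerate` column.

The **detection threshold** (default: mean abundance ≥ 1 in at least one
stage, in FPKM-like units) has no published reference value; 1 FPKM is the
conventional rule of thumb for "reliably detected" in bulk RNA-seq. It is a
visible parameter of `test_contrast()`, `detection_filter()` and
`run_config()`, and it only affects the `detected_*` bookkeeping — never
eligibility for the polysome rules.

## Compositional analysis of fraction profiles

qPCR-based profiles over the four gradient groups — free (F), monosome (M),
light polysome (LP), heavy polysome (HP) — are compositions: only the
relative allocation of a transcript across the gradient is meaningful. The
analysis therefore

1. applies the **closure operator** (each component divided by the row
   total, so components sum to 1) per replicate;
2. computes a **fraction difference** such as HP − F per replicate — a
   higher mean difference means greater relative abundance in the minuend;
3. compares the per-replicate differences between two conditions with
   **Welch's t-test**, two-sided, unpaired.

Closure is idempotent and scale-invariant, and all pairwise differences of
closed profiles lie in [−1, 1]; these invariants are asserted to 1e-12 in
the test suite. Computing differences per replicate and then testing across
replicates is the only reading consistent with a t-test between conditions;
testing differences of condition means would leave no residual degrees of
freedom. No correction is applied across the six possible fraction pairs by
default, matching the nominal-significance convention for these small
targeted comparisons; `bh_adjust()` is available when a family-wise view is
wanted.

qPCR quantification uses the Livak ΔΔCt method: `dCt = Ct_target −
Ct_reference` per sample (e.g. Gapdh as reference), condition means of dCt
compared to the control condition, and `fold = 2^(−ΔΔCt)`; replicate spread
is reported as the standard deviation of dCt, the scale on which the data
are approximately normal.

## Permutation gene-set enrichment

The overlap between a gene list produced by the classifier (e.g. derepressed
isoform orthologs) and a disease gene set is tested against an empirical
null: `n_permutations` (default 10,000) same-size lists are drawn from the
background universe **without replacement**, and the p-value is the fraction
of draws whose overlap with the target set is at least the observed one
(ties count, per the "at least as many" rule). Identifier matching is exact
and case-sensitive; no ortholog or symbol conversion is attempted, so input
lists must already live in the universe's identifier space. Members outside
the universe are an error by default; `clip_to_universe = TRUE` intersects
first and warns, for workflows whose background was assembled independently
of the input lists.

Because this null is exactly the hypergeometric distribution,
`hypergeometric_tail()` provides the closed-form tail as an independent
oracle; the test suite verifies the permutation estimate against it to
within three Monte-Carlo standard errors at 100,000 draws. The literal
empirical rule can return p = 0; the reported `p_perm` preserves that
literal value (a multiple of `1/n_permutations`) together with the raw
exceedance count, while the displayed `neg_log10_p` uses the `(count + 1) /
(n + 1)` pseudocount so heatmaps stay finite. `pseudocount = TRUE` switches
`p_perm` itself to the pseudocounted form.

`enrichment_grid()` evaluates every (input set, target set) pair, deriving
an independent sub-seed per pair from the master seed, so the grid is
invariant to the order in which pairs are computed and adding a set never
perturbs the other cells.

## What the simulator emulates — and what it does not

`simulate_polysome_experiment()` reproduces the design of a two-stage,
three-fraction screen with three biological replicates per (stage, fraction)
cell and plants known states: transcriptional changes scale all fractions at
stage B, repression/derepression scales only the polysome fraction
(down/up), and `monosome_shift` scales only the monosome fraction. An
optional `mass_conserving` mode mirrors polysome gains by monosome losses
(truncated at zero), reflecting the cartoon of mRNA exchanging between the
two pools; it is off by default because the magnitude of that exchange is
not quantified by the data the model is based on. A configurable share of
derepressed isoforms is planted with input abundance far below the detection
threshold at both stages, so the "derepressed but undetected in total RNA"
class is exercisable end to end.

Noise is negative binomial with `variance = mu + dispersion * mu^2`
(`dispersion = 0.1`, `baseline_mean = 50` by default — a mid-expressed
transcript with ~32% biological CV, typical of bulk RNA-seq between
biological replicates; `dispersion = 0` gives Poisson). FPKM-like estimates
carry no published variance model, so the NB choice is the standard RNA-seq
stand-in, with a log-normal alternative (`noise_model = "lognormal"`,
matched coefficient of variation) as a robustness switch. The simulator does
**not** emulate: per-isoform mean heterogeneity, length/GC biases,
quantification uncertainty from read assignment, correlated noise between
fractions of the same spin, or partial-effect mixtures. Passing the recovery
tests therefore shows the pipeline is correct and well calibrated under a
clean generative model, not that real data meet its assumptions.

Simulated gradient profiles (`simulate_fraction_profiles()`) move
`shift_delta` of mass from F to HP in the second condition and apply
multiplicative log-normal noise; with the default `noise_sd = 0.05` (±5%
per-component measurement error, a realistic qPCR-to-qPCR spread) and three
fractionations per condition, a 0.2 shift is detected by the HP − F Welch
test in essentially every run.

## Numerical and design choices

* **Pseudocount** 1.0 on the abundance scale before the log2 transform:
  stabilises the log at low FPKM-like values and makes `log2fc` defined for
  zeros. Configurable.
* **Seeds**: every stochastic entry point requires an explicit seed and
  restores the caller's RNG state; identical seeds give bit-identical
  output. Multi-step procedures (the pipeline, the enrichment grid) derive
  per-stage/per-pair sub-seeds deterministically from one master seed.
* **Stage order**: stages are free strings; the earlier stage is the one
  listed first in the sample sheet (or given first in `stages`).
  "Derepressed" always means an A→B increase in polysome association.
* **Largest-remainder allocation** converts state proportions into exact
  per-state counts, so planted compositions are deterministic.
* **Tie/degenerate conventions**: all-zero compositions are a degeneracy
  error, not silently dropped; constant-in-both-groups contrasts get
  `p = 1`; `q >= p` ordering is inherited from the step-up procedure.
* **Problem sizes in the checks**: classifier recovery uses 2,000 isoforms ×
  20 seeds at fold 4 and dispersion 0.1 (measured sensitivity ≈ 0.97, false
  discovery proportion ≈ 0.04 at `alpha = 0.05`); null calibration uses 200
  steady-only simulations of 300 isoforms; the permutation-vs-exact check
  uses 20 random configurations at 100,000 draws. These sizes give
  Monte-Carlo error well inside the asserted margins while keeping a full
  run in tens of seconds.

## Limitations

* Gene-level aggregation of isoform states, more than two stages, and
  translation-efficiency regression models are out of scope; the unit of
  analysis is one isoform in one two-stage contrast.
* The monosome_shift category is this package's explicit rendering of
  "changed in the gradient but not in polysomes or input"; studies differ in
  whether they report such a class at all.
* Count-model tests (negative-binomial GLMs) are deliberately not offered:
  the inputs are FPKM-like normalized abundances, for which a log-scale
  location test with moderated variances is the appropriate tool.
* The enrichment test treats gene sets as unstructured identifier sets;
  competitive ranked-list methods (GSEA-style) are a different question and
  are not provided.

## A minimal end-to-end run

```{r, eval = FALSE}
cfg <- run_config(
  out_dir = "polystate_demo", seed = 7,
  simulate = list(n_isoforms = 400, dispersion = 0.1, effect_fold = 4,
                  state_proportions = c(steady = 0.8, repressed = 0.1,
                                        derepressed = 0.1)))
manifest <- run_pipeline(cfg)
manifest$results$summary
```

The same configuration can live in a YAML file (see
`system.file("extdata", "demo_run.yaml", package = "polystate")`) and be run
with `run_pipeline("demo_run.yaml")`; rerunning either form reproduces every
output file byte for byte.
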