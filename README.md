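# polystate

Classification of mRNA isoforms into translational-regulation states from
two-stage, three-fraction polysome-profiling data, with the companion
analyses such a screen needs: compositional comparison of sucrose-gradient
fraction profiles, permutation gene-set enrichment against disease gene
lists, and ΔΔCt quantification of qPCR validation experiments. A
synthetic-data generator with planted ground truth makes every stage of the
pipeline verifiable without any sequencing data.

The package is written for transcriptomics analysts working on translational
control — developmental neurobiology being the motivating setting — who have
isoform-by-sample abundance tables (FPKM-like values) for input (total RNA),
monosome (40S-60S-80S) and polysome fractions at two stages, and want
reproducible, testable state calls rather than a one-off spreadsheet
analysis.

## The model

For each isoform and each fraction, stage B is compared to stage A on
`log2(abundance + pseudocount)` across replicates (empirical-Bayes moderated
t by default, textbook Welch's t as an option), with Benjamini–Hochberg FDR
control within the fraction and directions called at `q ≤ α` (default
α = 0.05). The three per-fraction calls are combined by strict precedence:

1. input changed → `transcription_up` / `transcription_down`
2. else polysome down → `repressed`
3. else polysome up → `derepressed`
4. else monosome changed → `monosome_shift`
5. else → `steady`

so the translational classes contain only isoforms with steady total
abundance. Fraction profiles (F, M, LP, HP) are first closed —
`x_i / Σx_j`, the closure operator of compositional data — then differences
such as HP − F are computed per replicate and compared between conditions
with two-sided Welch's t. Gene-set overlaps are tested against an empirical
null of same-size draws from a background universe without replacement,
`p = #{draws with overlap ≥ observed} / n_permutations`, with the exact
hypergeometric tail `Σ_{j≥k} C(T,j) C(B−T,n−j) / C(B,n)` available as an
analytic oracle. qPCR folds follow Livak: `ΔΔCt = mean ΔCt(condition) −
mean ΔCt(control)`, `fold = 2^(−ΔΔCt)`.

## Worked example

```r
library(polystate)

cfg <- system.file("extdata", "demo_run.yaml", package = "polystate")
manifest <- run_pipeline(cfg)   # writes TSVs + manifest.json to polystate_demo/
manifest$results$summary
```

```
  transcription_up transcription_down repressed derepressed monosome_shift
1                0                  0        35          40              0
  steady n_isoforms translationally_altered below_detection_derepressed
1    325        400                      75                           4
```

The demo simulates 400 isoforms with 10% planted repression and 10% planted
derepression at fold 4 (NB dispersion 0.1, 3 replicates per stage and
fraction, seed 7). Of the 80 planted translational isoforms the classifier
recovers 75 (`translationally_altered`, sensitivity 0.925) with 1 false call
(false-discovery proportion 0.013); 4 of the 40 derepressed calls are below
the input detection threshold, the planted rate. Rerunning the same config
reproduces every file byte for byte.

Individual stages are plain tibble-in/tibble-out functions that compose with
the pipe:

```r
sim <- simulate_polysome_experiment(simulation_config(
  n_isoforms = 400, seed = 7,
  state_proportions = c(steady = 0.8, repressed = 0.1, derepressed = 0.1)))

polysome <- test_contrast(sim$abundance, sim$samples, "polysome")
glance(polysome)          # up/down counts at alpha
autoplot(polysome)        # volcano plot

classify_states(
  test_contrast(sim$abundance, sim$samples, "input"),
  test_contrast(sim$abundance, sim$samples, "monosome"),
  polysome) |>
  summarize_states()

profiles <- simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1),
                                       shift_delta = 0.2, seed = 1)
fraction_difference_test(profiles, minuend = "HP", subtrahend = "F")

gs <- simulate_gene_sets(20, 5, 8, planted_overlap = 5, seed = 2)
permutation_enrichment(gs$input_set, gs$target_set, gs$universe,
                       n_permutations = 10000, seed = 3)
hypergeometric_tail(5, 5, 8, 20)   # 56/15504 ≈ 0.00361, the exact oracle
```

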