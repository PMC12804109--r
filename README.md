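# rateseqr

Kinetic analysis of pulse-only 4-thiouracil (4tU) metabolic labeling
("approach to equilibrium") RNA-seq experiments, for yeast
transcriptomics labs measuring how mutations change mRNA synthesis and
decay genome-wide.

Steady-state RNA-seq cannot separate synthesis from decay: a transcript
can stay flat because nothing changed, or because a synthesis defect is
buffered by slower turnover. In a pulse-only labeling experiment the
labeled pool of each transcript rises toward its steady-state level as

    Y(t) = Yeq * (1 - exp(-alpha * t)),

so the shape of the rise encodes the decay rate constant
`alpha = alpha_RNA - alpha_growth` (growth-corrected, with
`alpha_growth = ln2 / doubling time`). From `alpha` follow the half-life
`t1/2 = ln2 / alpha` and the synthesis rate
`k_syn = alpha * [mRNA]`, with per-cell abundance calibrated from
steady-state counts against a 60,000 molecules/cell transcriptome.
Whole-cell spike-ins (a second species mixed at a fixed 14:1 cell ratio)
provide normalization factors that preserve global shifts — the package's
central use case is detecting coupled global changes in synthesis and
decay (transcript buffering) between genotypes.

The package provides, module by module:

* a **synthetic-data generator** with known per-transcript ground truth
  (labeling time courses, steady-state libraries, reporter shutoff
  curves; negative binomial counting noise),
* **count-table handling**: species split, spike-in median-of-ratios size
  factors, normalization, the <15-reads-across-samples filter, exact TSV
  round-trips,
* **kinetic fitting**: deterministic variable-projection least squares of
  the labeling model per transcript, with growth-rate correction,
  saturation flagging and derived half-lives / abundances / synthesis
  rates,
* **genotype comparison**: fold changes, Wilcoxon rank-sum tests (exact
  by enumeration for small samples), the Spearman buffering correlation,
  top-percentile gene sets, BH adjustment, threshold selections and
  hypergeometric gene-set overlaps,
* **reporter quantification**: transcription-shutoff half-life fits and
  loading-normalized relative expression with Welch t-tests,
* a **pipeline layer** (`run_config()`, `pipeline_simulate()`,
  `pipeline_fit()`, `pipeline_compare()`) driving simulate → normalize →
  fit → compare from one YAML-serializable config.

## Worked example

Simulate a two-genotype experiment (wild type vs a slow-growing mutant
with a global 3.7-fold synthesis and 3.2-fold decay reduction), fit both
genotypes and summarize:

```r
library(rateseqr)

cfg  <- run_config(list(seed = 11, design = list(n_transcripts = 300)))
sim  <- pipeline_simulate(cfg, "simdata")
fits <- pipeline_fit(sim$labeling, sim$steady, cfg)
fits$WT
#> <rate_fit> genotype WT: 300 converged, 0 failed

res <- pipeline_compare(fits$WT$estimates, fits$mutant$estimates)
round(res$summary$decay$median_ratio, 2)      # WT/mutant median decay ratio
#> [1] 3.02
round(res$summary$synthesis$median_ratio, 2)  # WT/mutant median synthesis ratio
#> [1] 4.25
signif(res$summary$decay$p_value, 3)          # Wilcoxon rank-sum, decay
#> [1] 5.95e-45
round(res$summary$buffering$rho, 3)           # buffering correlation
#> [1] 0.934
round(median(fits$WT$estimates$half_life_min), 2)  # WT median half-life, min
#> [1] 2.91
```

Reading the output: the mutant's decay constants are recovered as ~3-fold
lower and its synthesis rates several-fold lower than wild type (at this
small desk scale the ratios carry a few tens of percent of sampling
noise; at 2000 transcripts they recover the simulated 3.2/3.7 factors to
within ~10%). The strong positive Spearman correlation between
per-transcript decay and synthesis fold changes is the transcript
buffering signature: transcripts losing the most synthesis also decay the
most slowly, keeping steady-state levels comparatively stable. The WT
median half-life of ~2.9 min reflects the simulated decay-rate
distribution (median 0.259 min^-1, i.e. 2.7 min).

Per-transcript caveat: fits flagged `saturated` are at the identifiability
ceiling of the 6–90 min labeling grid and mean "at least this fast" —
see the methods vignette (`vignettes/rateseq-kinetics.Rmd`) for the
model, noise limits and design choices.

## Acceptance script

`scripts/acceptance.R` regenerates the package's headline numbers from
scratch — it simulates fresh data at 2000 transcripts, runs the full
filter/normalize/fit/compare pipeline, and reports the recovered
WT/mutant median synthesis-rate ratio, the WT/mutant median decay-rate
ratio, and the wild-type median decay constant, writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All simulation randomness derives from `--seed`.
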