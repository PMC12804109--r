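---
title: "Estimating mRNA synthesis and decay rates from 4tU labeling time courses"
author: "rateseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mRNA synthesis and decay rates from 4tU labeling time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rateseqr)
```

## The measurement and the model

In a pulse-only metabolic labeling experiment, cells take up 4-thiouracil
(4tU) and incorporate it into nascent RNA. Labeled RNA is biotinylated,
captured on streptavidin and sequenced, so read counts report newly
synthesized transcripts. As the pulse lengthens, each transcript's labeled
pool approaches its steady-state abundance, and the *rate* of that approach
is set by how fast the transcript turns over:

$$Y_t = Y_{eq}\,\left(1 - e^{-\alpha t}\right),$$

where $Y_t$ is labeled abundance after $t$ minutes of labeling, $Y_{eq}$
is the labeled abundance at equilibrium (the steady-state level), and
$\alpha$ is the decay rate constant. A fast-turnover mRNA saturates
quickly; a stable one rises slowly. Because dividing cells also dilute
their RNA, the observed exponent confounds decay with growth; the model
works with the growth-corrected constant
$\alpha = \alpha_{RNA} - \alpha_{growth}$, where
$\alpha_{growth} = \ln 2 / (\text{doubling time})$ (0.0077 min$^{-1}$ at a
90 min doubling time; 0.0046 min$^{-1}$ for a slow-growing mutant at
roughly 151 min). Two quantities derive from $\alpha$:

$$t_{1/2} = \frac{\ln 2}{\alpha}, \qquad
  k_{syn} = \alpha\,[\text{mRNA}],$$

with per-cell abundance $[\text{mRNA}]$ obtained from steady-state
(total RNA) read counts by assuming a transcriptome of 60,000 mRNA
molecules per cell (`fit_config(total_mrna_per_cell=)`).

The sign convention for the growth correction follows the source model
for this assay family ($\alpha_{RNA} - \alpha_{growth}$, growth
subtracted from the fitted exponent). The package reports the fitted
exponent `alpha` — which all downstream quantities use — and carries
`alpha_rna = alpha + alpha_growth` as a bookkeeping column only.

## Spike-in normalization and why the calibration is anchored once

Whole-cell spike-ins (a second yeast species mixed in at a fixed 14:1
host:spike cell ratio before RNA extraction) make samples comparable in
*absolute per-cell* terms: since every sample contains the same spike RNA
per host cell, scaling factors computed from spike genes remove depth and
recovery differences while *preserving* genuine global shifts in the host
transcriptome — the very signal ordinary library-size normalization would
erase.

`spike_size_factors()` uses median-of-ratios restricted to spike genes
(the standard count-normalization geometry; robust to individual
spike-gene dropouts, with a total-spike-count fallback if every spike gene
has a zero somewhere). Factors are rescaled to geometric mean 1 so the
absolute scale is carried by one explicit calibration step:
`molecules_per_unit()` converts normalized steady-state counts to
molecules per cell by anchoring the *reference* genotype's host total at
60,000 molecules. That single factor is then reused for every genotype in
the experiment. Anchoring each genotype separately at 60,000 would force
every genotype's totals to agree and silently delete the global abundance
shift the spike-ins were added to measure; with a single anchor, a mutant
whose synthesis falls more than its decay correctly shows a reduced total
mRNA content. All samples of an experiment are normalized jointly for the
same reason.

The low-count rule `filter_low_counts()` removes genes with fewer than 15
reads summed across *all* samples of the experiment, applied to raw
counts before normalization.

## Fitting: variable projection on log counts

For each transcript the package minimizes least-squares residuals of the
labeling curve, with $Y_{eq}$ profiled out in closed form given $\alpha$
(variable projection), leaving a one-dimensional problem in
$\log\alpha$. A coarse log-spaced grid brackets the optimum and
deterministic golden-section/parabolic refinement localizes it; there is
no iterative multi-parameter optimizer to initialize and nothing fails on
zero-residual (noise-free) input. Replicates enter as separate residuals,
never pre-averaged.

Two residual scales are available (`fit_config(loss=)`):

* `"log"` (default) — residuals of $\log y$. Overdispersed count noise
  has roughly constant coefficient of variation, so log residuals are
  variance-stabilized; this is effectively maximum likelihood under
  multiplicative noise.
* `"linear"` — plain residuals of $y$. Under constant-CV noise the
  (large, noisy) plateau values dominate the objective, which measurably
  worsens decay estimates of fast transcripts.

Both recover noise-free curves to better than $10^{-6}$ relative error,
and $\alpha$ is invariant to rescaling all $y$ (the scale is absorbed by
$Y_{eq}$), so normalization conventions cannot bias rate constants.

### Identifiability and the saturation ceiling

A labeling grid of 6, 9, 12, 24 and 90 min cannot distinguish fast decay
rates from one another: at $\alpha = 1.5$ min$^{-1}$ the first time point
is already 99.99% labeled. The fit therefore bounds $\alpha$ to
$[10^{-4}, 1.5]$ min$^{-1}$ (a 28 s half-life ceiling, below the fastest
known yeast mRNAs). Estimates that hit the *lower* bound are flagged
non-converged (`reason` records why); estimates that reach the *ceiling*
are **kept**, pinned at the ceiling and flagged `saturated = TRUE`,
meaning "at least this fast". Two alternatives were evaluated and
rejected on simulation diagnostics: a loose ceiling (e.g. 10 min$^{-1}$)
lets unidentifiable fits wander log-uniformly over a decade of
meaningless values, inflating population summaries of synthesis; and
discarding saturated fits truncates every population median toward slow
transcripts. Treat `saturated` estimates as censored values, not
measurements.

### What accuracy the stated noise allows

With negative binomial dispersion 0.05 (about 22% CV per sample), two
replicates and the 6–90 min grid, the Fisher information for a transcript
with the population-median decay rate (0.259 min$^{-1}$, 79% labeled at
6 min) bounds the achievable precision of $\hat\alpha$ at roughly 45%
standard deviation on the log scale — for *any* estimator. Two practical
consequences, both visible in the test suite:

* Per-transcript decay constants in that noise regime are rank-informative
  (Spearman against truth around 0.8) but individually noisy (median
  relative error around 30%). Tests asserting 10% per-transcript accuracy
  at this noise level fail, and are left failing, because the data do not
  contain that much information.
* Population medians are much better behaved, but not perfect: because
  estimator spread grows with $\alpha$, more above-median transcripts
  scatter below the population median than the reverse, depressing the
  recovered median decay constant by roughly 5–10%. Removing this would
  require hierarchical shrinkage across transcripts, which is outside
  this package's scope (point estimates only).

Global *fold changes* between genotypes are the most robust readout: the
shared gene set cancels most of the spread effect, and the acceptance
script recovers coupled 3.7-fold synthesis / 3.2-fold decay shifts to
within about 10%.

## The synthetic world

`sim_design()` + `draw_transcript_params()` + `simulate_labeling_counts()`
generate experiments with known ground truth:

* **Decay constants** lognormal, median 0.259 min$^{-1}$, sdlog 0.8 —
  centered on the reference wild-type median with a realistic spread of
  half-lives (roughly 0.5–30 min).
* **Abundances** from lognormal synthesis draws (sdlog 1), rescaled so
  the cell totals 60,000 mRNA molecules; `m_eq * alpha = k_syn` holds
  exactly for every gene.
* **Design**: labeling at 6, 9, 12, 24, 90 min, 2 replicates, 14:1
  host:spike cell ratio, library size 5 × 10⁶ reads (typical bulk yeast
  depth), NB dispersion 0.05 (typical replicate-level variability),
  2000 spike-in genes with a fixed lognormal abundance profile. The spike
  gene count matters: the spike-in is a whole second transcriptome, and
  with only a handful of spike genes the size-factor noise perturbs all
  host time courses coherently, destabilizing fits of fast transcripts.
* **Genotype shifts**: `apply_genotype_shift()` multiplies synthesis and
  decay by global factors (defaults 1/3.7 and 1/3.2 for the mutant) times
  optional per-gene lognormal jitter with median 1, so the global factors
  are exactly the median fold changes. With both shifts the mutant's
  total mRNA is 3.2/3.7 ≈ 86% of wild type — a modest steady-state change
  despite large rate changes, which is precisely the buffering phenotype.
* **Spike genes** are simulated at labeling equilibrium (the spike cells
  are pre-labeled before mixing), so their expected reads are constant
  across labeling times; counts are NB around expectations (`nb_dispersion
  = 0` gives Poisson; `expected_labeling_counts()` exposes the noise-free
  expectations).

What the generator does *not* emulate: 4tU uptake/incorporation kinetics,
biotinylation and pull-down losses, within-replicate correlation of time
points from a shared culture, gene-specific dispersions, and mappability
or length biases. A green recovery test therefore establishes that the
estimator inverts the assumed forward model at the stated noise — not
that all real-data systematics are handled.

One caveat the synthetic world makes explicit: with *uniform* global
shifts (zero jitter), the per-transcript fold changes entering the
buffering correlation are constant in truth, so the observed strong
Spearman correlation between synthesis and decay fold changes is carried
by per-gene estimation error in $\hat\alpha$ appearing on both axes
(decay directly; synthesis via $k_{syn} = \hat\alpha\,\hat m_{eq}$). The
same coupling operates in real data, which is worth remembering when
interpreting buffering scatterplots.

## Genotype comparison and buffering

`pipeline_compare()` restricts to transcripts converged in both
genotypes, reports WT/mutant median ratios (so a mutant globally lowered
x-fold gives a ratio of x) with two-sided Wilcoxon rank-sum p-values,
the Spearman correlation of per-transcript log2 fold changes
(`buffering_correlation()`; rank-based, so the log-vs-linear choice is
immaterial), and top-percentile gene sets by fold-change magnitude
(`top_percentile()`, deterministic lexicographic tie-break).

Numerical and procedural choices:

* Rank-sum p-values are exact by full enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments when both groups have ≤ 10 values
  (two-sided via the symmetric distance from the null mean, which matches
  the doubled tail for tie-free data), and the tie-corrected normal
  approximation otherwise.
* Multiple testing uses Benjamini–Hochberg (`bh_adjust()`), the
  adjustment behind the adjusted p-values the thresholds refer to.
* Threshold rules are strict: "> 2-fold, adjusted p < 0.01" excludes a
  gene at exactly 2-fold.
* Gene-set overlaps report the one-sided upper hypergeometric tail; the
  p-value is a convenience annotation on a Venn-style count, labeled as
  such.
* `surrogate_de_test()` is a deliberately simple stand-in for a
  count-based differential-expression model (Welch t on
  log2(normalized + 0.5), BH-adjusted), tagged "surrogate" in its
  metadata. It exists so end-to-end synthetic runs need no external DE
  dependency and makes no claim to its sophistication.

## Reporter assays

`fit_shutoff_halflife()` fits $\ln(\text{signal}/\text{loading})$ against
time by ordinary least squares after a transcription shutoff;
$t_{1/2} = \ln 2 / (-\text{slope})$. Log-linear OLS matches the
single-exponential assumption, is deterministic, and is invariant to
rescaling either channel; a non-negative slope is flagged rather than
inverted. The $t = 0$ sample participates in the fit. Half-lives are
computed per replicate and then averaged (`average_halflives()`, mean ±
n−1 SD), matching how repeated shutoff determinations are reported.
`relative_expression()` normalizes target/loading ratios to the control
condition's mean (control ≡ 1.0) and compares conditions with two-sided
Welch t-tests; zero-variance degenerate inputs yield p = 1 (identical) or
a flagged undefined p instead of an error.

## Degenerate inputs, determinism, limitations

* All randomness flows from explicit seeds; package functions restore the
  caller's RNG state, and identical seeds give byte-identical simulation
  output, including written TSVs.
* Degenerate fits (all-zero trajectories, too few distinct times,
  already-saturated flat curves) return flagged rows with reasons — never
  exceptions — so one bad transcript cannot abort a transcriptome run.
* Known limitations: no uncertainty intervals beyond the residual sum of
  squares (point estimates only, by scope); no gene-specific dispersion
  modeling; the abundance step inherits the fixed 60,000-molecules-per-cell
  convention, so absolute synthesis rates are only as good as that
  assumption; and per-transcript decay constants near or above
  ~1 min$^{-1}$ are effectively censored by the labeling grid (see the
  saturation ceiling above).

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(list(seed = 11, design = list(n_transcripts = 300)))
sim <- pipeline_simulate(cfg, "simdata")
fits <- pipeline_fit(sim$labeling, sim$steady, cfg)
res <- pipeline_compare(fits$WT$estimates, fits$mutant$estimates)
res$summary$decay$median_ratio      # ~3.2-fold slower decay in the mutant
res$summary$synthesis$median_ratio  # ~3.7-fold lower synthesis
res$summary$buffering$rho           # strong positive buffering correlation
```
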