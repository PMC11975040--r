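---
title: "Functional scoring of deep mutational scanning screens with dmsfunc"
author: "dmsfunc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional scoring of deep mutational scanning screens with dmsfunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsfunc)
```

# The assay and the model

`dmsfunc` analyzes pooled deep mutational scanning (DMS) proliferation
screens of a tumor-suppressor ORF re-expressed in deficient cell lines.
Because re-expression of a *functional* allele suppresses proliferation,
selection acts against function: after growth competition, loss-of-function
(LOF) variants *enrich* and functional variants *deplete*. Each replicate
screen contributes one early and one late sequencing sample; variant
abundance is estimated from integer read counts (the output of an upstream
saturation-mutagenesis variant caller, consumed here as a counts table).

For a variant $v$ in replicate $r$ the abundance change is

$$\mathrm{L2FC}_{v,r} = \log_2
  \frac{f_{v,r}^{\mathrm{late}}}{f_{v,r}^{\mathrm{early}}},\qquad
  f_{v}=\frac{c_{v}+c_0}{\sum_u (c_u+c_0)},$$

with pseudocount $c_0 = 0.5$ by default. The upstream assay does not fix a
normalization, so both the pseudocount and the reference sample (the
per-replicate early gDNA timepoint by default) are configuration, not
constants.

## The rolling silent baseline

Silent (synonymous) variants carry the wild-type protein and define the
neutral behavior of the screen — but that behavior drifts along the coding
sequence (library representation, tile effects, local codon context). The
package therefore standardizes each variant against the silent variants
*near its own residue*: for every position $p$ it collects the silent
L2FCs within $\pm 2$ codons (a 5-codon window, truncated at the ORF ends)
and records their sample mean and $n-1$ SD. The functional z-score is

$$z_{v,r} = \frac{\mathrm{L2FC}_{v,r} -
  \overline{\mathrm{L2FC}}^{\,\mathrm{silent}}_{p(v),r}}
  {\mathrm{SD}^{\,\mathrm{silent}}_{p(v),r}},$$

computed per replicate and averaged across replicates; the cross-replicate
SD flags variants whose effect is context-dependent.

Numerical choices that the windowed estimator forces, all surfaced as
parameters:

* **Sparse windows.** A window with fewer than `min_silent = 3` silent
  variants expands symmetrically one codon at a time until satisfied (or
  the whole ORF is covered); positions still short are unscorable. An SD
  from fewer than three points is too unstable to divide by, and window
  borrowing is also what guarantees a baseline for residues that have no
  synonymous codon at all.
* **Zero SD.** An all-equal window would give infinite z; the
  replicate-wide silent SD is substituted and the position flagged
  (`sd_floored`). If that SD is itself zero the replicate is unusable.
* **Self-inclusion.** A silent variant's own window includes itself — the
  window is defined by position, not by identity. A leave-one-out mode
  exists (`leave_one_out = TRUE`) but is off by default.
* **Ends.** Windows are truncated, never mirrored: only physical
  neighbors inform the baseline.
* **$n-1$ denominators** everywhere a sample SD appears.

## Downstream classification

* `callLof()`: a variant is LOF when its cross-replicate mean z strictly
  exceeds 2.
* `residueIntolerance()`: each residue is summarized by the mean z of its
  (up to 19) missense substitutions; the cutoff is the mean plus two SDs
  of the residue averages, recomputed from the supplied score set — never
  a hard-coded number. Residues with fewer than `min_substitutions = 10`
  scored substitutions are excluded from cutoff estimation; whether they
  may still be flagged is the `cutoff_scope` switch, since either reading
  of "all residues" is defensible.
* `positionalProfile()` and `heatmapMatrix()` reproduce the standard
  per-class positional traces and the substitution-by-position matrix.

## Predictor benchmarking and the multi-omic quadrant test

Computational predictors score single-nucleotide variants, while the
screen scores codon-level variants. `expandToSnvs()` enumerates, for each
library variant, the single-base changes of its reference codon that
reproduce the same protein-level change; `mergeDmsPredictor()` resolves
each predictor SNV to the library variant it encodes (exact alternate
codon first, protein-level change as fallback) — matching is at the
protein-consequence level because a screen library has no genome
coordinates. Thresholds (CADD PHRED 20, AlphaMissense 0.56, REVEL 0.78)
are inclusive, matching the tools' published recommendations.
`rocAuc()` implements the tie-corrected midrank Mann–Whitney AUC.

`quadrantConcordance()` takes paired region/gene log2 fold changes
(e.g. differential chromatin accessibility matched to the annotated
gene's differential expression), filters both members at $|\mathrm{L2FC}|
> 1$, and counts sign quadrants. "Deviation from a uniform quadrant
distribution" is operationalized as independence of the two sign margins
in a 2×2 table — the only construction under which a Fisher exact test is
defined; margin skew alone is deliberately not penalized.
`fisherExact2x2()` computes the exact two-sided p by full hypergeometric
enumeration with the standard probability-mass rule.

# The synthetic screen generator

`simulateScreen()` emulates the structure of a real deposited screen:
three replicate cell-line contexts, early/late sampling, a codon library
with silent/missense/nonsense/frameshift classes, log-normal library
representation skew, selection against functional alleles, and
multinomial sequencing noise. The generative model is

$$a^{\mathrm{late}}_{v,r} \propto a^0_v\,
  (1 - e_v s_r)^{d}\; 2^{b(p_v)}\; g_{v,r},$$

where $a^0_v$ is log-normal (σ = 0.5), $e_v$ is residual activity
(1 functional, 0 LOF, intermediate for partial alleles), $d = 6$
doublings, $b(p)$ a sinusoidal positional offset (off by default), and
$g_{v,r}$ gamma-distributed multiplicative noise (shape 25, i.e. 20% CV —
a typical pooled-screen overdispersion; the assay itself reports none).
Counts are multinomial at $5\times10^5$ reads per sample. Fitness acts
multiplicatively per doubling because the assay is exponential growth;
the closed-form enrichment gap between LOF and functional variants is
$d\,\log_2\!\big(1/(1-s)\big) \approx 3.09$ at the defaults
($s = 0.3$), which the test suite checks against the simulated screens.

Two modeling decisions deserve emphasis:

* **Replicate heterogeneity is systematic, not resampled.** The replicate
  contexts of a real screen are *fixed* cell lines with different modes
  of gene disruption, so their selection strengths are modeled as fixed,
  evenly spaced multipliers spanning ±20% of the configured $s$
  (0.8, 1.0, 1.2 for three replicates). This keeps the expected
  enrichment gap deterministic (3.109 for three replicates, within 0.7%
  of the single-$s$ closed form) instead of adding a ±0.25 random offset
  per simulated screen, which resampling the multipliers would do.
* **What the generator does *not* emulate.** Real screens have tile-level
  batch effects, PCR jackpots and chimeras, variant-calling errors and
  position-correlated noise beyond a smooth trend. Passing recovery tests
  on these simulations therefore validates the *statistics* (calibration
  of the baseline, recovery of planted effects, closed-form behavior),
  not the upstream read processing.

Desk-scale defaults (ORF of 120 residues, depth $5\times10^5$) keep the
whole validation suite fast; a full-length screen is a configuration
change (`orf_length = 385`).

## Why the rolling window exists: an ablation

With a positional bias of 1 log2 unit, a position-naive baseline
mis-centers variants near the bias extremes. The package ships two
ablations of `silentBaseline()`:

* `"global-mean"` replaces the windowed mean with the replicate-wide
  silent mean but keeps the local scale model. This isolates the window's
  purpose, and under bias it inflates the null fraction of mean z > 2
  calls to roughly 25% while the rolling baseline stays near 0.1%.
* `"global-pooled"` also replaces the SD with the replicate-wide silent
  SD. Under a smooth sinusoidal bias this ablation *cannot* show the
  inflation even though it is just as miscalibrated: the bias variance
  enters the denominator, and the largest bias deviation divided by the
  inflated SD is bounded by $\sqrt 2 < 2$, so nothing crosses the z > 2
  threshold — the miscalibration is masked by a loss of power instead.
  This is why the mean-only ablation is the meaningful control for the
  windowing, and the pooled ablation is reported alongside it as a
  cautionary diagnostic.

```{r ablation, eval = FALSE}
sim <- simulateScreen(simConfig(suppression = 0,
                                lof_fraction_missense = 0,
                                positional_bias_amplitude = 1, seed = 1))
fp <- function(fs) mean(scoreTable(fs)$mean_z > 2, na.rm = TRUE)
fp(scoreScreen(simCounts(sim), sim@library))                       # ~0.001
fp(scoreScreen(simCounts(sim), sim@library, baseline = "global-mean")) # ~0.24
```

# Worked example

```{r example, eval = FALSE}
cfg <- simConfig(lof_cluster = list(c(50, 60)), seed = 7)
sim <- simulateScreen(cfg)
fs <- scoreScreen(simCounts(sim), sim@library)
calls <- callLof(fs)
prof <- residueIntolerance(fs)
evaluateRecovery(fs, simTruth(sim))
```

`runPipeline()` executes the same stages from a YAML configuration and
writes every artifact (counts, scores, baseline, LOF and residue tables,
heatmap matrix, optional concordance/ROC/quadrant reports) as
tab-separated files with a configuration echo; a thin subcommand script
(`inst/scripts/dmsfunc.R`) exposes it from a shell.

# Limitations

* The library enumerator is an emulation: real saturation-mutagenesis
  libraries do not document which codon encodes each missense change or
  how many synonymous codons each position received, so class
  compositions will differ from any particular deposited library.
* Frameshifts are modeled as single-base deletions at the first codon
  base, one per position; real frameshift alleles are heterogeneous.
* SNV-to-variant matching is protein-level; genomic-coordinate liftover,
  predictor execution and label-database retrieval are out of scope
  (predictor and label tables are consumed as files).
* The quadrant test treats pairs as independent; correlated peaks or
  multi-peak genes are not modeled.
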