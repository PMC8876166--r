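---
title: "Methods: integrative transcriptome–miRNome comparison of MSCs"
author: "mscmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative transcriptome–miRNome comparison of MSCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscmir)
```

# The design and the model

`mscmir` analyses a two-group bulk design with two molecular layers measured
on the same samples: transcript abundances in FPKM and mature-miRNA
abundances in TPM, with a reference tissue (iWAT-derived MSCs) and a test
tissue (pancreas-derived MSCs), eight biological replicates per group by
default. The package makes three modelling commitments, each chosen to stay
close to how this type of dataset is conventionally analysed:

* **Welch's *t*-test on raw abundances.** Each feature is tested for a group
  difference with the unequal-variance two-sided *t*-test and
  Welch–Satterthwaite degrees of freedom, directly on the FPKM/TPM values.
  No count model is fitted: the input is already length- and
  depth-normalised, and upstream quantification is out of scope. A
  `log_transform` switch applies the test to `log2(x + pseudocount)` instead,
  but it is off by default to mirror the direct test on abundances.
* **Unadjusted p-values.** Significance is unadjusted `p < alpha`
  (default 0.05) throughout, the convention of the exploratory screen this
  pipeline implements. Benjamini–Hochberg values can be added as an extra
  column (`adjust = TRUE`) but never drive any decision, so the headline
  counts always refer to the unadjusted rule.
* **Fold changes on group means with a pseudocount.**
  `log2fc = log2((mean_test + c)/(mean_ref + c))` with `c = 0.01`. Computing
  the ratio of group means (rather than the mean of per-sample log ratios)
  is monotone, robust to single zero observations, and defined for all
  non-negative data; the pseudocount only matters for features whose means
  approach zero, which the expression floor largely removes.

## Filtering and outliers

Features with mean abundance below 1 (FPKM or TPM) over all non-excluded
samples of both groups jointly are removed before testing; a feature at
exactly the floor is retained. Sample exclusion is always explicit: the
sample sheet carries an `excluded` column, and `flag_outlier_samples()` only
*advises*, flagging samples whose median Spearman correlation to the others
falls below 0.8. The criterion by which the original study excluded its one
miRNA outlier sample is not recorded anywhere, so this flag is a documented,
reproducible stand-in, not a reconstruction.

## Degenerate features

Zero variance in both groups is not an error: with equal means the feature
is a perfect null (`t = 0`, `p = 1`); with unequal means both variances are
floored at machine epsilon, which yields a near-zero p-value, and the
feature is flagged in the `degenerate` column so downstream users can see
that the inference there rests on the floor, not on replication.

## Transcript-to-gene collapsing

A gene is differentially expressed (a DEG) when at least one of its
transcripts is significant. Direction is inherited when all significant
transcripts agree in sign and is `discordant` otherwise; discordant genes
are reported but excluded from every direction-dependent step (the
consistency filter, the secretome split, enrichment direction z-scores),
because no single direction is defined for them.

# miRNA integration

The integration rule is deliberately minimal: a validated miRNA→gene edge is
retained when the miRNA is significant, the gene is a DEG with a coherent
direction, and the two fold changes are anti-correlated in sign — the
repressive mode of miRNA action. No expression correlation across samples is
computed; only group-level fold-change signs enter, so the filter is exactly
reproducible from the two differential tables. Pairs with
|gene log2FC| > 1.5 are flagged `strong`; miRNAs with `p < 0.05` and
|log2FC| ≥ 2 are additionally reported as tissue-exclusive (a reporting
overlay — the filter itself uses all significant miRNAs). Interaction tables
from several databases are merged by union with provenance carried through,
and miRNA identifiers are matched exactly (arm-specific, e.g. miR-204-5p);
family expansion is a data-preparation concern, not an analysis step.

The headline integration statistic, `fraction_degs_explained`, is the number
of distinct genes in retained pairs divided by the number of *measured*
DEGs. Because the DEG set at unadjusted α = 0.05 contains an α-level share
of false-positive genes, this fraction systematically underestimates the
true coupled fraction by the factor (true DEGs)/(measured DEGs) — about
0.8 under the default simulation settings. This is a property of the
statistic as defined (the same dilution is present when it is computed on
real data), not of the implementation; the synthetic-data tests document it
quantitatively.

# Enrichment

Over-representation per term is the one-sided hypergeometric upper tail
`P[X >= k]` with the universe defaulting to the *expressed* set (features
surviving the floor), in the spirit of a detected background. Gates follow
the DAVID-style convention: overlap count ≥ 10 for DEG queries and ≥ 3 for
miRNA-target queries, fold enrichment strictly above 2, unadjusted
`p < 0.05`; the `passes` column is exactly the conjunction of the three.
The EASE variant (tail evaluated at `k − 1`) is available as a switch for
users who want DAVID's more conservative score. Terms are signed with the
GO-circle z-score `(#up − #down)/sqrt(#up + #down)` over the overlapping
genes' directions; the overlap-empty case is defined as 0. Only
over-representation is tested; depletion, GO-graph topology and web-service
calls are out of scope. P-values below 2.2e-16 are reported at full computed
precision — the conventional "p < 2.2e-16" is a display floor, not a value.

The marker-overlap test ranks genes by mean abundance over all samples with
a deterministic lexicographic tie-break, takes the top 1000, and applies a
one-sided Fisher exact test. The reported odds ratio is the sample odds
ratio `(a·d)/(b·c)` — chosen over the conditional-MLE estimate that
`fisher.test()` prints because it is the closed-form quantity users can
recompute from the four printed cells; with a zero cell it is reported as
infinite with a flag (a Haldane +0.5 correction is optional).

# qPCR

Relative expression is `2^(−ΔCt)` against a reference gene measured in the
same sample (default *Eef2*). Group summaries are reported both as the
geometric mean (arithmetic mean of ΔCt, then transformed — the natural
summary on the method's log scale) and the arithmetic mean of the relative
expressions; the two diverge as within-group ΔCt variance grows, which is
itself useful diagnostic information. Efficiency-corrected models are out of
scope.

# The synthetic-data generator

`simulate_dataset()` is first-class, tested code: it is the package's
substitute for the raw study data, which lives behind an external accession
and database snapshots and is not desk-reproducible. It emulates:

* log-normal baseline abundances, log2-baseline ~ N(3, 2) — under which
  about 93% of features pass the mean ≥ 1 floor, so filtering is genuinely
  exercised;
* 8 samples per group with multiplicative log-normal noise of CV 0.3
  (mean-one, so effects are unbiased on the abundance scale);
* true group effects applied multiplicatively (`2^δ`) to test-group samples,
  with |δ| ~ 1 + Exponential(mean 1) and random sign, on 20% of genes and
  10% of miRNAs (every transcript of a gene inherits the gene's effect, so
  collapsing is exercised without artificial discordance; a
  `discordant_fraction` switch injects sign-flipped transcripts on demand);
* repressive coupling: 40% of DE genes are driven by a DE miRNA; the driven
  gene's effect has magnitude `0.75·|δ_miRNA| + N(0, 0.1)`, floored at 0.25,
  with the sign forced opposite the driver's. The floor-and-force
  construction guarantees the ground-truth invariant that every coupled pair
  is sign-opposite (an additive-noise formulation could flip signs for weak
  drivers);
* an interaction table of the true edges plus five decoy edges per miRNA,
  decoys attached to non-DE genes only, so the consistency filter has a
  populated rejection region;
* gene sets in which five designated terms draw 60% of their members from
  true DE genes (null terms sample uniformly), a secreted-gene list (12% of
  genes), and a marker list sampled with probability increasing steeply in
  baseline abundance so the top-expressed overlap test has signal.

One integer seed drives a single pseudo-random stream in a fixed draw order;
a fixed seed makes every emitted file byte-identical, which the tests assert
with checksums. The infeasibility guard rejects configurations whose coupled
genes exceed `n_DE_miRNAs × max_targets_per_mirna` (default 20 per miRNA).

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: heavy-tailed and zero-inflated abundance
distributions, sample-level batch effects, correlated noise between the two
layers beyond the designed coupling, miRNA families with shared seeds, and
annotation errors. Conclusions about calibration and recovery transfer to
real data only to the extent that the log-normal, independent-noise picture
holds.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 600–5000 features and the
default 8 + 8 samples: large enough that binomial error on a type-I estimate
at α = 0.05 over 5000 features is ±0.003, small enough that the whole suite
runs in a few minutes on one CPU. The exhaustive enrichment oracle covers
every contingency configuration with universe size ≤ 60 (about 1.15 million
(N, K, n, k) combinations) against direct probability-mass summation written
with `lchoose`, independent of the `phyper` path used by the implementation;
agreement is required to 1e-10. Welch statistics are computed vectorised
from row means and variances and are cross-checked feature-by-feature
against `stats::t.test` in the unit tests. Ties in abundance ranking are
broken lexicographically; equal fold changes in secreted-candidate ranking
likewise — every ordering the package emits is deterministic.

# Known limitations

* The Welch test on raw FPKM/TPM is the design being reproduced, not the
  state of the art for RNA-seq; count-based shrinkage models are explicitly
  out of scope.
* `fraction_degs_explained` inherits false-positive dilution from its
  measured-DEG denominator (see above); at high true coupling the recovered
  fraction plateaus below the simulated coupling fraction.
* Direction consistency is a sign filter on group-level fold changes; it
  cannot distinguish direct repression from co-regulation.
* The secretome and marker analyses are exactly as informative as the
  user-supplied gene lists; the package performs no sequence-based secretion
  prediction.
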