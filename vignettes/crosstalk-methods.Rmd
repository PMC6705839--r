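---
title: "Methods: moderated-t differential expression, permutation GSEA and multi-treatment overlap accounting"
author: "nrcrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated-t DE, permutation GSEA and overlap accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrcrosstalk)
suppressPackageStartupMessages(library(SummarizedExperiment))
```

# The analysis problem

Nuclear receptors (NRs) such as FXR, LXR and PPAR&alpha; are
ligand-activated transcription factors that regulate overlapping branches
of hepatic metabolism. A recurring question in multi-treatment
transcriptomic designs is *where* the cross-talk between such regulators
lives: do different ligands regulate the **same genes**, or different genes
that converge on the **same pathways**? `nrcrosstalk` implements a complete
pipeline for answering that question in a design with several ligand
treatments, shared vehicle/untreated controls, and two sampling time points
(an early one capturing direct target genes, a late one capturing
downstream cascades):

1. **Preprocessing** — collapse a probe-level log2 expression matrix to one
   row per gene symbol.
2. **Differential expression** — a per-time-point five-group linear model
   with empirical-Bayes moderated t-statistics, testing each treatment
   against a pooled control group.
3. **Gene-set enrichment** — a weighted Kolmogorov–Smirnov running-sum
   statistic on |t|-ranked lists, with a *sample-permutation* null that
   reruns the entire model at every iteration.
4. **Cross-talk accounting** — disjoint overlap partitions of DE genes and
   enriched pathways by exact ligand subset, time-profile summaries,
   category cross-tabulations, activation/inhibition ratios and
   leading-edge core-gene counts.
5. **Synthetic data** — a generator that emulates the design with planted
   effects and planted enriched sets, used for parameter-recovery and
   error-rate validation throughout the test suite.

# Probe collapsing

Probes without a gene symbol are discarded. When several probes map to one
symbol, the probe with the highest unbiased sample variance across the
arrays of a configurable time point (default 4h) is kept: the
highest-variance probe is the most informative isoform proxy for a
*differential* analysis, where a flat probe contributes nothing regardless
of its mean level. Two numerical choices are deliberate:

* the variance is the unbiased (n−1) estimator — the convention is
  configurable in spirit but fixed in v1;
* variance ties keep the lexicographically smallest probe identifier, so
  the result never depends on annotation order.

Missing values are rejected outright: the upstream normalization (RMA-style
summaries) produces complete matrices, and silent imputation would be worse
than an error.

# The linear model and moderated t

For each time point the samples form five groups: the four ligand
treatments and one control group pooling DMSO vehicle and untreated samples
(`poolControls()`). Pooling is valid when vehicle and untreated cells share
a common expression baseline; the synthetic generator enforces this by
construction and exposes a `dmsoOffset` switch to stress-test the
assumption. The model is fitted in its group-mean parameterization
(`fitGroups()`), which is exactly least squares on a one-hot design:
per-gene group means, residual variance $s^2_g$ and residual degrees of
freedom $d = n - 5$.

Gene-wise variances are moderated toward a scaled inverse chi-square prior
with parameters $(d_0, s_0^2)$ estimated by moment matching on the log
variances (`estimateModeration()`). With
$e_g = \log s^2_g - \psi(d/2) + \log(d/2)$:

$$\psi'(d_0/2) = \max\!\big(0,\ \widehat{\mathrm{var}}(e) - \psi'(d/2)\big),
\qquad
s_0^2 = \exp\!\big(\overline{e} + \psi(d_0/2) - \log(d_0/2)\big),$$

where $\psi$, $\psi'$ are the digamma and trigamma functions and the
trigamma equation is solved by Newton iteration (`trigammaInverse()`). When
the observed spread of log variances does not exceed what sampling noise
alone explains, $d_0 = \infty$ and $s_0^2 = \exp(\overline e)$, the
geometric-mean-consistent limit. Genes with $s^2_g = 0$ carry no
log-variance information and are excluded from *estimation*, but are still
moderated (their posterior variance is positive whenever $d_0 > 0$).
Estimation requires at least 100 genes with positive residual variance;
below that the moment estimates are unreliable and the function refuses
rather than guessing.

The moderated statistic for a treatment-versus-control contrast is

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
\tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{1/n_t + 1/n_c}},$$

with two-sided p-values from a t distribution on $d + d_0$ degrees of
freedom (normal at $d_0 = \infty$; at $d_0 = 0$ the statistic reduces to
the ordinary pooled-variance t). Per-contrast Benjamini–Hochberg adjustment
and a configurable threshold (default adjusted p < 0.05, no fold-change
filter) produce the DE calls. The DE threshold is a package default chosen
by field convention — the cross-talk accounting downstream is threshold
agnostic in structure, and a `pool` switch allows adjusting all four
contrasts as one family for sensitivity analysis.

# Weighted KS enrichment with a sample-permutation null

Gene sets are first intersected with the analyzed universe, then sets with
fewer than 10 or more than 500 remaining genes are dropped (inclusive
bounds). Genes are ranked by decreasing $|\tilde t|$ and the same
$|\tilde t|^q$ (default $q = 1$; $q = 0$ gives the classic unweighted KS
statistic) serves as the weight. The running sum gains
$w_i / \sum_{j \in S} w_j$ at members and loses $1/(N - N_S)$ at
non-members; the enrichment score (ES) is the **maximum** of the running
sum and the peak index is the smallest rank attaining it. Only the positive
deviation is scored: because ranking is by absolute t, depletion at the top
of the list is not a meaningful signal for positively enriched pathways,
and the signed two-sided variant is deliberately out of scope. The
**leading edge** — the set members at or before the peak — identifies the
genes driving the signal.

The null distribution is built by sample permutation: at each of `nPerm`
iterations (default 500, per time point) the sample-to-group assignment is
shuffled uniformly among assignments preserving group sizes, and the
*entire* pipeline — group-mean fit, re-estimation of the moderation prior,
moderated t for all four contrasts, re-ranking, scoring of every set — is
rerun on the permuted labels. Permutations are drawn with replacement (no
enumeration or deduplication). The empirical p-value of a set is the
proportion of permutations with a **strictly** higher null ES than
observed; no pseudo-count is added by default (a `pseudoCount` option gives
the $(1+k)/(1+B)$ estimator for users needing strictly positive p-values),
and no cross-set ES normalization is performed — the per-set proportion is
the estimator, exactly. Raw p-values of all sets across the four contrasts
of one time point are pooled into a single BH family (`adjustGlobal()`),
and a set is called (potentially) enriched when its adjusted p-value is
strictly below 0.2 — a deliberately permissive screen whose liberal
threshold reflects the coarse granularity of permutation p-values at
moderate `nPerm`.

Determinism: permutation $b$ uses seed `seed + b`, so any single iteration
is reproducible in isolation and the whole pipeline is bit-reproducible
given (data, config, seed).

# Cross-talk accounting

DE and enrichment calls per (ligand, time point) become a membership table;
each entity present for at least one selected ligand is assigned to exactly
one disjoint class: the exact subset of selected ligands affecting it.
**Sharing is computed on the union over time points** — an entity is shared
by two ligands if both call it at *any* time point, not necessarily the
same one. This convention is what makes per-ligand totals consistent with
time-combined classes in the summary tables. On top of the partition the
package derives per-ligand sharing tables, time-profile summaries
(4h only / both / 24h only), category cross-tabulations against a
user-supplied pathway-to-category map (unmapped pathways default to
"Other"; automatic classification from pathway-database hierarchies is out
of scope), activation/inhibition ratios per class-ligand connection, and
leading-edge core genes — genes recurring in at least
$\lceil 0.10 \times n_\text{pathways}\rceil$ leading edges of a category
(ceiling, because "at least 10%" acts on integer counts).

Further conventions, each genuinely open and decided once:

* *Direction conflicts* (up at 4h, down at 24h): the 24h direction is
  reported and the gene is flagged as a conflict; a single ratio per
  connection needs a single direction, and the later time point reflects
  the consolidated response.
* *Percentages* are printed to one decimal and computed on exact integer
  rationals; an exact .x5 tie rounds down in the one-decimal tables
  (matching the summary-table convention) and away from zero in integer
  coverage summaries.
* *Strong regulation* in the annotation helper means |log2 fold change|
  strictly above 1.2 **among DE genes**; the DE gate precedes magnitude,
  so a large but non-significant fold change stays "unchanged". The
  threshold is on the log2 scale and configurable.

# The synthetic-data generator

`simulationConfig()` defaults encode the emulated design: two time points
(4h, 24h), six conditions — FXR-L, LXR-L, PPARa-L, CDCA, DMSO, untreated —
with three biological replicates each (36 arrays), planted effects
additive on the log2 scale, and gene-wise true variances drawn from
$s_0^2\, d_0 / \chi^2_{d_0}$. Defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `nGenes` | 5000 | the package's default desk-scale problem size; large enough for stable moment estimation of the variance prior |
| `d0True`, `s0sqTrue` | 4, 0.09 | moderately heavy-tailed variance prior around a residual sd of 0.3, typical of log2 microarray intensities |
| `lfcMean`, `lfcSd` | 1, 0.5 | planted \|log2 fold change\| is \|N(1, 0.5)\|; real effect-size magnitudes are not identifiable from printed summaries, so these are explicit, exposed choices |
| `fracDown` | 0.5 | activation and repression equally likely |
| `baselineMean`, `baselineSd` | 7, 2 | log2 intensity baselines in the usual microarray range |
| `probesPerGene` | (0.7, 0.2, 0.1) | most genes measured by one probe set, a minority by two or three |
| `fracUnmappedProbes` | 0.1 | a realistic share of unannotated probes for the collapsing step to discard |
| `dePartition` | `crosstalkPartition()` | a scaled-down planted overlap structure: a dominant FXR-L response, small LXR-L and PPARa-L responses, modest pairwise sharing, and CDCA overlapping FXR-L by 62% |
| `nGeneSets`, `setSizeRange` | 100, (10, 60) | desk-scale collection within the enforced 10–500 window |
| `fracPlantedSets`, `plantedSetDeFraction` | 0.1, 0.5 | planted sets draw half their members from a target treatment's affected genes |

The planted-effect partition honours its class counts *exactly*; effect
signs are drawn per gene with a shared sign across time points and
independent magnitudes per active time point. DMSO and untreated samples
are generated from the same null mean, so control pooling is valid by
construction; `dmsoOffset` deliberately breaks it. Replicate "batches" are
**not** modeled by default because the analyzed linear model has no batch
term; `batchSd` adds a per-(gene, replicate) random intercept for
robustness experiments. Planted gene sets cycle their target treatments
over those with enough affected genes to fill the DE share of a maximal
set.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: probe-level summarization artifacts and
spatial effects, correlated gene-gene expression (noise is independent
across genes, so permutation nulls are cleaner than on real arrays),
annotation errors, and treatment-specific variance changes. Recovery rates
on synthetic data are therefore upper bounds on real-data behaviour, not
estimates of it.

# Validation strategy and problem sizes

The test suite validates every stage against an independent route:
probe collapsing against a brute-force per-gene argmax; the group-mean fit
against per-gene `lm()`; moderated t against a direct formula oracle (to
1e-10) and against limma on heterogeneous-variance data; the moderation
moment estimator against its generating parameters (d0 within ±25%, s0²
within ±10% at 5000 genes) and against `limma::fitFDist`; the enrichment
score against explicit running-sum accumulation on 1000+ random fixtures
and a hand-enumerated five-gene example (ES = 7/15 at peak rank 2); the
permutation null against an end-to-end replay of its seeded iterations;
empirical p-value uniformity under a global null (KS < 0.1 at 200 sets ×
200 permutations); the DE false-call rate against its nominal level across
20 seeds; planted-set recovery (≥ 8 of 10 planted sets at the 0.2
threshold with 200 permutations); and the overlap partition against the
published summary tables' complete set arithmetic. Simulation sizes in the
suite (250–2000 genes, 10–200 sets, 8–200 permutations) are the package's
chosen validation scales: large enough for the statistical assertions'
tolerances, small enough to keep the suite fast.

# Known limitations

* One-sided positive ES only; preranked (gene-permutation) GSEA modes are
  out of scope.
* No array weights, duplicate-correlation, or trend/robust moderation
  variants.
* The five-group model assumes a complete design per time point; missing
  cells are an error, not handled by reweighting.
* Percentile granularity of permutation p-values is 1/`nPerm`; at the
  default 500 iterations the smallest nonzero p is 0.002.
* The category map is a manual input; the package ships no pathway
  database.

# Session info

```{r}
sessionInfo()
```
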