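# nrcrosstalk

Pathway-level cross-talk analysis for multi-treatment transcriptomics.

Nuclear receptors (NRs) such as FXR, LXR and PPARα are ligand-activated
transcription factors with overlapping metabolic programs. When several NR
ligands are profiled side by side against shared controls, the central
question is where their cross-talk lives: do treatments regulate the *same
genes*, or different genes converging on the *same pathways*?
`nrcrosstalk` implements the full pipeline for answering this in a design
with four ligand treatments (FXR-L, LXR-L, PPARa-L and the natural FXR
agonist CDCA), pooled DMSO/untreated controls, and two time points
(4h — direct targets; 24h — downstream cascades):

* **Probe collapsing** — one row per gene symbol, keeping each gene's
  highest-variance probe (variance computed on the 4h arrays, unbiased
  estimator, deterministic tie-breaks).
* **Moderated-t differential expression** — a per-time-point five-group
  linear model (four treatments + pooled control); empirical-Bayes
  variance moderation toward a scaled inverse-χ² prior with parameters
  (d₀, s₀²) estimated by moment matching on log residual variances
  (trigamma inversion by Newton iteration); contrast statistic
  t̃ = β̂ / (s̃ √(1/nₜ + 1/n_c)) with s̃² = (d₀s₀² + d s²)/(d₀ + d), p-values
  on d + d₀ degrees of freedom, per-contrast Benjamini–Hochberg calls.
* **Weighted-KS gene-set enrichment** — |t̃|-ranked, |t̃|-weighted
  running-sum score (positive deviation, smallest-peak convention), a
  **sample-permutation** null that reruns the entire linear model,
  moderation and ranking at each of 500 iterations, strict-inequality
  empirical p-values, globally pooled BH across the four contrasts of a
  time point, enrichment at adjusted p < 0.2, and leading-edge extraction.
* **Cross-talk accounting** — disjoint overlap partitions by exact ligand
  subset (union over time points), per-ligand sharing tables with
  one-decimal percentages, time-profile summaries, pathway-category
  cross-tabulations, activation/inhibition ratios and leading-edge
  core-gene counts.
* **Synthetic studies** — a generator emulating the 2 × 18-array design
  with planted effects, a scaled inverse-χ² variance prior and planted
  enriched sets, plus a machine-readable ground truth for recovery tests.

The central containers are Bioconductor S4 classes
(`ProbeExperiment`/`GeneExperiment` extend `SummarizedExperiment`); result
tables are plain data.frames.

## Worked example

Simulate a study, collapse probes, call DE genes, run permutation GSEA and
partition the calls by ligand subset:

```r
library(nrcrosstalk)

cfg <- simulationConfig(nGenes = 2000, nGeneSets = 50, seed = 42)
sim <- simulateStudy(cfg)        # $truth, $probes, $sets

genes <- collapseProbes(sim$probes, varianceTimePoint = "4h")
genes
#> class: GeneExperiment
#> dim: 2000 36
#> rownames(2000): G00001 G00002 ... G01999 G02000

de <- rbind(runDE(genes, "4h"), runDE(genes, "24h"))
table(contrast = de$contrast[de$de], time_point = de$time_point[de$de])
#>          time_point
#> contrast  24h  4h
#>   CDCA     17  12
#>   FXR-L   100  34
#>   LXR-L     2   2
#>   PPARa-L  11   2

gsea <- rbind(
  runGsea(genes, "4h",  sim$sets, nPerm = 100, seed = 42),
  runGsea(genes, "24h", sim$sets, nPerm = 100, seed = 43))

mt   <- buildMembership(asCalls(de), kind = "gene")
part <- partitionOverlaps(mt, c("FXR-L", "LXR-L", "PPARa-L"))
ligandSummary(part, "FXR-L")
#>                        label               class   n  pct
#> 1                      alone               FXR-L 121 96.8
#> 2             sh. with LXR-L         FXR-L+LXR-L   0  0.0
#> 3           sh. with PPARa-L       FXR-L+PPARa-L   4  3.2
#> 4 sh. with LXR-L and PPARa-L FXR-L+LXR-L+PPARa-L   0  0.0
```

The DE table mirrors the expected biology of the design: a dominant FXR-L
response that grows between 4h and 24h, small LXR-L/PPARa-L responses, and
a CDCA response overlapping FXR-L. The sharing table reads as: of the 125
genes regulated by FXR-L, 96.8% are FXR-L-specific and 3.2% are shared
with PPARa-L. Against the generator's ground truth, the enrichment screen
recovers every planted set at the 0.2 threshold:

```r
truth <- truthSets(sim$truth)
table(planted = truth$planted,
      called = tapply(gsea$enriched, gsea$set, any)[truth$set])
#>        called
#> planted FALSE TRUE
#>   FALSE    43    2
#>   TRUE      0    5
```

`runPipeline(pipelineConfig(...))` chains all stages (simulate-or-load →
preprocess → DE → GSEA → crosstalk) into an output directory with TSV/JSON
results and a manifest sufficient to re-run the analysis; configs can be
read from YAML with `readPipelineConfig()`.

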