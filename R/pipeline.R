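## End-to-end runner: simulate-or-load -> preprocess -> DE (both time
## points) -> GSEA (both time points) -> crosstalk, with a JSON manifest
## that suffices to re-run the pipeline. All randomness derives from one
## root seed, split deterministically per stage (and per permutation
## inside the GSEA stage), so every output file is reproducible
## bit-identically under a fixed config.

#' Pipeline configuration
#'
#' Either supply input paths (`exprPath` + `sheetPath`, optionally
#' `annotPath` for probe-level input, plus `gmtPath`) or a
#' \linkS4class{SimulationConfig} in `simulation` to generate inputs.
#'
#' @param exprPath,sheetPath,annotPath,gmtPath,categoryMapPath input file
#'   paths (`NULL` where unused).
#' @param simulation optional \linkS4class{SimulationConfig}; when set the
#'   input paths are ignored and a synthetic study is generated.
#' @param alphaDe DE threshold on the BH-adjusted p-value (default 0.05).
#' @param alphaGsea enrichment threshold (default 0.2).
#' @param nPerm sample permutations per time point (default 500).
#' @param weightExponent weight exponent of the running sum (default 1).
#' @param minSetSize,maxSetSize gene-set size window (defaults 10, 500).
#' @param varianceTimePoint time point whose arrays drive probe selection
#'   (default `"4h"`).
#' @param seed integer root seed.
#' @param outDir output directory.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(exprPath = NULL, sheetPath = NULL,
                           annotPath = NULL, gmtPath = NULL,
                           categoryMapPath = NULL, simulation = NULL,
                           alphaDe = 0.05, alphaGsea = 0.2, nPerm = 500,
                           weightExponent = 1, minSetSize = 10,
                           maxSetSize = 500, varianceTimePoint = "4h",
                           seed = 1, outDir = "crosstalk-out") {
  stopifnot(alphaDe > 0, alphaDe <= 1, alphaGsea > 0, alphaGsea <= 1,
            nPerm >= 1, minSetSize >= 1, minSetSize <= maxSetSize)
  if (is.null(simulation) && (is.null(exprPath) || is.null(sheetPath) ||
                              is.null(gmtPath)))
    stop("either a simulation config or exprPath + sheetPath + gmtPath ",
         "must be given")
  if (!is.null(simulation)) stopifnot(is(simulation, "SimulationConfig"))
  structure(list(
    exprPath = exprPath, sheetPath = sheetPath, annotPath = annotPath,
    gmtPath = gmtPath, categoryMapPath = categoryMapPath,
    simulation = simulation, alphaDe = alphaDe, alphaGsea = alphaGsea,
    nPerm = as.integer(nPerm), weightExponent = weightExponent,
    minSetSize = as.integer(minSetSize), maxSetSize = as.integer(maxSetSize),
    varianceTimePoint = varianceTimePoint, seed = as.integer(seed),
    outDir = outDir), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; an optional
#' `simulation` mapping mirrors [simulationConfig()] arguments (the
#' `dePartition` key, if present, is a table with columns `treatments`,
#' `profile`, `n`). Arguments supplied via `...` override file values.
#'
#' @param path YAML file.
#' @param ... overrides, as in [pipelineConfig()].
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    simArgs <- y$simulation
    if (!is.null(simArgs$dePartition))
      simArgs$dePartition <- do.call(
        rbind, lapply(simArgs$dePartition, as.data.frame))
    y$simulation <- do.call(simulationConfig, simArgs)
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: `simulate`/`load`, `preprocess`, `de` (each time point), `gsea`
#' (each time point), `crosstalk`. Results, inputs (when simulated) and a
#' manifest are written under `config$outDir`.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory stage results
#'   (`genes`, `de`, `gsea`, `crosstalk`, `manifest`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outDir
  for (d in file.path(out, c(".", "inputs", "genes", "pathways", "crosstalk")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  counts <- list()

  ## stage 1: simulate or load
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- .stage("simulate", simulateStudy(config$simulation))
    probes <- sim$probes; sets <- sim$sets; truth <- sim$truth
    .stage("simulate", {
      writeExpression(probes, file.path(out, "inputs", "expression.tsv"),
                      file.path(out, "inputs", "sample_sheet.tsv"),
                      file.path(out, "inputs", "annotation.tsv"))
      writeGmt(sets, file.path(out, "inputs", "gene_sets.gmt"))
      writeGroundTruth(truth, file.path(out, "inputs", "truth.json"))
    })
    say("simulate: ", nrow(probes), " probes x ", ncol(probes), " samples, ",
        length(sets), " gene sets")
  } else {
    probes <- .stage("load", readExpression(config$exprPath,
                                            config$sheetPath,
                                            config$annotPath))
    sets <- .stage("load", readGmt(config$gmtPath))
    say("load: ", nrow(probes), " rows x ", ncol(probes), " samples, ",
        length(sets), " gene sets")
  }
  counts$probes <- nrow(probes)
  counts$samples <- ncol(probes)
  counts$sets_input <- length(sets)

  ## stage 2: preprocess (skip collapsing when input is already gene level)
  genes <- .stage("preprocess", {
    if (is(probes, "ProbeExperiment"))
      collapseProbes(probes, config$varianceTimePoint)
    else probes
  })
  writeExpression(genes, file.path(out, "genes.tsv"))
  say("preprocess: ", nrow(genes), " genes retained")
  counts$genes <- nrow(genes)

  timePoints <- unique(sampleSheet(genes)$time_point)
  treatments <- intersect(c("FXR-L", "LXR-L", "PPARa-L", "CDCA"),
                          unique(sampleSheet(genes)$condition))

  ## stage 3: differential expression per time point
  de <- .stage("de", do.call(rbind, lapply(timePoints, function(tp)
    runDE(genes, tp, alpha = config$alphaDe, treatments = treatments))))
  for (tp in timePoints) for (tr in treatments) {
    sub <- de[de$time_point == tp & de$contrast == tr, ]
    .writeTsv(sub, file.path(out, "genes",
                             paste0(gsub("[^A-Za-z0-9]", "_", tr), "_",
                                    tp, ".tsv")))
  }
  counts$de_calls <- sum(de$de)
  say("de: ", counts$de_calls, " DE calls across ",
      length(timePoints) * length(treatments), " contrasts")

  ## stage 4: GSEA per time point (seed split: time-point index * 10^6)
  gsea <- .stage("gsea", do.call(rbind, lapply(seq_along(timePoints),
    function(i) runGsea(genes, timePoints[i], sets,
                        nPerm = config$nPerm,
                        seed = config$seed + i * 1000000L,
                        alpha = config$alphaGsea,
                        q = config$weightExponent,
                        minSize = config$minSetSize,
                        maxSize = config$maxSetSize,
                        treatments = treatments))))
  for (tp in timePoints)
    .writeTsv(gsea[gsea$time_point == tp, ],
              file.path(out, "pathways", paste0(tp, ".tsv")))
  counts$sets_tested <- length(unique(gsea$set))
  counts$enriched_calls <- sum(gsea$enriched)
  say("gsea: ", counts$sets_tested, " sets tested, ",
      counts$enriched_calls, " enrichment calls")

  ## stage 5: crosstalk accounting
  ct <- .stage("crosstalk", {
    geneMt <- buildMembership(asCalls(de), kind = "gene")
    pathMt <- buildMembership(asCalls(gsea), kind = "pathway")
    synth <- setdiff(treatments, "CDCA")
    res <- list(
      gene_partition_all = partitionOverlaps(geneMt, treatments),
      gene_partition_synth = partitionOverlaps(geneMt, synth),
      path_partition_all = partitionOverlaps(pathMt, treatments),
      path_partition_synth = partitionOverlaps(pathMt, synth))
    res$gene_profiles <- timepointProfileSummary(res$gene_partition_all)
    res$path_profiles <- timepointProfileSummary(res$path_partition_all)
    res$gene_ligand_tables <- lapply(setNames(synth, synth), function(lg)
      ligandSummary(res$gene_partition_synth, lg))
    res$path_ligand_tables <- lapply(setNames(synth, synth), function(lg)
      ligandSummary(res$path_partition_synth, lg))
    res$edges <- overlapEdges(res$gene_partition_synth, geneMt)
    if (!is.null(config$categoryMapPath)) {
      cmap <- readCategoryMap(config$categoryMapPath)
      res$categories <- categorize(res$path_partition_synth, cmap)
      res$category_coverage <- categoryCoverage(res$path_partition_synth, cmap)
    }
    res
  })
  .writeTsv(ct$gene_profiles, file.path(out, "crosstalk", "gene_profiles.tsv"))
  .writeTsv(ct$path_profiles, file.path(out, "crosstalk", "path_profiles.tsv"))
  .writeTsv(ct$edges, file.path(out, "crosstalk", "edges.tsv"))
  for (lg in names(ct$gene_ligand_tables))
    .writeTsv(ct$gene_ligand_tables[[lg]],
              file.path(out, "crosstalk",
                        paste0("genes_", gsub("[^A-Za-z0-9]", "_", lg), ".tsv")))
  summaryJson <- list(
    gene_counts = as.list(overlapCounts(ct$gene_partition_synth)),
    path_counts = as.list(overlapCounts(ct$path_partition_synth)),
    gene_profiles = ct$gene_profiles, path_profiles = ct$path_profiles)
  jsonlite::write_json(summaryJson, file.path(out, "crosstalk", "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("crosstalk: ", nrow(ct$gene_partition_all@assignment), " genes, ",
      nrow(ct$path_partition_all@assignment), " pathways partitioned")

  manifest <- list(
    package_version = as.character(packageVersion("nrcrosstalk")),
    seed = config$seed,
    config = config[setdiff(names(config), "simulation")],
    simulated = !is.null(config$simulation),
    stages = c("simulate/load", "preprocess", "de", "gsea", "crosstalk"),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(genes = genes, de = de, gsea = gsea, crosstalk = ct,
                 truth = truth, manifest = manifest))
}
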