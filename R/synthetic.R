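## Synthetic study generator: emulates a two-time-point, six-condition
## nuclear-receptor ligand experiment (3 biological replicates each) with
## planted treatment-specific and shared differential effects, gene-wise
## variances from a scaled inverse chi-square prior, probe-level redundancy,
## and planted enriched gene sets. Ground truth is machine readable so the
## downstream pipeline can be tested for parameter recovery.

.TREATMENTS <- c("FXR-L", "LXR-L", "PPARa-L", "CDCA")
.CONTROLS <- c("DMSO", "untreated")
.CONDITIONS <- c(.TREATMENTS, .CONTROLS)
.TIMEPOINTS <- c("4h", "24h")
.PROFILES <- c("early-only", "both", "late-only")

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the design of the emulated experiment: two time points
#' (4h, 24h), six conditions (four ligand treatments, DMSO vehicle and
#' untreated controls), three biological replicates each, gene-wise true
#' variances from a scaled inverse chi-square prior, and a planted
#' differential-expression partition with treatment-specific and shared
#' effects.
#'
#' @slot nGenes number of genes.
#' @slot probesPerGene probability over 1, 2 or 3 probe sets per gene.
#' @slot fracUnmappedProbes fraction of all probes carrying no gene symbol.
#' @slot replicates replicates per condition per time point.
#' @slot conditions ordered condition labels (treatments then controls).
#' @slot timePoints the two time-point labels.
#' @slot dePartition data.frame (`treatments`, `profile`, `n`): planted genes
#'   per exact treatment subset (labels joined by `"+"`) and time profile
#'   (`early-only`, `both`, `late-only`). Entries are disjoint classes.
#' @slot lfcMean,lfcSd planted |log2 fold change| is `|N(lfcMean, lfcSd)|`.
#' @slot fracDown probability a planted effect is negative.
#' @slot d0True,s0sqTrue variance-prior degrees of freedom and scale; true
#'   gene variances are `s0sqTrue * d0True / chisq(d0True)`.
#' @slot baselineMean,baselineSd gene baseline log2 intensity distribution.
#' @slot dmsoOffset optional mean shift of DMSO samples (default 0; a
#'   nonzero value stress-tests the control-pooling assumption).
#' @slot batchSd optional per-(gene, replicate) random batch intercept sd
#'   (default 0; the modeled linear design has no batch term).
#' @slot nGeneSets,setSizeRange,fracPlantedSets,plantedSetDeFraction gene-set
#'   collection parameters: collection size, uniform size range, fraction of
#'   sets planted around a treatment, and the fraction of each planted set's
#'   members drawn from that treatment's affected genes.
#' @slot seed root seed; all generator randomness derives from it.
#' @export
setClass("SimulationConfig", representation(
  nGenes = "integer", probesPerGene = "numeric", fracUnmappedProbes = "numeric",
  replicates = "integer", conditions = "character", timePoints = "character",
  dePartition = "data.frame", lfcMean = "numeric", lfcSd = "numeric",
  fracDown = "numeric", d0True = "numeric", s0sqTrue = "numeric",
  baselineMean = "numeric", baselineSd = "numeric", dmsoOffset = "numeric",
  batchSd = "numeric", nGeneSets = "integer", setSizeRange = "integer",
  fracPlantedSets = "numeric", plantedSetDeFraction = "numeric",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  p <- object@probesPerGene
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "probesPerGene must be 3 probabilities summing to 1")
  if (object@fracUnmappedProbes < 0 || object@fracUnmappedProbes >= 1)
    msg <- c(msg, "fracUnmappedProbes must be in [0, 1)")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be positive")
  dp <- object@dePartition
  if (nrow(dp)) {
    if (!all(c("treatments", "profile", "n") %in% colnames(dp)))
      msg <- c(msg, "dePartition needs columns treatments, profile, n")
    else {
      if (!all(dp$profile %in% .PROFILES))
        msg <- c(msg, "unknown time profile in dePartition")
      labs <- unique(unlist(strsplit(dp$treatments, "+", fixed = TRUE)))
      if (!all(labs %in% object@conditions))
        msg <- c(msg, "dePartition names a label outside conditions")
      if (anyDuplicated(paste(dp$treatments, dp$profile)))
        msg <- c(msg, "dePartition classes must be disjoint (no duplicate keys)")
      if (any(dp$n < 0)) msg <- c(msg, "dePartition counts must be >= 0")
      if (sum(dp$n) > object@nGenes)
        msg <- c(msg, "dePartition counts exceed nGenes")
    }
  }
  for (nm in c("lfcSd", "d0True", "s0sqTrue", "baselineSd"))
    if (slot(object, nm) <= 0 && nm != "lfcSd" ||
        (nm == "lfcSd" && slot(object, nm) < 0))
      msg <- c(msg, paste(nm, "must be strictly positive"))
  if (object@fracDown < 0 || object@fracDown > 1)
    msg <- c(msg, "fracDown must be in [0, 1]")
  if (object@fracPlantedSets < 0 || object@fracPlantedSets > 1)
    msg <- c(msg, "fracPlantedSets must be in [0, 1]")
  if (object@plantedSetDeFraction < 0 || object@plantedSetDeFraction > 1)
    msg <- c(msg, "plantedSetDeFraction must be in [0, 1]")
  if (length(object@setSizeRange) != 2L ||
      object@setSizeRange[1L] < 1L ||
      object@setSizeRange[1L] > object@setSizeRange[2L])
    msg <- c(msg, "setSizeRange must be positive with min <= max")
  if (length(msg)) msg else TRUE
})

#' Planted differential-expression partition with FXR/CDCA sharing
#'
#' Builds a `dePartition` data.frame for [simulationConfig()]. Counts are
#' per exact treatment subset and time profile. CDCA, the natural FXR
#' ligand, is planted so that `cdcaFxrShare` of its genes are shared with
#' FXR-L (emulating the strong overlap between the natural and synthetic
#' FXR agonists), the rest being CDCA-specific.
#'
#' @param fxrOnly,lxrOnly,pparOnly,fxrLxr,fxrPpar,lxrPpar,allThree named
#'   3-vectors of gene counts per profile `(early-only, both, late-only)`.
#' @param cdcaTotal total CDCA-affected genes.
#' @param cdcaFxrShare fraction of CDCA genes shared with FXR-L.
#' @return data.frame with columns `treatments`, `profile`, `n`.
#' @export
crosstalkPartition <- function(fxrOnly = c(31, 20, 102),
                               lxrOnly = c(0, 1, 2),
                               pparOnly = c(3, 1, 9),
                               fxrLxr = c(0, 1, 1),
                               fxrPpar = c(3, 2, 10),
                               lxrPpar = c(0, 0, 1),
                               allThree = c(0, 1, 0),
                               cdcaTotal = 52,
                               cdcaFxrShare = 0.62) {
  stopifnot(cdcaFxrShare >= 0, cdcaFxrShare <= 1)
  nShared <- round(cdcaFxrShare * cdcaTotal)
  nAlone <- cdcaTotal - nShared
  spread <- function(key, counts) {
    data.frame(treatments = key, profile = .PROFILES, n = as.integer(counts),
               stringsAsFactors = FALSE)
  }
  # CDCA counts get a late-heavy profile split like the synthetic ligands
  split3 <- function(n) {
    e <- floor(n * 0.2); b <- floor(n * 0.15); c(e, b, n - e - b)
  }
  dp <- rbind(
    spread("FXR-L", fxrOnly),
    spread("LXR-L", lxrOnly),
    spread("PPARa-L", pparOnly),
    spread("FXR-L+LXR-L", fxrLxr),
    spread("FXR-L+PPARa-L", fxrPpar),
    spread("LXR-L+PPARa-L", lxrPpar),
    spread("FXR-L+LXR-L+PPARa-L", allThree),
    spread("CDCA", split3(nAlone)),
    spread("FXR-L+CDCA", split3(nShared)))
  dp[dp$n > 0L, , drop = FALSE]
}

#' @rdname SimulationConfig-class
#' @param nGenes,probesPerGene,fracUnmappedProbes,replicates,conditions,timePoints,dePartition,lfcMean,lfcSd,fracDown,d0True,s0sqTrue,baselineMean,baselineSd,dmsoOffset,batchSd,nGeneSets,setSizeRange,fracPlantedSets,plantedSetDeFraction,seed see the class slots.
#' @export
simulationConfig <- function(nGenes = 5000,
                             probesPerGene = c(0.7, 0.2, 0.1),
                             fracUnmappedProbes = 0.1,
                             replicates = 3,
                             conditions = .CONDITIONS,
                             timePoints = .TIMEPOINTS,
                             dePartition = crosstalkPartition(),
                             lfcMean = 1, lfcSd = 0.5, fracDown = 0.5,
                             d0True = 4, s0sqTrue = 0.09,
                             baselineMean = 7, baselineSd = 2,
                             dmsoOffset = 0, batchSd = 0,
                             nGeneSets = 100, setSizeRange = c(10, 60),
                             fracPlantedSets = 0.1,
                             plantedSetDeFraction = 0.5,
                             seed = 1) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), probesPerGene = probesPerGene,
      fracUnmappedProbes = fracUnmappedProbes,
      replicates = as.integer(replicates),
      conditions = conditions, timePoints = timePoints,
      dePartition = dePartition, lfcMean = lfcMean, lfcSd = lfcSd,
      fracDown = fracDown, d0True = d0True, s0sqTrue = s0sqTrue,
      baselineMean = baselineMean, baselineSd = baselineSd,
      dmsoOffset = dmsoOffset, batchSd = batchSd,
      nGeneSets = as.integer(nGeneSets),
      setSizeRange = as.integer(setSizeRange),
      fracPlantedSets = fracPlantedSets,
      plantedSetDeFraction = plantedSetDeFraction,
      seed = as.integer(seed))
}

#' Ground truth of a synthetic study
#'
#' @slot genes data.frame: `gene`, `treatments` (subset key, `""` if
#'   unaffected), `profile` (`NA` if unaffected), `lfc_4h`, `lfc_24h`
#'   (signed planted log2 fold changes; 0 where inactive), `var_true`.
#' @slot sets data.frame: `set`, `planted` flag, `target` treatment
#'   (`NA` for null sets).
#' @slot probes data.frame: `probe_id`, `gene` (`NA` for unmapped probes),
#'   `baseline`, `var_true` (unmapped probes carry their own).
#' @export
setClass("GroundTruth", representation(
  genes = "data.frame", sets = "data.frame", probes = "data.frame"))

setValidity("GroundTruth", function(object) {
  g <- object@genes
  msg <- character()
  late <- g$profile %in% c("both", "late-only")
  if (any(late & g$lfc_24h == 0))
    msg <- c(msg, "late/both-profile genes must have a nonzero 24h effect")
  if (any(g$profile %in% "early-only" & g$lfc_24h != 0))
    msg <- c(msg, "early-only genes must have a zero 24h effect")
  if (nrow(object@sets) && !is.logical(object@sets$planted))
    msg <- c(msg, "set planted flags must be logical")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genes), "genes (",
      sum(object@genes$treatments != ""), "affected ),",
      nrow(object@sets), "sets (", sum(object@sets$planted), "planted ),",
      nrow(object@probes), "probes\n")
})

#' @describeIn GroundTruth-class the per-gene truth table.
#' @param truth a `GroundTruth`.
#' @export
truthGenes <- function(truth) truth@genes

#' @describeIn GroundTruth-class the per-set truth table.
#' @export
truthSets <- function(truth) truth@sets

#' @describeIn GroundTruth-class the probe annotation table.
#' @export
truthProbes <- function(truth) truth@probes

#' Draw the ground truth of a synthetic study
#'
#' Assigns planted effects per the configured partition (counts honored
#' exactly), draws signed log2 fold changes (`|N(lfcMean, lfcSd)|`, negative
#' with probability `fracDown`, drawn independently per active time point
#' with a common sign), true gene variances from
#' `s0sqTrue * d0True / chisq(d0True)`, gene baselines, probe multiplicity
#' and the planted/null split of the gene-set collection. Deterministic
#' given `seed`.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GroundTruth}.
#' @export
generateTruth <- function(config) {
  validObject(config)
  withr::with_seed(config@seed, .generateTruthImpl(config))
}

.generateTruthImpl <- function(config) {
  n <- config@nGenes
  genes <- sprintf("G%05d", seq_len(n))
  dp <- config@dePartition
  treatments <- rep("", n)
  profile <- rep(NA_character_, n)
  at <- 0L
  if (nrow(dp)) for (i in seq_len(nrow(dp))) {
    k <- dp$n[i]
    if (k > 0L) {
      idx <- at + seq_len(k)
      treatments[idx] <- dp$treatments[i]
      profile[idx] <- dp$profile[i]
      at <- at + k
    }
  }
  sign <- ifelse(runif(n) < config@fracDown, -1, 1)
  mag4 <- abs(rnorm(n, config@lfcMean, config@lfcSd))
  mag24 <- abs(rnorm(n, config@lfcMean, config@lfcSd))
  lfc4 <- ifelse(profile %in% c("early-only", "both"), sign * mag4, 0)
  lfc24 <- ifelse(profile %in% c("both", "late-only"), sign * mag24, 0)
  varTrue <- config@s0sqTrue * config@d0True / rchisq(n, df = config@d0True)
  baseline <- rnorm(n, config@baselineMean, config@baselineSd)
  geneTab <- data.frame(gene = genes, treatments = treatments,
                        profile = profile, lfc_4h = lfc4, lfc_24h = lfc24,
                        var_true = varTrue, baseline = baseline,
                        stringsAsFactors = FALSE)

  # probe multiplicity and unmapped probes
  kPerGene <- sample(1:3, n, replace = TRUE, prob = config@probesPerGene)
  nMapped <- sum(kPerGene)
  f <- config@fracUnmappedProbes
  nUnmapped <- round(f / (1 - f) * nMapped)
  probeGene <- c(rep(genes, kPerGene), rep(NA_character_, nUnmapped))
  nProbes <- length(probeGene)
  probeIds <- sprintf("p%06d_at", seq_len(nProbes))
  gi <- match(probeGene, genes)
  probeTab <- data.frame(
    probe_id = probeIds, gene = probeGene,
    baseline = ifelse(is.na(gi),
                      rnorm(nProbes, config@baselineMean, config@baselineSd),
                      baseline[gi]),
    var_true = ifelse(is.na(gi),
                      config@s0sqTrue * config@d0True / rchisq(nProbes, config@d0True),
                      varTrue[gi]),
    stringsAsFactors = FALSE)

  # planted / null split of the gene-set collection; targets cycle over the
  # treatments that actually have planted genes
  nSets <- config@nGeneSets
  setNamesV <- sprintf("SET%03d", seq_len(nSets))
  nPlanted <- round(config@fracPlantedSets * nSets)
  # planted targets cycle over treatments whose affected-gene pool can fill
  # the DE share of the largest possible set
  affectedTreatments <- unique(unlist(strsplit(
    dp$treatments[dp$n > 0L], "+", fixed = TRUE)))
  poolSize <- vapply(affectedTreatments, function(tr)
    sum(dp$n[vapply(strsplit(dp$treatments, "+", fixed = TRUE),
                    function(s) tr %in% s, TRUE)]), 0)
  need <- ceiling(config@plantedSetDeFraction * config@setSizeRange[2L])
  affectedTreatments <- affectedTreatments[poolSize >= need]
  if (nPlanted > 0L && !length(affectedTreatments))
    stop("cannot plant enriched sets: no treatment has >= ", need,
         " planted genes")
  target <- rep(NA_character_, nSets)
  if (nPlanted > 0L)
    target[seq_len(nPlanted)] <-
      rep_len(affectedTreatments, nPlanted)
  setTab <- data.frame(set = setNamesV,
                       planted = seq_len(nSets) <= nPlanted,
                       target = target, stringsAsFactors = FALSE)
  new("GroundTruth", genes = geneTab, sets = setTab, probes = probeTab)
}

#' Generate the probe-level expression matrix and sample sheet
#'
#' For each time point, `replicates` samples per condition. Expression of a
#' mapped probe is its gene's baseline, plus the planted effect in samples
#' of an affecting treatment at an active time point, plus Gaussian noise
#' with the gene's true variance (independent across probes of the same
#' gene). DMSO and untreated samples share the null mean, so pooling them
#' into one control group is valid by construction (a nonzero `dmsoOffset`
#' breaks this deliberately). Deterministic given the config seed.
#'
#' @param truth a \linkS4class{GroundTruth} from the same config.
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ProbeExperiment}.
#' @export
generateExpression <- function(truth, config) {
  validObject(config)
  withr::with_seed(config@seed + 1L, .generateExpressionImpl(truth, config))
}

.generateExpressionImpl <- function(truth, config) {
  pt <- truth@probes
  gt <- truth@genes
  conds <- config@conditions
  tps <- config@timePoints
  reps <- config@replicates
  sheet <- expand.grid(replicate = paste0("r", seq_len(reps)),
                       condition = conds, time_point = tps,
                       stringsAsFactors = FALSE)[, 3:1]
  sheet$sample_id <- paste(sheet$condition, sheet$time_point,
                           sheet$replicate, sep = "_")
  nS <- nrow(sheet)
  nP <- nrow(pt)
  gi <- match(pt$gene, gt$gene)

  # planted effect per probe x sample; affecting-treatment lookups are
  # precomputed at the gene level
  trList <- strsplit(gt$treatments, "+", fixed = TRUE)
  eff <- matrix(0, nP, nS)
  isEarly <- sheet$time_point == tps[1L]
  for (cond in unique(sheet$condition)) {
    hitGene <- vapply(trList, function(s) cond %in% s, TRUE)
    hit <- !is.na(gi) & hitGene[pmax(gi, 1L)]
    if (!any(hit)) next
    js <- which(sheet$condition == cond)
    for (j in js) {
      lfc <- if (isEarly[j]) gt$lfc_4h else gt$lfc_24h
      eff[hit, j] <- lfc[gi[hit]]
    }
  }
  if (config@dmsoOffset != 0)
    eff[, sheet$condition == "DMSO"] <- eff[, sheet$condition == "DMSO"] +
      config@dmsoOffset
  noise <- matrix(rnorm(nP * nS, sd = rep(sqrt(pt$var_true), nS)), nP, nS)
  values <- pt$baseline + eff + noise
  if (config@batchSd > 0) {
    for (r in unique(sheet$replicate)) {
      b <- rnorm(nP, sd = config@batchSd)
      values[, sheet$replicate == r] <- values[, sheet$replicate == r] + b
    }
  }
  dimnames(values) <- list(pt$probe_id, sheet$sample_id)
  ann <- data.frame(probe_id = pt$probe_id, gene_symbol = pt$gene,
                    stringsAsFactors = FALSE)
  probeExperiment(values, sheet, ann)
}

#' Generate the gene-set collection
#'
#' Planted sets draw `plantedSetDeFraction` of their members from genes
#' affected by the set's target treatment and the rest from unaffected
#' genes; null sets draw uniformly from unaffected genes. Sizes are uniform
#' within `setSizeRange`. Deterministic given the config seed.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
generateGeneSets <- function(truth, config) {
  validObject(config)
  withr::with_seed(config@seed + 2L, .generateGeneSetsImpl(truth, config))
}

.generateGeneSetsImpl <- function(truth, config) {
  gt <- truth@genes
  st <- truth@sets
  unaffected <- gt$gene[gt$treatments == ""]
  affectedBy <- function(tr) {
    gt$gene[vapply(strsplit(gt$treatments, "+", fixed = TRUE),
                   function(s) tr %in% s, TRUE)]
  }
  rng <- config@setSizeRange
  sets <- vector("list", nrow(st))
  names(sets) <- st$set
  for (i in seq_len(nrow(st))) {
    size <- if (rng[1L] == rng[2L]) rng[1L]
            else sample(rng[1L]:rng[2L], 1L)
    if (st$planted[i]) {
      pool <- affectedBy(st$target[i])
      nDe <- round(config@plantedSetDeFraction * size)
      if (nDe > length(pool))
        stop("planted set size ", size, " needs ", nDe,
             " affected genes; only ", length(pool), " available")
      if (size - nDe > length(unaffected))
        stop("not enough unaffected genes for set of size ", size)
      sets[[i]] <- c(sample(pool, nDe), sample(unaffected, size - nDe))
    } else {
      if (size > length(unaffected))
        stop("not enough unaffected genes for set of size ", size)
      sets[[i]] <- sample(unaffected, size)
    }
  }
  geneSetCollection(sets, source = "synthetic")
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [generateTruth()], [generateExpression()] and
#' [generateGeneSets()] from one config.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements `truth`, `probes` (a
#'   \linkS4class{ProbeExperiment}) and `sets`
#'   (a \linkS4class{GeneSetCollection}).
#' @export
simulateStudy <- function(config = simulationConfig()) {
  truth <- generateTruth(config)
  list(truth = truth,
       probes = generateExpression(truth, config),
       sets = generateGeneSets(truth, config))
}
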