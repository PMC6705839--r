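#' @import methods
#' @importFrom stats var rnorm rchisq runif pt p.adjust setNames ave
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Probe-level expression container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are microarray probe sets
#' and whose columns are samples. `colData` must carry `condition`,
#' `time_point` and `replicate`; `rowData` must carry `gene_symbol`
#' (`NA` for probes that map to no gene). Values are normalized log2
#' intensities with no missing entries.
#'
#' @seealso [probeExperiment()], [collapseProbes()]
#' @export
setClass("ProbeExperiment", contains = "SummarizedExperiment")

#' Gene-level expression container
#'
#' A \linkS4class{SummarizedExperiment} with one row per gene symbol,
#' produced by [collapseProbes()] or constructed directly from a gene-level
#' matrix. Same `colData` requirements as \linkS4class{ProbeExperiment}.
#'
#' @seealso [geneExperiment()]
#' @export
setClass("GeneExperiment", contains = "SummarizedExperiment")

.validExprSE <- function(object, requireSymbols) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("at least one assay is required")
  x <- assay(object)
  if (!is.numeric(x)) msg <- c(msg, "assay values must be numeric")
  if (anyNA(x)) msg <- c(msg, "missing expression values are not supported")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "row identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  cd <- colData(object)
  need <- c("condition", "time_point", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (requireSymbols && !("gene_symbol" %in% colnames(rowData(object))))
    msg <- c(msg, "rowData lacks a 'gene_symbol' column")
  if (length(msg)) msg else TRUE
}

setValidity("ProbeExperiment", function(object) .validExprSE(object, TRUE))
setValidity("GeneExperiment", function(object) {
  ok <- .validExprSE(object, FALSE)
  if (!isTRUE(ok)) return(ok)
  if (anyNA(rownames(object))) return("gene symbols must not be NA")
  TRUE
})

#' Construct a ProbeExperiment
#'
#' @param values numeric matrix of log2 intensities, probes x samples, with
#'   probe identifiers as row names and sample identifiers as column names.
#' @param sampleSheet data.frame with columns `sample_id`, `condition`,
#'   `time_point`, `replicate`; one row per matrix column.
#' @param annotation data.frame with columns `probe_id`, `gene_symbol`
#'   (empty string or `NA` for unmapped probes); one row per matrix row.
#' @return A \linkS4class{ProbeExperiment}.
#' @export
probeExperiment <- function(values, sampleSheet, annotation) {
  cd <- .sheetToColData(sampleSheet, colnames(values))
  ann <- annotation[match(rownames(values), annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("annotation is missing probe(s): ",
         paste(utils::head(setdiff(rownames(values), annotation$probe_id), 5L),
               collapse = ", "))
  sym <- as.character(ann$gene_symbol)
  sym[!is.na(sym) & sym == ""] <- NA_character_
  rd <- DataFrame(gene_symbol = sym, row.names = rownames(values))
  new("ProbeExperiment", SummarizedExperiment(
    assays = list(exprs = values), colData = cd, rowData = rd))
}

#' Construct a GeneExperiment
#'
#' @param values numeric matrix of log2 intensities, genes x samples, gene
#'   symbols as row names.
#' @param sampleSheet data.frame as for [probeExperiment()].
#' @return A \linkS4class{GeneExperiment}.
#' @export
geneExperiment <- function(values, sampleSheet) {
  cd <- .sheetToColData(sampleSheet, colnames(values))
  new("GeneExperiment", SummarizedExperiment(
    assays = list(exprs = values), colData = cd))
}

.sheetToColData <- function(sheet, sampleIds) {
  need <- c("sample_id", "condition", "time_point", "replicate")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  idx <- match(sampleIds, sheet$sample_id)
  if (anyNA(idx))
    stop("sample(s) in matrix absent from sheet: ",
         paste(sampleIds[is.na(idx)], collapse = ", "))
  extra <- setdiff(sheet$sample_id, sampleIds)
  if (length(extra))
    stop("sample(s) in sheet absent from matrix: ", paste(extra, collapse = ", "))
  s <- sheet[idx, , drop = FALSE]
  DataFrame(condition = as.character(s$condition),
            time_point = as.character(s$time_point),
            replicate = as.character(s$replicate),
            row.names = sampleIds)
}

#' Sample sheet of an expression container
#'
#' @param x a \linkS4class{ProbeExperiment} or \linkS4class{GeneExperiment}.
#' @return data.frame with columns `sample_id`, `condition`, `time_point`,
#'   `replicate`.
#' @export
sampleSheet <- function(x) {
  cd <- colData(x)
  data.frame(sample_id = rownames(cd), condition = cd$condition,
             time_point = cd$time_point, replicate = cd$replicate,
             stringsAsFactors = FALSE)
}

#' Per-time-point grouping of samples into treatments and a pooled control
#'
#' Produced by [poolControls()]; consumed by the linear-model and
#' permutation machinery.
#'
#' @slot timePoint single time-point label.
#' @slot groups factor of group assignments, named by sample identifier;
#'   levels are the treatment labels followed by the control label.
#' @slot treatments treatment labels, in model order.
#' @slot controlLabel label of the pooled control group.
#' @export
setClass("DesignSpec", representation(
  timePoint = "character", groups = "factor",
  treatments = "character", controlLabel = "character"))

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (length(object@timePoint) != 1L) msg <- c(msg, "timePoint must be scalar")
  if (is.null(names(object@groups)) || anyDuplicated(names(object@groups)))
    msg <- c(msg, "groups must be named by unique sample identifiers")
  lev <- levels(object@groups)
  if (!setequal(lev, c(object@treatments, object@controlLabel)))
    msg <- c(msg, "group levels must be the treatments plus the control label")
  if (sum(object@groups == object@controlLabel) == 0L)
    msg <- c(msg, "control group is empty")
  if (length(msg)) msg else TRUE
})

#' @describeIn DesignSpec group sizes, named by group label.
#' @param design a `DesignSpec`.
#' @export
groupSizes <- function(design) {
  stopifnot(is(design, "DesignSpec"))
  table(design@groups)
}

#' Per-gene group-mean fit of the five-group linear model
#'
#' @slot coefficients genes x groups matrix of group means (log2 units).
#' @slot sigma2 per-gene residual variance (log2 squared units).
#' @slot df residual degrees of freedom (scalar for a complete design).
#' @slot groupSizes integer group sizes, named by group label.
#' @export
setClass("LinearFit", representation(
  coefficients = "matrix", sigma2 = "numeric", df = "numeric",
  groupSizes = "integer"))

setValidity("LinearFit", function(object) {
  msg <- character()
  if (nrow(object@coefficients) != length(object@sigma2))
    msg <- c(msg, "coefficients and sigma2 disagree on gene count")
  if (any(object@sigma2 < 0)) msg <- c(msg, "residual variances must be >= 0")
  if (object@df <= 0) msg <- c(msg, "residual degrees of freedom must be > 0")
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes variance-moderation parameters
#'
#' The scaled inverse chi-square prior on gene-wise residual variances:
#' `d0` prior degrees of freedom (may be `Inf`; `0` disables moderation)
#' and `s0sq` prior variance.
#'
#' @slot d0 prior degrees of freedom.
#' @slot s0sq prior variance.
#' @export
setClass("ModerationParams", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("ModerationParams", function(object) {
  if (length(object@d0) != 1L || length(object@s0sq) != 1L)
    return("d0 and s0sq must be scalars")
  if (is.na(object@d0) || object@d0 < 0) return("d0 must be >= 0")
  if (is.na(object@s0sq) || object@s0sq <= 0) return("s0sq must be > 0")
  TRUE
})

#' @rdname ModerationParams-class
#' @param d0,s0sq prior degrees of freedom and prior variance.
#' @export
moderationParams <- function(d0, s0sq) new("ModerationParams", d0 = d0, s0sq = s0sq)

#' @describeIn ModerationParams-class prior degrees of freedom.
#' @param params a `ModerationParams`.
#' @export
priorDf <- function(params) params@d0

#' @describeIn ModerationParams-class prior variance.
#' @export
priorVar <- function(params) params@s0sq

#' Named collection of gene sets
#'
#' @slot sets named list of character vectors of gene symbols (deduplicated).
#' @slot source free-text provenance tag.
#' @export
setClass("GeneSetCollection", representation(sets = "list", source = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)) ||
        any(names(object@sets) == ""))
      msg <- c(msg, "set names must be present and unique")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "set members must be deduplicated")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors; duplicate members within a
#'   set are removed.
#' @param source provenance tag.
#' @export
geneSetCollection <- function(sets = list(), source = "") {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  new("GeneSetCollection", sets = sets, source = source)
}

#' @describeIn GeneSetCollection-class the named list of member vectors.
#' @param collection a `GeneSetCollection`.
#' @export
geneSets <- function(collection) collection@sets

#' @describeIn GeneSetCollection-class number of sets.
#' @param x a `GeneSetCollection`.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' |t|-ranked, |t|-weighted gene list
#'
#' Genes ordered by decreasing weight `|t|^q`; rank 1 carries the largest
#' weight. Every gene of the universe appears exactly once.
#'
#' @slot genes gene symbols in rank order.
#' @slot weights non-increasing, non-negative weights.
#' @export
setClass("RankedList", representation(genes = "character", weights = "numeric"))

setValidity("RankedList", function(object) {
  msg <- character()
  if (length(object@genes) != length(object@weights))
    msg <- c(msg, "genes and weights differ in length")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene symbols")
  if (length(object@weights) > 1L && any(diff(object@weights) > 1e-12))
    msg <- c(msg, "weights must be non-increasing with rank")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Sample-permutation null distribution of enrichment scores
#'
#' @slot es named list (one element per contrast) of `nPerm x nSets`
#'   matrices of null enrichment scores, set names as column names.
#' @slot nPerm number of permutations.
#' @slot seed root seed the permutations were derived from.
#' @export
setClass("PermutationNull", representation(
  es = "list", nPerm = "integer", seed = "integer"))

setValidity("PermutationNull", function(object) {
  if (!length(object@es)) return("empty null")
  ok <- vapply(object@es, function(m) is.matrix(m) && nrow(m) == object@nPerm, TRUE)
  if (!all(ok)) return("each contrast needs an nPerm-row matrix")
  TRUE
})

#' Presence/direction table of entities across ligands and time points
#'
#' One row per (entity, ligand) with logical presence at each time point and,
#' for genes, the regulation direction at each time point.
#'
#' @slot data data.frame with columns `entity`, `ligand`, `at_4h`, `at_24h`,
#'   `dir_4h`, `dir_24h`, `profile`.
#' @slot kind `"gene"` or `"pathway"`.
#' @export
setClass("MembershipTable", representation(data = "data.frame", kind = "character"))

setValidity("MembershipTable", function(object) {
  need <- c("entity", "ligand", "at_4h", "at_24h", "dir_4h", "dir_24h", "profile")
  if (!all(need %in% colnames(object@data))) return("malformed membership data")
  if (!object@kind %in% c("gene", "pathway")) return("kind must be gene or pathway")
  if (nrow(object@data) &&
      any(!object@data$at_4h & !object@data$at_24h))
    return("entities must be present at >= 1 time point per row")
  TRUE
})

#' @describeIn MembershipTable-class the underlying data.frame.
#' @param table a `MembershipTable`.
#' @export
membershipData <- function(table) table@data

#' Disjoint overlap partition of entities by exact ligand subset
#'
#' Each entity that is present for at least one selected ligand is assigned
#' to exactly one class: the exact subset of selected ligands for which it
#' is present (at any time point). Class keys join ligand labels with `"+"`.
#'
#' @slot assignment data.frame with columns `entity`, `class`, `profile`.
#' @slot ligands the selected ligands, in display order.
#' @slot counts entity count per non-empty ligand subset, named by class key.
#' @export
setClass("OverlapPartition", representation(
  assignment = "data.frame", ligands = "character", counts = "integer"))

setValidity("OverlapPartition", function(object) {
  if (sum(object@counts) != nrow(object@assignment))
    return("class counts must sum to the number of assigned entities")
  TRUE
})

#' @describeIn OverlapPartition-class entity counts per disjoint class.
#' @param partition an `OverlapPartition`.
#' @export
overlapCounts <- function(partition) partition@counts

## ---- show methods -------------------------------------------------------

setMethod("show", "DesignSpec", function(object) {
  sz <- table(object@groups)
  cat("DesignSpec @", object@timePoint, "--",
      paste(sprintf("%s(n=%d)", names(sz), as.integer(sz)), collapse = ", "), "\n")
})

setMethod("show", "LinearFit", function(object) {
  cat("LinearFit:", nrow(object@coefficients), "genes,",
      ncol(object@coefficients), "groups, residual df =", object@df, "\n")
})

setMethod("show", "ModerationParams", function(object) {
  cat(sprintf("ModerationParams: d0 = %s, s0sq = %.6g\n",
              format(object@d0), object@s0sq))
})

setMethod("show", "GeneSetCollection", function(object) {
  n <- length(object@sets)
  cat("GeneSetCollection:", n, "sets")
  if (n) {
    sz <- lengths(object@sets)
    cat(" (sizes ", min(sz), "-", max(sz), ")", sep = "")
  }
  if (nzchar(object@source)) cat(" [", object@source, "]", sep = "")
  cat("\n")
})

setMethod("show", "RankedList", function(object) {
  cat("RankedList:", length(object@genes), "genes; top:",
      paste(utils::head(object@genes, 3L), collapse = ", "), "\n")
})

setMethod("show", "PermutationNull", function(object) {
  cat("PermutationNull:", object@nPerm, "permutations x",
      ncol(object@es[[1L]]), "sets x", length(object@es), "contrasts\n")
})

setMethod("show", "MembershipTable", function(object) {
  cat("MembershipTable (", object@kind, "): ",
      length(unique(object@data$entity)), " entities, ",
      length(unique(object@data$ligand)), " ligands\n", sep = "")
})

setMethod("show", "OverlapPartition", function(object) {
  cat("OverlapPartition over {", paste(object@ligands, collapse = ", "), "}: ",
      nrow(object@assignment), " entities in ",
      sum(object@counts > 0L), " non-empty classes\n", sep = "")
})
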