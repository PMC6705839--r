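#' Collapse a probe-level matrix to one row per gene symbol
#'
#' Reproduces the two probe-filtering steps of the analyzed design: (1)
#' probes with no gene symbol are discarded; (2) when several probes map to
#' the same gene symbol, only the probe with the highest unbiased (n-1)
#' sample variance across the arrays of `varianceTimePoint` is retained.
#' Variance ties are resolved by keeping the lexicographically smallest
#' probe identifier, so the result does not depend on annotation order.
#' Rows of the result are sorted by gene symbol.
#'
#' @param probes a \linkS4class{ProbeExperiment}.
#' @param varianceTimePoint time-point label whose arrays are used for the
#'   variance computation (default `"4h"`).
#' @return A \linkS4class{GeneExperiment}; `rowData` records the retained
#'   probe and its selection variance.
#' @export
collapseProbes <- function(probes, varianceTimePoint = "4h") {
  stopifnot(is(probes, "ProbeExperiment"))
  validObject(probes)
  cd <- colData(probes)
  vcols <- which(cd$time_point == varianceTimePoint)
  if (!length(vcols))
    stop("time point '", varianceTimePoint, "' has no samples")
  if (length(vcols) < 2L)
    stop("variance computation needs >= 2 samples at '", varianceTimePoint, "'")
  sym <- rowData(probes)$gene_symbol
  mapped <- which(!is.na(sym) & sym != "")
  if (!length(mapped)) stop("no probe maps to a gene symbol")

  x <- assay(probes)[mapped, vcols, drop = FALSE]
  m <- ncol(x)
  v <- (rowSums(x^2) - rowSums(x)^2 / m) / (m - 1)
  ord <- order(sym[mapped], -v, rownames(probes)[mapped])
  keep <- mapped[ord][!duplicated(sym[mapped][ord])]

  values <- assay(probes)[keep, , drop = FALSE]
  rn <- rownames(values)
  rownames(values) <- sym[keep]
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = colData(probes),
    rowData = DataFrame(probe_id = rn,
                        selection_variance = v[match(keep, mapped)],
                        row.names = sym[keep]))
  new("GeneExperiment", se)
}

#' Group the samples of one time point into treatments plus a pooled control
#'
#' DMSO vehicle and untreated samples are combined into a single control
#' group; each remaining condition forms its own treatment group. This is
#' the design of the five-coefficient linear model from which the four
#' treatment-versus-control contrasts are extracted.
#'
#' @param x a \linkS4class{ProbeExperiment}, \linkS4class{GeneExperiment}
#'   or sample-sheet data.frame.
#' @param timePoint time-point label to model.
#' @param treatments treatment condition labels, in model order.
#' @param controls condition labels pooled into the control group; samples
#'   from any subset of these that is present are pooled (absence of one
#'   control condition is not an error).
#' @return A \linkS4class{DesignSpec}.
#' @export
poolControls <- function(x, timePoint,
                         treatments = c("FXR-L", "LXR-L", "PPARa-L", "CDCA"),
                         controls = c("DMSO", "untreated")) {
  sheet <- if (is.data.frame(x)) x else sampleSheet(x)
  s <- sheet[sheet$time_point == timePoint, , drop = FALSE]
  if (!nrow(s)) stop("time point '", timePoint, "' has no samples")
  if (!any(s$condition %in% controls))
    stop("no control samples (", paste(controls, collapse = "/"),
         ") at time point '", timePoint, "'")
  keep <- s$condition %in% c(treatments, controls)
  s <- s[keep, , drop = FALSE]
  grp <- ifelse(s$condition %in% controls, "control", s$condition)
  missing <- setdiff(treatments, grp)
  if (length(missing))
    stop("treatment group(s) with no samples at '", timePoint, "': ",
         paste(missing, collapse = ", "))
  groups <- factor(grp, levels = c(treatments, "control"))
  names(groups) <- s$sample_id
  new("DesignSpec", timePoint = timePoint, groups = groups,
      treatments = treatments, controlLabel = "control")
}
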