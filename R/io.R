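## Plain-text formats: GMT gene sets, TSV expression matrices / sample
## sheets / annotations / result tables, JSON ground truth and summaries.

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Duplicate members within a line are removed with a warning; duplicate
#' set names are an error; a line with fewer than three fields is a parse
#' error reported with its line number.
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " in '", path,
         "': fewer than 3 fields")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate set name(s) in '", path, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  ndup <- vapply(sets, anyDuplicated, 0L)
  if (any(ndup > 0L))
    warning("duplicate member symbols removed in set(s): ",
            paste(nms[ndup > 0L], collapse = ", "))
  names(sets) <- nms
  geneSetCollection(sets, source = path)
}

#' Write a GMT gene-set file
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @export
writeGmt <- function(collection, path, descriptions = NULL) {
  sets <- collection@sets
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns `sample_id`, `condition`, `time_point`,
#'   `replicate`.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  s <- .readTsv(path)
  need <- c("sample_id", "condition", "time_point", "replicate")
  miss <- setdiff(need, colnames(s))
  if (length(miss))
    stop("sample sheet '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  s$replicate <- as.character(s$replicate)
  s
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix TSV has probe or gene identifiers in the first column and one
#' column per sample. Non-numeric or missing cells are rejected with their
#' row/column coordinates; matrix and sheet must agree on the sample set.
#' With a probe annotation the result is a \linkS4class{ProbeExperiment},
#' otherwise row identifiers are taken as gene symbols and a
#' \linkS4class{GeneExperiment} is returned.
#'
#' @param exprPath expression TSV path.
#' @param sheetPath sample-sheet TSV path.
#' @param annotPath optional probe annotation TSV (`probe_id`,
#'   `gene_symbol`; empty gene_symbol means unmapped).
#' @return A \linkS4class{ProbeExperiment} or \linkS4class{GeneExperiment}.
#' @export
readExpression <- function(exprPath, sheetPath, annotPath = NULL) {
  raw <- .readTsv(exprPath)
  ids <- as.character(raw[[1L]])
  m <- raw[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    cell <- m[[j]]
    if (!is.numeric(cell)) {
      conv <- suppressWarnings(as.numeric(cell))
      bad <- which(is.na(conv) & !is.na(cell))
      if (length(bad))
        stop("non-numeric value at row ", ids[bad[1L]], ", column '",
             colnames(m)[j], "' of '", exprPath, "'")
      m[[j]] <- cell <- conv
    }
    if (anyNA(cell))
      stop("missing value at row ", ids[which(is.na(cell))[1L]],
           ", column '", colnames(m)[j], "' of '", exprPath, "'")
  }
  values <- as.matrix(m)
  rownames(values) <- ids
  sheet <- readSampleSheet(sheetPath)
  if (is.null(annotPath)) return(geneExperiment(values, sheet))
  ann <- .readTsv(annotPath)
  if (!all(c("probe_id", "gene_symbol") %in% colnames(ann)))
    stop("annotation '", annotPath, "' needs columns probe_id, gene_symbol")
  probeExperiment(values, sheet, ann)
}

#' Write an expression container as TSV (matrix, sheet, annotation)
#'
#' @param x a \linkS4class{ProbeExperiment} or \linkS4class{GeneExperiment}.
#' @param exprPath matrix output path (first column `id`).
#' @param sheetPath optional sample-sheet output path.
#' @param annotPath optional annotation output path (probe containers only).
#' @export
writeExpression <- function(x, exprPath, sheetPath = NULL, annotPath = NULL) {
  df <- data.frame(id = rownames(x), as.data.frame(assay(x),
                   check.names = FALSE), check.names = FALSE)
  .writeTsv(df, exprPath)
  if (!is.null(sheetPath)) .writeTsv(sampleSheet(x), sheetPath)
  if (!is.null(annotPath)) {
    sym <- rowData(x)$gene_symbol
    sym[is.na(sym)] <- ""
    .writeTsv(data.frame(probe_id = rownames(x), gene_symbol = sym,
                         stringsAsFactors = FALSE), annotPath)
  }
  invisible(exprPath)
}

#' Read a pathway-to-category map
#'
#' @param path TSV with columns `pathway`, `category`.
#' @return named character vector (pathway -> category).
#' @export
readCategoryMap <- function(path) {
  m <- .readTsv(path)
  if (!all(c("pathway", "category") %in% colnames(m)))
    stop("category map '", path, "' needs columns pathway, category")
  setNames(as.character(m$category), m$pathway)
}

#' Write the ground truth of a synthetic study as JSON
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(genes = truth@genes, sets = truth@sets, probes = truth@probes),
    path, dataframe = "columns", na = "null", digits = NA)
  invisible(path)
}

#' Read a ground truth JSON back
#'
#' @param path JSON written by [writeGroundTruth()].
#' @return A \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as.data.frame(x$genes, stringsAsFactors = FALSE)
  g$profile <- as.character(g$profile)
  p <- as.data.frame(x$probes, stringsAsFactors = FALSE)
  p$gene <- as.character(p$gene)
  s <- as.data.frame(x$sets, stringsAsFactors = FALSE)
  s$target <- as.character(s$target)
  new("GroundTruth", genes = g, sets = s, probes = p)
}
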