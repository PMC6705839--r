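## Cross-talk accounting: turns per-ligand, per-time-point DE and
## enrichment calls into disjoint overlap partitions (which entities are
## exclusive to one treatment, which are shared), time-profile summaries,
## category cross-tabulations, activation/inhibition ratios and
## leading-edge core-gene counts. "Shared" is always computed on the union
## over time points: an entity is shared by two ligands if both call it at
## ANY time point, not necessarily the same one -- this is what makes the
## per-ligand totals consistent with the time-combined classes.

## Percentage rounding on exact rationals (counts), immune to binary
## representation error. One-decimal table percentages resolve exact .x5
## ties downward (the summary-table convention); integer coverage
## percentages resolve them away from zero.
.pctRound <- function(n, total, digits = 1, tie = c("down", "up")) {
  tie <- match.arg(tie)
  total <- max(total, 1L)
  p <- 10^digits
  num <- as.numeric(n) * 100 * p
  k <- num %/% total
  r <- num %% total
  up <- r / total > 0.5 | (2 * r == total & tie == "up")
  (k + as.numeric(up)) / p
}

#' Build a membership table from per-ligand calls
#'
#' @param calls data.frame with columns `entity`, `ligand`, `time_point`
#'   (`"4h"` or `"24h"`) and, for genes, optionally `direction`
#'   (`"up"`/`"down"`). One row per call; duplicated (entity, ligand,
#'   time_point) rows must agree on direction.
#' @param kind `"gene"` or `"pathway"`.
#' @return A \linkS4class{MembershipTable}.
#' @export
buildMembership <- function(calls, kind = c("gene", "pathway")) {
  kind <- match.arg(kind)
  need <- c("entity", "ligand", "time_point")
  if (!all(need %in% colnames(calls)))
    stop("calls need columns: ", paste(need, collapse = ", "))
  empty <- data.frame(entity = character(), ligand = character(),
                      at_4h = logical(), at_24h = logical(),
                      dir_4h = character(), dir_24h = character(),
                      profile = character(), stringsAsFactors = FALSE)
  if (!nrow(calls)) return(new("MembershipTable", data = empty, kind = kind))
  if (!all(calls$time_point %in% c("4h", "24h")))
    stop("time_point must be '4h' or '24h'")
  hasDir <- "direction" %in% colnames(calls)
  key <- paste(calls$entity, calls$ligand, calls$time_point, sep = "\r")
  if (anyDuplicated(key)) {
    if (hasDir) {
      nd <- tapply(calls$direction, key, function(d) length(unique(d)))
      if (any(nd > 1L))
        stop("conflicting duplicate calls for ",
             sub("\r.*", "", names(nd)[which(nd > 1L)[1L]]))
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  sel <- function(tp) calls$time_point == tp
  pick <- function(tp, col) {
    i <- which(sel(tp))
    setNames(if (hasDir && col == "dir") calls$direction[i]
             else rep(TRUE, length(i)),
             paste(calls$entity[i], calls$ligand[i], sep = "\r"))
  }
  pairs <- unique(calls[, c("entity", "ligand")])
  pk <- paste(pairs$entity, pairs$ligand, sep = "\r")
  at4 <- pk %in% paste(calls$entity[sel("4h")], calls$ligand[sel("4h")], sep = "\r")
  at24 <- pk %in% paste(calls$entity[sel("24h")], calls$ligand[sel("24h")], sep = "\r")
  d4 <- d24 <- rep(NA_character_, nrow(pairs))
  if (hasDir) {
    d4 <- unname(pick("4h", "dir")[pk])
    d24 <- unname(pick("24h", "dir")[pk])
  }
  out <- data.frame(entity = pairs$entity, ligand = pairs$ligand,
                    at_4h = at4, at_24h = at24, dir_4h = d4, dir_24h = d24,
                    profile = ifelse(at4 & at24, "both",
                                     ifelse(at4, "4h only", "24h only")),
                    stringsAsFactors = FALSE)
  new("MembershipTable", data = out, kind = kind)
}

#' Convert DE or enrichment results to crosstalk calls
#'
#' @param results a DE data.frame (from [runDE()]; rows with `de = TRUE`
#'   are kept) or an enrichment data.frame (from [runGsea()]; rows with
#'   `enriched = TRUE` are kept), possibly row-bound across time points.
#' @return calls data.frame for [buildMembership()].
#' @export
asCalls <- function(results) {
  if ("de" %in% colnames(results)) {
    r <- results[results$de, , drop = FALSE]
    data.frame(entity = r$gene, ligand = r$contrast,
               time_point = r$time_point, direction = r$direction,
               stringsAsFactors = FALSE)
  } else if ("enriched" %in% colnames(results)) {
    r <- results[results$enriched, , drop = FALSE]
    data.frame(entity = r$set, ligand = r$contrast,
               time_point = r$time_point, stringsAsFactors = FALSE)
  } else stop("results carry neither DE nor enrichment calls")
}

#' Partition entities by the exact subset of ligands affecting them
#'
#' Every entity present (at any time point) for at least one of the
#' selected ligands is assigned to exactly one disjoint class: the exact
#' subset of selected ligands for which it is present. The entity's time
#' profile (4h only / both / 24h only) is the union of its presence across
#' the selected ligands.
#'
#' @param table a \linkS4class{MembershipTable}.
#' @param ligands selected ligand labels, in display order.
#' @return An \linkS4class{OverlapPartition} whose counts cover every
#'   non-empty subset of `ligands` (zero counts included).
#' @export
partitionOverlaps <- function(table, ligands) {
  stopifnot(is(table, "MembershipTable"), length(ligands) >= 1L)
  d <- table@data[table@data$ligand %in% ligands, , drop = FALSE]
  allKeys <- .subsetKeys(ligands)
  if (!nrow(d)) {
    return(new("OverlapPartition",
               assignment = data.frame(entity = character(),
                                       class = character(),
                                       profile = character(),
                                       stringsAsFactors = FALSE),
               ligands = ligands,
               counts = setNames(integer(length(allKeys)), allKeys)))
  }
  byEnt <- split(d, d$entity)
  cls <- vapply(byEnt, function(r)
    paste(ligands[ligands %in% r$ligand], collapse = "+"), "")
  prof <- vapply(byEnt, function(r) {
    a4 <- any(r$at_4h); a24 <- any(r$at_24h)
    if (a4 && a24) "both" else if (a4) "4h only" else "24h only"
  }, "")
  assignment <- data.frame(entity = names(byEnt), class = unname(cls),
                           profile = unname(prof), stringsAsFactors = FALSE)
  counts <- setNames(integer(length(allKeys)), allKeys)
  tab <- table(assignment$class)
  counts[names(tab)] <- as.integer(tab)
  new("OverlapPartition", assignment = assignment, ligands = ligands,
      counts = counts)
}

.subsetKeys <- function(ligands) {
  k <- length(ligands)
  keys <- character()
  for (size in seq_len(k))
    keys <- c(keys, apply(utils::combn(ligands, size), 2L,
                          paste, collapse = "+"))
  keys
}

#' Per-ligand sharing summary (one central-section block of the overlap
#' table)
#'
#' For one ligand's scope: how many of its entities are exclusive
#' (`alone`) and how many are shared with each combination of the other
#' selected ligands. Percentages are of the ligand's total, rounded to one
#' decimal.
#'
#' @param partition an \linkS4class{OverlapPartition}.
#' @param ligand the scope ligand.
#' @return data.frame `label`, `class`, `n`, `pct`; the ligand total is
#'   attached as `attr(, "total")`.
#' @export
ligandSummary <- function(partition, ligand) {
  stopifnot(ligand %in% partition@ligands)
  keys <- names(partition@counts)
  inClass <- vapply(strsplit(keys, "+", fixed = TRUE),
                    function(s) ligand %in% s, TRUE)
  keys <- keys[inClass]
  sizes <- lengths(strsplit(keys, "+", fixed = TRUE))
  keys <- keys[order(sizes)]
  n <- partition@counts[keys]
  total <- sum(n)
  label <- vapply(strsplit(keys, "+", fixed = TRUE), function(s) {
    others <- setdiff(s, ligand)
    if (!length(others)) "alone"
    else paste("sh. with", paste(others, collapse = " and "))
  }, "")
  out <- data.frame(label = label, class = keys, n = as.integer(n),
                    pct = .pctRound(n, total),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- as.integer(total)
  out
}

#' Time-profile summary across all ligands of a partition
#'
#' Counts of entities found only at 4h, only at 24h, or at both time
#' points, over the union of the selected ligands, with percentages of the
#' combined total (one decimal).
#'
#' @param partition an \linkS4class{OverlapPartition}.
#' @return data.frame `profile`, `n`, `pct`; total as `attr(, "total")`.
#' @export
timepointProfileSummary <- function(partition) {
  stopifnot(is(partition, "OverlapPartition"))
  lev <- c("4h only", "24h only", "both")
  n <- setNames(integer(3L), lev)
  tab <- table(partition@assignment$profile)
  n[names(tab)] <- as.integer(tab)
  total <- sum(n)
  out <- data.frame(profile = lev, n = as.integer(n),
                    pct = .pctRound(n, total),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- as.integer(total)
  out
}

#' Cross-tabulate overlap classes against pathway categories
#'
#' @param partition an \linkS4class{OverlapPartition} of pathways.
#' @param categoryMap named character vector mapping pathway name to
#'   category; pathways absent from the map fall into `"Other"`.
#' @return data.frame `class`, `category`, `n`, `pct_within_class` (one
#'   decimal, of the class total).
#' @export
categorize <- function(partition, categoryMap) {
  a <- partition@assignment
  cat <- unname(categoryMap[a$entity])
  cat[is.na(cat)] <- "Other"
  lev <- unique(c(categoryMap, "Other"))
  out <- do.call(rbind, lapply(names(partition@counts), function(k) {
    sel <- a$class == k
    n <- vapply(lev, function(cc) sum(sel & cat == cc), 0L)
    data.frame(class = k, category = lev, n = as.integer(n),
               pct_within_class = .pctRound(n, sum(sel)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Category coverage of a pathway partition
#'
#' Fraction of all partitioned pathways in each category, as the nearest
#' integer percentage.
#'
#' @inheritParams categorize
#' @return data.frame `category`, `n`, `pct`.
#' @export
categoryCoverage <- function(partition, categoryMap) {
  a <- partition@assignment
  cat <- unname(categoryMap[a$entity])
  cat[is.na(cat)] <- "Other"
  lev <- unique(c(categoryMap, "Other"))
  n <- vapply(lev, function(cc) sum(cat == cc), 0L)
  data.frame(category = lev, n = as.integer(n),
             pct = .pctRound(n, nrow(a), digits = 0, tie = "up"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Activation/inhibition ratio of a class-ligand connection
#'
#' For the entities of one overlap class, counts how many are up- versus
#' down-regulated by each ligand of the class. A gene contributes its
#' direction at the time point(s) where it is called; if it is called at
#' both time points with conflicting directions, the 24h direction is
#' reported and the gene is counted as a conflict.
#'
#' @param table a gene-kind \linkS4class{MembershipTable}.
#' @param class character vector of ligands defining the exact class.
#' @param ligands selected-ligand universe the class lives in (defaults to
#'   all ligands present in the table).
#' @return data.frame `ligand`, `n_up`, `n_down`, `n_conflict`.
#' @export
directionRatio <- function(table, class,
                           ligands = sort(unique(table@data$ligand))) {
  stopifnot(is(table, "MembershipTable"))
  if (table@kind != "gene")
    stop("direction ratios are defined for gene tables only")
  part <- partitionOverlaps(table, ligands)
  key <- paste(ligands[ligands %in% class], collapse = "+")
  ents <- part@assignment$entity[part@assignment$class == key]
  d <- table@data
  do.call(rbind, lapply(class, function(lg) {
    r <- d[d$entity %in% ents & d$ligand == lg, , drop = FALSE]
    dir <- ifelse(r$at_24h, r$dir_24h, r$dir_4h)
    conflict <- r$at_4h & r$at_24h & !is.na(r$dir_4h) & !is.na(r$dir_24h) &
      r$dir_4h != r$dir_24h
    data.frame(ligand = lg, n_up = sum(dir == "up", na.rm = TRUE),
               n_down = sum(dir == "down", na.rm = TRUE),
               n_conflict = sum(conflict), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Classify regulation strength of a log fold change
#'
#' DE gating precedes magnitude: a gene that is not called DE is
#' `unchanged` regardless of its fold change. Among DE genes, `strong`
#' means `|lfc|` strictly above `threshold` (log2 scale), `weak`
#' otherwise.
#'
#' @param lfc numeric log2 fold changes.
#' @param de logical DE calls, same length.
#' @param threshold strong-regulation cutoff (default 1.2).
#' @return character vector over `strong-down`, `weak-down`, `unchanged`,
#'   `weak-up`, `strong-up`.
#' @export
annotateRegulation <- function(lfc, de, threshold = 1.2) {
  stopifnot(length(lfc) == length(de), all(is.finite(lfc)))
  strong <- abs(lfc) > threshold
  up <- lfc >= 0
  out <- ifelse(!de, "unchanged",
                ifelse(strong,
                       ifelse(up, "strong-up", "strong-down"),
                       ifelse(up, "weak-up", "weak-down")))
  out
}

#' Core genes recurring across the leading edges of a category
#'
#' Counts, for every gene, how many of the category's pathways contain it
#' in their leading edge, and flags genes appearing in at least
#' `ceiling(fraction * n_pathways)` of them.
#'
#' @param leadingEdges named list: pathway -> character vector of
#'   leading-edge genes.
#' @param fraction recurrence threshold as a fraction of the pathway count
#'   (default 0.10).
#' @return data.frame `gene`, `n_leading_edges`, `qualifies`, sorted by
#'   decreasing count; the integer threshold is `attr(, "threshold")`.
#' @export
coreGeneCounts <- function(leadingEdges, fraction = 0.10) {
  stopifnot(is.list(leadingEdges), length(leadingEdges) >= 1L)
  nPath <- length(leadingEdges)
  thr <- ceiling(fraction * nPath)
  tab <- table(unlist(lapply(leadingEdges, unique)))
  out <- data.frame(gene = names(tab), n_leading_edges = as.integer(tab),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_leading_edges, out$gene), , drop = FALSE]
  out$qualifies <- out$n_leading_edges >= thr
  rownames(out) <- NULL
  attr(out, "threshold") <- as.integer(thr)
  out
}

#' Core genes shared between two categories
#'
#' @param a,b `coreGeneCounts()` results for two categories.
#' @return character vector of qualifying genes common to both.
#' @export
coreGeneOverlap <- function(a, b) {
  intersect(a$gene[a$qualifies], b$gene[b$qualifies])
}

#' Fig-1-style node-edge export of a partition
#'
#' One row per (non-empty class, member ligand) connection with up/down
#' gene counts when a gene membership table is supplied.
#'
#' @param partition an \linkS4class{OverlapPartition}.
#' @param table optional gene-kind \linkS4class{MembershipTable} for
#'   direction counts.
#' @return data.frame `class`, `ligand`, `n`, and for gene tables `n_up`,
#'   `n_down`.
#' @export
overlapEdges <- function(partition, table = NULL) {
  keys <- names(partition@counts)[partition@counts > 0L]
  rows <- lapply(keys, function(k) {
    members <- strsplit(k, "+", fixed = TRUE)[[1L]]
    base <- data.frame(class = k, ligand = members,
                       n = partition@counts[[k]],
                       row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(table) && table@kind == "gene") {
      dr <- directionRatio(table, members, ligands = partition@ligands)
      base$n_up <- dr$n_up[match(base$ligand, dr$ligand)]
      base$n_down <- dr$n_down[match(base$ligand, dr$ligand)]
    }
    base
  })
  do.call(rbind, rows)
}
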