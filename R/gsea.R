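## Weighted Kolmogorov-Smirnov gene-set enrichment against |t|-ranked
## lists, with a sample-permutation null that reruns the full linear-model/
## moderation/ranking pipeline at every iteration. Only the positive
## deviation of the running sum is scored: ranking by absolute t makes
## depletion at the top uninformative for positively enriched pathways.

#' Restrict a collection to the analyzed universe and size window
#'
#' Each set is first intersected with the universe (genes absent from the
#' expression matrix are removed from the set); sets whose reduced size
#' falls below `minSize` or above `maxSize` are then discarded. Bounds are
#' inclusive.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of analyzed gene symbols.
#' @param minSize,maxSize retained size window (defaults 10 and 500).
#' @return the filtered \linkS4class{GeneSetCollection} (possibly empty).
#' @export
filterSets <- function(collection, universe, minSize = 10, maxSize = 500) {
  stopifnot(is(collection, "GeneSetCollection"), length(universe) > 0)
  reduced <- lapply(collection@sets, intersect, universe)
  keep <- lengths(reduced) >= minSize & lengths(reduced) <= maxSize
  geneSetCollection(reduced[keep], source = collection@source)
}

#' Rank genes by absolute moderated t
#'
#' Genes are sorted by decreasing `|t|`; the same `|t|` (raised to the
#' weight exponent `q`) serves as the gene's weight in the running sum.
#' Ties in `|t|` are broken by gene symbol so the ranking is deterministic
#' and independent of input order. `q = 0` gives the classic unweighted KS
#' statistic.
#'
#' @param t named numeric vector of moderated t-statistics, one per
#'   universe gene.
#' @param q weight exponent (default 1).
#' @return A \linkS4class{RankedList}.
#' @export
rankByAbsT <- function(t, q = 1) {
  if (is.null(names(t))) stop("t must be named by gene symbol")
  if (anyDuplicated(names(t))) stop("duplicate gene symbols in t")
  a <- abs(t)
  ord <- order(-a, names(t))
  new("RankedList", genes = names(t)[ord], weights = unname(a[ord])^q)
}

#' Weighted running-sum enrichment score of one gene set
#'
#' With `N` universe genes and a set S of `N_S` members, the running sum
#' starts at 0 and, at rank i, gains `w_i / sum(w in S)` if gene i is a
#' member and loses `1 / (N - N_S)` otherwise. The enrichment score is the
#' maximum of the running sum (positive deviation only) and the peak index
#' is the smallest rank attaining it.
#'
#' @param ranked a \linkS4class{RankedList}.
#' @param members character vector of set members; only members present in
#'   the ranked universe count.
#' @return list with `es`, `peak` (rank index) and `running` (the full
#'   length-`N` running sum).
#' @export
enrichmentScore <- function(ranked, members) {
  stopifnot(is(ranked, "RankedList"))
  hit <- ranked@genes %in% members
  nS <- sum(hit)
  N <- length(hit)
  if (nS == 0L) stop("no set member is present in the ranked universe")
  if (nS == N) stop("set covers the whole universe; miss penalty undefined")
  W <- sum(ranked@weights[hit])
  if (W == 0) stop("all member weights are zero")
  inc <- ifelse(hit, ranked@weights / W, -1 / (N - nS))
  running <- cumsum(inc)
  peak <- which.max(running)
  list(es = running[peak], peak = peak, running = running)
}

## Fast ES used inside permutations: the running-sum maximum is always
## attained at a hit position (the sum decreases strictly between hits), so
## only hit positions are evaluated. weights must be the full ranked weight
## vector; hitPos the sorted ranks of the members.
.esAtHits <- function(weights, hitPos, N) {
  m <- length(hitPos)
  W <- sum(weights[hitPos])
  if (W == 0) return(NA_real_)
  max(cumsum(weights[hitPos]) / W - (hitPos - seq_len(m)) / (N - m))
}

#' Sample-permutation null distribution of enrichment scores
#'
#' At each iteration the sample-to-group assignment of the design is
#' permuted uniformly at random among assignments preserving the group
#' sizes (drawn with replacement across iterations), and the entire
#' statistic pipeline is rerun on the permuted labels: group-mean fit,
#' re-estimation of the moderation prior, moderated t for all four
#' contrasts, re-ranking, and scoring of every set. Permutation `b` uses
#' seed `seed + b`, so any single iteration is reproducible in isolation.
#'
#' @param expr a \linkS4class{GeneExperiment}.
#' @param design a \linkS4class{DesignSpec} for one time point.
#' @param collection a filtered \linkS4class{GeneSetCollection}.
#' @param nPerm number of permutations (default 500).
#' @param seed integer root seed.
#' @param q weight exponent passed to [rankByAbsT()].
#' @return A \linkS4class{PermutationNull}.
#' @export
permutationNull <- function(expr, design, collection, nPerm = 500, seed = 1,
                            q = 1) {
  stopifnot(is(expr, "GeneExperiment"), is(design, "DesignSpec"),
            is(collection, "GeneSetCollection"))
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  samples <- names(design@groups)
  x <- assay(expr)[, samples, drop = FALSE]
  labels <- design@groups
  nSets <- length(collection@sets)
  out <- lapply(design@treatments, function(tr)
    matrix(NA_real_, nPerm, nSets,
           dimnames = list(NULL, names(collection@sets))))
  names(out) <- design@treatments
  for (b in seq_len(nPerm)) {
    perm <- withr::with_seed(seed + b, sample.int(length(labels)))
    pg <- labels[perm]
    names(pg) <- samples
    scores <- .scoreAllContrasts(x, pg, design, collection, q)
    for (tr in design@treatments) out[[tr]][b, ] <- scores[[tr]]
  }
  new("PermutationNull", es = out, nPerm = nPerm, seed = as.integer(seed))
}

## one full pipeline pass on a (possibly permuted) labeling: fit, moderate,
## t per contrast, rank, score every set; returns list contrast -> ES vector
.scoreAllContrasts <- function(x, groups, design, collection, q) {
  fit <- .fitGroupsMatrix(x, groups)
  params <- estimateModeration(fit)
  d0 <- params@d0; s0sq <- params@s0sq; d <- fit@df
  s2post <- if (is.infinite(d0)) rep(s0sq, length(fit@sigma2))
            else (d0 * s0sq + d * fit@sigma2) / (d0 + d)
  nC <- fit@groupSizes[[design@controlLabel]]
  genes <- rownames(x)
  N <- length(genes)
  lapply(setNames(design@treatments, design@treatments), function(tr) {
    nT <- fit@groupSizes[[tr]]
    lfc <- fit@coefficients[, tr] - fit@coefficients[, design@controlLabel]
    tstat <- lfc / sqrt(s2post * (1 / nT + 1 / nC))
    a <- abs(tstat)
    ord <- order(-a, genes)
    w <- a[ord]^q
    rankOf <- integer(N)
    rankOf[ord] <- seq_len(N)
    names(rankOf) <- genes
    vapply(collection@sets, function(s) {
      .esAtHits(w, sort(rankOf[s]), N)
    }, 0)
  })
}

#' Empirical permutation p-values
#'
#' The p-value of a set (per contrast) is the proportion of permutations
#' whose null enrichment score strictly exceeds the observed one; no
#' pseudo-count and no cross-set normalization.
#'
#' @param observed `nSets x nContrasts` matrix of observed enrichment
#'   scores (set names as row names, contrasts as column names).
#' @param null a \linkS4class{PermutationNull} on the same collection.
#' @param pseudoCount if `TRUE`, use `(1 + #higher) / (1 + nPerm)` so p is
#'   strictly positive.
#' @return matrix of the same shape as `observed`.
#' @export
empiricalP <- function(observed, null, pseudoCount = FALSE) {
  stopifnot(is.matrix(observed), is(null, "PermutationNull"))
  if (!all(colnames(observed) %in% names(null@es)))
    stop("observed contrasts missing from the permutation null")
  p <- observed
  for (ct in colnames(observed)) {
    nm <- null@es[[ct]]
    if (!identical(colnames(nm), rownames(observed)))
      stop("set mismatch between observed scores and permutation null")
    higher <- colSums(nm > rep(observed[, ct], each = nrow(nm)))
    p[, ct] <- if (pseudoCount) (1 + higher) / (1 + null@nPerm)
               else higher / null@nPerm
  }
  p
}

#' Globally pooled BH adjustment across the contrasts of one time point
#'
#' The raw p-values of all sets across all four contrasts of a time point
#' are pooled into a single family, adjusted by Benjamini-Hochberg, and
#' redistributed to their positions.
#'
#' @param p `nSets x nContrasts` matrix of raw empirical p-values.
#' @return matrix of adjusted p-values, same shape.
#' @export
adjustGlobal <- function(p) {
  stopifnot(is.matrix(p))
  if (anyNA(p)) stop("missing p-values")
  adj <- adjustBH(as.vector(p))
  matrix(adj, nrow(p), ncol(p), dimnames = dimnames(p))
}

#' Flag enriched gene sets
#'
#' A set is called (potentially) enriched when its adjusted p-value is
#' strictly below `alpha` (default 0.2).
#'
#' @param adjP adjusted p-values (any shape).
#' @param alpha threshold.
#' @return logical of the same shape.
#' @export
callEnriched <- function(adjP, alpha = 0.2) adjP < alpha

#' Leading-edge subset of a gene set
#'
#' The set members ranked at or before the running-sum peak, in rank order:
#' the genes that drive the enrichment signal.
#'
#' @param ranked a \linkS4class{RankedList}.
#' @param members set members.
#' @param peak peak rank index from [enrichmentScore()].
#' @return character vector of leading-edge genes.
#' @export
leadingEdge <- function(ranked, members, peak) {
  stopifnot(is(ranked, "RankedList"), peak >= 1)
  top <- ranked@genes[seq_len(peak)]
  top[top %in% members]
}

#' Gene-set enrichment for one time point, end to end
#'
#' Filters the collection against the expression universe, computes
#' observed enrichment scores on the |t|-ranked lists of the four
#' treatment-versus-control contrasts, builds the sample-permutation null,
#' derives empirical p-values, adjusts them globally across the four
#' contrasts, flags enrichment at `alpha`, and extracts leading edges.
#'
#' @param expr a \linkS4class{GeneExperiment}.
#' @param timePoint time point to analyze.
#' @param collection a \linkS4class{GeneSetCollection} (unfiltered).
#' @param nPerm permutations (default 500).
#' @param seed root seed for the permutation stream.
#' @param alpha enrichment threshold on the adjusted p-value (default 0.2).
#' @param q weight exponent.
#' @param minSize,maxSize set-size window after universe intersection.
#' @param treatments,controls passed to [poolControls()].
#' @param pseudoCount passed to [empiricalP()].
#' @return data.frame with one row per set x contrast: `set`, `contrast`,
#'   `time_point`, `size`, `es`, `peak_rank`, `p_value`, `adj_p_value`,
#'   `enriched`, `leading_edge` (comma-joined symbols in rank order).
#' @export
runGsea <- function(expr, timePoint, collection, nPerm = 500, seed = 1,
                    alpha = 0.2, q = 1, minSize = 10, maxSize = 500,
                    treatments = c("FXR-L", "LXR-L", "PPARa-L", "CDCA"),
                    controls = c("DMSO", "untreated"), pseudoCount = FALSE) {
  design <- poolControls(expr, timePoint, treatments, controls)
  filtered <- filterSets(collection, rownames(expr), minSize, maxSize)
  setsV <- names(filtered@sets)
  if (!length(setsV)) {
    return(data.frame(set = character(), contrast = character(),
                      time_point = character(), size = integer(),
                      es = numeric(), peak_rank = integer(),
                      p_value = numeric(), adj_p_value = numeric(),
                      enriched = logical(), leading_edge = character(),
                      stringsAsFactors = FALSE))
  }
  fit <- fitGroups(expr, design)
  params <- estimateModeration(fit)
  stats <- moderatedT(fit, params, design)

  obs <- matrix(NA_real_, length(setsV), length(treatments),
                dimnames = list(setsV, treatments))
  peaks <- obs
  ledges <- matrix("", length(setsV), length(treatments),
                   dimnames = list(setsV, treatments))
  for (tr in treatments) {
    st <- stats[stats$contrast == tr, ]
    ranked <- rankByAbsT(setNames(st$t, st$gene), q = q)
    for (s in setsV) {
      sc <- enrichmentScore(ranked, filtered@sets[[s]])
      obs[s, tr] <- sc$es
      peaks[s, tr] <- sc$peak
      ledges[s, tr] <- paste(leadingEdge(ranked, filtered@sets[[s]], sc$peak),
                             collapse = ",")
    }
  }
  null <- permutationNull(expr, design, filtered, nPerm = nPerm, seed = seed,
                          q = q)
  p <- empiricalP(obs, null, pseudoCount = pseudoCount)
  adjP <- adjustGlobal(p)
  enr <- callEnriched(adjP, alpha)

  do.call(rbind, lapply(treatments, function(tr) {
    data.frame(set = setsV, contrast = tr, time_point = timePoint,
               size = lengths(filtered@sets)[setsV],
               es = obs[, tr], peak_rank = as.integer(peaks[, tr]),
               p_value = p[, tr], adj_p_value = adjP[, tr],
               enriched = enr[, tr], leading_edge = ledges[, tr],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
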