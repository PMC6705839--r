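## Per-time-point five-group linear model with empirical-Bayes moderated
## t-statistics. The model is fitted in its group-mean parameterization
## (equivalent to least squares on a one-hot design); moderation shrinks
## gene-wise residual variances toward a scaled inverse chi-square prior
## whose parameters are estimated by moment matching on the log variances.

#' Fit per-gene group means and residual variances
#'
#' @param expr a \linkS4class{GeneExperiment} containing every sample of the
#'   design (extra samples, e.g. from the other time point, are ignored).
#' @param design a \linkS4class{DesignSpec}.
#' @return A \linkS4class{LinearFit}. Residual degrees of freedom are
#'   `n_samples - n_groups`.
#' @export
fitGroups <- function(expr, design) {
  stopifnot(is(expr, "GeneExperiment"), is(design, "DesignSpec"))
  samples <- names(design@groups)
  missing <- setdiff(samples, colnames(expr))
  if (length(missing))
    stop("design sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  x <- assay(expr)[, samples, drop = FALSE]
  .fitGroupsMatrix(x, design@groups)
}

## group-mean least squares on a plain matrix; shared with the permutation
## machinery where constructing SummarizedExperiments per iteration would
## dominate the run time
.fitGroupsMatrix <- function(x, groups) {
  lev <- levels(groups)
  nk <- tabulate(groups, nbins = length(lev))
  if (any(nk == 0L)) stop("group(s) with no samples: ",
                          paste(lev[nk == 0L], collapse = ", "))
  n <- ncol(x)
  df <- n - length(lev)
  if (df <= 0L) stop("no residual degrees of freedom (n <= number of groups)")
  ind <- outer(as.integer(groups), seq_along(lev), "==") + 0
  means <- x %*% ind %*% diag(1 / nk, length(lev))
  colnames(means) <- lev
  rss <- rowSums(x^2) - drop(means^2 %*% nk)
  rss[rss < 0] <- 0  # guard against cancellation at ~0 residuals
  new("LinearFit", coefficients = means, sigma2 = rss / df, df = df,
      groupSizes = setNames(as.integer(nk), lev))
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration. Vectorized.
#'
#' @param y positive target values.
#' @return x with `trigamma(x) = y` to ~1e-10 relative accuracy.
#' @export
trigammaInverse <- function(y) {
  out <- y
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  todo <- y <= 1e7 & y >= 1e-6
  x <- 0.5 + 1 / y[todo]
  for (i in seq_len(75L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (!length(x) || max(-dif / x) < 1e-12) break
  }
  out[todo] <- x
  out
}

#' Estimate the variance-moderation prior by moment matching
#'
#' With `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`, the prior degrees of
#' freedom solve `trigamma(d0/2) = var(e) - trigamma(d/2)` (monotone
#' root-finding on the trigamma function; `d0 = Inf` when the right-hand
#' side is non-positive, i.e. the observed spread of log variances is no
#' larger than sampling noise alone explains) and
#' `s0sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`
#' (limit `exp(mean(e))` at `d0 = Inf`). Genes with zero residual variance
#' are excluded from estimation (they carry no log-variance information)
#' but are still moderated downstream.
#'
#' @param fit a \linkS4class{LinearFit} with at least 100 genes of positive
#'   residual variance.
#' @return A \linkS4class{ModerationParams}.
#' @export
estimateModeration <- function(fit) {
  stopifnot(is(fit, "LinearFit"))
  s2 <- fit@sigma2[fit@sigma2 > 0]
  if (!length(s2)) stop("all residual variances are zero; cannot moderate")
  if (length(s2) < 100L)
    stop("moderation prior estimation needs >= 100 genes with positive ",
         "residual variance (have ", length(s2), ")")
  d <- fit@df
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  rhs <- var(e) - trigamma(d / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigammaInverse(rhs)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  moderationParams(d0, s0sq)
}

#' Moderated t-statistics for the four treatment-versus-control contrasts
#'
#' Posterior variance `s2post = (d0*s0sq + d*s2) / (d0 + d)` (equal to
#' `s0sq` at `d0 = Inf`, to `s2` at `d0 = 0`); the contrast standard error
#' is `sqrt(s2post * (1/n_t + 1/n_c))`; two-sided p-values come from a t
#' distribution with `d + d0` degrees of freedom (normal at `d0 = Inf`).
#'
#' @param fit a \linkS4class{LinearFit}.
#' @param params a \linkS4class{ModerationParams} (typically estimated from
#'   the same fit).
#' @param design the \linkS4class{DesignSpec} the fit came from.
#' @return data.frame with one row per gene x contrast: `gene`, `contrast`
#'   (treatment label), `lfc`, `t`, `p_value`.
#' @export
moderatedT <- function(fit, params, design) {
  stopifnot(is(fit, "LinearFit"), is(params, "ModerationParams"),
            is(design, "DesignSpec"))
  d0 <- params@d0; s0sq <- params@s0sq
  d <- fit@df
  s2post <- if (is.infinite(d0)) rep(s0sq, length(fit@sigma2))
            else (d0 * s0sq + d * fit@sigma2) / (d0 + d)
  dfTotal <- d + d0
  nC <- fit@groupSizes[[design@controlLabel]]
  genes <- rownames(fit@coefficients)
  res <- lapply(design@treatments, function(tr) {
    nT <- fit@groupSizes[[tr]]
    lfc <- fit@coefficients[, tr] - fit@coefficients[, design@controlLabel]
    se <- sqrt(s2post * (1 / nT + 1 / nC))
    if (any(se == 0 & lfc != 0))
      stop("zero standard error with nonzero effect; residual and prior ",
           "variance both degenerate")
    t <- ifelse(lfc == 0, 0, lfc / se)
    p <- 2 * pt(-abs(t), df = dfTotal)
    data.frame(gene = genes, contrast = tr, lfc = unname(lfc),
               t = unname(t), p_value = unname(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals raw p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
adjustBH <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes
#'
#' Adds (or refreshes) per-contrast BH-adjusted p-values, flags genes with
#' adjusted p below `alpha`, and annotates the regulation direction from
#' the sign of the log fold change.
#'
#' @param results contrast data.frame from [moderatedT()]; may span several
#'   contrasts and time points.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param pool if `TRUE`, adjust all p-values in `results` as one family
#'   instead of per contrast (and per time point, when present).
#' @return the input with columns `adj_p_value`, `de`, `direction` added.
#' @export
callDE <- function(results, alpha = 0.05, pool = FALSE) {
  stopifnot(is.data.frame(results), alpha >= 0, alpha <= 1)
  fam <- if (pool) rep("all", nrow(results))
         else if ("time_point" %in% colnames(results))
           paste(results$contrast, results$time_point)
         else results$contrast
  results$adj_p_value <- ave(results$p_value, fam, FUN = adjustBH)
  results$de <- results$adj_p_value < alpha
  results$direction <- ifelse(results$lfc < 0, "down", "up")
  results
}

#' Differential expression for one time point, end to end
#'
#' [poolControls()] then [fitGroups()], [estimateModeration()],
#' [moderatedT()] and [callDE()].
#'
#' @param expr a \linkS4class{GeneExperiment}.
#' @param timePoint time point to analyze.
#' @param alpha DE threshold on the BH-adjusted p-value.
#' @param treatments,controls passed to [poolControls()].
#' @param pool adjust p-values across the four contrasts as one family.
#' @return contrast data.frame with a `time_point` column.
#' @export
runDE <- function(expr, timePoint, alpha = 0.05,
                  treatments = c("FXR-L", "LXR-L", "PPARa-L", "CDCA"),
                  controls = c("DMSO", "untreated"), pool = FALSE) {
  design <- poolControls(expr, timePoint, treatments, controls)
  fit <- fitGroups(expr, design)
  params <- estimateModeration(fit)
  res <- moderatedT(fit, params, design)
  res$time_point <- timePoint
  callDE(res, alpha = alpha, pool = pool)
}
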