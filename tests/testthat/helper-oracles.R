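# Independent oracles, written against the definitions rather than the
# package internals, for dual-route checks.

# Explicit running-sum accumulation of the weighted KS statistic.
oracleRunningSum <- function(weights, hit) {
  N <- length(weights)
  nS <- sum(hit)
  W <- sum(weights[hit])
  r <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- if (hit[i]) acc + weights[i] / W else acc - 1 / (N - nS)
    r[i] <- acc
  }
  r
}

oracleES <- function(weights, hit) {
  r <- oracleRunningSum(weights, hit)
  list(es = max(r), peak = which.max(r), running = r)
}

# Normal-equations least squares on the one-hot design, per gene via lm().
oracleGroupFit <- function(x, groups) {
  f <- factor(groups)
  fits <- apply(x, 1L, function(y) {
    m <- lm(y ~ 0 + f)
    c(coef(m), s2 = sum(resid(m)^2) / m$df.residual)
  })
  t(fits)
}

# Direct evaluation of the moderated-t formulas from group summaries
# computed with tapply (independent of the package's matrix algebra).
oracleModeratedT <- function(x, groups, treatment, control, d0, s0sq) {
  f <- factor(groups)
  nk <- table(f)
  means <- t(apply(x, 1L, function(y) tapply(y, f, mean)))
  d <- ncol(x) - nlevels(f)
  s2 <- apply(x, 1L, function(y) {
    mu <- tapply(y, f, mean)
    sum((y - mu[as.character(f)])^2) / d
  })
  s2post <- (d0 * s0sq + d * s2) / (d0 + d)
  lfc <- means[, treatment] - means[, control]
  se <- sqrt(s2post * (1 / nk[[treatment]] + 1 / nk[[control]]))
  t <- lfc / se
  list(lfc = unname(lfc), t = unname(t),
       p = unname(2 * pt(-abs(t), df = d + d0)))
}

# Brute-force subset assignment: which exact subset of ligand->entity sets
# contains each entity.
oracleSubsetAssignment <- function(ligandSets) {
  ents <- unique(unlist(ligandSets))
  setNames(vapply(ents, function(e) {
    paste(names(ligandSets)[vapply(ligandSets, function(s) e %in% s, TRUE)],
          collapse = "+")
  }, ""), ents)
}

# A small complete study fixture for pipeline-level tests.
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    nGenes = 300, nGeneSets = 15, setSizeRange = c(10, 25),
    fracPlantedSets = 0.2, plantedSetDeFraction = 0.6,
    dePartition = data.frame(
      treatments = c("FXR-L", "FXR-L", "LXR-L", "FXR-L+LXR-L"),
      profile = c("both", "late-only", "both", "both"),
      n = c(40, 10, 25, 10), stringsAsFactors = FALSE),
    lfcMean = 1.5, lfcSd = 0.3, s0sqTrue = 0.09, seed = 11)
  defaults[names(args)] <- args
  if (!"dePartition" %in% names(args) && defaults$nGenes < 300) {
    sc <- defaults$nGenes / 300
    defaults$dePartition$n <- pmax(1L, as.integer(defaults$dePartition$n * sc))
    if (!"fracPlantedSets" %in% names(args)) defaults$fracPlantedSets <- 0
    if (!"setSizeRange" %in% names(args)) defaults$setSizeRange <- c(5, 12)
  }
  do.call(simulationConfig, defaults)
}

# Membership calls realizing a given class -> count partition, one ligand
# subset key per class ("A+B"), all at the same time point.
callsFromPartition <- function(classCounts, timePoint = "4h",
                               prefix = "e") {
  rows <- list()
  at <- 0L
  for (k in names(classCounts)) {
    n <- classCounts[[k]]
    if (n == 0L) next
    ents <- paste0(prefix, at + seq_len(n))
    at <- at + n
    for (lg in strsplit(k, "+", fixed = TRUE)[[1L]])
      rows[[length(rows) + 1L]] <- data.frame(
        entity = ents, ligand = lg, time_point = timePoint,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
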