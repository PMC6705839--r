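suppressPackageStartupMessages(library(SummarizedExperiment))

.fitFixture <- function(nGenes = 30, seed = 3) {
  withr::local_seed(seed)
  sheet <- data.frame(
    sample_id = paste0("s", 1:12),
    condition = rep(c("FXR-L", "LXR-L", "PPARa-L", "CDCA", "DMSO",
                      "untreated"), each = 2),
    time_point = "4h", replicate = paste0("r", 1:12),
    stringsAsFactors = FALSE)
  m <- matrix(rnorm(nGenes * 12), nGenes, 12,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sheet$sample_id))
  ge <- geneExperiment(m, sheet)
  list(ge = ge, design = poolControls(sheet, "4h"), m = m, sheet = sheet)
}

test_that("group means and residuals are exact on a constant fixture", {
  fx <- .fitFixture()
  m <- fx$m
  m[1L, ] <- rep(c(1, 2, 3, 4, 5, 5), each = 2)  # within-group constant
  ge <- geneExperiment(m, fx$sheet)
  fit <- fitGroups(ge, fx$design)
  expect_equal(unname(fit@coefficients[1L, ]), c(1, 2, 3, 4, 5))
  expect_equal(fit@sigma2[[1L]], 0)
  expect_equal(fit@df, 7)
})

test_that("a global shift moves means but not residual variances", {
  fx <- .fitFixture()
  fit <- fitGroups(fx$ge, fx$design)
  ge2 <- geneExperiment(fx$m + 3, fx$sheet)
  fit2 <- fitGroups(ge2, fx$design)
  expect_equal(fit2@coefficients, fit@coefficients + 3)
  expect_equal(fit2@sigma2, fit@sigma2)
})

test_that("the group-mean fit equals a per-gene lm() oracle", {
  fx <- .fitFixture(nGenes = 30)
  fit <- fitGroups(fx$ge, fx$design)
  oracle <- oracleGroupFit(fx$m, as.character(fx$design@groups[colnames(fx$m)]))
  # lm coefficient columns are alphabetical in the factor levels
  for (g in levels(fx$design@groups))
    expect_equal(unname(fit@coefficients[, g]),
                 unname(oracle[, paste0("f", g)]), tolerance = 1e-10)
  expect_equal(unname(fit@sigma2), unname(oracle[, "s2"]), tolerance = 1e-10)
})

test_that("trigamma inversion matches forward evaluation", {
  expect_equal(trigammaInverse(trigamma(2)), 2, tolerance = 1e-8)
  x <- c(0.1, 0.5, 1, 5, 20)
  expect_equal(trigammaInverse(trigamma(x)), x, tolerance = 1e-8)
})

test_that("moderation recovers the generating prior on simulated variances", {
  withr::local_seed(42)
  n <- 5000; d0 <- 4; s0sq <- 1; d <- 13
  varTrue <- s0sq * d0 / rchisq(n, d0)
  s2 <- varTrue * rchisq(n, d) / d
  fit <- new("LinearFit",
             coefficients = matrix(0, n, 5,
                                   dimnames = list(sprintf("g%04d", 1:n),
                                                   c("a", "b", "c", "d", "control"))),
             sigma2 = s2, df = d,
             groupSizes = c(a = 3L, b = 3L, c = 3L, d = 3L, control = 6L))
  params <- estimateModeration(fit)
  expect_gt(priorDf(params), 3); expect_lt(priorDf(params), 5)
  expect_gt(priorVar(params), 0.9); expect_lt(priorVar(params), 1.1)
})

test_that("equal observed variances give an infinite prior df", {
  withr::local_seed(6)
  fit <- new("LinearFit",
             coefficients = matrix(c(rnorm(200), rep(0, 200)), 200, 2,
                                   dimnames = list(sprintf("g%03d", 1:200),
                                                   c("a", "control"))),
             sigma2 = rep(0.25, 200), df = 10,
             groupSizes = c(a = 3L, control = 6L))
  params <- estimateModeration(fit)
  expect_identical(priorDf(params), Inf)
  # zero dispersion: s0sq is the d0 -> Inf limit exp(mean(e)) of the
  # moment estimator, the value consistent with the common log variance
  s0 <- 0.25 * exp(log(5) - digamma(5))
  expect_equal(priorVar(params), s0, tolerance = 1e-12)
  design <- new("DesignSpec", timePoint = "4h",
                groups = factor(setNames(rep(c("a", "control"), c(3, 6)),
                                         paste0("s", 1:9)),
                                levels = c("a", "control")),
                treatments = "a", controlLabel = "control")
  res <- moderatedT(fit, params, design)
  # d0 = Inf: t = lfc / (s0 * sqrt(1/n_t + 1/n_c)) exactly, p is normal
  expect_equal(res$t, res$lfc / sqrt(s0 * (1 / 3 + 1 / 6)),
               tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$t)), tolerance = 1e-12)
})

test_that("moderation parameter estimation matches limma's fitFDist", {
  skip_if_not_installed("limma")
  withr::local_seed(8)
  s2 <- rexp(1000, 2) + 0.01
  fit <- new("LinearFit",
             coefficients = matrix(0, 1000, 2,
                                   dimnames = list(sprintf("g%04d", 1:1000),
                                                   c("a", "control"))),
             sigma2 = s2, df = 13, groupSizes = c(a = 3L, control = 6L))
  params <- estimateModeration(fit)
  ref <- limma::fitFDist(s2, df1 = 13)
  expect_equal(priorDf(params), ref$df2, tolerance = 1e-6)
  expect_equal(priorVar(params), ref$scale, tolerance = 1e-6)
})

test_that("moderated t matches the independent formula oracle to 1e-10", {
  fx <- .fitFixture(nGenes = 20, seed = 11)
  fit <- fitGroups(fx$ge, fx$design)
  params <- moderationParams(d0 = 4, s0sq = 0.5)
  res <- moderatedT(fit, params, fx$design)
  groups <- as.character(fx$design@groups[colnames(fx$m)])
  groups[groups == "control"] <- "control"
  for (tr in fx$design@treatments) {
    o <- oracleModeratedT(fx$m, groups, tr, "control", 4, 0.5)
    r <- res[res$contrast == tr, ]
    expect_equal(r$lfc, o$lfc, tolerance = 1e-10)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("the full moderated pipeline agrees with limma", {
  skip_if_not_installed("limma")
  fx <- .fitFixture(nGenes = 400, seed = 21)
  # heterogeneous gene variances so the prior df estimate is finite (the
  # two moment estimators share the finite-d0 branch)
  scale <- sqrt(4 / rchisq(400, 4))
  m <- fx$m * scale
  fx$ge <- geneExperiment(m, fx$sheet)
  fx$m <- m
  fit <- fitGroups(fx$ge, fx$design)
  params <- estimateModeration(fit)
  res <- moderatedT(fit, params, fx$design)

  groups <- fx$design@groups[colnames(fx$m)]
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- make.names(levels(groups))  # FXR.L etc.
  lfit <- limma::lmFit(fx$m, design)
  cm <- limma::makeContrasts(
    contrasts = paste0(setdiff(colnames(design), "control"), " - control"),
    levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  for (i in seq_along(fx$design@treatments)) {
    r <- res[res$contrast == fx$design@treatments[i], ]
    expect_equal(r$t, unname(eb$t[, i]), tolerance = 1e-6)
    expect_equal(r$p_value, unname(eb$p.value[, i]), tolerance = 1e-6)
  }
})

test_that("d0 = 0 reproduces the ordinary pooled-variance t", {
  fx <- .fitFixture(nGenes = 15, seed = 2)
  fit <- fitGroups(fx$ge, fx$design)
  res <- moderatedT(fit, moderationParams(0, 1), fx$design)
  tr <- "FXR-L"
  lfc <- fit@coefficients[, tr] - fit@coefficients[, "control"]
  se <- sqrt(fit@sigma2 * (1 / 2 + 1 / 4))
  expect_equal(res$t[res$contrast == tr], unname(lfc / se), tolerance = 1e-12)
})

test_that("negating the matrix negates effects and statistics", {
  fx <- .fitFixture(nGenes = 150, seed = 13)
  fit <- fitGroups(fx$ge, fx$design)
  params <- estimateModeration(fit)
  res <- moderatedT(fit, params, fx$design)
  geN <- geneExperiment(-fx$m, fx$sheet)
  fitN <- fitGroups(geN, fx$design)
  resN <- moderatedT(fitN, estimateModeration(fitN), fx$design)
  expect_equal(resN$lfc, -res$lfc, tolerance = 1e-12)
  expect_equal(resN$t, -res$t, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjustBH(0.3), 0.3)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::local_seed(4)
  p <- runif(50)
  q <- adjustBH(p)
  expect_true(all(q >= p))
  expect_identical(order(q[order(p)]), seq_len(50L))  # monotone in p order
  expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE calling respects the alpha boundary", {
  fx <- .fitFixture(nGenes = 150, seed = 5)
  fit <- fitGroups(fx$ge, fx$design)
  res <- moderatedT(fit, estimateModeration(fit), fx$design)
  expect_identical(sum(callDE(res, alpha = 0)$de), 0L)
  all1 <- callDE(res, alpha = 1)
  expect_identical(all1$de, all1$adj_p_value < 1)
  called <- callDE(res, alpha = 0.5)
  expect_true(all(called$direction[called$de] ==
                    ifelse(called$lfc[called$de] < 0, "down", "up")))
})

test_that("null data keep the DE rate at or below the nominal level", {
  # global null across seeds: fraction of genes called at BH 0.05
  rates <- vapply(1:20, function(s) {
    cfg <- simulationConfig(
      nGenes = 800, fracPlantedSets = 0, nGeneSets = 2,
      probesPerGene = c(1, 0, 0), fracUnmappedProbes = 0,
      dePartition = data.frame(treatments = character(),
                               profile = character(), n = integer()),
      seed = 1000 + s)
    truth <- generateTruth(cfg)
    pe <- generateExpression(truth, cfg)
    ge <- collapseProbes(pe, "4h")
    de <- runDE(ge, "4h", alpha = 0.05)
    mean(tapply(de$de, de$gene, any))
  }, 0)
  expect_lte(mean(rates), 0.05 + 3 * sqrt(0.05 / 800))
})

test_that("planted strong effects are detected with high power", {
  cfg <- simulationConfig(
    nGenes = 600, lfcMean = 1.5, lfcSd = 0, s0sqTrue = 0.09, d0True = 20,
    fracPlantedSets = 0, nGeneSets = 2, probesPerGene = c(1, 0, 0),
    fracUnmappedProbes = 0,
    dePartition = data.frame(treatments = "FXR-L", profile = "both", n = 100),
    seed = 77)
  sim <- simulateStudy(cfg)
  ge <- collapseProbes(sim$probes, "4h")
  de <- runDE(ge, "4h", alpha = 0.05)
  planted <- truthGenes(sim$truth)$gene[truthGenes(sim$truth)$treatments == "FXR-L"]
  hits <- de$de[de$contrast == "FXR-L"][match(planted,
                                              de$gene[de$contrast == "FXR-L"])]
  expect_gte(mean(hits), 0.92)
})
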