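test_that("membership records per-ligand presence and time profiles", {
  calls <- data.frame(
    entity = c("g1", "g1", "g2", "g3"),
    ligand = c("FXR-L", "FXR-L", "FXR-L", "LXR-L"),
    time_point = c("4h", "24h", "4h", "24h"),
    direction = c("up", "down", "up", "down"),
    stringsAsFactors = FALSE)
  mt <- buildMembership(calls, "gene")
  d <- membershipData(mt)
  expect_identical(d$profile[d$entity == "g1"], "both")
  expect_identical(d$profile[d$entity == "g2"], "4h only")
  expect_identical(d$profile[d$entity == "g3"], "24h only")
  expect_identical(d$dir_4h[d$entity == "g1"], "up")
  expect_identical(d$dir_24h[d$entity == "g1"], "down")
})

test_that("empty call lists give an empty membership table", {
  mt <- buildMembership(data.frame(entity = character(),
                                   ligand = character(),
                                   time_point = character()), "gene")
  expect_identical(nrow(membershipData(mt)), 0L)
  part <- partitionOverlaps(mt, c("FXR-L", "LXR-L"))
  expect_identical(sum(overlapCounts(part)), 0L)
})

test_that("conflicting duplicate calls are rejected", {
  calls <- data.frame(entity = "g1", ligand = "FXR-L",
                      time_point = c("4h", "4h"),
                      direction = c("up", "down"), stringsAsFactors = FALSE)
  expect_error(buildMembership(calls, "gene"), "conflicting")
})

test_that("overlap partitioning matches the explicit three-set example", {
  # A = {a,b,c}, B = {b,c,d}, C = {c}
  calls <- rbind(
    data.frame(entity = c("a", "b", "c"), ligand = "A", time_point = "4h"),
    data.frame(entity = c("b", "c", "d"), ligand = "B", time_point = "4h"),
    data.frame(entity = "c", ligand = "C", time_point = "4h"))
  part <- partitionOverlaps(buildMembership(calls, "gene"), c("A", "B", "C"))
  n <- overlapCounts(part)
  expect_identical(unname(n[c("A", "B", "C", "A+B", "A+C", "B+C", "A+B+C")]),
                   c(1L, 1L, 0L, 1L, 0L, 0L, 1L))
})

test_that("partitioning equals a brute-force subset-assignment oracle", {
  withr::local_seed(23)
  ligands <- c("FXR-L", "LXR-L", "PPARa-L")
  sets <- lapply(setNames(ligands, ligands), function(i)
    sample(paste0("g", 1:60), sample(10:40, 1L)))
  calls <- do.call(rbind, lapply(ligands, function(lg)
    data.frame(entity = sets[[lg]], ligand = lg,
               time_point = sample(c("4h", "24h"), length(sets[[lg]]),
                                   replace = TRUE),
               stringsAsFactors = FALSE)))
  part <- partitionOverlaps(buildMembership(calls, "gene"), ligands)
  oracle <- oracleSubsetAssignment(sets)
  a <- part@assignment
  expect_identical(setNames(a$class, a$entity)[names(oracle)], oracle)
  # counts are order-invariant
  part2 <- partitionOverlaps(
    buildMembership(calls[rev(seq_len(nrow(calls))), ], "gene"), ligands)
  expect_identical(overlapCounts(part2), overlapCounts(part))
})

test_that("sharing is computed on the union over time points", {
  # FXR calls at 4h only, LXR calls the same gene at 24h only: still shared
  calls <- data.frame(entity = "g1", ligand = c("FXR-L", "LXR-L"),
                      time_point = c("4h", "24h"), stringsAsFactors = FALSE)
  part <- partitionOverlaps(buildMembership(calls, "gene"),
                            c("FXR-L", "LXR-L"))
  expect_identical(unname(overlapCounts(part)["FXR-L+LXR-L"]), 1L)
})

test_that("a single selected ligand collects all its entities in one class", {
  calls <- data.frame(entity = paste0("g", 1:7), ligand = "FXR-L",
                      time_point = "4h", stringsAsFactors = FALSE)
  part <- partitionOverlaps(buildMembership(calls, "gene"), "FXR-L")
  expect_identical(unname(overlapCounts(part)["FXR-L"]), 7L)
})

test_that("profile summary partitions the entity total", {
  calls <- rbind(
    callsFromPartition(c("FXR-L" = 5), timePoint = "4h", prefix = "a"),
    callsFromPartition(c("FXR-L" = 3), timePoint = "24h", prefix = "b"))
  both <- data.frame(entity = paste0("c", 1:2), ligand = "FXR-L",
                     time_point = rep(c("4h", "24h"), each = 2),
                     stringsAsFactors = FALSE)
  part <- partitionOverlaps(buildMembership(rbind(calls, both), "gene"),
                            "FXR-L")
  ps <- timepointProfileSummary(part)
  expect_identical(setNames(ps$n, ps$profile),
                   c("4h only" = 5L, "24h only" = 3L, "both" = 2L))
  expect_identical(attr(ps, "total"), 10L)
  expect_equal(sum(ps$pct), 100, tolerance = 0.3)
})

test_that("category cross-tabulation and coverage follow the map", {
  counts <- c("FXR-L" = 6, "FXR-L+LXR-L" = 4)
  part <- partitionOverlaps(
    buildMembership(callsFromPartition(counts, prefix = "P"), "pathway"),
    c("FXR-L", "LXR-L"))
  # first 6 pathways (FXR-only) Metabolism; shared 4: 3 CellGrowthDeath + 1 unmapped
  cmap <- setNames(c(rep("Metabolism", 6), rep("CellGrowthDeath", 3)),
                   paste0("P", 1:9))
  tab <- categorize(part, cmap)
  shared <- tab[tab$class == "FXR-L+LXR-L", ]
  expect_identical(shared$n[shared$category == "CellGrowthDeath"], 3L)
  expect_identical(shared$n[shared$category == "Other"], 1L)
  expect_equal(shared$pct_within_class[shared$category == "CellGrowthDeath"],
               75)
  cov <- categoryCoverage(part, cmap)
  expect_identical(setNames(cov$n, cov$category),
                   c(Metabolism = 6L, CellGrowthDeath = 3L, Other = 1L))
  expect_identical(cov$pct[cov$category == "Metabolism"], 60)
})

test_that("direction ratios count signs with 24h precedence on conflict", {
  calls <- data.frame(
    entity = c("g1", "g2", "g3", "g3"),
    ligand = "FXR-L",
    time_point = c("4h", "4h", "4h", "24h"),
    direction = c("up", "up", "down", "up"),  # g3 conflicts; 24h wins
    stringsAsFactors = FALSE)
  mt <- buildMembership(calls, "gene")
  dr <- directionRatio(mt, "FXR-L", ligands = "FXR-L")
  expect_identical(dr$n_up, 3L)
  expect_identical(dr$n_down, 0L)
  expect_identical(dr$n_conflict, 1L)
})

test_that("direction ratios match a per-gene sign-count oracle", {
  withr::local_seed(9)
  n <- 40
  calls <- data.frame(entity = paste0("g", 1:n), ligand = "FXR-L",
                      time_point = sample(c("4h", "24h"), n, replace = TRUE),
                      direction = sample(c("up", "down"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  mt <- buildMembership(calls, "gene")
  dr <- directionRatio(mt, "FXR-L", ligands = "FXR-L")
  expect_identical(dr$n_up, sum(calls$direction == "up"))
  expect_identical(dr$n_down, sum(calls$direction == "down"))
})

test_that("pathway tables have no direction ratios", {
  mt <- buildMembership(callsFromPartition(c("FXR-L" = 3)), "pathway")
  expect_error(directionRatio(mt, "FXR-L", ligands = "FXR-L"), "gene tables")
})

test_that("regulation labels gate on the DE call before magnitude", {
  expect_identical(
    annotateRegulation(c(1.2, -2, 3, 0.4, -0.1), c(TRUE, TRUE, FALSE, TRUE, FALSE)),
    c("weak-up", "strong-down", "unchanged", "weak-up", "unchanged"))
  expect_identical(annotateRegulation(1.21, TRUE), "strong-up")
})

test_that("core-gene counting applies the ceiling threshold", {
  le10 <- setNames(rep(list("gX"), 1), "p1")
  le10 <- c(le10, setNames(lapply(2:10, function(i) paste0("q", i)),
                           paste0("p", 2:10)))
  cc <- coreGeneCounts(le10, fraction = 0.10)
  expect_true(cc$qualifies[cc$gene == "gX"])  # 1 >= ceil(1) with 10 pathways
  le20 <- setNames(lapply(1:20, function(i)
    if (i == 1) "gX" else paste0("q", i)), paste0("p", 1:20))
  cc20 <- coreGeneCounts(le20, fraction = 0.10)
  expect_false(cc20$qualifies[cc20$gene == "gX"])  # 1 < ceil(2)
})

test_that("core-gene counts match a brute-force membership oracle", {
  withr::local_seed(14)
  le <- lapply(setNames(1:12, paste0("p", 1:12)), function(i)
    sample(paste0("g", 1:30), sample(5:15, 1L)))
  cc <- coreGeneCounts(le, fraction = 0.25)
  for (g in cc$gene) {
    n <- sum(vapply(le, function(s) g %in% s, TRUE))
    expect_identical(cc$n_leading_edges[cc$gene == g], n)
    expect_identical(cc$qualifies[cc$gene == g], n >= ceiling(0.25 * 12))
  }
  other <- coreGeneCounts(le[1:6], fraction = 0.25)
  expect_identical(coreGeneOverlap(cc, other),
                   intersect(cc$gene[cc$qualifies], other$gene[other$qualifies]))
})

test_that("overlap edges expose class-ligand connections with directions", {
  calls <- data.frame(entity = c("g1", "g1", "g2"),
                      ligand = c("FXR-L", "LXR-L", "FXR-L"),
                      time_point = "4h",
                      direction = c("up", "down", "down"),
                      stringsAsFactors = FALSE)
  mt <- buildMembership(calls, "gene")
  part <- partitionOverlaps(mt, c("FXR-L", "LXR-L"))
  e <- overlapEdges(part, mt)
  shared <- e[e$class == "FXR-L+LXR-L", ]
  expect_identical(shared$n_up[shared$ligand == "FXR-L"], 1L)
  expect_identical(shared$n_down[shared$ligand == "LXR-L"], 1L)
})
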