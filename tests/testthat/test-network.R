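test_that("source intersection keeps only consensus edges", {
  tp <- TargetPredictionTable(data.frame(
    mir_id = c("m1", "m1", "m1", "m2", "m2"),
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    source = c("A", "B", "A", "A", "B")))
  map <- intersectTargetSources(tp, c("A", "B"))
  expect_identical(map, list(m1 = "g1"))   # g2/g3/g4 single-source

  expect_error(intersectTargetSources(tp, c("A", "C")),
               "required source absent.*C")

  # restriction to the analyzed universe
  map2 <- intersectTargetSources(tp, "A", universe = c("g2", "g3"))
  expect_identical(map2, list(m1 = "g2", m2 = "g3"))
})

test_that("source intersection matches a brute-force set oracle", {
  set.seed(20)
  mirs <- sprintf("m%02d", 1:15)
  genes <- sprintf("g%03d", 1:60)
  tab <- unique(data.frame(
    mir_id = sample(mirs, 500, TRUE),
    gene_id = sample(genes, 500, TRUE),
    source = sample(c("A", "B", "C"), 500, TRUE)))
  tp <- TargetPredictionTable(tab)
  map <- intersectTargetSources(tp, c("A", "B"))
  for (m in mirs) {
    inA <- tab$gene_id[tab$mir_id == m & tab$source == "A"]
    inB <- tab$gene_id[tab$mir_id == m & tab$source == "B"]
    want <- sort(intersect(inA, inB))
    got <- if (m %in% names(map)) map[[m]] else character()
    expect_identical(got, want)
  }
})

test_that("background frequencies recount the DE table exactly", {
  dirs <- c(rep("up", 10), rep("down", 20), rep("neutral", 70))
  de <- makeDEResult(sprintf("g%03d", 1:100), dirs)
  bg <- backgroundFrequencies(de, "stress_in_males")
  expect_identical(unname(bg), c(10L, 20L, 70L))
  expect_equal(sum(bg), 100L)

  allNeutral <- makeDEResult(letters[1:5], rep("neutral", 5))
  expect_identical(unname(backgroundFrequencies(allNeutral,
                                                "stress_in_males")),
                   c(0L, 0L, 5L))
})

test_that("per-miR chi-squared matches closed forms and a distribution oracle", {
  ids <- sprintf("g%04d", 1:1000)
  dirs <- c(rep("up", 100), rep("down", 200), rep("neutral", 700))
  de <- makeDEResult(ids, dirs)

  # targets proportional to the background: chi2 = 0, p = 1
  prop <- c(ids[1:10], ids[101:120], ids[301:370])
  res <- chiSquaredTargetEnrichment(list(m1 = prop), de, "stress_in_males")
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)

  # hand-computed df-2 case: obs (10,10,30), expected (5,10,35)
  obs <- c(ids[1:10], ids[101:110], ids[301:330])
  res2 <- chiSquaredTargetEnrichment(list(m1 = obs), de, "stress_in_males")
  expect_equal(res2$chisq, 25 / 5 + 0 + 25 / 35, tolerance = 1e-12)
  expect_equal(res2$p, exp(-res2$chisq / 2), tolerance = 1e-12)

  # random target draws: p equals the chisq.test oracle to 1e-10
  set.seed(21)
  for (i in 1:25) {
    tg <- sample(ids, 50)
    mine <- chiSquaredTargetEnrichment(list(m = tg), de, "stress_in_males")
    obsCounts <- c(mine$obs_up, mine$obs_down, mine$obs_neutral)
    oracle <- suppressWarnings(
      chisq.test(obsCounts, p = c(100, 200, 700) / 1000))
    expect_equal(mine$chisq, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-10)
  }

  # chi-squared p-values are uniform under random target draws; the
  # universe is kept much larger than the draw so the without-replacement
  # finite-population correction is negligible and the multinomial null
  # the test assumes holds
  bigIds <- sprintf("G%06d", 1:1e5)
  bigDE <- makeDEResult(bigIds, rep(c("up", "down", "neutral"),
                                    c(1e4, 2e4, 7e4)))
  set.seed(22)
  randomTargets <- lapply(1:1000, function(i) sample(bigIds, 1000))
  names(randomTargets) <- sprintf("m%04d", seq_along(randomTargets))
  pvals <- chiSquaredTargetEnrichment(randomTargets, bigDE,
                                      "stress_in_males")$p
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  # exclusions: too few or no in-universe targets
  expect_warning(
    none <- chiSquaredTargetEnrichment(list(m = c("zzz1", "zzz2")), de,
                                       "stress_in_males"),
    "no targets in the analyzed universe")
  expect_equal(nrow(none), 0L)
  expect_warning(
    chiSquaredTargetEnrichment(list(m = ids[1:3]), de, "stress_in_males"),
    "fewer than 5")

  # low expected counts are flagged, not dropped
  small <- makeDEResult(ids[1:100], c(rep("up", 1), rep("down", 2),
                                      rep("neutral", 97)))
  resLow <- chiSquaredTargetEnrichment(list(m = ids[1:20]), small,
                                       "stress_in_males")
  expect_true(resLow$low_expected)
})

test_that("the contingency-mode chi-squared matches the 2x3 oracle", {
  ids <- sprintf("g%04d", 1:500)
  dirs <- c(rep("up", 60), rep("down", 90), rep("neutral", 350))
  de <- makeDEResult(ids, dirs)
  set.seed(23)
  tg <- sample(ids, 40)
  mine <- chiSquaredTargetEnrichment(list(m = tg), de, "stress_in_males",
                                     mode = "contingency")
  obs <- c(mine$obs_up, mine$obs_down, mine$obs_neutral)
  tab <- rbind(obs, c(60, 90, 350) - obs)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(mine$chisq, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up rule and dominates Bonferroni", {
  bh <- bhAdjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(bh$adjusted, rep(0.04, 4))
  expect_true(all(bh$reject))

  expect_equal(bhAdjust(0.031)$adjusted, 0.031)

  set.seed(24)
  p <- runif(50)^2
  adj <- bhAdjust(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-14))
  expect_true(all(adj <= 1))
  bonf <- p.adjust(p, "bonferroni") < 0.05
  expect_true(all(which(bonf) %in% which(bhAdjust(p)$reject)))
})

test_that("association classification applies the direction rule and skips neutral targets", {
  mirDE <- makeDEResult(c("m1", "m2"), c("up", "down"),
                        logFC = c(1.5, -1.2))
  geneDE <- makeDEResult(c("g1", "g2", "g3"), c("down", "up", "neutral"),
                         logFC = c(-1, 0.8, 0.1))
  targets <- list(m1 = c("g1", "g2", "g3"), m2 = c("g1", "g3"))
  net <- classifyAssociations(c("m1", "m2"), targets, mirDE, geneDE,
                              "stress_in_males")
  e <- net@edges
  expect_equal(nrow(e), 3L)   # g3 neutral, never an edge
  expect_false("g3" %in% e$gene_id)
  get <- function(m, g) e$association[e$mir_id == m & e$gene_id == g]
  expect_identical(get("m1", "g1"), "negative")  # up vs down
  expect_identical(get("m1", "g2"), "positive")  # up vs up
  expect_identical(get("m2", "g1"), "positive")  # down vs down

  neutralMir <- makeDEResult(c("m1", "m2"), c("neutral", "down"))
  expect_error(classifyAssociations("m1", targets, neutralMir, geneDE,
                                    "stress_in_males"))
})

test_that("network summaries partition exactly", {
  mirDE <- makeDEResult(c("m1", "m2"), c("up", "up"))
  geneDE <- makeDEResult(c("g1", "g2", "g3", "g4"),
                         c("down", "down", "down", "up"))
  # shared target g1, private g2 / g3
  targets <- list(m1 = c("g1", "g2"), m2 = c("g1", "g3"))
  net <- classifyAssociations(c("m1", "m2"), targets, mirDE, geneDE,
                              "stress_in_males")
  s <- summarizeNetwork(net, deGenes = c("g1", "g2", "g3", "g4"),
                        deMirs = c("m1", "m2", "m9"))
  expect_equal(s$n_genes_targeted, 3)
  expect_equal(s$genes_multi_mir, 1)
  expect_equal(s$genes_one_mir, 2)
  expect_equal(s$genes_one_mir + s$genes_multi_mir, s$n_genes_targeted)
  expect_equal(s$genes_negative_only + s$genes_positive_only +
                 s$genes_both_signs, s$n_genes_targeted)
  expect_equal(s$frac_de_genes_targeted, 3 / 4)
  expect_equal(s$n_mirs_surviving, 2)
  expect_equal(s$frac_de_mirs_surviving, 2 / 3)

  empty <- summarizeNetwork(MiRGeneNetwork(), character(), character())
  expect_equal(empty$n_genes_targeted, 0)
  expect_equal(empty$n_mirs_surviving, 0)
})

test_that("planted coupling makes coupled miRs survive selection preferentially", {
  survC <- c(); survN <- c()
  for (s in 1:5) {
    sim <- simulateExperiment(simulationConfig(nGenes = 3000, nMirs = 200,
                                               seed = s))
    mde <- runDE(sim$mir)
    de <- runDE(sim$mrna)
    res <- mirTargetNetwork(mde, de, sim$predictions, "stress_in_males")
    enr <- res$enrichment
    coupledMirs <- unique(sim$truth$coupled_edges$mir_id[
      sim$truth$coupled_edges$sex == "male"])
    isC <- enr$mir_id %in% coupledMirs
    survC <- c(survC, enr$survives[isC])
    survN <- c(survN, enr$survives[!isC])
    # structural: no neutral nodes ever
    expect_false(any(res$network@mirNodes$direction == "neutral"))
    expect_false(any(res$network@geneNodes$direction == "neutral"))
  }
  expect_gt(mean(survC), mean(survN))
})
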