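test_that("count filter applies the per-cell expression rule", {
  design <- makeDesign()
  counts <- matrix(0L, 3, 12,
                   dimnames = list(c("allLow", "oneCell", "partCell"),
                                   design$sample_id))
  maleStress <- design$sample_id[design$sex == "male" &
                                   design$condition == "stress"]
  counts["oneCell", maleStress] <- 6L            # 3/3 >= 0.8 -> kept
  counts["partCell", maleStress] <- c(6L, 6L, 0L) # 2/3 < 0.8 -> dropped
  counts["allLow", ] <- 5L                        # never > 5 -> dropped
  # keep one gene expressed everywhere so the filter has a survivor
  counts <- rbind(counts, ubiq = 100L)
  se <- StressExperiment(counts, design, "mRNA")
  kept <- rownames(filterLowCounts(se))
  expect_setequal(kept, c("oneCell", "ubiq"))

  lowOnly <- StressExperiment(counts["allLow", , drop = FALSE], design,
                              "mRNA")
  expect_error(filterLowCounts(lowOnly), "no features pass filter")
})

test_that("log-CPM matches its closed form and is scale-stable", {
  counts <- matrix(c(100, 1e6 - 100, 0, 1e6), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  lc <- logCPM(counts)
  expect_equal(lc["a", "s1"], log2((100 + 0.5) / (1e6 + 1) * 1e6),
               tolerance = 1e-12)
  expect_equal(lc["a", "s1"], 6.6511, tolerance = 1e-4)
  expect_equal(lc["a", "s2"], -1.0000, tolerance = 1e-4)

  # CPM scale invariance in the large-count limit
  big <- matrix(c(5000, 995000), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_lt(max(abs(logCPM(2 * big) - logCPM(big))), 1e-4)

  zero <- matrix(c(0L, 0L), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(logCPM(zero), "zero total")
})

test_that("precision weights are flat for homoscedastic data and track known SD tiers", {
  design <- makeDesign()
  X <- model.matrix(~ 0 + factor(paste(design$sex, design$condition)))
  set.seed(1)
  # homoscedastic: same Gaussian noise at every abundance
  G <- 200
  lc <- matrix(rnorm(G * 12, sd = 0.4), G, 12,
               dimnames = list(sprintf("g%03d", 1:G), design$sample_id)) +
    seq(2, 10, length.out = G)
  counts <- round(2^lc)
  w <- voomWeights(lc, counts, X)
  expect_true(all(w > 0))
  expect_lt(max(w) / min(w), 1.5)

  # two abundance tiers with SD 1.0 (low) and 0.5 (high):
  # weights should differ by about (1.0/0.5)^2 = 4
  sd <- rep(c(1, 0.5), each = 100)
  mu <- rep(c(3, 10), each = 100)
  lc2 <- matrix(rnorm(200 * 12, sd = rep(sd, 12)), 200, 12,
                dimnames = list(sprintf("g%03d", 1:200),
                                design$sample_id)) + mu
  counts2 <- round(2^lc2)
  w2 <- voomWeights(lc2, counts2, X)
  ratio <- mean(w2[101:200, ]) / mean(w2[1:100, ])
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)

  idx <- c(1, 4, 7, 10)   # one library per group: zero residual df
  expect_error(voomWeights(lc[, idx], counts[, idx], X[idx, ]),
               "residual degrees of freedom")
  expect_error(voomWeights(lc[, 1:3], counts[, 1:3], X[1:3, ]),
               "fewer samples than model columns")
})

test_that("weighted group-means fit matches OLS at equal weights and a brute-force WLS oracle", {
  design <- makeDesign()
  set.seed(2)
  G <- 25
  lc <- matrix(rnorm(G * 12), G, 12,
               dimnames = list(sprintf("g%02d", 1:G), design$sample_id))
  wEq <- matrix(1, G, 12)
  fit <- fitContrasts(lc, wEq, design)
  grp <- paste(design$sex, design$condition, sep = "_")
  for (g in 1:5) {
    mns <- tapply(lc[g, ], grp, mean)
    expect_equal(unname(fit$beta[g, "stress_in_males"]),
                 unname(mns["male_stress"] - mns["male_control"]),
                 tolerance = 1e-12)
    expect_equal(unname(fit$beta[g, "stress_in_females"]),
                 unname(mns["female_stress"] - mns["female_control"]),
                 tolerance = 1e-12)
  }

  # exact group means (0,1,0,0) -> male contrast 1, female contrast 0
  mc <- ifelse(grp == "male_stress", 1, 0)
  lcExact <- matrix(rep(mc, each = 2), 2, 12, byrow = FALSE,
                    dimnames = list(c("a", "b"), design$sample_id))
  fitE <- fitContrasts(lcExact, matrix(1, 2, 12), design)
  expect_equal(unname(fitE$beta[, "stress_in_males"]), c(1, 1))
  expect_equal(unname(fitE$beta[, "stress_in_females"]), c(0, 0))

  # random weights: beta equals the normal-equations solution to 1e-10
  set.seed(3)
  w <- matrix(runif(G * 12, 0.2, 5), G, 12)
  fitW <- fitContrasts(lc, w, design)
  X <- model.matrix(~ 0 + factor(grp,
                                 levels = c("male_control", "male_stress",
                                            "female_control",
                                            "female_stress")))
  cm <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (g in seq_len(G)) {
    W <- diag(w[g, ])
    bOracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% lc[g, ])
    expect_equal(unname(fitW$beta[g, ]), as.vector(t(cm) %*% bOracle),
                 tolerance = 1e-10)
  }

  expect_error(fitContrasts(lc, wEq, design,
                            list(bad = c(1, 1, 0, 0))), "sum to zero")
})

test_that("variance moderation shrinks correctly and is calibrated on a Gaussian null", {
  # identical residual SDs are a fixed point of the shrinkage
  fit <- list(beta = matrix(rnorm(20), 10, 2,
                            dimnames = list(letters[1:10], c("c1", "c2"))),
              stdevUnscaled = matrix(0.5, 10, 2,
                                     dimnames = list(letters[1:10],
                                                     c("c1", "c2"))),
              sigma = rep(0.7, 10), df = 8,
              Amean = rep(5, 10))
  de <- moderateAndTest(fit)
  sm <- deTable(de)$sigma_moderated
  # every feature shrinks to one common value; the common value carries the
  # log-scale unbiasedness correction exp(log(df/2) - digamma(df/2)) the
  # method-of-moments prior applies, so it sits just above s_g
  expect_equal(sm, rep(sm[1], 10), tolerance = 1e-12)
  expect_equal(sm[1], 0.7 * sqrt((8 / 2) / exp(digamma(8 / 2))),
               tolerance = 1e-10)
  expect_equal(sm[1], 0.7, tolerance = 0.08)

  # moderated variance lies between the observed and the prior variance
  set.seed(4)
  fit$sigma <- sqrt(rchisq(10, 8) / 8)
  de2 <- moderateAndTest(fit)
  s2 <- fit$sigma^2
  st2 <- deTable(de2)$sigma_moderated^2
  s02 <- de2@priorVar
  expect_true(all(st2 >= pmin(s2, s02) - 1e-12 &
                    st2 <= pmax(s2, s02) + 1e-12))

  # Gaussian null calibration: fraction p < 0.05 in [0.04, 0.06]
  design <- makeDesign()
  set.seed(5)
  G <- 5000
  lc <- matrix(rnorm(G * 12), G, 12,
               dimnames = list(sprintf("g%04d", 1:G), design$sample_id))
  f <- fitContrasts(lc, matrix(1, G, 12), design)
  deN <- moderateAndTest(f)
  frac <- mean(deTable(deN)$p_stress_in_males < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)

  fit$sigma <- rep(0, 10)
  expect_error(moderateAndTest(fit), "degenerate variances")
})

test_that("direction classification applies the p and fold-change thresholds", {
  thr <- analysisThresholds()
  expect_identical(classifyDirection(0.40, 0.03, thr), "up")
  expect_identical(classifyDirection(0.20, 0.001, thr), "neutral")
  expect_identical(classifyDirection(-0.50, 0.04, thr), "down")
  expect_identical(classifyDirection(0.40, 0.07, thr), "neutral")
  # boundary: log2(1.3) exactly qualifies
  expect_identical(classifyDirection(log2(1.3), 0.01, thr), "up")
})

test_that("the DE path reproduces an independent voom/eBayes implementation", {
  skip_if_not_installed("limma")
  skip_if_not_installed("SummarizedExperiment")
  sim <- simulateExperiment(simulationConfig(nGenes = 600, nMirs = 40,
                                             seed = 5))
  se <- filterLowCounts(sim$mrna)
  counts <- SummarizedExperiment::assay(se, "counts")
  d <- designTable(se)
  grp <- factor(paste(d$sex, d$condition, sep = "_"),
                levels = c("male_control", "male_stress",
                           "female_control", "female_stress"))
  X <- model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  v <- limma::voom(counts, X, lib.size = colSums(counts))
  cm <- cbind(stress_in_males = c(-1, 1, 0, 0),
              stress_in_females = c(0, 0, -1, 1))
  fitL <- limma::eBayes(limma::contrasts.fit(limma::lmFit(v, X), cm))
  de <- runDE(sim$mrna)
  tb <- deTable(de)
  expect_identical(tb$feature_id, rownames(fitL$coefficients))
  expect_lt(max(abs(tb$logFC_stress_in_males - fitL$coefficients[, 1])),
            1e-8)
  expect_lt(max(abs(tb$p_stress_in_males - fitL$p.value[, 1])), 1e-8)
  expect_lt(max(abs(tb$p_stress_in_females - fitL$p.value[, 2])), 1e-8)
})

test_that("effects planted in one sex do not inflate the other sex's calls", {
  rates <- sapply(101:103, function(s) {
    cfg <- simulationConfig(nGenes = 1500, nMirs = 40,
                            geneEffectFraction = c(male = 0, female = 0.1),
                            mirEffectFraction = c(male = 0, female = 0),
                            couplingProb = 0, seed = s)
    sim <- simulateExperiment(cfg)
    de <- runDE(sim$mrna)
    mean(deTable(de)$p_stress_in_males < 0.05)
  })
  expect_lt(mean(rates), 0.08)   # male contrast stays at the null rate
})
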