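# shared in-code fixtures

# a minimal 12-library factorial design (3 libraries per sex x condition)
makeDesign <- function(librariesPerCell = 3, poolSize = 5) {
  g <- expand.grid(rep = seq_len(librariesPerCell),
                   condition = c("control", "stress"),
                   sex = c("male", "female"), stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d",
                        ifelse(g$sex == "male", "M", "F"),
                        ifelse(g$condition == "stress", "S", "C"), g$rep),
    sex = g$sex, condition = g$condition,
    estrous = ifelse(g$sex == "male", "not_applicable", "estrus"),
    pool_size = poolSize, stringsAsFactors = FALSE)
}

# counts with simple Poisson noise around a per-feature mean
makeCounts <- function(nFeatures, design, means = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(means)) means <- rep(100, nFeatures)
  m <- matrix(rpois(nFeatures * nrow(design), means), nrow = nFeatures,
              dimnames = list(sprintf("f%03d", seq_len(nFeatures)),
                              design$sample_id))
  m
}

makeSE <- function(nFeatures = 50, assayType = "mRNA", seed = 42,
                   means = NULL) {
  design <- makeDesign()
  StressExperiment(makeCounts(nFeatures, design, means, seed), design,
                   assayType)
}

# tiny DEResult built directly from a direction/effect table
makeDEResult <- function(ids, dir, logFC = NULL,
                         contrast = "stress_in_males",
                         thresholds = analysisThresholds()) {
  if (is.null(logFC))
    logFC <- ifelse(dir == "up", 1, ifelse(dir == "down", -1, 0))
  p <- ifelse(dir == "neutral", 0.9, 0.01)
  tb <- data.frame(feature_id = ids, AveExpr = 5, sigma = 1,
                   sigma_moderated = 1, stringsAsFactors = FALSE)
  tb[[paste0("logFC_", contrast)]] <- logFC
  tb[[paste0("t_", contrast)]] <- logFC
  tb[[paste0("p_", contrast)]] <- p
  tb[[paste0("dir_", contrast)]] <- dir
  new("DEResult", table = tb, contrasts = contrast, priorDF = 10,
      priorVar = 1, thresholds = thresholds)
}
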