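#' Simulation configuration
#'
#' Parameters of the synthetic paired miR/mRNA experiment. The defaults
#' emulate the pooled-library factorial design the analysis assumes: 2 sexes
#' x 2 conditions x 3 replicate libraries, each library a pool of 5 animals,
#' negative-binomial animal-level counts with a dispersion trend
#' \code{a0 + a1/mean}, log-normal library-size factors, sex-specific stress
#' effects that are asymmetric between the sexes, and planted
#' anti-correlated miR-target coupling: a true target of a stress-regulated
#' miR receives, with probability \code{couplingProb}, an opposing log2
#' effect attenuated by \code{attenuation}. Two noisy prediction sources
#' report the true target edges with imperfect sensitivity plus false
#' positives. Feature dimensions default to a scaled-down universe
#' (5000 genes, 400 miRs).
#'
#' @param nGenes,nMirs numbers of mRNA and miR features.
#' @param librariesPerCell replicate libraries per sex-by-condition cell.
#' @param poolSize animals pooled per library.
#' @param dispersionA0,dispersionA1 NB dispersion trend
#'   \code{a0 + a1 / mean} at the animal level.
#' @param librarySizeMean,librarySizeCV mean and coefficient of variation of
#'   the log-normal per-animal library-size factors.
#' @param baselineMeanlog,baselineSdlog log-normal baseline mean-count
#'   distribution (natural-log scale), spanning roughly four orders of
#'   magnitude by default.
#' @param geneEffectFraction,mirEffectFraction named (\code{male},
#'   \code{female}) fractions of features truly stress-regulated per sex.
#' @param geneUpFraction,mirUpFraction fraction of each sex's regulated
#'   features that are upregulated.
#' @param effectSize |log2 fold change| of a direct stress effect.
#' @param effectSets optional explicit effect sets overriding the sampled
#'   ones: a list \code{list(gene = list(male = list(up =, down =), female
#'   = ...), mir = ...)} of feature indices.
#' @param couplingProb probability a true target of a regulated miR receives
#'   the anti-correlated effect.
#' @param attenuation multiplier on the (negated) miR effect passed to a
#'   coupled target.
#' @param targetsPerMir mean number of true targets per miR (Poisson).
#' @param sources data.frame with columns \code{name}, \code{sensitivity},
#'   \code{false_per_mir} describing each prediction source.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return validated config list.
#' @export
simulationConfig <- function(nGenes = 5000, nMirs = 400,
                             librariesPerCell = 3, poolSize = 5,
                             dispersionA0 = 0.05, dispersionA1 = 2,
                             librarySizeMean = 1, librarySizeCV = 0.2,
                             baselineMeanlog = log(20), baselineSdlog = 2.3,
                             geneEffectFraction = c(male = 0.05,
                                                    female = 0.05),
                             geneUpFraction = c(male = 0.30, female = 0.33),
                             mirEffectFraction = c(male = 0.05,
                                                   female = 0.035),
                             mirUpFraction = c(male = 0.60, female = 0.64),
                             effectSize = 1,
                             effectSets = NULL,
                             couplingProb = 0.8, attenuation = 0.5,
                             targetsPerMir = 25,
                             sources = data.frame(
                               name = c("sourceA", "sourceB"),
                               sensitivity = c(0.85, 0.80),
                               false_per_mir = c(10, 10)),
                             seed = 1L) {
  cfg <- list(nGenes = nGenes, nMirs = nMirs,
              librariesPerCell = librariesPerCell, poolSize = poolSize,
              dispersionA0 = dispersionA0, dispersionA1 = dispersionA1,
              librarySizeMean = librarySizeMean,
              librarySizeCV = librarySizeCV,
              baselineMeanlog = baselineMeanlog,
              baselineSdlog = baselineSdlog,
              geneEffectFraction = geneEffectFraction,
              geneUpFraction = geneUpFraction,
              mirEffectFraction = mirEffectFraction,
              mirUpFraction = mirUpFraction,
              effectSize = effectSize, effectSets = effectSets,
              couplingProb = couplingProb, attenuation = attenuation,
              targetsPerMir = targetsPerMir, sources = sources,
              seed = as.integer(seed))
  probs <- c(geneEffectFraction, geneUpFraction, mirEffectFraction,
             mirUpFraction, couplingProb,
             sources$sensitivity)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(c("male", "female") %in% names(geneEffectFraction)),
            all(c("male", "female") %in% names(mirEffectFraction)),
            nGenes >= 1, nMirs >= 1, librariesPerCell >= 1, poolSize >= 1,
            dispersionA0 > 0, dispersionA1 >= 0,
            librarySizeMean > 0, librarySizeCV >= 0,
            attenuation >= 0, targetsPerMir >= 0,
            all(c("name", "sensitivity", "false_per_mir") %in%
                  colnames(sources)))
  cfg
}

# sample disjoint up/down index sets for one sex, or validate explicit ones
sampleEffectSets <- function(nFeatures, fraction, upFraction, explicit) {
  if (!is.null(explicit)) {
    idx <- c(explicit$up, explicit$down)
    if (length(idx) && (max(idx) > nFeatures || min(idx) < 1))
      stop("effect set references out-of-range feature index")
    if (anyDuplicated(idx))
      stop("up and down effect sets must be disjoint")
    return(list(up = as.integer(explicit$up),
                down = as.integer(explicit$down)))
  }
  nReg <- round(nFeatures * fraction)
  reg <- sample.int(nFeatures, nReg)
  nUp <- round(nReg * upFraction)
  list(up = sort(reg[seq_len(nUp)]),
       down = sort(reg[setdiff(seq_len(nReg), seq_len(nUp))]))
}

# pooled NB library counts: sum of poolSize animal draws; animals of the
# affected sex/condition have their means shifted by 2^(log2 effect)
drawAssayCounts <- function(cfg, baseMeans, log2Effects, design, ids) {
  G <- length(baseMeans)
  sdlog <- sqrt(log(1 + cfg$librarySizeCV^2))
  meanlog <- log(cfg$librarySizeMean) - sdlog^2 / 2
  phi <- cfg$dispersionA0 + cfg$dispersionA1 / baseMeans
  counts <- matrix(0L, G, nrow(design),
                   dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    eff <- if (design$condition[j] == "stress")
      log2Effects[, design$sex[j]] else numeric(G)
    mu0 <- baseMeans * 2^eff
    acc <- integer(G)
    for (a in seq_len(cfg$poolSize)) {
      s <- stats::rlnorm(1, meanlog, sdlog)
      acc <- acc + stats::rnbinom(G, mu = mu0 * s, size = 1 / phi)
    }
    counts[, j] <- acc
  }
  counts
}

#' Simulate a paired miR/mRNA stress experiment
#'
#' Generates the full study bundle: miR and mRNA
#' \linkS4class{StressExperiment}s over a shared 12-library design, a
#' two-source \linkS4class{TargetPredictionTable}, and a ground-truth record
#' for recovery testing. Each library count is a sum of \code{poolSize}
#' animal-level negative-binomial draws; stressed animals of an affected sex
#' have feature means scaled by \code{2^effect}; coupled targets of
#' regulated miRs carry the opposing attenuated effect; female libraries are
#' drawn in estrus or proestrus only. Fully reproducible from
#' \code{config$seed}.
#'
#' @param config from \code{\link{simulationConfig}}.
#' @return list with elements \code{mir}, \code{mrna}
#'   (\linkS4class{StressExperiment}s), \code{design} (data.frame),
#'   \code{predictions} (\linkS4class{TargetPredictionTable}) and
#'   \code{truth} (list: per-sex true up/down miR and gene ids, true and
#'   coupled edges, baseline means, per-sex net log2 effects).
#' @export
simulateExperiment <- function(config = simulationConfig()) {
  cfg <- config
  set.seed(cfg$seed)
  geneIds <- sprintf("gene%05d", seq_len(cfg$nGenes))
  mirIds <- sprintf("mir-%04d", seq_len(cfg$nMirs))
  sexes <- c("male", "female")

  geneBase <- stats::rlnorm(cfg$nGenes, cfg$baselineMeanlog,
                            cfg$baselineSdlog)
  mirBase <- stats::rlnorm(cfg$nMirs, cfg$baselineMeanlog, cfg$baselineSdlog)

  # true regulatory map: which genes each miR genuinely targets
  trueTargets <- lapply(seq_len(cfg$nMirs), function(i) {
    k <- min(stats::rpois(1, cfg$targetsPerMir), cfg$nGenes)
    sort(sample.int(cfg$nGenes, k))
  })
  names(trueTargets) <- mirIds

  mirEff <- matrix(0, cfg$nMirs, 2, dimnames = list(mirIds, sexes))
  geneEff <- matrix(0, cfg$nGenes, 2, dimnames = list(geneIds, sexes))
  coupled <- list()
  for (sx in sexes) {
    ms <- sampleEffectSets(cfg$nMirs, cfg$mirEffectFraction[[sx]],
                           cfg$mirUpFraction[[sx]],
                           cfg$effectSets$mir[[sx]])
    gs <- sampleEffectSets(cfg$nGenes, cfg$geneEffectFraction[[sx]],
                           cfg$geneUpFraction[[sx]],
                           cfg$effectSets$gene[[sx]])
    mirEff[ms$up, sx] <- cfg$effectSize
    mirEff[ms$down, sx] <- -cfg$effectSize
    geneEff[gs$up, sx] <- cfg$effectSize
    geneEff[gs$down, sx] <- -cfg$effectSize
    for (i in c(ms$up, ms$down)) {
      tg <- trueTargets[[i]]
      hit <- tg[stats::runif(length(tg)) < cfg$couplingProb]
      if (!length(hit)) next
      add <- -mirEff[i, sx] * cfg$attenuation
      geneEff[hit, sx] <- geneEff[hit, sx] + add
      coupled[[length(coupled) + 1L]] <- data.frame(
        sex = sx, mir_id = mirIds[i], gene_id = geneIds[hit],
        mir_log2fc = mirEff[i, sx], gene_log2fc_added = add,
        stringsAsFactors = FALSE)
    }
  }
  coupledEdges <- if (length(coupled)) do.call(rbind, coupled) else
    data.frame(sex = character(), mir_id = character(),
               gene_id = character(), mir_log2fc = numeric(),
               gene_log2fc_added = numeric())

  design <- expand.grid(rep = seq_len(cfg$librariesPerCell),
                        condition = c("control", "stress"),
                        sex = sexes, stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("%s_%s_%d",
                        ifelse(design$sex == "male", "M", "F"),
                        ifelse(design$condition == "stress", "S", "C"),
                        design$rep),
    sex = design$sex, condition = design$condition,
    estrous = ifelse(design$sex == "male", "not_applicable",
                     c("estrus", "proestrus")[design$rep %% 2L + 1L]),
    pool_size = cfg$poolSize, stringsAsFactors = FALSE)

  mrnaCounts <- drawAssayCounts(cfg, geneBase, geneEff, design, geneIds)
  mirCounts <- drawAssayCounts(cfg, mirBase, mirEff, design, mirIds)

  # noisy prediction sources over the true edge set
  predRows <- list()
  for (r in seq_len(nrow(cfg$sources))) {
    src <- cfg$sources$name[r]
    sens <- cfg$sources$sensitivity[r]
    fpRate <- cfg$sources$false_per_mir[r]
    for (i in seq_len(cfg$nMirs)) {
      tg <- trueTargets[[i]]
      rep_tg <- tg[stats::runif(length(tg)) < sens]
      nFalse <- stats::rpois(1, fpRate)
      pool <- setdiff(seq_len(cfg$nGenes), tg)
      false_tg <- if (nFalse > 0 && length(pool))
        sample(pool, min(nFalse, length(pool))) else integer()
      all_tg <- c(rep_tg, false_tg)
      if (length(all_tg))
        predRows[[length(predRows) + 1L]] <- data.frame(
          mir_id = mirIds[i], gene_id = geneIds[all_tg], source = src,
          stringsAsFactors = FALSE)
    }
  }
  predictions <- TargetPredictionTable(do.call(rbind, predRows))

  trueEdges <- data.frame(
    mir_id = rep(mirIds, lengths(trueTargets)),
    gene_id = geneIds[unlist(trueTargets)],
    stringsAsFactors = FALSE)

  truth <- list(
    male = list(mir_up = mirIds[mirEff[, "male"] > 0],
                mir_down = mirIds[mirEff[, "male"] < 0],
                gene_up = geneIds[geneEff[, "male"] > 0],
                gene_down = geneIds[geneEff[, "male"] < 0]),
    female = list(mir_up = mirIds[mirEff[, "female"] > 0],
                  mir_down = mirIds[mirEff[, "female"] < 0],
                  gene_up = geneIds[geneEff[, "female"] > 0],
                  gene_down = geneIds[geneEff[, "female"] < 0]),
    true_edges = trueEdges,
    coupled_edges = coupledEdges,
    gene_baseline = stats::setNames(geneBase, geneIds),
    mir_baseline = stats::setNames(mirBase, mirIds),
    gene_log2_effects = geneEff,
    mir_log2_effects = mirEff)

  list(mir = StressExperiment(mirCounts, design, "miR"),
       mrna = StressExperiment(mrnaCounts, design, "mRNA"),
       design = design, predictions = predictions, truth = truth)
}

#' Simulate a null experiment
#'
#' Identical machinery to \code{\link{simulateExperiment}} with every effect
#' set forced empty: no stress regulation and no coupling, so downstream
#' p-values are calibration checks.
#'
#' @param config from \code{\link{simulationConfig}}.
#' @return same bundle as \code{\link{simulateExperiment}}; all truth effect
#'   sets empty.
#' @export
simulateNullExperiment <- function(config = simulationConfig()) {
  config$geneEffectFraction[] <- 0
  config$mirEffectFraction[] <- 0
  config$effectSets <- NULL
  config$couplingProb <- 0
  simulateExperiment(config)
}
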