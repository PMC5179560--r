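#' Intersect target predictions across sources
#'
#' Keeps a (miR, gene) pair only when every required prediction source
#' reports it -- the consensus rule used to limit predicted targets to those
#' supported by two independent algorithms -- then optionally restricts the
#' targets to the analyzed gene universe.
#'
#' @param predictions a \linkS4class{TargetPredictionTable}.
#' @param requiredSources character vector of source names; all must be
#'   present in the table.
#' @param universe optional character vector of analyzed gene ids; targets
#'   outside it are dropped.
#' @return named list: miR id -> character vector of consensus target genes
#'   (miRs left with no targets are dropped).
#' @export
intersectTargetSources <- function(predictions, requiredSources,
                                   universe = NULL) {
  stopifnot(is(predictions, "TargetPredictionTable"))
  requiredSources <- unique(as.character(requiredSources))
  if (length(requiredSources) < 1L) stop("need at least one required source")
  p <- predictions(predictions)
  missing <- setdiff(requiredSources, unique(p$source))
  if (length(missing))
    stop("required source absent from predictions: ", missing[1L])
  p <- p[p$source %in% requiredSources, , drop = FALSE]
  key <- paste(p$mir_id, p$gene_id, sep = "\r")
  nSrc <- rowsum(rep(1L, nrow(p)), key)
  consensus <- rownames(nSrc)[nSrc[, 1L] == length(requiredSources)]
  if (!length(consensus)) return(list())
  parts <- strsplit(consensus, "\r", fixed = TRUE)
  mir <- vapply(parts, `[`, character(1L), 1L)
  gene <- vapply(parts, `[`, character(1L), 2L)
  if (!is.null(universe)) {
    keep <- gene %in% universe
    mir <- mir[keep]; gene <- gene[keep]
  }
  if (!length(mir)) return(list())
  out <- split(gene, mir)
  lapply(out[sort(names(out))], function(x) sort(unique(x)))
}

#' Direction frequencies of the analyzed gene universe
#'
#' Counts the up-, down- and neutral genes of one contrast over the whole
#' filtered universe; these frequencies are the background the per-miR
#' chi-squared tests compare against.
#'
#' @param de a \linkS4class{DEResult} for the mRNA assay.
#' @param contrast contrast name.
#' @return named integer vector \code{c(up, down, neutral)} summing to the
#'   universe size.
#' @export
backgroundFrequencies <- function(de, contrast) {
  stopifnot(is(de, "DEResult"))
  d <- deTable(de)[[paste0("dir_", contrast)]]
  if (is.null(d)) stop("unknown contrast: ", contrast)
  c(up = sum(d == "up"), down = sum(d == "down"),
    neutral = sum(d == "neutral"))
}

#' Per-miR chi-squared enrichment of target direction frequencies
#'
#' For each miR, counts its in-universe targets that are up, down and
#' neutral in the given contrast and tests that trichotomy against the
#' universe background. The default is a goodness-of-fit test (expected
#' counts proportional to the background frequencies, df = 2); a 2x3
#' contingency variant (targets vs the rest of the universe) is available
#' via \code{mode = "contingency"}. miRs with fewer than \code{minTargets}
#' in-universe targets are excluded with a warning; cells with expected
#' count below 1 are flagged, not dropped.
#'
#' @param targets named list miR -> target gene ids (from
#'   \code{\link{intersectTargetSources}}), normally already restricted to
#'   the differentially expressed miRs of the contrast.
#' @param de mRNA \linkS4class{DEResult} covering the filtered universe.
#' @param contrast contrast name.
#' @param background optional background counts; default
#'   \code{\link{backgroundFrequencies}} of the same contrast.
#' @param minTargets minimum in-universe targets to test a miR.
#' @param mode \code{"gof"} or \code{"contingency"}.
#' @return data.frame, one row per tested miR: observed and expected
#'   up/down/neutral counts, chi-squared statistic, df, p, and a
#'   low-expected flag.
#' @export
chiSquaredTargetEnrichment <- function(targets, de, contrast,
                                       background = NULL, minTargets = 5,
                                       mode = c("gof", "contingency")) {
  mode <- match.arg(mode)
  stopifnot(is(de, "DEResult"))
  tb <- deTable(de)
  dirs <- tb[[paste0("dir_", contrast)]]
  if (is.null(dirs)) stop("unknown contrast: ", contrast)
  names(dirs) <- tb$feature_id
  if (is.null(background)) background <- backgroundFrequencies(de, contrast)
  stopifnot(all(c("up", "down", "neutral") %in% names(background)))
  background <- background[c("up", "down", "neutral")]
  rows <- list()
  for (mir in names(targets)) {
    tg <- intersect(targets[[mir]], tb$feature_id)
    if (!length(tg)) {
      warning("miR '", mir, "' has no targets in the analyzed universe; ",
              "excluded")
      next
    }
    if (length(tg) < minTargets) {
      warning("miR '", mir, "' has fewer than ", minTargets,
              " in-universe targets; excluded")
      next
    }
    td <- dirs[tg]
    obs <- c(up = sum(td == "up"), down = sum(td == "down"),
             neutral = sum(td == "neutral"))
    if (mode == "gof") {
      expd <- length(tg) * background / sum(background)
      chisq <- sum((obs - expd)^2 / expd)
      dfree <- 2L
    } else {
      rest <- background - obs
      tab <- rbind(target = obs, rest = rest)
      expd2 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      chisq <- sum((tab - expd2)^2 / expd2)
      expd <- expd2["target", ]
      dfree <- 2L
    }
    rows[[mir]] <- data.frame(
      mir_id = mir, n_targets = length(tg),
      obs_up = obs[["up"]], obs_down = obs[["down"]],
      obs_neutral = obs[["neutral"]],
      exp_up = expd[["up"]], exp_down = expd[["down"]],
      exp_neutral = expd[["neutral"]],
      chisq = chisq, df = dfree,
      p = stats::pchisq(chisq, df = dfree, lower.tail = FALSE),
      low_expected = any(expd < 1),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mir_id = character(), n_targets = integer(),
               obs_up = integer(), obs_down = integer(),
               obs_neutral = integer(), exp_up = numeric(),
               exp_down = numeric(), exp_neutral = numeric(),
               chisq = numeric(), df = integer(), p = numeric(),
               low_expected = logical())
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up FDR adjustment (monotone, capped at 1) with rejections at the
#' given alpha.
#'
#' @param p numeric vector of p-values.
#' @param alpha rejection threshold on the adjusted scale.
#' @return list with \code{adjusted} and logical \code{reject}.
#' @export
bhAdjust <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted < alpha)
}

#' Build the signed miR-gene association network
#'
#' For every surviving miR (post chi-squared selection) and each of its
#' in-universe targets that is itself differentially expressed in the same
#' contrast, adds an edge classified \code{negative} when miR and target
#' move in opposite directions and \code{positive} when they move together.
#' Neutral targets are excluded; surviving miRs are required to be
#' differentially expressed.
#'
#' @param survivingMirs character vector of miR ids that passed selection.
#' @param targets named list miR -> target genes.
#' @param mirDE miR-assay \linkS4class{DEResult}.
#' @param de mRNA-assay \linkS4class{DEResult}.
#' @param contrast contrast name.
#' @return a \linkS4class{MiRGeneNetwork}.
#' @export
classifyAssociations <- function(survivingMirs, targets, mirDE, de,
                                 contrast) {
  stopifnot(is(mirDE, "DEResult"), is(de, "DEResult"))
  mt <- deTable(mirDE)
  gt <- deTable(de)
  dcol <- paste0("dir_", contrast)
  fcol <- paste0("logFC_", contrast)
  mirDir <- stats::setNames(mt[[dcol]], mt$feature_id)
  mirFC <- stats::setNames(mt[[fcol]], mt$feature_id)
  geneDir <- stats::setNames(gt[[dcol]], gt$feature_id)
  geneFC <- stats::setNames(gt[[fcol]], gt$feature_id)
  edges <- list()
  for (mir in survivingMirs) {
    md <- mirDir[[mir]]
    if (is.null(md) || is.na(md))
      stop("surviving miR '", mir, "' not in miR DE table")
    stopifnot(md %in% c("up", "down"))   # selection runs on DE miRs only
    for (g in intersect(targets[[mir]], names(geneDir))) {
      gd <- geneDir[[g]]
      if (gd == "neutral") next
      edges[[length(edges) + 1L]] <- data.frame(
        mir_id = mir, gene_id = g,
        association = if (gd == md) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(mir_id = character(), gene_id = character(),
               association = character())
  mirIds <- unique(e$mir_id)
  geneIds <- unique(e$gene_id)
  MiRGeneNetwork(
    mirNodes = data.frame(id = mirIds,
                          direction = unname(mirDir[mirIds]),
                          log2FC = unname(mirFC[mirIds]),
                          stringsAsFactors = FALSE),
    geneNodes = data.frame(id = geneIds,
                           direction = unname(geneDir[geneIds]),
                           log2FC = unname(geneFC[geneIds]),
                           stringsAsFactors = FALSE),
    edges = e)
}

#' Summarize a miR-gene network
#'
#' Headline fractions of the integration analysis: how many differentially
#' expressed genes are miR-targeted, how association signs partition those
#' genes, how many are hit by one vs several miRs, and what fraction of the
#' DE miRs survived selection.
#'
#' @param network a \linkS4class{MiRGeneNetwork}.
#' @param deGenes character vector: the sex's DE gene ids (up and down).
#' @param deMirs character vector: the sex's DE miR ids.
#' @return named list of counts and fractions; count partitions sum to their
#'   totals.
#' @export
summarizeNetwork <- function(network, deGenes, deMirs) {
  e <- network@edges
  genes <- unique(e$gene_id)
  signTab <- if (nrow(e))
    table(factor(e$gene_id, genes), factor(e$association,
                                           c("negative", "positive")))
  else matrix(0L, 0, 2)
  negOnly <- sum(signTab[, 1L] > 0 & signTab[, 2L] == 0)
  posOnly <- sum(signTab[, 1L] == 0 & signTab[, 2L] > 0)
  both <- sum(signTab[, 1L] > 0 & signTab[, 2L] > 0)
  mirsPerGene <- if (nrow(e))
    tapply(e$mir_id, factor(e$gene_id, genes),
           function(x) length(unique(x)))
  else integer()
  nSurv <- nrow(network@mirNodes)
  list(
    n_genes_targeted = length(genes),
    frac_de_genes_targeted =
      if (length(deGenes)) length(genes) / length(deGenes) else 0,
    genes_negative_only = negOnly,
    genes_positive_only = posOnly,
    genes_both_signs = both,
    genes_one_mir = sum(mirsPerGene == 1),
    genes_multi_mir = sum(mirsPerGene >= 2),
    n_mirs_surviving = nSurv,
    frac_de_mirs_surviving =
      if (length(deMirs)) nSurv / length(deMirs) else 0)
}

#' Run the full per-sex miR-target integration analysis
#'
#' The sequence: consensus target intersection restricted to the analyzed
#' mRNA universe, per-miR chi-squared direction-frequency enrichment over
#' the sex's differentially expressed miRs, Benjamini-Hochberg selection
#' (family = all tested miRs of this sex), signed network construction from
#' the surviving miRs, and the summary fractions.
#'
#' @param mirDE miR-assay \linkS4class{DEResult}.
#' @param de mRNA-assay \linkS4class{DEResult}.
#' @param predictions a \linkS4class{TargetPredictionTable} (or a
#'   pre-computed named target list).
#' @param contrast contrast name (one sex's stress contrast).
#' @param requiredSources sources every kept prediction must appear in.
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @param minTargets minimum in-universe targets to test a miR.
#' @param mode chi-squared flavor, see
#'   \code{\link{chiSquaredTargetEnrichment}}.
#' @return list: \code{enrichment} (chi-squared table with BH columns),
#'   \code{network} (\linkS4class{MiRGeneNetwork}), \code{summary} (from
#'   \code{\link{summarizeNetwork}}), \code{targets} (the consensus map
#'   restricted to DE miRs).
#' @export
mirTargetNetwork <- function(mirDE, de, predictions, contrast,
                             requiredSources = NULL,
                             thresholds = analysisThresholds(),
                             minTargets = 5, mode = c("gof", "contingency")) {
  mode <- match.arg(mode)
  universe <- deTable(de)$feature_id
  if (is(predictions, "TargetPredictionTable")) {
    if (is.null(requiredSources))
      requiredSources <- predictionSources(predictions)
    targetMap <- intersectTargetSources(predictions, requiredSources,
                                        universe)
  } else targetMap <- lapply(predictions, intersect, universe)
  deMirs <- c(deList(mirDE, contrast, "up"), deList(mirDE, contrast, "down"))
  targetMap <- targetMap[intersect(names(targetMap), deMirs)]
  enr <- chiSquaredTargetEnrichment(targetMap, de, contrast,
                                    minTargets = minTargets, mode = mode)
  if (nrow(enr)) {
    bh <- bhAdjust(enr$p, thresholds$network_bh_alpha)
    enr$p_bh <- bh$adjusted
    enr$survives <- bh$reject
    mdir <- deTable(mirDE)
    enr$mir_direction <-
      mdir[[paste0("dir_", contrast)]][match(enr$mir_id, mdir$feature_id)]
  } else {
    enr$p_bh <- numeric()
    enr$survives <- logical()
    enr$mir_direction <- character()
  }
  surviving <- enr$mir_id[enr$survives]
  net <- classifyAssociations(surviving, targetMap, mirDE, de, contrast)
  smry <- summarizeNetwork(
    net,
    deGenes = c(deList(de, contrast, "up"), deList(de, contrast, "down")),
    deMirs = deMirs)
  list(enrichment = enr, network = net, summary = smry, targets = targetMap)
}
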