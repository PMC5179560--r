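#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SEX_LEVELS <- c("male", "female")
.CONDITION_LEVELS <- c("stress", "control")
.ESTROUS_LEVELS <- c("estrus", "proestrus", "metestrus", "diestrus",
                     "not_applicable")
.ASSAY_TYPES <- c("miR", "mRNA")

#' StressExperiment: counts plus a factorial sex-by-stress design
#'
#' A \linkS4class{SummarizedExperiment} carrying one non-negative integer
#' count assay (\code{"counts"}) for either a miRNA or an mRNA experiment,
#' with the sample design (sex, condition, estrous stage, pool size) in
#' \code{colData}. Each library is understood as a pool of \code{pool_size}
#' animals sequenced as one sample.
#'
#' @slot assayType either \code{"miR"} or \code{"mRNA"}.
#'
#' @seealso \code{\link{StressExperiment}} for the constructor,
#'   \code{\link{readCountMatrix}} to build one from files.
#' @exportClass StressExperiment
setClass("StressExperiment",
  contains = "SummarizedExperiment",
  slots = c(assayType = "character"))

setValidity("StressExperiment", function(object) {
  msg <- character()
  if (length(object@assayType) != 1L || !object@assayType %in% .ASSAY_TYPES)
    msg <- c(msg, sprintf("assayType must be one of: %s",
                          paste(.ASSAY_TYPES, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated feature id: %s",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicated sample id: %s",
                          colnames(object)[duplicated(colnames(object))][1L]))
  cd <- SummarizedExperiment::colData(object)
  need <- c("sex", "condition", "estrous", "pool_size")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, sprintf("colData lacks column(s): %s",
                          paste(miss, collapse = ", ")))
  else {
    if (!all(cd$sex %in% .SEX_LEVELS))
      msg <- c(msg, "sex must be 'male' or 'female'")
    if (!all(cd$condition %in% .CONDITION_LEVELS))
      msg <- c(msg, "condition must be 'stress' or 'control'")
    if (!all(cd$estrous %in% .ESTROUS_LEVELS))
      msg <- c(msg, sprintf("estrous must be one of: %s",
                            paste(.ESTROUS_LEVELS, collapse = ", ")))
    bad <- cd$sex == "male" & cd$estrous != "not_applicable"
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "male samples must have estrous = not_applicable")
    if (!all(cd$pool_size >= 1))
      msg <- c(msg, "pool_size must be a positive integer")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StressExperiment
#'
#' @param counts integer matrix, features x samples, with row and column
#'   names.
#' @param design \code{data.frame} with columns \code{sample_id}, \code{sex},
#'   \code{condition}, \code{estrous}, \code{pool_size}; \code{sample_id}
#'   must match \code{colnames(counts)} exactly (any order).
#' @param assayType \code{"miR"} or \code{"mRNA"}.
#' @return a validated \linkS4class{StressExperiment}.
#' @examples
#' counts <- matrix(rpois(8, 20), 2, 4,
#'                  dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' design <- data.frame(
#'   sample_id = paste0("s", 1:4),
#'   sex = rep(c("male", "female"), each = 2),
#'   condition = rep(c("control", "stress"), 2),
#'   estrous = c("not_applicable", "not_applicable", "estrus", "proestrus"),
#'   pool_size = 5)
#' se <- StressExperiment(counts, design, "mRNA")
#' @export
StressExperiment <- function(counts, design, assayType = c("mRNA", "miR")) {
  assayType <- match.arg(assayType)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature (row) and sample (column) names")
  design <- validateDesign(design)
  if (!setequal(design$sample_id, colnames(counts)) ||
      nrow(design) != ncol(counts))
    stop("design sample_ids must match count matrix columns exactly")
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  cd <- DataFrame(design[, c("sex", "condition", "estrous", "pool_size")],
                  row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("StressExperiment", se, assayType = assayType)
}

# design-table invariants shared by the constructor and readDesign()
validateDesign <- function(design) {
  need <- c("sample_id", "sex", "condition", "estrous", "pool_size")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  for (col in c("sample_id", "sex", "condition", "estrous"))
    design[[col]] <- as.character(design[[col]])
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id: ",
         design$sample_id[duplicated(design$sample_id)][1L])
  badSex <- setdiff(design$sex, .SEX_LEVELS)
  if (length(badSex)) stop("unknown sex token: ", badSex[1L])
  badCond <- setdiff(design$condition, .CONDITION_LEVELS)
  if (length(badCond)) stop("unknown condition token: ", badCond[1L])
  badEst <- setdiff(design$estrous, .ESTROUS_LEVELS)
  if (length(badEst)) stop("unknown estrous token: ", badEst[1L])
  if (any(design$sex == "male" & design$estrous != "not_applicable"))
    stop("male samples must have estrous = not_applicable")
  if (anyNA(design$pool_size) || any(design$pool_size < 1) ||
      any(design$pool_size != round(design$pool_size)))
    stop("pool_size must be a positive integer")
  cells <- table(factor(design$sex, .SEX_LEVELS),
                 factor(design$condition, .CONDITION_LEVELS))
  if (any(cells == 0)) {
    i <- which(cells == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty cell: no samples for %s/%s",
                 .SEX_LEVELS[i[1L]], .CONDITION_LEVELS[i[2L]]))
  }
  design
}

#' TargetPredictionTable: miRNA target predictions keyed by source
#'
#' Holds records (mir_id, gene_id, source) from one or more prediction
#' algorithms (e.g. TargetScan-style seed matching and miRWalk-style
#' archives). Duplicate triples are collapsed at construction with a warning.
#'
#' @slot predictions data.frame with columns mir_id, gene_id, source.
#' @exportClass TargetPredictionTable
setClass("TargetPredictionTable",
  slots = c(predictions = "data.frame"))

setValidity("TargetPredictionTable", function(object) {
  p <- object@predictions
  need <- c("mir_id", "gene_id", "source")
  if (!all(need %in% colnames(p)))
    return("predictions needs columns mir_id, gene_id, source")
  if (anyNA(p[need])) return("NA values not allowed in predictions")
  if (anyDuplicated(p[need])) return("duplicate (mir, gene, source) triples")
  TRUE
})

#' @param predictions data.frame with columns \code{mir_id}, \code{gene_id},
#'   \code{source}.
#' @rdname TargetPredictionTable-class
#' @export
TargetPredictionTable <- function(predictions) {
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  for (col in c("mir_id", "gene_id", "source"))
    predictions[[col]] <- as.character(predictions[[col]])
  ndup <- anyDuplicated(predictions[, c("mir_id", "gene_id", "source")])
  if (ndup) {
    predictions <- unique(predictions[, c("mir_id", "gene_id", "source")])
    warning("collapsed duplicate (mir, gene, source) triples")
  }
  rownames(predictions) <- NULL
  new("TargetPredictionTable",
      predictions = predictions[, c("mir_id", "gene_id", "source")])
}

#' GeneSetCollection: named sets of gene identifiers
#'
#' A lightweight container for gene-set collections such as pathway or GO
#' term memberships read from GMT files. Set names are unique and every set
#' is non-empty.
#'
#' @slot sets named list of character vectors.
#' @slot description one description string per set.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  slots = c(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("set names must be present and unique")
  if (any(lengths(object@sets) == 0L)) {
    empty <- names(object@sets)[lengths(object@sets) == 0L][1L]
    return(sprintf("gene set '%s' is empty", empty))
  }
  if (length(object@description) != length(object@sets))
    return("one description per set required")
  TRUE
})

#' @param sets named list of character vectors of gene ids.
#' @param description optional character vector of per-set descriptions.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(description)) description <- rep("", length(sets))
  new("GeneSetCollection", sets = sets, description = description)
}

#' DEResult: per-feature differential expression statistics
#'
#' The fitted result of the weighted linear model with empirical-Bayes
#' moderation: one row per analyzed feature with average log2 expression and,
#' per contrast, the log2 fold change, moderated t, p-value and direction
#' call (\code{up}/\code{down}/\code{neutral}).
#'
#' @slot table data.frame, one row per feature.
#' @slot contrasts names of the fitted contrasts.
#' @slot priorDF empirical-Bayes prior degrees of freedom (may be Inf).
#' @slot priorVar empirical-Bayes prior variance.
#' @slot thresholds the \code{\link{analysisThresholds}} used for calls.
#' @exportClass DEResult
setClass("DEResult",
  slots = c(table = "data.frame", contrasts = "character",
            priorDF = "numeric", priorVar = "numeric", thresholds = "list"))

setValidity("DEResult", function(object) {
  tb <- object@table
  for (ct in object@contrasts) {
    pcol <- paste0("p_", ct)
    dcol <- paste0("dir_", ct)
    if (!all(c(paste0("logFC_", ct), pcol, dcol) %in% colnames(tb)))
      return(sprintf("missing columns for contrast '%s'", ct))
    p <- tb[[pcol]]
    if (any(p < 0 | p > 1, na.rm = TRUE))
      return("p-values must lie in [0, 1]")
    if (!all(tb[[dcol]] %in% c("up", "down", "neutral")))
      return("direction must be up/down/neutral")
  }
  TRUE
})

#' MiRGeneNetwork: signed bipartite miRNA-gene association network
#'
#' Nodes are stress-regulated miRNAs (that survived the per-miR chi-squared
#' selection) and their differentially expressed target genes; each edge is
#' classified \code{negative} (miR and target regulated in opposite
#' directions -- the canonical repressive relationship) or \code{positive}
#' (same direction). Neutral features never appear as nodes.
#'
#' @slot mirNodes data.frame: id, direction, log2FC.
#' @slot geneNodes data.frame: id, direction, log2FC.
#' @slot edges data.frame: mir_id, gene_id, association.
#' @exportClass MiRGeneNetwork
setClass("MiRGeneNetwork",
  slots = c(mirNodes = "data.frame", geneNodes = "data.frame",
            edges = "data.frame"))

setValidity("MiRGeneNetwork", function(object) {
  e <- object@edges
  if (!all(c("mir_id", "gene_id", "association") %in% colnames(e)))
    return("edges needs columns mir_id, gene_id, association")
  if (!all(e$association %in% c("negative", "positive")))
    return("association must be 'negative' or 'positive'")
  if (!all(e$mir_id %in% object@mirNodes$id))
    return("edge references unknown miR node")
  if (!all(e$gene_id %in% object@geneNodes$id))
    return("edge references unknown gene node")
  if (any(object@mirNodes$direction == "neutral") ||
      any(object@geneNodes$direction == "neutral"))
    return("network nodes must be differentially expressed (non-neutral)")
  if (nrow(e)) {
    mdir <- object@mirNodes$direction[match(e$mir_id, object@mirNodes$id)]
    gdir <- object@geneNodes$direction[match(e$gene_id, object@geneNodes$id)]
    want <- ifelse(mdir == gdir, "positive", "negative")
    if (!all(e$association == want))
      return("edge association inconsistent with node directions")
  }
  TRUE
})

#' @param mirNodes,geneNodes data.frames with columns id, direction, log2FC.
#' @param edges data.frame with columns mir_id, gene_id, association.
#' @rdname MiRGeneNetwork-class
#' @export
MiRGeneNetwork <- function(mirNodes, geneNodes, edges) {
  blank <- function(x) data.frame(id = character(), direction = character(),
                                  log2FC = numeric())
  if (missing(mirNodes) || !nrow(mirNodes)) mirNodes <- blank()
  if (missing(geneNodes) || !nrow(geneNodes)) geneNodes <- blank()
  if (missing(edges) || !nrow(edges))
    edges <- data.frame(mir_id = character(), gene_id = character(),
                        association = character())
  rownames(mirNodes) <- rownames(geneNodes) <- rownames(edges) <- NULL
  new("MiRGeneNetwork", mirNodes = mirNodes, geneNodes = geneNodes,
      edges = edges)
}
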