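#' @rdname StressExperiment-class
#' @param object a miRstress object.
#' @export
setGeneric("assayType", function(object) standardGeneric("assayType"))

#' @rdname StressExperiment-class
#' @export
setMethod("assayType", "StressExperiment", function(object) object@assayType)

#' @rdname StressExperiment-class
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @describeIn StressExperiment-class the sample design as a plain
#'   data.frame with a \code{sample_id} column.
#' @export
setMethod("designTable", "StressExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  data.frame(sample_id = rownames(cd),
             sex = cd$sex, condition = cd$condition,
             estrous = cd$estrous, pool_size = cd$pool_size,
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "StressExperiment", function(object) {
  cat(sprintf("StressExperiment (%s): %d features x %d libraries\n",
              object@assayType, nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  tab <- table(paste(cd$sex, cd$condition, sep = "/"))
  cat("  libraries per cell:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname TargetPredictionTable-class
#' @param object a \linkS4class{TargetPredictionTable}.
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname TargetPredictionTable-class
#' @export
setMethod("predictions", "TargetPredictionTable",
          function(object) object@predictions)

#' @rdname TargetPredictionTable-class
#' @export
setGeneric("predictionSources",
           function(object) standardGeneric("predictionSources"))

#' @describeIn TargetPredictionTable-class the distinct prediction sources
#'   present, sorted.
#' @export
setMethod("predictionSources", "TargetPredictionTable",
          function(object) sort(unique(object@predictions$source)))

setMethod("show", "TargetPredictionTable", function(object) {
  cat(sprintf("TargetPredictionTable: %d records, %d miRs, sources: %s\n",
              nrow(object@predictions),
              length(unique(object@predictions$mir_id)),
              paste(predictionSources(object), collapse = ", ")))
})

#' @rdname GeneSetCollection-class
#' @param object a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(object@sets),
              if (length(object@sets)) min(lengths(object@sets)) else 0L,
              if (length(object@sets)) max(lengths(object@sets)) else 0L))
})

#' @rdname DEResult-class
#' @param object a \linkS4class{DEResult}.
#' @export
setGeneric("deTable", function(object) standardGeneric("deTable"))

#' @rdname DEResult-class
#' @export
setMethod("deTable", "DEResult", function(object) object@table)

#' @rdname DEResult-class
#' @export
setGeneric("deContrasts", function(object) standardGeneric("deContrasts"))

#' @rdname DEResult-class
#' @export
setMethod("deContrasts", "DEResult", function(object) object@contrasts)

setMethod("show", "DEResult", function(object) {
  cat(sprintf("DEResult: %d features, contrasts: %s\n", nrow(object@table),
              paste(object@contrasts, collapse = ", ")))
  for (ct in object@contrasts) {
    d <- object@table[[paste0("dir_", ct)]]
    cat(sprintf("  %s: %d up, %d down, %d neutral\n", ct,
                sum(d == "up"), sum(d == "down"), sum(d == "neutral")))
  }
  cat(sprintf("  prior df %.3g, prior variance %.3g\n",
              object@priorDF, object@priorVar))
})

setMethod("show", "MiRGeneNetwork", function(object) {
  cat(sprintf(
    "MiRGeneNetwork: %d miRs, %d genes, %d edges (%d negative, %d positive)\n",
    nrow(object@mirNodes), nrow(object@geneNodes), nrow(object@edges),
    sum(object@edges$association == "negative"),
    sum(object@edges$association == "positive")))
})

#' Extract a directional feature list from a DEResult
#'
#' @param object a \linkS4class{DEResult}.
#' @param contrast contrast name, e.g. \code{"stress_in_males"}.
#' @param direction \code{"up"}, \code{"down"} or \code{"neutral"}.
#' @return character vector of feature ids.
#' @export
deList <- function(object, contrast, direction = c("up", "down", "neutral")) {
  stopifnot(is(object, "DEResult"))
  direction <- match.arg(direction)
  if (!contrast %in% object@contrasts)
    stop("unknown contrast: ", contrast)
  tb <- object@table
  tb$feature_id[tb[[paste0("dir_", contrast)]] == direction]
}
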