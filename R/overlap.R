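#' One-sided hypergeometric overlap test
#'
#' Exact enrichment p-value for observing an intersection of size at least
#' \code{k} between a list of size \code{nA} and a list of size \code{nB}
#' drawn from a fixed background of \code{N} features: \code{P(X >= k)} for
#' \code{X ~ Hypergeometric(N, nA, nB)}. The tail is summed exactly in log
#' space, so tiny p-values (the interesting ones) keep full relative
#' precision.
#'
#' @param nA,nB sizes of the two lists.
#' @param k observed intersection size.
#' @param N background (universe) size.
#' @return the enrichment p-value.
#' @examples
#' fisherOverlap(324, 116, 9, 19827)   # 1.23e-4
#' @export
fisherOverlap <- function(nA, nB, k, N) {
  stopifnot(length(nA) == 1L, length(nB) == 1L, length(k) == 1L,
            length(N) == 1L)
  if (nA > N || nB > N) stop("list size exceeds background size")
  if (k > min(nA, nB)) stop("intersection exceeds the smaller list")
  if (k < 0) stop("negative intersection")
  if (k == 0) return(1)
  kk <- k:min(nA, nB)
  logTerms <- lchoose(nA, kk) + lchoose(N - nA, nB - kk) - lchoose(N, nB)
  m <- max(logTerms)
  min(1, exp(m + log(sum(exp(logTerms - m)))))
}

#' Pairwise directional overlap tests
#'
#' Tests every unordered pair of the supplied feature lists (or an explicit
#' selection of pairs) against the fixed background with
#' \code{\link{fisherOverlap}}. Supplying the up and down lists of both
#' sexes yields the same-direction and opposite-direction comparisons in one
#' call. Output order is deterministic (lexicographic pair names).
#'
#' @param lists named list of character id vectors; deduplicated.
#' @param N background size; every member must come from a universe of this
#'   size.
#' @param pairs optional 2-column matrix or data.frame of list names
#'   selecting the comparisons; default all unordered pairs.
#' @param universe optional character vector enumerating the background;
#'   when given, its length is used as \code{N} and membership is enforced.
#' @return data.frame with one row per comparison: list names and sizes,
#'   intersection size and members, expected overlap \code{nA*nB/N}, and
#'   p-value.
#' @export
pairwiseOverlaps <- function(lists, N = NULL, pairs = NULL, universe = NULL) {
  stopifnot(is.list(lists), !is.null(names(lists)))
  lists <- lapply(lists, function(x) unique(as.character(x)))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    for (nm in names(lists)) {
      out <- setdiff(lists[[nm]], universe)
      if (length(out))
        stop("list '", nm, "' has member outside the universe: ", out[1L])
    }
    N <- length(universe)
  }
  if (is.null(N)) stop("supply N or a universe")
  if (is.null(pairs)) {
    nms <- sort(names(lists))
    if (length(nms) < 2L) {
      return(data.frame(list_a = character(), list_b = character(),
                        n_a = integer(), n_b = integer(), k = integer(),
                        expected = numeric(), p = numeric(),
                        intersection = character()))
    }
    pairs <- t(utils::combn(nms, 2L))
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    if (!a %in% names(lists) || !b %in% names(lists))
      stop("unknown list name in pairs")
    inter <- intersect(lists[[a]], lists[[b]])
    nA <- length(lists[[a]]); nB <- length(lists[[b]])
    data.frame(list_a = a, list_b = b, n_a = nA, n_b = nB,
               k = length(inter), expected = nA * nB / N,
               p = fisherOverlap(nA, nB, length(inter), N),
               intersection = paste(sort(inter), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$list_a, out$list_b), , drop = FALSE]
}

#' Gene-set overrepresentation analysis
#'
#' One-sided Fisher's exact (hypergeometric) enrichment of a query gene list
#' in each set of a collection, against an explicit universe -- the in-house
#' stand-in for pathway/GO knowledgebase queries. A set is called
#' significant when -log10(p) reaches \code{enrich_neglogp} (default 1.3,
#' i.e. p <= 0.05); a BH-adjusted column is provided alongside.
#'
#' @param query character vector of gene ids; members outside the universe
#'   are dropped with a warning.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background gene ids (deduplicated).
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @return data.frame sorted by p then set name: set name and sizes, overlap
#'   size and members, p, -log10(p), BH-adjusted p, significance flag.
#' @export
overrepresentationTest <- function(query, sets, universe,
                                   thresholds = analysisThresholds()) {
  stopifnot(is(sets, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  rows <- lapply(names(sets@sets), function(nm) {
    inUniverse <- intersect(sets@sets[[nm]], universe)
    overlap <- intersect(inUniverse, query)
    p <- if (length(inUniverse) == 0L) 1
         else fisherOverlap(length(inUniverse), length(query),
                            length(overlap), N)
    data.frame(set = nm, set_size = length(inUniverse),
               query_size = length(query), overlap = length(overlap),
               members = paste(sort(overlap), collapse = ","),
               p = p, neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$neg_log10_p >= thresholds$enrich_neglogp
  rownames(out) <- NULL
  out
}
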