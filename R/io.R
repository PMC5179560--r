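#' Read a count matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds feature ids. Cells must be non-negative integers;
#' violations are rejected with the offending (feature, sample) coordinate
#' rather than coerced.
#'
#' @param path file path.
#' @param assayType \code{"miR"} or \code{"mRNA"}; recorded as an attribute.
#' @return integer matrix (features x samples) with an \code{assayType}
#'   attribute; row and column order as in the file.
#' @seealso \code{\link{StressExperiment}} to pair the matrix with a design.
#' @export
readCountMatrix <- function(path, assayType = c("mRNA", "miR")) {
  assayType <- match.arg(assayType)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("count TSV needs a feature column plus samples")
  featureIds <- tab[[1L]]
  sampleIds <- colnames(tab)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicated sample id in header: ",
         sampleIds[duplicated(sampleIds)][1L])
  if (anyDuplicated(featureIds))
    stop("duplicated feature id: ", featureIds[duplicated(featureIds)][1L])
  num <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(featureIds, sampleIds))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count at feature '%s', sample '%s': '%s' (must be a non-negative integer)",
      featureIds[bad[1L, 1L]], sampleIds[bad[1L, 2L]],
      tab[bad[1L, 1L], bad[1L, 2L] + 1L]))
  }
  storage.mode(num) <- "integer"
  attr(num, "assayType") <- assayType
  num
}

#' Write a count matrix to TSV
#'
#' @param counts matrix with feature row names and sample column names.
#' @param path output path.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTable(df, path)
}

#' Read a sample design table from CSV
#'
#' Columns: sample_id, sex (male/female), condition (stress/control), estrous
#' (estrus/proestrus/metestrus/diestrus/not_applicable), pool_size (animals
#' pooled per library). Token and structural invariants (males carry
#' not_applicable, every sex-by-condition cell populated) are enforced.
#'
#' @param path CSV file path.
#' @return validated design data.frame.
#' @export
readDesign <- function(path) {
  design <- utils::read.csv(path, stringsAsFactors = FALSE)
  design <- validateDesign(design)
  design$pool_size <- as.integer(design$pool_size)
  design
}

#' Write a design table to CSV
#' @param design design data.frame.
#' @param path output path.
#' @export
writeDesign <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
}

#' Read miRNA target predictions from TSV
#'
#' Expects columns mir_id, gene_id, source. Duplicate triples are collapsed
#' with a warning. Identifiers are treated as case-sensitive opaque strings;
#' no symbol remapping is attempted.
#'
#' @param path TSV path.
#' @return a \linkS4class{TargetPredictionTable}.
#' @export
readTargetPredictions <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("mir_id", "gene_id", "source")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("target TSV lacks column(s): ", paste(miss, collapse = ", "))
  TargetPredictionTable(tab[need])
}

#' Write target predictions to TSV
#' @param object a \linkS4class{TargetPredictionTable}.
#' @param path output path.
#' @export
writeTargetPredictions <- function(object, path) {
  writeTable(predictions(object), path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, fields tab-separated -- set name,
#' description, then member gene ids. Empty sets and duplicate set names are
#' errors (named in the message).
#'
#' @param path GMT path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1L])
  desc <- vapply(fields, function(f)
    if (length(f) >= 2L) f[2L] else "", character(1L))
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members[nzchar(members)]
  })
  names(sets) <- nm
  empty <- nm[lengths(sets) == 0L]
  if (length(empty))
    stop("gene set '", empty[1L], "' has no members")
  GeneSetCollection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param object a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @export
writeGeneSets <- function(object, path) {
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(object@sets), object@description, object@sets)
  writeLines(unname(lines), path)
}

#' Write a data.frame as headered TSV
#'
#' Deterministic column order (as supplied), no quoting, '.' decimal
#' separator. The lossless partner of the read* functions.
#'
#' @param rows data.frame.
#' @param path output path.
#' @export
writeTable <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Export a miRNA-gene network
#'
#' Three dialects: \code{"SIF"} for Cytoscape (relation tokens:
#' \code{represses} for a negative association, \code{coexpressed} for a
#' positive one), \code{"GraphML"} with node attributes (kind, direction,
#' log2FC) and the edge association sign, and \code{"edge-TSV"}, the lossless
#' tabular dialect.
#'
#' @param network a \linkS4class{MiRGeneNetwork}.
#' @param path output path.
#' @param format one of \code{"SIF"}, \code{"GraphML"}, \code{"edge-TSV"}.
#' @export
writeNetwork <- function(network, path, format = c("SIF", "GraphML",
                                                   "edge-TSV")) {
  stopifnot(is(network, "MiRGeneNetwork"))
  if (length(format) == 1L && !format %in% c("SIF", "GraphML", "edge-TSV"))
    stop("unknown network format: ", format)
  format <- match.arg(format)
  e <- network@edges
  if (format == "SIF") {
    rel <- ifelse(e$association == "negative", "represses", "coexpressed")
    writeLines(if (nrow(e)) paste(e$mir_id, rel, e$gene_id, sep = "\t")
               else character(), path)
  } else if (format == "edge-TSV") {
    m <- network@mirNodes[match(e$mir_id, network@mirNodes$id), ]
    g <- network@geneNodes[match(e$gene_id, network@geneNodes$id), ]
    out <- data.frame(mir_id = e$mir_id, gene_id = e$gene_id,
                      association = e$association,
                      mir_direction = m$direction, gene_direction = g$direction,
                      mir_log2FC = m$log2FC, gene_log2FC = g$log2FC,
                      stringsAsFactors = FALSE)
    if (!nrow(e))
      out <- out[0L, ]
    writeTable(out, path)
  } else {
    g <- asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a MiRGeneNetwork to an igraph graph
#'
#' Bipartite graph with vertex attributes \code{kind} (\code{"miR"} or
#' \code{"gene"}), \code{direction} and \code{log2FC}, and edge attribute
#' \code{association}.
#'
#' @param network a \linkS4class{MiRGeneNetwork}.
#' @return an \code{igraph} object.
#' @export
asIgraph <- function(network) {
  verts <- rbind(
    data.frame(name = network@mirNodes$id, kind = "miR",
               direction = network@mirNodes$direction,
               log2FC = network@mirNodes$log2FC,
               stringsAsFactors = FALSE),
    data.frame(name = network@geneNodes$id, kind = "gene",
               direction = network@geneNodes$direction,
               log2FC = network@geneNodes$log2FC,
               stringsAsFactors = FALSE))
  edges <- data.frame(from = network@edges$mir_id,
                      to = network@edges$gene_id,
                      association = network@edges$association,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Read a network back from the edge-TSV dialect
#' @param path edge-TSV path written by \code{\link{writeNetwork}}.
#' @return a \linkS4class{MiRGeneNetwork}.
#' @export
readNetworkEdgeTSV <- function(path) {
  e <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(e)) return(MiRGeneNetwork())
  mir <- unique(e[, c("mir_id", "mir_direction", "mir_log2FC")])
  gene <- unique(e[, c("gene_id", "gene_direction", "gene_log2FC")])
  MiRGeneNetwork(
    mirNodes = data.frame(id = mir$mir_id, direction = mir$mir_direction,
                          log2FC = mir$mir_log2FC, stringsAsFactors = FALSE),
    geneNodes = data.frame(id = gene$gene_id, direction = gene$gene_direction,
                           log2FC = gene$gene_log2FC, stringsAsFactors = FALSE),
    edges = e[, c("mir_id", "gene_id", "association")])
}
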