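#' Pipeline configuration
#'
#' One structured document driving \code{\link{runPipeline}}. Either a
#' simulation config (the default: a self-contained synthetic run) or a set
#' of input paths must be supplied. All randomness flows from \code{seed}.
#'
#' @param simulation a \code{\link{simulationConfig}}, or \code{NULL} to
#'   read real inputs from \code{inputs}.
#' @param inputs named list of paths (\code{mir_counts}, \code{mrna_counts},
#'   \code{design}, \code{targets}, optional \code{gene_sets}) used when
#'   \code{simulation} is \code{NULL}.
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @param contrasts see \code{\link{stressContrasts}}.
#' @param requiredSources prediction sources required for the target
#'   consensus; default all sources present.
#' @param nSyntheticSets number of gene sets to fabricate for the
#'   enrichment stage when no GMT is supplied (synthetic stand-in
#'   collection).
#' @param minTargets minimum in-universe targets to test a miR.
#' @param seed integer root seed.
#' @return config list.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           inputs = NULL,
                           thresholds = analysisThresholds(),
                           contrasts = stressContrasts(),
                           requiredSources = NULL,
                           nSyntheticSets = 15,
                           minTargets = 5,
                           seed = 1L) {
  if (is.null(simulation) && is.null(inputs))
    stop("supply a simulation config or input paths")
  list(simulation = simulation, inputs = inputs, thresholds = thresholds,
       contrasts = contrasts, requiredSources = requiredSources,
       nSyntheticSets = nSyntheticSets, minTargets = minTargets,
       seed = as.integer(seed))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML document whose top-level keys mirror the arguments of
#' \code{\link{pipelineConfig}}, \code{\link{simulationConfig}} and
#' \code{\link{analysisThresholds}}; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return config list as from \code{\link{pipelineConfig}}.
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$inputs)) NULL else {
    args <- y$simulation
    if (is.null(args)) simulationConfig() else {
      for (nm in c("geneEffectFraction", "geneUpFraction",
                   "mirEffectFraction", "mirUpFraction"))
        if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
      if (!is.null(args$sources))
        args$sources <- do.call(rbind,
          lapply(args$sources, as.data.frame))
      do.call(simulationConfig, args)
    }
  }
  thr <- if (is.null(y$thresholds)) analysisThresholds()
         else do.call(analysisThresholds, y$thresholds)
  pipelineConfig(simulation = sim, inputs = y$inputs, thresholds = thr,
                 requiredSources = y$requiredSources,
                 nSyntheticSets = y$nSyntheticSets %||% 15,
                 minTargets = y$minTargets %||% 5,
                 seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulation (or input loading), filtering and differential expression for
#' both assays, directional lists and pairwise overlap tests, per-sex
#' miR-target network analysis, gene-set overrepresentation, and a JSON
#' manifest with a checksum for every artifact. Identical config and seed
#' reproduce identical checksums. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message(...)
  thr <- config$thresholds
  note("thresholds: p<", thr$p_cut, ", FC>=", thr$fc_cut,
       ", filter >", thr$filter_min_count, " reads in >=",
       thr$filter_min_fraction * 100, "% of a cell, BH alpha ",
       thr$network_bh_alpha, ", enrichment -log10(p)>=", thr$enrich_neglogp)
  artifacts <- character()
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  bundle <- stage("inputs", {
    if (!is.null(config$simulation)) {
      cfg <- config$simulation
      cfg$seed <- config$seed
      sim <- simulateExperiment(cfg)
      writeCountMatrix(SummarizedExperiment::assay(sim$mir, "counts"),
                       keep(file.path(outdir, "mir_counts.tsv")))
      writeCountMatrix(SummarizedExperiment::assay(sim$mrna, "counts"),
                       keep(file.path(outdir, "mrna_counts.tsv")))
      writeDesign(sim$design, keep(file.path(outdir, "design.csv")))
      writeTargetPredictions(sim$predictions,
                             keep(file.path(outdir, "targets.tsv")))
      sim
    } else {
      inp <- config$inputs
      design <- readDesign(inp$design)
      list(mir = StressExperiment(readCountMatrix(inp$mir_counts, "miR"),
                                  design, "miR"),
           mrna = StressExperiment(readCountMatrix(inp$mrna_counts, "mRNA"),
                                   design, "mRNA"),
           design = design,
           predictions = readTargetPredictions(inp$targets),
           geneSetsPath = inp$gene_sets)
    }
  })

  de <- stage("de", {
    out <- list(mir = runDE(bundle$mir, thr, config$contrasts),
                mrna = runDE(bundle$mrna, thr, config$contrasts))
    writeTable(deTable(out$mir), keep(file.path(outdir, "de_mir.tsv")))
    writeTable(deTable(out$mrna), keep(file.path(outdir, "de_mrna.tsv")))
    note("DE: ", nrow(deTable(out$mrna)), " genes / ",
         nrow(deTable(out$mir)), " miRs analyzed")
    out
  })

  stage("overlap", {
    for (assay in c("mrna", "mir")) {
      d <- de[[assay]]
      lists <- list()
      for (ct in deContrasts(d)) {
        sexTag <- if (grepl("female", ct)) "female" else "male"
        lists[[paste0(sexTag, "_up")]] <- deList(d, ct, "up")
        lists[[paste0(sexTag, "_down")]] <- deList(d, ct, "down")
      }
      ov <- pairwiseOverlaps(lists, N = nrow(deTable(d)))
      writeTable(ov, keep(file.path(outdir,
                                    paste0("overlap_", assay, ".tsv"))))
    }
  })

  networks <- stage("network", {
    out <- list()
    for (ct in deContrasts(de$mrna)) {
      sexTag <- if (grepl("female", ct)) "female" else "male"
      res <- mirTargetNetwork(de$mir, de$mrna, bundle$predictions, ct,
                              requiredSources = config$requiredSources,
                              thresholds = thr,
                              minTargets = config$minTargets)
      writeTable(res$enrichment,
                 keep(file.path(outdir,
                                paste0("chisq_", sexTag, ".tsv"))))
      writeNetwork(res$network,
                   keep(file.path(outdir,
                                  paste0("network_", sexTag, ".sif"))),
                   "SIF")
      writeNetwork(res$network,
                   keep(file.path(outdir,
                                  paste0("network_", sexTag,
                                         "_edges.tsv"))), "edge-TSV")
      writeNetwork(res$network,
                   keep(file.path(outdir,
                                  paste0("network_", sexTag,
                                         ".graphml"))), "GraphML")
      writeTable(data.frame(metric = names(res$summary),
                            value = unlist(res$summary)),
                 keep(file.path(outdir,
                                paste0("network_summary_", sexTag,
                                       ".tsv"))))
      note("network (", sexTag, "): ", res$summary$n_mirs_surviving,
           " surviving miRs, ", res$summary$n_genes_targeted,
           " targeted genes")
      out[[sexTag]] <- res
    }
    out
  })

  stage("enrich", {
    universe <- deTable(de$mrna)$feature_id
    sets <- if (!is.null(bundle$geneSetsPath))
      readGeneSets(bundle$geneSetsPath)
    else {
      # synthetic stand-in collection: random sets over the universe
      set.seed(config$seed + 104729L)
      n <- config$nSyntheticSets
      GeneSetCollection(
        stats::setNames(lapply(seq_len(n), function(i)
          sample(universe, min(length(universe),
                               max(10, stats::rpois(1, 50))))),
          sprintf("synthetic_set_%02d", seq_len(n))))
    }
    for (ct in deContrasts(de$mrna)) {
      sexTag <- if (grepl("female", ct)) "female" else "male"
      query <- c(deList(de$mrna, ct, "up"), deList(de$mrna, ct, "down"))
      enr <- overrepresentationTest(query, sets, universe, thr)
      writeTable(enr, keep(file.path(outdir,
                                     paste0("enrichment_", sexTag,
                                            ".tsv"))))
    }
  })

  manifest <- stage("manifest", {
    sums <- tools::md5sum(artifacts)
    m <- list(seed = config$seed,
              thresholds = thr,
              artifacts = lapply(seq_along(artifacts), function(i)
                list(path = basename(artifacts[i]),
                     md5 = unname(sums[i]))))
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })
  note("pipeline complete: ", length(artifacts), " artifacts in ", outdir)
  invisible(manifest)
}
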