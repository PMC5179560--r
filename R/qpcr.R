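#' Relative quantification by the 2^-ddCt method
#'
#' Normalizes each sample's target Ct to the mean of its reference-gene Cts
#' (\code{dCt}), centers on the mean control-group \code{dCt}
#' (\code{ddCt}), and converts to linear fold change \code{2^-ddCt}. Fold
#' changes are then rescaled so the control-group mean is exactly 1.
#'
#' @param ct long-format data.frame with columns \code{sample},
#'   \code{group} (\code{stress}/\code{control}), \code{gene}, \code{ct}.
#' @param target target gene name.
#' @param references character vector of reference gene names (default two
#'   stable references).
#' @return data.frame: sample, group, dct, ddct, fold.
#' @export
deltaDeltaCt <- function(ct, target, references = c("Lsm4", "Kcnc2")) {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(all(need %in% colnames(ct)))
  if (!all(ct$group %in% c("stress", "control")))
    stop("group must be 'stress' or 'control'")
  samples <- unique(ct$sample)
  rows <- lapply(samples, function(s) {
    sub <- ct[ct$sample == s, ]
    tCt <- sub$ct[sub$gene == target]
    if (length(tCt) != 1L || is.na(tCt))
      stop("sample '", s, "' lacks a single target Ct for '", target, "'")
    refCt <- vapply(references, function(r) {
      v <- sub$ct[sub$gene == r]
      if (length(v) != 1L || is.na(v))
        stop("sample '", s, "' is missing reference Ct for '", r, "'")
      v
    }, numeric(1L))
    data.frame(sample = s, group = sub$group[1L],
               dct = tCt - mean(refCt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ctrl <- out$dct[out$group == "control"]
  if (!length(ctrl)) stop("need at least one control sample")
  out$ddct <- out$dct - mean(ctrl)
  out$fold <- 2^(-out$ddct)
  # exact renormalization: mean control fold == 1 (2^-mean != mean of 2^-x)
  out$fold <- out$fold / mean(out$fold[out$group == "control"])
  rownames(out) <- NULL
  out
}

#' Grubbs outlier filtering
#'
#' Two-sided Grubbs test: the most extreme point is removed when
#' \code{G = max|x - mean| / sd} exceeds the t-based critical value at
#' \code{alpha}; the test is re-applied until nothing is removed or
#' \code{maxRemovals} is reached. A cruder \code{"2sd"} mode instead removes
#' every point further than two SDs from the mean.
#'
#' @param values numeric vector (n >= 3 for a test; shorter vectors are
#'   returned unchanged with a warning).
#' @param alpha significance level of the Grubbs test.
#' @param mode \code{"grubbs"} or \code{"2sd"}.
#' @param maxRemovals cap on removals in Grubbs mode.
#' @return list with \code{kept} and \code{removed} values.
#' @export
grubbsFilter <- function(values, alpha = 0.05, mode = c("grubbs", "2sd"),
                         maxRemovals = 1L) {
  mode <- match.arg(mode)
  x <- values
  removed <- numeric()
  if (length(x) < 3L) {
    warning("fewer than 3 values; outlier test skipped")
    return(list(kept = x, removed = removed))
  }
  if (mode == "2sd") {
    repeat {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) break
      out <- abs(x - mean(x)) > 2 * s
      if (!any(out) || length(x) - sum(out) < 3L) break
      removed <- c(removed, x[out])
      x <- x[!out]
    }
    return(list(kept = x, removed = removed))
  }
  while (length(removed) < maxRemovals && length(x) >= 3L) {
    n <- length(x)
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      warning("zero variance; no outlier test possible")
      break
    }
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    Gcrit <- ((n - 1) / sqrt(n)) *
      sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G <= Gcrit) break
    drop <- which.max(dev)
    removed <- c(removed, x[drop])
    x <- x[-drop]
  }
  list(kept = x, removed = removed)
}

#' Two-group comparison with variance-driven test selection
#'
#' Assesses variance equality with a two-sided F-test at 0.05; equal
#' variances give a pooled-variance two-tailed t-test, unequal variances a
#' two-tailed Mann-Whitney U test.
#'
#' @param stress,control numeric fold-change vectors (n >= 2 each).
#' @return list: \code{test} ("t" or "mann-whitney"), \code{statistic}
#'   (t or U), \code{df} (t only), \code{p}, \code{var_test_p}.
#' @export
compareGroups <- function(stress, control) {
  if (length(stress) < 2L || length(control) < 2L)
    stop("each group needs at least 2 values after outlier filtering")
  vt <- stats::var.test(stress, control)
  if (is.na(vt$p.value) || vt$p.value >= 0.05) {
    tt <- stats::t.test(stress, control, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p = if (is.na(tt$p.value)) 1 else tt$p.value,
         var_test_p = vt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(stress, control,
                                              exact = NULL))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         df = NA_real_, p = wt$p.value, var_test_p = vt$p.value)
  }
}

#' Full qPCR validation of one target gene
#'
#' The 2^-ddCt pipeline: reference-gene normalization, per-group outlier
#' filtering on the fold-change scale, and the two-group comparison with
#' variance-driven test selection.
#'
#' @param ct long-format Ct table, see \code{\link{deltaDeltaCt}}.
#' @param target target gene name.
#' @param references reference gene names.
#' @param outlierMode \code{"grubbs"}, \code{"2sd"} or \code{"none"}.
#' @param alpha outlier-test significance level.
#' @return list: per-sample \code{folds} table (with kept flag), group
#'   means, the test record from \code{\link{compareGroups}}, and removed
#'   outliers per group.
#' @export
qpcrAnalysis <- function(ct, target, references = c("Lsm4", "Kcnc2"),
                         outlierMode = c("grubbs", "2sd", "none"),
                         alpha = 0.05) {
  outlierMode <- match.arg(outlierMode)
  folds <- deltaDeltaCt(ct, target, references)
  folds$kept <- TRUE
  removed <- list(stress = numeric(), control = numeric())
  if (outlierMode != "none") {
    for (g in c("stress", "control")) {
      idx <- which(folds$group == g)
      filt <- grubbsFilter(folds$fold[idx], alpha = alpha,
                           mode = outlierMode)
      if (length(filt$removed)) {
        removed[[g]] <- filt$removed
        folds$kept[idx][folds$fold[idx] %in% filt$removed] <- FALSE
      }
    }
  }
  keptS <- folds$fold[folds$kept & folds$group == "stress"]
  keptC <- folds$fold[folds$kept & folds$group == "control"]
  cmp <- compareGroups(keptS, keptC)
  list(folds = folds,
       group_means = c(stress = mean(keptS), control = mean(keptC)),
       test = cmp, removed = removed)
}
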