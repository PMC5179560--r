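.GROUP_LEVELS <- c("male_control", "male_stress",
                   "female_control", "female_stress")

#' Analysis thresholds
#'
#' The cutoffs used throughout the pipeline. Differential expression uses an
#' uncorrected p < 0.05 together with a linear fold-change threshold of 1.3;
#' the count filter keeps a feature when it exceeds 5 reads in at least 80%
#' of the samples of any one sex-by-condition cell; enrichment significance
#' is -log10(p) >= 1.3; the per-miR chi-squared selection applies
#' Benjamini-Hochberg at 0.05. Overlap tests run against fixed candidate
#' universes (19,827 mRNAs, 781 miRs by default).
#'
#' @param p_cut uncorrected p-value cutoff for a DE call.
#' @param fc_cut linear fold-change cutoff (> 1).
#' @param filter_min_count reads a sample must exceed to count as expressed.
#' @param filter_min_fraction required fraction of samples within a cell.
#' @param enrich_neglogp -log10(p) significance cutoff for enrichment.
#' @param network_bh_alpha BH-adjusted alpha for the chi-squared selection.
#' @param background_mrna,background_mir fixed overlap-universe sizes.
#' @return validated named list of thresholds.
#' @export
analysisThresholds <- function(p_cut = 0.05, fc_cut = 1.3,
                               filter_min_count = 5,
                               filter_min_fraction = 0.8,
                               enrich_neglogp = 1.3,
                               network_bh_alpha = 0.05,
                               background_mrna = 19827,
                               background_mir = 781) {
  stopifnot(p_cut > 0, p_cut < 1, fc_cut > 1,
            filter_min_fraction > 0, filter_min_fraction <= 1,
            filter_min_count >= 0, enrich_neglogp > 0,
            network_bh_alpha > 0, network_bh_alpha < 1,
            background_mrna >= 1, background_mir >= 1)
  list(p_cut = p_cut, fc_cut = fc_cut,
       filter_min_count = filter_min_count,
       filter_min_fraction = filter_min_fraction,
       enrich_neglogp = enrich_neglogp,
       network_bh_alpha = network_bh_alpha,
       background_mrna = background_mrna,
       background_mir = background_mir)
}

#' Default per-sex stress contrasts
#'
#' Contrast vectors over the four group means, in the order male_control,
#' male_stress, female_control, female_stress. Each is stressed minus
#' same-sex control, so the model controls baseline sex differences while
#' estimating the stress effect within each sex.
#'
#' @return named list of numeric contrast vectors summing to zero.
#' @export
stressContrasts <- function() {
  list(stress_in_males   = c(-1, 1, 0, 0),
       stress_in_females = c(0, 0, -1, 1))
}

groupFactor <- function(design) {
  factor(paste(design$sex, design$condition, sep = "_"),
         levels = .GROUP_LEVELS)
}

#' Filter low-abundance features
#'
#' A feature is retained when, in at least one sex-by-condition cell, the
#' fraction of samples with more than \code{filter_min_count} reads reaches
#' \code{filter_min_fraction}. Feature order is preserved.
#'
#' @param se a \linkS4class{StressExperiment}.
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @return the filtered \linkS4class{StressExperiment}.
#' @export
filterLowCounts <- function(se, thresholds = analysisThresholds()) {
  stopifnot(is(se, "StressExperiment"))
  counts <- SummarizedExperiment::assay(se, "counts")
  grp <- groupFactor(designTable(se))
  expressed <- counts > thresholds$filter_min_count
  keep <- rep(FALSE, nrow(counts))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    if (!length(cols)) next
    frac <- rowMeans(expressed[, cols, drop = FALSE])
    keep <- keep | frac >= thresholds$filter_min_fraction
  }
  if (!any(keep)) stop("no features pass filter")
  se[keep, ]
}

#' Log2 counts per million
#'
#' \code{log2((count + 0.5) / (library_size + 1) * 1e6)}: the offset log-CPM
#' scale on which the precision-weighted linear models are fit.
#'
#' @param counts integer matrix or \linkS4class{StressExperiment}.
#' @return numeric matrix of the same dimensions.
#' @export
logCPM <- function(counts) {
  if (is(counts, "StressExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample with zero total counts: ", colnames(counts)[lib == 0][1L])
  t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
}

#' Precision weights from the mean-variance trend
#'
#' Fits unweighted feature-wise linear models, computes the square root of
#' each residual SD, estimates a lowess trend of sqrt-SD against mean log2
#' count, and predicts a sqrt-SD for every observation at its fitted log2
#' count by interpolation of the trend (clamped at the trend range ends).
#' The observation weight is predicted-sqrt-SD to the power -4, so
#' observations in the noisy low-count regime are down-weighted in the
#' subsequent weighted least squares fit.
#'
#' @param logcpm matrix from \code{\link{logCPM}}.
#' @param counts the count matrix the log-CPM was computed from.
#' @param designMatrix model matrix (samples x coefficients).
#' @param span lowess span.
#' @return positive weight matrix, same dimensions as \code{logcpm}.
#' @export
voomWeights <- function(logcpm, counts, designMatrix, span = 0.5) {
  if (is(counts, "StressExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  n <- ncol(logcpm)
  p <- qr(designMatrix)$rank
  if (n < ncol(designMatrix))
    stop("fewer samples than model columns")
  if (n - p < 2L)
    stop("need at least 2 residual degrees of freedom")
  fit <- stats::lm.fit(designMatrix, t(logcpm))
  res <- as.matrix(fit$residuals)              # samples x features
  sg <- sqrt(colSums(res^2) / (n - p))
  sqrtSD <- sqrt(sg)
  lib <- colSums(counts)
  # mean log2 count per feature (log-CPM shifted back to the count scale)
  sx <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
  ok <- sg > 0
  if (sum(ok) < 10L) ok <- rep(TRUE, length(sg))
  trend <- stats::lowess(sx[ok], sqrtSD[ok], f = span)
  coefs <- as.matrix(fit$coefficients)
  fittedLogcpm <- designMatrix %*% coefs       # samples x features
  fittedLogCount <- fittedLogcpm + (log2(lib + 1) - log2(1e6))
  pred <- stats::approx(trend$x, trend$y, xout = as.vector(fittedLogCount),
                        rule = 2, ties = mean)$y
  pred <- pmax(pred, 1e-4)                     # guard against a trend at zero
  w <- matrix(pred^-4, nrow = n, ncol = nrow(logcpm))
  t(w)
}

#' Fit the group-means linear model with contrasts
#'
#' Weighted least squares per feature on the saturated group-means
#' parameterization of the 2x2 sex-by-stress design; contrast estimates are
#' linear combinations of the four fitted group means. Equal weights reduce
#' the fit to ordinary least squares group-mean differences.
#'
#' @param logcpm log2-CPM matrix (features x samples).
#' @param weights observation weight matrix, same dimensions.
#' @param design design data.frame (or \linkS4class{StressExperiment}).
#' @param contrasts named list of length-4 contrast vectors over the groups
#'   male_control, male_stress, female_control, female_stress; each must sum
#'   to zero. Default \code{\link{stressContrasts}}.
#' @return list with per-feature \code{beta} (features x contrasts),
#'   \code{stdevUnscaled} (sqrt of the unscaled contrast variance),
#'   \code{sigma} (weighted residual SD), \code{df} residual degrees of
#'   freedom, and \code{Amean} mean log2 expression.
#' @export
fitContrasts <- function(logcpm, weights, design,
                         contrasts = stressContrasts()) {
  if (is(design, "StressExperiment")) design <- designTable(design)
  grp <- groupFactor(design)
  if (any(is.na(grp)) || nlevels(droplevels(grp)) < 4L)
    stop("all four sex-by-condition groups must be represented")
  for (nm in names(contrasts)) {
    cv <- contrasts[[nm]]
    if (length(cv) != 4L || abs(sum(cv)) > 1e-12)
      stop("contrast '", nm, "' must be length 4 and sum to zero")
  }
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  if (qr(X)$rank < ncol(X)) stop("singular design")
  G <- nrow(logcpm)
  C <- matrix(unlist(contrasts), nrow = 4L,
              dimnames = list(.GROUP_LEVELS, names(contrasts)))
  n <- ncol(logcpm)
  dfRes <- n - ncol(X)
  beta <- matrix(NA_real_, G, ncol(C),
                 dimnames = list(rownames(logcpm), colnames(C)))
  stdevUnscaled <- beta
  sigma <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    y <- logcpm[g, ]
    XtW <- t(X * w)
    xtwx <- XtW %*% X
    cov <- solve(xtwx)
    b <- cov %*% (XtW %*% y)
    r <- y - as.vector(X %*% b)
    sigma[g] <- sqrt(sum(w * r^2) / dfRes)
    beta[g, ] <- as.vector(t(C) %*% b)
    stdevUnscaled[g, ] <- sqrt(diag(t(C) %*% cov %*% C))
  }
  list(beta = beta, stdevUnscaled = stdevUnscaled, sigma = sigma,
       df = dfRes, Amean = rowMeans(logcpm))
}

# Newton solve of trigamma(y) = x, vectorized (monotone decreasing map)
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# moment-match a scaled F prior on the residual variances: returns prior df
# d0 (possibly Inf) and prior variance s02, from the log-variance moments
fitVariancePrior <- function(sg2, df) {
  ok <- sg2 > 0
  if (!any(ok)) stop("degenerate variances: all residual variances are zero")
  z <- log(sg2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderation and tests
#'
#' Estimates a prior (d0, s0^2) for the residual variances by moment
#' matching on the log variances, shrinks each feature's variance to the
#' convex combination \code{(d0 s0^2 + df s_g^2) / (d0 + df)}, and tests
#' each contrast with a moderated t statistic on \code{d0 + df} degrees of
#' freedom (two-sided). An infinite prior df collapses every variance to
#' s0^2. Direction calls apply \code{\link{classifyDirection}}.
#'
#' @param fit output of \code{\link{fitContrasts}}.
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @return a \linkS4class{DEResult}.
#' @export
moderateAndTest <- function(fit, thresholds = analysisThresholds()) {
  if (length(fit$sigma) < 2L) stop("need at least 2 features")
  prior <- fitVariancePrior(fit$sigma^2, fit$df)
  d0 <- prior$d0
  s02 <- prior$s02
  if (is.infinite(d0)) {
    stilde2 <- rep(s02, length(fit$sigma))
    dfTotal <- Inf
  } else {
    stilde2 <- (d0 * s02 + fit$df * fit$sigma^2) / (d0 + fit$df)
    dfTotal <- d0 + fit$df
  }
  tb <- data.frame(feature_id = rownames(fit$beta),
                   AveExpr = fit$Amean,
                   sigma = fit$sigma,
                   sigma_moderated = sqrt(stilde2),
                   stringsAsFactors = FALSE, row.names = NULL)
  for (ct in colnames(fit$beta)) {
    tstat <- fit$beta[, ct] / (sqrt(stilde2) * fit$stdevUnscaled[, ct])
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    tb[[paste0("logFC_", ct)]] <- fit$beta[, ct]
    tb[[paste0("t_", ct)]] <- tstat
    tb[[paste0("p_", ct)]] <- p
    tb[[paste0("dir_", ct)]] <- classifyDirection(fit$beta[, ct], p,
                                                  thresholds)
  }
  new("DEResult", table = tb, contrasts = colnames(fit$beta),
      priorDF = d0, priorVar = s02, thresholds = thresholds)
}

#' Classify a feature's direction of regulation
#'
#' \code{up} when p < p_cut and the log2 fold change reaches
#' \code{log2(fc_cut)}; \code{down} for the mirror case; otherwise
#' \code{neutral}.
#'
#' @param log2FC numeric vector of log2 fold changes.
#' @param p numeric vector of p-values.
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @return character vector in \{up, down, neutral\}.
#' @export
classifyDirection <- function(log2FC, p, thresholds = analysisThresholds()) {
  lfc <- log2(thresholds$fc_cut)
  out <- rep("neutral", length(log2FC))
  out[p < thresholds$p_cut & log2FC >= lfc] <- "up"
  out[p < thresholds$p_cut & log2FC <= -lfc] <- "down"
  out
}

#' Run the full differential expression path for one assay
#'
#' Count filter, log-CPM, precision weights, weighted group-means fit with
#' per-sex stress contrasts, and empirical-Bayes moderated tests.
#'
#' @param se a \linkS4class{StressExperiment}.
#' @param thresholds see \code{\link{analysisThresholds}}.
#' @param contrasts see \code{\link{fitContrasts}}.
#' @return a \linkS4class{DEResult} over the filtered feature universe.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 300, nMirs = 50,
#'                                            seed = 1))
#' de <- runDE(sim$mrna)
#' head(deTable(de))
#' @export
runDE <- function(se, thresholds = analysisThresholds(),
                  contrasts = stressContrasts()) {
  se <- filterLowCounts(se, thresholds)
  counts <- SummarizedExperiment::assay(se, "counts")
  lc <- logCPM(counts)
  grp <- groupFactor(designTable(se))
  X <- stats::model.matrix(~ 0 + grp)
  w <- voomWeights(lc, counts, X)
  fit <- fitContrasts(lc, w, designTable(se), contrasts)
  moderateAndTest(fit, thresholds)
}
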