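#' Median-of-ratios size factors
#'
#' DESeq-style: per sample, the median ratio of counts to the per-feature
#' geometric mean, computed over features positive in every sample. Falls
#' back to library size / mean library size when no feature is positive
#' everywhere.
#'
#' @param counts features x samples matrix.
#' @return numeric vector of size factors (one per sample).
#' @export
medianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (any(allPos)) {
    lg <- rowMeans(log(counts[allPos, , drop = FALSE]))
    sf <- apply(counts[allPos, , drop = FALSE], 2,
                function(cj) median(exp(log(cj) - lg)))
    if (all(is.finite(sf)) && all(sf > 0)) return(sf)
  }
  lib <- colSums(counts)
  lib / mean(lib)
}

#' Two-group negative-binomial Wald test
#'
#' Normalizes each group by its size factors, estimates the NB dispersion
#' \eqn{\alpha} by method of moments (variance = \eqn{\mu + \alpha\mu^2}),
#' and tests the difference of log means with a Wald statistic whose
#' variance follows from the NB mean-variance relation by the delta
#' method. \code{dispersion = "common"} (default) uses a single
#' across-gene moment estimate, the mean of per-gene moment estimates over
#' genes with pooled normalized mean above 5, which keeps the null
#' calibrated at small replicate numbers; \code{"per-gene"} uses the
#' per-gene moment estimate \eqn{\hat\alpha = \max(\alpha_{min},
#' (s^2 - \bar m)/\bar m^2)}.
#'
#' Swapping the groups negates the log2 fold change and leaves p
#' unchanged. All-zero features get p = 1 and log2FC = 0.
#'
#' @param countsA,countsB features x replicates count matrices.
#' @param sizeFactorsA,sizeFactorsB size factors; computed jointly by
#'   \code{\link{medianOfRatios}} when NULL.
#' @param alphaMin dispersion floor.
#' @param dispersion \code{"common"} or \code{"per-gene"}.
#' @return data.frame with \code{log2FC} and \code{p}; the dispersion used
#'   is attached as attribute \code{alpha}.
#' @export
nbTestTwoGroup <- function(countsA, countsB, sizeFactorsA = NULL,
                           sizeFactorsB = NULL, alphaMin = 1e-8,
                           dispersion = c("common", "per-gene")) {
  dispersion <- match.arg(dispersion)
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  if (nrow(countsA) != nrow(countsB)) stop("feature sets differ")
  nA <- ncol(countsA); nB <- ncol(countsB)
  if (is.null(sizeFactorsA) || is.null(sizeFactorsB)) {
    sf <- medianOfRatios(cbind(countsA, countsB))
    sizeFactorsA <- sf[seq_len(nA)]; sizeFactorsB <- sf[nA + seq_len(nB)]
  }
  a <- sweep(countsA, 2, sizeFactorsA, "/")
  b <- sweep(countsB, 2, sizeFactorsB, "/")
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- if (nA > 1) apply(a, 1, var) else rep(0, nrow(a))
  vB <- if (nB > 1) apply(b, 1, var) else rep(0, nrow(b))
  df <- max(nA - 1, 0) + max(nB - 1, 0)
  if (df < 1) stop("need at least 2 replicates in total across groups")
  sp <- (max(nA - 1, 0) * vA + max(nB - 1, 0) * vB) / df
  mbar <- (nA * mA + nB * mB) / (nA + nB)
  perGene <- pmax(alphaMin, (sp - mbar) / mbar^2)
  perGene[mbar == 0] <- alphaMin
  alpha <- if (dispersion == "common") {
    ok <- mbar > 5
    if (any(ok)) rep(max(alphaMin, mean(((sp - mbar) / mbar^2)[ok])),
                     length(mA)) else rep(alphaMin, length(mA))
  } else perGene
  log2FC <- log2((mB + 0.5) / (mA + 0.5))
  se2 <- (mA + alpha * mA^2) / (nA * (mA + 0.5)^2) +
         (mB + alpha * mB^2) / (nB * (mB + 0.5)^2)
  z <- (log(mB + 0.5) - log(mA + 0.5)) / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  zero <- mA + mB == 0
  p[zero] <- 1; log2FC[zero] <- 0
  p[se2 == 0 & !zero] <- 1
  out <- data.frame(log2FC = log2FC, p = p, row.names = rownames(countsA))
  attr(out, "alpha") <- alpha
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p ascending, takes \eqn{\min_{j \ge i} p_{(j)} m / j}, clips at 1
#' and restores the original order.
#'
#' @param p vector of probabilities in [0, 1].
#' @return adjusted values, same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Call differentially expressed features across the control/case design
#'
#' Compares every control group to every case group (the study design is
#' 2 living controls x 6 post-mortem groups = 12 comparisons per assay),
#' applies Benjamini-Hochberg within each comparison, and flags features
#' with |log2FC| > \code{lfcThresh} and FDR < \code{fdrThresh}.
#'
#' @param se count \code{SummarizedExperiment} with design in
#'   \code{colData()}.
#' @param controlLabels,caseLabels time labels of control and case groups.
#' @param lfcThresh,fdrThresh DE thresholds (defaults |log2FC| > 1,
#'   FDR < 0.05).
#' @param dispersion passed to \code{\link{nbTestTwoGroup}}.
#' @return data.frame with columns feature, comparison, log2FC, p, fdr,
#'   is_de.
#' @export
callDEFeatures <- function(se, controlLabels, caseLabels, lfcThresh = 1,
                           fdrThresh = 0.05,
                           dispersion = c("common", "per-gene")) {
  dispersion <- match.arg(dispersion)
  design <- as.data.frame(colData(se))
  counts <- assay(se, "counts")
  known <- unique(design$time_label)
  bad <- setdiff(c(controlLabels, caseLabels), known)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  res <- list()
  for (ctl in controlLabels) for (cs in caseLabels) {
    cA <- counts[, design$time_label == ctl, drop = FALSE]
    cB <- counts[, design$time_label == cs, drop = FALSE]
    t2 <- nbTestTwoGroup(cA, cB, dispersion = dispersion)
    fdr <- bhAdjust(t2$p)
    res[[paste0(ctl, "_vs_", cs)]] <- data.frame(
      feature = rownames(counts),
      comparison = paste0(ctl, "_vs_", cs),
      log2FC = t2$log2FC, p = t2$p, fdr = fdr,
      is_de = abs(t2$log2FC) > lfcThresh & fdr < fdrThresh,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Union of DE features over all comparisons
#'
#' @param deTable result of \code{\link{callDEFeatures}}.
#' @return character vector of features DE in at least one comparison.
#' @export
deFeatureUnion <- function(deTable) {
  unique(deTable$feature[deTable$is_de])
}

#' Core shared features: DE in every comparison
#'
#' The strict intersection of per-comparison DE sets; with the full
#' design this is the core post-mortem-related gene (CPRG) set.
#'
#' @param deTable result of \code{\link{callDEFeatures}}.
#' @return character vector of features DE in all comparisons.
#' @export
coreSharedFeatures <- function(deTable) {
  comps <- unique(deTable$comparison)
  if (length(comps) == 0) stop("no comparisons in DE table")
  sets <- lapply(comps, function(cmp)
    deTable$feature[deTable$comparison == cmp & deTable$is_de])
  Reduce(intersect, sets)
}
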