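resolveExpr <- function(x, design = NULL, assay = 1) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(design)) design <- as.data.frame(colData(x))
    vals <- assay(x, assay)
  } else {
    vals <- as.matrix(x)
    if (is.null(design)) stop("a design is required for a plain matrix")
  }
  if (nrow(design) != ncol(vals)) stop("design does not match samples")
  list(values = vals, design = design)
}

absCorSafe <- function(m) {
  suppressWarnings(cc <- cor(m))
  cc[is.na(cc)] <- 0
  abs(cc)
}

#' Build candidate DNB modules by hierarchical clustering
#'
#' Genes are clustered on the distance 1 - |Pearson correlation| computed
#' across all samples. By default the expression values are first centred
#' within each time point, so the correlation measures replicate-level
#' fluctuation rather than shared time-course shape — the quantity the
#' DNB statistics evaluate. The tree is cut at each size in
#' \code{nModules} and all resulting gene sets of at least \code{minSize}
#' are pooled (duplicates removed), giving several candidate sets for
#' \code{\link{detectTippingPoint}} to score.
#'
#' @param x expression \code{SummarizedExperiment} or matrix
#'   (log-scale values recommended).
#' @param design design data.frame (from \code{colData} when omitted).
#' @param nModules vector of tree-cut sizes.
#' @param minSize minimum module size; smaller groups are discarded.
#' @param linkage hclust agglomeration method.
#' @param centerWithinTime centre expression within each time point
#'   before computing the clustering correlation.
#' @return list of character vectors (gene sets).
#' @export
candidateModules <- function(x, design = NULL,
                             nModules = c(50, 100, 200),
                             minSize = 5L, linkage = "ward.D2",
                             centerWithinTime = TRUE) {
  r <- resolveExpr(x, design)
  vals <- r$values; design <- r$design
  if (nrow(vals) < minSize) stop("fewer genes than minSize")
  if (centerWithinTime) {
    for (t in unique(design$time_index)) {
      j <- design$time_index == t
      vals[, j] <- vals[, j] - rowMeans(vals[, j, drop = FALSE])
    }
  }
  d <- as.dist(1 - absCorSafe(t(vals)))
  hc <- hclust(d, method = linkage)
  cands <- list()
  for (k in pmin(nModules, nrow(vals))) {
    cl <- split(rownames(vals), cutree(hc, k = k))
    cands <- c(cands, unname(cl[lengths(cl) >= minSize]))
  }
  cands[!duplicated(lapply(cands, sort))]
}

#' Per-time DNB statistics of a gene module
#'
#' All statistics are computed across replicates within the single time
#' point \code{t}: \code{sdAvg} is the mean within-time SD over member
#' genes; \code{pccIn} the mean absolute Pearson correlation over member
#' pairs; \code{pccOut} the mean absolute correlation between members and
#' non-members; and the composite index
#' \code{ci = sdAvg * pccIn / max(pccOut, eps)}.
#'
#' @param module character vector of member gene ids.
#' @param x expression object (see \code{\link{candidateModules}}).
#' @param design design data.frame.
#' @param t 0-based time index.
#' @param eps floor on \code{pccOut} keeping the index finite.
#' @return named numeric: sdAvg, pccIn, pccOut, ci.
#' @export
moduleStatistics <- function(module, x, design = NULL, t, eps = 0.01) {
  r <- resolveExpr(x, design)
  vals <- r$values; design <- r$design
  cols <- design$time_index == t
  if (sum(cols) < 2) stop("need at least 2 replicates at time ", t)
  if (!length(module) || length(module) >= nrow(vals))
    stop("module and its complement must both be non-empty")
  miss <- setdiff(module, rownames(vals))
  if (length(miss)) stop("unknown genes: ", paste(head(miss), collapse = ", "))
  Xt <- vals[, cols, drop = FALSE]
  cc <- absCorSafe(t(Xt))
  inIdx <- rownames(vals) %in% module
  cin <- cc[inIdx, inIdx, drop = FALSE]
  sdAvg <- mean(apply(Xt[inIdx, , drop = FALSE], 1, sd))
  pccIn <- if (sum(inIdx) > 1) mean(cin[upper.tri(cin)]) else 1
  pccOut <- mean(cc[inIdx, !inIdx, drop = FALSE])
  c(sdAvg = sdAvg, pccIn = pccIn, pccOut = pccOut,
    ci = sdAvg * pccIn / max(pccOut, eps))
}

# trajectories for many candidates, computing each per-time correlation
# matrix only once
dnbTrajectories <- function(candidates, vals, design, eps = 0.01) {
  times <- sort(unique(design$time_index))
  ids <- rownames(vals)
  out <- do.call(rbind, lapply(seq_along(candidates), function(i)
    data.frame(candidate = i, time = times, sdAvg = NA_real_,
               pccIn = NA_real_, pccOut = NA_real_)))
  for (t in times) {
    cols <- design$time_index == t
    if (sum(cols) < 2) stop("need at least 2 replicates at time ", t)
    Xt <- vals[, cols, drop = FALSE]
    sds <- apply(Xt, 1, sd)
    cc <- absCorSafe(t(Xt))
    for (i in seq_along(candidates)) {
      inIdx <- ids %in% candidates[[i]]
      cin <- cc[inIdx, inIdx, drop = FALSE]
      row <- out$candidate == i & out$time == t
      out$sdAvg[row] <- mean(sds[inIdx])
      out$pccIn[row] <- if (sum(inIdx) > 1) mean(cin[upper.tri(cin)]) else 1
      out$pccOut[row] <- mean(cc[inIdx, !inIdx, drop = FALSE])
    }
  }
  out$strength <- out$pccIn / pmax(out$pccOut, eps)
  out$ci <- out$sdAvg * out$strength
  out
}

#' Detect the tipping point among candidate DNB modules
#'
#' For every candidate the per-time trajectories of average SD and
#' correlation strength (pccIn / pccOut) are computed; a candidate is
#' eligible when both peak at the same time point (the simultaneous-peak
#' rule). Among eligible candidates the one with the largest peak
#' composite index is selected; ties are broken by larger module, then by
#' lexicographic gene ids. When no candidate is eligible an explicit
#' no-transition report is returned.
#'
#' @param candidates list of gene sets (see \code{\link{candidateModules}}).
#' @param x expression object.
#' @param design design data.frame.
#' @param eps pccOut floor.
#' @return a \code{\linkS4class{DNBReport}}.
#' @export
detectTippingPoint <- function(candidates, x, design = NULL, eps = 0.01) {
  if (!length(candidates)) stop("no candidate modules supplied")
  r <- resolveExpr(x, design)
  traj <- dnbTrajectories(candidates, r$values, r$design, eps)
  times <- sort(unique(r$design$time_index))
  peakCI <- argSD <- argST <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    tr <- traj[traj$candidate == i, ]
    argSD[i] <- tr$time[which.max(tr$sdAvg)]
    argST[i] <- tr$time[which.max(tr$strength)]
    peakCI[i] <- max(tr$ci)
  }
  elig <- argSD == argST
  if (!any(elig))
    return(new("DNBReport", genes = character(0), time = NA_integer_,
               ci = numeric(0), trajectories = traj, permP = NA_real_))
  ord <- order(!elig, -peakCI, -lengths(candidates),
               vapply(candidates, function(g) paste(sort(g), collapse = ","),
                      ""))
  best <- ord[1]
  tr <- traj[traj$candidate == best, ]
  new("DNBReport", genes = sort(candidates[[best]]),
      time = as.integer(tr$time[which.max(tr$ci)]),
      ci = setNames(tr$ci, tr$time), trajectories = traj, permP = NA_real_)
}

#' Permutation p-value for a DNB module's composite index
#'
#' Permutes the time labels of the samples and recomputes the composite
#' index at time \code{t}; p is the proportion of permutations reaching
#' the observed value, with the observed configuration counted in both
#' numerator and denominator, so p lies in [1/(nPerm+1), 1].
#'
#' @param module gene set.
#' @param x expression object.
#' @param design design data.frame.
#' @param t 0-based time index of the called tipping point.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param eps pccOut floor.
#' @return permutation probability.
#' @export
dnbPermutationP <- function(module, x, design = NULL, t, nPerm = 1000L,
                            seed = NULL, eps = 0.01) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  r <- resolveExpr(x, design)
  vals <- r$values; design <- r$design
  if (!is.null(seed)) set.seed(seed)
  obs <- moduleStatistics(module, vals, design, t, eps)["ci"]
  hits <- 0L
  permDesign <- design
  for (i in seq_len(nPerm)) {
    permDesign$time_index <- design$time_index[sample.int(nrow(design))]
    ci <- moduleStatistics(module, vals, permDesign, t, eps)["ci"]
    if (ci >= obs) hits <- hits + 1L
  }
  (hits + 1) / (nPerm + 1)
}
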