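#' Standardize expression into per-gene time profiles
#'
#' Replicates are averaged within each time point, then each gene's
#' profile is z-scored along the time axis (mean 0, SD 1). Genes whose
#' profile has zero SD are dropped with a warning.
#'
#' @param em \code{SummarizedExperiment} (first assay used) or numeric
#'   matrix.
#' @param design design data.frame; taken from \code{colData(em)} when
#'   \code{em} is a \code{SummarizedExperiment}.
#' @return genes x timepoints matrix of standardized profiles, columns
#'   ordered by \code{time_index}.
#' @export
standardizeProfiles <- function(em, design = NULL) {
  if (is(em, "SummarizedExperiment")) {
    if (is.null(design)) design <- as.data.frame(colData(em))
    vals <- assay(em, 1)
  } else vals <- as.matrix(em)
  if (is.null(design)) stop("a design is required for a plain matrix")
  times <- sort(unique(design$time_index))
  if (length(times) < 2) stop("need at least 2 time points")
  prof <- vapply(times, function(t)
    rowMeans(vals[, design$time_index == t, drop = FALSE]),
    numeric(nrow(vals)))
  colnames(prof) <- paste0("T", times)
  sds <- apply(prof, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profile(s) dropped")
    prof <- prof[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (prof - rowMeans(prof)) / sds
}

#' Fuzzy c-means clustering of time profiles
#'
#' Minimizes \eqn{\sum_{ij} u_{ij}^m \|x_i - c_j\|^2} by alternating
#' membership and centroid updates. The fuzzifier \code{m = 1} is the
#' hard limit in which memberships become 0/1 indicators and the
#' iteration is exactly Lloyd's k-means; \code{m > 1} gives the standard
#' soft updates \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{ik})^{2/(m-1)}}.
#' Runs \code{nstart} restarts and keeps the best objective;
#' deterministic given \code{seed}.
#'
#' @param profiles genes x timepoints matrix (typically from
#'   \code{\link{standardizeProfiles}}).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (>= 1).
#' @param maxIter,tol iteration cap and relative objective tolerance.
#' @param nstart random restarts.
#' @param seed RNG seed for the restarts.
#' @return a \code{\linkS4class{FuzzyClustering}}.
#' @export
fuzzyCMeans <- function(profiles, c, m = 1, maxIter = 200L, tol = 1e-6,
                        nstart = 5L, seed = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (c < 2) stop("c must be at least 2")
  if (m < 1) stop("m must be at least 1")
  if (c > n) stop("more clusters than genes")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    ctr <- profiles[sample.int(n, c), , drop = FALSE]
    fit <- if (m == 1) fcmHard(profiles, ctr, maxIter)
           else fcmSoft(profiles, ctr, m, maxIter, tol)
    if (is.null(best) ||
        fit$objective[length(fit$objective)] <
          best$objective[length(best$objective)])
      best <- fit
  }
  u <- best$u
  rownames(u) <- rownames(profiles)
  new("FuzzyClustering", k = as.integer(c), m = as.numeric(m),
      membership = u, centroids = best$centroids,
      objective = best$objective)
}

sqDistToCentroids <- function(x, ctr) {
  # n x c matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(ctr))) -
    2 * x %*% t(ctr) + outer(rep(1, nrow(x)), rowSums(ctr^2))
}

fcmHard <- function(x, ctr, maxIter) {
  n <- nrow(x); c <- nrow(ctr)
  assign <- rep(0L, n); obj <- numeric(0)
  for (it in seq_len(maxIter)) {
    d2 <- pmax(sqDistToCentroids(x, ctr), 0)
    newAssign <- max.col(-d2, ties.method = "first")
    obj <- c(obj, sum(d2[cbind(seq_len(n), newAssign)]))
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (j in seq_len(c)) {
      mem <- assign == j
      if (any(mem)) ctr[j, ] <- colMeans(x[mem, , drop = FALSE])
      else ctr[j, ] <- x[which.max(d2[cbind(seq_len(n), assign)]), ]
    }
  }
  u <- matrix(0, n, c)
  u[cbind(seq_len(n), assign)] <- 1
  list(u = u, centroids = ctr, objective = obj)
}

fcmSoft <- function(x, ctr, m, maxIter, tol) {
  n <- nrow(x); c <- nrow(ctr)
  obj <- numeric(0)
  for (it in seq_len(maxIter)) {
    d2 <- pmax(sqDistToCentroids(x, ctr), 1e-12)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    obj <- c(obj, sum(um * d2))
    ctr <- (t(um) %*% x) / colSums(um)
    if (it > 1 && abs(obj[it - 1] - obj[it]) <=
        tol * max(obj[it - 1], .Machine$double.eps)) break
  }
  list(u = u, centroids = ctr, objective = obj)
}

#' Assign time-specific genes from a fuzzy clustering
#'
#' A cluster is time-specific for time t when its centroid attains its
#' maximum at t and exceeds the second-highest centroid value by at least
#' \code{peakMargin} (z-score units). A gene belongs to the time point of
#' the time-specific cluster in which it has its maximal membership,
#' provided that membership is at least \code{minMembership}; each gene
#' maps to at most one time point, so the returned sets are disjoint.
#'
#' @param fc a \code{\linkS4class{FuzzyClustering}}.
#' @param minMembership membership threshold.
#' @param peakMargin required centroid peak margin on the z scale.
#' @return named list, one element per time-specific time index
#'   (name = 0-based index), each a character vector of gene ids.
#' @export
timeSpecificAssignment <- function(fc, minMembership = 0.5,
                                   peakMargin = 0.5) {
  ctr <- centroids(fc)
  nT <- ncol(ctr)
  peakTime <- rep(NA_integer_, nrow(ctr))
  for (j in seq_len(nrow(ctr))) {
    o <- order(ctr[j, ], decreasing = TRUE)
    if (ctr[j, o[1]] - ctr[j, o[2]] >= peakMargin)
      peakTime[j] <- o[1] - 1L
  }
  u <- memberships(fc)
  top <- max.col(u, ties.method = "first")
  ok <- u[cbind(seq_len(nrow(u)), top)] >= minMembership &
        !is.na(peakTime[top])
  out <- split(rownames(u)[ok], peakTime[top[ok]])
  out[order(as.integer(names(out)))]
}
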