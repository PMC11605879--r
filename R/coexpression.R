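#' Combined mRNA + miRNA time profiles
#'
#' Averages replicates to one value per time point for each assay,
#' z-scores every feature across the time axis and stacks mRNA rows over
#' miRNA rows. Both assays must share the same set of time indices
#' (replicate numbers may differ). Constant features are dropped with a
#' warning.
#'
#' @param emMrna,emMirna expression \code{SummarizedExperiment}s (or
#'   matrices with designs supplied).
#' @param designMrna,designMirna designs when matrices are given.
#' @return features x timepoints matrix of standardized profiles.
#' @export
buildCombinedProfiles <- function(emMrna, emMirna, designMrna = NULL,
                                  designMirna = NULL) {
  a <- resolveExpr(emMrna, designMrna)
  b <- resolveExpr(emMirna, designMirna)
  ta <- sort(unique(a$design$time_index))
  tb <- sort(unique(b$design$time_index))
  if (!identical(ta, tb)) stop("assays have mismatched time axes")
  pa <- suppressWarnings(standardizeProfiles(a$values, a$design))
  pb <- suppressWarnings(standardizeProfiles(b$values, b$design))
  dropped <- (nrow(a$values) - nrow(pa)) + (nrow(b$values) - nrow(pb))
  if (dropped > 0) warning(dropped, " constant feature(s) dropped")
  rbind(pa, pb)
}

#' Topological overlap network from profiles
#'
#' Pearson correlation over the time axis, unsigned soft-threshold
#' adjacency \eqn{a_{ij} = |cor_{ij}|^\beta} (diagonal set to 0), and the
#' topological overlap measure
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
#'                      {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_u a_{iu}} and \eqn{TOM_{ii} = 1} by convention.
#'
#' @param profiles features x timepoints matrix.
#' @param beta soft-threshold power (> 0).
#' @return a \code{\linkS4class{CoexprNetwork}} (modules not yet
#'   assigned).
#' @export
tomFromProfiles <- function(profiles, beta = 6) {
  if (beta <= 0) stop("beta must be positive")
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop("need at least 3 features")
  a <- absCorSafe(t(profiles))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  new("CoexprNetwork", features = rownames(profiles), beta = beta,
      adjacency = a, tom = tom,
      modules = setNames(rep(NA_integer_, nrow(profiles)),
                         rownames(profiles)),
      eigenprofiles = matrix(0, 0, ncol(profiles)), profiles = profiles)
}

moduleEigenprofile <- function(profiles) {
  if (nrow(profiles) == 1) return(profiles[1, ] / max(sd(profiles[1, ]), 1e-12))
  v <- svd(scale(t(profiles), center = TRUE, scale = FALSE))$u[, 1]
  if (sum(v * colMeans(profiles)) < 0) v <- -v
  v
}

#' Detect co-expression modules on the TOM
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut into
#' \code{nModules} groups; groups smaller than \code{minSize} are left
#' unassigned. Modules whose eigenprofiles (first principal component of
#' member profiles, sign-aligned to the module mean) correlate above
#' \code{mergeCor} are merged iteratively, most-correlated pair first.
#'
#' @param net a \code{\linkS4class{CoexprNetwork}}.
#' @param nModules tree-cut size (>= 1).
#' @param minSize minimum module size.
#' @param mergeCor eigenprofile correlation above which modules merge;
#'   set above 1 to disable merging.
#' @return the network with \code{modules} and \code{eigenprofiles}
#'   filled in (module ids renumbered 1..m).
#' @export
detectCoexpressionModules <- function(net, nModules, minSize = 3L,
                                      mergeCor = 0.85) {
  if (nModules < 1) stop("nModules must be at least 1")
  hc <- hclust(as.dist(1 - net@tom), method = "average")
  cl <- cutree(hc, k = min(nModules, length(net@features)))
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < minSize])] <- NA_integer_
  prof <- net@profiles
  repeat {
    mods <- sort(unique(cl[!is.na(cl)]))
    if (length(mods) < 2) break
    eig <- t(vapply(mods, function(m)
      moduleEigenprofile(prof[which(cl == m), , drop = FALSE]),
      numeric(ncol(prof))))
    ec <- suppressWarnings(cor(t(eig)))
    ec[!is.finite(ec)] <- 0
    diag(ec) <- -Inf
    if (max(ec) <= mergeCor) break
    ij <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    cl[cl == mods[ij[2]]] <- mods[ij[1]]
  }
  mods <- sort(unique(cl[!is.na(cl)]))
  relabel <- setNames(seq_along(mods), mods)
  newCl <- ifelse(is.na(cl), NA_integer_,
                  relabel[as.character(cl)])
  eig <- if (length(mods))
    t(vapply(mods, function(m)
      moduleEigenprofile(prof[which(cl == m), , drop = FALSE]),
      numeric(ncol(prof)))) else matrix(0, 0, ncol(prof))
  net@modules <- setNames(as.integer(newCl), net@features)
  net@eigenprofiles <- eig
  net
}

permEnv <- new.env(parent = emptyenv())

# all permutations of 1..n, one per row (iterative insertion build)
allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(permEnv[[key]])) return(permEnv[[key]])
  p <- matrix(1L, 1, 1)
  if (n > 1) for (k in 2:n) {
    old <- p
    p <- matrix(0L, nrow(old) * k, k)
    row <- 0L
    for (pos in seq_len(k)) {
      left <- old[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos < k) old[, pos:(k - 1), drop = FALSE] else
        matrix(0L, nrow(old), 0)
      p[row + seq_len(nrow(old)), ] <- cbind(left, rep(k, nrow(old)), right)
      row <- row + nrow(old)
    }
  }
  permEnv[[key]] <- p
  p
}

spearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  suppressWarnings(r <- cor(rx, ry))
  if (is.na(r)) 0 else r
}

nullRhoDistribution <- function(n) {
  key <- paste0("null", n)
  if (!is.null(permEnv[[key]])) return(permEnv[[key]])
  P <- allPermutations(n)
  r <- seq_len(n)
  rc <- r - mean(r)
  denom <- sum(rc^2)
  vals <- as.vector((matrix(rc[P], nrow(P), n) %*% rc) / denom)
  permEnv[[key]] <- sort(abs(vals))
  permEnv[[key]]
}

#' Exact small-sample Spearman correlation test
#'
#' Spearman rho on (mid)ranks with a two-sided p-value computed by full
#' enumeration of all n! rank permutations for n <= 8 (40,320
#' permutations at n = 8); the t approximation is used for larger n.
#' Tied data are handled with midranks, enumerating the observed rank
#' multiset.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return list with \code{rho} and two-sided \code{p}.
#' @export
spearmanExact <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("lengths differ")
  if (n < 4) stop("need at least 4 observations")
  rho <- spearmanRho(x, y)
  if (n > 8) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    return(list(rho = rho, p = min(1, 2 * pt(-abs(tt), n - 2))))
  }
  rx <- rank(x); ry <- rank(y)
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    P <- allPermutations(n)
    xc <- rx - mean(rx); yc <- ry - mean(ry)
    denom <- sqrt(sum(xc^2) * sum(yc^2))
    if (denom == 0) return(list(rho = 0, p = 1))
    vals <- abs(as.vector((matrix(yc[P], nrow(P), n) %*% xc) / denom))
  } else {
    vals <- nullRhoDistribution(n)
  }
  p <- mean(vals >= abs(rho) - 1e-12)
  list(rho = rho, p = p)
}

#' Spearman filter for candidate mRNA-miRNA pairs
#'
#' Computes Spearman rho between the time-point mean profiles of each
#' candidate pair with an exact enumeration p-value
#' (\code{\link{spearmanExact}}) and flags pairs with
#' rho < \code{rhoMax} and p < \code{pMax} — strongly negatively
#' correlated pairs, as expected for a repressive miRNA and its target.
#'
#' @param profiles feature x timepoints matrix covering both assays
#'   (e.g. \code{\link{buildCombinedProfiles}}).
#' @param pairs data.frame with columns \code{mrna}, \code{mirna}.
#' @param rhoMax,pMax filter thresholds.
#' @return the pair table with \code{rho}, \code{p} and \code{pass}
#'   columns appended.
#' @export
spearmanPairFilter <- function(profiles, pairs, rhoMax = -0.8,
                               pMax = 0.05) {
  if (ncol(profiles) < 4) stop("need at least 4 time points")
  miss <- setdiff(unique(c(pairs$mrna, pairs$mirna)), rownames(profiles))
  if (length(miss))
    stop("features absent from profiles: ", paste(head(miss), collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i)
    spearmanExact(profiles[pairs$mrna[i], ], profiles[pairs$mirna[i], ]))
  pairs$rho <- vapply(res, `[[`, 1, "rho")
  pairs$p <- vapply(res, `[[`, 1, "p")
  pairs$pass <- pairs$rho < rhoMax & pairs$p < pMax
  pairs
}

#' Expression-based target pairs
#'
#' A pair is an expression target when both members are assigned to the
#' same co-expression module AND the pair passes the Spearman filter.
#'
#' @param net a clustered \code{\linkS4class{CoexprNetwork}}.
#' @param pairRecords output of \code{\link{spearmanPairFilter}}.
#' @return the records with \code{same_module} and \code{is_target}
#'   columns appended.
#' @export
expressionTargets <- function(net, pairRecords) {
  mods <- moduleAssignments(net)
  mm <- mods[pairRecords$mrna]
  mi <- mods[pairRecords$mirna]
  pairRecords$same_module <- !is.na(mm) & !is.na(mi) & mm == mi
  pairRecords$is_target <- pairRecords$same_module & pairRecords$pass
  pairRecords
}
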