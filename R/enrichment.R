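#' Hypergeometric over-representation probability
#'
#' Upper-tail probability of drawing at least \code{k} annotated members
#' in a set of size \code{n} from a background of \code{N} features of
#' which \code{K} are annotated:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
#'       \binom{N}{n}}
#' (the one-sided Fisher test for over-representation). Vectorized over
#' \code{k}, \code{n}, \code{K}.
#'
#' @param k annotated members in the set.
#' @param n set size.
#' @param K annotated members in the background.
#' @param N background size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeometricTest <- function(k, n, K, N) {
  if (any(k < 0) || any(k > n) || any(n > N) || any(K > N) || any(K < 0))
    stop("require 0 <= k <= n <= N and 0 <= K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term with at least one set member against the
#' background universe using \code{\link{hypergeometricTest}}, adjusts
#' with Benjamini-Hochberg across the tested terms, and sorts by FDR.
#' Set members missing from the annotation count toward the set size n
#' but toward no term's k.
#'
#' @param geneSet character vector of feature ids.
#' @param annotation data.frame with columns \code{term_id},
#'   \code{term_name} (optional), \code{gene_id}.
#' @param background character vector; must contain the gene set.
#' @param fdrThresh significance threshold.
#' @return data.frame with term_id, term_name, k, n, K, N, p, fdr,
#'   significant.
#' @export
enrichSet <- function(geneSet, annotation, background,
                      fdrThresh = 0.05) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% background))
    stop("gene set must be contained in the background")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  n <- length(geneSet); N <- length(background)
  terms <- split(unique(ann[, c("term_id", "gene_id")])$gene_id,
                 unique(ann[, c("term_id", "gene_id")])$term_id)
  kk <- vapply(terms, function(g) sum(geneSet %in% g), 0L)
  keep <- kk >= 1
  if (!any(keep))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  terms <- terms[keep]; kk <- kk[keep]
  KK <- lengths(terms)
  p <- hypergeometricTest(kk, n, KK, N)
  fdr <- bhAdjust(p)
  nameMap <- if ("term_name" %in% names(annotation))
    setNames(annotation$term_name, annotation$term_id) else NULL
  out <- data.frame(term_id = names(terms),
                    term_name = if (is.null(nameMap)) NA_character_ else
                      unname(nameMap[names(terms)]),
                    k = kk, n = n, K = KK, N = N, p = p, fdr = fdr,
                    significant = fdr < fdrThresh,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}
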