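asRnaChars <- function(seq) {
  s <- toupper(as.character(seq))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s)) stop("illegal characters in sequence")
  strsplit(s, "")[[1]]
}

asDnaString <- function(seq) {
  s <- toupper(as.character(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) stop("illegal characters in sequence")
  s
}

# allowed UTR (DNA) letters pairing each miRNA base; G:U wobble adds
# G~U(T) and U~G
pairLetters <- function(mBase, allowGU) {
  wc <- c(A = "T", C = "G", G = "C", U = "A")[mBase]
  if (!allowGU) return(wc)
  extra <- c(A = "", C = "", G = "T", U = "G")[mBase]
  paste0(wc, extra)
}

iupac <- c(A = "A", C = "C", G = "G", T = "T",
           CT = "Y", TC = "Y", AG = "R", GA = "R")

# seed pattern on the UTR, 5'->3': UTR position s+k pairs miRNA
# position 8-k, k = 0..6
seedPattern <- function(mirChars, allowGU) {
  letters <- vapply(0:6, function(k)
    iupac[[pairLetters(mirChars[8 - k], allowGU)]], "")
  paste(letters, collapse = "")
}

#' Scan a UTR for miRNA seed matches
#'
#' Reports every UTR position where miRNA positions 2-8 (1-based from the
#' 5' end) pair antiparallel Watson-Crick with the UTR; G:U wobble pairs
#' are admitted only with \code{allowGU}. The scan is
#' orientation-specific: reversing the UTR abolishes hits.
#'
#' @param mirnaSeq miRNA sequence (RNA or DNA alphabet).
#' @param utrSeq UTR sequence (RNA or DNA alphabet).
#' @param allowGU admit G:U wobble pairs in the seed.
#' @return data.frame with 0-based half-open \code{start}, \code{end}
#'   (always width 7) per hit.
#' @export
seedScan <- function(mirnaSeq, utrSeq, allowGU = FALSE) {
  m <- asRnaChars(mirnaSeq)
  if (length(m) < 8) stop("miRNA must be at least 8 nt")
  u <- asDnaString(utrSeq)
  if (nchar(u) < 7)
    return(data.frame(start = integer(0), end = integer(0)))
  hits <- Biostrings::matchPattern(seedPattern(m, allowGU),
                                   Biostrings::DNAString(u),
                                   fixed = c(pattern = FALSE, subject = TRUE))
  st <- BiocGenerics::start(hits) - 1L
  data.frame(start = st, end = st + 7L)
}

#' Score a miRNA/UTR-window duplex
#'
#' Gapless antiparallel pairing with the register anchored at the window
#' 3' end: miRNA position i (1-based, 5' end) pairs the window base
#' \code{W - i} (0-based) for a window of width W; positions beyond the
#' window are unpaired and score as mismatches. The alignment score is
#' +5 per Watson-Crick pair, +1 per G:U, -3 per mismatch, with seed
#' positions 2-8 doubled; the energy score sums -3.0 per G:C, -2.0 per
#' A:U and -1.0 per G:U over paired positions (pseudo kcal/mol; more
#' negative is stronger).
#'
#' @param mirnaSeq miRNA sequence.
#' @param utrWindow UTR window (see \code{\link{sequenceTargets}}).
#' @return named numeric: \code{align}, \code{energy}.
#' @export
siteScore <- function(mirnaSeq, utrWindow) {
  m <- asRnaChars(mirnaSeq)
  w <- asRnaChars(chartr("T", "U", toupper(as.character(utrWindow))))
  if (!length(w)) stop("empty window")
  L <- length(m); W <- length(w)
  align <- 0; energy <- 0
  for (i in seq_len(L)) {
    j <- W - i + 1L  # 1-based window index
    weight <- if (i >= 2 && i <= 8) 2 else 1
    if (j < 1 || j > W) { align <- align - 3 * weight; next }
    duplex <- paste0(m[i], w[j])
    if (duplex %in% c("AU", "UA", "CG", "GC")) {
      align <- align + 5 * weight
      energy <- energy + if (duplex %in% c("CG", "GC")) -3 else -2
    } else if (duplex %in% c("GU", "UG")) {
      align <- align + 1 * weight
      energy <- energy - 1
    } else {
      align <- align - 3 * weight
    }
  }
  c(align = align, energy = energy)
}

#' Sequence-based miRNA target pairs
#'
#' Scans every miRNA against every UTR for seed matches, scores each hit
#' over the window obtained by extending the 7-nt seed site across the
#' full miRNA register (one extra base 3' of the seed site for miRNA
#' position 1 and the remainder 5'-ward, where the miRNA 3' region
#' pairs), and retains a pair when at least one site passes both
#' criteria: alignment score >= \code{alignMin} AND energy score <=
#' \code{energyMax}. Requiring two independent criteria plays the role
#' of intersecting the predictions of two independent tools.
#'
#' @param mirnas named \code{RNAStringSet} (or DNA / character vector).
#' @param utrs named \code{DNAStringSet} (or character vector).
#' @param alignMin,energyMax score thresholds.
#' @param allowGU admit G:U seed pairs.
#' @return list with \code{pairs} (data.frame mrna, mirna) and
#'   \code{sites} (per-hit table with scores and pass flag).
#' @export
sequenceTargets <- function(mirnas, utrs, alignMin = 80, energyMax = -20,
                            allowGU = FALSE) {
  mirnas <- setNames(as.character(mirnas), names(mirnas))
  utrs <- setNames(vapply(as.character(utrs), asDnaString, ""), names(utrs))
  if (is.null(names(mirnas)) || is.null(names(utrs)))
    stop("mirnas and utrs must be named")
  utrSet <- Biostrings::DNAStringSet(utrs)
  sites <- list()
  for (mid in names(mirnas)) {
    m <- asRnaChars(mirnas[[mid]])
    if (length(m) < 8) stop("miRNA ", mid, " shorter than 8 nt")
    L <- length(m)
    hits <- Biostrings::vmatchPattern(
      seedPattern(m, allowGU), utrSet,
      fixed = c(pattern = FALSE, subject = TRUE))
    for (g in which(lengths(hits) > 0)) {
      gid <- names(utrs)[g]
      for (s in BiocGenerics::start(hits[[g]]) - 1L) {
        wStart <- max(0L, s + 8L - L)
        wEnd <- min(nchar(utrs[[gid]]), s + 8L)
        sc <- siteScore(mirnas[[mid]],
                        substr(utrs[[gid]], wStart + 1L, wEnd))
        sites[[length(sites) + 1L]] <- data.frame(
          mirna = mid, mrna = gid, start = s, end = s + 7L,
          align_score = unname(sc["align"]),
          energy_score = unname(sc["energy"]),
          pass = sc["align"] >= alignMin && sc["energy"] <= energyMax,
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna = character(0), mrna = character(0),
               start = integer(0), end = integer(0),
               align_score = numeric(0), energy_score = numeric(0),
               pass = logical(0), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  pairs <- unique(sites[sites$pass, c("mrna", "mirna")])
  rownames(pairs) <- NULL
  list(pairs = pairs, sites = sites)
}
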