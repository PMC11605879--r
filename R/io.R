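#' Read and validate a sample design table
#'
#' The design TSV has columns \code{sample_id}, \code{assay}
#' (\code{"mrna"} or \code{"mirna"}), \code{time_label},
#' \code{time_index} (0-based, dense) and \code{replicate}.
#'
#' @param path path to a tab-separated design table.
#' @return a validated \code{data.frame}.
#' @export
readDesign <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validateDesign(d)
  d
}

validateDesign <- function(d) {
  need <- c("sample_id", "assay", "time_label", "time_index", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(d$assay %in% c("mrna", "mirna")))
    stop("assay must be 'mrna' or 'mirna'")
  key <- paste(d$assay, d$time_index, d$replicate)
  if (anyDuplicated(key))
    stop("(assay, time_index, replicate) combinations must be unique")
  for (a in unique(d$assay)) {
    ti <- sort(unique(d$time_index[d$assay == a]))
    if (!identical(ti, seq(0L, max(ti))))
      stop("time_index must be dense from 0 for assay ", a)
  }
  invisible(TRUE)
}

#' Assemble a validated count matrix
#'
#' Builds the package's count container: a
#' \link[SummarizedExperiment]{SummarizedExperiment} with a \code{counts}
#' assay, the design in \code{colData()} and (for mRNA) feature lengths in
#' \code{rowData()$length}.
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param design design \code{data.frame} covering the sample columns.
#' @param lengths optional named vector of feature lengths (nt).
#' @return a \code{SummarizedExperiment}.
#' @export
makeCountMatrix <- function(counts, design, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and sample names")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  validateDesign(design)
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx))
    stop("samples absent from design: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  cd <- DataFrame(design[idx, , drop = FALSE])
  rownames(cd) <- colnames(counts)
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(lengths)) {
    len <- lengths[rownames(counts)]
    if (anyNA(len)) stop("lengths missing for some features")
    if (any(len <= 0)) stop("lengths must be positive")
    rd$length <- as.numeric(len)
  }
  SummarizedExperiment(assays = list(counts = counts),
                       rowData = rd, colData = cd)
}

#' Read a count matrix from TSV
#'
#' First column of the counts file is the feature id; remaining columns
#' are samples. Every sample must appear in the design; negative,
#' non-integer or duplicated entries are rejected.
#'
#' @param path counts TSV.
#' @param designPath design TSV (see \code{\link{readDesign}}).
#' @param lengthsPath optional TSV with columns \code{feature_id},
#'   \code{length}.
#' @return a \code{SummarizedExperiment} (see \code{\link{makeCountMatrix}}).
#' @export
readCounts <- function(path, designPath, lengthsPath = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("counts file needs a feature column and samples")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts")
  rownames(m) <- ids
  lengths <- NULL
  if (!is.null(lengthsPath)) {
    lt <- read.delim(lengthsPath, stringsAsFactors = FALSE)
    lengths <- setNames(lt$length, lt$feature_id)
  }
  makeCountMatrix(m, readDesign(designPath), lengths)
}

#' Write a count matrix (and its design) as TSV
#'
#' @param se a count \code{SummarizedExperiment}.
#' @param path counts TSV destination.
#' @param designPath optional design TSV destination.
#' @param lengthsPath optional lengths TSV destination.
#' @export
writeCounts <- function(se, path, designPath = NULL, lengthsPath = NULL) {
  m <- assay(se, "counts")
  out <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(designPath))
    write.table(as.data.frame(colData(se)), designPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(lengthsPath) && !is.null(rowData(se)$length))
    write.table(data.frame(feature_id = rownames(m),
                           length = rowData(se)$length),
                lengthsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize counts to FPKM, TPM or CPM
#'
#' FPKM divides by feature length (kb) and library size (millions);
#' TPM first length-normalizes to rates and then scales each sample to
#' one million, so every TPM column sums to 1e6; CPM is count / library
#' size x 1e6 (the convention used for mature miRNAs, whose lengths are
#' nearly constant; values are reported in TPM units).
#'
#' @param se count \code{SummarizedExperiment}.
#' @param mode \code{"fpkm"}, \code{"tpm"} or \code{"cpm"}.
#' @return a \code{SummarizedExperiment} with the normalized assay (named
#'   by mode) and provenance in \code{metadata()}.
#' @export
normalizeExpression <- function(se, mode = c("fpkm", "tpm", "cpm")) {
  mode <- match.arg(mode)
  m <- assay(se, "counts")
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(m)[lib == 0], collapse = ", "))
  if (mode %in% c("fpkm", "tpm")) {
    len <- rowData(se)$length
    if (is.null(len)) stop(mode, " requires feature lengths")
    if (mode == "fpkm") {
      vals <- m * 1e9 / outer(len, lib)
    } else {
      rate <- m / len
      vals <- sweep(rate, 2, colSums(rate), "/") * 1e6
    }
  } else {
    vals <- sweep(m, 2, lib, "/") * 1e6
  }
  out <- se
  SummarizedExperiment::assays(out, withDimnames = FALSE) <-
    c(setNames(list(vals), mode), list(counts = m))
  metadata(out)$unit <- toupper(mode)
  metadata(out)$lib_size <- lib
  out
}

#' Abundance filters for mRNA and miRNA features
#'
#' mRNA rule: minimum FPKM over all samples at least \code{fpkmMin}.
#' miRNA rules (both must hold): raw count > 0 in at least
#' \code{minReps} replicates at some single time point, and mean
#' TPM over all samples at least \code{tpmMeanMin}. All thresholds are
#' inclusive.
#'
#' @param em normalized \code{SummarizedExperiment} (FPKM for mRNA,
#'   TPM/CPM for miRNA).
#' @param cm count \code{SummarizedExperiment} (needed for the miRNA
#'   replicate-detection rule; defaults to \code{em}, which still carries
#'   its counts assay).
#' @param rule \code{"mrna"} or \code{"mirna"}.
#' @param fpkmMin,minReps,tpmMeanMin rule thresholds.
#' @return character vector of retained feature ids.
#' @export
filterFeatures <- function(em, cm = em, rule = c("mrna", "mirna"),
                           fpkmMin = 0.1, minReps = 2L, tpmMeanMin = 1) {
  rule <- match.arg(rule)
  if (rule == "mrna") {
    vals <- assay(em, 1)
    keep <- apply(vals, 1, min) >= fpkmMin
  } else {
    counts <- assay(cm, "counts")
    design <- as.data.frame(colData(cm))
    det <- rep(FALSE, nrow(counts))
    for (t in unique(design$time_index)) {
      cols <- design$time_index == t
      det <- det | rowSums(counts[, cols, drop = FALSE] > 0) >= minReps
    }
    vals <- assay(em, 1)
    keep <- det & rowMeans(vals) >= tpmMeanMin
  }
  rownames(em)[keep]
}

#' QC summary: PCA coordinates and sample correlations
#'
#' PCA is computed on log2(x + 1), centred per feature; the correlation
#' matrix is Pearson between sample columns on the same scale.
#'
#' @param em normalized \code{SummarizedExperiment} or numeric matrix.
#' @return list with \code{pca} (a \code{prcomp} fit on samples) and
#'   \code{correlation} (samples x samples).
#' @export
qcSummary <- function(em) {
  vals <- if (is(em, "SummarizedExperiment")) assay(em, 1) else as.matrix(em)
  if (ncol(vals) < 2) stop("need at least 2 samples")
  lx <- log2(vals + 1)
  keep <- apply(lx, 1, sd) > 0
  if (!any(keep)) stop("constant matrix: QC summary undefined")
  lx <- lx[keep, , drop = FALSE]
  pca <- prcomp(t(lx), center = TRUE, scale. = FALSE)
  list(pca = pca, correlation = cor(lx))
}
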