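#' Configuration for the synthetic post-mortem time course
#'
#' Returns a validated configuration for
#' \code{\link{simulateTimecourse}}. Defaults mirror the study design the
#' package targets: 8 time points (2 living controls, 6 post-mortem),
#' 3 mRNA and 2 miRNA replicates per point, negative-binomial counts with
#' variance \eqn{\mu + \alpha\mu^2}, planted two-fold-squared differential
#' expression, single-time-point expression peaks, a DNB module whose
#' replicate-level variance and intra-correlation spike at one time point,
#' and miRNA-target pairs coupled through a negative slope on the miRNA
#' z-profile with seed-complementary UTR sites.
#'
#' @param nTimepoints number of time points (first two are living
#'   controls).
#' @param nRepsMrna,nRepsMirna replicates per time point per assay.
#' @param nGenes,nMirnas feature counts.
#' @param fracDE fraction of genes with planted differential expression in
#'   the post-mortem groups.
#' @param lfcDE planted |log2 fold change| (also the amplitude of planted
#'   miRNA time profiles).
#' @param fracTSG fraction of genes with a planted single-time peak.
#' @param tsgPeakHeight multiplicative peak factor.
#' @param dnbSize planted DNB module size (at least 5).
#' @param dnbTimeIndex 0-based planted transition time.
#' @param dnbSdFactor standard-deviation inflation at the transition
#'   (1 = no plant).
#' @param dnbRhoIn planted intra-module correlation at the transition;
#'   must not exceed \code{1 - 1/dnbSdFactor^2}.
#' @param nTruePairs number of planted mRNA-miRNA pairs (distinct genes
#'   and distinct miRNAs).
#' @param pairSlope negative coupling strength (log2 units per miRNA
#'   z-unit).
#' @param dispersion NB dispersion \eqn{\alpha} (> 0).
#' @param utrLen UTR length in nucleotides.
#' @param mirnaLen mature miRNA length.
#' @param seed RNG seed; all draws flow from one generator.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(nTimepoints = 8L, nRepsMrna = 3L, nRepsMirna = 2L,
                      nGenes = 2000L, nMirnas = 100L,
                      fracDE = 0.1, lfcDE = 2, fracTSG = 0.2,
                      tsgPeakHeight = 4, dnbSize = 30L, dnbTimeIndex = 3L,
                      dnbSdFactor = 5, dnbRhoIn = 0.8, nTruePairs = 20L,
                      pairSlope = 2, dispersion = 0.1, utrLen = 500L,
                      mirnaLen = 22L, seed = 20240131L) {
  cfg <- list(nTimepoints = as.integer(nTimepoints),
              nRepsMrna = as.integer(nRepsMrna),
              nRepsMirna = as.integer(nRepsMirna),
              nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
              fracDE = fracDE, lfcDE = lfcDE, fracTSG = fracTSG,
              tsgPeakHeight = tsgPeakHeight, dnbSize = as.integer(dnbSize),
              dnbTimeIndex = as.integer(dnbTimeIndex),
              dnbSdFactor = dnbSdFactor, dnbRhoIn = dnbRhoIn,
              nTruePairs = as.integer(nTruePairs), pairSlope = pairSlope,
              dispersion = dispersion, utrLen = as.integer(utrLen),
              mirnaLen = as.integer(mirnaLen), seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (nTimepoints < 1 || nRepsMrna < 1 || nRepsMirna < 1 ||
        nGenes < 1 || nMirnas < 1)
      stop("counts in the configuration must be positive")
    if (fracDE < 0 || fracDE > 1 || fracTSG < 0 || fracTSG > 1)
      stop("fractions must lie in [0, 1]")
    if (dnbTimeIndex < 0 || dnbTimeIndex >= nTimepoints)
      stop("dnbTimeIndex must be < nTimepoints")
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (dnbSize < 5) stop("dnbSize must be at least 5")
    if (dnbSdFactor > 1 && dnbRhoIn > 1 - 1 / dnbSdFactor^2)
      stop("dnbRhoIn must not exceed 1 - 1/dnbSdFactor^2")
    if (nTruePairs > nGenes || nTruePairs > nMirnas)
      stop("nTruePairs cannot exceed nGenes or nMirnas")
    if (mirnaLen < 8) stop("mirnaLen must be at least 8")
  })
  invisible(TRUE)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$nGenes, "genes /", x$nMirnas, "miRNAs,",
      x$nTimepoints, "time points\n")
  invisible(x)
}

timeLabels <- function(n) paste0("T", seq_len(n) - 1L)

#' Generate the sample design for a configuration
#'
#' One record per (assay, time point, replicate); deterministic given the
#' configuration.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return design \code{data.frame} (see \code{\link{readDesign}}).
#' @export
generateDesign <- function(cfg) {
  validateSimConfig(cfg)
  one <- function(assay, reps) {
    d <- expand.grid(replicate = seq_len(reps),
                     time_index = seq_len(cfg$nTimepoints) - 1L)
    data.frame(sample_id = sprintf("%s_T%d_r%d", assay, d$time_index,
                                   d$replicate),
               assay = assay,
               time_label = paste0("T", d$time_index),
               time_index = as.integer(d$time_index),
               replicate = as.integer(d$replicate),
               stringsAsFactors = FALSE)
  }
  rbind(one("mrna", cfg$nRepsMrna), one("mirna", cfg$nRepsMirna))
}

# first post-mortem time index: indices 0,1 are the living controls
postmortemStart <- function(nT) if (nT > 2) 2L else max(nT - 1L, 1L)

#' Simulate the paired mRNA/miRNA time course with planted truth
#'
#' Baseline gene means are log-normal (log 50, sd 1.2 for mRNA;
#' log 200, sd 1.0 for miRNA). Planted roles (DE, time-specific peak, DNB
#' module, pair target) are assigned to disjoint gene sets drawn from
#' genes with baseline mean >= 10 counts, since planted structure is only
#' discoverable in features that survive abundance filtering. DE genes
#' gain +/- \code{lfcDE} log2 units in every post-mortem group; TSG genes
#' are multiplied by \code{tsgPeakHeight} at one time point; DNB genes
#' share a replicate-level latent Gaussian factor at the transition time
#' (standardized to unit realized variance so the planted inflation is
#' present in every dataset); each planted miRNA receives an i.i.d.
#' N(0, lfcDE^2) log2 time profile and its target gene's log2 mean is
#' shifted by \code{-pairSlope} times the z-scored miRNA profile. Counts
#' are NB with variance \eqn{\mu + \alpha\mu^2}. Random mature miRNA and
#' UTR sequences are generated and seed-complementary sites embedded for
#' the true pairs (\code{\link{embedSeedSites}}); a synthetic annotation
#' table (including a term covering the DNB module) is attached.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with elements \code{mrna}, \code{mirna} (count
#'   \code{SummarizedExperiment}s), \code{truth} (\code{\linkS4class{SimTruth}}),
#'   \code{utrs} (\code{DNAStringSet}), \code{mirnaSeqs}
#'   (\code{RNAStringSet}) and \code{annotation} (\code{data.frame}).
#' @export
simulateTimecourse <- function(cfg) {
  validateSimConfig(cfg)
  set.seed(cfg$seed)
  nT <- cfg$nTimepoints
  geneIds <- sprintf("gene%04d", seq_len(cfg$nGenes))
  mirIds <- sprintf("mir%03d", seq_len(cfg$nMirnas))
  design <- generateDesign(cfg)
  dMr <- design[design$assay == "mrna", ]
  dMi <- design[design$assay == "mirna", ]

  mu0 <- setNames(rlnorm(cfg$nGenes, log(50), 1.2), geneIds)
  lengths <- setNames(pmax(200, round(rlnorm(cfg$nGenes, log(1500), 0.5))),
                      geneIds)
  mu0mir <- setNames(rlnorm(cfg$nMirnas, log(200), 1.0), mirIds)

  nDE <- round(cfg$fracDE * cfg$nGenes)
  nTSG <- round(cfg$fracTSG * cfg$nGenes)
  # pair members need deep coverage: their planted profiles swing by
  # several log2 units and anti-correlation is only quantifiable while
  # counts stay clear of zero
  highExpr <- geneIds[mu0 >= 100]
  if (length(highExpr) < cfg$nTruePairs)
    stop("too few well-expressed genes for the planted pairs")
  tgtGenes <- sample(highExpr, cfg$nTruePairs)
  # DNB genes likewise: the latent factor swings several log2 units and a
  # lowly expressed gene's downswings censor at zero counts
  dnbPool <- setdiff(highExpr, tgtGenes)
  if (length(dnbPool) < cfg$dnbSize)
    stop("too few well-expressed genes for the DNB module")
  dnbGenes <- sample(dnbPool, cfg$dnbSize)
  eligible <- setdiff(geneIds[mu0 >= 10], c(tgtGenes, dnbGenes))
  needed <- nDE + nTSG
  if (length(eligible) < needed)
    stop("too few well-expressed genes to plant all roles")
  pool <- sample(eligible)
  deGenes <- pool[seq_len(nDE)]
  tsgGenes <- pool[nDE + seq_len(nTSG)]
  eligMir <- mirIds[mu0mir >= 100]
  if (length(eligMir) < cfg$nTruePairs)
    stop("too few well-expressed miRNAs for the planted pairs")
  pairMirs <- sample(eligMir, cfg$nTruePairs)

  # per-sample log2 means, mRNA
  lmu <- matrix(log2(mu0), cfg$nGenes, nrow(dMr),
                dimnames = list(geneIds, dMr$sample_id))
  pm <- dMr$time_index >= postmortemStart(nT)
  deDir <- integer(0)
  if (nDE > 0 && any(pm)) {
    deDir <- sample(c(-1L, 1L), nDE, replace = TRUE)
    lmu[deGenes, pm] <- lmu[deGenes, pm] + deDir * cfg$lfcDE
  }
  tsgPeak <- integer(0)
  if (nTSG > 0) {
    tsgPeak <- sample(seq_len(nT) - 1L, nTSG, replace = TRUE)
    for (t in unique(tsgPeak)) {
      g <- tsgGenes[tsgPeak == t]
      cols <- dMr$time_index == t
      lmu[g, cols] <- lmu[g, cols] + log2(cfg$tsgPeakHeight)
    }
  }

  # planted miRNA profiles and coupled targets (deterministic effects)
  lmuMir <- matrix(log2(mu0mir), cfg$nMirnas, nrow(dMi),
                   dimnames = list(mirIds, dMi$sample_id))
  if (cfg$nTruePairs > 0 && nT >= 2) {
    # planted miRNA profiles: a few co-regulated groups (as in miRNA
    # families), each traversing an evenly spaced ladder of levels in
    # random time order, so every time point is distinguishable and
    # grouped pairs form co-expression modules of workable size
    nGroups <- min(5L, cfg$nTruePairs)
    ladder <- seq(-1, 1, length.out = nT)
    shapes <- lapply(seq_len(nGroups), function(g) sample(ladder))
    groups <- rep(seq_len(nGroups), length.out = cfg$nTruePairs)
    prof <- cfg$lfcDE * do.call(rbind, shapes)[groups, , drop = FALSE]
    zprof <- t(scale(t(prof)))
    for (i in seq_len(cfg$nTruePairs)) {
      lmuMir[pairMirs[i], ] <- lmuMir[pairMirs[i], ] +
        prof[i, dMi$time_index + 1L]
      lmu[tgtGenes[i], ] <- lmu[tgtGenes[i], ] -
        cfg$pairSlope * zprof[i, dMr$time_index + 1L]
    }
  }

  # deterministic per-time log2 means (before the replicate-level DNB
  # factor), used to derive the truth tables
  detMr <- vapply(seq_len(nT) - 1L, function(t)
    lmu[, match(t, dMr$time_index)], numeric(cfg$nGenes))
  detMi <- vapply(seq_len(nT) - 1L, function(t)
    lmuMir[, match(t, dMi$time_index)], numeric(cfg$nMirnas))

  # DNB latent factor at the transition, log2 scale
  if (cfg$dnbSdFactor > 1) {
    f <- cfg$dnbSdFactor
    vnb <- (1 / mu0[dnbGenes] + cfg$dispersion) / log(2)^2
    latent <- (f^2 - 1) * vnb
    sharedV <- pmin(cfg$dnbRhoIn * f^2 * vnb, latent)
    idioV <- latent - sharedV
    cols <- which(dMr$time_index == cfg$dnbTimeIndex)
    R <- length(cols)
    zf <- rnorm(R)
    E <- matrix(rnorm(cfg$dnbSize * R), cfg$dnbSize, R)
    if (R >= 3) {  # unit realized variance so the plant is present
      zf <- (zf - mean(zf)) / sd(zf)
      E <- t(scale(t(E)))
    }
    lmu[dnbGenes, cols] <- lmu[dnbGenes, cols] +
      outer(sqrt(sharedV), zf) + sqrt(idioV) * E
  }

  size <- 1 / cfg$dispersion
  cMr <- matrix(rnbinom(length(lmu), mu = 2^lmu, size = size),
                nrow(lmu), dimnames = dimnames(lmu))
  cMi <- matrix(rnbinom(length(lmuMir), mu = 2^lmuMir, size = size),
                nrow(lmuMir), dimnames = dimnames(lmuMir))
  storage.mode(cMr) <- "integer"
  storage.mode(cMi) <- "integer"

  # sequences + planted seed sites
  mirnaSeqs <- RNAStringSet(setNames(vapply(seq_len(cfg$nMirnas), function(i)
    paste(sample(c("A", "C", "G", "U"), cfg$mirnaLen, replace = TRUE),
          collapse = ""), ""), mirIds))
  utrs <- DNAStringSet(setNames(vapply(seq_len(cfg$nGenes), function(i)
    paste(sample(c("A", "C", "G", "T"), cfg$utrLen, replace = TRUE),
          collapse = ""), ""), geneIds))
  truePairs <- data.frame(mrna = tgtGenes, mirna = pairMirs,
                          stringsAsFactors = FALSE)
  emb <- embedSeedSites(mirnaSeqs, utrs, truePairs)
  utrs <- emb$utrs

  # synthetic annotation: one term per planted structure plus random terms
  ann <- data.frame(term_id = character(0), term_name = character(0),
                    gene_id = character(0), stringsAsFactors = FALSE)
  addTerm <- function(ann, id, name, genes)
    rbind(ann, data.frame(term_id = id, term_name = name, gene_id = genes,
                          stringsAsFactors = FALSE))
  ann <- addTerm(ann, "TERM_DNB", "planted DNB module", dnbGenes)
  if (nDE > 0) ann <- addTerm(ann, "TERM_DE", "planted DE genes", deGenes)
  for (i in seq_len(30)) {
    sz <- sample(10:50, 1)
    ann <- addTerm(ann, sprintf("TERM_%02d", i), sprintf("random term %d", i),
                   sample(geneIds, sz))
  }

  ctlIdx <- seq_len(min(2L, nT)) - 1L
  caseIdx <- if (nT >= 2) postmortemStart(nT):(nT - 1L) else integer(0)
  lfcThresh <- 1
  deTruth <- demTruth <- list()
  for (a in ctlIdx) for (b in setdiff(caseIdx, a)) {
    cmp <- paste0("T", a, "_vs_T", b)
    deTruth[[cmp]] <- geneIds[abs(detMr[, b + 1] - detMr[, a + 1]) > lfcThresh]
    demTruth[[cmp]] <- mirIds[abs(detMi[, b + 1] - detMi[, a + 1]) > lfcThresh]
  }
  truth <- new("SimTruth",
               deGenes = deTruth, demGenes = demTruth,
               tsgMap = setNames(as.integer(tsgPeak), tsgGenes),
               dnbGenes = dnbGenes,
               dnbTime = if (cfg$dnbSdFactor > 1) cfg$dnbTimeIndex else NA_integer_,
               truePairs = truePairs,
               plantedSites = emb$sites,
               params = c(unclass(cfg),
                          list(baselineMrna = c(log(50), 1.2),
                               baselineMirna = c(log(200), 1.0),
                               deDirection = deDir)))
  list(mrna = makeCountMatrix(cMr, dMr, lengths),
       mirna = makeCountMatrix(cMi, dMi),
       truth = truth, utrs = utrs, mirnaSeqs = mirnaSeqs, annotation = ann)
}

#' Embed seed-complementary target sites into UTRs
#'
#' For every true pair, the reverse complement of the full mature miRNA is
#' written into the target UTR at a random offset, so the site carries a
#' perfect seed match (positions 2-8) plus extended complementarity. The
#' recorded interval is the 7-nt seed site (0-based, half-open, on the UTR
#' 5'->3'). UTRs of non-pair genes are untouched.
#'
#' @param mirnaSeqs \code{RNAStringSet} (or DNA, auto-converted).
#' @param utrs \code{DNAStringSet}.
#' @param truePairs data.frame with columns \code{mrna}, \code{mirna}.
#' @return list with modified \code{utrs} and a \code{sites} data.frame
#'   (mrna, mirna, start, end).
#' @export
embedSeedSites <- function(mirnaSeqs, utrs, truePairs) {
  if (min(width(utrs)) < 7) stop("UTRs must be at least 7 nt")
  sites <- data.frame(mrna = character(0), mirna = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(truePairs) == 0) return(list(utrs = utrs, sites = sites))
  useq <- as.character(utrs)
  for (i in seq_len(nrow(truePairs))) {
    mid <- truePairs$mirna[i]; gid <- truePairs$mrna[i]
    mir <- DNAStringSet(RNAStringSet(mirnaSeqs[mid]))[[1]]
    site <- as.character(reverseComplement(mir))
    L <- nchar(site)
    ulen <- nchar(useq[gid])
    if (ulen < L) stop("UTR of ", gid, " shorter than the miRNA")
    off <- sample.int(ulen - L + 1L, 1L) - 1L
    substr(useq[gid], off + 1L, off + L) <- site
    # seed (miRNA positions 2-8) occupies the last-but-one 7 nt of the site
    sites <- rbind(sites, data.frame(
      mrna = gid, mirna = mid,
      start = off + L - 8L, end = off + L - 1L, stringsAsFactors = FALSE))
  }
  list(utrs = DNAStringSet(setNames(useq, names(utrs))), sites = sites)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes counts, design, gene lengths, sequences (DNA alphabet on disk),
#' the synthetic annotation and the truth tables; the set round-trips
#' losslessly through \code{\link{readFixture}}.
#'
#' @param sim result of \code{\link{simulateTimecourse}}.
#' @param dir destination directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeFixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeCounts(sim$mrna, p("counts_mrna.tsv"), lengthsPath = p("gene_lengths.tsv"))
  writeCounts(sim$mirna, p("counts_mirna.tsv"))
  design <- rbind(as.data.frame(colData(sim$mrna)),
                  as.data.frame(colData(sim$mirna)))
  write.table(design, p("design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeXStringSet(sim$utrs, p("utrs.fasta"))
  writeXStringSet(DNAStringSet(sim$mirnaSeqs), p("mirnas.fasta"))
  write.table(sim$annotation, p("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  truthList <- list(deGenes = tr@deGenes, demGenes = tr@demGenes,
                    tsgMap = as.list(tr@tsgMap),
                    dnbGenes = tr@dnbGenes, dnbTime = tr@dnbTime,
                    truePairs = tr@truePairs, plantedSites = tr@plantedSites,
                    params = tr@params)
  write_json(truthList, p("truth.json"), auto_unbox = TRUE, digits = NA,
             null = "null", na = "null")
  invisible(dir)
}

#' Read a fixture directory written by \code{\link{writeFixture}}
#'
#' @param dir fixture directory.
#' @return list shaped like the output of \code{\link{simulateTimecourse}}.
#' @export
readFixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  mrna <- readCounts(p("counts_mrna.tsv"), p("design.tsv"),
                     p("gene_lengths.tsv"))
  mirna <- readCounts(p("counts_mirna.tsv"), p("design.tsv"))
  utrs <- readDNAStringSet(p("utrs.fasta"))
  mirnaSeqs <- RNAStringSet(readDNAStringSet(p("mirnas.fasta")))
  ann <- read.delim(p("annotation.tsv"), stringsAsFactors = FALSE)
  tl <- read_json(p("truth.json"), simplifyVector = TRUE)
  truth <- new("SimTruth",
               deGenes = lapply(tl$deGenes, as.character),
               demGenes = lapply(tl$demGenes, as.character),
               tsgMap = setNames(as.integer(unlist(tl$tsgMap)),
                                 names(tl$tsgMap)),
               dnbGenes = as.character(tl$dnbGenes),
               dnbTime = if (is.null(tl$dnbTime)) NA_integer_ else
                 as.integer(tl$dnbTime),
               truePairs = as.data.frame(tl$truePairs),
               plantedSites = as.data.frame(tl$plantedSites),
               params = tl$params)
  list(mrna = mrna, mirna = mirna, truth = truth, utrs = utrs,
       mirnaSeqs = mirnaSeqs, annotation = ann)
}
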