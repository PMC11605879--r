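`%||%` <- function(a, b) if (is.null(a)) b else a

pairKey <- function(d) paste(d$mrna, d$mirna, sep = "\r")

#' Intersect sequence- and expression-based pair evidence
#'
#' A pair is a final target when it is supported by the sequence route
#' (seed match passing both duplex criteria) AND the expression route
#' (co-expression module co-membership plus the negative Spearman
#' filter).
#'
#' @param seqPairs data.frame (mrna, mirna) from
#'   \code{\link{sequenceTargets}}.
#' @param exprPairs data.frame (mrna, mirna) of expression targets.
#' @param mrnaIds,mirnaIds the feature universes both routes were
#'   computed on; pairs referencing ids outside them raise an error.
#' @return data.frame with columns mrna, mirna, seed_support,
#'   expr_support, status (\code{candidate} or \code{final_target}).
#' @export
multiCriteriaPairs <- function(seqPairs, exprPairs, mrnaIds, mirnaIds) {
  all <- unique(rbind(seqPairs[, c("mrna", "mirna")],
                      exprPairs[, c("mrna", "mirna")]))
  if (nrow(all)) {
    if (!all(all$mrna %in% mrnaIds))
      stop("pair mRNA ids outside the analysis universe")
    if (!all(all$mirna %in% mirnaIds))
      stop("pair miRNA ids outside the analysis universe")
  }
  all$seed_support <- pairKey(all) %in% pairKey(seqPairs)
  all$expr_support <- pairKey(all) %in% pairKey(exprPairs)
  all$status <- ifelse(all$seed_support & all$expr_support,
                       "final_target", "candidate")
  rownames(all) <- NULL
  all
}

#' Post-mortem pairs: final targets with both members differentially expressed
#'
#' @param finalPairs output of \code{\link{multiCriteriaPairs}}.
#' @param degs DEG union (mRNA ids).
#' @param dems DEM union (miRNA ids).
#' @return the table with is_deg, is_dem appended and status upgraded to
#'   \code{postmortem_pair} where both hold for a final target.
#' @export
postmortemPairs <- function(finalPairs, degs, dems) {
  finalPairs$is_deg <- finalPairs$mrna %in% degs
  finalPairs$is_dem <- finalPairs$mirna %in% dems
  up <- finalPairs$status == "final_target" & finalPairs$is_deg &
    finalPairs$is_dem
  finalPairs$status[up] <- "postmortem_pair"
  finalPairs
}

writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Simulate -> normalize -> filter -> differential expression ->
#' temporal clustering -> DNB detection -> sequence targets ->
#' co-expression -> integration -> enrichment, writing per-stage TSV/JSON
#' outputs and a manifest (parameters, seed, package version, md5 sums)
#' to \code{outDir}. Outputs are fully reproducible: rerunning with the
#' same configuration yields byte-identical files.
#'
#' @param config configuration list, or path to a YAML file. Recognised
#'   entries (all optional): \code{sim} (arguments to
#'   \code{\link{simConfig}}), \code{cluster} (list: c, m, peakMargin),
#'   \code{dnb} (list: nModules, minSize, nPerm), \code{targets} (list:
#'   alignMin, energyMax), \code{coexpr} (list: beta, nModules, minSize,
#'   mergeCor, rhoMax, pMax), \code{de} (list: lfcThresh, fdrThresh),
#'   \code{skipDE} (logical; when TRUE the post-mortem pair stage reports
#'   "unavailable").
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) config <- read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  scfg <- do.call(simConfig, config$sim %||% list())

  stage <- "simulate"
  res <- tryCatch({
    sim <- simulateTimecourse(scfg)

    stage <- "normalize"
    fpkm <- normalizeExpression(sim$mrna, "fpkm")
    tpm <- normalizeExpression(sim$mirna, "cpm")

    stage <- "filter"
    keepG <- filterFeatures(fpkm, rule = "mrna")
    keepM <- filterFeatures(tpm, rule = "mirna")
    fpkm <- fpkm[keepG, ]; tpm <- tpm[keepM, ]
    mrna <- sim$mrna[keepG, ]; mirna <- sim$mirna[keepM, ]

    labels <- timeLabels(scfg$nTimepoints)
    controls <- labels[seq_len(min(2, length(labels) - 1))]
    cases <- setdiff(labels, controls)
    deCfg <- config$de %||% list()
    skipDE <- isTRUE(config$skipDE)
    degs <- dems <- NULL
    deMrna <- deMirna <- NULL
    if (!skipDE) {
      stage <- "diffexpr"
      deMrna <- callDEFeatures(mrna, controls, cases,
                               lfcThresh = deCfg$lfcThresh %||% 1,
                               fdrThresh = deCfg$fdrThresh %||% 0.05)
      deMirna <- callDEFeatures(mirna, controls, cases,
                                lfcThresh = deCfg$lfcThresh %||% 1,
                                fdrThresh = deCfg$fdrThresh %||% 0.05)
      degs <- deFeatureUnion(deMrna)
      dems <- deFeatureUnion(deMirna)
      writeTsv(deMrna, p("de_mrna.tsv"))
      writeTsv(deMirna, p("de_mirna.tsv"))
      writeTsv(data.frame(feature = coreSharedFeatures(deMrna)),
               p("core_shared_genes.tsv"))
    }

    stage <- "cluster"
    clCfg <- config$cluster %||% list()
    lx <- log2(assay(fpkm, "fpkm") + 1)
    prof <- suppressWarnings(
      standardizeProfiles(lx, as.data.frame(colData(fpkm))))
    fc <- fuzzyCMeans(prof, c = clCfg$c %||% 12L, m = clCfg$m %||% 1,
                      seed = scfg$seed + 1L)
    tsg <- timeSpecificAssignment(fc,
                                  peakMargin = clCfg$peakMargin %||% 0.5)
    writeTsv(data.frame(
      gene = unlist(tsg, use.names = FALSE),
      time = rep(as.integer(names(tsg)), lengths(tsg))), p("tsg.tsv"))

    stage <- "dnb"
    dnbCfg <- config$dnb %||% list()
    design <- as.data.frame(colData(fpkm))
    cands <- candidateModules(lx, design,
                              nModules = dnbCfg$nModules %||%
                                c(50, 100, 200, 400),
                              minSize = dnbCfg$minSize %||% 5L)
    report <- detectTippingPoint(cands, lx, design)
    if (length(dnbGenes(report)) && (dnbCfg$nPerm %||% 0) > 0)
      report@permP <- dnbPermutationP(dnbGenes(report), lx, design,
                                      tippingTime(report),
                                      nPerm = dnbCfg$nPerm,
                                      seed = scfg$seed + 2L)
    writeTsv(report@trajectories, p("dnb_trajectories.tsv"))
    write_json(list(genes = dnbGenes(report),
                    time = tippingTime(report),
                    permP = report@permP),
               p("dnb_report.json"), auto_unbox = TRUE, digits = NA,
               na = "null")

    stage <- "targets"
    tgCfg <- config$targets %||% list()
    seqT <- sequenceTargets(sim$mirnaSeqs[keepM], sim$utrs[keepG],
                            alignMin = tgCfg$alignMin %||% 80,
                            energyMax = tgCfg$energyMax %||% -20)
    writeTsv(seqT$sites, p("seed_sites.tsv"))

    stage <- "coexpr"
    cxCfg <- config$coexpr %||% list()
    profs <- buildCombinedProfiles(
      log2(assay(fpkm, "fpkm") + 1), log2(assay(tpm, "cpm") + 1),
      as.data.frame(colData(fpkm)), as.data.frame(colData(tpm)))
    net <- tomFromProfiles(profs, beta = cxCfg$beta %||% 6)
    net <- detectCoexpressionModules(net,
                                     nModules = cxCfg$nModules %||% 20L,
                                     minSize = cxCfg$minSize %||% 3L,
                                     mergeCor = cxCfg$mergeCor %||% 0.85)
    mods <- moduleAssignments(net)
    sameMod <- expand.grid(mrna = intersect(keepG, names(mods)),
                           mirna = intersect(keepM, names(mods)),
                           stringsAsFactors = FALSE)
    mm <- mods[sameMod$mrna]; mi <- mods[sameMod$mirna]
    sameMod <- sameMod[!is.na(mm) & !is.na(mi) & mm == mi, , drop = FALSE]
    recs <- if (nrow(sameMod))
      spearmanPairFilter(profs, sameMod,
                         rhoMax = cxCfg$rhoMax %||% -0.8,
                         pMax = cxCfg$pMax %||% 0.05)
    else cbind(sameMod, rho = numeric(0), p = numeric(0),
               pass = logical(0))
    recs <- expressionTargets(net, recs)
    writeTsv(recs, p("expression_pairs.tsv"))

    stage <- "integrate"
    exprPairs <- recs[recs$is_target, c("mrna", "mirna"), drop = FALSE]
    pairs <- multiCriteriaPairs(seqT$pairs, exprPairs, keepG, keepM)
    pmStatus <- "ok"
    if (!skipDE) {
      pairs <- postmortemPairs(pairs, degs, dems)
    } else {
      pmStatus <- "unavailable: differential expression was skipped"
    }
    writeTsv(pairs, p("pairs.tsv"))

    stage <- "enrich"
    target <- if (length(dnbGenes(report))) dnbGenes(report) else degs
    enr <- if (length(target))
      enrichSet(intersect(target, keepG), sim$annotation, keepG)
    else NULL
    if (!is.null(enr)) writeTsv(enr, p("enrichment.tsv"))

    list(sim = sim, fpkm = fpkm, tpm = tpm, deMrna = deMrna,
         deMirna = deMirna, degs = degs, dems = dems, clustering = fc,
         tsg = tsg, dnb = report, seqTargets = seqT, network = net,
         pairRecords = recs, pairs = pairs, enrichment = enr,
         postmortemStatus = pmStatus)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE))

  manifest <- list(
    package = "ThanatoSeq",
    version = as.character(utils::packageVersion("ThanatoSeq")),
    seed = scfg$seed,
    config = config,
    sim_params = unclass(scfg),
    postmortem_status = res$postmortemStatus,
    outputs = {
      fs <- sort(setdiff(list.files(outDir), "manifest.json"))
      setNames(as.list(unname(md5sum(file.path(outDir, fs)))), fs)
    })
  write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA,
             na = "null", null = "null", pretty = TRUE)
  invisible(res)
}
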