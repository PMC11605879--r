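#' Class definitions
#'
#' Count and expression matrices are plain
#' \link[SummarizedExperiment]{SummarizedExperiment} objects: the
#' \code{counts} assay holds non-negative integers, feature lengths (mRNA)
#' live in \code{rowData()$length}, the sample design in \code{colData()},
#' and normalization provenance in \code{metadata()}. The S4 classes below
#' hold derived results.
#'
#' @name ThanatoSeq-classes
NULL

#' Fuzzy c-means clustering of standardized time profiles
#'
#' @slot k cluster count.
#' @slot m fuzzifier; \code{m = 1} is the hard (k-means) limit, where
#'   memberships are 0/1 indicators.
#' @slot membership genes x clusters matrix; every row sums to 1.
#' @slot centroids clusters x timepoints matrix on the z-score scale.
#' @slot objective objective-function trace of the best restart
#'   (non-increasing).
#'
#' @export
setClass("FuzzyClustering",
  representation(k = "integer", m = "numeric", membership = "matrix",
                 centroids = "matrix", objective = "numeric"))

setValidity("FuzzyClustering", function(object) {
  msg <- character()
  u <- object@membership
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroid rows must equal k")
  if (ncol(u) != object@k)
    msg <- c(msg, "membership columns must equal k")
  if (any(u < -1e-9 | u > 1 + 1e-9))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (nrow(u) > 0 && max(abs(rowSums(u) - 1)) > 1e-9)
    msg <- c(msg, "memberships of each gene must sum to 1")
  if (!all(is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn FuzzyClustering membership matrix accessor
#' @param object a \code{FuzzyClustering}
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @rdname FuzzyClustering
#' @export
setMethod("memberships", "FuzzyClustering", function(object) object@membership)

#' @describeIn FuzzyClustering centroid matrix accessor
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname FuzzyClustering
#' @export
setMethod("centroids", "FuzzyClustering", function(object) object@centroids)

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering: ", nrow(object@membership), " genes, k = ",
      object@k, ", m = ", object@m, "\n", sep = "")
  cat("  final objective: ",
      format(object@objective[length(object@objective)]), " (",
      length(object@objective), " iterations)\n", sep = "")
})

#' Dynamical network biomarker report
#'
#' Produced by \code{\link{detectTippingPoint}}. When no candidate module
#' has coinciding standard-deviation and correlation-strength peaks, the
#' report is the explicit no-transition result: \code{dnbGenes()} empty and
#' \code{tippingTime()} \code{NA}.
#'
#' @slot genes selected DNB module (feature ids); empty if no transition.
#' @slot time 0-based tipping-point time index; \code{NA} if none.
#' @slot ci composite-index trajectory of the selected module.
#' @slot trajectories per-candidate statistics: a data.frame with columns
#'   candidate, time, sdAvg, pccIn, pccOut, strength, ci.
#' @slot permP permutation p-value (NA until \code{\link{dnbPermutationP}}).
#'
#' @export
setClass("DNBReport",
  representation(genes = "character", time = "integer", ci = "numeric",
                 trajectories = "data.frame", permP = "numeric"))

setValidity("DNBReport", function(object) {
  if (length(object@genes) && is.na(object@time))
    return("a selected module requires a tipping time")
  TRUE
})

#' @describeIn DNBReport selected module accessor
#' @param object a \code{DNBReport}
#' @export
setGeneric("dnbGenes", function(object) standardGeneric("dnbGenes"))

#' @rdname DNBReport
#' @export
setMethod("dnbGenes", "DNBReport", function(object) object@genes)

#' @describeIn DNBReport tipping-point time accessor (0-based index)
#' @export
setGeneric("tippingTime", function(object) standardGeneric("tippingTime"))

#' @rdname DNBReport
#' @export
setMethod("tippingTime", "DNBReport", function(object) object@time)

setMethod("show", "DNBReport", function(object) {
  if (!length(object@genes)) {
    cat("DNBReport: no transition detected\n")
  } else {
    cat("DNBReport: ", length(object@genes),
        " genes, tipping point at time index ", object@time, "\n", sep = "")
    cat("  peak CI: ", format(max(object@ci)), sep = "")
    if (!is.na(object@permP))
      cat(", permutation p = ", format(object@permP), sep = "")
    cat("\n")
  }
})

#' Weighted co-expression network with topological overlap
#'
#' @slot features feature ids (mRNA then miRNA).
#' @slot beta soft-threshold power of the unsigned adjacency
#'   \eqn{a_{ij} = |cor_{ij}|^\beta}.
#' @slot adjacency adjacency matrix (diagonal 0 for TOM computation).
#' @slot tom topological overlap matrix, diagonal 1.
#' @slot modules named integer vector feature -> module id; NA means
#'   unassigned (module smaller than the minimum size).
#' @slot eigenprofiles module x timepoints matrix of first principal
#'   components, sign-aligned to the module mean profile.
#' @slot profiles the feature x timepoints profile matrix the network was
#'   built from.
#'
#' @export
setClass("CoexprNetwork",
  representation(features = "character", beta = "numeric",
                 adjacency = "matrix", tom = "matrix",
                 modules = "integer", eigenprofiles = "matrix",
                 profiles = "matrix"))

setValidity("CoexprNetwork", function(object) {
  msg <- character()
  a <- object@adjacency; tomm <- object@tom
  if (any(a < -1e-12 | a > 1 + 1e-12)) msg <- c(msg, "adjacency outside [0,1]")
  if (any(tomm < -1e-9 | tomm > 1 + 1e-9)) msg <- c(msg, "TOM outside [0,1]")
  if (nrow(tomm) && max(abs(diag(tomm) - 1)) > 1e-12)
    msg <- c(msg, "TOM diagonal must be 1")
  if (nrow(tomm) && max(abs(tomm - t(tomm))) > 1e-9)
    msg <- c(msg, "TOM must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoexprNetwork module assignment accessor
#' @param object a \code{CoexprNetwork}
#' @export
setGeneric("moduleAssignments", function(object) standardGeneric("moduleAssignments"))

#' @rdname CoexprNetwork
#' @export
setMethod("moduleAssignments", "CoexprNetwork", function(object) object@modules)

setMethod("show", "CoexprNetwork", function(object) {
  nm <- length(unique(object@modules[!is.na(object@modules)]))
  cat("CoexprNetwork: ", length(object@features), " features, beta = ",
      object@beta, "\n", sep = "")
  if (length(object@modules))
    cat("  ", nm, " modules (", sum(is.na(object@modules)),
        " features unassigned)\n", sep = "")
})

#' Planted ground truth of a synthetic time course
#'
#' @slot deGenes named list: comparison label -> gene ids whose planted
#'   (deterministic) log2-mean difference between the two groups exceeds
#'   the DE calling threshold.
#' @slot demGenes named list: the analogous per-comparison miRNA sets.
#' @slot tsgMap named integer vector: gene -> planted peak time (0-based).
#' @slot dnbGenes planted DNB module gene ids.
#' @slot dnbTime planted transition time index (0-based).
#' @slot truePairs data.frame with columns mrna, mirna.
#' @slot plantedSites data.frame with columns mrna, mirna, start, end
#'   (0-based half-open seed interval on the UTR).
#' @slot params the generator configuration used.
#'
#' @export
setClass("SimTruth",
  representation(deGenes = "list", demGenes = "list",
                 tsgMap = "integer", dnbGenes = "character",
                 dnbTime = "integer", truePairs = "data.frame",
                 plantedSites = "data.frame", params = "list"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (nrow(object@truePairs)) {
    key <- function(d) paste(d$mrna, d$mirna)
    if (!all(key(object@truePairs) %in% key(object@plantedSites)))
      msg <- c(msg, "every true pair needs at least one planted site")
  }
  if (length(object@tsgMap) && any(names(object@tsgMap) %in% object@dnbGenes))
    msg <- c(msg, "TSG and DNB gene sets must be disjoint")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: ", length(unique(unlist(object@deGenes))), " DE genes, ",
      length(object@tsgMap), " TSGs, ", length(object@dnbGenes),
      " DNB genes (transition at index ", object@dnbTime, "), ",
      nrow(object@truePairs), " true pairs\n", sep = "")
})
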