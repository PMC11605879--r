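suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# one small simulated dataset shared across test files
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateTimecourse(
        simConfig(nGenes = 300, nMirnas = 40, seed = 424242))
    cache
  }
})

# toy count container: counts matrix + minimal design
toyCounts <- function(counts, lengths = NULL, assayName = "mrna") {
  nT <- ncol(counts)
  design <- data.frame(
    sample_id = colnames(counts), assay = assayName,
    time_label = paste0("T", seq_len(nT) - 1),
    time_index = seq_len(nT) - 1L, replicate = 1L,
    stringsAsFactors = FALSE)
  makeCountMatrix(counts, design, lengths)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

pairKeys <- function(d) paste(d$mrna, d$mirna)
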