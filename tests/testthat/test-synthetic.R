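test_that("generated design matches the study layout", {
  d <- generateDesign(simConfig())
  expect_equal(sum(d$assay == "mrna"), 24)   # 8 time points x 3 reps
  expect_equal(sum(d$assay == "mirna"), 16)  # 8 time points x 2 reps
  expect_false(anyDuplicated(paste(d$assay, d$time_index, d$replicate)) > 0)

  d1 <- generateDesign(simConfig(nTimepoints = 1, nRepsMrna = 1,
                                 dnbTimeIndex = 0))
  expect_equal(sum(d1$assay == "mrna"), 1)

  cfg <- simConfig(seed = 99)
  expect_identical(generateDesign(cfg), generateDesign(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(fracDE = 1.5), "fractions")
  expect_error(simConfig(dnbTimeIndex = 8), "nTimepoints")
  expect_error(simConfig(dispersion = 0), "dispersion")
  expect_error(simConfig(dnbSize = 3), "dnbSize")
  expect_error(simConfig(nTruePairs = 200, nMirnas = 50), "nTruePairs")
})

test_that("simulation is reproducible and plants are recorded", {
  cfg <- simConfig(nGenes = 200, nMirnas = 30, nTruePairs = 5, dnbSize = 8,
                   seed = 11)
  a <- simulateTimecourse(cfg)
  b <- simulateTimecourse(cfg)
  expect_identical(assay(a$mrna, "counts"), assay(b$mrna, "counts"))
  expect_identical(as.character(a$utrs), as.character(b$utrs))
  tr <- a$truth
  expect_length(tr@dnbGenes, 8)
  expect_equal(tr@dnbTime, 3L)
  expect_equal(nrow(tr@truePairs), 5)
  # roles disjoint
  expect_length(intersect(tr@dnbGenes, names(tr@tsgMap)), 0)
  expect_length(intersect(tr@dnbGenes, tr@truePairs$mrna), 0)
  # every true pair carries a planted 7-nt seed site
  expect_setequal(pairKeys(tr@truePairs), pairKeys(tr@plantedSites))
  expect_true(all(tr@plantedSites$end - tr@plantedSites$start == 7))
})

test_that("null configuration yields calibrated downstream DE calls", {
  cfg <- simConfig(nGenes = 4000, nMirnas = 40, nTruePairs = 0, fracDE = 0,
                   fracTSG = 0, dnbSdFactor = 1, pairSlope = 0, seed = 21)
  sim <- simulateTimecourse(cfg)
  expect_length(unlist(sim$truth@deGenes), 0)
  counts <- assay(sim$mrna, "counts")
  des <- as.data.frame(colData(sim$mrna))
  t2 <- nbTestTwoGroup(counts[, des$time_label == "T0"],
                       counts[, des$time_label == "T4"])
  expect_gt(mean(t2$p < 0.05), 0.02)
  expect_lt(mean(t2$p < 0.05), 0.08)
})

test_that("dispersion near zero approaches the Poisson limit", {
  cfg <- simConfig(nGenes = 10000, nMirnas = 40, nTimepoints = 1,
                   nRepsMrna = 40, fracDE = 0, fracTSG = 0, dnbSdFactor = 1,
                   pairSlope = 0, nTruePairs = 0, dispersion = 1e-6,
                   dnbTimeIndex = 0, seed = 31)
  m <- assay(simulateTimecourse(cfg)$mrna, "counts")
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(median(ratio, na.rm = TRUE) - 1), 0.05)
})

test_that("true-pair profiles are strongly anti-correlated", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    sim <- simulateTimecourse(
      simConfig(nGenes = 300, nMirnas = 40, seed = 500 + s))
    profM <- standardizeProfiles(log2(assay(sim$mrna, "counts") + 1),
                                 as.data.frame(colData(sim$mrna)))
    profI <- standardizeProfiles(log2(assay(sim$mirna, "counts") + 1),
                                 as.data.frame(colData(sim$mirna)))
    tp <- sim$truth@truePairs
    rho <- vapply(seq_len(nrow(tp)), function(i)
      spearmanRho(profM[tp$mrna[i], ], profI[tp$mirna[i], ]), 1)
    hits <- hits + sum(rho < -0.8); total <- total + length(rho)
  }
  expect_gte(hits / total, 0.9)
})

test_that("embedded seed sites are reverse complements of the seed", {
  mir <- Biostrings::RNAStringSet(c(m1 = "AGAGGUAGUAGGUUGUAUAGUU"))  # let-7
  utr <- Biostrings::DNAStringSet(c(g1 = paste(rep("A", 60), collapse = ""),
                                    g2 = paste(rep("A", 60), collapse = "")))
  set.seed(1)
  emb <- embedSeedSites(mir, utr, data.frame(mrna = "g1", mirna = "m1"))
  s <- emb$sites
  expect_equal(nrow(s), 1)
  seedSite <- substr(as.character(emb$utrs[["g1"]]), s$start + 1, s$end)
  expect_equal(seedSite, "CTACCTC")  # revcomp of GAGGUAG (positions 2-8)
  expect_equal(as.character(emb$utrs[["g2"]]),
               paste(rep("A", 60), collapse = ""))
  # no pairs: untouched
  emb0 <- embedSeedSites(mir, utr, data.frame(mrna = character(0),
                                              mirna = character(0)))
  expect_identical(as.character(emb0$utrs), as.character(utr))
  expect_error(
    embedSeedSites(mir, Biostrings::DNAStringSet(c(g1 = "ACGTA")),
                   data.frame(mrna = "g1", mirna = "m1")),
    "at least 7")
})

test_that("fixtures round-trip losslessly", {
  sim <- simulateTimecourse(
    simConfig(nGenes = 150, nMirnas = 12, nTruePairs = 4, dnbSize = 6,
              seed = 77))
  dir <- tempfile()
  writeFixture(sim, dir)
  back <- readFixture(dir)
  expect_identical(assay(back$mrna, "counts"), assay(sim$mrna, "counts"))
  expect_identical(assay(back$mirna, "counts"), assay(sim$mirna, "counts"))
  expect_identical(as.character(back$utrs), as.character(sim$utrs))
  expect_equal(length(back$utrs) + length(back$mirnaSeqs), 150 + 12)
  expect_identical(back$truth@dnbGenes, sim$truth@dnbGenes)
  expect_identical(back$truth@tsgMap, sim$truth@tsgMap)
  expect_equal(back$truth@truePairs, sim$truth@truePairs)
  expect_true(validObject(back$truth))
  # byte-identical regeneration
  dir2 <- tempfile()
  writeFixture(simulateTimecourse(
    simConfig(nGenes = 150, nMirnas = 12, nTruePairs = 4, dnbSize = 6,
              seed = 77)), dir2)
  f <- list.files(dir)
  expect_identical(unname(tools::md5sum(file.path(dir, f))),
                   unname(tools::md5sum(file.path(dir2, f))))
})
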