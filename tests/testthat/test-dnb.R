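toyDesign <- function(nT, reps) {
  data.frame(sample_id = paste0("s", seq_len(nT * reps)), assay = "mrna",
             time_label = paste0("T", rep(seq_len(nT) - 1, each = reps)),
             time_index = rep(seq_len(nT) - 1L, each = reps),
             replicate = rep(seq_len(reps), nT), stringsAsFactors = FALSE)
}

test_that("perfectly correlated blocks become candidate modules", {
  set.seed(1)
  base1 <- rnorm(24); base2 <- rnorm(24)
  x <- rbind(t(sapply(1:6, function(i) 2 * base1 + i)),
             t(sapply(1:6, function(i) -3 * base2 + i)))
  rownames(x) <- paste0("g", 1:12)
  colnames(x) <- paste0("s", 1:24)
  cands <- candidateModules(x, toyDesign(4, 6), nModules = 2,
                            centerWithinTime = FALSE)
  expect_setequal(vapply(cands, function(g) paste(sort(g), collapse = ","),
                         ""),
                  c(paste(sort(paste0("g", 1:6)), collapse = ","),
                    paste(sort(paste0("g", 7:12)), collapse = ",")))
})

test_that("cutting to singletons leaves no candidates", {
  set.seed(2)
  x <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:8)))
  cands <- candidateModules(x, toyDesign(4, 2), nModules = 12, minSize = 5)
  expect_length(cands, 0)
  expect_error(detectTippingPoint(cands, x, toyDesign(4, 2)),
               "no candidate")
  expect_error(candidateModules(x[1:3, ], toyDesign(4, 2), minSize = 5),
               "fewer genes")
})

test_that("module statistics follow their definitions", {
  set.seed(3)
  des <- toyDesign(2, 4)
  x <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("g", 1:10), des$sample_id))
  x["g2", ] <- x["g1", ] * 2 + 3   # identical profile up to affine map
  st <- moduleStatistics(c("g1", "g2"), x, des, t = 0)
  expect_equal(unname(st["pccIn"]), 1, tolerance = 1e-12)
  expect_equal(unname(st["ci"]),
               unname(st["sdAvg"] * st["pccIn"] / max(st["pccOut"], 0.01)),
               tolerance = 1e-12)
  expect_error(moduleStatistics("g1", x[, c(1, 5)],
                                des[c(1, 5), ], t = 0), "2 replicates")
  expect_error(moduleStatistics(character(0), x, des, 0), "non-empty")
  expect_error(moduleStatistics(rownames(x), x, des, 0), "non-empty")
})

test_that("independent modules still show the small-sample correlation floor", {
  # with 3 replicates the null mean |r| is far from zero (~2/pi)
  set.seed(4)
  des <- toyDesign(1, 3)
  x <- matrix(rnorm(600 * 3), 600, 3,
              dimnames = list(paste0("g", 1:600), des$sample_id))
  st <- moduleStatistics(paste0("g", 1:30), x, des, t = 0)
  expect_gt(st["pccOut"], 0.5)
  expect_lt(st["pccOut"], 0.75)
})

test_that("intra-module correlation approaches the planted value with many replicates", {
  cfg <- simConfig(nGenes = 300, nMirnas = 40, nRepsMrna = 60, seed = 6)
  sim <- simulateTimecourse(cfg)
  lx <- log2(assay(sim$mrna, "counts") + 1)
  des <- as.data.frame(colData(sim$mrna))
  st <- moduleStatistics(sim$truth@dnbGenes, lx, des, t = 3)
  expect_lt(abs(st["pccIn"] - 0.8), 0.05)
})

test_that("a planted transition is detected at the planted time", {
  sim <- simulateTimecourse(simConfig(nGenes = 400, nMirnas = 40,
                                      nRepsMrna = 6, seed = 515))
  lx <- log2(assay(sim$mrna, "counts") + 1)
  des <- as.data.frame(colData(sim$mrna))
  cands <- c(list(sim$truth@dnbGenes),
             candidateModules(lx, des, nModules = c(20, 40)))
  rep <- detectTippingPoint(cands, lx, des)
  expect_equal(tippingTime(rep), 3L)
  expect_gte(jaccard(dnbGenes(rep), sim$truth@dnbGenes), 0.7)
  # deterministic
  rep2 <- detectTippingPoint(cands, lx, des)
  expect_identical(dnbGenes(rep), dnbGenes(rep2))
  # gene order leaves the trajectories invariant
  perm <- sample(nrow(lx))
  rep3 <- detectTippingPoint(cands, lx[perm, ], des)
  expect_identical(dnbGenes(rep3), dnbGenes(rep))
})

test_that("mismatched SD and correlation peaks are ineligible", {
  set.seed(7)
  des <- toyDesign(4, 6)
  # module: exactly collinear at t0 (correlation peak), large independent
  # noise at t3 (SD peak)
  x <- matrix(rnorm(20 * 24, sd = 0.1), 20, 24,
              dimnames = list(paste0("g", 1:20), des$sample_id))
  shared <- rnorm(6)
  for (g in 1:6) {
    x[g, des$time_index == 0] <- g * shared
    x[g, des$time_index == 3] <- rnorm(6, sd = 5)
  }
  rep <- detectTippingPoint(list(paste0("g", 1:6)), x, des)
  expect_length(dnbGenes(rep), 0)
  expect_true(is.na(tippingTime(rep)))
})

test_that("permutation p stays within its bounds", {
  sim <- smallSim()
  lx <- log2(assay(sim$mrna, "counts") + 1)
  des <- as.data.frame(colData(sim$mrna))
  p <- dnbPermutationP(sim$truth@dnbGenes, lx, des, t = 3, nPerm = 49,
                       seed = 1)
  expect_gte(p, 1 / 50)
  expect_lte(p, 1)
  expect_lte(p, 0.05)  # planted transition is significant
  expect_error(dnbPermutationP(sim$truth@dnbGenes, lx, des, t = 3,
                               nPerm = 0), "nPerm")
})
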