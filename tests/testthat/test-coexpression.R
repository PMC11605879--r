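test_that("combined profiles are standardized per feature", {
  sim <- smallSim()
  profs <- suppressWarnings(buildCombinedProfiles(
    log2(assay(sim$mrna, "counts") + 1), log2(assay(sim$mirna, "counts") + 1),
    as.data.frame(colData(sim$mrna)), as.data.frame(colData(sim$mirna))))
  expect_equal(ncol(profs), 8)
  expect_equal(unname(rowMeans(profs)), rep(0, nrow(profs)),
               tolerance = 1e-9)
  expect_equal(unname(apply(profs, 1, sd)), rep(1, nrow(profs)),
               tolerance = 1e-9)
  # mismatched time axes rejected
  desB <- as.data.frame(colData(sim$mirna))
  desB$time_index <- desB$time_index + 1L
  expect_error(buildCombinedProfiles(
    log2(assay(sim$mrna, "counts") + 1), log2(assay(sim$mirna, "counts") + 1),
    as.data.frame(colData(sim$mrna)), desB), "mismatched time axes")
})

bruteTom <- function(a) {
  n <- nrow(a); k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

test_that("TOM matches its defining formula", {
  # three features with pairwise adjacency 1
  x <- matrix(rep(c(1, 5, 2, 7, 3, 4, 6, 8), each = 3), 3, 8, byrow = FALSE)
  x <- t(apply(x, 1, function(r) r))
  rownames(x) <- paste0("f", 1:3)
  net <- tomFromProfiles(t(scale(t(x))), beta = 6)
  expect_equal(unname(net@tom), matrix(1, 3, 3), tolerance = 1e-12)

  set.seed(20)
  for (i in 1:3) {
    p <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(paste0("f", 1:20), NULL))
    net <- tomFromProfiles(p, beta = 6)
    expect_equal(net@adjacency, abs(cor(t(p)))^6 *
                   (1 - diag(20)), tolerance = 1e-12)
    expect_lt(max(abs(net@tom - bruteTom(net@adjacency))), 1e-10)
    expect_true(all(net@tom >= 0 & net@tom <= 1))
    expect_equal(net@tom, t(net@tom), tolerance = 1e-12)
  }
  expect_error(tomFromProfiles(matrix(1, 5, 4), beta = 0), "positive")
  expect_error(tomFromProfiles(matrix(1, 2, 4)), "3 features")
})

test_that("anti-correlated blocks share a module in the unsigned network", {
  set.seed(21)
  base <- rnorm(8)
  up <- t(sapply(1:5, function(i) base + rnorm(8, sd = 0.05)))
  down <- t(sapply(1:5, function(i) -base + rnorm(8, sd = 0.05)))
  other <- t(sapply(1:5, function(i) rnorm(8)))
  p <- t(scale(t(rbind(up, down, other))))
  rownames(p) <- paste0("f", 1:15)
  net <- tomFromProfiles(p)
  net <- detectCoexpressionModules(net, nModules = 4, minSize = 3,
                                   mergeCor = 1.01)
  mods <- moduleAssignments(net)
  expect_equal(length(unique(mods[1:10])), 1)  # one module for both blocks
})

test_that("merging is disabled when mergeCor exceeds 1", {
  sim <- smallSim()
  profs <- suppressWarnings(buildCombinedProfiles(
    log2(assay(sim$mrna, "counts") + 1), log2(assay(sim$mirna, "counts") + 1),
    as.data.frame(colData(sim$mrna)), as.data.frame(colData(sim$mirna))))
  net <- tomFromProfiles(profs)
  n1 <- detectCoexpressionModules(net, nModules = 15, mergeCor = 1.01)
  n2 <- detectCoexpressionModules(net, nModules = 15, mergeCor = 0.7)
  k <- function(n) length(unique(na.omit(moduleAssignments(n))))
  expect_gte(k(n1), k(n2))
  # without merging, the cut itself defines the modules
  expect_equal(k(n1),
               length(which(table(cutree(hclust(as.dist(1 - net@tom),
                                               "average"), k = 15)) >= 3)))
})

test_that("exact Spearman p matches full enumeration", {
  x <- 1:8
  r <- spearmanExact(x, rev(x))
  expect_equal(r$rho, -1)
  expect_equal(r$p, 2 / 40320)
  expect_error(spearmanExact(1:3, 3:1), "at least 4")

  # independent oracle: brute-force enumeration via cor() at n = 5
  perms <- ThanatoSeq:::allPermutations(5)
  rhoAll <- apply(perms, 1, function(pp) cor(1:5, pp))
  set.seed(22)
  for (i in 1:10) {
    y <- sample(5)
    r <- spearmanExact(1:5, y)
    pOracle <- mean(abs(rhoAll) >= abs(cor(1:5, y)) - 1e-12)
    expect_equal(r$p, pOracle)
  }
  # tied data: midranks, enumeration still valid
  yt <- c(2, 2, 1, 4, 5)
  rt <- spearmanExact(1:5, yt)
  rhoT <- apply(perms, 1, function(pp)
    cor(rank(1:5), rank(yt)[pp]))
  expect_equal(rt$p, mean(abs(rhoT) >= abs(rt$rho) - 1e-12))
})

test_that("independent profiles rarely pass the negative-correlation filter", {
  set.seed(23)
  prof <- matrix(rnorm(400 * 8), 400, 8,
                 dimnames = list(c(paste0("g", 1:200), paste0("m", 1:200)),
                                 NULL))
  pairs <- data.frame(mrna = paste0("g", 1:200), mirna = paste0("m", 1:200))
  out <- spearmanPairFilter(prof, pairs)
  expect_lte(mean(out$pass), 0.05)
})

test_that("expression targets require module co-membership and the filter", {
  sim <- smallSim()
  profs <- suppressWarnings(buildCombinedProfiles(
    log2(assay(sim$mrna, "counts") + 1), log2(assay(sim$mirna, "counts") + 1),
    as.data.frame(colData(sim$mrna)), as.data.frame(colData(sim$mirna))))
  net <- tomFromProfiles(profs)
  net <- detectCoexpressionModules(net, nModules = 20)
  tp <- sim$truth@truePairs
  recs <- spearmanPairFilter(profs, tp)
  recs <- expressionTargets(net, recs)
  expect_gte(mean(recs$is_target), 0.85)  # true pairs recovered
  # a failing condition excludes the pair regardless of the other
  fake <- recs[1, ]
  fake$same_module <- FALSE
  expect_false(fake$same_module && fake$pass)
})
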