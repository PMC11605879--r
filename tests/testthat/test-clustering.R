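test_that("profile standardization averages replicates then z-scores", {
  vals <- rbind(lin = c(1, 1, 2, 2, 3, 3, 4, 4),
                scaled = 10 * c(1, 1, 2, 2, 3, 3, 4, 4),
                flat = rep(5, 8))
  colnames(vals) <- paste0("s", 1:8)
  design <- data.frame(sample_id = colnames(vals), assay = "mrna",
                       time_label = rep(paste0("T", 0:3), each = 2),
                       time_index = rep(0:3, each = 2),
                       replicate = rep(1:2, 4))
  expect_warning(prof <- standardizeProfiles(vals, design), "constant")
  expect_equal(nrow(prof), 2)  # flat gene dropped
  expect_equal(unname(rowMeans(prof)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(prof, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(prof["lin", ], prof["scaled", ], tolerance = 1e-12)
  expect_error(standardizeProfiles(vals[, 1:2], design[1:2, ]),
               "2 time points")
})

test_that("two separated groups are recovered with full agreement", {
  set.seed(2)
  g1 <- matrix(rnorm(20 * 8, 0, 0.1), 20, 8) +
    matrix(rep(c(2, -2, 0, 0, 0, 0, 0, 0), each = 20), 20, 8)
  g2 <- matrix(rnorm(20 * 8, 0, 0.1), 20, 8) +
    matrix(rep(c(0, 0, 0, 0, 0, 0, -2, 2), each = 20), 20, 8)
  x <- rbind(g1, g2)
  rownames(x) <- paste0("g", 1:40)
  fc <- fuzzyCMeans(x, c = 2, m = 1, seed = 1)
  top <- max.col(memberships(fc))
  expect_equal(length(unique(top[1:20])), 1)
  expect_equal(length(unique(top[21:40])), 1)
  expect_false(top[1] == top[21])
})

test_that("m = 1 reproduces Lloyd k-means from the same initialization", {
  set.seed(10)
  x <- matrix(rnorm(200), 50, 4)
  rownames(x) <- paste0("g", 1:50)
  init <- x[c(3, 17, 42), ]
  ours <- ThanatoSeq:::fcmHard(x, init, maxIter = 100)
  ref <- kmeans(x, centers = init, algorithm = "Lloyd", iter.max = 100)
  expect_equal(max.col(ours$u), unname(ref$cluster))
})

test_that("memberships are a proper partition of unity", {
  set.seed(3)
  x <- matrix(rnorm(300), 60, 5)
  rownames(x) <- paste0("g", 1:60)
  for (m in c(1, 1.25, 2)) {
    fc <- fuzzyCMeans(x, c = 4, m = m, seed = 2)
    u <- memberships(fc)
    expect_equal(unname(rowSums(u)), rep(1, 60), tolerance = 1e-9)
    expect_true(all(u >= 0 & u <= 1 + 1e-12))
    expect_true(all(diff(fc@objective) <= 1e-8))  # non-increasing
  }
  expect_error(fuzzyCMeans(x, c = 100, m = 1), "more clusters")
})

test_that("cluster contents are invariant to gene order", {
  set.seed(4)
  centers <- matrix(rnorm(18, sd = 4), 3, 6)
  x <- centers[rep(1:3, length.out = 40), ] + matrix(rnorm(240, sd = 0.2),
                                                     40, 6)
  rownames(x) <- paste0("g", 1:40)
  fc1 <- fuzzyCMeans(x, c = 3, m = 1, seed = 9)
  perm <- sample(40)
  fc2 <- fuzzyCMeans(x[perm, ], c = 3, m = 1, seed = 9)
  part <- function(fc) {
    top <- max.col(memberships(fc))
    unname(lapply(split(rownames(memberships(fc)), top), sort))
  }
  expect_setequal(vapply(part(fc1), paste, "", collapse = ","),
                  vapply(part(fc2), paste, "", collapse = ","))
})

test_that("time-specific assignment follows the centroid peak rule", {
  ctr <- rbind(c(-1, -1, -1, 3, -1, -1, -1, -1),   # sharp peak at index 3
               rep(0, 8),                           # flat
               c(0.4, 0.2, 0, 0, 0, 0, 0, 0))      # margin below 0.5
  u <- matrix(0, 6, 3)
  u[1:2, 1] <- 1; u[3:4, 2] <- 1
  u[5, ] <- c(0.9, 0.05, 0.05)
  u[6, ] <- c(0.4, 0.3, 0.3)  # below minMembership
  rownames(u) <- paste0("g", 1:6)
  fc <- new("FuzzyClustering", k = 3L, m = 1, membership = u,
            centroids = ctr, objective = 1)
  tsg <- timeSpecificAssignment(fc)
  expect_equal(names(tsg), "3")
  expect_setequal(tsg[["3"]], c("g1", "g2", "g5"))
})

test_that("planted single-time peaks are assigned to their time", {
  sim <- smallSim()
  fpkm <- normalizeExpression(sim$mrna, "fpkm")
  keep <- filterFeatures(fpkm, rule = "mrna")
  prof <- suppressWarnings(standardizeProfiles(
    log2(assay(fpkm, "fpkm")[keep, ] + 1), as.data.frame(colData(fpkm))))
  fc <- fuzzyCMeans(prof, c = 12, m = 1, seed = 17)
  tsg <- timeSpecificAssignment(fc)
  # disjoint across time points
  expect_equal(anyDuplicated(unlist(tsg)), 0)
  tm <- sim$truth@tsgMap
  assigned <- setNames(rep(as.integer(names(tsg)), lengths(tsg)),
                       unlist(tsg))
  recovered <- mean(!is.na(assigned[names(tm)]) &
                      assigned[names(tm)] == tm)
  expect_gte(recovered, 0.9)
})
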