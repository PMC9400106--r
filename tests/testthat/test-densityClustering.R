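# feature transforms, knee epsilon, DBSCAN, multi-level protocol

fakeFeatureSet <- function(m, element = "C") {
  colnames(m) <- featureColumns()
  info <- data.frame(entry = paste0("t", seq_len(nrow(m))), frame = "f",
                     element = element, group = "4n",
                     inconsistent = FALSE, stringsAsFactors = FALSE)
  methods::new("FeatureSet", features = m, info = info,
               transform = "original", scaleFactor = 1)
}

test_that("subtraction recenters kappa, kappa' and Pval per element", {
  m <- matrix(0, 2, 18)
  m[, 1] <- c(1.05, 0.98); m[, 2] <- c(4.2, 6.1); m[, 3] <- c(0.9, 1.1)
  fs <- fakeFeatureSet(m, element = c("C", "O"))
  out <- transformFeatures(fs, "subtract")
  expect_equal(out@features[, "kappa"], c(0.05, -0.02))
  expect_equal(out@features[, "Pval"], c(0.2, 0.1))
  expect_equal(out@features[, "kappap"], c(-0.1, 0.1))
  expect_equal(out@features[, -(1:3)], m[, -(1:3)],
               ignore_attr = TRUE)   # Plm untouched
})

test_that("normalizing a constant column yields 1/sqrt(n) entries", {
  n <- 16
  m <- matrix(0, n, 18)
  m[, 1] <- 3; m[, 4] <- rnorm(n)
  fs <- fakeFeatureSet(m)
  expect_warning(out <- transformFeatures(fs, "normalize"), "zero-norm")
  expect_equal(out@features[, "kappa"], rep(1 / sqrt(n), n))
  expect_equal(sum(out@features[, 4]^2), 1)
  expect_true(all(out@features[, 5] == 0))
})

test_that("subtract+normalize matches an independent two-pass oracle", {
  set.seed(33)
  n <- 40
  m <- matrix(rnorm(n * 18, 0, 0.2), n, 18)
  m[, 1] <- 1 + rnorm(n, 0, 0.02); m[, 3] <- 1 + rnorm(n, 0, 0.02)
  els <- sample(c("C", "N", "O"), n, TRUE)
  m[, 2] <- c(C = 4, N = 5, O = 6)[els] + rnorm(n, 0, 0.1)
  fs <- fakeFeatureSet(m, element = els)
  out <- transformFeatures(fs, "subtract-normalize")
  # straightforward reimplementation, column by column
  ref <- m
  ref[, 1] <- ref[, 1] - 1; ref[, 3] <- ref[, 3] - 1
  ref[, 2] <- ref[, 2] - c(C = 4, N = 5, O = 6)[els]
  for (j in 1:18) ref[, j] <- ref[, j] / sqrt(sum(ref[, j]^2))
  expect_equal(out@features, ref, tolerance = 1e-12, ignore_attr = TRUE)
  # uniform scale factor applies last
  out2 <- transformFeatures(fs, "subtract-normalize", scaleFactor = 11064)
  expect_equal(out2@features, ref * 11064, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("knee epsilon lands between blob spread and blob separation", {
  set.seed(41)
  blob <- function(center, n, sdv) sweep(matrix(rnorm(n * 18, 0, sdv),
                                                n, 18), 2, center, "+")
  c1 <- rep(0, 18); c2 <- c(1, rep(0, 17))   # separation 1.0
  m <- rbind(blob(c1, 30, 0.01), blob(c2, 30, 0.01))
  eps <- estimateEps(m, k = 2)
  expect_gt(eps, 0.05 * 0.6)   # above typical 18-dim intra distances...
  expect_gt(eps, max(stats::dist(m[1:30, 1]) * 0))  # (guard: positive)
  expect_lt(eps, 0.9)          # ...but far below the separation
  expect_gt(eps, 0.02)
})

test_that("knee epsilon on a uniform grid approximates the spacing", {
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.2), y = seq(0, 1, 0.2)))
  eps <- estimateEps(g, k = 2)
  expect_equal(eps, 0.2, tolerance = 0.2 * 0.2)
})

test_that("exact duplicates are removed before knee estimation", {
  set.seed(43)
  m <- matrix(rnorm(60), 20, 3)
  expect_equal(estimateEps(rbind(m, m), k = 2), estimateEps(m, k = 2))
  # fully degenerate input errors
  expect_error(estimateEps(matrix(1, 30, 3), k = 2), "degenerate")
})

test_that("dbscan separates planted blobs and flags isolated points", {
  set.seed(47)
  blob <- function(center, n, sdv = 0.02)
    sweep(matrix(rnorm(n * 3, 0, sdv), n, 3), 2, center, "+")
  m <- rbind(blob(c(0, 0, 0), 12), blob(c(1, 0, 0), 12), c(5, 5, 5))
  lab <- dbscan(m, eps = 0.2, minPts = 2)
  expect_equal(lab[25], -1L)
  expect_equal(sort(unique(lab[1:24])), c(0L, 1L))
  expect_equal(length(unique(lab[1:12])), 1)
  expect_equal(length(unique(lab[13:24])), 1)
  # translation invariance
  expect_identical(dbscan(m + 100, eps = 0.2, minPts = 2), lab)
  # deterministic numbering by first member row
  expect_equal(lab[1], 0L)
  expect_equal(lab[13], 1L)
})

test_that("dbscan agrees with the brute-force reference on random data", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:12) {
    n <- 120
    m <- matrix(rnorm(n * 4), n, 4)
    # mixture of regimes: tight pairs, blobs, noise
    m[1:40, ] <- m[1:40, ] * 0.1
    eps <- stats::runif(1, 0.1, 0.8)
    minPts <- sample(2:4, 1)
    a <- dbscan(m, eps, minPts)
    b <- dbscanReference(m, eps, minPts)
    expect_true(samePartition(a, b),
                label = sprintf("rep %d eps %.2f minPts %d", rep, eps,
                                minPts))
  }
})

test_that("multi-level clustering subdivides on Plm sd and stops", {
  set.seed(59)
  # 2 super-blobs, each with 3 sub-blobs separated enough that the
  # super-cluster Plm sd exceeds 0.05
  sub <- function(center) sweep(matrix(rnorm(10 * 18, 0, 0.003), 10, 18),
                                2, center, "+")
  m <- NULL; truth <- integer(0)
  for (s in 0:1) {
    for (k in 0:2) {
      ctr <- rep(0, 18); ctr[2] <- s * 5        # Pval splits supers
      ctr[4 + k] <- 0.25                        # Plm splits subs
      m <- rbind(m, sub(ctr)); truth <- c(truth, rep(s * 3 + k, 10))
    }
    lone <- rep(0, 18); lone[2] <- s * 5; lone[10] <- 0.8
    m <- rbind(m, lone); truth <- c(truth, 6 + s)   # isolated point
  }
  fs <- fakeFeatureSet(m)
  ml <- multilevelCluster(fs, minPts = 2, eps = 1.0)
  # manual first-level eps merges each super-blob; Plm sd forces level 2
  expect_true(all(lengths(strsplit(ml$paths, "_")) == 2))
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(ml$paths, truth), 0.9)
})

test_that("a tight single blob stays one cluster with a length-1 path", {
  set.seed(61)
  m <- matrix(rnorm(30 * 18, 0, 0.005), 30, 18)
  fs <- fakeFeatureSet(m)
  ml <- multilevelCluster(fs, eps = 0.5)
  expect_equal(unique(ml$paths), "0")
  expect_equal(nrow(ml$log), 1)
})

test_that("an eps schedule is replayed deterministically", {
  set.seed(67)
  sub <- function(center) sweep(matrix(rnorm(8 * 18, 0, 0.004), 8, 18),
                                2, center, "+")
  m <- rbind(sub(rep(0, 18)), sub(c(0, 0, 0, 0.3, rep(0, 14))),
             sub(c(0, 5, 0, 0, rep(0, 14))))
  fs <- fakeFeatureSet(m)
  sched <- c("0" = 0.1)
  ml1 <- multilevelCluster(fs, eps = 1.0, epsSchedule = sched)
  ml2 <- multilevelCluster(fs, eps = 1.0, epsSchedule = sched)
  expect_identical(ml1$paths, ml2$paths)
  expect_true("schedule" %in% ml1$log$source)
  # epsilon decreases along the subdivision path
  expect_true(all(diff(ml1$log$eps[order(nchar(ml1$log$path))]) <= 0))
  # max_levels = 1 keeps all paths flat
  ml3 <- multilevelCluster(fs, eps = 1.0, maxLevels = 1)
  expect_true(all(!grepl("_", ml3$paths)))
})

test_that("cluster report finds dominant multipoles and symmetry", {
  m <- matrix(0, 6, 18)
  m[, 1] <- 1; m[, 2] <- 4; m[, 3] <- 1
  m[, featureColumns() == "P32"] <- -0.3
  fs <- fakeFeatureSet(m)
  rep1 <- clusterReport(fs, rep("0", 6))
  expect_equal(rep1$n, 6)
  expect_equal(rep1$dominant, "-P32")
  expect_equal(rep1$pointGroup, "-43m")
  expect_equal(rep1$`sd.P32`, 0)
  expect_equal(rep1$`mean.P32`, -0.3)
})
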