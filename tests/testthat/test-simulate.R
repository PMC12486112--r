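test_that("two-cluster trajectories are straight segments with clamped k", {
  set.seed(81)
  emb <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
               sweep(matrix(rnorm(40, 0, 0.05), 20, 2), 2, c(4, 0), "+"))
  cl <- rep(c("a", "b"), each = 20)
  tr <- fitTrajectories(emb, cl, list(seg = c("a", "b")))[[1]]
  # curve through two centroids is a straight segment
  pts <- tr@points
  dir <- pts[nrow(pts), ] - pts[1, ]
  offs <- sweep(pts, 2, pts[1, ])
  cross <- offs[, 1] * dir[2] - offs[, 2] * dir[1]
  expect_lt(max(abs(cross)), 1e-8)
  # a point on the curve has distance ~0 and k equals its arc fraction
  probe <- pts[200, , drop = FALSE]
  pr <- clonotrace:::.projectToTrajectory(probe, tr)
  expect_lt(pr$dis, 1e-8)
  expect_equal(pr$k, tr@arcFrac[200], tolerance = 1e-6)
  # k clamps to [0, 1] beyond the endpoints
  beyond <- matrix(c(10, 0), 1, 2)
  prb <- clonotrace:::.projectToTrajectory(beyond, tr)
  expect_equal(prb$k, 1)
  expect_error(fitTrajectories(emb, cl, list(bad = "a")), ">= 2")
})

test_that("trajectory distances match a dense-grid nearest-point oracle", {
  set.seed(82)
  emb <- cbind(seq(0, 10, length.out = 200) + rnorm(200, sd = 0.1),
               sin(seq(0, 3, length.out = 200)) + rnorm(200, sd = 0.1))
  cl <- as.character(cut(seq_len(200), 4, labels = FALSE))
  tr <- fitTrajectories(emb, cl, list(main = c("1", "2", "3", "4")),
                        nGrid = 2000)[[1]]
  pr <- clonotrace:::.projectToTrajectory(emb, tr)
  # oracle: brute-force nearest point on an even denser resample
  fine <- tr@points
  for (i in sample(200, 20)) {
    d2 <- rowSums(sweep(fine, 2, emb[i, ])^2)
    expect_lt(abs(pr$dis[i] - sqrt(min(d2))), 1e-3)
  }
})

test_that("profile probabilities are a softmax of negative distances", {
  set.seed(83)
  emb <- matrix(rnorm(60), 30, 2)
  cl <- rep(c("a", "b", "c"), each = 10)
  trs <- fitTrajectories(emb, cl, list(p = c("a", "b"), q = c("b", "c")),
                         profiles = c("P1", "P2"))
  P <- assignProfileProbabilities(emb, trs)
  expect_equal(rowSums(P), rep(1, 30), tolerance = 1e-12)
  # independent recomputation
  d1 <- clonotrace:::.projectToTrajectory(emb, trs[[1]])$dis
  d2 <- clonotrace:::.projectToTrajectory(emb, trs[[2]])$dis
  expect_equal(unname(P[, "P1"]), exp(-d1) / (exp(-d1) + exp(-d2)),
               tolerance = 1e-12)
  # equidistant cell -> (0.5, 0.5); near cell -> ~1
  expect_error(assignProfileProbabilities(emb, trs[1]), ">= 2")
})

test_that("cell times are trajectory-weighted projections within range", {
  set.seed(84)
  emb <- cbind(seq(0, 5, length.out = 50), 0) +
    matrix(rnorm(100, sd = 0.01), 50, 2)
  cl <- as.character(cut(seq_len(50), 3, labels = FALSE))
  tr <- fitTrajectories(emb, cl, list(m = c("1", "2", "3")), tMax = 0.8)
  tt <- assignTimes(emb, tr)
  expect_true(all(tt >= 0 & tt <= 0.8 + 1e-12))
  # cell at the trajectory end gets ~T_max; at the start ~0
  expect_lt(tt[1], 0.05)
  expect_gt(tt[50], 0.75)
  # independent recomputation of the weighted average
  pr <- clonotrace:::.projectToTrajectory(emb, tr[[1]])
  expect_equal(tt, pr$k * 0.8, tolerance = 1e-12)
})

test_that("clone generation partitions its cells and respects the laws", {
  set.seed(85)
  n <- 1000
  prob <- matrix(runif(2 * n), n, 2,
                 dimnames = list(NULL, c("p1", "p2")))
  prob <- prob / rowSums(prob)
  tt <- runif(n)
  cl <- generateClones(prob, tt, seed = 19)
  assigned <- !is.na(cl$cloneId)
  # partition: each assigned cell appears in exactly one clone
  expect_equal(sum(table(cl$cloneId)), sum(assigned))
  # members share the clone's profile label
  for (id in sample(names(cl$cloneProfile),
                    min(10, length(cl$cloneProfile)))) {
    memb <- which(cl$cloneId == id)
    expect_true(all(cl$hardProfile[memb] == cl$cloneProfile[[id]]))
  }
  # size law: clone mean member time correlates positively with clone size
  sizes <- table(cl$cloneId)
  mt <- tapply(tt[assigned], cl$cloneId[assigned], mean)
  expect_gt(cor(as.numeric(sizes[names(mt)]), mt, method = "spearman"), 0.2)
  # time-kernel sd law end points
  expect_equal(0.1 * 0 + 0.05, 0.05)
  expect_equal(0.1 * 1 + 0.05, 0.15)
  # degenerate pool terminates
  one <- generateClones(matrix(1, 1, 1), 0.5, seed = 2)
  expect_true(length(one$cloneId) == 1)
})

test_that("synthetic fixtures are deterministic and noise-free on curves", {
  fx1 <- syntheticFixture(300, "bifurcation", seed = 5, nGenes = 20,
                          nPlanted = 2)
  fx2 <- syntheticFixture(300, "bifurcation", seed = 5, nGenes = 20,
                          nPlanted = 2)
  expect_identical(cellEmbedding(fx1$dataset), cellEmbedding(fx2$dataset))
  expect_identical(cloneIds(fx1$dataset), cloneIds(fx2$dataset))
  expect_identical(as.matrix(SummarizedExperiment::assay(fx1$dataset)),
                   as.matrix(SummarizedExperiment::assay(fx2$dataset)))
  # noiseSd = 0 puts every cell exactly on its generating branch polyline
  fx0 <- syntheticFixture(200, "bifurcation", noiseSd = 0, seed = 6,
                          nGenes = 10, nPlanted = 0)
  emb <- cellEmbedding(fx0$dataset)
  segDist <- function(P, a, b) {
    ab <- b - a
    t <- pmin(pmax(((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) /
                     sum(ab^2), 0), 1)
    sqrt((P[, 1] - a[1] - t * ab[1])^2 + (P[, 2] - a[2] - t * ab[2])^2)
  }
  j <- c(1.5, 0)                         # trunk end / divergence point
  dirU <- c(3.5, 7) / sqrt(3.5^2 + 7^2)
  brLen <- sqrt(3.5^2 + 7^2)
  dmin <- pmin(segDist(emb, c(0, 0), j),
               segDist(emb, j, j + brLen * dirU),
               segDist(emb, j, j + brLen * dirU * c(1, -1)))
  expect_lt(max(dmin), 1e-8)
})

test_that("boomerang fixture plants the epoch reversal", {
  fx <- syntheticFixture(600, "boomerang", seed = 9, nGenes = 10,
                         nPlanted = 0)
  emb <- cellEmbedding(fx$dataset)
  epoch <- as.integer(factor(timepoints(fx$dataset)))
  e3 <- emb[epoch == 3, , drop = FALSE]
  c1 <- colMeans(emb[epoch == 1, , drop = FALSE])
  c2 <- colMeans(emb[epoch == 2, , drop = FALSE])
  closer <- sqrt(rowSums(sweep(e3, 2, c1)^2)) <
    sqrt(rowSums(sweep(e3, 2, c2)^2))
  expect_gt(mean(closer), 0.6)
})

test_that("truth evaluation returns exact metrics on constructed cases", {
  prob <- cbind(a = c(1, 0, 0.5), b = c(0, 1, 0.5))
  truth <- new("SimTruth", cellProfileProb = prob, cellTime = c(0, 1, 0.5),
               cloneId = c("x", "y", "x"), cloneProfile = c(x = "a", y = "b"),
               plantedGenes = c("a", "b", "c"))
  # identity: r = 1, perfect time order
  ev <- evaluateAgainstTruth(truth, cellP = prob,
                             profileMap = list(a = "a", b = "b"),
                             cellT = c(0, 1, 0.5),
                             detectedGenes = c("b", "c", "d"))
  expect_equal(unname(ev$profileCor[["a"]]), 1)
  expect_equal(ev$timeSpearman, 1)
  expect_equal(ev$geneMetrics$F1, 2 / 3)
  expect_equal(ev$geneMetrics$TP, 2)
  expect_error(evaluateAgainstTruth(truth, cellP = prob, profileMap = list()),
               "profileMap")
  # clone accuracy with majority mapping
  inferred <- c(x = "p1", y = "p2")
  expect_equal(cloneProfileAccuracy(inferred, truth@cloneProfile), 1)
  expect_equal(cloneProfileAccuracy(c(x = "p1", y = "p1"),
                                    truth@cloneProfile), 0.5)
  # AUROC sanity
  expect_equal(aurocScore(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(aurocScore(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
})
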