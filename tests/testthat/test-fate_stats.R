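test_that("hard-label fate test equals the classical ANCOVA oracle", {
  set.seed(70)
  n <- 40
  group <- rep(c(TRUE, FALSE), each = n / 2)
  t <- runif(n)
  y <- 0.5 + 0.3 * t + ifelse(group, 0.4 * t, 0) + rnorm(n, sd = 0.3)
  cellP <- cbind(a = as.numeric(group), b = as.numeric(!group))
  got <- fateGeneTest(y, t, cellP, "a", df = 1)
  oracle <- oracleAncovaF(y, t, factor(group))
  expect_equal(got$F_stat[1], oracle$F, tolerance = 1e-9)
  expect_equal(got$p_value[1], oracle$p, tolerance = 1e-9)
})

test_that("fate test is null when groups share means and slopes", {
  set.seed(71)
  n <- 60
  group <- rep(c(TRUE, FALSE), each = n / 2)
  t <- runif(n)
  y <- 1 + 0.2 * t + rnorm(n, sd = 0.4)
  cellP <- cbind(a = as.numeric(group), b = as.numeric(!group))
  got <- fateGeneTest(y, t, cellP, "a", df = 1)
  expect_gt(got$p_value[1], 0.01)
  # all-one-profile design is reported as rank deficient
  cellP1 <- cbind(a = rep(1, n), b = rep(0, n))
  deg <- fateGeneTest(y, t, cellP1, "a", df = 1)
  expect_true(is.na(deg$F_stat[1]))
  expect_match(deg$note[1], "rank-deficient")
})

test_that("fate-test type-I error is nominal under a soft-weight null", {
  set.seed(72)
  n <- 200
  t <- runif(n)
  Pa <- runif(n)
  cellP <- cbind(a = Pa, b = 1 - Pa)
  nGenes <- 4000
  E <- matrix(rnorm(nGenes * n), nGenes, n)
  res <- fateGeneTest(E, t, cellP, "a", df = 1)
  rate <- mean(res$p_value < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nGenes)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
  # p-value histogram roughly uniform (KS on a coarse grid)
  expect_lt(suppressWarnings(ks.test(res$p_value, "punif"))$statistic, 0.04)
})

test_that("BH correction equals the brute-force oracle", {
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdrCorrect(0.2), 0.2)
  set.seed(73)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(fdrCorrect(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("weighted Cohen's d matches textbook and replication oracles", {
  x <- c(rnorm(50), rnorm(50, 1))
  wa <- c(rep(1, 50), rep(0, 50))
  wb <- 1 - wa
  set.seed(74)
  xx <- c(-1, 1, -1, 1)                   # unit-ish variance toy
  d0 <- weightedCohensD(c(0 + xx, 1 + xx),
                        c(rep(1, 4), rep(0, 4)), c(rep(0, 4), rep(1, 4)))
  expect_equal(abs(d0), 1 / sd(xx), tolerance = 1e-12)
  expect_equal(weightedCohensD(x, wa, wa), 0)
  # integer-scaled soft weights agree with replicated pseudo-observations
  xs <- rnorm(6)
  wa2 <- c(3, 1, 2, 0, 0, 0)
  wb2 <- c(0, 0, 1, 2, 4, 1)
  rep_a <- rep(xs, wa2)
  rep_b <- rep(xs, wb2)
  plain <- (mean(rep_a) - mean(rep_b)) /
    sqrt(((length(rep_a) - 1) * var(rep_a) +
          (length(rep_b) - 1) * var(rep_b)) /
         (length(rep_a) + length(rep_b) - 2))
  expect_equal(weightedCohensD(xs, wa2, wb2), plain, tolerance = 1e-9)
})

test_that("plasticity equals the loop oracle and scales as c^2", {
  # two cells at (0,0) and (1,0) with equal weight: mu = (.5, 0), v = .25
  X <- rbind(c(0, 0), c(1, 0))
  Q <- matrix(c(1, 1), 2, 1, dimnames = list(NULL, "cl"))
  res <- clonePlasticity(X, Q)
  expect_equal(res$plasticity[1], 0.25)
  expect_equal(unname(res$mean[1, ]), c(0.5, 0))
  # all mass on one cell -> 0
  expect_equal(clonePlasticity(X, matrix(c(1, 0), 2, 1))$plasticity[1], 0)
  # random clone vs explicit loop oracle
  set.seed(75)
  X50 <- matrix(rnorm(150), 50, 3)
  w <- runif(50)
  got <- clonePlasticity(X50, matrix(w, 50, 1))$plasticity[1]
  expect_lt(abs(got - oraclePlasticity(X50, w)), 1e-10)
  # rigid motion invariance and c^2 scaling
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  X2 <- matrix(rnorm(40), 20, 2)
  w2 <- runif(20)
  v0 <- clonePlasticity(X2, matrix(w2, 20, 1))$plasticity[1]
  vR <- clonePlasticity(sweep(X2 %*% R, 2, c(3, -2), "+"),
                        matrix(w2, 20, 1))$plasticity[1]
  expect_equal(vR, v0, tolerance = 1e-10)
  expect_equal(clonePlasticity(X2 * 2.5, matrix(w2, 20, 1))$plasticity[1],
               2.5^2 * v0, tolerance = 1e-10)
  expect_warning(clonePlasticity(X2, cbind(w2, 0)), "zero-mass")
})

test_that("module score self-controls to ~0 and is deterministic", {
  set.seed(76)
  E <- matrix(rnorm(200 * 100, mean = 5), 200, 100,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  s1 <- moduleScore(E, rownames(E), nBins = 10, nCtrl = 300, seed = 3)
  expect_lt(max(abs(s1)), 0.15)           # set == control population
  # constant matrix scores exactly zero
  Ec <- matrix(2, 50, 10, dimnames = list(paste0("g", 1:50), NULL))
  expect_equal(max(abs(moduleScore(Ec, paste0("g", 1:10), seed = 1))), 0)
  # deterministic under a fixed seed; warns on absent genes
  set <- sprintf("g%03d", 1:12)
  a <- moduleScore(E, set, seed = 9)
  b <- moduleScore(E, set, seed = 9)
  expect_identical(a, b)
  expect_warning(moduleScore(E, c(set, "nope"), seed = 9), "absent")
  expect_error(moduleScore(E, "nope"), "no gene")
})

test_that("baseline fate labelling follows clone terminal reach", {
  clone <- c("a", "a", "b", "b", NA)
  clus <- c("1", "5", "2", "3", "5")
  g <- cloneFateGroups(clone, clus, terminalClusters = "5")
  expect_equal(g, c(TRUE, TRUE, FALSE, FALSE, NA))
})

test_that("baseline DE is null-calibrated and MNN filter matches oracle", {
  set.seed(78)
  n <- 60
  E <- matrix(rnorm(40 * n), 40, n, dimnames = list(paste0("g", 1:40), NULL))
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  res <- baselineDE(E, group = grp)
  expect_lt(mean(res$p_value < 0.05), 0.15)   # ~5% nominal, small-m noise
  # kMnn = Inf keeps every cell
  tvals <- runif(n)
  resInf <- baselineDE(E, group = grp, time = tvals, timeMatch = TRUE,
                       kMnn = Inf)
  expect_equal(resInf$n_group_a[1], sum(grp))
  # disjoint time ranges: MNN filter keeps exactly the brute-force set
  tA <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  tB <- c(0.25, 0.35, 0.45, 0.5)
  kept <- clonotrace:::.mnnKeep(tA, tB, k = 2)
  # brute force
  d <- abs(outer(tA, tB, "-"))
  nnA <- apply(d, 1, function(r) order(r)[1:2])
  nnB <- apply(d, 2, function(r) order(r)[1:2])
  keepA <- keepB <- c()
  for (a in seq_along(tA)) for (b in nnA[, a])
    if (a %in% nnB[, b]) { keepA <- union(keepA, a); keepB <- union(keepB, b) }
  expect_setequal(kept$A, keepA)
  expect_setequal(kept$B, keepB)
  expect_error(baselineDE(E, group = rep(TRUE, n)), "nonempty")
})
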