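test_that("Leiden profiles respect disconnected clone cliques", {
  # two cliques with no connecting edge -> exactly two profiles
  V <- Matrix::bdiag(matrix(1, 4, 4), matrix(1, 4, 4))
  rownames(V) <- colnames(V) <- paste0("c", 1:8)
  prof <- suppressWarnings(clusterProfiles(as(V, "CsparseMatrix"), seed = 3))
  P <- profileMatrix(prof)
  expect_equal(ncol(P), 2L)
  expect_true(all(rowSums(P) == 1))
  expect_equal(unname(P[1:4, ]), unname(P[rep(1, 4), ]))  # same community
  # resolution -> 0 on a connected graph collapses to one profile
  Vc <- matrix(1, 6, 6)
  prof0 <- clusterProfiles(as(Matrix::Matrix(Vc, sparse = TRUE),
                              "CsparseMatrix"), resolution = 1e-6)
  expect_equal(ncol(profileMatrix(prof0)), 1L)
})

test_that("target-S mode reaches the requested profile count", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 5, 0.1), 10, 2),
             matrix(rnorm(20, 10, 0.1), 10, 2))
  D <- as.matrix(dist(X))
  emb <- embedClones(D, d = 2, kClone = 5, umap = FALSE)
  prof <- clusterProfiles(emb, nProfiles = 3, seed = 1)
  expect_equal(ncol(profileMatrix(prof)), 3L)
})

test_that("cell projection QP preserves mass and zero rows", {
  Q <- rbind(c(1, 0), c(0.5, 0.5), c(0, 0))
  P <- diag(2)
  prof <- projectProfilesToCells(Q, P)
  expect_equal(cellProfiles(prof)[1, ], c(1, 0))
  # both clones in the same profile aggregate to mass one
  P2 <- matrix(c(1, 1), 2, 1)
  expect_equal(unname(projectProfilesToCells(Q, P2)@cellP[2, 1]), 1)
  expect_equal(sum(cellProfiles(prof)[3, ]), 0)
  # random Q, P: cellP row sums equal Q row sums
  set.seed(14)
  Qr <- matrix(runif(50), 10, 5)
  Pr <- matrix(runif(15), 5, 3)
  Pr <- Pr / rowSums(Pr)
  expect_equal(rowSums(Qr %*% Pr), rowSums(Qr), tolerance = 1e-12)
  expect_error(projectProfilesToCells(Qr, matrix(1, 4, 2)), "clones")
})

test_that("cellP and cell pseudotime are invariant to clone relabeling", {
  set.seed(26)
  Q <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("c", 1:4)))
  Q <- Q / rowSums(Q)
  P <- diag(4); rownames(P) <- colnames(Q)
  Tv <- setNames(runif(4), colnames(Q))
  base <- as.vector(Q %*% Tv)
  perm <- c(3, 1, 4, 2)
  got <- cellPseudotime(Q[, perm], Tv[perm])
  expect_equal(got, base, tolerance = 1e-12)
})

test_that("enrichment p-values match exhaustive label enumeration", {
  # 6 cells, 3 types (2 each), 2 profiles with hard assignment
  cellP <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(1, 0), c(0, 1))
  type <- c("A", "A", "B", "B", "C", "C")
  # exhaustive: all 6! label orderings
  perms <- NULL
  allP <- combinat_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  labs <- allP(1:6)
  Ind <- stats::model.matrix(~ 0 + factor(type))
  obs <- t(cellP) %*% Ind
  exact <- matrix(0, 2, 3)
  for (pp in labs) {
    msk <- t(cellP) %*% Ind[pp, ]
    exact <- exact + (msk >= obs - 1e-12)
  }
  exact <- exact / length(labs)
  got <- profileEnrichmentTest(cellP, type, nPerm = 4000, seed = 5)
  expect_lt(max(abs(got@pValue - exact)), 0.05)
  # extreme enrichment floor: p = (1 + 0)/(1 + nPerm) at best
  expect_true(all(got@pValue >= 1 / 4001))
})

test_that("enrichment type-I error is at most nominal under the null", {
  set.seed(99)
  hits <- 0; total <- 0
  for (rep in 1:200) {
    cellP <- matrix(runif(40), 20, 2)
    cellP <- cellP / rowSums(cellP)
    type <- sample(rep(c("A", "B"), 10))
    res <- profileEnrichmentTest(cellP, type, nPerm = 199, seed = rep)
    hits <- hits + sum(res@pValue <= 0.05)
    total <- total + length(res@pValue)
  }
  expect_lte(hits / total, 0.05)
})

test_that("graph reweighting matches a brute-force triple loop", {
  set.seed(33)
  emb <- matrix(rnorm(30), 15, 2)
  g <- suppressWarnings(buildCellKnnGraph(emb, k = 3))
  Q <- matrix(runif(30), 15, 2)
  Q <- Q / rowSums(Q)
  V <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  out <- reweightCellGraph(g, Q, as(Matrix::Matrix(V, sparse = TRUE),
                                    "CsparseMatrix"), eps = 1e-3)
  A0 <- as.matrix(g@adjacency)
  A1 <- as.matrix(out@adjacency)
  QVQ <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15) for (a in 1:2) for (b in 1:2)
    QVQ[i, j] <- QVQ[i, j] + Q[i, a] * V[a, b] * Q[j, b]
  for (i in 1:15) for (j in 1:15) {
    if (A0[i, j] > 0)
      expect_equal(A1[i, j], A0[i, j] / max(QVQ[i, j], 1e-3),
                   tolerance = 1e-10)
  }
})

test_that("reweighting inflates clonally unrelated edges by the eps floor", {
  emb <- cbind(c(0, 1, 2), 0)
  g <- buildCellKnnGraph(emb, k = 1)
  Q <- rbind(c(1, 0), c(1, 0), c(0, 1))
  V <- Matrix::Diagonal(2)               # no cross-clone affinity
  out <- reweightCellGraph(g, Q, as(V, "CsparseMatrix"), eps = 1e-3)
  A0 <- as.matrix(g@adjacency); A1 <- as.matrix(out@adjacency)
  expect_equal(A1[1, 2], A0[1, 2])       # same clone, agreement 1
  expect_equal(A1[2, 3], A0[2, 3] / 1e-3)  # unrelated -> inflated
})

test_that("diffusion pseudotime orders a line and roots at zero", {
  set.seed(18)
  x <- sort(runif(30, 0, 10))
  coords <- cbind(x, 0)
  pt <- diffusionPseudotime(coords, root = 1)
  expect_equal(unname(pt[1]), 0)
  expect_true(all(diff(pt) > 0))         # strictly monotone along the chain
  expect_equal(max(pt), 1)
})

test_that("clone pseudotime recovers planted branch depth", {
  # 20 clones on two branches departing a common root
  set.seed(41)
  depth <- c(seq(0, 1, length.out = 10), seq(0.1, 1, length.out = 10))
  branch <- rep(c(1, 2), each = 10)
  X <- cbind(depth * 4, ifelse(branch == 1, depth, -depth) * 2) +
    matrix(rnorm(40, sd = 0.05), 20, 2)
  D <- as.matrix(dist(X))
  emb <- embedClones(D, d = 2, kClone = 4, umap = FALSE)
  rownames(emb@mds) <- paste0("cl", 1:20)
  pt <- clonePseudotime(emb, root = "cl1")
  expect_equal(unname(clonePseudotimes(pt)[["cl1"]]), 0)
  expect_gt(cor(clonePseudotimes(pt), depth, method = "spearman"), 0.95)
})

test_that("cell pseudotime is the Q-weighted clone average within range", {
  Tv <- c(a = 0.4, b = 0.6, c = 0.2)
  Q <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0, 0, 0))
  colnames(Q) <- names(Tv)
  t <- cellPseudotime(Q, Tv)
  expect_equal(t[1], 0.4)
  expect_equal(t[2], 0.5)
  expect_true(is.na(t[3]))
  set.seed(55)
  Qr <- matrix(runif(60), 20, 3, dimnames = list(NULL, names(Tv)))
  Qr <- Qr / rowSums(Qr)
  tr <- cellPseudotime(Qr, Tv)
  expect_true(all(tr >= min(Tv) - 1e-12 & tr <= max(Tv) + 1e-12))
})

test_that("root-condition picks the clone most enriched in the condition", {
  Q <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  colnames(Q) <- c("early", "late")
  tp <- c("d0", "d0", "d7", "d7")
  set.seed(2)
  X <- matrix(rnorm(4), 2, 2, dimnames = list(c("early", "late"), NULL))
  D <- as.matrix(dist(rbind(c(0, 0), c(3, 0))))
  dimnames(D) <- list(c("early", "late"), c("early", "late"))
  emb <- embedClones(D, d = 1, kClone = 1, umap = FALSE)
  pt <- clonePseudotime(emb, rootCondition = "d0", Q = Q, timepoint = tp)
  expect_equal(pt@root, "early")
})
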