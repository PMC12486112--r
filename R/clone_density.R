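#' Build a symmetrized kNN graph over cells
#'
#' Finds the k nearest neighbours of every cell in the embedding (Euclidean
#' distance), symmetrizes by edge union, and derives a row-stochastic
#' affinity matrix W from a Gaussian kernel with per-cell adaptive bandwidth
#' (the distance to the ceiling(k/2)-th neighbour):
#' \deqn{a_{ij} = \exp(-d_{ij}^2 / (\sigma_i \sigma_j)), \quad
#'       W = \mathrm{rownorm}(A).}
#'
#' @param x a \linkS4class{CellDataset} or a cells x D coordinate matrix.
#' @param k number of neighbours (must be < number of cells).
#' @return a \linkS4class{CellGraph}.  A warning is emitted when the graph
#'   is disconnected; component labels are recorded.
#' @export
buildCellKnnGraph <- function(x, k = 30) {
  emb <- if (is(x, "CellDataset")) cellEmbedding(x) else as.matrix(x)
  n <- nrow(emb)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  nn <- RANN::nn2(emb, k = k + 1L)
  idx <- nn$nn.idx[, -1L, drop = FALSE]
  d <- nn$nn.dists[, -1L, drop = FALSE]
  i <- rep(seq_len(n), k)
  j <- as.vector(idx)
  w <- as.vector(d)
  # union symmetrization: both directions of every kNN edge carry the same
  # Euclidean length, so deduplicating ordered pairs is exact
  ii <- c(i, j); jj <- c(j, i); ww <- c(w, w)
  dup <- duplicated(ii + (as.numeric(jj) - 1) * n)
  A <- Matrix::sparseMatrix(i = ii[!dup], j = jj[!dup], x = ww[!dup],
                            dims = c(n, n))
  diag(A) <- 0
  A <- Matrix::drop0(A)
  sigma <- nn$nn.dists[, ceiling(k / 2) + 1L]
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-12)
  Ts <- .sparseTriplets(A)
  aff <- exp(-(Ts$x^2) / (sigma[Ts$i] * sigma[Ts$j]))
  Aff <- Matrix::sparseMatrix(i = Ts$i, j = Ts$j, x = aff, dims = c(n, n))
  rs <- Matrix::rowSums(Aff)
  rs[rs == 0] <- 1
  W <- as(Matrix::Diagonal(x = 1 / rs) %*% Aff, "CsparseMatrix")
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  if (max(comp) > 1L)
    warning("cell graph has ", max(comp), " connected components")
  new("CellGraph", k = as.integer(k), adjacency = as(A, "dgCMatrix"),
      affinity = as(W, "dgCMatrix"), components = as.integer(comp))
}

.sparseTriplets <- function(M) {
  M <- as(M, "TsparseMatrix")
  list(i = M@i + 1L, j = M@j + 1L, x = M@x)
}

#' Seed the cell-to-clone assignment matrix
#'
#' Member cells of expanded clone j receive seed weight ln(C_j)/C_j (so total
#' seeded mass per clone grows logarithmically with clone size, damping the
#' influence of very large clones); all other entries are zero.  Alternative
#' initializers: \code{"inverse_size"} (1/C_j) and \code{"uniform"} (1).
#'
#' @param clones a \linkS4class{CloneTable}.
#' @param nCellsTotal total number of cells N (defaults to the value recorded
#'   in the clone table).
#' @param method seed weight scheme.
#' @return a \linkS4class{CloneAssignment} at stage \code{"initial"}.
#' @export
initializeAssignment <- function(clones, nCellsTotal = NULL,
                                 method = c("log_size", "inverse_size",
                                            "uniform")) {
  method <- match.arg(method)
  n <- if (is.null(nCellsTotal)) clones@nCellsTotal else as.integer(nCellsTotal)
  M <- nClones(clones)
  Q <- matrix(0, n, M, dimnames = list(NULL, cloneNames(clones)))
  for (j in seq_len(M)) {
    Cj <- clones@cloneSizes[j]
    w <- switch(method, log_size = log(Cj) / Cj,
                inverse_size = 1 / Cj, uniform = 1)
    Q[clones@members[[j]], j] <- w
  }
  new("CloneAssignment", Q = Q, stage = "initial", alpha = NA_real_,
      confident = rep(TRUE, n), divergence = rep(NA_real_, n))
}

.propagate <- function(Q0, W, alpha, maxIter, tol) {
  Q <- Q0
  for (it in seq_len(maxIter)) {
    Qn <- alpha * as.matrix(W %*% Q) + (1 - alpha) * Q0
    delta <- max(abs(Qn - Q))
    Q <- Qn
    if (delta < tol) break
  }
  Q
}

#' Propagate clone labels over the cell graph
#'
#' Iterates the anchored label-propagation update
#' \deqn{Q^{(t+1)} = \alpha W Q^{(t)} + (1-\alpha) Q^{(0)}}
#' until the maximum absolute change falls below \code{tol}; for
#' \eqn{\alpha < 1} this converges to the closed form
#' \eqn{(1-\alpha)(I-\alpha W)^{-1} Q^{(0)}}.
#'
#' @param Q0 a \linkS4class{CloneAssignment} at stage initial (or a numeric
#'   matrix of seeds).
#' @param graph a \linkS4class{CellGraph}.
#' @param alpha smoothing parameter in [0, 1); alpha = 0 returns the seeds.
#' @param maxIter,tol iteration controls.
#' @return a \linkS4class{CloneAssignment} at stage \code{"propagated"}.
#' @export
propagateLabels <- function(Q0, graph, alpha = 0.5, maxIter = 200,
                            tol = 1e-6) {
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1): alpha = 1 has no seed anchoring")
  Qm <- if (is(Q0, "CloneAssignment")) Q0@Q else as.matrix(Q0)
  Q <- .propagate(Qm, graph@affinity, alpha, maxIter, tol)
  new("CloneAssignment", Q = Q, stage = "propagated", alpha = alpha,
      confident = rep(TRUE, nrow(Q)),
      divergence = rep(NA_real_, nrow(Q)))
}

#' Bootstrap confidence filter for propagated assignments
#'
#' Repeats propagation \code{nBoot} times, each time masking the seeds of a
#' uniformly random fraction beta of the labeled cells.  Per cell, the
#' divergence is the mean pairwise L1 distance between its row-normalized
#' assignment rows across bootstrap replicates; cells with divergence above
#' the threshold (default: the 90th percentile of the divergence
#' distribution) are flagged unconfident and their rows zeroed.
#'
#' @param Q0 seed \linkS4class{CloneAssignment} (stage initial).
#' @param graph a \linkS4class{CellGraph}.
#' @param alpha propagation smoothing parameter.
#' @param beta fraction of labeled cells masked per bootstrap, in (0, 1).
#' @param nBoot number of bootstrap replicates (>= 2).
#' @param divThreshold divergence cutoff; NULL uses the 90th percentile.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param maxIter,tol propagation controls.
#' @return a \linkS4class{CloneAssignment} at stage \code{"filtered"} with
#'   the propagated Q, confident mask and per-cell divergence.
#' @export
bootstrapFilter <- function(Q0, graph, alpha = 0.5, beta = 0.2, nBoot = 20,
                            divThreshold = NULL, seed = 1, maxIter = 200,
                            tol = 1e-6) {
  stopifnot(beta > 0, beta < 1, nBoot >= 2)
  Qm <- if (is(Q0, "CloneAssignment")) Q0@Q else as.matrix(Q0)
  labeled <- which(rowSums(Qm) > 0)
  n <- nrow(Qm)
  set.seed(seed)
  reps <- vector("list", nBoot)
  nMask <- max(1L, round(beta * length(labeled)))
  for (b in seq_len(nBoot)) {
    mask <- sample(labeled, nMask)
    Qb <- Qm
    Qb[mask, ] <- 0
    reps[[b]] <- .rowNormalize(.propagate(Qb, graph@affinity, alpha,
                                          maxIter, tol))
  }
  # mean pairwise L1 across replicates, accumulated per pair
  div <- numeric(n)
  npair <- 0L
  for (a in seq_len(nBoot - 1L)) for (b in seq.int(a + 1L, nBoot)) {
    div <- div + rowSums(abs(reps[[a]] - reps[[b]]))
    npair <- npair + 1L
  }
  div <- div / npair
  thr <- if (is.null(divThreshold)) stats::quantile(div, 0.9) else divThreshold
  confident <- div <= thr
  if (!any(confident)) stop("bootstrap filter excluded every cell")
  Q <- .propagate(Qm, graph@affinity, alpha, maxIter, tol)
  Q[!confident, ] <- 0
  new("CloneAssignment", Q = Q, stage = "filtered", alpha = alpha,
      confident = as.logical(confident), divergence = div)
}

.rowNormalize <- function(Q) {
  rs <- rowSums(Q)
  rs[rs == 0] <- 1
  Q / rs
}

#' Threshold a soft assignment to its top probability mass
#'
#' Per cell, sorts clone probabilities in decreasing order, keeps the
#' smallest prefix reaching \code{mass} (a fraction of the row total), zeroes
#' the rest and renormalizes the row to sum to one.  All-zero rows stay zero.
#'
#' @param Q a \linkS4class{CloneAssignment} (or numeric matrix).
#' @param mass fraction of cumulative probability mass to retain, in (0, 1].
#' @return a \linkS4class{CloneAssignment} at stage \code{"thresholded"}.
#' @export
thresholdAssignment <- function(Q, mass = 0.9) {
  stopifnot(mass > 0, mass <= 1)
  obj <- if (is(Q, "CloneAssignment")) Q else
    new("CloneAssignment", Q = as.matrix(Q), stage = "propagated",
        alpha = NA_real_, confident = rep(TRUE, nrow(Q)),
        divergence = rep(NA_real_, nrow(Q)))
  Qm <- obj@Q
  out <- .thresholdRows(Qm, mass)
  new("CloneAssignment", Q = out, stage = "thresholded", alpha = obj@alpha,
      confident = obj@confident, divergence = obj@divergence)
}

.thresholdRows <- function(Qm, mass) {
  out <- matrix(0, nrow(Qm), ncol(Qm), dimnames = dimnames(Qm))
  for (i in seq_len(nrow(Qm))) {
    row <- Qm[i, ]
    s <- sum(row)
    if (s <= 0) next
    o <- order(row, decreasing = TRUE)
    cs <- cumsum(row[o])
    keepN <- which(cs >= mass * s - 1e-12)[1]
    keep <- o[seq_len(keepN)]
    out[i, keep] <- row[keep] / sum(row[keep])
  }
  out
}

#' Estimate clone densities end to end
#'
#' Convenience pipeline for the density-estimation stage: builds (or reuses)
#' the cell kNN graph, seeds Q from the expanded-clone table, propagates,
#' applies the bootstrap confidence filter and thresholds to the top
#' probability mass.
#'
#' @param dataset a \linkS4class{CellDataset}.
#' @param clones a \linkS4class{CloneTable} (default: expanded clones at
#'   threshold 10).
#' @param graph optional precomputed \linkS4class{CellGraph}.
#' @param k kNN parameter when the graph is built here.
#' @param alpha,beta,nBoot,divThreshold,mass stage parameters (see the
#'   individual functions).
#' @param seed RNG seed for the bootstrap.
#' @param maxIter,tol propagation controls.
#' @return list with elements \code{assignment} (thresholded
#'   \linkS4class{CloneAssignment}), \code{graph} and \code{clones}.
#' @export
cloneDensity <- function(dataset, clones = NULL, graph = NULL, k = 30,
                         alpha = 0.5, beta = 0.2, nBoot = 20,
                         divThreshold = NULL, mass = 0.9, seed = 1,
                         maxIter = 200, tol = 1e-6) {
  if (is.null(clones)) clones <- filterExpandedClones(dataset)
  if (is.null(graph)) graph <- buildCellKnnGraph(dataset, k = k)
  Q0 <- initializeAssignment(clones)
  filt <- bootstrapFilter(Q0, graph, alpha = alpha, beta = beta,
                          nBoot = nBoot, divThreshold = divThreshold,
                          seed = seed, maxIter = maxIter, tol = tol)
  list(assignment = thresholdAssignment(filt, mass = mass), graph = graph,
       clones = clones)
}

#' @rdname CloneAssignment-class
#' @export
setMethod("assignmentMatrix", "CloneAssignment", function(x) x@Q)

#' @rdname CloneAssignment-class
#' @export
setMethod("assignmentStage", "CloneAssignment", function(x) x@stage)

setMethod("show", "CloneAssignment", function(object) {
  cat("CloneAssignment (stage ", object@stage, "): ", nrow(object@Q),
      " cells x ", ncol(object@Q), " clones; ",
      sum(rowSums(object@Q) > 0), " cells with mass\n", sep = "")
})

setMethod("show", "CellGraph", function(object) {
  cat("CellGraph: ", nrow(object@adjacency), " cells, k = ", object@k, ", ",
      length(object@adjacency@x) / 2, " undirected edges, ",
      max(object@components), " component(s)\n", sep = "")
})
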