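#' Cluster clones into clonotype profiles (Leiden)
#'
#' Runs Leiden community detection (modularity objective) on the clone kNN
#' graph to partition the M clones into S clonotype profiles.  Either a
#' resolution is given, or a target number of profiles: in target mode the
#' resolution is bisected until the community count matches (or the interval
#' collapses, in which case the closest count wins).
#'
#' @param embedding a \linkS4class{CloneEmbedding} (or a sparse clone
#'   affinity matrix).
#' @param resolution Leiden resolution (default 1).
#' @param nProfiles optional target number of profiles S.
#' @param seed RNG seed (Leiden is stochastic).
#' @return a \linkS4class{ProfileAssignment} with the one-hot P (cellP is
#'   filled by \code{\link{projectProfilesToCells}}).
#' @export
clusterProfiles <- function(embedding, resolution = 1, nProfiles = NULL,
                            seed = 1) {
  V <- if (is(embedding, "CloneEmbedding")) embedding@affinity else
    as(embedding, "CsparseMatrix")
  M <- nrow(V)
  A <- V
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no > 1L)
    warning("clone graph has multiple components; profiles respect them")
  runLeiden <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 5))
  }
  if (M == 1L) {
    warning("single clone: one profile")
    memb <- 1L
  } else if (is.null(nProfiles)) {
    memb <- runLeiden(resolution)
  } else {
    lo <- 1e-4; hi <- 50
    memb <- runLeiden(resolution)
    best <- memb
    for (it in 1:40) {
      mid <- sqrt(lo * hi)
      memb <- runLeiden(mid)
      S <- length(unique(memb))
      if (abs(S - nProfiles) < abs(length(unique(best)) - nProfiles))
        best <- memb
      if (S == nProfiles) { best <- memb; break }
      if (S < nProfiles) lo <- mid else hi <- mid
    }
    memb <- best
    if (length(unique(memb)) != nProfiles)
      warning("target profile count ", nProfiles, " not reached; using ",
              length(unique(memb)))
  }
  memb <- as.integer(factor(memb))
  S <- max(memb)
  P <- matrix(0, M, S,
              dimnames = list(rownames(V), paste0("profile", seq_len(S))))
  P[cbind(seq_len(M), memb)] <- 1
  new("ProfileAssignment", P = P,
      cellP = matrix(0, 0, S, dimnames = list(NULL, colnames(P))))
}

#' Project clone profiles to cells
#'
#' Computes the cell-to-profile probability matrix cellP = Q P.  Cells with
#' zero assignment mass keep zero rows.
#'
#' @param Q a thresholded \linkS4class{CloneAssignment} (or matrix).
#' @param profiles a \linkS4class{ProfileAssignment} (or matrix P).
#' @return the updated \linkS4class{ProfileAssignment} with cellP filled.
#' @export
projectProfilesToCells <- function(Q, profiles) {
  Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
  P <- if (is(profiles, "ProfileAssignment")) profiles@P else
    as.matrix(profiles)
  if (ncol(Qm) != nrow(P))
    stop("Q has ", ncol(Qm), " clones but P has ", nrow(P), " rows")
  cellP <- Qm %*% P
  if (is(profiles, "ProfileAssignment")) {
    profiles@cellP <- cellP
    profiles
  } else {
    new("ProfileAssignment", P = P, cellP = cellP)
  }
}

#' Profile-by-cell-type enrichment permutation test
#'
#' Builds the S x K contingency table of cell-to-profile mass per cell type
#' and tests enrichment by permuting the cell type labels: the one-sided
#' empirical p-value for cell (s, k) is (1 + #\{permuted mass >= observed\})
#' / (1 + nPerm).  BH-adjusted q-values are reported alongside.
#'
#' @param cellP N x S cell-to-profile matrix (or
#'   \linkS4class{ProfileAssignment}).
#' @param clusterId per-cell type labels (length N; NA cells dropped).
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return an \linkS4class{EnrichmentResult}.
#' @export
profileEnrichmentTest <- function(cellP, clusterId, nPerm = 1000, seed = 1) {
  stopifnot(nPerm >= 100)
  CP <- if (is(cellP, "ProfileAssignment")) cellP@cellP else as.matrix(cellP)
  keep <- !is.na(clusterId)
  CP <- CP[keep, , drop = FALSE]
  f <- factor(clusterId[keep])
  Ind <- stats::model.matrix(~ 0 + f)
  colnames(Ind) <- levels(f)
  obs <- t(CP) %*% Ind                     # S x K mass table
  zeroType <- colSums(obs) == 0
  if (any(zeroType))
    warning("cell type(s) with zero assigned mass: ",
            paste(colnames(obs)[zeroType], collapse = ", "))
  set.seed(seed)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  n <- nrow(CP)
  for (b in seq_len(nPerm)) {
    perm <- t(CP) %*% Ind[sample.int(n), , drop = FALSE]
    exceed <- exceed + (perm >= obs - 1e-12)
  }
  p <- (1 + exceed) / (1 + nPerm)
  p[, zeroType] <- 1
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  dimnames(p) <- dimnames(q) <- dimnames(obs)
  new("EnrichmentResult", observed = as.matrix(obs), pValue = p, qValue = q,
      nPerm = as.integer(nPerm))
}

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", nrow(object@observed), "profiles x",
      ncol(object@observed), "cell types;", object@nPerm, "permutations;",
      sum(object@qValue < 0.05), "cells with q < 0.05\n")
})

#' Reweight cell-graph distances by clone-neighbourhood agreement
#'
#' Divides each cell-graph edge length by the clone-affinity agreement of
#' its endpoints, \eqn{D'_{ij} = D_{ij} / \max((Q V Q^\top)_{ij},
#' \epsilon)}: edges between cells whose clones are identical or neighbours
#' in the clone embedding keep (or shrink) their length, while edges between
#' clonally unrelated cells are inflated (by up to 1/epsilon).
#'
#' @param graph a \linkS4class{CellGraph}.
#' @param Q a thresholded \linkS4class{CloneAssignment} (or matrix).
#' @param V clone affinity (sparse, unit diagonal) or a
#'   \linkS4class{CloneEmbedding}.
#' @param eps floor for the agreement term (default 1e-3).
#' @return a new \linkS4class{CellGraph} with reweighted edge lengths and a
#'   recomputed row-stochastic affinity.
#' @export
reweightCellGraph <- function(graph, Q, V, eps = 1e-3) {
  Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
  Vm <- if (is(V, "CloneEmbedding")) V@affinity else as(V, "CsparseMatrix")
  A <- Qm %*% as.matrix(Vm)               # N x M
  Ts <- .sparseTriplets(graph@adjacency)
  agree <- rowSums(A[Ts$i, , drop = FALSE] * Qm[Ts$j, , drop = FALSE])
  newLen <- Ts$x / pmax(agree, eps)
  n <- nrow(Qm)
  Adj <- Matrix::sparseMatrix(i = Ts$i, j = Ts$j, x = newLen,
                              dims = c(n, n))
  # refresh the Gaussian affinity with adaptive bandwidths on the new lengths
  Ts2 <- .sparseTriplets(Adj)
  sigma <- rep(1, n)
  byRow <- split(Ts2$x, Ts2$i)
  kk <- ceiling(graph@k / 2)
  for (nm in names(byRow)) {
    v <- sort(byRow[[nm]])
    sigma[as.integer(nm)] <- v[min(length(v), kk)]
  }
  sigma[sigma <= 0] <- 1e-12
  aff <- exp(-(Ts2$x^2) / (sigma[Ts2$i] * sigma[Ts2$j]))
  Aff <- Matrix::sparseMatrix(i = Ts2$i, j = Ts2$j, x = aff, dims = c(n, n))
  rs <- Matrix::rowSums(Aff)
  rs[rs == 0] <- 1
  W <- as(Matrix::Diagonal(x = 1 / rs) %*% Aff, "CsparseMatrix")
  new("CellGraph", k = graph@k, adjacency = as(Adj, "dgCMatrix"),
      affinity = as(W, "dgCMatrix"), components = graph@components)
}

#' Diffusion pseudotime from coordinates
#'
#' Classic diffusion pseudotime on a dense Gaussian kernel: the kernel (with
#' bandwidth sigma, default the median pairwise distance) is
#' density-normalized, its diffusion components are computed, and the
#' pseudotime of point i is the diffusion distance to the root
#' \deqn{\mathrm{dpt}(i) = \sqrt{\sum_{k \ge 2}
#'   \left(\tfrac{\lambda_k}{1-\lambda_k}\right)^2 (\psi_k(i) -
#'   \psi_k(\mathrm{root}))^2},}
#' rescaled to [0, 1] with the root at 0.
#'
#' @param coords points x dims coordinate matrix (or a distance matrix via
#'   \code{isDistance = TRUE}).
#' @param root index (or rowname) of the root point.
#' @param nComp number of diffusion components (default 10).
#' @param sigma kernel bandwidth; default median pairwise distance.
#' @param isDistance interpret \code{coords} as a distance matrix.
#' @return numeric pseudotime vector in [0, 1], named like the input rows.
#' @export
diffusionPseudotime <- function(coords, root, nComp = 10, sigma = NULL,
                                isDistance = FALSE) {
  D <- if (isDistance) as.matrix(coords) else
    as.matrix(stats::dist(as.matrix(coords)))
  n <- nrow(D)
  if (is.character(root)) root <- match(root, rownames(D))
  if (is.na(root) || root < 1 || root > n) stop("invalid root")
  if (is.null(sigma)) sigma <- stats::median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  K <- exp(-(D / sigma)^2)
  dc <- .diffusionComponents(K, nComp = min(nComp, n - 1L))
  lambda <- dc$lambda
  if (any(lambda > 1 - 1e-12))
    stop("diffusion kernel is (numerically) disconnected")
  scale <- lambda / (1 - lambda)
  psi <- dc$psi
  diffs <- sweep(psi, 2, psi[root, ], "-")
  dpt <- sqrt(rowSums(sweep(diffs, 2, scale, "*")^2))
  mx <- max(dpt)
  if (mx > 0) dpt <- dpt / mx
  names(dpt) <- rownames(D)
  dpt
}

#' Clone-level pseudotime
#'
#' Diffusion pseudotime over the clone MDS coordinates, rooted either at a
#' named clone or at the clone most enriched in a root condition (the clone
#' whose assignment mass is most concentrated in cells of the given
#' timepoint).
#'
#' @param embedding a \linkS4class{CloneEmbedding}.
#' @param root clone id (or index) to use as the root, or NULL.
#' @param rootCondition timepoint label defining the root condition (used
#'   with \code{Q} and \code{timepoint} when \code{root} is NULL).
#' @param Q assignment matrix, required for \code{rootCondition}.
#' @param timepoint per-cell timepoint labels, required for
#'   \code{rootCondition}.
#' @param nComp diffusion components.
#' @return a \linkS4class{PseudotimeResult} with cloneT filled (cellT empty
#'   until \code{\link{cellPseudotime}}).
#' @export
clonePseudotime <- function(embedding, root = NULL, rootCondition = NULL,
                            Q = NULL, timepoint = NULL, nComp = 10) {
  mds <- embedding@mds
  ids <- rownames(mds)
  if (is.null(root)) {
    if (is.null(rootCondition) || is.null(Q) || is.null(timepoint))
      stop("supply either root, or rootCondition together with Q and ",
           "timepoint")
    Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
    inCond <- !is.na(timepoint) & timepoint == rootCondition
    if (!any(inCond)) stop("no cell has timepoint '", rootCondition, "'")
    frac <- colSums(Qm[inCond, , drop = FALSE]) /
      pmax(colSums(Qm), .Machine$double.eps)
    root <- ids[which.max(frac)]
  }
  if (is.numeric(root)) root <- ids[root]
  dpt <- diffusionPseudotime(mds, root = root, nComp = nComp)
  new("PseudotimeResult", cloneT = dpt, cellT = numeric(0),
      root = as.character(root))
}

#' Project clone pseudotime to cells
#'
#' cell_t = Q T: the pseudotime of a cell is the assignment-weighted average
#' of its clones' pseudotimes.  Cells without assignment mass get NA.
#'
#' @param Q a thresholded \linkS4class{CloneAssignment} (or matrix whose
#'   nonzero rows sum to one).
#' @param pseudotime a \linkS4class{PseudotimeResult} (or named cloneT
#'   vector).
#' @return the updated \linkS4class{PseudotimeResult} (or, given a plain
#'   vector, the numeric cell pseudotime).
#' @export
cellPseudotime <- function(Q, pseudotime) {
  Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
  Tv <- if (is(pseudotime, "PseudotimeResult")) pseudotime@cloneT else
    pseudotime
  if (!is.null(colnames(Qm)) && !is.null(names(Tv)))
    Tv <- Tv[colnames(Qm)]
  t <- as.vector(Qm %*% Tv)
  t[rowSums(Qm) <= 0] <- NA_real_
  if (is(pseudotime, "PseudotimeResult")) {
    pseudotime@cellT <- t
    pseudotime
  } else t
}

#' @rdname ProfileAssignment-class
#' @export
setMethod("profileMatrix", "ProfileAssignment", function(x) x@P)

#' @rdname ProfileAssignment-class
#' @export
setMethod("cellProfiles", "ProfileAssignment", function(x) x@cellP)

#' @rdname PseudotimeResult-class
#' @export
setMethod("clonePseudotimes", "PseudotimeResult", function(x) x@cloneT)

#' @rdname PseudotimeResult-class
#' @export
setMethod("cellPseudotimes", "PseudotimeResult", function(x) x@cellT)

setMethod("show", "ProfileAssignment", function(object) {
  cat("ProfileAssignment:", nrow(object@P), "clones ->", ncol(object@P),
      "profiles;", nrow(object@cellP), "cells projected\n")
})

setMethod("show", "PseudotimeResult", function(object) {
  cat("PseudotimeResult: root clone", object@root, ";",
      length(object@cloneT), "clones;", length(object@cellT),
      "cells projected\n")
})
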