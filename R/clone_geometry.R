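#' Graph-geodesic cost matrix over a cell subset
#'
#' All-pairs shortest-path lengths on the cell kNN graph (edge weight =
#' Euclidean edge length), restricted to the requested subset.  Shortest
#' paths on the graph approximate geodesic distances on the manifold the
#' embedding samples.
#'
#' @param graph a \linkS4class{CellGraph}.
#' @param subset integer cell indices (rows of the cost matrix).
#' @param to optional second subset (columns); defaults to \code{subset}.
#' @return numeric matrix of geodesic distances; pairs in different graph
#'   components are \code{Inf} (with a warning).
#' @export
geodesicCost <- function(graph, subset, to = subset) {
  if (!length(subset)) stop("subset must be nonempty")
  g <- igraph::graph_from_adjacency_matrix(graph@adjacency,
                                           mode = "undirected",
                                           weighted = TRUE)
  D <- igraph::distances(g, v = subset, to = to)
  if (any(is.infinite(D)))
    warning("some cell pairs lie in different graph components")
  dimnames(D) <- list(as.character(subset), as.character(to))
  D
}

# --- exact optimal transport (transportation simplex) -----------------------
# Solves min <C, F> s.t. rowSums(F) = a, colSums(F) = b, F >= 0 by the
# classic NW-corner + MODI method.  Supplies are epsilon-perturbed to keep
# the basis non-degenerate; the final cost is re-solved exactly on the
# optimal basis tree with the unperturbed marginals.
.transportSimplex <- function(a, b, C, maxPivots = 100000L) {
  m <- length(a); n <- length(b)
  eps <- 1e-9 / max(m, 1)
  ap <- a + eps
  bp <- b
  bp[n] <- bp[n] + m * eps
  # NW corner initial basic feasible solution
  basis <- matrix(0L, m + n - 1L, 2L)
  flow <- numeric(m + n - 1L)
  i <- 1L; j <- 1L; k <- 0L
  ra <- ap; rb <- bp
  while (i <= m && j <= n) {
    k <- k + 1L
    basis[k, ] <- c(i, j)
    f <- min(ra[i], rb[j])
    flow[k] <- f
    ra[i] <- ra[i] - f
    rb[j] <- rb[j] - f
    if (ra[i] <= rb[j]) i <- i + 1L else j <- j + 1L
  }
  nb <- k
  basis <- basis[seq_len(nb), , drop = FALSE]
  flow <- flow[seq_len(nb)]
  for (pivot in seq_len(maxPivots)) {
    # potentials u, v from the basis tree (u[1] = 0)
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    repeat {
      progressed <- FALSE
      for (e in seq_len(nb)) {
        bi <- basis[e, 1]; bj <- basis[e, 2]
        if (!is.na(u[bi]) && is.na(v[bj])) {
          v[bj] <- C[bi, bj] - u[bi]; progressed <- TRUE
        } else if (is.na(u[bi]) && !is.na(v[bj])) {
          u[bi] <- C[bi, bj] - v[bj]; progressed <- TRUE
        }
      }
      if (!anyNA(u) && !anyNA(v)) break
      if (!progressed) stop("transport basis is not a spanning tree")
    }
    red <- C - outer(u, v, "+")
    red[basis] <- 0
    ent <- arrayInd(which.min(red), dim(red))
    if (red[ent] >= -1e-11) break
    ei <- ent[1]; ej <- ent[2]
    # find cycle: path between row-node ei and col-node ej in the basis tree
    adj <- vector("list", m + n)
    for (e in seq_len(nb)) {
      rn <- basis[e, 1]; cn <- m + basis[e, 2]
      adj[[rn]] <- c(adj[[rn]], e)
      adj[[cn]] <- c(adj[[cn]], e)
    }
    # BFS from row ei to col m+ej
    prevEdge <- integer(m + n); prevNode <- integer(m + n)
    seen <- logical(m + n)
    queue <- ei; seen[ei] <- TRUE
    target <- m + ej
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      if (nd == target) break
      for (e in adj[[nd]]) {
        other <- if (basis[e, 1] == nd) m + basis[e, 2] else basis[e, 1]
        if (!seen[other]) {
          seen[other] <- TRUE
          prevEdge[other] <- e
          prevNode[other] <- nd
          queue <- c(queue, other)
        }
      }
    }
    path <- integer(0)
    nd <- target
    while (nd != ei) {
      path <- c(prevEdge[nd], path)
      nd <- prevNode[nd]
    }
    # alternate signs around the cycle: entering arc is +, then -, +, ...
    signs <- rep(c(-1, 1), length.out = length(path))
    minus <- path[signs == -1]
    theta <- min(flow[minus])
    leave <- minus[which.min(flow[minus])]
    flow[path] <- flow[path] + signs * theta
    basis[leave, ] <- c(ei, ej)
    flow[leave] <- theta
  }
  # exact flow on the optimal basis tree with unperturbed marginals
  flowExact <- .treeFlow(basis, a, b, m, n)
  sum(C[basis] * flowExact)
}

# unique flow on a spanning tree of the transportation bipartite graph
.treeFlow <- function(basis, a, b, m, n) {
  nb <- nrow(basis)
  deg <- integer(m + n)
  adj <- vector("list", m + n)
  for (e in seq_len(nb)) {
    rn <- basis[e, 1]; cn <- m + basis[e, 2]
    adj[[rn]] <- c(adj[[rn]], e); adj[[cn]] <- c(adj[[cn]], e)
    deg[rn] <- deg[rn] + 1L; deg[cn] <- deg[cn] + 1L
  }
  supply <- c(a, -b)     # row nodes supply, col nodes demand
  flow <- numeric(nb)
  used <- logical(nb)
  leaves <- which(deg == 1L)
  while (length(leaves)) {
    nd <- leaves[1]; leaves <- leaves[-1]
    e <- NA_integer_
    for (cand in adj[[nd]]) if (!used[cand]) { e <- cand; break }
    if (is.na(e)) next
    rn <- basis[e, 1]; cn <- m + basis[e, 2]
    other <- if (nd == rn) cn else rn
    f <- if (nd <= m) supply[nd] else -supply[nd]
    flow[e] <- f
    # arc carries f from row to col; update the other endpoint's balance
    if (nd <= m) supply[other] <- supply[other] + f else
      supply[other] <- supply[other] - f
    supply[nd] <- if (nd <= m) 0 else 0
    used[e] <- TRUE
    deg[other] <- deg[other] - 1L
    deg[nd] <- 0L
    if (deg[other] == 1L) leaves <- c(leaves, other)
  }
  flow
}

#' Exact earth mover's distance between two densities
#'
#' Solves the optimal-transport linear program between two discrete
#' densities over the same cell support with a transportation-simplex
#' solver; the cost matrix is typically a graph-geodesic cost from
#' \code{\link{geodesicCost}}.
#'
#' @param p,q non-negative densities (normalized to sum one internally).
#' @param cost cost matrix, rows indexing the support of p, columns of q.
#' @return the optimal transport cost (a single number).
#' @export
emdExact <- function(p, q, cost) {
  if (sum(p) <= 0 || sum(q) <= 0) stop("zero-mass density")
  p <- p / sum(p); q <- q / sum(q)
  sp <- which(p > 0); sq <- which(q > 0)
  C <- as.matrix(cost)[sp, sq, drop = FALSE]
  if (any(!is.finite(C))) {
    mx <- max(C[is.finite(C)], 0)
    C[!is.finite(C)] <- mx * 10
  }
  .transportSimplex(p[sp], q[sq], C)
}

#' Approximate clone-to-clone distance via top-assigned cells
#'
#' Scalable surrogate for the exact EMD: selects the top \code{x} cells of
#' each clone by assignment probability (all cells when a clone has fewer
#' than x), computes for each selected cell of clone i the mean graph
#' distance to its \code{k} nearest selected cells of clone j, averages
#' those over clone i's cells, repeats in the reverse direction, and
#' returns the mean of the two directional measurements.
#'
#' @param Q assignment matrix (\linkS4class{CloneAssignment} or matrix).
#' @param graph a \linkS4class{CellGraph}.
#' @param i,j clone indices or names.
#' @param x number of top cells to keep per clone.
#' @param k number of nearest cross-clone cells to average over.
#' @param clones optional \linkS4class{CloneTable}; when given, the top-x
#'   selection pool is the clone's member cells (ranked by assignment
#'   probability), otherwise all cells with nonzero probability.
#' @param cost optional precomputed geodesic cost over all cells involved
#'   (named by cell index), to amortize shortest-path computation.
#' @return a single non-negative number, symmetric in i and j.
#' @export
emdApprox <- function(Q, graph, i, j, x = 50, k = 5, clones = NULL,
                      cost = NULL) {
  Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
  if (identical(i, j)) return(0)         # self-distance by definition
  mem <- .memberPools(clones, Qm)
  si <- .topCells(Qm[, i], x, mem[[if (is.character(i)) i else
    colnames(Qm)[i] %||% i]])
  sj <- .topCells(Qm[, j], x, mem[[if (is.character(j)) j else
    colnames(Qm)[j] %||% j]])
  if (!length(si) || !length(sj)) stop("empty clone support for pair (",
                                       i, ", ", j, ")")
  if (is.null(cost)) {
    D <- geodesicCost(graph, si, sj)
  } else {
    D <- cost[as.character(si), as.character(sj), drop = FALSE]
  }
  .approxFromCost(D, k)
}

.topCells <- function(col, x, members = NULL) {
  sup <- if (is.null(members)) which(col > 0) else members
  if (length(sup) <= x) return(sup)
  sup[order(col[sup], decreasing = TRUE)[seq_len(x)]]
}

# named list of member-cell pools (NULL entries when no CloneTable given)
.memberPools <- function(clones, Qm) {
  if (is.null(clones))
    return(stats::setNames(vector("list", ncol(Qm)),
                           colnames(Qm) %||% as.character(seq_len(ncol(Qm)))))
  cloneMembers(clones)
}

.approxFromCost <- function(D, k) {
  meanK <- function(v, k) mean(sort(v)[seq_len(min(k, length(v)))])
  dij <- mean(apply(D, 1, meanK, k = k))
  dji <- mean(apply(D, 2, meanK, k = k))
  (dij + dji) / 2
}

#' Pairwise clone distance matrix
#'
#' Computes the full symmetric matrix of clone-to-clone distances from the
#' smoothed densities in Q, either by exact EMD over graph-geodesic costs or
#' by the scalable top-cell approximation.  \code{method = "auto"} picks
#' exact EMD when there are at most 200 clones and every clone support has
#' at most 500 cells, and the approximation otherwise.
#'
#' @param Q a thresholded \linkS4class{CloneAssignment} (or matrix).
#' @param graph a \linkS4class{CellGraph}.
#' @param method "auto", "exact" or "approx".
#' @param x,k approximation parameters.
#' @param clones optional \linkS4class{CloneTable}: restricts the top-x
#'   selection of the approximation to each clone's member cells.
#' @return a \linkS4class{CloneDistance}.
#' @export
cloneDistanceMatrix <- function(Q, graph, method = c("auto", "exact",
                                                     "approx"),
                                x = 50, k = 5, clones = NULL) {
  method <- match.arg(method)
  Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
  M <- ncol(Qm)
  if (M < 2) stop("need at least two clones")
  support <- lapply(seq_len(M), function(j) which(Qm[, j] > 0))
  if (method == "auto")
    method <- if (M <= 200 && max(lengths(support)) <= 500) "exact" else
      "approx"
  D <- matrix(0, M, M, dimnames = list(colnames(Qm), colnames(Qm)))
  if (method == "exact") {
    cells <- sort(unique(unlist(support)))
    cost <- geodesicCost(graph, cells)
    pos <- match(seq_len(nrow(Qm)), cells)
    if (any(!is.finite(cost))) {
      mx <- max(cost[is.finite(cost)], 0)
      cost[!is.finite(cost)] <- mx * 10
      warning("disconnected cell pairs: infinite geodesics replaced by ",
              "10 x max finite distance")
    }
    for (a in seq_len(M - 1)) for (b in seq.int(a + 1, M)) {
      sa <- support[[a]]; sb <- support[[b]]
      val <- tryCatch(
        .transportSimplex(Qm[sa, a] / sum(Qm[sa, a]),
                          Qm[sb, b] / sum(Qm[sb, b]),
                          cost[pos[sa], pos[sb], drop = FALSE]),
        error = function(e) stop("EMD failed for clone pair (",
                                 colnames(Qm)[a], ", ", colnames(Qm)[b],
                                 "): ", conditionMessage(e)))
      D[a, b] <- D[b, a] <- val
    }
  } else {
    mem <- .memberPools(clones, Qm)
    sel <- lapply(seq_len(M), function(j) .topCells(Qm[, j], x, mem[[j]]))
    cells <- sort(unique(unlist(sel)))
    cost <- geodesicCost(graph, cells)
    if (any(!is.finite(cost))) {
      mx <- max(cost[is.finite(cost)], 0)
      cost[!is.finite(cost)] <- mx * 10
      warning("disconnected cell pairs: infinite geodesics replaced by ",
              "10 x max finite distance")
    }
    key <- as.character(cells)
    rownames(cost) <- colnames(cost) <- key
    for (a in seq_len(M - 1)) for (b in seq.int(a + 1, M)) {
      Dsub <- cost[as.character(sel[[a]]), as.character(sel[[b]]),
                   drop = FALSE]
      D[a, b] <- D[b, a] <- .approxFromCost(Dsub, k)
    }
  }
  new("CloneDistance", D = D,
      method = if (method == "exact") "exact_emd" else "approx",
      params = list(x = x, k = k))
}

# --- clone embedding --------------------------------------------------------

# metric MDS by SMACOF majorization, initialized from classical scaling
.smacof <- function(D, d, maxIter = 300, tol = 1e-9) {
  M <- nrow(D)
  d <- min(d, M - 1L)
  X <- stats::cmdscale(D, k = d)
  if (ncol(X) < d) X <- cbind(X, matrix(0, M, d - ncol(X)))
  W <- matrix(1, M, M); diag(W) <- 0
  stress <- function(X) {
    dx <- as.matrix(stats::dist(X))
    sum(W * (D - dx)^2) / 2
  }
  s0 <- stress(X)
  for (it in seq_len(maxIter)) {
    dx <- as.matrix(stats::dist(X))
    dx[dx < 1e-12] <- 1e-12
    Bm <- -W * D / dx
    diag(Bm) <- 0
    diag(Bm) <- -rowSums(Bm)
    X <- Bm %*% X / M
    s1 <- stress(X)
    if (abs(s0 - s1) < tol * max(s0, 1e-12)) break
    s0 <- s1
  }
  list(X = X, stress = s0)
}

#' Embed clones from their pairwise distance matrix
#'
#' Produces the three clone-level views used downstream: metric MDS
#' coordinates (SMACOF, the space in which clone pseudotime is inferred), a
#' diffusion map (Gaussian kernel on the clone distances, bandwidth = median
#' entry), a 2-D UMAP display, and the clone kNN affinity matrix V (binary,
#' union-symmetrized, unit diagonal) built in MDS space.
#'
#' @param D a \linkS4class{CloneDistance} (or symmetric matrix).
#' @param d target MDS/diffusion dimensionality (default 10, capped at
#'   M - 1).
#' @param kClone neighbours for the clone kNN graph (capped at M - 1);
#'   the default NULL scales with the clone count, min(15, max(4, M / 8)),
#'   so small clone sets keep a sparse, structure-preserving graph.
#' @param seed RNG seed (UMAP).
#' @param umap logical; compute the UMAP view (needs M > 4).
#' @return a \linkS4class{CloneEmbedding}.
#' @export
embedClones <- function(D, d = 10, kClone = NULL, seed = 1, umap = TRUE) {
  Dm <- if (is(D, "CloneDistance")) D@D else as.matrix(D)
  if (any(!is.finite(Dm))) {
    bad <- which(!is.finite(Dm), arr.ind = TRUE)
    stop("non-finite clone distances, e.g. pair (", bad[1, 1], ", ",
         bad[1, 2], ")")
  }
  M <- nrow(Dm)
  if (is.null(kClone)) kClone <- min(15L, max(4L, round(M / 8)))
  md <- .smacof(Dm, d)
  mds <- md$X
  rownames(mds) <- rownames(Dm)
  # diffusion map on a Gaussian kernel over the clone distances
  off <- Dm[upper.tri(Dm)]
  sigma <- stats::median(off)
  if (!is.finite(sigma) || sigma <= 0) sigma <- mean(off) + 1e-12
  K <- exp(-(Dm / sigma)^2)
  dm <- .diffusionComponents(K, nComp = min(d, M - 1L))
  diffusion <- dm$coords
  rownames(diffusion) <- rownames(Dm)
  um <- NULL
  if (umap && M > 4) {
    nn <- min(kClone, M - 1L)
    um <- uwot::umap(mds, n_neighbors = max(2L, nn), seed = seed,
                     n_threads = 1)
    rownames(um) <- rownames(Dm)
  }
  kk <- min(kClone, M - 1L)
  V <- .binaryKnnAffinity(mds, kk)
  dimnames(V) <- list(rownames(Dm), rownames(Dm))
  new("CloneEmbedding", mds = mds, diffusion = diffusion, umap = um,
      affinity = as(V, "dgCMatrix"),
      params = list(d = d, kClone = kClone, seed = seed,
                    stress = md$stress))
}

.binaryKnnAffinity <- function(X, k) {
  M <- nrow(X)
  nn <- RANN::nn2(X, k = min(k + 1L, M))
  idx <- nn$nn.idx[, -1L, drop = FALSE]
  i <- rep(seq_len(M), ncol(idx))
  j <- as.vector(idx)
  A <- Matrix::sparseMatrix(i = c(i, j, seq_len(M)),
                            j = c(j, i, seq_len(M)),
                            x = 1, dims = c(M, M), use.last.ij = FALSE)
  A@x[] <- 1   # union, binary, diagonal 1
  as(A, "CsparseMatrix")
}

# density-normalized diffusion components of a symmetric kernel
.diffusionComponents <- function(K, nComp) {
  q <- rowSums(K)
  K1 <- K / outer(q, q)
  r <- rowSums(K1)
  S <- K1 / outer(sqrt(r), sqrt(r))    # symmetric conjugate of the operator
  eig <- eigen(S, symmetric = TRUE)
  lambda <- eig$values
  psi <- eig$vectors / sqrt(r)         # right eigenvectors of the transition op
  keep <- seq.int(2L, min(nComp + 1L, length(lambda)))
  list(lambda = lambda[keep],
       coords = sweep(psi[, keep, drop = FALSE], 2, lambda[keep], "*"),
       psi = psi[, keep, drop = FALSE])
}

#' @rdname CloneDistance-class
#' @export
setMethod("distanceMatrix", "CloneDistance", function(x) x@D)

#' @rdname CloneEmbedding-class
#' @export
setMethod("cloneCoords", "CloneEmbedding", function(x, type = "mds") {
  switch(match.arg(type, c("mds", "diffusion", "umap")),
         mds = x@mds, diffusion = x@diffusion, umap = x@umap)
})

#' @rdname CloneEmbedding-class
#' @export
setMethod("cloneAffinity", "CloneEmbedding", function(x) x@affinity)

setMethod("show", "CloneDistance", function(object) {
  cat("CloneDistance (", object@method, "): ", nrow(object@D), " clones\n",
      sep = "")
})

setMethod("show", "CloneEmbedding", function(object) {
  cat("CloneEmbedding:", nrow(object@mds), "clones;",
      ncol(object@mds), "MDS dims; stress",
      format(object@params$stress, digits = 4), "\n")
})
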