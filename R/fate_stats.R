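#' Fate-driving gene test (soft-assignment nested F-test)
#'
#' Within a transcriptomic cluster, models gene expression along pseudotime
#' separately for the target profile a and the aggregated control profile b
#' (all other profiles), using the cell-to-profile probabilities to blend
#' the two mean functions:
#' \deqn{g(t_i) = P_{ia} B(t_i)\beta_a + P_{ib} B(t_i)\beta_b,}
#' with \eqn{B(t) = (1, t)} for \code{df = 1} (a B-spline basis with df
#' interior degrees for larger df).  The null model shares one
#' \eqn{\beta}: \eqn{g(t_i) = B(t_i)\beta}.  The nested-model F-test asks
#' whether the target profile's expression trend differs from the rest.
#' With hard assignments and df = 1 this is exactly the classical two-group
#' ANCOVA interaction F-test.
#'
#' @param expression genes x cells matrix (or a single numeric vector).
#' @param cellT per-cell pseudotime.
#' @param cellP N x S cell-to-profile matrix (or
#'   \linkS4class{ProfileAssignment}).
#' @param targetProfile column name or index of the target profile a.
#' @param cells optional logical/integer subset (the transcriptomic
#'   cluster); cells with zero profile mass or missing pseudotime are
#'   dropped automatically.
#' @param df spline degrees of freedom (1 = linear regression).
#' @param transform optional expression transform, "none" or "sqrt".
#' @return a \code{\link[S4Vectors]{DataFrame}} with one row per gene:
#'   F statistic, p-value, BH q-value, weighted Cohen's d and the counts
#'   used; genes whose design is rank-deficient get NA with a reason.
#' @export
fateGeneTest <- function(expression, cellT, cellP, targetProfile, cells = NULL,
                         df = 1, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  E <- if (is.null(dim(expression)))
    matrix(expression, nrow = 1, dimnames = list("gene1", NULL)) else
    as.matrix(expression)
  CP <- if (is(cellP, "ProfileAssignment")) cellP@cellP else as.matrix(cellP)
  if (is.character(targetProfile))
    targetProfile <- match(targetProfile, colnames(CP))
  if (is.null(cells)) cells <- seq_len(ncol(E))
  if (is.logical(cells)) cells <- which(cells)
  mass <- rowSums(CP)
  use <- cells[mass[cells] > 0 & !is.na(cellT[cells])]
  if (length(use) < 10)
    stop("need >= 10 cells with assignment mass in the cluster subset")
  Pa <- CP[use, targetProfile] / mass[use]
  if (sum(Pa) <= 0) stop("target profile has no mass in the subset")
  Pb <- 1 - Pa
  t <- cellT[use]
  B <- if (df == 1) cbind(1, t) else if (df == 2)
    cbind(1, t, t^2) else cbind(1, splines::bs(t, df = df))
  Xfull <- cbind(Pa * B, Pb * B)
  Xnull <- B
  dfFull <- qr(Xfull)$rank
  dfNull <- qr(Xnull)$rank
  nUse <- length(use)
  out <- S4Vectors::DataFrame(
    gene = rownames(E) %||% paste0("gene", seq_len(nrow(E))),
    F_stat = NA_real_, p_value = NA_real_, q_value = NA_real_,
    cohens_d = NA_real_, n_cells = nUse, df_spline = as.integer(df),
    note = NA_character_)
  if (dfFull <= dfNull) {
    out$note <- "rank-deficient design (all cells in one profile?)"
    return(out)
  }
  qf <- qr(Xfull)
  qn <- qr(Xnull)
  for (g in seq_len(nrow(E))) {
    y <- E[g, use]
    if (transform == "sqrt") y <- sqrt(pmax(y, 0))
    rssF <- sum(qr.resid(qf, y)^2)
    rssN <- sum(qr.resid(qn, y)^2)
    df1 <- dfFull - dfNull
    df2 <- nUse - dfFull
    if (df2 <= 0 || rssF <= 0) next
    Fg <- ((rssN - rssF) / df1) / (rssF / df2)
    out$F_stat[g] <- max(Fg, 0)
    out$p_value[g] <- stats::pf(max(Fg, 0), df1, df2, lower.tail = FALSE)
    out$cohens_d[g] <- weightedCohensD(y, Pa, Pb)
  }
  out$q_value <- fdrCorrect(out$p_value)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR correction
#'
#' Monotone step-up BH adjustment (a thin wrapper over
#' \code{stats::p.adjust}); NAs are passed through.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
fdrCorrect <- function(p) stats::p.adjust(p, method = "BH")

#' Weighted Cohen's d between two soft groups
#'
#' Effect size (mu_a - mu_b) / pooled SD with the cell-to-profile masses as
#' frequency weights; matches the unweighted Cohen's d exactly when weights
#' are replication counts.
#'
#' @param x numeric values (e.g. one gene's expression).
#' @param wa,wb non-negative weights for group a and b (same length as x).
#' @return signed effect size; +/-Inf (with a warning) when the pooled SD
#'   is zero.
#' @export
weightedCohensD <- function(x, wa, wb) {
  stopifnot(sum(wa) > 0, sum(wb) > 0)
  wm <- function(w) sum(w * x) / sum(w)
  wv <- function(w, mu) sum(w * (x - mu)^2) / (sum(w) - 1)
  ma <- wm(wa); mb <- wm(wb)
  va <- wv(wa, ma); vb <- wv(wb, mb)
  na <- sum(wa); nb <- sum(wb)
  pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  if (pooled <= 0) {
    warning("zero pooled SD; returning signed infinity")
    return(sign(ma - mb) * Inf)
  }
  (ma - mb) / pooled
}

#' Clone plasticity: trace of the assignment-weighted covariance
#'
#' For each clone, its column of Q is normalized to weights
#' \eqn{w_i = Q_{ik} / \sum_j Q_{jk}}, and the plasticity is the trace of
#' the weighted covariance of the member-cell embedding coordinates,
#' \eqn{v_k = \mathrm{tr}\,\Sigma_k} with
#' \eqn{\Sigma_k = \sum_i w_i (x_i - \mu_k)(x_i - \mu_k)^\top}.  It
#' measures how widely a clone spreads across cell states (embedding
#' units squared).
#'
#' @param embedding cells x D coordinate matrix (or a
#'   \linkS4class{CellDataset}).
#' @param Q assignment matrix (\linkS4class{CloneAssignment} or matrix).
#' @return \code{\link[S4Vectors]{DataFrame}} with clone_id, plasticity v,
#'   and the weighted mean coordinates; zero-mass clones are skipped with a
#'   warning.
#' @export
clonePlasticity <- function(embedding, Q) {
  X <- if (is(embedding, "CellDataset")) cellEmbedding(embedding) else
    as.matrix(embedding)
  Qm <- if (is(Q, "CloneAssignment")) Q@Q else as.matrix(Q)
  massOK <- colSums(Qm) > 0
  if (any(!massOK))
    warning("skipping zero-mass clone(s): ",
            paste(colnames(Qm)[!massOK], collapse = ", "))
  keep <- which(massOK)
  v <- numeric(length(keep))
  mu <- matrix(NA_real_, length(keep), ncol(X))
  for (idx in seq_along(keep)) {
    k <- keep[idx]
    w <- Qm[, k] / sum(Qm[, k])
    m <- colSums(w * X)
    cen <- sweep(X, 2, m)
    v[idx] <- sum(w * rowSums(cen^2))
    mu[idx, ] <- m
  }
  out <- S4Vectors::DataFrame(
    clone_id = colnames(Qm)[keep] %||% as.character(keep),
    plasticity = v)
  out$mean <- mu
  out
}

#' Binned-control module score
#'
#' Gene-set score per cell: all genes are binned into \code{nBins}
#' equal-frequency bins of average expression; for each gene of the set,
#' \code{nCtrl} control genes are drawn from the same bin; the score is the
#' mean expression of the set minus the mean expression of the pooled
#' controls, per cell.
#'
#' @param expression genes x cells matrix of (log) expression.
#' @param geneSet character vector of gene names; genes absent from the
#'   matrix are dropped with a warning.
#' @param nBins number of average-expression bins.
#' @param nCtrl controls drawn per set gene (capped at bin size).
#' @param seed RNG seed (control draws are random).
#' @return numeric score per cell.
#' @export
moduleScore <- function(expression, geneSet, nBins = 24, nCtrl = 100,
                        seed = 1) {
  E <- as.matrix(expression)
  present <- intersect(geneSet, rownames(E))
  if (!length(present)) stop("no gene of the set is present in the matrix")
  if (length(present) < length(geneSet))
    warning(length(geneSet) - length(present),
            " gene(s) of the set absent from the matrix; dropped")
  avg <- rowMeans(E)
  nBins <- min(nBins, length(unique(rank(avg, ties.method = "first"))))
  bins <- cut(rank(avg, ties.method = "first"), breaks = nBins,
              labels = FALSE)
  names(bins) <- rownames(E)
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    pool <- setdiff(names(bins)[bins == bins[g]], g)
    if (!length(pool)) pool <- g
    ctrl <- c(ctrl, sample(pool, min(nCtrl, length(pool))))
  }
  setMean <- colMeans(E[present, , drop = FALSE])
  if (!length(ctrl)) return(setMean)
  setMean - colMeans(E[ctrl, , drop = FALSE])
}

#' Label cells by whether their clone reaches terminal fates
#'
#' Baseline fate labelling: a clone "reaches" a fate when at least one of
#' its cells lies in one of the named terminal clusters; all cells of such
#' clones are labelled with that fate.
#'
#' @param cloneId per-cell clone labels (NA allowed).
#' @param clusterId per-cell cluster labels.
#' @param terminalClusters character vector of terminal cluster ids.
#' @return logical per cell: TRUE when the cell's clone reaches a terminal
#'   cluster, FALSE otherwise, NA for unlabelled cells.
#' @export
cloneFateGroups <- function(cloneId, clusterId, terminalClusters) {
  reach <- tapply(clusterId %in% terminalClusters, cloneId, any)
  out <- as.logical(reach[cloneId])
  out[is.na(cloneId)] <- NA
  out
}

.mnnKeep <- function(tA, tB, k) {
  if (!is.finite(k)) return(list(A = seq_along(tA), B = seq_along(tB)))
  k <- as.integer(k)
  dAB <- abs(outer(tA, tB, "-"))
  nnAB <- t(apply(dAB, 1, function(r) order(r)[seq_len(min(k, length(r)))]))
  nnBA <- t(apply(dAB, 2, function(r) order(r)[seq_len(min(k, length(r)))]))
  keepA <- logical(length(tA)); keepB <- logical(length(tB))
  for (a in seq_along(tA)) for (b in nnAB[a, ]) {
    if (a %in% nnBA[b, ]) { keepA[a] <- TRUE; keepB[b] <- TRUE }
  }
  list(A = which(keepA), B = which(keepB))
}

#' Baseline differential expression between fate groups
#'
#' The benchmark baseline: cells are hard-classified by whether their clone
#' reaches the target terminal fates, optionally filtered to the
#' time-overlapping subsets via top-k mutual nearest neighbours on a 1-D
#' time value (cells without a mutual neighbour are dropped), and each gene
#' is tested with Wilcoxon's rank-sum test, BH corrected.
#'
#' @param expression genes x cells matrix.
#' @param cells subset of cells (the target cluster); logical or indices.
#' @param group logical/2-level per-cell fate labels (see
#'   \code{\link{cloneFateGroups}}).
#' @param time per-cell time values for the MNN filter.
#' @param timeMatch apply the MNN time filter.
#' @param kMnn neighbours for the MNN filter (Inf disables filtering).
#' @return \code{\link[S4Vectors]{DataFrame}} with gene, p_value, q_value
#'   and the group sizes used.
#' @export
baselineDE <- function(expression, cells = NULL, group, time = NULL,
                       timeMatch = FALSE, kMnn = 10) {
  E <- as.matrix(expression)
  if (is.null(cells)) cells <- seq_len(ncol(E))
  if (is.logical(cells)) cells <- which(cells)
  g <- group[cells]
  keep <- !is.na(g)
  cells <- cells[keep]; g <- as.logical(g[keep])
  if (!any(g) || all(g)) stop("both fate groups must be nonempty")
  A <- cells[g]; B <- cells[!g]
  if (timeMatch) {
    if (is.null(time)) stop("timeMatch requires time values")
    kept <- .mnnKeep(time[A], time[B], kMnn)
    A <- A[kept$A]; B <- B[kept$B]
    if (!length(A) || !length(B))
      stop("a fate group became empty after MNN time filtering")
  }
  p <- apply(E[, c(A, B), drop = FALSE], 1, function(y) {
    ya <- y[seq_along(A)]; yb <- y[-seq_along(A)]
    if (length(unique(c(ya, yb))) == 1L) return(1)
    stats::wilcox.test(ya, yb, exact = FALSE)$p.value
  })
  S4Vectors::DataFrame(gene = rownames(E) %||% paste0("gene",
                                                      seq_len(nrow(E))),
                       p_value = p, q_value = fdrCorrect(p),
                       n_group_a = length(A), n_group_b = length(B))
}
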