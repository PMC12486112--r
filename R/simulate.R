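#' Fit trajectories through ordered cluster centroids
#'
#' Each trajectory is a natural cubic spline through the centroids of an
#' ordered cluster sequence, densely sampled and arc-length parameterized;
#' a two-cluster path degenerates to a straight segment.  Point-to-curve
#' distance and the relative projection position k(i, j) in [0, 1] are
#' computed against the dense sample.
#'
#' @param embedding cells x D coordinates (or a \linkS4class{CellDataset}).
#' @param clusterId per-cell cluster labels.
#' @param paths list of ordered cluster-id vectors (>= 2 clusters each).
#' @param profiles profile label per trajectory (recycled; default the
#'   path names or "profile1", "profile2", ...).
#' @param tMax upper bound of each trajectory's time range (recycled;
#'   ranges always start at 0).
#' @param nGrid dense-sample resolution.
#' @return list of \linkS4class{Trajectory} objects.
#' @export
fitTrajectories <- function(embedding, clusterId, paths, profiles = NULL,
                            tMax = 1, nGrid = 400) {
  X <- if (is(embedding, "CellDataset")) cellEmbedding(embedding) else
    as.matrix(embedding)
  if (is.null(names(paths)))
    names(paths) <- paste0("traj", seq_along(paths))
  if (is.null(profiles)) profiles <- names(paths)
  profiles <- rep_len(profiles, length(paths))
  tMax <- rep_len(tMax, length(paths))
  lapply(seq_along(paths), function(p) {
    path <- as.character(paths[[p]])
    if (length(path) < 2) stop("path '", names(paths)[p],
                               "' needs >= 2 clusters")
    cent <- t(vapply(path, function(cl) {
      idx <- which(!is.na(clusterId) & clusterId == cl)
      if (!length(idx)) stop("cluster '", cl, "' is empty")
      colMeans(X[idx, , drop = FALSE])
    }, numeric(ncol(X))))
    # chord-length parameter over centroids, natural spline per dimension
    chord <- c(0, cumsum(sqrt(rowSums(diff(cent)^2))))
    s <- seq(0, max(chord), length.out = nGrid)
    pts <- vapply(seq_len(ncol(X)), function(d)
      stats::spline(chord, cent[, d], xout = s, method = "natural")$y,
      numeric(nGrid))
    arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    arcFrac <- if (max(arc) > 0) arc / max(arc) else arc
    new("Trajectory", id = names(paths)[p], profile = profiles[p],
        path = path, points = pts, arcFrac = arcFrac, tMax = tMax[p])
  })
}

# distance and arc-fraction of every cell against one trajectory
.projectToTrajectory <- function(X, traj) {
  pts <- traj@points
  d2 <- outer(rowSums(X^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(X)), rowSums(pts^2)) - 2 * X %*% t(pts)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first")
  list(dis = sqrt(d2[cbind(seq_len(nrow(X)), nearest)]),
       k = traj@arcFrac[nearest])
}

#' Soft profile probabilities from trajectory distances
#'
#' For each profile, takes the minimum distance of each cell to the
#' profile's trajectories and converts distances to probabilities by a
#' softmax over negative distances:
#' \eqn{P_i(\mathrm{profile}) \propto e^{-\min_j \mathrm{dis}(i, j)}}.
#'
#' @param embedding cells x D coordinates (or \linkS4class{CellDataset}).
#' @param trajectories list of \linkS4class{Trajectory} (>= 2 profiles).
#' @return N x (number of profiles) probability matrix, rows sum to one.
#' @export
assignProfileProbabilities <- function(embedding, trajectories) {
  X <- if (is(embedding, "CellDataset")) cellEmbedding(embedding) else
    as.matrix(embedding)
  prof <- vapply(trajectories, function(tr) tr@profile, character(1))
  uprof <- unique(prof)
  if (length(uprof) < 2) stop("need trajectories from >= 2 profiles")
  dis <- vapply(trajectories, function(tr) .projectToTrajectory(X, tr)$dis,
                numeric(nrow(X)))
  minDis <- vapply(uprof, function(pf)
    do.call(pmin, as.data.frame(dis[, prof == pf, drop = FALSE])),
    numeric(nrow(X)))
  w <- exp(minDis * -1)
  P <- w / rowSums(w)
  colnames(P) <- uprof
  P
}

#' Assign per-cell times from trajectory projections
#'
#' The time of cell i is the softmax-weighted average of its projected
#' positions over all trajectories:
#' \deqn{t_i = \sum_j \frac{e^{-\mathrm{dis}(i,j)}}{\sum_l
#'   e^{-\mathrm{dis}(i,l)}} \, k(i,j) \, T_j,}
#' where k(i, j) is the arc-length fraction of the projection and T_j the
#' trajectory's time-range upper bound (a cell at the end of a trajectory
#' with range [0, 0.8] gets time 0.8).
#'
#' @param embedding cells x D coordinates (or \linkS4class{CellDataset}).
#' @param trajectories list of \linkS4class{Trajectory}.
#' @return numeric time per cell in [0, max T_j].
#' @export
assignTimes <- function(embedding, trajectories) {
  X <- if (is(embedding, "CellDataset")) cellEmbedding(embedding) else
    as.matrix(embedding)
  proj <- lapply(trajectories, function(tr) .projectToTrajectory(X, tr))
  dis <- vapply(proj, `[[`, numeric(nrow(X)), "dis")
  kk <- vapply(proj, `[[`, numeric(nrow(X)), "k")
  tj <- vapply(trajectories, function(tr) tr@tMax, numeric(1))
  w <- exp(-dis)
  w <- w / rowSums(w)
  rowSums(w * sweep(kk, 2, tj, "*"))
}

#' Generate clones by time-kernel sampling within profiles
#'
#' Each cell first draws a hard profile label from its soft profile
#' probabilities.  Within each profile, clones are generated by iterative
#' sampling without replacement: a random remaining cell becomes the clone
#' center; with t its time, the clone size is one draw from an exponential
#' distribution with mean \code{meanBase * meanFactor^t} (rounded up), and
#' that many remaining same-profile cells are sampled with probabilities
#' proportional to the Normal(t, 0.1 t + 0.05) density of their times.
#' Sampled cells are removed from the pool; the iteration stops when a
#' drawn size exceeds the remaining pool (leaving those cells unassigned,
#' which mirrors real data where many cells are not in expanded clones).
#'
#' @param profileProb N x P soft profile probabilities.
#' @param cellTime per-cell simulated times.
#' @param seed RNG seed.
#' @param meanBase,meanFactor exponential-mean law parameters (mean clone
#'   size = meanBase * meanFactor^t, default 15 * 10^t).
#' @param sdSlope,sdIntercept time-kernel SD law (sd = sdSlope t +
#'   sdIntercept, default 0.1 t + 0.05).
#' @return list with \code{cloneId} (per cell, NA when unassigned),
#'   \code{cloneProfile} (named character) and \code{hardProfile} (per
#'   cell).
#' @export
generateClones <- function(profileProb, cellTime, seed = 1, meanBase = 15,
                           meanFactor = 10, sdSlope = 0.1,
                           sdIntercept = 0.05) {
  set.seed(seed)
  P <- as.matrix(profileProb)
  n <- nrow(P)
  profs <- colnames(P) %||% paste0("profile", seq_len(ncol(P)))
  colnames(P) <- profs
  cum <- P / rowSums(P)
  if (ncol(cum) > 1)
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
  hard <- profs[max.col(cum >= stats::runif(n), ties.method = "first")]
  cloneId <- rep(NA_character_, n)
  cloneProfile <- character(0)
  counter <- 0L
  for (pf in profs) {
    pool <- which(hard == pf)
    while (length(pool) > 0) {
      center <- if (length(pool) == 1) pool else sample(pool, 1)
      t0 <- cellTime[center]
      size <- ceiling(stats::rexp(1, rate = 1 / (meanBase *
                                                   meanFactor^t0)))
      if (size > length(pool)) break
      wts <- stats::dnorm(cellTime[pool], mean = t0,
                          sd = sdSlope * t0 + sdIntercept) + 1e-300
      members <- if (size == length(pool)) pool else
        c(center, sample(setdiff(pool, center), size - 1L,
                         prob = wts[match(setdiff(pool, center), pool)]))
      counter <- counter + 1L
      id <- sprintf("%s_clone%03d", pf, counter)
      cloneId[members] <- id
      cloneProfile[id] <- pf
      pool <- setdiff(pool, members)
    }
  }
  list(cloneId = cloneId, cloneProfile = cloneProfile, hardProfile = hard)
}

#' Self-contained synthetic lineage-tracing fixture
#'
#' Generates a branching (or boomerang) cell embedding with Gaussian noise,
#' cluster labels, trajectory-derived ground-truth profile probabilities
#' and times, clones drawn by the exponential-size / Gaussian-time-kernel
#' protocol, and an expression matrix with planted fate-biased genes
#' (mean-shifted in the bipotent profile before the divergence point).
#'
#' Topologies: \code{"bifurcation"} — a trunk splitting into two fate
#' branches, with a bipotent profile (trajectories to both fates) and a
#' unipotent profile (one fate); \code{"three_branch"} — same with a third,
#' spatially separate unipotent branch; \code{"boomerang"} — a single arc
#' whose late end returns close to (but short of) the start, the planted
#' reversal that breaks transcriptome-proximity pseudotime.
#'
#' @param nCells number of cells (>= 100).
#' @param topology fixture shape.
#' @param noiseSd Gaussian noise SD around the branch curves (embedding
#'   units; curves have unit-order scale ~10).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param nGenes,nPlanted,effectSize expression layer controls.
#' @return list with \code{dataset} (a \linkS4class{CellDataset} with clone,
#'   cluster and timepoint labels), \code{truth} (a \linkS4class{SimTruth})
#'   and \code{trajectories}.
#' @export
syntheticFixture <- function(nCells,
                             topology = c("bifurcation", "boomerang",
                                          "three_branch"),
                             noiseSd = 0.15, seed = 1, nGenes = 120,
                             nPlanted = 12, effectSize = 0.8) {
  topology <- match.arg(topology)
  stopifnot(nCells >= 100)
  set.seed(seed)
  if (topology %in% c("bifurcation", "three_branch")) {
    # cell density grows ~10^t along the trajectory, matching the 10^t
    # clone-size growth law: sampling is proportional to the expanding
    # population a barcoding experiment draws from
    u <- log10(1 + 9 * stats::runif(nCells))
    trunkLen <- 1.5
    brLen <- sqrt(3.5^2 + 7^2)
    total <- trunkLen + brLen
    tDiv <- trunkLen / total
    nBranch <- if (topology == "three_branch") 3L else 2L
    branch <- sample.int(nBranch, nCells, replace = TRUE)
    dirs <- rbind(c(3.5, 7), c(3.5, -7), c(-5, 0))[seq_len(nBranch), ,
                                                   drop = FALSE]
    dirs <- dirs / sqrt(rowSums(dirs^2))
    base <- t(vapply(seq_len(nCells), function(i) {
      s <- u[i] * total
      if (s <= trunkLen) c(s, 0) else
        c(trunkLen, 0) + (s - trunkLen) * dirs[branch[i], ]
    }, numeric(2)))
    cluster <- ifelse(u <= tDiv, "0",
                      paste0(2 * branch - ifelse(u <= tDiv + (1 - tDiv) / 2,
                                                 1, 0)))
    emb <- base + matrix(stats::rnorm(2 * nCells, sd = noiseSd), ncol = 2)
    pathsOf <- function(b) c("0", 2 * b - 1, 2 * b)
    if (topology == "bifurcation") {
      paths <- list(x = pathsOf(1), y = pathsOf(2), z = pathsOf(2))
      profiles <- c("bipotent", "bipotent", "unipotent")
    } else {
      paths <- list(x = pathsOf(1), y = pathsOf(2), z = pathsOf(3))
      profiles <- c("bipotent", "bipotent", "unipotent")
    }
    trajs <- fitTrajectories(emb, cluster, paths, profiles, tMax = 1)
  } else {                               # boomerang: out-and-back hairpin
    u <- stats::runif(nCells)
    armLen <- 6; gap <- 2
    turn <- pi * gap / 2                 # semicircular turn of radius gap/2
    total <- 2 * armLen + turn
    s <- u * total
    base <- t(vapply(s, function(si) {
      if (si <= armLen) c(si, 0)
      else if (si <= armLen + turn) {
        phi <- (si - armLen) / (gap / 2)  # 0..pi around the turn
        c(armLen + (gap / 2) * sin(phi), (gap / 2) * (1 - cos(phi)))
      } else c(armLen - (si - armLen - turn), gap)
    }, numeric(2)))
    cluster <- as.character(pmin(floor(u * 6), 5))
    emb <- base + matrix(stats::rnorm(2 * nCells, sd = noiseSd), ncol = 2)
    trajs <- fitTrajectories(emb, cluster,
                             paths = list(main = as.character(0:5)),
                             profiles = "main", tMax = 1, nGrid = 600)
    # a single lineage: profile probabilities degenerate to one column
  }
  if (topology == "boomerang") {
    prob <- matrix(1, nCells, 1, dimnames = list(NULL, "main"))
  } else {
    prob <- assignProfileProbabilities(emb, trajs)
  }
  tt <- assignTimes(emb, trajs)
  cl <- generateClones(prob, tt, seed = seed + 1L)
  # expression layer: smooth baseline in time + planted pre-divergence shift
  geneNames <- sprintf("g%03d", seq_len(nGenes))
  a <- stats::rnorm(nGenes)
  b <- stats::runif(nGenes, -0.3, 0.3)   # mild drift: gene dynamics are
  # assumed simple within the short time frame of a cluster
  E <- outer(a, rep(1, nCells)) + outer(b, tt) +
    matrix(stats::rnorm(nGenes * nCells, sd = 0.5), nGenes, nCells)
  planted <- character(0)
  if (topology != "boomerang" && nPlanted > 0) {
    # early fate-bias genes: mean shift in bipotent-profile cells, full
    # strength before the fate divergence and decaying smoothly through
    # commitment (logistic switch-off centered at t = 0.4)
    planted <- geneNames[seq_len(nPlanted)]
    hit <- cl$hardProfile == "bipotent"
    shift <- effectSize * stats::plogis(-(tt - 0.4) / 0.1)
    E[seq_len(nPlanted), hit] <- E[seq_len(nPlanted), hit] +
      rep(shift[hit], each = nPlanted)
  }
  dimnames(E) <- list(geneNames, sprintf("cell%05d", seq_len(nCells)))
  epoch <- paste0("e", pmin(floor(tt / max(tt) * 3) + 1, 3))
  dataset <- CellDataset(E, emb, cloneId = cl$cloneId, clusterId = cluster,
                         timepoint = epoch)
  truth <- new("SimTruth", cellProfileProb = prob, cellTime = tt,
               cloneId = cl$cloneId, cloneProfile = cl$cloneProfile,
               plantedGenes = planted)
  list(dataset = dataset, truth = truth, trajectories = trajs)
}

#' Area under the ROC curve of a score against binary labels
#'
#' Rank-based (Mann-Whitney) AUROC; ties share ranks.
#'
#' @param score numeric score, higher = more likely positive.
#' @param positive logical labels.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(score, positive) {
  positive <- as.logical(positive)
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0) stop("need both classes")
  r <- rank(score)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Majority-mapping accuracy of inferred clone profiles
#'
#' Maps every inferred profile to the most frequent true label among its
#' clones and reports the fraction of clones whose mapped label matches the
#' truth (standard clustering accuracy).
#'
#' @param inferred named (by clone) inferred profile labels.
#' @param truth named true labels (e.g. SimTruth cloneProfile), matched by
#'   clone name.
#' @return accuracy in [0, 1].
#' @export
cloneProfileAccuracy <- function(inferred, truth) {
  common <- intersect(names(inferred), names(truth))
  if (!length(common)) stop("no overlapping clone names")
  inf <- inferred[common]; tru <- truth[common]
  mapped <- vapply(split(tru, inf), function(v)
    names(sort(table(v), decreasing = TRUE))[1], character(1))
  mean(mapped[inf] == tru)
}

#' Compare inferred results against simulation ground truth
#'
#' Computes (i) the Pearson correlation, per truth lineage, between the
#' summed inferred cell-to-profile mass of the mapped profiles and the true
#' lineage probability; (ii) the Spearman correlation of inferred cell
#' pseudotime with true time; (iii) precision/recall/F1 of a detected gene
#' list against the planted genes.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param cellP inferred N x S cell-to-profile matrix (or
#'   \linkS4class{ProfileAssignment}); optional.
#' @param profileMap named list: truth lineage -> character vector of
#'   inferred profile columns (required with cellP).
#' @param cellT inferred per-cell pseudotime; optional.
#' @param detectedGenes character vector of detected genes; optional.
#' @return list with profileCor, timeSpearman and geneMetrics entries (NULL
#'   when the corresponding input is absent).
#' @export
evaluateAgainstTruth <- function(truth, cellP = NULL, profileMap = NULL,
                                 cellT = NULL, detectedGenes = NULL) {
  out <- list(profileCor = NULL, timeSpearman = NULL, geneMetrics = NULL)
  if (!is.null(cellP)) {
    if (is.null(profileMap) || !length(profileMap))
      stop("profileMap is required (truth lineage -> inferred profiles)")
    CP <- if (is(cellP, "ProfileAssignment")) cellP@cellP else
      as.matrix(cellP)
    mass <- rowSums(CP)
    ok <- mass > 0
    out$profileCor <- vapply(names(profileMap), function(lin) {
      cols <- intersect(profileMap[[lin]], colnames(CP))
      stats::cor(rowSums(CP[ok, cols, drop = FALSE]) / mass[ok],
                 truth@cellProfileProb[ok, lin])
    }, numeric(1))
  }
  if (!is.null(cellT)) {
    ok <- !is.na(cellT)
    out$timeSpearman <- stats::cor(cellT[ok], truth@cellTime[ok],
                                   method = "spearman")
  }
  if (!is.null(detectedGenes)) {
    tp <- length(intersect(detectedGenes, truth@plantedGenes))
    fp <- length(setdiff(detectedGenes, truth@plantedGenes))
    fn <- length(setdiff(truth@plantedGenes, detectedGenes))
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out$geneMetrics <- list(TP = tp, FP = fp, FN = fn, precision = prec,
                            recall = rec, F1 = f1)
  }
  out
}
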