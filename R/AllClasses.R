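#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t Diagonal drop0 diag diag<-
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim reducedDim<-
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' CellDataset: cells with embedding, expression and clonal metadata
#'
#' A thin extension of \linkS4class{SingleCellExperiment}: the expression
#' matrix (genes x cells, normalized log counts) is stored as the
#' \code{"logcounts"} assay, the low-dimensional cell embedding (cells x D,
#' e.g. PCA coordinates) as the \code{"embedding"} reduced dimension, and the
#' clonal metadata (\code{clone_id}, \code{cluster_id}, \code{timepoint},
#' \code{sample_id}) as \code{colData} columns.  Cells without a clone label
#' carry \code{NA}.
#'
#' @section Validity:
#' The embedding must exist, be all-finite, and have at least two columns;
#' there must be at least one cell.
#'
#' @export
setClass("CellDataset", contains = "SingleCellExperiment")

setValidity("CellDataset", function(object) {
  if (ncol(object) < 1L) return("dataset must contain at least one cell")
  sce <- as(object, "SingleCellExperiment")   # plain-class accessors avoid
  rd <- SingleCellExperiment::reducedDimNames(sce)  # validity recursion
  if (!("embedding" %in% rd))
    return("reducedDim 'embedding' is required")
  emb <- reducedDim(sce, "embedding")
  if (ncol(emb) < 2L) return("embedding must have >= 2 dimensions")
  if (!all(is.finite(emb)))
    return("embedding contains non-finite entries")
  TRUE
})

#' CloneTable: expanded clones and their member cells
#'
#' Holds the M clones that pass the expansion threshold (default 10 cells),
#' their sizes and the (1-based) indices of their member cells.  Member lists
#' are disjoint by construction.
#'
#' @slot cloneId character vector of clone labels (length M).
#' @slot cloneSizes integer vector of member counts.
#' @slot members list of integer vectors of cell indices.
#' @slot expandedThreshold the minimum clone size used for the filter.
#' @slot nCellsTotal number of cells in the parent dataset.
#' @export
setClass("CloneTable",
  representation(cloneId = "character", cloneSizes = "integer",
                 members = "list", expandedThreshold = "integer",
                 nCellsTotal = "integer"))

setValidity("CloneTable", function(object) {
  M <- length(object@cloneId)
  if (length(object@cloneSizes) != M || length(object@members) != M)
    return("cloneId, cloneSizes and members must have equal length")
  if (M && any(object@cloneSizes < object@expandedThreshold))
    return("all clone sizes must be >= expandedThreshold")
  if (M && any(lengths(object@members) != object@cloneSizes))
    return("member list lengths must match cloneSizes")
  idx <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(idx)) return("clone member lists must be disjoint")
  if (length(idx) && (min(idx) < 1L || max(idx) > object@nCellsTotal))
    return("member indices out of range")
  TRUE
})

#' CellGraph: symmetrized kNN graph over cells
#'
#' @slot k number of neighbours requested.
#' @slot adjacency sparse symmetric N x N matrix of Euclidean edge lengths
#'   (zero diagonal; a stored entry is an edge).
#' @slot affinity sparse row-stochastic N x N matrix W used for label
#'   propagation (rows sum to one).
#' @slot components integer vector of connected-component membership.
#' @export
setClass("CellGraph",
  representation(k = "integer", adjacency = "dgCMatrix",
                 affinity = "dgCMatrix", components = "integer"))

setValidity("CellGraph", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
  rs <- Matrix::rowSums(object@affinity)
  if (any(abs(rs[rs > 0] - 1) > 1e-9))
    return("affinity rows must sum to 1")
  TRUE
})

#' CloneAssignment: cell-to-clone soft assignment matrix Q
#'
#' The N x M matrix Q of soft cell-to-clone assignment probabilities, tagged
#' with its processing stage: \code{initial} (seeded from clone membership),
#' \code{propagated} (after label propagation), \code{filtered} (after the
#' bootstrap confidence filter zeroed unstable rows) or \code{thresholded}
#' (after top-mass thresholding and row renormalization).
#'
#' @slot Q numeric matrix, N x M, non-negative; columns named by clone.
#' @slot stage character, one of initial/propagated/filtered/thresholded.
#' @slot alpha the smoothing parameter used for propagation (NA for initial).
#' @slot confident logical N-vector from the bootstrap filter.
#' @slot divergence numeric N-vector of bootstrap divergences (NA before).
#' @export
setClass("CloneAssignment",
  representation(Q = "matrix", stage = "character", alpha = "numeric",
                 confident = "logical", divergence = "numeric"))

setValidity("CloneAssignment", function(object) {
  if (any(object@Q < 0)) return("Q entries must be non-negative")
  if (!object@stage %in% c("initial", "propagated", "filtered", "thresholded"))
    return("unknown stage")
  if (object@stage == "thresholded") {
    rs <- rowSums(object@Q)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      return("thresholded rows with mass must sum to 1")
  }
  if (object@stage == "initial" &&
      any(rowSums(object@Q > 0) > 1L))
    return("initial rows may have at most one nonzero")
  TRUE
})

#' CloneDistance: pairwise clone-to-clone distance matrix
#'
#' @slot D symmetric M x M non-negative matrix of earth-mover distances.
#' @slot method "exact_emd" or "approx".
#' @slot params list of parameters used (x, k for the approximation).
#' @export
setClass("CloneDistance",
  representation(D = "matrix", method = "character", params = "list"))

setValidity("CloneDistance", function(object) {
  D <- object@D
  if (nrow(D) != ncol(D)) return("D must be square")
  if (any(abs(diag(D)) > 1e-12)) return("D diagonal must be zero")
  if (max(abs(D - t(D))) > 1e-8) return("D must be symmetric")
  if (any(D < 0)) return("D must be non-negative")
  TRUE
})

#' CloneEmbedding: low-dimensional clone coordinates and clone kNN graph
#'
#' @slot mds M x d metric MDS coordinates (the space used for pseudotime).
#' @slot diffusion M x d diffusion-map coordinates.
#' @slot umap M x 2 UMAP display coordinates (may be NULL for tiny M).
#' @slot affinity sparse M x M clone kNN affinity V (binary, unit diagonal).
#' @slot params list (d, kClone, seed, stress).
#' @export
setClass("CloneEmbedding",
  representation(mds = "matrix", diffusion = "matrix",
                 umap = "matrixOrNULL", affinity = "dgCMatrix",
                 params = "list"))

#' ProfileAssignment: clone-to-profile and cell-to-profile memberships
#'
#' @slot P M x S clone-to-profile matrix; rows sum to one (one-hot for
#'   Leiden clustering).
#' @slot cellP N x S cell-to-profile matrix QP; zero Q rows stay zero.
#' @export
setClass("ProfileAssignment",
  representation(P = "matrix", cellP = "matrix"))

setValidity("ProfileAssignment", function(object) {
  if (any(abs(rowSums(object@P) - 1) > 1e-9))
    return("P rows must sum to 1")
  rs <- rowSums(object@cellP)
  if (any(abs(rs[rs > 1e-12] - 1) > 1e-6))
    return("nonzero cellP rows must sum to 1")
  TRUE
})

#' PseudotimeResult: clone-level and projected cell-level pseudotime
#'
#' @slot cloneT named numeric vector in [0, 1]; the root clone is 0.
#' @slot cellT numeric per-cell pseudotime Q T (NA for unassigned cells).
#' @slot root clone id used as the diffusion root.
#' @export
setClass("PseudotimeResult",
  representation(cloneT = "numeric", cellT = "numeric", root = "character"))

setValidity("PseudotimeResult", function(object) {
  if (!object@root %in% names(object@cloneT))
    return("root must be one of the clones")
  if (abs(object@cloneT[[object@root]]) > 1e-12)
    return("root clone pseudotime must be 0")
  TRUE
})

#' EnrichmentResult: profile-by-cell-type permutation enrichment
#'
#' @slot observed S x K matrix of observed cell-to-profile mass per cell type.
#' @slot pValue S x K matrix of one-sided empirical p-values.
#' @slot qValue S x K matrix of BH-adjusted p-values.
#' @slot nPerm number of permutations.
#' @export
setClass("EnrichmentResult",
  representation(observed = "matrix", pValue = "matrix", qValue = "matrix",
                 nPerm = "integer"))

#' SimTruth: ground truth emitted by the simulator
#'
#' @slot cellProfileProb N x (number of profiles) matrix of true soft profile
#'   probabilities (rows sum to one).
#' @slot cellTime true per-cell time in [0, max T].
#' @slot cloneId per-cell clone label (NA when unassigned).
#' @slot cloneProfile named character: true profile of each clone.
#' @slot plantedGenes character vector of fate-biased gene names.
#' @export
setClass("SimTruth",
  representation(cellProfileProb = "matrix", cellTime = "numeric",
                 cloneId = "character", cloneProfile = "character",
                 plantedGenes = "character"))

setValidity("SimTruth", function(object) {
  if (any(abs(rowSums(object@cellProfileProb) - 1) > 1e-9))
    return("cellProfileProb rows must sum to 1")
  if (length(object@cellTime) != nrow(object@cellProfileProb))
    return("cellTime length mismatch")
  TRUE
})

#' Trajectory: arc-length parameterized spline through cluster centroids
#'
#' @slot id trajectory identifier.
#' @slot profile profile the trajectory belongs to.
#' @slot path ordered cluster ids the spline interpolates.
#' @slot points dense sample of the curve (grid x D).
#' @slot arcFrac arc-length fraction in [0, 1] at each grid point.
#' @slot tMax upper bound of the trajectory's time range.
#' @export
setClass("Trajectory",
  representation(id = "character", profile = "character", path = "character",
                 points = "matrix", arcFrac = "numeric", tMax = "numeric"))
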