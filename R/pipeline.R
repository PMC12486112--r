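#' Run the full clone-informed analysis pipeline
#'
#' Convenience wrapper chaining the stages: expanded-clone filtering, cell
#' kNN graph, label-propagated clone densities (with bootstrap confidence
#' filtering and thresholding), clone distance matrix, clone embedding,
#' Leiden clonotype profiles, cell projection, and clone-informed
#' pseudotime.
#'
#' @param dataset a \linkS4class{CellDataset} with clone labels.
#' @param minCells expansion threshold.
#' @param k cell-graph neighbours.
#' @param alpha,beta,nBoot,mass density-stage parameters.
#' @param distanceMethod "auto", "exact" or "approx".
#' @param x,kApprox approximation parameters.
#' @param d,kClone embedding parameters.
#' @param resolution,nProfiles Leiden controls.
#' @param rootClone,rootCondition pseudotime root (clone id, or the
#'   timepoint whose most-enriched clone roots the trajectory); when both
#'   are NULL pseudotime is skipped.
#' @param seed RNG seed for every stochastic stage.
#' @param umap compute the clone UMAP view.
#' @return list with clones, graph, assignment, distance, embedding,
#'   profiles and pseudotime (NULL when skipped).
#' @export
runClonotrace <- function(dataset, minCells = 10, k = 30, alpha = 0.5,
                          beta = 0.2, nBoot = 20, mass = 0.9,
                          distanceMethod = "auto", x = 50, kApprox = 5,
                          d = 10, kClone = NULL, resolution = 1,
                          nProfiles = NULL, rootClone = NULL,
                          rootCondition = NULL, seed = 1, umap = TRUE) {
  clones <- filterExpandedClones(dataset, minCells = minCells)
  dens <- cloneDensity(dataset, clones, k = k, alpha = alpha, beta = beta,
                       nBoot = nBoot, mass = mass, seed = seed)
  dist <- cloneDistanceMatrix(dens$assignment, dens$graph,
                              method = distanceMethod, x = x, k = kApprox,
                              clones = clones)
  emb <- embedClones(dist, d = d, kClone = kClone, seed = seed, umap = umap)
  prof <- clusterProfiles(emb, resolution = resolution,
                          nProfiles = nProfiles, seed = seed)
  prof <- projectProfilesToCells(dens$assignment, prof)
  pt <- NULL
  if (!is.null(rootClone) || !is.null(rootCondition)) {
    pt <- clonePseudotime(emb, root = rootClone,
                          rootCondition = rootCondition,
                          Q = dens$assignment,
                          timepoint = timepoints(dataset))
    pt <- cellPseudotime(dens$assignment, pt)
  }
  list(clones = clones, graph = dens$graph, assignment = dens$assignment,
       distance = dist, embedding = emb, profiles = prof, pseudotime = pt)
}
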