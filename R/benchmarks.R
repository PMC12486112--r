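#' End-to-end recovery benchmark on the bifurcation fixture
#'
#' Generates the branching fixture, runs the full pipeline (densities,
#' clone distances, embedding, Leiden profiles, clone-informed pseudotime),
#' maps each inferred profile to its majority true potency, and scores
#' (i) clone-level bipotent/unipotent accuracy, (ii) the AUROC of the
#' fate-gene F-test for the planted early-bias genes (tested in the
#' divergence-region clusters, trunk + early shared branch), and (iii) the
#' Spearman correlation of the clone-informed cell pseudotime with true
#' simulated time.  Also runs the Wilcoxon baseline on the same cells for
#' comparison.
#'
#' @param nCells fixture size (default 5000).
#' @param seed fixture and pipeline RNG seed.
#' @param nProfiles Leiden target profile count (default 8).
#' @param df spline degrees of freedom for the fate test.
#' @return list with accuracy, fateAuroc, baselineAuroc, timeSpearman,
#'   nClones, nProfiles, fateTable and the pipeline result.
#' @export
benchmarkBifurcation <- function(nCells = 5000, seed = 0, nProfiles = 8,
                                 df = 1) {
  fx <- syntheticFixture(nCells, "bifurcation", seed = seed)
  d <- fx$dataset
  res <- suppressWarnings(runClonotrace(
    d, umap = FALSE, distanceMethod = "approx", nProfiles = nProfiles,
    rootCondition = "e1", seed = seed + 1))
  P <- profileMatrix(res$profiles)
  inferred <- stats::setNames(colnames(P)[max.col(P)], rownames(P))
  truth <- fx$truth@cloneProfile
  accuracy <- cloneProfileAccuracy(inferred, truth)
  # aggregate inferred profiles into the two potency groups by majority
  mapped <- vapply(split(truth[names(inferred)], inferred), function(v)
    names(sort(table(v), decreasing = TRUE))[1], character(1))
  CP <- cellProfiles(res$profiles)
  agg <- cbind(
    bipotent = rowSums(CP[, names(mapped)[mapped == "bipotent"],
                          drop = FALSE]),
    unipotent = rowSums(CP[, names(mapped)[mapped == "unipotent"],
                           drop = FALSE]))
  cellT <- cellPseudotimes(res$pseudotime)
  E <- as.matrix(SummarizedExperiment::assay(d, "logcounts"))
  divergenceCells <- clusterIds(d) %in% c("0", "3")
  ft <- fateGeneTest(E, cellT, agg, "bipotent", cells = divergenceCells,
                     df = df)
  planted <- ft$gene %in% fx$truth@plantedGenes
  fateAuroc <- aurocScore(ft$F_stat, planted)
  # baseline: clone-reaches-terminal-fate Wilcoxon with MNN time matching
  grp <- cloneFateGroups(cloneIds(d), clusterIds(d),
                         terminalClusters = "2")   # branch-A terminal
  bl <- tryCatch(
    baselineDE(E, cells = divergenceCells, group = grp, time = cellT,
               timeMatch = TRUE, kMnn = 10),
    error = function(e) NULL)
  baselineAuroc <- if (is.null(bl)) NA_real_ else
    aurocScore(-log10(pmax(bl$p_value, 1e-300)),
               bl$gene %in% fx$truth@plantedGenes)
  ev <- evaluateAgainstTruth(fx$truth, cellT = cellT)
  list(accuracy = accuracy, fateAuroc = fateAuroc,
       baselineAuroc = baselineAuroc, timeSpearman = ev$timeSpearman,
       nClones = nClones(res$clones), nProfiles = ncol(P),
       fateTable = ft, pipeline = res, fixture = fx)
}

#' Pseudotime repair benchmark on the boomerang fixture
#'
#' Generates the out-and-back fixture whose late cells return near the
#' start of the trajectory, runs the clone-informed pipeline, and compares
#' the clone-informed cell pseudotime against classic dense-kernel
#' diffusion pseudotime computed directly on the cell coordinates: the
#' former should order the three sampling epochs correctly while the
#' latter is fooled by the planted transcriptomic reversal.
#'
#' @param nCells fixture size (default 1500).
#' @param seed RNG seed.
#' @return list with cloneInformedSpearman, transcriptomicSpearman,
#'   epochMeans, nClones and the pipeline result.
#' @export
benchmarkBoomerang <- function(nCells = 1500, seed = 0) {
  fx <- syntheticFixture(nCells, "boomerang", seed = seed, nGenes = 50,
                         nPlanted = 0)
  d <- fx$dataset
  epoch <- as.integer(factor(timepoints(d)))
  res <- suppressWarnings(runClonotrace(
    d, umap = FALSE, distanceMethod = "approx", rootCondition = "e1",
    seed = seed + 1))
  cellT <- cellPseudotimes(res$pseudotime)
  ok <- !is.na(cellT)
  ci <- stats::cor(cellT[ok], epoch[ok], method = "spearman")
  dpt <- diffusionPseudotime(cellEmbedding(d),
                             root = which.min(fx$truth@cellTime))
  tr <- stats::cor(dpt, epoch, method = "spearman")
  list(cloneInformedSpearman = ci, transcriptomicSpearman = tr,
       epochMeans = tapply(cellT[ok], epoch[ok], mean),
       nClones = nClones(res$clones), pipeline = res, fixture = fx)
}
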