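#' Construct a CellDataset
#'
#' @param expression genes x cells matrix of normalized log counts (dense or
#'   sparse).  Column names are cell barcodes, row names gene ids.
#' @param embedding cells x D numeric matrix of low-dimensional cell
#'   coordinates (e.g. PCA); must be all-finite with D >= 2.
#' @param cloneId,clusterId,timepoint,sampleId optional per-cell labels;
#'   recycled NA when absent.  Cells with missing clone label are retained.
#' @return a validated \linkS4class{CellDataset}.
#' @examples
#' expr <- matrix(rpois(20, 2), 4, 5,
#'                dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' emb <- matrix(rnorm(10), 5, 2)
#' cd <- CellDataset(expr, emb, cloneId = c("A", "A", NA, "B", "B"))
#' nCells(cd)
#' @export
CellDataset <- function(expression, embedding, cloneId = NULL,
                        clusterId = NULL, timepoint = NULL, sampleId = NULL) {
  expression <- as(expression, "CsparseMatrix")
  embedding <- as.matrix(embedding)
  if (ncol(expression) != nrow(embedding))
    stop("expression has ", ncol(expression), " cells but embedding has ",
         nrow(embedding), " rows")
  n <- ncol(expression)
  pad <- function(v) {
    if (is.null(v)) return(rep(NA_character_, n))
    if (length(v) != n) stop("metadata length does not match cell count")
    as.character(v)
  }
  cd <- DataFrame(clone_id = pad(cloneId), cluster_id = pad(clusterId),
                  timepoint = pad(timepoint), sample_id = pad(sampleId))
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("cell", seq_len(n))
  rownames(cd) <- colnames(expression)
  rownames(embedding) <- colnames(expression)
  sce <- SingleCellExperiment(
    assays = list(logcounts = expression),
    colData = cd,
    reducedDims = list(embedding = embedding))
  new("CellDataset", sce)
}

#' @rdname nCells
#' @export
setMethod("nCells", "CellDataset", function(x) ncol(x))

#' @rdname CellDataset-class
#' @aliases cellEmbedding
#' @param x a CellDataset
#' @export
setMethod("cellEmbedding", "CellDataset",
          function(x) reducedDim(x, "embedding"))

#' @rdname CellDataset-class
#' @export
setMethod("cloneIds", "CellDataset", function(x) colData(x)$clone_id)

#' @rdname CellDataset-class
#' @param value replacement per-cell clone labels
#' @export
setMethod("cloneIds<-", "CellDataset", function(x, value) {
  colData(x)$clone_id <- as.character(value)
  x
})

#' @rdname CellDataset-class
#' @export
setMethod("clusterIds", "CellDataset", function(x) colData(x)$cluster_id)

#' @rdname CellDataset-class
#' @export
setMethod("timepoints", "CellDataset", function(x) colData(x)$timepoint)

#' @rdname CellDataset-class
#' @export
setMethod("sampleIds", "CellDataset", function(x) colData(x)$sample_id)

setMethod("show", "CellDataset", function(object) {
  cat("CellDataset:", ncol(object), "cells,", nrow(object), "genes,",
      ncol(reducedDim(object, "embedding")), "embedding dims\n")
  cl <- cloneIds(object)
  cat("  clone labels:", sum(!is.na(cl)), "cells in",
      length(unique(cl[!is.na(cl)])), "clones\n")
})

#' Load a CellDataset from MTX + CSV files
#'
#' Reads a MatrixMarket expression matrix (genes x cells, optionally with
#' sidecar features/barcodes TSVs next to it), a headered CSV of embedding
#' coordinates (cells x D) and a headered CSV of per-cell metadata with
#' optional columns \code{clone_id}, \code{cluster_id}, \code{timepoint},
#' \code{sample_id}.  Row counts must agree across the three inputs.
#'
#' @param expressionPath path to a .mtx file.
#' @param embeddingPath path to the embedding CSV.
#' @param metadataPath path to the metadata CSV (optional).
#' @return a \linkS4class{CellDataset}.
#' @export
loadCellDataset <- function(expressionPath, embeddingPath,
                            metadataPath = NULL) {
  for (p in c(expressionPath, embeddingPath, metadataPath))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  expr <- as(Matrix::readMM(expressionPath), "CsparseMatrix")
  dirn <- dirname(expressionPath)
  feat <- file.path(dirn, "features.tsv")
  barc <- file.path(dirn, "barcodes.tsv")
  if (file.exists(feat))
    rownames(expr) <- utils::read.table(feat, sep = "\t",
                                        stringsAsFactors = FALSE)[[1]]
  if (file.exists(barc))
    colnames(expr) <- utils::read.table(barc, sep = "\t",
                                        stringsAsFactors = FALSE)[[1]]
  emb <- as.matrix(utils::read.csv(embeddingPath))
  if (nrow(emb) != ncol(expr))
    stop("dimension mismatch: ", embeddingPath, " has ", nrow(emb),
         " rows but ", expressionPath, " has ", ncol(expr), " cells")
  if (!all(is.finite(emb)))
    stop("non-finite embedding entries in ", embeddingPath)
  md <- NULL
  if (!is.null(metadataPath)) {
    md <- utils::read.csv(metadataPath, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (nrow(md) != ncol(expr))
      stop("dimension mismatch: ", metadataPath, " has ", nrow(md),
           " rows but ", expressionPath, " has ", ncol(expr), " cells")
  }
  get <- function(col) if (!is.null(md) && col %in% names(md)) {
    v <- md[[col]]; v[v == ""] <- NA; v
  } else NULL
  CellDataset(expr, emb, cloneId = get("clone_id"),
              clusterId = get("cluster_id"), timepoint = get("timepoint"),
              sampleId = get("sample_id"))
}

# --- minimal AnnData (.h5ad) layout support via rhdf5 -----------------------

.readH5Matrix <- function(path, name) {
  info <- rhdf5::h5ls(path)
  here <- info[info$group == paste0("/", name) |
               (info$group == "/" & info$name == name), , drop = FALSE]
  if (any(info$group == "/" & info$name == name & info$otype == "H5I_DATASET")) {
    x <- rhdf5::h5read(path, name)
    return(t(as.matrix(x)))            # h5 stores row-major; anndata is cells x genes
  }
  grp <- paste0("/", name)
  attrs <- rhdf5::h5readAttributes(path, grp)
  enc <- attrs[["encoding-type"]]
  shape <- as.integer(attrs[["shape"]])
  data <- as.numeric(rhdf5::h5read(path, paste0(grp, "/data")))
  indices <- as.integer(rhdf5::h5read(path, paste0(grp, "/indices")))
  indptr <- as.integer(rhdf5::h5read(path, paste0(grp, "/indptr")))
  if (identical(enc, "csr_matrix")) {
    m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr,
                              x = data, dims = rev(shape))  # genes x cells
  } else {
    m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                              x = data, dims = shape)
    m <- Matrix::t(m)
  }
  m
}

.readH5ObsColumn <- function(path, col) {
  grp <- paste0("/obs/", col)
  at <- tryCatch(rhdf5::h5readAttributes(path, grp), error = function(e) NULL)
  if (!is.null(at) && identical(at[["encoding-type"]], "categorical")) {
    codes <- as.integer(rhdf5::h5read(path, paste0(grp, "/codes")))
    cats <- as.character(rhdf5::h5read(path, paste0(grp, "/categories")))
    out <- rep(NA_character_, length(codes))
    out[codes >= 0L] <- cats[codes[codes >= 0L] + 1L]
    return(out)
  }
  as.character(rhdf5::h5read(path, grp))
}

#' Read a CellDataset from an AnnData .h5ad file
#'
#' Minimal reader for the AnnData on-disk layout (dense or CSR/CSC \code{X},
#' categorical or plain \code{obs} columns, \code{obsm} embeddings) built on
#' rhdf5.  The embedding is taken from \code{obsm[[embeddingKey]]}.
#'
#' @param path path to the .h5ad file.
#' @param embeddingKey name of the obsm entry holding the cell embedding.
#' @return a \linkS4class{CellDataset}.
#' @export
readH5ADCellDataset <- function(path, embeddingKey = "X_pca") {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- rhdf5::h5ls(path)
  expr <- .readH5Matrix(path, "X")     # genes x cells
  emb <- rhdf5::h5read(path, paste0("obsm/", embeddingKey))
  emb <- t(as.matrix(emb))             # stored D x N column-major
  obsCols <- info$name[info$group == "/obs"]
  getcol <- function(col) {
    if (!col %in% obsCols) return(NULL)
    v <- .readH5ObsColumn(path, col)
    v[v == ""] <- NA                     # empty strings encode missing
    v
  }
  idx <- tryCatch(as.character(rhdf5::h5read(path, "obs/_index")),
                  error = function(e) NULL)
  if (!is.null(idx)) colnames(expr) <- idx
  vidx <- tryCatch(as.character(rhdf5::h5read(path, "var/_index")),
                   error = function(e) NULL)
  if (!is.null(vidx)) rownames(expr) <- vidx
  CellDataset(expr, emb, cloneId = getcol("clone_id"),
              clusterId = getcol("cluster_id"),
              timepoint = getcol("timepoint"), sampleId = getcol("sample_id"))
}

#' Write a CellDataset (plus optional derived matrices) to .h5ad
#'
#' Writes the AnnData layout: dense \code{X} (cells x genes), \code{obs}
#' metadata columns, the embedding under \code{obsm/X_pca}, and any extra
#' named matrices under \code{obsm/}.  Intended for interchange of
#' desk-scale objects, not production-size matrices.
#'
#' @param dataset a \linkS4class{CellDataset}.
#' @param path output file path (overwritten).
#' @param obsm named list of additional cells x k matrices (e.g. cellP).
#' @return invisibly, \code{path}.
#' @export
writeH5ADCellDataset <- function(dataset, path, obsm = list()) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  X <- as.matrix(assay(dataset, "logcounts"))
  rhdf5::h5write(t(X), path, "X")      # cells x genes on disk
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(colnames(dataset), path, "obs/_index")
  for (col in c("clone_id", "cluster_id", "timepoint", "sample_id")) {
    v <- colData(dataset)[[col]]
    v[is.na(v)] <- ""
    rhdf5::h5write(v, path, paste0("obs/", col))
  }
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(rownames(dataset), path, "var/_index")
  rhdf5::h5createGroup(path, "obsm")
  rhdf5::h5write(t(cellEmbedding(dataset)), path, "obsm/X_pca")
  for (nm in names(obsm)) rhdf5::h5write(t(as.matrix(obsm[[nm]])), path,
                                         paste0("obsm/", nm))
  rhdf5::H5close()
  invisible(path)
}

# --- TCR clonotype derivation ----------------------------------------------

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read 10x filtered_contig_annotations.csv
#'
#' Expects at least the columns \code{barcode}, \code{chain}, \code{cdr3},
#' \code{productive}, \code{umis}, \code{reads}; optional \code{sample_id}
#' and \code{timepoint} columns are carried through.
#'
#' @param path CSV path.
#' @return a data.frame of contig records.
#' @export
readTCRContigs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "chain", "cdr3", "productive", "umis", "reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing contig columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Derive per-cell clone labels from paired TCR CDR3 sequences
#'
#' Cells are assigned to clones by identical CDR3 alpha and beta amino-acid
#' sequences within each grouping unit (sample, or sample + timepoint).
#' Non-productive contigs are dropped.  When a cell has several productive
#' contigs of the same chain, the one with the highest UMI count is kept
#' (ties: highest read count, then lexicographically smallest CDR3).  Cells
#' lacking either chain get a missing clone label.
#'
#' @param contigs data.frame of contig records (see \code{readTCRContigs});
#'   columns barcode, chain (TRA/TRB), cdr3, productive, umis, reads, and
#'   optionally sample_id / timepoint.
#' @param groupBy \code{"sample"} or \code{"sample_timepoint"}.
#' @return named character vector: clone id per cell barcode (NA when the
#'   cell lacks a productive TRA/TRB pair).
#' @export
deriveClonesFromTCR <- function(contigs,
                                groupBy = c("sample", "sample_timepoint")) {
  groupBy <- match.arg(groupBy)
  df <- contigs
  prod <- tolower(as.character(df$productive)) %in% c("true", "t", "1", "yes")
  df <- df[prod & df$chain %in% c("TRA", "TRB"), , drop = FALSE]
  bad <- grepl("[*_]", df$cdr3) |
    !vapply(strsplit(df$cdr3, ""), function(s) all(s %in% .AA), logical(1))
  df <- df[!bad, , drop = FALSE]
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample1"
  if (!"timepoint" %in% names(df)) df$timepoint <- "tp1"
  key <- if (groupBy == "sample") df$sample_id else
    paste(df$sample_id, df$timepoint, sep = "|")
  df$group <- key
  # deterministic best contig per (cell, chain)
  o <- order(df$barcode, df$chain, -df$umis, -df$reads, df$cdr3,
             method = "radix")
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c("barcode", "chain")]), , drop = FALSE]
  cells <- unique(contigs$barcode)
  tra <- df[df$chain == "TRA", ]
  trb <- df[df$chain == "TRB", ]
  out <- rep(NA_character_, length(cells))
  names(out) <- cells
  both <- intersect(tra$barcode, trb$barcode)
  if (length(both)) {
    a <- tra[match(both, tra$barcode), ]
    b <- trb[match(both, trb$barcode), ]
    out[both] <- paste(a$group, a$cdr3, b$cdr3, sep = ":")
  }
  out
}

#' Filter to expanded clones
#'
#' Keeps clones with at least \code{minCells} member cells (default 10, the
#' expansion threshold used to seed density estimation); all other cells are
#' treated as unassigned context for label propagation.
#'
#' @param dataset a \linkS4class{CellDataset} with clone labels.
#' @param minCells expansion threshold (positive integer).
#' @return a \linkS4class{CloneTable}.
#' @export
filterExpandedClones <- function(dataset, minCells = 10) {
  cl <- cloneIds(dataset)
  if (all(is.na(cl))) stop("no cell carries a clone label")
  tab <- table(cl[!is.na(cl)])
  keep <- names(tab)[tab >= minCells]
  if (!length(keep))
    stop("no clone reaches ", minCells,
         " cells; consider lowering the expansion threshold")
  keep <- sort(keep)
  members <- lapply(keep, function(k) which(!is.na(cl) & cl == k))
  new("CloneTable", cloneId = keep,
      cloneSizes = as.integer(lengths(members)), members = members,
      expandedThreshold = as.integer(minCells),
      nCellsTotal = nCells(dataset))
}

#' @rdname CloneTable-class
#' @export
setMethod("nClones", "CloneTable", function(x) length(x@cloneId))

#' @rdname CloneTable-class
#' @export
setMethod("cloneNames", "CloneTable", function(x) x@cloneId)

#' @rdname CloneTable-class
#' @export
setMethod("cloneSizes", "CloneTable",
          function(x) stats::setNames(x@cloneSizes, x@cloneId))

#' @rdname CloneTable-class
#' @export
setMethod("cloneMembers", "CloneTable",
          function(x) stats::setNames(x@members, x@cloneId))

setMethod("show", "CloneTable", function(object) {
  cat("CloneTable:", length(object@cloneId), "expanded clones (threshold",
      object@expandedThreshold, "cells);",
      sum(object@cloneSizes), "of", object@nCellsTotal, "cells assigned\n")
})
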