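#' @describeIn CellDataset number of cells
#' @param x a \linkS4class{CellDataset} or \linkS4class{CloneTable}
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CloneTable-class
#' @param x object
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))

#' @rdname CloneTable-class
#' @export
setGeneric("cloneNames", function(x) standardGeneric("cloneNames"))

#' @rdname CloneTable-class
#' @export
setGeneric("cloneSizes", function(x) standardGeneric("cloneSizes"))

#' @rdname CloneTable-class
#' @export
setGeneric("cloneMembers", function(x) standardGeneric("cloneMembers"))

#' @rdname CellDataset-class
#' @export
setGeneric("cellEmbedding", function(x) standardGeneric("cellEmbedding"))

#' @rdname CellDataset-class
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname CellDataset-class
#' @export
setGeneric("cloneIds<-", function(x, value) standardGeneric("cloneIds<-"))

#' @rdname CellDataset-class
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname CellDataset-class
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname CellDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname CloneAssignment-class
#' @param x object
#' @export
setGeneric("assignmentMatrix", function(x) standardGeneric("assignmentMatrix"))

#' @rdname CloneAssignment-class
#' @export
setGeneric("assignmentStage", function(x) standardGeneric("assignmentStage"))

#' @rdname CloneDistance-class
#' @param x object
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname CloneEmbedding-class
#' @param x object
#' @param type which coordinates: "mds", "diffusion" or "umap"
#' @export
setGeneric("cloneCoords", function(x, type = "mds") standardGeneric("cloneCoords"))

#' @rdname CloneEmbedding-class
#' @export
setGeneric("cloneAffinity", function(x) standardGeneric("cloneAffinity"))

#' @rdname ProfileAssignment-class
#' @param x object
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname ProfileAssignment-class
#' @export
setGeneric("cellProfiles", function(x) standardGeneric("cellProfiles"))

#' @rdname PseudotimeResult-class
#' @param x object
#' @export
setGeneric("clonePseudotimes", function(x) standardGeneric("clonePseudotimes"))

#' @rdname PseudotimeResult-class
#' @export
setGeneric("cellPseudotimes", function(x) standardGeneric("cellPseudotimes"))
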