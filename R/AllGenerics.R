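#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setGeneric("voxelWidths", function(x) standardGeneric("voxelWidths"))

#' @rdname accessors
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))

#' @rdname accessors
#' @export
setGeneric("domainSide", function(x) standardGeneric("domainSide"))

#' @rdname accessors
#' @export
setGeneric("transferConstant", function(x) standardGeneric("transferConstant"))

#' @rdname accessors
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname accessors
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))

#' @rdname accessors
#' @export
setGeneric("initialCounts", function(x) standardGeneric("initialCounts"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("speciesCounts", function(x, ...) standardGeneric("speciesCounts"))

#' @rdname accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname accessors
#' @export
setGeneric("transferLog", function(x) standardGeneric("transferLog"))

#' @rdname accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @rdname ensembleSeries
#' @export
setGeneric("ensembleSeries", function(x, ...) standardGeneric("ensembleSeries"))

#' @rdname accessors
#' @export
setGeneric("ensembleMean", function(x) standardGeneric("ensembleMean"))

#' @rdname accessors
#' @export
setGeneric("ensembleSD", function(x) standardGeneric("ensembleSD"))
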