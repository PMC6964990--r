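#' Accessors
#'
#' Small accessor methods for the package's S4 classes. `speciesNames`
#' returns species identifiers; `nLevels`, `voxelWidths`, `voxelCounts` and
#' `domainSide` describe a mesh hierarchy (or the hierarchy implied by a
#' model); `speciesTable` / `reactionTable` give data.frame views of a
#' model; `sampleTimes`, `speciesCounts`, `eventLog`, `transferLog`,
#' `trajectories`, `ensembleMean` and `ensembleSD` extract trajectory and
#' ensemble contents.
#'
#' @param x the object.
#' @param ... for `speciesCounts`, an optional `species` character vector
#'   selecting columns.
#' @name accessors
NULL

#' @rdname accessors
setMethod("speciesNames", "RDModel", function(x)
  vapply(x@species, function(s) s@name, character(1)))

#' @rdname accessors
setMethod("speciesNames", "TrajectoryEnsemble", function(x) x@speciesNames)

#' @rdname accessors
setMethod("nLevels", "MeshHierarchy", function(x) x@nLevels)

#' @rdname accessors
setMethod("nLevels", "RDModel", function(x) x@nLevels)

#' @rdname accessors
setMethod("voxelWidths", "MeshHierarchy", function(x)
  x@side / 2^(0:(x@nLevels - 1L)))

#' @rdname accessors
setMethod("voxelWidths", "RDModel", function(x)
  voxelWidths(meshHierarchy(x@nLevels, x@volume)))

#' @rdname accessors
setMethod("voxelCounts", "MeshHierarchy", function(x)
  (2^(0:(x@nLevels - 1L)))^3)

#' @rdname accessors
setMethod("voxelCounts", "RDModel", function(x)
  voxelCounts(meshHierarchy(x@nLevels, x@volume)))

#' @rdname accessors
setMethod("domainSide", "MeshHierarchy", function(x) x@side)

#' @rdname accessors
setMethod("domainSide", "RDModel", function(x) x@volume^(1 / 3))

#' @rdname accessors
setMethod("transferConstant", "RDModel", function(x) x@transferC)

#' @rdname accessors
setMethod("speciesTable", "RDModel", function(x)
  data.frame(name = speciesNames(x),
             D = vapply(x@species, function(s) s@D, numeric(1)),
             radius = vapply(x@species, function(s) s@radius, numeric(1)),
             row.names = NULL))

#' @rdname accessors
setMethod("reactionTable", "RDModel", function(x)
  data.frame(
    order = vapply(x@channels, function(ch) ch@order, integer(1)),
    reactants = vapply(x@channels, function(ch)
      paste(ch@reactants, collapse = " + "), character(1)),
    products = vapply(x@channels, function(ch)
      if (length(ch@products)) paste(ch@products, collapse = " + ")
      else "0", character(1)),
    rate = vapply(x@channels, function(ch) ch@rate, numeric(1)),
    row.names = NULL))

#' @rdname accessors
setMethod("initialCounts", "RDModel", function(x) {
  out <- setNames(integer(length(x@species)), speciesNames(x))
  if (length(x@init)) out[names(x@init)] <- x@init
  out
})

#' @rdname accessors
setMethod("sampleTimes", "Trajectory", function(x) x@times)

#' @rdname accessors
setMethod("sampleTimes", "TrajectoryEnsemble", function(x) x@times)

#' @rdname accessors
setMethod("sampleTimes", "EnsembleSeries", function(x) x@times)

#' @rdname accessors
setMethod("speciesCounts", "Trajectory", function(x, ...) {
  args <- list(...)
  if (!is.null(args$species)) x@counts[, args$species, drop = FALSE]
  else x@counts
})

#' @rdname accessors
setMethod("eventLog", "Trajectory", function(x) x@eventLog)

#' @rdname accessors
setMethod("transferLog", "Trajectory", function(x) x@transferLog)

#' @rdname accessors
setMethod("trajectories", "TrajectoryEnsemble", function(x) x@trajectories)

#' @rdname accessors
setMethod("ensembleMean", "EnsembleSeries", function(x) x@mean)

#' @rdname accessors
setMethod("ensembleSD", "EnsembleSeries", function(x) x@sd)

setMethod("length", "TrajectoryEnsemble", function(x) length(x@trajectories))

setMethod("show", "Species", function(object) {
  cat(sprintf("Species '%s': D = %g, radius = %g\n",
              object@name, object@D, object@radius))
})

setMethod("show", "ReactionChannel", function(object) {
  lhs <- if (object@order == 0L) "0"
         else paste(object@reactants, collapse = " + ")
  rhs <- if (length(object@products))
           paste(object@products, collapse = " + ") else "0"
  cat(sprintf("ReactionChannel (order %d): %s -> %s, rate = %g\n",
              object@order, lhs, rhs, object@rate))
})

setMethod("show", "RDModel", function(object) {
  cat(sprintf("RDModel '%s'\n", object@name))
  cat(sprintf("  %d species, %d channels, volume %g, %d mesh levels (finest %d^3 voxels)\n",
              length(object@species), length(object@channels),
              object@volume, object@nLevels, 2^(object@nLevels - 1L)))
  cat(sprintf("  C = %g, epsilon = %g\n", object@transferC, object@epsilon))
  st <- speciesTable(object)
  lv <- object@speciesLevels[st$name]
  ini <- initialCounts(object)[st$name]
  st$finestLevel <- ifelse(is.na(lv), "auto", lv)
  st$init <- ini
  print(st, row.names = FALSE)
  cat("Channels:\n")
  print(reactionTable(object), row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "MeshHierarchy", function(object) {
  cat(sprintf("MeshHierarchy: %d levels on a cube of side %g\n",
              object@nLevels, object@side))
  print(data.frame(level = 0:(object@nLevels - 1L),
                   perAxis = 2^(0:(object@nLevels - 1L)),
                   nVoxels = voxelCounts(object),
                   width = voxelWidths(object)), row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "VoxelRef", function(object) {
  cat(sprintf("VoxelRef: level %d, ijk = (%s)\n", object@level,
              paste(object@ijk, collapse = ", ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d sample points, %d species, %s events, final time %g\n",
              length(object@times), ncol(object@counts),
              format(object@nEvents, big.mark = ","), object@finalTime))
  if (nrow(object@eventLog))
    cat(sprintf("  reaction log: %d records\n", nrow(object@eventLog)))
  if (nrow(object@transferLog))
    cat(sprintf("  transfer log: %d records\n", nrow(object@transferLog)))
  invisible(NULL)
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("TrajectoryEnsemble: %d trajectories of model '%s', %d sample points\n",
              length(object@trajectories), object@modelName,
              length(object@times)))
  invisible(NULL)
})

setMethod("show", "EnsembleSeries", function(object) {
  cat(sprintf("EnsembleSeries over %d trajectories, %d sample points, species: %s\n",
              object@n, length(object@times),
              paste(colnames(object@mean), collapse = ", ")))
  invisible(NULL)
})
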