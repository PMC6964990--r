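#' Chemical species
#'
#' One chemical species: a name, a diffusion constant `D` (length^2/time)
#' and a reaction radius (length). The radius enters bimolecular rate
#' conversion as part of the pair sum sigma = radius_A + radius_B; it must
#' be strictly positive for any species taking part in a bimolecular
#' channel (checked at model construction).
#'
#' @slot name single character identifier.
#' @slot D diffusion constant, >= 0.
#' @slot radius reaction radius, >= 0.
#' @aliases Species
#' @exportClass Species
setClass("Species",
  slots = c(name = "character", D = "numeric", radius = "numeric"))

setValidity("Species", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@D) != 1L || !is.finite(object@D) || object@D < 0)
    msg <- c(msg, "'D' must be a single finite value >= 0")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius < 0)
    msg <- c(msg, "'radius' must be a single finite value >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn Species-class constructor.
#' @param name species identifier.
#' @param D diffusion constant (length^2/time).
#' @param radius reaction radius (length).
#' @export
rdSpecies <- function(name, D, radius = 0) {
  new("Species", name = as.character(name), D = as.numeric(D),
      radius = as.numeric(radius))
}

#' Reaction channel
#'
#' A zeroth-, first- or second-order reaction channel. The microscopic
#' rate has units molecules/time (order 0), 1/time (order 1) or
#' volume/time (order 2, 3D). For second-order channels the per-pair
#' mesoscopic firing rate on each mesh level is derived at simulation
#' time via [mesoRate()].
#'
#' @slot order integer 0, 1 or 2 (number of reactants).
#' @slot reactants character vector of reactant species names (length = order).
#' @slot products character vector of product species names (possibly empty).
#' @slot rate microscopic rate constant, >= 0.
#' @aliases ReactionChannel
#' @exportClass ReactionChannel
setClass("ReactionChannel",
  slots = c(order = "integer", reactants = "character",
            products = "character", rate = "numeric"))

setValidity("ReactionChannel", function(object) {
  msg <- character()
  if (length(object@order) != 1L || !(object@order %in% 0:2))
    msg <- c(msg, "'order' must be 0, 1 or 2")
  if (length(object@reactants) != object@order)
    msg <- c(msg, "number of reactants must equal the reaction order")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate < 0)
    msg <- c(msg, "'rate' must be a single finite value >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReactionChannel-class constructor; the order is inferred
#'   from the number of reactants.
#' @param reactants character vector of 0, 1 or 2 reactant names.
#' @param products character vector of product names (may be empty).
#' @param rate microscopic rate constant.
#' @export
reaction <- function(reactants, products, rate) {
  reactants <- as.character(reactants)
  new("ReactionChannel", order = length(reactants), reactants = reactants,
      products = as.character(products), rate = as.numeric(rate))
}

#' Reaction-diffusion model
#'
#' A complete model: species, reaction channels, a cubic domain, the mesh
#' hierarchy depth and the solver parameters (transfer constant `C`,
#' relative rate-error tolerance `epsilon`, horizon, sampling). Initial
#' copy numbers are a named integer vector; molecules are placed uniformly
#' on each species' finest level unless a simulation call overrides the
#' placement.
#'
#' `speciesLevels` optionally pins each species to a fixed finest level
#' (0 = coarsest). Entries set to `NA` are assigned automatically from the
#' admissible-mesh criterion by [assignSpeciesLevels()].
#'
#' @slot name model label.
#' @slot species list of [Species-class] objects.
#' @slot channels list of [ReactionChannel-class] objects.
#' @slot volume domain volume (the domain is a cube of side volume^(1/3)).
#' @slot nLevels number of mesh levels in the hierarchy.
#' @slot transferC transfer constant: a molecule must diffuse a distance `C` times
#'   the local voxel width (on average) before promotion to a coarser mesh.
#' @slot epsilon tolerance on the relative mean-rebind-time error used to
#'   pick each species' finest admissible mesh level.
#' @slot init named integer vector of initial copy numbers.
#' @slot speciesLevels named integer vector of per-species finest levels
#'   (NA = assign automatically).
#' @slot tFinal default simulation horizon.
#' @slot nSamples default number of sampling intervals (the time series has
#'   nSamples + 1 points including t = 0).
#' @slot nTrajectories default ensemble size.
#' @slot seed default RNG seed (NA = leave the RNG state alone).
#' @aliases RDModel
#' @exportClass RDModel
setClass("RDModel",
  slots = c(name = "character", species = "list", channels = "list",
            volume = "numeric", nLevels = "integer", transferC = "numeric",
            epsilon = "numeric", init = "integer",
            speciesLevels = "integer", tFinal = "numeric",
            nSamples = "integer", nTrajectories = "integer",
            seed = "integer"))

setValidity("RDModel", function(object) {
  msg <- character()
  sp <- vapply(object@species, function(s) is(s, "Species"), logical(1))
  ch <- vapply(object@channels, function(x) is(x, "ReactionChannel"),
               logical(1))
  if (!all(sp)) msg <- c(msg, "'species' must be a list of Species objects")
  if (!all(ch))
    msg <- c(msg, "'channels' must be a list of ReactionChannel objects")
  if (length(msg)) return(msg)
  nm <- vapply(object@species, function(s) s@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "species names must be unique")
  refs <- unlist(lapply(object@channels,
                        function(x) c(x@reactants, x@products)))
  bad <- setdiff(refs, nm)
  if (length(bad))
    msg <- c(msg, paste0("channels reference unknown species: ",
                         paste(bad, collapse = ", ")))
  bi <- unlist(lapply(object@channels,
                      function(x) if (x@order == 2L) x@reactants))
  for (s in object@species)
    if (s@name %in% bi && s@radius <= 0)
      msg <- c(msg, paste0("species '", s@name, "' takes part in a ",
                           "bimolecular channel but has radius <= 0"))
  if (length(object@volume) != 1L || object@volume <= 0)
    msg <- c(msg, "'volume' must be a single positive value")
  if (length(object@nLevels) != 1L || object@nLevels < 1L)
    msg <- c(msg, "'nLevels' must be >= 1")
  if (length(object@transferC) != 1L || object@transferC <= 0)
    msg <- c(msg, "'C' must be a single positive value (Inf disables transfers)")
  if (length(object@epsilon) != 1L || object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be a single positive value")
  if (length(object@init) && (is.null(names(object@init)) ||
      !all(names(object@init) %in% nm)))
    msg <- c(msg, "'init' must be named with known species names")
  if (any(object@init < 0, na.rm = TRUE))
    msg <- c(msg, "initial copy numbers must be >= 0")
  if (length(object@speciesLevels)) {
    if (is.null(names(object@speciesLevels)) ||
        !all(names(object@speciesLevels) %in% nm))
      msg <- c(msg, "'speciesLevels' must be named with known species names")
    lv <- object@speciesLevels[!is.na(object@speciesLevels)]
    if (any(lv < 0L | lv >= object@nLevels))
      msg <- c(msg, "'speciesLevels' entries must lie in [0, nLevels)")
  }
  if (length(msg)) msg else TRUE
})

#' Build a reaction-diffusion model
#'
#' @param species list of [rdSpecies()] objects.
#' @param channels list of [reaction()] objects.
#' @param volume domain volume; the domain is a cube of side volume^(1/3).
#' @param nLevels hierarchy depth (level 0 is the single-voxel coarsest mesh,
#'   the finest mesh has (2^(nLevels-1))^3 voxels).
#' @param init named integer vector of initial copy numbers.
#' @param C transfer constant (dimensionless, default 20).
#' @param epsilon mesh-admissibility tolerance (default 0.025).
#' @param speciesLevels optional named integer vector pinning species to
#'   finest levels; species not listed (or NA) are assigned automatically.
#' @param tFinal,nSamples,nTrajectories,seed default simulation settings.
#' @param name model label.
#' @return an [RDModel-class] object.
#' @examples
#' m <- rdModel(
#'   species  = list(rdSpecies("A", D = 1, radius = 0.0025),
#'                   rdSpecies("B", D = 1, radius = 0.0025),
#'                   rdSpecies("C", D = 1, radius = 0.0025)),
#'   channels = list(reaction(c("A", "B"), "C", 1)),
#'   volume = 1, nLevels = 7, init = c(A = 10, B = 10))
#' m
#' @export
rdModel <- function(species, channels, volume = 1, nLevels = 7L,
                    init = integer(), C = 20, epsilon = 0.025,
                    speciesLevels = integer(), tFinal = 1, nSamples = 100L,
                    nTrajectories = 1L, seed = NA_integer_,
                    name = "model") {
  init <- setNames(as.integer(init), names(init))
  nm <- vapply(species, function(s) s@name, character(1))
  lv <- rep(NA_integer_, length(nm))
  names(lv) <- nm
  if (length(speciesLevels))
    lv[names(speciesLevels)] <- as.integer(speciesLevels)
  new("RDModel", name = name, species = species, channels = channels,
      volume = as.numeric(volume), nLevels = as.integer(nLevels),
      transferC = as.numeric(C), epsilon = as.numeric(epsilon), init = init,
      speciesLevels = lv, tFinal = as.numeric(tFinal),
      nSamples = as.integer(nSamples),
      nTrajectories = as.integer(nTrajectories), seed = as.integer(seed))
}

#' Nested Cartesian mesh hierarchy
#'
#' A stack of nested cubic meshes on a cubic domain. Level l (0-based,
#' 0 = coarsest) has 2^l voxels per axis of width side/2^l, so each voxel
#' on level l+1 is fully contained in exactly one parent voxel on level l
#' and each voxel on level l < L-1 has exactly 8 children. Parent/child
#' topology is pure index arithmetic and is never stored.
#'
#' @slot nLevels number of levels L.
#' @slot side domain edge length (volume^(1/3)).
#' @aliases MeshHierarchy
#' @exportClass MeshHierarchy
setClass("MeshHierarchy",
  slots = c(nLevels = "integer", side = "numeric"))

setValidity("MeshHierarchy", function(object) {
  msg <- character()
  if (length(object@nLevels) != 1L || object@nLevels < 1L)
    msg <- c(msg, "'nLevels' must be a single integer >= 1")
  if (length(object@side) != 1L || !is.finite(object@side) ||
      object@side <= 0)
    msg <- c(msg, "'side' must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' @describeIn MeshHierarchy-class constructor from a domain volume.
#' @param nLevels number of levels.
#' @param volume domain volume (cube of side volume^(1/3)).
#' @export
meshHierarchy <- function(nLevels, volume = 1) {
  new("MeshHierarchy", nLevels = as.integer(nLevels),
      side = as.numeric(volume)^(1 / 3))
}

#' Voxel reference
#'
#' Identifies one voxel: a level index and a 0-based integer triple
#' `ijk`, each coordinate in [0, 2^level).
#'
#' @slot level mesh level (0 = coarsest).
#' @slot ijk integer triple of 0-based voxel coordinates.
#' @aliases VoxelRef
#' @exportClass VoxelRef
setClass("VoxelRef", slots = c(level = "integer", ijk = "integer"))

setValidity("VoxelRef", function(object) {
  msg <- character()
  if (length(object@level) != 1L || object@level < 0L)
    msg <- c(msg, "'level' must be a single integer >= 0")
  if (length(object@ijk) != 3L)
    msg <- c(msg, "'ijk' must be an integer triple")
  else if (any(object@ijk < 0L) || any(object@ijk >= 2L^object@level))
    msg <- c(msg, "'ijk' out of bounds for this level")
  if (length(msg)) msg else TRUE
})

#' @describeIn VoxelRef-class constructor.
#' @param level mesh level.
#' @param ijk integer triple (0-based).
#' @export
voxelRef <- function(level, ijk) {
  new("VoxelRef", level = as.integer(level), ijk = as.integer(ijk))
}

#' Single simulated trajectory
#'
#' Per-species copy numbers recorded on a fixed sample-time grid, plus the
#' optional reaction and transfer event logs.
#'
#' @slot times sample times.
#' @slot counts integer matrix, one row per sample time, one column per
#'   species.
#' @slot eventLog data.frame of reaction events (time, kind, channel,
#'   actor uids, product uids/levels/voxels); empty unless requested.
#' @slot transferLog data.frame of level transfers (time, uid, from/to
#'   level and voxel); empty unless requested.
#' @slot finalState data.frame of molecules alive at the end (uid, species,
#'   level, i, j, k, tSinceTransfer).
#' @slot finalTime simulation time at which the run stopped.
#' @slot nEvents number of events executed.
#' @aliases Trajectory
#' @exportClass Trajectory
setClass("Trajectory",
  slots = c(times = "numeric", counts = "matrix", eventLog = "data.frame",
            transferLog = "data.frame", finalState = "data.frame",
            finalTime = "numeric", nEvents = "numeric"))

#' Ensemble of trajectories
#'
#' A list of [Trajectory-class] objects sharing one sample-time grid.
#'
#' @slot trajectories list of Trajectory objects.
#' @slot times shared sample times.
#' @slot speciesNames column order of the count matrices.
#' @slot modelName label of the generating model.
#' @slot seed seed used for the ensemble (NA if none set).
#' @aliases TrajectoryEnsemble
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  slots = c(trajectories = "list", times = "numeric",
            speciesNames = "character", modelName = "character",
            seed = "integer"))

#' Ensemble summary time series
#'
#' Per-time-point ensemble mean and standard deviation of the species
#' copy numbers.
#'
#' @slot times sample times.
#' @slot mean matrix of ensemble means (time x species).
#' @slot sd matrix of ensemble standard deviations.
#' @slot n number of trajectories summarised.
#' @aliases EnsembleSeries
#' @exportClass EnsembleSeries
setClass("EnsembleSeries",
  slots = c(times = "numeric", mean = "matrix", sd = "matrix",
            n = "integer"))
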