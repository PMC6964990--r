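#' Fine-to-coarse transfer time
#'
#' Time a molecule must have diffused, since its birth or last transfer,
#' before it is promoted from its current level to the parent mesh:
#' t_transfer = (C h_l)^2 / (6 D), i.e. the time to diffuse an RMS
#' distance of C voxel widths. Molecules with D = 0 are never promoted
#' (infinite transfer time).
#'
#' @param model an [RDModel-class].
#' @param species species name.
#' @param level mesh level(s); default all levels.
#' @param C transfer constant override.
#' @return numeric vector of transfer times (possibly `Inf`).
#' @examples
#' transferTime(rdFixture("single_layer"), "S11", level = 6)  # ~ 0.0163
#' @export
transferTime <- function(model, species, level = 0:(model@nLevels - 1L),
                         C = model@transferC) {
  st <- speciesTable(model)
  i <- match(species, st$name)
  if (is.na(i)) stop("unknown species '", species, "'")
  stopifnot(all(level >= 0L), all(level < model@nLevels))
  h <- domainSide(model) / 2^level
  if (st$D[i] <= 0) return(rep(Inf, length(level)))
  (C * h)^2 / (6 * st$D[i])
}

## Resolve per-species finest levels: explicit argument beats the model's
## pinned levels beats the automatic mesh criterion.
.resolveLevels <- function(model, speciesLevels = NULL,
                           singleMeshLevel = NULL, epsilon = model@epsilon) {
  nm <- speciesNames(model)
  if (!is.null(singleMeshLevel)) {
    stopifnot(singleMeshLevel >= 0L, singleMeshLevel < model@nLevels)
    return(setNames(rep(as.integer(singleMeshLevel), length(nm)), nm))
  }
  lv <- model@speciesLevels[nm]
  if (!is.null(speciesLevels)) lv[names(speciesLevels)] <-
      as.integer(speciesLevels)
  if (anyNA(lv)) {
    auto <- assignSpeciesLevels(model, epsilon)
    lv[is.na(lv)] <- auto[names(lv)[is.na(lv)]]
  }
  storage.mode(lv) <- "integer"
  lv
}

## Build the flat engine description shared by all trajectories of a run.
.prepareEngine <- function(model, C = model@transferC, epsilon = model@epsilon,
                           speciesLevels = NULL, singleMeshLevel = NULL,
                           quiet = FALSE) {
  nm <- speciesNames(model)
  st <- speciesTable(model)
  lv <- .resolveLevels(model, speciesLevels, singleMeshLevel, epsilon)
  hs <- voxelWidths(model)
  nCh <- length(model@channels)
  kMeso <- matrix(0, nrow = max(nCh, 1L), ncol = model@nLevels)
  belowStar <- character()
  for (i in seq_len(nCh)) {
    ch <- model@channels[[i]]
    if (ch@order != 2L) next
    sg <- .channelSigma(model, ch)
    Dp <- .channelD(model, ch)
    kMeso[i, ] <- mesoRate(ch@rate, sg, Dp, hs, warn = FALSE)
    ## pairs can only meet at levels at or coarser than the reactants'
    ## finest levels; the firing rate must be usable there
    used <- seq_len(min(lv[ch@reactants]) + 1L)
    if (ch@rate > 0 && any(kMeso[i, used] <= 0))
      stop("channel ", i, ": non-positive mesoscopic rate on a level ",
           "where its reactants can meet")
    if (any(hs[used] < criticalMeshSize(sg)))
      belowStar <- c(belowStar, paste0(
        "channel ", i, " (sigma = ", signif(sg, 5), ", h* = ",
        signif(criticalMeshSize(sg), 5), ")"))
  }
  if (!quiet && length(belowStar))
    message("note: finest mesh below the critical size h* for ",
            paste(belowStar, collapse = "; "))
  list(
    nSpecies = length(nm), nLevels = model@nLevels,
    side = domainSide(model),
    D = st$D, bornLevel = unname(lv),
    order = vapply(model@channels, function(x) x@order, integer(1)),
    re1 = vapply(model@channels, function(x)
      if (x@order >= 1L) match(x@reactants[1], nm) - 1L else -1L,
      integer(1)),
    re2 = vapply(model@channels, function(x)
      if (x@order == 2L) match(x@reactants[2], nm) - 1L else -1L,
      integer(1)),
    products = lapply(model@channels, function(x)
      as.integer(match(x@products, nm) - 1L)),
    kMicro = vapply(model@channels, function(x) x@rate, numeric(1)),
    kMeso = kMeso, C = C, speciesLevels = lv, speciesNames = nm)
}

## Uniform initial placement on each species' finest level (R-side so the
## whole run consumes one seeded RNG stream). `placement` overrides:
## data.frame(species, level, i, j, k).
.samplePlacement <- function(prep, initCounts, placement = NULL) {
  if (!is.null(placement)) {
    sp <- match(as.character(placement$species), prep$speciesNames) - 1L
    if (anyNA(sp)) stop("placement references unknown species")
    lev <- as.integer(placement$level)
    if (any(lev < 0L) || any(lev >= prep$nLevels))
      stop("placement level out of range")
    n <- 2L^lev
    ijk <- cbind(as.integer(placement$i), as.integer(placement$j),
                 as.integer(placement$k))
    if (any(ijk < 0L) || any(ijk >= n))
      stop("placement voxel out of range")
    return(cbind(sp, lev, ijk, deparse.level = 0))
  }
  rows <- lapply(seq_along(initCounts), function(s) {
    cnt <- initCounts[s]
    if (cnt == 0L) return(NULL)
    lev <- prep$bornLevel[s]
    n <- 2L^lev
    cbind(rep(s - 1L, cnt), rep(lev, cnt),
          sample.int(n, cnt, replace = TRUE) - 1L,
          sample.int(n, cnt, replace = TRUE) - 1L,
          sample.int(n, cnt, replace = TRUE) - 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(0L, 0, 5)
  storage.mode(out) <- "integer"
  out
}

.runOne <- function(prep, initCounts, placement, control) {
  init <- .samplePlacement(prep, initCounts, placement)
  res <- .npmRun(c(prep, list(init = init)), control)
  counts <- res$counts
  colnames(counts) <- prep$speciesNames
  ev <- as.data.frame(res$reactions)
  if (nrow(ev))
    ev$kind <- c("unimolecular", "bimolecular", "birth")[ev$kind]
  tf <- as.data.frame(res$transfers)
  fs <- as.data.frame(res$finalState$state)
  names(fs) <- c("uid", "species", "level", "i", "j", "k")
  if (nrow(fs)) fs$species <- prep$speciesNames[fs$species + 1L]
  fs$tSinceTransfer <- res$finalState$tSinceTransfer
  new("Trajectory", times = control$sampleTimes, counts = counts,
      eventLog = ev, transferLog = tf, finalState = fs,
      finalTime = res$finalTime, nEvents = res$nEvents)
}

#' Simulate trajectories of a reaction-diffusion model
#'
#' Runs the hierarchical next-particle solver. By default every molecule
#' starts on its species' finest admissible level and is promoted to
#' coarser meshes as it diffuses; `singleMeshLevel` pins all species to
#' one level and disables transfers (the classic single-mesh solver),
#' and `wellMixed = TRUE` is shorthand for pinning to level 0, which is
#' the chemical-master-equation limit.
#'
#' @param model an [RDModel-class].
#' @param nTrajectories number of independent trajectories.
#' @param tFinal simulation horizon.
#' @param sampleTimes sorted sample times in `[0, tFinal]`; default
#'   `nSamples + 1` equidistant points from 0 to `tFinal`.
#' @param nSamples number of sampling intervals when `sampleTimes` is NULL.
#' @param seed RNG seed (`NULL` leaves the RNG state alone). One seeded
#'   stream drives placement and all events, so identical calls are
#'   reproducible bit for bit.
#' @param C transfer constant; `Inf` disables fine-to-coarse transfers.
#' @param epsilon mesh-criterion tolerance for automatic level assignment.
#' @param speciesLevels optional named integer vector overriding finest
#'   levels for some species.
#' @param singleMeshLevel pin all species to this level and disable
#'   transfers.
#' @param wellMixed shorthand for `singleMeshLevel = 0`.
#' @param initCounts named initial copy numbers (default the model's).
#' @param placement optional data.frame (species, level, i, j, k) of
#'   explicit initial molecules, overriding `initCounts`.
#' @param recordReactions,recordTransfers record reaction / transfer
#'   event logs on each trajectory.
#' @param stopChannel,stopCount stop a trajectory once the given channel
#'   (index into the model's channel list) has fired `stopCount` times.
#' @param maxEvents per-trajectory event budget guard.
#' @param quiet suppress the resolved-model notes.
#' @return a [TrajectoryEnsemble-class] (or a single [Trajectory-class]
#'   when `nTrajectories = 1`).
#' @examples
#' m <- rdFixture("single_layer")
#' tr <- simulateTrajectories(m, tFinal = 0.05, nSamples = 5, seed = 1,
#'                            quiet = TRUE)
#' speciesCounts(tr)
#' @export
simulateTrajectories <- function(model, nTrajectories = 1L,
                                 tFinal = model@tFinal, sampleTimes = NULL,
                                 nSamples = model@nSamples, seed = NULL,
                                 C = model@transferC, epsilon = model@epsilon,
                                 speciesLevels = NULL,
                                 singleMeshLevel = NULL, wellMixed = FALSE,
                                 initCounts = NULL, placement = NULL,
                                 recordReactions = FALSE,
                                 recordTransfers = FALSE,
                                 stopChannel = NULL, stopCount = 1,
                                 maxEvents = 1e12, quiet = FALSE) {
  stopifnot(is(model, "RDModel"))
  if (wellMixed) singleMeshLevel <- 0L
  if (!is.null(singleMeshLevel)) C <- Inf  # pinned runs never transfer
  if (is.null(sampleTimes))
    sampleTimes <- seq(0, tFinal, length.out = nSamples + 1L)
  if (is.unsorted(sampleTimes) || any(sampleTimes < 0) ||
      (is.finite(tFinal) && any(sampleTimes > tFinal)))
    stop("'sampleTimes' must be sorted and within [0, tFinal]")
  if (!is.null(seed)) set.seed(seed)
  prep <- .prepareEngine(model, C = C, epsilon = epsilon,
                         speciesLevels = speciesLevels,
                         singleMeshLevel = singleMeshLevel, quiet = quiet)
  ic <- initialCounts(model)
  if (!is.null(initCounts)) {
    ic[] <- 0L
    ic[names(initCounts)] <- as.integer(initCounts)
  }
  control <- list(tFinal = as.numeric(tFinal), sampleTimes = sampleTimes,
                  stopChannel = if (is.null(stopChannel)) -1L
                                else as.integer(stopChannel) - 1L,
                  stopCount = as.numeric(stopCount),
                  recordReactions = isTRUE(recordReactions),
                  recordTransfers = isTRUE(recordTransfers),
                  maxEvents = as.numeric(maxEvents))
  trs <- vector("list", nTrajectories)
  for (i in seq_len(nTrajectories))
    trs[[i]] <- .runOne(prep, ic, placement, control)
  if (nTrajectories == 1L) return(trs[[1]])
  new("TrajectoryEnsemble", trajectories = trs, times = sampleTimes,
      speciesNames = prep$speciesNames, modelName = model@name,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Locate a reaction channel by its reactants and products
#'
#' @param model an [RDModel-class].
#' @param reactants,products character vectors (order-insensitive); either
#'   may be omitted to match on the other alone.
#' @return integer index into the model's channel list.
#' @export
channelIndex <- function(model, reactants = NULL, products = NULL) {
  hit <- vapply(model@channels, function(ch) {
    ok <- TRUE
    if (!is.null(reactants))
      ok <- ok && setequal(ch@reactants, reactants) &&
        length(ch@reactants) == length(reactants)
    if (!is.null(products))
      ok <- ok && setequal(ch@products, products) &&
        length(ch@products) == length(products)
    ok
  }, logical(1))
  if (sum(hit) != 1L)
    stop("channel lookup matched ", sum(hit), " channels")
  which(hit)
}
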