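#' Well-mixed direct-method SSA
#'
#' Gillespie's direct stochastic simulation algorithm on the well-mixed
#' (single voxel) interpretation of a model: propensities are k (order 0),
#' k x (order 1) and k_pair x1 x2 (order 2; x (x - 1) / 2 pairs for a
#' self-reaction). By default the bimolecular per-pair rate is the
#' mesoscopic rate of the one-voxel mesh, [mesoRate()] at h = V^(1/3) —
#' exactly how the coarsest hierarchy level reacts, so the SSA is the
#' distributional oracle for the solver restricted to one level. Pure
#' mass-action k/V per pair is available with `massAction = TRUE` for
#' comparison.
#'
#' @param model an [RDModel-class].
#' @param tFinal horizon.
#' @param sampleTimes sample grid (default `nSamples + 1` equidistant
#'   points).
#' @param nSamples number of sampling intervals when `sampleTimes` is NULL.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param nTrajectories ensemble size.
#' @param initCounts named initial copy numbers (default the model's).
#' @param massAction use k/V per pair instead of the mesoscopic rate.
#' @return a [TrajectoryEnsemble-class] (or a single [Trajectory-class]
#'   when `nTrajectories = 1`).
#' @examples
#' tr <- ssaRun(rdFixture("single_layer"), tFinal = 1, nSamples = 10,
#'              seed = 1)
#' speciesCounts(tr)[11, ]
#' @export
ssaRun <- function(model, tFinal = model@tFinal, sampleTimes = NULL,
                   nSamples = model@nSamples, seed = NULL,
                   nTrajectories = 1L, initCounts = NULL,
                   massAction = FALSE) {
  stopifnot(is(model, "RDModel"))
  if (is.null(sampleTimes))
    sampleTimes <- seq(0, tFinal, length.out = nSamples + 1L)
  if (!is.null(seed)) set.seed(seed)
  nm <- speciesNames(model)
  ic <- initialCounts(model)
  if (!is.null(initCounts)) {
    ic[] <- 0L
    ic[names(initCounts)] <- as.integer(initCounts)
  }
  side <- domainSide(model)
  chans <- model@channels
  ord <- vapply(chans, function(x) x@order, integer(1))
  ## per-channel effective rate entering the propensity
  kEff <- vapply(seq_along(chans), function(i) {
    ch <- chans[[i]]
    if (ch@order != 2L) return(ch@rate)
    if (massAction) return(ch@rate / model@volume)
    mesoRate(ch@rate, .channelSigma(model, ch), .channelD(model, ch),
             side, warn = FALSE)
  }, numeric(1))
  stoich <- lapply(chans, function(ch) {
    dx <- setNames(numeric(length(nm)), nm)
    for (r in ch@reactants) dx[r] <- dx[r] - 1
    for (p in ch@products) dx[p] <- dx[p] + 1
    dx
  })
  propensity <- function(x) vapply(seq_along(chans), function(i) {
    ch <- chans[[i]]
    switch(as.character(ord[i]),
      "0" = kEff[i],
      "1" = kEff[i] * x[ch@reactants[1]],
      "2" = {
        r <- ch@reactants
        pairs <- if (r[1] == r[2]) x[r[1]] * (x[r[1]] - 1) / 2
                 else x[r[1]] * x[r[2]]
        kEff[i] * pairs
      })
  }, numeric(1))

  oneRun <- function() {
    x <- as.numeric(ic); names(x) <- nm
    out <- matrix(0L, length(sampleTimes), length(nm),
                  dimnames = list(NULL, nm))
    t <- 0; si <- 1L; nEv <- 0
    repeat {
      a <- propensity(x)
      a0 <- sum(a)
      tNext <- if (a0 <= 0) Inf else t + rexp(1, a0)
      while (si <= length(sampleTimes) && sampleTimes[si] < tNext) {
        out[si, ] <- as.integer(x); si <- si + 1L
      }
      if (tNext > tFinal || si > length(sampleTimes) && a0 <= 0) {
        while (si <= length(sampleTimes)) {
          out[si, ] <- as.integer(x); si <- si + 1L
        }
        break
      }
      t <- tNext
      j <- sample.int(length(a), 1L, prob = a)
      x <- x + stoich[[j]]
      nEv <- nEv + 1
    }
    new("Trajectory", times = sampleTimes, counts = out,
        eventLog = data.frame(), transferLog = data.frame(),
        finalState = data.frame(), finalTime = min(t, tFinal),
        nEvents = nEv)
  }
  trs <- lapply(seq_len(nTrajectories), function(i) oneRun())
  if (nTrajectories == 1L) return(trs[[1]])
  new("TrajectoryEnsemble", trajectories = trs, times = sampleTimes,
      speciesNames = nm, modelName = model@name,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
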