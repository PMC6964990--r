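#' Ensemble mean and standard deviation time series
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param ... unused.
#' @return an [EnsembleSeries-class].
#' @rdname ensembleSeries
#' @export
setMethod("ensembleSeries", "TrajectoryEnsemble", function(x, ...) {
  arr <- vapply(x@trajectories, function(tr) tr@counts,
                matrix(0L, length(x@times), length(x@speciesNames)))
  mu <- apply(arr, c(1, 2), mean)
  sdm <- apply(arr, c(1, 2), sd)
  dimnames(mu) <- dimnames(sdm) <- list(NULL, x@speciesNames)
  new("EnsembleSeries", times = x@times, mean = mu, sd = sdm,
      n = length(x@trajectories))
})

#' Relative error between two ensemble time series
#'
#' The trajectory-error metric: the summed absolute difference between
#' the ensemble mean series, normalised by the summed reference means,
#' E = sum_i |m_test(t_i) - m_ref(t_i)| / sum_i m_ref(t_i), summed over
#' the selected species. The unnormalised sum is attached as attribute
#' `"absolute"`.
#'
#' @param test,reference [EnsembleSeries-class] objects on identical
#'   sample grids (a [TrajectoryEnsemble-class] is summarised on the fly).
#' @param species species to include (default: all shared columns).
#' @return the relative error E, with attribute `absolute`.
#' @examples
#' # identical series have error 0; a constant offset d on a constant
#' # reference r gives d / r
#' @export
seriesError <- function(test, reference, species = NULL) {
  if (is(test, "TrajectoryEnsemble")) test <- ensembleSeries(test)
  if (is(reference, "TrajectoryEnsemble"))
    reference <- ensembleSeries(reference)
  stopifnot(is(test, "EnsembleSeries"), is(reference, "EnsembleSeries"))
  if (length(test@times) != length(reference@times) ||
      any(abs(test@times - reference@times) >
          1e-9 * (1 + max(abs(reference@times)))))
    stop("sample grids differ")
  if (is.null(species))
    species <- intersect(colnames(test@mean), colnames(reference@mean))
  mt <- test@mean[, species, drop = FALSE]
  mr <- reference@mean[, species, drop = FALSE]
  denom <- sum(mr)
  if (denom <= 0) stop("reference series sums to zero")
  absErr <- sum(abs(mt - mr))
  structure(absErr / denom, absolute = absErr)
}

#' Copy-number distribution at a fixed time
#'
#' Empirical distribution of one species' copy number at a given sample
#' time across the trajectories of an ensemble, with integer-valued bins.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param species species name.
#' @param t sample time (must match a grid point).
#' @return list with `counts` (one value per trajectory), `density`
#'   (table over integer values), `mean` and `sd`.
#' @export
endpointDensity <- function(ensemble, species, t) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"),
            species %in% ensemble@speciesNames)
  i <- which(abs(ensemble@times - t) <=
             1e-9 * (1 + abs(t)))
  if (length(i) != 1L)
    stop("'t' must match exactly one sample time of the ensemble")
  v <- vapply(ensemble@trajectories, function(tr) tr@counts[i, species],
              numeric(1))
  list(counts = v, density = table(factor(v, levels = min(v):max(v))),
       mean = mean(v), sd = sd(v))
}

#' Extract rebinding times from a reaction event log
#'
#' For a reversible pair A + B <-> AB tracked one pair at a time, the
#' rebinding time is the interval between a dissociation and the next
#' association. The log must come from a run with `recordReactions =
#' TRUE` of a model containing exactly one matching dissociation /
#' association channel pair and at most one pair in flight at any time
#' (ambiguous pairing is refused, since gaps could not be attributed).
#'
#' @param x a [Trajectory-class] with a reaction log, or the log
#'   data.frame itself.
#' @param model the generating [RDModel-class] (identifies the channel
#'   pair).
#' @return numeric vector of rebinding durations (possibly empty).
#' @export
collectRebinds <- function(x, model) {
  log <- if (is(x, "Trajectory")) x@eventLog else x
  stopifnot(is(model, "RDModel"))
  ## the reversible pair: a 2-product unimolecular channel whose products
  ## are the reactants of a bimolecular channel producing its reactant
  pair <- NULL
  for (i in seq_along(model@channels)) {
    u <- model@channels[[i]]
    if (u@order != 1L || length(u@products) != 2L) next
    for (j in seq_along(model@channels)) {
      b <- model@channels[[j]]
      if (b@order != 2L) next
      if (setequal(b@reactants, u@products) &&
          identical(sort(b@products), sort(u@reactants))) {
        if (!is.null(pair)) stop("multiple reversible pairs in the model")
        pair <- c(dis = i, assoc = j)
      }
    }
  }
  if (is.null(pair)) stop("no reversible dissociation/association pair")
  ## at most one pair may be in flight: total initial copies of the
  ## complex and the free partners must not exceed one pair
  ic <- initialCounts(model)
  u <- model@channels[[pair["dis"]]]
  if (ic[u@reactants] + max(ic[u@products]) > 1L)
    stop("ambiguous pairing: more than one reactive pair can coexist")
  if (!nrow(log)) return(numeric())
  keep <- log$channel %in% pair
  tms <- log$time[keep]
  chs <- log$channel[keep]
  out <- numeric(0)
  pending <- NA_real_
  for (r in seq_along(tms)) {
    if (chs[r] == pair["dis"]) {
      if (!is.na(pending)) stop("two dissociations without an association")
      pending <- tms[r]
    } else if (!is.na(pending)) {
      out <- c(out, tms[r] - pending)
      pending <- NA_real_
    }
  }
  out
}

#' Run the rebinding benchmark
#'
#' Simulates a reversible-pair model until a target number of
#' associations has fired and returns the dissociation-to-reassociation
#' gaps. With the default hierarchy the products of each dissociation
#' are co-placed on the finest mesh and promoted outward as they
#' diffuse; `singleMeshLevel` gives the single-mesh reference sample.
#'
#' @param model a reversible-pair model (default [rdFixture]`("rebind")`).
#' @param nRebinds target number of rebind events.
#' @param seed RNG seed.
#' @param C transfer constant.
#' @param singleMeshLevel pin all species to one level (reference mode).
#' @param maxEvents event budget guard.
#' @return numeric vector of `nRebinds` rebinding times.
#' @export
runRebindBenchmark <- function(model = rdFixture("rebind"),
                               nRebinds = 1e4, seed = NULL, C = model@transferC,
                               singleMeshLevel = NULL, maxEvents = 1e12) {
  assoc <- NULL
  for (j in seq_along(model@channels))
    if (model@channels[[j]]@order == 2L) assoc <- j
  if (is.null(assoc)) stop("model has no association channel")
  tr <- simulateTrajectories(model, nTrajectories = 1L, tFinal = Inf,
                             sampleTimes = 0, seed = seed, C = C,
                             singleMeshLevel = singleMeshLevel,
                             recordReactions = TRUE, stopChannel = assoc,
                             stopCount = nRebinds, maxEvents = maxEvents,
                             quiet = TRUE)
  collectRebinds(tr, model)
}
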