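## Lattice constants of the Green's function correction. The 3D value is
## exercised throughout; the 2D value only enters the 2D formula branch,
## which is exposed for reference but not used by the (3D-only) simulator.
.C2 <- 0.1951
.C3 <- 1.5164

#' Lattice Green's function correction
#'
#' The correction G(h, sigma) that converts a microscopic association rate
#' into the per-pair mesoscopic firing rate of a voxel of width h (see
#' [mesoRate()]). In 3D, G(h, sigma) = 1/(4 pi sigma) - C3/(6 h) with
#' C3 = 1.5164; it vanishes at the critical mesh size h* = (2/3) pi C3
#' sigma and tends to 1/(4 pi sigma) as h grows. The 2D branch
#' (1/(2 pi)) log(h / (sqrt(pi) sigma)) - (1/4)(3/(2 pi)) + C2, with
#' C2 = 0.1951, is provided for completeness; only the 3D branch is used
#' by the simulator.
#'
#' @param h voxel width (> 0); vectorised.
#' @param sigma summed reaction radius of the pair (> 0).
#' @param dim 2 or 3.
#' @return the correction (1/length in 3D, dimensionless in 2D).
#' @examples
#' greenCorrection(1 / 64, 0.0025)          # ~ 15.656
#' greenCorrection(criticalMeshSize(0.01), 0.01)  # 0
#' @export
greenCorrection <- function(h, sigma, dim = 3) {
  if (any(h <= 0) || sigma <= 0)
    stop("'h' and 'sigma' must be positive")
  if (!(dim %in% c(2, 3))) stop("'dim' must be 2 or 3")
  if (dim == 3) 1 / (4 * pi * sigma) - .C3 / (6 * h)
  else (1 / (2 * pi)) * log(h / (sqrt(pi) * sigma)) -
    (1 / 4) * (3 / (2 * pi)) + .C2
}

#' Critical (optimal) mesh size
#'
#' The mesh width at which the 3D Green's function correction vanishes,
#' h* = (2/3) pi C3 sigma (about 3.18 sigma). At h = h* the mesoscopic
#' model reproduces the microscopic mean binding time exactly; finer
#' meshes make the on-lattice model less, not more, accurate.
#'
#' @param sigma summed reaction radius (> 0); vectorised.
#' @return h*.
#' @examples
#' criticalMeshSize(2 * 0.00246)   # ~ 1/64
#' @export
criticalMeshSize <- function(sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  (2 / 3) * pi * .C3 * sigma
}

#' Mesoscopic bimolecular reaction rate
#'
#' Converts a microscopic association rate k (volume/time in 3D) into the
#' per-pair firing rate of two molecules sharing a voxel of width h:
#' k_meso = (k / h^d) / (1 + (k / D) G(h, sigma)), where D is the sum of
#' the two diffusion constants and G is [greenCorrection()]. For h below
#' the critical mesh size the conversion is still returned, with a
#' warning, since accuracy (not validity) degrades there.
#'
#' @param kMicro microscopic rate (>= 0).
#' @param sigma summed reaction radius (> 0).
#' @param D summed diffusion constant of the pair (> 0 when kMicro > 0).
#' @param h voxel width (> 0); vectorised.
#' @param dim 2 or 3.
#' @param warn warn when h < h* (3D only).
#' @return per-pair firing rate (1/time).
#' @examples
#' mesoRate(1, 0.0025, 1, 1 / 64)   # ~ 1.574e4
#' @export
mesoRate <- function(kMicro, sigma, D, h, dim = 3, warn = TRUE) {
  if (kMicro < 0) stop("'kMicro' must be >= 0")
  if (kMicro == 0) return(rep(0, length(h)))
  if (D <= 0)
    stop("'D' must be positive when 'kMicro' > 0 (correction undefined)")
  if (warn && dim == 3 && any(h < criticalMeshSize(sigma)))
    warning("mesh width below the critical size h*; ",
            "accuracy degrades on meshes finer than h* = ",
            signif(criticalMeshSize(sigma), 5), call. = FALSE)
  G <- greenCorrection(h, sigma, dim)
  denom <- 1 + (kMicro / D) * G
  if (any(denom <= 0))
    stop("mesh too fine: the rate conversion denominator 1 + (k/D) G ",
         "is not positive")
  (kMicro / h^dim) / denom
}

#' Relative mean-rebind-time error of a mesh
#'
#' W(h) = (k / D) G(h, sigma): the relative error of the mesoscopic mean
#' rebind time against the microscopic model on a mesh of width h. W
#' vanishes at the critical mesh size, is negative below it, and
#' increases towards k / (4 pi sigma D) as h grows.
#'
#' @inheritParams mesoRate
#' @return dimensionless relative error; vectorised over `h`.
#' @export
rebindError <- function(kMicro, sigma, D, h, dim = 3) {
  if (kMicro < 0) stop("'kMicro' must be >= 0")
  if (kMicro == 0) return(rep(0, length(h)))
  if (D <= 0) stop("'D' must be positive when 'kMicro' > 0")
  (kMicro / D) * greenCorrection(h, sigma, dim)
}

## channel-level pair parameters: sigma = sum of reactant radii,
## D = sum of reactant diffusion constants
.channelSigma <- function(model, ch) {
  st <- speciesTable(model)
  sum(st$radius[match(ch@reactants, st$name)])
}

.channelD <- function(model, ch) {
  st <- speciesTable(model)
  sum(st$D[match(ch@reactants, st$name)])
}

#' Mesoscopic rates, rebind errors and critical sizes for a model
#'
#' Tabulates, for every bimolecular channel and mesh level, the pair
#' parameters (sigma, D), the per-pair mesoscopic rate, the relative
#' rebind-time error W(h) and the critical mesh size h*.
#'
#' @param model an [RDModel-class].
#' @return data.frame with one row per (bimolecular channel, level).
#' @export
mesoRateTable <- function(model) {
  hs <- voxelWidths(model)
  rows <- list()
  rt <- reactionTable(model)
  for (i in seq_along(model@channels)) {
    ch <- model@channels[[i]]
    if (ch@order != 2L) next
    sg <- .channelSigma(model, ch)
    Dp <- .channelD(model, ch)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = i, reaction = paste(rt$reactants[i], "->", rt$products[i]),
      level = seq_along(hs) - 1L, h = hs, sigma = sg, D = Dp,
      kMeso = mesoRate(ch@rate, sg, Dp, hs, warn = FALSE),
      W = rebindError(ch@rate, sg, Dp, hs),
      hStar = criticalMeshSize(sg))
  }
  if (!length(rows))
    return(data.frame(channel = integer(), reaction = character(),
                      level = integer(), h = numeric(), sigma = numeric(),
                      D = numeric(), kMeso = numeric(), W = numeric(),
                      hStar = numeric()))
  do.call(rbind, rows)
}

#' Assign each species its finest required mesh level
#'
#' For every species taking part in a bimolecular channel, finds the
#' coarsest level whose voxel width h satisfies the admissible-mesh
#' criterion k / (1 + epsilon) < k_meso h^3 (equivalently W(h) < epsilon)
#' for every bimolecular channel the species participates in. Since W(h)
#' grows with h, fine meshes satisfy the criterion and coarse ones do
#' not; the assigned level is the coarsest admissible one. Species with
#' no bimolecular involvement are assigned level 0 (the coarsest,
#' well-mixed mesh). If even the finest level fails the criterion the
#' finest level is assigned with a warning: the benchmark systems are
#' deliberately parameterised at exactly this edge.
#'
#' @param model an [RDModel-class].
#' @param epsilon tolerance (defaults to the model's).
#' @return named integer vector of level indices (0 = coarsest).
#' @examples
#' assignSpeciesLevels(rdFixture("single_layer"))
#' @export
assignSpeciesLevels <- function(model, epsilon = model@epsilon) {
  stopifnot(epsilon > 0)
  hs <- voxelWidths(model)
  nm <- speciesNames(model)
  out <- setNames(rep(0L, length(nm)), nm)
  ## admissible[ch, l]: channel ch satisfies the criterion on level l
  biIdx <- which(vapply(model@channels, function(x) x@order == 2L,
                        logical(1)))
  if (!length(biIdx)) return(out)
  adm <- matrix(NA, length(biIdx), length(hs))
  for (j in seq_along(biIdx)) {
    ch <- model@channels[[biIdx[j]]]
    sg <- .channelSigma(model, ch)
    Dp <- .channelD(model, ch)
    km <- mesoRate(ch@rate, sg, Dp, hs, warn = FALSE)
    adm[j, ] <- ch@rate / (1 + epsilon) < km * hs^3
  }
  for (s in nm) {
    inCh <- vapply(seq_along(biIdx), function(j)
      s %in% model@channels[[biIdx[j]]]@reactants, logical(1))
    if (!any(inCh)) next
    ok <- apply(adm[inCh, , drop = FALSE], 2, all)
    if (any(ok)) {
      out[s] <- which(ok)[1] - 1L   # coarsest admissible level
    } else {
      out[s] <- length(hs) - 1L
      warning("species '", s, "': even the finest level violates the ",
              "mesh criterion at epsilon = ", epsilon,
              "; assigning the finest level", call. = FALSE)
    }
  }
  out
}
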