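# Small models built in code for the unit tests.

# one immobile coarse molecule + one diffusing fine molecule with an
# irreversible association
bindingPairModel <- function(k = 1, radius = 0.0025, D = 1) {
  rdModel(
    species = list(rdSpecies("A", 0, radius), rdSpecies("B", D, radius),
                   rdSpecies("AB", 0, 2 * radius)),
    channels = list(reaction(c("A", "B"), "AB", k)),
    init = c(A = 1L, B = 1L), nLevels = 7L, name = "binding-pair")
}

# pure diffusion: one inert species, no reactions
diffusionOnlyModel <- function(D = 1, nLevels = 7L) {
  rdModel(species = list(rdSpecies("X", D, 0)), channels = list(),
          init = c(X = 1L), nLevels = nLevels, name = "diffusion-only")
}

# pure decay
decayModel <- function(k = 2, n = 500L) {
  rdModel(species = list(rdSpecies("A", 1, 0)),
          channels = list(reaction("A", character(0), k)),
          init = c(A = n), nLevels = 4L, name = "decay")
}

# random small well-formed model for property tests
randomModel <- function(seed) {
  set.seed(seed)
  nSp <- sample(2:4, 1)
  nm <- paste0("X", seq_len(nSp))
  sp <- lapply(nm, function(s)
    rdSpecies(s, D = runif(1, 0.5, 2), radius = runif(1, 0.002, 0.004)))
  chans <- list()
  # one dissociation, one association, maybe a decay / birth
  if (nSp >= 3) {
    chans <- c(chans, list(reaction(nm[1], nm[2:3], runif(1, 0.5, 2)),
                           reaction(nm[2:3], nm[1], runif(1, 0.5, 2))))
  } else {
    chans <- c(chans, list(reaction(nm[1:2], nm[1], runif(1, 0.5, 2))))
  }
  if (runif(1) < 0.5)
    chans <- c(chans, list(reaction(nm[nSp], character(0),
                                    runif(1, 0.5, 2))))
  if (runif(1) < 0.5)
    chans <- c(chans, list(reaction(character(0), nm[1],
                                    runif(1, 1, 5))))
  ini <- setNames(sample(1:20, nSp, replace = TRUE), nm)
  rdModel(species = sp, channels = chans, init = ini, nLevels = 5L,
          name = paste0("random-", seed))
}

# run the engine through the internal entry point to inspect
# initialization diagnostics
rawEngineRun <- function(model, placement, tFinal = 0,
                         sampleTimes = 0, ...) {
  prep <- hrdme:::.prepareEngine(model, quiet = TRUE, ...)
  init <- hrdme:::.samplePlacement(prep, initialCounts(model), placement)
  ctrl <- list(tFinal = tFinal, sampleTimes = sampleTimes,
               stopChannel = -1L, stopCount = 0,
               recordReactions = FALSE, recordTransfers = FALSE,
               maxEvents = 1e9)
  hrdme:::.npmRun(c(prep, list(init = init)), ctrl)
}
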