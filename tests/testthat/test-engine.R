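# The next-particle event loop.

test_that("initialization queues the expected tentative events", {
  # two co-located reactive molecules: 2 diffusion + 1 bimolecular event
  mb <- bindingPairModel()
  pl <- data.frame(species = c("A", "B"), level = 5,
                   i = 3, j = 4, k = 5)
  res <- rawEngineRun(mb, pl, speciesLevels = c(A = 5L, B = 5L, AB = 5L))
  # one diffusion event (A is immobile, D = 0) plus the pair event
  expect_identical(res$initEvents, c(1L, 0L, 1L, 0L))
  # molecules on a mesh with neighbours: one diffusion event each, one
  # unimolecular event per molecule with a unimolecular channel
  md <- decayModel(k = 1, n = 100L)
  pl <- data.frame(species = "A", level = 2,
                   i = rep(0:3, 25), j = rep(0:3, each = 25), k = 1)
  res <- rawEngineRun(md, pl, speciesLevels = c(A = 2L))
  expect_identical(res$initEvents[1:2], c(100L, 100L))
  # a birth channel holds exactly one pending event
  mb2 <- rdModel(species = list(rdSpecies("S", 1, 0)),
                 channels = list(reaction(character(0), "S", 3)),
                 nLevels = 3L, name = "birth")
  res <- rawEngineRun(mb2, NULL)
  expect_identical(res$initEvents, c(0L, 0L, 0L, 1L))
})

test_that("diffusion alone conserves molecules and reaches the horizon", {
  m <- diffusionOnlyModel(D = 1, nLevels = 5L)
  tr <- simulateTrajectories(m, tFinal = 2, nSamples = 20,
                             singleMeshLevel = 4, seed = 2, quiet = TRUE)
  expect_true(all(speciesCounts(tr) == 1L))
  expect_gt(tr@nEvents, 100)
})

test_that("unimolecular decay matches the exponential law exactly", {
  k <- 2
  m <- decayModel(k = k, n = 500L)
  tr <- simulateTrajectories(m, tFinal = 30, nSamples = 10,
                             recordReactions = TRUE,
                             speciesLevels = c(A = 0L), seed = 4,
                             quiet = TRUE)
  ev <- eventLog(tr)
  expect_identical(nrow(ev), 500L)   # every molecule decays once
  expect_gt(ks.test(ev$time, pexp, rate = k)$p.value, 0.01)
})

test_that("bimolecular events require co-location through the ancestor chain", {
  mb <- bindingPairModel()
  lv <- c(A = 5L, B = 6L, AB = 6L)
  # long enough for the co-located pair to fire often, far too short for
  # the distant molecule to diffuse across the domain
  short <- 2e-4
  # B's fine voxel inside A's coarse voxel: the pair can fire
  inPl <- data.frame(species = c("A", "B"), level = c(5, 6),
                     i = c(0, 1), j = c(0, 1), k = c(0, 1))
  # B outside A's subtree: no reaction possible yet
  outPl <- data.frame(species = c("A", "B"), level = c(5, 6),
                      i = c(0, 63), j = c(0, 63), k = c(0, 63))
  nIn <- nOut <- 0L
  for (s in 1:150) {
    set.seed(s)
    a <- simulateTrajectories(mb, tFinal = short, sampleTimes = c(0, short),
                              placement = inPl, speciesLevels = lv,
                              quiet = TRUE)
    b <- simulateTrajectories(mb, tFinal = short, sampleTimes = c(0, short),
                              placement = outPl, speciesLevels = lv,
                              quiet = TRUE)
    nIn <- nIn + unname(speciesCounts(a)[2, "AB"] == 1L)
    nOut <- nOut + unname(speciesCounts(b)[2, "AB"] == 1L)
  }
  expect_identical(nOut, 0L)
  expect_gt(nIn, 20L)
})

test_that("cross-level pairs fire at the rate of the coarser mesh", {
  # immobile molecule on the one-voxel mesh + a diffusing fine molecule:
  # binding is exponential with the coarse-mesh mesoscopic rate no matter
  # how the fine molecule moves or is promoted
  mb <- bindingPairModel()
  rate0 <- mesoRate(1, 0.005, 1, 1, warn = FALSE)
  ens <- simulateTrajectories(mb, nTrajectories = 1500, tFinal = Inf,
                              sampleTimes = 0,
                              speciesLevels = c(A = 0L, B = 6L, AB = 0L),
                              stopChannel = 1, stopCount = 1, seed = 77,
                              quiet = TRUE)
  bind <- vapply(trajectories(ens), function(x) x@finalTime, numeric(1))
  expect_gt(ks.test(bind, pexp, rate = rate0)$p.value, 0.01)
})

test_that("event times are non-decreasing and runs are reproducible", {
  for (s in c(101, 202, 303)) {
    m <- randomModel(s)
    tr <- suppressWarnings(
      simulateTrajectories(m, tFinal = 0.5, nSamples = 10,
                           recordReactions = TRUE, seed = s, quiet = TRUE))
    ev <- eventLog(tr)
    if (nrow(ev)) expect_false(is.unsorted(ev$time))
    expect_true(all(speciesCounts(tr) >= 0L))
    tr2 <- suppressWarnings(
      simulateTrajectories(m, tFinal = 0.5, nSamples = 10,
                           recordReactions = TRUE, seed = s, quiet = TRUE))
    expect_identical(speciesCounts(tr), speciesCounts(tr2))
    expect_identical(eventLog(tr)$time, eventLog(tr2)$time)
  }
})

test_that("a zero-horizon run echoes the initial counts", {
  m <- rdFixture("single_layer")
  tr <- simulateTrajectories(m, tFinal = 0, sampleTimes = 0, seed = 1,
                             quiet = TRUE)
  expect_identical(unname(speciesCounts(tr)[1, ]),
                   unname(initialCounts(m)))
})

test_that("birth events replenish at the zeroth-order rate", {
  k <- 50
  m <- rdModel(species = list(rdSpecies("S", 1, 0)),
               channels = list(reaction(character(0), "S", k)),
               nLevels = 4L, speciesLevels = c(S = 3L), name = "birth")
  ens <- simulateTrajectories(m, nTrajectories = 200, tFinal = 1,
                              nSamples = 4, seed = 55, quiet = TRUE)
  endCounts <- vapply(trajectories(ens),
                      function(tr) tr@counts[5, "S"], numeric(1))
  # Poisson(k): mean within 4 standard errors
  expect_lt(abs(mean(endCounts) - k), 4 * sqrt(k / 200))
})
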