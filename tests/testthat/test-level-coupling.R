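# Fine-to-coarse promotion and product placement across levels.

test_that("transfer time is (C h)^2 / (6 D)", {
  m <- rdFixture("single_layer")
  expect_equal(transferTime(m, "S11", level = 6), (20 / 64)^2 / 6,
               tolerance = 1e-12)
  expect_equal(transferTime(m, "S11", level = 6), 0.01628,
               tolerance = 1e-3)
  tt <- transferTime(m, "S11")
  expect_equal(tt[-7] / tt[-1], rep(4, 6))  # quadruples per coarser level
  expect_equal(transferTime(m, "S11", level = 6, C = 1),
               transferTime(m, "S11", level = 6) / 400)
  m0 <- rdModel(species = list(rdSpecies("A", 0, 0)), channels = list(),
                init = c(A = 1L), nLevels = 4L)
  expect_identical(transferTime(m0, "A"), rep(Inf, 4))
  expect_error(transferTime(m, "nope"), "unknown species")
})

test_that("a diffusing molecule climbs the hierarchy level by level", {
  # born on the finest level, promoted one level at a time once its
  # diffusion clock exceeds each level's transfer time
  m <- diffusionOnlyModel(D = 1, nLevels = 7L)
  pl <- data.frame(species = "X", level = 6, i = 31, j = 31, k = 31)
  tr <- simulateTrajectories(m, tFinal = 30, sampleTimes = c(0, 30),
                             placement = pl, speciesLevels = c(X = 6L),
                             recordTransfers = TRUE, seed = 8,
                             quiet = TRUE)
  tf <- transferLog(tr)
  expect_identical(tf$fromLevel, 6:1)
  expect_identical(tf$toLevel, 5:0)
  # each promotion fires at (or just after) the accumulated clock
  thresholds <- transferTime(m, "X")[tf$fromLevel + 1L]
  waits <- diff(c(0, tf$time))
  expect_true(all(waits >= thresholds))
  # the event queue resolves jumps much faster than the transfer times,
  # so the overshoot past each threshold is small
  expect_true(all(waits <= thresholds * 1.05))
  # promotion preserves position coarsely: the target voxel is the parent
  n <- 2^tf$fromLevel
  fi <- tf$fromVoxel %% n
  fj <- (tf$fromVoxel %/% n) %% n
  fk <- tf$fromVoxel %/% n^2
  np <- 2^tf$toLevel
  expect_identical(tf$toVoxel,
                   as.integer((fi %/% 2) + np * (fj %/% 2) +
                              np^2 * (fk %/% 2)))
  # final resting place is the single coarsest voxel
  expect_identical(tr@finalState$level, 0L)
})

test_that("molecules below the transfer threshold or at level 0 stay put", {
  m <- diffusionOnlyModel(D = 1, nLevels = 7L)
  # horizon far below the level-6 transfer time: no promotion
  tr <- simulateTrajectories(m, tFinal = 1e-3, sampleTimes = c(0, 1e-3),
                             placement = data.frame(species = "X",
                               level = 6, i = 3, j = 3, k = 3),
                             speciesLevels = c(X = 6L),
                             recordTransfers = TRUE, seed = 1,
                             quiet = TRUE)
  expect_identical(nrow(transferLog(tr)), 0L)
  expect_identical(tr@finalState$level, 6L)
  # level-0 molecules have nowhere to go and never transfer
  tr0 <- simulateTrajectories(m, tFinal = 100, sampleTimes = c(0, 100),
                              speciesLevels = c(X = 0L),
                              recordTransfers = TRUE, seed = 1,
                              quiet = TRUE)
  expect_identical(nrow(transferLog(tr0)), 0L)
})

test_that("disabling transfers reproduces the single-mesh solver exactly", {
  m <- rdFixture("single_layer")
  a <- simulateTrajectories(m, tFinal = 0.3, nSamples = 30, seed = 17,
                            speciesLevels = c(S1 = 6L, S11 = 6L,
                                              S12 = 6L, S2 = 6L),
                            C = Inf, quiet = TRUE)
  b <- simulateTrajectories(m, tFinal = 0.3, nSamples = 30, seed = 17,
                            singleMeshLevel = 6, quiet = TRUE)
  expect_identical(speciesCounts(a), speciesCounts(b))
})

test_that("dissociation products are co-placed in one finest-level voxel", {
  m <- rdFixture("single_layer")
  tr <- simulateTrajectories(m, tFinal = 0.5, nSamples = 5,
                             recordReactions = TRUE, seed = 23,
                             quiet = TRUE)
  ev <- eventLog(tr)
  dis <- ev[ev$channel == 1L, ]
  expect_gt(nrow(dis), 10L)
  expect_true(all(dis$p1Level == 6L))
  expect_true(all(dis$p2Level == 6L))
  expect_identical(dis$p1Voxel, dis$p2Voxel)
})

test_that("products on a finer level are uniform over the descendants", {
  # immobile level-0 emitters dissociate; the shared product voxel on
  # level 2 must be uniform over all 64 descendants
  m <- rdModel(
    species = list(rdSpecies("A", 0, 0), rdSpecies("P1", 0, 0),
                   rdSpecies("P2", 0, 0)),
    channels = list(reaction("A", c("P1", "P2"), 1)),
    init = c(A = 10000L), nLevels = 3L,
    speciesLevels = c(A = 0L, P1 = 2L, P2 = 2L), name = "emitter")
  tr <- simulateTrajectories(m, tFinal = 20, sampleTimes = c(0, 20),
                             recordReactions = TRUE, seed = 32,
                             quiet = TRUE)
  ev <- eventLog(tr)
  expect_gt(nrow(ev), 9900L)
  obs <- tabulate(ev$p1Voxel + 1L, nbins = 64)
  expect_gt(chisq.test(obs)$p.value, 0.01)
  # product of a coarser target level takes the unique ancestor:
  # association products of the binding pair land on level 0
  mb <- bindingPairModel()
  trb <- simulateTrajectories(mb, tFinal = Inf, sampleTimes = 0,
                              speciesLevels = c(A = 0L, B = 6L, AB = 0L),
                              stopChannel = 1, stopCount = 1,
                              recordReactions = TRUE, seed = 3,
                              quiet = TRUE)
  evb <- eventLog(trb)
  expect_identical(evb$p1Level, 0L)
  expect_identical(evb$p1Voxel, 0L)
})
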