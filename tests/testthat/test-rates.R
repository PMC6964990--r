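# Mesoscopic rate conversion and mesh-criterion machinery.

test_that("3D Green's function correction matches its closed form", {
  # direct evaluation: 1/(4 pi 0.0025) - 1.5164/(6/64)
  expect_equal(greenCorrection(1 / 64, 0.0025),
               1 / (4 * pi * 0.0025) - 1.5164 * 64 / 6, tolerance = 1e-12)
  expect_equal(greenCorrection(1 / 64, 0.0025), 15.656, tolerance = 1e-4)
  # large-h limit is the Smoluchowski contact term
  expect_equal(greenCorrection(1e9, 0.0025), 1 / (4 * pi * 0.0025),
               tolerance = 1e-6)
  # root at the critical mesh size, for any sigma
  for (sg in c(1e-4, 0.00246, 0.005, 1))
    expect_equal(greenCorrection(criticalMeshSize(sg), sg), 0,
                 tolerance = 1e-12)
  expect_error(greenCorrection(0, 0.01), "positive")
  expect_error(greenCorrection(0.1, -1), "positive")
  expect_error(greenCorrection(0.1, 0.01, dim = 4), "dim")
})

test_that("2D branch is finite, increasing in h and log-divergent", {
  h <- 10^seq(-2, 3, length.out = 50)
  g <- greenCorrection(h, 0.005, dim = 2)
  expect_true(all(is.finite(g)))
  expect_true(all(diff(g) > 0))
  # log growth: equal increments per decade of h
  dec <- greenCorrection(c(1, 10, 100), 0.005, dim = 2)
  expect_equal(diff(dec)[1], diff(dec)[2], tolerance = 1e-10)
  expect_equal(diff(dec)[1], log(10) / (2 * pi), tolerance = 1e-10)
})

test_that("critical mesh size is (2/3) pi C3 sigma", {
  expect_equal(criticalMeshSize(1), (2 / 3) * pi * 1.5164,
               tolerance = 1e-12)
  expect_equal(round(criticalMeshSize(1), 1), 3.2)
  # the rebind benchmark geometry: summed radius 2 x 0.00246 gives ~ 1/64
  expect_equal(criticalMeshSize(2 * 0.00246), 1 / 64, tolerance = 2e-3)
  # linear in sigma
  expect_equal(criticalMeshSize(0.02), 2 * criticalMeshSize(0.01))
  expect_error(criticalMeshSize(-1), "positive")
})

test_that("mesoscopic rate conversion follows the correction formula", {
  G <- greenCorrection(1 / 64, 0.0025)
  expect_equal(mesoRate(1, 0.0025, 1, 1 / 64, warn = FALSE),
               64^3 / (1 + G), tolerance = 1e-12)
  expect_equal(mesoRate(1, 0.0025, 1, 1 / 64, warn = FALSE), 1.574e4,
               tolerance = 1e-3)
  # k -> 0: correction factor -> 1, rate -> k/h^3
  k <- 1e-9
  expect_equal(mesoRate(k, 0.0025, 1, 1 / 8, warn = FALSE) / (k * 8^3), 1,
               tolerance = 1e-6)
  # at h = h* the rate is exactly k/h^3
  hstar <- criticalMeshSize(0.0025)
  expect_equal(mesoRate(1, 0.0025, 1, hstar), 1 / hstar^3,
               tolerance = 1e-12)
  # a mildly diffusion-influenced channel warns below h*; a strongly
  # diffusion-limited one is rejected there (conversion breaks down)
  expect_warning(mesoRate(0.01, 0.0025, 1, hstar / 2), "critical")
  expect_error(mesoRate(1, 0.0025, 1, hstar / 2, warn = FALSE),
               "too fine")
  expect_error(mesoRate(1, 0.0025, 0, 1 / 8), "positive")
  expect_equal(mesoRate(0, 0.0025, 1, 1 / 8), 0)
})

test_that("k_meso h^3 equals k at h* and falls to the well-mixed rate beyond", {
  h <- criticalMeshSize(0.005) * 2^seq(0, 12, by = 0.5)
  v <- mesoRate(1, 0.005, 1, h, warn = FALSE) * h^3
  expect_equal(v[1], 1, tolerance = 1e-12)    # exact at the critical size
  expect_true(all(diff(v) < 0))               # coarser meshes react slower
  expect_true(all(v <= 1 + 1e-9))
  # h -> infinity: the Collins-Kimball effective rate k/(1 + k/(4 pi s D))
  expect_equal(v[length(v)], 1 / (1 + 1 / (4 * pi * 0.005)),
               tolerance = 1e-3)
})

test_that("rebind error W(h) has the right sign structure and limits", {
  sg <- 0.005; hstar <- criticalMeshSize(sg)
  expect_equal(rebindError(1, sg, 1, hstar), 0, tolerance = 1e-12)
  expect_lt(rebindError(1, sg, 1, hstar / 2), 0)
  expect_gt(rebindError(1, sg, 1, 2 * hstar), 0)
  h <- hstar * 2^seq(-2, 8, by = 0.25)
  expect_true(all(diff(rebindError(1, sg, 1, h)) > 0))
  expect_equal(rebindError(1, sg, 1, 1e9), 1 / (4 * pi * sg),
               tolerance = 1e-6)
  # frozen spot value: k/D times the correction at h = 1/64
  expect_equal(rebindError(1, 0.0025, 1, 1 / 64),
               greenCorrection(1 / 64, 0.0025), tolerance = 1e-12)
})

test_that("species level assignment picks the coarsest admissible mesh", {
  m <- rdFixture("single_layer")
  lv <- assignSpeciesLevels(m)
  # species without bimolecular involvement live on the coarsest mesh
  expect_identical(lv[["S1"]], 0L)
  expect_identical(lv[["S2"]], 0L)
  # the fast-rebinding intermediates need the finest mesh at eps = 0.025
  expect_identical(lv[["S11"]], 6L)
  expect_identical(lv[["S12"]], 6L)
  # a huge tolerance admits the coarsest level for everything
  lvBig <- assignSpeciesLevels(m, epsilon = 1e6)
  expect_true(all(lvBig == 0L))
  # monotone in epsilon: a larger tolerance never yields a finer level
  eps <- c(0.01, 0.025, 0.1, 1, 10, 100)
  lvs <- sapply(eps, function(e) assignSpeciesLevels(m, epsilon = e))
  expect_true(all(apply(lvs, 1, function(r) all(diff(r) <= 0))))
})

test_that("levels fall back to the finest mesh with a warning when no level is admissible", {
  # sigma far too small for this hierarchy: even the finest mesh is coarse
  m <- rdModel(species = list(rdSpecies("A", 1, 1e-5),
                              rdSpecies("B", 1, 1e-5),
                              rdSpecies("AB", 1, 2e-5)),
               channels = list(reaction(c("A", "B"), "AB", 1)),
               nLevels = 4L, init = c(A = 1L, B = 1L))
  ws <- capture_warnings(lv <- assignSpeciesLevels(m))
  expect_length(ws, 2L)  # one warning per affected species
  expect_match(ws, "finest", all = TRUE)
  expect_identical(lv[["A"]], 3L)
  expect_identical(lv[["B"]], 3L)
})

test_that("mesoRateTable tabulates every bimolecular channel and level", {
  m <- rdFixture("single_layer")
  tab <- mesoRateTable(m)
  expect_identical(nrow(tab), 7L)  # one bi channel x 7 levels
  expect_equal(tab$hStar, rep(criticalMeshSize(0.005), 7))
  expect_equal(tab$kMeso[tab$level == 6],
               mesoRate(1, 0.005, 2, 1 / 64, warn = FALSE))
  expect_true(all(diff(tab$W) < 0))  # W shrinks as the mesh refines
})
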