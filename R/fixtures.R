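#' Built-in benchmark models
#'
#' Fully parameterised benchmark systems on the unit cube with a 7-level
#' hierarchy (coarsest 1 voxel, finest 64^3 = 262144 voxels), transfer
#' constant C = 20 and mesh tolerance epsilon = 0.025:
#'
#' \describe{
#'   \item{`rebind`}{A reversible pair S1 + S2 <-> S3 (association rate
#'     1.0, all reaction radii 0.00246 so the summed radius 0.00492 puts
#'     the critical mesh size at about 1/64, D = 1). Starts with a single
#'     bound S3. The dissociation rate does not influence the
#'     rebinding-time distribution and is set to 10 so most simulation
#'     time is spent in the unbound (rebinding) phase.}
#'   \item{`single_layer`}{The dissociation-rebinding chain
#'     S1 -> S11 + S12 -> S2 with k1 = k2 = 1, all radii 0.0025, D = 1,
#'     100 S1 molecules initially. S1 and S2 live on the coarsest mesh;
#'     the short-lived intermediates S11/S12 require the finest mesh.
#'     Default horizon 5 with 100 sampling intervals.}
#'   \item{`double_layer`}{Two chained layers,
#'     S1 -> S11 + S12 -> S2 -> S21 + S22 -> S3, all rates 1.0,
#'     otherwise as `single_layer`.}
#'   \item{`mapk`}{A MAPK phosphorylation-dephosphorylation cascade: a
#'     kinase KK drives K -> Kp -> Kpp through enzyme-substrate
#'     complexes, a phosphatase P reverses both steps, and the enzymes
#'     leave each catalytic step in an inactive starred form that relaxes
#'     at rate k7 = 693147.18. All radii 0.0024599, D = 1; 120 K, 30 KK
#'     and 30 P initially. All species are pinned to the finest mesh (no
#'     coarse-graining assumption is made for this system); pass
#'     `autoLevels = TRUE` to assign levels from the mesh criterion
#'     instead. Default horizon 50.}
#' }
#'
#' @param name one of `"rebind"`, `"single_layer"`, `"double_layer"`,
#'   `"mapk"`.
#' @param autoLevels for `mapk`: assign species levels from the mesh
#'   criterion instead of pinning everything to the finest mesh.
#' @return an [RDModel-class].
#' @examples
#' rdFixture("rebind")
#' initialCounts(rdFixture("mapk"))[c("K", "KK", "P")]
#' @export
rdFixture <- function(name = c("rebind", "single_layer", "double_layer",
                               "mapk"), autoLevels = FALSE) {
  name <- match.arg(name)
  switch(name,
    rebind = rdModel(
      name = "rebind",
      species = list(rdSpecies("S1", 1, 0.00246),
                     rdSpecies("S2", 1, 0.00246),
                     rdSpecies("S3", 1, 0.00246)),
      channels = list(reaction(c("S1", "S2"), "S3", 1.0),
                      reaction("S3", c("S1", "S2"), 10.0)),
      volume = 1, nLevels = 7L, init = c(S3 = 1L),
      C = 20, epsilon = 0.025, tFinal = 10, nSamples = 100L),
    single_layer = rdModel(
      name = "single_layer",
      species = list(rdSpecies("S1", 1, 0.0025),
                     rdSpecies("S11", 1, 0.0025),
                     rdSpecies("S12", 1, 0.0025),
                     rdSpecies("S2", 1, 0.0025)),
      channels = list(reaction("S1", c("S11", "S12"), 1.0),
                      reaction(c("S11", "S12"), "S2", 1.0)),
      volume = 1, nLevels = 7L, init = c(S1 = 100L),
      C = 20, epsilon = 0.025, tFinal = 5, nSamples = 100L,
      nTrajectories = 200L),
    double_layer = rdModel(
      name = "double_layer",
      species = list(rdSpecies("S1", 1, 0.0025),
                     rdSpecies("S11", 1, 0.0025),
                     rdSpecies("S12", 1, 0.0025),
                     rdSpecies("S2", 1, 0.0025),
                     rdSpecies("S21", 1, 0.0025),
                     rdSpecies("S22", 1, 0.0025),
                     rdSpecies("S3", 1, 0.0025)),
      channels = list(reaction("S1", c("S11", "S12"), 1.0),
                      reaction(c("S11", "S12"), "S2", 1.0),
                      reaction("S2", c("S21", "S22"), 1.0),
                      reaction(c("S21", "S22"), "S3", 1.0)),
      volume = 1, nLevels = 7L, init = c(S1 = 100L),
      C = 20, epsilon = 0.025, tFinal = 5, nSamples = 100L,
      nTrajectories = 200L),
    mapk = {
      sg <- 0.0024599
      sp <- c("K", "Kp", "Kpp", "KK", "KKs", "P", "Ps",
              "KK_K", "KK_Kp", "P_Kpp", "P_Kp")
      k1 <- 0.0448346; k2 <- 1.35; k3 <- 1.5
      k4 <- 0.0929902; k5 <- 1.73; k6 <- 15.0; k7 <- 693147.18
      m <- rdModel(
        name = "mapk",
        species = lapply(sp, function(s) rdSpecies(s, 1, sg)),
        channels = list(
          reaction(c("KK", "K"), "KK_K", k1),
          reaction("KK_K", c("KK", "K"), k2),
          reaction("KK_K", c("KKs", "Kp"), k3),
          reaction(c("KK", "Kp"), "KK_Kp", k4),
          reaction("KK_Kp", c("KK", "Kp"), k5),
          reaction("KK_Kp", c("KKs", "Kpp"), k6),
          reaction(c("P", "Kpp"), "P_Kpp", k1),
          reaction("P_Kpp", c("P", "Kpp"), k2),
          reaction("P_Kpp", c("Ps", "Kp"), k3),
          reaction(c("P", "Kp"), "P_Kp", k4),
          reaction("P_Kp", c("P", "Kp"), k5),
          reaction("P_Kp", c("Ps", "K"), k6),
          reaction("KKs", "KK", k7),
          reaction("Ps", "P", k7)),
        volume = 1, nLevels = 7L,
        init = c(K = 120L, KK = 30L, P = 30L),
        C = 20, epsilon = 0.025, tFinal = 50, nSamples = 100L,
        speciesLevels = if (autoLevels) integer()
                        else setNames(rep(6L, length(sp)), sp))
      m
    })
}
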