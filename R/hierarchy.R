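#' Mesh hierarchy topology
#'
#' Parent/child/ancestor maps and the same-level neighbour topology of the
#' nested Cartesian hierarchy. All maps are index arithmetic: the parent of
#' voxel (level, ijk) is (level - 1, floor(ijk / 2)); the 8 children of
#' (level, ijk) are (level + 1, 2 ijk + delta) for delta in \{0, 1\}^3.
#' Neighbours are the face-adjacent voxels on the same level; faces on the
#' domain boundary are simply absent (reflective boundary), so an interior
#' voxel has 6 neighbours and a corner voxel 3.
#'
#' @param v a [VoxelRef-class].
#' @param hierarchy a [MeshHierarchy-class] (needed to know where the
#'   finest level ends).
#' @param level target level for `ancestorAt`.
#' @return `parentVoxel` and `ancestorAt` a [VoxelRef-class]; `childVoxels`
#'   a list of 8 `VoxelRef`s; `voxelNeighbors` a list of 3 to 6 `VoxelRef`s
#'   (empty on level 0).
#' @examples
#' parentVoxel(voxelRef(3, c(5, 2, 7)))           # level 2, (2, 1, 3)
#' length(voxelNeighbors(voxelRef(2, c(0, 0, 0)))) # corner: 3
#' @name hierarchy-topology
NULL

#' @rdname hierarchy-topology
#' @export
parentVoxel <- function(v) {
  stopifnot(is(v, "VoxelRef"))
  if (v@level == 0L)
    stop("voxel on level 0 has no parent")
  voxelRef(v@level - 1L, v@ijk %/% 2L)
}

#' @rdname hierarchy-topology
#' @export
childVoxels <- function(v, hierarchy) {
  stopifnot(is(v, "VoxelRef"), is(hierarchy, "MeshHierarchy"))
  if (v@level >= hierarchy@nLevels - 1L)
    stop("voxel on the finest level has no children")
  delta <- expand.grid(0:1, 0:1, 0:1)
  lapply(seq_len(8), function(r)
    voxelRef(v@level + 1L, 2L * v@ijk + as.integer(delta[r, ])))
}

#' @rdname hierarchy-topology
#' @export
ancestorAt <- function(v, level) {
  stopifnot(is(v, "VoxelRef"))
  level <- as.integer(level)
  if (level > v@level)
    stop("'level' must be at or coarser than the voxel's level")
  voxelRef(level, v@ijk %/% 2L^(v@level - level))
}

#' @rdname hierarchy-topology
#' @export
voxelNeighbors <- function(v) {
  stopifnot(is(v, "VoxelRef"))
  n <- 2L^v@level
  out <- list()
  for (ax in 1:3) for (d in c(-1L, 1L)) {
    ijk <- v@ijk
    ijk[ax] <- ijk[ax] + d
    if (ijk[ax] >= 0L && ijk[ax] < n)
      out[[length(out) + 1L]] <- voxelRef(v@level, ijk)
  }
  out
}

#' Diffusion jump rate on a mesh level
#'
#' The diffusive jump process moves a molecule to a uniformly chosen
#' face-adjacent neighbour. The per-face rate on level l is D / h_l^2; the
#' total firing rate is (number of existing neighbours) x D / h_l^2, so
#' boundary voxels fire more slowly (reflective boundary) and the single
#' level-0 voxel does not diffuse at all.
#'
#' @param hierarchy a [MeshHierarchy-class].
#' @param D diffusion constant of the species.
#' @param level mesh level (0-based).
#' @param voxel optional [VoxelRef-class]; when given, the total rate uses
#'   that voxel's actual neighbour count instead of the interior count 6.
#' @return list with `perFace` (rate per existing face) and `total`.
#' @examples
#' h <- meshHierarchy(7)
#' jumpRate(h, D = 1, level = 6)$total   # interior: 6 * 64^2 = 24576
#' @export
jumpRate <- function(hierarchy, D, level, voxel = NULL) {
  stopifnot(is(hierarchy, "MeshHierarchy"), D >= 0,
            level >= 0, level < hierarchy@nLevels)
  h <- hierarchy@side / 2^level
  perFace <- D / h^2
  nNb <- if (level == 0L) 0L
         else if (is.null(voxel)) 6L
         else length(voxelNeighbors(voxel))
  list(perFace = perFace, total = nNb * perFace)
}

#' Summarise a mesh hierarchy
#'
#' Per-level voxel counts, widths and (optionally) per-species total
#' interior diffusion jump rates for a model.
#'
#' @param hierarchy a [MeshHierarchy-class].
#' @param model optional [RDModel-class]; adds one jump-rate column per
#'   species.
#' @param file optional path; when given the table is also written as a
#'   tab-separated report.
#' @return the summary data.frame, invisibly when `file` is given.
#' @export
hierarchySummary <- function(hierarchy, model = NULL, file = NULL) {
  lv <- 0:(hierarchy@nLevels - 1L)
  out <- data.frame(level = lv, perAxis = 2L^lv,
                    nVoxels = voxelCounts(hierarchy),
                    width = voxelWidths(hierarchy))
  if (!is.null(model)) {
    st <- speciesTable(model)
    for (i in seq_len(nrow(st)))
      out[[paste0("jump.", st$name[i])]] <-
        ifelse(lv == 0L, 0, 6 * st$D[i] / out$width^2)
  }
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
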