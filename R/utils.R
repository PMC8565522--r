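# Geometry helpers shared across modules. Voxel indices are 0-based and
# voxel-centred: integer (i,j,k) maps exactly onto a voxel centre in world mm.

#' Build a diagonal voxel-to-world affine centred on the grid
#'
#' World coordinates place the midsagittal plane at x = 0, so hemisphere
#' membership is simply the sign of world x. The grid centre voxel maps to the
#' world origin.
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric vector of length 3, mm per voxel.
#' @return a 4x4 affine matrix mapping 0-based voxel indices to world mm.
#' @export
default_affine <- function(grid_shape, voxel_size) {
  stopifnot(length(grid_shape) == 3, length(voxel_size) == 3,
            all(grid_shape >= 1), all(voxel_size > 0))
  centre <- (grid_shape - 1) / 2
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel_size, 3, 3)
  A[1:3, 4] <- -voxel_size * centre
  A
}

#' Map world-mm points to continuous 0-based voxel coordinates
#'
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of continuous voxel coordinates.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

#' Map 0-based voxel indices to world mm
#'
#' @param ijk n x 3 matrix of (possibly fractional) voxel coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

# Nearest-voxel mapping: n x 3 world points -> n x 3 integer 0-based indices.
nearest_voxel <- function(xyz, affine) {
  round(world_to_voxel(xyz, affine))
}

# Convert 0-based (i,j,k) rows to 1-based linear indices into an array of the
# given dim; returns NA for out-of-bounds rows.
voxel_linear_index <- function(ijk, dim) {
  ok <- ijk[, 1] >= 0 & ijk[, 1] < dim[1] &
        ijk[, 2] >= 0 & ijk[, 2] < dim[2] &
        ijk[, 3] >= 0 & ijk[, 3] < dim[3]
  idx <- 1 + ijk[, 1] + dim[1] * (ijk[, 2] + dim[2] * ijk[, 3])
  idx[!ok] <- NA_integer_
  idx
}

# Deterministic per-stage seed fan-out: one user seed yields independent,
# re-runnable stage seeds.  stage_seed(seed, k) = (seed * 1009 + k) mod 2^31-1.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% (2^31 - 1))
}

#' Network names for a K-network parcellation
#'
#' The canonical 7-network names (VIS, SM, DA, VA, LN, FPN, DMN) or generic
#' `N1..N17` for the 17-network variant.
#'
#' @param K number of networks.
#' @return character vector of length `K`.
#' @export
network_names <- function(K) {
  if (K == 7) c("VIS", "SM", "DA", "VA", "LN", "FPN", "DMN")
  else paste0("N", seq_len(K))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
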