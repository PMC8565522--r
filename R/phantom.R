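# Synthetic midsagittal phantom: a callosal slab crossed by homotopic bundles
# whose crossing zones are network-specific, plus bilateral cortical label
# boxes for each functional network. All geometry is deterministic given the
# grid; the phantom defines the ground truth every downstream stage is
# checked against.

# Internal layout constants (in voxels): each network owns a 3-voxel-wide
# anterior-posterior block, separated by 2-voxel gaps; the callosal slab is
# 3 voxels thick across the midline and 3 voxels tall.
.zone_width  <- 3L
.zone_gap    <- 2L
.y_margin    <- 3L
.slab_half   <- 1L   # slab spans centre +/- 1 voxel in x
.zone_height <- 3L

#' Generate a synthetic corpus-callosum phantom
#'
#' Constructs a common-space phantom holding a binary callosal mask confined
#' to a slab around the midsagittal plane, an integer label volume with one
#' homotopic pair of cortical boxes per functional network (left/right
#' decided by the sign of world x), and per-network ground-truth crossing
#' zones ordered anterior to posterior inside the mask. The crossing zones
#' are pairwise disjoint and their union is contained in the callosal mask.
#'
#' @param K number of functional networks, 7 (canonical) or 17.
#' @param grid_shape optional integer vector of length 3; defaults to the
#'   smallest grid that fits `K` disjoint zones with margins.
#' @param voxel_size mm per axis, default 2 mm isotropic.
#' @param seed unused (the geometry is deterministic); kept so all
#'   generators share one signature.
#' @return an object of class `cc_phantom`: a list with elements
#'   `grid_shape`, `voxel_size`, `affine`, `cc_mask` (logical array),
#'   `network_labels` (integer array, 0 background), `crossing_zones`
#'   (integer array, 0 outside any zone), `K`, and `zone_table` (one row per
#'   network with the zone's voxel-centre ranges).
#' @examples
#' ph <- make_phantom(K = 7)
#' sum(ph$cc_mask)            # callosal template voxel count V
#' table(ph$crossing_zones[ph$crossing_zones > 0])
#' @export
make_phantom <- function(K = 7, grid_shape = NULL, voxel_size = c(2, 2, 2),
                         seed = NULL) {
  if (!K %in% c(7L, 17L)) stop("K must be 7 or 17")
  K <- as.integer(K)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  pitch <- .zone_width + .zone_gap
  need_y <- 2L * .y_margin + K * .zone_width + (K - 1L) * .zone_gap
  if (is.null(grid_shape)) grid_shape <- c(13L, need_y, 9L)
  grid_shape <- as.integer(grid_shape)
  cx <- (grid_shape[1] - 1L) %/% 2L
  if (grid_shape[2] < need_y || grid_shape[1] < 13L || grid_shape[3] < 9L)
    stop("grid too small to place ", K, " disjoint crossing zones ",
         "(need at least 13 x ", need_y, " x 9 voxels)")

  affine <- default_affine(grid_shape, voxel_size)
  cz <- (grid_shape[3] - 1L) %/% 2L
  z0 <- cz - (.zone_height - 1L) %/% 2L          # 0-based zone z range
  zr <- z0 + seq_len(.zone_height) - 1L

  cc_mask <- array(FALSE, grid_shape)
  zones   <- array(0L, grid_shape)
  labels  <- array(0L, grid_shape)

  slab_x <- (cx - .slab_half):(cx + .slab_half)          # 0-based
  y_first <- .y_margin
  y_last  <- .y_margin + K * pitch - .zone_gap - 1L
  cc_mask[slab_x + 1L, (y_first:y_last) + 1L, zr + 1L] <- TRUE

  left_x  <- 1:3                                          # 0-based columns
  right_x <- (grid_shape[1] - 4L):(grid_shape[1] - 2L)
  zone_table <- data.frame(network = seq_len(K),
                           y0 = NA_integer_, y1 = NA_integer_,
                           z0 = NA_integer_, z1 = NA_integer_)
  for (n in seq_len(K)) {
    ys <- .y_margin + (n - 1L) * pitch
    yy <- ys + seq_len(.zone_width) - 1L
    zones[slab_x + 1L, yy + 1L, zr + 1L] <- n
    labels[left_x + 1L, yy + 1L, zr + 1L] <- n
    labels[right_x + 1L, yy + 1L, zr + 1L] <- n
    zone_table$y0[n] <- ys; zone_table$y1[n] <- ys + .zone_width - 1L
    zone_table$z0[n] <- z0; zone_table$z1[n] <- z0 + .zone_height - 1L
  }

  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 affine = affine, cc_mask = cc_mask,
                 network_labels = labels, crossing_zones = zones,
                 K = K, zone_table = zone_table,
                 left_x = left_x, right_x = right_x),
            class = "cc_phantom")
}

#' @export
print.cc_phantom <- function(x, ...) {
  cat("Synthetic callosal phantom\n")
  cat("  grid: ", paste(x$grid_shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_size, collapse = "x"), " mm\n", sep = "")
  cat("  networks (K):", x$K, "\n")
  cat("  callosal mask voxels (V):", sum(x$cc_mask), "\n")
  cat("  crossing-zone voxels:", sum(x$crossing_zones > 0), "\n")
  invisible(x)
}

# World-mm centres of the crossing-zone voxel columns for network n: one row
# per (y, z) column the bundle should thread. Used by the tractogram
# generator to guarantee full zone coverage at zero jitter.
zone_columns <- function(phantom, n) {
  zt <- phantom$zone_table[n, ]
  g <- expand.grid(y = zt$y0:zt$y1, z = zt$z0:zt$z1)
  voxel_to_world(cbind(0, g$y, g$z), phantom$affine)[, 2:3, drop = FALSE]
}

# World x of the lateral cortical box centres.
hemisphere_x <- function(phantom) {
  lx <- voxel_to_world(cbind(mean(phantom$left_x), 0, 0), phantom$affine)[1]
  rx <- voxel_to_world(cbind(mean(phantom$right_x), 0, 0), phantom$affine)[1]
  c(left = lx, right = rx)
}
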