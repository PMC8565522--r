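# From streamlines to callosal connection-count maps FN(s,v,n) and
# connection-probability maps P(s,v,n).

#' Dilate a label volume by a physical radius
#'
#' Every label mask is dilated by a Euclidean ball of `radius_mm`
#' (anisotropic voxel sizes respected). Where dilations overlap, the voxel
#' is resolved to the nearest original label; exact distance ties go to the
#' lower label index. Originally labelled voxels keep their label.
#'
#' @param labels integer array, 0 = background.
#' @param voxel_size mm per axis.
#' @param radius_mm dilation radius in mm (>= 0); the conventional choice
#'   for capturing streamline endpoints at the grey-white boundary is 2 mm.
#' @return integer array of the same shape.
#' @export
dilate_labels <- function(labels, voxel_size, radius_mm = 2) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  dm <- dim(labels)
  voxel_size <- rep_len(voxel_size, 3)
  r <- floor(radius_mm / voxel_size)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  offs$dist <- sqrt((offs$dx * voxel_size[1])^2 +
                    (offs$dy * voxel_size[2])^2 +
                    (offs$dz * voxel_size[3])^2)
  offs <- offs[offs$dist <= radius_mm + 1e-9, ]
  offs <- offs[order(offs$dist), ]

  out <- labels
  best <- array(Inf, dm)
  best[labels > 0] <- 0
  for (i in seq_len(nrow(offs))) {
    d <- c(offs$dx[i], offs$dy[i], offs$dz[i])
    if (all(d == 0)) next
    sh <- shift_array(labels, d)
    dist <- offs$dist[i]
    upd <- sh > 0 & (dist < best - 1e-9 |
                       (abs(dist - best) < 1e-9 & sh < out & out > 0))
    out[upd] <- sh[upd]
    best[upd] <- dist
  }
  out
}

# Translate an integer array by voxel offset d, zero-filling.
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(0L, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      dst[[ax]] <- (1 + d[ax]):dm[ax]
      src[[ax]] <- 1:(dm[ax] - d[ax])
    } else {
      dst[[ax]] <- 1:(dm[ax] + d[ax])
      src[[ax]] <- (1 - d[ax]):dm[ax]
    }
    if (abs(d[ax]) >= dm[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Densify a streamline to point spacing <= step (mm) by linear interpolation
# along arc length, then map to distinct 0-based voxel indices (nearest
# voxel centre, deduplicated per streamline). Returns linear 1-based array
# indices (NA-free; out-of-grid points dropped).
rasterize_streamline <- function(points, affine, dim, step) {
  if (nrow(points) < 2) stop("streamline needs at least 2 points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) {
    dense <- points[1, , drop = FALSE]
  } else {
    grid <- seq(0, total, by = step)
    if (grid[length(grid)] < total) grid <- c(grid, total)
    dense <- cbind(stats::approx(s, points[, 1], xout = grid)$y,
                   stats::approx(s, points[, 2], xout = grid)$y,
                   stats::approx(s, points[, 3], xout = grid)$y)
  }
  ijk <- nearest_voxel(dense, affine)
  idx <- voxel_linear_index(ijk, dim)
  unique(idx[!is.na(idx)])
}

#' Assign streamlines to functional networks
#'
#' A streamline is accepted for network n iff both endpoints fall in
#' label-n voxels of the (typically dilated) cortical label volume, the
#' endpoints lie in opposite hemispheres (sign of world x), and its voxel
#' path intersects the callosal mask. Heterotopic streamlines (endpoints in
#' two different networks) are rejected.
#'
#' @param tractogram list of n x 3 world-mm matrices.
#' @param cc_mask logical/binary 3-D array, the callosal mask.
#' @param labels integer label array (use [dilate_labels()] output).
#' @param affine 4x4 voxel-to-world affine shared by both volumes.
#' @param voxel_size mm per axis (used for the traversal step).
#' @return integer vector, one entry per streamline: the network id or
#'   `NA` if rejected.
#' @export
assign_streamlines <- function(tractogram, cc_mask, labels, affine,
                               voxel_size = NULL) {
  dm <- dim(labels)
  if (!identical(dim(cc_mask), dm)) stop("cc_mask and labels shapes differ")
  if (is.null(voxel_size)) voxel_size <- .affine_voxel_size(affine)
  step <- 0.5 * min(voxel_size)
  vapply(tractogram, function(p) {
    if (is.null(dim(p)) || nrow(p) < 2) stop("empty streamline")
    ends <- p[c(1, nrow(p)), , drop = FALSE]
    ijk <- nearest_voxel(ends, affine)
    li <- voxel_linear_index(ijk, dm)
    if (anyNA(li)) return(NA_integer_)
    l1 <- labels[li[1]]; l2 <- labels[li[2]]
    if (l1 == 0 || l1 != l2) return(NA_integer_)
    if (sign(ends[1, 1]) * sign(ends[2, 1]) >= 0) return(NA_integer_)
    path <- rasterize_streamline(p, affine, dm, step)
    if (!any(cc_mask[path] != 0)) return(NA_integer_)
    as.integer(l1)
  }, integer(1))
}

.affine_voxel_size <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' Count callosal streamline traversals per network
#'
#' Builds the per-subject connection-count map FN(s,v,n): for each accepted
#' streamline of network n, every distinct callosal voxel on its path is
#' incremented by one in channel n (a voxel visited twice by one streamline
#' counts once).
#'
#' @inheritParams assign_streamlines
#' @param K number of networks (defaults to `max(labels)`).
#' @param subject_id optional id stored in the result.
#' @return object of class `cc_connmap`: list with `counts` (4-D integer
#'   array, 4th axis = network), `K`, `affine`, `subject_id`, and `qc`
#'   (accepted/rejected tallies).
#' @export
count_connections <- function(tractogram, cc_mask, labels, affine,
                              K = NULL, subject_id = NULL,
                              voxel_size = NULL) {
  dm <- dim(labels)
  if (!identical(dim(cc_mask), dm))
    stop("mismatched volume shapes between cc_mask and labels")
  if (is.null(K)) K <- max(labels)
  if (is.null(voxel_size)) voxel_size <- .affine_voxel_size(affine)
  step <- 0.5 * min(voxel_size)
  assign <- assign_streamlines(tractogram, cc_mask, labels, affine, voxel_size)
  counts <- array(0L, c(dm, K))
  plane <- prod(dm)
  for (i in which(!is.na(assign))) {
    path <- rasterize_streamline(tractogram[[i]], affine, dm, step)
    path <- path[cc_mask[path] != 0]
    if (length(path))
      counts[path + (assign[i] - 1) * plane] <-
        counts[path + (assign[i] - 1) * plane] + 1L
  }
  structure(list(counts = counts, K = K, affine = affine,
                 subject_id = subject_id,
                 qc = list(n_streamlines = length(tractogram),
                           accepted = sum(!is.na(assign)),
                           rejected = sum(is.na(assign)),
                           per_network = tabulate(assign, nbins = K))),
            class = "cc_connmap")
}

#' @export
print.cc_connmap <- function(x, ...) {
  cat("Callosal connection-count map",
      if (!is.null(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  cat("  K =", x$K, "| accepted:", x$qc$accepted,
      "| rejected:", x$qc$rejected, "\n")
  invisible(x)
}

#' Normalize a connection-count map to connection probabilities
#'
#' P(s,v,n) = FN(s,v,n) / sum_n FN(s,v,n): at each voxel the counts are
#' divided by the voxel's total across networks, so channels sum to one on
#' the support (voxels traversed by at least one accepted streamline) and
#' are zero elsewhere.
#'
#' @param map a [count_connections()] result.
#' @return object of class `cc_probmap`: list with `probs` (4-D array),
#'   `support` (logical 3-D array), `K`, `affine`, `subject_id`.
#' @export
normalize_connections <- function(map) {
  stopifnot(inherits(map, "cc_connmap"))
  dm <- dim(map$counts)
  total <- array(rowSums(matrix(map$counts, ncol = dm[4])), dm[1:3])
  support <- total > 0
  probs <- array(0, dm)
  denom <- array(rep(total, dm[4]), dm)
  nz <- denom > 0
  probs[nz] <- map$counts[nz] / denom[nz]
  structure(list(probs = probs, support = support, K = map$K,
                 affine = map$affine, subject_id = map$subject_id),
            class = "cc_probmap")
}

#' @export
print.cc_probmap <- function(x, ...) {
  cat("Callosal connection-probability map",
      if (!is.null(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  cat("  K =", x$K, "| support voxels:", sum(x$support), "\n")
  invisible(x)
}
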