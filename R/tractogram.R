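# Synthetic homotopic streamline bundles. Each on-target streamline is a
# quadratic Bezier arc from a left-hemisphere cortical box, across the
# callosal slab through the network's crossing zone, to the homotopic right
# box. Crossing points cycle deterministically over every (y, z) voxel
# column of the zone so that, at zero jitter, a bundle covers its zone
# completely; endpoint and crossing jitter then model the endpoint
# dispersion of probabilistic tractography.

# Quadratic Bezier through control points p0, p1, p2 sampled at point
# spacing <= step (mm), approximated on the control polygon length.
bezier_arc <- function(p0, p1, p2, step) {
  len <- sqrt(sum((p1 - p0)^2)) + sqrt(sum((p2 - p1)^2))
  # the curve speed is bounded by twice the control-polygon legs, so 2*len
  # sample points guarantee gaps <= step
  m <- max(ceiling(2 * len / step) + 1, 8)
  t <- seq(0, 1, length.out = m)
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  dimnames(b) <- NULL
  b
}

#' Generate a synthetic tractogram for one subject
#'
#' For each requested network, emits `bundle_counts[n]` streamlines.
#' On-target streamlines connect homotopic cortical boxes through the
#' network's callosal crossing zone; a fraction `off_target_fraction` is
#' replaced by distractors that either stay within one hemisphere or
#' terminate outside every cortical label, and so must be rejected by the
#' connectivity stage. Point spacing never exceeds half the smallest voxel
#' dimension.
#'
#' @param phantom a [make_phantom()] object.
#' @param bundle_counts named integer vector (names = network ids as
#'   integers) or unnamed length-K vector of streamline counts.
#' @param endpoint_jitter_mm sd (mm) of isotropic Gaussian jitter applied to
#'   the two endpoints; the crossing point receives half this jitter.
#'   Default 1 mm.
#' @param off_target_fraction fraction of each bundle replaced by
#'   distractor streamlines, in \[0, 1). Default 0.1.
#' @param seed integer seed.
#' @return list of n x 3 world-mm matrices of class `cc_tractogram`, with
#'   attribute `truth`: the generating network id per streamline
#'   (`NA` for distractors).
#' @export
make_tractogram <- function(phantom, bundle_counts,
                            endpoint_jitter_mm = 1,
                            off_target_fraction = 0.1, seed = NULL) {
  if (endpoint_jitter_mm < 0) stop("endpoint_jitter_mm must be >= 0")
  if (off_target_fraction < 0 || off_target_fraction >= 1)
    stop("off_target_fraction must lie in [0, 1)")
  if (is.null(names(bundle_counts)))
    names(bundle_counts) <- seq_along(bundle_counts)
  nets <- as.integer(names(bundle_counts))
  if (any(is.na(nets)) || any(!nets %in% seq_len(phantom$K)))
    stop("bundle requested for a network label absent from the phantom")
  if (!is.null(seed)) set.seed(seed)

  step <- 0.5 * min(phantom$voxel_size)
  hx <- hemisphere_x(phantom)
  jit <- function(sd) if (sd > 0) stats::rnorm(3, 0, sd) else c(0, 0, 0)

  streams <- list()
  truth <- integer(0)
  for (b in seq_along(bundle_counts)) {
    n <- nets[b]
    cnt <- bundle_counts[b]
    if (cnt < 1) next
    cols <- zone_columns(phantom, n)
    n_off <- round(off_target_fraction * cnt)
    for (i in seq_len(cnt)) {
      if (i <= cnt - n_off) {
        yz <- cols[((i - 1) %% nrow(cols)) + 1, ]
        p0 <- c(hx["left"], yz[1], yz[2]) + jit(endpoint_jitter_mm)
        p2 <- c(hx["right"], yz[1], yz[2]) + jit(endpoint_jitter_mm)
        p1 <- c(0, yz[1], yz[2]) + jit(endpoint_jitter_mm / 2)
        streams[[length(streams) + 1]] <- bezier_arc(p0, p1, p2, step)
        truth <- c(truth, n)
      } else {
        streams[[length(streams) + 1]] <-
          .distractor(phantom, hx, i %% 2 == 0, endpoint_jitter_mm, step)
        truth <- c(truth, NA_integer_)
      }
    }
  }
  structure(streams, class = "cc_tractogram", truth = truth)
}

# Distractor streamlines: same-hemisphere U-arcs between two left-hemisphere
# boxes (never touch the callosal slab), or arcs terminating above every
# cortical label.
.distractor <- function(phantom, hx, same_hemi, jitter, step) {
  ks <- sample(seq_len(phantom$K), 2, replace = TRUE)
  c1 <- zone_columns(phantom, ks[1]); c2 <- zone_columns(phantom, ks[2])
  yz1 <- c1[sample(nrow(c1), 1), ]; yz2 <- c2[sample(nrow(c2), 1), ]
  j <- function() if (jitter > 0) stats::rnorm(3, 0, jitter) else c(0, 0, 0)
  if (same_hemi) {
    # left-to-left arc bowing toward (but never reaching) the midline
    p0 <- c(hx["left"], yz1[1], yz1[2]) + j()
    p2 <- c(hx["left"], yz2[1], yz2[2]) + j()
    p1 <- c(hx["left"] / 2, (yz1[1] + yz2[1]) / 2, (yz1[2] + yz2[2]) / 2)
  } else {
    # crosses the midline but ends above the cortical boxes (label 0)
    top_z <- voxel_to_world(cbind(0, 0, phantom$grid_shape[3] - 1),
                            phantom$affine)[3]
    p0 <- c(hx["left"], yz1[1], top_z)
    p2 <- c(hx["right"], yz2[1], top_z)
    p1 <- c(0, (yz1[1] + yz2[1]) / 2, top_z)
  }
  bezier_arc(p0, p1, p2, step)
}

#' @export
print.cc_tractogram <- function(x, ...) {
  npts <- vapply(x, nrow, 1L)
  cat("Tractogram:", length(x), "streamlines,",
      sum(npts), "points\n")
  tr <- attr(x, "truth")
  if (!is.null(tr))
    cat("  generated on-target:", sum(!is.na(tr)),
        "| distractors:", sum(is.na(tr)), "\n")
  invisible(x)
}
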