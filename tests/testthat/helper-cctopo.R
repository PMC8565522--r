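# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use different algorithms than the package internals.

default_phantom <- function(K = 7) make_phantom(K)

# Probability maps for a phantom cohort, one per subject.
cohort_maps <- function(phantom, n_subjects, seed, bundle_count = 20,
                        jitter = 1, off_target = 0.1) {
  dil <- dilate_labels(phantom$network_labels, phantom$voxel_size, 2)
  counts <- stats::setNames(rep(bundle_count, phantom$K),
                            seq_len(phantom$K))
  lapply(seq_len(n_subjects), function(s) {
    tg <- make_tractogram(phantom, counts, endpoint_jitter_mm = jitter,
                          off_target_fraction = off_target,
                          seed = seed * 1000 + s)
    normalize_connections(count_connections(tg, phantom$cc_mask, dil,
                                            phantom$affine, K = phantom$K,
                                            voxel_size = phantom$voxel_size))
  })
}

# Brute-force rasterization oracle: walk every segment at a fine fixed step,
# map each sample to the nearest voxel centre by explicit inverse-affine
# arithmetic, deduplicate.
oracle_rasterize <- function(points, affine, dim, voxel_size,
                             step = 0.25 * min(voxel_size)) {
  inv <- solve(affine)
  vox <- integer(0)
  for (i in seq_len(nrow(points) - 1)) {
    p0 <- points[i, ]; p1 <- points[i + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    for (t in ts) {
      w <- p0 + t * (p1 - p0)
      ijk <- round(inv[1:3, 1:3] %*% w + inv[1:3, 4])
      if (all(ijk >= 0) && all(ijk < dim))
        vox <- c(vox, 1 + ijk[1] + dim[1] * (ijk[2] + dim[2] * ijk[3]))
    }
  }
  sort(unique(vox))
}

# Exact analytic traversal oracle: for every polyline segment, split the
# parameter range at every half-integer crossing in continuous voxel
# coordinates (the boundaries of the nearest-voxel rounding cells) and round
# the interval midpoints. Yields exactly the set of voxels whose rounding
# cell the polyline passes through; any point-sampled mapping is a subset.
oracle_exact_traversal <- function(points, affine, dim) {
  inv <- solve(affine)
  u <- t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])  # continuous voxel coords
  vox <- integer(0)
  emit <- function(ijk) {
    if (all(ijk >= 0) && all(ijk < dim))
      vox <<- c(vox, 1 + ijk[1] + dim[1] * (ijk[2] + dim[2] * ijk[3]))
  }
  for (i in seq_len(nrow(u) - 1)) {
    a <- u[i, ]; b <- u[i + 1, ]
    ts <- c(0, 1)
    for (ax in 1:3) {
      d <- b[ax] - a[ax]
      if (d == 0) next
      ks <- seq(ceiling(min(a[ax], b[ax]) - 0.5),
                floor(max(a[ax], b[ax]) - 0.5))
      ts <- c(ts, ((ks + 0.5) - a[ax]) / d)
    }
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    mids <- (ts[-1] + ts[-length(ts)]) / 2
    for (t in c(0, mids, 1)) emit(round(a + t * (b - a)))
  }
  sort(unique(vox))
}

# Evaluate a generative model row's trajectory at given ages.
eval_traj_row <- function(row, ages) {
  row$intercept + row$linear * ages + row$quadratic * ages^2
}

# Normal-equations oracle for the quadratic fit.
oracle_quadfit <- function(ages, values) {
  X <- cbind(1, ages, ages^2)
  drop(solve(t(X) %*% X, t(X) %*% values))
}

# Minimal hand-built probability map (for algebraic tests).
manual_probmap <- function(probs, K, affine = diag(4)) {
  dm <- dim(probs)
  support <- array(rowSums(matrix(probs, ncol = dm[4])) > 0, dm[1:3])
  structure(list(probs = probs, support = support, K = K,
                 affine = affine, subject_id = "manual"),
            class = "cc_probmap")
}

# Scalar records table for the statistics modules: P.<net> columns from a
# supplied matrix plus demographics.
manual_records <- function(cohort, P, di = NULL) {
  out <- as.data.frame(cohort)
  for (j in seq_len(ncol(P))) out[[paste0("P.", colnames(P)[j])]] <- P[, j]
  if (!is.null(di))
    for (nm in names(di)) out[[nm]] <- di[[nm]]
  class(out) <- c("cc_records", "data.frame")
  out
}
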