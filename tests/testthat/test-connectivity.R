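test_that("label dilation matches the Euclidean-ball definition", {
  # radius 0 is the identity
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  expect_identical(dilate_labels(lab, c(2, 2, 2), 0), lab)
  expect_error(dilate_labels(lab, c(2, 2, 2), -1), ">= 0")
  # single voxel, 2 mm radius, 2 mm voxels: the 6-neighbourhood plus centre
  out <- dilate_labels(lab, c(2, 2, 2), 2)
  expect_equal(sum(out == 1), 7)
  got <- which(out == 1, arr.ind = TRUE)
  dist <- sqrt(rowSums((sweep(got, 2, c(3, 3, 3)) * 2)^2))
  expect_true(all(dist <= 2 + 1e-9))
})

test_that("dilation preserves original labels and breaks ties to the lower index", {
  lab <- array(0L, c(7, 3, 3))
  lab[3, 2, 2] <- 2L; lab[4, 2, 2] <- 1L   # two adjacent labels
  out <- dilate_labels(lab, c(2, 2, 2), 2)
  expect_equal(out[3, 2, 2], 2L)
  expect_equal(out[4, 2, 2], 1L)
  # voxel equidistant (2 mm) from both seeds -> lower label wins
  expect_equal(out[2, 2, 2], 2L)   # only label 2 within 2 mm
  expect_equal(out[5, 2, 2], 1L)
  # equidistant tie: labels at (1,.) and (5,.), voxel 3 is 4 mm from both
  lab2 <- array(0L, c(5, 1, 1)); lab2[1, 1, 1] <- 5L; lab2[5, 1, 1] <- 3L
  out2 <- dilate_labels(lab2, c(2, 2, 2), 4)
  expect_equal(out2[3, 1, 1], 3L)
})

test_that("streamline assignment enforces homotopy, hemispheres and callosal passage", {
  ph <- default_phantom()
  dil <- dilate_labels(ph$network_labels, ph$voxel_size, 2)
  hx <- c(-8, 8)
  zone_y <- function(n) mean(range(which(apply(
    ph$crossing_zones == n, 2, any)))) - 1  # 0-based y centre
  yz1 <- voxel_to_world(cbind(0, zone_y(1), 4), ph$affine)[, 2:3]
  # same-hemisphere streamline: rejected
  s_same <- cbind(seq(-8, -6, length.out = 10), yz1[1], yz1[2])
  # heterotopic: endpoints in networks 1 (left) and 2 (right)
  yz2 <- voxel_to_world(cbind(0, zone_y(2), 4), ph$affine)[, 2:3]
  s_het <- cbind(seq(-8, 8, length.out = 30),
                 seq(yz1[1], yz2[1], length.out = 30), yz1[2])
  # proper homotopic network-1 streamline
  s_ok <- cbind(seq(-8, 8, length.out = 30), yz1[1], yz1[2])
  asg <- assign_streamlines(list(s_same, s_het, s_ok), ph$cc_mask, dil,
                            ph$affine, ph$voxel_size)
  expect_equal(asg, c(NA_integer_, NA_integer_, 1L))
  expect_error(assign_streamlines(list(matrix(0, 1, 3)), ph$cc_mask, dil,
                                  ph$affine, ph$voxel_size),
               "empty streamline")
})

test_that("counting increments each traversed callosal voxel once per streamline", {
  ph <- default_phantom()
  dil <- dilate_labels(ph$network_labels, ph$voxel_size, 2)
  zone_y <- mean(range(which(apply(ph$crossing_zones == 1, 2, any)))) - 1
  yz <- voxel_to_world(cbind(0, zone_y, 4), ph$affine)[, 2:3]
  s <- cbind(seq(-8, 8, length.out = 30), yz[1], yz[2])
  # two identical streamlines -> count 2 in every traversed zone voxel
  cm <- count_connections(list(s, s), ph$cc_mask, dil, ph$affine, K = 7,
                          voxel_size = ph$voxel_size)
  ch <- cm$counts[, , , 1]
  expect_true(all(ch[ch > 0] == 2))
  # a streamline that doubles back over the same voxels still counts once
  k <- nrow(s)
  loop <- rbind(s[1:(k - 1), ], s[(k - 1):(k - 6), ], s[(k - 5):k, ])
  cml <- count_connections(list(loop), ph$cc_mask, dil, ph$affine, K = 7,
                           voxel_size = ph$voxel_size)
  expect_true(all(cml$counts <= 1L))
  expect_gt(sum(cml$counts[, , , 1]), 0)
})

test_that("probability normalization is exact on and off the support", {
  cm <- structure(list(counts = array(0L, c(2, 1, 1, 7)), K = 7,
                       affine = diag(4), subject_id = "s"),
                  class = "cc_connmap")
  cm$counts[1, 1, 1, 1] <- 3L; cm$counts[1, 1, 1, 2] <- 1L
  pm <- normalize_connections(cm)
  expect_equal(pm$probs[1, 1, 1, ], c(0.75, 0.25, 0, 0, 0, 0, 0))
  expect_equal(pm$probs[2, 1, 1, ], rep(0, 7))
  expect_identical(as.vector(pm$support), c(TRUE, FALSE))
})

test_that("channel probabilities sum to one on the support of real maps", {
  ph <- default_phantom()
  maps <- cohort_maps(ph, 2, seed = 31)
  for (pm in maps) {
    tot <- apply(pm$probs, c(1, 2, 3), sum)
    expect_true(all(abs(tot[pm$support] - 1) < 1e-9))
    expect_true(all(tot[!pm$support] == 0))
  }
})

test_that("counting is order-invariant and monotone in added streamlines", {
  ph <- default_phantom()
  dil <- dilate_labels(ph$network_labels, ph$voxel_size, 2)
  tg <- make_tractogram(ph, c(`1` = 10, `3` = 10), seed = 8)
  perm <- sample(length(tg))
  cm1 <- count_connections(tg, ph$cc_mask, dil, ph$affine, K = 7,
                           voxel_size = ph$voxel_size)
  cm2 <- count_connections(tg[perm], ph$cc_mask, dil, ph$affine, K = 7,
                           voxel_size = ph$voxel_size)
  expect_identical(cm1$counts, cm2$counts)
  extra <- make_tractogram(ph, c(`1` = 1), seed = 9)
  cm3 <- count_connections(c(tg, extra), ph$cc_mask, dil, ph$affine, K = 7,
                           voxel_size = ph$voxel_size)
  expect_true(all(cm3$counts >= cm1$counts))
})

test_that("fast voxel traversal is sound against an exact analytic oracle", {
  ph <- default_phantom()
  # axis-parallel line through known voxel centres: exact agreement
  y0 <- voxel_to_world(cbind(0, 10, 4), ph$affine)[, 2:3]
  s <- cbind(c(-8, 8), y0[1], y0[2])
  fast <- sort(cctopo:::rasterize_streamline(s, ph$affine, ph$grid_shape, 1))
  expect_identical(fast,
                   oracle_exact_traversal(s, ph$affine, ph$grid_shape))
  # random oblique polylines: every fast voxel lies in the exact traversal
  # set, and the fast pass covers the bulk of it (it can only miss voxels
  # whose chord through the rounding cell is shorter than the sampling
  # step; random oblique lines graze far more corners than real bundles)
  set.seed(17)
  missed <- total <- 0
  for (i in 1:100) {
    npts <- sample(3:12, 1)
    pts <- cbind(runif(npts, -12, 12), runif(npts, -38, 38),
                 runif(npts, -8, 8))
    fast <- sort(cctopo:::rasterize_streamline(pts, ph$affine,
                                               ph$grid_shape, 1))
    exact <- oracle_exact_traversal(pts, ph$affine, ph$grid_shape)
    expect_true(all(fast %in% exact))
    # finer point sampling stays inside the exact set too
    fine <- oracle_rasterize(pts, ph$affine, ph$grid_shape, ph$voxel_size)
    expect_true(all(fine %in% exact))
    missed <- missed + length(setdiff(exact, fast))
    total <- total + length(exact)
  }
  expect_lt(missed / total, 0.2)
})
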