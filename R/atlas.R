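# Population-level probabilistic atlas, maximum-likelihood hard
# segmentation, and multi-label Dice reproducibility.

#' Build a population probabilistic atlas from subject probability maps
#'
#' Voxel-wise arithmetic mean of the subject connection-probability maps:
#' P(v,n) = (1/S) * sum_s P(s,v,n).
#'
#' @param maps list of [normalize_connections()] results on one grid.
#' @param cc_mask the template callosal mask (logical array); its voxel
#'   count V is recorded and used as the denominator of subregional
#'   connection probabilities.
#' @return object of class `cc_atlas`: list with `probs` (4-D array), `S`
#'   (subjects averaged), `V` (template callosal voxel count), `K`,
#'   `affine`, `cc_mask`.
#' @export
build_atlas <- function(maps, cc_mask) {
  if (length(maps) < 1) stop("need at least one probability map")
  dm <- dim(maps[[1]]$probs)
  K <- maps[[1]]$K
  for (m in maps) {
    if (!inherits(m, "cc_probmap")) stop("maps must be cc_probmap objects")
    if (!identical(dim(m$probs), dm) || m$K != K)
      stop("heterogeneous grids or K across subject maps")
  }
  acc <- array(0, dm)
  for (m in maps) acc <- acc + m$probs
  acc <- acc / length(maps)
  structure(list(probs = acc, S = length(maps), V = sum(cc_mask != 0),
                 K = K, affine = maps[[1]]$affine, cc_mask = cc_mask != 0),
            class = "cc_atlas")
}

#' @export
print.cc_atlas <- function(x, ...) {
  cat("Population callosal connection atlas\n")
  cat("  subjects averaged (S):", x$S, "| template voxels (V):", x$V,
      "| K =", x$K, "\n")
  invisible(x)
}

#' Maximum-likelihood hard segmentation of an atlas
#'
#' Labels each voxel with the network of highest population connection
#' probability; exact ties resolve to the lowest network index, and voxels
#' with zero probability everywhere stay 0.
#'
#' @param atlas a [build_atlas()] result.
#' @return integer 3-D label array.
#' @export
hard_segment <- function(atlas) {
  dm <- dim(atlas$probs)
  m <- matrix(atlas$probs, ncol = dm[4])
  lab <- max.col(m, ties.method = "first")
  lab[rowSums(m) == 0] <- 0L
  array(as.integer(lab), dm[1:3])
}

#' Multi-label Dice similarity between two segmentations
#'
#' Per label l (background 0 excluded): 2|A_l n B_l| / (|A_l| + |B_l|).
#' Labels absent from both volumes are omitted and noted. Two summary
#' means are reported: unweighted, and size-weighted by |A_l| + |B_l| (the
#' headline reproducibility figure).
#'
#' @param labels_a,labels_b integer label arrays on one grid.
#' @param K optional number of labels to consider (default: max observed).
#' @return object of class `cc_dice`: list with `per_label` (data.frame),
#'   `weighted_mean`, `unweighted_mean`, `omitted` (labels in neither).
#' @export
dice_overlap <- function(labels_a, labels_b, K = NULL) {
  if (!identical(dim(labels_a), dim(labels_b)))
    stop("label volumes must share one grid")
  if (is.null(K)) K <- max(max(labels_a), max(labels_b), 1)
  res <- data.frame(label = seq_len(K), size_a = NA_real_,
                    size_b = NA_real_, intersection = NA_real_,
                    dice = NA_real_)
  omitted <- integer(0)
  for (l in seq_len(K)) {
    a <- labels_a == l
    b <- labels_b == l
    sa <- sum(a); sb <- sum(b)
    if (sa + sb == 0) { omitted <- c(omitted, l); next }
    res$size_a[l] <- sa; res$size_b[l] <- sb
    res$intersection[l] <- sum(a & b)
    res$dice[l] <- 2 * res$intersection[l] / (sa + sb)
  }
  keep <- !res$label %in% omitted
  pl <- res[keep, , drop = FALSE]
  w <- pl$size_a + pl$size_b
  structure(list(per_label = pl,
                 weighted_mean = sum(pl$dice * w) / sum(w),
                 unweighted_mean = mean(pl$dice),
                 omitted = omitted),
            class = "cc_dice")
}

#' @export
print.cc_dice <- function(x, ...) {
  cat("Multi-label Dice report\n")
  print(x$per_label, row.names = FALSE)
  cat(sprintf("  size-weighted mean: %.4f | unweighted mean: %.4f\n",
              x$weighted_mean, x$unweighted_mean))
  if (length(x$omitted))
    cat("  labels absent from both volumes:",
        paste(x$omitted, collapse = ", "), "\n")
  invisible(x)
}

#' Split-half reproducibility of the hard segmentation
#'
#' Randomly splits the cohort into two age- and sex-matched halves
#' (stratified on age bin x sex, each stratum divided as evenly as
#' possible, odd subjects assigned alternately), builds a probabilistic
#' atlas and hard segmentation per half, and reports their multi-label
#' Dice similarity.
#'
#' @param cohort a [make_cohort()] table.
#' @param maps list of subject probability maps, one per cohort row, same
#'   order.
#' @param cc_mask template callosal mask.
#' @param seed integer seed for the stratified shuffle.
#' @return object of class `cc_splithalf`: list with `dice` (a `cc_dice`),
#'   `assignment` (1/2 per subject), `halves` (per-half descriptors).
#' @export
split_half <- function(cohort, maps, cc_mask, seed = NULL) {
  if (nrow(cohort) < 4) stop("split-half needs at least 4 subjects")
  if (length(maps) != nrow(cohort))
    stop("need exactly one probability map per cohort row")
  if (!is.null(seed)) set.seed(seed)
  strata <- interaction(cohort$age_group, cohort$sex, drop = TRUE)
  if (any(table(strata) < 2))
    warning("some age-group x sex strata have a single subject; ",
            "they are pooled and assigned alternately")
  assignment <- integer(nrow(cohort))
  toggle <- 0L
  for (s in levels(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    h <- length(idx) %/% 2
    assignment[idx[seq_len(h)]] <- 1L
    if (h >= 1) assignment[idx[h + seq_len(h)]] <- 2L
    if (length(idx) %% 2 == 1) {
      assignment[idx[length(idx)]] <- 1L + toggle
      toggle <- 1L - toggle
    }
  }
  halves <- lapply(1:2, function(g) {
    sel <- assignment == g
    list(n = sum(sel),
         mean_age = mean(cohort$age[sel]),
         sd_age = stats::sd(cohort$age[sel]),
         males = sum(cohort$sex[sel] == 1),
         females = sum(cohort$sex[sel] == 0))
  })
  seg <- lapply(1:2, function(g)
    hard_segment(build_atlas(maps[assignment == g], cc_mask)))
  structure(list(dice = dice_overlap(seg[[1]], seg[[2]],
                                     K = maps[[1]]$K),
                 assignment = assignment, halves = halves),
            class = "cc_splithalf")
}

#' @export
print.cc_splithalf <- function(x, ...) {
  cat("Split-half reproducibility\n")
  for (g in 1:2)
    cat(sprintf("  half %d: n=%d, age %.1f +/- %.1f, M/F %d/%d\n", g,
                x$halves[[g]]$n, x$halves[[g]]$mean_age, x$halves[[g]]$sd_age,
                x$halves[[g]]$males, x$halves[[g]]$females))
  print(x$dice)
  invisible(x)
}
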