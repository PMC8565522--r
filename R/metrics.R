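# Per-subject scalar extraction: subregional connection probability P(s,n),
# probability-weighted diffusion indices DI(s,n), and covariate
# residualization.

#' Subregional connection probability P(s,n)
#'
#' P(s,n) = sum_v P(s,v,n) / V, the mean connection probability over the V
#' voxels of the template callosal mask (voxels without support contribute
#' zero). Summed over networks this equals (support voxels)/V <= 1.
#'
#' @param map a [normalize_connections()] probability map.
#' @param cc_mask template callosal mask; its voxel count is V.
#' @return named numeric vector of length K.
#' @export
connection_probability <- function(map, cc_mask) {
  V <- sum(cc_mask != 0)
  if (V == 0) stop("empty template callosal mask")
  dm <- dim(map$probs)
  if (!identical(dim(cc_mask), dm[1:3])) stop("map grid does not match mask")
  m <- matrix(map$probs, ncol = dm[4])
  p <- colSums(m[as.vector(cc_mask != 0), , drop = FALSE]) / V
  names(p) <- network_names(map$K)
  p
}

#' Probability-weighted mean of a diffusion index
#'
#' DI = sum_v w(v) * DI(v) / sum_v w(v) over voxels with positive weight
#' whose FA exceeds the threshold (default 0.2, excluding grey matter and
#' CSF partial-volume voxels). The FA gate is taken from the subject's FA
#' volume for every index, including MD/RD/AD.
#'
#' @param weights 3-D array of nonnegative weights (a probability-map
#'   channel).
#' @param index_volume 3-D array of the diffusion index being extracted.
#' @param fa_volume 3-D array of the subject's FA.
#' @param fa_threshold voxels with FA <= this are excluded; default 0.2.
#' @return the weighted mean, or `NA` (with a warning) when no voxel
#'   survives.
#' @export
weighted_index <- function(weights, index_volume, fa_volume,
                           fa_threshold = 0.2) {
  stopifnot(identical(dim(weights), dim(index_volume)),
            identical(dim(weights), dim(fa_volume)))
  sel <- weights > 0 & fa_volume > fa_threshold
  if (!any(sel)) {
    warning("no voxel survives the weight and FA-threshold filters; ",
            "returning NA")
    return(NA_real_)
  }
  sum(weights[sel] * index_volume[sel]) / sum(weights[sel])
}

#' Residualize values on nuisance covariates
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus the
#' covariate columns, with the grand mean added back, so the output is on
#' the original scale, mean-preserving, and idempotent. Age must not be in
#' `covariates` when the residuals feed the aging-trajectory fit.
#'
#' @param values numeric vector.
#' @param covariates data.frame of numeric covariates (e.g. TIV, sex,
#'   education years).
#' @return numeric vector of residualized values.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stop("missing covariate values")
  if (nrow(covariates) != length(values))
    stop("values and covariates disagree in length")
  if (length(values) < ncol(covariates) + 2)
    stop("need at least 2 more subjects than covariates")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, values) + mean(values)
}

#' Extract per-subject subregional records
#'
#' Combines demographics, subregional connection probabilities and
#' probability-weighted diffusion indices into one wide table, adding
#' residualized diffusion indices (nuisance covariates: TIV, sex,
#' education; age deliberately not regressed out, so the aging signal
#' survives for trajectory fitting).
#'
#' Weights for the diffusion-index extraction default to the population
#' atlas channels (`weight_source = "population"`); set
#' `weight_source = "subject"` to weight by each subject's own map.
#'
#' @param cohort a [make_cohort()] table.
#' @param maps list of subject probability maps (same order as `cohort`).
#' @param di_volumes list of per-subject diffusion-volume lists (elements
#'   `FA`, `MD`, `RD`, `AD`), same order.
#' @param atlas a [build_atlas()] result.
#' @param fa_threshold FA gate for index extraction, default 0.2.
#' @param weight_source `"population"` (default) or `"subject"`.
#' @return a `data.frame` of class `cc_records`: demographics, then columns
#'   `P.<net>`, `<index>.<net>` and `<index>.<net>.resid`.
#' @export
subject_records <- function(cohort, maps, di_volumes, atlas,
                            fa_threshold = 0.2,
                            weight_source = c("population", "subject")) {
  weight_source <- match.arg(weight_source)
  stopifnot(length(maps) == nrow(cohort),
            length(di_volumes) == nrow(cohort))
  K <- atlas$K
  nets <- network_names(K)
  out <- as.data.frame(cohort)
  for (n in seq_len(K)) out[[paste0("P.", nets[n])]] <- NA_real_
  for (ix in c("FA", "MD", "RD", "AD"))
    for (n in seq_len(K)) out[[paste0(ix, ".", nets[n])]] <- NA_real_

  for (s in seq_len(nrow(cohort))) {
    p <- connection_probability(maps[[s]], atlas$cc_mask)
    out[s, paste0("P.", nets)] <- p
    for (n in seq_len(K)) {
      w <- if (weight_source == "population") atlas$probs[, , , n]
           else maps[[s]]$probs[, , , n]
      for (ix in c("FA", "MD", "RD", "AD"))
        out[s, paste0(ix, ".", nets[n])] <- suppressWarnings(
          weighted_index(w, di_volumes[[s]][[ix]], di_volumes[[s]]$FA,
                         fa_threshold))
    }
  }
  covs <- out[, c("tiv_cm3", "sex", "education_years")]
  for (ix in c("FA", "MD", "RD", "AD"))
    for (n in seq_len(K)) {
      col <- paste0(ix, ".", nets[n])
      v <- out[[col]]
      ok <- !is.na(v)
      res <- rep(NA_real_, length(v))
      if (sum(ok) >= ncol(covs) + 2)
        res[ok] <- residualize(v[ok], covs[ok, , drop = FALSE])
      out[[paste0(col, ".resid")]] <- res
    }
  class(out) <- c("cc_records", "data.frame")
  out
}
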