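# Generative aging model for the diffusion indices: per subregion x index a
# quadratic trajectory DI = C + A*age + B*age^2, plus covariate effects and
# Gaussian noise calibrated so a least-squares refit recovers a prescribed
# coefficient of determination.

# Default quadratic coefficients for the 7 canonical callosal subregions, as
# reported by a large (n = 1086, ages 21-90) lifespan DTI cohort. Printed
# scales: FA linear x1e-2, quadratic x1e-4; diffusivities (mm^2/s) intercept
# x1e-3, linear x1e-5, quadratic x1e-7. r2 is the published fit R^2 used to
# calibrate simulation noise.
.di_defaults <- list(
  FA = data.frame(
    network   = c("VIS", "SM", "DA", "VA", "LN", "FPN", "DMN"),
    intercept = c(0.737, 0.585, 0.644, 0.550, 0.468, 0.541, 0.581),
    linear    = c(0.138, 0.160, 0.294, 0.291, 0.151, 0.312, 0.244) * 1e-2,
    quadratic = c(-0.143, -0.229, -0.337, -0.326, -0.210, -0.344, -0.283) * 1e-4,
    r2        = c(0.008, 0.059, 0.083, 0.070, 0.016, 0.088, 0.093)),
  MD = data.frame(
    network   = c("VIS", "SM", "DA", "VA", "LN", "FPN", "DMN"),
    intercept = c(0.962, 1.205, 1.062, 1.188, 1.250, 1.196, 1.156) * 1e-3,
    linear    = c(-0.474, -1.060, -0.873, -0.980, -1.145, -0.941, -0.894) * 1e-5,
    quadratic = c(0.531, 1.243, 0.979, 1.162, 1.318, 1.089, 1.017) * 1e-7,
    r2        = c(0.047, 0.170, 0.196, 0.212, 0.117, 0.203, 0.209)),
  RD = data.frame(
    network   = c("VIS", "SM", "DA", "VA", "LN", "FPN", "DMN"),
    intercept = c(0.480, 0.787, 0.629, 0.794, 0.921, 0.810, 0.754) * 1e-3,
    linear    = c(-0.383, -0.866, -0.800, -0.891, -0.962, -0.883, -0.794) * 1e-5,
    quadratic = c(0.429, 1.051, 0.911, 1.044, 1.133, 1.014, 0.917) * 1e-7,
    r2        = c(0.027, 0.141, 0.163, 0.177, 0.085, 0.179, 0.194)),
  AD = data.frame(
    network   = c("VIS", "SM", "DA", "VA", "LN", "FPN", "DMN"),
    intercept = c(1.926, 2.041, 1.927, 1.977, 1.908, 1.967, 1.961) * 1e-3,
    linear    = c(-0.655, -1.447, -1.018, -1.157, -1.510, -1.058, -1.093) * 1e-5,
    quadratic = c(0.734, 1.627, 1.115, 1.397, 1.690, 1.241, 1.217) * 1e-7,
    r2        = c(0.042, 0.164, 0.142, 0.198, 0.097, 0.181, 0.165))
)

#' Default generative aging model for the diffusion indices
#'
#' One row per subregion x index with quadratic trajectory coefficients in
#' absolute units (FA dimensionless, diffusivities in mm^2/s) — the printed
#' power-of-ten scales of the source table are expanded here, once. The `r2`
#' column is the published fit R^2 that [noise_sd_for_r2()] turns into a
#' residual standard deviation. For `K = 17` the seven canonical rows are
#' recycled cyclically across subnetworks.
#'
#' @param K number of networks (7 or 17).
#' @return a `data.frame` with columns `network`, `index`, `intercept`
#'   (C), `linear` (A, per year), `quadratic` (B, per year^2), `r2`.
#' @examples
#' m <- di_model_default()
#' subset(m, network == "DMN" & index == "FA")
#' @export
di_model_default <- function(K = 7) {
  if (!K %in% c(7L, 17L)) stop("K must be 7 or 17")
  rows <- do.call(rbind, lapply(names(.di_defaults), function(ix) {
    d <- .di_defaults[[ix]]
    d$index <- ix
    d
  }))
  if (K == 17) {
    nets <- network_names(17)
    rows <- do.call(rbind, lapply(1:17, function(n) {
      src <- ((n - 1) %% 7) + 1
      d <- rows[rows$network == .di_defaults$FA$network[src], ]
      d$network <- nets[n]
      d
    }))
  }
  rownames(rows) <- NULL
  rows[, c("network", "index", "intercept", "linear", "quadratic", "r2")]
}

# Look up one model row; accepts a model data.frame plus network/index names.
model_row <- function(model, network, index) {
  r <- model[model$network == network & model$index == index, ]
  if (nrow(r) != 1) stop("no generative model row for ", network, "/", index)
  r
}

# Evaluate the quadratic trajectory of a model row at the given ages.
eval_trajectory <- function(row, age) {
  row$intercept + row$linear * age + row$quadratic * age^2
}

#' Residual standard deviation reproducing a target R-squared
#'
#' For a quadratic signal f(age) = C + A*age + B*age^2 and ages drawn from
#' the given distribution, returns the noise standard deviation sigma with
#' sigma^2 = Var\[f(age)\] * (1 - R2) / R2, so that a least-squares quadratic
#' refit on a large simulated cohort attains the target R^2. Var is the
#' population variance of f over the age grid.
#'
#' @param coefs either a model row (as returned by [di_model_default()]) or
#'   a numeric vector `c(intercept, linear, quadratic)`.
#' @param target_r2 target coefficient of determination, in (0, 1).
#' @param ages age grid or sample defining the age distribution; default the
#'   integer grid 21:90 (uniform ages).
#' @return noise standard deviation (same units as the index).
#' @examples
#' row <- subset(di_model_default(), network == "DMN" & index == "FA")
#' noise_sd_for_r2(row, row$r2)
#' @export
noise_sd_for_r2 <- function(coefs, target_r2, ages = 21:90) {
  if (!is.numeric(target_r2) || length(target_r2) != 1 ||
      target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must lie strictly inside (0, 1)")
  if (is.data.frame(coefs))
    coefs <- c(coefs$intercept, coefs$linear, coefs$quadratic)
  f <- coefs[1] + coefs[2] * ages + coefs[3] * ages^2
  v <- mean((f - mean(f))^2)
  sqrt(v * (1 - target_r2) / target_r2)
}

#' Simulate per-subject index values from one generative row
#'
#' Scalar-level counterpart of [make_diffusion_volumes()]: draws integer ages
#' uniformly on \[21, 90\], evaluates the row's quadratic trajectory and adds
#' Gaussian noise whose standard deviation is calibrated (via
#' [noise_sd_for_r2()]) to the row's `r2` unless given explicitly.
#'
#' @param row one row of a generative model table.
#' @param n number of subjects.
#' @param seed integer seed.
#' @param ages optional age vector (overrides the uniform draw).
#' @param noise_sd optional noise standard deviation.
#' @return `data.frame` with columns `age` and `value`.
#' @export
simulate_index_values <- function(row, n, seed = NULL, ages = NULL,
                                  noise_sd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ages)) ages <- sample(21:90, n, replace = TRUE)
  if (is.null(noise_sd)) noise_sd <- noise_sd_for_r2(row, row$r2)
  value <- eval_trajectory(row, ages) + stats::rnorm(length(ages), 0, noise_sd)
  data.frame(age = ages, value = value)
}

#' Generate per-subject diffusion-index volumes
#'
#' Fills each crossing zone n of the phantom with
#' `C_n + A_n*age + B_n*age^2 + covariate terms + noise` for each index
#' (FA, MD, RD, AD). Noise has two components: a subject-level deviation
#' shared by all voxels of a zone (between-subject variability, calibrated
#' to the row's `r2` by default) and independent voxel-level noise
#' (spatial heterogeneity, default a quarter of the subject deviation).
#' Callosal voxels outside every zone receive FA below 0.2 with probability
#' `low_fa_prob` (exercising the FA-threshold filter) and generic white
#' matter diffusivities. FA is clipped to \[0, 1\] and diffusivities floored
#' at a small positive value.
#'
#' Covariate effects apply to centred covariates — (TIV - 1400 cm^3),
#' (education - 10 y), (sex - 0.5) — so the trajectory intercepts remain the
#' cohort-mean trajectories; all three default to zero.
#'
#' @param phantom a [make_phantom()] object.
#' @param subject one row of a [make_cohort()] table.
#' @param model generative table, default [di_model_default()].
#' @param seed integer seed.
#' @param subject_sd named or scalar subject-level noise sd; `NULL` (default)
#'   calibrates each row via [noise_sd_for_r2()] to its `r2`; 0 disables.
#' @param voxel_sd voxel-level noise sd; `NULL` = subject_sd / 4.
#' @param betas covariate effects `c(tiv=, sex=, education=)` per unit of
#'   the centred covariate, applied to every index; default all zero.
#' @param low_fa_prob probability that a non-zone callosal voxel gets FA
#'   below the 0.2 threshold.
#' @return named list of four numeric arrays (`FA`, `MD`, `RD`, `AD`) on the
#'   phantom grid, with the phantom affine attached as attribute `affine`.
#' @export
make_diffusion_volumes <- function(phantom, subject, model = NULL, seed = NULL,
                                   subject_sd = NULL, voxel_sd = NULL,
                                   betas = c(tiv = 0, sex = 0, education = 0),
                                   low_fa_prob = 0.5) {
  if (subject$age < 21 || subject$age > 90)
    stop("subject age outside [21, 90]")
  if (is.null(model)) model <- di_model_default(phantom$K)
  needed <- expand.grid(network = network_names(phantom$K),
                        index = c("FA", "MD", "RD", "AD"))
  have <- paste(model$network, model$index)
  if (!all(paste(needed$network, needed$index) %in% have))
    stop("model lacks entries for some subregion x index combinations")
  if (!is.null(seed)) set.seed(seed)

  cov_term <- function(b) {
    b <- as.list(b)
    (b$tiv %||% 0) * (subject$tiv_cm3 - 1400) +
      (b$sex %||% 0) * (subject$sex - 0.5) +
      (b$education %||% 0) * (subject$education_years - 10)
  }
  cov_shift <- cov_term(betas)

  nets <- network_names(phantom$K)
  vols <- list()
  for (ix in c("FA", "MD", "RD", "AD")) {
    vol <- array(0, phantom$grid_shape)
    for (n in seq_len(phantom$K)) {
      row <- model_row(model, nets[n], ix)
      s_sd <- subject_sd
      if (is.null(s_sd)) s_sd <- noise_sd_for_r2(row, row$r2)
      v_sd <- voxel_sd %||% (s_sd / 4)
      vox <- which(phantom$crossing_zones == n)
      base <- eval_trajectory(row, subject$age) + cov_shift +
        stats::rnorm(1, 0, s_sd)
      vol[vox] <- base + stats::rnorm(length(vox), 0, v_sd)
    }
    # Non-zone callosal background: a deterministic low-FA quota (first
    # fraction of voxels in index order) so that zero-noise volumes are
    # identical whatever the seed; voxel noise rides on top when enabled.
    other <- which(phantom$cc_mask & phantom$crossing_zones == 0)
    if (length(other)) {
      bg_sd <- voxel_sd %||% 0
      if (ix == "FA") {
        n_low <- round(low_fa_prob * length(other))
        vol[other] <- rep(0.35, length(other))
        if (n_low > 0) vol[other[seq_len(n_low)]] <- 0.12
        if (bg_sd > 0)
          vol[other] <- vol[other] + stats::rnorm(length(other), 0, bg_sd)
      } else {
        bg <- c(MD = 0.95e-3, RD = 0.65e-3, AD = 1.9e-3)[[ix]]
        vol[other] <- bg
        if (bg_sd > 0)
          vol[other] <- vol[other] + stats::rnorm(length(other), 0, bg_sd)
      }
    }
    if (ix == "FA") vol <- pmin(pmax(vol, 0), 1)
    else vol[] <- pmax(vol, 1e-6)
    attr(vol, "affine") <- phantom$affine
    vols[[ix]] <- vol
  }
  vols
}
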