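# Quadratic lifespan trajectory model: DI = C + A*age + B*age^2, the core
# estimator of the package. fit_quadratic() is a classic fitting function
# returning a classed object with the usual methods.

#' Fit a quadratic aging trajectory
#'
#' Least-squares fit of a diffusion index (or any subregional measure) on
#' `(1, age, age^2)`. Reports the raw-age parameterization
#' `value = C + A*age + B*age^2`, the fit R^2, the adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1) with p = 2 regressors, the
#' overall-F p-value, and the turning-point age -A/(2B) (a maximum of the
#' fitted curve when B < 0, a minimum when B > 0), flagged when it falls
#' outside the observed age range. Internally ages are centred before
#' solving and the coefficients mapped back, guarding against
#' ill-conditioning of the raw design.
#'
#' @param ages numeric vector of ages in years.
#' @param values numeric vector of the same length; `NA` pairs are dropped.
#' @return an object of class `cc_quadfit` with components `coefficients`
#'   (named `intercept`, `age`, `age2`), `se`, `vcov`, `r2`, `r2_adj`,
#'   `f_statistic`, `p_value`, `sigma`, `n`, `age_range`, `turning`,
#'   `fitted`, `residuals`, `ages`, `values`.
#' @examples
#' a <- 21:90
#' y <- 0.58 + 0.0024 * a - 2.8e-5 * a^2 + rnorm(70, 0, 0.03)
#' fit <- fit_quadratic(a, y)
#' fit
#' coef(fit)
#' turning_age(fit)
#' @seealso [fit_all()] for fitting every subregion x index cell of a
#'   records table, [turning_age()].
#' @export
fit_quadratic <- function(ages, values) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  n <- length(ages)
  if (n < 4) stop("need at least 4 subjects with finite age and value")
  if (length(unique(ages)) < 3)
    stop("degenerate design: ages take fewer than 3 distinct values")

  # centred fit for conditioning, mapped back to the raw parameterization
  mu <- mean(ages)
  ac <- ages - mu
  Xc <- cbind(1, ac, ac^2)
  qx <- qr(Xc)
  bc <- qr.coef(qx, values)
  # value = bc1 + bc2*(a-mu) + bc3*(a-mu)^2  ->  raw C, A, B
  B <- bc[3]
  A <- bc[2] - 2 * bc[3] * mu
  C <- bc[1] - bc[2] * mu + bc[3] * mu^2
  coefs <- c(intercept = unname(C), age = unname(A), age2 = unname(B))

  fitted <- drop(Xc %*% bc)
  resid <- values - fitted
  rss <- sum(resid^2)
  tss <- sum((values - mean(values))^2)
  r2 <- 1 - rss / tss
  p <- 2
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sigma2 <- rss / (n - p - 1)
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  p_value <- stats::pf(f, p, n - p - 1, lower.tail = FALSE)

  # covariance of the raw coefficients via the centring transform
  Tm <- rbind(c(1, -mu, mu^2), c(0, 1, -2 * mu), c(0, 0, 1))
  Vc <- chol2inv(qr.R(qx)) * sigma2
  Vr <- Tm %*% Vc %*% t(Tm)
  dimnames(Vr) <- list(names(coefs), names(coefs))

  fit <- structure(list(coefficients = coefs,
                        se = sqrt(diag(Vr)), vcov = Vr,
                        r2 = r2, r2_adj = r2_adj,
                        f_statistic = f, p_value = p_value,
                        sigma = sqrt(sigma2), n = n,
                        age_range = range(ages),
                        fitted = fitted, residuals = resid,
                        ages = ages, values = values),
                   class = "cc_quadfit")
  fit$turning <- turning_age(fit)
  fit
}

#' Turning-point age of a fitted quadratic trajectory
#'
#' The extremum -A/(2B) of the fitted curve: the age of peak value when
#' B < 0 (typical for FA) or of minimum value when B > 0 (typical for the
#' diffusivities). Returns `NULL` when B = 0 (no turning point); the result
#' carries an `in_range` flag comparing the extremum with the observed age
#' range.
#'
#' @param fit a [fit_quadratic()] object, or a numeric vector
#'   `c(intercept, linear, quadratic)`.
#' @param age_range optional observed age range for the `in_range` flag
#'   (taken from the fit when available).
#' @return `NULL` if B = 0, else a list with `age`, `kind`
#'   (`"maximum"`/`"minimum"`), `in_range`.
#' @export
turning_age <- function(fit, age_range = NULL) {
  if (inherits(fit, "cc_quadfit")) {
    co <- fit$coefficients
    age_range <- age_range %||% fit$age_range
  } else co <- c(intercept = fit[1], age = fit[2], age2 = fit[3])
  A <- unname(co["age"]); B <- unname(co["age2"])
  if (B == 0) return(NULL)
  t <- -A / (2 * B)
  list(age = t,
       kind = if (B < 0) "maximum" else "minimum",
       in_range = if (is.null(age_range)) NA
                  else t >= age_range[1] && t <= age_range[2])
}

#' @export
print.cc_quadfit <- function(x, digits = 4, ...) {
  cat("Quadratic aging trajectory: value = C + A*age + B*age^2\n")
  cat(sprintf("  C = %.*g, A = %.*g, B = %.*g  (n = %d)\n",
              digits, x$coefficients[1], digits, x$coefficients[2],
              digits, x$coefficients[3], x$n))
  cat(sprintf("  R^2 = %.3f, adjusted R^2 = %.3f, F = %.2f, p = %.3g\n",
              x$r2, x$r2_adj, x$f_statistic, x$p_value))
  if (!is.null(x$turning))
    cat(sprintf("  turning point (%s) at %.1f years%s\n", x$turning$kind,
                x$turning$age,
                if (isTRUE(x$turning$in_range)) "" else " [outside range]"))
  invisible(x)
}

#' @export
summary.cc_quadfit <- function(object, ...) {
  tval <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(abs(tval), object$n - 3,
                                          lower.tail = FALSE))
  out <- list(coefficients = tab, r2 = object$r2, r2_adj = object$r2_adj,
              f_statistic = object$f_statistic, p_value = object$p_value,
              sigma = object$sigma, n = object$n, turning = object$turning)
  class(out) <- "summary.cc_quadfit"
  out
}

#' @export
print.summary.cc_quadfit <- function(x, ...) {
  cat("Quadratic aging trajectory fit\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual sigma %.4g on %d df; R^2 %.3f, adj. %.3f; F %.2f, p %.3g\n",
              x$sigma, x$n - 3, x$r2, x$r2_adj, x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
coef.cc_quadfit <- function(object, ...) object$coefficients

#' @export
vcov.cc_quadfit <- function(object, ...) object$vcov

#' @export
residuals.cc_quadfit <- function(object, ...) object$residuals

#' @export
fitted.cc_quadfit <- function(object, ...) object$fitted

#' @export
predict.cc_quadfit <- function(object, newdata = NULL, ...) {
  ages <- if (is.null(newdata)) object$ages
          else if (is.data.frame(newdata)) newdata$age
          else newdata
  co <- unname(object$coefficients)
  co[1] + co[2] * ages + co[3] * ages^2
}

#' @export
simulate.cc_quadfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- predict(object)
  out <- as.data.frame(replicate(nsim, m + stats::rnorm(object$n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.cc_quadfit <- function(x, ..., main = "Quadratic aging trajectory") {
  graphics::plot(x$ages, x$values, pch = 16, cex = 0.5,
                 col = grDevices::grey(0.55), xlab = "age (years)",
                 ylab = "value", main = main, ...)
  a <- seq(x$age_range[1], x$age_range[2], length.out = 200)
  graphics::lines(a, predict(x, a), lwd = 2, col = "firebrick")
  if (!is.null(x$turning) && isTRUE(x$turning$in_range))
    graphics::points(x$turning$age, predict(x, x$turning$age), pch = 15,
                     col = "navy", cex = 1.2)
  invisible(x)
}

#' Fit quadratic trajectories for every subregion x index
#'
#' One [fit_quadratic()] per (network, index) cell of a records table,
#' using the residualized diffusion indices. Cells with fewer than 4
#' usable subjects are reported as failed and the run continues.
#'
#' @param records a [subject_records()] table.
#' @param indices which indices to fit, default FA/MD/RD/AD.
#' @param networks which networks, default all found in `records`.
#' @param use_residualized fit the covariate-residualized values (default)
#'   or the raw extractions.
#' @return a `data.frame` of class `cc_trajtable`, one row per cell:
#'   coefficients, `r2`, `r2_adj`, `p_value`, `turning_age`,
#'   `turning_in_range`, `n`, `status`; the fitted `cc_quadfit` objects are
#'   attached as attribute `fits` (named `<index>.<network>`).
#' @export
fit_all <- function(records, indices = c("FA", "MD", "RD", "AD"),
                    networks = NULL, use_residualized = TRUE) {
  if (nrow(records) == 0) stop("empty records table")
  if (is.null(networks)) {
    pcols <- grep("^P\\.", names(records), value = TRUE)
    networks <- sub("^P\\.", "", pcols)
  }
  rows <- list(); fits <- list()
  for (ix in indices) for (net in networks) {
    col <- paste0(ix, ".", net, if (use_residualized) ".resid" else "")
    cell <- list(network = net, index = ix, intercept = NA_real_,
                 linear = NA_real_, quadratic = NA_real_, r2 = NA_real_,
                 r2_adj = NA_real_, p_value = NA_real_,
                 turning_age = NA_real_, turning_in_range = NA,
                 n = 0L, status = "failed")
    v <- records[[col]]
    ok <- !is.na(v) & !is.na(records$age)
    if (!is.null(v) && sum(ok) >= 4 &&
        length(unique(records$age[ok])) >= 3) {
      fit <- fit_quadratic(records$age[ok], v[ok])
      cell[c("intercept", "linear", "quadratic")] <-
        as.list(unname(fit$coefficients))
      cell$r2 <- fit$r2; cell$r2_adj <- fit$r2_adj
      cell$p_value <- fit$p_value; cell$n <- fit$n
      if (!is.null(fit$turning)) {
        cell$turning_age <- fit$turning$age
        cell$turning_in_range <- fit$turning$in_range
      }
      cell$status <- "ok"
      fits[[paste0(ix, ".", net)]] <- fit
    }
    rows[[length(rows) + 1]] <- as.data.frame(cell)
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("cc_trajtable", "data.frame")
  out
}

#' Trajectory table scaled to conventional printing units
#'
#' Rescales a [fit_all()] table to the conventional reporting scales: FA
#' linear x1e2 and quadratic x1e4; diffusivity intercept x1e3, linear x1e5
#' and quadratic x1e7 (mm^2/s).
#'
#' @param table a `cc_trajtable`.
#' @return data.frame with columns `network`, `index`, `intercept`,
#'   `linear`, `quadratic` (scaled), `r2`, `r2_adj`, `p_value`,
#'   `turning_age`.
#' @export
trajectory_table <- function(table) {
  out <- as.data.frame(table)
  fa <- out$index == "FA"
  out$intercept[!fa] <- out$intercept[!fa] * 1e3
  out$linear[fa] <- out$linear[fa] * 1e2
  out$linear[!fa] <- out$linear[!fa] * 1e5
  out$quadratic[fa] <- out$quadratic[fa] * 1e4
  out$quadratic[!fa] <- out$quadratic[!fa] * 1e7
  out[, c("network", "index", "intercept", "linear", "quadratic",
          "r2", "r2_adj", "p_value", "turning_age")]
}

#' Fitted-curve coordinates for plotting
#'
#' Evaluates every fitted trajectory on a dense age grid, for downstream
#' plotting of the per-subregion aging curves.
#'
#' @param table a [fit_all()] result.
#' @param ages age grid, default 21:90.
#' @return long data.frame with columns `network`, `index`, `age`, `value`.
#' @export
trajectory_curves <- function(table, ages = 21:90) {
  fits <- attr(table, "fits")
  if (is.null(fits) || !length(fits)) stop("table carries no fitted models")
  do.call(rbind, lapply(names(fits), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(network = parts[2], index = parts[1], age = ages,
               value = predict(fits[[nm]], ages))
  }))
}

#' @export
print.cc_trajtable <- function(x, ...) {
  cat("Quadratic aging trajectories (", sum(x$status == "ok"), " of ",
      nrow(x), " cells fitted)\n", sep = "")
  print(trajectory_table(x), row.names = FALSE, digits = 3)
  invisible(x)
}
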