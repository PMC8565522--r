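test_that("quadratic fit recovers noiseless coefficients exactly", {
  m <- di_model_default()
  ages <- rep(21:90, 3)
  for (i in c(1, 10, 20, 28)) {
    row <- m[i, ]
    y <- row$intercept + row$linear * ages + row$quadratic * ages^2
    fit <- fit_quadratic(ages, y)
    expect_equal(unname(coef(fit)),
                 c(row$intercept, row$linear, row$quadratic),
                 tolerance = 1e-9)
    expect_equal(fit$r2, 1)
  }
})

test_that("fit matches the normal-equations oracle on random data", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    ages <- sample(21:90, n, replace = TRUE)
    y <- rnorm(n, 0.5 + 0.001 * ages, 0.05)
    if (length(unique(ages)) < 3) next
    fit <- fit_quadratic(ages, y)
    expect_equal(unname(coef(fit)), unname(oracle_quadfit(ages, y)),
                 tolerance = 1e-10)
  }
})

test_that("age shifting maps back to the uncentred parameterization", {
  set.seed(31)
  ages <- sample(21:90, 200, replace = TRUE)
  y <- 0.6 + 0.002 * ages - 2e-5 * ages^2 + rnorm(200, 0, 0.03)
  f0 <- fit_quadratic(ages, y)
  delta <- 55
  fs <- fit_quadratic(ages - delta, y)
  # map shifted coefficients back: C' + A'(a-d) + B'(a-d)^2
  cs <- coef(fs)
  back <- c(cs[1] - cs[2] * delta + cs[3] * delta^2,
            cs[2] - 2 * cs[3] * delta,
            cs[3])
  expect_equal(unname(coef(f0)), unname(back), tolerance = 1e-8)
})

test_that("adjusted R2, F p-value and degenerate designs behave", {
  set.seed(5)
  ages <- sample(21:90, 100, replace = TRUE)
  y <- rnorm(100, 0.5 + 0.001 * ages, 0.05)
  fit <- fit_quadratic(ages, y)
  expect_lte(fit$r2_adj, fit$r2)
  expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * 99 / 97, tolerance = 1e-12)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  expect_error(fit_quadratic(rep(50, 10), rnorm(10)), "degenerate")
  expect_error(fit_quadratic(21:23, rnorm(3)), "at least 4")
})

test_that("turning age is the analytic extremum and survives a grid cross-check", {
  # dorsal-attention FA row: A = 0.294e-2, B = -0.337e-4
  t <- turning_age(c(0.644, 0.294e-2, -0.337e-4), age_range = c(21, 90))
  expect_equal(t$age, 0.294e-2 / (2 * 0.337e-4), tolerance = 1e-12)
  expect_equal(t$age, 43.6, tolerance = 0.01)
  expect_equal(t$kind, "maximum")
  expect_true(t$in_range)
  # grid arg-max of the fitted curve agrees to grid resolution
  grid <- seq(21, 90, by = 0.01)
  curve <- 0.644 + 0.294e-2 * grid - 0.337e-4 * grid^2
  expect_lt(abs(grid[which.max(curve)] - t$age), 0.01)
  # no quadratic term: no turning point
  expect_null(turning_age(c(1, 0.1, 0)))
  # A = 0, B < 0: extremum at age 0, flagged outside range
  t0 <- turning_age(c(1, 0, -1e-4), age_range = c(21, 90))
  expect_equal(t0$age, 0)
  expect_false(t0$in_range)
})

test_that("model methods are coherent", {
  set.seed(77)
  ages <- sample(21:90, 300, replace = TRUE)
  y <- 0.58 + 0.0024 * ages - 2.8e-5 * ages^2 + rnorm(300, 0, 0.05)
  fit <- fit_quadratic(ages, y)
  expect_equal(predict(fit), unname(fit$fitted), tolerance = 1e-12)
  expect_equal(predict(fit, data.frame(age = 50)),
               sum(coef(fit) * c(1, 50, 2500)))
  expect_equal(fitted(fit) + residuals(fit), y[is.finite(y)])
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(300L, 3L))
  s <- summary(fit)
  expect_equal(unname(s$coefficients[, "Estimate"]), unname(coef(fit)))
  # standard errors agree with lm
  lmfit <- lm(y ~ ages + I(ages^2))
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(lmfit)))),
               tolerance = 1e-8)
})

test_that("fit_all covers every cell and tolerates failures", {
  set.seed(41)
  co <- make_cohort(40, seed = 41)
  m <- di_model_default()
  di <- list()
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    col <- paste0(row$index, ".", row$network, ".resid")
    di[[col]] <- eval_traj_row(row, co$age) +
      rnorm(40, 0, noise_sd_for_r2(row, row$r2))
  }
  rec <- manual_records(co, matrix(0.1, 40, 7,
                                   dimnames = list(NULL, network_names(7))),
                        di)
  tab <- fit_all(rec)
  expect_equal(nrow(tab), 28)
  expect_true(all(tab$status == "ok"))
  expect_equal(length(attr(tab, "fits")), 28)
  # scaled printing table restores the conventional units
  sc <- trajectory_table(tab)
  fa_dmn <- subset(sc, network == "DMN" & index == "FA")
  raw <- subset(as.data.frame(tab), network == "DMN" & index == "FA")
  expect_equal(fa_dmn$linear, raw$linear * 1e2)
  md_va <- subset(sc, network == "VA" & index == "MD")
  raw_md <- subset(as.data.frame(tab), network == "VA" & index == "MD")
  expect_equal(md_va$intercept, raw_md$intercept * 1e3)
  # curves are evaluable
  cv <- trajectory_curves(tab, ages = c(30, 60))
  expect_equal(nrow(cv), 56)
  # a cell with too few values fails without stopping the run
  rec$FA.VIS.resid[3:40] <- NA
  tab2 <- fit_all(rec)
  expect_equal(subset(as.data.frame(tab2), network == "VIS" &
                        index == "FA")$status, "failed")
  expect_equal(sum(tab2$status == "ok"), 27)
  expect_error(fit_all(rec[0, ]), "empty")
})
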