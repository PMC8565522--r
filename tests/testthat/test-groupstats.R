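# Simulated records for the group-comparison models: P(s,n) with optional
# group effects, independent covariates.
sim_group_records <- function(n_per_group = 20, effect = 0, noise = 0.01,
                              seed = 1) {
  set.seed(seed)
  groups <- cctopo:::AGE_GROUP_LEVELS
  lo <- c(21, 31, 41, 51, 61, 71, 81)
  age <- unlist(lapply(lo, function(l) sample(l:(l + 9), n_per_group, TRUE)))
  co <- data.frame(id = sprintf("s%03d", seq_along(age)), age = age,
                   sex = rbinom(length(age), 1, 0.5),
                   education_years = round(runif(length(age), 6, 20)),
                   tiv_cm3 = rnorm(length(age), 1400, 110),
                   age_group = age_group_of(age))
  mu <- 0.14 - effect * (age > 60)
  P <- matrix(0.1, length(age), 7,
              dimnames = list(NULL, network_names(7)))
  P[, "DMN"] <- mu + rnorm(length(age), 0, noise)
  manual_records(co, P)
}

test_that("Bonferroni arithmetic and contrast cardinality are right", {
  rec <- sim_group_records(seed = 2)
  cmp <- compare_age_groups(rec, "DMN")
  expect_equal(cmp$m, 21)
  expect_equal(nrow(cmp$pairwise), 21)
  expect_true(all(cmp$pairwise$p_bonferroni >= cmp$pairwise$p_raw))
  expect_true(all(cmp$pairwise$p_bonferroni <= 1))
  expect_equal(cmp$pairwise$p_bonferroni,
               pmin(1, cmp$pairwise$p_raw * 21))
  # a raw p of 0.01 with m = 21 is not significant after correction
  expect_false(min(1, 0.01 * 21) < 0.05 * 1)
})

test_that("with null covariate effects the ANCOVA reduces to a one-way comparison", {
  rec <- sim_group_records(n_per_group = 60, seed = 3)
  cmp <- compare_age_groups(rec, "DMN")
  d <- data.frame(y = rec$P.DMN, g = factor(rec$age_group))
  oneway <- anova(lm(y ~ g, data = d))
  # covariates carry no signal: omnibus F close to the unadjusted one
  expect_lt(abs(cmp$omnibus$F - oneway$`F value`[1]) / oneway$`F value`[1],
            0.15)
  # and the covariate coefficients are negligible against the group spread
  full <- lm(P.DMN ~ factor(age_group) + sex + education_years + tiv_cm3,
             data = as.data.frame(rec))
  expect_lt(abs(coef(full)[["tiv_cm3"]]) * sd(rec$tiv_cm3), 0.005)
})

test_that("adjusted-mean differences agree with an independent implementation", {
  skip_if_not_installed("emmeans")
  rec <- sim_group_records(n_per_group = 15, effect = 0.02, seed = 4)
  cmp <- compare_age_groups(rec, "DMN")
  d <- data.frame(y = rec$P.DMN, age_group = factor(rec$age_group),
                  sex = rec$sex, education = rec$education_years,
                  tiv = rec$tiv_cm3)
  fit <- lm(y ~ age_group + sex + education + tiv, data = d)
  em <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "age_group"),
                                        "pairwise", adjust = "none"))
  # emmeans reports group_i - group_j; our table is group_j - group_i
  expect_equal(sort(abs(cmp$pairwise$difference)),
               sort(abs(em$estimate)), tolerance = 1e-9)
  expect_equal(sort(cmp$pairwise$p_raw), sort(em$p.value),
               tolerance = 1e-9)
})

test_that("null simulations keep the omnibus test calibrated", {
  # smoke-scale null check (the full 2000-replicate calibration lives in
  # the acceptance suite)
  set.seed(6)
  rejections <- vapply(1:200, function(i) {
    rec <- sim_group_records(n_per_group = 10, seed = 6000 + i)
    compare_age_groups(rec, "DMN")$omnibus$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("a step decrease after 60 is detected against the youngest group", {
  rec <- sim_group_records(n_per_group = 40, effect = 0.03, seed = 7)
  cmp <- compare_age_groups(rec, "DMN")
  expect_lt(cmp$omnibus$p_value, 1e-6)
  pw <- cmp$pairwise
  old <- c("61-70", "71-80", "81-90")
  for (g in old) {
    row <- pw[pw$group_i == "21-30" & pw$group_j == g, ]
    expect_true(row$significant)
    expect_lt(row$difference, 0)
  }
  # permuting group labels destroys the effect
  rec_perm <- rec
  set.seed(8)
  rec_perm$age_group <- sample(rec_perm$age_group)
  cmp_perm <- compare_age_groups(rec_perm, "DMN")
  expect_gt(cmp_perm$omnibus$p_value, 1e-4)
})

test_that("groups with fewer than two subjects are dropped with a warning", {
  rec <- sim_group_records(n_per_group = 10, seed = 9)
  idx_old <- which(rec$age_group == "81-90")
  rec_small <- rec[-idx_old[-1], ]   # keep a single 81-90 subject
  expect_warning(cmp <- compare_age_groups(rec_small, "DMN"), "dropping")
  expect_equal(cmp$m, 15)   # 6 remaining groups
})

test_that("between-subregion comparisons use paired contrasts with Bonferroni", {
  set.seed(10)
  co <- make_cohort(60, seed = 10)
  di <- list()
  m <- di_model_default()
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    di[[paste0(row$index, ".", row$network)]] <-
      eval_traj_row(row, co$age) + rnorm(60, 0, 0.02)
  }
  # make two subregions identical for the triviality check
  di$FA.SM <- di$FA.VA
  rec <- manual_records(co, matrix(0.1, 60, 7,
                                   dimnames = list(NULL, network_names(7))),
                        di)
  cmp <- compare_subregions(rec, "FA")
  expect_equal(cmp$m, 21)
  expect_equal(nrow(cmp$pairwise), 21)
  row <- cmp$pairwise[cmp$pairwise$network_i == "SM" &
                        cmp$pairwise$network_j == "VA", ]
  expect_equal(row$difference, 0)
  expect_equal(row$p_bonferroni, 1)
  expect_false(row$significant)
  # FA ordering: the posterior subregions (VIS, DA) sit on top
  expect_setequal(cmp$ordering[1:2], c("VIS", "DA"))
})
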