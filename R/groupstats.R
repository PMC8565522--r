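# Covariate-adjusted comparisons: subregional connection probability across
# age groups (ANCOVA-style linear model + Bonferroni pairwise contrasts),
# and paired between-subregion comparisons of residualized diffusion
# indices.

#' Compare subregional connection probability across age groups
#'
#' Fits `P(s,n) ~ age_group + sex + education + TIV` as an ordinary linear
#' model (equivalent to an ANCOVA with the group factor of interest),
#' reports the omnibus F test of the group factor, and all pairwise
#' adjusted-mean differences between groups with pooled-error t tests and
#' Bonferroni correction (m = g(g-1)/2 contrasts).
#'
#' @param records a [subject_records()] table (columns `P.<network>`,
#'   `age_group`, `sex`, `education_years`, `tiv_cm3`).
#' @param network network name, e.g. `"DMN"`.
#' @param alpha significance level on the corrected p, default 0.05.
#' @return object of class `cc_groupcmp`: list with `network`, `omnibus`
#'   (`F`, `df`, `p_value`), `pairwise` (data.frame with `group_i`,
#'   `group_j`, `difference` (j - i adjusted means), `se`, `p_raw`,
#'   `p_bonferroni`, `significant`), `m` (number of contrasts), `dropped`
#'   (groups with < 2 subjects).
#' @export
compare_age_groups <- function(records, network, alpha = 0.05) {
  col <- paste0("P.", network)
  if (!col %in% names(records)) stop("no connection-probability column for ",
                                     network)
  d <- data.frame(y = records[[col]],
                  age_group = factor(records$age_group),
                  sex = records$sex,
                  education = records$education_years,
                  tiv = records$tiv_cm3)
  d <- d[stats::complete.cases(d), ]
  tab <- table(d$age_group)
  dropped <- names(tab)[tab < 2]
  if (length(dropped)) {
    warning("dropping age groups with < 2 subjects: ",
            paste(dropped, collapse = ", "))
    d <- d[!d$age_group %in% dropped, ]
  }
  d$age_group <- droplevels(d$age_group)
  g <- nlevels(d$age_group)
  if (g < 2) stop("need at least 2 age groups with >= 2 subjects")

  full <- stats::lm(y ~ age_group + sex + education + tiv, data = d)
  reduced <- stats::lm(y ~ sex + education + tiv, data = d)
  an <- stats::anova(reduced, full)
  omnibus <- list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                  p_value = an$`Pr(>F)`[2])

  # pairwise adjusted-mean differences: with treatment coding and shared
  # covariate values, group j - group i equals the difference of the group
  # coefficients
  cf <- stats::coef(full)
  V <- stats::vcov(full)
  lev <- levels(d$age_group)
  cname <- function(l) paste0("age_group", l)
  m <- g * (g - 1) / 2
  rows <- list()
  rdf <- full$df.residual
  for (i in 1:(g - 1)) for (j in (i + 1):g) {
    cvec <- stats::setNames(numeric(length(cf)), names(cf))
    if (i > 1) cvec[cname(lev[i])] <- -1
    cvec[cname(lev[j])] <- 1
    diff <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    t <- diff / se
    p_raw <- 2 * stats::pt(abs(t), rdf, lower.tail = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(group_i = lev[i], group_j = lev[j], difference = diff,
                 se = se, p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * m))
  }
  pw <- do.call(rbind, rows)
  pw$significant <- pw$p_bonferroni < alpha
  structure(list(network = network, omnibus = omnibus, pairwise = pw,
                 m = m, dropped = dropped, n = nrow(d)),
            class = "cc_groupcmp")
}

#' @export
print.cc_groupcmp <- function(x, ...) {
  cat("Age-group comparison of connection probability:", x$network, "\n")
  cat(sprintf("  omnibus F(%d, %d) = %.3f, p = %.4g  (n = %d)\n",
              x$omnibus$df[1], x$omnibus$df[2], x$omnibus$F,
              x$omnibus$p_value, x$n))
  sig <- x$pairwise[x$pairwise$significant, ]
  cat("  significant pairs (Bonferroni, m =", x$m, "):",
      if (nrow(sig)) "" else "none", "\n")
  if (nrow(sig))
    print(sig[, c("group_i", "group_j", "difference", "p_bonferroni")],
          row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pairwise comparison of a diffusion index between subregions
#'
#' Within-subject design: the index is residualized on age, sex, education
#' and TIV (all nuisance factors for a between-subregion contrast), then
#' every subregion pair is compared with a paired t test,
#' Bonferroni-corrected over m = K(K-1)/2 pairs. Subjects missing the
#' index in either member of a pair are dropped from that pair.
#'
#' @param records a [subject_records()] table.
#' @param index one of `"FA"`, `"MD"`, `"RD"`, `"AD"`.
#' @param alpha significance level on the corrected p, default 0.05.
#' @return object of class `cc_subregioncmp`: list with `index`, `pairwise`
#'   (data.frame `network_i`, `network_j`, `difference` (i - j),
#'   `p_raw`, `p_bonferroni`, `significant`, `n`), `m`, and `ordering`
#'   (networks sorted by decreasing adjusted mean).
#' @export
compare_subregions <- function(records, index, alpha = 0.05) {
  pcols <- grep("^P\\.", names(records), value = TRUE)
  nets <- sub("^P\\.", "", pcols)
  covs <- data.frame(age = records$age, sex = records$sex,
                     education = records$education_years,
                     tiv = records$tiv_cm3)
  res <- list()
  for (net in nets) {
    v <- records[[paste0(index, ".", net)]]
    if (is.null(v)) stop("records lack ", index, " values for ", net)
    r <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    if (sum(ok) >= ncol(covs) + 2)
      r[ok] <- residualize(v[ok], covs[ok, , drop = FALSE])
    res[[net]] <- r
  }
  K <- length(nets)
  m <- K * (K - 1) / 2
  rows <- list()
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    xi <- res[[nets[i]]]; xj <- res[[nets[j]]]
    ok <- !is.na(xi) & !is.na(xj)
    di <- xi[ok] - xj[ok]
    if (sum(ok) >= 2 && stats::sd(di) > 0) {
      tt <- stats::t.test(xi[ok], xj[ok], paired = TRUE)
      p_raw <- tt$p.value
      diff <- unname(tt$estimate)
    } else {
      # identical values in the two subregions: difference 0, no evidence
      diff <- mean(di)
      p_raw <- if (all(di == 0)) 1 else NA_real_
    }
    rows[[length(rows) + 1]] <-
      data.frame(network_i = nets[i], network_j = nets[j],
                 difference = diff, p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * m), n = sum(ok))
  }
  pw <- do.call(rbind, rows)
  pw$significant <- !is.na(pw$p_bonferroni) & pw$p_bonferroni < alpha
  means <- vapply(res, mean, 1, na.rm = TRUE)
  structure(list(index = index, pairwise = pw, m = m,
                 ordering = names(sort(means, decreasing = TRUE)),
                 means = means),
            class = "cc_subregioncmp")
}

#' @export
print.cc_subregioncmp <- function(x, ...) {
  cat("Between-subregion comparison of", x$index, "\n")
  cat("  ordering (high to low):", paste(x$ordering, collapse = " > "), "\n")
  cat("  significant pairs:", sum(x$pairwise$significant), "of", x$m, "\n")
  invisible(x)
}
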