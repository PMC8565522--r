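# Synthetic cohort tables: age, sex, education and total intracranial
# volume, with the seven canonical decade-style age bins.

AGE_GROUP_LEVELS <- c("21-30", "31-40", "41-50", "51-60",
                      "61-70", "71-80", "81-90")

# Published group sizes for the reference 1,086-subject cohort, used by the
# "table1" age distribution mode.
.reference_group_sizes <- c(73L, 41L, 42L, 413L, 305L, 188L, 24L)

#' Age bin of an age in years
#'
#' Deterministic mapping of integer ages 21-90 onto the seven bins
#' ("21-30" ... "81-90"); age 60 falls in "51-60", 61 in "61-70".
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `"21-30"` ... `"81-90"`.
#' @export
age_group_of <- function(age) {
  if (any(age < 21 | age > 90)) stop("ages must lie within [21, 90]")
  cut(age, breaks = c(20, 30, 40, 50, 60, 70, 80, 90),
      labels = AGE_GROUP_LEVELS, right = TRUE)
}

#' Generate a synthetic cohort table
#'
#' Draws integer ages either uniformly on 21-90 or in "table1" mode, which
#' reproduces the reference study's seven group sizes (73, 41, 42, 413, 305,
#' 188, 24 at n = 1086; proportionally scaled otherwise) with uniform ages
#' within each bin. Sex is balanced Bernoulli(0.5) coded 0/1; education
#' (years) declines with age and total intracranial volume (TIV, cm^3)
#' shrinks mildly with age, mimicking typical lifespan cohorts.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param age_distribution `"uniform"` (default) or `"table1"`.
#' @param seed integer seed; the table is fully deterministic given it.
#' @return a `data.frame` of class `cc_cohort` with columns `id`, `age`,
#'   `sex`, `education_years`, `tiv_cm3`, `age_group`.
#' @examples
#' co <- make_cohort(20, seed = 1)
#' table(co$age_group)
#' @export
make_cohort <- function(n_subjects, age_distribution = c("uniform", "table1"),
                        seed = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  age_distribution <- match.arg(age_distribution)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_subjects)

  if (age_distribution == "uniform") {
    age <- sample(21:90, n, replace = TRUE)
  } else {
    sizes <- .scale_group_sizes(n)
    lo <- c(21, 31, 41, 51, 61, 71, 81)
    hi <- c(30, 40, 50, 60, 70, 80, 90)
    age <- unlist(lapply(seq_along(sizes), function(g)
      if (sizes[g] > 0) sample(lo[g]:hi[g], sizes[g], replace = TRUE)
      else integer(0)))
  }

  sex <- stats::rbinom(n, 1L, 0.5)
  education <- pmin(pmax(round(stats::rnorm(n, 18 - 0.18 * (age - 25), 3.5)), 0), 22)
  tiv <- round(stats::rnorm(n, 1480 - 2.5 * (age - 25), 120), 1)
  tiv <- pmax(tiv, 900)

  out <- data.frame(id = sprintf("sub-%04d", seq_len(n)),
                    age = as.integer(age), sex = sex,
                    education_years = as.integer(education),
                    tiv_cm3 = tiv,
                    age_group = age_group_of(age),
                    stringsAsFactors = FALSE)
  class(out) <- c("cc_cohort", "data.frame")
  out
}

# Scale the reference group sizes to a total of n, largest-remainder rounding.
.scale_group_sizes <- function(n) {
  ref <- .reference_group_sizes
  if (n == sum(ref)) return(ref)
  raw <- ref / sum(ref) * n
  sz <- floor(raw)
  rem <- n - sum(sz)
  if (rem > 0) {
    order_frac <- order(raw - sz, decreasing = TRUE)
    sz[order_frac[seq_len(rem)]] <- sz[order_frac[seq_len(rem)]] + 1
  }
  as.integer(sz)
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x), "subjects\n")
  print(table(x$age_group))
  invisible(x)
}
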