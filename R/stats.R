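#' Two-sided Fisher's exact test for a 2x2 table
#'
#' With the table margins fixed, the two-sided p-value is the sum of the
#' hypergeometric probabilities of all tables whose point probability does
#' not exceed that of the observed table (the point-probability tail
#' definition, as used by the classical statistical packages). Probabilities
#' are computed in log space via `lchoose`, accurate well beyond 12
#' significant digits for the table sizes of interest.
#'
#' @param table A 2x2 matrix of non-negative integer counts (rows = group,
#'   columns = detected / not detected), or a length-4 vector `c(a, b, c, d)`
#'   read row-wise.
#' @return An object of class `fisher_result`: list with `p` (two-sided
#'   p-value), `point_prob` (probability of the observed table), and `table`.
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(0, 31, 2, 26), 2, 2, byrow = TRUE))$p
fisher_exact_two_sided <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !identical(dim(table), c(2L, 2L))) {
    abort("`table` must be a 2x2 matrix or a length-4 vector")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  n_total <- sum(table)
  if (n_total < 1) abort("table must contain at least one observation")

  r1 <- sum(table[1, ])
  c1 <- sum(table[, 1])
  a_obs <- table[1, 1]
  support <- max(0, r1 + c1 - n_total):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n_total - c1, r1 - support) -
    lchoose(n_total, r1)
  logp_obs <- logp[support == a_obs]
  # p-values of tables "no more probable" than observed, with a relative
  # tolerance guarding against floating-point ties
  in_tail <- logp <= logp_obs + log(1 + 1e-7)
  p <- min(1, sum(exp(logp[in_tail])))
  structure(
    list(p = p, point_prob = exp(logp_obs), table = table),
    class = "fisher_result"
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf(
    "Fisher's exact test (two-sided): p = %.4g (point probability %.4g)\n",
    x$p, x$point_prob
  ))
  invisible(x)
}

#' @export
tidy.fisher_result <- function(x, ...) {
  tibble(
    p.value = x$p, point_prob = x$point_prob,
    method = "Fisher's exact test (two-sided, point-probability tail)"
  )
}

mwu_u_stat <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y)) # midranks for ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  c(u1 = u1, u2 = u2)
}

mwu_exact_p <- function(x, y) {
  # full enumeration over all assignments of the pooled ranks to group 1;
  # two-sided tail by symmetry of the null U distribution about n1*n2/2
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

mwu_normal_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(1) # all values tied
  }
  z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2) # continuity correction
  z <- max(z, 0)
  min(1, 2 * pnorm(-z))
}

#' Mann-Whitney U test
#'
#' Rank-sum two-sample test with midranks for ties. The reported statistic is
#' `U = min(U1, U2)`. The two-sided p-value is exact -- by full enumeration
#' of all rank assignments -- when both samples have at most 10 observations
#' and there are no ties; otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`. `"exact"`
#'   errors when ties are present.
#' @return An object of class `mwu_result`: list with `U`, `p`, `n1`, `n2`,
#'   `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  u <- mwu_u_stat(x, y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = length(x) <= 10 && length(y) <= 10 && !has_ties
  )
  if (use_exact && has_ties) {
    abort("exact mode requires untied samples; use mode = \"normal\"")
  }
  p <- if (use_exact) mwu_exact_p(x, y) else mwu_normal_p(x, y)
  structure(
    list(
      U = unname(min(u)), p = p, n1 = length(x), n2 = length(y),
      method = if (use_exact) "exact" else "normal_tie_corrected"
    ),
    class = "mwu_result"
  )
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U test: U(%d,%d) = %g, p = %.4g (%s)\n",
    x$n1, x$n2, x$U, x$p, x$method
  ))
  invisible(x)
}

#' @export
tidy.mwu_result <- function(x, ...) {
  tibble(statistic = x$U, p.value = x$p, method = x$method)
}

#' @export
glance.mwu_result <- function(x, ...) {
  tibble(statistic = x$U, p.value = x$p, n1 = x$n1, n2 = x$n2, method = x$method)
}

#' Integer percent occurrence
#'
#' `100 * k / n` rounded half away from zero to an integer percent -- the
#' rounding that reproduces reported detection frequencies.
#'
#' @param k Count of positives (vectorized), `0 <= k <= n`.
#' @param n Total count, `n > 0`.
#' @return Integer percent(s).
#' @export
#' @examples
#' percent_occurrence(17, 31) # 55
percent_occurrence <- function(k, n) {
  if (any(n <= 0)) abort("`n` must be > 0")
  if (any(k < 0) || any(k > n)) abort("need 0 <= k <= n")
  as.integer(floor(100 * k / n + 0.5))
}
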