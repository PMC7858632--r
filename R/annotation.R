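# Small-sample enrichment statistics (2x2 Fisher exact with conditional-MLE
# odds ratio) and liability-scale variance explained by associated variants.

# Noncentral hypergeometric log-likelihood support and weights for a 2x2
# table with margins (m1 = a+b, m2 = c+d, n1 = a+c) at log odds ratio theta.
nchg_support <- function(m1, m2, n1) max(0, n1 - m2):min(m1, n1)

nchg_logweights <- function(x, m1, m2, n1, theta) {
  lchoose(m1, x) + lchoose(m2, n1 - x) + x * theta
}

nchg_mean <- function(m1, m2, n1, theta) {
  x <- nchg_support(m1, m2, n1)
  lw <- nchg_logweights(x, m1, m2, n1, theta)
  w <- exp(lw - max(lw))
  sum(x * w) / sum(w)
}

nchg_tail <- function(a, m1, m2, n1, theta, upper = TRUE) {
  x <- nchg_support(m1, m2, n1)
  lw <- nchg_logweights(x, m1, m2, n1, theta)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  if (upper) sum(w[x >= a]) else sum(w[x <= a])
}

solve_theta <- function(f, lo = -50, hi = 50) {
  if (f(lo) * f(hi) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fisher exact test for a 2x2 table with conditional-MLE odds ratio
#'
#' Two-sided P by the probability-mass rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one. The odds ratio is the conditional maximum-likelihood
#' estimate solving `E[a | margins, OR] = a` under the noncentral
#' hypergeometric distribution, with a 95% CI from inverting the conditional
#' one-sided tests. Degenerate margins give P = 1 with an undefined-OR flag.
#'
#' @param a,b,c,d Non-negative integer cells (rows = groups, columns = in/out
#'   of the gene set).
#' @return List with `p`, `or` (conditional MLE; 0 or Inf at the support
#'   boundary, flagged), `ci`, and flags `or_defined`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0)
    return(list(p = 1, or = NA_real_, ci = c(NA_real_, NA_real_),
                or_defined = FALSE, degenerate = TRUE))
  x <- nchg_support(m1, m2, n1)
  pr <- stats::dhyper(x, m1, m2, n1)
  p_obs <- stats::dhyper(a, m1, m2, n1)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  at_lo <- a == min(x); at_hi <- a == max(x)
  or <- if (at_lo && at_hi) 1 else if (at_lo) 0 else if (at_hi) Inf else {
    th <- solve_theta(function(t) nchg_mean(m1, m2, n1, t) - a)
    exp(th)
  }
  # CI by inverting the conditional test (as fisher.test does)
  ci_lo <- if (at_lo) 0 else {
    th <- solve_theta(function(t) nchg_tail(a, m1, m2, n1, t, upper = TRUE) - 0.025)
    exp(th)
  }
  ci_hi <- if (at_hi) Inf else {
    th <- solve_theta(function(t) nchg_tail(a, m1, m2, n1, t, upper = FALSE) - 0.025)
    exp(th)
  }
  list(p = p, or = or, ci = c(ci_lo, ci_hi),
       or_defined = is.finite(or) && or > 0, degenerate = FALSE)
}

# Solve the baseline odds so that the multiplicative-odds penetrances
# average to the population lifetime risk K.
solve_baseline_odds <- function(p, R, K) {
  fg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  f <- function(lo0) {
    odds <- exp(lo0) * R^(0:2)
    sum(fg * odds / (1 + odds)) - K
  }
  lo <- log(K) - 40; hi <- log(0.5 / (1 - 0.5))
  if (f(lo) > 0 || f(hi) < 0) stop("no penetrance solution in (0, 1)")
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-14)$root)
}

#' Liability-scale variance explained by one risk variant
#'
#' Under Hardy-Weinberg genotype frequencies and multiplicative odds
#' (genotype odds `odds0 * R^g`) scaled so the average penetrance equals the
#' lifetime risk K, each genotype's penetrance is mapped to a mean liability
#' on the standard-normal liability scale (`mu_g = t - qnorm(1 - pen_g)` with
#' threshold `t = qnorm(1 - K)`); the between-genotype variance of those
#' means is the variance explained.
#'
#' @param p Risk-allele frequency in (0, 1).
#' @param R Per-allele odds ratio (> 0).
#' @param K Population lifetime risk in (0, 0.5).
#' @return List with `variance`, genotype `penetrance`, `mu` and frequencies.
#' @export
liability_variance_explained <- function(p, R, K) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (!is.finite(K) || K <= 0 || K >= 0.5) stop("K must lie in (0, 0.5)")
  fg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  odds0 <- solve_baseline_odds(p, R, K)
  pen <- odds0 * R^(0:2) / (1 + odds0 * R^(0:2))
  t0 <- stats::qnorm(1 - K)
  mu <- t0 - stats::qnorm(1 - pen)
  mbar <- sum(fg * mu)
  list(variance = sum(fg * (mu - mbar)^2), penetrance = pen, mu = mu,
       genotype_freq = fg, threshold = t0)
}

#' Total liability variance explained by independent variants
#'
#' Sums per-variant liability-scale variances under the independence
#' assumption (recorded in the output).
#'
#' @param inputs Data frame with columns `p`, `R`, `K` (one row per variant).
#' @return List with `total`, `per_variant` and `assumes_independence = TRUE`.
#' @export
total_variance_explained <- function(inputs) {
  stopifnot(nrow(inputs) >= 1, all(c("p", "R", "K") %in% names(inputs)))
  per <- vapply(seq_len(nrow(inputs)), function(i)
    liability_variance_explained(inputs$p[i], inputs$R[i], inputs$K[i])$variance,
    0)
  list(total = sum(per), per_variant = per, assumes_independence = TRUE)
}
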