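# Independent brute-force / enumeration oracles used to cross-check the
# package implementations. These deliberately use the most direct possible
# computation, not the package's code paths.

# Logistic MLE by generic numeric optimization of the log-likelihood.
oracle_logistic_mle <- function(X, y) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))$par
}

# Hardy-Weinberg exact P by direct enumeration of all genotype tables with
# the observed allele-count margins.
oracle_hwe_enum <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  hets <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (n_alt - h) / 2
    rr <- n - aa - h
    exp(lfactorial(n) - lfactorial(rr) - lfactorial(h) - lfactorial(aa) +
          h * log(2) + lfactorial(n_alt) + lfactorial(2 * n - n_alt) -
          lfactorial(2 * n))
  }, 0)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Fisher exact two-sided P by enumeration over all tables with the observed
# margins (probability-mass rule).
oracle_fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  x <- max(0, n1 - m2):min(m1, n1)
  pr <- vapply(x, function(k)
    exp(lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(m1 + m2, n1)), 0)
  p_obs <- pr[match(a, x)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Single-causal posteriors by explicit enumeration of the one-causal
# configurations: configuration j has likelihood proportional to ABF_j.
oracle_posterior_enum <- function(labf) {
  lik <- exp(labf - max(labf))
  lik / sum(lik)
}

# Colocalization posteriors by brute-force enumeration of all causal-variant
# pair configurations for the two traits.
oracle_coloc_enum <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  m <- length(bf1)
  w0 <- 1
  w1 <- sum(p1 * bf1)
  w2 <- sum(p2 * bf2)
  w3 <- 0; w4 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) w4 <- w4 + p12 * bf1[i] * bf2[j]
    else w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
  }
  w <- c(w0, w1, w2, w3, w4)
  stats::setNames(w / sum(w), paste0("PP", 0:4))
}

# EHH at each position by explicit enumeration of all carrier haplotype
# pairs, checking identity over every variant between the core and x.
oracle_ehh_points <- function(hap, core, allele, idx) {
  carriers <- which(hap[, core] == allele)
  n <- length(carriers)
  pairs <- utils::combn(carriers, 2)
  vapply(seq_along(idx), function(k) {
    span <- if (idx[k] > core) (core + 1):idx[k] else idx[k]:(core - 1)
    same <- vapply(seq_len(ncol(pairs)), function(pp)
      all(hap[pairs[1, pp], span] == hap[pairs[2, pp], span]), TRUE)
    sum(same) / choose(n, 2)
  }, 0)
}

# Raw iHS by brute-force: pair-enumerated EHH curves for both alleles,
# trapezoid-integrated over bp with the same truncation rule.
oracle_ihs_raw <- function(panel, core, stop_ehh = 0.05) {
  hap <- panel$haplotypes
  pos <- panel$positions
  m <- ncol(hap)
  one_side <- function(allele, idx) {
    if (length(idx) == 0) return(list(pos = numeric(0), ehh = numeric(0)))
    e <- numeric(0); keep <- integer(0)
    for (k in seq_along(idx)) {
      v <- oracle_ehh_points(hap, core, allele, idx[k])
      e <- c(e, v); keep <- c(keep, idx[k])
      if (v < stop_ehh) break
    }
    list(pos = pos[keep], ehh = e)
  }
  curve_int <- function(allele) {
    r <- one_side(allele, if (core < m) (core + 1):m else integer(0))
    l <- one_side(allele, if (core > 1) (core - 1):1 else integer(0))
    x <- c(rev(l$pos), pos[core], r$pos)
    y <- c(rev(l$ehh), 1, r$ehh)
    sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  }
  log(curve_int(0L) / curve_int(1L))
}

# Liability-scale variance by numeric integration: genotype liability means
# are found by grid inversion of the normal tail rather than qnorm.
oracle_liability_grid <- function(p, R, K) {
  fg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  f <- function(lo0) {
    odds <- exp(lo0) * R^(0:2)
    sum(fg * odds / (1 + odds)) - K
  }
  odds0 <- exp(stats::uniroot(f, c(log(K) - 40, 0), tol = 1e-14)$root)
  pen <- odds0 * R^(0:2) / (1 + odds0 * R^(0:2))
  t0 <- stats::qnorm(1 - K)
  tail_prob <- function(mu) {  # numeric quadrature of the normal tail
    x <- seq(t0 - mu, t0 - mu + 12, length.out = 20001)
    sum(stats::dnorm(x)) * (x[2] - x[1])
  }
  mu <- vapply(pen, function(pe)
    stats::uniroot(function(m) tail_prob(m) - pe, c(-2, 2), tol = 1e-10)$root,
    0)
  mbar <- sum(fg * mu)
  sum(fg * (mu - mbar)^2)
}

# AUC by exhaustive pair counting: concordant + half ties over all
# case-control pairs.
oracle_auc_pairs <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}
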