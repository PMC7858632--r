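# Five-hypothesis colocalization from per-variant approximate Bayes factors,
# and the empirical unrelated-phenotype baseline comparison.

#' Colocalization posterior probabilities (PP0-PP4)
#'
#' From the per-variant log Bayes factors of two traits over the same variant
#' set, evaluates the five hypotheses: H0 no association; H1/H2 association
#' with trait 1/2 only; H3 both traits, two distinct causal variants; H4 both
#' traits, one shared causal variant. Unnormalized weights are 1,
#' `p1 * sum(BF1)`, `p2 * sum(BF2)`,
#' `p1 p2 (sum(BF1) sum(BF2) - sum(BF1 BF2))` and `p12 * sum(BF1 BF2)`;
#' all accumulation is in log space.
#'
#' @param labf1,labf2 Per-variant log ABFs for the two traits.
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait 1,
#'   trait 2, or both (defaults 1e-4, 1e-4, 1e-5).
#' @return A `coloc_result` list with `pp` (PP0..PP4, summing to 1) and the
#'   priors.
#' @export
coloc_pp <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (length(labf1) != length(labf2)) stop("variant sets differ")
  if (any(c(p1, p2, p12) < 0)) stop("priors must be non-negative")
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  ls1 <- logsumexp(labf1)
  ls2 <- logsumexp(labf2)
  ls12 <- logsumexp(labf1 + labf2)
  lh <- c(h0 = 0,
          h1 = log(p1) + ls1,
          h2 = log(p2) + ls2,
          h3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
          h4 = log(p12) + ls12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_variants = length(labf1)),
            class = "coloc_result")
}

#' Compare an observed colocalization against an unrelated-phenotype baseline
#'
#' Places the observed PP4 within the empirical distribution of PP4 values
#' obtained by colocalizing the same locus against phenotypes with no true
#' relationship (the LD-difference control). The add-one empirical P is
#' `(1 + #baseline >= observed) / (1 + n)`; the locus is flagged as exceeding
#' the baseline when the observed PP4 is above every baseline value.
#'
#' @param observed A `coloc_result` (or a bare PP4 value).
#' @param baseline A list of `coloc_result`s (or numeric PP4 vector), >= 5
#'   runs.
#' @return List with `pp4`, `baseline_mean`, `baseline_sd`, `quantile`,
#'   `empirical_p` and `exceeds_baseline`.
#' @export
coloc_baseline <- function(observed, baseline) {
  pp4 <- if (inherits(observed, "coloc_result")) observed$pp[["PP4"]] else observed
  base <- if (is.numeric(baseline)) baseline
          else vapply(baseline, function(x) x$pp[["PP4"]], 0)
  if (length(base) < 5) stop("need at least 5 baseline runs")
  n <- length(base)
  emp_p <- (1 + sum(base >= pp4)) / (1 + n)
  list(pp4 = pp4, baseline_mean = mean(base), baseline_sd = stats::sd(base),
       quantile = mean(base < pp4), empirical_p = emp_p,
       exceeds_baseline = pp4 > max(base) || emp_p <= 1 / (n + 1))
}
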