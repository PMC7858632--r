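# Wakefield approximate Bayes factors, single-causal-variant posteriors,
# 95% credible sets, locus boundaries from recombination maps, and the
# trans-ancestral joint fine-map.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield log approximate Bayes factor
#'
#' `ABF = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` for a variant with
#' Wald statistic `z`, effect variance `V = se^2` and prior effect variance
#' `W`; computed and returned in log space.
#'
#' @param z Wald z statistic(s).
#' @param V Variance(s) of the effect estimate (se squared).
#' @param W Prior variance of the true effect; default `0.2^2` on the
#'   log-odds scale, the usual choice for binary traits.
#' @return log ABF (vectorized).
#' @export
wakefield_labf <- function(z, V, W = 0.04) {
  if (any(!is.finite(V)) || any(V <= 0) || any(W <= 0))
    stop("variances must be positive")
  r <- W / (V + W)
  0.5 * log1p(-r) + z^2 * r / 2
}

#' Single-causal-variant posterior probabilities
#'
#' With a uniform prior over which one variant in the locus is causal,
#' posterior_j = ABF_j / sum_k ABF_k, computed by log-sum-exp.
#'
#' @param labf Per-variant log approximate Bayes factors.
#' @return Posterior probabilities summing to 1.
#' @export
single_causal_posterior <- function(labf) {
  if (length(labf) == 0) stop("empty locus")
  exp(labf - logsumexp(labf))
}

#' 95% credible set
#'
#' Variants sorted by descending posterior are accumulated until the
#' cumulative mass reaches `mass`; posterior ties at the boundary are all
#' included.
#'
#' @param posteriors Normalized posterior probabilities.
#' @param ids Variant identifiers (defaults to indices).
#' @param mass Target cumulative mass in (0, 1].
#' @return List with `ids`, `indices` and achieved `mass`.
#' @export
credible_set <- function(posteriors, ids = seq_along(posteriors), mass = 0.95) {
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  ord <- order(posteriors, decreasing = TRUE)
  cum <- cumsum(posteriors[ord])
  k <- which(cum >= mass - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  # include boundary ties
  while (k < length(ord) &&
         abs(posteriors[ord[k + 1]] - posteriors[ord[k]]) < 1e-12) k <- k + 1
  sel <- ord[seq_len(k)]
  list(ids = ids[sel], indices = sort(sel), mass = sum(posteriors[sel]))
}

#' Fine-map a locus from association statistics
#'
#' @param assoc `assoc_table` rows for the locus (one ancestry or a meta).
#' @param W Prior effect variance for [wakefield_labf()].
#' @param mass Credible-set mass.
#' @param label Ancestry label stored on the result.
#' @return A `locus_finemap` list: per-variant `labf`, `posterior`, the
#'   credible set, and the label.
#' @export
finemap_locus <- function(assoc, W = 0.04, mass = 0.95, label = "single") {
  labf <- wakefield_labf(assoc$Z, assoc$SE^2, W)
  post <- single_causal_posterior(labf)
  structure(list(ids = assoc$SNP, labf = labf, posterior = post,
                 credible_set = credible_set(post, assoc$SNP, mass),
                 label = label),
            class = "locus_finemap")
}

#' Trans-ancestral single-causal fine-map
#'
#' Under a shared single causal variant, per-variant joint evidence is the
#' product of the two ancestries' Bayes factors (sum of log ABFs); posteriors
#' and the credible set follow as in the single-ancestry case.
#'
#' @param labf_eas,labf_eur Per-variant log ABFs over the same aligned
#'   variant set.
#' @param ids Variant identifiers.
#' @param mass Credible-set mass.
#' @return A `locus_finemap` with label `"trans"`.
#' @export
trans_ancestral_finemap <- function(labf_eas, labf_eur,
                                    ids = seq_along(labf_eas), mass = 0.95) {
  if (length(labf_eas) != length(labf_eur))
    stop("variant sets differ between ancestries")
  joint <- labf_eas + labf_eur
  post <- single_causal_posterior(joint)
  structure(list(ids = ids, labf = joint, posterior = post,
                 credible_set = credible_set(post, ids, mass), label = "trans"),
            class = "locus_finemap")
}

#' Locus boundaries from a recombination-rate map
#'
#' Extends outward from the lead position until the first map point whose
#' rate reaches `rate_threshold` cM/Mb on each side; absent such a point the
#' interval is clipped to the map edge. A hotspot exactly at the lead gives a
#' degenerate one-sided interval, which is flagged.
#'
#' @param lead_pos Lead variant position (bp).
#' @param map Data frame with columns `pos` (bp) and `rate` (cM/Mb), sorted.
#' @param rate_threshold Boundary rate in cM/Mb (default 10).
#' @return List with `start`, `end` (0-based half-open), `degenerate` flag.
#' @export
define_locus <- function(lead_pos, map, rate_threshold = 10) {
  stopifnot(all(c("pos", "rate") %in% names(map)))
  map <- map[order(map$pos), ]
  if (lead_pos < min(map$pos) || lead_pos > max(map$pos))
    stop("lead position outside the recombination map")
  hot <- map$pos[map$rate >= rate_threshold]
  left <- hot[hot <= lead_pos]
  right <- hot[hot >= lead_pos]
  start <- if (length(left)) max(left) else min(map$pos)
  end <- if (length(right)) min(right) else max(map$pos)
  degenerate <- any(hot == lead_pos)
  list(start = start, end = max(end, start + 1L), lead = lead_pos,
       degenerate = degenerate)
}
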