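# Fixed-effect inverse-variance meta-analysis, Cochran's Q heterogeneity,
# Benjamini-Hochberg adjustment, and the four-category ancestry
# classification of disease loci.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Decide how a second study's alleles align to a reference pair
#'
#' Returns `"same"` when the effect/other alleles match, `"flip"` when they
#' are swapped (beta sign and EAF must be flipped), `"ambiguous"` for
#' strand-ambiguous A/T and C/G pairs that do not match directly, and
#' `"mismatch"` otherwise. Strand complements are resolved before comparison.
#'
#' @param ref_a1,ref_a2 Reference effect and other alleles.
#' @param a1,a2 Candidate effect and other alleles.
#' @return One of "same", "flip", "ambiguous", "mismatch".
#' @export
align_alleles <- function(ref_a1, ref_a2, a1, a2) {
  ambiguous <- function(x, y) COMPLEMENT[[x]] == y
  if (a1 == ref_a1 && a2 == ref_a2) return("same")
  if (a1 == ref_a2 && a2 == ref_a1) return("flip")
  if (ambiguous(ref_a1, ref_a2)) return("ambiguous")
  ca1 <- COMPLEMENT[[a1]]; ca2 <- COMPLEMENT[[a2]]
  if (ca1 == ref_a1 && ca2 == ref_a2) return("same")
  if (ca1 == ref_a2 && ca2 == ref_a1) return("flip")
  "mismatch"
}

check_meta_input <- function(beta, se) {
  if (length(beta) != length(se) || length(beta) < 1)
    stop("need matched beta and se vectors with at least one study")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study effects with weights `1/se^2`: pooled beta is the weighted mean
#' and pooled se is `1/sqrt(sum(w))`.
#'
#' @param beta Per-study effect sizes (log odds ratios) on aligned alleles.
#' @param se Per-study standard errors.
#' @return List with `beta`, `se`, `z`, `p`, `weights` and `k`.
#' @export
fixed_effect_meta <- function(beta, se) {
  check_meta_input(beta, se)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)), weights = w,
       k = length(beta))
}

#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance weighted sum of squared deviations of study
#' effects from their fixed-effect pool; under homogeneity Q is chi-square
#' with k - 1 degrees of freedom.
#'
#' @param beta,se Per-study effects and standard errors (k >= 2).
#' @return List with `Q`, `df` and `p`.
#' @export
cochran_q <- function(beta, se) {
  check_meta_input(beta, se)
  if (length(beta) < 2) stop("Cochran's Q needs at least two studies")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b)^2)
  df <- length(beta) - 1
  list(Q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted P-values with monotonicity enforcement, capped at 1,
#' returned in the input order.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted P-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Recover a standard error from a printed odds ratio and P-value
#'
#' `se = |log OR| / qnorm(1 - P/2)`; approximate when OR and P are rounded.
#'
#' @param or Odds ratio.
#' @param p Two-sided P-value.
#' @return Standard error of log OR.
#' @export
se_from_or_p <- function(or, p) abs(log(or)) / stats::qnorm(1 - p / 2)

#' Wald 95% confidence interval for an odds ratio
#' @param beta Log odds ratio.
#' @param se Standard error of beta.
#' @return Length-2 vector (lower, upper) on the OR scale.
#' @export
or_ci <- function(beta, se) exp(beta + c(-1.96, 1.96) * se)

#' Classify a disease locus by cross-ancestry effect heterogeneity
#'
#' Category 4: risk allele absent or rare (MAF < `maf_rare`) in one ancestry
#' (checked first). Category 3 (ancestry-heterogeneous): FDR-adjusted
#' Cochran's Q P < 0.05. Category 2 (putative heterogeneous): raw Q P < 0.05.
#' Category 1: ancestry-shared. Within category 3 the locus is flagged
#' ancestry-specific when one ancestry has P < 5e-8, the other P > 0.01, and
#' the Wald 95% CIs of the two odds ratios do not overlap.
#'
#' @param eas,eur Lists (or one-row data frames) with `BETA`, `SE`, `P` for
#'   the same aligned variant in each ancestry.
#' @param cq_p Raw Cochran's Q P-value.
#' @param cq_fdr_p FDR-adjusted Q P-value (over the lead-variant batch).
#' @param maf_eas,maf_eur Minor allele frequencies (NA means absent).
#' @param maf_rare Rarity cutoff for category 4.
#' @return List with `category` (1-4), `ancestry_specific` flag, `which_ancestry`
#'   and the supporting OR CIs.
#' @export
classify_locus <- function(eas, eur, cq_p, cq_fdr_p, maf_eas, maf_eur,
                           maf_rare = 0.01) {
  if (missing(maf_eas) || missing(maf_eur)) stop("MAF required in both ancestries")
  absent <- function(maf) is.na(maf) | maf < maf_rare
  ci_eas <- or_ci(eas$BETA, eas$SE); ci_eur <- or_ci(eur$BETA, eur$SE)
  if (xor(absent(maf_eas), absent(maf_eur))) {
    return(list(category = 4L, ancestry_specific = FALSE,
                which_ancestry = if (absent(maf_eas)) "EUR" else "EAS",
                or_ci_eas = ci_eas, or_ci_eur = ci_eur))
  }
  category <- if (cq_fdr_p < 0.05) 3L else if (cq_p < 0.05) 2L else 1L
  specific <- FALSE; which_anc <- NA_character_
  if (category == 3L) {
    no_overlap <- ci_eas[2] < ci_eur[1] || ci_eur[2] < ci_eas[1]
    if (eas$P < 5e-8 && eur$P > 0.01 && no_overlap) {
      specific <- TRUE; which_anc <- "EAS"
    } else if (eur$P < 5e-8 && eas$P > 0.01 && no_overlap) {
      specific <- TRUE; which_anc <- "EUR"
    }
  }
  list(category = category, ancestry_specific = specific,
       which_ancestry = which_anc, or_ci_eas = ci_eas, or_ci_eur = ci_eur)
}
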