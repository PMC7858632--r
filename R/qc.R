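# Per-cohort quality control: Hardy-Weinberg exact test, variant and sample
# filters, method-of-moments relatedness (PI_HAT), inbreeding coefficient,
# genotype PCA for ancestry/batch covariates.

#' Default QC thresholds
#'
#' Variant call rate >= 0.90, MAF >= 0.005, Hardy-Weinberg exact P >= 1e-4
#' (assessed in controls), per-sample missingness <= 0.05, pairwise PI_HAT
#' <= 0.125 and |inbreeding F| <= 0.05.
#'
#' @param variant_call_rate_min,maf_min,hwe_p_min,sample_missing_max,ibd_pi_hat_max,inbreeding_abs_max
#'   Filter thresholds.
#' @param hwe_in_controls_only Logical; restrict the Hardy-Weinberg test to
#'   controls (the GWAS convention).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.90, maf_min = 0.005,
                          hwe_p_min = 1e-4, sample_missing_max = 0.05,
                          ibd_pi_hat_max = 0.125, inbreeding_abs_max = 0.05,
                          hwe_in_controls_only = TRUE) {
  stopifnot(variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1,
            ibd_pi_hat_max >= 0, ibd_pi_hat_max <= 1, inbreeding_abs_max >= 0)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact two-sided P by enumerating every heterozygote count compatible with
#' the observed allele-count margins and summing the probabilities of
#' configurations no more likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Two-sided exact P-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes")
  n_alt <- 2 * n_hom_alt + n_het
  n_rare <- min(n_alt, 2 * n - n_alt)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # P(het = h | margins) via log factorials, normalized over the support
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - hom_r - h
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, 0)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with margins")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

genotype_counts <- function(g) {
  c(hom_ref = sum(g == 0, na.rm = TRUE), het = sum(g == 1, na.rm = TRUE),
    hom_alt = sum(g == 2, na.rm = TRUE))
}

#' Variant-level quality control
#'
#' Removes variants failing call rate, minor-allele-frequency, or
#' Hardy-Weinberg filters. All filters are evaluated on the input data (not
#' sequentially re-estimated), so the operation is idempotent.
#'
#' @param cohort A [genotype_cohort()]; genotypes may contain NA.
#' @param thresholds A [qc_thresholds()].
#' @return List with the filtered `cohort` and a `report` of per-filter
#'   removal counts.
#' @export
variant_qc <- function(cohort, thresholds = qc_thresholds()) {
  g <- cohort$genotypes
  if (ncol(g) == 0 || nrow(g) == 0) stop("empty cohort")
  call_rate <- colMeans(!is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  g_hwe <- if (thresholds$hwe_in_controls_only)
    g[cohort$phenotypes == 0L, , drop = FALSE] else g
  hwe_p <- vapply(seq_len(ncol(g_hwe)), function(j) {
    cnt <- genotype_counts(g_hwe[, j])
    if (sum(cnt) == 0) return(1)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, 0)
  fail_call <- call_rate < thresholds$variant_call_rate_min
  fail_maf <- maf < thresholds$maf_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  keep <- !(fail_call | fail_maf | fail_hwe)
  out <- cohort
  out$genotypes <- g[, keep, drop = FALSE]
  out$variants <- cohort$variants[keep, , drop = FALSE]
  if (!is.null(out$truth)) {
    out$truth$beta <- out$truth$beta[keep]
    out$truth$category <- out$truth$category[keep]
    out$truth$panel_derived_freq <- out$truth$panel_derived_freq[keep]
  }
  list(cohort = out,
       report = list(n_input = ncol(g), n_removed = sum(!keep),
                     fail_call_rate = sum(fail_call), fail_maf = sum(fail_maf),
                     fail_hwe = sum(fail_hwe)))
}

#' Pairwise method-of-moments relatedness (PI_HAT)
#'
#' Estimates P(IBD = 1) and P(IBD = 2) per sample pair from identity-by-state
#' counts and sample allele frequencies (the PLINK method-of-moments
#' construction) and returns PI_HAT = P(IBD=2) + P(IBD=1)/2, truncated to
#' `[0, 1]`.
#'
#' @param cohort A [genotype_cohort()] or genotype matrix.
#' @param freqs Optional allele frequencies; estimated from the data if NULL.
#' @return Symmetric N x N PI_HAT matrix (diagonal NA).
#' @export
ibd_pi_hat <- function(cohort, freqs = NULL) {
  g <- if (inherits(cohort, "genotype_cohort")) cohort$genotypes else as.matrix(cohort)
  if (nrow(g) < 2) stop("need at least two samples")
  if (is.null(freqs)) freqs <- colMeans(g, na.rm = TRUE) / 2
  poly <- freqs > 0 & freqs < 1
  if (!any(poly)) stop("no polymorphic variants: PI_HAT is uninformative")
  g <- g[, poly, drop = FALSE]; p <- freqs[poly]; q <- 1 - p
  # expected IBS class probabilities given IBD state, summed over variants
  e0_0 <- sum(2 * p^2 * q^2)
  e1_0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- ncol(g)
  # pairwise IBS class counts via indicator-matrix products (missing -> 0)
  valid <- (!is.na(g)) * 1
  a0 <- (!is.na(g) & g == 0L) * 1
  a1 <- (!is.na(g) & g == 1L) * 1
  a2 <- (!is.na(g) & g == 2L) * 1
  n_valid <- tcrossprod(valid)
  ibs0 <- tcrossprod(a0, a2) + tcrossprod(a2, a0)
  ibs2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  ibs1 <- n_valid - ibs0 - ibs2
  scale <- n_valid / m  # rescale expectations for missingness
  p0 <- ibs0 / (e0_0 * scale)
  p1 <- (ibs1 - p0 * e1_0 * scale) / (e1_1 * scale)
  p2 <- (ibs2 - p0 * e2_0 * scale - p1 * e2_1 * scale) / n_valid
  out <- p2 + 0.5 * p1
  out[] <- pmin(1, pmax(0, out))
  diag(out) <- NA_real_
  dimnames(out) <- list(rownames(g), rownames(g))
  out
}

#' Per-sample inbreeding coefficient
#'
#' F = 1 - observed heterozygote count / expected heterozygote count, with the
#' expectation `sum(2 p (1 - p))` over the sample's non-missing variants.
#'
#' @param genotypes Dosage vector (one sample) or matrix (samples in rows).
#' @param freqs Allele frequencies per variant.
#' @return Numeric F (vector for a matrix input).
#' @export
inbreeding_coefficient <- function(genotypes, freqs) {
  g <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1)
  stopifnot(ncol(g) == length(freqs))
  f <- vapply(seq_len(nrow(g)), function(i) {
    ok <- !is.na(g[i, ]) & freqs > 0 & freqs < 1
    e_het <- sum(2 * freqs[ok] * (1 - freqs[ok]))
    if (e_het == 0) stop("expected heterozygosity is zero")
    1 - sum(g[i, ok] == 1) / e_het
  }, 0)
  if (is.matrix(genotypes)) f else f[1]
}

#' Sample-level quality control
#'
#' Applies, in order: per-sample missingness, relatedness (one member of each
#' pair with PI_HAT above the cap is dropped -- the member with higher
#' missingness, ties broken towards the later sample id), and |F| inbreeding
#' bounds.
#'
#' @param cohort A [genotype_cohort()].
#' @param thresholds A [qc_thresholds()].
#' @return List with the filtered `cohort` and a removal `report`.
#' @export
sample_qc <- function(cohort, thresholds = qc_thresholds()) {
  g <- cohort$genotypes
  miss <- rowMeans(is.na(g))
  drop_miss <- miss > thresholds$sample_missing_max
  keep <- which(!drop_miss)
  drop_rel <- character(0)
  if (length(keep) >= 2) {
    sub <- g[keep, , drop = FALSE]
    ph <- ibd_pi_hat(sub)
    repeat {
      over <- which(ph > thresholds$ibd_pi_hat_max, arr.ind = TRUE)
      over <- over[over[, 1] < over[, 2], , drop = FALSE]
      if (nrow(over) == 0) break
      i <- over[1, 1]; j <- over[1, 2]
      mi <- miss[keep][i]; mj <- miss[keep][j]
      victim <- if (mi > mj) i else if (mj > mi) j else max(i, j)
      drop_rel <- c(drop_rel, rownames(sub)[victim])
      ph <- ph[-victim, -victim, drop = FALSE]
      keep <- keep[-victim]
      sub <- g[keep, , drop = FALSE]
      if (length(keep) < 2) break
    }
  }
  n_rel <- length(drop_rel)
  freqs <- colMeans(g[keep, , drop = FALSE], na.rm = TRUE) / 2
  fcoef <- inbreeding_coefficient(g[keep, , drop = FALSE], freqs)
  drop_f <- abs(fcoef) > thresholds$inbreeding_abs_max
  keep <- keep[!drop_f]
  if (length(keep) == 0) stop("all samples removed by QC")
  out <- cohort
  out$genotypes <- g[keep, , drop = FALSE]
  out$phenotypes <- cohort$phenotypes[keep]
  out$covariates <- cohort$covariates[keep, , drop = FALSE]
  list(cohort = out,
       report = list(n_input = nrow(g), fail_missing = sum(drop_miss),
                     fail_relatedness = n_rel, fail_inbreeding = sum(drop_f),
                     n_kept = length(keep)))
}

#' Genotype principal components
#'
#' Variants are standardized as `(g - 2p) / sqrt(2p(1-p))` (missing genotypes
#' mean-imputed), and the top `k` components extracted by singular value
#' decomposition. Each component's sign is fixed so that its
#' largest-magnitude variant loading is positive.
#'
#' @param cohort A [genotype_cohort()] or genotype matrix.
#' @param k Number of components.
#' @return List with `scores` (N x k), `loadings`, `sdev` and `var_explained`.
#' @export
genotype_pca <- function(cohort, k = 4L) {
  g <- if (inherits(cohort, "genotype_cohort")) cohort$genotypes else as.matrix(cohort)
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  if (nrow(g) < k + 1) stop("need at least k + 1 samples")
  z <- sweep(g, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  sv <- svd(z, nu = k, nv = k)
  if (k > sum(sv$d > 1e-8)) stop("k exceeds the rank of the genotype matrix")
  flip <- vapply(seq_len(k), function(i) {
    l <- sv$v[, i]; sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
                  2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(g)
  list(scores = scores, loadings = loadings, sdev = sv$d[seq_len(k)] / sqrt(nrow(g) - 1),
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}
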