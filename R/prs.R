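# Clumping + thresholding polygenic risk scores, standardized scoring, AUC
# with DeLong confidence interval and Youden cutoff, and decile odds ratios.

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-P unclaimed variant and removes every
#' variant within `window_bp` whose squared dosage correlation with it is at
#' least `r2_max`. P ties break by position, then allele order.
#'
#' @param assoc `assoc_table` rows (needs SNP, BP, P, A1).
#' @param cohort A [genotype_cohort()] supplying the LD reference genotypes.
#' @param r2_max Clump r-squared threshold (default 0.1).
#' @param window_bp Clump window (default 500 kb).
#' @return Character vector of retained (index) variant ids.
#' @export
ld_clump <- function(assoc, cohort, r2_max = 0.1, window_bp = 5e5) {
  common <- intersect(assoc$SNP, cohort$variants$id)
  if (length(common) == 0) stop("no overlap between association and genotype variants")
  a <- assoc[match(common, assoc$SNP), ]
  g <- cohort$genotypes[, match(common, cohort$variants$id), drop = FALSE]
  ord <- order(a$P, a$BP, a$A1)
  claimed <- rep(FALSE, nrow(a))
  kept <- character(0)
  for (i in ord) {
    if (claimed[i]) next
    kept <- c(kept, a$SNP[i])
    claimed[i] <- TRUE
    near <- which(!claimed & abs(a$BP - a$BP[i]) <= window_bp)
    if (length(near)) {
      r2 <- suppressWarnings(stats::cor(g[, i], g[, near]))^2
      claimed[near[!is.na(r2) & r2 >= r2_max]] <- TRUE
    }
  }
  kept
}

#' Build a clumping + thresholding PRS model
#'
#' For each P threshold in the grid, the model weights are the training betas
#' of the clumped variants passing the threshold; the threshold maximizing
#' AUC in the tuning cohort is selected.
#'
#' @param assoc Training `assoc_table` (summary statistics).
#' @param clumped Variant ids retained by [ld_clump()].
#' @param tune_cohort A [genotype_cohort()] disjoint from the training data.
#' @param p_grid P-value threshold grid.
#' @return A `prs_model` list: data frame of `snp`, `effect_allele`, `weight`,
#'   plus the chosen threshold and the per-threshold tuning AUCs.
#' @export
build_prs_model <- function(assoc, clumped, tune_cohort,
                            p_grid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                       0.1, 0.5, 1)) {
  if (length(p_grid) == 0) stop("empty threshold grid")
  a <- assoc[assoc$SNP %in% clumped & is.finite(assoc$P), ]
  aucs <- rep(NA_real_, length(p_grid))
  for (i in seq_along(p_grid)) {
    sel <- a[a$P <= p_grid[i], ]
    if (nrow(sel) == 0) next
    model_i <- list(weights = data.frame(snp = sel$SNP, effect_allele = sel$A1,
                                         weight = sel$BETA))
    sc <- tryCatch(score_samples(model_i, tune_cohort), error = function(e) NULL)
    if (is.null(sc)) next
    aucs[i] <- evaluate_auc(sc, tune_cohort$phenotypes)$auc
  }
  if (all(is.na(aucs))) stop("no variant passes any threshold")
  best <- which.max(aucs)  # first maximum -> most stringent threshold on ties
  sel <- a[a$P <= p_grid[best], ]
  structure(list(weights = data.frame(snp = sel$SNP, effect_allele = sel$A1,
                                      weight = sel$BETA),
                 p_threshold = p_grid[best], tuning_auc = aucs,
                 p_grid = p_grid),
            class = "prs_model")
}

#' Score a cohort with a PRS model
#'
#' Raw score is the weighted sum of effect-allele dosages; model variants
#' missing from the cohort are skipped (count recorded). Scores are
#' standardized to mean 0, sd 1 over the scored cohort, cases and controls
#' combined. The result is invariant to strand-consistent allele
#' re-encoding: when the model's effect allele is the cohort's ancestral
#' allele the dosage is flipped to `2 - g`.
#'
#' @param model A `prs_model` (or list with a `weights` data frame).
#' @param cohort A [genotype_cohort()].
#' @return Standardized score vector with attribute `n_missing`.
#' @export
score_samples <- function(model, cohort) {
  w <- model$weights
  idx <- match(w$snp, cohort$variants$id)
  present <- !is.na(idx)
  if (!any(present)) stop("no model variants present in the cohort")
  if (nrow(cohort$genotypes) < 2) stop("need at least two samples")
  g <- cohort$genotypes[, idx[present], drop = FALSE]
  eff <- w$effect_allele[present]
  flip <- eff == cohort$variants$ancestral[idx[present]]
  g[, flip] <- 2L - g[, flip]
  raw <- as.numeric(g %*% w$weight[present])
  if (stats::sd(raw) == 0) stop("zero score variance")
  out <- (raw - mean(raw)) / stats::sd(raw)
  attr(out, "n_missing") <- sum(!present)
  out
}

#' AUC, DeLong confidence interval, and the Youden-optimal cutoff
#'
#' AUC via the Mann-Whitney relation with tie correction, its 95% CI by
#' DeLong's method, and the cutoff maximizing sensitivity + specificity
#' (ties resolved to the lower cutoff), all through the pROC package.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 case labels.
#' @return List with `auc`, `ci` (length 2), `cutoff`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  if (nrow(best) > 1) best <- best[which.min(best$threshold), ]
  list(auc = as.numeric(pROC::auc(r)), ci = ci[c(1, 3)],
       cutoff = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity)
}

#' Decile odds ratios relative to the lowest-score decile
#'
#' Samples are ranked by score and cut into ten equal groups (remainders go
#' to the lower deciles). Each decile's odds ratio against decile 1 carries a
#' Woolf (log-scale Wald) 95% CI; zero cells get the Haldane-Anscombe 0.5
#' correction and are flagged.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 case labels.
#' @return Data frame with per-decile case/control counts, `or`, `ci_lo`,
#'   `ci_hi` and the `corrected` flag (decile 1 row has OR 1 by definition).
#' @export
decile_odds_ratios <- function(scores, labels) {
  n <- length(scores)
  stopifnot(length(labels) == n, sum(labels == 1) >= 10, sum(labels == 0) >= 10)
  ord <- order(scores, seq_len(n))
  base <- n %/% 10; rem <- n %% 10
  sizes <- rep(base, 10) + c(rep(1, rem), rep(0, 10 - rem))
  decile <- rep(seq_len(10), times = sizes)[order(ord)]
  tab <- t(vapply(seq_len(10), function(d)
    c(case = sum(labels[decile == d] == 1),
      control = sum(labels[decile == d] == 0)), c(case = 0, control = 0)))
  if (tab[1, "case"] == 0 && tab[1, "control"] == 0)
    stop("decile 1 is empty")
  out <- data.frame(decile = seq_len(10), n_case = tab[, "case"],
                    n_control = tab[, "control"], or = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, corrected = FALSE)
  out$or[1] <- 1
  for (d in 2:10) {
    cells <- c(tab[d, "case"], tab[d, "control"], tab[1, "case"],
               tab[1, "control"])
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
    se <- sqrt(sum(1 / cells))
    out$or[d] <- exp(lor)
    out$ci_lo[d] <- exp(lor - 1.96 * se)
    out$ci_hi[d] <- exp(lor + 1.96 * se)
    out$corrected[d] <- corrected
  }
  out
}
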