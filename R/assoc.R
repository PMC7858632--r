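# Additive logistic association with covariates, Wald statistics and the
# genomic inflation factor.

CHISQ1_MEDIAN <- 0.4549364231  # median of the 1-df chi-square, fixed to 10 digits

new_assoc_table <- function(df) {
  class(df) <- c("assoc_table", "data.frame")
  df
}

# IRLS logistic fit on a prebuilt design matrix; returns beta/se for the last
# column plus convergence/separation flags.
logistic_fit_last <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  w <- fit$weights
  xtwx <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  beta <- fit$coefficients[ncol(X)]
  converged <- isTRUE(fit$converged) && !is.null(cov) && is.finite(beta) &&
    abs(beta) < 15
  se <- if (is.null(cov)) NA_real_ else sqrt(cov[ncol(X), ncol(X)])
  if (!is.null(se) && is.finite(se) && se > 100) converged <- FALSE
  list(beta = beta, se = se, converged = converged)
}

#' Per-variant additive logistic association
#'
#' Fits, for each variant, a maximum-likelihood logistic regression
#' (iteratively reweighted least squares) of case status on derived-allele
#' dosage plus covariates, reporting the Wald z and two-sided P. Missing
#' genotypes are handled complete-case per variant. Non-convergence or
#' separation is flagged per variant instead of failing the run.
#'
#' @param cohort A [genotype_cohort()].
#' @param covariates Data frame of covariates (default: the cohort's own);
#'   factors are expanded to dummies. Use `NULL` for none.
#' @param variants Optional variant-id subset.
#' @return An `assoc_table` data frame with the fixed column set SNP, CHR, BP,
#'   A1 (effect = derived allele), A2, EAF, BETA, SE, Z, P, N plus a
#'   `converged` flag.
#' @export
logistic_assoc <- function(cohort, covariates = cohort$covariates,
                           variants = NULL) {
  y <- cohort$phenotypes
  if (!all(y %in% c(0L, 1L))) stop("phenotype must be binary 0/1")
  g <- cohort$genotypes
  idx <- if (is.null(variants)) seq_len(ncol(g))
         else match(variants, cohort$variants$id)
  if (anyNA(idx)) stop("unknown variant id requested")
  X0 <- matrix(1, nrow(g), 1)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (any(apply(mm[, -1, drop = FALSE], 2, stats::sd) == 0))
      stop("constant covariate supplied")
    X0 <- mm
  }
  res <- lapply(idx, function(j) {
    d <- g[, j]
    ok <- !is.na(d)
    fit <- logistic_fit_last(cbind(X0[ok, , drop = FALSE], d[ok]), y[ok])
    eaf <- mean(d[ok]) / 2
    if (stats::var(d[ok]) == 0)
      fit <- list(beta = NA_real_, se = NA_real_, converged = FALSE)
    data.frame(SNP = cohort$variants$id[j], CHR = cohort$variants$chrom[j],
               BP = cohort$variants$pos[j], A1 = cohort$variants$derived[j],
               A2 = cohort$variants$ancestral[j], EAF = eaf,
               BETA = if (fit$converged) unname(fit$beta) else NA_real_,
               SE = if (fit$converged) unname(fit$se) else NA_real_,
               N = sum(ok), converged = fit$converged)
  })
  out <- do.call(rbind, res)
  out$Z <- out$BETA / out$SE
  out$P <- 2 * stats::pnorm(-abs(out$Z))
  new_assoc_table(out[, c(assoc_columns, "converged")])
}

#' Genomic inflation factor
#'
#' `lambda_GC` = median observed association chi-square (z squared) divided by
#' the 1-df chi-square median 0.4549364231.
#'
#' @param assoc An `assoc_table`, or a numeric vector of z statistics.
#' @return Numeric inflation factor.
#' @export
lambda_gc <- function(assoc) {
  z <- if (is.data.frame(assoc)) assoc$Z else assoc
  z <- z[is.finite(z)]
  if (length(z) == 0) stop("no finite association statistics")
  stats::median(z^2) / CHISQ1_MEDIAN
}
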