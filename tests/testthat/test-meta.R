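test_that("fixed-effect meta matches closed forms and shrinks se by sqrt(n)", {
  m1 <- fixed_effect_meta(0.1, 0.1)
  expect_equal(m1$beta, 0.1)
  expect_equal(m1$se, 0.1)
  m2 <- fixed_effect_meta(c(0.1, 0.1), c(0.1, 0.1))
  expect_equal(m2$beta, 0.1)
  expect_equal(m2$se, 0.1 / sqrt(2))
  m3 <- fixed_effect_meta(c(0.2, 0.0), c(0.1, 0.1))
  expect_equal(m3$beta, 0.1)
  expect_equal(m3$se, 0.1 / sqrt(2))
  m9 <- fixed_effect_meta(rep(0.2, 9), rep(0.3, 9))
  expect_equal(m9$se, 0.3 / 3)
  expect_error(fixed_effect_meta(0.1, 0))
})

test_that("fixed-effect meta agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(21)
  b <- rnorm(5, 0.1, 0.05); s <- runif(5, 0.02, 0.2)
  m <- fixed_effect_meta(b, s)
  rm <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$beta, as.numeric(rm$beta), tolerance = 1e-9)
  expect_equal(m$se, rm$se, tolerance = 1e-9)
  q <- cochran_q(b, s)
  expect_equal(q$Q, rm$QE, tolerance = 1e-9)
  expect_equal(q$p, rm$QEp, tolerance = 1e-9)
})

test_that("Cochran's Q matches closed forms and is order-invariant", {
  q0 <- cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.05, 0.2))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)
  q <- cochran_q(c(0.1, -0.1), c(0.05, 0.05))
  expect_equal(q$Q, 8)
  expect_equal(q$p, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(q$p, 0.00468, tolerance = 1e-3)
  set.seed(22)
  b <- rnorm(4); s <- runif(4, 0.1, 0.3)
  perm <- c(3, 1, 4, 2)
  expect_equal(cochran_q(b, s)$Q, cochran_q(b[perm], s[perm])$Q)
  expect_error(cochran_q(0.1, 0.1), "two studies")
})

test_that("published-style (OR, P) inputs reproduce the lead-variant Q tests", {
  # EAS OR 0.97 / P 0.332 vs EUR OR 1.21 / P 1.10e-8, se recovered from the
  # printed pairs: heterogeneity P lands on the 1e-6 order of magnitude
  b <- c(log(0.97), log(1.21))
  s <- c(se_from_or_p(0.97, 3.32e-1), se_from_or_p(1.21, 1.10e-8))
  q <- cochran_q(b, s)
  expect_gt(q$p, 1e-7)
  expect_lt(q$p, 1e-5)
  # a homogeneous lead variant: OR 0.84/0.82, both ancestries concordant
  b2 <- c(log(0.84), log(0.82))
  s2 <- c(se_from_or_p(0.84, 4.12e-6), se_from_or_p(0.82, 1.38e-4))
  expect_gt(cochran_q(b2, s2)$p, 0.05)
})

test_that("BH adjustment follows the step-up rule and bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(23)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_identical(adj, p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("allele alignment flips, rejects and flags ambiguity correctly", {
  expect_equal(align_alleles("A", "G", "A", "G"), "same")
  expect_equal(align_alleles("A", "G", "G", "A"), "flip")
  expect_equal(align_alleles("A", "G", "T", "C"), "same")   # strand complement
  expect_equal(align_alleles("A", "G", "C", "T"), "flip")
  expect_equal(align_alleles("A", "T", "T", "A"), "flip")   # direct match wins
  expect_equal(align_alleles("A", "T", "A", "G"), "ambiguous")
  expect_equal(align_alleles("A", "G", "A", "C"), "mismatch")
})

test_that("locus classification applies the category rules in order", {
  mk <- function(beta, se, p) list(BETA = beta, SE = se, P = p)
  # homogeneous lead variant -> category 1
  c1 <- classify_locus(mk(log(0.84), 0.04, 2e-6), mk(log(0.84), 0.05, 1e-4),
                       cq_p = 0.648, cq_fdr_p = 0.9, maf_eas = 0.3,
                       maf_eur = 0.3)
  expect_equal(c1$category, 1L)
  # raw-significant only -> category 2
  c2 <- classify_locus(mk(0.2, 0.04, 1e-7), mk(0.05, 0.04, 0.2),
                       cq_p = 0.02, cq_fdr_p = 0.12, maf_eas = 0.3,
                       maf_eur = 0.3)
  expect_equal(c2$category, 2L)
  # FDR-significant, EAS-specific with non-overlapping CIs
  b_eas <- log(1.30); se_eas <- (log(1.40) - log(1.20)) / (2 * 1.96)
  b_eur <- log(1.00); se_eur <- (log(1.05) - log(0.95)) / (2 * 1.96)
  c3 <- classify_locus(mk(b_eas, se_eas, 1e-10), mk(b_eur, se_eur, 0.5),
                       cq_p = 0.001, cq_fdr_p = 0.01, maf_eas = 0.3,
                       maf_eur = 0.3)
  expect_equal(c3$category, 3L)
  expect_true(c3$ancestry_specific)
  expect_equal(c3$which_ancestry, "EAS")
  # rare in one ancestry wins over everything
  c4 <- classify_locus(mk(0.3, 0.05, 1e-10), mk(0.3, 0.05, 1e-10),
                       cq_p = 1e-6, cq_fdr_p = 1e-5, maf_eas = 0.3,
                       maf_eur = 0.002)
  expect_equal(c4$category, 4L)
  expect_equal(c4$which_ancestry, "EAS")
  expect_error(classify_locus(mk(0.1, 0.1, 0.1), mk(0.1, 0.1, 0.1), 0.5, 0.5),
               "MAF")
})

test_that("shared-effect loci are mislabelled heterogeneous at most at the FDR rate", {
  # simulate 200 shared-effect lead variants across two ancestries, classify,
  # and check the category-3 false-label rate
  set.seed(24)
  n_loci <- 200
  beta_true <- rnorm(n_loci, 0.15, 0.05)
  se1 <- runif(n_loci, 0.03, 0.06); se2 <- runif(n_loci, 0.03, 0.06)
  b1 <- rnorm(n_loci, beta_true, se1); b2 <- rnorm(n_loci, beta_true, se2)
  cq <- vapply(seq_len(n_loci), function(i)
    cochran_q(c(b1[i], b2[i]), c(se1[i], se2[i]))$p, 0)
  fdr <- bh_adjust(cq)
  cats <- vapply(seq_len(n_loci), function(i)
    classify_locus(list(BETA = b1[i], SE = se1[i], P = 1e-9),
                   list(BETA = b2[i], SE = se2[i], P = 1e-9),
                   cq[i], fdr[i], 0.3, 0.3)$category, 0L)
  expect_lte(mean(cats == 3L), 0.05 + 3 * sqrt(0.05 * 0.95 / n_loci))
})
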