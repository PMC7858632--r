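make_panel <- function(hap, positions = NULL) {
  m <- ncol(hap)
  if (is.null(positions)) positions <- seq_len(m) * 1000
  alleles <- data.frame(ancestral = rep("A", m), derived = rep("C", m))
  haplotype_panel(hap, positions, alleles, "EAS")
}

test_that("Fst matches the hand-evaluated heterozygosity formulas", {
  expect_equal(fst(0.3, 0.3, 50, 50)$fst, 0)
  fix <- fst(0, 1, 50, 50)
  expect_equal(fix$p_bar, 0.5)
  expect_equal(fix$ht, 0.5)
  expect_equal(fix$hs, 0)
  expect_equal(fix$fst, 1)
  hand <- fst(0.1, 0.4, 100, 100)
  expect_equal(hand$ht, 0.375)
  expect_equal(hand$hs, 0.33)
  expect_equal(hand$fst, 0.12)
  mono <- fst(0, 0, 10, 10)
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$fst))
})

test_that("Fst is symmetric in populations and allele labels", {
  set.seed(51)
  p1 <- runif(20); p2 <- runif(20)
  expect_equal(fst(p1, p2, 120, 80)$fst, fst(p2, p1, 80, 120)$fst)
  expect_equal(fst(p1, p2, 120, 80)$fst, fst(1 - p1, 1 - p2, 120, 80)$fst)
})

test_that("EHH equals direct pair counting and is monotone", {
  # 4 derived carriers splitting 2/2 at the first flanking variant
  hap <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 1), c(1, 0, 0),
               c(0, 0, 0), c(0, 1, 1))
  pan <- make_panel(hap)
  cur <- ehh_curve(pan, core = 1, allele = "derived", stop_ehh = 0)
  expect_equal(cur$ehh[cur$positions == cur$core_pos], 1)
  expect_equal(cur$ehh[cur$positions == 2000], 2 / 6, tolerance = 1e-12)
  # identical carriers: EHH stays 1
  same <- make_panel(rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 1), c(0, 1, 0)))
  expect_true(all(ehh_curve(same, 1, "derived", 0)$ehh == 1))
  single <- make_panel(rbind(c(1, 1), c(0, 0)))
  expect_error(ehh_curve(single, 1, "derived"), "carrier")
  # monotone non-increasing outward on random panels
  set.seed(52)
  for (r in 1:5) {
    hp <- matrix(rbinom(16 * 15, 1, 0.5), 16, 15)
    hp[, 8] <- rep(c(0, 1), each = 8)
    pp <- make_panel(hp)
    cc <- ehh_curve(pp, 8, "derived", 0)
    core_at <- which(cc$positions == cc$core_pos)
    expect_true(all(diff(cc$ehh[core_at:length(cc$ehh)]) <= 1e-12))
    expect_true(all(diff(rev(cc$ehh[1:core_at])) <= 1e-12))
  }
})

test_that("raw iHS equals brute-force pair enumeration on small panels", {
  set.seed(53)
  for (r in 1:5) {
    hap <- matrix(rbinom(18 * 21, 1, 0.5), 18, 21)
    hap[, 11] <- rep(c(0L, 1L), c(9, 9))
    pan <- make_panel(hap, positions = cumsum(sample(500:2000, 21)))
    got <- ihs_raw(pan, 11)
    expect_true(got$defined)
    expect_equal(got$ihs_raw, oracle_ihs_raw(pan, 11), tolerance = 1e-10)
  }
})

test_that("symmetric haplotype structure gives raw iHS of zero", {
  half <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
  hap <- cbind(rbind(half, half), rep(c(0L, 1L), each = 8))
  hap <- hap[, c(1:5, 11, 6:10)]
  pan <- make_panel(hap)
  r <- ihs_raw(pan, 6)
  expect_equal(r$ihh_a, r$ihh_d, tolerance = 1e-12)
  expect_equal(r$ihs_raw, 0, tolerance = 1e-12)
})

test_that("imposed sweeps drive the core standardized iHS negative", {
  # strong-sweep settings: swept haplotype (40 kb) short relative to the
  # ~300 kb contig, so the core competes against an honest genome background;
  # bins coarsened to 10 for a 150-variant scan (50 near-empty bins would
  # leave 2-3 scores per bin and cap the standardized value by construction)
  hits <- 0
  for (r in 1:8) {
    cfg <- sim_config(n_variants = 300, n_blocks = 3, block_recomb = 0.05,
                      founder_haplotypes = 100, n_haplotypes = 120,
                      seed = 600 + r)
    panels <- simulate_two_pop_haplotypes(cfg)
    core <- 150
    swept <- impose_sweep(panels$EAS,
                          sweep_spec(core, "EAS", 0.75, 4e4,
                                     mutation_noise = 0.002),
                          seed = 700 + r)
    cores <- sort(unique(c(seq(5, 295, by = 2), core)))
    scan <- ihs_standardize(ihs_scan(swept, cores = cores), n_bins = 10,
                            drop_edge_truncated = FALSE)
    expect_lt(scan$ihs_raw[scan$core == core], 0)  # derived haplotypes longer
    std <- scan$ihs_std[scan$core == core]
    thresh <- quantile(scan$ihs_std, 0.05, na.rm = TRUE)
    if (is.finite(std) && std <= thresh) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * 8)
})

test_that("standardized iHS has mean 0, sd 1 per occupied bin, ranks preserved", {
  set.seed(54)
  scan <- data.frame(variant = paste0("v", 1:300), core = 1:300,
                     ihh_a = 1, ihh_d = 1,
                     ihs_raw = rnorm(300, 0.2, 0.8),
                     derived_freq = runif(300),
                     edge_truncated = FALSE, defined = TRUE)
  std <- ihs_standardize(scan)
  for (b in unique(std$bin)) {
    v <- std$ihs_std[std$bin == b & !is.na(std$ihs_std)]
    if (length(v) >= 2) {
      expect_equal(mean(v), 0, tolerance = 1e-9)
      expect_equal(sd(v), 1, tolerance = 1e-9)
      raw <- std$ihs_raw[std$bin == b & !is.na(std$ihs_std)]
      expect_equal(order(v), order(raw))
    }
  }
  expect_equal(transgwas:::ihs_bin_index(1.0), 50L)  # last bin right-closed
  expect_equal(transgwas:::ihs_bin_index(0), 1L)
})

test_that("empirical Fst P-values follow the add-one counting rule", {
  bg <- c(0.01, 0.02, 0.05, 0.08, 0.03, 0.15, 0.04, 0.06, 0.07, 0.09)
  expect_equal(fst_empirical_pvalue(0.005, bg), 1)          # below the minimum
  expect_equal(fst_empirical_pvalue(0.2, bg), 1 / 11)       # above the maximum
  expect_equal(fst_empirical_pvalue(0.055, bg), (1 + 5) / 11)  # hand count
  expect_error(fst_empirical_pvalue(0.1, numeric(0)), "empty")
})

test_that("cross-ancestry iHS correlation is computed per category", {
  set.seed(55)
  x <- rnorm(60)
  r1 <- ihs_category_correlation(x, x, rep(1, 60))
  expect_equal(r1$r, 1)
  y1 <- rnorm(200); y2 <- rnorm(200)
  r0 <- ihs_category_correlation(y1, y2, rep(1, 200))
  expect_lt(abs(r0$r), 3 / sqrt(200))
  shared <- rnorm(80)
  rsh <- ihs_category_correlation(shared + rnorm(80, 0, 0.5),
                                  shared + rnorm(80, 0, 0.5), rep("c1", 80))
  expect_lt(rsh$p, 0.05)
  expect_gt(rsh$r, 0)
  expect_error(ihs_category_correlation(x[1:2], x[1:2], c(1, 1)), "fewer than 3")
})
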