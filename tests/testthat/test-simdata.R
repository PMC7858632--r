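test_that("sim_config rejects out-of-range fields", {
  expect_error(sim_config(block_recomb = 1.2), "probability")
  expect_error(sim_config(block_recomb = NaN), "probability")
  expect_error(sim_config(n_variants = 5, n_blocks = 10))
  expect_error(sim_config(drift = c(EAS = 0.05, EUR = 1.0)), "drift")
  expect_error(sim_config(prevalence_by_pop = c(EAS = 0, EUR = 1e-3)),
               "prevalence")
  expect_error(sim_config(prevalence_by_pop = c(EAS = 0.6, EUR = 1e-3)),
               "prevalence")
})

test_that("effect category truth derives from the beta map and re-applies", {
  expect_equal(causal_effect(1, c(EAS = 0.3, EUR = 0.3))$category_truth, "shared")
  expect_equal(causal_effect(1, c(EAS = 0.3, EUR = 0))$category_truth, "specific")
  expect_equal(causal_effect(1, c(EAS = 0.3, EUR = 0.1))$category_truth,
               "heterogeneous")
  expect_error(causal_effect(1, c(EAS = 0.3, EUR = 0.1), category = "shared"),
               "inconsistent")
  cfg <- sim_config(n_variants = 60, n_blocks = 6, seed = 3,
                    effect_spec = list(causal_effect(5, c(EAS = 0.3, EUR = 0.3)),
                                       causal_effect(30, c(EAS = 0.4, EUR = 0))))
  panels <- simulate_two_pop_haplotypes(cfg)
  co <- simulate_case_control_cohort(panels$EAS, cfg$effect_spec, 0.01, 50, 50,
                                     seed = 4)
  for (eff in cfg$effect_spec) {
    i <- eff$variant_index
    expect_equal(co$truth$category[i],
                 transgwas:::derive_effect_category(eff$beta_by_pop))
  }
})

test_that("panels are deterministic given the seed and share one variant set", {
  cfg <- sim_config(n_variants = 200, n_blocks = 10, seed = 11)
  p1 <- simulate_two_pop_haplotypes(cfg)
  p2 <- simulate_two_pop_haplotypes(cfg)
  expect_identical(p1, p2)
  expect_identical(p1$EAS$positions, p1$EUR$positions)
  expect_identical(p1$EAS$alleles, p1$EUR$alleles)
  p3 <- simulate_two_pop_haplotypes(sim_config(n_variants = 200, n_blocks = 10,
                                               seed = 12))
  expect_false(identical(p1$EAS$haplotypes, p3$EAS$haplotypes))
})

test_that("zero drift leaves frequency differences centred at zero", {
  cfg <- sim_config(n_variants = 1200, n_blocks = 60,
                    drift = c(EAS = 0, EUR = 0), seed = 21)
  panels <- simulate_two_pop_haplotypes(cfg)
  dif <- panels$EAS$derived_freq - panels$EUR$derived_freq
  expect_lt(abs(mean(dif)), 3 * sd(dif) / sqrt(40))  # block-clustered error
  f <- fst(panels$EAS$derived_freq, panels$EUR$derived_freq, 100, 100)$fst
  expect_lt(mean(f, na.rm = TRUE), 0.02)  # only founder/panel sampling noise
})

test_that("drifted panels recover the frequency-simulation oracle's mean Fst", {
  drift <- 0.05
  cfg <- sim_config(n_variants = 2000, n_blocks = 100,
                    drift = c(EAS = drift, EUR = drift), seed = 31)
  panels <- simulate_two_pop_haplotypes(cfg)
  n2 <- cfg$n_haplotypes / 2
  f <- fst(panels$EAS$derived_freq, panels$EUR$derived_freq, n2, n2)$fst
  # block-clustered standard error of the panel mean (variants within a
  # block are correlated through the founder mosaic)
  blocks <- attr(panels, "blocks")
  bm <- tapply(f, blocks, mean, na.rm = TRUE)
  se_panel <- sd(bm) / sqrt(length(bm))
  o <- expected_fst_oracle(drift, cfg$founder_haplotypes, cfg$n_haplotypes,
                           n_sim = 40000, seed = 32)
  expect_lt(abs(mean(f, na.rm = TRUE) - o$mean_fst),
            3 * sqrt(se_panel^2 + o$se^2))
})

test_that("cohort genotypes conserve sampled-haplotype frequencies exactly", {
  cfg <- sim_config(n_variants = 80, n_blocks = 8, seed = 41)
  panels <- simulate_two_pop_haplotypes(cfg)
  co <- simulate_case_control_cohort(panels$EAS, list(), 0.01, 100, 100,
                                     seed = 42)
  pairs <- co$truth$sampled_haplotypes
  hap_freq <- colMeans(panels$EAS$haplotypes[c(pairs[, 1], pairs[, 2]), ])
  expect_equal(colMeans(co$genotypes) / 2, hap_freq, tolerance = 1e-12)
  expect_true(all(co$genotypes ==
    panels$EAS$haplotypes[pairs[, 1], ] + panels$EAS$haplotypes[pairs[, 2], ]))
  expect_equal(sum(co$phenotypes), 100)
  expect_equal(sum(co$phenotypes == 0), 100)
})

test_that("unascertained sampling matches the prevalence within binomial error", {
  cfg <- sim_config(n_variants = 40, n_blocks = 4, seed = 51)
  panels <- simulate_two_pop_haplotypes(cfg)
  k <- 0.02; n <- 150000
  co <- simulate_case_control_cohort(panels$EAS, list(), k, n_case = NULL,
                                     n_total = n, seed = 52)
  expect_lt(abs(mean(co$phenotypes) - k), 3 * sqrt(k * (1 - k) / n))
})

test_that("cohorts are deterministic and unattainable case counts error", {
  cfg <- sim_config(n_variants = 40, n_blocks = 4, seed = 61)
  panels <- simulate_two_pop_haplotypes(cfg)
  a <- simulate_case_control_cohort(panels$EAS, list(), 0.01, 60, 60, seed = 62)
  b <- simulate_case_control_cohort(panels$EAS, list(), 0.01, 60, 60, seed = 62)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_error(simulate_case_control_cohort(panels$EAS, list(), 1e-4, 5000, 10,
                                            seed = 63, max_draws = 2e4),
               "bottleneck")
})

test_that("imposed sweeps hit the target frequency and degenerate cases hold", {
  cfg <- sim_config(n_variants = 120, n_blocks = 2, block_recomb = 0.02,
                    seed = 71)
  panels <- simulate_two_pop_haplotypes(cfg)
  pan <- panels$EAS
  core <- 60
  cur <- pan$derived_freq[core]
  # same target, zero extension: identity
  sp0 <- sweep_spec(core, "EAS", max(cur, 1 / nrow(pan$haplotypes)), 0)
  same <- impose_sweep(pan, sp0, seed = 72)
  if (cur > 0) expect_identical(same$haplotypes, pan$haplotypes)
  # full fixation
  sp1 <- sweep_spec(core, "EAS", 1.0, 40000)
  fixed <- impose_sweep(pan, sp1, seed = 73)
  expect_equal(fixed$derived_freq[core], 1)
  # target frequency reached
  sp <- sweep_spec(core, "EAS", 0.7, 40000)
  swept <- impose_sweep(pan, sp, seed = 74)
  expect_equal(swept$derived_freq[core], 0.7, tolerance = 1 / nrow(pan$haplotypes))
  expect_error(sweep_spec(core, "EAS", 1.5, 0), "target_derived_frequency")
})
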