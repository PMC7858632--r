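#!/usr/bin/env Rscript
# Stage 1: generate the two-ancestry synthetic study.
#
# Builds haplotype panels for an East-Asian-like and a European-like
# population (Balding-Nichols drift 0.05, founder-mosaic LD), places shared,
# ancestry-specific and heterogeneous causal effects, imposes one recent
# sweep in the EAS panel, and ascertains case-control cohorts at the lifetime
# risks used throughout (1 per 1000 EAS-like, 0.3 per 1000 EUR-like).
# Writes phased VCFs, phenotype TSVs and truth manifests under results/sim/.

suppressPackageStartupMessages(library(transgwas))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

effects <- list(
  causal_effect(100, c(EAS = 0.25, EUR = 0.25)),   # shared
  causal_effect(300, c(EAS = 0.35, EUR = 0)),      # EAS-specific
  causal_effect(500, c(EAS = 0, EUR = 0.35)),      # EUR-specific
  causal_effect(700, c(EAS = 0.30, EUR = 0.12))    # heterogeneous
)
# panel large enough to draw the cohorts without haplotype reuse, so the
# relatedness filter sees genuinely unrelated individuals
cfg <- sim_config(n_variants = 800, n_blocks = 40, founder_haplotypes = 100,
                  n_haplotypes = 10000, drift = c(EAS = 0.05, EUR = 0.05),
                  prevalence_by_pop = c(EAS = 1e-3, EUR = 3e-4),
                  effect_spec = effects,
                  sweep_spec = list(sweep_spec(300, "EAS", 0.75, 5e4)),
                  seed = 20260922L)

panels <- simulate_two_pop_haplotypes(cfg)
panels$EAS <- impose_sweep(panels$EAS, cfg$sweep_spec[[1]], seed = cfg$seed + 1)

cohorts <- list(
  EAS = simulate_case_control_cohort(panels$EAS, effects,
                                     cfg$prevalence_by_pop[["EAS"]],
                                     1200, 1200, seed = cfg$seed + 2,
                                     cohort_id = "EAS1", replace = FALSE),
  EUR = simulate_case_control_cohort(panels$EUR, effects,
                                     cfg$prevalence_by_pop[["EUR"]],
                                     1200, 1200, seed = cfg$seed + 3,
                                     cohort_id = "EUR1", replace = FALSE)
)

for (pop in names(panels)) {
  write_phased_vcf(panels[[pop]], sprintf("results/sim/panel_%s.vcf", pop))
  write_phenotypes(cohorts[[pop]], sprintf("results/sim/pheno_%s.tsv", pop))
  write_truth_manifest(cohorts[[pop]], sprintf("results/sim/truth_%s.json", pop))
  saveRDS(cohorts[[pop]], sprintf("results/sim/cohort_%s.rds", pop))
  saveRDS(panels[[pop]], sprintf("results/sim/panel_%s.rds", pop))
}
cat("Simulated", cfg$n_variants, "variants;",
    "EAS case fraction", mean(cohorts$EAS$phenotypes), "\n")
cat("Causal truth: shared@100, EAS-specific@300 (swept), EUR-specific@500,",
    "heterogeneous@700\n")
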