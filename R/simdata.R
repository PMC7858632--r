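# Two-ancestry synthetic cohort generator: Balding-Nichols allele-frequency
# drift, founder-mosaic LD, optional recent-sweep haplotype structure, and
# liability-threshold case-control ascertainment with known per-variant truth.

#' Simulation configuration for the two-ancestry cohort generator
#'
#' Collects every knob of the synthetic study design: variant count and LD
#' block structure, founder pool and panel sizes, per-population drift
#' coefficients (Balding-Nichols), lifetime disease risks, causal-effect and
#' sweep specifications, and the master seed from which all randomness flows.
#'
#' @param n_variants Number of variants on the single simulated contig.
#' @param n_blocks Number of LD blocks; adjacent blocks are independent.
#' @param block_recomb Per-site probability of switching founder template
#'   within a block (mosaic copying); between blocks the template is always
#'   redrawn.
#' @param founder_haplotypes Founder pool size per population; within-block
#'   haplotype mosaics copy from this pool.
#' @param n_haplotypes Emitted panel size (haplotypes) per population.
#' @param drift Named numeric vector of per-population Balding-Nichols drift
#'   coefficients in `[0, 1)`; names define the two population labels.
#' @param prevalence_by_pop Named lifetime risks in (0, 0.5); defaults are the
#'   East-Asian-like 1 per 1000 and European-like 0.3 per 1000 used for
#'   systemic lupus erythematosus.
#' @param effect_spec List of [causal_effect()] objects.
#' @param sweep_spec Optional list of [sweep_spec()] objects.
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_variants = 1000L, n_blocks = 50L, block_recomb = 0.05,
                       founder_haplotypes = 100L, n_haplotypes = 200L,
                       drift = c(EAS = 0.05, EUR = 0.05),
                       prevalence_by_pop = c(EAS = 1e-3, EUR = 3e-4),
                       effect_spec = list(), sweep_spec = NULL, seed = 1L) {
  stopifnot(is.numeric(n_variants), n_variants >= 1,
            is.numeric(n_blocks), n_blocks >= 1, n_variants >= n_blocks,
            is.numeric(founder_haplotypes), founder_haplotypes >= 2,
            is.numeric(n_haplotypes), n_haplotypes >= 2)
  if (!is.finite(block_recomb) || block_recomb < 0 || block_recomb > 1)
    stop("block_recomb must be a probability in [0,1]")
  if (length(drift) != 2L || is.null(names(drift)) || any(!nzchar(names(drift))))
    stop("drift must be a named vector for exactly two populations")
  if (any(!is.finite(drift)) || any(drift < 0) || any(drift >= 1))
    stop("drift coefficients must be finite and in [0, 1)")
  if (any(!is.finite(prevalence_by_pop)) || any(prevalence_by_pop <= 0) ||
      any(prevalence_by_pop >= 0.5))
    stop("prevalences must lie in (0, 0.5)")
  if (!setequal(names(prevalence_by_pop), names(drift)))
    stop("prevalence_by_pop and drift must name the same populations")
  for (eff in effect_spec) {
    if (!inherits(eff, "causal_effect")) stop("effect_spec entries must be causal_effect objects")
    if (eff$variant_index < 1 || eff$variant_index > n_variants)
      stop("causal variant_index out of range")
  }
  structure(list(n_variants = as.integer(n_variants),
                 n_blocks = as.integer(n_blocks),
                 block_recomb = block_recomb,
                 founder_haplotypes = as.integer(founder_haplotypes),
                 n_haplotypes = as.integer(n_haplotypes),
                 drift = drift, prevalence_by_pop = prevalence_by_pop,
                 effect_spec = effect_spec, sweep_spec = sweep_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify one causal variant's per-population effect
#'
#' @param variant_index Index of the causal variant in the panel.
#' @param beta_by_pop Named vector of per-allele log odds ratios (one entry per
#'   population). The truth category is derived from this map and checked
#'   against `category` when supplied.
#' @param category Optional truth label: `"shared"` (identical nonzero betas),
#'   `"specific"` (beta zero in exactly one population), `"heterogeneous"`
#'   (differing nonzero betas) or `"absent_in_pop"`.
#' @return An object of class `causal_effect`.
#' @export
causal_effect <- function(variant_index, beta_by_pop, category = NULL) {
  stopifnot(length(variant_index) == 1L, is.numeric(beta_by_pop),
            !is.null(names(beta_by_pop)))
  derived <- derive_effect_category(beta_by_pop)
  if (!is.null(category)) {
    if (category %in% c("shared", "specific") && category != derived)
      stop(sprintf("category '%s' inconsistent with beta map (looks '%s')",
                   category, derived))
  } else category <- derived
  structure(list(variant_index = as.integer(variant_index),
                 beta_by_pop = beta_by_pop, category_truth = category),
            class = "causal_effect")
}

# Rule used both to derive manifest categories and to re-check them.
derive_effect_category <- function(beta_by_pop) {
  nz <- beta_by_pop != 0
  if (sum(nz) == 0L) return("absent_in_pop")
  if (sum(!nz) == 1L && length(beta_by_pop) > 1L) return("specific")
  if (all(nz) && length(unique(beta_by_pop)) == 1L) return("shared")
  "heterogeneous"
}

#' Specify a recent selective sweep to impose on one population's panel
#'
#' @param core_variant_index Index of the swept (core) variant.
#' @param population Population label the sweep applies to.
#' @param target_derived_frequency Post-sweep derived-allele frequency in (0,1].
#' @param homozygosity_extension Length (bp) of the shared haplotype imposed
#'   around the core.
#' @param mutation_noise Per-site flip probability applied to copied segments
#'   (excluding the core).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(core_variant_index, population, target_derived_frequency,
                       homozygosity_extension, mutation_noise = 0.01) {
  if (!is.finite(target_derived_frequency) || target_derived_frequency <= 0 ||
      target_derived_frequency > 1)
    stop("target_derived_frequency must lie in (0, 1]")
  stopifnot(homozygosity_extension >= 0, mutation_noise >= 0, mutation_noise < 1)
  structure(list(core_variant_index = as.integer(core_variant_index),
                 population = population,
                 target_derived_frequency = target_derived_frequency,
                 homozygosity_extension = homozygosity_extension,
                 mutation_noise = mutation_noise),
            class = "sweep_spec")
}

#' Construct a phased haplotype panel
#'
#' @param haplotypes H x M binary matrix; 1 codes the derived allele.
#' @param positions Strictly increasing 1-based bp positions (length M).
#' @param alleles Data frame with columns `ancestral` and `derived`.
#' @param population Population label.
#' @param chrom Contig name.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions, alleles, population,
                            chrom = "1") {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(all(haplotypes %in% c(0L, 1L)), length(positions) == ncol(haplotypes),
            nrow(alleles) == ncol(haplotypes))
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing and unique")
  daf <- colMeans(haplotypes)
  structure(list(haplotypes = haplotypes, positions = as.integer(positions),
                 alleles = alleles, population = population, chrom = chrom,
                 variant_id = if (!is.null(rownames(alleles))) rownames(alleles)
                              else paste0("var", seq_along(positions)),
                 derived_freq = daf, monomorphic = daf == 0 | daf == 1),
            class = "haplotype_panel")
}

# Founder-mosaic haplotype synthesis for one population: each emitted
# haplotype copies a founder template, switching template with probability
# `block_recomb` per site within a block and always at block boundaries.
mosaic_copy <- function(founders, n_hap, blocks, block_recomb) {
  n_f <- nrow(founders); m <- ncol(founders)
  out <- matrix(0L, n_hap, m)
  block_start <- !duplicated(blocks)
  for (i in seq_len(n_hap)) {
    switch_here <- stats::runif(m) < block_recomb | block_start
    switch_here[1L] <- TRUE
    ids <- sample.int(n_f, sum(switch_here), replace = TRUE)
    path <- ids[cumsum(switch_here)]
    out[i, ] <- founders[cbind(path, seq_len(m))]
  }
  out
}

block_index <- function(n_variants, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_variants))
}

#' Simulate haplotype panels for two drifted populations
#'
#' Ancestral derived-allele frequencies are drawn once, then drifted
#' independently per population under the Balding-Nichols model (beta
#' distribution with variance `c * p * (1 - p)` for drift coefficient `c`).
#' Within-block LD comes from mosaic copying off a founder pool; blocks are
#' mutually independent. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A named list of two [haplotype_panel()] objects sharing one variant
#'   set, with the ancestral frequency draw attached as attribute
#'   `ancestral_freq`.
#' @export
simulate_two_pop_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    m <- config$n_variants
    pops <- names(config$drift)
    p_anc <- stats::runif(m, 0.05, 0.95)
    positions <- cumsum(sample(500:1500, m, replace = TRUE))
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, m, replace = TRUE)
    der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), "")
    alleles <- data.frame(ancestral = anc, derived = der)
    rownames(alleles) <- sprintf("rs%06d", seq_len(m))
    blocks <- block_index(m, config$n_blocks)
    panels <- list()
    for (pop in pops) {
      cc <- config$drift[[pop]]
      p_pop <- if (cc == 0) p_anc else
        stats::rbeta(m, p_anc * (1 - cc) / cc, (1 - p_anc) * (1 - cc) / cc)
      founders <- matrix(stats::rbinom(config$founder_haplotypes * m, 1L,
                                       rep(p_pop, each = config$founder_haplotypes)),
                         config$founder_haplotypes, m)
      hap <- mosaic_copy(founders, config$n_haplotypes, blocks, config$block_recomb)
      panels[[pop]] <- haplotype_panel(hap, positions, alleles, pop)
    }
    attr(panels, "ancestral_freq") <- p_anc
    attr(panels, "blocks") <- blocks
    panels
  })
}

#' Impose a recent selective sweep on a haplotype panel
#'
#' The derived-allele frequency at the core variant is moved to the target by
#' recoding core alleles on randomly chosen haplotypes; all carriers of the
#' derived core allele then have the window of `homozygosity_extension` bp
#' around the core replaced by one template carrier's segment, with small
#' per-site mutation noise, which lengthens derived-allele haplotype
#' homozygosity (the signature iHS detects).
#'
#' @param panel A [haplotype_panel()].
#' @param spec A [sweep_spec()].
#' @param seed Integer seed for carrier choice and mutation noise.
#' @return The modified panel.
#' @export
impose_sweep <- function(panel, spec, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "sweep_spec"))
  j <- spec$core_variant_index
  if (j < 1 || j > ncol(panel$haplotypes)) stop("core variant not in panel")
  hap <- panel$haplotypes
  n <- nrow(hap)
  target_n <- round(spec$target_derived_frequency * n)
  if (target_n < 1 || target_n > n)
    stop(sprintf("target derived frequency %.3f unreachable with %d haplotypes",
                 spec$target_derived_frequency, n))
  withr::with_seed(seed, {
    carriers <- which(hap[, j] == 1L)
    non <- which(hap[, j] == 0L)
    if (length(carriers) == 0L) {
      carriers <- sample(non, 1L); hap[carriers, j] <- 1L
      non <- setdiff(non, carriers)
    }
    if (length(carriers) > target_n) {
      drop <- sample(carriers, length(carriers) - target_n)
      hap[drop, j] <- 0L
      carriers <- setdiff(carriers, drop)
    } else if (length(carriers) < target_n) {
      add <- sample(non, target_n - length(carriers))
      hap[add, j] <- 1L
      carriers <- c(carriers, add)
    }
    half <- spec$homozygosity_extension / 2
    win <- which(panel$positions >= panel$positions[j] - half &
                 panel$positions <= panel$positions[j] + half)
    win <- setdiff(win, j)
    if (length(win) > 0L && length(carriers) > 1L) {
      template <- hap[carriers[1L], win]
      for (i in carriers) {
        seg <- template
        if (spec$mutation_noise > 0) {
          flip <- stats::runif(length(seg)) < spec$mutation_noise
          seg[flip] <- 1L - seg[flip]
        }
        hap[i, win] <- seg
      }
    }
  })
  haplotype_panel(hap, panel$positions, panel$alleles, panel$population,
                  panel$chrom)
}

#' Construct a genotype cohort object
#'
#' @param genotypes N x M dosage matrix counting derived alleles (0/1/2, NA for
#'   missing).
#' @param phenotypes Binary 0/1 case status vector.
#' @param covariates Data frame of per-sample covariates (may have 0 columns).
#' @param variants Data frame of variant metadata (id, chrom, pos, ancestral,
#'   derived).
#' @param cohort_id,population Labels.
#' @param truth Optional truth manifest (list).
#' @return An object of class `genotype_cohort`.
#' @export
genotype_cohort <- function(genotypes, phenotypes, covariates, variants,
                            cohort_id, population, truth = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(all(genotypes %in% c(0L, 1L, 2L, NA)),
            length(phenotypes) == nrow(genotypes),
            all(phenotypes %in% c(0L, 1L)),
            nrow(variants) == ncol(genotypes))
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("%s_s%04d", cohort_id, seq_len(nrow(genotypes)))
  structure(list(genotypes = genotypes, phenotypes = as.integer(phenotypes),
                 covariates = covariates, variants = variants,
                 cohort_id = cohort_id, population = population, truth = truth),
            class = "genotype_cohort")
}

# Inverse Mills ratio at the liability threshold: converts a per-allele log
# odds ratio into the per-allele liability shift that induces it for a rare
# trait (log OR ~ b * dnorm(t)/(1 - pnorm(t))).
liability_scale_factor <- function(prevalence) {
  t0 <- stats::qnorm(1 - prevalence)
  stats::dnorm(t0) / prevalence
}

#' Simulate an ascertained case-control cohort from a haplotype panel
#'
#' Individuals are formed by random pairing of panel haplotypes (with
#' replacement). Disease status follows a liability-threshold model: the
#' genetic liability is the sum over causal variants of centred derived-allele
#' dosage times a per-allele liability coefficient obtained from the specified
#' log odds ratio via the rare-disease inverse-Mills factor; standard-normal
#' noise is added and the threshold is set so the population lifetime risk
#' equals `prevalence`. Cases are oversampled until `n_case` is reached.
#'
#' @param panel A [haplotype_panel()].
#' @param effects List of [causal_effect()] objects (betas looked up by the
#'   panel's population label).
#' @param prevalence Lifetime risk in (0, 0.5).
#' @param n_case,n_control Requested case and control counts. When `n_case` is
#'   `NULL`, `n_total` individuals are drawn without ascertainment.
#' @param seed Integer seed.
#' @param cohort_id Cohort label.
#' @param n_total Unascertained sample size (used only when `n_case` is NULL).
#' @param max_draws Cap on liability draws before erroring.
#' @param replace Sample haplotypes with replacement. The default reuses
#'   haplotypes freely (any cohort size from any panel); `replace = FALSE`
#'   uses every panel haplotype at most once, which requires
#'   `>= 2 * (n_case + n_control)` haplotypes and yields genuinely unrelated
#'   individuals (no pair shares a haplotype) -- use this for cohorts that
#'   will go through relatedness QC.
#' @return A [genotype_cohort()] whose `truth` manifest records per-variant
#'   true log odds ratios and effect categories.
#' @export
simulate_case_control_cohort <- function(panel, effects, prevalence,
                                         n_case = NULL, n_control = NULL,
                                         seed = 1L, cohort_id = panel$population,
                                         n_total = NULL, max_draws = 2e7,
                                         replace = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 0.5)
    stop("prevalence must lie in (0, 0.5)")
  hap <- panel$haplotypes
  n_hap <- nrow(hap); m <- ncol(hap)
  beta <- numeric(m)
  categ <- rep("none", m)
  for (eff in effects) {
    b <- eff$beta_by_pop
    beta[eff$variant_index] <- if (panel$population %in% names(b))
      b[[panel$population]] else 0
    categ[eff$variant_index] <- eff$category_truth
  }
  causal <- which(beta != 0)
  lam <- liability_scale_factor(prevalence)
  b_liab <- beta[causal] / lam
  # genetic liability variance from the empirical haplotype covariance at the
  # causal sites (dosage covariance is twice the haplotype covariance)
  var_g <- if (length(causal) > 0) {
    cv <- stats::cov(hap[, causal, drop = FALSE]) * 2 * (n_hap - 1) / n_hap
    as.numeric(t(b_liab) %*% cv %*% b_liab)
  } else 0
  thr <- stats::qnorm(1 - prevalence) * sqrt(1 + var_g)
  mu <- if (length(causal) > 0) 2 * colMeans(hap[, causal, drop = FALSE]) else numeric(0)

  ascertained <- !is.null(n_case)
  if (ascertained) stopifnot(n_control >= 1, n_case >= 1)
  else stopifnot(!is.null(n_total), n_total >= 2)
  n_requested <- if (ascertained) n_case + n_control else n_total
  if (!replace && n_hap < 2 * n_requested)
    stop(sprintf(paste0("panel has %d haplotypes but %d are needed without ",
                        "replacement; enable replace = TRUE or enlarge the panel"),
                 n_hap, 2 * n_requested))

  # per-haplotype genetic score: pair liability is score[h1] + score[h2]
  hap_score <- if (length(causal) > 0)
    as.numeric(hap[, causal, drop = FALSE] %*% b_liab) else rep(0, n_hap)
  centre <- sum(b_liab * mu)

  withr::with_seed(seed, {
    pair_case <- pair_ctrl <- matrix(integer(0), 0, 2)
    used <- rep(FALSE, n_hap)  # without-replacement bookkeeping
    # choose up to `need` candidate indices; without replacement, skip any
    # pair whose haplotypes were already claimed by a selected individual
    accept <- function(idx, h1, h2, need) {
      if (replace) {
        sel <- idx[seq_len(min(need, length(idx)))]
      } else {
        sel <- integer(need); cnt <- 0L
        for (k in idx) {
          if (cnt >= need) break
          if (used[h1[k]] || used[h2[k]] || h1[k] == h2[k]) next
          used[c(h1[k], h2[k])] <<- TRUE
          cnt <- cnt + 1L; sel[cnt] <- k
        }
        sel <- sel[seq_len(cnt)]
      }
      cbind(h1[sel], h2[sel])
    }
    drawn <- 0L
    repeat {
      need_case <- if (ascertained) n_case - nrow(pair_case) else 0L
      need_ctrl <- if (ascertained) n_control - nrow(pair_ctrl) else 0L
      if (ascertained && need_case <= 0L && need_ctrl <= 0L) break
      if (!ascertained) {
        if (replace) {
          h1 <- sample.int(n_hap, n_total, replace = TRUE)
          h2 <- sample.int(n_hap, n_total, replace = TRUE)
        } else {
          perm <- sample.int(n_hap, 2 * n_total)
          h1 <- perm[seq_len(n_total)]
          h2 <- perm[n_total + seq_len(n_total)]
        }
        status <- (hap_score[h1] + hap_score[h2] - centre +
                     stats::rnorm(n_total)) > thr
        pair_case <- cbind(h1[status], h2[status])
        pair_ctrl <- cbind(h1[!status], h2[!status])
        break
      }
      nb <- min(max(5e4, ceiling(1.5 * max(need_case, 1) / prevalence)),
                max_draws - drawn)
      h1 <- sample.int(n_hap, nb, replace = TRUE)
      h2 <- sample.int(n_hap, nb, replace = TRUE)
      liab <- hap_score[h1] + hap_score[h2] - centre
      status <- (liab + stats::rnorm(nb)) > thr
      drawn <- drawn + nb
      if (need_case > 0L && any(status))
        pair_case <- rbind(pair_case, accept(which(status), h1, h2, need_case))
      if (need_ctrl > 0L && any(!status))
        pair_ctrl <- rbind(pair_ctrl, accept(which(!status), h1, h2, need_ctrl))
      if (drawn >= max_draws &&
          (nrow(pair_case) < n_case || nrow(pair_ctrl) < n_control))
        stop(sprintf(paste0("could not reach %d cases after %d liability draws ",
                            "(prevalence %.2g is the bottleneck)"),
                     n_case, drawn, prevalence))
    }
    pairs <- rbind(pair_case, pair_ctrl)
    pheno <- c(rep(1L, nrow(pair_case)), rep(0L, nrow(pair_ctrl)))
    geno <- hap[pairs[, 1], , drop = FALSE] + hap[pairs[, 2], , drop = FALSE]
    storage.mode(geno) <- "integer"
    covar <- data.frame(batch = factor(sample(c("chipA", "chipB"),
                                              nrow(geno), replace = TRUE)))
    variants <- data.frame(id = panel$variant_id, chrom = panel$chrom,
                           pos = panel$positions,
                           ancestral = panel$alleles$ancestral,
                           derived = panel$alleles$derived)
    truth <- list(beta = beta, category = categ, prevalence = prevalence,
                  threshold = thr, liability_var_genetic = var_g,
                  sampled_haplotypes = pairs,
                  panel_derived_freq = panel$derived_freq)
    genotype_cohort(geno, pheno, covar, variants, cohort_id,
                    panel$population, truth)
  })
}
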