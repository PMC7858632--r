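# Plain-text interchange: phased VCF with INFO/AA, phenotype/covariate TSV,
# association-table TSV with fixed column order, truth-manifest JSON.

#' Write a haplotype panel as a phased VCF
#'
#' Consecutive haplotypes are paired into diploid samples; GT uses the phased
#' `|` separator, positions are 1-based on one contig, and the ancestral
#' allele is recorded as INFO/AA. REF is the ancestral allele, ALT the derived.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path.
#' @export
write_phased_vcf <- function(panel, path) {
  hap <- panel$haplotypes
  if (nrow(hap) %% 2 != 0) stop("need an even number of haplotypes to pair")
  n_s <- nrow(hap) / 2
  samples <- sprintf("%s_s%04d", panel$population, seq_len(n_s))
  gt <- matrix(paste(hap[seq(1, nrow(hap), 2), ], hap[seq(2, nrow(hap), 2), ],
                     sep = "|"),
               n_s, ncol(hap))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", panel$chrom),
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(hap)), function(j) {
    paste(c(panel$chrom, panel$positions[j], panel$variant_id[j],
            panel$alleles$ancestral[j], panel$alleles$derived[j], ".", "PASS",
            paste0("AA=", panel$alleles$ancestral[j]), "GT", gt[, j]),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF back into a haplotype panel
#'
#' Uses `vcfR` for parsing; requires phased GT and an INFO/AA annotation to
#' set iHS polarity (alleles matching AA are coded ancestral = 0).
#'
#' @param path VCF file path.
#' @param population Population label for the panel.
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, population = "pop") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("|", gt, fixed = TRUE))) stop("GT must be phased ('|')")
  a1 <- t(apply(gt, 1, function(r) as.integer(sub("\\|.*", "", r))))
  a2 <- t(apply(gt, 1, function(r) as.integer(sub(".*\\|", "", r))))
  hap <- matrix(0L, 2 * ncol(gt), nrow(gt))
  hap[seq(1, nrow(hap), 2), ] <- t(a1)
  hap[seq(2, nrow(hap), 2), ] <- t(a2)
  fix <- vcfR::getFIX(v)
  aa <- sub(".*AA=([^;]+).*", "\\1", v@fix[, "INFO"])
  ref_is_anc <- aa == fix[, "REF"]
  # where ALT is ancestral, flip so 1 always codes the derived allele
  if (any(!ref_is_anc)) {
    flip <- which(!ref_is_anc)
    hap[, flip] <- 1L - hap[, flip]
  }
  alleles <- data.frame(ancestral = aa,
                        derived = ifelse(ref_is_anc, fix[, "ALT"], fix[, "REF"]))
  rownames(alleles) <- fix[, "ID"]
  haplotype_panel(hap, as.integer(fix[, "POS"]), alleles, population,
                  chrom = fix[1, "CHROM"])
}

#' Write sample phenotypes (and covariates) as TSV
#'
#' @param cohort A [genotype_cohort()].
#' @param path Output path.
#' @param coding `"01"` for 0 = control / 1 = case, `"12"` for the PLINK-style
#'   1 = control / 2 = case.
#' @export
write_phenotypes <- function(cohort, path, coding = c("01", "12")) {
  coding <- match.arg(coding)
  status <- cohort$phenotypes + if (coding == "12") 1L else 0L
  df <- cbind(data.frame(sample = rownames(cohort$genotypes), status = status),
              cohort$covariates)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

assoc_columns <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "Z",
                   "P", "N")

#' Write an association table TSV with fixed column order
#'
#' Columns: SNP, CHR, BP, A1 (effect allele), A2, EAF, BETA, SE, Z, P, N.
#'
#' @param assoc An `assoc_table` data frame from [logistic_assoc()] or
#'   assembled manually.
#' @param path Output path.
#' @export
write_assoc_table <- function(assoc, path) {
  stopifnot(all(assoc_columns %in% names(assoc)))
  utils::write.table(assoc[, assoc_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association table TSV
#' @param path Input path.
#' @return An `assoc_table` data frame.
#' @export
read_assoc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(assoc_columns %in% names(df)))
  class(df) <- c("assoc_table", "data.frame")
  df
}

#' Write the truth manifest of a simulated cohort as JSON
#' @param cohort A [genotype_cohort()] carrying a truth manifest.
#' @param path Output path.
#' @export
write_truth_manifest <- function(cohort, path) {
  if (is.null(cohort$truth)) stop("cohort has no truth manifest")
  tr <- cohort$truth
  jsonlite::write_json(list(cohort_id = cohort$cohort_id,
                            population = cohort$population,
                            prevalence = tr$prevalence,
                            variant_id = cohort$variants$id,
                            beta = tr$beta, category = tr$category),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a simulation configuration from JSON
#'
#' @param path JSON file with fields matching the [sim_config()] arguments;
#'   `effect_spec` entries carry `variant_index` and `beta_by_pop`.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  effects <- list()
  if (!is.null(x$effect_spec) && length(x$effect_spec))
    effects <- lapply(seq_len(nrow(x$effect_spec)), function(i)
      causal_effect(x$effect_spec$variant_index[i],
                    unlist(x$effect_spec$beta_by_pop[i, , drop = TRUE])))
  sim_config(n_variants = x$n_variants, n_blocks = x$n_blocks,
             block_recomb = x$block_recomb,
             founder_haplotypes = x$founder_haplotypes,
             n_haplotypes = x$n_haplotypes,
             drift = unlist(x$drift),
             prevalence_by_pop = unlist(x$prevalence_by_pop),
             effect_spec = effects, seed = x$seed)
}
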