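# Selection signatures: Wright's Fst from pooled and subpopulation expected
# heterozygosity, extended haplotype homozygosity (EHH), integrated haplotype
# scores (iHS) with 50-bin frequency standardization, and empirical P-values.

#' Wright's fixation index for two populations
#'
#' `Fst = (Ht - Hs) / Ht`, with `Ht = 2 p_bar (1 - p_bar)` the expected
#' heterozygosity at the sample-size-weighted pooled frequency and
#' `Hs = (H1 N1 + H2 N2) / (N1 + N2)` the weighted subpopulation expected
#' heterozygosity. A monomorphic pool (Ht = 0) yields NA with a flag rather
#' than an error. Vectorized over variants.
#'
#' @param p1,p2 Allele frequencies in the two populations.
#' @param n1,n2 Sample sizes of the two populations.
#' @return Data frame with `fst`, `ht`, `hs`, `p_bar`, per-population `h1`,
#'   `h2` and the `monomorphic` flag.
#' @export
fst <- function(p1, p2, n1, n2) {
  stopifnot(length(p1) == length(p2), n1 > 0, n2 > 0)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  ht <- 2 * p_bar * (1 - p_bar)
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  hs <- (h1 * n1 + h2 * n2) / (n1 + n2)
  f <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  data.frame(fst = f, ht = ht, hs = hs, p_bar = p_bar, h1 = h1, h2 = h2,
             monomorphic = ht == 0)
}

# Unbiased pair-counting homozygosity of a grouping: sum C(n_k,2) / C(n,2).
pair_homozygosity <- function(groups) {
  n <- length(groups)
  tab <- table(groups)
  sum(choose(tab, 2)) / choose(n, 2)
}

#' Extended haplotype homozygosity curve around a core allele
#'
#' EHH at distance x is the probability that two distinct carrier haplotypes
#' of the core allele are identical over every variant between the core and
#' x, estimated by unbiased pair counting. Computed outward in both
#' directions, truncating when EHH drops below `stop_ehh`; truncation at the
#' panel edge is flagged.
#'
#' @param panel A [haplotype_panel()].
#' @param core Core variant index.
#' @param allele `"derived"` or `"ancestral"` core allele.
#' @param stop_ehh Stop threshold (default 0.05).
#' @return An `ehh_curve` list: `positions`, `ehh` (ordered along the
#'   chromosome, EHH = 1 at the core), `core_pos`, carrier count and
#'   `edge_truncated` flag.
#' @export
ehh_curve <- function(panel, core, allele = c("derived", "ancestral"),
                      stop_ehh = 0.05) {
  allele <- match.arg(allele)
  hap <- panel$haplotypes
  carriers <- which(hap[, core] == if (allele == "derived") 1L else 0L)
  if (length(carriers) < 2) stop("fewer than 2 carrier haplotypes")
  sub <- hap[carriers, , drop = FALSE]
  m <- ncol(sub)
  walk <- function(idx) {  # idx: variant indices outward from the core
    groups <- rep(1L, nrow(sub))
    ehh <- numeric(length(idx))
    hit_edge <- TRUE
    for (k in seq_along(idx)) {
      groups <- groups * 2L + sub[, idx[k]]
      groups <- match(groups, unique(groups))  # re-pack to avoid overflow
      ehh[k] <- pair_homozygosity(groups)
      if (ehh[k] < stop_ehh) { ehh <- ehh[seq_len(k)]; hit_edge <- FALSE; break }
    }
    list(ehh = ehh, hit_edge = hit_edge && length(idx) > 0)
  }
  right_idx <- if (core < m) (core + 1L):m else integer(0)
  left_idx <- if (core > 1) (core - 1L):1L else integer(0)
  r <- walk(right_idx); l <- walk(left_idx)
  pos <- c(rev(panel$positions[left_idx[seq_along(l$ehh)]]),
           panel$positions[core],
           panel$positions[right_idx[seq_along(r$ehh)]])
  vals <- c(rev(l$ehh), 1, r$ehh)
  structure(list(positions = pos, ehh = vals,
                 core_pos = panel$positions[core], core = core,
                 allele = allele, n_carriers = length(carriers),
                 edge_truncated = r$hit_edge || l$hit_edge),
            class = "ehh_curve")
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Raw integrated haplotype score at one variant
#'
#' Integrates the ancestral- and derived-allele EHH curves over position
#' (trapezoid rule, bp) to iHH_A and iHH_D; the raw iHS is
#' `ln(iHH_A / iHH_D)`. Large negative values mean long derived-allele
#' haplotypes. Undefined integrals (a zero iHH) are flagged rather than
#' thrown.
#'
#' @param panel A [haplotype_panel()] with ancestral alleles annotated.
#' @param core Core variant index.
#' @param stop_ehh EHH truncation threshold.
#' @return An `ihs_result` list with `ihh_a`, `ihh_d`, `ihs_raw`,
#'   `derived_freq`, `edge_truncated` and `defined` flags.
#' @export
ihs_raw <- function(panel, core, stop_ehh = 0.05) {
  daf <- panel$derived_freq[core]
  n <- nrow(panel$haplotypes)
  if (min(daf, 1 - daf) * n < 2)
    return(structure(list(core = core, ihh_a = NA_real_, ihh_d = NA_real_,
                          ihs_raw = NA_real_, derived_freq = daf,
                          edge_truncated = FALSE, defined = FALSE),
                     class = "ihs_result"))
  ca <- ehh_curve(panel, core, "ancestral", stop_ehh)
  cd <- ehh_curve(panel, core, "derived", stop_ehh)
  ihh_a <- trapz(ca$positions, ca$ehh)
  ihh_d <- trapz(cd$positions, cd$ehh)
  defined <- ihh_a > 0 && ihh_d > 0
  structure(list(core = core, ihh_a = ihh_a, ihh_d = ihh_d,
                 ihs_raw = if (defined) log(ihh_a / ihh_d) else NA_real_,
                 derived_freq = daf,
                 edge_truncated = ca$edge_truncated || cd$edge_truncated,
                 defined = defined),
            class = "ihs_result")
}

#' Scan a panel for raw iHS at many variants
#' @param panel A [haplotype_panel()].
#' @param cores Variant indices (default: all polymorphic).
#' @param stop_ehh EHH truncation threshold.
#' @return Data frame of per-variant iHS components.
#' @export
ihs_scan <- function(panel, cores = which(!panel$monomorphic),
                     stop_ehh = 0.05) {
  rows <- lapply(cores, function(j) {
    r <- ihs_raw(panel, j, stop_ehh)
    data.frame(variant = panel$variant_id[j], core = j, ihh_a = r$ihh_a,
               ihh_d = r$ihh_d, ihs_raw = r$ihs_raw,
               derived_freq = r$derived_freq,
               edge_truncated = r$edge_truncated, defined = r$defined)
  })
  do.call(rbind, rows)
}

ihs_bin_index <- function(daf, n_bins = 50L) {
  pmin(floor(daf * n_bins) + 1L, n_bins)  # right-closed last bin
}

#' Standardize raw iHS within derived-allele-frequency bins
#'
#' Scores are standardized to mean 0, sd 1 within each of `n_bins`
#' equal-width derived-allele-frequency bins (last bin right-closed). Curves
#' truncated at the panel edge are excluded by default; bins with fewer than
#' two finite scores are flagged unstandardizable (NA).
#'
#' @param scan Data frame from [ihs_scan()].
#' @param n_bins Number of frequency bins (default 50).
#' @param drop_edge_truncated Exclude edge-truncated scores.
#' @return The input with `bin` and `ihs_std` columns added.
#' @export
ihs_standardize <- function(scan, n_bins = 50L, drop_edge_truncated = TRUE) {
  scan$bin <- ihs_bin_index(scan$derived_freq, n_bins)
  usable <- scan$defined & is.finite(scan$ihs_raw) &
    (!drop_edge_truncated | !scan$edge_truncated)
  scan$ihs_std <- NA_real_
  for (b in unique(scan$bin[usable])) {
    sel <- usable & scan$bin == b
    if (sum(sel) < 2) next
    mu <- mean(scan$ihs_raw[sel]); sdv <- stats::sd(scan$ihs_raw[sel])
    if (sdv > 0) scan$ihs_std[sel] <- (scan$ihs_raw[sel] - mu) / sdv
  }
  scan
}

#' Empirical P-value of an observed Fst against a genome background
#'
#' Add-one convention: `P = (1 + #background >= observed) / (1 + n)`.
#'
#' @param observed Observed Fst.
#' @param background Genome-wide background Fst values.
#' @return Empirical P.
#' @export
fst_empirical_pvalue <- function(observed, background) {
  background <- background[is.finite(background)]
  if (length(background) == 0) stop("empty background")
  (1 + sum(background >= observed)) / (1 + length(background))
}

#' Cross-ancestry correlation of standardized iHS, per locus category
#'
#' Pearson correlation (with two-sided P) of standardized iHS scores between
#' ancestries, computed separately within each locus category.
#'
#' @param ihs_eas,ihs_eur Standardized iHS vectors over paired variants.
#' @param categories Locus category per variant.
#' @return Data frame with per-category `n`, `r` and `p`.
#' @export
ihs_category_correlation <- function(ihs_eas, ihs_eur, categories) {
  stopifnot(length(ihs_eas) == length(ihs_eur),
            length(categories) == length(ihs_eas))
  rows <- lapply(sort(unique(categories)), function(cat) {
    sel <- categories == cat & is.finite(ihs_eas) & is.finite(ihs_eur)
    if (sum(sel) < 3) stop(sprintf("fewer than 3 pairs in category %s", cat))
    ct <- stats::cor.test(ihs_eas[sel], ihs_eur[sel])
    data.frame(category = cat, n = sum(sel), r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, rows)
}
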