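#' Select germline variants eligible for allele drop-out assessment
#'
#' Keeps germline variants with coverage >= 8 in both the germline and the
#' WGA sample, >= 5 variant reads representing >= 5% of the germline reads at
#' the position, and genotype quality >= 30. All boundaries are inclusive.
#'
#' @param paired data.frame with one row per variant and columns
#'   `germline_depth`, `germline_alt`, `gq`, `wga_depth` (plus any
#'   identifiers, carried through).
#' @param min_depth,min_alt_reads,min_alt_frac,min_gq thresholds.
#' @return the eligible subset of `paired`.
#' @export
select_reliable_germline_variants <- function(paired, min_depth = 8,
                                              min_alt_reads = 5,
                                              min_alt_frac = 0.05,
                                              min_gq = 30) {
  need <- c("germline_depth", "germline_alt", "gq", "wga_depth")
  stopifnot(all(need %in% names(paired)))
  frac <- ifelse(paired$germline_depth > 0,
                 paired$germline_alt / paired$germline_depth, 0)
  keep <- paired$germline_depth >= min_depth &
    paired$wga_depth >= min_depth &
    paired$germline_alt >= min_alt_reads &
    frac >= min_alt_frac &
    paired$gq >= min_gq
  paired[keep, , drop = FALSE]
}

#' Estimate the allele drop-out rate of a WGA sample
#'
#' For each eligible germline-heterozygous variant, the ref/alt read
#' proportions in the germline and the WGA sample are compared with a
#' two-sided Fisher exact test. A variant is scored as having undergone ADO
#' when the test is significant (p < `alpha`), the germline VAF lies in
#' \[0.2, 0.8\] and the WGA VAF is < 0.1 or > 0.9. The ADO rate is the
#' fraction of ADO calls among heterozygous-band eligible variants.
#'
#' @param paired data.frame with columns `germline_ref`, `germline_alt`,
#'   `wga_ref`, `wga_alt` (one row per eligible variant).
#' @param alpha significance level of the Fisher test.
#' @param het_band germline-VAF interval defining assessable heterozygotes.
#' @param extreme_vaf WGA VAF beyond which one allele is considered lost.
#' @return list with `assessments` (per-variant data.frame: counts, VAFs,
#'   `fisher_p`, `is_ado`, `eligible_het`) and `ado_rate`.
#' @export
estimate_ado <- function(paired, alpha = 0.05, het_band = c(0.2, 0.8),
                         extreme_vaf = c(0.1, 0.9)) {
  need <- c("germline_ref", "germline_alt", "wga_ref", "wga_alt")
  stopifnot(all(need %in% names(paired)), nrow(paired) >= 1)
  g_tot <- paired$germline_ref + paired$germline_alt
  w_tot <- paired$wga_ref + paired$wga_alt
  if (any(g_tot == 0 | w_tot == 0)) {
    warning("skipping ", sum(g_tot == 0 | w_tot == 0),
            " site(s) with zero total reads")
    paired <- paired[g_tot > 0 & w_tot > 0, , drop = FALSE]
    g_tot <- paired$germline_ref + paired$germline_alt
    w_tot <- paired$wga_ref + paired$wga_alt
  }
  if (!nrow(paired)) stop("no assessable sites")
  g_vaf <- paired$germline_alt / g_tot
  w_vaf <- paired$wga_alt / w_tot
  p <- vapply(seq_len(nrow(paired)), function(i) {
    m <- matrix(c(paired$germline_ref[i], paired$germline_alt[i],
                  paired$wga_ref[i], paired$wga_alt[i]), nrow = 2)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  het <- g_vaf >= het_band[1] & g_vaf <= het_band[2]
  extreme <- w_vaf < extreme_vaf[1] | w_vaf > extreme_vaf[2]
  is_ado <- p < alpha & het & extreme
  out <- cbind(paired,
               data.frame(germline_vaf = g_vaf, wga_vaf = w_vaf,
                          fisher_p = p, eligible_het = het, is_ado = is_ado))
  if (!any(het)) warning("no heterozygous-band variants; ADO rate undefined")
  list(assessments = out,
       ado_rate = if (any(het)) sum(is_ado) / sum(het) else NA_real_)
}

#' Estimate the per-megabase false-positive rate of a WGA sample
#'
#' All calls of the sample that are found neither in the primary tumor nor in
#' the CDX are counted as potential false positives (conservative rule), and
#' divided by the number of megabases of target covered at >= 8x in the same
#' sample.
#'
#' @param calls variant ids called in the WGA sample.
#' @param pt_union,cdx_set variant ids of the primary-tumor union and the
#'   CDX.
#' @param covered either the number of target bases covered >= 8x, or a
#'   BED-like data.frame (`chrom`, `start`, `end`, half-open) whose interval
#'   lengths are summed.
#' @return data.frame with `n_false_positive_events`, `covered_bases_ge8`,
#'   `fpr_per_mb`.
#' @export
estimate_fpr <- function(calls, pt_union, cdx_set, covered) {
  if (is.data.frame(covered)) {
    covered <- sum(covered$end - covered$start)
  }
  if (!is.numeric(covered) || covered <= 0)
    stop("zero covered bases: false-positive rate undefined")
  n_fp <- length(setdiff(unique(calls), union(pt_union, cdx_set)))
  data.frame(n_false_positive_events = n_fp,
             covered_bases_ge8 = covered,
             fpr_per_mb = n_fp / (covered / 1e6))
}

#' Pair germline and WGA read counts for ADO estimation
#'
#' Convenience join of two per-SNP count tables (as produced by
#' [simulate_cohort()]) on (chrom, pos).
#'
#' @param germline per-SNP counts of the germline sample, with a `gq` column.
#' @param wga per-SNP counts of the WGA sample.
#' @return data.frame with the columns required by
#'   [select_reliable_germline_variants()] and [estimate_ado()].
#' @export
pair_snp_counts <- function(germline, wga) {
  m <- merge(germline, wga, by = c("chrom", "pos"),
             suffixes = c("_g", "_w"))
  data.frame(chrom = m$chrom, pos = m$pos,
             germline_ref = m$ref_count_g, germline_alt = m$alt_count_g,
             germline_depth = m$ref_count_g + m$alt_count_g,
             gq = if ("gq" %in% names(m)) m$gq else
               if ("gq_g" %in% names(m)) m$gq_g else 99L,
             wga_ref = m$ref_count_w, wga_alt = m$alt_count_w,
             wga_depth = m$ref_count_w + m$alt_count_w,
             stringsAsFactors = FALSE)
}
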