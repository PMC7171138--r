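#' Score one known aberration in a noisy CTC sample by allelic imbalance
#'
#' CTC copy-number profiles after WGA are usually too noisy for direct
#' segmentation, but an aberration already called in a cleaner reference
#' sample (CDX, cell line or a PT specimen) leaves a detectable footprint:
#' inside the aberrant segment, the CTC's BAF tends to deviate from 0.5 in
#' the same direction as the reference's BAF at the same SNP (the two samples
#' share the affected haplotype). SNPs inside the segment are counted as
#' consistent (same direction) or discordant (opposite), the same counts are
#' collected over background SNPs taken from copy-neutral, non-LOH reference
#' segments, and a (two-sided) Fisher exact test asks whether the
#' consistent/discordant split in the segment differs from the background.
#' The aberration is scored present when p < `alpha` and at least
#' `min_consistent_frac` of informative SNPs are consistent; the fraction
#' conjunct enforces the direction of the enrichment.
#'
#' A CTC SNP is informative when its depth is at least `min_reads` and its
#' BAF deviates from 0.5 by more than `deviation`; the reference direction at
#' a SNP is the sign of (reference BAF - 0.5). When the reference segment
#' itself shows no allelic imbalance (mean mirrored BAF within `deviation`
#' of 0.5, e.g. a balanced gain), the footprint is undefined and the
#' aberration is reported `not_evaluable` with `lrr_only = TRUE`.
#'
#' @param segment one-row data.frame (`chrom`, `start`, `end`) delimiting
#'   the aberration.
#' @param ref_track reference-sample `snp_track` ([compute_lrr_baf()]).
#' @param ctc_track CTC-sample `snp_track`.
#' @param background_snps data.frame (`chrom`, `pos`) of SNPs in reference
#'   copy-neutral non-LOH segments.
#' @param min_reads,deviation informativeness thresholds for CTC SNPs.
#' @param alpha significance level.
#' @param min_consistent_frac minimum fraction of consistent SNPs.
#' @return one-row data.frame: `n_consistent`, `n_discordant`, `bg_consistent`,
#'   `bg_discordant`, `fisher_p`, `fraction_consistent`, `status`
#'   (`"present"`, `"absent"` or `"not_evaluable"`), `lrr_only`.
#' @export
score_aberration_in_ctc <- function(segment, ref_track, ctc_track,
                                    background_snps,
                                    min_reads = 10, deviation = 0.1,
                                    alpha = 0.05,
                                    min_consistent_frac = 0.8) {
  res <- data.frame(n_consistent = 0L, n_discordant = 0L,
                    bg_consistent = 0L, bg_discordant = 0L,
                    fisher_p = NA_real_, fraction_consistent = NA_real_,
                    status = "not_evaluable", lrr_only = FALSE,
                    stringsAsFactors = FALSE)
  count_dirs <- function(keys) {
    rk <- paste(ref_track$chrom, ref_track$pos)
    ck <- paste(ctc_track$chrom, ctc_track$pos)
    i <- match(keys, rk); j <- match(keys, ck)
    ok <- !is.na(i) & !is.na(j)
    i <- i[ok]; j <- j[ok]
    ref_dir <- sign(ref_track$baf[i] - 0.5)
    ctc_baf <- ctc_track$baf[j]
    inf <- !is.na(ctc_baf) & ctc_track$depth[j] >= min_reads &
      abs(ctc_baf - 0.5) > deviation & !is.na(ref_dir) & ref_dir != 0
    ctc_dir <- sign(ctc_baf - 0.5)
    c(consistent = sum(inf & ctc_dir == ref_dir),
      discordant = sum(inf & ctc_dir != ref_dir))
  }
  in_seg <- ref_track$chrom == segment$chrom &
    ref_track$pos >= segment$start & ref_track$pos <= segment$end
  if (!any(in_seg)) return(res)
  ## reference segment must itself be allelically imbalanced
  if (mean(mirrored_baf(ref_track$baf[in_seg]), na.rm = TRUE) - 0.5 <=
      deviation) {
    res$lrr_only <- TRUE
    return(res)
  }
  seg_keys <- paste(ref_track$chrom[in_seg], ref_track$pos[in_seg])
  ns <- count_dirs(seg_keys)
  nb <- count_dirs(paste(background_snps$chrom, background_snps$pos))
  res$n_consistent <- ns[["consistent"]]
  res$n_discordant <- ns[["discordant"]]
  res$bg_consistent <- nb[["consistent"]]
  res$bg_discordant <- nb[["discordant"]]
  n_inf <- sum(ns)
  if (n_inf == 0L || sum(nb) == 0L) return(res)
  res$fraction_consistent <- ns[["consistent"]] / n_inf
  res$fisher_p <- stats::fisher.test(
    matrix(c(ns[["consistent"]], ns[["discordant"]],
             nb[["consistent"]], nb[["discordant"]]), nrow = 2))$p.value
  res$status <- if (res$fisher_p < alpha &&
                    res$fraction_consistent >= min_consistent_frac)
    "present" else "absent"
  res
}

#' Screen a catalog of aberrations across CTC samples
#'
#' Applies [score_aberration_in_ctc()] to every (aberration, CTC sample)
#' pair. Background SNPs are drawn from the reference sample's copy-neutral,
#' non-LOH segments.
#'
#' @param catalog data.frame of aberrant segments (`aberration_id`, `chrom`,
#'   `start`, `end`); typically gains/losses called in the CDX, cell line or
#'   PT specimens.
#' @param ref_track `snp_track` of the reference sample.
#' @param ref_segments classified reference segments ([classify_segments()]),
#'   used to locate copy-neutral non-LOH background SNPs.
#' @param ctc_tracks named list of CTC `snp_track`s.
#' @param ... thresholds passed to [score_aberration_in_ctc()].
#' @return list with `status` (aberration x sample character matrix with
#'   values `present` / `absent` / `not_evaluable`) and `details` (long
#'   data.frame of all assessments).
#' @export
rescue_all <- function(catalog, ref_track, ref_segments, ctc_tracks, ...) {
  stopifnot(nrow(catalog) >= 1)
  neutral <- ref_segments[!is.na(ref_segments$klass) &
                            ref_segments$klass == "neutral" &
                            !ref_segments$loh, , drop = FALSE]
  bg_idx <- rep(FALSE, nrow(ref_track))
  for (k in seq_len(nrow(neutral))) {
    bg_idx <- bg_idx | (ref_track$chrom == neutral$chrom[k] &
                          ref_track$pos >= neutral$start[k] &
                          ref_track$pos <= neutral$end[k])
  }
  background <- ref_track[bg_idx, c("chrom", "pos")]
  status <- matrix("not_evaluable", nrow(catalog), length(ctc_tracks),
                   dimnames = list(catalog$aberration_id, names(ctc_tracks)))
  rows <- list()
  for (k in seq_len(nrow(catalog))) {
    for (s in names(ctc_tracks)) {
      a <- score_aberration_in_ctc(catalog[k, ], ref_track, ctc_tracks[[s]],
                                   background, ...)
      status[k, s] <- a$status
      a$aberration_id <- catalog$aberration_id[k]
      a$ctc_sample_id <- s
      rows[[length(rows) + 1L]] <- a
    }
  }
  list(status = status, details = do.call(rbind, rows))
}
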