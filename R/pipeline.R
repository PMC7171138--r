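#' Run the full comparative-genomics pipeline on a cohort
#'
#' Chains every stage of the analysis on a (simulated or file-backed)
#' cohort: tumor-normal somatic post-filtering per tumor sample, low-VAF
#' rescue across tumor samples, the high-confidence CTC rule, ADO and FPR
#' estimation for WGA samples, allele-specific copy-number calling on bulk
#' tumor samples, cross-sample aberration matching, allelic-imbalance rescue
#' of the aberration catalog in CTC pools, status-matrix accounting
#' (recurrence histogram, Venn partition, VAF clustering) and
#' maximum-parsimony phylogeny reconstruction with branch assignment.
#'
#' The false-positive rate is computed on caller-emitted calls (before the
#' hard filters), mirroring its definition as the density of caller events
#' absent from both the primary tumor and the CDX.
#'
#' @param cohort a `ctc_cohort` from [simulate_cohort()].
#' @param policy a [filter_policy()].
#' @param cna_nperm permutations for the segmentation test.
#' @param ratchet_iterations,seed tree-search parameters.
#' @return a list with components `calls`, `hc_ctc`, `ado`, `fpr`, `cna`,
#'   `catalog`, `ctc_rescue`, `status`, `pt_histogram`, `venn`,
#'   `clustering`, `phylogeny`.
#' @export
run_pipeline <- function(cohort, policy = filter_policy(), cna_nperm = 100,
                         ratchet_iterations = 200, seed = 1) {
  samples <- cohort$samples
  tumor_ids <- samples$sample_id[samples$role %in%
                                   c("pt", "ctc", "cdx", "cell_line")]
  pt_ids <- samples$sample_id[samples$role == "pt"]
  ctc_ids <- samples$sample_id[samples$role == "ctc"]
  bulk_ids <- samples$sample_id[samples$role %in% c("pt", "cdx", "cell_line")]
  wga_ids <- samples$sample_id[samples$is_wga]
  obs <- cohort$observations

  ## --- somatic filtering -------------------------------------------------
  filtered <- do.call(rbind, lapply(tumor_ids, function(s) {
    apply_somatic_filters(somatic_candidates(cohort, s), policy)
  }))
  primary <- filtered[filtered$retained, c("variant_id", "sample_id")]

  ## --- low-VAF rescue ----------------------------------------------------
  norm <- obs[obs$sample_id == "germline", ]
  rc <- obs[obs$sample_id %in% tumor_ids,
            c("variant_id", "sample_id", "depth", "alt_count")]
  rc$normal_alt <- norm$alt_count[match(rc$variant_id, norm$variant_id)]
  calls <- rescue_low_vaf(primary, rc, policy, tumor_samples = tumor_ids)

  ## --- high-confidence CTC set (raw per-pool primary calls) --------------
  pt_union <- unique(calls$variant_id[calls$sample_id %in% pt_ids])
  cdx_set <- unique(calls$variant_id[calls$sample_id == "CDX"])
  ctc_primary <- lapply(setNames(ctc_ids, ctc_ids), function(s) {
    primary$variant_id[primary$sample_id == s]
  })
  hc_ctc <- high_confidence_ctc_set(ctc_primary, pt_union, cdx_set)

  ## final call set: bulk calls (incl. rescued) + high-confidence CTC calls
  calls_final <- rbind(
    calls[!(calls$sample_id %in% ctc_ids), c("variant_id", "sample_id")],
    hc_ctc)

  ## --- WGA quality control ----------------------------------------------
  ado <- NULL
  if ("CD45" %in% samples$sample_id && "germline" %in% samples$sample_id) {
    paired <- pair_snp_counts(cohort$snp_counts[["germline"]],
                              cohort$snp_counts[["CD45"]])
    eligible <- select_reliable_germline_variants(paired)
    ado <- estimate_ado(eligible)
  }
  fpr <- do.call(rbind, lapply(wga_ids, function(s) {
    called <- obs$variant_id[obs$sample_id == s & obs$called]
    cbind(sample_id = s,
          estimate_fpr(called, pt_union, cdx_set, cohort$coverage[[s]]))
  }))

  ## --- copy number on bulk tumor samples ---------------------------------
  cna <- lapply(setNames(bulk_ids, bulk_ids), function(s) {
    call_cna(cohort$snp_counts[[s]], cohort$snp_counts[["germline"]],
             nperm = cna_nperm)
  })
  catalog <- match_aberrations(lapply(cna, `[[`, "segments"))

  ## --- allelic-imbalance rescue of the catalog in CTC pools --------------
  ctc_rescue <- NULL
  if (nrow(catalog) && "CDX" %in% bulk_ids && length(ctc_ids)) {
    ctc_tracks <- lapply(setNames(ctc_ids, ctc_ids), function(s) {
      compute_lrr_baf(cohort$snp_counts[[s]], cohort$snp_counts[["germline"]])
    })
    cdx_catalog <- catalog[grepl("CDX", catalog$samples), , drop = FALSE]
    if (nrow(cdx_catalog)) {
      ctc_rescue <- rescue_all(cdx_catalog, cna[["CDX"]]$track,
                               cna[["CDX"]]$segments, ctc_tracks)
    }
  }

  ## --- accounting --------------------------------------------------------
  alterations <- unique(calls_final$variant_id)
  depths <- obs[obs$sample_id %in% tumor_ids,
                c("variant_id", "sample_id", "depth")]
  status <- build_status_matrix(alterations, calls_final, depths, tumor_ids)
  pt_hist <- recurrence_histogram(status, pt_ids)
  groups <- list(PT = pt_ids, CTC = ctc_ids,
                 CDX = intersect(c("CDX", "cell_line"), tumor_ids))
  venn <- venn_partition(status, groups)

  ## per-sample VAF at the identified somatic variants (any supporting read
  ## counts as presence, the readcount-based convention of the method)
  vaf_mat <- matrix(0, length(alterations), length(tumor_ids),
                    dimnames = list(alterations, tumor_ids))
  ok <- obs$sample_id %in% tumor_ids & obs$variant_id %in% alterations &
    obs$alt_count > 0
  vaf_mat[cbind(obs$variant_id[ok], obs$sample_id[ok])] <-
    ifelse(is.na(obs$vaf[ok]), 0, obs$vaf[ok])
  ## cells without sufficient coverage are unknown, not absent
  low <- obs$sample_id %in% tumor_ids & obs$variant_id %in% alterations &
    obs$depth < policy$min_depth & !(obs$alt_count > 0)
  vaf_mat[cbind(obs$variant_id[low], obs$sample_id[low])] <- NA
  clustering <- tryCatch(cluster_samples_by_vaf(vaf_mat),
                         error = function(e) NULL)

  ## --- phylogeny ---------------------------------------------------------
  csq <- cohort$variants$consequence_class[
    match(alterations, cohort$variants$variant_id)]
  cmat <- build_character_matrix(vaf_mat, consequence_class = csq)
  phylo <- NULL; branch <- NULL
  if (nrow(cmat) >= 1 && ncol(cmat) >= 4) {
    phylo <- parsimony_ratchet(cmat, iterations = ratchet_iterations,
                               seed = seed)
    cna_mat <- NULL
    if (nrow(catalog)) {
      cna_mat <- matrix(0L, nrow(catalog), length(tumor_ids),
                        dimnames = list(catalog$aberration_id, tumor_ids))
      for (k in seq_len(nrow(catalog))) {
        carriers <- strsplit(catalog$samples[k], ",")[[1]]
        if (!is.null(ctc_rescue) &&
            catalog$aberration_id[k] %in% rownames(ctc_rescue$status)) {
          st <- ctc_rescue$status[catalog$aberration_id[k], ]
          carriers <- c(carriers, colnames(ctc_rescue$status)[st == "present"])
          ne <- colnames(ctc_rescue$status)[st == "not_evaluable"]
          cna_mat[k, intersect(ne, tumor_ids)] <- NA
        } else if (length(ctc_ids)) {
          ## aberration never screened in CTC pools: unknown there
          cna_mat[k, intersect(ctc_ids, tumor_ids)] <- NA
        }
        cna_mat[k, intersect(carriers, tumor_ids)] <- 1L
      }
    }
    branch <- assign_branch_alterations(phylo, cmat, cna_mat)
  }

  list(calls = calls, filtered = filtered, hc_ctc = hc_ctc,
       calls_final = calls_final, ado = ado, fpr = fpr,
       cna = cna, catalog = catalog, ctc_rescue = ctc_rescue,
       status = status, pt_histogram = pt_hist, venn = venn,
       clustering = clustering, phylogeny = phylo, branches = branch)
}
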