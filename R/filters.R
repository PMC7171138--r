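#' Somatic post-filtering policy
#'
#' Thresholds for tumor-normal somatic variant post-filtering, the low-VAF
#' rescue and the high-confidence CTC rule. Defaults: caller flag `PASS` or
#' `t_lod_fstar`, coverage >= 8 in tumor and matched normal, base-quality sum
#' score (QSS) >= 30, tumor VAF >= 0.05 with >= 5 variant reads, and normal
#' VAF exactly 0. Rescue requires the variant to pass primary filters in at
#' least `rescue_min_samples` tumor samples and to show at least
#' `rescue_min_alt_reads` supporting reads at VAF >= `rescue_min_vaf` (normal
#' still variant-free) in the rescued sample.
#'
#' @param min_depth minimum depth in tumor and normal.
#' @param min_qss minimum QSS.
#' @param min_vaft minimum tumor VAF.
#' @param min_alt_reads minimum variant-supporting reads in the tumor.
#' @param max_vafn maximum normal VAF (0 = any variant read in the normal
#'   rejects the call).
#' @param accepted_flags caller FILTER values accepted.
#' @param rescue_min_samples tumor samples that must pass primary filters
#'   before a variant becomes rescuable elsewhere.
#' @param rescue_min_alt_reads,rescue_min_vaf read support required in the
#'   rescued sample.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(min_depth = 8, min_qss = 30, min_vaft = 0.05,
                          min_alt_reads = 5, max_vafn = 0,
                          accepted_flags = c("PASS", "t_lod_fstar"),
                          rescue_min_samples = 2, rescue_min_alt_reads = 2,
                          rescue_min_vaf = 0.01) {
  p <- list(min_depth = min_depth, min_qss = min_qss, min_vaft = min_vaft,
            min_alt_reads = min_alt_reads, max_vafn = max_vafn,
            accepted_flags = accepted_flags,
            rescue_min_samples = rescue_min_samples,
            rescue_min_alt_reads = rescue_min_alt_reads,
            rescue_min_vaf = rescue_min_vaf)
  num <- unlist(p[c("min_depth", "min_qss", "min_vaft", "min_alt_reads",
                    "max_vafn", "rescue_min_samples", "rescue_min_alt_reads",
                    "rescue_min_vaf")])
  if (any(num < 0)) stop("thresholds must be non-negative")
  structure(p, class = "filter_policy")
}

#' Apply tumor-normal somatic post-filters
#'
#' Evaluates each candidate call against the policy and records, for rejected
#' calls, the first failing rule. Rules are checked in the order: caller
#' blacklist, caller filter flag, coverage in tumor and normal, QSS, tumor
#' VAF, variant-read count, normal contamination. Zero depth in either sample
#' is a rejection with reason `"insufficient_coverage"`, not an error.
#'
#' @param candidates data.frame with one row per candidate call and columns
#'   `variant_id`, `sample_id`, `depth`, `alt_count`, `filter_flag`, `qss`,
#'   `normal_depth`, `normal_alt`, and optionally `caller_blacklist`.
#' @param policy a [filter_policy()].
#' @return the input with logical `retained` and character `reason`
#'   (`NA` for retained calls) columns appended.
#' @export
apply_somatic_filters <- function(candidates, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  need <- c("variant_id", "sample_id", "depth", "alt_count", "filter_flag",
            "qss", "normal_depth", "normal_alt")
  if (!all(need %in% names(candidates)))
    stop("missing columns: ", paste(setdiff(need, names(candidates)), collapse = ", "))
  x <- candidates
  if (is.null(x$caller_blacklist)) x$caller_blacklist <- FALSE

  vaft <- ifelse(x$depth > 0, x$alt_count / x$depth, NA_real_)
  vafn <- ifelse(x$normal_depth > 0, x$normal_alt / x$normal_depth, NA_real_)

  reason <- rep(NA_character_, nrow(x))
  fail <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason <<- ifelse(is.na(reason) & cond, why, reason)
  }
  fail(x$caller_blacklist, "caller_blacklist")
  fail(!(x$filter_flag %in% policy$accepted_flags), "filter_flag")
  fail(x$depth < policy$min_depth | x$normal_depth < policy$min_depth,
       "insufficient_coverage")
  fail(x$qss < policy$min_qss, "low_qss")
  fail(vaft < policy$min_vaft, "low_vaf")
  fail(x$alt_count < policy$min_alt_reads, "insufficient_alt_reads")
  fail(vafn > policy$max_vafn, "normal_support")

  x$retained <- is.na(reason)
  x$reason <- reason
  x
}

#' Rescue low-VAF variants shared across tumor samples
#'
#' A variant that passed primary filters in at least `rescue_min_samples`
#' tumor samples is added to any other tumor sample where it was not called
#' but shows supporting reads (>= `rescue_min_alt_reads` variant reads at
#' VAF >= `rescue_min_vaf`) and remains variant-free in the matched normal.
#' Samples with no read-count entry at the variant are treated as not covered
#' and never rescued.
#'
#' @param calls data.frame of retained primary calls (`variant_id`,
#'   `sample_id`).
#' @param readcounts data.frame of read counts across all tumor samples
#'   (`variant_id`, `sample_id`, `depth`, `alt_count`, `normal_alt`).
#' @param policy a [filter_policy()].
#' @param tumor_samples character vector of sample ids eligible for rescue.
#' @return data.frame of calls augmented with rescued entries; column
#'   `rescued` marks the additions.
#' @export
rescue_low_vaf <- function(calls, readcounts, policy = filter_policy(),
                           tumor_samples = unique(readcounts$sample_id)) {
  stopifnot(inherits(policy, "filter_policy"))
  calls <- unique(calls[c("variant_id", "sample_id")])
  calls$rescued <- FALSE
  n_pass <- table(calls$variant_id)
  shared <- names(n_pass)[n_pass >= policy$rescue_min_samples]
  if (!length(shared)) return(calls)

  rc <- readcounts[readcounts$variant_id %in% shared &
                     readcounts$sample_id %in% tumor_samples, ]
  key <- paste(rc$variant_id, rc$sample_id)
  already <- paste(calls$variant_id, calls$sample_id)
  rc <- rc[!(key %in% already), ]
  vaf <- ifelse(rc$depth > 0, rc$alt_count / rc$depth, 0)
  ok <- rc$alt_count >= policy$rescue_min_alt_reads &
    vaf >= policy$rescue_min_vaf &
    rc$normal_alt <= policy$max_vafn * pmax(rc$depth, 1)
  if (any(ok)) {
    add <- data.frame(variant_id = rc$variant_id[ok],
                      sample_id = rc$sample_id[ok], rescued = TRUE,
                      stringsAsFactors = FALSE)
    calls <- rbind(calls, add)
  }
  calls[order(calls$variant_id, calls$sample_id), ]
}

#' High-confidence CTC variant set
#'
#' A variant called in a CTC pool is kept only when corroborated elsewhere:
#' present in at least one primary-tumor specimen, or in the CDX, or in at
#' least one other CTC pool.
#'
#' @param ctc_calls named list of per-pool variant-id vectors.
#' @param pt_union variant ids called in any PT specimen (post-filter,
#'   including rescued calls).
#' @param cdx_set variant ids called in the CDX.
#' @return data.frame (`variant_id`, `sample_id`) of high-confidence CTC
#'   calls; empty for empty input.
#' @export
high_confidence_ctc_set <- function(ctc_calls, pt_union, cdx_set) {
  if (!length(ctc_calls) || !sum(lengths(ctc_calls))) {
    return(data.frame(variant_id = character(), sample_id = character(),
                      stringsAsFactors = FALSE))
  }
  pools <- names(ctc_calls)
  out <- lapply(pools, function(p) {
    v <- unique(ctc_calls[[p]])
    other <- unique(unlist(ctc_calls[setdiff(pools, p)]))
    keep <- v[v %in% pt_union | v %in% cdx_set | v %in% other]
    if (!length(keep)) return(NULL)
    data.frame(variant_id = keep, sample_id = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(variant_id = character(),
                                      sample_id = character(),
                                      stringsAsFactors = FALSE)
  res
}

#' Build the somatic-candidate table for one tumor sample of a cohort
#'
#' Joins the tumor sample's caller output with the matched germline read
#' counts, yielding the input expected by [apply_somatic_filters()].
#'
#' @param cohort a `ctc_cohort` from [simulate_cohort()] (or an object with
#'   the same `observations` layout).
#' @param sample_id tumor sample to extract.
#' @param normal_id matched normal sample (default `"germline"`).
#' @param called_only keep caller-emitted candidates only (default) or all
#'   sites.
#' @return candidate data.frame.
#' @export
somatic_candidates <- function(cohort, sample_id, normal_id = "germline",
                               called_only = TRUE) {
  obs <- cohort$observations
  t <- obs[obs$sample_id == sample_id, ]
  n <- obs[obs$sample_id == normal_id, ]
  if (called_only) t <- t[t$called, ]
  i <- match(t$variant_id, n$variant_id)
  data.frame(variant_id = t$variant_id, sample_id = sample_id,
             depth = t$depth, alt_count = t$alt_count,
             filter_flag = t$filter_flag, qss = t$qss,
             caller_blacklist = t$caller_blacklist,
             normal_depth = n$depth[i], normal_alt = n$alt_count[i],
             stringsAsFactors = FALSE)
}
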