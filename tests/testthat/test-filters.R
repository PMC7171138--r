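boundary_candidate <- function(...) {
  base <- data.frame(variant_id = "v1", sample_id = "T",
                     depth = 100, alt_count = 5, filter_flag = "PASS",
                     qss = 30, caller_blacklist = FALSE,
                     normal_depth = 100, normal_alt = 0,
                     stringsAsFactors = FALSE)
  mod <- list(...)
  for (n in names(mod)) base[[n]] <- mod[[n]]
  base
}

test_that("all filter boundaries are inclusive and normal support is fatal", {
  ## exactly at every threshold: retained
  f <- apply_somatic_filters(boundary_candidate())
  expect_true(f$retained)
  ## 5 alt reads of 100 is VAF 0.05: the VAF rule is satisfied at equality
  expect_true(apply_somatic_filters(boundary_candidate(depth = 8,
    alt_count = 5, normal_depth = 8))$retained)
  ## one variant read in the normal rejects (VAFN must be exactly 0)
  f2 <- apply_somatic_filters(boundary_candidate(normal_alt = 1))
  expect_false(f2$retained)
  expect_equal(f2$reason, "normal_support")
  ## just below each threshold: rejected with the first failing rule
  expect_equal(apply_somatic_filters(boundary_candidate(depth = 7))$reason,
               "insufficient_coverage")
  expect_equal(apply_somatic_filters(boundary_candidate(normal_depth = 0))$reason,
               "insufficient_coverage")
  expect_equal(apply_somatic_filters(boundary_candidate(qss = 29))$reason,
               "low_qss")
  expect_equal(apply_somatic_filters(boundary_candidate(alt_count = 4))$reason,
               "low_vaf")
  expect_equal(apply_somatic_filters(boundary_candidate(alt_count = 4,
               depth = 50))$reason, "insufficient_alt_reads")
  expect_equal(apply_somatic_filters(boundary_candidate(
    filter_flag = "clustered_events"))$reason, "filter_flag")
  expect_equal(apply_somatic_filters(boundary_candidate(
    caller_blacklist = TRUE))$reason, "caller_blacklist")
})

test_that("filter decisions equal the independent rule-by-rule oracle", {
  pol <- filter_policy()
  cand <- random_candidates(500, seed = 12)
  got <- apply_somatic_filters(cand, pol)$retained
  want <- vapply(seq_len(nrow(cand)), function(i) {
    oracle_filter_one(cand[i, ], pol)
  }, logical(1))
  expect_equal(got, want)
})

test_that("filtering is idempotent and monotone in the thresholds", {
  cand <- random_candidates(400, seed = 3)
  f1 <- apply_somatic_filters(cand)
  kept <- f1[f1$retained, names(cand)]
  f2 <- apply_somatic_filters(kept)
  expect_true(all(f2$retained))
  ## tightening any threshold never enlarges the retained set
  tighter <- list(filter_policy(min_depth = 20), filter_policy(min_qss = 45),
                  filter_policy(min_vaft = 0.15),
                  filter_policy(min_alt_reads = 10),
                  filter_policy(accepted_flags = "PASS"))
  for (pol in tighter) {
    f3 <- apply_somatic_filters(cand, pol)
    expect_true(all(f3$variant_id[f3$retained] %in% f1$variant_id[f1$retained]))
  }
})

test_that("low-VAF rescue requires multi-sample support and read evidence", {
  calls <- data.frame(variant_id = c("v1", "v1", "v2"),
                      sample_id = c("PT_1", "PT_2", "PT_1"),
                      stringsAsFactors = FALSE)
  rc <- data.frame(
    variant_id = c("v1", "v1", "v1", "v1", "v2", "v2"),
    sample_id = c("PT_1", "PT_2", "CDX", "PT_3", "CDX", "PT_2"),
    depth = c(100, 100, 100, 100, 100, 100),
    alt_count = c(30, 20, 3, 1, 8, 0),
    normal_alt = 0, stringsAsFactors = FALSE)
  out <- rescue_low_vaf(calls, rc)
  ## v1 passes in two samples; 3 reads at VAF 0.03 in the CDX rescue it there
  expect_true(any(out$variant_id == "v1" & out$sample_id == "CDX" & out$rescued))
  ## 1 supporting read is below the rescue support threshold
  expect_false(any(out$variant_id == "v1" & out$sample_id == "PT_3"))
  ## v2 passes in a single sample: never rescued despite 8 reads in the CDX
  expect_false(any(out$variant_id == "v2" & out$sample_id == "CDX"))
  ## a variant with alt reads in the matched normal is not rescued
  rc2 <- rc; rc2$normal_alt[3] <- 2
  out2 <- rescue_low_vaf(calls, rc2)
  expect_false(any(out2$variant_id == "v1" & out2$sample_id == "CDX"))
  ## samples with no readcount entry are never rescued
  out3 <- rescue_low_vaf(calls, rc[-3, ])
  expect_false(any(out3$sample_id == "CDX"))
})

test_that("rescue is a no-op on a cohort without shared variants", {
  calls <- data.frame(variant_id = c("v1", "v2"), sample_id = c("A", "B"),
                      stringsAsFactors = FALSE)
  rc <- data.frame(variant_id = c("v1", "v2"), sample_id = c("B", "A"),
                   depth = 50, alt_count = 10, normal_alt = 0,
                   stringsAsFactors = FALSE)
  out <- rescue_low_vaf(calls, rc)
  expect_equal(sum(out$rescued), 0)
  expect_equal(nrow(out), 2)
})

test_that("the high-confidence CTC rule requires corroboration", {
  pools <- list(CTC_1 = c("a", "b", "c"), CTC_2 = c("b", "d"),
                CTC_3 = character(0))
  hc <- high_confidence_ctc_set(pools, pt_union = "c", cdx_set = "d")
  ## "a": one pool, nowhere else -> excluded
  expect_false("a" %in% hc$variant_id)
  ## "b": two CTC pools only -> included in both
  expect_equal(sort(hc$sample_id[hc$variant_id == "b"]), c("CTC_1", "CTC_2"))
  ## "c": PT-backed; "d": CDX-backed
  expect_true(all(c("c", "d") %in% hc$variant_id))
  ## empty input -> empty set
  expect_equal(nrow(high_confidence_ctc_set(list(), "c", "d")), 0)
})

test_that("high-confidence filtering removes private WGA false positives on a simulated cohort", {
  coh <- small_cohort()
  ctc_ids <- coh$samples$sample_id[coh$samples$role == "ctc"]
  primary <- lapply(setNames(ctc_ids, ctc_ids), function(s) {
    f <- apply_somatic_filters(somatic_candidates(coh, s))
    f$variant_id[f$retained]
  })
  tr <- coh$truth$per_variant_truth
  fp_of <- function(ids, s) {
    sum(ids %in% tr$variant_id[tr$sample_id == s & tr$false_positive])
  }
  pt_ids <- coh$samples$sample_id[coh$samples$role == "pt"]
  pt_union <- unique(unlist(lapply(pt_ids, function(s) {
    f <- apply_somatic_filters(somatic_candidates(coh, s))
    f$variant_id[f$retained]
  })))
  cdx <- apply_somatic_filters(somatic_candidates(coh, "CDX"))
  hc <- high_confidence_ctc_set(primary, pt_union,
                                cdx$variant_id[cdx$retained])
  fp_before <- sum(vapply(ctc_ids, function(s) fp_of(primary[[s]], s),
                          numeric(1)))
  fp_after <- sum(vapply(ctc_ids, function(s) {
    fp_of(hc$variant_id[hc$sample_id == s], s)
  }, numeric(1)))
  expect_gt(fp_before, 0)
  expect_lt(fp_after, fp_before)
  ## true branch variants carried by the CTC lineage are retained
  ctc_branch <- coh$variants$variant_id[!is.na(coh$variants$branch) &
                                          coh$variants$branch == "ctc"]
  recovered <- mean(ctc_branch %in% hc$variant_id)
  expect_gt(recovered, 0.8)
})
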