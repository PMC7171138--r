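# Build a status matrix realizing a chosen per-alteration sample pattern.
pattern_matrix <- function(patterns, samples) {
  m <- matrix("not_mutated", length(patterns), length(samples),
              dimnames = list(names(patterns), samples))
  for (a in names(patterns)) m[a, patterns[[a]]] <- "mutated"
  class(m) <- c("status_matrix", class(m))
  m
}

test_that("status cells distinguish mutated, absent and not covered", {
  calls <- data.frame(variant_id = "v1", sample_id = "A",
                      stringsAsFactors = FALSE)
  depths <- data.frame(variant_id = c("v1", "v1", "v2", "v2"),
                       sample_id = c("A", "B", "A", "B"),
                       depth = c(50, 7, 100, 100))
  m <- build_status_matrix(c("v1", "v2"), calls, depths, c("A", "B"))
  expect_equal(m["v1", "A"], "mutated")
  expect_equal(m["v1", "B"], "not_covered")
  expect_equal(m["v2", "A"], "not_mutated")
  ## a cell with no depth entry at all counts as not covered
  m2 <- build_status_matrix(c("v1", "v2"), calls, depths[-4, ], c("A", "B"))
  expect_equal(m2["v2", "B"], "not_covered")
})

test_that("the recurrence histogram reproduces printed-style PT accounting", {
  ## eight specimens; 153 private mutations, 27 in two, 9 in three, 8 in
  ## four, 5 in five, 2 in six, 1 in seven
  pts <- paste0("PT_", 1:8)
  counts <- c(153, 27, 9, 8, 5, 2, 1)
  patterns <- list()
  for (k in seq_along(counts)) {
    for (i in seq_len(counts[k])) {
      patterns[[sprintf("m_%d_%d", k, i)]] <- pts[seq_len(k)]
    }
  }
  m <- pattern_matrix(patterns, pts)
  h <- recurrence_histogram(m)
  expect_equal(unname(h$histogram), c(153, 27, 9, 8, 5, 2, 1, 0))
  expect_equal(h$total, 205)
  ## 153 of 205 detected in a single specimen: 75% after half-up rounding
  expect_equal(floor(100 * h$histogram[["1"]] / h$total + 0.5), 75)
})

test_that("recurrence counts equal a brute-force per-row oracle", {
  set.seed(13)
  samples <- paste0("s", 1:6)
  m <- matrix(sample(c("mutated", "not_mutated", "not_covered"), 300, TRUE,
                     prob = c(.4, .4, .2)), 50, 6,
              dimnames = list(paste0("v", 1:50), samples))
  h <- recurrence_histogram(m, samples)
  k <- apply(m, 1, function(r) sum(r == "mutated"))
  expect_equal(unname(h$histogram),
               vapply(1:6, function(i) sum(k == i), integer(1)))
  expect_equal(h$total, sum(k > 0))
  ## empty matrix: all-zero histogram
  e <- recurrence_histogram(m[0, , drop = FALSE], samples)
  expect_equal(sum(e$histogram), 0)
  expect_equal(e$total, 0)
})

test_that("venn partition reproduces the PT/CTC/CDX worked example", {
  pts <- paste0("PT_", 1:8); ctcs <- paste0("CTC_", 1:6)
  cdx <- c("CDX", "cell_line")
  patterns <- c(
    setNames(replicate(172, "PT_1", simplify = FALSE),
             paste0("ptonly", 1:172)),
    setNames(replicate(32, c("PT_1", "CDX", "cell_line"), simplify = FALSE),
             paste0("ptcdx", 1:32)),
    list(ptctc = c("PT_2", "CTC_1")))
  m <- pattern_matrix(patterns, c(pts, ctcs, cdx))
  v <- venn_partition(m, list(PT = pts, CTC = ctcs, CDX = cdx),
                      denominator = 205)
  r <- setNames(v$regions$count, v$regions$region)
  expect_equal(unname(r["PT"]), 172)
  expect_equal(unname(r["PT&CDX"]), 32)
  expect_equal(unname(r["PT&CTC"]), 1)
  expect_equal(v$universe, 205)
  expect_equal(v$regions$percent[v$regions$region == "PT&CDX"], 16)
})

test_that("venn partition reproduces the CTC-universe percentages", {
  ## 62 CTC variants: 24 shared with PT and CDX, 1 with PT only, 11 with
  ## CDX only, 26 private
  pts <- "PT_1"; ctcs <- "CTC_1"; cdx <- "CDX"
  mk <- function(n, grp) setNames(replicate(n, grp, simplify = FALSE),
                                  paste0(paste(grp, collapse = ""), 1:n))
  patterns <- c(mk(24, c("CTC_1", "PT_1", "CDX")), mk(1, c("CTC_1", "PT_1")),
                mk(11, c("CTC_1", "CDX")), mk(26, "CTC_1"))
  m <- pattern_matrix(patterns, c(pts, ctcs, cdx))
  v <- venn_partition(m, list(PT = pts, CTC = ctcs, CDX = cdx),
                      denominator = 62)
  r <- setNames(v$regions$count, v$regions$region)
  pct <- function(n) floor(100 * n / 62 + 0.5)
  ## 25/62 from PT (40%), 35/62 in the CDX (56%), 24/62 in both (39%)
  expect_equal(pct(r[["PT&CTC&CDX"]] + r[["PT&CTC"]]), 40)
  expect_equal(pct(r[["PT&CTC&CDX"]] + r[["CTC&CDX"]]), 56)
  expect_equal(pct(r[["PT&CTC&CDX"]]), 39)
  expect_equal(v$universe, 62)
})

test_that("partition completeness holds and not-covered cells never flip it", {
  set.seed(14)
  samples <- paste0("s", 1:9)
  groups <- list(G1 = samples[1:3], G2 = samples[4:6], G3 = samples[7:9])
  m <- matrix(sample(c("mutated", "not_mutated", "not_covered"), 60 * 9, TRUE,
                     prob = c(.3, .5, .2)), 60, 9,
              dimnames = list(paste0("v", 1:60), samples))
  v <- suppressWarnings(venn_partition(m, groups))
  expect_equal(sum(v$regions$count), v$universe)
  ## replacing every not_covered cell by not_mutated leaves regions intact
  m2 <- m; m2[m2 == "not_covered"] <- "not_mutated"
  v2 <- suppressWarnings(venn_partition(m2, groups))
  expect_equal(v$regions, v2$regions)
  ## single-group matrix: one region holding everything present
  v3 <- suppressWarnings(venn_partition(m, list(ALL = samples)))
  expect_equal(v3$regions$region, "ALL")
  expect_equal(v3$regions$count, v3$universe)
})

test_that("cosine distances match a direct computation and degenerate input errors", {
  set.seed(15)
  v <- matrix(runif(60), 15, 4, dimnames = list(NULL, paste0("s", 1:4)))
  v[v < 0.3] <- 0
  cl <- cluster_samples_by_vaf(v, min_samples = 1)
  ## independent cosine computation, pairwise loops
  d <- as.matrix(cl$dist)
  for (i in 1:3) for (j in (i + 1):4) {
    want <- 1 - sum(v[, i] * v[, j]) /
      (sqrt(sum(v[, i]^2)) * sqrt(sum(v[, j]^2)))
    expect_equal(d[i, j], want, tolerance = 1e-12)
  }
  ## identical samples sit at zero cosine distance
  v2 <- cbind(v, s5 = v[, 1] * 2)   # proportional = same direction
  d2 <- as.matrix(cluster_samples_by_vaf(v2, min_samples = 1)$dist)
  expect_equal(d2["s1", "s5"], 0, tolerance = 1e-12)
  ## constant matrix: explicit error
  expect_error(cluster_samples_by_vaf(
    matrix(0.3, 5, 3, dimnames = list(NULL, c("a", "b", "c"))),
    min_samples = 1), "degenerate")
})

test_that("tumor samples cluster by lineage on a simulated cohort", {
  pp <- default_pipeline()
  cl <- pp$clustering
  expect_false(is.null(cl))
  ## cutting the dendrogram in two separates PT specimens from the
  ## CTC/CDX/cell-line lineage
  grp <- stats::cutree(cl$tree, k = 2)
  pt <- grp[grepl("^PT_", names(grp))]
  other <- grp[!grepl("^PT_", names(grp))]
  expect_equal(length(unique(pt)), 1)
  expect_equal(length(unique(other)), 1)
  expect_false(unique(pt) == unique(other))
})

test_that("aberration matching groups reciprocal-overlap segments across samples", {
  segs_a <- data.frame(chrom = c("chr1", "chr2"), start = c(10e6, 1e6),
                       end = c(50e6, 30e6), klass = c("loss", "gain"),
                       minor_cn = c(0, 1), loh = c(TRUE, FALSE))
  segs_b <- data.frame(chrom = c("chr1", "chr3"), start = c(12e6, 1e6),
                       end = c(48e6, 20e6), klass = c("loss", "loss"),
                       minor_cn = c(0, 0), loh = TRUE)
  cat <- match_aberrations(list(A = segs_a, B = segs_b))
  expect_equal(nrow(cat), 3)
  shared <- cat[cat$chrom == "chr1", ]
  expect_equal(shared$n_samples, 2)
  expect_equal(shared$samples, "A,B")
  ## same interval, opposite class: never merged
  segs_c <- data.frame(chrom = "chr1", start = 10e6, end = 50e6,
                       klass = "gain", minor_cn = 1, loh = FALSE)
  cat2 <- match_aberrations(list(A = segs_a, C = segs_c))
  expect_equal(sum(cat2$chrom == "chr1"), 2)
})
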