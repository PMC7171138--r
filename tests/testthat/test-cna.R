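# Closed-form expectations for a tumor/normal mixture: total copy c at
# purity p against a diploid normal, baseline copy c0 at LRR 0.
expected_lrr <- function(c, p, c0 = 2) {
  log2((p * c + 2 * (1 - p)) / (p * c0 + 2 * (1 - p)))
}
expected_mbaf <- function(M, m, p) {
  (p * M + (1 - p)) / (p * (M + m) + 2 * (1 - p))
}

# Synthetic SNP count tables with a known copy-number profile.
sim_pair <- function(n, cn_major, cn_minor, purity, depth = 200, seed = 1) {
  set.seed(seed)
  stopifnot(length(cn_major) == n, length(cn_minor) == n)
  tot <- purity * (cn_major + cn_minor) + 2 * (1 - purity)
  phase <- runif(n) < 0.5
  altc <- ifelse(phase, cn_major, cn_minor)
  baf <- (purity * altc + (1 - purity)) / tot
  nd <- rnbinom(n, mu = depth, size = 50) + 10
  td <- rnbinom(n, mu = depth * tot / 2, size = 50) + 1
  ta <- rbinom(n, td, baf)
  na <- rbinom(n, nd, 0.5)
  pos <- sort(sample.int(2e8, n))
  list(tumor = data.frame(chrom = "chr1", pos = pos, ref_count = td - ta,
                          alt_count = ta),
       normal = data.frame(chrom = "chr1", pos = pos, ref_count = nd - na,
                           alt_count = na))
}

test_that("LRR is zero and BAF balanced when tumor equals normal", {
  pr <- sim_pair(500, rep(1, 500), rep(1, 500), purity = 1, seed = 2)
  track <- compute_lrr_baf(pr$tumor, pr$normal)
  expect_lt(abs(mean(track$lrr)), 0.02)
  expect_lt(abs(mean(track$baf) - 0.5), 0.01)
  expect_lt(abs(median(track$lrr)), 0.02)
})

test_that("homozygous SNPs and zero-depth normals are excluded", {
  tumor <- data.frame(chrom = "chr1", pos = 1:4 * 100,
                      ref_count = c(50, 50, 50, 50),
                      alt_count = c(50, 0, 100, 50))
  normal <- data.frame(chrom = "chr1", pos = 1:4 * 100,
                       ref_count = c(100, 100, 0, 0),
                       alt_count = c(100, 5, 100, 0))
  track <- compute_lrr_baf(tumor, normal)
  ## kept: only pos 100 (het). pos 200 hom-ref, pos 300 hom-alt, pos 400
  ## zero normal depth
  expect_equal(track$pos, 100)
})

test_that("a clonal one-copy loss shows the closed-form LRR and mirrored BAF", {
  ## 20% of the chromosome deleted (CN 1+0), purity 1
  n <- 1000
  M <- rep(1, n); m <- rep(1, n)
  M[401:600] <- 1; m[401:600] <- 0
  pr <- sim_pair(n, M, m, purity = 1, seed = 3)
  track <- compute_lrr_baf(pr$tumor, pr$normal)
  idx <- track$pos >= pr$tumor$pos[401] & track$pos <= pr$tumor$pos[600]
  expect_lt(abs(mean(track$lrr[idx]) - log2(0.5)), 0.1)
  expect_gt(mean(mirrored_baf(track$baf[idx])), 0.95)
})

test_that("CBS finds no breakpoints in constant signal", {
  set.seed(4)
  x <- rnorm(300, sd = 0.1)
  track <- data.frame(chrom = rep(c("chrA", "chrB"), each = 150),
                      pos = rep(1:150 * 1e5, 2), lrr = x, baf = 0.5)
  segs <- segment_genome(track, nperm = 100)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_snps, c(150, 150))
})

test_that("segments tile every chromosome without gap or overlap", {
  coh <- small_cohort()
  track <- compute_lrr_baf(coh$snp_counts[["CDX"]], coh$snp_counts[["germline"]])
  set.seed(5)
  segs <- segment_genome(track)
  for (ch in unique(track$chrom)) {
    s <- segs[segs$chrom == ch, ]
    t <- track[track$chrom == ch, ]
    expect_equal(s$start[1], min(t$pos))
    expect_equal(s$end[nrow(s)], max(t$pos))
    expect_equal(sum(s$n_snps), nrow(t))
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
})

test_that("the ploidy/purity lattice fit recovers a clean diploid with losses", {
  ## 10 segments; two of them one-copy losses, purity 0.7
  p <- 0.7
  segs <- data.frame(
    chrom = paste0("chr", 1:10), start = 1, end = 30e6, n_snps = 200,
    mean_lrr = expected_lrr(c(2, 2, 1, 2, 2, 1, 2, 2, 2, 2), p),
    mean_mbaf = expected_mbaf(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                              c(1, 1, 0, 1, 1, 0, 1, 1, 1, 1), p))
  set.seed(6)
  segs$mean_lrr <- segs$mean_lrr + rnorm(10, sd = 0.02)
  segs$mean_mbaf <- segs$mean_mbaf + rnorm(10, sd = 0.01)
  fit <- fit_ploidy_purity(segs)
  expect_equal(fit$fit$ploidy, 2)
  expect_lt(abs(fit$fit$purity - p), 0.05)
  expect_false(fit$fit$wgd_flag)
  expect_equal(fit$segments$total_cn, c(2, 2, 1, 2, 2, 1, 2, 2, 2, 2))
  expect_equal(fit$segments$minor_cn[3], 0)
})

test_that("a genome-doubled sample is fitted as tetraploid with the WGD flag", {
  p <- 0.9
  major <- c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  minor <- c(2, 2, 1, 2, 2, 0, 2, 2, 1, 2)   # post-WGD single-copy losses
  segs <- data.frame(
    chrom = paste0("chr", 1:10), start = 1, end = 30e6, n_snps = 200,
    mean_lrr = expected_lrr(major + minor, p, c0 = 4),
    mean_mbaf = expected_mbaf(major, minor, p))
  set.seed(7)
  segs$mean_lrr <- segs$mean_lrr + rnorm(10, sd = 0.02)
  segs$mean_mbaf <- segs$mean_mbaf + rnorm(10, sd = 0.01)
  fit <- fit_ploidy_purity(segs)
  expect_equal(fit$fit$ploidy, 4)
  expect_true(fit$fit$wgd_flag)
  expect_lt(abs(fit$fit$purity - p), 0.05)
  expect_equal(fit$segments$total_cn, major + minor)
})

test_that("invalid purity grids are rejected", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 1e6, n_snps = 50,
                     mean_lrr = 0, mean_mbaf = 0.55)
  expect_error(fit_ploidy_purity(segs, purity_grid = c(0, 0.5)), "positive")
})

test_that("ploidy-relative classification matches its threshold definition exactly", {
  ## exhaustive oracle over CN 0..8 x ploidy {1.5, 2, 3, 4} x minor 0..cn/2
  grid <- expand.grid(cn = 0:8, ploidy = c(1.5, 2, 3, 4))
  for (i in seq_len(nrow(grid))) {
    cn <- grid$cn[i]; pl <- grid$ploidy[i]
    for (minor in 0:floor(cn / 2)) {
      seg <- data.frame(total_cn = cn, minor_cn = minor)
      got <- classify_segments(seg, data.frame(ploidy = pl))
      want <- if (cn < 0.5) "homozygous_deletion"
        else if (cn > pl + 2) "high_amp"
        else if (cn > pl + 0.5) "gain"
        else if (cn < pl - 0.5) "loss"
        else "neutral"
      expect_equal(got$klass, want,
                   info = sprintf("cn=%d ploidy=%.1f", cn, pl))
      expect_equal(got$loh, minor == 0)
    }
  }
  ## the quoted examples: ploidy 2 CN 3 is a gain; ploidy 4 CN 3 is a loss;
  ## CN (2,0) at ploidy 2 is copy-neutral LOH
  expect_equal(classify_segments(data.frame(total_cn = 3, minor_cn = 1),
                                 data.frame(ploidy = 2))$klass, "gain")
  expect_equal(classify_segments(data.frame(total_cn = 3, minor_cn = 1),
                                 data.frame(ploidy = 4))$klass, "loss")
  got <- classify_segments(data.frame(total_cn = 2, minor_cn = 0),
                           data.frame(ploidy = 2))
  expect_equal(got$klass, "neutral")
  expect_true(got$loh)
})
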