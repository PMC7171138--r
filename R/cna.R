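#' Compute per-SNP coverage log-ratio and B-allele frequency
#'
#' At each germline-heterozygous SNP shared by tumor and normal, the coverage
#' log-ratio is `log2((tumor depth / tumor median depth) / (normal depth /
#' normal median depth))` and the BAF is the alternate-read fraction in the
#' tumor. Heterozygosity is determined from the normal sample (VAF within
#' `het_band` at depth >= `min_normal_depth`); homozygous SNPs are excluded,
#' and SNPs with zero normal depth are skipped.
#'
#' @param tumor,normal per-SNP count tables (`chrom`, `pos`, `ref_count`,
#'   `alt_count`).
#' @param het_band normal-VAF interval defining heterozygous SNPs.
#' @param min_normal_depth minimum normal depth for genotyping.
#' @return a `snp_track` data.frame: `chrom`, `pos`, `lrr`, `baf`, `depth`.
#' @export
compute_lrr_baf <- function(tumor, normal, het_band = c(0.2, 0.8),
                            min_normal_depth = 8) {
  m <- merge(tumor, normal, by = c("chrom", "pos"), suffixes = c("_t", "_n"))
  td <- m$ref_count_t + m$alt_count_t
  nd <- m$ref_count_n + m$alt_count_n
  keep <- nd > 0
  m <- m[keep, ]; td <- td[keep]; nd <- nd[keep]
  nvaf <- m$alt_count_n / nd
  het <- nd >= min_normal_depth & nvaf >= het_band[1] & nvaf <= het_band[2]
  m <- m[het, ]; td <- td[het]; nd <- nd[het]
  if (!nrow(m)) stop("no heterozygous SNPs shared by tumor and normal")
  lrr <- log2((pmax(td, 0.5) / median(td)) / (nd / median(nd)))
  baf <- ifelse(td > 0, m$alt_count_t / td, NA_real_)
  out <- data.frame(chrom = m$chrom, pos = m$pos, lrr = lrr, baf = baf,
                    depth = td, stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(tumor$chrom)), out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("snp_track", "data.frame")
  out
}

#' Mirrored B-allele frequency
#'
#' Folds BAF about 0.5 (`|baf - 0.5| + 0.5`), the standard transform for
#' segmenting allelic imbalance irrespective of which haplotype is affected.
#'
#' @param baf numeric vector in \[0, 1\].
#' @return numeric vector in \[0.5, 1\].
#' @export
mirrored_baf <- function(baf) abs(baf - 0.5) + 0.5

## ---- circular binary segmentation --------------------------------------

# Best circular arc (i, j]: maximizes the two-sample mean-shift t statistic
# between the arc and its complement. Returns NULL when no admissible arc.
.arc_max <- function(x, min_width) {
  n <- length(x)
  if (n < 2L * min_width) return(NULL)
  S <- c(0, cumsum(x))
  tot <- S[n + 1L]
  idx <- 0:n
  D <- outer(S, S, "-")       # D[a, b] = sum over (b-1, a-1]
  W <- outer(idx, idx, "-")
  ok <- W >= min_width & W <= (n - min_width)
  if (!any(ok)) return(NULL)
  Wc <- pmin(pmax(W, 1L), n - 1L)    # clamp masked entries to a valid width
  Z <- abs(D / Wc - (tot - D) / (n - Wc)) / sqrt(1 / Wc + 1 / (n - Wc))
  Z[!ok] <- -Inf
  k <- which.max(Z)
  a <- (k - 1L) %% (n + 1L) + 1L
  b <- (k - 1L) %/% (n + 1L) + 1L
  list(i = b - 1L, j = a - 1L, stat = Z[k])    # arc = (i+1):j
}

# Permutation p-value for the best arc, with early stopping once significance
# is no longer attainable.
.arc_signif <- function(x, obs_stat, alpha, nperm, min_width) {
  limit <- floor(alpha * (nperm + 1)) - 1     # max exceedances allowed
  if (limit < 0) return(FALSE)
  exceed <- 0L
  for (b in seq_len(nperm)) {
    st <- .arc_max(sample(x), min_width)
    if (!is.null(st) && st$stat >= obs_stat) {
      exceed <- exceed + 1L
      if (exceed > limit) return(FALSE)
    }
  }
  (1 + exceed) / (1 + nperm) <= alpha
}

#' Circular binary segmentation of a single signal
#'
#' Recursive changepoint detection: the best circular arc of the signal is
#' found by maximizing the mean-shift t statistic over all arcs, its
#' significance is assessed by permutation, and significant splits are
#' recursed into. The signal is standardized by a robust noise estimate
#' (median absolute difference of successive values) so that permutation and
#' statistic are scale-free.
#'
#' @param x numeric signal ordered along the genome.
#' @param alpha significance level for accepting a split.
#' @param nperm number of permutations.
#' @param min_width minimum number of markers per segment.
#' @return integer vector of breakpoints (indices after which a segment
#'   ends), excluding the final index; empty when no change is found.
#' @export
cbs_breakpoints <- function(x, alpha = 0.01, nperm = 100, min_width = 10) {
  stopifnot(nperm >= 1, alpha > 0)
  x <- as.numeric(x)
  noise <- mad(diff(x)) / sqrt(2)
  if (!is.finite(noise) || noise == 0) noise <- sd(x)
  if (!is.finite(noise) || noise == 0) return(integer(0))
  z <- x / noise
  recurse <- function(lo, hi) {
    seg <- z[lo:hi]
    best <- .arc_max(seg, min_width)
    if (is.null(best)) return(integer(0))
    if (!.arc_signif(seg, best$stat, alpha, nperm, min_width))
      return(integer(0))
    cuts <- integer(0)
    if (best$i > 0L) cuts <- c(cuts, lo + best$i - 1L)
    if (best$j < length(seg)) cuts <- c(cuts, lo + best$j - 1L)
    bounds <- c(lo - 1L, cuts, hi)
    out <- cuts
    for (k in seq_len(length(bounds) - 1L)) {
      out <- c(out, recurse(bounds[k] + 1L, bounds[k + 1L]))
    }
    sort(unique(out))
  }
  recurse(1L, length(z))
}

#' Segment a SNP track into homogeneous copy-number segments
#'
#' Runs circular binary segmentation per chromosome on the coverage
#' log-ratio and on the mirrored BAF, takes the union of the two breakpoint
#' sets, and merges adjacent segments whose mean LRR and mean mirrored BAF
#' are indistinguishable. Chromosomes with fewer than `2 * min_width` SNPs
#' are returned as single segments. Segments partition the covered SNPs of
#' each chromosome.
#'
#' @param track a `snp_track` from [compute_lrr_baf()].
#' @param alpha,nperm,min_width CBS parameters (see [cbs_breakpoints()]).
#' @param merge_lrr,merge_mbaf adjacent segments are merged when their mean
#'   LRR differs by less than `merge_lrr` and mean mirrored BAF by less than
#'   `merge_mbaf`.
#' @param use_baf segment the mirrored BAF as well as the LRR (union of
#'   breakpoints); set `FALSE` for LRR-only segmentation.
#' @return data.frame of segments: `chrom`, `start`, `end` (1-based
#'   inclusive SNP span), `n_snps`, `mean_lrr`, `mean_mbaf`.
#' @export
segment_genome <- function(track, alpha = 0.01, nperm = 100, min_width = 10,
                           merge_lrr = 0.1, merge_mbaf = 0.05,
                           use_baf = TRUE) {
  stopifnot(all(c("chrom", "pos", "lrr", "baf") %in% names(track)))
  segs <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$pos), ]
    n <- nrow(t)
    bp <- integer(0)
    if (n >= 2 * min_width) {
      bp <- cbs_breakpoints(t$lrr, alpha, nperm, min_width)
      if (use_baf) {
        ok <- !is.na(t$baf)
        if (sum(ok) >= 2 * min_width) {
          bp_b <- cbs_breakpoints(mirrored_baf(t$baf[ok]), alpha, nperm,
                                  min_width)
          bp <- sort(unique(c(bp, which(ok)[bp_b])))
        }
      }
    }
    bounds <- c(0L, bp, n)
    lrr_sd <- mad(diff(t$lrr)) / sqrt(2)        # per-SNP noise, robust
    for (k in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = t$pos[idx[1L]], end = t$pos[idx[length(idx)]],
        n_snps = length(idx), mean_lrr = mean(t$lrr[idx]),
        mean_mbaf = mean(mirrored_baf(t$baf[idx]), na.rm = TRUE),
        mean_depth = if ("depth" %in% names(t)) mean(t$depth[idx]) else NA,
        lrr_sd = lrr_sd,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  ## merge indistinguishable neighbours within chromosomes
  merged <- list()
  for (ch in unique(out$chrom)) {
    s <- out[out$chrom == ch, ]
    acc <- s[1L, ]
    if (nrow(s) > 1L) for (k in 2:nrow(s)) {
      same <- abs(s$mean_lrr[k] - acc$mean_lrr[nrow(acc)]) < merge_lrr &&
        abs(s$mean_mbaf[k] - acc$mean_mbaf[nrow(acc)]) < merge_mbaf
      if (same) {
        i <- nrow(acc)
        w <- c(acc$n_snps[i], s$n_snps[k])
        acc$end[i] <- s$end[k]
        acc$mean_lrr[i] <- sum(w * c(acc$mean_lrr[i], s$mean_lrr[k])) / sum(w)
        acc$mean_mbaf[i] <- sum(w * c(acc$mean_mbaf[i], s$mean_mbaf[k])) / sum(w)
        acc$mean_depth[i] <- sum(w * c(acc$mean_depth[i], s$mean_depth[k])) / sum(w)
        acc$lrr_sd[i] <- sum(w * c(acc$lrr_sd[i], s$lrr_sd[k])) / sum(w)
        acc$n_snps[i] <- sum(w)
      } else {
        acc <- rbind(acc, s[k, ])
      }
    }
    merged[[ch]] <- acc
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

## ---- ploidy / purity lattice fit ---------------------------------------

.cn_lattice <- function(max_cn) {
  g <- expand.grid(minor = 0:max_cn, major = 0:max_cn)
  g <- g[g$major >= g$minor & g$major + g$minor <= max_cn, ]
  g$total <- g$major + g$minor
  g
}

#' Fit tumor ploidy and purity and assign allele-specific copy numbers
#'
#' Grid search over purity and the copy number at the median coverage level
#' (`baseline`), minimizing the SNP-weighted distance of each segment's
#' (mean LRR, mean mirrored BAF) pair to the lattice of integer
#' (major, minor) expectations under the two-component tumor/normal mixture
#' model: expected LRR of total copy `c` is
#' `log2((p c + 2(1-p)) / (p c0 + 2(1-p)))` and expected mirrored BAF of
#' `(M, m)` is `(p M + (1-p)) / (p (M+m) + 2(1-p))`. Each segment is assigned
#' its nearest lattice point; ploidy is the genome-length-weighted median
#' total copy number. A small penalty on the baseline breaks the scale
#' degeneracy in favour of the lower-ploidy interpretation when the data do
#' not discriminate.
#'
#' @param segments data.frame from [segment_genome()] (autosomes; any
#'   chromosome named `"chrX"`/`"chrY"` is excluded from the fit).
#' @param purity_grid,baseline_grid candidate purities (must be positive)
#'   and baseline copy numbers.
#' @param max_cn largest total copy number on the lattice.
#' @param baf_weight weight of the mirrored-BAF distance relative to LRR.
#' @param wgd_ploidy ploidy at or above which the whole-genome-doubling flag
#'   is set.
#' @return list with `fit` (data.frame: `purity`, `baseline`, `ploidy`,
#'   `wgd_flag`, `fit_residual`) and `segments` (input plus `major_cn`,
#'   `minor_cn`, `total_cn`).
#' @export
fit_ploidy_purity <- function(segments, purity_grid = seq(0.1, 1, by = 0.01),
                              baseline_grid = seq(1, 6, by = 0.1),
                              max_cn = 8, baf_weight = 2, wgd_ploidy = 3) {
  if (any(purity_grid <= 0)) stop("purity must be positive")
  segs <- segments[!(segments$chrom %in% c("chrX", "chrY", "X", "Y")), ]
  if (!nrow(segs)) stop("no autosomal segments")
  lat <- .cn_lattice(max_cn)
  w <- segs$n_snps
  glen <- segs$end - segs$start + 1
  ## Noise model per segment mean. BAF noise per SNP is binomial
  ## (sigma^2 = 0.25/depth); folding |b - 0.5| biases the mean of a
  ## balanced state upward by sigma * sqrt(2/pi) and shrinks its variance,
  ## so lattice expectations and variances must be folded the same way or
  ## the fit drifts towards low purity / high ploidy (thousands of neutral
  ## SNPs otherwise dilute the few aberrant segments that pin the purity).
  ## When the segment table carries no noise columns (e.g. synthetic
  ## segment-level input), plain squared distances are used.
  have_noise <- all(c("mean_depth", "lrr_sd") %in% names(segs)) &&
    !anyNA(segs$mean_depth) && !anyNA(segs$lrr_sd) && all(segs$lrr_sd > 0)
  sigma_b <- if (have_noise) sqrt(0.25 / pmax(segs$mean_depth, 1))
             else rep(0, nrow(segs))
  var_lrr <- if (have_noise) pmax(segs$lrr_sd^2 / w, 1e-8) else rep(1, nrow(segs))
  fold_mean <- function(delta, s) {
    if (s == 0) return(delta)
    delta * (2 * stats::pnorm(delta / s) - 1) + 2 * s * stats::dnorm(delta / s)
  }
  ## First pass: mean residual per (purity, baseline) combination.
  ## The mixture model carries an exact scale degeneracy — (p, profile C)
  ## and (p/(2-p), 2C) produce identical LRR and BAF — so the global
  ## minimum is selected with a tolerance, preferring the lowest baseline
  ## and then the highest purity among near-optimal fits. Genuine genome
  ## doublings survive this: their odd-copy segments make the halved
  ## interpretation misfit badly.
  grid <- expand.grid(purity = purity_grid, baseline = baseline_grid)
  grid$residual <- NA_real_
  baf_part <- function(p) {
    eb <- (p * lat$major + (1 - p)) / (p * lat$total + 2 * (1 - p))
    eb[lat$total == 0] <- 0.5
    delta <- eb - 0.5
    Eb <- matrix(0, nrow(segs), length(delta))
    Vb <- matrix(1, nrow(segs), length(delta))
    for (i in seq_len(nrow(segs))) {
      fm <- fold_mean(delta, sigma_b[i])
      Eb[i, ] <- 0.5 + fm
      if (have_noise) {
        Vb[i, ] <- pmax((delta^2 + sigma_b[i]^2 - fm^2) / w[i], 1e-8)
      }
    }
    if (have_noise) (segs$mean_mbaf - Eb)^2 / Vb
    else baf_weight * (segs$mean_mbaf - Eb)^2
  }
  seg_dist <- function(p, c0, B = baf_part(p)) {
    L <- log2(p * lat$total + 2 * (1 - p))
    A <- outer(segs$mean_lrr, L, "-") + log2(p * c0 + 2 * (1 - p))
    A^2 / var_lrr + B
  }
  for (p in purity_grid) {
    B <- baf_part(p)                      # the BAF part is c0-independent
    for (c0 in baseline_grid) {
      d <- seg_dist(p, c0, B)
      grid$residual[grid$purity == p & grid$baseline == c0] <-
        sum(apply(d, 1L, min)) / nrow(segs)
    }
  }
  if (all(!is.finite(grid$residual)))
    stop("degenerate fit: no lattice point selected")
  ## absolute floor in chi-square units per segment; raw squared distances
  ## (no noise columns) live on a much smaller scale
  tol_floor <- if (have_noise) 0.5 else 1e-4
  tol <- max(tol_floor, 0.15 * min(grid$residual, na.rm = TRUE))
  cand <- grid[grid$residual <= min(grid$residual, na.rm = TRUE) + tol, ]
  cand <- cand[order(cand$baseline, -cand$purity, cand$residual), ]
  best <- list(purity = cand$purity[1], baseline = cand$baseline[1],
               residual = cand$residual[1])
  d <- seg_dist(best$purity, best$baseline)
  best$assign <- apply(d, 1L, which.min)
  segs$major_cn <- lat$major[best$assign]
  segs$minor_cn <- lat$minor[best$assign]
  segs$total_cn <- lat$total[best$assign]
  ploidy <- weighted_median(segs$total_cn, glen)
  fit <- data.frame(purity = best$purity, baseline = best$baseline,
                    ploidy = ploidy, wgd_flag = ploidy >= wgd_ploidy,
                    fit_residual = best$residual)
  ## carry assignments back onto the full segment table (sex chroms get NA)
  out <- segments
  key <- paste(segs$chrom, segs$start)
  i <- match(paste(out$chrom, out$start), key)
  out$major_cn <- segs$major_cn[i]
  out$minor_cn <- segs$minor_cn[i]
  out$total_cn <- segs$total_cn[i]
  list(fit = fit, segments = out)
}

#' Classify segments relative to sample ploidy
#'
#' Ploidy-relative aberration classes: `gain` when total copy number exceeds
#' ploidy + 0.5, `loss` when below ploidy - 0.5, `high_amp` when above
#' ploidy + 2, `homozygous_deletion` when below 0.5, otherwise `neutral`.
#' `high_amp` and `homozygous_deletion` supersede `gain` and `loss`. LOH is
#' flagged whenever the minor-allele copy number is 0 (including
#' copy-neutral LOH).
#'
#' @param segments data.frame with `total_cn` and `minor_cn` columns.
#' @param fit one-row fit data.frame from [fit_ploidy_purity()] (or a list
#'   with a `ploidy` element).
#' @return `segments` with `klass` and `loh` columns appended.
#' @export
classify_segments <- function(segments, fit) {
  ploidy <- if (is.data.frame(fit)) fit$ploidy else fit[["ploidy"]]
  cn <- segments$total_cn
  klass <- rep("neutral", nrow(segments))
  klass[cn > ploidy + 0.5] <- "gain"
  klass[cn < ploidy - 0.5] <- "loss"
  klass[cn > ploidy + 2] <- "high_amp"
  klass[cn < 0.5] <- "homozygous_deletion"
  klass[is.na(cn)] <- NA_character_
  segments$klass <- klass
  segments$loh <- !is.na(segments$minor_cn) & segments$minor_cn == 0
  segments
}

#' Call copy-number aberrations for one tumor/normal pair
#'
#' Convenience wrapper chaining [compute_lrr_baf()], [segment_genome()],
#' [fit_ploidy_purity()] and [classify_segments()].
#'
#' @param tumor,normal per-SNP count tables.
#' @param ... passed to [segment_genome()].
#' @return list with `track`, `fit`, and classified `segments`.
#' @export
call_cna <- function(tumor, normal, ...) {
  track <- compute_lrr_baf(tumor, normal)
  segs <- segment_genome(track, ...)
  fp <- fit_ploidy_purity(segs)
  segs <- classify_segments(fp$segments, fp$fit)
  list(track = track, fit = fp$fit, segments = segs)
}
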