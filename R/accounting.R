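#' Build a ternary alteration-by-sample status matrix
#'
#' Each cell records whether the sample is mutated (called, including
#' rescued calls), not mutated, or not covered (depth below `min_depth` at
#' the site). Not-covered cells are excluded from sharing computations by
#' the downstream accounting functions.
#'
#' @param alterations character vector of alteration ids (matrix rows).
#' @param calls data.frame (`variant_id`, `sample_id`) of calls.
#' @param depths data.frame (`variant_id`, `sample_id`, `depth`) giving per
#'   cell coverage; missing entries are treated as depth 0.
#' @param samples character vector of sample ids (matrix columns).
#' @param min_depth coverage below which a cell is `not_covered`.
#' @return character matrix with values `"mutated"`, `"not_mutated"`,
#'   `"not_covered"`; class `status_matrix`.
#' @export
build_status_matrix <- function(alterations, calls, depths, samples,
                                min_depth = 8) {
  m <- matrix("not_mutated", length(alterations), length(samples),
              dimnames = list(alterations, samples))
  dk <- paste(depths$variant_id, depths$sample_id)
  grid <- expand.grid(variant_id = alterations, sample_id = samples,
                      stringsAsFactors = FALSE)
  d <- depths$depth[match(paste(grid$variant_id, grid$sample_id), dk)]
  d[is.na(d)] <- 0
  m[cbind(grid$variant_id, grid$sample_id)] <-
    ifelse(d < min_depth, "not_covered", "not_mutated")
  hit <- calls[calls$variant_id %in% alterations &
                 calls$sample_id %in% samples, ]
  if (nrow(hit)) m[cbind(hit$variant_id, hit$sample_id)] <- "mutated"
  class(m) <- c("status_matrix", class(m))
  m
}

#' Recurrence histogram of alterations over a sample subset
#'
#' Counts alterations by the number of subset samples in which they are
#' mutated (k = 1 .. subset size). The total is the number of alterations
#' mutated in at least one subset sample.
#'
#' @param matrix a `status_matrix` (or character matrix with the same
#'   values).
#' @param sample_subset columns to count over.
#' @return list with `histogram` (named integer vector over k) and `total`.
#' @export
recurrence_histogram <- function(matrix, sample_subset = colnames(matrix)) {
  stopifnot(length(sample_subset) >= 1,
            all(sample_subset %in% colnames(matrix)))
  sub <- matrix[, sample_subset, drop = FALSE]
  k <- rowSums(sub == "mutated")
  h <- vapply(seq_along(sample_subset), function(i) sum(k == i), integer(1))
  names(h) <- seq_along(sample_subset)
  list(histogram = h, total = sum(k >= 1))
}

#' Partition alterations by their group-presence signature
#'
#' Assigns every alteration present somewhere to exactly one region of the
#' Venn diagram over the given sample groups (e.g. PT specimens, CTC pools,
#' CDX + cell line), and reports per-region counts and percentages of a
#' declared denominator. Percentages use half-up integer rounding.
#' Alterations absent from every group are dropped from the universe with a
#' warning.
#'
#' @param matrix a `status_matrix`.
#' @param groups named list of character vectors of sample ids; groups must
#'   only reference matrix columns.
#' @param denominator denominator for percentages (default: universe size).
#' @return list with `regions` (data.frame: `region`, `count`, `percent`),
#'   `universe` (number of alterations present in >= 1 group) and
#'   `denominator`.
#' @export
venn_partition <- function(matrix, groups, denominator = NULL) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            all(unlist(groups) %in% colnames(matrix)))
  present <- vapply(groups, function(g) {
    rowSums(matrix[, g, drop = FALSE] == "mutated") > 0
  }, logical(nrow(matrix)))
  if (is.null(dim(present))) present <- rbind(present)
  sig <- apply(present, 1L, function(r) {
    paste(names(groups)[r], collapse = "&")
  })
  none <- sig == ""
  if (any(none)) {
    warning(sum(none), " alteration(s) absent from every group excluded")
    sig <- sig[!none]
  }
  universe <- length(sig)
  if (is.null(denominator)) denominator <- universe
  tab <- table(sig)
  regions <- data.frame(region = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  regions$percent <- round_half_up(100 * regions$count / denominator)
  list(regions = regions, universe = universe, denominator = denominator)
}

#' Cluster tumor samples by their VAF profiles
#'
#' Principal component analysis of the per-sample VAF vectors over
#' alterations present in at least two samples, and agglomerative
#' hierarchical clustering of the samples with cosine distance and Ward
#' linkage. Ward linkage over a non-Euclidean distance is used deliberately
#' (fidelity to common practice in mutation-profile clustering);
#' `linkage = "average"` is available as the mathematically safer fallback.
#'
#' @param vaf matrix (alterations x samples) of VAFs, 0 where absent.
#' @param min_samples alterations must be present (VAF > 0) in at least this
#'   many samples.
#' @param linkage `"ward.D2"` (default) or any `hclust` method.
#' @return list with `pca` (a `prcomp`), `dist` (cosine distance) and
#'   `tree` (an `hclust` over samples).
#' @export
cluster_samples_by_vaf <- function(vaf, min_samples = 2,
                                   linkage = "ward.D2") {
  stopifnot(is.matrix(vaf), ncol(vaf) >= 3)
  keep <- rowSums(vaf > 0, na.rm = TRUE) >= min_samples
  v <- vaf[keep, , drop = FALSE]
  v[is.na(v)] <- 0
  if (!nrow(v)) stop("no alteration present in >= min_samples samples")
  if (all(apply(v, 1L, function(r) length(unique(r)) == 1L)))
    stop("constant VAF matrix: PCA degenerate")
  pca <- prcomp(t(v), center = TRUE, scale. = FALSE)
  nrm <- sqrt(colSums(v^2))
  if (any(nrm == 0)) stop("sample with all-zero VAF vector")
  cs <- crossprod(v) / outer(nrm, nrm)
  d <- as.dist(1 - pmin(pmax(cs, -1), 1))
  list(pca = pca, dist = d, tree = hclust(d, method = linkage))
}

#' Match copy-number aberrations across samples
#'
#' Two sample-level segments are treated as the same aberration when they
#' have the same class and reciprocal overlap of at least `min_overlap`.
#' Greedy single-linkage grouping over all aberrant segments yields a
#' cross-sample aberration catalog.
#'
#' @param seg_list named list (by sample) of classified segment data.frames
#'   ([classify_segments()]); only non-neutral segments are used.
#' @param min_overlap reciprocal-overlap threshold.
#' @return data.frame catalog: `aberration_id`, `chrom`, `start`, `end`,
#'   `klass`, `samples` (comma-joined carriers), `n_samples`.
#' @export
match_aberrations <- function(seg_list, min_overlap = 0.5) {
  ab <- do.call(rbind, lapply(names(seg_list), function(s) {
    x <- seg_list[[s]]
    x <- x[!is.na(x$klass) & x$klass != "neutral", , drop = FALSE]
    if (!nrow(x)) return(NULL)
    x$sample_id <- s
    x[c("sample_id", "chrom", "start", "end", "klass")]
  }))
  if (is.null(ab) || !nrow(ab)) {
    return(data.frame(aberration_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), klass = character(),
                      samples = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  simple <- function(k) ifelse(k %in% c("gain", "high_amp"), "gain", "loss")
  ab$group <- NA_integer_
  g <- 0L
  for (i in seq_len(nrow(ab))) {
    if (!is.na(ab$group[i])) next
    g <- g + 1L
    ab$group[i] <- g
    for (j in seq_len(nrow(ab))[-i]) {
      if (!is.na(ab$group[j])) next
      if (ab$chrom[i] != ab$chrom[j]) next
      if (simple(ab$klass[i]) != simple(ab$klass[j])) next
      ov <- min(ab$end[i], ab$end[j]) - max(ab$start[i], ab$start[j]) + 1
      if (ov <= 0) next
      if (ov / (ab$end[i] - ab$start[i] + 1) >= min_overlap &&
          ov / (ab$end[j] - ab$start[j] + 1) >= min_overlap) {
        ab$group[j] <- g
      }
    }
  }
  out <- do.call(rbind, lapply(split(ab, ab$group), function(x) {
    data.frame(chrom = x$chrom[1], start = min(x$start), end = max(x$end),
               klass = simple(x$klass[1]),
               samples = paste(sort(unique(x$sample_id)), collapse = ","),
               n_samples = length(unique(x$sample_id)),
               stringsAsFactors = FALSE)
  }))
  out$aberration_id <- sprintf("ab_%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("aberration_id", "chrom", "start", "end", "klass", "samples",
        "n_samples")]
}
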