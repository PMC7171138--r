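#' Configuration for the synthetic CTC/CDX cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' emulate a prostate-cancer cohort in which a patient contributes eight
#' primary-tumor (PT) specimens, six FACS-sorted pools of five CTCs amplified
#' by WGA, a CTC-derived explant (CDX), a CDX-derived cell line, plus a bulk
#' germline sample and a WGA-amplified CD45-positive white-blood-cell pool.
#' Tumor samples are mixtures of clones drawn from a fixed five-clone lineage
#' (trunk -> PT branch and trunk -> CTC -> CDX -> cell line), with per-PT
#' private subclones providing primary-tumor heterogeneity.
#'
#' @param n_pt_specimens number of PT specimens.
#' @param n_ctc_pools number of CTC pools.
#' @param cells_per_pool cells per CTC pool (metadata only; pools are modeled
#'   as near-pure tumor mixtures).
#' @param n_clones number of core lineage clones; only the canonical 5-clone
#'   topology is supported.
#' @param n_truncal_snvs SNVs on the trunk (shared by every tumor cell).
#' @param snvs_per_branch SNVs per non-trunk lineage branch. Either a single
#'   count applied to all four branches or `NULL` for the canonical profile
#'   `c(pt = 9, ctc = 5, cdx = 37, line = 3)`.
#' @param pt_private_snvs private SNVs per PT specimen.
#' @param n_cnas total number of simulated copy-number events (excluding the
#'   optional whole-genome doubling).
#' @param mean_depth_bulk,mean_depth_wga mean sequencing depth for bulk and
#'   WGA samples (reads).
#' @param ado_rate per-site allele drop-out probability in WGA samples.
#' @param fpr_per_mb density of injected spurious calls in WGA samples,
#'   events per megabase of covered target.
#' @param target_size_mb size of the sequencing target in Mb.
#' @param dropout_fraction fraction of the target effectively uncovered
#'   (depth < 8) in WGA samples (locus dropout).
#' @param purity_by_sample optional named vector of tumor purities overriding
#'   the defaults (PT 0.6, CTC pools 0.9, CDX 0.9, cell line 0.98).
#' @param wgd_on_cdx place a whole-genome doubling on the CDX branch.
#' @param chrom_mb named vector of chromosome lengths in Mb; default 22
#'   autosomes with lengths decreasing from 240 to 60 Mb.
#' @param snp_spacing mean spacing of germline heterozygous SNPs in bp.
#' @param nb_size_bulk,nb_size_wga negative-binomial size (dispersion) of the
#'   depth model; WGA samples are more dispersed.
#' @param baf_conc_wga beta concentration of the WGA allele-fraction noise;
#'   smaller values give noisier BAF.
#' @param seed integer seed; a fixed seed yields a byte-identical cohort.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pt_specimens = 8, n_ctc_pools = 6, cells_per_pool = 5,
                       n_clones = 5,
                       n_truncal_snvs = 18, snvs_per_branch = NULL,
                       pt_private_snvs = 19, n_cnas = 16,
                       mean_depth_bulk = 100, mean_depth_wga = 60,
                       ado_rate = 0.2, fpr_per_mb = 14,
                       target_size_mb = 30, dropout_fraction = 0.2,
                       purity_by_sample = NULL, wgd_on_cdx = TRUE,
                       chrom_mb = NULL, snp_spacing = 1e6,
                       nb_size_bulk = 8, nb_size_wga = 1.5,
                       baf_conc_wga = 12, seed = 1L) {
  if (is.null(chrom_mb)) {
    chrom_mb <- setNames(round(seq(240, 60, length.out = 22)),
                         paste0("chr", 1:22))
  }
  if (is.null(snvs_per_branch)) {
    branch_snvs <- c(pt = 9, ctc = 5, cdx = 37, line = 3)
  } else {
    stopifnot(length(snvs_per_branch) == 1, snvs_per_branch >= 0)
    branch_snvs <- setNames(rep(as.integer(snvs_per_branch), 4),
                            c("pt", "ctc", "cdx", "line"))
  }
  cfg <- list(
    n_pt_specimens = as.integer(n_pt_specimens),
    n_ctc_pools = as.integer(n_ctc_pools),
    cells_per_pool = as.integer(cells_per_pool),
    n_clones = as.integer(n_clones),
    n_truncal_snvs = as.integer(n_truncal_snvs),
    branch_snvs = branch_snvs,
    pt_private_snvs = as.integer(pt_private_snvs),
    n_cnas = as.integer(n_cnas),
    mean_depth_bulk = mean_depth_bulk, mean_depth_wga = mean_depth_wga,
    ado_rate = ado_rate, fpr_per_mb = fpr_per_mb,
    target_size_mb = target_size_mb, dropout_fraction = dropout_fraction,
    purity_by_sample = purity_by_sample, wgd_on_cdx = isTRUE(wgd_on_cdx),
    chrom_mb = chrom_mb, snp_spacing = snp_spacing,
    nb_size_bulk = nb_size_bulk, nb_size_wga = nb_size_wga,
    baf_conc_wga = baf_conc_wga, seed = as.integer(seed))

  counts <- c(cfg$n_pt_specimens, cfg$n_ctc_pools, cfg$cells_per_pool,
              cfg$n_truncal_snvs, cfg$pt_private_snvs)
  if (any(counts < 1)) stop("counts must be positive")
  if (cfg$n_clones != 5L)
    stop("only the canonical five-clone lineage topology is supported")
  probs <- c(ado_rate, dropout_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (fpr_per_mb < 0 || target_size_mb <= 0 || snp_spacing <= 0)
    stop("rates and sizes must be non-negative")
  if (mean_depth_bulk <= 0 || mean_depth_wga <= 0)
    stop("negative or zero depth parameters rejected")
  if (cfg$n_cnas < 4 || cfg$n_cnas > length(chrom_mb))
    stop("n_cnas must be between 4 and the number of chromosomes")
  n_true <- cfg$n_truncal_snvs + sum(cfg$branch_snvs) +
    cfg$n_pt_specimens * cfg$pt_private_snvs
  exp_fp <- fpr_per_mb * target_size_mb * (1 - dropout_fraction)
  if (exp_fp > 10 * n_true)
    stop("degenerate cohort: expected false positives exceed true variants 10-fold")
  structure(cfg, class = "sim_config")
}

# Canonical clone lineage: parent of each clone. "normal" is the implicit root.
.clone_parents <- c(trunk = NA, pt = "trunk", ctc = "trunk",
                    cdx = "ctc", line = "cdx")

# All clones carrying an alteration acquired on the branch into `clone`.
.clone_descendants <- function(clone, parents = .clone_parents) {
  out <- clone
  repeat {
    kids <- names(parents)[parents %in% out & !(names(parents) %in% out)]
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

.default_purity <- function(samples) {
  p <- setNames(numeric(nrow(samples)), samples$sample_id)
  p[samples$role == "pt"] <- 0.6
  p[samples$role == "ctc"] <- 0.9
  p[samples$role == "cdx"] <- 0.9
  p[samples$role == "cell_line"] <- 0.98
  p
}

.sample_sheet <- function(cfg) {
  data.frame(
    sample_id = c("germline", "CD45",
                  paste0("PT_", seq_len(cfg$n_pt_specimens)),
                  paste0("CTC_", seq_len(cfg$n_ctc_pools)),
                  "CDX", "cell_line"),
    role = c("germline", "cd45",
             rep("pt", cfg$n_pt_specimens),
             rep("ctc", cfg$n_ctc_pools),
             "cdx", "cell_line"),
    is_wga = c(FALSE, TRUE,
               rep(FALSE, cfg$n_pt_specimens),
               rep(TRUE, cfg$n_ctc_pools),
               FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# Clone composition per sample, over core clones, per-PT private clones and
# "normal". Private PT subclones hold 30% of the tumor fraction.
.sample_composition <- function(samples, purity) {
  comp <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]; role <- samples$role[i]; p <- purity[[sid]]
    comp[[sid]] <- switch(role,
      germline = , cd45 = c(normal = 1),
      pt = setNames(c(0.7 * p, 0.3 * p, 1 - p),
                    c("pt", paste0("priv_", sid), "normal")),
      ctc = c(ctc = p, normal = 1 - p),
      cdx = c(cdx = p, normal = 1 - p),
      cell_line = c(line = p, normal = 1 - p))
  }
  comp
}

# Allocate CNA events to branches roughly as 3 truncal : 1 PT : 10 CTC : 2 CDX.
.allocate_cnas <- function(n) {
  base <- c(trunk = 3, pt = 1, ctc = 10, cdx = 2)
  k <- setNames(pmax(1, round(base / sum(base) * n)), names(base))
  k["ctc"] <- k["ctc"] + (n - sum(k))
  k
}

#' Simulate a CTC/CDX cohort with known clonal ground truth
#'
#' Generates (i) a clone tree with SNVs and copy-number events assigned to its
#' branches, (ii) per-sample variant observations (read counts, caller flags,
#' quality scores) for every simulated site in every sample, and (iii)
#' per-sample read-count tables at germline heterozygous SNPs. WGA samples
#' (CTC pools and the CD45 control) receive allele drop-out at `ado_rate`,
#' spurious private calls at `fpr_per_mb` over their covered target, locus
#' dropout on `dropout_fraction` of the target and overdispersed depth/BAF
#' noise; bulk samples have none of these artifacts. The germline and CD45
#' samples carry no somatic variants (the CD45 pool still acquires WGA
#' artifacts).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `ctc_cohort` with elements `truth` (clone tree,
#'   branch alterations, sample compositions and per-(variant, sample) truth
#'   flags), `samples` (sample sheet), `variants` (site table), `observations`
#'   (long per-site per-sample read-count table), `snp_counts` (named list of
#'   per-sample SNP count tables), `snps` (SNP positions and phase),
#'   `coverage` (per-sample covered-target BED-like tables) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  samples <- .sample_sheet(cfg)
  purity <- .default_purity(samples)
  if (!is.null(cfg$purity_by_sample)) {
    ov <- cfg$purity_by_sample
    stopifnot(all(names(ov) %in% samples$sample_id), all(ov >= 0 & ov <= 1))
    purity[names(ov)] <- ov
  }
  samples$purity <- purity[samples$sample_id]
  comp <- .sample_composition(samples, purity)

  chroms <- names(cfg$chrom_mb)
  chrom_len <- cfg$chrom_mb * 1e6

  ## --- germline heterozygous SNP scaffold -------------------------------
  snps <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(cfg$snp_spacing / 2, chrom_len[[ch]], by = cfg$snp_spacing)
    pos <- sort(round(pos + runif(length(pos), -0.2, 0.2) * cfg$snp_spacing))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  snps$snp_id <- paste0(snps$chrom, ":", snps$pos)
  snps$alt_on_hap1 <- runif(nrow(snps)) < 0.5   # phase of the alt (B) allele

  ## --- copy-number events along the lineage -----------------------------
  alloc <- .allocate_cnas(cfg$n_cnas)
  ev_branch <- rep(names(alloc), alloc)
  ev_chrom <- sample(chroms, length(ev_branch))
  ev_len <- runif(length(ev_branch), 20e6, 40e6)
  ev_start <- vapply(seq_along(ev_branch), function(i) {
    L <- chrom_len[[ev_chrom[i]]]
    runif(1, 1, max(1, L - ev_len[i]))
  }, numeric(1))
  kind_pool <- list(trunk = c("loss", "loss", "gain"), pt = "loss",
                    ctc = c(rep("loss", 7), rep("gain", 3)), cdx = "loss")
  ev_kind <- unlist(lapply(names(alloc), function(b) {
    rep_len(kind_pool[[b]], alloc[[b]])
  }))
  cnas <- data.frame(
    cna_id = sprintf("cna_%02d", seq_along(ev_branch)),
    branch = ev_branch, chrom = ev_chrom,
    start = round(ev_start), end = round(pmin(ev_start + ev_len, chrom_len[ev_chrom])),
    kind = ev_kind, hap = sample(1:2, length(ev_branch), replace = TRUE),
    stringsAsFactors = FALSE)

  ## per-clone haplotype copy numbers at each SNP
  clones <- names(.clone_parents)
  cn1 <- matrix(1L, nrow(snps), length(clones), dimnames = list(NULL, clones))
  cn2 <- cn1
  for (cl in clones) {   # clones listed parent-before-child
    par <- .clone_parents[[cl]]
    if (!is.na(par)) { cn1[, cl] <- cn1[, par]; cn2[, cl] <- cn2[, par] }
    if (cl == "cdx" && cfg$wgd_on_cdx) {
      cn1[, cl] <- 2L * cn1[, cl]; cn2[, cl] <- 2L * cn2[, cl]
    }
    for (k in which(cnas$branch == cl)) {
      idx <- snps$chrom == cnas$chrom[k] &
        snps$pos >= cnas$start[k] & snps$pos <= cnas$end[k]
      if (cnas$kind[k] == "loss") {
        if (cnas$hap[k] == 1) cn1[idx, cl] <- pmax(cn1[idx, cl] - 1L, 0L)
        else                  cn2[idx, cl] <- pmax(cn2[idx, cl] - 1L, 0L)
      } else {
        if (cnas$hap[k] == 1) cn1[idx, cl] <- cn1[idx, cl] + 1L
        else                  cn2[idx, cl] <- cn2[idx, cl] + 1L
      }
    }
  }

  ## --- target tiles (10 kb) for SNV placement and coverage masks --------
  n_tiles <- round(cfg$target_size_mb * 100)
  tile_chrom <- sample(chroms, n_tiles, replace = TRUE,
                       prob = cfg$chrom_mb / sum(cfg$chrom_mb))
  tile_start <- vapply(tile_chrom, function(ch) {
    1e4 * sample.int(floor(chrom_len[[ch]] / 1e4) - 1L, 1L)
  }, numeric(1))
  tiles <- data.frame(tile = seq_len(n_tiles), chrom = tile_chrom,
                      start = tile_start, end = tile_start + 1e4,
                      stringsAsFactors = FALSE)
  wga_ids <- samples$sample_id[samples$is_wga]
  dropped <- lapply(setNames(wga_ids, wga_ids), function(s) {
    which(runif(n_tiles) < cfg$dropout_fraction)
  })
  coverage <- lapply(setNames(samples$sample_id, samples$sample_id), function(s) {
    keep <- if (s %in% wga_ids) setdiff(seq_len(n_tiles), dropped[[s]])
            else seq_len(n_tiles)
    tiles[keep, c("chrom", "start", "end")]
  })

  ## --- somatic SNVs on branches -----------------------------------------
  branch_of <- c(rep("trunk", cfg$n_truncal_snvs),
                 rep(names(cfg$branch_snvs), cfg$branch_snvs),
                 rep(paste0("priv_PT_", seq_len(cfg$n_pt_specimens)),
                     each = cfg$pt_private_snvs))
  n_snv <- length(branch_of)
  snv_tile <- sample.int(n_tiles, n_snv, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(
    chrom = tiles$chrom[snv_tile],
    pos = tiles$start[snv_tile] + sample.int(1e4, n_snv, replace = TRUE),
    ref = ref, alt = alt, branch = branch_of, tile = snv_tile,
    consequence_class = sample(c("non-silent", "silent"), n_snv,
                               replace = TRUE, prob = c(0.75, 0.25)),
    is_driver = FALSE, stringsAsFactors = FALSE)
  variants <- variants[!duplicated(variants[c("chrom", "pos")]), ]
  variants$is_driver[match("trunk", variants$branch)] <- TRUE
  variants$consequence_class[match("trunk", variants$branch)] <- "non-silent"
  if (any(variants$branch == "pt")) {
    i <- match("pt", variants$branch)
    variants$is_driver[i] <- TRUE; variants$consequence_class[i] <- "non-silent"
  }
  variants$variant_id <- paste0(variants$chrom, ":", variants$pos, "_",
                                variants$ref, ">", variants$alt)

  ## carrier clone fractions per sample; private clones descend from "pt"
  carrier_frac <- function(branch, sid) {
    cc <- comp[[sid]]
    if (startsWith(branch, "priv_")) {
      return(unname(cc[branch] %||% 0))
    }
    sum(cc[intersect(.clone_descendants(branch), names(cc))], na.rm = TRUE) +
      sum(cc[startsWith(names(cc), "priv_")]) *
        as.numeric(branch %in% c("trunk", "pt"))
  }

  ## --- spurious (false-positive) calls in WGA samples -------------------
  fp_list <- lapply(wga_ids, function(s) {
    cov_tiles <- setdiff(seq_len(n_tiles), dropped[[s]])
    n_fp <- rpois(1, cfg$fpr_per_mb * length(cov_tiles) * 0.01)
    if (n_fp == 0) return(NULL)
    tl <- sample(cov_tiles, n_fp, replace = TRUE)
    r <- sample(bases, n_fp, replace = TRUE)
    data.frame(chrom = tiles$chrom[tl],
               pos = tiles$start[tl] + sample.int(1e4, n_fp, replace = TRUE),
               ref = r,
               alt = vapply(r, function(x) sample(setdiff(bases, x), 1),
                            character(1)),
               branch = NA_character_, tile = tl,
               consequence_class = sample(c("non-silent", "silent"), n_fp,
                                          replace = TRUE, prob = c(0.75, 0.25)),
               is_driver = FALSE, fp_sample = s, stringsAsFactors = FALSE)
  })
  fps <- do.call(rbind, fp_list)
  if (!is.null(fps)) {
    fps$variant_id <- paste0(fps$chrom, ":", fps$pos, "_", fps$ref, ">", fps$alt)
    fps <- fps[!duplicated(fps$variant_id) &
                 !(fps$variant_id %in% variants$variant_id), ]
  }
  variants$fp_sample <- NA_character_
  sites <- rbind(variants, fps)
  o <- order(match(sites$chrom, chroms), sites$pos)
  sites <- sites[o, ]
  rownames(sites) <- NULL

  ## --- per-sample variant observations ----------------------------------
  obs_list <- vector("list", nrow(samples))
  truth_list <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    wga <- samples$is_wga[i]
    ns <- nrow(sites)
    cf <- vapply(seq_len(ns), function(k) {
      b <- sites$branch[k]
      if (is.na(b)) 0 else carrier_frac(b, sid)
    }, numeric(1))
    is_fp_here <- !is.na(sites$fp_sample) & sites$fp_sample == sid

    if (wga) {
      depth <- rnbinom(ns, size = cfg$nb_size_wga, mu = cfg$mean_depth_wga)
      in_dropped <- sites$tile %in% dropped[[sid]]
      depth[in_dropped] <- sample(0:7, sum(in_dropped), replace = TRUE)
      # injected spurious calls are calls by construction: covered, supported
      depth[is_fp_here] <- 8 + rnbinom(sum(is_fp_here), size = cfg$nb_size_wga,
                                       mu = max(cfg$mean_depth_wga - 8, 1))
    } else {
      depth <- rnbinom(ns, size = cfg$nb_size_bulk, mu = cfg$mean_depth_bulk)
    }

    p_true <- 0.5 * cf
    ado_hit <- rep(FALSE, ns)
    p <- p_true
    if (wga) {
      het <- p_true > 0.05 & p_true < 0.95
      ado_hit <- het & runif(ns) < cfg$ado_rate
      # each allele's template molecules fail independently, so the rarer
      # allele is the one more likely to drop
      drop_alt <- runif(ns) < (1 - p_true)
      p[ado_hit & drop_alt] <- 0.02
      p[ado_hit & !drop_alt] <- 0.98
      noisy <- !ado_hit & p_true > 0
      if (any(noisy)) {
        p[noisy] <- rbeta(sum(noisy), p_true[noisy] * cfg$baf_conc_wga,
                          (1 - p_true[noisy]) * cfg$baf_conc_wga)
      }
    }
    p[is_fp_here] <- runif(sum(is_fp_here), 0.05, 0.3)
    alt_count <- rbinom(ns, depth, p)
    alt_count[is_fp_here] <- pmax(alt_count[is_fp_here], 2L)
    vaf <- ifelse(depth > 0, alt_count / depth, NA_real_)
    called <- (cf > 0 & alt_count >= 3 & !is.na(vaf) & vaf >= 0.03) | is_fp_here
    flag <- rep("PASS", ns)
    flag[is_fp_here] <- sample(c("PASS", "t_lod_fstar"), sum(is_fp_here),
                               replace = TRUE, prob = c(0.7, 0.3))
    qss <- ifelse(is_fp_here, round(runif(ns, 30, 55)), round(runif(ns, 35, 60)))

    obs_list[[i]] <- data.frame(
      variant_id = sites$variant_id, sample_id = sid,
      depth = depth, alt_count = alt_count, vaf = vaf,
      filter_flag = flag, qss = qss, caller_blacklist = FALSE,
      called = called, stringsAsFactors = FALSE)
    truth_list[[i]] <- data.frame(
      variant_id = sites$variant_id, sample_id = sid,
      truly_present = cf > 0, ado_dropped = ado_hit,
      false_positive = is_fp_here, stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs_list)
  per_variant_truth <- do.call(rbind, truth_list)

  ## --- per-sample SNP read counts ---------------------------------------
  alt_cn <- function(m1, m2) ifelse(snps$alt_on_hap1, m1, m2)
  snp_counts <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]; wga <- samples$is_wga[i]
    cc <- comp[[sid]]
    tot <- rep(0, nrow(snps)); altn <- rep(0, nrow(snps))
    for (cl in names(cc)) {
      prof <- if (startsWith(cl, "priv_")) "pt" else cl
      if (prof == "normal") {
        tot <- tot + cc[[cl]] * 2; altn <- altn + cc[[cl]] * 1
      } else {
        tot <- tot + cc[[cl]] * (cn1[, prof] + cn2[, prof])
        altn <- altn + cc[[cl]] * alt_cn(cn1[, prof], cn2[, prof])
      }
    }
    baf_exp <- ifelse(tot > 0, altn / tot, 0)
    lambda <- tot / 2
    if (wga) {
      depth <- rnbinom(nrow(snps), size = cfg$nb_size_wga,
                       mu = cfg$mean_depth_wga * lambda)
      low <- runif(nrow(snps)) < cfg$dropout_fraction
      depth[low] <- sample(0:7, sum(low), replace = TRUE)
      ado <- runif(nrow(snps)) < cfg$ado_rate
      drop_alt <- runif(nrow(snps)) < (1 - baf_exp)
      pb <- rbeta(nrow(snps), pmax(baf_exp, 1e-3) * cfg$baf_conc_wga,
                  pmax(1 - baf_exp, 1e-3) * cfg$baf_conc_wga)
      pb[ado & drop_alt] <- 0.02
      pb[ado & !drop_alt] <- 0.98
    } else {
      depth <- rnbinom(nrow(snps), size = cfg$nb_size_bulk,
                       mu = cfg$mean_depth_bulk * lambda)
      pb <- baf_exp
    }
    a <- rbinom(nrow(snps), depth, pb)
    tab <- data.frame(chrom = snps$chrom, pos = snps$pos,
                      ref_count = depth - a, alt_count = a,
                      stringsAsFactors = FALSE)
    if (sid == "germline") tab$gq <- sample(60:99, nrow(snps), replace = TRUE)
    snp_counts[[sid]] <- tab
  }

  truth <- list(
    clone_parents = .clone_parents,
    branch_snvs = split(sites$variant_id[!is.na(sites$branch)],
                        sites$branch[!is.na(sites$branch)]),
    branch_cnas = cnas,
    wgd_on_cdx = cfg$wgd_on_cdx,
    sample_composition = comp,
    per_variant_truth = per_variant_truth,
    clone_cn = list(hap1 = cn1, hap2 = cn2))

  structure(list(truth = truth, samples = samples,
                 variants = sites, observations = observations,
                 snp_counts = snp_counts, snps = snps,
                 tiles = tiles, coverage = coverage, config = cfg),
            class = "ctc_cohort")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Simulate one WGA observation at a single site
#'
#' Models the read-count outcome of whole-genome amplification at one locus:
#' depth is negative-binomial, and with probability `ado_rate` a heterozygous
#' site loses one allele so that its VAF collapses towards 0 or 1.
#'
#' @param true_genotype one of `"hom-ref"`, `"het"`, `"hom-alt"`.
#' @param depth_params list with `mean` and `size` of the negative-binomial
#'   depth distribution.
#' @param ado_rate allele drop-out probability for heterozygous sites.
#' @param seed optional integer seed.
#' @return one-row data.frame with `depth`, `alt_count`, `vaf`, `ado_dropped`.
#' @export
simulate_wga_site <- function(true_genotype = c("het", "hom-ref", "hom-alt"),
                              depth_params = list(mean = 60, size = 1.5),
                              ado_rate = 0.2, seed = NULL) {
  true_genotype <- match.arg(true_genotype)
  if (depth_params$mean <= 0 || depth_params$size <= 0)
    stop("negative depth parameters rejected")
  if (ado_rate < 0 || ado_rate > 1) stop("ado_rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  depth <- rnbinom(1, size = depth_params$size, mu = depth_params$mean)
  p <- switch(true_genotype, "hom-ref" = 0, "hom-alt" = 1, het = 0.5)
  ado <- FALSE
  if (true_genotype == "het" && runif(1) < ado_rate) {
    ado <- TRUE
    p <- if (runif(1) < 0.5) 0.02 else 0.98
  }
  alt <- rbinom(1, depth, p)
  data.frame(depth = depth, alt_count = alt,
             vaf = ifelse(depth > 0, alt / depth, NA_real_),
             ado_dropped = ado)
}
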