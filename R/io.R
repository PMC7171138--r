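#' Write a simulated cohort to standard file formats
#'
#' Emits a multi-sample VCFv4.2 (per-sample `DP`, `AD`, per-sample caller
#' filter in `FT`, quality sum score in `QS`), one SNP read-count TSV per
#' sample, a sample sheet TSV, per-sample coverage BED files (0-based
#' half-open) and the ground truth as JSON. Files round-trip losslessly
#' through [read_cohort()].
#'
#' @param cohort a `ctc_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_fixture <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  paths <- character(0)

  sites <- cohort$variants
  samples <- cohort$samples$sample_id
  obs <- cohort$observations
  key <- paste(obs$variant_id, obs$sample_id)

  gt_field <- function(sid) {
    i <- match(paste(sites$variant_id, sid), key)
    sprintf("%d:%d,%d:%s:%d",
            obs$depth[i], obs$depth[i] - obs$alt_count[i], obs$alt_count[i],
            obs$filter_flag[i], obs$qss[i])
  }
  gts <- vapply(samples, gt_field, character(nrow(sites)))
  info <- sprintf("CLS=%s%s", sites$consequence_class,
                  ifelse(sites$is_driver, ";DRIVER", ""))
  body <- cbind(sites$chrom, sites$pos, sites$variant_id, sites$ref,
                sites$alt, ".", ".", info, "DP:AD:FT:QS", gts)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(cohort$config$chrom_mb),
                  ",length=", cohort$config$chrom_mb * 1e6, ">"),
           "##FILTER=<ID=t_lod_fstar,Description=\"Tumor LOD below threshold\">",
           "##INFO=<ID=CLS,Number=1,Type=String,Description=\"Consequence class\">",
           "##INFO=<ID=DRIVER,Number=0,Type=Flag,Description=\"Driver annotation\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Per-sample caller filter\">",
           "##FORMAT=<ID=QS,Number=1,Type=Integer,Description=\"Quality sum score\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  vcf_path <- file.path(out_dir, "cohort.vcf")
  writeLines(c(hdr, apply(body, 1L, paste, collapse = "\t")), vcf_path)
  paths <- c(paths, vcf_path)

  for (s in names(cohort$snp_counts)) {
    p <- file.path(out_dir, paste0("snp_counts_", s, ".tsv"))
    write.table(cohort$snp_counts[[s]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  sheet_path <- file.path(out_dir, "samples.tsv")
  write.table(cohort$samples, sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, sheet_path)

  for (s in names(cohort$coverage)) {
    p <- file.path(out_dir, paste0("coverage_", s, ".bed"))
    bed <- cohort$coverage[[s]]
    write.table(data.frame(bed$chrom, format(bed$start, scientific = FALSE,
                                             trim = TRUE),
                           format(bed$end, scientific = FALSE, trim = TRUE)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, p)
  }

  truth_path <- file.path(out_dir, "truth.json")
  truth <- cohort$truth
  jsonlite::write_json(
    list(clone_parents = as.list(truth$clone_parents),
         branch_snvs = truth$branch_snvs,
         branch_cnas = truth$branch_cnas,
         wgd_on_cdx = truth$wgd_on_cdx,
         sample_composition = lapply(truth$sample_composition, as.list),
         per_variant_truth = truth$per_variant_truth),
    truth_path, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, truth_path)
  invisible(paths)
}

#' Read a cohort fixture back from disk
#'
#' Parses the VCF written by [write_fixture()] with `vcfR`, plus the sample
#' sheet, SNP count tables, coverage BEDs and truth JSON, reconstructing the
#' observation table.
#'
#' @param dir directory written by [write_fixture()].
#' @return a list mirroring the `ctc_cohort` structure (`samples`,
#'   `variants`, `observations`, `snp_counts`, `coverage`, `truth`).
#' @export
read_cohort <- function(dir) {
  vcf <- vcfR::read.vcfR(file.path(dir, "cohort.vcf"), verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  variants <- data.frame(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    consequence_class = sub("^CLS=([^;]+).*$", "\\1", info),
    is_driver = grepl("(^|;)DRIVER(;|$)", info),
    stringsAsFactors = FALSE)

  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  ft <- vcfR::extract.gt(vcf, "FT")
  qs <- vcfR::extract.gt(vcf, "QS", as.numeric = TRUE)
  alt_count <- apply(ad, 2L, function(x) as.integer(sub("^[0-9]+,", "", x)))
  obs <- do.call(rbind, lapply(colnames(dp), function(s) {
    data.frame(variant_id = fix$ID, sample_id = s,
               depth = as.integer(dp[, s]), alt_count = alt_count[, s],
               vaf = ifelse(dp[, s] > 0, alt_count[, s] / dp[, s], NA_real_),
               filter_flag = ft[, s], qss = as.integer(qs[, s]),
               stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL

  samples <- read.table(file.path(dir, "samples.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  snp_counts <- lapply(setNames(samples$sample_id, samples$sample_id),
                       function(s) {
    read.table(file.path(dir, paste0("snp_counts_", s, ".tsv")),
               header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  })
  coverage <- lapply(setNames(samples$sample_id, samples$sample_id),
                     function(s) {
    b <- read.table(file.path(dir, paste0("coverage_", s, ".bed")),
                    sep = "\t", stringsAsFactors = FALSE)
    names(b) <- c("chrom", "start", "end")
    b
  })
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(samples = samples, variants = variants, observations = obs,
       snp_counts = snp_counts, coverage = coverage, truth = truth)
}
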