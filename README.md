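# ctclineage

Comparative genomic inference for tumor cohorts that combine bulk
primary-tumor (PT) specimens, pools of circulating tumor cells (CTCs)
amplified by whole-genome amplification (WGA), and CTC-derived tumor models
— a CTC-derived explant (CDX) and a cell line grown from it. The package is
aimed at cancer-genomics analysts who need to decide, from exome data,
which alterations a CTC-derived model shares with the primary tumor, which
arose along the CTC lineage, and how trustworthy calls from heavily
amplified single-cell material are.

## What it computes

Starting from candidate somatic calls with read counts (callers and
alignment are upstream and out of scope), `ctclineage` provides:

* **Somatic post-filtering** — caller flag `PASS`/`t_lod_fstar`, coverage
  ≥ 8 in tumor and matched normal, QSS ≥ 30, tumor VAF ≥ 0.05 with ≥ 5
  variant reads, normal VAF = 0 — plus cross-sample rescue of low-VAF
  variants passing filters in ≥ 2 tumor samples, and a high-confidence rule
  for CTC calls (corroboration by a PT specimen, the CDX, or another pool).
* **WGA artifact estimates** — allele drop-out (ADO): heterozygous germline
  sites (VAF 0.2–0.8) whose WGA readout collapses below 0.1 or above 0.9
  with a significant Fisher exact test (p < 0.05); false-positive rate
  (FPR): caller events absent from PT and CDX per Mb of target covered
  ≥ 8x.
* **Allele-specific copy number** — per-SNP LRR/BAF, circular binary
  segmentation (implemented in the package), a purity/baseline lattice fit
  assigning integer (major, minor) copy numbers, ploidy as the
  length-weighted median copy number, and ploidy-relative classes: gain
  (> ploidy + 0.5), loss (< ploidy − 0.5), high-level amplification
  (> ploidy + 2), homozygous deletion (< 0.5), LOH (minor = 0).
* **CTC aberration screening** — known aberrations are detected in noisy
  CTC profiles by counting SNPs whose BAF deviates from 0.5 in the same
  direction as the reference sample, Fisher-testing the
  consistent/discordant split against copy-neutral background SNPs, and
  requiring p < 0.05 with ≥ 80% consistent SNPs.
* **Clonal accounting** — ternary status matrices (mutated / not mutated /
  not covered at depth < 8), recurrence histograms, Venn partitions with
  half-up integer percentages, PCA plus Ward/cosine clustering of VAF
  profiles.
* **Phylogeny** — maximum-parsimony trees (parsimony ratchet) from binary
  presence/absence matrices of non-silent alterations in ≥ 2 samples
  (present = VAF > 0), rooted through an all-zero pseudo-germline
  outgroup, with mutations and CNAs assigned to branches by their
  downstream sample sets.

Real CTC cohorts of this design are controlled-access, so the package
ships a synthetic-cohort generator (`simulate_cohort()`) with a known
five-clone lineage, branch-assigned SNVs/CNAs (including an optional
whole-genome doubling on the CDX branch), WGA artifacts and full ground
truth; the test suite validates every stage against that truth.

## Worked example

```r
library(ctclineage)

cohort <- simulate_cohort(sim_config(seed = 7))
res <- run_pipeline(cohort)

# WGA quality control
res$ado$ado_rate
#> [1] 0.2036963
res$fpr[res$fpr$sample_id == "CTC_1", "fpr_per_mb"]
#> [1] 12.97071

# primary-tumor mutation accounting
res$pt_histogram$total
#> [1] 157
res$venn$regions
#>       region count percent
#> 1        CDX    40      20
#> 2    CTC&CDX     5       2
#> 3         PT   139      69
#> 4 PT&CTC&CDX    18       9

# copy number: the CDX is genome-doubled, the primary tumor diploid
res$cna[["CDX"]]$fit[, c("purity", "ploidy", "wgd_flag")]
#>   purity ploidy wgd_flag
#> 1   0.91      4     TRUE

# phylogeny: PT clade versus the CTC/CDX/cell-line lineage
has_clade(res$phylogeny$tree, paste0("PT_", 1:8))
#> [1] TRUE
has_clade(res$phylogeny$tree, c(paste0("CTC_", 1:6), "CDX", "cell_line"))
#> [1] TRUE
```

Reading the output: the configured ADO rate (0.2) and false-positive
density (14/Mb) are recovered from the simulated CD45 control and CTC
pools; 157 mutations are detected across the eight PT specimens, most of
them private to a single specimen (the simulated primary tumor is
heterogeneous) while the shared fraction propagates into the CDX; the CDX
is called tetraploid with the whole-genome-doubling flag set; and the tree
splits the PT specimens from the CTC-derived lineage, with the CDX and its
cell line forming their own subclade.

`write_fixture(cohort, "out/")` exports the cohort as a multi-sample
VCFv4.2, per-sample SNP count TSVs, coverage BEDs, a sample sheet and the
ground-truth JSON; `read_cohort("out/")` reads them back losslessly.

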