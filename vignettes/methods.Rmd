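---
title: "Methods: comparative genomic inference for CTC-derived tumor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomic inference for CTC-derived tumor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ctclineage` reconstructs the clonal relationship between a patient's primary
tumor (PT) specimens, pools of circulating tumor cells (CTCs) amplified by
whole-genome amplification (WGA) before exome sequencing, and tumor models
grown from those CTCs — a CTC-derived explant (CDX) and a cell line derived
from it. The pipeline starts from candidate somatic calls with read counts
(it does not realign reads or re-implement the callers) and covers:

1. tumor–normal somatic post-filtering, cross-sample low-VAF rescue and a
   high-confidence rule for CTC calls;
2. quantification of WGA artifacts: allele drop-out (ADO) and the
   per-megabase false-positive rate (FPR);
3. allele-specific copy-number analysis from per-SNP coverage log-ratios
   (LRR) and B-allele frequencies (BAF): segmentation, ploidy/purity
   fitting, ploidy-relative aberration classes and LOH;
4. detection of known aberrations in noisy CTC samples through allelic
   imbalance;
5. set-accounting across sample groups (status matrices, recurrence
   histograms, Venn partitions, VAF-based sample clustering);
6. maximum-parsimony phylogeny reconstruction from binary presence/absence
   matrices with branch-wise alteration assignment.

Patient-derived CTC data are controlled-access, so the package ships a
synthetic-cohort generator (`simulate_cohort()`) with full clonal ground
truth; every stage is validated against that truth in the test suite.

# The synthetic cohort

## Clonal structure

The generator uses a fixed five-clone lineage that mirrors the biology the
pipeline is meant to resolve: a truncal clone ancestral to all tumor cells;
a PT branch; a CTC branch that also seeds the CDX; a CDX clone (optionally
carrying a whole-genome doubling, WGD); and a cell-line clone derived from
the CDX. Each PT specimen additionally receives a private subclone (30% of
its tumor fraction) so that the primary tumor shows the mutational
heterogeneity typical of multi-region sampling. Samples are clone mixtures:
by default PT purity 0.6, CTC pools 0.9, CDX 0.9, cell line 0.98, plus a
pure germline sample and a WGA-amplified CD45+ white-blood-cell pool that
carries WGA artifacts but no somatic variants.

Default per-branch alteration counts emulate a deeply sequenced prostate
cohort: 18 truncal SNVs plus 3 truncal copy-number events, 9 SNVs and one
CNA on the PT branch, 5 SNVs and 10 CNAs on the CTC branch, 37 SNVs and 2
post-WGD single-copy losses on the CDX branch, 3 cell-line private SNVs,
and 19 private SNVs per PT specimen. Copy-number events are 20–40 Mb,
placed on distinct chromosomes, and affect one randomly chosen haplotype;
WGD doubles both haplotypes before the CDX-branch losses are applied, so
the tetraploid genome contains odd-total segments — exactly the feature
that makes tetraploidy identifiable in real data.

## Read-count model

Depth is negative-binomial per site (bulk mean 100, size 8; WGA mean 60,
size 1.5 — WGA coverage is heavily overdispersed). WGA samples suffer three
artifact processes, applied independently per site:

* **Locus dropout**: a fraction (default 0.2) of the target has depth
  drawn uniformly from 0–7, i.e. below the pipeline's coverage floor.
* **Allele drop-out**: with probability `ado_rate` (default 0.2) one allele
  of a heterozygous site is lost and the allele fraction collapses to
  ~0.02 or ~0.98. The dropped allele is chosen with probability
  proportional to the other allele's abundance — each allele's template
  molecules fail independently, so the rarer allele is the one that
  usually drops; in a loss-of-heterozygosity region this correctly leaves
  the BAF direction intact. This is the operational definition used by the
  ADO estimator, not a physical polymerase model.
* **False positives**: spurious private calls are injected uniformly over
  the sample's covered target at `fpr_per_mb` (default 14, the middle of
  the 7–21 per Mb range typical of WGA exomes), with VAF drawn from
  0.05–0.3. Because they represent events the caller emitted, they are
  generated with supporting reads (depth at least 8, at least 2 variant
  reads); bulk samples receive none.

Away from dropout, WGA allele fractions get beta noise (concentration 12)
around their expectation, which is what makes direct copy-number calling
from CTC BAF profiles unreliable and motivates the imbalance-based rescue.

Simplifications a user should know about: simulated sites are independent
(no spatial correlation of amplification bias), SNV allele fractions ignore
the local copy-number state (expected VAF is 0.5 times the carrier-clone
fraction), and there is no read-level error model. Consequently, passing
recovery tests demonstrates correctness of the estimators under the stated
artifact model, not robustness to every failure mode of real WGA chemistry.

# Somatic filtering

Candidate calls are kept when the caller flag is `PASS` or `t_lod_fstar`,
coverage is at least 8 in tumor and matched normal, the base-quality sum
score is at least 30, the tumor VAF is at least 0.05 with at least 5
variant reads, and the normal sample carries no variant read. All
boundaries are inclusive; rejected calls carry the first failing rule so
filter audits are reproducible. A caller-internal blacklist is modeled as a
generic boolean flag.

Two cross-sample steps follow. *Rescue*: a variant passing primary filters
in at least two tumor samples is granted to further samples showing at
least 2 supporting reads at VAF ≥ 0.01 with a variant-free normal — the
numeric support threshold is our choice (the procedure it models used
readcount evidence without stating one) and is exposed in
`filter_policy()`. *High-confidence CTC rule*: a CTC call must be
corroborated by at least one PT specimen, the CDX, or another CTC pool;
corroboration is evaluated on raw per-pool primary calls by default (the
rescue-augmented mode is available), since counting rescue-augmented pools
would let one real pool vouch for itself through the rescue.

# WGA artifact estimation

**ADO.** Variants reliable in the germline (coverage ≥ 8 in germline and
WGA sample, ≥ 5 variant reads at ≥ 5%, genotype quality ≥ 30) are tested by
a two-sided Fisher exact test comparing ref/alt proportions between
germline and the WGA product; a site has dropped out when p < 0.05, the
germline VAF is within 0.2–0.8 and the WGA VAF is below 0.1 or above 0.9.
The reported rate divides dropped sites by heterozygous-band eligible
sites. Two-sidedness is a deliberate choice: the direction filter already
encodes the asymmetry, and a one-sided test would double-count it.

**FPR.** Every call of a WGA sample found neither in the PT union nor in
the CDX is counted as a potential false positive and divided by the
megabases of target covered at ≥ 8x in the same sample. The estimate is
computed on caller-emitted calls before the hard filters, matching its
definition as a property of the caller output; it is invariant to adding
truly shared variants.

# Copy-number analysis

At germline-heterozygous SNPs (normal VAF 0.2–0.8 at depth ≥ 8), LRR is
`log2((tumor depth / tumor median) / (normal depth / normal median))` and
BAF is the tumor alternate-read fraction. The formulas are standard
practice; median normalization means "LRR 0" corresponds to the sample's
median copy number, which the ploidy fit estimates as the `baseline`.

**Segmentation.** Circular binary segmentation is implemented in the
package: the best circular arc under the mean-shift t statistic is found by
a vectorized scan over all arcs, its significance assessed by permutation
(alpha 0.01, 100 permutations, with early stopping once significance is
unreachable), and significant splits recursed into. Both the LRR and the
mirrored BAF (`|BAF − 0.5| + 0.5`) are segmented; breakpoint sets are
unioned (the union/intersection choice is exposed via `use_baf`), segments
need at least 10 SNPs, and adjacent segments are merged when mean LRR
differs by less than 0.1 and mean mirrored BAF by less than 0.05. The
noise scale is estimated robustly from successive differences
(`mad(diff(x))/sqrt(2)`), so the permutation test is scale-free.

**Ploidy and purity.** A grid search over purity (0.1–1 by 0.01) and
baseline copy number (1–6 by 0.1) minimizes the distance of each segment's
(mean LRR, mean mirrored BAF) to the lattice of integer (major, minor)
expectations under a two-component tumor/normal mixture; each segment
takes its nearest lattice point, and ploidy is the genome-length-weighted
median total copy number. Two statistical details matter. First, folding:
the mirrored BAF of a perfectly balanced segment does not average 0.5 but
0.5 + σ√(2/π), where σ is the per-SNP binomial noise — lattice
expectations and variances are therefore folded through the same
transform, otherwise the fit drifts systematically towards low purity and
high ploidy. Second, distances are noise-normalized (χ², using the
segment's SNP count, mean depth and a robust per-SNP LRR noise estimate):
without this, the thousands of SNPs in copy-neutral segments dilute the
few aberrant segments that actually pin down the purity.

The mixture model carries an exact scale degeneracy: purity p with
profile C is observationally identical to purity p/(2−p) with profile 2C,
for every segment. The fit therefore selects among near-optimal
(purity, baseline) combinations — within a tolerance of the best residual
— the one with the lowest baseline and then the highest purity. A genuine
whole-genome doubling survives this preference because its odd-total
segments (e.g. post-WGD single-copy losses) make the halved
interpretation misfit far beyond the tolerance. The lattice fit is a
declared simplification with the same inputs and outputs as published
allele-specific genotyping methods; it does not reproduce their
pattern-recognition internals.

**Classes.** Relative to ploidy: gain above ploidy + 0.5, loss below
ploidy − 0.5, high-level amplification above ploidy + 2, homozygous
deletion below 0.5, otherwise neutral; LOH whenever the minor allele count
is 0. In a genome-doubled sample these thresholds intentionally call
single-copy losses "losses" relative to the tetraploid baseline.

# Aberrations in CTC samples

CTC profiles after WGA are too noisy for direct segmentation, but a
one-copy loss or unbalanced gain leaves a haplotype-consistent BAF skew.
For an aberration called in a reference sample (the CDX by default), SNPs
inside the segment are counted as consistent when the CTC BAF deviates from
0.5 in the same direction as the reference BAF at that SNP (deviation
> 0.1 with ≥ 10 reads; both thresholds exposed, and declared choices — the
underlying procedure states none). The same counts over background SNPs
from the reference's copy-neutral non-LOH segments enter a 2×2 Fisher test,
which controls for the CTC sample's own global WGA noise; the aberration is
present when p < 0.05 with at least 80% consistent SNPs. Balanced
aberrations (reference mirrored BAF within 0.1 of 0.5, e.g. pure-LRR
events) carry no usable footprint and are reported `not_evaluable` with an
`lrr_only` flag rather than absent.

# Accounting and clustering

Status matrices are ternary: mutated, not mutated, or not covered (depth
below 8) — uncovered cells never count as absence in sharing computations.
Venn partitions assign each alteration present anywhere to exactly one
region by its group signature; percentages use half-up integer rounding,
matching how such figures are conventionally reported. Copy-number events
are identified across samples by reciprocal overlap ≥ 50% with the same
direction (gain vs loss), an exposed threshold. Sample clustering uses PCA
and hierarchical clustering with cosine distance and Ward linkage; Ward
over a non-Euclidean distance is mathematically improper but reproduces
common practice for mutation profiles, and `linkage = "average"` is
available as the safer alternative.

# Phylogeny

Non-silent somatic alterations present in at least two samples are encoded
as binary characters (present = VAF > 0 from the readcounts, not from the
filtered call set). Cells without sufficient coverage may be `NA`: they
enter the parsimony machinery as the ambiguous state, because an uncovered
position carries no evidence either way — coding it 0 would let WGA locus
dropout vote against presence and measurably distorts the topology. Tree
search uses the parsimony ratchet (via `phangorn::pratchet`, the same
engine used in practice for such data; 200 iterations by default, fixed
seed, co-optimal trees retained and ties broken by the lexicographically
smallest Newick). An all-zero pseudo-germline outgroup is appended before
the search and used to root the result: the underlying procedure reports
trunk/branch structure from unrooted trees without stating its rooting, so
the outgroup construction is our declared choice. CNAs do not enter the
search; they are mapped onto the SNV tree afterwards.

For branch assignment, an alteration maps to the edge whose downstream
leaves equal its presence set; with unknown cells it maps to the smallest
clade containing every known-present sample and no known-absent one (the
two rules coincide when everything is observed). Alterations compatible
with no clade are flagged homoplastic rather than forced onto an edge;
mutation and CNA counts are reported separately per branch.

# Problem sizes and determinism

The default synthetic genome is 22 autosomes (240 down to 60 Mb) with
germline-heterozygous SNPs every ~1 Mb (~3,300 SNPs) and a 30 Mb exome-like
target — large enough for 20–40 Mb events to span dozens of SNPs while the
full pipeline (filters, QC, copy number on ten bulk samples, CTC rescue,
accounting, phylogeny) completes in well under a minute per stage on a
single core. The test suite uses an eight-chromosome reduction of the same
generator for per-module checks and the full default cohort for end-to-end
recovery. All randomness flows from the configuration seed; a fixed seed
reproduces the cohort and the tree byte-for-byte.

# Known limitations

* The generator's clone tree is fixed in shape; only branch lengths
  (alteration counts) and sample compositions vary.
* SNV VAFs ignore local copy number, so VAF-based subclonality analyses
  beyond presence/absence should not be read into the simulation.
* The ploidy fit reports a single clonal copy-number state per segment; no
  subclonal (fractional) states.
* The imbalance screen requires the reference sample to show allelic
  imbalance in the segment; balanced events can only be reported
  `not_evaluable` in CTCs.
* Ward linkage over cosine distance is kept for fidelity to field practice
  despite its formal impropriety.
* The ploidy/purity scale degeneracy is only broken by odd-copy segments
  or by the near-diploid preference; a sample whose aberrations are all
  observationally compatible with a doubled profile may be reported on the
  doubled ridge (purity p/(2−p), copy numbers 2C). Ploidy-relative classes,
  LOH flags and all downstream accounting are invariant under that mapping.
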