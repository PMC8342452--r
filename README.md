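# allelome

Allele-aware analyses for haplotype-resolved diploid genomes.

When both haplotypes of a diploid are assembled to chromosome scale, the two
copies of every gene — its alleles — become directly observable. `allelome`
re-implements, as a tested and reusable R pipeline, the allele-level analyses
used for such assemblies (the motivating system is a diploid plant with 11
homologous chromosome pairs, e.g. cultivated ginger, profiled by RNA-seq
over 7 tissues in 29 samples):

* **Allele pairing** — translated k-mer homology matching between the two
  haplotypes' CDS sets, dynamic-programming chaining of matches into
  collinear blocks (strictly monotone anchor ranks, MCScanX-like defaults:
  ≥5 anchors, gap ≤25), and removal of blocks that stem from an ancient
  whole-genome duplication (WGD) rather than allelism, via a median
  synonymous-divergence (Ks) ceiling.
* **Allelic expression bias** — TPM normalization, the "expressed if >0.5
  TPM in ≥1 of the samples" rule, a negative-binomial Wald test of allele A
  vs B per tissue (median-of-ratios size factors, pooled method-of-moments
  dispersion, BH adjustment within tissue) and the four-level category
  scheme: *none* (adjusted p ≥ 0.05), *smaller* (FC ≤ 2), *larger*
  (2 < FC < 8), *largest* (FC ≥ 8). Loci are ranked by the range of their
  significance-masked log2 fold-change profile: top 10% *dynamic*, bottom
  10% *stable*; tissue-to-tissue category changes are summarized as
  *neighboring* (one step) or *jumping* (two steps).
* **Coding divergence** — protein-guided codon alignment and NG86 Ka/Ks:
  fractional synonymous/nonsynonymous site counting, pathway-averaged
  difference counting, Jukes–Cantor correction
  d = −(3/4)·ln(1 − (4/3)p); Ks > 5 flagged as saturated.
* **Regulatory context** — PWM scanning of 2-kb promoters on both strands
  with *exact* p-values (dynamic-programming convolution of the discretized
  log-odds score distribution; hits at p < 1e−5, pseudocount 1e−8),
  per-motif min/max accounting of shared vs allele-specific TFBS, and
  nearest-TE distances from BED intervals.
* **Coexpression divergence** — unsigned weighted network (first soft power
  with scale-free fit ≥ 0.9), topological overlap, module detection with
  minimum size 60 and eigengene merge cut 0.15; allele pairs in different
  modules are *divergent* when their module eigengenes are farther apart
  than 50% of the median per-module maximum eigengene distance.
* **Molecular dating** — kernel-density Ks peak detection; rate calibration
  r = Ks/(2t) from a dated speciation anchor and event dating
  age = Ks/(2r); LTR retrotransposon insertion ages T = d/(2μ) at
  μ = 1.3e−8 substitutions/site/year; k-mer genome size
  = total k-mers / homozygous peak depth.
* **LTR lifecycle** — intact / solo / truncated classification from Gag-Pol
  and similarity evidence (library hit at E < 1e−10, overlap > 90%,
  identity > 90%; flanking Gag-Pol coverage ≥ 50%, identity ≥ 30% at
  E < 1e−8), single-linkage family clustering (70% mutual coverage, 60%
  identity) and removal-rate statistics (S:I, T:I, fraction of clusters
  with S:I > 3).

A seeded synthetic-data generator (`sim_config()`,
`generate_diploid_annotation()`, `simulate_counts()`, …) emits every input
the pipeline consumes — GFF3 annotation, CDS/promoter FASTA, TE BED, count
matrix and sample sheet, motif set, Ks samples, LTR records, k-mer
histogram — together with a planted truth table, so every stage has
recovery tests and the whole pipeline runs end to end without downloads.

## Worked example

```r
library(allelome)

## Date the recent WGD: calibrate the synonymous rate from a speciation
## anchor (Ks = 0.7 at 63.57 MYA), then date the paralog Ks peak at 0.3.
cal <- calibrate_rate(0.7, 63.57e6)
date_event(0.3, cal, label = "recent WGD")
#>        event ks_peak age_years  age_mya
#> 1 recent WGD     0.3  27244286 27.24429

## A small end-to-end synthetic run (2 chromosome pairs x 60 genes).
cfg <- sim_config(seed = 1, n_chromosome_pairs = 2, genes_per_chromosome = 60,
                  block_size = 20, n_ltr = 200, n_ks = 2000, cds_codons = 150)
rep <- run_pipeline(cfg, outdir = tempfile("demo_"), cluster_ltr = FALSE)
print(rep)
#> allelome run report
#>   seed 1; stages: pairing, ase, kaks, tfbs, te, coexpr, dating, ltr, contrasts
#>   pairing: 108 pairs from 4 blocks
#>   ase: 10 dynamic / 10 stable loci
#>   dating: Ks peaks at 0.30, 0.70
#>   LTR: S:I = 2.47
```

Reading the output: all 108 planted allele pairs (2 × 54 per haplotype
after 10% unpaired noise genes) are recovered in 4 collinear blocks, the
planted WGD decoy blocks having been removed by the Ks filter; exactly 10%
of loci are labelled dynamic and 10% stable; the kernel-density peaks of
the simulated Ks mixture sit at the planted 0.3 and 0.7; the solo:intact
ratio ≈ 2.5 reflects the planted 0.25/0.50/0.25 lifecycle mix under
sampling noise (S:I → 2.0 as n grows). The dated age printed above, 27.24
MYA, is the worked example the acceptance report re-computes.

A command-line front end is installed as `exec/allelome`
(`allelome run-all seed=1 outdir=out`), with subcommands `simulate`,
`run-all` and `report`; exit codes are 0 (ok), 2 (config error), 3 (data
error).

## Vignette

`vignettes/allele-analyses.Rmd` documents the models, the parameter
defaults and their provenance, the synthetic world the generator states,
numerical choices, and known limitations.
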