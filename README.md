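# methcross

Genetic analysis of CpG methylation in two-strain crosses and
recombinant inbred (RI) panels, from whole-genome bisulfite sequencing
(WGBS) pileups.

Inter-individual differences in cytosine methylation are substantially
driven by germline DNA sequence variation, but separating genetic from
stochastic and environmental variation requires a designed cross:
inbred parental strains to define strain differences, reciprocal F1
hybrids to separate allele effects (cis) from trans and
parent-of-origin effects on an identical genetic background, and an RI
panel to map the controlling loci.  `methcross` implements the full
statistical pipeline for that design — aimed at epigenomics
researchers analysing rodent cross data and at methodologists who need
a tested, simulation-backed reference implementation of each stage:

- **Methylation calling** — strand-specific C/T pileups; bisulfite
  conversion rates from unmethylated lambda spike-ins (F1) and a
  non-CpG regression (parentals); unbiased conversion-corrected
  levels `m = 100·max(0, c − t(1−r)/r)/(c+t)`; coverage (≥5× in ≥3
  replicates) and SNP/indel dyad filters.
- **Differential methylation** — two-sided Fisher exact test on
  replicate-pooled counts (exact hypergeometric enumeration),
  Benjamini–Hochberg FDR per analysis universe, 500-bp clustering of
  DMCs into DMRs with direction consistency.
- **Phasing, ASM and imprinting** — read-pair phasing by parental SNP
  alleles (C/T SNPs excluded; ties discarded), allele-specific
  methylation via the reciprocal-cross maternal/paternal comparison
  scheme, and parent-of-origin regions requiring direction-consistent
  significance on both genotype backgrounds.
- **Meth-QTL mapping** — single-marker LOD scans
  (`LOD = −(n/2)·log10(1−r²)`), Churchill–Doerge permutation
  p-values, the 5-Mbp cis/trans rule, intraclass-correlation
  heritability and cis variance explained.
- **Phenotype correlation (QTM)** — per-strain outlier screening
  (boxplot ∪ Grubbs ∪ Nalimov), Pearson correlation with BH control.
- **Sequence context** — nearest-SNP distance curves (CpG-disrupting
  SNPs tracked separately), position frequency matrices with
  information content against a non-uniform genomic background, and
  flanking AT→GC / GC→AT allele-change effects.
- **Profile structure** — hypergeometric downsampling to common
  depth, Ward clustering with within/between-group distances, PCA.
- **Synthetic crosses with known truth** — a first-class generator
  for parental, reciprocal-F1 and RI data (imprinted regions,
  cis/trans control, conversion failure, base error, phenotype
  coupling), so every stage has a recovery oracle.

## Worked example

Simulate the default study design (4 BN + 4 SHR + 4 of each reciprocal
F1 cross), call differential methylation and imprinting, and map
meth-QTL in a simulated RI panel:

```r
library(methcross)

cfg   <- sim_config(n_cpg = 4000, frac_dm = 0.02, n_imprinted = 2)
truth <- simulate_truth(cfg, seed = 42)
pl    <- simulate_pileups(truth, sim_design(), depth = 30, seed = 43)

conv  <- estimate_conversion_rates(pl$lambda, pl$noncpg, pl$design)
head(conv, 3)
#>   sample_id r_lambda r_noncpg    r_s   ok
#> 1      bn_1       NA   0.9834 0.9830 TRUE
#> 2      bn_2       NA   0.9918 0.9914 TRUE
#> 3      bn_3       NA   0.9759 0.9756 TRUE
```

Parental conversion rates are predicted from the F1 lambda/non-CpG
regression (hence no direct lambda estimate); all exceed the 0.97
working floor.

```r
rates <- setNames(conv$r_s, conv$sample_id)
par   <- pl$design[pl$design$role %in% c("BN", "SHR"), ]
dm <- call_dmcs_and_dmrs(pl$pileups[pl$pileups$sample_id %in% par$sample_id, ],
                         setNames(par$role, par$sample_id),
                         conv_rates = rates, variants = truth$variants)
sum(dm$dmc$significant)
#> 82        # of 4008 tested strand-specific CpGs, at FDR < 5%

po <- detect_po(pl$allele_pileups)
po$regions[, c("chrom", "start", "end", "n_cpg", "max_mean_diff", "allele")]
#>   chrom  start    end n_cpg max_mean_diff allele
#> 1  chr1 995400 995670    10          93.2      M
#> 2  chr1 997700 997970    10          92.5      M
```

Both planted imprinted regions (10 CpGs, maternal 95% / paternal 5%)
are recovered as single maternally hypermethylated regions with a
~93-point maximal mean difference.

```r
ri  <- simulate_ri_panel(truth, seed = 44)
qtl <- map_meth_qtl(ri, n_perm = 1000, seed = 45)
head(qtl[, c("locus", "peak_marker", "lod", "p", "class", "h2", "r2_cis")], 4)
#>      locus peak_marker  lod        p class    h2 r2_cis
#> 1 locus_01       m4_02 28.6 0.000999   cis 0.988  0.989
#> 2 locus_02       m2_09 33.5 0.000999   cis 0.980  0.995
#> 3 locus_03       m4_03 30.6 0.000999   cis 0.986  0.992
#> 4 locus_04       m3_06 25.4 0.000999   cis 0.976  0.982
```

Cis-controlled methylation loci map back to their controlling markers
with high LOD, permutation p at the 1/(n+1) floor, and near-unit
heritability under the default noise model.  See the methods vignette
(`vignettes/methcross-methods.Rmd`) for the models, parameter
defaults and their rationale.

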