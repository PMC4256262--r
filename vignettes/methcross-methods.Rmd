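---
title: "Genetic analysis of CpG methylation in two-strain crosses: models and methods"
author: "methcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic analysis of CpG methylation in two-strain crosses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcross)
```

# Overview

`methcross` implements the statistical pipeline for dissecting the
genetic control of CpG dinucleotide methylation in a two-strain rodent
cross design: two inbred parental strains (here labelled BN and SHR,
four biological replicates each), reciprocal F1 hybrids (dam listed
first: BNxSHR and SHRxBN), and a panel of recombinant inbred (RI)
strains descended from the same two founders.  From strand-specific
bisulfite-sequencing pileups it derives conversion-corrected
methylation levels, differentially methylated cytosines (DMCs) and
regions (DMRs), allele-specific methylation (ASM) and parent-of-origin
(PO) effects from phased F1 reads, methylation QTL (meth-QTL) with
permutation significance and cis/trans classification, heritability,
phenotype correlation (quantitative trait methylation, QTM), and
sequence-context statistics around differential CpGs.

Every stage can be exercised against the package's own synthetic-data
generator, which emits data together with the ground truth used to
create it, so recovery is measurable.

# Data model and coordinates

Methylation is measured per strand-specific cytosine: a CpG dyad
contributes two sites, one per strand, never collapsed.  A site is
keyed by `(chrom, pos, strand)` where `pos` is the 1-based coordinate
of the cytosine (for minus-strand sites, of the G seen on the forward
strand).  All internal coordinates are 1-based inclusive; only BED
export converts to 0-based half-open.  This avoids off-by-one mistakes
against VCF-style variant tables, which are also 1-based.

# Read processing

Bisulfite alignment itself is out of scope; the package implements the
contracts around it.  `convert_reference()` produces the C-to-T and
G-to-A converted references an aligner is driven with, plus the
SHR-allele-substituted reference (reducing allele-specific mapping
bias for SHR reads) and the N-masked reference for F1 reads of unknown
haplotype.  `preprocess_read_pair()` masks the conversion state (read 1
C→T, read 2 G→A), clips the first base (end-repair artefact) and
applies BWA's running-sum 3' quality trim at Q20.
`filter_and_clip()` removes clonal duplicates, pairs with mapping
quality below 20, pairs aligning under both reference conversions, and
invalid orientations, then clips the 3' ends of overlapping mates so
each fragment position is counted once.

Two details are under-determined by the protocol and were fixed here as
explicit choices: the clonal-duplicate key defaults to the 5'
coordinates of *both* mates plus bisulfite strand (a `leftmost`-only
switch is available), winners are chosen by highest summed base
quality with first-seen tie-breaks; and "higher quality end" in the
overlap rule means higher mean base quality across the overlap, ties
keeping read 1.  Both choices are deterministic, which matters more
for reproducibility than which variant is chosen.

# Conversion-rate estimation and corrected methylation

Bisulfite conversion failure makes unmethylated cytosines read as C,
inflating apparent methylation.  For F1 libraries the conversion rate
$r_s$ is estimated from the unmethylated lambda spike-in as the
fraction of converted calls, $t/(c+t)$.  Parental libraries (no usable
spike-in) are predicted from their genomic non-CpG conversion rate via
an ordinary least-squares fit of lambda conversion on non-CpG
conversion across the F1 samples.  Rates are expected to exceed 0.97;
lower values are flagged.

The corrected methylation level subtracts from the cytosine count the
number of unconverted (falsely methylated-looking) calls expected at
the site.  We estimate that count from the *converted* calls: each of
the $t$ converted calls represents an unmethylated cytosine that
converted (probability $r_s$), so $t\,(1-r_s)/r_s$ unmethylated
cytosines are expected to have failed conversion.  The corrected
percentage is

$$ m \;=\; 100 \cdot \frac{\max\!\big(0,\; c - t\,(1-r_s)/r_s\big)}{c+t}, $$

clamped to $[0,100]$.  This plug-in was chosen over the simpler
$c - (c{+}t)(1-r_s)$ subtraction because it is unbiased: its
expectation is exactly $100\,\theta$ for true methylation $\theta$ at
any conversion rate, whereas the coverage-based subtraction converges
to $100\,\theta\,r_s$ (a 3-point deficit at full methylation and
$r_s = 0.97$).  The converted count is never inflated; only the
cytosine count is corrected.

Site filters mirror standard practice: a site enters an analysis only
with combined C+T coverage of at least 5 in at least three replicates
of every group compared, and any site whose CpG dyad is hit by a SNP
or an indel footprint is removed, because an absent CpG is not a
methylation difference.  Filters run before multiple-testing
correction, so the FDR universe is the post-filter site set of each
analysis (parental, cross, ASM and PO universes are corrected
separately).

# Differential methylation

Replicate counts are pooled per group and each site's 2x2 table
(group x converted/unconverted) is tested with a two-sided Fisher
exact test, computed by full enumeration of the hypergeometric support
under the minimum-likelihood rule (all tables with probability not
exceeding the observed table's, with the customary $10^{-7}$ relative
tie tolerance).  Pooling across replicates, rather than per-replicate
dispersion modelling, is a deliberate fidelity choice: it reproduces
the analysis this design calls for rather than substituting a
beta-binomial model; the cost is that replicate-level overdispersion
is not absorbed, which the synthetic generator also does not simulate.
Benjamini-Hochberg q-values are computed per analysis universe and
sites with $q < 0.05$ are significant.

DMCs are clustered into DMRs by grouping significant sites no more
than 500 bp apart, irrespective of direction; sites at least 500 bp
from the next DMC remain singletons, so clustered plus singleton
counts always partition the total.  Per-region direction consistency
is reported.

# Phasing and allele-specific / parent-of-origin methylation

F1 read pairs are assigned to a parental haplotype by majority vote
over the SNP alleles they cover.  C/T SNPs are never used, since a
converted C is indistinguishable from a T allele; G/A SNPs are
likewise excluded on reverse-converted (OB) pairs, the mirror-image
confound.  An exact vote tie discards the pair as ambiguous; a pair
covering no usable SNP stays unphased.  On error-free reads this
procedure cannot misassign, which the tests verify as an identity.

ASM is detected on pooled phased counts with parental origin matched:
the maternal comparison tests the BN allele of BNxSHR against the SHR
allele of SHRxBN, the paternal comparison the BN allele of SHRxBN
against the SHR allele of BNxSHR.  Each comparison is Fisher-tested
and BH-corrected over its own testable universe (sites with 5x
coverage in at least three replicates of *each* phased read set); a
site is ASM when significant in either comparison.  A site significant
in both with opposite signs is kept but flagged discordant.  Whether
the published analysis corrected the two comparisons jointly or
separately is not stated; separate correction was chosen and is the
conservative reading of "either or both".

PO effects compare maternal against paternal transmission within each
genotype background (BN allele in BNxSHR vs BN allele in SHRxBN, and
the SHR analogue).  Only sites significant in both comparisons with
the same sign are PO; PO sites cluster into regions by the 500-bp
rule, reporting the maximum mean maternal-paternal difference and
which allele (M/P) is hypermethylated.  This two-background
consistency requirement is what separates genuine imprinting from
genotype-driven ASM, and the generator's genotype-only truths are
used to verify that PO calls stay at the false-positive floor.

# Meth-QTL mapping in the RI panel

Strain-mean methylation is treated as a quantitative trait.  For a
two-genotype RI panel single-marker linkage reduces to the
correlation form

$$ \mathrm{LOD} = -\tfrac{n}{2}\,\log_{10}\!\big(1 - r^2\big), $$

with $r$ the Pearson correlation between the coded genotype (B = 0,
S = 1) and the trait over the $n$ strains.  Genome-wide significance
is assessed by permuting trait values across strains and comparing
the observed maximum LOD with the permuted maxima,
$p = (1 + \#\{\max \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$.  The
default is 10^3^-10^4^ permutations — the add-one estimator cannot
return zero, and the vignette-scale analyses in this package use 1000,
the customary minimum for declaring non-significance.  A linkage is
cis when the peak marker lies within 5 Mbp of the methylation locus on
the same chromosome, trans otherwise, and NSL when $p \ge 0.05$.

Heritability uses the intraclass correlation from a one-way ANOVA of
replicate values across strains, $h^2 = (MS_B - MS_W)/(MS_B + (k-1)
MS_W)$ with $k$ the replicates per strain, clamped to $[0,1]$; the
exact estimator behind the published heritabilities is not restated in
the source methods, so the intraclass correlation — the standard
choice for strain panels — is documented here as an assumption.
Variance explained in cis is the squared correlation of strain means
with the coded peak genotype; on simulation it stays below $h^2$ up to
Monte-Carlo error, as it must.

# Phenotype correlation (QTM)

Raw phenotype replicates are screened for outliers once (no
iteration) per strain with the union of three flags: the boxplot
fences (1.5 IQR), the Grubbs test and the Nalimov test, both at
$\alpha = 0.05$ with critical values from the t-distribution form
(the Nalimov critical value is the Grubbs value scaled by
$\sqrt{n/(n-1)}$, which reproduces the published Nalimov tables at
$n-2$ degrees of freedom).  The union rule was chosen because all
three screens are listed as applied; with fewer than three values only
the boxplot rule can act.  Strain/trait means are then correlated with
strain-mean methylation by Pearson's test, BH-corrected over all
tested pairs; constant vectors are skipped and reported as untested.

# Sequence context

Distances from each CpG to its nearest SNP are interval distances to
the dyad; SNPs falling *inside* a dyad are CpG-disrupting and are
excluded from the ordinary distance but tracked in a separate curve,
so disruption enrichment can be ruled out independently.  Each CpG
contributes once per set.  Nucleotide preference around differential
CpGs is summarised as position frequency matrices over the 5 bp on
each side of the dyad, with per-position information content computed
as relative entropy against the genomic background (A/T 29%, C/G 21%)
— the only definition consistent with a non-uniform background; a
column at background frequencies scores exactly zero bits.  Allele
changes at the immediately flanking base are classified AT→GC, GC→AT
or neutral in the BN→SHR direction and cross-tabulated against the
sign of the methylation difference.

# Profile structure

Sample-level analyses equalise coverage by hypergeometric
downsampling of each site's calls to exactly 5 (integer-preserving and
mean-preserving), restrict to complete cases (5x in every included
sample or phased set) and drop variant-affected dyads.  Hierarchical
clustering uses Euclidean distances and Ward's minimum variance
method (`ward.D2`, the formulation consistent with raw Euclidean
input); PCA is centred, optionally unit-variance scaled, with each
component's sign fixed by forcing its largest-magnitude loading
positive so runs are comparable.

# The synthetic-data generator

`simulate_truth()` draws per-CpG methylation from a bimodal mixture
(most sites highly methylated, a ~10% low tail), marks 0.7% of CpGs
differentially methylated between the strains with effect sizes
uniform on 0.2-0.8, plants imprinted regions (default two regions of
ten CpGs at 30 bp spacing, maternal 0.95 / paternal 0.05), and lays
down SNPs at a background density of one per 750 bp with 5.3% of
differential CpGs given a SNP within 5 bp of the dyad — the set-points
of the emulated study design.  Conversion rates are drawn per sample
from 0.975-0.995 and a symmetric base error of 10^-3^ is applied after
conversion.  Counts are binomial at fixed depth; F1 samples split
depth binomially between the two alleles, and imprinted sites
methylate by the parental origin the cross implies.  The RI generator
produces marker-block mosaic genotypes (10 markers per toy
chromosome, adjacent-marker recombination 0.1), methylation loci
controlled in cis by the nearest marker or in trans by a marker on
another chromosome, and one phenotype coupled to a cis locus at a
target Pearson correlation of -0.75.

What the generator does *not* emulate: replicate-level biological
overdispersion (counts are exactly binomial), mapping artefacts,
non-CpG methylation, chromosome-scale methylation domains, and any
realistic read-error profile.  Passing recovery tests therefore
demonstrates correctness of the inferential machinery under its own
model, not robustness to the full noise structure of real WGBS data.

# Problem sizes and numerical choices

The test and acceptance analyses run at desk scale by design: 2,000 to
100,000 CpGs, depth 30, four replicates per group, 29-30 RI strains,
1,000 permutations per trait, 20-seed repetition for frequency
claims.  Genome-scale counts from the emulated study (tens of
thousands of DMCs among 10.6 million CpGs) are functions of the full
data and are not reproduced; the pipeline reproduces the *rates*,
recoveries and worked-example arithmetic instead.  Notable numerical
guards: Fisher tables with a zero group total are errors, not NaNs;
zero-variance traits give LOD 0 and monomorphic markers are skipped;
heritability guards the 0/0 case to 0; downsampling requires coverage
at or above target (enforced upstream by the complete-case filter);
and every stochastic step takes an explicit seed.

# Known limitations

Pooled Fisher testing ignores replicate overdispersion, so its FDR
control is exact only under the binomial model; the 5-Mbp cis window
on toy maps shorter than 5 Mbp makes every same-chromosome linkage
cis, which matches the scaled geometry but should be reconsidered for
real maps; phasing votes per read pair without haplotype assembly; and
the PO test requires testability in all four phased read sets, which
on real data concentrates power in SNP-dense regions.
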