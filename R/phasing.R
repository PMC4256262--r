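## Phasing of F1 read pairs by parental SNP alleles, and detection of
## allele-specific (ASM) and parent-of-origin (PO) methylation from the
## reciprocal-cross comparison scheme.
##
## Cross naming follows the dam-first convention: in the (BNxSHR)F1
## cross the BN allele is maternally derived; in (SHRxBN)F1 the SHR
## allele is.

.snp_usable <- function(variants, bs_strand) {
  v <- variants[variants$kind == "snp", , drop = FALSE]
  pair <- paste(pmin(v$bn_allele, v$shr_allele),
                pmax(v$bn_allele, v$shr_allele))
  keep <- pair != "C T"
  if (bs_strand %in% c("OB", "G2A")) keep <- keep & pair != "A G"
  v[keep, , drop = FALSE]
}

#' Phase a read pair by its SNP alleles
#'
#' Determines the parental haplotype of a read pair from the SNP
#' alleles it covers.  C/T SNPs are never used (bisulfite conversion is
#' indistinguishable from the allele); G/A SNPs are additionally
#' excluded on reverse-converted (OB) pairs for the symmetric reason.
#' The majority allele wins; an exact tie is `"ambiguous"` (discarded
#' downstream) and a pair covering no usable, matchable SNP is
#' `"unphased"`.
#'
#' @param pair One-row data frame or list with `chrom`, `start1`,
#'   `start2`, `seq1`, `seq2`, `bs_strand`.
#' @param variants Variant table.
#' @return One of `"BN"`, `"SHR"`, `"ambiguous"`, `"unphased"`.
#' @export
phase_read_pair <- function(pair, variants) {
  v <- .snp_usable(variants, pair$bs_strand)
  v <- v[v$chrom == pair$chrom, , drop = FALSE]
  votes <- c(BN = 0L, SHR = 0L)
  look <- function(seq, start) {
    end <- start + nchar(seq) - 1L
    vv <- v[v$pos >= start & v$pos <= end, , drop = FALSE]
    if (nrow(vv) == 0L) return()
    obs <- substr(rep(seq, nrow(vv)), vv$pos - start + 1L,
                  vv$pos - start + 1L)
    votes["BN"] <<- votes["BN"] + sum(obs == vv$bn_allele)
    votes["SHR"] <<- votes["SHR"] + sum(obs == vv$shr_allele)
  }
  look(pair$seq1, pair$start1)
  look(pair$seq2, pair$start2)
  if (sum(votes) == 0L) return("unphased")
  if (votes["BN"] == votes["SHR"]) return("ambiguous")
  names(votes)[which.max(votes)]
}

#' Phase all pairs of a read set
#'
#' @param pairs Data frame of (filtered) read pairs.
#' @param variants Variant table.
#' @return `pairs` with an added `phase` column.
#' @export
phase_reads <- function(pairs, variants) {
  pairs$phase <- vapply(seq_len(nrow(pairs)), function(i)
    phase_read_pair(pairs[i, ], variants), character(1))
  pairs
}

#' Build allele-resolved methylation profiles from phased reads
#'
#' Piles up cytosine/thymine calls separately for BN- and SHR-phased
#' reads of one F1 sample; ambiguous and unphased pairs are excluded.
#'
#' @param phased_pairs Output of [phase_reads()] after
#'   [filter_and_clip()].
#' @param sites Cytosine site table (`chrom`, `pos`, `strand`).
#' @param sample_id Sample identifier.
#' @param cross `"BNxSHR"` or `"SHRxBN"` (dam first).
#' @return Data frame with `chrom`, `pos`, `strand`, `sample_id`,
#'   `cross`, `allele`, `c_count`, `t_count`.
#' @export
build_allele_profiles <- function(phased_pairs, sites, sample_id, cross) {
  stopifnot(cross %in% c("BNxSHR", "SHRxBN"))
  out <- lapply(c("BN", "SHR"), function(al) {
    sub <- phased_pairs[phased_pairs$phase == al, , drop = FALSE]
    p <- pileup_cytosines(sub, sites, sample_id)
    data.frame(chrom = p$chrom, pos = p$pos, strand = p$strand,
               sample_id = sample_id, cross = cross, allele = al,
               c_count = p$c_count, t_count = p$t_count,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[res$c_count + res$t_count > 0, , drop = FALSE]
}

## Filter + pool allele pileups: a site is testable for a phased read
## set (cross, allele) iff >= min_reps replicates reach min_cov; pooled
## counts per (site, cross, allele) are returned for sites testable in
## all four sets.
.pool_allele <- function(allele_pileups, min_cov = 5L, min_reps = 3L) {
  a <- allele_pileups
  key <- paste(a$chrom, a$pos, a$strand)
  cell <- paste(a$cross, a$allele)
  covok <- (a$c_count + a$t_count) >= min_cov
  cnt <- tapply(covok, list(key, cell), sum, default = 0L)
  if (ncol(cnt) < 4) stop("need both crosses and both alleles")
  pass <- rownames(cnt)[apply(cnt >= min_reps, 1, all)]
  a <- a[key %in% pass, , drop = FALSE]
  key <- paste(a$chrom, a$pos, a$strand)
  cell <- paste(a$cross, a$allele)
  C <- tapply(a$c_count, list(key, cell), sum, default = 0L)
  T_ <- tapply(a$t_count, list(key, cell), sum, default = 0L)
  sk <- do.call(rbind, strsplit(rownames(C), " "))
  ord <- order(sk[, 1], as.integer(sk[, 2]))
  list(sites = data.frame(chrom = sk[ord, 1],
                          pos = as.integer(sk[ord, 2]),
                          strand = sk[ord, 3], stringsAsFactors = FALSE),
       C = C[ord, , drop = FALSE], T_ = T_[ord, , drop = FALSE])
}

.asm_one_comparison <- function(pool, cell1, cell2, fdr) {
  c1 <- pool$C[, cell1]; t1 <- pool$T_[, cell1]
  c2 <- pool$C[, cell2]; t2 <- pool$T_[, cell2]
  p <- fisher_p2(c1, t1, c2, t2)
  q <- bh_fdr(p)
  delta <- 100 * (c1 / (c1 + t1) - c2 / (c2 + t2))
  data.frame(p = p, q = q, delta = delta, sig = q < fdr)
}

#' Detect allele-specific methylation in reciprocal F1 crosses
#'
#' Compares methylation of the two parental alleles on matched
#' parental origin: the maternal comparison tests the BN allele of
#' (BNxSHR)F1 against the SHR allele of (SHRxBN)F1, the paternal
#' comparison the BN allele of (SHRxBN)F1 against the SHR allele of
#' (BNxSHR)F1.  Each comparison is Fisher-tested per site and
#' BH-corrected over its own testable universe; a site is ASM when
#' significant in either or both comparisons (a site significant in
#' both with opposite signs is kept but flagged discordant).
#'
#' @param allele_pileups Replicate-level allele-tagged counts
#'   (`chrom`, `pos`, `strand`, `sample_id`, `cross`, `allele`,
#'   `c_count`, `t_count`).
#' @param fdr FDR threshold per comparison.
#' @param min_cov,min_reps Phased-read-set site filter.
#' @return Data frame per testable site with per-comparison `p`/`q`,
#'   allele differences (`delta_mat`, `delta_pat`, BN minus SHR), the
#'   `asm` call and a `discordant` flag.
#' @export
detect_asm <- function(allele_pileups, fdr = 0.05, min_cov = 5L,
                       min_reps = 3L) {
  pool <- .pool_allele(allele_pileups, min_cov, min_reps)
  mat <- .asm_one_comparison(pool, "BNxSHR BN", "SHRxBN SHR", fdr)
  pat <- .asm_one_comparison(pool, "SHRxBN BN", "BNxSHR SHR", fdr)
  out <- pool$sites
  out$p_maternal <- mat$p; out$q_maternal <- mat$q
  out$delta_mat <- mat$delta
  out$p_paternal <- pat$p; out$q_paternal <- pat$q
  out$delta_pat <- pat$delta
  out$asm <- mat$sig | pat$sig
  out$discordant <- mat$sig & pat$sig & sign(mat$delta) != sign(pat$delta)
  out
}

#' Detect parent-of-origin specific methylation
#'
#' Compares methylation on the maternal and paternal allele separately
#' within the BN-derived chromosomes (BN allele in BNxSHR, maternal,
#' vs BN allele in SHRxBN, paternal) and within the SHR-derived
#' chromosomes.  A site is called PO only when both comparisons are
#' significant with the same sign; PO sites are clustered into regions
#' at the `gap` rule, reporting each region's maximum mean
#' maternal-paternal difference and which allele (M or P) is
#' hypermethylated.
#'
#' @inheritParams detect_asm
#' @param gap Region clustering gap in bp.
#' @return List with `sites` (per-site results and `po` call) and
#'   `regions` (PO regions with `max_mean_diff` in percentage points
#'   and `allele` in `M`/`P`).
#' @export
detect_po <- function(allele_pileups, fdr = 0.05, gap = 500L,
                      min_cov = 5L, min_reps = 3L) {
  pool <- .pool_allele(allele_pileups, min_cov, min_reps)
  ## maternal vs paternal on each genotype background
  bn <- .asm_one_comparison(pool, "BNxSHR BN", "SHRxBN BN", fdr)
  shr <- .asm_one_comparison(pool, "SHRxBN SHR", "BNxSHR SHR", fdr)
  out <- pool$sites
  out$p_bn <- bn$p; out$q_bn <- bn$q; out$delta_bn <- bn$delta
  out$p_shr <- shr$p; out$q_shr <- shr$q; out$delta_shr <- shr$delta
  out$po <- bn$sig & shr$sig & sign(bn$delta) == sign(shr$delta) &
    bn$delta != 0
  po_sites <- out[out$po, , drop = FALSE]
  if (nrow(po_sites)) {
    po_sites$delta_m <- (po_sites$delta_bn + po_sites$delta_shr) / 2
    regions <- cluster_dmrs(po_sites, gap = gap)
    regions$max_mean_diff <- vapply(regions$members, function(idx)
      max(abs(po_sites$delta_m[idx])), numeric(1))
    regions$allele <- vapply(regions$members, function(idx)
      if (mean(po_sites$delta_m[idx]) > 0) "M" else "P", character(1))
  } else {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), n_cpg = integer(),
                          max_mean_diff = numeric(), allele = character())
  }
  list(sites = out, regions = regions)
}

#' Differential methylation between the reciprocal crosses
#'
#' Standard two-group differential methylation on the unphased F1
#' pileups with groups BNxSHR vs SHRxBN.
#'
#' @param pileups Unphased F1 pileups.
#' @param design Sample sheet (`sample_id`, `role` with the F1 roles).
#' @param ... Passed to [call_dmcs_and_dmrs()].
#' @return As [call_dmcs_and_dmrs()].
#' @export
detect_cross_dm <- function(pileups, design, ...) {
  f1 <- design[grepl("^F1", design$role), ]
  groups <- stats::setNames(sub("F1_", "", f1$role), f1$sample_id)
  call_dmcs_and_dmrs(pileups[pileups$sample_id %in% f1$sample_id, ],
                     groups, ...)
}
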