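## Pre- and post-alignment read handling for bisulfite data and the
## strand-specific cytosine pileup.  Alignment itself is consumed, not
## performed: pairs arrive as coordinate-anchored records (the
## SAM-subset produced by the read simulator or an external aligner).

#' In silico conversion of a reference sequence
#'
#' Produces the converted reference sequences a bisulfite aligner is
#' driven with: `C2T` converts every C to T (forward converted
#' strand), `G2A` every G to A (reverse converted strand),
#' `allele_substitute` replaces the reference base with the SHR allele
#' at SNP positions (to reduce allele-specific mapping bias for SHR
#' reads), and `snp_mask` replaces every SNP position with N (for F1
#' reads of unknown haplotype).
#'
#' @param seq A single reference sequence string over A/C/G/T/N.
#' @param mode One of `"C2T"`, `"G2A"`, `"allele_substitute"`,
#'   `"snp_mask"`.
#' @param variants Variant table (required for the last two modes);
#'   only `kind == "snp"` rows are used.
#' @return The converted sequence (same length).
#' @export
convert_reference <- function(seq, mode = c("C2T", "G2A",
                                            "allele_substitute", "snp_mask"),
                              variants = NULL) {
  mode <- match.arg(mode)
  if (mode == "C2T") return(chartr("C", "T", seq))
  if (mode == "G2A") return(chartr("G", "A", seq))
  if (is.null(variants)) stop("variants required for mode ", mode)
  snp <- variants[variants$kind == "snp", , drop = FALSE]
  if (any(snp$pos > nchar(seq)))
    stop("variant position outside the sequence")
  s <- strsplit(seq, "")[[1]]
  if (mode == "snp_mask") s[snp$pos] <- "N"
  else s[snp$pos] <- snp$shr_allele
  paste(s, collapse = "")
}

## BWA-style 3' quality trimming: keep the prefix 1..i that maximises
## sum_{j>i} (qcut - q_j); no trimming when every suffix sum is <= 0.
.bwa_trim_len <- function(qual, qcut) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  if (L == 0L) return(0L)
  s <- rev(cumsum(rev(qcut - q)))  # s[i] = sum_{j>=i}(qcut - q_j)
  best <- max(s)
  if (best <= 0) return(L)
  cut <- max(which(s == best))     # trim from position `cut` onwards
  cut - 1L
}

#' Pre-process a read pair before bisulfite alignment
#'
#' Applies the pre-alignment contract: conversion-state masking (all C
#' calls of read 1 become T, all G calls of read 2 become A), clipping
#' of the first base of each read (end-repair artefact), and 3'
#' quality trimming with the BWA running-sum rule at the given cutoff.
#'
#' @param pair List or one-row data frame with `seq1`, `qual1`,
#'   `seq2`, `qual2` (phred+33 quality strings).
#' @param qcut Quality cutoff for 3' trimming.
#' @return List with masked/trimmed `seq1`, `qual1`, `seq2`, `qual2`
#'   and a logical `empty` flag set when a read lost all its bases.
#' @export
preprocess_read_pair <- function(pair, qcut = 20L) {
  one <- function(seq, qual, mask_from, mask_to) {
    seq <- chartr(mask_from, mask_to, seq)
    ## first-base clip
    seq <- substr(seq, 2L, nchar(seq))
    qual <- substr(qual, 2L, nchar(qual))
    keep <- .bwa_trim_len(qual, qcut)
    list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
  }
  r1 <- one(pair$seq1, pair$qual1, "C", "T")
  r2 <- one(pair$seq2, pair$qual2, "G", "A")
  list(seq1 = r1$seq, qual1 = r1$qual, seq2 = r2$seq, qual2 = r2$qual,
       empty = nchar(r1$seq) == 0L || nchar(r2$seq) == 0L)
}

.mean_qual <- function(qual, from, to) {
  if (to < from) return(-Inf)
  mean(utf8ToInt(substr(qual, from, to)) - 33L)
}

#' Post-alignment filtering and overlap clipping of aligned pairs
#'
#' Applies the post-alignment contract: removal of clonal duplicates
#' (one pair kept per duplicate key: highest summed base quality, ties
#' broken first-seen), of pairs below the mapping-quality cutoff, of
#' pairs mapping to both the converted forward and converted reverse
#' strand, and of pairs with invalid orientation; finally the 3' ends
#' of overlapping mates are clipped so the overlap is covered once, by
#' the mate with the higher mean base quality in the overlap (ties
#' keep read 1).
#'
#' @param pairs Data frame of aligned pairs (`pair_id`, `chrom`,
#'   `start1`, `start2`, `seq1`, `seq2`, `qual1`, `qual2`,
#'   `bs_strand`, `mapq`).
#' @param mapq_min Mapping-quality cutoff.
#' @param dup_key `"both"` keys duplicates on the 5' coordinates of
#'   both mates plus strand; `"leftmost"` on the leftmost coordinate
#'   plus strand only.
#' @return The retained pairs with effective (overlap-clipped) mate
#'   intervals in `start1_eff`/`end1_eff`/`start2_eff`/`end2_eff`.
#' @export
filter_and_clip <- function(pairs, mapq_min = 20L,
                            dup_key = c("both", "leftmost")) {
  dup_key <- match.arg(dup_key)
  p <- pairs
  ## dual-strand mappers: same pair aligned under both conversions
  tab <- table(p$pair_id, p$bs_strand)
  dual <- rownames(tab)[rowSums(tab > 0) > 1]
  p <- p[!(p$pair_id %in% dual), , drop = FALSE]
  ## mapping quality
  p <- p[p$mapq >= mapq_min, , drop = FALSE]
  ## orientation: mate 2 must not start before mate 1
  p <- p[p$start2 >= p$start1, , drop = FALSE]
  if (nrow(p) == 0L) return(cbind(p, start1_eff = integer(0)))
  ## clonal duplicates
  key <- if (dup_key == "both")
    paste(p$chrom, p$start1, p$start2, p$bs_strand)
  else paste(p$chrom, p$start1, p$bs_strand)
  sumq <- vapply(seq_len(nrow(p)), function(i)
    sum(utf8ToInt(p$qual1[i]) - 33L) + sum(utf8ToInt(p$qual2[i]) - 33L),
    numeric(1))
  ord <- order(key, -sumq, seq_len(nrow(p)))
  p <- p[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  p <- p[order(p$chrom, p$start1), , drop = FALSE]

  ## overlap clipping
  end1 <- p$start1 + nchar(p$seq1) - 1L
  end2 <- p$start2 + nchar(p$seq2) - 1L
  p$start1_eff <- p$start1; p$end1_eff <- end1
  p$start2_eff <- p$start2; p$end2_eff <- end2
  ov <- which(p$start2 <= end1)
  for (i in ov) {
    a <- p$start2[i]; b <- min(end1[i], end2[i])
    q1 <- .mean_qual(p$qual1[i], a - p$start1[i] + 1L, b - p$start1[i] + 1L)
    q2 <- .mean_qual(p$qual2[i], 1L, b - a + 1L)
    if (q1 >= q2) p$start2_eff[i] <- b + 1L   # clip mate2's overlapping end
    else p$end1_eff[i] <- a - 1L              # clip mate1's 3' end
  }
  rownames(p) <- NULL
  p
}

#' Strand-specific cytosine pileup
#'
#' Counts cytosine and thymine base calls at each requested cytosine
#' position from filtered, overlap-clipped pairs.  Forward-strand
#' cytosines are piled up from OT (C-to-T aligned) pairs, counting
#' C as methylated and T as converted; reverse-strand cytosines (whose
#' forward-coordinate base is G) from OB (G-to-A) pairs, counting G as
#' methylated (reported in `c_count`) and A as converted (`t_count`).
#' Any other base call increments `other_count`.
#'
#' @param pairs Output of [filter_and_clip()].
#' @param sites Data frame of cytosine sites (`chrom`, `pos`,
#'   `strand`); for `strand == "-"` `pos` is the forward coordinate of
#'   the G of the dyad.
#' @param sample_id Sample identifier stamped on the records.
#' @return Pileup data frame in the standard schema.
#' @export
pileup_cytosines <- function(pairs, sites, sample_id = "sample") {
  n <- nrow(sites)
  cc <- integer(n); tt <- integer(n); oo <- integer(n)
  want_strand <- ifelse(sites$strand == "+", "OT", "OB")
  meth_base <- ifelse(sites$strand == "+", "C", "G")
  conv_base <- ifelse(sites$strand == "+", "T", "A")
  for (i in seq_len(n)) {
    ps <- pairs[pairs$chrom == sites$chrom[i] &
                  pairs$bs_strand == want_strand[i], , drop = FALSE]
    if (nrow(ps) == 0L) next
    pos <- sites$pos[i]
    for (j in seq_len(nrow(ps))) {
      base <- NA_character_
      if (pos >= ps$start1_eff[j] && pos <= ps$end1_eff[j])
        base <- substr(ps$seq1[j], pos - ps$start1[j] + 1L,
                       pos - ps$start1[j] + 1L)
      else if (pos >= ps$start2_eff[j] && pos <= ps$end2_eff[j])
        base <- substr(ps$seq2[j], pos - ps$start2[j] + 1L,
                       pos - ps$start2[j] + 1L)
      if (is.na(base)) next
      if (base == meth_base[i]) cc[i] <- cc[i] + 1L
      else if (base == conv_base[i]) tt[i] <- tt[i] + 1L
      else oo[i] <- oo[i] + 1L
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
             sample_id = sample_id, c_count = cc, t_count = tt,
             other_count = oo, stringsAsFactors = FALSE)
}
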