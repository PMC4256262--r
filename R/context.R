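## Sequence-context statistics around differentially methylated CpGs:
## nearest-SNP distance distributions, background-corrected position
## frequency matrices with information content, and the effect of
## immediately adjacent allele changes on the direction of the
## methylation difference.

.GENOME_BG <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)

## nearest distance from each query position to a sorted vector of
## positions (same chromosome), interval distance to the CpG dyad
.nearest_dist <- function(qstart, qend, pos_sorted) {
  if (length(pos_sorted) == 0) return(rep(Inf, length(qstart)))
  i <- findInterval(qstart, pos_sorted)
  left <- ifelse(i >= 1, qstart - pos_sorted[pmax(i, 1)], Inf)
  right <- ifelse(i < length(pos_sorted),
                  pos_sorted[pmin(i + 1, length(pos_sorted))] - qend, Inf)
  j <- findInterval(qend, pos_sorted)
  inside <- j > i                  # some SNP within [qstart, qend]
  d <- pmax(0, pmin(left, right))
  d[inside] <- 0
  d
}

#' Distance-to-nearest-SNP statistics for CpG site sets
#'
#' For each named set of CpG sites computes the distance to the
#' nearest SNP (interval distance to the CpG dyad; SNPs falling inside
#' the dyad are CpG-disrupting and are excluded from the ordinary
#' distance but tracked in a separate disrupting-SNP curve) and the
#' cumulative fraction of CpGs with a SNP within `x` bp for
#' `x = 1..max_x`.
#'
#' @param cpg_sets Named list of site data frames (`chrom`, `pos`,
#'   `strand`); each CpG contributes once per set.
#' @param variants Variant table (SNPs used).
#' @param max_x Largest distance cutoff for the cumulative curves.
#' @return List with `distances` (per-set numeric vectors),
#'   `cumulative` (matrix, sets x cutoffs), `disrupting_cumulative`
#'   and a helper `fold(setA, setB, x)` computing enrichment between
#'   two sets at a cutoff.
#' @export
nearest_snp_stats <- function(cpg_sets, variants, max_x = 1000L) {
  snps <- variants[variants$kind == "snp", , drop = FALSE]
  if (nrow(snps) == 0) stop("empty variant table")
  ## a SNP is CpG-disrupting if it falls in any dyad of the union set
  all_sites <- unique(do.call(rbind, lapply(cpg_sets, function(s)
    s[, c("chrom", "pos", "strand")])))
  dy <- .dyad_positions(all_sites)
  dyad_keys <- c(paste(all_sites$chrom, dy[, 1]),
                 paste(all_sites$chrom, dy[, 2]))
  disrupting <- paste(snps$chrom, snps$pos) %in% dyad_keys
  by_chr <- function(v) lapply(split(v$pos, v$chrom), sort)
  snp_cl <- by_chr(snps[!disrupting, , drop = FALSE])
  dis_cl <- by_chr(snps[disrupting, , drop = FALSE])

  dist_for <- function(sites, cl) {
    dyx <- .dyad_positions(sites)
    d <- rep(Inf, nrow(sites))
    for (ch in unique(sites$chrom)) {
      i <- sites$chrom == ch
      d[i] <- .nearest_dist(dyx[i, 1], dyx[i, 2], cl[[ch]])
    }
    d
  }
  distances <- lapply(cpg_sets, dist_for, cl = snp_cl)
  dis_distances <- lapply(cpg_sets, dist_for, cl = dis_cl)
  cum <- function(dl) t(vapply(dl, function(d)
    vapply(seq_len(max_x), function(x) mean(d <= x), numeric(1)),
    numeric(max_x)))
  cumulative <- cum(distances)
  colnames(cumulative) <- seq_len(max_x)
  disrupting_cumulative <- cum(dis_distances)
  colnames(disrupting_cumulative) <- seq_len(max_x)
  fold <- function(setA, setB, x) {
    fa <- mean(distances[[setA]] <= x); fb <- mean(distances[[setB]] <= x)
    if (fb == 0) return(NA_real_)
    fa / fb
  }
  list(distances = distances, cumulative = cumulative,
       disrupting_cumulative = disrupting_cumulative, fold = fold)
}

#' Extract flanking windows around CpG sites
#'
#' Returns the 12 bp window (5 bp upstream, the CG dyad, 5 bp
#' downstream) around each site, optionally substituting the SHR
#' alleles at SNP positions.
#'
#' @param reference Named character vector of contig sequences.
#' @param sites Site data frame (`chrom`, `pos` of the C; forward
#'   strand coordinates).
#' @param allele `"bn"` (reference) or `"shr"` (substitute SHR SNP
#'   alleles).
#' @param variants Variant table (needed for `allele = "shr"`).
#' @return Character vector of 12-mers.
#' @export
extract_windows <- function(reference, sites, allele = c("bn", "shr"),
                            variants = NULL) {
  allele <- match.arg(allele)
  seqs <- reference
  if (allele == "shr") {
    if (is.null(variants)) stop("variants required for SHR windows")
    for (ch in unique(sites$chrom))
      seqs[[ch]] <- convert_reference(seqs[[ch]], "allele_substitute",
                                      variants[variants$chrom == ch, ])
  }
  vapply(seq_len(nrow(sites)), function(i)
    substr(seqs[[sites$chrom[i]]], sites$pos[i] - 5L, sites$pos[i] + 6L),
    character(1))
}

#' Position frequency matrices and information content by direction
#'
#' Builds one position frequency matrix per methylation-direction
#' class (hypermethylated / hypomethylated in SHR) from equal-length
#' 12 bp windows centred on the CpG, and computes the per-position
#' information content as the relative entropy of the observed base
#' frequencies against the genomic background
#' (`IC_j = sum_i p_ij log2(p_ij / b_i)`, with `0 log 0 = 0`).  The
#' two dyad columns are excluded.
#'
#' @param windows Character vector of 12-mers (positions -5..-1, C, G,
#'   +1..+5).
#' @param direction Numeric or character vector: positive /
#'   `"hyper"` for increased methylation in SHR, negative / `"hypo"`
#'   for decreased.
#' @param background Named base frequencies summing to 1.
#' @return List with elements `hyper` and `hypo`, each a list of
#'   `pfm` (4 x 10 counts, columns -5..-1, +1..+5) and `ic` (bits per
#'   position).
#' @export
build_pfm_ic <- function(windows, direction,
                         background = .GENOME_BG) {
  stopifnot(length(windows) == length(direction),
            abs(sum(background) - 1) < 1e-9)
  if (is.numeric(direction))
    direction <- ifelse(direction > 0, "hyper", "hypo")
  flank_cols <- c(1:5, 8:12)
  lab <- c(paste0("-", 5:1), paste0("+", 1:5))
  one_class <- function(w) {
    if (length(w) == 0) stop("empty direction class")
    m <- do.call(rbind, strsplit(w, ""))[, flank_cols, drop = FALSE]
    pfm <- vapply(seq_len(ncol(m)), function(j)
      table(factor(m[, j], levels = names(background))), numeric(4))
    colnames(pfm) <- lab
    p <- sweep(pfm, 2, colSums(pfm), "/")
    ic <- vapply(seq_len(ncol(p)), function(j) {
      pj <- p[, j]
      sum(ifelse(pj > 0, pj * log2(pj / background), 0))
    }, numeric(1))
    names(ic) <- lab
    list(pfm = pfm, ic = ic)
  }
  list(hyper = one_class(windows[direction == "hyper"]),
       hypo = one_class(windows[direction == "hypo"]))
}

#' Association of adjacent allele changes with methylation direction
#'
#' For differentially methylated CpGs with a SNP at the immediately
#' flanking base (one bp upstream of the C or one bp downstream of the
#' G), classifies the BN-to-SHR allele change as `AT>GC`, `GC>AT` or
#' `neutral` (within-class change) and cross-tabulates the two
#' directional classes against the sign of the methylation difference
#' (increased vs decreased in SHR), reporting the odds ratio and a
#' Fisher exact p.
#'
#' @param dm_sites Data frame with `chrom`, `pos` (forward coordinate
#'   of the C) and `delta_shr` (`m_SHR - m_BN`, percentage points).
#' @param variants Variant table.
#' @return List with `table` (class x direction counts including
#'   neutral), `odds_ratio` (AT>GC vs GC>AT for SHR-up vs SHR-down)
#'   and `p`.
#' @export
adjacent_allele_effects <- function(dm_sites, variants) {
  snps <- variants[variants$kind == "snp", , drop = FALSE]
  skey <- paste(snps$chrom, snps$pos)
  rows <- list()
  for (i in seq_len(nrow(dm_sites))) {
    for (fp in c(dm_sites$pos[i] - 1L, dm_sites$pos[i] + 2L)) {
      j <- match(paste(dm_sites$chrom[i], fp), skey)
      if (is.na(j)) next
      bn <- snps$bn_allele[j]; shr <- snps$shr_allele[j]
      cls <- if (bn %in% c("A", "T") && shr %in% c("G", "C")) "AT>GC"
      else if (bn %in% c("G", "C") && shr %in% c("A", "T")) "GC>AT"
      else "neutral"
      rows[[length(rows) + 1]] <- data.frame(
        class = cls,
        dir = if (dm_sites$delta_shr[i] > 0) "shr_up" else "shr_down",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no differentially methylated CpG with a flanking SNP")
  d <- do.call(rbind, rows)
  tab <- table(factor(d$class, c("AT>GC", "GC>AT", "neutral")),
               factor(d$dir, c("shr_up", "shr_down")))
  a <- tab["AT>GC", "shr_up"]; b <- tab["AT>GC", "shr_down"]
  cc <- tab["GC>AT", "shr_up"]; dd <- tab["GC>AT", "shr_down"]
  or <- (a * dd) / max(1e-12, (b * cc))
  p <- if ((a + b) > 0 && (cc + dd) > 0)
    fisher_p2(a, b, cc, dd) else NA_real_
  list(table = tab, odds_ratio = or, p = p)
}
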