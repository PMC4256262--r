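## Single-marker methylation-QTL mapping across a recombinant inbred
## panel: correlation-form LOD scores, permutation significance,
## cis/trans classification, heritability and variance explained.

#' Code a B/S genotype matrix numerically
#'
#' @param G Character matrix (strains x markers) over B/S/NA.
#' @return Numeric matrix with B = 0, S = 1.
#' @export
code_genotypes <- function(G) {
  M <- matrix(NA_real_, nrow(G), ncol(G), dimnames = dimnames(G))
  M[G == "B"] <- 0; M[G == "S"] <- 1
  M
}

#' Single-marker LOD scan of a quantitative trait
#'
#' For each marker the LOD score is `-(n/2) * log10(1 - r^2)` with `r`
#' the Pearson correlation between the coded genotype (B = 0, S = 1)
#' and the trait over strains with non-missing data.  Monomorphic
#' markers are skipped (LOD `NA`); a constant trait scores 0
#' everywhere.
#'
#' @param trait Named numeric vector of strain trait values.
#' @param G Genotype matrix (strains x markers, B/S/NA).
#' @param marker_map Marker map (`marker`, `chrom`, `pos`).
#' @return List with `lod` (per-marker data frame) and `peak` (row of
#'   the maximising marker).
#' @export
lod_scan <- function(trait, G, marker_map) {
  strains <- intersect(names(trait), rownames(G))
  if (length(strains) < 8)
    stop("need at least 8 strains with trait and genotype data")
  y <- trait[strains]
  M <- code_genotypes(G[strains, , drop = FALSE])
  lod <- vapply(colnames(M), function(mk) {
    g <- M[, mk]
    ok <- !is.na(g) & !is.na(y)
    if (sum(ok) < 8) return(NA_real_)
    if (stats::sd(g[ok]) == 0) return(NA_real_)
    if (stats::sd(y[ok]) == 0) return(0)
    r <- stats::cor(g[ok], y[ok])
    -(sum(ok) / 2) * log10(1 - r^2)
  }, numeric(1))
  df <- data.frame(marker = marker_map$marker,
                   chrom = marker_map$chrom, pos = marker_map$pos,
                   lod = lod[marker_map$marker],
                   stringsAsFactors = FALSE)
  peak <- df[which.max(df$lod), ]
  list(lod = df, peak = peak)
}

## max LOD over markers for a trait matrix (strains x traits), used by
## the permutation test; missing-free fast path via matrix algebra
.max_lod_matrix <- function(M, Y) {
  n <- nrow(M)
  Mc <- scale(M); Yc <- scale(Y)
  keep <- !is.na(attr(Mc, "scaled:scale")) & attr(Mc, "scaled:scale") > 0
  Mc <- Mc[, keep, drop = FALSE]
  R <- crossprod(Mc, Yc) / (n - 1)          # markers x traits correlations
  L <- -(n / 2) * log10(pmax(1 - R^2, 1e-300))
  apply(L, 2, max)
}

#' Permutation p-value for a trait's peak LOD
#'
#' Permutes trait values across strains (genotypes fixed), recomputes
#' the genome-wide maximum LOD for every permutation, and reports
#' `p = (1 + #{permuted max >= observed max}) / (n_perm + 1)`.
#'
#' @param trait Named strain trait vector (no missing values).
#' @param G Genotype matrix.
#' @param marker_map Marker map.
#' @param n_perm Number of permutations (values below 1000 trigger a
#'   warning: below the customary minimum).
#' @param seed Integer seed.
#' @return List with `p`, `obs_max_lod` and `n_perm`.
#' @export
permutation_pvalue <- function(trait, G, marker_map, n_perm = 10000L,
                               seed = 1L) {
  if (n_perm < 1000) warning("fewer than 1000 permutations")
  strains <- intersect(names(trait), rownames(G))
  y <- trait[strains]
  M <- code_genotypes(G[strains, , drop = FALSE])
  if (anyNA(M)) {
    ## impute NA genotypes to the marker mean for the permutation scan
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  obs <- .max_lod_matrix(M, matrix(y, ncol = 1))
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  perm_max <- .max_lod_matrix(M, P)
  list(p = (1 + sum(perm_max >= obs)) / (n_perm + 1),
       obs_max_lod = unname(obs), n_perm = n_perm)
}

#' Classify a linkage as cis, trans or not significant
#'
#' Not significant (`"NSL"`) when the permutation p is at or above
#' 0.05; otherwise `"cis"` when the peak marker lies on the same
#' chromosome within `window` bp of the trait's genomic location, else
#' `"trans"`.
#'
#' @param peak One-row data frame with `chrom` and `pos` of the peak
#'   marker.
#' @param trait_chrom,trait_pos Genomic location of the methylation
#'   amplicon / CpG.
#' @param p Permutation p-value.
#' @param window cis window in bp (default 5 Mbp).
#' @return `"cis"`, `"trans"` or `"NSL"`.
#' @export
classify_linkage <- function(peak, trait_chrom, trait_pos, p,
                             window = 5e6) {
  if (p >= 0.05) return("NSL")
  if (peak$chrom == trait_chrom && abs(peak$pos - trait_pos) <= window)
    "cis" else "trans"
}

#' Heritability and cis variance explained
#'
#' Heritability is the intraclass correlation from a one-way ANOVA of
#' replicate values across strains,
#' `h2 = (MSB - MSW) / (MSB + (k - 1) * MSW)` with `k` the (average)
#' number of replicates per strain, clamped to `[0, 1]`; the variance
#' explained at the peak is the squared Pearson correlation of strain
#' means with the coded peak genotype.
#'
#' @param values Data frame with `strain`, `value` (replicate-level).
#' @param peak_genotype Optional named B/S vector (per strain) at the
#'   peak marker.
#' @return List with `h2`, `r2_cis` (NA when no genotype given) and
#'   `k`.
#' @export
heritability_and_r2 <- function(values, peak_genotype = NULL) {
  tab <- table(values$strain)
  if (any(tab < 2)) stop("need >= 2 replicates per strain for h2")
  a <- length(tab); N <- nrow(values)
  k <- (N - sum(tab^2) / N) / (a - 1)       # balanced designs: k = n_rep
  means <- tapply(values$value, values$strain, mean)
  grand <- mean(values$value)
  ssb <- sum(tab * (means[names(tab)] - grand)^2)
  ssw <- sum((values$value - means[values$strain])^2)
  msb <- ssb / (a - 1); msw <- ssw / (N - a)
  denom <- msb + (k - 1) * msw
  h2 <- if (denom == 0) 0 else min(1, max(0, (msb - msw) / denom))
  r2 <- NA_real_
  if (!is.null(peak_genotype)) {
    g <- ifelse(peak_genotype[names(means)] == "S", 1, 0)
    ok <- !is.na(g)
    r2 <- if (stats::sd(g[ok]) > 0) stats::cor(g[ok], means[ok])^2 else NA_real_
  }
  list(h2 = h2, r2_cis = unname(r2), k = k)
}

#' 2-LOD support interval around a peak
#'
#' The contiguous run of markers on the peak chromosome whose LOD is
#' within 2 of the peak LOD.
#'
#' @param lod Per-marker LOD data frame from [lod_scan()].
#' @param drop LOD drop defining the interval.
#' @return One-row data frame with `chrom`, `start`, `end`.
#' @export
lod_support_interval <- function(lod, drop = 2) {
  peak <- lod[which.max(lod$lod), ]
  on_chr <- lod[lod$chrom == peak$chrom, ]
  on_chr <- on_chr[order(on_chr$pos), ]
  pk <- which(on_chr$marker == peak$marker)
  ok <- !is.na(on_chr$lod) & on_chr$lod >= peak$lod - drop
  lo <- pk; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < nrow(on_chr) && ok[hi + 1]) hi <- hi + 1
  data.frame(chrom = peak$chrom, start = on_chr$pos[lo],
             end = on_chr$pos[hi], stringsAsFactors = FALSE)
}

#' Map all methylation traits of an RI panel
#'
#' Convenience scan: strain means over replicates are mapped per
#' locus; each locus gets its peak, permutation p, cis/trans/NSL call,
#' heritability and cis variance explained.
#'
#' @param ri An [simulate_ri_panel()] object (or a list with the same
#'   elements).
#' @param n_perm Permutations per trait.
#' @param seed Integer seed.
#' @param window cis window in bp.
#' @return Data frame, one row per locus.
#' @export
map_meth_qtl <- function(ri, n_perm = 10000L, seed = 1L, window = 5e6) {
  res <- lapply(seq_len(nrow(ri$loci)), function(i) {
    loc <- ri$loci[i, ]
    vals <- ri$meth[ri$meth$locus == loc$locus, ]
    trait <- tapply(vals$value, vals$strain, mean)
    scan <- lod_scan(trait, ri$genotypes, ri$marker_map)
    perm <- permutation_pvalue(trait, ri$genotypes, ri$marker_map,
                               n_perm = n_perm, seed = seed + i)
    cls <- classify_linkage(scan$peak, loc$chrom, loc$pos, perm$p,
                            window = window)
    her <- heritability_and_r2(vals[, c("strain", "value")],
                               ri$genotypes[, scan$peak$marker])
    data.frame(locus = loc$locus, chrom = loc$chrom, pos = loc$pos,
               peak_marker = scan$peak$marker,
               peak_chrom = scan$peak$chrom, peak_pos = scan$peak$pos,
               lod = scan$peak$lod, p = perm$p, class = cls,
               h2 = her$h2, r2_cis = her$r2_cis,
               true_control = loc$control,
               true_marker = loc$controlling_marker,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
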