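## Differential methylation: Fisher exact testing on pooled replicate
## counts, Benjamini-Hochberg FDR, clustering of differentially
## methylated cytosines (DMCs) into regions (DMRs), and set-overlap
## enrichment.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact two-sided p by full enumeration of the hypergeometric support:
#' the sum of the probabilities of all tables (with the observed
#' margins) whose probability does not exceed that of the observed
#' table (minimum-likelihood rule, with the customary 1e-7 relative
#' tolerance for ties).
#'
#' @param c1,t1,c2,t2 Converted/unconverted counts of the two groups
#'   (vectorised; repeated tables are computed once).
#' @return Vector of p-values.
#' @export
fisher_p2 <- function(c1, t1, c2, t2) {
  stopifnot(length(c1) == length(t1), length(c1) == length(c2),
            length(c1) == length(t2))
  one <- function(a, b, cc, d) {
    if (a + b == 0 || cc + d == 0)
      stop("zero total in one group of the Fisher table")
    m <- a + cc; n <- b + d; k <- a + b
    lo <- max(0L, k - n); hi <- min(k, m)
    supp <- lo:hi
    dens <- stats::dhyper(supp, m, n, k)
    sum(dens[dens <= dens[supp == a] * (1 + 1e-7)])
  }
  key <- paste(c1, t1, c2, t2)
  u <- which(!duplicated(key))
  pu <- vapply(u, function(i) one(c1[i], t1[i], c2[i], t2[i]), numeric(1))
  pmin(1, pu[match(key, key[u])])
}

#' Fisher test on replicate counts pooled per group
#'
#' Sums C/T counts across replicates within each group and tests the
#' pooled 2x2 table for independence of group and conversion state.
#' The methylation difference is computed on conversion-corrected
#' pooled percentages when conversion rates are supplied, otherwise on
#' raw pooled percentages.
#'
#' @param counts1,counts2 Two-column matrices (or data frames) of
#'   per-replicate `c` and `t` counts for group 1 and group 2.
#' @param r1,r2 Optional pooled conversion rates used to correct the
#'   group percentages.
#' @return List with `p`, `delta_m` (group1 - group2, percentage
#'   points) and the pooled table.
#' @export
fisher_test_pooled <- function(counts1, counts2, r1 = NULL, r2 = NULL) {
  counts1 <- as.matrix(counts1); counts2 <- as.matrix(counts2)
  C1 <- sum(counts1[, 1]); T1 <- sum(counts1[, 2])
  C2 <- sum(counts2[, 1]); T2 <- sum(counts2[, 2])
  p <- fisher_p2(C1, T1, C2, T2)
  m1 <- if (is.null(r1)) 100 * C1 / (C1 + T1) else
    corrected_methylation(C1, T1, r1)
  m2 <- if (is.null(r2)) 100 * C2 / (C2 + T2) else
    corrected_methylation(C2, T2, r2)
  list(p = p, delta_m = m1 - m2,
       table = matrix(c(C1, T1, C2, T2), 2, byrow = TRUE,
                      dimnames = list(c("group1", "group2"), c("C", "T"))))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values, monotone in p rank and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  stats::p.adjust(p, method = "BH")
}

#' Cluster differentially methylated cytosines into regions
#'
#' Groups DMC positions not further than `gap` bp apart (irrespective
#' of direction) into regions; DMCs at least `gap` bp from the next
#' DMC remain singletons.  Both strands of a dyad cluster by position.
#'
#' @param dmc Data frame with `chrom`, `pos` and optionally `delta_m`.
#' @param gap Maximum within-region gap in bp.
#' @return Data frame of regions: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_cpg`, `direction_consistent`, `singleton`, and
#'   `members` (list column of row indices into `dmc`).
#' @export
cluster_dmrs <- function(dmc, gap = 500L) {
  if (nrow(dmc) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      direction_consistent = logical(),
                      singleton = logical()))
  ord <- order(dmc$chrom, dmc$pos)
  d <- dmc[ord, , drop = FALSE]
  newreg <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                diff(d$pos) > gap)
  rid <- cumsum(newreg)
  regs <- lapply(split(seq_len(nrow(d)), rid), function(idx) {
    dd <- d[idx, , drop = FALSE]
    dirc <- if (!is.null(dd$delta_m))
      all(dd$delta_m > 0) || all(dd$delta_m < 0) else NA
    data.frame(chrom = dd$chrom[1], start = min(dd$pos),
               end = max(dd$pos), n_cpg = nrow(dd),
               direction_consistent = dirc,
               singleton = nrow(dd) == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regs)
  out$members <- unname(split(ord, rid))
  rownames(out) <- NULL
  out
}

#' Call differentially methylated cytosines and regions
#'
#' Runs the full two-group differential methylation analysis: site
#' filters (coverage and variant removal), replicate pooling, Fisher
#' exact test per site, Benjamini-Hochberg correction over the
#' post-filter universe, significance at `q < fdr`, and clustering of
#' significant sites into regions at the `gap` rule.
#'
#' @param pileups Long pileup table.
#' @param groups Named vector mapping `sample_id` to one of exactly
#'   two group labels.
#' @param conv_rates Optional named vector of per-sample conversion
#'   rates used for corrected methylation differences.
#' @param variants Optional variant table for dyad filtering.
#' @param fdr FDR threshold.
#' @param gap DMR clustering gap in bp.
#' @param min_cov,min_reps Site filter thresholds.
#' @return List with `dmc` (per-site results: pooled counts, `p`, `q`,
#'   `delta_m`, `significant`) and `dmr` (regions over the significant
#'   sites).
#' @export
call_dmcs_and_dmrs <- function(pileups, groups, conv_rates = NULL,
                               variants = NULL, fdr = 0.05, gap = 500L,
                               min_cov = 5L, min_reps = 3L) {
  glev <- unique(groups)
  if (length(glev) != 2) stop("exactly two groups required")
  filt <- apply_site_filters(pileups, groups, variants,
                             min_cov = min_cov, min_reps = min_reps)
  if (nrow(filt) == 0)
    return(list(dmc = data.frame(), dmr = data.frame()))
  filt$group <- groups[filt$sample_id]
  key <- paste(filt$chrom, filt$pos, filt$strand)
  C <- tapply(filt$c_count, list(key, filt$group), sum, default = 0L)
  T_ <- tapply(filt$t_count, list(key, filt$group), sum, default = 0L)
  sk <- do.call(rbind, strsplit(rownames(C), " "))
  res <- data.frame(chrom = sk[, 1], pos = as.integer(sk[, 2]),
                    strand = sk[, 3],
                    c1 = C[, glev[1]], t1 = T_[, glev[1]],
                    c2 = C[, glev[2]], t2 = T_[, glev[2]],
                    stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$pos), ]
  rownames(res) <- NULL
  res$p <- fisher_p2(res$c1, res$t1, res$c2, res$t2)
  res$q <- bh_fdr(res$p)
  if (!is.null(conv_rates)) {
    ## pooled group conversion rate: coverage-weighted sample mean
    grate <- function(g) {
      sams <- names(groups)[groups == g]
      f <- filt[filt$sample_id %in% sams, ]
      stats::weighted.mean(conv_rates[f$sample_id], f$c_count + f$t_count)
    }
    r1 <- grate(glev[1]); r2 <- grate(glev[2])
    m1 <- corrected_methylation(res$c1, res$t1, r1)
    m2 <- corrected_methylation(res$c2, res$t2, r2)
  } else {
    m1 <- 100 * res$c1 / (res$c1 + res$t1)
    m2 <- 100 * res$c2 / (res$c2 + res$t2)
  }
  res$m1 <- m1; res$m2 <- m2
  res$delta_m <- m1 - m2
  res$significant <- res$q < fdr
  dmr <- cluster_dmrs(res[res$significant, , drop = FALSE], gap = gap)
  list(dmc = res, dmr = dmr, groups = glev)
}

#' Overlap enrichment of two site sets within a universe
#'
#' Fold enrichment of the intersection over its expectation under
#' independence, with a 1-df chi-square on the 2x2 membership table.
#'
#' @param setA,setB Character vectors of element identifiers, subsets
#'   of `universe`.
#' @param universe Character vector of all tested elements.
#' @return List with `fold`, `chisq`, `p`, `observed` and `expected`
#'   intersection sizes.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  U <- length(unique(universe))
  if (U == 0) stop("empty universe")
  A <- unique(setA); B <- unique(setB)
  nA <- length(A); nB <- length(B)
  nAB <- length(intersect(A, B))
  expAB <- nA * nB / U
  fold <- if (expAB > 0) nAB / expAB else NA_real_
  o <- c(nAB, nA - nAB, nB - nAB, U - nA - nB + nAB)
  rowt <- c(nA, U - nA); colt <- c(nB, U - nB)
  e <- outer(rowt, colt) / U
  x2 <- sum((matrix(o, 2, byrow = TRUE) - e)^2 / e)
  list(fold = fold, chisq = x2,
       p = stats::pchisq(x2, df = 1, lower.tail = FALSE),
       observed = nAB, expected = expAB)
}
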