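## Conversion-rate estimation, conversion-corrected methylation levels
## and the standard site filters.

#' Estimate per-sample bisulfite conversion rates
#'
#' For F1 samples the conversion rate is the fraction of converted
#' calls on the unmethylated lambda spike-in, `t / (c + t)`.  Parental
#' samples (no usable spike-in) are predicted from their genomic
#' non-CpG conversion rate through an ordinary least squares fit of
#' lambda conversion on non-CpG conversion across the F1 samples;
#' predictions are clamped to `[0, 1]`.
#'
#' @param lambda_pileups Lambda-contig pileups for the F1 samples.
#' @param noncpg_pileups Non-CpG cytosine pileups for all samples.
#' @param design Sample sheet with `sample_id` and `role`.
#' @return Data frame with `sample_id`, `r_lambda`, `r_noncpg`, `r_s`
#'   (final rate used) and `ok` (`TRUE` when `r_s > 0.97`, the expected
#'   working range).
#' @export
estimate_conversion_rates <- function(lambda_pileups, noncpg_pileups,
                                      design) {
  conv_of <- function(df) {
    agg <- stats::aggregate(cbind(c_count, t_count) ~ sample_id, df, sum)
    cov <- agg$c_count + agg$t_count
    if (any(cov == 0)) stop("zero coverage for conversion estimation")
    stats::setNames(agg$t_count / cov, agg$sample_id)
  }
  r_noncpg <- conv_of(noncpg_pileups)
  f1 <- design$sample_id[grepl("^F1", design$role)]
  parental <- design$sample_id[design$role %in% c("BN", "SHR")]
  if (is.null(lambda_pileups) || !any(lambda_pileups$sample_id %in% f1))
    stop("lambda pileups required for F1 samples")
  r_lambda <- conv_of(lambda_pileups)

  out <- data.frame(sample_id = design$sample_id,
                    r_lambda = NA_real_,
                    r_noncpg = r_noncpg[design$sample_id],
                    r_s = NA_real_, stringsAsFactors = FALSE)
  out$r_lambda[match(names(r_lambda), out$sample_id)] <- r_lambda
  out$r_s[out$sample_id %in% f1] <- out$r_lambda[out$sample_id %in% f1]

  if (length(parental)) {
    pts <- out[out$sample_id %in% f1, ]
    pts <- pts[!is.na(pts$r_lambda) & !is.na(pts$r_noncpg), ]
    if (nrow(pts) < 2)
      stop("need at least 2 F1 samples to fit the conversion regression")
    fit <- stats::lm(r_lambda ~ r_noncpg, data = pts)
    pred <- stats::predict(fit, newdata = out[out$sample_id %in% parental, ])
    out$r_s[out$sample_id %in% parental] <- pmin(1, pmax(0, pred))
  }
  out$ok <- out$r_s > 0.97
  rownames(out) <- NULL
  out
}

#' Conversion-corrected methylation level
#'
#' Corrects the raw percentage of cytosine calls for incomplete
#' bisulfite conversion by subtracting the expected number of
#' unconverted (falsely methylated-looking) cytosine calls from `c`.
#' That expected count is estimated from the converted calls: each
#' converted call represents an unmethylated cytosine that converted
#' (probability `r_s`), so `t * (1 - r_s) / r_s` unmethylated
#' cytosines are expected to have failed conversion and be sitting in
#' `c`.  The corrected level
#' `m = 100 * max(0, c - t * (1 - r_s) / r_s) / (c + t)`
#' is an unbiased estimator of the true methylation percentage
#' (`E[m] -> 100 * theta` with increasing depth); negative corrected
#' counts clamp to zero and `t` is never inflated.
#'
#' @param c,t Cytosine and thymine call counts (vectorised).
#' @param r_s Bisulfite conversion rate(s) in `(0, 1]`.
#' @return Corrected methylation in percent, in `[0, 100]`.
#' @export
corrected_methylation <- function(c, t, r_s) {
  stopifnot(all(c >= 0), all(t >= 0), all(r_s > 0 & r_s <= 1))
  cov <- c + t
  if (any(cov == 0)) stop("zero coverage at some site")
  pmin(100, pmax(0, 100 * (c - t * (1 - r_s) / r_s) / cov))
}

.dyad_positions <- function(sites) {
  ## forward-coordinate span of the CpG dyad for each strand-specific site
  first <- ifelse(sites$strand == "+", sites$pos, sites$pos - 1L)
  cbind(first, first + 1L)
}

#' Identify sites whose dinucleotide is hit by sequence variation
#'
#' A CpG site is affected when a SNP falls on either base of its dyad
#' or an indel's reference footprint overlaps the dyad.
#'
#' @param sites Data frame with `chrom`, `pos`, `strand`.
#' @param variants Variant table.
#' @return Logical vector along `sites`.
#' @export
variant_affected <- function(sites, variants) {
  if (is.null(variants) || nrow(variants) == 0)
    return(rep(FALSE, nrow(sites)))
  dy <- .dyad_positions(sites)
  vstart <- variants$pos
  vend <- variants$pos + ifelse(variants$kind == "indel",
                                pmax(nchar(variants$bn_allele),
                                     nchar(variants$shr_allele)) - 1L, 0L)
  hit <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    vi <- which(variants$chrom == ch)
    if (!length(vi)) next
    ## interval overlap: dyad [first, first+1] vs variant [vstart, vend]
    vs <- vstart[vi]; ve <- vend[vi]
    ord <- order(vs)
    vs <- vs[ord]; ve <- ve[ord]
    maxlen <- max(ve - vs) + 1L
    for (i in si) {
      lo <- dy[i, 1]; hi <- dy[i, 2]
      k <- findInterval(hi, vs)
      while (k >= 1 && vs[k] + maxlen > lo) {
        if (ve[k] >= lo) { hit[i] <- TRUE; break }
        k <- k - 1
      }
    }
  }
  hit
}

#' Apply coverage and variant site filters
#'
#' A site passes for a group iff at least `min_reps` replicates have
#' combined C+T coverage of at least `min_cov`; for multi-group
#' analyses it must pass in every group.  Sites whose CpG dyad is
#' affected by a SNP or indel are removed.  Filtering only ever
#' removes sites.
#'
#' @param pileups Long pileup table (standard schema).
#' @param groups Named character vector mapping `sample_id` to group.
#' @param variants Optional variant table.
#' @param min_cov,min_reps Filter thresholds.
#' @return The filtered pileup table (rows at passing sites only).
#' @export
apply_site_filters <- function(pileups, groups, variants = NULL,
                               min_cov = 5L, min_reps = 3L) {
  p <- pileups
  p$group <- groups[p$sample_id]
  if (anyNA(p$group)) stop("pileup contains samples missing from groups")
  key <- paste(p$chrom, p$pos, p$strand)
  covok <- (p$c_count + p$t_count) >= min_cov
  ## per (site, group): number of replicates with sufficient coverage
  cnt <- tapply(covok, list(key, p$group), sum, default = 0L)
  pass <- rownames(cnt)[apply(cnt >= min_reps, 1, all)]
  keep <- key %in% pass
  if (!is.null(variants)) {
    sites <- unique(p[, c("chrom", "pos", "strand")])
    aff <- variant_affected(sites, variants)
    bad <- paste(sites$chrom, sites$pos, sites$strand)[aff]
    keep <- keep & !(key %in% bad)
  }
  out <- p[keep, setdiff(names(p), "group"), drop = FALSE]
  rownames(out) <- NULL
  out
}
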