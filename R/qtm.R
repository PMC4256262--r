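## Quantitative trait methylation (QTM): correlation of methylation
## traits with physiological phenotypes across the RI panel, after a
## per-strain outlier screen.

#' Grubbs critical value
#'
#' Two-sided critical value for the Grubbs extreme-outlier statistic
#' `G = max|x - mean| / sd` at level `alpha`, from the t-distribution
#' form with a Bonferroni-type `alpha / (2n)` quantile.
#'
#' @param n Sample size.
#' @param alpha Significance level.
#' @return Critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- stats::qt(1 - alpha / (2 * n), df = n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Nalimov critical value
#'
#' Critical value for the Nalimov statistic
#' `q = |x - mean| / sd * sqrt(n / (n - 1))`, obtained from the Grubbs
#' critical value through the exact relation `q = G * sqrt(n/(n-1))`
#' (it reproduces the published Nalimov tables at n - 2 degrees of
#' freedom).
#'
#' @inheritParams grubbs_critical
#' @return Critical value.
#' @export
nalimov_critical <- function(n, alpha = 0.05) {
  grubbs_critical(n, alpha) * sqrt(n / (n - 1))
}

#' Remove outliers from replicate measurements within a strain
#'
#' A value is removed iff flagged by any of: boxplot rule (outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`), Grubbs test, or Nalimov test (both
#' at `alpha = 0.05`).  The screen is applied once, without iteration.
#' With fewer than 3 values only the boxplot rule applies; zero
#' variance removes nothing.
#'
#' @param values Numeric vector of raw replicate measurements.
#' @param alpha Level for Grubbs and Nalimov.
#' @return List with `retained`, `removed` (values), `flags` (logical
#'   removal mask along `values`) and per-test masks.
#' @export
remove_outliers <- function(values, alpha = 0.05) {
  n <- length(values)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  box <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  grubbs <- nalimov <- rep(FALSE, n)
  s <- stats::sd(values)
  if (n >= 3 && !is.na(s) && s > 0) {
    z <- abs(values - mean(values)) / s
    grubbs <- z > grubbs_critical(n, alpha)
    nalimov <- z * sqrt(n / (n - 1)) > nalimov_critical(n, alpha)
  }
  flags <- box | grubbs | nalimov
  list(retained = values[!flags], removed = values[flags], flags = flags,
       boxplot = box, grubbs = grubbs, nalimov = nalimov)
}

#' Summarise phenotypes per strain after outlier removal
#'
#' @param phenotypes Phenotype table (`strain`, `trait`, `replicate`,
#'   `value`).
#' @param alpha Outlier screen level.
#' @return Data frame with `strain`, `trait`, `mean`, `se`, `n`,
#'   `n_removed`.
#' @export
summarize_phenotypes <- function(phenotypes, alpha = 0.05) {
  sp <- split(phenotypes, list(phenotypes$strain, phenotypes$trait),
              drop = TRUE)
  out <- lapply(sp, function(df) {
    res <- remove_outliers(df$value, alpha)
    v <- res$retained
    data.frame(strain = df$strain[1], trait = df$trait[1],
               mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), n_removed = length(res$removed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlate methylation traits with phenotypes across strains
#'
#' Pearson correlation test for every (methylation locus, phenotype
#' trait) pair over strains with both values, with Benjamini-Hochberg
#' adjustment over all tested pairs.  Pairs with a constant vector are
#' skipped and reported with `NA`.
#'
#' @param meth Data frame of strain-level methylation (`strain`,
#'   `locus`, `value`) -- typically strain means.
#' @param pheno_summary Output of [summarize_phenotypes()].
#' @param min_strains Minimum strains per pair.
#' @return Data frame with `locus`, `trait`, `r`, `p`, `q`,
#'   `n_strains`.
#' @export
correlate_traits <- function(meth, pheno_summary, min_strains = 8L) {
  loci <- unique(meth$locus)
  traits <- unique(pheno_summary$trait)
  rows <- list()
  for (lc in loci) {
    mv <- meth[meth$locus == lc, ]
    x <- stats::setNames(mv$value, mv$strain)
    for (tr in traits) {
      pv <- pheno_summary[pheno_summary$trait == tr, ]
      y <- stats::setNames(pv$mean, pv$strain)
      common <- intersect(names(x), names(y))
      if (length(common) < min_strains) next
      xs <- x[common]; ys <- y[common]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          locus = lc, trait = tr, r = NA_real_, p = NA_real_,
          n_strains = length(common), stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(xs, ys, method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        locus = lc, trait = tr, r = unname(ct$estimate),
        p = ct$p.value, n_strains = length(common),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  if (any(tested)) out$q[tested] <- bh_fdr(out$p[tested])
  rownames(out) <- NULL
  out
}
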