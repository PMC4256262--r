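## Sample-level structure of methylation profiles: coverage-equalised
## hierarchical clustering, principal component analysis, and
## within/between-group distance summaries.

#' Downsample C/T calls to a common depth
#'
#' Hypergeometric subsampling without replacement of `target` base
#' calls from the `c` cytosine and `t` thymine calls at a site;
#' integer-preserving and unbiased
#' (`E[c' / target] = c / (c + t)`).
#'
#' @param c,t Count vectors (each `c + t >= target`).
#' @param target Target depth.
#' @param seed Integer seed.
#' @return List with `c` and `t` summing to `target`.
#' @export
downsample_to_depth <- function(c, t, target = 5L, seed = 1L) {
  if (any(c + t < target))
    stop("coverage below target at some site; filter first")
  set.seed(seed)
  cp <- stats::rhyper(length(c), c, t, target)
  list(c = cp, t = target - cp)
}

#' Build a sites-by-samples methylation profile matrix
#'
#' Restricts to complete-case sites (coverage at least `min_cov` in
#' every included sample), removes variant-affected dyads, equalises
#' coverage by hypergeometric downsampling to `min_cov` calls, and
#' returns raw percentages.
#'
#' @param pileups Long pileup table.
#' @param samples Sample ids to include (default: all in `pileups`).
#' @param variants Optional variant table.
#' @param min_cov Coverage floor and downsampling target.
#' @param seed Integer seed for the downsampling.
#' @param downsample Set `FALSE` to skip coverage equalisation.
#' @return Numeric matrix (sites x samples) of methylation
#'   percentages; row names are `chrom:pos:strand`.
#' @export
build_profile_matrix <- function(pileups, samples = NULL, variants = NULL,
                                 min_cov = 5L, seed = 1L,
                                 downsample = TRUE) {
  p <- pileups
  if (is.null(samples)) samples <- unique(p$sample_id)
  p <- p[p$sample_id %in% samples, , drop = FALSE]
  key <- paste(p$chrom, p$pos, p$strand, sep = ":")
  cov <- p$c_count + p$t_count
  ok <- tapply(cov >= min_cov, key, sum, default = 0L)
  complete <- names(ok)[ok == length(samples)]
  p <- p[key %in% complete, , drop = FALSE]
  if (!is.null(variants)) {
    sites <- unique(p[, c("chrom", "pos", "strand")])
    aff <- variant_affected(sites, variants)
    bad <- paste(sites$chrom, sites$pos, sites$strand, sep = ":")[aff]
    p <- p[!(paste(p$chrom, p$pos, p$strand, sep = ":") %in% bad), ,
           drop = FALSE]
  }
  if (nrow(p) == 0) stop("no complete-case sites")
  if (downsample) {
    ds <- downsample_to_depth(p$c_count, p$t_count, min_cov, seed)
    m <- 100 * ds$c / min_cov
  } else m <- 100 * p$c_count / (p$c_count + p$t_count)
  key <- paste(p$chrom, p$pos, p$strand, sep = ":")
  mat <- tapply(m, list(key, p$sample_id), mean)
  mat <- mat[, samples, drop = FALSE]
  storage.mode(mat) <- "double"
  mat
}

#' Hierarchical clustering of methylation profiles
#'
#' Euclidean distances between the per-sample methylation vectors,
#' clustered by Ward's minimum variance method; with group labels the
#' mean within-group and between-group pairwise distances are
#' reported.
#'
#' @param mat Sites x samples profile matrix.
#' @param groups Optional named vector mapping sample to group.
#' @return List with `hclust`, `dist`, `newick` (dendrogram as a
#'   Newick string), `within` and `between` mean distances (NA without
#'   groups).
#' @export
cluster_profiles <- function(mat, groups = NULL) {
  if (ncol(mat) < 3) stop("need at least 3 samples")
  if (nrow(mat) < 2) stop("need at least 2 sites")
  d <- stats::dist(t(mat), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  within <- between <- NA_real_
  if (!is.null(groups)) {
    dm <- as.matrix(d)
    g <- groups[colnames(dm)]
    same <- outer(g, g, "==") & upper.tri(dm)
    diff <- outer(g, g, "!=") & upper.tri(dm)
    within <- mean(dm[same]); between <- mean(dm[diff])
  }
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, dist = d, newick = nwk,
       within = within, between = between)
}

#' Principal component analysis of methylation profiles
#'
#' Centred (optionally unit-variance scaled) PCA of the samples;
#' variance fractions sum to 100% and each component's sign is fixed
#' by forcing its largest-magnitude loading positive.
#'
#' @param mat Sites x samples profile matrix.
#' @param scaling `"none"` or `"unit_variance"` (zero-variance sites
#'   are dropped before scaling).
#' @return List with `scores` (samples x PCs), `loadings` (sites x
#'   PCs), `var_pct`.
#' @export
pca_profiles <- function(mat, scaling = c("none", "unit_variance")) {
  scaling <- match.arg(scaling)
  X <- t(mat)                       # samples x sites
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("zero-variance profile matrix")
  if (scaling == "unit_variance") X <- X[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = scaling == "unit_variance")
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_pct = var_pct)
}
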