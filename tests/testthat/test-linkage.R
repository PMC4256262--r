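ri_fixture <- function(seed = 71, ...) {
  tr <- simulate_truth(sim_config(n_cpg = 1500L, frac_dm = 0.05,
                                  dm_effect_range = c(0.4, 0.4),
                                  n_imprinted = 0L, n_noncpg = 50L),
                       seed = seed)
  simulate_ri_panel(tr, seed = seed + 1, ...)
}

test_that("LOD has the closed correlation form", {
  # build a trait with r^2 = 0.5 against one marker's coding
  set.seed(72)
  n <- 29
  g <- rep(c(0, 1), length.out = n)
  eps <- rnorm(n); eps <- residuals(lm(eps ~ g))
  y <- g + eps * sd(g) / sd(eps)         # r^2 exactly 0.5
  G <- matrix(ifelse(g == 1, "S", "B"), n, 1,
              dimnames = list(paste0("RI", 1:n), "m1"))
  mm <- data.frame(marker = "m1", chrom = "chr1", pos = 100L,
                   stringsAsFactors = FALSE)
  scan <- lod_scan(setNames(y, rownames(G)), G, mm)
  expect_equal(scan$lod$lod, -(n / 2) * log10(0.5), tolerance = 1e-9)
  expect_equal(scan$lod$lod, 4.364935, tolerance = 1e-5)
  # uncorrelated trait gives LOD ~ 0; constant trait exactly 0
  expect_equal(lod_scan(setNames(rep(5, n), rownames(G)), G, mm)$lod$lod, 0)
})

test_that("LOD is invariant to affine transformation of the trait", {
  ri <- ri_fixture(seed = 73)
  trait <- tapply(ri$meth$value[ri$meth$locus == ri$loci$locus[1]],
                  ri$meth$strain[ri$meth$locus == ri$loci$locus[1]], mean)
  s1 <- lod_scan(trait, ri$genotypes, ri$marker_map)
  s2 <- lod_scan(3 - 2 * trait, ri$genotypes, ri$marker_map)
  expect_equal(s1$lod$lod, s2$lod$lod, tolerance = 1e-10)
})

test_that("permutation p is deterministic and floors at 1/(n+1)", {
  ri <- ri_fixture(seed = 74)
  loc <- ri$loci[ri$loci$control == "cis", ][1, ]
  trait <- tapply(ri$meth$value[ri$meth$locus == loc$locus],
                  ri$meth$strain[ri$meth$locus == loc$locus], mean)
  p1 <- permutation_pvalue(trait, ri$genotypes, ri$marker_map,
                           n_perm = 1000, seed = 5)
  p2 <- permutation_pvalue(trait, ri$genotypes, ri$marker_map,
                           n_perm = 1000, seed = 5)
  expect_identical(p1, p2)
  # perfect segregation: no permutation can beat the observed max
  g <- ri$genotypes[, loc$controlling_marker]
  perfect <- setNames(ifelse(g == "S", 1, 0), names(g))
  pp <- permutation_pvalue(perfect, ri$genotypes, ri$marker_map,
                           n_perm = 1000, seed = 6)
  expect_equal(pp$p, 1 / 1001)
  expect_warning(permutation_pvalue(trait, ri$genotypes, ri$marker_map,
                                    n_perm = 500, seed = 7), "1000")
})

test_that("cis/trans/NSL classification follows the 5 Mbp window rule", {
  peak_near <- data.frame(chrom = "chr1", pos = 3e6)
  peak_far <- data.frame(chrom = "chr2", pos = 3e6)
  expect_equal(classify_linkage(peak_near, "chr1", 1L, p = 0.001), "cis")
  expect_equal(classify_linkage(peak_far, "chr1", 1L, p = 0.001), "trans")
  expect_equal(classify_linkage(peak_near, "chr1", 1L, p = 0.2), "NSL")
  # boundary: exactly 5 Mbp away is cis, beyond is trans
  pk <- data.frame(chrom = "chr1", pos = 5e6 + 10)
  expect_equal(classify_linkage(pk, "chr1", 10, p = 0.01), "cis")
  pk2 <- data.frame(chrom = "chr1", pos = 5e6 + 11)
  expect_equal(classify_linkage(pk2, "chr1", 10, p = 0.01), "trans")
})

test_that("planted cis and trans loci map to their controlling markers", {
  ri <- ri_fixture(seed = 75, sd_strain = 1, sd_rep = 3)
  qtl <- map_meth_qtl(ri, n_perm = 1000, seed = 76)
  cis <- qtl[qtl$true_control == "cis", ]
  expect_true(all(cis$class == "cis"))
  expect_true(all(cis$lod > 4))
  trans <- qtl[qtl$true_control == "trans", ]
  expect_true(all(trans$class == "trans"))
  expect_equal(trans$peak_marker, trans$true_marker)
  expect_true(all(qtl$class[qtl$true_control == "null"] == "NSL"))
})

test_that("heritability matches the hand-worked one-way ANOVA", {
  vals <- data.frame(strain = rep(c("a", "b", "c"), each = 2),
                     value = c(10, 12, 20, 22, 30, 32))
  h <- heritability_and_r2(vals)
  expect_equal(h$h2, 198 / 202, tolerance = 1e-12)
  expect_equal(h$k, 2)
  # degenerate: all values equal -> guarded to 0
  flat <- data.frame(strain = rep(c("a", "b", "c"), each = 2), value = 7)
  expect_equal(heritability_and_r2(flat)$h2, 0)
  expect_error(heritability_and_r2(
    data.frame(strain = c("a", "b"), value = 1:2)), "replicates")
})

test_that("simulated heritability is recovered within tolerance", {
  # h2 = 0.6: strain variance 6, replicate variance 4
  set.seed(77)
  reps <- 2L; n <- 30L
  mu <- rnorm(n, 50, sqrt(6))
  vals <- data.frame(strain = rep(sprintf("s%02d", 1:n), each = reps),
                     value = rep(mu, each = reps) +
                       rnorm(n * reps, 0, sqrt(4)))
  h <- heritability_and_r2(vals)
  expect_lt(abs(h$h2 - 0.6), 0.15)
})

test_that("cis variance explained does not exceed heritable variance", {
  ri <- ri_fixture(seed = 78, sd_strain = 1, sd_rep = 3)
  qtl <- map_meth_qtl(ri, n_perm = 1000, seed = 79)
  cis <- qtl[qtl$true_control == "cis", ]
  expect_true(all(cis$r2_cis <= cis$h2 + 0.1))
})

test_that("the 2-LOD support interval brackets the peak", {
  ri <- ri_fixture(seed = 80, sd_strain = 1, sd_rep = 3)
  loc <- ri$loci[ri$loci$control == "cis", ][1, ]
  trait <- tapply(ri$meth$value[ri$meth$locus == loc$locus],
                  ri$meth$strain[ri$meth$locus == loc$locus], mean)
  scan <- lod_scan(trait, ri$genotypes, ri$marker_map)
  ci <- lod_support_interval(scan$lod)
  expect_equal(ci$chrom, scan$peak$chrom)
  expect_lte(ci$start, scan$peak$pos)
  expect_gte(ci$end, scan$peak$pos)
})
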