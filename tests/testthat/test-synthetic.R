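test_that("truth generation is deterministic and respects the DM fraction", {
  cfg <- sim_config(n_cpg = 10000L, frac_dm = 0.007, n_imprinted = 0L)
  tr1 <- simulate_truth(cfg, seed = 11)
  tr2 <- simulate_truth(cfg, seed = 11)
  expect_identical(tr1$sites, tr2$sites)
  expect_identical(tr1$variants, tr2$variants)
  n_dm <- sum(tr1$sites$is_dm)
  expect_equal(n_dm, round(0.007 * nrow(tr1$sites)))
  expect_gt(n_dm, 55); expect_lt(n_dm, 85)   # ~70 at this scale
  expect_true(all(tr1$sites$theta_bn >= 0 & tr1$sites$theta_bn <= 1))
  expect_true(all(abs(tr1$sites$theta_shr - tr1$sites$theta_bn)[tr1$sites$is_dm] >= 0.2))
})

test_that("a null configuration has identical strain methylation", {
  tr <- simulate_truth(sim_config(n_cpg = 500L, frac_dm = 0,
                                  n_imprinted = 0L), seed = 2)
  expect_identical(tr$sites$theta_bn, tr$sites$theta_shr)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_cpg = 10L, n_imprinted = 5L,
                          imprinted_size = 10L), "imprinted")
})

test_that("reference carries a CG dyad at every simulated site", {
  tr <- tiny_truth(seed = 5)
  s <- tr$sites
  dinuc <- substr(rep(tr$reference[["chr1"]], nrow(s)), s$pos, s$pos + 1L)
  expect_true(all(dinuc == "CG"))
})

test_that("pileup counts follow the conversion/error model", {
  # fully methylated, perfect conversion, no error: every call is C
  cfg <- sim_config(n_cpg = 50L, n_chrom = 1L, chrom_length = 10000L,
                    frac_dm = 0, n_imprinted = 0L, base_error = 0,
                    conv_range = c(1, 1), n_noncpg = 10L)
  tr <- simulate_truth(cfg, seed = 3)
  tr$sites$theta_bn <- 1; tr$sites$theta_shr <- 1
  des <- data.frame(sample_id = "bn_1", role = "BN", replicate = 1L)
  pl <- simulate_pileups(tr, des, depth = 20, seed = 4)
  expect_true(all(pl$pileups$c_count == 20L))

  # unmethylated with r_s = 0.97: mean c/(c+t) converges to 1 - r_s
  cfg2 <- sim_config(n_cpg = 10000L, frac_dm = 0, n_imprinted = 0L,
                     base_error = 0, conv_range = c(0.97, 0.97),
                     n_noncpg = 10L)
  tr2 <- simulate_truth(cfg2, seed = 6)
  tr2$sites$theta_bn <- 0; tr2$sites$theta_shr <- 0
  pl2 <- simulate_pileups(tr2, des, depth = 20, seed = 7)
  frac <- with(pl2$pileups, sum(c_count) / sum(c_count + t_count))
  expect_equal(frac, 0.03, tolerance = 0.1)

  # lambda spike-in: overall unconverted fraction ~ 1 - r_s
  cfg3 <- sim_config(n_cpg = 100L, frac_dm = 0, n_imprinted = 0L,
                     base_error = 0, conv_range = c(0.98, 0.98))
  tr3 <- simulate_truth(cfg3, seed = 8)
  f1 <- data.frame(sample_id = "f1_1", role = "F1_BNxSHR", replicate = 1L)
  pl3 <- simulate_pileups(tr3, f1, depth = 30, seed = 9)
  lam_frac <- with(pl3$lambda, sum(c_count) / sum(c_count + t_count))
  expect_equal(lam_frac, 0.02, tolerance = 0.15)
})

test_that("F1 allele pileups split depth and sum to the unphased pileup", {
  tr <- tiny_truth(seed = 10)
  des <- sim_design(2L)
  pl <- simulate_pileups(tr, des, depth = 30, seed = 11)
  a <- pl$allele_pileups
  tot <- tapply(a$c_count + a$t_count,
                paste(a$chrom, a$pos, a$sample_id), sum)
  expect_true(all(tot == 30L))
  ac <- tapply(a$c_count, paste(a$chrom, a$pos, a$sample_id), sum)
  p <- pl$pileups[grepl("x", pl$pileups$sample_id), ]
  pc <- setNames(p$c_count, paste(p$chrom, p$pos, p$sample_id))
  expect_equal(as.vector(ac[names(pc)]), unname(pc))
})

test_that("simulated read pairs are deterministic and carry haplotype alleles", {
  tr <- tiny_truth(seed = 12)
  r1 <- simulate_f1_reads(tr, n_pairs = 50, seed = 13)
  r2 <- simulate_f1_reads(tr, n_pairs = 50, seed = 13)
  expect_identical(r1, r2)
  expect_error(simulate_f1_reads(tr, n_pairs = 0), "positive")
  # at covered non-C/T SNPs an OT read shows its haplotype's allele
  v <- tr$variants[tr$variants$kind == "snp", ]
  v <- v[!(pmin(v$bn_allele, v$shr_allele) == "C" &
             pmax(v$bn_allele, v$shr_allele) == "T"), ]
  checked <- 0L
  for (i in seq_len(nrow(r1))) {
    p <- r1[i, ]
    if (p$bs_strand != "OT") next
    end1 <- p$start1 + nchar(p$seq1) - 1L
    vv <- v[v$pos >= p$start1 & v$pos <= end1, ]
    vv <- vv[!(vv$bn_allele %in% c("C") | vv$shr_allele %in% c("C")), ]
    if (nrow(vv) == 0) next
    obs <- substr(rep(p$seq1, nrow(vv)), vv$pos - p$start1 + 1L,
                  vv$pos - p$start1 + 1L)
    want <- if (p$true_hap == "BN") vv$bn_allele else vv$shr_allele
    expect_equal(obs, want)
    checked <- checked + nrow(vv)
  }
  expect_gt(checked, 0L)
})

test_that("RI genotypes are whole-chromosome blocks at zero recombination", {
  tr <- tiny_truth(seed = 14, frac_dm = 0.1)
  # single-contig truth: cis-only loci
  ri <- simulate_ri_panel(tr, n_strains = 10, recomb_rate = 0,
                          n_cis = 4L, n_trans = 0L, n_null = 1L, seed = 15)
  for (ch in unique(ri$marker_map$chrom)) {
    mk <- ri$marker_map$marker[ri$marker_map$chrom == ch]
    per_strain <- apply(ri$genotypes[, mk, drop = FALSE], 1,
                        function(g) length(unique(g)))
    expect_true(all(per_strain == 1L))
  }
  expect_error(simulate_ri_panel(tr, n_strains = 3), "4")
})

test_that("cis-controlled loci separate strain means by genotype", {
  tr <- simulate_truth(sim_config(n_cpg = 2000L, frac_dm = 0.05,
                                  dm_effect_range = c(0.4, 0.4),
                                  n_imprinted = 0L), seed = 16)
  ri <- simulate_ri_panel(tr, n_strains = 30, sd_strain = 1, sd_rep = 3,
                          seed = 17)
  loc <- ri$loci[ri$loci$control == "cis", ][1, ]
  means <- tapply(ri$meth$value[ri$meth$locus == loc$locus],
                  ri$meth$strain[ri$meth$locus == loc$locus], mean)
  g <- ri$genotypes[names(means), loc$controlling_marker]
  tt <- t.test(means[g == "B"], means[g == "S"])
  expect_lt(tt$p.value, 1e-6)
})

test_that("the phenotype attains the configured correlation at 29 strains", {
  tr <- simulate_truth(sim_config(n_cpg = 2000L, frac_dm = 0.05,
                                  n_imprinted = 0L), seed = 18)
  ri <- simulate_ri_panel(tr, n_strains = 29, rho = -0.75, seed = 19)
  meth <- tapply(ri$meth$value[ri$meth$locus == ri$pheno_locus],
                 ri$meth$strain[ri$meth$locus == ri$pheno_locus], mean)
  ph <- ri$phenotype
  pm <- tapply(ph$value, ph$strain, mean)
  r <- cor(meth[names(pm)], pm)
  expect_lt(abs(r - (-0.75)), 0.15)
})
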