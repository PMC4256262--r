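mk_phase_pair <- function(seq1, start1 = 100L, seq2 = "AAAA",
                          start2 = 300L, bs = "OT", chrom = "chr1") {
  list(chrom = chrom, start1 = start1, start2 = start2,
       seq1 = seq1, seq2 = seq2, bs_strand = bs)
}

mk_var <- function(pos, bn, shr, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, bn_allele = bn, shr_allele = shr,
             kind = "snp", stringsAsFactors = FALSE)
}

test_that("majority vote, tie and C/T exclusion rules", {
  v <- rbind(mk_var(101L, "A", "G"), mk_var(103L, "A", "C"))
  # both covered alleles are BN
  expect_equal(phase_read_pair(mk_phase_pair("AAAA"), v), "BN")
  # one BN one SHR: exact tie, discarded
  expect_equal(phase_read_pair(mk_phase_pair("AAAC"), v), "ambiguous")
  # only a C/T SNP covered: unphased
  vct <- mk_var(101L, "C", "T")
  expect_equal(phase_read_pair(mk_phase_pair("ACAA"), vct), "unphased")
  # G/A SNPs are additionally excluded on reverse-converted pairs
  vga <- mk_var(101L, "G", "A")
  expect_equal(phase_read_pair(mk_phase_pair("AGAA"), vga), "BN")
  expect_equal(phase_read_pair(mk_phase_pair("AGAA", bs = "OB"), vga),
               "unphased")
  # no SNP covered at all
  expect_equal(phase_read_pair(mk_phase_pair("AAAA"), mk_var(900L, "A", "G")),
               "unphased")
  # majority wins 2:1
  v3 <- rbind(mk_var(101L, "A", "G"), mk_var(102L, "A", "G"),
              mk_var(103L, "A", "G"))
  expect_equal(phase_read_pair(mk_phase_pair("AAAG"), v3), "BN")
})

test_that("phasing is perfectly accurate on error-free reads", {
  tr <- tiny_truth(seed = 51)
  rd <- simulate_f1_reads(tr, n_pairs = 400, seed = 52, error_rate = 0)
  ph <- phase_reads(filter_and_clip(rd), tr$variants)
  voted <- ph[ph$phase %in% c("BN", "SHR"), ]
  expect_gt(nrow(voted), 10)
  expect_equal(mean(voted$phase == voted$true_hap), 1)
})

test_that("allele profiles from phased reads equal truth-grouped profiles", {
  tr <- tiny_truth(seed = 53)
  rd <- simulate_f1_reads(tr, n_pairs = 400, seed = 54, error_rate = 0)
  kept <- filter_and_clip(rd)
  ph <- phase_reads(kept, tr$variants)
  phased <- ph[ph$phase %in% c("BN", "SHR"), ]
  sites <- tr$sites[, c("chrom", "pos", "strand")]
  got <- build_allele_profiles(phased, sites, "f1_1", "BNxSHR")
  # oracle: group the same reads by their true haplotype instead
  want <- do.call(rbind, lapply(c("BN", "SHR"), function(al) {
    sub <- phased[phased$true_hap == al, , drop = FALSE]
    p <- pileup_cytosines(sub, sites, "f1_1")
    p$cross <- "BNxSHR"; p$allele <- al
    p[p$c_count + p$t_count > 0,
      c("chrom", "pos", "strand", "sample_id", "cross", "allele",
        "c_count", "t_count")]
  }))
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[order(got$allele, got$pos), ],
               want[order(want$allele, want$pos), ])
})

test_that("strong reciprocal allele differences are called ASM", {
  counts <- list("BNxSHR BN" = c(90L, 10L), "BNxSHR SHR" = c(10L, 90L),
                 "SHRxBN BN" = c(88L, 12L), "SHRxBN SHR" = c(12L, 88L))
  asm <- detect_asm(allele_fixture(counts))
  expect_equal(nrow(asm), 1L)
  expect_true(asm$asm)
  expect_false(asm$discordant)
  # flat profile: not ASM
  flat <- lapply(counts, function(x) c(50L, 50L))
  names(flat) <- names(counts)
  expect_false(detect_asm(allele_fixture(flat))$asm)
})

test_that("ASM recovery on simulated truth with planted allele effects", {
  cfg <- sim_config(n_cpg = 1500L, n_chrom = 2L, chrom_length = 4e5L,
                    frac_dm = 0.01, dm_effect_range = c(0.5, 0.5),
                    n_imprinted = 0L, n_noncpg = 100L)
  tr <- simulate_truth(cfg, seed = 55)
  pl <- simulate_pileups(tr, sim_design(), depth = 30, seed = 56)
  asm <- detect_asm(pl$allele_pileups)
  key <- paste(asm$chrom, asm$pos)
  truth_key <- paste(tr$sites$chrom, tr$sites$pos)[tr$sites$is_dm]
  recall <- mean(truth_key[truth_key %in% key] %in% key[asm$asm])
  expect_gt(recall, 0.8)
  fp <- mean(asm$asm[!(key %in% truth_key)])
  expect_lte(fp, 0.05)
})

test_that("parent-of-origin calls need consistent direction on both backgrounds", {
  # maternal hypermethylation on both genotype backgrounds
  po_counts <- list("BNxSHR BN" = c(90L, 10L),    # maternal BN
                    "SHRxBN BN" = c(12L, 88L),    # paternal BN
                    "SHRxBN SHR" = c(85L, 15L),   # maternal SHR
                    "BNxSHR SHR" = c(10L, 90L))   # paternal SHR
  po <- detect_po(allele_fixture(po_counts))
  expect_true(po$sites$po)
  expect_equal(po$regions$allele, "M")
  expect_gt(po$regions$max_mean_diff, 50)
  # significant on the BN background only: not PO
  one_bg <- list("BNxSHR BN" = c(90L, 10L), "SHRxBN BN" = c(12L, 88L),
                 "SHRxBN SHR" = c(50L, 50L), "BNxSHR SHR" = c(50L, 50L))
  expect_false(detect_po(allele_fixture(one_bg))$sites$po)
  # opposite directions on the two backgrounds: not PO
  opp <- list("BNxSHR BN" = c(90L, 10L), "SHRxBN BN" = c(10L, 90L),
              "SHRxBN SHR" = c(10L, 90L), "BNxSHR SHR" = c(90L, 10L))
  expect_false(detect_po(allele_fixture(opp))$sites$po)
})

test_that("genotype-only allele differences do not produce PO calls", {
  cfg <- sim_config(n_cpg = 1000L, n_chrom = 2L, chrom_length = 3e5L,
                    frac_dm = 0.02, dm_effect_range = c(0.5, 0.5),
                    n_imprinted = 0L, n_noncpg = 100L)
  tr <- simulate_truth(cfg, seed = 57)
  pl <- simulate_pileups(tr, sim_design(), depth = 30, seed = 58)
  po <- detect_po(pl$allele_pileups)
  expect_lte(mean(po$sites$po), 0.01)
})

test_that("an imprinted region is recovered as one region with direction", {
  cfg <- sim_config(n_cpg = 400L, n_chrom = 1L, chrom_length = 2e5L,
                    frac_dm = 0, n_imprinted = 1L, imprinted_size = 10L,
                    theta_m = 0.95, theta_p = 0.05, n_noncpg = 100L)
  tr <- simulate_truth(cfg, seed = 59)
  pl <- simulate_pileups(tr, sim_design(), depth = 30, seed = 60)
  po <- detect_po(pl$allele_pileups)
  expect_equal(nrow(po$regions), 1L)
  expect_equal(po$regions$allele, "M")
  expect_equal(po$regions$n_cpg, 10L)
  expect_gt(po$regions$max_mean_diff, 75)
})

test_that("reciprocal-cross DM is far rarer than parental DM on shared truth", {
  cfg <- sim_config(n_cpg = 1500L, n_chrom = 2L, chrom_length = 4e5L,
                    frac_dm = 0.03, dm_effect_range = c(0.4, 0.6),
                    n_imprinted = 0L, n_noncpg = 100L)
  tr <- simulate_truth(cfg, seed = 61)
  pl <- simulate_pileups(tr, sim_design(), depth = 30, seed = 62)
  cross <- detect_cross_dm(pl$pileups, pl$design,
                           variants = tr$variants)
  par_des <- pl$design[pl$design$role %in% c("BN", "SHR"), ]
  parental <- call_dmcs_and_dmrs(
    pl$pileups[pl$pileups$sample_id %in% par_des$sample_id, ],
    setNames(par_des$role, par_des$sample_id), variants = tr$variants)
  n_cross <- sum(cross$dmc$significant)
  n_par <- sum(parental$dmc$significant)
  expect_gt(n_par, 20)
  expect_lt(n_cross, n_par / 10)
})
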