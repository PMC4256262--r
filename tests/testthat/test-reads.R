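test_that("reference conversion targets only the requested bases", {
  expect_equal(convert_reference("ACGT", "C2T"), "ATGT")
  expect_equal(convert_reference("ACGT", "G2A"), "ACAT")
  v <- data.frame(chrom = "c", pos = 2L, bn_allele = "C",
                  shr_allele = "G", kind = "snp", stringsAsFactors = FALSE)
  expect_equal(convert_reference("ACGT", "snp_mask", v), "ANGT")
  expect_equal(convert_reference("ACGT", "allele_substitute", v), "AGGT")
  expect_error(convert_reference("ACGT", "snp_mask"), "variants")
  v$pos <- 99L
  expect_error(convert_reference("ACGT", "snp_mask", v), "outside")
})

test_that("pre-alignment masking, first-base clip and quality trim", {
  hi <- strrep(rawToChar(as.raw(33 + 35)), 4)      # Q35 everywhere
  pair <- list(seq1 = "CCAT", qual1 = hi, seq2 = "GGAT", qual2 = hi)
  out <- preprocess_read_pair(pair)
  expect_equal(out$seq1, "TAT")                    # mask then clip
  expect_equal(out$seq2, "AAT")
  expect_false(out$empty)

  # all qualities >= Q20: no 3' trimming beyond the first-base clip
  expect_equal(nchar(out$seq1), 3L)

  # low-quality 3' tail is trimmed by the running-sum rule
  q <- paste0(strrep(rawToChar(as.raw(33 + 30)), 5),
              strrep(rawToChar(as.raw(33 + 2)), 5))
  pair2 <- list(seq1 = "AATTAATTAA", qual1 = q,
                seq2 = "AATTAATTAA", qual2 = q)
  out2 <- preprocess_read_pair(pair2, qcut = 20)
  expect_equal(nchar(out2$seq1), 4L)   # 10 - 1 clip - 5 low-Q tail

  # a fully low-quality read trims to nothing and is flagged
  lo <- strrep(rawToChar(as.raw(33 + 2)), 4)
  out3 <- preprocess_read_pair(list(seq1 = "ACGT", qual1 = lo,
                                    seq2 = "ACGT", qual2 = lo))
  expect_true(out3$empty)
})

mk_pair <- function(id, start1, start2 = start1 + 100L, mapq = 60L,
                    bs = "OT", seq1 = "ACGT", seq2 = "ACGT",
                    q1 = NULL, q2 = NULL, chrom = "chr1") {
  qd <- strrep(rawToChar(as.raw(33 + 30)), nchar(seq1))
  data.frame(pair_id = id, chrom = chrom, start1 = start1,
             start2 = start2, seq1 = seq1, seq2 = seq2,
             qual1 = if (is.null(q1)) qd else q1,
             qual2 = if (is.null(q2)) qd else q2,
             bs_strand = bs, mapq = mapq, stringsAsFactors = FALSE)
}

test_that("clonal duplicates collapse to the highest-quality pair", {
  hiq <- strrep(rawToChar(as.raw(33 + 38)), 4)
  pairs <- rbind(mk_pair("a", 100L), mk_pair("b", 100L, q1 = hiq),
                 mk_pair("c", 500L))
  kept <- filter_and_clip(pairs)
  expect_equal(nrow(kept), 2L)
  expect_true("b" %in% kept$pair_id)     # higher summed quality wins
  # first-seen wins on exact quality ties
  pairs2 <- rbind(mk_pair("x", 100L), mk_pair("y", 100L))
  expect_equal(filter_and_clip(pairs2)$pair_id[1], "x")
})

test_that("mapping-quality boundary and dual-strand removal", {
  pairs <- rbind(mk_pair("a", 100L, mapq = 19L),
                 mk_pair("b", 200L, mapq = 20L),
                 mk_pair("d", 400L, bs = "OT"),
                 mk_pair("d", 400L, bs = "OB"))
  kept <- filter_and_clip(pairs)
  expect_identical(kept$pair_id, "b")
})

test_that("filtering is idempotent", {
  tr <- tiny_truth(seed = 31)
  rd <- simulate_f1_reads(tr, n_pairs = 80, seed = 32)
  once <- filter_and_clip(rd)
  twice <- filter_and_clip(once[, names(rd)])
  expect_equal(twice[, names(rd)], once[, names(rd)])
})

test_that("overlapping mates are counted once in the pileup", {
  # mates overlap by 10 bp over a C site
  seqs <- strrep("C", 30)
  p <- mk_pair("a", 100L, start2 = 120L, seq1 = seqs, seq2 = seqs)
  p$qual1 <- strrep(rawToChar(as.raw(33 + 30)), 30)
  p$qual2 <- p$qual1
  kept <- filter_and_clip(p)
  site <- data.frame(chrom = "chr1", pos = 125L, strand = "+",
                     stringsAsFactors = FALSE)
  pile <- pileup_cytosines(kept, site)
  expect_equal(pile$c_count + pile$t_count + pile$other_count, 1L)
})

test_that("pileup is strand-specific", {
  p1 <- rbind(mk_pair("a", 100L, seq1 = "CCCC"),
              mk_pair("b", 100L, start2 = 210L, seq1 = "CCCC"),
              mk_pair("c", 100L, start2 = 220L, seq1 = "CCCC"),
              mk_pair("d", 100L, start2 = 230L, seq1 = "TCCC"))
  kept <- filter_and_clip(p1)
  site <- data.frame(chrom = "chr1", pos = 100L, strand = "+",
                     stringsAsFactors = FALSE)
  pile <- pileup_cytosines(kept, site)
  expect_equal(pile$c_count, 3L)
  expect_equal(pile$t_count, 1L)

  # reverse-strand site: G counts as methylated, A as converted
  p2 <- rbind(mk_pair("a", 100L, bs = "OB", seq1 = "GAAA"),
              mk_pair("b", 100L, start2 = 210L, bs = "OB", seq1 = "GAAA"),
              mk_pair("c", 100L, start2 = 220L, bs = "OB", seq1 = "AAAA"))
  kept2 <- filter_and_clip(p2)
  site2 <- data.frame(chrom = "chr1", pos = 100L, strand = "-",
                      stringsAsFactors = FALSE)
  pile2 <- pileup_cytosines(kept2, site2)
  expect_equal(pile2$c_count, 2L)
  expect_equal(pile2$t_count, 1L)
})

test_that("read-level pileup recovers the simulated methylation level", {
  cfg <- sim_config(n_cpg = 60L, n_chrom = 1L, chrom_length = 6000L,
                    frac_dm = 0, n_imprinted = 0L, base_error = 0,
                    n_noncpg = 20L, snp_density = 0)
  tr <- simulate_truth(cfg, seed = 33)
  tr$sites$theta_bn <- 0.8; tr$sites$theta_shr <- 0.8
  rd <- simulate_f1_reads(tr, n_pairs = 3000, seed = 34, conv_rate = 1)
  kept <- filter_and_clip(rd, dup_key = "both")
  pile <- pileup_cytosines(kept, tr$sites[, c("chrom", "pos", "strand")])
  tot_c <- sum(pile$c_count); tot <- sum(pile$c_count + pile$t_count)
  expect_gt(tot, 500)
  ci <- binom.test(tot_c, tot, 0.8)$conf.int
  expect_gt(0.8 + 0.02, ci[1]); expect_lt(0.8 - 0.02, ci[2])
})
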