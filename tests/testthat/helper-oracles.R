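# Independent oracles and small fixture builders shared by the tests.

# Exhaustive hypergeometric enumeration of the two-sided Fisher p,
# computed from binomial coefficients (a numeric path independent of
# the dhyper-based implementation).  Same minimum-likelihood tie rule.
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b; m <- a + c; n <- b + d; N <- m + n
  supp <- max(0, k - n):min(k, m)
  p <- exp(lchoose(m, supp) + lchoose(n, k - supp) - lchoose(N, k))
  min(1, sum(p[p <= p[supp == a] * (1 + 1e-7)]))
}

# A small dense truth set: one short contig, high CpG density, useful
# for read-level tests.
tiny_truth <- function(seed = 42, n_cpg = 200, chrom_length = 20000L,
                       ...) {
  simulate_truth(sim_config(n_cpg = n_cpg, n_chrom = 1L,
                            chrom_length = chrom_length,
                            n_imprinted = 0L, n_noncpg = 200L, ...),
                 seed = seed)
}

# Replicate-level allele pileup table built from explicit per-cell
# counts: counts is a list keyed "cross allele" of c(c, t), replicated
# n_rep times at one site.
allele_fixture <- function(counts, n_rep = 3L, chrom = "chr1",
                           pos = 1000L) {
  rows <- list()
  for (cell in names(counts)) {
    ca <- strsplit(cell, " ")[[1]]
    for (r in seq_len(n_rep))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, pos = pos, strand = "+",
        sample_id = paste0(tolower(ca[1]), "_", r),
        cross = ca[1], allele = ca[2],
        c_count = counts[[cell]][1], t_count = counts[[cell]][2],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Multi-site variant of allele_fixture: per-site list of cell counts.
allele_fixture_sites <- function(site_counts, pos, n_rep = 3L,
                                 chrom = "chr1") {
  do.call(rbind, lapply(seq_along(pos), function(i)
    allele_fixture(site_counts[[i]], n_rep = n_rep, chrom = chrom,
                   pos = pos[i])))
}
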