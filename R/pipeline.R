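## End-to-end convenience driver over the synthetic study design.

#' Run the full analysis pipeline on a simulated study
#'
#' Chains the stages end to end on synthetic data with known truth:
#' truth simulation, pileup simulation for the parental and reciprocal
#' F1 design, conversion-rate estimation, parental differential
#' methylation with DMR clustering, reciprocal-cross differential
#' methylation, allele-specific and parent-of-origin detection on the
#' phased (allele-tagged) F1 profiles, recombinant-inbred meth-QTL
#' mapping, phenotype correlation, sequence-context statistics and
#' profile clustering/PCA.
#'
#' @param config A [sim_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param depth Simulated read depth.
#' @param n_perm Permutations per linkage trait.
#' @param fdr FDR threshold used throughout.
#' @return Named list with the per-stage results plus the underlying
#'   `truth`, `pileups` and `ri` objects.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, depth = 30L,
                         n_perm = 1000L, fdr = 0.05) {
  truth <- simulate_truth(config, seed = seed)
  design <- sim_design()
  pl <- simulate_pileups(truth, design, depth = depth, seed = seed + 1L)

  conv <- estimate_conversion_rates(pl$lambda, pl$noncpg, design)
  rates <- stats::setNames(conv$r_s, conv$sample_id)

  par_design <- design[design$role %in% c("BN", "SHR"), ]
  par_groups <- stats::setNames(par_design$role, par_design$sample_id)
  par_pil <- pl$pileups[pl$pileups$sample_id %in% par_design$sample_id, ]
  parental <- call_dmcs_and_dmrs(par_pil, par_groups, conv_rates = rates,
                                 variants = truth$variants, fdr = fdr)

  cross <- detect_cross_dm(pl$pileups, design, conv_rates = rates,
                           variants = truth$variants, fdr = fdr)
  asm <- detect_asm(pl$allele_pileups, fdr = fdr)
  po <- detect_po(pl$allele_pileups, fdr = fdr)

  ri <- simulate_ri_panel(truth, seed = seed + 2L)
  qtl <- map_meth_qtl(ri, n_perm = n_perm, seed = seed + 3L)
  pheno <- summarize_phenotypes(ri$phenotype)
  meth_means <- stats::aggregate(value ~ strain + locus, ri$meth, mean)
  qtm <- correlate_traits(meth_means, pheno)

  dmc <- parental$dmc
  sig <- dmc[dmc$significant, , drop = FALSE]
  context <- if (nrow(sig) >= 2) {
    win <- extract_windows(truth$reference, sig, "shr", truth$variants)
    list(snp = nearest_snp_stats(
      list(tested = dmc, dm = sig), truth$variants),
      pfm = build_pfm_ic(win, -sig$delta_m))
  }

  list(truth = truth, pileups = pl, conversion = conv,
       parental = parental, cross = cross, asm = asm, po = po,
       ri = ri, qtl = qtl, qtm = qtm, context = context)
}
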