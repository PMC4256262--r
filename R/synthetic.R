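## Synthetic WGBS crosses with known truth.
##
## The generator emulates the study design the pipeline targets: two
## inbred parental strains (BN, SHR; four replicates each), reciprocal
## F1 crosses with allele-resolved methylation including imprinted
## regions, a recombinant-inbred (RI) panel of marker-block mosaics,
## binomial read sampling with bisulfite conversion failure and base
## error, an unmethylated lambda spike-in contig, and a phenotype
## linearly coupled to methylation at a chosen locus.

.BASE_FREQ <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)

#' Simulation configuration
#'
#' Defaults mirror the emulated study design at desk scale: ~0.7% of
#' CpGs differentially methylated between strains, bisulfite conversion
#' rates above 97%, imprinted regions with strong maternal/paternal
#' contrast, a background SNP about every 750 bp and 5.3% of
#' differentially methylated CpGs carrying a SNP within 5 bp of the
#' dyad.
#'
#' @param n_cpg Number of CpG dyads across the autosome-like contigs.
#' @param n_chrom Number of autosome-like contigs.
#' @param chrom_length Length of each contig in bp.
#' @param frac_dm Fraction of CpGs differentially methylated between
#'   the strains.
#' @param dm_effect_range Range of |theta_BN - theta_SHR| for
#'   differential CpGs (drawn uniformly).
#' @param n_imprinted Number of imprinted regions.
#' @param imprinted_size CpGs per imprinted region.
#' @param imprint_spacing Spacing in bp between imprinted CpGs.
#' @param theta_m,theta_p Methylation of the maternally / paternally
#'   inherited allele inside imprinted regions.
#' @param conv_range Range of per-sample bisulfite conversion rates.
#' @param base_error Symmetric base substitution error rate applied
#'   after conversion.
#' @param snp_density Background SNP rate per bp.
#' @param frac_dm_with_snp Fraction of differential CpGs with a planted
#'   SNP within 5 bp of the dyad.
#' @param frac_disrupting Fraction of CpGs carrying a CpG-disrupting
#'   SNP (at the C or G of the dyad).
#' @param flank_assoc_prob Probability that a planted SNP immediately
#'   flanking a differential CpG is oriented so that an AT-to-GC change
#'   in SHR accompanies increased SHR methylation.
#' @param n_noncpg Number of non-CpG cytosine positions tracked for
#'   conversion-rate estimation.
#' @param lambda_length Length of the unmethylated lambda-like spike-in
#'   contig.
#' @return A named list of class `mx_config`.
#' @export
sim_config <- function(n_cpg = 10000L, n_chrom = 4L, chrom_length = 1e6L,
                       frac_dm = 0.007, dm_effect_range = c(0.2, 0.8),
                       n_imprinted = 2L, imprinted_size = 10L,
                       imprint_spacing = 30L,
                       theta_m = 0.95, theta_p = 0.05,
                       conv_range = c(0.975, 0.995), base_error = 0.001,
                       snp_density = 1 / 750, frac_dm_with_snp = 0.053,
                       frac_disrupting = 0.002, flank_assoc_prob = 0.8,
                       n_noncpg = 2000L, lambda_length = 5000L) {
  cfg <- list(n_cpg = as.integer(n_cpg), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length), frac_dm = frac_dm,
              dm_effect_range = dm_effect_range,
              n_imprinted = as.integer(n_imprinted),
              imprinted_size = as.integer(imprinted_size),
              imprint_spacing = as.integer(imprint_spacing),
              theta_m = theta_m, theta_p = theta_p,
              conv_range = conv_range, base_error = base_error,
              snp_density = snp_density,
              frac_dm_with_snp = frac_dm_with_snp,
              frac_disrupting = frac_disrupting,
              flank_assoc_prob = flank_assoc_prob,
              n_noncpg = as.integer(n_noncpg),
              lambda_length = as.integer(lambda_length))
  stopifnot(cfg$n_cpg > 0, cfg$frac_dm >= 0, cfg$frac_dm <= 1,
            all(cfg$conv_range >= 0 & cfg$conv_range <= 1),
            cfg$theta_m >= 0, cfg$theta_m <= 1,
            cfg$theta_p >= 0, cfg$theta_p <= 1)
  if (cfg$n_imprinted * cfg$imprinted_size > cfg$n_cpg)
    stop("more imprinted CpGs requested than CpGs simulated")
  class(cfg) <- "mx_config"
  cfg
}

.random_seq <- function(n) {
  sample(names(.BASE_FREQ), n, replace = TRUE, prob = .BASE_FREQ)
}

## Baseline methylation: bimodal, mostly high, a small very-low class.
.draw_theta <- function(n) {
  cls <- sample(1:3, n, replace = TRUE, prob = c(0.75, 0.15, 0.10))
  th <- numeric(n)
  th[cls == 1] <- stats::rbeta(sum(cls == 1), 9, 1)
  th[cls == 2] <- stats::rbeta(sum(cls == 2), 2, 2)
  th[cls == 3] <- stats::rbeta(sum(cls == 3), 1, 9)
  th
}

#' Simulate ground truth for a two-strain methylome
#'
#' Generates reference contigs (plus a fully unmethylated lambda-like
#' spike-in), per-CpG true methylation for both strains, imprinted
#' regions with maternal/paternal levels, an inter-strain variant table
#' with SNPs planted near differential CpGs, and the non-CpG cytosine
#' positions used for conversion-rate estimation.  Deterministic given
#' `seed`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return A list of class `mx_truth` with elements `sites` (per-CpG
#'   truth table), `variants`, `reference` (named character vector of
#'   contig sequences), `noncpg` (chrom/pos of non-CpG cytosines),
#'   `lambda_sites`, `imprinted_regions` and `config`.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))

  ## reference contigs
  reference <- vapply(chroms, function(ch)
    paste(.random_seq(cfg$chrom_length), collapse = ""), character(1))
  lambda <- paste(.random_seq(cfg$lambda_length), collapse = "")

  ## regular CpG dyads, uniform placement with a minimum 10 bp gap
  per_chrom <- .split_count(cfg$n_cpg, cfg$n_chrom)
  sites <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(i) {
    n <- per_chrom[i]
    pos <- sort(sample(seq(50L, cfg$chrom_length - 50L, by = 10L), n))
    data.frame(chrom = chroms[i], pos = pos, stringsAsFactors = FALSE)
  }))
  sites$strand <- "+"

  ## imprinted blocks appended on the first contig, clear of other CpGs
  imprinted_regions <- NULL
  if (cfg$n_imprinted > 0) {
    span <- cfg$imprinted_size * cfg$imprint_spacing
    anchors <- seq(from = cfg$chrom_length - cfg$n_imprinted * (span + 2000L),
                   by = span + 2000L, length.out = cfg$n_imprinted)
    imp <- do.call(rbind, lapply(seq_len(cfg$n_imprinted), function(k) {
      pos <- anchors[k] + cfg$imprint_spacing * (seq_len(cfg$imprinted_size) - 1L)
      data.frame(chrom = chroms[1], pos = as.integer(pos),
                 strand = "+", region = k, stringsAsFactors = FALSE)
    }))
    sites <- sites[!(sites$chrom == chroms[1] &
                       sites$pos >= min(imp$pos) - 10L), , drop = FALSE]
    imprinted_regions <- data.frame(
      region = seq_len(cfg$n_imprinted), chrom = chroms[1],
      start = as.integer(anchors),
      end = as.integer(anchors + span - cfg$imprint_spacing + 1L))
  } else imp <- NULL

  n_reg <- nrow(sites)
  sites$theta_bn <- .draw_theta(n_reg)
  sites$is_dm <- FALSE
  n_dm <- round(cfg$frac_dm * n_reg)
  dm_idx <- sample(n_reg, n_dm)
  sites$is_dm[dm_idx] <- TRUE
  delta <- stats::runif(n_dm, cfg$dm_effect_range[1], cfg$dm_effect_range[2])
  ## push theta_BN toward a side that can accommodate the effect
  base <- sites$theta_bn[dm_idx]
  up <- stats::runif(n_dm) < 0.5          # SHR higher than BN
  base[up]  <- pmin(base[up], 0.98 - delta[up])
  base[!up] <- pmax(base[!up], 0.02 + delta[!up])
  sites$theta_bn[dm_idx] <- base
  sites$theta_shr <- sites$theta_bn
  sites$theta_shr[dm_idx] <- base + ifelse(up, delta, -delta)
  sites$is_imprinted <- FALSE
  sites$imprint_region <- NA_integer_

  if (!is.null(imp)) {
    imp$theta_bn <- (cfg$theta_m + cfg$theta_p) / 2
    imp$theta_shr <- imp$theta_bn
    imp$is_dm <- FALSE
    imp$is_imprinted <- TRUE
    imp$imprint_region <- imp$region
    imp$region <- NULL
    sites <- rbind(sites, imp[, names(sites)])
  }
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL

  ## force a CG dyad at every site
  reference <- .plant_dinucleotides(reference, sites)

  ## variants: background SNPs, planted near-DM SNPs, disrupting SNPs,
  ## and a few indels
  variants <- .simulate_variants(cfg, chroms, reference, sites)

  ## non-CpG cytosines for conversion-rate estimation (tracked as
  ## positions; all truly unmethylated)
  noncpg <- .find_noncpg_c(reference, cfg$n_noncpg)

  ## lambda CpG-context cytosines (all unmethylated)
  lam_c <- gregexpr("C", lambda, fixed = TRUE)[[1]]
  lam_c <- lam_c[lam_c > 0]
  lambda_sites <- data.frame(chrom = "lambda",
                             pos = as.integer(lam_c), strand = "+",
                             stringsAsFactors = FALSE)

  structure(list(sites = sites, variants = variants,
                 reference = c(reference, lambda = lambda),
                 noncpg = noncpg, lambda_sites = lambda_sites,
                 imprinted_regions = imprinted_regions,
                 config = cfg, seed = seed),
            class = "mx_truth")
}

.split_count <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

.plant_dinucleotides <- function(reference, sites) {
  for (ch in unique(sites$chrom)) {
    s <- strsplit(reference[[ch]], "")[[1]]
    p <- sites$pos[sites$chrom == ch]
    s[p] <- "C"; s[p + 1L] <- "G"
    reference[[ch]] <- paste(s, collapse = "")
  }
  reference
}

.other_base <- function(base, transversion_only = FALSE) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

.simulate_variants <- function(cfg, chroms, reference, sites) {
  dyad <- c(paste(sites$chrom, sites$pos),
            paste(sites$chrom, sites$pos + 1L))
  refbase <- function(ch, pos) {
    vapply(seq_along(pos), function(i)
      substr(reference[[ch[i]]], pos[i], pos[i]), character(1))
  }
  out <- list()

  ## background SNPs, uniform, off the CpG dyads
  n_bg <- stats::rpois(1, cfg$snp_density * cfg$chrom_length * cfg$n_chrom)
  if (n_bg > 0) {
    bg_ch <- sample(chroms, n_bg, replace = TRUE)
    bg_pos <- sample.int(cfg$chrom_length - 10L, n_bg, replace = TRUE) + 5L
    keep <- !(paste(bg_ch, bg_pos) %in% dyad)
    bg_ch <- bg_ch[keep]; bg_pos <- bg_pos[keep]
    bn <- refbase(bg_ch, bg_pos)
    if (length(bg_ch))
      out$bg <- data.frame(chrom = bg_ch, pos = bg_pos, bn_allele = bn,
                           shr_allele = .other_base(bn), kind = "snp",
                           stringsAsFactors = FALSE)
  }

  ## planted SNPs within 5 bp of differential CpGs; half of the ones at
  ## the immediately flanking base carry the AT->GC association with the
  ## direction of the methylation difference
  dm <- sites[sites$is_dm, , drop = FALSE]
  n_plant <- round(cfg$frac_dm_with_snp * nrow(dm))
  if (n_plant > 0 && nrow(dm) > 0) {
    pick <- dm[sample(nrow(dm), n_plant), , drop = FALSE]
    offs <- sample(c(-5:-1, 2:6), n_plant, replace = TRUE)
    flank <- sample(c(TRUE, FALSE), n_plant, replace = TRUE, prob = c(.5, .5))
    offs[flank] <- sample(c(-1L, 2L), sum(flank), replace = TRUE)
    ppos <- pick$pos + offs
    pbn <- character(n_plant); pshr <- character(n_plant)
    shr_up <- pick$theta_shr > pick$theta_bn
    for (i in seq_len(n_plant)) {
      if (flank[i] && stats::runif(1) < cfg$flank_assoc_prob) {
        ## orient allele change with methylation direction
        if (shr_up[i]) { pbn[i] <- sample(c("A", "T"), 1)
                         pshr[i] <- sample(c("G", "C"), 1) }
        else           { pbn[i] <- sample(c("G", "C"), 1)
                         pshr[i] <- sample(c("A", "T"), 1) }
      } else {
        pbn[i] <- refbase(pick$chrom[i], ppos[i])
        pshr[i] <- .other_base(pbn[i])
      }
    }
    out$planted <- data.frame(chrom = pick$chrom, pos = ppos,
                              bn_allele = pbn, shr_allele = pshr,
                              kind = "snp", stringsAsFactors = FALSE)
  }

  ## CpG-disrupting SNPs on a small fraction of non-DM CpGs
  n_dis <- round(cfg$frac_disrupting * nrow(sites))
  if (n_dis > 0) {
    cand <- sites[!sites$is_dm & !sites$is_imprinted, , drop = FALSE]
    pick <- cand[sample(nrow(cand), min(n_dis, nrow(cand))), , drop = FALSE]
    at_c <- sample(c(TRUE, FALSE), nrow(pick), replace = TRUE)
    dpos <- ifelse(at_c, pick$pos, pick$pos + 1L)
    dbn <- ifelse(at_c, "C", "G")
    dshr <- ifelse(at_c, "T", "A")     # classic CG > TG / CG > CA loss
    out$disrupting <- data.frame(chrom = pick$chrom, pos = dpos,
                                 bn_allele = dbn, shr_allele = dshr,
                                 kind = "snp", stringsAsFactors = FALSE)
  }

  ## a few background indels
  n_ind <- round(n_bg * 0.05)
  if (n_ind > 0) {
    ich <- sample(chroms, n_ind, replace = TRUE)
    ipos <- sample.int(cfg$chrom_length - 20L, n_ind, replace = TRUE) + 10L
    keep <- !(paste(ich, ipos) %in% dyad)
    ich <- ich[keep]; ipos <- ipos[keep]
    if (length(ich)) {
      ibn <- refbase(ich, ipos)
      out$indel <- data.frame(chrom = ich, pos = ipos, bn_allele = ibn,
                              shr_allele = paste0(ibn, "A"), kind = "indel",
                              stringsAsFactors = FALSE)
    }
  }

  if (length(out) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      bn_allele = character(), shr_allele = character(),
                      kind = character(), stringsAsFactors = FALSE))
  v <- do.call(rbind, out)
  v <- v[v$bn_allele != v$shr_allele, ]
  v <- v[!duplicated(paste(v$chrom, v$pos)), ]
  v <- v[order(v$chrom, v$pos), ]
  rownames(v) <- NULL
  v
}

.find_noncpg_c <- function(reference, n) {
  picks <- list()
  chroms <- setdiff(names(reference), "lambda")
  per <- .split_count(n, length(chroms))
  for (i in seq_along(chroms)) {
    s <- reference[[chroms[i]]]
    cpos <- gregexpr("C", s, fixed = TRUE)[[1]]
    nxt <- vapply(cpos + 1L, function(p) substr(s, p, p), character(1))
    cand <- cpos[nxt != "G" & cpos < nchar(s)]
    picks[[i]] <- data.frame(chrom = chroms[i],
                             pos = as.integer(sort(sample(cand, per[i]))),
                             strand = "+", stringsAsFactors = FALSE)
  }
  do.call(rbind, picks)
}

#' Standard sample design for a simulated experiment
#'
#' Four replicates per parental strain and per reciprocal cross,
#' matching the emulated design.
#'
#' @param n_rep Replicates per group.
#' @return Data frame with `sample_id`, `role`, `replicate`.
#' @export
sim_design <- function(n_rep = 4L) {
  roles <- c("BN", "SHR", "F1_BNxSHR", "F1_SHRxBN")
  do.call(rbind, lapply(roles, function(r)
    data.frame(sample_id = paste0(tolower(sub("F1_", "", r)), "_", seq_len(n_rep)),
               role = r, replicate = seq_len(n_rep),
               stringsAsFactors = FALSE)))
}

## Per-site expected C-call probability under the conversion/error model
.p_c_call <- function(theta, r_s, err) {
  p <- theta + (1 - theta) * (1 - r_s)
  p * (1 - 2 * err) + err
}

#' Simulate strand-specific C/T pileups under the conversion model
#'
#' For every sample in `design` draws binomial C/T counts at each CpG
#' site with C-call probability `theta + (1 - theta) * (1 - r_s)` and a
#' symmetric base error applied after conversion.  F1 samples
#' additionally emit two allele-tagged pileups (BN allele, SHR allele)
#' at roughly half depth each; imprinted sites methylate by the parental
#' origin the cross implies (dam listed first in the cross name).
#' Lambda-contig pileups (fully unmethylated, modulo conversion
#' failure) are produced for F1 samples and non-CpG cytosine pileups
#' for all samples.
#'
#' @param truth An [simulate_truth()] object.
#' @param design Sample sheet as from [sim_design()].
#' @param depth Read depth per site (total; F1 alleles split
#'   binomially).
#' @param seed Integer seed.
#' @param conv_rates Optional named vector of per-sample conversion
#'   rates; drawn from `config$conv_range` when `NULL`.
#' @return List of class `mx_pileups` with elements `pileups`
#'   (unphased CpG pileups for all samples), `allele_pileups` (F1
#'   allele-tagged counts), `lambda`, `noncpg`, `conv_rates` and
#'   `design`.
#' @export
simulate_pileups <- function(truth, design = sim_design(), depth = 30L,
                             seed = 1L, conv_rates = NULL) {
  stopifnot(inherits(truth, "mx_truth"), depth > 0)
  depth <- as.integer(depth)
  if (!all(design$role %in% c("BN", "SHR", "F1_BNxSHR", "F1_SHRxBN")))
    stop("unknown role in design: ",
         paste(setdiff(design$role,
                       c("BN", "SHR", "F1_BNxSHR", "F1_SHRxBN")),
               collapse = ","))
  set.seed(seed)
  cfg <- truth$config
  if (is.null(conv_rates)) {
    conv_rates <- stats::runif(nrow(design), cfg$conv_range[1],
                               cfg$conv_range[2])
    names(conv_rates) <- design$sample_id
  }
  err <- cfg$base_error
  st <- truth$sites
  n <- nrow(st)

  pil <- list(); apil <- list(); lam <- list(); ncp <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]; role <- design$role[i]
    rs <- conv_rates[[sid]]
    if (role %in% c("BN", "SHR")) {
      theta <- if (role == "BN") st$theta_bn else st$theta_shr
      cc <- stats::rbinom(n, depth, .p_c_call(theta, rs, err))
      pil[[sid]] <- data.frame(chrom = st$chrom, pos = st$pos,
                               strand = st$strand, sample_id = sid,
                               c_count = cc, t_count = depth - cc,
                               other_count = 0L, stringsAsFactors = FALSE)
    } else {
      cross <- sub("F1_", "", role)
      ## maternal allele is the dam's (listed first in the cross name)
      maternal_allele <- if (cross == "BNxSHR") "BN" else "SHR"
      th_bn <- ifelse(st$is_imprinted,
                      ifelse(maternal_allele == "BN", cfg$theta_m, cfg$theta_p),
                      st$theta_bn)
      th_shr <- ifelse(st$is_imprinted,
                       ifelse(maternal_allele == "SHR", cfg$theta_m, cfg$theta_p),
                       st$theta_shr)
      d_bn <- stats::rbinom(n, depth, 0.5)
      d_shr <- depth - d_bn
      c_bn <- stats::rbinom(n, d_bn, .p_c_call(th_bn, rs, err))
      c_shr <- stats::rbinom(n, d_shr, .p_c_call(th_shr, rs, err))
      apil[[sid]] <- data.frame(
        chrom = rep(st$chrom, 2), pos = rep(st$pos, 2),
        strand = rep(st$strand, 2), sample_id = sid, cross = cross,
        allele = rep(c("BN", "SHR"), each = n),
        c_count = c(c_bn, c_shr),
        t_count = c(d_bn - c_bn, d_shr - c_shr),
        stringsAsFactors = FALSE)
      pil[[sid]] <- data.frame(chrom = st$chrom, pos = st$pos,
                               strand = st$strand, sample_id = sid,
                               c_count = c_bn + c_shr,
                               t_count = depth - (c_bn + c_shr),
                               other_count = 0L, stringsAsFactors = FALSE)
      ## lambda spike-in: fully unmethylated
      ls <- truth$lambda_sites
      lc <- stats::rbinom(nrow(ls), depth, .p_c_call(0, rs, err))
      lam[[sid]] <- data.frame(chrom = ls$chrom, pos = ls$pos,
                               strand = ls$strand, sample_id = sid,
                               c_count = lc, t_count = depth - lc,
                               other_count = 0L, stringsAsFactors = FALSE)
    }
    ## non-CpG cytosines (unmethylated) for every sample
    nc <- truth$noncpg
    ncc <- stats::rbinom(nrow(nc), depth, .p_c_call(0, rs, err))
    ncp[[sid]] <- data.frame(chrom = nc$chrom, pos = nc$pos,
                             strand = nc$strand, sample_id = sid,
                             c_count = ncc, t_count = depth - ncc,
                             other_count = 0L, stringsAsFactors = FALSE)
  }
  structure(list(pileups = do.call(rbind, pil),
                 allele_pileups = if (length(apil)) do.call(rbind, apil),
                 lambda = if (length(lam)) do.call(rbind, lam),
                 noncpg = do.call(rbind, ncp),
                 conv_rates = conv_rates, design = design),
            class = "mx_pileups")
}

#' Simulate F1 read pairs for phasing tests
#'
#' Draws paired reads from a window of one contig.  Each pair is
#' assigned a true parental haplotype (BN or SHR with equal
#' probability); its bases carry that haplotype's SNP alleles, CpG
#' cytosines methylate according to the haplotype's true level, and
#' bisulfite conversion (C to T on OT-strand pairs, G to A on OB) is
#' applied to unmethylated cytosines with the sample conversion rate.
#'
#' @param truth An [simulate_truth()] object.
#' @param n_pairs Number of read pairs.
#' @param seed Integer seed.
#' @param chrom Contig to draw from.
#' @param window Optional `c(start, end)` restriction.
#' @param read_len Read length.
#' @param insert Outer fragment length.
#' @param conv_rate Conversion rate for the simulated sample.
#' @param error_rate Per-base substitution error rate (0 gives
#'   error-free reads).
#' @return Data frame of class `mx_reads`: one row per pair with mate
#'   coordinates, sequences, qualities, bisulfite strand (`OT`/`OB`),
#'   mapping quality and the true haplotype.
#' @export
simulate_f1_reads <- function(truth, n_pairs = 200L, seed = 1L,
                              chrom = "chr1", window = NULL,
                              read_len = 50L, insert = 150L,
                              conv_rate = 0.99, error_rate = 0) {
  stopifnot(inherits(truth, "mx_truth"))
  if (n_pairs <= 0) stop("n_pairs must be positive")
  set.seed(seed)
  seq_full <- truth$reference[[chrom]]
  len <- nchar(seq_full)
  if (is.null(window)) window <- c(1L, len - insert - 1L)
  vars <- truth$variants
  vars <- vars[vars$chrom == chrom & vars$kind == "snp", , drop = FALSE]
  st <- truth$sites[truth$sites$chrom == chrom, , drop = FALSE]
  theta <- stats::setNames(st$theta_bn, st$pos)       # per-haplotype below
  theta_shr <- stats::setNames(st$theta_shr, st$pos)

  starts <- sample(seq(window[1], window[2]), n_pairs, replace = TRUE)
  hap <- sample(c("BN", "SHR"), n_pairs, replace = TRUE)
  bs <- sample(c("OT", "OB"), n_pairs, replace = TRUE)

  mk_read <- function(start, hap_i, bs_i) {
    bases <- strsplit(substr(seq_full, start, start + read_len - 1L), "")[[1]]
    pos <- start:(start + read_len - 1L)
    ## haplotype alleles
    hit <- match(pos, vars$pos)
    has <- which(!is.na(hit))
    if (length(has)) {
      al <- if (hap_i == "BN") vars$bn_allele[hit[has]] else
        vars$shr_allele[hit[has]]
      bases[has] <- al
    }
    ## bisulfite conversion
    if (bs_i == "OT") {
      cs <- which(bases == "C")
      for (j in cs) {
        p <- pos[j]
        th <- if (hap_i == "BN") theta[as.character(p)] else
          theta_shr[as.character(p)]
        meth <- if (!is.na(th)) stats::runif(1) < th else FALSE
        if (!meth && stats::runif(1) < conv_rate) bases[j] <- "T"
      }
    } else {
      ## OB reads observe the reverse strand: G at a forward-strand CpG
      ## G position reflects the reverse-strand cytosine
      gs <- which(bases == "G")
      for (j in gs) {
        p <- pos[j]
        th <- if (hap_i == "BN") theta[as.character(p - 1L)] else
          theta_shr[as.character(p - 1L)]
        meth <- if (!is.na(th)) stats::runif(1) < th else FALSE
        if (!meth && stats::runif(1) < conv_rate) bases[j] <- "A"
      }
    }
    if (error_rate > 0) {
      flip <- which(stats::runif(read_len) < error_rate)
      if (length(flip)) bases[flip] <- .other_base(bases[flip])
    }
    paste(bases, collapse = "")
  }

  seq1 <- character(n_pairs); seq2 <- character(n_pairs)
  start2 <- starts + insert - read_len
  for (i in seq_len(n_pairs)) {
    seq1[i] <- mk_read(starts[i], hap[i], bs[i])
    seq2[i] <- mk_read(start2[i], hap[i], bs[i])
  }
  qual <- paste(rep(rawToChar(as.raw(33L + 30L)), read_len), collapse = "")
  structure(data.frame(pair_id = paste0("p", seq_len(n_pairs)),
                       chrom = chrom, start1 = starts, start2 = start2,
                       seq1 = seq1, seq2 = seq2,
                       qual1 = qual, qual2 = qual,
                       bs_strand = bs, mapq = 60L, true_hap = hap,
                       stringsAsFactors = FALSE),
            class = c("mx_reads", "data.frame"))
}

#' Simulate a recombinant inbred panel with cis/trans methylation control
#'
#' RI genotypes are generated as marker-block mosaics: the first marker
#' of each chromosome is B or S with equal probability and adjacent
#' markers recombine at a configured rate.  Methylation loci (drawn
#' from the differential CpGs of `truth`) are controlled in cis by
#' their nearest marker, in trans by a marker on another chromosome, or
#' left unlinked; per-strain replicate values follow the controlling
#' genotype's parental level plus strain and replicate noise.  One
#' phenotype is generated with target Pearson correlation `rho` to the
#' methylation of a chosen cis locus.
#'
#' @param truth An [simulate_truth()] object.
#' @param n_strains Number of RI strains.
#' @param markers_per_chrom Markers per chromosome, evenly spaced
#'   (default echoes the panel's average marker spacing scaled to the
#'   toy map).
#' @param n_cis,n_trans,n_null Numbers of cis-, trans- and
#'   unlinked methylation loci.
#' @param recomb_rate Recombination probability between adjacent
#'   markers.
#' @param sd_strain Between-strain residual noise (percentage points).
#' @param sd_rep Within-strain replicate noise (percentage points).
#' @param n_rep Replicates per strain.
#' @param rho Target Pearson correlation between the phenotype and the
#'   phenotype-coupled locus's strain-mean methylation.
#' @param seed Integer seed.
#' @return List of class `mx_ri` with `genotypes` (strain x marker
#'   matrix), `marker_map`, `loci` (locus truth incl. controlling
#'   marker and type), `meth` (strain/locus/replicate methylation
#'   percentages), `phenotype` (strain/trait/replicate/value) and
#'   `pheno_locus`.
#' @export
simulate_ri_panel <- function(truth, n_strains = 29L,
                              markers_per_chrom = 10L,
                              n_cis = 8L, n_trans = 2L, n_null = 2L,
                              recomb_rate = 0.1, sd_strain = 2,
                              sd_rep = 4, n_rep = 2L, rho = -0.75,
                              seed = 1L) {
  stopifnot(inherits(truth, "mx_truth"))
  if (n_strains < 4) stop("need at least 4 RI strains")
  set.seed(seed)
  cfg <- truth$config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  strains <- sprintf("RI%02d", seq_len(n_strains))

  ## marker map: evenly spaced per chromosome
  marker_map <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    pos <- round(seq(cfg$chrom_length / (markers_per_chrom + 1),
                     cfg$chrom_length * markers_per_chrom /
                       (markers_per_chrom + 1),
                     length.out = markers_per_chrom))
    data.frame(marker = sprintf("m%d_%02d", i, seq_len(markers_per_chrom)),
               chrom = chroms[i], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))

  ## genotypes: block mosaic per chromosome
  G <- matrix(NA_character_, n_strains, nrow(marker_map),
              dimnames = list(strains, marker_map$marker))
  for (s in seq_len(n_strains)) {
    for (ch in chroms) {
      idx <- which(marker_map$chrom == ch)
      g <- character(length(idx))
      g[1] <- sample(c("B", "S"), 1)
      if (length(idx) > 1)
        for (j in 2:length(idx))
          g[j] <- if (stats::runif(1) < recomb_rate)
            setdiff(c("B", "S"), g[j - 1]) else g[j - 1]
      G[s, idx] <- g
    }
  }

  ## methylation loci from the differential CpGs
  dm <- truth$sites[truth$sites$is_dm, , drop = FALSE]
  n_loci <- n_cis + n_trans + n_null
  if (nrow(dm) < n_loci) stop("not enough differential CpGs for the panel")
  pick <- dm[sample(nrow(dm), n_loci), , drop = FALSE]
  type <- c(rep("cis", n_cis), rep("trans", n_trans), rep("null", n_null))
  ctrl <- character(n_loci)
  for (i in seq_len(n_loci)) {
    if (type[i] == "cis") {
      cand <- marker_map[marker_map$chrom == pick$chrom[i], ]
      ctrl[i] <- cand$marker[which.min(abs(cand$pos - pick$pos[i]))]
    } else if (type[i] == "trans") {
      cand <- marker_map[marker_map$chrom != pick$chrom[i], ]
      ctrl[i] <- cand$marker[sample(nrow(cand), 1)]
    } else ctrl[i] <- NA_character_
  }
  loci <- data.frame(locus = sprintf("locus_%02d", seq_len(n_loci)),
                     chrom = pick$chrom, pos = pick$pos,
                     theta_bn = pick$theta_bn, theta_shr = pick$theta_shr,
                     control = type, controlling_marker = ctrl,
                     stringsAsFactors = FALSE)

  ## per-strain methylation values (%)
  meth <- list()
  strain_level <- matrix(NA_real_, n_strains, n_loci,
                         dimnames = list(strains, loci$locus))
  for (i in seq_len(n_loci)) {
    if (is.na(ctrl[i])) {
      mu <- rep(100 * (loci$theta_bn[i] + loci$theta_shr[i]) / 2, n_strains)
    } else {
      g <- G[, ctrl[i]]
      mu <- ifelse(g == "B", 100 * loci$theta_bn[i], 100 * loci$theta_shr[i])
    }
    lv <- mu + stats::rnorm(n_strains, 0, sd_strain)
    strain_level[, i] <- lv
    for (r in seq_len(n_rep)) {
      val <- pmin(100, pmax(0, lv + stats::rnorm(n_strains, 0, sd_rep)))
      meth[[length(meth) + 1]] <- data.frame(
        strain = strains, locus = loci$locus[i], replicate = r,
        value = val, stringsAsFactors = FALSE)
    }
  }
  meth <- do.call(rbind, meth)

  ## phenotype coupled to the first cis locus
  pheno_locus <- loci$locus[match("cis", loci$control)]
  x <- strain_level[, pheno_locus]
  slope <- if (rho < 0) -1 else 1
  noise_sd <- abs(slope) * stats::sd(x) * sqrt(1 / rho^2 - 1)
  y <- 100 + slope * x + stats::rnorm(n_strains, 0, noise_sd)
  phenotype <- do.call(rbind, lapply(seq_len(n_rep), function(r)
    data.frame(strain = strains, trait = "pheno1", replicate = r,
               value = y + stats::rnorm(n_strains, 0, noise_sd / 4),
               stringsAsFactors = FALSE)))

  structure(list(genotypes = G, marker_map = marker_map, loci = loci,
                 meth = meth, phenotype = phenotype,
                 pheno_locus = pheno_locus,
                 strain_level = strain_level, rho = rho, seed = seed),
            class = "mx_ri")
}
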