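# Reproducible simulation experiments used to validate the pipeline's
# statistical properties. Each returns plain numeric summaries so the same
# drivers back both the test suite and the acceptance script. Problem sizes
# are chosen for desk-scale runs; the methods vignette discusses them.

#' Conversion-rate recovery experiment
#'
#' Simulates one library whose unmethylated spike-in contributes at least
#' `min_spike_c` cytosine observations (0.5% of reads at the configured
#' conversion rate), then estimates the global conversion rate from the
#' spike-in.
#'
#' @param seed master seed.
#' @param conversion_rate true per-cytosine conversion probability.
#' @param min_spike_c targeted minimum number of spike-in cytosines.
#' @return list with the `conversion_estimate`, the truth, and the absolute
#'   error in units of the binomial standard error.
#' @export
conversion_recovery_experiment <- function(seed, conversion_rate = 0.9995,
                                           min_spike_c = 1e5) {
  # ~25 cytosine observations per 100-nt read; size the library so the
  # 0.5% spike-in share clears the target with margin
  depth <- ceiling(min_spike_c / 0.0049 / 25 / (20 * 900 / 100) * 1.15)
  cfg <- sim_config(n_transcripts = 20, depth = depth,
                    conversion_rate = conversion_rate, seed = seed)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  rd <- simulate_reads(tx, truth, cfg, 1, 1)
  est <- estimate_conversion_rate(rd)
  se <- sqrt(conversion_rate * (1 - conversion_rate) / est$n_total_c)
  list(estimate = est, truth = conversion_rate,
       abs_err_se = abs(est$r - conversion_rate) / se)
}

#' Planted-site recovery experiment for the calling cascade
#'
#' Plants `n_sites` m5C sites at a fixed level on interior cytosines (where
#' read coverage reaches its nominal depth) of an otherwise unmethylated
#' transcriptome, simulates two replicate libraries, runs the full calling
#' cascade with replicate intersection, and scores sensitivity and the
#' empirical false-discovery proportion against the remaining (null)
#' cytosines.
#'
#' @param seed master seed.
#' @param n_sites number of planted sites.
#' @param level planted methylation level.
#' @param depth mean per-site coverage per replicate.
#' @return list with `sensitivity`, `fdp`, `n_called`, `n_null_cytosines`.
#' @export
calling_recovery_experiment <- function(seed, n_sites = 200, level = 0.3,
                                        depth = 50) {
  cfg <- sim_config(n_transcripts = 45, depth = depth,
                    resistant_fraction = 0, sites_per_transcript = 0,
                    dms_fraction = 0, seed = seed)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  ann <- tx$annotation
  nonspike <- ann$transcript_id[!ann$is_spike_in]
  allc <- data.table::rbindlist(lapply(nonspike, function(id)
    data.table::data.table(transcript_id = id,
                           pos = cytosine_positions(tx$seq[[id]]))))
  len_of <- ann$length[match(allc$transcript_id, ann$transcript_id)]
  interior <- allc[allc$pos >= cfg$read_length &
                     allc$pos <= len_of - cfg$read_length]
  set.seed(derive_seed(seed, 6L))
  pick <- interior[sample(nrow(interior), n_sites)]
  truth$sites <- data.table::data.table(
    transcript_id = pick$transcript_id,
    gene_id = ann$gene_id[match(pick$transcript_id, ann$transcript_id)],
    pos = pick$pos, type = "stable",
    level_t1 = level, level_t2 = level, level_t3 = level,
    archetype = NA_character_)
  st <- lapply(1:2, function(r) {
    rd <- simulate_reads(tx, truth, cfg, 1, r)
    f <- three_c_filter(rd)
    conv <- estimate_conversion_rate(rd)
    pile <- build_pileups(f$clean, rd, ann)
    suppressWarnings(apply_site_filters(call_site_pvalues(pile, conv)))
  })
  hc <- merge_replicates(st[[1]], st[[2]])
  called <- paste(hc$transcript_id, hc$pos)
  planted <- paste(pick$transcript_id, pick$pos)
  list(sensitivity = mean(planted %in% called),
       fdp = if (length(called)) mean(!(called %in% planted)) else 0,
       n_called = length(called),
       n_null_cytosines = nrow(allc) - n_sites)
}

#' Label-permuted null experiment for differential methylation
#'
#' Simulates four replicate libraries of the same condition, splits them
#' into two pseudo-conditions (a label permutation under the null), and
#' reports the fraction of eligible sites called differentially methylated.
#'
#' @param seed master seed.
#' @return the DMS fraction (0 when no site is eligible).
#' @export
dms_null_experiment <- function(seed) {
  cfg <- sim_config(n_transcripts = 40, depth = 40, seed = seed)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  piles <- vector("list", 4); sts <- vector("list", 4)
  for (r in 1:4) {
    rd <- simulate_reads(tx, truth, cfg, 1, r)
    f <- three_c_filter(rd)
    conv <- estimate_conversion_rate(rd)
    pile <- build_pileups(f$clean, rd, tx$annotation)
    piles[[r]] <- pile
    sts[[r]] <- suppressWarnings(
      apply_site_filters(call_site_pvalues(pile, conv)))
  }
  hc_a <- merge_replicates(sts[[1]], sts[[2]])
  hc_b <- merge_replicates(sts[[3]], sts[[4]])
  elig <- select_eligible_sites(piles[1:2], piles[3:4], hc_a, hc_b)
  if (nrow(elig) == 0L) return(0)
  out <- classify_dms(dm_records(elig, piles[1:2], piles[3:4]), quiet = TRUE)
  mean(out$direction != "ns")
}

#' Null-matrix calibration experiment for differential expression
#'
#' Simulates a count matrix with no planted expression effects and reports
#' the fraction of genes with BH-adjusted p at or below 0.05 between two
#' time points.
#'
#' @param seed master seed.
#' @param n_genes number of genes.
#' @return fraction of significant genes.
#' @export
de_null_experiment <- function(seed, n_genes = 2000) {
  cfg <- sim_config(n_transcripts = n_genes, deg_fraction = 0,
                    dms_fraction = 0, sites_per_transcript = 0, seed = seed)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  cnt <- simulate_counts(truth, cfg)
  dsn <- attr(cnt, "design")
  res <- de_test(cnt[, dsn$timepoint == 0], cnt[, dsn$timepoint == 2],
                 quiet = TRUE)
  mean(res$padj <= 0.05)
}

#' Structure-filter efficacy experiment
#'
#' Generates a transcriptome with planted hairpins, predicts resistant
#' regions with the internal fold, and measures which fraction of
#' in-hairpin cytosines (the false-positive class) versus planted true
#' sites (always outside hairpins) fall inside predicted regions and would
#' therefore be removed.
#'
#' @param seed master seed.
#' @return list with `false_removed` and `true_removed` fractions.
#' @export
structure_efficacy_experiment <- function(seed) {
  cfg <- sim_config(n_transcripts = 40, resistant_fraction = 0.5,
                    seed = seed)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  ann <- tx$annotation
  ns <- ann$transcript_id[!ann$is_spike_in]
  regions <- predict_resistant_regions_all(tx$seq[ns])
  hp <- tx$hairpins
  false_sites <- data.table::rbindlist(lapply(seq_len(nrow(hp)), function(i) {
    cp <- cytosine_positions(tx$seq[[hp$transcript_id[i]]])
    cp <- cp[cp >= hp$start[i] & cp <= hp$end[i]]
    if (!length(cp)) return(NULL)
    data.table::data.table(transcript_id = hp$transcript_id[i], pos = cp)
  }))
  in_region <- function(s) {
    hit <- rep(FALSE, nrow(s))
    for (k in seq_len(nrow(regions)))
      hit <- hit | (s$transcript_id == regions$transcript_id[k] &
                      s$pos >= regions$start[k] & s$pos <= regions$end[k])
    hit
  }
  list(false_removed = mean(in_region(false_sites)),
       true_removed = mean(in_region(truth$sites)))
}

#' Methylation-expression coupling recovery experiment
#'
#' Simulates a two-condition comparison in which every transcript carries
#' one differential site and the planted expression shifts correlate with
#' the planted methylation change at strength `rho`. Runs calling,
#' differential methylation and differential expression, then correlates
#' the estimated level differences of called DMS with the estimated log2
#' fold changes.
#'
#' @param seed master seed.
#' @param rho planted coupling (default -0.4; use 0 for the null).
#' @param n_transcripts number of DMS-carrying genes simulated.
#' @return list with `r`, `p`, `n` from [correlate_meth_expr()].
#' @export
coupling_experiment <- function(seed, rho = -0.4, n_transcripts = 400) {
  cfg <- sim_config(n_transcripts = n_transcripts, utr5_len = 50,
                    cds_len = 220, utr3_len = 180, depth = 30,
                    dms_fraction = 1, coupling_rho = rho, seed = seed)
  tx <- generate_transcriptome(cfg)
  truth <- plant_truth(tx, cfg)
  piles <- list(list(), list()); sts <- list(list(), list())
  for (t in 1:2) for (r in 1:2) {
    rd <- simulate_reads(tx, truth, cfg, t, r)
    f <- three_c_filter(rd)
    conv <- estimate_conversion_rate(rd)
    pile <- build_pileups(f$clean, rd, tx$annotation)
    piles[[t]][[r]] <- pile
    sts[[t]][[r]] <- suppressWarnings(
      apply_site_filters(call_site_pvalues(pile, conv)))
  }
  hc_a <- merge_replicates(sts[[1]][[1]], sts[[1]][[2]])
  hc_b <- merge_replicates(sts[[2]][[1]], sts[[2]][[2]])
  elig <- select_eligible_sites(piles[[1]], piles[[2]], hc_a, hc_b)
  out <- classify_dms(dm_records(elig, piles[[1]], piles[[2]]), quiet = TRUE)
  sig <- out[out$direction != "ns", ]
  cnt <- simulate_counts(truth, cfg)
  dsn <- attr(cnt, "design")
  de <- de_test(cnt[, dsn$timepoint == 0], cnt[, dsn$timepoint == 2],
                quiet = TRUE)
  ct <- correlate_meth_expr(sig, de,
                            gene_map = tx$annotation[, c("transcript_id",
                                                         "gene_id")])
  list(r = ct$r, p = ct$p, n = ct$n)
}
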