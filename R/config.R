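#' Simulation configuration for the synthetic RNA BS-seq experiment
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' the design of a KCl-depolarization time course in cultured neurons profiled
#' by RNA bisulfite sequencing: three time points (0, 2 and 6 h) with two
#' biological replicates each, an in vitro transcribed unmethylated spike-in
#' at 0.5% of reads for conversion-rate calibration, a per-cytosine bisulfite
#' conversion probability of 0.9995, planted m5C sites whose methylation
#' levels have median close to 0.2, a small fraction of globally
#' incompletely converted reads, hairpin (conversion-resistant) regions, and
#' a planted negative coupling between methylation change and expression
#' change.
#'
#' @param n_transcripts number of (non-spike-in) transcripts; one gene each.
#' @param utr5_len,cds_len,utr3_len mean segment lengths in nt. The defaults
#'   keep the transcriptome-average 5'UTR:CDS:3'UTR length ratio at 5:22:18,
#'   the ratio that motivates the 5/22/18 metagene bin split.
#' @param depth mean per-site read coverage per library.
#' @param read_length simulated read length (nt).
#' @param conversion_rate probability that an unmethylated cytosine is
#'   converted (read as T) by bisulfite treatment; default 0.9995.
#' @param incomplete_read_fraction fraction of reads drawn from a failed
#'   conversion process (each cytosine unconverted with probability 0.5).
#' @param spike_in_fraction fraction of reads originating from the
#'   unmethylated spike-in transcript; default 0.005 (0.5%).
#' @param spike_in_length length of the spike-in transcript (nt).
#' @param level_shape1,level_shape2 Beta shape parameters for planted
#'   methylation levels; Beta(2, 7) has median about 0.20.
#' @param sites_per_transcript mean number of stable (non-differential)
#'   planted m5C sites per transcript (Poisson).
#' @param dms_fraction fraction of transcripts carrying one differentially
#'   methylated site.
#' @param dms_delta methylation-level change planted at differential sites.
#' @param dms_archetype_weights five nonnegative weights for the temporal
#'   archetypes of differential sites: up-then-down, up-and-stay,
#'   down-then-up, monotone-up, monotone-down.
#' @param deg_fraction fraction of non-DMS genes with a planted expression
#'   archetype.
#' @param deg_archetype_weights four nonnegative weights for expression
#'   archetypes: monotone-down, early (up at 2 h, back down by 6 h),
#'   down-then-up, late (monotone up).
#' @param resistant_fraction fraction of transcripts receiving one planted
#'   hairpin (conversion-resistant) region.
#' @param hairpin_stem,hairpin_loop stem and loop lengths (nt) of planted
#'   hairpins.
#' @param mean_counts median expected expression count per gene and library.
#' @param counts_sdlog log-normal spread of per-gene baseline expression.
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param coupling_rho target correlation between planted methylation change
#'   and planted log2 expression change at DMS-carrying genes; negative by
#'   default.
#' @param coupling_sd standard deviation (log2 units) of coupled expression
#'   shifts.
#' @param n_timepoints,n_replicates experimental design; fixed at 3 x 2 in
#'   the emulated study but configurable.
#' @param seed master integer seed; all stages derive their streams from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 20, seed = 1)
#' cfg$conversion_rate
sim_config <- function(n_transcripts = 100,
                       utr5_len = 100, cds_len = 440, utr3_len = 360,
                       depth = 50,
                       read_length = 100,
                       conversion_rate = 0.9995,
                       incomplete_read_fraction = 0.02,
                       spike_in_fraction = 0.005,
                       spike_in_length = 1700,
                       level_shape1 = 2, level_shape2 = 7,
                       sites_per_transcript = 2,
                       dms_fraction = 0.25,
                       dms_delta = 0.3,
                       dms_archetype_weights = c(up_down = 0.45,
                                                 up_stay = 0.25,
                                                 down_up = 0.07,
                                                 up_up = 0.18,
                                                 down_down = 0.05),
                       deg_fraction = 0.3,
                       deg_archetype_weights = c(down = 0.38,
                                                 early = 0.11,
                                                 down_up = 0.28,
                                                 late = 0.23),
                       resistant_fraction = 0.3,
                       hairpin_stem = 25, hairpin_loop = 4,
                       mean_counts = 500,
                       counts_sdlog = 0.7,
                       nb_dispersion = 0.05,
                       coupling_rho = -0.4,
                       coupling_sd = 1.5,
                       n_timepoints = 3, n_replicates = 2,
                       seed = 1) {
  check_count(n_transcripts, "n_transcripts")
  check_pos(utr5_len, "utr5_len"); check_pos(cds_len, "cds_len")
  check_pos(utr3_len, "utr3_len")
  check_pos(depth, "depth"); check_count(read_length, "read_length", min = 20)
  check_prob(conversion_rate, "conversion_rate")
  check_prob(incomplete_read_fraction, "incomplete_read_fraction")
  check_prob(spike_in_fraction, "spike_in_fraction")
  check_count(spike_in_length, "spike_in_length", min = 100)
  check_pos(level_shape1, "level_shape1"); check_pos(level_shape2, "level_shape2")
  if (!is.numeric(sites_per_transcript) || sites_per_transcript < 0)
    stopf("'sites_per_transcript' must be nonnegative")
  check_prob(dms_fraction, "dms_fraction")
  check_prob(dms_delta, "dms_delta")
  check_prob(deg_fraction, "deg_fraction")
  check_prob(resistant_fraction, "resistant_fraction")
  check_count(hairpin_stem, "hairpin_stem", min = 6)
  check_count(hairpin_loop, "hairpin_loop", min = 3)
  check_pos(mean_counts, "mean_counts"); check_pos(counts_sdlog, "counts_sdlog")
  check_pos(nb_dispersion, "nb_dispersion")
  check_pos(coupling_sd, "coupling_sd")
  if (!is.numeric(coupling_rho) || length(coupling_rho) != 1L ||
      is.na(coupling_rho) || abs(coupling_rho) > 1)
    stopf("'coupling_rho' must be in [-1, 1]")
  if (length(dms_archetype_weights) != 5L || any(dms_archetype_weights < 0) ||
      sum(dms_archetype_weights) <= 0)
    stopf("'dms_archetype_weights' must be 5 nonnegative weights with positive sum")
  if (length(deg_archetype_weights) != 4L || any(deg_archetype_weights < 0) ||
      sum(deg_archetype_weights) <= 0)
    stopf("'deg_archetype_weights' must be 4 nonnegative weights with positive sum")
  check_count(n_timepoints, "n_timepoints", min = 2)
  check_count(n_replicates, "n_replicates", min = 1)
  check_count(seed, "seed", min = -.Machine$integer.max)

  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    depth = depth, read_length = as.integer(read_length),
    conversion_rate = conversion_rate,
    incomplete_read_fraction = incomplete_read_fraction,
    spike_in_fraction = spike_in_fraction,
    spike_in_length = as.integer(spike_in_length),
    level_shape1 = level_shape1, level_shape2 = level_shape2,
    sites_per_transcript = sites_per_transcript,
    dms_fraction = dms_fraction, dms_delta = dms_delta,
    dms_archetype_weights = dms_archetype_weights,
    deg_fraction = deg_fraction,
    deg_archetype_weights = deg_archetype_weights,
    resistant_fraction = resistant_fraction,
    hairpin_stem = as.integer(hairpin_stem),
    hairpin_loop = as.integer(hairpin_loop),
    mean_counts = mean_counts, counts_sdlog = counts_sdlog,
    nb_dispersion = nb_dispersion,
    coupling_rho = coupling_rho, coupling_sd = coupling_sd,
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic RNA BS-seq configuration\n")
  cat(sprintf("  %d transcripts (+1 spike-in), mean segments %g/%g/%g nt\n",
              x$n_transcripts, x$utr5_len, x$cds_len, x$utr3_len))
  cat(sprintf("  depth %g, read length %d, conversion rate %.4f\n",
              x$depth, x$read_length, x$conversion_rate))
  cat(sprintf("  design: %d time points x %d replicates; seed %d\n",
              x$n_timepoints, x$n_replicates, x$seed))
  invisible(x)
}

#' Site-filter thresholds for high-confidence m5C calling
#'
#' The filter cascade retains a candidate site only if (i) clean coverage
#' `C >= min_cov`, methylation level `m >= min_level` and methylated depth
#' `M >= min_meth` (the "standard" filter); (ii) its signal-to-noise ratio is
#' strictly greater than `min_sn`; and (iii) its BH-adjusted non-conversion
#' p-value is strictly below `max_fdr`. Strictness follows the stated
#' inequalities: level/coverage/depth are inclusive, S/N and FDR are strict.
#'
#' @param min_cov minimum clean coverage (default 20).
#' @param min_level minimum methylation level (default 0.1).
#' @param min_meth minimum methylated cytosine depth (default 6).
#' @param min_sn signal-to-noise ratio that must be exceeded (default 0.9).
#' @param max_fdr BH-adjusted p-value bound, exclusive (default 0.05).
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_cov = 20, min_level = 0.1, min_meth = 6,
                              min_sn = 0.9, max_fdr = 0.05) {
  check_count(min_cov, "min_cov", min = 0)
  check_prob(min_level, "min_level")
  check_count(min_meth, "min_meth", min = 0)
  check_prob(min_sn, "min_sn")
  check_prob(max_fdr, "max_fdr")
  structure(list(min_cov = as.integer(min_cov), min_level = min_level,
                 min_meth = as.integer(min_meth), min_sn = min_sn,
                 max_fdr = max_fdr),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf(paste0("m5C site filters: C >= %d, m >= %g, M >= %d, ",
                     "S/N > %g, BH-adjusted p < %g\n"),
              x$min_cov, x$min_level, x$min_meth, x$min_sn, x$max_fdr))
  invisible(x)
}
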