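#' Partition reads by the 3-unconverted-C rule
#'
#' Reads with more than 3 unconverted cytosines are treated as incompletely
#' bisulfite-converted ("noise"); all other reads, including reads without
#' any cytosine, are "clean". Exactly 3 unconverted cytosines is still
#' clean. The partition is exhaustive and disjoint, and the operation is
#' idempotent.
#'
#' @param reads an `m5c_reads` object (see [simulate_reads()] or
#'   [read_reads_tsv()]).
#' @param max_unconverted boundary of the rule (default 3; a read is noise
#'   iff its unconverted-C count exceeds it).
#' @return list with `clean` and `noise`, both `m5c_reads` objects.
#' @export
#' @examples
#' tx <- generate_transcriptome(cfg <- sim_config(n_transcripts = 5, seed = 1))
#' rd <- simulate_reads(tx, plant_truth(tx, cfg), cfg)
#' f <- three_c_filter(rd)
#' nrow(f$clean$reads) + nrow(f$noise$reads) == nrow(rd$reads)
three_c_filter <- function(reads, max_unconverted = 3L) {
  stopifnot(inherits(reads, "m5c_reads"))
  noisy <- reads$reads$n_unconverted > max_unconverted
  list(clean = reads_subset(reads, reads$reads$read_id[!noisy]),
       noise = reads_subset(reads, reads$reads$read_id[noisy]))
}

#' Estimate the global bisulfite conversion rate from the spike-in
#'
#' Every cytosine of the unmethylated spike-in transcript should read as T
#' after bisulfite treatment, so the fraction converted across spike-in
#' reads estimates the global conversion rate. Spike-in reads failing the
#' 3-unconverted-C rule are excluded first (idempotently, so the function
#' accepts either a raw or an already filtered read set): such reads come
#' from globally failed conversions, which the pipeline discards as noise
#' everywhere, and averaging them into the calibration would misstate the
#' failure rate that the site-calling null model actually faces. For a
#' genuinely converted library the exclusion is essentially never triggered
#' (upper-tail probability about 1e-9 per read at the default rate), so the
#' estimator remains an unbiased binomial proportion. The 95% interval is
#' Clopper-Pearson.
#'
#' @param reads an `m5c_reads` object containing spike-in reads (flagged in
#'   `reads$reads$is_spike_in`).
#' @param max_unconverted the 3C-rule boundary (default 3).
#' @return object of class `conversion_estimate`: list with `r`,
#'   `n_total_c`, `n_converted_c` and `ci95`.
#' @export
estimate_conversion_rate <- function(reads, max_unconverted = 3L) {
  stopifnot(inherits(reads, "m5c_reads"))
  sp <- reads$reads[reads$reads$is_spike_in &
                      reads$reads$n_unconverted <= max_unconverted, ]
  n_total <- sum(sp$n_c)
  if (nrow(sp) == 0L || n_total == 0L)
    stopf(paste0("no spike-in cytosines observed: the unmethylated spike-in ",
                 "control is required to estimate the conversion rate"))
  n_conv <- n_total - sum(sp$n_unconverted)
  ci <- stats::binom.test(n_conv, n_total)$conf.int
  structure(list(r = n_conv / n_total,
                 n_total_c = n_total, n_converted_c = n_conv,
                 ci95 = as.numeric(ci)),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf("Bisulfite conversion rate: %.4f%% (%d / %d spike-in Cs; 95%% CI %.4f%%-%.4f%%)\n",
              100 * x$r, x$n_converted_c, x$n_total_c,
              100 * x$ci95[1], 100 * x$ci95[2]))
  invisible(x)
}

#' Build per-cytosine pileups with signal-to-noise ratios
#'
#' Aggregates conversion evidence per covered cytosine. For each site,
#' `total_cov` counts all reads covering the cytosine (clean and
#' 3C-failed), `clean_cov` counts only clean reads, `meth_count` is the
#' number of unconverted observations among clean reads, `level` is
#' `meth_count / clean_cov`, and `sn_ratio = clean_cov / total_cov` (the
#' fraction of coverage contributed by well-converted reads).
#'
#' @param clean_reads `m5c_reads` of reads passing [three_c_filter()].
#' @param all_reads `m5c_reads` of all reads (clean + noise).
#' @param annotation transcript annotation data.frame (with
#'   `transcript_id`, `strand`).
#' @return a `data.table` of class `m5c_pileup` with columns
#'   `transcript_id`, `pos` (1-based), `strand`, `total_cov`, `clean_cov`,
#'   `meth_count`, `level`, `sn_ratio`.
#' @export
build_pileups <- function(clean_reads, all_reads, annotation) {
  stopifnot(inherits(clean_reads, "m5c_reads"),
            inherits(all_reads, "m5c_reads"))
  unknown <- setdiff(unique(all_reads$reads$transcript_id),
                     annotation$transcript_id)
  if (length(unknown))
    stopf("reads reference unknown transcript(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  empty <- data.table::data.table(
    transcript_id = character(), pos = integer(), strand = character(),
    total_cov = integer(), clean_cov = integer(), meth_count = integer(),
    level = numeric(), sn_ratio = numeric())
  if (nrow(all_reads$calls) == 0L) {
    data.table::setattr(empty, "class", c("m5c_pileup", class(empty)))
    return(empty)
  }
  total <- all_reads$calls[, .(total_cov = .N), by = .(transcript_id, pos)]
  cln <- clean_reads$calls[, .(clean_cov = .N,
                               meth_count = sum(unconverted)),
                           by = .(transcript_id, pos)]
  pile <- merge(total, cln, by = c("transcript_id", "pos"), all.x = TRUE)
  pile[is.na(clean_cov), `:=`(clean_cov = 0L, meth_count = 0L)]
  pile[, level := ifelse(clean_cov > 0, meth_count / clean_cov, NA_real_)]
  pile[, sn_ratio := clean_cov / total_cov]
  pile[, strand := annotation$strand[match(transcript_id,
                                           annotation$transcript_id)]]
  data.table::setcolorder(pile, names(empty))
  data.table::setorder(pile, transcript_id, pos)
  class(pile) <- c("m5c_pileup", "data.table", "data.frame")
  pile[]
}
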