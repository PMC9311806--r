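#' Simulate one RNA BS-seq library in transcript space
#'
#' Draws reads uniformly along each transcript at the configured mean depth
#' and emits, for every cytosine covered by a read, a binary conversion
#' state. An unmethylated cytosine is left unconverted with probability
#' `1 - conversion_rate`; a planted m5C site is left unconverted with
#' probability equal to its planted level at the requested time point.
#' Within planted hairpin (conversion-resistant) regions the conversion
#' probability is multiplied by 0.1, mimicking structure-protected cytosines.
#' A configured fraction of reads models bisulfite failure: each of their
#' cytosines is unconverted with probability 0.5, which makes most of them
#' violate the 3-unconverted-C rule. Spike-in reads are drawn from the
#' unmethylated spike-in transcript so that they make up
#' `spike_in_fraction` of the library.
#'
#' Reads are alignment-free: coordinates are transcript positions (1-based),
#' since all downstream filters operate on aligned conversion evidence.
#'
#' @param transcriptome a [generate_transcriptome()] result.
#' @param truth a [plant_truth()] result.
#' @param config the matching [sim_config()].
#' @param timepoint time-point index (1-based).
#' @param replicate replicate index (1-based).
#' @return an object of class `m5c_reads`: list with `reads` (one row per
#'   read: `read_id`, `transcript_id`, `start`, `end`, `n_c`,
#'   `n_unconverted`, `is_spike_in`) and `calls` (one row per covered
#'   cytosine: `read_id`, `transcript_id`, `pos`, `unconverted`).
#' @export
simulate_reads <- function(transcriptome, truth, config,
                           timepoint = 1L, replicate = 1L) {
  stopifnot(inherits(transcriptome, "m5c_transcriptome"),
            inherits(truth, "m5c_truth"),
            inherits(config, "sim_config"))
  check_prob(config$conversion_rate, "conversion_rate")
  check_count(timepoint, "timepoint")
  check_count(replicate, "replicate")
  if (timepoint > config$n_timepoints)
    stopf("timepoint %d exceeds configured n_timepoints = %d",
          timepoint, config$n_timepoints)
  set.seed(derive_seed(config$seed, 3L, timepoint, replicate))

  ann <- transcriptome$annotation
  rl <- config$read_length
  r <- config$conversion_rate
  f <- config$spike_in_fraction
  lvl_col <- paste0("level_t", timepoint)

  # expected read counts: uniform depth over non-spike transcripts, spike-in
  # reads at the configured fraction of the library
  lambda <- config$depth * ann$length / rl
  lambda[ann$is_spike_in] <- 0
  n_reads <- stats::rpois(nrow(ann), lambda)
  n_spike <- stats::rpois(1, sum(lambda) * f / (1 - f))
  n_reads[ann$is_spike_in] <- n_spike

  hp <- transcriptome$hairpins
  sites <- truth$sites

  reads_acc <- vector("list", nrow(ann))
  calls_acc <- vector("list", nrow(ann))
  idx0 <- 0L
  for (i in seq_len(nrow(ann))) {
    nr <- n_reads[i]
    if (nr == 0L) next
    id <- ann$transcript_id[i]
    len <- ann$length[i]
    cpos <- cytosine_positions(transcriptome$seq[[id]])

    starts <- if (len <= rl) rep(1L, nr)
              else sample.int(len - rl + 1L, nr, replace = TRUE)
    ends <- pmin(starts + rl - 1L, len)

    # per-position unconversion probability for this transcript/time point
    p_unc <- rep(1 - r, len)
    ts <- sites[sites$transcript_id == id, ]
    if (nrow(ts)) p_unc[ts$pos] <- ts[[lvl_col]]
    if (!ann$is_spike_in[i]) {
      th <- hp[hp$transcript_id == id, ]
      if (nrow(th)) {
        rng <- th$start[1]:th$end[1]
        p_unc[rng] <- 1 - 0.1 * (1 - p_unc[rng])
      }
    }

    lo <- findInterval(starts - 1L, cpos) + 1L
    hi <- findInterval(ends, cpos)
    n_c <- pmax(hi - lo + 1L, 0L)
    has <- n_c > 0L
    rid <- sprintf("t%dr%d_%07d", timepoint, replicate, idx0 + seq_len(nr))
    idx0 <- idx0 + nr

    incomplete <- stats::runif(nr) < config$incomplete_read_fraction

    if (any(has)) {
      cidx <- sequence(n_c[has], from = lo[has])
      pos <- cpos[cidx]
      ridx <- rep(which(has), n_c[has])
      pv <- p_unc[pos]
      pv[incomplete[ridx]] <- 0.5
      unconv <- stats::rbinom(length(pos), 1L, pv) == 1L
      calls_acc[[i]] <- data.table::data.table(
        read_id = rid[ridx], transcript_id = id, pos = pos,
        unconverted = unconv)
      n_unc <- integer(nr)
      agg <- rowsum(as.integer(unconv), ridx)
      n_unc[as.integer(rownames(agg))] <- agg[, 1]
    } else {
      n_unc <- integer(nr)
    }

    reads_acc[[i]] <- data.table::data.table(
      read_id = rid, transcript_id = id, start = starts, end = ends,
      n_c = n_c, n_unconverted = n_unc,
      is_spike_in = ann$is_spike_in[i])
  }

  reads <- data.table::rbindlist(reads_acc)
  calls <- data.table::rbindlist(calls_acc)
  structure(list(reads = reads, calls = calls,
                 library = list(timepoint = timepoint, replicate = replicate)),
            class = "m5c_reads")
}

#' @export
print.m5c_reads <- function(x, ...) {
  cat(sprintf("RNA BS-seq read set: %d reads (%.2f%% spike-in), %d cytosine calls\n",
              nrow(x$reads), 100 * mean(x$reads$is_spike_in), nrow(x$calls)))
  if (!is.null(x$library$timepoint))
    cat(sprintf("  library: time point %s, replicate %s\n",
                x$library$timepoint, x$library$replicate))
  invisible(x)
}

# subset an m5c_reads object by read id (internal)
reads_subset <- function(x, ids) {
  structure(list(
    reads = x$reads[x$reads$read_id %chin% ids, ],
    calls = x$calls[x$calls$read_id %chin% ids, ],
    library = x$library), class = "m5c_reads")
}

#' Simulate the gene-level expression count matrix
#'
#' Draws overdispersed (negative binomial) counts for every gene across the
#' configured time points and replicates. Expected counts are the gene's
#' baseline mean times its archetype multiplier at each time point times a
#' per-library size factor (log-normal, sd 0.15). Early-archetype genes peak
#' at 2 h and fall back by 6 h; late genes rise through 6 h; null genes are
#' flat; genes coupled to a differential methylation site get the correlated
#' multipliers planted by [plant_truth()].
#'
#' @param truth a [plant_truth()] result.
#' @param config the matching [sim_config()].
#' @return integer matrix, genes x (time points x replicates), with a
#'   `design` attribute (data.frame of sample, timepoint, replicate).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "m5c_truth"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 4L))
  genes <- truth$genes
  tp <- config$n_timepoints
  nr <- config$n_replicates
  nlib <- tp * nr
  sf <- exp(stats::rnorm(nlib, 0, 0.15))
  hours <- truth$timepoints

  mult <- as.matrix(genes[, paste0("mult_t", seq_len(tp)), with = FALSE])
  mat <- matrix(0L, nrow(genes), nlib)
  design <- data.frame(sample = character(nlib), timepoint = numeric(nlib),
                       replicate = integer(nlib))
  k <- 0L
  for (t in seq_len(tp)) {
    for (rep_i in seq_len(nr)) {
      k <- k + 1L
      mu <- genes$base_mean * mult[, t] * sf[k]
      mat[, k] <- stats::rnbinom(nrow(genes), size = 1 / config$nb_dispersion,
                                 mu = mu)
      design$sample[k] <- sprintf("t%g_rep%d", hours[t], rep_i)
      design$timepoint[k] <- hours[t]
      design$replicate[k] <- rep_i
    }
  }
  dimnames(mat) <- list(genes$gene_id, design$sample)
  attr(mat, "design") <- design
  mat
}
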