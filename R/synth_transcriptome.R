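#' Generate a synthetic transcriptome with segment annotation
#'
#' Builds `n_transcripts` random mRNA-like transcripts, each with a 5'UTR,
#' CDS and 3'UTR whose mean lengths follow the configured 5:22:18 ratio, plus
#' one unmethylatable spike-in transcript used for conversion-rate
#' calibration. A configurable fraction of transcripts receives one planted
#' hairpin (a perfect inverted repeat) whose interval is recorded; these act
#' as conversion-resistant regions downstream.
#'
#' Sequences are uniform random over A/C/G/T (transcripts are represented in
#' DNA alphabet; structure prediction accepts T or U). Output is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `m5c_transcriptome`: a list with `seq` (named
#'   character vector), `annotation` (data.frame with `transcript_id`,
#'   `gene_id`, `strand`, `length`, `utr5_end`, `cds_end`, `is_spike_in`;
#'   1-based closed segment boundaries) and `hairpins` (data.frame of planted
#'   hairpin intervals).
#' @export
#' @examples
#' tx <- generate_transcriptome(sim_config(n_transcripts = 5, seed = 1))
#' tx$annotation
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_transcripts

  rlen <- function(mean_len, min_len) {
    # gamma draw with CV 0.2 keeps lengths positive and realistically spread
    pmax(min_len, round(stats::rgamma(n, shape = 25, scale = mean_len / 25)))
  }
  u5 <- rlen(config$utr5_len, 20L)
  cds <- rlen(config$cds_len, 60L)
  u3 <- rlen(config$utr3_len, 20L)
  len <- as.integer(u5 + cds + u3)

  rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                       replace = TRUE), collapse = "")
  seqs <- vapply(len, rand_seq, character(1))
  ids <- sprintf("tx%04d", seq_len(n))
  genes <- sprintf("gene%04d", seq_len(n))

  # plant one hairpin (perfect inverted repeat) in the CDS of a random subset
  n_hp <- floor(config$resistant_fraction * n)
  hp_tx <- if (n_hp > 0) sort(sample.int(n, n_hp)) else integer()
  hp_len <- 2L * config$hairpin_stem + config$hairpin_loop
  hp_start <- integer(0); hp_end <- integer(0); hp_id <- character(0)
  for (i in hp_tx) {
    lo <- u5[i] + 1L
    hi <- u5[i] + cds[i] - hp_len
    if (hi <= lo) next
    s0 <- sample(lo:hi, 1L)
    stem <- paste(sample(c("A", "C", "G", "T"), config$hairpin_stem,
                         replace = TRUE), collapse = "")
    loop <- paste(sample(c("A", "C", "G", "T"), config$hairpin_loop,
                         replace = TRUE), collapse = "")
    hp <- paste0(stem, loop, revcomp(stem))
    substr(seqs[i], s0, s0 + hp_len - 1L) <- hp
    hp_id <- c(hp_id, ids[i])
    hp_start <- c(hp_start, s0)
    hp_end <- c(hp_end, s0 + hp_len - 1L)
  }

  spike_seq <- rand_seq(config$spike_in_length)
  seqs <- c(seqs, spike_seq)
  names(seqs) <- c(ids, "spikein")

  annotation <- data.frame(
    transcript_id = c(ids, "spikein"),
    gene_id = c(genes, "spikein"),
    strand = "+",
    length = c(len, config$spike_in_length),
    utr5_end = c(as.integer(u5), 0L),
    cds_end = c(as.integer(u5 + cds), 0L),
    is_spike_in = c(rep(FALSE, n), TRUE),
    stringsAsFactors = FALSE
  )

  structure(list(
    seq = seqs,
    annotation = annotation,
    hairpins = data.frame(transcript_id = hp_id, start = hp_start,
                          end = hp_end, stringsAsFactors = FALSE)
  ), class = "m5c_transcriptome")
}

#' @export
print.m5c_transcriptome <- function(x, ...) {
  n <- nrow(x$annotation)
  cat(sprintf("Synthetic transcriptome: %d transcripts (%d spike-in), %d planted hairpins\n",
              n, sum(x$annotation$is_spike_in), nrow(x$hairpins)))
  cat(sprintf("  total length %.0f nt, mean %.0f nt\n",
              sum(x$annotation$length), mean(x$annotation$length)))
  invisible(x)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", s), "")[[1]]), collapse = "")
}

# cytosine positions (1-based) of a sequence string
cytosine_positions <- function(s) {
  which(strsplit(s, "")[[1]] == "C")
}

dms_level_pattern <- function(archetype, base, delta) {
  lv <- switch(archetype,
    up_down   = c(base, base + delta, base),
    up_stay   = c(base, base + delta, base + delta),
    down_up   = c(base + delta, base, base + delta),
    up_up     = c(base, base + delta / 2, base + delta),
    down_down = c(base + delta, base + delta / 2, base),
    stop("unknown archetype: ", archetype)
  )
  pmin(pmax(lv, 0.02), 0.95)
}

deg_mult_pattern <- function(archetype) {
  switch(archetype,
    down    = c(1, 1 / 3, 1 / 6),
    early   = c(1, 4, 1),
    down_up = c(1, 1 / 4, 2.5),
    late    = c(1, 1.5, 4),
    null    = c(1, 1, 1),
    stop("unknown archetype: ", archetype)
  )
}

#' Plant ground-truth methylation sites and gene expression archetypes
#'
#' Selects cytosines on each non-spike-in transcript as planted m5C sites.
#' Stable sites keep one Beta-distributed methylation level across all time
#' points (Beta(2, 7) by default, median about 0.2). A fraction of
#' transcripts carries one differentially methylated site following one of
#' five temporal archetypes (up-then-down, up-and-stay, down-then-up,
#' monotone up, monotone down). The spike-in transcript never receives a
#' site. Gene expression archetypes (monotone down, early, down-then-up,
#' late) are assigned to a fraction of the remaining genes; genes carrying a
#' differential site instead receive expression shifts whose log2 fold
#' changes correlate with the planted methylation change at strength
#' `coupling_rho` (negative by default).
#'
#' Sites are never planted inside planted hairpin regions, so hairpin
#' cytosines that survive calling are false positives by construction.
#'
#' @param transcriptome a [generate_transcriptome()] result.
#' @param config the same [sim_config()] used to build it.
#' @return an object of class `m5c_truth`: list with `sites` (data.table of
#'   planted sites and per-time-point levels), `genes` (data.table of
#'   expression archetypes, baseline means and per-time-point multipliers),
#'   `resistant_regions`, `coupling_rho` and `timepoints` (hours).
#' @export
plant_truth <- function(transcriptome, config) {
  stopifnot(inherits(transcriptome, "m5c_transcriptome"),
            inherits(config, "sim_config"))
  if (sum(config$dms_archetype_weights) <= 0)
    stopf("all DMS archetype weights are zero")
  set.seed(derive_seed(config$seed, 2L))

  ann <- transcriptome$annotation
  tx <- ann$transcript_id[!ann$is_spike_in]
  n <- length(tx)
  tp <- config$n_timepoints
  hours <- if (tp == 3L) c(0, 2, 6) else seq(0, by = 2, length.out = tp)

  hp <- transcriptome$hairpins
  arch_names <- c("up_down", "up_stay", "down_up", "up_up", "down_down")

  n_dms <- floor(config$dms_fraction * n)
  dms_tx <- if (n_dms > 0) sort(sample.int(n, n_dms)) else integer()

  site_list <- vector("list", n)
  for (i in seq_len(n)) {
    id <- tx[i]
    cpos <- cytosine_positions(transcriptome$seq[[id]])
    # keep planted truth outside hairpins: in-hairpin non-conversion is the
    # false-positive class the structure filter exists to remove
    in_hp <- hp$transcript_id == id
    if (any(in_hp))
      cpos <- cpos[cpos < hp$start[in_hp][1] | cpos > hp$end[in_hp][1]]
    if (length(cpos) == 0L) next
    n_stable <- stats::rpois(1, config$sites_per_transcript)
    want_dms <- i %in% dms_tx
    n_pick <- min(length(cpos), n_stable + as.integer(want_dms))
    if (n_pick == 0L) next
    pick <- sort(sample(cpos, n_pick))
    type <- rep("stable", n_pick)
    if (want_dms && n_pick > 0L) type[sample.int(n_pick, 1L)] <- "dms"
    site_list[[i]] <- data.table::data.table(
      transcript_id = id,
      gene_id = ann$gene_id[match(id, ann$transcript_id)],
      pos = pick, type = type)
  }
  sites <- data.table::rbindlist(site_list)
  if (nrow(sites) == 0L)
    sites <- data.table::data.table(transcript_id = character(),
                                    gene_id = character(), pos = integer(),
                                    type = character())

  # per-site levels
  lv <- matrix(NA_real_, nrow(sites), tp)
  base <- pmin(pmax(stats::rbeta(nrow(sites), config$level_shape1,
                                 config$level_shape2), 0.02), 0.95)
  stable_rows <- which(sites$type == "stable")
  lv[stable_rows, ] <- base[stable_rows]
  dms_rows <- which(sites$type == "dms")
  archetype <- rep(NA_character_, nrow(sites))
  if (length(dms_rows)) {
    archetype[dms_rows] <- sample(arch_names, length(dms_rows), replace = TRUE,
                                  prob = config$dms_archetype_weights)
    for (j in dms_rows) {
      b <- min(base[j], 0.6)   # headroom for +delta patterns
      pat <- dms_level_pattern(archetype[j], b, config$dms_delta)
      lv[j, ] <- if (tp == 3L) pat else rep(pat[1], tp)
    }
  }
  sites[, paste0("level_t", seq_len(tp)) := as.data.table(lv)]
  sites$archetype <- archetype

  # gene table: expression archetypes and multipliers
  genes <- data.table::data.table(
    gene_id = ann$gene_id[!ann$is_spike_in],
    transcript_id = tx)
  genes$base_mean <- stats::rlnorm(n, log(config$mean_counts),
                                   config$counts_sdlog)
  genes$archetype <- "null"
  dms_genes <- unique(sites$gene_id[sites$type == "dms"])
  non_dms <- setdiff(genes$gene_id, dms_genes)
  n_deg <- floor(config$deg_fraction * length(non_dms))
  deg_pick <- if (n_deg > 0) sample(non_dms, n_deg) else character()
  deg_arch <- c("down", "early", "down_up", "late")
  genes$archetype[genes$gene_id %in% deg_pick] <-
    sample(deg_arch, length(deg_pick), replace = TRUE,
           prob = config$deg_archetype_weights)
  genes$archetype[genes$gene_id %in% dms_genes] <- "coupled"

  mult <- t(vapply(genes$archetype,
                   function(a) if (a == "coupled") c(1, 1, 1)
                               else deg_mult_pattern(a),
                   numeric(3)))
  if (tp != 3L) mult <- matrix(1, n, tp)

  # coupled genes: expression log2 shifts correlated with planted delta-m
  if (length(dms_genes) && tp == 3L) {
    dsub <- sites[sites$type == "dms" & sites$gene_id %in% dms_genes, ]
    dsub <- dsub[!duplicated(dsub$gene_id), ]
    rho <- config$coupling_rho
    zs <- function(x) if (length(x) > 1L && stats::sd(x) > 0)
      (x - mean(x)) / stats::sd(x) else rep(0, length(x))
    for (col in c(2L, 3L)) {
      dm <- dsub[[paste0("level_t", col)]] - dsub$level_t1
      e <- (rho * zs(dm) + sqrt(1 - rho^2) * stats::rnorm(nrow(dsub))) *
        config$coupling_sd
      idx <- match(dsub$gene_id, genes$gene_id)
      mult[idx, col] <- 2^e
    }
  }
  colnames(mult) <- paste0("mult_t", seq_len(tp))
  genes <- cbind(genes, data.table::as.data.table(mult))

  structure(list(
    sites = sites,
    genes = genes,
    resistant_regions = transcriptome$hairpins,
    coupling_rho = config$coupling_rho,
    timepoints = hours
  ), class = "m5c_truth")
}

#' @export
print.m5c_truth <- function(x, ...) {
  cat(sprintf("Planted ground truth: %d m5C sites (%d differential) on %d genes\n",
              nrow(x$sites), sum(x$sites$type == "dms"),
              length(unique(x$sites$gene_id))))
  cat(sprintf("  %d resistant regions; methylation-expression coupling rho = %g\n",
              nrow(x$resistant_regions), x$coupling_rho))
  invisible(x)
}
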