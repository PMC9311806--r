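#' Run the full synthetic m5C analysis pipeline
#'
#' Orchestrates every stage end to end on simulated data: transcriptome and
#' ground-truth generation, per-library read simulation, 3C filtering,
#' spike-in conversion-rate estimation, pileups, binomial site calling with
#' the filter cascade, the secondary-structure filter, replicate
#' intersection, the three-way site overlap, expression simulation,
#' differential expression with early/late response-gene classification,
#' pair-wise differential methylation, and the integration analytics
#' (metagene profile, sequence-context matrix, Z-score clustering,
#' methylation-expression correlation and its sign categories). All stage
#' outputs are written to `outdir` as plain-text tables together with a
#' JSON manifest recording package version, seed, thresholds, per-stage
#' record counts and per-file row counts and checksums. Identical config
#' and seed give identical outputs.
#'
#' If a stage fails, the run aborts with the failing stage named and a
#' `.partial` marker file is left in `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param thresholds site [filter_thresholds()].
#' @param dm_alpha DMS adjusted-p threshold (inclusive; default 0.05).
#' @param deg_alpha,deg_min_fc DEG thresholds (see [call_degs()]).
#' @param dm_min_cov per-replicate coverage floor for DMS eligibility.
#' @param max_span,min_helix,min_paired_frac structure-filter constants.
#' @param fold_method `"internal"` or `"rnafold"` (external hook).
#' @param k_deg,k_dms cluster counts for the expression and methylation
#'   profile clustering.
#' @param write_reads also write the (large) per-read TSVs.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         thresholds = filter_thresholds(),
                         dm_alpha = 0.05, deg_alpha = 0.05, deg_min_fc = 2,
                         dm_min_cov = 10L,
                         max_span = 150L, min_helix = 6L,
                         min_paired_frac = 0.8,
                         fold_method = c("internal", "rnafold"),
                         k_deg = 4L, k_dms = 5L,
                         write_reads = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  fold_method <- match.arg(fold_method)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(outdir, ".partial")
  file.create(partial)
  stage <- "setup"
  counts_log <- list()
  files <- character(0)
  put <- function(obj, name, writer = write_sites_tsv) {
    path <- file.path(outdir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }

  res <- tryCatch({
    stage <- "simulate_transcriptome"
    msg("generating transcriptome and ground truth", quiet = quiet)
    tx <- generate_transcriptome(config)
    truth <- plant_truth(tx, config)
    put(tx$seq, "transcriptome.fa", write_fasta)
    put(tx$annotation, "annotation.tsv", write_annotation_tsv)
    put(truth$sites, "truth_sites.tsv")
    put(truth$genes, "truth_genes.tsv",
        function(o, p) data.table::fwrite(o, p, sep = "\t"))
    counts_log$transcripts <- nrow(tx$annotation)
    counts_log$planted_sites <- nrow(truth$sites)

    stage <- "structure_prediction"
    msg("predicting conversion-resistant regions", quiet = quiet)
    ann <- tx$annotation
    seqs_fold <- tx$seq[!ann$is_spike_in[match(names(tx$seq),
                                               ann$transcript_id)]]
    regions <- predict_resistant_regions_all(
      seqs_fold, max_span = max_span, min_helix = min_helix,
      min_paired_frac = min_paired_frac, method = fold_method)
    put(regions, "resistant_regions.tsv",
        function(o, p) data.table::fwrite(o, p, sep = "\t"))
    counts_log$resistant_regions <- nrow(regions)

    tp_n <- config$n_timepoints
    rep_n <- config$n_replicates
    hours <- truth$timepoints
    pileups <- vector("list", tp_n)
    filtered <- vector("list", tp_n)
    conv_rates <- matrix(NA_real_, tp_n, rep_n)

    for (t in seq_len(tp_n)) {
      pileups[[t]] <- vector("list", rep_n)
      filtered[[t]] <- vector("list", rep_n)
      for (rep_i in seq_len(rep_n)) {
        lib <- sprintf("t%g_rep%d", hours[t], rep_i)
        stage <- paste0("reads_", lib)
        msg("simulating library ", lib, quiet = quiet)
        rd <- simulate_reads(tx, truth, config, timepoint = t,
                             replicate = rep_i)
        if (write_reads)
          put(rd, paste0("reads_", lib, ".tsv"), write_reads_tsv)

        stage <- paste0("conversion_rate_", lib)
        conv <- estimate_conversion_rate(rd)
        conv_rates[t, rep_i] <- conv$r

        stage <- paste0("pileup_", lib)
        f3 <- three_c_filter(rd)
        pile <- build_pileups(f3$clean, rd, tx$annotation)
        pileups[[t]][[rep_i]] <- pile
        put(pile, paste0("pileup_", lib, ".tsv"))

        stage <- paste0("calling_", lib)
        st <- call_site_pvalues(pile, conv)
        st <- apply_site_filters(st, thresholds)
        st <- remove_structural_sites(st, regions, quiet = quiet)
        filtered[[t]][[rep_i]] <- st
        put(st, paste0("sites_", lib, ".tsv"))
      }
    }
    counts_log$conversion_rates <- as.numeric(t(conv_rates))

    stage <- "replicate_intersection"
    hc <- vector("list", tp_n)
    for (t in seq_len(tp_n)) {
      passing <- lapply(filtered[[t]], function(s) s[s$pass == TRUE, ])
      hc[[t]] <- Reduce(merge_replicates, passing)
      put(hc[[t]], sprintf("highconf_t%g.tsv", hours[t]))
    }
    names(hc) <- sprintf("t%g", hours)
    counts_log$high_confidence <- vapply(hc, nrow, integer(1))

    union_sites <- unique(data.table::rbindlist(
      lapply(hc, function(s) s[, .(transcript_id, pos, strand, level)])),
      by = c("transcript_id", "pos"))
    put(union_sites, "sites_union.bed", export_sites_bed)
    counts_log$union_sites <- nrow(union_sites)

    venn <- NULL
    if (tp_n == 3L) {
      stage <- "condition_overlap"
      venn <- condition_overlap(hc)
      put(data.frame(part = names(venn), count = as.integer(venn)),
          "venn_parts.tsv",
          function(o, p) data.table::fwrite(o, p, sep = "\t"))
    }

    stage <- "simulate_counts"
    msg("simulating expression counts", quiet = quiet)
    cnt <- simulate_counts(truth, config)
    put(cnt, "counts.tsv", write_counts_tsv)
    design <- attr(cnt, "design")

    stage <- "differential_expression"
    pairs <- utils::combn(tp_n, 2, simplify = FALSE)
    de <- list()
    for (pr in pairs) {
      nm <- sprintf("%gv%g", hours[pr[1]], hours[pr[2]])
      a <- cnt[, design$timepoint == hours[pr[1]], drop = FALSE]
      b <- cnt[, design$timepoint == hours[pr[2]], drop = FALSE]
      de[[nm]] <- call_degs(de_test(a, b, quiet = quiet),
                            alpha = deg_alpha, min_fc = deg_min_fc)
      put(de[[nm]], paste0("de_", nm, ".tsv"),
          function(o, p) data.table::fwrite(o, p, sep = "\t"))
    }
    counts_log$degs <- vapply(de, function(x) sum(x$direction != "ns"),
                              integer(1))

    early_late <- NULL
    if (tp_n == 3L) {
      stage <- "early_late"
      early_late <- classify_early_late(de[[1]], de[[2]], de[[3]])
      el <- data.frame(
        gene_id = c(early_late$early, early_late$late),
        class = rep(c("early", "late"),
                    c(length(early_late$early), length(early_late$late))))
      put(el, "early_late.tsv",
          function(o, p) data.table::fwrite(o, p, sep = "\t"))
      counts_log$early <- length(early_late$early)
      counts_log$late <- length(early_late$late)
    }

    stage <- "differential_methylation"
    gene_map <- tx$annotation[, c("transcript_id", "gene_id")]
    dms <- list()
    for (pr in pairs) {
      nm <- sprintf("%gv%g", hours[pr[1]], hours[pr[2]])
      elig <- select_eligible_sites(pileups[[pr[1]]], pileups[[pr[2]]],
                                    hc[[pr[1]]], hc[[pr[2]]],
                                    min_cov = dm_min_cov)
      rec <- dm_records(elig, pileups[[pr[1]]], pileups[[pr[2]]])
      dms[[nm]] <- classify_dms(rec, alpha = dm_alpha, quiet = quiet)
      put(dms[[nm]], paste0("dms_", nm, ".tsv"))
    }
    counts_log$dms <- vapply(dms, function(x) sum(x$direction != "ns"),
                             integer(1))

    stage <- "integration"
    msg("integration analytics", quiet = quiet)
    meta <- metagene_profile(union_sites, tx$annotation)
    put(data.frame(bin = 1:45, count = meta$counts, percent = meta$percent,
                   smoothed = meta$smoothed), "metagene.tsv",
        function(o, p) data.table::fwrite(o, p, sep = "\t"))
    pfm <- motif_pfm(union_sites, tx$seq)
    put(data.frame(base = rownames(pfm$counts), pfm$counts,
                   check.names = FALSE), "motif_pfm.tsv",
        function(o, p) data.table::fwrite(o, p, sep = "\t"))

    clusters <- list()
    if (tp_n == 3L) {
      deg_genes <- unique(unlist(lapply(de, function(x)
        x$gene_id[x$direction != "ns"])))
      if (length(deg_genes) >= k_deg) {
        prof <- log2(t(vapply(deg_genes, function(g) {
          vapply(seq_len(tp_n), function(t)
            mean(cnt[g, design$timepoint == hours[t]]), numeric(1))
        }, numeric(tp_n))) + 0.5)
        ok <- apply(prof, 1, stats::sd) > 0
        if (sum(ok) >= k_deg)
          clusters$deg <- zscore_cluster(prof[ok, , drop = FALSE], k_deg,
                                         seed = derive_seed(config$seed, 8L))
      }
      dms_keys <- unique(data.table::rbindlist(lapply(dms, function(x)
        x[direction != "ns", .(transcript_id, pos)])))
      if (nrow(dms_keys) >= k_dms) {
        lvl <- vapply(seq_len(tp_n), function(t) {
          pool <- data.table::rbindlist(pileups[[t]])[
            , .(C = sum(clean_cov), M = sum(meth_count)),
            by = .(transcript_id, pos)]
          i <- match(paste(dms_keys$transcript_id, dms_keys$pos),
                     paste(pool$transcript_id, pool$pos))
          (pool$M / pool$C)[i]
        }, numeric(nrow(dms_keys)))
        if (nrow(dms_keys) == 1L) lvl <- matrix(lvl, nrow = 1L)
        rownames(lvl) <- paste0(dms_keys$transcript_id, ":", dms_keys$pos)
        ok <- !apply(lvl, 1, anyNA) & apply(lvl, 1, stats::sd) > 0
        if (sum(ok, na.rm = TRUE) >= k_dms)
          clusters$dms <- zscore_cluster(lvl[which(ok), , drop = FALSE],
                                         k_dms,
                                         seed = derive_seed(config$seed, 9L))
      }
      for (nm in names(clusters))
        put(data.frame(id = names(clusters[[nm]]$labels),
                       cluster = as.integer(clusters[[nm]]$labels)),
            paste0("clusters_", nm, ".tsv"),
            function(o, p) data.table::fwrite(o, p, sep = "\t"))
    }

    correlations <- list()
    categories <- list()
    for (nm in names(dms)) {
      sig <- dms[[nm]][dms[[nm]]$direction != "ns", ]
      if (nrow(sig) >= 3L) {
        correlations[[nm]] <- correlate_meth_expr(sig, de[[nm]],
                                                  gene_map = gene_map)
        categories[[nm]] <- categorize_correlation(sig, de[[nm]],
                                                   gene_map = gene_map)
      } else {
        msg("too few DMS for correlation in ", nm, quiet = quiet)
      }
    }
    if (length(correlations)) {
      cor_tab <- data.frame(
        comparison = names(correlations),
        n = vapply(correlations, `[[`, numeric(1), "n"),
        r = vapply(correlations, `[[`, numeric(1), "r"),
        p = vapply(correlations, `[[`, numeric(1), "p"))
      put(cor_tab, "meth_expr_correlation.tsv",
          function(o, p) data.table::fwrite(o, p, sep = "\t"))
    }

    stage <- "manifest"
    manifest <- list(
      package = "m5cpipe",
      version = as.character(utils::packageVersion("m5cpipe")),
      seed = config$seed,
      thresholds = unclass(thresholds),
      dm_alpha = dm_alpha, deg_alpha = deg_alpha, deg_min_fc = deg_min_fc,
      structure = list(max_span = max_span, min_helix = min_helix,
                       min_paired_frac = min_paired_frac,
                       method = fold_method),
      counts = counts_log,
      files = data.frame(
        file = basename(files),
        rows = vapply(files, function(f)
          if (grepl("\\.fa$", f)) NA_integer_
          else length(readLines(f)) - !grepl("\\.bed$", f), integer(1)),
        md5 = unname(tools::md5sum(files))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(transcriptome = tx, truth = truth, regions = regions,
         pileups = pileups, sites = filtered, high_confidence = hc,
         venn = venn, counts = cnt, de = de, early_late = early_late,
         dms = dms, metagene = meta, pfm = pfm, clusters = clusters,
         correlations = correlations, categories = categories,
         manifest = manifest)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  unlink(partial)
  invisible(res)
}
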