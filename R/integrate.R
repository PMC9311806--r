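#' Z-score standardize temporal profiles and cluster with k-means
#'
#' Each row (a gene's expression profile or a site's methylation profile
#' across time points) is standardized to mean 0 and sample SD 1, then
#' clustered by k-means with `nstart = 10` restarts under a fixed seed.
#' Cluster labels are relabeled by descending cluster size so the labeling
#' is deterministic.
#'
#' @param mat numeric matrix, rows = profiles, columns = time points. Every
#'   row must have nonzero variance.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @return list with `labels` (integer vector, named by rownames),
#'   `centers` (k x ncol matrix of per-cluster mean Z-score profiles) and
#'   `zscores` (the standardized matrix).
#' @export
zscore_cluster <- function(mat, k, seed = 1L) {
  mat <- as.matrix(mat)
  check_count(k, "k")
  rsd <- apply(mat, 1, stats::sd)
  if (any(rsd == 0 | is.na(rsd))) {
    bad <- which(rsd == 0 | is.na(rsd))[1]
    stopf("row %s has zero variance and cannot be Z-scored",
          rownames(mat)[bad] %||% bad)
  }
  z <- t(scale(t(mat)))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (k > nrow(z)) stopf("k = %d exceeds the number of rows (%d)", k, nrow(z))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = 10)
  ord <- order(tabulate(km$cluster, k), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  names(labels) <- rownames(mat)
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(labels = labels, centers = centers, zscores = z)
}

metagene_bins <- c(utr5 = 5L, cds = 22L, utr3 = 18L)

#' Metagene profile of m5C sites along the 5'UTR/CDS/3'UTR model
#'
#' Maps every site on an annotated mRNA into one of 45 ordered bins: 5 for
#' the 5'UTR, 22 for the CDS and 18 for the 3'UTR (mirroring the
#' transcriptome-average segment-length ratio). A site at relative position
#' `f` (in `[0, 1)`) of segment `s` falls in bin `offset(s) + floor(f *
#' bins(s)) + 1`. Per-bin percentages are over all binned sites and sum to
#' 100; the smoothed track is a window-3 moving average, truncated at the
#' edges. Sites on transcripts without mRNA segmentation (e.g. the
#' spike-in, or noncoding RNA) are excluded and counted.
#'
#' @param sites `m5c_sites` (or data.frame with `transcript_id`, `pos`).
#' @param annotation annotation data.frame with `transcript_id`, `length`,
#'   `utr5_end`, `cds_end` (1-based closed; `utr5_end = cds_end = 0` marks a
#'   transcript without mRNA segmentation).
#' @return object of class `metagene_profile`: list with `counts`,
#'   `percent`, `smoothed` (each length 45), `n_sites`, `n_excluded`.
#' @export
metagene_profile <- function(sites, annotation) {
  s <- as.data.frame(sites)
  ann <- as.data.frame(annotation)
  idx <- match(s$transcript_id, ann$transcript_id)
  if (anyNA(idx))
    stopf("site(s) on unannotated transcript: %s",
          paste(head(unique(s$transcript_id[is.na(idx)]), 3), collapse = ", "))
  len <- ann$length[idx]; u5 <- ann$utr5_end[idx]; ce <- ann$cds_end[idx]
  if (any(s$pos < 1 | s$pos > len))
    stopf("site position outside annotated transcript length")
  mrna <- u5 > 0 & ce > u5 & ce < len
  n_excluded <- sum(!mrna)
  pos <- s$pos[mrna]; u5 <- u5[mrna]; ce <- ce[mrna]; len <- len[mrna]

  seg <- ifelse(pos <= u5, 1L, ifelse(pos <= ce, 2L, 3L))
  seg_start <- cbind(1L, u5 + 1L, ce + 1L)[cbind(seq_along(pos), seg)]
  seg_len <- cbind(u5, ce - u5, len - ce)[cbind(seq_along(pos), seg)]
  f <- (pos - seg_start) / seg_len
  offset <- c(0L, 5L, 27L)[seg]
  bin <- offset + floor(f * metagene_bins[seg]) + 1L
  stopifnot(all(bin >= 1L & bin <= 45L))

  counts <- tabulate(bin, 45L)
  percent <- if (sum(counts) > 0) 100 * counts / sum(counts) else
    rep(NA_real_, 45L)
  smoothed <- vapply(seq_len(45L), function(i) {
    w <- max(1L, i - 1L):min(45L, i + 1L)
    mean(percent[w])
  }, numeric(1))
  structure(list(counts = counts, percent = percent, smoothed = smoothed,
                 n_sites = sum(counts), n_excluded = n_excluded),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("Metagene profile: %d mRNA sites binned (%d excluded)\n",
              x$n_sites, x$n_excluded))
  seg_pct <- c(utr5 = sum(x$percent[1:5]), cds = sum(x$percent[6:27]),
               utr3 = sum(x$percent[28:45]))
  cat(sprintf("  %%%s: %.1f  %%%s: %.1f  %%%s: %.1f\n",
              "5'UTR", seg_pct[1], "CDS", seg_pct[2], "3'UTR", seg_pct[3]))
  invisible(x)
}

#' Position frequency matrix of the sequence context around m5C sites
#'
#' Counts A/C/G/U at offsets -window..+window around each site (the center
#' column is all C by construction, since sites are cytosines). Windows
#' truncated at transcript edges contribute gaps, which are reported per
#' offset.
#'
#' @param sites `m5c_sites` (or data.frame with `transcript_id`, `pos`).
#' @param sequences named character vector of transcript sequences.
#' @param window half-window size in nt (default 5).
#' @return object of class `motif_pfm`: list with `counts` (4 x (2*window+1)
#'   matrix, rows A/C/G/U), `gaps` (per-offset truncation counts) and
#'   `n_sites`.
#' @export
motif_pfm <- function(sites, sequences, window = 5L) {
  s <- as.data.frame(sites)
  check_count(window, "window")
  offs <- -window:window
  counts <- matrix(0L, 4, length(offs),
                   dimnames = list(c("A", "C", "G", "U"),
                                   as.character(offs)))
  gaps <- stats::setNames(integer(length(offs)), as.character(offs))
  for (i in seq_len(nrow(s))) {
    seq_i <- sequences[[s$transcript_id[i]]]
    if (is.null(seq_i) || is.na(seq_i))
      stopf("no sequence for transcript %s", s$transcript_id[i])
    n <- nchar(seq_i)
    base_at_center <- substr(seq_i, s$pos[i], s$pos[i])
    if (!base_at_center %in% c("C", "c"))
      stopf("site %s:%d is not a cytosine", s$transcript_id[i], s$pos[i])
    for (k in seq_along(offs)) {
      p <- s$pos[i] + offs[k]
      if (p < 1 || p > n) {
        gaps[k] <- gaps[k] + 1L
      } else {
        b <- chartr("acgtuT", "ACGUUU", substr(seq_i, p, p))
        if (b %in% rownames(counts))
          counts[b, k] <- counts[b, k] + 1L
      }
    }
  }
  structure(list(counts = counts, gaps = gaps, n_sites = nrow(s)),
            class = "motif_pfm")
}

#' @export
print.motif_pfm <- function(x, ...) {
  cat(sprintf("Sequence context PFM over %d sites (offsets %s..%s)\n",
              x$n_sites, colnames(x$counts)[1],
              colnames(x$counts)[ncol(x$counts)]))
  print(x$counts)
  invisible(x)
}

#' Correlate methylation change with expression change
#'
#' Pairs each DMS-carrying site with its gene's log2 expression fold change
#' (x) and the site's methylation level difference `delta_m` (y), and
#' reports the Pearson correlation with a two-sided test. Sites whose gene
#' has no DE result are dropped and counted.
#'
#' @param records `dms_records` with `delta_m` and a `gene_id` column (or a
#'   `gene_map` can be supplied).
#' @param de `de_results` with `log2fc`.
#' @param gene_map optional data.frame (`transcript_id`, `gene_id`) used
#'   when `records` lacks `gene_id`.
#' @return object of class `meth_expr_cor`: list with `n`, `r`, `p`,
#'   `n_dropped` and the per-pair `table`.
#' @export
correlate_meth_expr <- function(records, de, gene_map = NULL) {
  rec <- data.table::as.data.table(records)
  if (is.null(rec$gene_id)) {
    if (is.null(gene_map)) stopf("records lack gene_id and no gene_map given")
    rec[, gene_id := gene_map$gene_id[match(transcript_id,
                                            gene_map$transcript_id)]]
  }
  de <- data.table::as.data.table(de)
  rec[, log2fc := de$log2fc[match(gene_id, de$gene_id)]]
  n_dropped <- sum(is.na(rec$log2fc))
  rec <- rec[!is.na(log2fc)]
  if (nrow(rec) < 3L)
    stopf("fewer than 3 DMS-gene pairs (%d); correlation undefined", nrow(rec))
  ct <- stats::cor.test(rec$log2fc, rec$delta_m)
  structure(list(n = nrow(rec), r = unname(ct$estimate), p = ct$p.value,
                 n_dropped = n_dropped,
                 table = rec[, .(transcript_id, pos, gene_id, delta_m, log2fc)]),
            class = "meth_expr_cor")
}

#' @export
print.meth_expr_cor <- function(x, ...) {
  cat(sprintf("Methylation-expression correlation: R = %.3f, p = %.3g (n = %d pairs)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Categorize DMS-gene pairs by the sign concordance of their changes
#'
#' Each DMS-carrying gene pair is assigned exactly one category: positive
#' correlation (hyper DMS with an up-regulated DEG, or hypo DMS with a
#' down-regulated DEG), negative correlation (hyper with down, or hypo with
#' up), or neutral (the gene is not a DEG). The three categories partition
#' the DMS-gene pair set.
#'
#' @param records `dms_records` with `direction` and `gene_id`.
#' @param de `de_results` with `direction` (see [call_degs()]).
#' @param gene_map optional transcript-to-gene map as in
#'   [correlate_meth_expr()].
#' @return data.table of DMS pairs with `category`; attribute `counts`
#'   holds the per-category totals.
#' @export
categorize_correlation <- function(records, de, gene_map = NULL) {
  rec <- data.table::as.data.table(records)
  if (is.null(rec$gene_id)) {
    if (is.null(gene_map)) stopf("records lack gene_id and no gene_map given")
    rec[, gene_id := gene_map$gene_id[match(transcript_id,
                                            gene_map$transcript_id)]]
  }
  rec <- rec[direction %in% c("hyper", "hypo")]
  de <- data.table::as.data.table(de)
  rec[, de_direction := de$direction[match(gene_id, de$gene_id)]]
  rec[is.na(de_direction), de_direction := "ns"]
  rec[, category := data.table::fifelse(
    de_direction == "ns", "neutral",
    data.table::fifelse((direction == "hyper") == (de_direction == "up"),
                        "positive", "negative"))]
  out <- rec[, .(transcript_id, pos, gene_id, direction, de_direction,
                 category)]
  counts <- c(positive = sum(out$category == "positive"),
              negative = sum(out$category == "negative"),
              neutral = sum(out$category == "neutral"))
  data.table::setattr(out, "counts", counts)
  out[]
}
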