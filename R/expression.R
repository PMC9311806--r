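#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio to the per-gene geometric mean, using genes expressed in every
#' sample.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) stopf("no gene is expressed in every sample")
  lg <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - ref)))
}

#' Differential expression between two conditions
#'
#' A documented substitute for a full negative-binomial analysis: counts are
#' normalized by median-of-ratios size factors, log2-transformed with a
#' pseudocount of 0.5, and tested gene-wise with an empirical-Bayes
#' moderated t-test on the normalized log counts (limma, with a
#' mean-variance trend). The reported `log2fc` is
#' `log2((mean_B + 0.5) / (mean_A + 0.5))` on normalized means, and p-values
#' are BH-adjusted over all tested genes. Genes with zero counts in every
#' sample of both conditions are excluded and logged. For real data, results
#' of an external DE tool can be supplied instead via
#' [import_de_results()].
#'
#' @param counts_a,counts_b count matrices (genes x replicates) for the two
#'   conditions, with identical row names.
#' @param quiet suppress log lines.
#' @return data.table of class `de_results`: `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `p`, `padj`.
#' @export
de_test <- function(counts_a, counts_b, quiet = FALSE) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (ncol(counts_a) < 2L || ncol(counts_b) < 2L)
    stopf("at least 2 replicates per condition are required")
  if (!identical(rownames(counts_a), rownames(counts_b)))
    stopf("count matrices must share the same genes in the same order")
  all_counts <- cbind(counts_a, counts_b)
  zero <- rowSums(all_counts) == 0
  if (any(zero)) {
    msg(sprintf("%d gene(s) with all-zero counts excluded", sum(zero)),
        quiet = quiet)
    all_counts <- all_counts[!zero, , drop = FALSE]
  }
  sf <- size_factors(all_counts)
  norm <- sweep(all_counts, 2, sf, "/")
  na <- ncol(counts_a)
  grp <- factor(rep(c("A", "B"), c(na, ncol(counts_b))), levels = c("A", "B"))
  logn <- log2(norm + 0.5)
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(logn, design), trend = TRUE)
  pv <- fit$p.value[, 2]
  mean_a <- rowMeans(norm[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(norm[, -seq_len(na), drop = FALSE])
  out <- data.table::data.table(
    gene_id = rownames(all_counts),
    mean_a = mean_a, mean_b = mean_b,
    log2fc = log2((mean_b + 0.5) / (mean_a + 0.5)),
    p = as.numeric(pv),
    padj = stats::p.adjust(pv, method = "BH"))
  class(out) <- c("de_results", "data.table", "data.frame")
  out[]
}

#' Import differential expression results from an external tool
#'
#' Accepts a tab-separated file with columns `gene_id` (or `gene`),
#' `log2fc` and `padj`, as produced by standard DE tools, so that
#' downstream DEG calling and integration can run on real-data results.
#'
#' @param path TSV path.
#' @return `de_results` data.table.
#' @export
import_de_results <- function(path) {
  x <- data.table::fread(path)
  nm <- names(x)
  if ("gene" %in% nm && !"gene_id" %in% nm)
    data.table::setnames(x, "gene", "gene_id")
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(x)))
    stopf("DE results file must provide columns: %s",
          paste(need, collapse = ", "))
  class(x) <- c("de_results", "data.table", "data.frame")
  x[]
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated when its adjusted p-value is at most `alpha` and
#' its linear fold change is strictly greater than `min_fc`; down-regulated
#' symmetrically when the fold change is strictly below `1 / min_fc`. A
#' fold change of exactly 2 is not a DEG under the default thresholds.
#'
#' @param results `de_results` table.
#' @param alpha adjusted p-value threshold, inclusive (default 0.05).
#' @param min_fc linear fold-change threshold, exclusive (default 2).
#' @return the table with a `direction` column (`up`, `down`, `ns`).
#' @export
call_degs <- function(results, alpha = 0.05, min_fc = 2) {
  res <- data.table::as.data.table(results)
  fc <- 2^res$log2fc
  res[, direction := "ns"]
  res[!is.na(padj) & padj <= alpha & fc > min_fc, direction := "up"]
  res[!is.na(padj) & padj <= alpha & fc < 1 / min_fc, direction := "down"]
  class(res) <- c("de_results", "data.table", "data.frame")
  res[]
}

#' @export
print.de_results <- function(x, ...) {
  cat(sprintf("Differential expression: %d genes", nrow(x)))
  if (!is.null(x$direction))
    cat(sprintf("; %d up, %d down",
                sum(x$direction == "up"), sum(x$direction == "down")))
  cat("\n")
  invisible(x)
}

#' Classify early and late response genes across the time course
#'
#' With comparisons 0 h vs 2 h, 0 h vs 6 h and 2 h vs 6 h (later condition
#' as numerator throughout): early response genes are up-regulated at 2 h
#' and down-regulated again between 2 h and 6 h; late response genes are
#' up-regulated at 6 h relative to 0 h and still rising between 2 h and
#' 6 h. The two sets are disjoint by construction, since a gene cannot be
#' both up and down in the 2 h vs 6 h comparison.
#'
#' @param deg_0v2,deg_0v6,deg_2v6 `de_results` with `direction` (see
#'   [call_degs()]) for the three comparisons.
#' @return list with character vectors `early` and `late`.
#' @export
classify_early_late <- function(deg_0v2, deg_0v6, deg_2v6) {
  dirs <- function(x, d) x$gene_id[x$direction == d]
  early <- intersect(dirs(deg_0v2, "up"), dirs(deg_2v6, "down"))
  late <- intersect(dirs(deg_0v6, "up"), dirs(deg_2v6, "up"))
  stopifnot(length(intersect(early, late)) == 0L)
  list(early = sort(early), late = sort(late))
}
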