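#' Binomial non-conversion test for candidate m5C sites
#'
#' Under the null hypothesis that a cytosine is unmethylated, each of its
#' `C` clean observations is unconverted with probability `1 - r`, where `r`
#' is the spike-in-estimated conversion rate. The p-value is the upper-tail
#' binomial probability of observing at least `M` unconverted cytosines.
#' `M = 0` gives p = 1. With `r = 1` any `M >= 1` is impossible under the
#' null; such sites receive the minimum representable double and a
#' `p_underflow` flag.
#'
#' Sites with zero clean coverage cannot be tested and are dropped with a
#' warning.
#'
#' @param pileups an `m5c_pileup` (see [build_pileups()]).
#' @param conv a `conversion_estimate` (see [estimate_conversion_rate()]),
#'   or a single numeric conversion rate in (0, 1].
#' @return `m5c_sites`: the pileup rows with `p` (and `p_underflow`) added.
#' @export
call_site_pvalues <- function(pileups, conv) {
  r <- if (inherits(conv, "conversion_estimate")) conv$r else conv
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1)
    stopf("conversion rate must be in (0, 1]")
  sites <- data.table::as.data.table(pileups)
  zero <- sites$clean_cov == 0L
  if (any(zero)) {
    warnf("%d site(s) with zero clean coverage skipped", sum(zero))
    sites <- sites[!zero, ]
  }
  p <- stats::pbinom(sites$meth_count - 1L, sites$clean_cov, 1 - r,
                     lower.tail = FALSE)
  underflow <- p <= 0 & sites$meth_count >= 1L
  p[underflow] <- .Machine$double.xmin
  sites[, p := p]
  sites[, p_underflow := underflow]
  class(sites) <- c("m5c_sites", "data.table", "data.frame")
  sites[]
}

#' Apply the standard, signal-to-noise and FDR site filters
#'
#' Flags each candidate site against the filter cascade: the standard filter
#' (clean coverage, methylation level and methylated depth at or above their
#' thresholds), the signal-to-noise filter (`sn_ratio` strictly greater than
#' `min_sn`; a site at exactly the threshold fails) and the FDR filter
#' (BH-adjusted p strictly below `max_fdr`). Following the stated filter
#' order, the BH adjustment is computed over the sites that survive the
#' standard filter; sites failing the standard filter get `padj = NA`.
#'
#' @param sites `m5c_sites` with p-values (see [call_site_pvalues()]).
#' @param thresholds a [filter_thresholds()] object.
#' @return `m5c_sites` with `padj`, per-filter flags (`pass_standard`,
#'   `pass_sn`, `pass_fdr`) and the overall `pass`.
#' @export
apply_site_filters <- function(sites, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) == 0L) {
    sites[, `:=`(padj = numeric(), pass_standard = logical(),
                 pass_sn = logical(), pass_fdr = logical(), pass = logical())]
    class(sites) <- c("m5c_sites", "data.table", "data.frame")
    return(sites[])
  }
  if (is.null(sites$p)) stopf("p-values missing: run call_site_pvalues() first")
  th <- thresholds
  sites[, pass_standard := clean_cov >= th$min_cov & level >= th$min_level &
          meth_count >= th$min_meth]
  sites[, pass_sn := sn_ratio > th$min_sn]
  sites[, padj := NA_real_]
  sites[pass_standard == TRUE, padj := stats::p.adjust(p, method = "BH")]
  sites[, pass_fdr := !is.na(padj) & padj < th$max_fdr]
  sites[, pass := pass_standard & pass_sn & pass_fdr]
  class(sites) <- c("m5c_sites", "data.table", "data.frame")
  sites[]
}

#' @export
print.m5c_sites <- function(x, ...) {
  cat(sprintf("m5C site table: %d sites", nrow(x)))
  if (!is.null(x$pass)) cat(sprintf(", %d passing all filters", sum(x$pass)))
  cat("\n")
  if (nrow(x)) print(data.table::as.data.table(utils::head(x, 5)))
  invisible(x)
}

#' Intersect passing sites across biological replicates
#'
#' A site is high-confidence only if it passes all filters in both
#' replicates. Methylated and clean counts are pooled across the two
#' replicates, so the merged level is `(M1 + M2) / (C1 + C2)`. The result
#' carries the per-replicate overlap percentages and the Pearson correlation
#' of levels on the shared sites as attributes (`overlap_pct`,
#' `level_correlation`).
#'
#' @param rep1,rep2 `m5c_sites` tables from the two replicates (only rows
#'   with `pass == TRUE` are used when the flag is present).
#' @return `m5c_sites` of high-confidence sites with pooled counts and
#'   merged levels.
#' @export
merge_replicates <- function(rep1, rep2) {
  take <- function(x) {
    x <- data.table::as.data.table(x)
    if (!is.null(x$pass)) x <- x[pass == TRUE, ]
    x
  }
  a <- take(rep1); b <- take(rep2)
  m <- merge(a[, .(transcript_id, pos, strand,
                   clean_cov1 = clean_cov, meth_count1 = meth_count,
                   level1 = level)],
             b[, .(transcript_id, pos,
                   clean_cov2 = clean_cov, meth_count2 = meth_count,
                   level2 = level)],
             by = c("transcript_id", "pos"))
  m[, clean_cov := clean_cov1 + clean_cov2]
  m[, meth_count := meth_count1 + meth_count2]
  m[, level := meth_count / clean_cov]
  out <- m[, .(transcript_id, pos, strand, clean_cov, meth_count, level)]
  data.table::setorder(out, transcript_id, pos)
  data.table::setattr(out, "overlap_pct",
    c(rep1 = if (nrow(a)) 100 * nrow(m) / nrow(a) else NA_real_,
      rep2 = if (nrow(b)) 100 * nrow(m) / nrow(b) else NA_real_))
  data.table::setattr(out, "level_correlation",
    if (nrow(m) >= 3 && stats::sd(m$level1) > 0 && stats::sd(m$level2) > 0)
      stats::cor(m$level1, m$level2) else NA_real_)
  class(out) <- c("m5c_sites", "data.table", "data.frame")
  out[]
}

#' Seven-part Venn partition of site sets across three conditions
#'
#' Partitions the union of three high-confidence site sets (keyed by
#' transcript and position) into the seven disjoint membership classes. The
#' part counts always sum to the size of the union.
#'
#' @param sets named list of three `m5c_sites` tables (or data.frames with
#'   `transcript_id` and `pos`).
#' @return named integer vector with one count per membership class (e.g.
#'   `"t0" , "t2", "t6", "t0&t2", ..., "t0&t2&t6"`) plus attribute `union`.
#' @export
condition_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3L)
  nm <- names(sets) %||% c("A", "B", "C")
  keys <- lapply(sets, function(s) {
    s <- as.data.frame(s)
    unique(paste(s$transcript_id, s$pos, sep = ":"))
  })
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  out <- vapply(combos, function(cmb) {
    inside <- rowSums(member[, cmb, drop = FALSE]) == length(cmb)
    outside <- rowSums(member[, -cmb, drop = FALSE]) == 0
    sum(inside & (length(cmb) == 3L | outside))
  }, integer(1))
  names(out) <- vapply(combos, function(cmb) paste(nm[cmb], collapse = "&"),
                       character(1))
  attr(out, "union") <- length(all_keys)
  out
}
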