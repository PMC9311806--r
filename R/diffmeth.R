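#' Select sites eligible for differential methylation testing
#'
#' A site enters the comparison of two conditions only if its clean coverage
#' is at least `min_cov` (default 10) in every replicate of both conditions
#' and it is a high-confidence site in at least one of the two conditions.
#'
#' @param pileups_a,pileups_b lists of per-replicate `m5c_pileup` tables for
#'   conditions A and B.
#' @param hc_a,hc_b high-confidence `m5c_sites` for the two conditions (see
#'   [merge_replicates()]).
#' @param min_cov minimum clean coverage per replicate (default 10).
#' @return data.table of eligible keys (`transcript_id`, `pos`).
#' @export
select_eligible_sites <- function(pileups_a, pileups_b, hc_a, hc_b,
                                  min_cov = 10L) {
  stopifnot(is.list(pileups_a), is.list(pileups_b))
  key <- function(x) paste(x$transcript_id, x$pos, sep = ":")
  hc_keys <- union(key(hc_a), key(hc_b))
  if (length(hc_keys) == 0L)
    return(data.table::data.table(transcript_id = character(),
                                  pos = integer()))
  reps <- c(pileups_a, pileups_b)
  ok <- rep(TRUE, length(hc_keys))
  for (pu in reps) {
    cov <- pu$clean_cov[match(hc_keys, key(pu))]
    ok <- ok & !is.na(cov) & cov >= min_cov
  }
  keep <- hc_keys[ok]
  if (length(keep) == 0L)
    return(data.table::data.table(transcript_id = character(),
                                  pos = integer()))
  parts <- data.table::tstrsplit(keep, ":", fixed = TRUE)
  data.table::data.table(transcript_id = as.character(parts[[1]]),
                         pos = as.integer(parts[[2]]))
}

#' Two-sided Fisher exact test and odds ratio for a methylation 2x2 table
#'
#' Tests methylated/unmethylated counts of one site pooled per condition.
#' The two-sided p-value follows the minimum-likelihood convention: the sum
#' of hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. The odds
#' ratio is the sample odds ratio `(M_A * U_B) / (U_A * M_B)`; when any cell
#' is zero, 0.5 is added to every cell for the odds ratio only (the p-value
#' stays exact).
#'
#' All four arguments are vectorized over sites.
#'
#' @param m_a,u_a methylated/unmethylated counts in condition A.
#' @param m_b,u_b methylated/unmethylated counts in condition B.
#' @return data.frame with `p` and `or`.
#' @export
#' @examples
#' fisher_dm_test(6, 14, 6, 14)   # identical proportions: p = 1, OR = 1
fisher_dm_test <- function(m_a, u_a, m_b, u_b) {
  kc <- cbind(m_a, u_a, m_b, u_b)
  if (any(kc < 0) || any(kc != round(kc)))
    stopf("counts must be nonnegative integers")
  n_a <- m_a + u_a
  n_b <- m_b + u_b
  if (any(n_a + n_b == 0)) stopf("all-zero 2x2 table")
  if (any(n_a == 0 | n_b == 0)) stopf("both condition totals must be positive")
  p <- vapply(seq_along(m_a), function(i) {
    m <- m_a[i] + m_b[i]
    lo <- max(0L, m - n_b[i]); hi <- min(n_a[i], m)
    pr <- stats::dhyper(lo:hi, n_a[i], n_b[i], m)
    obs <- pr[(lo:hi) == m_a[i]]
    sum(pr[pr <= obs * (1 + 1e-7)])
  }, numeric(1))
  p <- pmin(p, 1)
  zero <- m_a == 0 | u_a == 0 | m_b == 0 | u_b == 0
  or <- ifelse(zero,
               ((m_a + 0.5) * (u_b + 0.5)) / ((u_a + 0.5) * (m_b + 0.5)),
               (m_a * u_b) / (u_a * m_b))
  data.frame(p = p, or = or)
}

#' Differential methylation analysis between two conditions
#'
#' Pools methylated/unmethylated counts per condition across replicates at
#' each eligible site, runs [fisher_dm_test()], and computes the level
#' difference `delta_m = m_B - m_A` (later condition minus earlier).
#'
#' @param eligible key table from [select_eligible_sites()].
#' @param pileups_a,pileups_b per-replicate `m5c_pileup` lists.
#' @return data.table of class `dms_records` with pooled counts, levels,
#'   `delta_m`, `or`, `p`.
#' @export
dm_records <- function(eligible, pileups_a, pileups_b) {
  pool <- function(pileups) {
    dt <- data.table::rbindlist(lapply(pileups, data.table::as.data.table))
    dt <- dt[, .(C = sum(clean_cov), M = sum(meth_count)),
             by = .(transcript_id, pos)]
    dt
  }
  a <- pool(pileups_a); b <- pool(pileups_b)
  rec <- data.table::as.data.table(eligible)
  rec <- merge(rec, a, by = c("transcript_id", "pos"), all.x = TRUE)
  data.table::setnames(rec, c("C", "M"), c("C_a", "M_a"))
  rec <- merge(rec, b, by = c("transcript_id", "pos"), all.x = TRUE)
  data.table::setnames(rec, c("C", "M"), c("C_b", "M_b"))
  miss <- is.na(rec$C_a) | is.na(rec$C_b)
  if (any(miss)) {
    warnf("%d eligible site(s) missing replicate data; excluded", sum(miss))
    rec <- rec[!miss]
  }
  rec[, `:=`(U_a = C_a - M_a, U_b = C_b - M_b)]
  rec[, `:=`(m_a = M_a / C_a, m_b = M_b / C_b)]
  rec[, delta_m := m_b - m_a]
  ft <- fisher_dm_test(rec$M_a, rec$U_a, rec$M_b, rec$U_b)
  rec[, `:=`(or = ft$or, p = ft$p)]
  class(rec) <- c("dms_records", "data.table", "data.frame")
  rec[]
}

#' Classify differentially methylated sites
#'
#' BH-adjusts the Fisher p-values over all eligible sites (the BH universe
#' is the eligible set) and calls a site a DMS when its adjusted p-value is
#' at most `alpha`. DMS are hypermethylated when `delta_m > 0` (the later
#' condition is higher) and hypomethylated when `delta_m < 0`. A
#' significant site with `delta_m == 0` cannot arise from a Fisher-exact
#' rejection except in degenerate ties; such rows are flagged and logged.
#'
#' @param records a `dms_records` table (see [dm_records()]).
#' @param alpha adjusted-p threshold, inclusive (default 0.05).
#' @param quiet suppress log lines.
#' @return the records with `padj` and `direction` (`hyper`, `hypo`, `ns`).
#' @export
classify_dms <- function(records, alpha = 0.05, quiet = FALSE) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0L) {
    rec[, `:=`(padj = numeric(), direction = character())]
    class(rec) <- c("dms_records", "data.table", "data.frame")
    return(rec[])
  }
  rec[, padj := stats::p.adjust(p, method = "BH")]
  rec[, direction := "ns"]
  rec[padj <= alpha & delta_m > 0, direction := "hyper"]
  rec[padj <= alpha & delta_m < 0, direction := "hypo"]
  anom <- rec$padj <= alpha & rec$delta_m == 0
  if (any(anom))
    msg(sprintf("%d significant site(s) with zero level change flagged 'ns'",
                sum(anom)), quiet = quiet)
  class(rec) <- c("dms_records", "data.table", "data.frame")
  rec[]
}

#' @export
print.dms_records <- function(x, ...) {
  cat(sprintf("Differential methylation: %d eligible sites", nrow(x)))
  if (!is.null(x$direction))
    cat(sprintf("; %d hyper, %d hypo DMS",
                sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  cat("\n")
  invisible(x)
}
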