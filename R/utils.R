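# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each simulation stage (and each library within a stage) draws from its own
#' RNG stream so that, e.g., regenerating reads for one time point does not
#' perturb the transcriptome. Streams are derived deterministically from the
#' master seed by fixed offsets and kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage integer stage code (each generator stage has a fixed code).
#' @param timepoint,replicate optional sub-stream indices.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stage, timepoint = 0L, replicate = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 127L + stage * 7919L + timepoint * 101L +
                replicate * 13L) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msg <- function(..., quiet = FALSE) {
  if (!quiet) message("[m5cpipe] ", ...)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1] (got %s)",
          name, paste(format(x), collapse = ","))
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stopf("'%s' must be an integer >= %s (got %s)", name, min, format(x))
  invisible(as.integer(x))
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("'%s' must be a positive number (got %s)", name, format(x))
  invisible(x)
}

# merge possibly-overlapping 1-based closed intervals; df has start, end
merge_intervals <- function(start, end) {
  if (length(start) == 0L)
    return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
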