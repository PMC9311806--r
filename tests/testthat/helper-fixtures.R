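# hand-built read sets and pileups used across tests

# spec: list of reads; each read a list(id, tx, start, pos = integer vector of
# cytosine positions, unconv = logical vector, spike = flag)
make_reads <- function(spec) {
  if (length(spec) == 0) {
    return(structure(list(
      reads = data.table::data.table(
        read_id = character(), transcript_id = character(), start = integer(),
        end = integer(), n_c = integer(), n_unconverted = integer(),
        is_spike_in = logical()),
      calls = data.table::data.table(
        read_id = character(), transcript_id = character(), pos = integer(),
        unconverted = logical()),
      library = list()), class = "m5c_reads"))
  }
  reads <- data.table::rbindlist(lapply(spec, function(r) data.table::data.table(
    read_id = r$id, transcript_id = r$tx,
    start = r$start %||% 1L,
    end = (r$start %||% 1L) + 99L,
    n_c = length(r$pos %||% integer()),
    n_unconverted = sum(r$unconv %||% logical()),
    is_spike_in = isTRUE(r$spike))))
  calls <- data.table::rbindlist(lapply(spec, function(r) {
    if (length(r$pos %||% integer()) == 0) return(NULL)
    data.table::data.table(read_id = r$id, transcript_id = r$tx,
                           pos = as.integer(r$pos),
                           unconverted = as.logical(r$unconv))
  }))
  if (nrow(calls) == 0)
    calls <- data.table::data.table(read_id = character(),
                                    transcript_id = character(),
                                    pos = integer(), unconverted = logical())
  structure(list(reads = reads, calls = calls, library = list()),
            class = "m5c_reads")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n_reads covering one site on one transcript, n_unconv of them unconverted
site_reads <- function(tx = "tx1", pos = 10L, n = 20L, n_unconv = 6L,
                       extra_unconv_per_read = 0L, id_prefix = "r") {
  lapply(seq_len(n), function(i) {
    uc <- i <= n_unconv
    if (extra_unconv_per_read > 0) {
      ps <- c(pos, pos + seq_len(extra_unconv_per_read) * 2L)
      list(id = paste0(id_prefix, i), tx = tx, start = 1L, pos = ps,
           unconv = c(uc, rep(TRUE, extra_unconv_per_read)))
    } else {
      list(id = paste0(id_prefix, i), tx = tx, start = 1L, pos = pos,
           unconv = uc)
    }
  })
}

simple_annotation <- function(tx = "tx1", len = 900L, u5 = 100L, cds = 440L) {
  data.frame(transcript_id = tx, gene_id = paste0("g_", tx), strand = "+",
             length = len, utr5_end = u5, cds_end = u5 + cds,
             is_spike_in = FALSE)
}

make_pileup <- function(transcript_id, pos, clean_cov, meth_count,
                        total_cov = clean_cov) {
  dt <- data.table::data.table(
    transcript_id = transcript_id, pos = as.integer(pos), strand = "+",
    total_cov = as.integer(total_cov), clean_cov = as.integer(clean_cov),
    meth_count = as.integer(meth_count),
    level = meth_count / clean_cov,
    sn_ratio = clean_cov / total_cov)
  class(dt) <- c("m5c_pileup", "data.table", "data.frame")
  dt
}
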