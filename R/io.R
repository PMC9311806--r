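# Readers and writers for the pipeline's plain-text formats. All files use
# 1-based closed coordinates; read records store cytosine offsets relative
# to the read start (0-based) with states '1' = unconverted.

#' Write transcript sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write/read the GTF-lite annotation table
#'
#' Tab-separated with columns `transcript_id`, `gene_id`, `strand`,
#' `utr5_end`, `cds_end`, `length`, `is_spike_in` (1-based closed
#' boundaries).
#' @param annotation annotation data.frame.
#' @param path file path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  cols <- c("transcript_id", "gene_id", "strand", "utr5_end", "cds_end",
            "length", "is_spike_in")
  data.table::fwrite(annotation[, cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write aligned reads as TSV
#'
#' Columns: `read_id`, `transcript_id`, `start` (1-based), `cytosine_offsets`
#' (comma-separated 0-based offsets from the read start), `states` (string
#' of 0/1 per cytosine, 1 = unconverted), `is_spike_in`.
#' @param reads an `m5c_reads` object.
#' @param path file path.
#' @export
write_reads_tsv <- function(reads, path) {
  stopifnot(inherits(reads, "m5c_reads"))
  rd <- reads$reads
  cl <- reads$calls
  off <- states <- character(nrow(rd))
  if (nrow(cl)) {
    start_of <- rd$start[match(cl$read_id, rd$read_id)]
    grp <- collapse_by_read(cl$read_id, cl$pos - start_of,
                            as.integer(cl$unconverted))
    i <- match(grp$read_id, rd$read_id)
    off[i] <- grp$offsets
    states[i] <- grp$states
  }
  out <- data.frame(read_id = rd$read_id, transcript_id = rd$transcript_id,
                    start = rd$start, cytosine_offsets = off,
                    states = states, is_spike_in = as.integer(rd$is_spike_in))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

collapse_by_read <- function(read_id, offsets, states) {
  dt <- data.table::data.table(read_id = read_id, off = offsets, st = states)
  dt[, .(offsets = paste(off, collapse = ","),
         states = paste(st, collapse = "")), by = read_id]
}

#' Read aligned reads from TSV
#' @param path file written by [write_reads_tsv()].
#' @return an `m5c_reads` object.
#' @export
read_reads_tsv <- function(path) {
  x <- data.table::fread(path, colClasses = list(
    character = c("read_id", "transcript_id", "cytosine_offsets", "states")))
  has <- nchar(x$cytosine_offsets) > 0
  calls_list <- NULL
  if (any(has)) {
    offs <- strsplit(x$cytosine_offsets[has], ",", fixed = TRUE)
    n_c <- lengths(offs)
    calls_list <- data.table::data.table(
      read_id = rep(x$read_id[has], n_c),
      transcript_id = rep(x$transcript_id[has], n_c),
      pos = as.integer(unlist(offs)) + rep(x$start[has], n_c),
      unconverted = unlist(strsplit(x$states[has], "", fixed = TRUE)) == "1")
  } else {
    calls_list <- data.table::data.table(
      read_id = character(), transcript_id = character(),
      pos = integer(), unconverted = logical())
  }
  n_c_all <- integer(nrow(x))
  n_c_all[has] <- nchar(x$states[has])
  n_unc <- integer(nrow(x))
  if (any(has))
    n_unc[has] <- vapply(strsplit(x$states[has], "", fixed = TRUE),
                         function(s) sum(s == "1"), integer(1))
  reads <- data.table::data.table(
    read_id = x$read_id, transcript_id = x$transcript_id,
    start = as.integer(x$start),
    end = NA_integer_,
    n_c = n_c_all, n_unconverted = n_unc,
    is_spike_in = as.logical(x$is_spike_in))
  structure(list(reads = reads, calls = calls_list, library = list()),
            class = "m5c_reads")
}

#' Write a site or pileup table as TSV
#'
#' Positions are written 1-based under the column name `pos_1based`.
#' @param sites `m5c_pileup`/`m5c_sites`/`dms_records` table.
#' @param path file path.
#' @export
write_sites_tsv <- function(sites, path) {
  x <- data.table::as.data.table(sites)
  if ("pos" %in% names(x)) data.table::setnames(x, "pos", "pos_1based")
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  x <- data.table::fread(path)
  if ("pos_1based" %in% names(x)) data.table::setnames(x, "pos_1based", "pos")
  x[]
}

#' Export m5C sites as BED6 (transcript space)
#'
#' BED uses 0-based half-open intervals, so a site at 1-based position `p`
#' becomes `start = p - 1`, `end = p`. The name is `transcript:pos`
#' (1-based) and the score is `round(1000 * level)`.
#'
#' @param sites site table with `transcript_id`, `pos`, `level`, `strand`.
#' @param path output path.
#' @export
export_sites_bed <- function(sites, path) {
  s <- as.data.frame(sites)
  bed <- data.frame(
    chrom = s$transcript_id,
    start = s$pos - 1L,
    end = s$pos,
    name = paste0(s$transcript_id, ":", s$pos),
    score = as.integer(round(1000 * s$level)),
    strand = if (!is.null(s$strand)) s$strand else "+")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site export back
#' @param path BED path written by [export_sites_bed()].
#' @return data.table with `transcript_id`, `pos` (1-based), `level`,
#'   `strand`.
#' @export
read_sites_bed <- function(path) {
  x <- data.table::fread(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  data.table::data.table(transcript_id = x$chrom,
                         pos = as.integer(x$end),
                         level = x$score / 1000,
                         strand = x$strand)
}

#' Write/read a gene count matrix as TSV
#' @param counts matrix with gene rownames.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  x <- data.table::fread(path)
  m <- as.matrix(x[, -1])
  rownames(m) <- x[[1]]
  m
}
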