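#' Predict conversion-resistant (stably base-paired) regions
#'
#' Bisulfite conversion fails inside stable RNA secondary structure, so
#' unconverted cytosines there mimic methylation. This predictor reports
#' intervals likely to resist conversion. Two methods are available:
#'
#' * `"internal"` (default): maximum complementary pairing (Watson-Crick
#'   plus G:U) by a Nussinov-style recursion constrained to pair spans of at
#'   most `max_span` bases and helices of at least `min_helix` stacked
#'   pairs. Every maximal helix defines a candidate interval from its 5'
#'   arm to its 3' arm; intervals whose paired-base fraction reaches
#'   `min_paired_frac` are reported (overlapping intervals merged). This is
#'   a pairing-fraction heuristic, not free-energy minimization.
#' * `"rnafold"`: delegate folding to an external `RNAfold` executable
#'   (`--maxBPspan max_span -T temperature --MEA mea_gamma`), parse the
#'   dot-bracket output and extract regions by the same helix rule.
#'
#' @param sequence a single RNA/DNA sequence string over A/C/G/T/U.
#' @param max_span maximum allowed base-pair span (nt), default 150.
#' @param min_helix minimum stacked helix length (pairs), default 6.
#' @param min_paired_frac minimum paired-base fraction of a reported
#'   interval, default 0.8.
#' @param min_loop minimum hairpin-loop size (nt), default 3 (internal
#'   method only).
#' @param method `"internal"` or `"rnafold"`.
#' @param temperature,mea_gamma passed to the external folding program only;
#'   the internal heuristic has no temperature notion.
#' @param rnafold path to the RNAfold executable.
#' @return data.frame of class `resistant_regions` with `start`, `end`
#'   (1-based closed) and `pairing_score`.
#' @export
#' @examples
#' # a perfect hairpin is reported; an unstructured sequence is not
#' stem <- "GGCAUCGUACGAUCGGAUCC"
#' hp <- paste0(stem, "GAAA", "GGAUCCGAUCGUACGAUGCC")
#' predict_resistant_regions(hp)
#' predict_resistant_regions(strrep("A", 60))
predict_resistant_regions <- function(sequence, max_span = 150L,
                                      min_helix = 6L, min_paired_frac = 0.8,
                                      min_loop = 3L,
                                      method = c("internal", "rnafold"),
                                      temperature = 70, mea_gamma = 0.1,
                                      rnafold = "RNAfold") {
  method <- match.arg(method)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  bad <- regexpr("[^ACGTU]", s)
  if (bad > 0)
    stopf("invalid character '%s' at position %d", substr(s, bad, bad), bad)
  check_count(max_span, "max_span"); check_count(min_helix, "min_helix")
  check_prob(min_paired_frac, "min_paired_frac")

  partner <- if (method == "internal") {
    .nussinov_pairing(s, as.integer(max_span), as.integer(min_helix),
                      as.integer(min_loop))
  } else {
    db <- run_rnafold(s, max_span = max_span, temperature = temperature,
                      mea_gamma = mea_gamma, rnafold = rnafold)
    parse_dot_bracket(db)
  }
  regions_from_pairing(partner, min_helix = min_helix,
                       min_paired_frac = min_paired_frac)
}

# extract resistant intervals from a partner vector (1-based, 0 = unpaired)
regions_from_pairing <- function(partner, min_helix, min_paired_frac) {
  n <- length(partner)
  empty <- structure(
    data.frame(start = integer(), end = integer(), pairing_score = numeric()),
    class = c("resistant_regions", "data.frame"))
  if (n == 0L) return(empty)
  five <- which(partner > seq_len(n))       # 5' sides of pairs
  if (length(five) == 0L) return(empty)
  # maximal stacks: consecutive positions whose partners step down by one
  brk <- c(TRUE, diff(five) != 1L | diff(partner[five]) != -1L)
  grp <- cumsum(brk)
  starts <- tapply(five, grp, min)
  lens <- tabulate(grp)
  keep <- lens >= min_helix
  if (!any(keep)) return(empty)
  cand_s <- as.integer(starts[keep])
  cand_e <- as.integer(partner[cand_s])     # 3' end of the closing pair
  frac <- vapply(seq_along(cand_s), function(i)
    mean(partner[cand_s[i]:cand_e[i]] > 0), numeric(1))
  ok <- frac >= min_paired_frac
  if (!any(ok)) return(empty)
  mrg <- merge_intervals(cand_s[ok], cand_e[ok])
  mrg$pairing_score <- vapply(seq_len(nrow(mrg)), function(i)
    mean(partner[mrg$start[i]:mrg$end[i]] > 0), numeric(1))
  structure(mrg, class = c("resistant_regions", "data.frame"))
}

#' Parse a dot-bracket secondary structure string
#'
#' Converts `(`, `)` and `.` notation (as emitted by folding programs) into
#' a partner vector: position `i` holds the 1-based index it pairs with, or
#' 0 if unpaired.
#'
#' @param db dot-bracket string.
#' @return integer partner vector.
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        stopf("unbalanced ')' at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    } else if (ch[i] != ".") {
      stopf("unexpected character '%s' at position %d", ch[i], i)
    }
  }
  if (length(stack))
    stopf("unbalanced '(' at position %d", stack[length(stack)])
  partner
}

# invoke an external RNAfold binary and return its structure line
run_rnafold <- function(sequence, max_span, temperature, mea_gamma,
                        rnafold = "RNAfold") {
  if (Sys.which(rnafold) == "")
    stopf("external folding executable '%s' not found", rnafold)
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(c(">q", sequence), fa)
  # run inside a scratch directory: the folder drops dot-plot side files
  old_wd <- setwd(tempdir())
  on.exit(setwd(old_wd), add = TRUE)
  out <- suppressWarnings(system2(
    rnafold,
    args = c("--maxBPspan", max_span, "-T", temperature,
             paste0("--MEA=", format(mea_gamma)), "--noPS", "-i", fa),
    stdout = TRUE, stderr = FALSE))
  struct_lines <- grep("^[().,{}|]+( |$)", out, value = TRUE)
  if (length(struct_lines) == 0L)
    stopf("could not parse folding output (%d lines)", length(out))
  mea <- grep("MEA=", struct_lines, value = TRUE)
  line <- if (length(mea)) mea[1] else struct_lines[1]
  gsub("[^().]", ".", strsplit(line, " ")[[1]][1])
}

#' Remove m5C sites inside conversion-resistant regions
#'
#' Drops every site whose position lies inside a predicted resistant region
#' of the same transcript (1-based closed intervals; a site on the boundary
#' base is removed). The removed rows are attached as attribute `removed`.
#'
#' @param sites `m5c_sites` (or data.frame with `transcript_id`, `pos`).
#' @param regions data.frame with `transcript_id`, `start`, `end`.
#' @param quiet suppress the log line.
#' @return the retained sites, same class as the input.
#' @export
remove_structural_sites <- function(sites, regions, quiet = FALSE) {
  cls <- class(sites)
  s <- data.table::as.data.table(sites)
  if (nrow(s) == 0L || is.null(regions) || nrow(regions) == 0L) {
    out <- s
    data.table::setattr(out, "removed", s[0])
    class(out) <- cls
    msg(sprintf("structure filter removed 0 of %d sites", nrow(s)),
        quiet = quiet)
    return(out)
  }
  r <- data.table::as.data.table(regions)
  hit <- rep(FALSE, nrow(s))
  for (k in seq_len(nrow(r))) {
    hit <- hit | (s$transcript_id == r$transcript_id[k] &
                    s$pos >= r$start[k] & s$pos <= r$end[k])
  }
  out <- s[!hit]
  data.table::setattr(out, "removed", s[hit])
  class(out) <- cls
  msg(sprintf("structure filter removed %d of %d sites", sum(hit), nrow(s)),
      quiet = quiet)
  out
}

#' Predict resistant regions for every transcript of a transcriptome
#'
#' Convenience wrapper running [predict_resistant_regions()] across a set of
#' sequences and binding the results with a `transcript_id` column.
#'
#' @param sequences named character vector of sequences.
#' @param ... passed to [predict_resistant_regions()].
#' @return data.frame with `transcript_id`, `start`, `end`, `pairing_score`.
#' @export
predict_resistant_regions_all <- function(sequences, ...) {
  out <- lapply(names(sequences), function(id) {
    r <- predict_resistant_regions(sequences[[id]], ...)
    if (nrow(r)) cbind(transcript_id = id, as.data.frame(r))
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), pairing_score = numeric())
  out
}
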