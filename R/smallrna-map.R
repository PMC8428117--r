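#' Parameters for exact small-RNA mapping
#'
#' Candidate piRNAs are defined operationally: 22-35 nt sequences placed at
#' 100% identity with full read coverage. Identity is fixed at 1 in this
#' module by design; only the length window is tunable.
#'
#' @param min_len,max_len inclusive read-length bounds (nt).
#' @param require_full_coverage placements must cover the whole read.
#' @return parameter list.
#' @export
pirna_params <- function(min_len = 22L, max_len = 35L,
                         require_full_coverage = TRUE) {
  p <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
            require_full_coverage = isTRUE(require_full_coverage),
            identity = 1.0)
  if (p$min_len > p$max_len) stop("min_len > max_len")
  p
}

#' Filter reads by length
#'
#' @param reads sequence record set.
#' @param params [pirna_params()].
#' @return the surviving records, with a message logging the counts.
#' @export
length_filter <- function(reads, params = pirna_params()) {
  if (!nrow(reads)) return(reads)
  len <- nchar(reads$seq)
  keep <- len >= params$min_len & len <= params$max_len
  message(sum(keep), "/", length(keep), " reads within [",
          params$min_len, ", ", params$max_len, "] nt")
  reads[keep, , drop = FALSE]
}

#' Map reads to a genome at 100% identity and coverage
#'
#' Records every genomic occurrence of each read (forward and reverse
#' complement, via [Biostrings::matchPattern()]), computes per-read copy
#' numbers and per-chromosome placement sets, and flags reads exclusive to
#' `target_chrom`. Overlapping occurrences all count (copy number counts
#' occurrences, not disjoint intervals); a palindromic read matching both
#' strands of one locus counts that physical copy once, with the
#' both-strand count reported alongside.
#'
#' @param reads length-filtered sequence record set.
#' @param genome sequence record set.
#' @param params [pirna_params()].
#' @param target_chrom chromosome name for the exclusivity flag; defaults
#'   to the first genome record.
#' @return list with `placements` (`read_id`, `chrom`, `start`, `end`
#'   0-based half-open, `strand`) and `summary` (`read_id`, `length`,
#'   `copy_count`, `copy_count_both_strands`, `chromosomes`
#'   (comma-collapsed), `target_exclusive`); unplaced reads appear with
#'   `copy_count` 0.
#' @export
map_exact <- function(reads, genome, params = pirna_params(),
                      target_chrom = genome$id[1]) {
  subjects <- lapply(genome$seq, Biostrings::DNAString)
  plc <- list()
  summ <- list()
  for (i in seq_len(nrow(reads))) {
    rid <- reads$id[i]
    rseq <- reads$seq[i]
    rc <- reverse_complement(rseq)
    palindromic <- rseq == rc
    rows <- list()
    for (g in seq_len(nrow(genome))) {
      fw <- Biostrings::start(Biostrings::matchPattern(rseq, subjects[[g]]))
      if (length(fw)) rows[[length(rows) + 1L]] <-
          data.frame(read_id = rid, chrom = genome$id[g], start = fw - 1L,
                     end = fw - 1L + nchar(rseq), strand = "+",
                     stringsAsFactors = FALSE)
      rv <- Biostrings::start(Biostrings::matchPattern(rc, subjects[[g]]))
      if (length(rv)) rows[[length(rows) + 1L]] <-
          data.frame(read_id = rid, chrom = genome$id[g], start = rv - 1L,
                     end = rv - 1L + nchar(rseq), strand = "-",
                     stringsAsFactors = FALSE)
    }
    p <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    n_both <- nrow(p)
    if (palindromic && n_both)                    # one physical copy per site
      p <- p[p$strand == "+", , drop = FALSE]
    p <- p[order(p$chrom, p$start, p$strand, method = "radix"), ,
           drop = FALSE]
    plc[[length(plc) + 1L]] <- p
    chroms <- sort(unique(p$chrom))
    summ[[length(summ) + 1L]] <- data.frame(
      read_id = rid, length = nchar(rseq), copy_count = nrow(p),
      copy_count_both_strands = n_both,
      chromosomes = paste(chroms, collapse = ","),
      target_exclusive = length(chroms) == 1L && chroms[1] == target_chrom,
      stringsAsFactors = FALSE)
  }
  empty_p <- data.frame(read_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  empty_s <- data.frame(read_id = character(), length = integer(),
                        copy_count = integer(),
                        copy_count_both_strands = integer(),
                        chromosomes = character(),
                        target_exclusive = logical(),
                        stringsAsFactors = FALSE)
  list(placements = if (length(plc)) do.call(rbind, plc) else empty_p,
       summary = if (length(summ)) do.call(rbind, summ) else empty_s)
}

#' Match reads back to their source transcripts
#'
#' Exact full-length substring matches of each read (or its reverse
#' complement) within each transcript; a read "derives from" the
#' transcript set iff it matches at least once.
#'
#' @param reads length-filtered sequence record set.
#' @param transcripts sequence record set.
#' @return list with `matches` (`read_id`, `transcript_id`, `offset`
#'   0-based, `strand`) and `derived` (`read_id`, `derives` logical).
#' @export
match_to_transcripts <- function(reads, transcripts) {
  subjects <- lapply(transcripts$seq, Biostrings::DNAString)
  rows <- list()
  derived <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rseq <- reads$seq[i]
    rc <- reverse_complement(rseq)
    for (t in seq_len(nrow(transcripts))) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") rseq else rc
        if (strand == "-" && rc == rseq) next
        off <- Biostrings::start(Biostrings::matchPattern(pat, subjects[[t]]))
        if (length(off)) {
          derived[i] <- TRUE
          rows[[length(rows) + 1L]] <-
            data.frame(read_id = reads$id[i],
                       transcript_id = transcripts$id[t],
                       offset = off - 1L, strand = strand,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), transcript_id = character(),
               offset = integer(), strand = character(),
               stringsAsFactors = FALSE)
  list(matches = matches,
       derived = data.frame(read_id = reads$id, derives = derived,
                            stringsAsFactors = FALSE))
}
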