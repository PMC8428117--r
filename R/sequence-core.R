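#' @importFrom stats rnorm runif setNames sd t.test
#' @importFrom utils read.delim write.table head
NULL

# Internal alphabet constants. All comparisons happen in the DNA alphabet
# after U -> T normalization; the moltype flag only records what was read.
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a sequence record set
#'
#' A sequence record set is the package's lightweight container for named
#' nucleotide sequences: a `data.frame` with columns `id`, `seq` and
#' `moltype`. Sequences are stored uppercase over `{A,C,G,T,N}`; `U` is
#' accepted on input, recorded via `moltype = "RNA"` and normalized to `T`
#' so that RNA oligos and genomic DNA can be compared directly.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of nucleotide sequences (any case; `U`
#'   allowed, but not mixed with `T` in one sequence).
#' @return data.frame with columns `id`, `seq` (normalized), `moltype`.
#' @examples
#' seq_set(c("a", "b"), c("acgt", "GAAGCAGAUGAGUAUAUG"))
#' @export
seq_set <- function(id, seq) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- toupper(seq)
  if (any(grepl("\\s", seq))) stop("whitespace inside sequence")
  bad <- grepl("[^ACGTUN]", seq)
  if (any(bad)) stop("non-nucleotide characters in: ",
                     paste(head(id[bad]), collapse = ", "))
  has_u <- grepl("U", seq, fixed = TRUE)
  has_t <- grepl("T", seq, fixed = TRUE)
  if (any(has_u & has_t)) stop("U and T co-occur in: ",
                               paste(head(id[has_u & has_t]), collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence for: ",
                              paste(head(id[!nzchar(seq)]), collapse = ", "))
  data.frame(id = id,
             seq = gsub("U", "T", seq, fixed = TRUE),
             moltype = ifelse(has_u, "RNA", "DNA"),
             stringsAsFactors = FALSE)
}

#' Reverse complement of a nucleotide string
#'
#' Complements and reverses `s`. The alphabet is detected from the string:
#' sequences containing `U` are treated as RNA (`A<->U`), everything else as
#' DNA (`A<->T`). `N` maps to `N`. Vectorized over `s`.
#'
#' @param s character vector of nucleotide strings over `{A,C,G,T,U,N}`
#'   (case-insensitive).
#' @return character vector of reverse complements, same alphabet as input.
#' @examples
#' reverse_complement("GAAGCAGAUGAGUAUAUG")  # "CAUAUACUCAUCUGCUUC"
#' reverse_complement("ACGTN")               # "NACGT"
#' @export
reverse_complement <- function(s) {
  s <- toupper(as.character(s))
  if (any(grepl("[^ACGTUN]", s))) stop("non-nucleotide character in input")
  if (any(grepl("U", s) & grepl("T", s))) stop("U and T co-occur in input")
  is_rna <- grepl("U", s, fixed = TRUE)
  out <- character(length(s))
  out[!is_rna] <- str_rev(chartr("ACGT", "TGCA", s[!is_rna]))
  out[is_rna]  <- str_rev(chartr("ACGU", "UGCA", s[is_rna]))
  out
}

str_rev <- function(s) {
  vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

#' Hamming distance between two equal-length nucleotide strings
#'
#' Counts positions at which the two strings differ. `N` never matches
#' anything, including another `N` -- a conservative rule that avoids
#' inventing homology through ambiguous bases.
#'
#' @param a,b nucleotide strings of equal length.
#' @return integer mismatch count.
#' @examples
#' hamming("ACGT", "ACGA")  # 1
#' hamming("ANGT", "ANGT")  # 1 (N mismatches N)
#' @export
hamming <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths (",
                                 nchar(a), " vs ", nchar(b), ")")
  if (nchar(a) == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

#' Read a FASTA file into a sequence record set
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file via
#' [Biostrings::readBStringSet()] and applies the package's normalization:
#' uppercase, `U -> T` with `moltype = "RNA"`. Record order is preserved;
#' identifiers are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return sequence record set (see [seq_set()]); zero-row with a warning
#'   for an empty file.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), seq = character(),
                      moltype = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(ss))
  seq_set(ids, as.character(ss))
}

#' Write a sequence record set to FASTA
#'
#' Sequences flagged `moltype = "RNA"` are rendered back in the RNA
#' alphabet (`T -> U`); DNA records are written as stored.
#'
#' @param x sequence record set.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  seqs <- x$seq
  if ("moltype" %in% names(x)) {
    rna <- x$moltype == "RNA"
    seqs[rna] <- gsub("T", "U", seqs[rna], fixed = TRUE)
  }
  ss <- Biostrings::BStringSet(setNames(seqs, x$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Fetch one sequence from a record set by id.
seq_of <- function(x, id) {
  i <- match(id, x$id)
  if (is.na(i)) stop("unknown sequence id: ", id)
  x$seq[i]
}

# Character-vector view of a string (internal hot path helper).
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Genomic interval constructor (0-based, half-open)
#'
#' All coordinates inside the package are 0-based half-open; conversion to
#' the 1-based inclusive convention happens only at GFF3/BED boundaries.
#'
#' @param chrom chromosome name.
#' @param start,end integer bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return one-row data.frame with the four fields.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) stop("invalid interval bounds")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# Extract genome substring [start, end) from a named sequence vector,
# optionally reverse-complemented.
genome_sub <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(seq_of(genome, chrom), start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}
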