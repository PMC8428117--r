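#' Exon chain: a transcript's placement on the genome
#'
#' An exon chain records where a (spliced) transcript sits on a genome:
#' an ordered set of exon intervals on one chromosome and strand, plus the
#' fraction of transcript bases that match the genome there. Chains are the
#' common currency between the aligner, the splice annotator and the
#' homology scanner.
#'
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"` (transcribed strand).
#' @param exons data.frame with 0-based half-open `start`, `end` columns,
#'   in ascending genomic order, non-overlapping.
#' @param identity fraction of transcript bases matching the genome.
#' @param score chain score (sum of anchor lengths minus intron penalties);
#'   `NA` for truth chains.
#' @return object of class `exon_chain`.
#' @export
exon_chain <- function(transcript_id, chrom, strand, exons,
                       identity = NA_real_, score = NA_real_) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (nrow(exons) == 0L) stop("exon chain needs at least one exon")
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons must be disjoint and ascending")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons,
                 identity = identity, score = score),
            class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat(sprintf("exon_chain %s %s:%d-%d(%s) %d exon(s), identity %.4g\n",
              x$transcript_id, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), x$identity))
  invisible(x)
}

# Total transcript length implied by a chain.
chain_tx_length <- function(chain) sum(chain$exons$end - chain$exons$start)

# Genomic span of a chain.
chain_span <- function(chain) c(min(chain$exons$start), max(chain$exons$end))

#' Spliced transcript sequence implied by an exon chain
#'
#' Concatenates the exon substrings of the genome; for `-` strand chains
#' the concatenation is reverse-complemented so the result reads 5' to 3'
#' on the transcribed strand.
#'
#' @param chain an [exon_chain()].
#' @param genome sequence record set containing `chain$chrom`.
#' @return nucleotide string.
#' @export
spliced_sequence <- function(chain, genome) {
  g <- seq_of(genome, chain$chrom)
  s <- paste(substring(g, chain$exons$start + 1L, chain$exons$end),
             collapse = "")
  if (chain$strand == "-") s <- reverse_complement(s)
  s
}

#' Structural equality of two exon chains
#'
#' Compares placement only: chromosome, strand and exact exon intervals.
#' Identity and score are ignored.
#'
#' @param a,b [exon_chain()] objects.
#' @return logical.
#' @export
chains_identical <- function(a, b) {
  a$chrom == b$chrom && a$strand == b$strand &&
    nrow(a$exons) == nrow(b$exons) &&
    all(a$exons$start == b$exons$start) && all(a$exons$end == b$exons$end)
}

#' Write exon chains to GFF3
#'
#' One `mRNA` feature per chain with `exon` children (and one `gene` per
#' chain group), 1-based inclusive coordinates, via
#' [rtracklayer::export.gff3()].
#'
#' @param chains list of [exon_chain()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chains_gff3 <- function(chains, path) {
  rows <- list()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    mrna_id <- sprintf("%s.chain%d", ch$transcript_id, i)
    sp <- chain_span(ch)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = ch$chrom, start = sp[1] + 1L, end = sp[2],
                 strand = ch$strand, type = "mRNA", ID = mrna_id,
                 Parent = NA_character_, stringsAsFactors = FALSE)
    ex <- ch$exons
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = ch$chrom, start = ex$start + 1L, end = ex$end,
                 strand = ch$strand, type = "exon",
                 ID = sprintf("%s.exon%d", mrna_id, seq_len(nrow(ex))),
                 Parent = mrna_id, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read exon chains from GFF3
#'
#' Inverse of [write_chains_gff3()]: rebuilds one [exon_chain()] per
#' `mRNA` feature from its `exon` children. The transcript id is the mRNA
#' `ID` stripped of its `.chainN` suffix.
#'
#' @param path GFF3 file written by [write_chains_gff3()].
#' @return named list of chains (names are mRNA ids).
#' @export
read_chains_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_mrna <- md$type == "mRNA"
  out <- list()
  for (i in which(is_mrna)) {
    mid <- md$ID[i]
    kids <- which(vapply(md$Parent, function(p) mid %in% p, logical(1)))
    ex <- gr[kids]
    ex <- ex[order(GenomicRanges::start(ex))]
    out[[mid]] <- exon_chain(
      transcript_id = sub("\\.chain\\d+$", "", mid),
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      strand = as.character(GenomicRanges::strand(gr[i])),
      exons = data.frame(start = GenomicRanges::start(ex) - 1L,
                         end = GenomicRanges::end(ex)))
  }
  out
}
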