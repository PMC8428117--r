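#' Annotate splice junctions of an exon chain
#'
#' Extracts the donor and acceptor dinucleotides of every intron, read on
#' the transcribed strand (for `-` chains the forward-genome intron shows
#' the CT..AC mirror of the canonical signal). A junction is canonical iff
#' the intron starts `GT` (donor) and ends `AG` (acceptor) -- the
#' consensus often written acceptor-first as "AG/GT".
#'
#' @param chain an [exon_chain()].
#' @param genome sequence record set containing the chain's chromosome.
#' @return data.frame with one row per intron in transcript order:
#'   `transcript_id`, `intron`, `chrom`, `donor_pos`, `acceptor_pos`
#'   (0-based first/last intron base on the transcribed reading),
#'   `donor_dinuc`, `acceptor_dinuc`, `canonical`. Zero rows for a
#'   single-exon chain.
#' @export
annotate_junctions <- function(chain, genome) {
  ex <- chain$exons
  n <- nrow(ex)
  empty <- data.frame(transcript_id = character(), intron = integer(),
                      chrom = character(), donor_pos = integer(),
                      acceptor_pos = integer(), donor_dinuc = character(),
                      acceptor_dinuc = character(), canonical = logical(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  g <- seq_of(genome, chain$chrom)
  if (max(ex$end) > nchar(g)) stop("chain exceeds chromosome bounds")
  rows <- lapply(seq_len(n - 1L), function(i) {
    i_start <- ex$end[i]          # 0-based intron bounds on forward genome
    i_end <- ex$start[i + 1L]
    if (chain$strand == "+") {
      don <- substr(g, i_start + 1L, i_start + 2L)
      acc <- substr(g, i_end - 1L, i_end)
      dp <- i_start; ap <- i_end - 1L
    } else {
      don <- reverse_complement(substr(g, i_end - 1L, i_end))
      acc <- reverse_complement(substr(g, i_start + 1L, i_start + 2L))
      dp <- i_end - 1L; ap <- i_start
    }
    data.frame(transcript_id = chain$transcript_id, intron = NA_integer_,
               chrom = chain$chrom, donor_pos = dp, acceptor_pos = ap,
               donor_dinuc = don, acceptor_dinuc = acc,
               canonical = don == "GT" && acc == "AG",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (chain$strand == "-") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  out$intron <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the master exon catalog of a locus
#'
#' Union of the distinct exon intervals of a chain set sharing one locus,
#' ordered by genomic start (then end) and labelled `e1, e2, ...`.
#' Identical intervals are merged; overlapping-but-unequal intervals stay
#' distinct, since they encode alternative splice sites.
#'
#' @param chains list of [exon_chain()]s on one chromosome.
#' @return data.frame `label`, `start`, `end`.
#' @export
build_exon_catalog <- function(chains) {
  chroms <- unique(vapply(chains, `[[`, character(1), "chrom"))
  if (length(chroms) != 1L)
    stop("chains on different chromosomes: ", paste(chroms, collapse = ", "))
  iv <- unique(do.call(rbind, lapply(chains, `[[`, "exons")))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  data.frame(label = paste0("e", seq_len(nrow(iv))),
             start = iv$start, end = iv$end, stringsAsFactors = FALSE)
}

#' Classify splicing-event differences between two isoforms
#'
#' Decomposes the symmetric difference of two exon chains into elementary
#' events, greedily over genomic order: intron retention (one chain's exon
#' spans the other's exon-intron-exon), boundary shifts on shared exons
#' (donor side: alternative 5' splice site; acceptor side: alternative 3';
#' both: complex), exon skipping (internal exon absent with flanks intact),
#' mutually exclusive exons (adjacent catalog exons, one per chain, shared
#' flanks), with any residual difference reported as one complex event.
#' Differences at the outermost transcript ends that do not move an intron
#' boundary are reported as `end_variation`, outside the six categories
#' (fixed amplification primers pin transcript ends, so these are not
#' splicing events).
#'
#' @param a,b [exon_chain()]s on the same locus.
#' @param catalog exon catalog from [build_exon_catalog()] covering both
#'   chains (used for mutually-exclusive adjacency).
#' @return data.frame `isoform_a`, `isoform_b`, `event_type`, `exons`
#'   (involved intervals as `start-end` strings); zero rows for
#'   structurally identical chains.
#' @export
classify_events <- function(a, b, catalog) {
  if (a$chrom != b$chrom)
    stop("chains from different loci: ", a$chrom, " vs ", b$chrom)
  evt <- function(type, ivs) data.frame(
    isoform_a = a$transcript_id, isoform_b = b$transcript_id,
    event_type = type,
    exons = paste(sprintf("%d-%d", ivs$start, ivs$end), collapse = ","),
    stringsAsFactors = FALSE)
  A <- a$exons; B <- b$exons
  keyA <- sprintf("%d-%d", A$start, A$end)
  keyB <- sprintf("%d-%d", B$start, B$end)
  onlyA <- A[!(keyA %in% keyB), , drop = FALSE]
  onlyB <- B[!(keyB %in% keyA), , drop = FALSE]
  events <- list()
  drop_row <- function(df, row) df[!(df$start == row$start &
                                       df$end == row$end), , drop = FALSE]

  # intron retention: exon of one chain == two adjacent exons of the other
  for (side in 1:2) {
    X <- if (side == 1) onlyA else onlyB
    other <- if (side == 1) B else A
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      jj <- which(other$start == x$start)
      if (!length(jj) || jj == nrow(other)) next
      if (other$end[jj + 1L] == x$end &&
          other$end[jj] < other$start[jj + 1L]) {
        events[[length(events) + 1L]] <-
          evt("intron_retention", rbind(x, other[jj:(jj + 1L), ]))
        if (side == 1) {
          onlyA <- drop_row(onlyA, x)
          onlyB <- drop_row(onlyB, other[jj, ])
          onlyB <- drop_row(onlyB, other[jj + 1L, ])
        } else {
          onlyB <- drop_row(onlyB, x)
          onlyA <- drop_row(onlyA, other[jj, ])
          onlyA <- drop_row(onlyA, other[jj + 1L, ])
        }
      }
    }
  }

  # boundary shifts on overlapping exon pairs
  if (nrow(onlyA) && nrow(onlyB)) {
    for (i in rev(seq_len(nrow(onlyA)))) {
      x <- onlyA[i, ]
      ov <- which(onlyB$start < x$end & onlyB$end > x$start)
      if (length(ov) != 1L) next
      y <- onlyB[ov, ]
      first_x <- x$start == min(A$start) && y$start == min(B$start)
      last_x <- x$end == max(A$end) && y$end == max(B$end)
      type <- NULL
      if (x$start == y$start && x$end != y$end) {
        type <- if (last_x) "end_variation" else
          if (a$strand == "+") "alt_5ss" else "alt_3ss"
      } else if (x$end == y$end && x$start != y$start) {
        type <- if (first_x) "end_variation" else
          if (a$strand == "+") "alt_3ss" else "alt_5ss"
      } else {
        type <- "complex"
      }
      events[[length(events) + 1L]] <- evt(type, rbind(x, y))
      onlyA <- drop_row(onlyA, x)
      onlyB <- drop_row(onlyB, y)
    }
  }

  # mutually exclusive: adjacent catalog exons, one per chain, shared flanks
  if (nrow(onlyA) && nrow(onlyB)) {
    ckey <- sprintf("%d-%d", catalog$start, catalog$end)
    for (i in rev(seq_len(nrow(onlyA)))) {
      x <- onlyA[i, ]
      for (j in seq_len(nrow(onlyB))) {
        y <- onlyB[j, ]
        ci <- match(sprintf("%d-%d", x$start, x$end), ckey)
        cj <- match(sprintf("%d-%d", y$start, y$end), ckey)
        if (is.na(ci) || is.na(cj) || abs(ci - cj) != 1L) next
        if (mxe_flanks(x, y, A, B)) {
          events[[length(events) + 1L]] <- evt("mutually_exclusive",
                                               rbind(x, y))
          onlyA <- drop_row(onlyA, x)
          onlyB <- drop_row(onlyB, y)
          break
        }
      }
    }
  }

  # exon skipping: internal exon with intact flanks, absent from the other
  for (side in 1:2) {
    X <- if (side == 1) onlyA else onlyB
    own <- if (side == 1) A else B
    other <- if (side == 1) B else A
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      pos <- which(own$start == x$start & own$end == x$end)
      if (pos == 1L || pos == nrow(own)) next
      if (shared_flanks(x, own, other)) {
        events[[length(events) + 1L]] <- evt("exon_skipping", x)
        if (side == 1) onlyA <- drop_row(onlyA, x) else
          onlyB <- drop_row(onlyB, x)
      }
    }
  }

  # residual differences: one complex event
  if (nrow(onlyA) || nrow(onlyB))
    events[[length(events) + 1L]] <- evt("complex", rbind(onlyA, onlyB))
  if (!length(events))
    return(data.frame(isoform_a = character(), isoform_b = character(),
                      event_type = character(), exons = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

# Mutually-exclusive flank test: x's neighbours in A equal y's in B.
mxe_flanks <- function(x, y, A, B) {
  px <- which(A$start == x$start & A$end == x$end)
  py <- which(B$start == y$start & B$end == y$end)
  same <- function(i, j, X, Y) {
    inx <- i >= 1L && i <= nrow(X); iny <- j >= 1L && j <= nrow(Y)
    if (inx != iny) return(FALSE)
    !inx || (X$start[i] == Y$start[j] && X$end[i] == Y$end[j])
  }
  same(px - 1L, py - 1L, A, B) && same(px + 1L, py + 1L, A, B)
}

# x's neighbours in `own` are both present and adjacent in `other`.
shared_flanks <- function(x, own, other) {
  pos <- which(own$start == x$start & own$end == x$end)
  okey <- sprintf("%d-%d", other$start, other$end)
  prv <- if (pos > 1L) sprintf("%d-%d", own$start[pos - 1L],
                               own$end[pos - 1L]) else NA
  nxt <- if (pos < nrow(own)) sprintf("%d-%d", own$start[pos + 1L],
                                      own$end[pos + 1L]) else NA
  pi <- if (is.na(prv)) NA_integer_ else match(prv, okey)
  ni <- if (is.na(nxt)) NA_integer_ else match(nxt, okey)
  if (!is.na(prv) && is.na(pi)) return(FALSE)
  if (!is.na(nxt) && is.na(ni)) return(FALSE)
  if (!is.na(pi) && !is.na(ni) && ni != pi + 1L) return(FALSE)
  TRUE
}
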