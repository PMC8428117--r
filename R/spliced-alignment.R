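#' Alignment parameters for near-identical spliced placement
#'
#' The aligner assumes transcripts are near-identical (substitution-only)
#' copies of their loci, as holds for clones of a multi-copy repeat locus;
#' it seeds on maximal exact matches, chains them colinearly, and closes
#' gaps into exon/intron structure with canonical GT..AG placement.
#'
#' @param anchor_k minimum exact-match anchor length.
#' @param min_intron,max_intron allowed intron size range (nt).
#' @param identity_threshold minimum fraction of transcript bases matching
#'   the genome for a placement to be reported.
#' @param boundary_window nt each exon boundary may shift to reach a
#'   canonical GT..AG intron.
#' @param intron_penalty chain score penalty per intron.
#' @param max_loci cap on placements reported per transcript.
#' @return validated parameter list.
#' @export
align_params <- function(anchor_k = 18L, min_intron = 30L,
                         max_intron = 50000L, identity_threshold = 0.97,
                         boundary_window = 10L, intron_penalty = 2,
                         max_loci = 50L) {
  p <- list(anchor_k = as.integer(anchor_k), min_intron = as.integer(min_intron),
            max_intron = as.integer(max_intron),
            identity_threshold = identity_threshold,
            boundary_window = as.integer(boundary_window),
            intron_penalty = intron_penalty, max_loci = as.integer(max_loci))
  if (p$anchor_k < 4L) stop("anchor_k must be >= 4")
  if (p$identity_threshold <= 0 || p$identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (p$min_intron < 1L || p$max_intron < p$min_intron)
    stop("bad intron size range")
  p
}

#' Find maximal exact-match anchors between a transcript and a genome
#'
#' Reports every maximal exact match of length `>= anchor_k` between the
#' transcript (both strands) and every chromosome, as a data.frame of
#' (transcript interval, genome interval) pairs. Transcript coordinates
#' are on the scan strand (the reverse complement for `-` anchors), which
#' keeps chaining colinear in both coordinates.
#'
#' @param transcript single-row sequence record (or plain string).
#' @param genome sequence record set.
#' @param params [align_params()].
#' @return data.frame: `chrom`, `strand`, `t_start`, `t_end`, `g_start`,
#'   `g_end` (0-based half-open), `length`.
#' @export
find_anchors <- function(transcript, genome, params = align_params()) {
  tseq <- if (is.data.frame(transcript)) transcript$seq[1] else transcript
  k <- params$anchor_k
  out <- list()
  if (nchar(tseq) < k) return(empty_anchors())
  for (gi in seq_len(nrow(genome))) {
    gidx <- kmer_index(chars(genome$seq[gi]), k)
    for (strand in c("+", "-")) {
      qs <- if (strand == "-") reverse_complement(tseq) else tseq
      qidx <- kmer_index(chars(qs), k)
      shared <- intersect(names(qidx), names(gidx))
      if (!length(shared)) next
      pairs <- do.call(rbind, lapply(shared, function(km)
        expand.grid(t = qidx[[km]], g = gidx[[km]])))
      d <- pairs$g - pairs$t
      for (dd in unique(d)) {
        tp <- sort(pairs$t[d == dd])
        # consecutive k-mer hits collapse into one maximal exact match
        brk <- c(0L, which(diff(tp) != 1L), length(tp))
        for (b in seq_len(length(brk) - 1L)) {
          t1 <- tp[brk[b] + 1L]; t2 <- tp[brk[b + 1L]]
          out[[length(out) + 1L]] <- data.frame(
            chrom = genome$id[gi], strand = strand,
            t_start = t1 - 1L, t_end = t2 + k - 1L,
            g_start = t1 + dd - 1L, g_end = t2 + dd + k - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_anchors())
  a <- do.call(rbind, out)
  a$length <- a$t_end - a$t_start
  a <- a[order(a$chrom, a$strand, a$g_start, a$t_start, method = "radix"), ]
  rownames(a) <- NULL
  a
}

empty_anchors <- function() {
  data.frame(chrom = character(), strand = character(), t_start = integer(),
             t_end = integer(), g_start = integer(), g_end = integer(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Chain anchors and fill gaps into exon chains
#'
#' Builds colinear anchor chains (dynamic programming maximizing summed
#' anchor length minus `intron_penalty` per intron, ties broken towards the
#' smallest genomic span, which prevents chimeric chains across locus
#' copies), closes inter-anchor gaps either within an exon (equal-length
#' gap, substitutions only) or as an intron of length within
#' `[min_intron, max_intron]`, and slides each intron boundary within
#' `boundary_window` to a canonical GT..AG placement (canonical first, then
#' maximal exon identity, then leftmost). Chains are extracted iteratively
#' (best first, anchors on used genome intervals removed) so that every
#' locus copy above `identity_threshold` is reported.
#'
#' @param anchors anchor data.frame from [find_anchors()] (one transcript).
#' @param transcript single-row sequence record with the transcript.
#' @param genome sequence record set.
#' @param params [align_params()].
#' @return list of [exon_chain()] objects, best score first; empty if no
#'   placement reaches `identity_threshold`.
#' @export
chain_and_fill <- function(anchors, transcript, genome,
                           params = align_params()) {
  tid <- if (is.data.frame(transcript)) transcript$id[1] else "transcript"
  tseq <- if (is.data.frame(transcript)) transcript$seq[1] else transcript
  n <- nchar(tseq)
  chains <- list()
  for (key in unique(paste(anchors$chrom, anchors$strand))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    chrom <- parts[1]; strand <- parts[2]
    sub <- anchors[anchors$chrom == chrom & anchors$strand == strand, ,
                   drop = FALSE]
    qs <- if (strand == "-") reverse_complement(tseq) else tseq
    qv <- chars(qs)
    gv <- chars(seq_of(genome, chrom))
    avail <- rep(TRUE, nrow(sub))
    for (iter in seq_len(params$max_loci)) {
      idx <- which(avail)
      if (!length(idx)) break
      best <- best_chain_dp(sub[idx, , drop = FALSE], params)
      if (is.null(best)) break
      picked <- sub[idx[best], , drop = FALSE]
      ch <- fill_chain(picked, qv, gv, chrom, strand, tid, n, params)
      used <- range(picked$g_start, picked$g_end)
      avail <- avail & !(sub$g_start < used[2] & sub$g_end > used[1])
      if (!is.null(ch) && ch$identity >= params$identity_threshold)
        chains[[length(chains) + 1L]] <- ch
    }
  }
  if (!length(chains)) return(list())
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
               vapply(chains, function(c) c$exons$start[1], integer(1)))
  chains[ord]
}

# DP for the best colinear chain; returns row indices into `a`.
best_chain_dp <- function(a, params) {
  n <- nrow(a)
  if (!n) return(NULL)
  ord <- order(a$t_start, a$g_start)
  a <- a[ord, , drop = FALSE]
  score <- a$length; span <- a$g_end - a$g_start; prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    for (i in seq_len(j - 1L)) {
      dt <- a$t_start[j] - a$t_end[i]
      dg <- a$g_start[j] - a$g_end[i]
      if (dt < 0L || dg < dt) next
      gap <- dg - dt
      pen <- if (gap == 0L) 0 else params$intron_penalty
      if (gap != 0L && (gap < params$min_intron || gap > params$max_intron))
        next
      cand <- score[i] + a$length[j] - pen
      cspan <- (a$g_end[j] - a$g_start[j]) + span[i] + dg
      if (cand > score[j] ||
          (cand == score[j] && cspan < span[j])) {
        score[j] <- cand
        span[j] <- cspan
        prev[j] <- i
      }
    }
  }
  jbest <- which.max(score - span / 1e9)
  path <- jbest
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  ord[path]
}

# Close gaps of a picked anchor chain into exons; returns exon_chain.
#
# Exon boundaries for each intron gap are chosen locally (canonical GT..AG
# first, then maximal fill identity, then leftmost); overall identity is
# then computed in one pass against the spliced genome sequence the chain
# implies, which keeps the accounting exact regardless of how boundaries
# slid into anchors.
fill_chain <- function(a, qv, gv, chrom, strand, tid, tx_len, params) {
  a <- a[order(a$t_start), , drop = FALSE]
  m <- nrow(a)
  G <- length(gv)
  d1 <- a$g_start[1] - a$t_start[1]
  left_clip <- max(0L, -d1)                  # transcript bases off contig
  exon_start <- max(0L, d1)
  exons <- list()
  for (j in seq_len(m - 1L)) {
    dt <- a$t_start[j + 1L] - a$t_end[j]
    dg <- a$g_start[j + 1L] - a$g_end[j]
    if (dg == dt) next                       # same exon, substitutions only
    di <- a$g_end[j] - a$t_end[j]            # left diagonal offset
    dj <- a$g_start[j + 1L] - a$t_start[j + 1L]  # right diagonal offset
    w <- params$boundary_window
    tb_lo <- max(a$t_end[j] - min(w, a$length[j] - 1L), 1L)
    tb_hi <- min(a$t_start[j + 1L] + min(w, a$length[j + 1L] - 1L),
                 tx_len - 1L)
    if (tb_hi < tb_lo) return(NULL)
    tbs <- tb_lo:tb_hi                       # 0-based boundary candidates
    # matched bases across the contested region if the boundary sits at tb:
    # positions < tb map to the left diagonal, >= tb to the right one
    reg <- if (tb_hi > tb_lo) (tb_lo + 1L):tb_hi else integer()  # 1-based
    gl <- pmin(pmax(reg + di, 1L), G); gr <- pmin(pmax(reg + dj, 1L), G)
    ml <- reg + di >= 1L & reg + di <= G & qv[reg] == gv[gl] & qv[reg] != "N"
    mr <- reg + dj >= 1L & reg + dj <= G & qv[reg] == gv[gr] & qv[reg] != "N"
    cum_l <- c(0L, cumsum(ml)); cum_r <- c(0L, cumsum(mr))
    last <- length(cum_r)
    fillm <- cum_l[tbs - tb_lo + 1L] + (cum_r[last] - cum_r[tbs - tb_lo + 1L])
    donor <- tbs + di                        # 0-based first intron base
    accep <- tbs + dj                        # 0-based first base after intron
    okb <- donor >= 0L & accep <= G
    don2 <- paste0(gv[pmin(donor + 1L, G)], gv[pmin(donor + 2L, G)])
    acc2 <- paste0(gv[pmax(accep - 1L, 1L)], gv[pmax(accep, 1L)])
    canon <- okb & if (strand == "+") don2 == "GT" & acc2 == "AG" else
      don2 == "CT" & acc2 == "AC"
    pick_from <- if (any(canon)) which(canon) else which(okb)
    if (!length(pick_from)) return(NULL)
    pick <- pick_from[order(-fillm[pick_from], tbs[pick_from])][1]
    tb <- tbs[pick]
    exons[[length(exons) + 1L]] <- c(exon_start, tb + di)
    exon_start <- tb + dj
  }
  dm <- a$g_end[m] - a$t_end[m]
  right_clip <- max(0L, tx_len + dm - G)
  exons[[length(exons) + 1L]] <- c(exon_start, min(G, tx_len + dm))
  exdf <- as.data.frame(do.call(rbind, exons))
  names(exdf) <- c("start", "end")
  if (any(exdf$end <= exdf$start)) return(NULL)
  spliced <- unlist(lapply(seq_len(nrow(exdf)), function(i)
    gv[(exdf$start[i] + 1L):exdf$end[i]]))
  tx_part <- if (tx_len - right_clip >= left_clip + 1L)
    qv[(left_clip + 1L):(tx_len - right_clip)] else character()
  if (length(spliced) != length(tx_part)) return(NULL)
  matches <- sum(tx_part == spliced & tx_part != "N")
  n_intron <- nrow(exdf) - 1L
  exon_chain(tid, chrom, strand, exdf,
             identity = matches / tx_len,
             score = sum(a$length) - params$intron_penalty * n_intron)
}

#' Align a transcript set to a genome
#'
#' Runs [find_anchors()] and [chain_and_fill()] for every transcript.
#'
#' @param transcripts sequence record set.
#' @param genome sequence record set.
#' @param params [align_params()].
#' @return named list (by transcript id) of chain lists; a transcript with
#'   no placement above threshold maps to an empty list.
#' @export
align_transcripts <- function(transcripts, genome, params = align_params()) {
  out <- vector("list", nrow(transcripts))
  names(out) <- transcripts$id
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, , drop = FALSE]
    out[[i]] <- chain_and_fill(find_anchors(tr, genome, params), tr,
                               genome, params)
  }
  out
}

# Best (first) chain per transcript as a named list, dropping unplaced.
best_chains <- function(chains_by_tx) {
  keep <- vapply(chains_by_tx, length, integer(1)) > 0L
  lapply(chains_by_tx[keep], `[[`, 1L)
}

#' Partition transcripts into shared-locus and multi-locus groups
#'
#' Transcripts whose best placements mutually overlap (same chromosome,
#' overlapping genomic spans, transitively) form one locus group; a
#' transcript is "single-locus" if it has exactly one surviving placement.
#' The per-transcript copy count is its number of surviving chains.
#'
#' @param chains_by_tx output of [align_transcripts()].
#' @return data.frame: `transcript_id`, `n_loci`, `best_identity`,
#'   `locus_group` (integer component id, `NA` if unplaced),
#'   `single_locus` (logical; `NA` if unplaced).
#' @export
assign_locus_groups <- function(chains_by_tx) {
  ids <- names(chains_by_tx)
  n <- length(ids)
  n_loci <- vapply(chains_by_tx, length, integer(1))
  best_id <- vapply(chains_by_tx, function(ch)
    if (length(ch)) ch[[1]]$identity else NA_real_, numeric(1))
  span <- lapply(chains_by_tx, function(ch)
    if (length(ch)) c(ch[[1]]$chrom, chain_span(ch[[1]])) else NULL)
  group <- rep(NA_integer_, n)
  placed <- which(n_loci > 0L)
  if (length(placed)) {
    # union-find over overlapping best placements
    parent <- seq_along(placed)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (x in seq_along(placed)) for (y in seq_len(x - 1L)) {
      a <- span[[placed[x]]]; b <- span[[placed[y]]]
      if (a[1] == b[1] &&
          as.integer(a[2]) < as.integer(b[3]) &&
          as.integer(b[2]) < as.integer(a[3])) {
        ra <- findp(x); rb <- findp(y)
        if (ra != rb) parent[ra] <- rb
      }
    }
    roots <- vapply(seq_along(placed), findp, integer(1))
    group[placed] <- match(roots, unique(roots))
  }
  data.frame(transcript_id = ids, n_loci = n_loci,
             best_identity = best_id, locus_group = group,
             single_locus = ifelse(n_loci > 0L, n_loci == 1L, NA),
             stringsAsFactors = FALSE)
}
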