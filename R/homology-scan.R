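#' Scan parameter sets for short-homology search
#'
#' Two presets mirror the two search regimes used when tracing candidate
#' piRNA target sites: `"deregulated"` (10-16 nt stretches, at most one
#' mismatch -- the regime for UTRs of deregulated genes) and `"utrdb"`
#' (16-30 nt, up to two mismatches -- the regime for a whole UTR database).
#'
#' @param mode `"deregulated"` or `"utrdb"`; sets the defaults below.
#' @param min_len,max_len inclusive length bounds of a reported stretch.
#' @param max_mismatch maximum Hamming mismatches tolerated.
#' @param orientations subset of `c("+/+", "+/-")`: target matches the
#'   query strand directly, or its reverse complement.
#' @param junction_min_overhang minimum nt a junction-spanning match must
#'   extend on each side of an exon-exon boundary.
#' @return list of validated scan parameters.
#' @export
scan_params <- function(mode = c("deregulated", "utrdb"),
                        min_len = NULL, max_len = NULL, max_mismatch = NULL,
                        orientations = c("+/+", "+/-"),
                        junction_min_overhang = 1L) {
  mode <- match.arg(mode)
  def <- if (mode == "deregulated") list(10L, 16L, 1L) else list(16L, 30L, 2L)
  p <- list(mode = mode,
            min_len = as.integer(min_len %||% def[[1]]),
            max_len = as.integer(max_len %||% def[[2]]),
            max_mismatch = as.integer(max_mismatch %||% def[[3]]),
            orientations = orientations,
            junction_min_overhang = as.integer(junction_min_overhang))
  if (p$min_len > p$max_len) stop("min_len > max_len")
  if (p$max_mismatch < 0L) stop("max_mismatch < 0")
  if (!all(p$orientations %in% c("+/+", "+/-")) || !length(p$orientations))
    stop("orientations must be a non-empty subset of {+/+, +/-}")
  if (p$junction_min_overhang < 1L) stop("junction_min_overhang < 1")
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Maximal windows with <= k mismatches along one diagonal.
#
# mm: logical mismatch vector along the overlapping stretch of a diagonal.
# Returns a matrix with columns (start, end, mismatches), 1-based inclusive
# relative to mm. A window is reported iff its length lies in
# [min_len, max_len] and no 1-nt extension keeps both the mismatch budget
# and the length cap (the maximality rule).
#
# Every maximal window is right-maximal, i.e. of the form [i, j*(i)] with
# j*(i) = min(f(i), i + max_len - 1) where f(i) is the largest j keeping
# <= k mismatches; so enumerating left endpoints suffices.
diag_maximal_windows <- function(mm, min_len, max_len, k) {
  L <- length(mm)
  if (L < min_len) return(NULL)
  cs <- c(0L, cumsum(mm))                 # cs[j+1] = mismatches in 1..j
  i <- seq_len(L)
  f <- findInterval(cs[i] + k + 0.5, cs[-1])   # largest j with budget kept
  jstar <- pmin(f, i + max_len - 1L)
  len <- jstar - i + 1L
  ok <- len >= min_len
  if (!any(ok)) return(NULL)
  i <- i[ok]; jstar <- jstar[ok]; len <- len[ok]
  # left extension of [i, j*]: needs room, budget and length cap
  lext <- i > 1L & (len + 1L) <= max_len &
    (cs[jstar + 1L] - cs[pmax(i - 1L, 1L)]) <= k
  i <- i[!lext]; jstar <- jstar[!lext]
  if (!length(i)) return(NULL)
  cbind(start = i, end = jstar, mismatches = cs[jstar + 1L] - cs[i])
}

# Mismatch vector of the diagonal with offset d (t_index = q_index + d),
# given character vectors qv, tv. Returns list(q0 = first query index,
# mm = logical vector) or NULL if the overlap is empty.
diag_mismatch <- function(qv, tv, d) {
  n <- length(qv); m <- length(tv)
  lo <- max(1L, 1L - d); hi <- min(n, m - d)
  if (hi < lo) return(NULL)
  qs <- qv[lo:hi]; ts <- tv[(lo + d):(hi + d)]
  list(q0 = lo, mm = qs != ts | qs == "N" | ts == "N")
}

# Windows -> hit rows in original query coordinates (0-based half-open).
diag_windows_to_hits <- function(win, q0, d, n, orientation) {
  qs1 <- q0 + win[, "start"] - 1L          # 1-based query start (scan strand)
  qe1 <- q0 + win[, "end"] - 1L            # 1-based query end
  ts0 <- qs1 + d - 1L                      # 0-based target start
  te0 <- qe1 + d
  if (orientation == "+/-") {              # map back from revcomp(query)
    tmp <- n - qe1
    qe1 <- n - qs1 + 1L
    qs1 <- tmp + 1L
  }
  data.frame(q_start = qs1 - 1L, q_end = qe1,
             t_start = ts0, t_end = te0,
             mismatches = unname(win[, "mismatches"]),
             stringsAsFactors = FALSE)
}

scan_pair_diagonals <- function(qv, tv, diags, params, orientation, n_query) {
  out <- vector("list", length(diags))
  for (ii in seq_along(diags)) {
    dm <- diag_mismatch(qv, tv, diags[ii])
    if (is.null(dm)) next
    win <- diag_maximal_windows(dm$mm, params$min_len, params$max_len,
                                params$max_mismatch)
    if (is.null(win)) next
    out[[ii]] <- diag_windows_to_hits(win, dm$q0, diags[ii], n_query,
                                      orientation)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Positions (1-based) of every w-mer of s, keyed by w-mer string.
kmer_index <- function(sv, w) {
  L <- length(sv)
  if (L < w) return(list())
  n <- L - w + 1L
  km <- substring(paste(sv, collapse = ""), seq_len(n), seq_len(n) + w - 1L)
  split(seq_len(n), km)
}

#' Find short mismatch-tolerant homology stretches
#'
#' Reports every *maximal* pair of equal-length substrings (query vs target
#' for `+/+`, reverse-complemented query vs target for `+/-`) whose Hamming
#' distance is at most `max_mismatch` and whose length lies in
#' `[min_len, max_len]`. Maximal means no 1-nt extension on either side
#' stays within both the mismatch budget and the length cap.
#'
#' The search seeds on exact `floor(min_len / (max_mismatch + 1))`-mers
#' (pigeonhole: every reportable stretch contains such an exact word), then
#' extends along the implied diagonals. [scan_homology_naive()] is the
#' brute-force reference implementation of the same definition.
#'
#' @param queries,targets sequence record sets ([seq_set()]).
#' @param params scan parameters from [scan_params()].
#' @return data.frame of hits: `query_id`, `q_start`, `q_end` (0-based
#'   half-open on the query's own strand), `target_id`, `t_start`, `t_end`,
#'   `orientation`, `length`, `mismatches`, ordered by
#'   (query_id, q_start, target_id, t_start, orientation). For `+/-` hits,
#'   `hamming(reverse_complement(query substring), target substring)` equals
#'   `mismatches`.
#' @export
scan_homology <- function(queries, targets, params = scan_params()) {
  w <- max(3L, params$min_len %/% (params$max_mismatch + 1L))
  tchars <- lapply(targets$seq, chars)
  tidx <- lapply(tchars, kmer_index, w = w)
  res <- list()
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$seq[qi]
    n <- nchar(qseq)
    if (n < params$min_len) next
    for (orient in params$orientations) {
      qs <- if (orient == "+/-") reverse_complement(qseq) else qseq
      qv <- chars(qs)
      qidx <- kmer_index(qv, w)
      for (ti in seq_len(nrow(targets))) {
        shared <- intersect(names(qidx), names(tidx[[ti]]))
        if (!length(shared)) next
        diags <- unique(unlist(lapply(shared, function(km) {
          as.vector(outer(tidx[[ti]][[km]], qidx[[km]], "-"))
        }), use.names = FALSE))
        hits <- scan_pair_diagonals(qv, tchars[[ti]], diags, params,
                                    orient, n)
        if (is.null(hits)) next
        hits$query_id <- queries$id[qi]
        hits$target_id <- targets$id[ti]
        hits$orientation <- orient
        res[[length(res) + 1L]] <- hits
      }
    }
  }
  finish_hits(res)
}

#' Brute-force reference scanner
#'
#' Enumerates all diagonals of every query/target pair and checks the hit
#' definition window-by-window. Used as the in-tree correctness oracle for
#' [scan_homology()]; identical output contract.
#'
#' @inheritParams scan_homology
#' @return same as [scan_homology()].
#' @export
scan_homology_naive <- function(queries, targets, params = scan_params()) {
  res <- list()
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$seq[qi]
    n <- nchar(qseq)
    if (n < params$min_len) next
    for (orient in params$orientations) {
      qs <- if (orient == "+/-") reverse_complement(qseq) else qseq
      qv <- chars(qs)
      for (ti in seq_len(nrow(targets))) {
        tv <- chars(targets$seq[ti])
        m <- length(tv)
        hits <- list()
        for (d in seq.int(1L - n, m - 1L)) {
          dm <- diag_mismatch(qv, tv, d)
          if (is.null(dm)) next
          win <- naive_windows(dm$mm, params)
          if (is.null(win)) next
          hits[[length(hits) + 1L]] <-
            diag_windows_to_hits(win, dm$q0, d, n, orient)
        }
        if (!length(hits)) next
        hits <- do.call(rbind, hits)
        hits$query_id <- queries$id[qi]
        hits$target_id <- targets$id[ti]
        hits$orientation <- orient
        res[[length(res) + 1L]] <- hits
      }
    }
  }
  finish_hits(res)
}

# Literal check of the hit definition on one diagonal: every (start, len)
# window is tested for budget, length bounds and non-extendability.
naive_windows <- function(mm, params) {
  L <- length(mm)
  k <- params$max_mismatch
  cs <- c(0L, cumsum(mm))
  nmm <- function(i, j) cs[j + 1L] - cs[i]   # mismatches in [i, j]
  out <- list()
  for (i in seq_len(L)) {
    for (len in params$min_len:params$max_len) {
      j <- i + len - 1L
      if (j > L) break
      if (nmm(i, j) > k) next
      ext_left <- i > 1L && len + 1L <= params$max_len && nmm(i - 1L, j) <= k
      ext_right <- j < L && len + 1L <= params$max_len && nmm(i, j + 1L) <= k
      if (ext_left || ext_right) next
      out[[length(out) + 1L]] <- c(start = i, end = j,
                                   mismatches = nmm(i, j))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

finish_hits <- function(res) {
  cols <- c("query_id", "q_start", "q_end", "target_id", "t_start", "t_end",
            "orientation", "length", "mismatches")
  if (!length(res)) {
    return(data.frame(query_id = character(), q_start = integer(),
                      q_end = integer(), target_id = character(),
                      t_start = integer(), t_end = integer(),
                      orientation = character(), length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, res)
  h$length <- h$q_end - h$q_start
  h <- h[cols]
  h <- h[order(h$query_id, h$q_start, h$target_id, h$t_start, h$orientation,
               method = "radix"), ]
  rownames(h) <- NULL
  h
}

#' Classify hits as exonic or exon-junction-spanning
#'
#' A hit is junction-spanning iff its query (transcript-coordinate)
#' interval covers at least one exon-exon boundary with at least
#' `junction_min_overhang` nt on each side; such a match can only exist in
#' the spliced RNA, not in the genome.
#'
#' @param hits hit data.frame from [scan_homology()].
#' @param chains named list of exon chains (see [chain_and_fill()]), one
#'   per query transcript; only exon widths in transcript order are used.
#'   Single-exon transcripts make every hit exonic.
#' @param junction_min_overhang minimum overhang (nt) on each side.
#' @return `hits` with a `location` column (`"exonic"` or `"junction"`).
#' @export
classify_location <- function(hits, chains, junction_min_overhang = 1L) {
  if (!nrow(hits)) {
    hits$location <- character()
    return(hits)
  }
  loc <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ch <- chains[[hits$query_id[i]]]
    if (is.null(ch)) stop("no exon chain for query ", hits$query_id[i])
    b <- transcript_boundaries(ch)
    qs <- hits$q_start[i]; qe <- hits$q_end[i]
    loc[i] <- if (length(b) &&
                  any(b - qs >= junction_min_overhang &
                      qe - b >= junction_min_overhang)) "junction" else "exonic"
  }
  hits$location <- loc
  hits
}

#' Exon-exon boundary positions of a chain in transcript coordinates
#'
#' 0-based positions between bases, in transcript order; empty for
#' single-exon chains.
#'
#' @param chain an [exon_chain()].
#' @return integer vector.
#' @export
transcript_boundaries <- function(chain) {
  w <- chain$exons$end - chain$exons$start
  if (chain$strand == "-") w <- rev(w)
  if (length(w) < 2L) return(integer())
  cumsum(w)[-length(w)]
}

#' Collapse hits to unique homologous stretches and summarize
#'
#' Two-step reduction mirroring how a set of raw matches becomes a count of
#' distinct candidate piRNA stretches: (1) overlapping maximal hits of the
#' same query/target/orientation sharing at least half of the shorter
#' query interval are merged, keeping the longer (then lower-mismatch, then
#' leftmost) one; (2) surviving hits are collapsed by identical query-strand
#' substring. A unique stretch is `"junction"` if any member hit is.
#'
#' @param hits classified hits (from [classify_location()]).
#' @param queries sequence record set supplying the query sequences.
#' @return list with `unique` (one row per unique stretch: `stretch`,
#'   `location`, `n_hits`, plus a representative hit's coordinates) and
#'   `summary` (`n_unique_stretches`, `n_exonic`, `n_junction`,
#'   `pct_exonic`, `pct_junction`; percentages to 2 decimals).
#' @export
dedupe_unique_stretches <- function(hits, queries) {
  if (!nrow(hits)) {
    return(list(unique = data.frame(stretch = character(),
                                    location = character(),
                                    n_hits = integer(),
                                    stringsAsFactors = FALSE),
                summary = data.frame(n_unique_stretches = 0L, n_exonic = 0L,
                                     n_junction = 0L, pct_exonic = NA_real_,
                                     pct_junction = NA_real_)))
  }
  hits <- merge_shifted_hits(hits)
  hits$stretch <- substring(queries$seq[match(hits$query_id, queries$id)],
                            hits$q_start + 1L, hits$q_end)
  grp <- split(seq_len(nrow(hits)), hits$stretch)
  uq <- do.call(rbind, lapply(grp, function(ix) {
    rep_i <- ix[which.min(hits$mismatches[ix])]
    data.frame(stretch = hits$stretch[rep_i],
               location = if (any(hits$location[ix] == "junction"))
                 "junction" else "exonic",
               n_hits = length(ix),
               query_id = hits$query_id[rep_i],
               q_start = hits$q_start[rep_i],
               q_end = hits$q_end[rep_i],
               stringsAsFactors = FALSE)
  }))
  uq <- uq[order(uq$stretch, method = "radix"), ]
  rownames(uq) <- NULL
  n <- nrow(uq)
  ne <- sum(uq$location == "exonic")
  nj <- n - ne
  list(unique = uq,
       summary = data.frame(n_unique_stretches = n, n_exonic = ne,
                            n_junction = nj,
                            pct_exonic = round(100 * ne / n, 2),
                            pct_junction = round(100 * nj / n, 2)))
}

# Merge trivially shifted variants of one stretch: same query, target and
# orientation, query intervals overlapping by >= half the shorter one.
merge_shifted_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$query_id, hits$target_id, hits$orientation)
  for (ix in split(seq_len(nrow(hits)), key)) {
    if (length(ix) < 2L) next
    # rank: longer first, then fewer mismatches, then leftmost
    ord <- ix[order(-hits$length[ix], hits$mismatches[ix], hits$q_start[ix])]
    for (a in seq_along(ord)) {
      ia <- ord[a]
      if (!keep[ia]) next
      for (b in seq_along(ord)) {
        ib <- ord[b]
        if (ib == ia || !keep[ib]) next
        ov <- min(hits$q_end[ia], hits$q_end[ib]) -
          max(hits$q_start[ia], hits$q_start[ib])
        if (ov >= 0.5 * min(hits$length[ia], hits$length[ib]) &&
            b > a) keep[ib] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}
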