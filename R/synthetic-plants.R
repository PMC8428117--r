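#' Plant homology stretches into random UTR backgrounds
#'
#' Realizes every [plant_spec()] of the config: a substring of a transcript
#' (or its reverse complement for `+/-`), carrying exactly the requested
#' number of substitutions, written into a random-background UTR at a
#' recorded position. Junction plants straddle a truth exon-exon boundary
#' with at least 1 nt on each side; exonic plants lie within one exon.
#'
#' Ground-truth identifiability is enforced actively: the 1-nt flanks of
#' every plant are set to mismatch the corresponding query extension (so
#' the planted window is maximal), and the background is sanitized --
#' off-truth maximal scan hits are destroyed by point mutations outside all
#' planted regions, iterating scan/mutate until the scanner's unique-stretch
#' table equals the planted truth exactly. See the methods vignette for why
#' this is required for exact-coordinate recovery.
#'
#' @param cfg a [synth_config()].
#' @param transcripts transcript record set from [make_isoform_set()].
#' @param truth_chains named chain list from [make_isoform_set()].
#' @return list with `utrs` (sequence record set) and `truth_hits`
#'   (data.frame in [scan_homology()] hit layout plus `location`).
#' @export
plant_utr_matches <- function(cfg, transcripts, truth_chains) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 2L, plant_utr_matches_impl(cfg, transcripts,
                                                  truth_chains))
}

plant_utr_matches_impl <- function(cfg, transcripts, truth_chains) {
  params <- scan_params(cfg$scan_mode)
  specs <- cfg$planted_hits
  if (length(specs) &&
      max(vapply(specs, `[[`, integer(1), "length")) >
      max(nchar(transcripts$seq)))
    stop("config error: plant longer than any transcript")
  utr_ids <- sprintf("utr%d", seq_len(cfg$n_utrs))

  for (attempt in seq_len(12L)) {
    utrs <- vapply(seq_len(cfg$n_utrs), function(i) rand_dna(cfg$utr_length),
                   character(1))
    names(utrs) <- utr_ids
    protected <- lapply(utrs, function(u) integer())   # 1-based positions
    truth <- list()
    failed <- FALSE
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      ui <- if (is.na(sp$utr_index)) ((si - 1L) %% cfg$n_utrs) + 1L else
        sp$utr_index
      used <- vapply(truth, function(r)
        substr(seq_of(transcripts, r$query_id), r$q_start + 1L, r$q_end),
        character(1))
      pl <- place_one_plant(sp, transcripts, truth_chains, utrs[[ui]],
                            protected[[ui]], params, used)
      if (is.null(pl)) { failed <- TRUE; break }
      utrs[[ui]] <- pl$utr
      protected[[ui]] <- c(protected[[ui]], pl$protect)
      row <- pl$hit
      row$target_id <- utr_ids[ui]
      truth[[length(truth) + 1L]] <- row
    }
    if (failed) next
    truth <- if (length(truth)) do.call(rbind, truth) else empty_truth_hits()
    utr_set <- seq_set(utr_ids, unname(utrs))
    if (!nrow(truth)) return(list(utrs = utr_set, truth_hits = truth))

    clean <- sanitize_background(transcripts, truth_chains, utr_set, truth,
                                 protected, params)
    if (!is.null(clean)) {
      ord <- order(truth$query_id, truth$q_start, truth$target_id,
                   truth$t_start, method = "radix")
      return(list(utrs = clean, truth_hits = truth[ord, , drop = FALSE]))
    }
  }
  stop("could not realize planted hits after 12 attempts; ",
       "try different plant specs or a larger UTR background")
}

empty_truth_hits <- function() {
  data.frame(query_id = character(), q_start = integer(), q_end = integer(),
             target_id = character(), t_start = integer(), t_end = integer(),
             orientation = character(), length = integer(),
             mismatches = integer(), location = character(),
             stringsAsFactors = FALSE)
}

# Place one plant. The realized plant must be locally unique: every
# maximal scan hit falling entirely within the planted region (its
# sub-windows can by chance resemble *other* transcript positions, which
# no background mutation could ever remove) must carry the planted query
# substring itself. Window and insert position are re-drawn until that
# holds; returns NULL if no admissible placement is found.
place_one_plant <- function(sp, transcripts, truth_chains, utr, protect,
                            params, used_strings = character()) {
  L <- sp$length
  m <- nchar(utr)
  cand <- 2:(m - L)                                 # room for both flanks
  # keep >= 4 mutable background bases between protected spans, so no
  # scan window can bridge two plants without a sanitizable free base
  cand <- cand[!vapply(cand, function(p)
    any((p - 5L):(p + L + 4L) %in% protect), logical(1))]
  if (!length(cand)) return(NULL)
  for (try in seq_len(30L)) {
    tx_id <- if (is.na(sp$transcript_id))
      sample(transcripts$id, 1L) else sp$transcript_id
    txseq <- seq_of(transcripts, tx_id)
    qv <- chars(txseq)
    n <- length(qv)
    b <- transcript_boundaries(truth_chains[[tx_id]])
    qs <- pick_query_start(sp$location, L, n, b)
    if (is.null(qs)) next
    qe <- qs + L
    window <- substr(txseq, qs + 1L, qe)
    if (window %in% used_strings) next    # planted stretches must be distinct
    sub <- if (sp$orientation == "+/-") reverse_complement(window) else window
    sv <- chars(sub)
    if (sp$mismatches > 0L) {
      # interior positions only: a 1-nt-shifted frame then always retains
      # every planted mismatch and adds a flank mismatch, overrunning the
      # budget, so no shifted frame can outrank the plant
      k <- params$max_mismatch
      mpos <- sample((k + 1L):(L - k), sp$mismatches)
      sv[mpos] <- other_base(sv[mpos])
    }
    t1 <- sample(cand, 1L)                          # 1-based start in UTR
    uv <- chars(utr)
    uv[t1:(t1 + L - 1L)] <- sv
    # poison flanks so no extension of the planted window can match
    if (sp$orientation == "+/+") {
      if (qs >= 1L) uv[t1 - 1L] <- other_base(qv[qs])
      if (qe < n)   uv[t1 + L]  <- other_base(qv[qe + 1L])
    } else {
      if (qe < n)   uv[t1 - 1L] <- other_base(reverse_complement(qv[qe + 1L]))
      if (qs >= 1L) uv[t1 + L]  <- other_base(reverse_complement(qv[qs]))
    }
    if (!plant_locally_unique(uv, t1, L, transcripts, window, params)) next
    return(list(utr = paste(uv, collapse = ""),
                protect = (t1 - 1L):(t1 + L),
                hit = data.frame(query_id = tx_id, q_start = qs, q_end = qe,
                                 target_id = NA_character_, t_start = t1 - 1L,
                                 t_end = t1 - 1L + L,
                                 orientation = sp$orientation,
                                 length = L, mismatches = sp$mismatches,
                                 location = sp$location,
                                 stringsAsFactors = FALSE)))
  }
  NULL
}

# Screen the plant's immutable span (plant + 1-nt poison flanks) on its
# own: background mutations can never touch it, so every scan window that
# fits inside it must be benign *whatever the surrounding background
# becomes*. Scanning the transcripts against just that segment enumerates
# exactly those windows (any valid inside window has a maximal-in-segment
# superwindow). A hit is benign iff it carries the planted substring, or
# it is a shifted variant (same query, orientation, >= half query-interval
# overlap) of a hit that does -- those are collapsed by the merge step and
# can never outrank the plant, whose engineered mismatches sit away from
# the edges. Anything else (an alternative-splice-context window from a
# differently spliced isoform, a chance resemblance to another transcript
# region) forces a re-draw of the plant.
plant_locally_unique <- function(uv, t1, L, transcripts, window, params) {
  lo <- max(1L, t1 - 1L)
  hi <- min(length(uv), t1 + L)
  seg <- seq_set("seg", paste(uv[lo:hi], collapse = ""))
  hits <- scan_homology(transcripts, seg, params)
  if (!nrow(hits)) return(FALSE)                    # plant itself must show
  hits$stretch <- substring(
    transcripts$seq[match(hits$query_id, transcripts$id)],
    hits$q_start + 1L, hits$q_end)
  wins <- hits[hits$stretch == window, , drop = FALSE]
  if (!nrow(wins)) return(FALSE)
  rest <- hits[hits$stretch != window, , drop = FALSE]
  for (i in seq_len(nrow(rest))) {
    ov <- wins$query_id == rest$query_id[i] &
      wins$orientation == rest$orientation[i] &
      (pmin(wins$q_end, rest$q_end[i]) - pmax(wins$q_start, rest$q_start[i])) >=
      0.5 * pmin(wins$length, rest$length[i])
    if (!any(ov)) return(FALSE)
  }
  TRUE
}

# 0-based query start respecting the requested exonic/junction location.
pick_query_start <- function(location, L, n, boundaries) {
  if (location == "exonic") {
    seg <- cbind(start = c(0L, boundaries), end = c(boundaries, n))
    seg <- seg[seg[, "end"] - seg[, "start"] >= L, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    i <- sample(nrow(seg), 1L)
    lo <- seg[i, "start"]; hi <- seg[i, "end"] - L
    if (hi < lo) return(NULL)
    sample(lo:hi, 1L)
  } else {
    if (!length(boundaries)) return(NULL)
    bb <- sample(boundaries, 1L)
    lo <- max(0L, bb - L + 1L); hi <- min(n - L, bb - 1L)
    if (hi < lo) return(NULL)
    sample(lo:hi, 1L)
  }
}

# Iteratively mutate off-truth hit windows in the UTR background until the
# scanner's deduped output equals the planted truth. Returns the clean UTR
# record set, or NULL if an off-truth hit cannot be destroyed (its window
# lies entirely inside planted regions).
sanitize_background <- function(transcripts, truth_chains, utr_set, truth,
                                protected, params) {
  exp_unique <- expected_unique(truth, transcripts)
  for (round in seq_len(40L)) {
    hits <- scan_homology(transcripts, utr_set, params)
    hits <- classify_location(hits, truth_chains, params$junction_min_overhang)
    if (truth_recovered(truth, hits)) {
      dd <- dedupe_unique_stretches(hits, transcripts)
      got <- dd$unique[, c("stretch", "location")]
      got <- got[order(got$stretch, method = "radix"), ]
      if (nrow(got) == nrow(exp_unique) &&
          all(got$stretch == exp_unique$stretch) &&
          all(got$location == exp_unique$location))
        return(utr_set)
    }
    merged <- merge_shifted_hits(hits)
    merged$stretch <- substring(
      transcripts$seq[match(merged$query_id, transcripts$id)],
      merged$q_start + 1L, merged$q_end)
    bad <- merged[!(merged$stretch %in% exp_unique$stretch), , drop = FALSE]
    if (!nrow(bad)) return(NULL)   # truth itself missing: replant upstream
    mutated <- FALSE
    for (i in seq_len(nrow(bad))) {
      ui <- match(bad$target_id[i], utr_set$id)
      pos <- (bad$t_start[i] + 1L):bad$t_end[i]          # 1-based
      free <- setdiff(pos, protected[[ui]])
      if (!length(free)) next
      p <- free[which.min(abs(free - mean(pos)))]
      uv <- chars(utr_set$seq[ui])
      uv[p] <- other_base(uv[p])
      utr_set$seq[ui] <- paste(uv, collapse = "")
      mutated <- TRUE
    }
    if (!mutated) return(NULL)
  }
  NULL
}

# Expected unique-stretch table implied by the planted truth.
expected_unique <- function(truth, transcripts) {
  truth$stretch <- substring(
    transcripts$seq[match(truth$query_id, transcripts$id)],
    truth$q_start + 1L, truth$q_end)
  agg <- lapply(split(truth, truth$stretch), function(g) {
    data.frame(stretch = g$stretch[1],
               location = if (any(g$location == "junction")) "junction"
               else "exonic", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out[order(out$stretch, method = "radix"), , drop = FALSE]
}

# Every truth hit present in the scan output with exact coordinates,
# orientation, mismatch count and location.
truth_recovered <- function(truth, hits) {
  if (!nrow(truth)) return(TRUE)
  key <- function(d) paste(d$query_id, d$q_start, d$q_end, d$target_id,
                           d$t_start, d$t_end, d$orientation, d$mismatches,
                           d$location)
  all(key(truth) %in% key(hits))
}

#' Sample piRNA-sized reads from transcripts, plus verified decoys
#'
#' Draws `n_pirna_reads` substrings of the transcripts with lengths uniform
#' in `pirna_length_range`, and `n_decoys` random reads rejection-sampled
#' until neither they nor their reverse complements occur anywhere in the
#' genome or the transcripts (guaranteeing zero placements downstream).
#'
#' @param cfg a [synth_config()].
#' @param transcripts transcript record set.
#' @param genome genome record set (for decoy exclusion).
#' @return list with `reads` (record set) and `truth` (data.frame
#'   `read_id`, `source`, `offset` 0-based, `length`, `is_decoy`).
#' @export
sample_pirna_reads <- function(cfg, transcripts, genome) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 3L, sample_pirna_reads_impl(cfg, transcripts, genome))
}

sample_pirna_reads_impl <- function(cfg, transcripts, genome) {
  rng <- cfg$pirna_length_range
  if (rng[2] > max(nchar(transcripts$seq)))
    stop("config error: pirna length range exceeds transcript length")
  ids <- character(0); seqs <- character(0); truth <- list()
  for (i in seq_len(cfg$n_pirna_reads)) {
    len <- sample(rng[1]:rng[2], 1L)
    ok <- which(nchar(transcripts$seq) >= len)
    ti <- if (length(ok) > 1L) sample(ok, 1L) else ok
    off <- sample(0:(nchar(transcripts$seq[ti]) - len), 1L)
    ids <- c(ids, sprintf("read%03d", i))
    seqs <- c(seqs, substr(transcripts$seq[ti], off + 1L, off + len))
    truth[[length(truth) + 1L]] <-
      data.frame(read_id = ids[length(ids)], source = transcripts$id[ti],
                 offset = off, length = len, is_decoy = FALSE,
                 stringsAsFactors = FALSE)
  }
  haystack <- c(genome$seq, transcripts$seq)
  for (i in seq_len(cfg$n_decoys)) {
    repeat {
      len <- sample(rng[1]:rng[2], 1L)
      cand <- rand_dna(len)
      if (!any(grepl(cand, haystack, fixed = TRUE)) &&
          !any(grepl(reverse_complement(cand), haystack, fixed = TRUE)))
        break
    }
    ids <- c(ids, sprintf("decoy%02d", i))
    seqs <- c(seqs, cand)
    truth[[length(truth) + 1L]] <-
      data.frame(read_id = ids[length(ids)], source = NA_character_,
                 offset = NA_integer_, length = len, is_decoy = TRUE,
                 stringsAsFactors = FALSE)
  }
  list(reads = seq_set(ids, seqs),
       truth = do.call(rbind, truth))
}

#' Generate a replicate qPCR Ct table with a known fold change
#'
#' Emulates a two-group (test vs control) qPCR experiment quantified
#' against a reference gene: the target-gene Ct in the test group is
#' shifted by `-log2(true_fold_change)` cycles relative to control (so the
#' Livak estimate 2^-ddCt recovers `true_fold_change`), the reference gene
#' is unshifted, and Gaussian noise of sd `sd_noise` is added to every
#' well.
#'
#' @param cfg a [synth_config()]; uses `cfg$ct_spec` and `cfg$seed`.
#' @return data.frame with columns `group` (`test`/`control`), `replicate`,
#'   `role` (`target`/`reference`), `ct`.
#' @export
make_ct_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 4L, make_ct_table_impl(cfg))
}

make_ct_table_impl <- function(cfg) {
  sp <- cfg$ct_spec
  shift <- -log2(sp$true_fold_change)
  base_ref <- 20; base_target <- 24
  rows <- expand.grid(replicate = seq_len(sp$n_replicates),
                      role = c("target", "reference"),
                      group = c("control", "test"),
                      stringsAsFactors = FALSE)
  ct <- ifelse(rows$role == "reference", base_ref,
               base_target + ifelse(rows$group == "test", shift, 0))
  ct <- ct + rnorm(nrow(rows), sd = sp$sd_noise)
  data.frame(group = rows$group, replicate = rows$replicate,
             role = rows$role, ct = ct, stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs every generator of the config and writes `genome.fa`,
#' `transcripts.fa`, `utrs.fa`, `reads.fa`, `truth.gff3` (truth exon
#' chains), `truth_hits.tsv`, `truth_events.tsv`, `truth_reads.tsv` and
#' `ct_table.tsv` under `dir`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the in-memory dataset (list with `genome`, `truth`,
#'   `transcripts`, `truth_chains`, `truth_events`, `utrs`, `truth_hits`,
#'   `reads`, `read_truth`, `ct_table`).
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- make_genome(cfg)
  iso <- make_isoform_set(cfg, g)
  pl <- plant_utr_matches(cfg, iso$transcripts, iso$truth_chains)
  rd <- sample_pirna_reads(cfg, iso$transcripts, g$genome)
  ct <- make_ct_table(cfg)
  write_fasta(g$genome, file.path(dir, "genome.fa"))
  write_fasta(iso$transcripts, file.path(dir, "transcripts.fa"))
  write_fasta(pl$utrs, file.path(dir, "utrs.fa"))
  write_fasta(rd$reads, file.path(dir, "reads.fa"))
  write_chains_gff3(iso$truth_chains, file.path(dir, "truth.gff3"))
  write_tsv(pl$truth_hits, file.path(dir, "truth_hits.tsv"))
  write_tsv(iso$truth_events, file.path(dir, "truth_events.tsv"))
  write_tsv(rd$truth, file.path(dir, "truth_reads.tsv"))
  write_tsv(ct, file.path(dir, "ct_table.tsv"))
  invisible(list(genome = g$genome, truth = g$truth,
                 transcripts = iso$transcripts,
                 truth_chains = iso$truth_chains,
                 truth_events = iso$truth_events,
                 utrs = pl$utrs, truth_hits = pl$truth_hits,
                 reads = rd$reads, read_truth = rd$truth, ct_table = ct))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
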