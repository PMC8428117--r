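#' Synthetic dataset configuration
#'
#' Describes a ground-truthed toy dataset emulating the study system: a
#' Y-like chromosome carrying several mutated copies of a spliced ncRNA
#' locus, an isoform set spanning all six alternative-splicing event
#' classes with canonical GT..AG introns, UTR sets with planted 10-16 nt
#' homology stretches, piRNA-sized reads sampled from the transcripts plus
#' verified decoys, and replicate qPCR Ct tables with a known fold change.
#'
#' The locus carries engineered alternative splice sites so that every
#' event class yields canonical junctions: exon 2 holds an internal `GT`
#' 12 nt before its end (alternative donor) and an internal `AG` 12 nt
#' after its start (used by the two-boundary "complex" variant), exon
#' `K-1` holds an internal `AG` (alternative acceptor, 12 nt in);
#' exons 3 and 4 are a mutually exclusive pair (the
#' reference isoform carries exon 3 and never exon 4); the intron between
#' the last two exons is the retention site. Every exon starts and ends
#' with a non-`G` base so that maximal exact anchors terminate exactly at
#' the GT..AG boundaries, keeping the generator's exon chains exactly
#' recoverable by the aligner.
#'
#' @param seed integer RNG seed; every generator is a pure function of
#'   (config, seed).
#' @param n_locus_copies genomic copies of the locus on the main chromosome.
#' @param copy_mutation_rate per-base substitution probability applied to
#'   copies 2..n (copy 1 is the reference locus the truth chains refer to).
#' @param exon_lengths integer vector (>= 6 exons, each >= 30 nt).
#' @param intron_lengths integer vector of `length(exon_lengths) - 1`
#'   intron sizes, each >= 30 nt.
#' @param n_isoforms number of transcripts including the reference isoform.
#' @param event_mix named proportions over the six event classes
#'   `skip`, `alt5`, `alt3`, `mxe`, `intron_retention`, `complex`.
#' @param n_utrs,utr_length UTR count and length for the homology targets.
#' @param planted_hits list of [plant_spec()] objects; default plants 8
#'   exonic and 2 junction stretches mixing lengths, orientations and
#'   mismatch counts.
#' @param scan_mode scan parameter preset the plants are designed for.
#' @param pirna_length_range inclusive read-length range, within 18-40 nt.
#' @param n_pirna_reads,n_decoys transcript-derived read and decoy counts.
#' @param ct_spec list `(true_fold_change, sd_noise, n_replicates)` for the
#'   Ct table generator.
#' @param chrom_main,chrom_decoy chromosome names.
#' @param spacer_length random sequence between locus copies.
#' @param decoy_chrom_length decoy chromosome length.
#' @return validated config list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_locus_copies = 3L,
                         copy_mutation_rate = 0.01,
                         exon_lengths = c(72L, 58L, 50L, 54L, 61L, 66L),
                         intron_lengths = c(46L, 39L, 35L, 42L, 51L),
                         n_isoforms = 7L,
                         event_mix = c(skip = 1, alt5 = 1, alt3 = 1, mxe = 1,
                                       intron_retention = 1, complex = 1) / 6,
                         n_utrs = 4L,
                         utr_length = 120L,
                         planted_hits = default_plants(),
                         scan_mode = "deregulated",
                         pirna_length_range = c(22L, 35L),
                         n_pirna_reads = 30L,
                         n_decoys = 5L,
                         ct_spec = list(true_fold_change = 1 / 3,
                                        sd_noise = 0.2, n_replicates = 4L),
                         chrom_main = "chrY_synth",
                         chrom_decoy = "chr1_synth",
                         spacer_length = 60L,
                         decoy_chrom_length = 300L) {
  cfg <- list(seed = as.integer(seed), n_locus_copies = as.integer(n_locus_copies),
              copy_mutation_rate = copy_mutation_rate,
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              n_isoforms = as.integer(n_isoforms), event_mix = event_mix,
              n_utrs = as.integer(n_utrs), utr_length = as.integer(utr_length),
              planted_hits = planted_hits, scan_mode = scan_mode,
              pirna_length_range = as.integer(pirna_length_range),
              n_pirna_reads = as.integer(n_pirna_reads),
              n_decoys = as.integer(n_decoys), ct_spec = ct_spec,
              chrom_main = chrom_main, chrom_decoy = chrom_decoy,
              spacer_length = as.integer(spacer_length),
              decoy_chrom_length = as.integer(decoy_chrom_length))
  if (length(cfg$exon_lengths) < 6L)
    stop("config error: need at least 6 exons (event sites are exons 2, 3/4 and K-1)")
  if (length(cfg$intron_lengths) != length(cfg$exon_lengths) - 1L)
    stop("config error: need one intron fewer than exons")
  if (any(cfg$exon_lengths < 30L)) stop("config error: exons must be >= 30 nt")
  if (any(cfg$intron_lengths < 30L)) stop("config error: introns must be >= 30 nt")
  if (abs(sum(cfg$event_mix) - 1) > 1e-8)
    stop("config error: event_mix proportions must sum to 1")
  if (!all(names(cfg$event_mix) %in% c("skip", "alt5", "alt3", "mxe",
                                       "intron_retention", "complex")))
    stop("config error: unknown event class in event_mix")
  if (cfg$pirna_length_range[1] < 18L || cfg$pirna_length_range[2] > 40L ||
      cfg$pirna_length_range[1] > cfg$pirna_length_range[2])
    stop("config error: pirna_length_range must lie within [18, 40]")
  if (cfg$n_locus_copies < 1L) stop("config error: n_locus_copies < 1")
  if (cfg$copy_mutation_rate < 0 || cfg$copy_mutation_rate > 0.2)
    stop("config error: copy_mutation_rate outside [0, 0.2]")
  if (!is.null(cfg$ct_spec)) {
    if (cfg$ct_spec$true_fold_change <= 0)
      stop("config error: true_fold_change must be > 0")
    if (cfg$ct_spec$sd_noise < 0) stop("config error: sd_noise < 0")
    if (cfg$ct_spec$n_replicates < 2L) stop("config error: n_replicates < 2")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Specification of one planted homology stretch
#'
#' A plant is exactly recoverable by a maximal-hit scanner only if no 1-nt
#' extension can stay within the scan budget, so either `length` must equal
#' the mode's `max_len` or `mismatches` must equal its `max_mismatch`; the
#' constructor enforces this against `mode`.
#'
#' @param length stretch length (10-16 for mode `"deregulated"`, 16-30 for
#'   `"utrdb"`).
#' @param mismatches planted Hamming mismatch count.
#' @param orientation `"+/+"` or `"+/-"`.
#' @param location `"exonic"` or `"junction"` (junction plants straddle an
#'   exon-exon boundary with >= 1 nt on each side).
#' @param utr_index 1-based UTR to receive the plant (`NA` = assign
#'   round-robin).
#' @param transcript_id source transcript (`NA` = random).
#' @param mode scan mode the plant must be identifiable under.
#' @return `plant_spec` list.
#' @export
plant_spec <- function(length, mismatches = 0L, orientation = "+/+",
                       location = "exonic", utr_index = NA_integer_,
                       transcript_id = NA_character_,
                       mode = "deregulated") {
  p <- scan_params(mode)
  length <- as.integer(length); mismatches <- as.integer(mismatches)
  if (length < p$min_len || length > p$max_len)
    stop("plant length outside [", p$min_len, ", ", p$max_len, "]")
  if (mismatches > p$max_mismatch) stop("plant mismatches exceed scan budget")
  if (length != p$max_len && mismatches != p$max_mismatch)
    stop("unidentifiable plant: need length == max_len or mismatches == max_mismatch")
  if (!orientation %in% c("+/+", "+/-")) stop("bad orientation")
  if (!location %in% c("exonic", "junction")) stop("bad location")
  structure(list(length = length, mismatches = mismatches,
                 orientation = orientation, location = location,
                 utr_index = as.integer(utr_index),
                 transcript_id = transcript_id),
            class = "plant_spec")
}

# Default plant mix: 8 exonic + 2 junction, both orientations, 0-1 mismatch.
default_plants <- function() {
  list(plant_spec(16, 0, "+/+", "exonic"),
       plant_spec(12, 1, "+/-", "exonic"),
       plant_spec(14, 1, "+/+", "exonic"),
       plant_spec(16, 0, "+/-", "exonic"),
       plant_spec(11, 1, "+/+", "exonic"),
       plant_spec(16, 1, "+/-", "exonic"),
       plant_spec(13, 1, "+/+", "exonic"),
       plant_spec(15, 1, "+/-", "exonic"),
       plant_spec(16, 0, "+/+", "junction"),
       plant_spec(12, 1, "+/-", "junction"))
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Random base different from each element of `from`.
other_base <- function(from) {
  vapply(from, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# Locus event-site layout given exon count K.
locus_sites <- function(K) {
  list(alt5_exon = 2L, alt3_exon = K - 1L, mxe_pair = c(3L, 4L),
       ir_pair = c(K - 1L, K), delta = 12L,
       reference_exons = setdiff(seq_len(K), 4L),
       skip_candidates = setdiff(2L:(K - 1L), 4L))
}

#' Generate the synthetic genome
#'
#' Builds a main chromosome carrying `n_locus_copies` copies of a base
#' locus (exons interleaved with canonical GT..AG introns, alternative
#' splice sites engineered as described in [synth_config()]), separated by
#' random spacers, plus one random decoy chromosome. Copy 1 is unmutated
#' and is the locus all truth chains refer to; copies 2..n receive random
#' substitutions at `copy_mutation_rate`.
#'
#' @param cfg a [synth_config()].
#' @return list with `genome` (sequence record set of the two chromosomes)
#'   and `truth`: base exon/intron sequences, per-copy locus and exon
#'   intervals (0-based half-open on the main chromosome), and the event
#'   site layout.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!length(cfg$exon_lengths) || !length(cfg$intron_lengths))
    stop("config error: empty exon or intron list")
  with_seed(cfg$seed, make_genome_impl(cfg))
}

make_genome_impl <- function(cfg) {
  K <- length(cfg$exon_lengths)
  sites <- locus_sites(K)
  d <- sites$delta
  exon_seqs <- character(K)
  for (i in seq_len(K)) {
    len <- cfg$exon_lengths[i]
    v <- sample(DNA_BASES, len, replace = TRUE)
    v[1] <- sample(c("A", "C", "T"), 1L)       # non-G termini: anchors stop
    v[len] <- sample(c("A", "C", "T"), 1L)     # exactly at GT..AG boundaries
    if (i == sites$alt5_exon) {
      v[(len - d + 1L):(len - d + 2L)] <- c("G", "T")  # alternative donor
      v[c(d - 1L, d)] <- c("A", "G")                   # acceptor for 'complex'
      v[d + 1L] <- sample(c("A", "C", "T"), 1L)
      v[len - d] <- sample(c("A", "C", "T"), 1L)
    }
    if (i == sites$alt3_exon) {
      v[c(d - 1L, d)] <- c("A", "G")                   # alternative acceptor
      v[d + 1L] <- sample(c("A", "C", "T"), 1L)
    }
    exon_seqs[i] <- paste(v, collapse = "")
  }
  intron_seqs <- vapply(cfg$intron_lengths, function(len) {
    paste0("GT", rand_dna(len - 4L), "AG")
  }, character(1))
  parts <- character(2L * K - 1L)
  parts[seq(1L, 2L * K - 1L, 2L)] <- exon_seqs
  parts[seq(2L, 2L * K - 2L, 2L)] <- intron_seqs
  base_locus <- paste(parts, collapse = "")
  locus_len <- nchar(base_locus)
  exon_local_start <- cumsum(c(0L, head(cfg$exon_lengths, -1L) +
                                 cfg$intron_lengths))
  exon_local <- data.frame(exon = seq_len(K), start = exon_local_start,
                           end = exon_local_start + cfg$exon_lengths)

  copies <- character(cfg$n_locus_copies)
  copies[1] <- base_locus
  if (cfg$n_locus_copies > 1L) {
    for (j in 2:cfg$n_locus_copies) {
      v <- chars(base_locus)
      hit <- runif(locus_len) < cfg$copy_mutation_rate
      if (any(hit)) v[hit] <- other_base(v[hit])
      copies[j] <- paste(v, collapse = "")
    }
  }
  spacers <- vapply(seq_len(cfg$n_locus_copies + 1L),
                    function(i) rand_dna(cfg$spacer_length), character(1))
  main <- paste0(paste0(spacers[seq_len(cfg$n_locus_copies)], copies,
                        collapse = ""), spacers[cfg$n_locus_copies + 1L])
  copy_start <- cfg$spacer_length +
    (seq_len(cfg$n_locus_copies) - 1L) * (locus_len + cfg$spacer_length)
  decoy <- rand_dna(cfg$decoy_chrom_length)
  genome <- seq_set(c(cfg$chrom_main, cfg$chrom_decoy), c(main, decoy))

  exon_tbl <- do.call(rbind, lapply(seq_len(cfg$n_locus_copies), function(j) {
    data.frame(copy = j, exon = exon_local$exon,
               start = copy_start[j] + exon_local$start,
               end = copy_start[j] + exon_local$end)
  }))
  list(genome = genome,
       truth = list(exon_seqs = exon_seqs, intron_seqs = intron_seqs,
                    exon_local = exon_local, locus_length = locus_len,
                    sites = sites,
                    copies = data.frame(copy = seq_len(cfg$n_locus_copies),
                                        start = copy_start,
                                        end = copy_start + locus_len),
                    exons = exon_tbl,
                    chrom_main = cfg$chrom_main,
                    chrom_decoy = cfg$chrom_decoy))
}

#' Generate an isoform set with known splicing events
#'
#' Splices `n_isoforms` transcripts from copy 1 of the locus. The first is
#' the reference isoform (all exons except the mutually exclusive partner,
#' exon 4); each further isoform carries one event drawn from
#' `cfg$event_mix`. Every retained junction is canonical GT..AG by
#' construction.
#'
#' @param cfg a [synth_config()].
#' @param genome_truth output of [make_genome()].
#' @return list with `transcripts` (sequence record set), `truth_chains`
#'   (named list of [exon_chain()]s on the main chromosome) and
#'   `truth_events` (data.frame `isoform`, `event_type`, `detail`).
#' @export
make_isoform_set <- function(cfg, genome_truth) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 1L, make_isoform_set_impl(cfg, genome_truth))
}

make_isoform_set_impl <- function(cfg, genome_truth) {
  tr <- genome_truth$truth
  genome <- genome_truth$genome
  K <- nrow(tr$exon_local)
  s <- tr$sites
  ex1 <- tr$exons[tr$exons$copy == 1L, ]     # copy-1 genomic exon intervals
  exon_iv <- function(i) c(ex1$start[ex1$exon == i], ex1$end[ex1$exon == i])

  ref_exons <- s$reference_exons
  iso_exons <- function(keep, mods = list()) {
    # keep: exon indices; mods: list(exon -> c(start_shift, end_shift)) or
    # "merge" entries c(i, j) handled by caller
    iv <- t(vapply(keep, exon_iv, numeric(2)))
    df <- data.frame(start = iv[, 1], end = iv[, 2])
    for (nm in names(mods)) {
      i <- match(as.integer(nm), keep)
      df$start[i] <- df$start[i] + mods[[nm]][1]
      df$end[i] <- df$end[i] + mods[[nm]][2]
    }
    df[order(df$start), ]
  }

  n_ev <- cfg$n_isoforms - 1L
  if (n_ev < 0L) stop("config error: n_isoforms must be >= 1")
  types <- if (n_ev > 0L)
    sample(names(cfg$event_mix), n_ev, replace = TRUE, prob = cfg$event_mix)
  else character()

  chains <- list()
  events <- list()
  d <- s$delta
  make_chain <- function(id, exdf) exon_chain(id, tr$chrom_main, "+", exdf,
                                              identity = 1, score = NA_real_)
  chains[["isoRef"]] <- make_chain("isoRef", iso_exons(ref_exons))
  for (i in seq_len(n_ev)) {
    id <- sprintf("iso%02d", i)
    ty <- types[i]
    if (ty == "skip") {
      sk <- if (length(s$skip_candidates) > 1L)
        sample(s$skip_candidates, 1L) else s$skip_candidates
      exdf <- iso_exons(setdiff(ref_exons, sk))
      detail <- paste0("skip_e", sk)
    } else if (ty == "alt5") {
      mods <- setNames(list(c(0L, -d)), s$alt5_exon)
      exdf <- iso_exons(ref_exons, mods)
      detail <- paste0("alt5_e", s$alt5_exon, "_minus", d)
    } else if (ty == "alt3") {
      mods <- setNames(list(c(d, 0L)), s$alt3_exon)
      exdf <- iso_exons(ref_exons, mods)
      detail <- paste0("alt3_e", s$alt3_exon, "_plus", d)
    } else if (ty == "mxe") {
      exdf <- iso_exons(sort(c(setdiff(ref_exons, s$mxe_pair[1]),
                               s$mxe_pair[2])))
      detail <- paste0("mxe_e", s$mxe_pair[1], "_to_e", s$mxe_pair[2])
    } else if (ty == "intron_retention") {
      keep <- ref_exons
      exdf <- iso_exons(keep)
      a <- exon_iv(s$ir_pair[1]); b <- exon_iv(s$ir_pair[2])
      exdf <- exdf[!(exdf$start %in% c(a[1], b[1])), , drop = FALSE]
      exdf <- rbind(exdf, data.frame(start = a[1], end = b[2]))
      exdf <- exdf[order(exdf$start), ]
      detail <- paste0("ir_e", s$ir_pair[1], "_e", s$ir_pair[2])
    } else if (ty == "complex") {
      mods <- setNames(list(c(d, -d)), s$alt5_exon)
      exdf <- iso_exons(ref_exons, mods)
      detail <- paste0("complex_e", s$alt5_exon, "_both_boundaries")
    } else stop("unknown event type: ", ty)
    chains[[id]] <- make_chain(id, exdf)
    taxon <- c(skip = "exon_skipping", alt5 = "alt_5ss", alt3 = "alt_3ss",
               mxe = "mutually_exclusive",
               intron_retention = "intron_retention", complex = "complex")
    events[[length(events) + 1L]] <-
      data.frame(isoform = id, event_type = unname(taxon[ty]),
                 detail = detail, stringsAsFactors = FALSE)
  }
  seqs <- vapply(chains, spliced_sequence, character(1), genome = genome)
  list(transcripts = seq_set(names(chains), unname(seqs)),
       truth_chains = chains,
       truth_events = if (length(events)) do.call(rbind, events) else
         data.frame(isoform = character(), event_type = character(),
                    detail = character(), stringsAsFactors = FALSE))
}
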