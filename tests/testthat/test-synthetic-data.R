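test_that("make_genome is deterministic and lays out the requested copies", {
  cfg <- synth_config(seed = 21, n_locus_copies = 5)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(nrow(g1$truth$copies), 5L)
  # copies are disjoint, in order
  cp <- g1$truth$copies
  expect_true(all(cp$start[-1] >= head(cp$end, -1)))
})

test_that("with zero mutation, truth exons read back from the genome exactly", {
  d <- toy_dataset(seed = 22)
  ex <- d$truth$exons[d$truth$exons$copy == 1, ]
  for (i in seq_len(nrow(ex))) {
    expect_identical(
      substr(seq_of(d$genome, d$truth$chrom_main), ex$start[i] + 1, ex$end[i]),
      d$truth$exon_seqs[ex$exon[i]])
  }
})

test_that("isoform constructions realize their event classes", {
  cfg <- synth_config(seed = 23, n_locus_copies = 1, copy_mutation_rate = 0,
                      n_isoforms = 13)
  g <- make_genome(cfg)
  iso <- make_isoform_set(cfg, g)
  expect_identical(nrow(iso$transcripts), 13L)
  k <- nrow(g$truth$exon_local)
  ref <- iso$truth_chains[["isoRef"]]
  expect_identical(nrow(ref$exons), k - 1L)      # MXE partner not in reference
  for (r in seq_len(nrow(iso$truth_events))) {
    ev <- iso$truth_events[r, ]
    ch <- iso$truth_chains[[ev$isoform]]
    if (ev$event_type == "exon_skipping")
      expect_lt(nrow(ch$exons), nrow(ref$exons))
    if (ev$event_type == "intron_retention") {
      # transcript contains the retained intron verbatim
      ir <- g$truth$sites$ir_pair
      intron <- g$truth$intron_seqs[ir[1]]
      expect_true(grepl(intron, seq_of(iso$transcripts, ev$isoform),
                        fixed = TRUE))
    }
    if (ev$event_type == "mutually_exclusive")
      expect_identical(nrow(ch$exons), nrow(ref$exons))
  }
  # every junction of every truth chain is canonical
  juncs <- do.call(rbind, lapply(iso$truth_chains, annotate_junctions,
                                 genome = g$genome))
  expect_true(all(juncs$canonical))
})

test_that("planted hits are recovered exactly and verify by hamming", {
  d <- toy_dataset(seed = 24, n_isoforms = 3)
  pl <- plant_utr_matches(d$cfg, d$transcripts, d$chains)
  th <- pl$truth_hits
  expect_identical(nrow(th), 10L)
  for (i in seq_len(nrow(th))) {
    qsub <- substr(seq_of(d$transcripts, th$query_id[i]),
                   th$q_start[i] + 1, th$q_end[i])
    tsub <- substr(seq_of(pl$utrs, th$target_id[i]),
                   th$t_start[i] + 1, th$t_end[i])
    if (th$orientation[i] == "+/-") qsub <- reverse_complement(qsub)
    expect_identical(hamming(qsub, tsub), th$mismatches[i])
  }
  # scanner recovers each planted hit at exact coordinates
  p <- scan_params(d$cfg$scan_mode)
  h <- classify_location(scan_homology(d$transcripts, pl$utrs, p), d$chains)
  key <- function(x) paste(x$query_id, x$q_start, x$q_end, x$target_id,
                           x$t_start, x$t_end, x$orientation, x$mismatches,
                           x$location)
  expect_true(all(key(th) %in% key(h)))
})

test_that("with zero plants the scanner output equals the oracle's chance hits", {
  cfg <- synth_config(seed = 25, n_locus_copies = 1, copy_mutation_rate = 0,
                      n_isoforms = 2, planted_hits = list())
  g <- make_genome(cfg)
  iso <- make_isoform_set(cfg, g)
  pl <- plant_utr_matches(cfg, iso$transcripts, iso$truth_chains)
  expect_identical(nrow(pl$truth_hits), 0L)
  p <- scan_params("deregulated")
  expect_same_hits(scan_homology(iso$transcripts, pl$utrs, p),
                   scan_homology_naive(iso$transcripts, pl$utrs, p))
})

test_that("plant_spec rejects unidentifiable or out-of-range plants", {
  expect_error(plant_spec(12, 0), "unidentifiable")
  expect_error(plant_spec(9, 1), "outside")
  expect_error(plant_spec(16, 2), "budget")
  expect_silent(plant_spec(16, 0))
  expect_silent(plant_spec(12, 1))
})

test_that("sampled reads trace back to transcripts; decoys never place", {
  d <- toy_dataset(seed = 26)
  rd <- sample_pirna_reads(d$cfg, d$transcripts, d$genome)
  tr <- rd$truth
  rng <- d$cfg$pirna_length_range
  expect_true(all(nchar(rd$reads$seq) >= rng[1] &
                    nchar(rd$reads$seq) <= rng[2]))
  real <- tr[!tr$is_decoy, ]
  for (i in seq_len(nrow(real))) {
    expect_identical(
      substr(seq_of(d$transcripts, real$source[i]), real$offset[i] + 1,
             real$offset[i] + real$length[i]),
      seq_of(rd$reads, real$read_id[i]))
  }
  decoys <- rd$reads[rd$reads$id %in% tr$read_id[tr$is_decoy], , drop = FALSE]
  mp <- map_exact(decoys, d$genome)
  expect_true(all(mp$summary$copy_count == 0L))
})

test_that("Ct generator recovers configured fold changes exactly when noise-free", {
  cfg0 <- synth_config(seed = 27, ct_spec = list(true_fold_change = 1,
                                                 sd_noise = 0, n_replicates = 3))
  ct <- make_ct_table(cfg0)
  expect_identical(length(unique(ct$ct[ct$role == "target"])), 1L)
  expect_identical(livak(ct)$fold_change, 1)
  cfg3 <- synth_config(seed = 27, ct_spec = list(true_fold_change = 1 / 3,
                                                 sd_noise = 0, n_replicates = 4))
  expect_equal(livak(make_ct_table(cfg3))$fold_change, 1 / 3,
               tolerance = 1e-12)
})

test_that("config validation catches bad settings", {
  expect_error(synth_config(event_mix = c(skip = 1, alt5 = 1)), "sum to 1")
  expect_error(synth_config(intron_lengths = c(10L, 40L, 40L, 40L, 40L)),
               "introns")
  expect_error(synth_config(pirna_length_range = c(10, 35)), "18, 40")
  expect_error(synth_config(exon_lengths = c(50L, 50L)), "6 exons")
  expect_error(synth_config(ct_spec = list(true_fold_change = -1,
                                           sd_noise = 0, n_replicates = 4)),
               "true_fold_change")
})

test_that("simulate_dataset writes a complete, parseable dataset", {
  dir <- file.path(tempdir(), "simds")
  d <- simulate_dataset(synth_config(seed = 28, n_isoforms = 3), dir)
  files <- c("genome.fa", "transcripts.fa", "utrs.fa", "reads.fa",
             "truth.gff3", "truth_hits.tsv", "truth_events.tsv",
             "truth_reads.tsv", "ct_table.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  expect_identical(read_fasta(file.path(dir, "genome.fa")), d$genome)
  chains <- read_chains_gff3(file.path(dir, "truth.gff3"))
  expect_identical(length(chains), length(d$truth_chains))
  # GFF3 round-trip preserves exon structure
  got <- chains[[1]]
  want <- d$truth_chains[[got$transcript_id]]
  expect_true(chains_identical(got, want))
  unlink(dir, recursive = TRUE)
})
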