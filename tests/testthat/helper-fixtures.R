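# Shared fixture builders for the test suite. Everything is generated in
# code; no data files are read.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Small mutation-free dataset with exact truth, reused across modules.
toy_dataset <- function(seed = 7, n_isoforms = 4L, n_locus_copies = 1L) {
  cfg <- synth_config(seed = seed, n_locus_copies = n_locus_copies,
                      copy_mutation_rate = 0, n_isoforms = n_isoforms)
  g <- make_genome(cfg)
  iso <- make_isoform_set(cfg, g)
  list(cfg = cfg, genome = g$genome, truth = g$truth,
       transcripts = iso$transcripts, chains = iso$truth_chains,
       events = iso$truth_events)
}

# Minimal two-exon toy: two short exons split by the 11-nt canonical
# intron GTAAGTTTTAG.
two_exon_toy <- function() {
  list(genome = seq_set("chr", paste0("CCGGA", "GTAAGTTTTAG", "TACGT")),
       transcript = seq_set("t1", "CCGGATACGT"),
       params = align_params(anchor_k = 5, min_intron = 5))
}

expect_same_hits <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a, b, ignore_attr = TRUE)
}
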