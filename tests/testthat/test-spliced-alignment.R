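test_that("anchors cover a transcript equal to a genome substring", {
  set.seed(31)
  g <- seq_set("chr", random_dna(400))
  tx <- seq_set("t", substr(g$seq, 101, 180))
  a <- find_anchors(tx, g, align_params())
  fw <- a[a$strand == "+", ]
  expect_identical(nrow(fw), 1L)
  expect_identical(fw$t_start, 0L)
  expect_identical(fw$t_end, 80L)
  expect_identical(fw$g_start, 100L)
})

test_that("the two-exon toy resolves to one chain with the canonical intron", {
  toy <- two_exon_toy()
  a <- find_anchors(toy$transcript, toy$genome, toy$params)
  fw <- a[a$strand == "+", ]
  expect_identical(fw$t_start, c(0L, 5L))
  expect_identical(fw$g_start, c(0L, 16L))
  ch <- chain_and_fill(a, toy$transcript, toy$genome, toy$params)
  expect_identical(length(ch), 1L)
  expect_identical(ch[[1]]$exons$start, c(0L, 16L))
  expect_identical(ch[[1]]$exons$end, c(5L, 21L))
  expect_identical(ch[[1]]$identity, 1)
  j <- annotate_junctions(ch[[1]], toy$genome)
  expect_identical(j$donor_dinuc, "GT")
  expect_identical(j$acceptor_dinuc, "AG")
  expect_true(j$canonical)
})

test_that("a reverse-complemented transcript maps to the minus strand", {
  toy <- two_exon_toy()
  rc <- seq_set("t1", reverse_complement(toy$transcript$seq))
  ch <- chain_and_fill(find_anchors(rc, toy$genome, toy$params), rc,
                       toy$genome, toy$params)
  expect_identical(length(ch), 1L)
  expect_identical(ch[[1]]$strand, "-")
  expect_identical(ch[[1]]$exons, data.frame(start = c(0L, 16L),
                                             end = c(5L, 21L)))
  # the forward-genome GT..AG intron reads CT..AC for a minus-strand
  # transcript, so this junction is correctly non-canonical
  j <- annotate_junctions(ch[[1]], toy$genome)
  expect_identical(j$donor_dinuc, "CT")
  expect_identical(j$acceptor_dinuc, "AC")
  expect_false(j$canonical)
})

test_that("a transcript present at three identical loci yields three chains", {
  d <- toy_dataset(seed = 32, n_isoforms = 2, n_locus_copies = 3)
  al <- align_transcripts(d$transcripts, d$genome, align_params())
  for (id in names(al)) {
    expect_identical(length(al[[id]]), 3L)
    exdf <- lapply(al[[id]], function(c) c$exons$end - c$exons$start)
    expect_identical(exdf[[1]], exdf[[2]])  # identical exon structure
    expect_identical(exdf[[1]], exdf[[3]])
  }
  lg <- assign_locus_groups(al)
  expect_true(all(lg$n_loci == 3L))
  expect_true(all(!lg$single_locus))
})

test_that("chains are exactly the generator truth on mutation-free data", {
  for (seed in c(41, 42, 43)) {
    d <- toy_dataset(seed = seed, n_isoforms = 7)
    al <- align_transcripts(d$transcripts, d$genome, align_params())
    for (id in names(d$chains)) {
      expect_identical(length(al[[id]]), 1L)
      expect_true(chains_identical(al[[id]][[1]], d$chains[[id]]))
      expect_identical(al[[id]][[1]]$identity, 1)
    }
  }
})

test_that("emitted chains shift with genome padding and nothing else", {
  d <- toy_dataset(seed = 33, n_isoforms = 2)
  pad <- 137L
  set.seed(33)
  padded <- d$genome
  padded$seq[1] <- paste0(random_dna(pad), padded$seq[1])
  a1 <- align_transcripts(d$transcripts, d$genome, align_params())
  a2 <- align_transcripts(d$transcripts, padded, align_params())
  for (id in names(a1)) {
    e1 <- a1[[id]][[1]]$exons
    e2 <- a2[[id]][[1]]$exons
    expect_identical(e2$start, e1$start + pad)
    expect_identical(e2$end, e1$end + pad)
  }
})

test_that("unplaced transcripts are reported, not dropped", {
  set.seed(34)
  g <- seq_set("chr", random_dna(500))
  tx <- seq_set(c("hit", "miss"), c(substr(g$seq, 51, 150), random_dna(100)))
  al <- align_transcripts(tx, g, align_params())
  lg <- assign_locus_groups(al)
  expect_identical(lg$transcript_id, c("hit", "miss"))
  expect_identical(lg$n_loci, c(1L, 0L))
  expect_true(is.na(lg$locus_group[2]))
})

test_that("chains below the identity threshold are discarded", {
  set.seed(35)
  g <- seq_set("chr", random_dna(300))
  tx_seq <- substr(g$seq, 101, 200)
  v <- chars(tx_seq)
  mut <- c(10, 30, 50, 70, 90)                 # 5% divergence, 19-nt runs
  for (m in mut) v[m] <- setdiff(c("A", "C", "G", "T"), v[m])[1]
  tx <- seq_set("t", paste(v, collapse = ""))
  expect_identical(length(chain_and_fill(find_anchors(tx, g, align_params()),
                                         tx, g, align_params())), 0L)
  loose <- align_params(identity_threshold = 0.8)
  ch <- chain_and_fill(find_anchors(tx, g, loose), tx, g, loose)
  expect_identical(length(ch), 1L)
  expect_equal(ch[[1]]$identity, 0.95, tolerance = 1e-12)
})
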