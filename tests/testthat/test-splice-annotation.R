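test_that("single-exon chains have no junctions", {
  g <- seq_set("chr", "ACGTACGTACGT")
  ch <- exon_chain("t", "chr", "+", data.frame(start = 0L, end = 12L))
  expect_identical(nrow(annotate_junctions(ch, g)), 0L)
})

test_that("exon catalog merges identical and keeps variant intervals", {
  c1 <- exon_chain("a", "chr", "+",
                   data.frame(start = c(0L, 100L, 200L),
                              end = c(50L, 150L, 250L)))
  c2 <- exon_chain("b", "chr", "+",
                   data.frame(start = c(0L, 200L), end = c(50L, 250L)))
  cat1 <- build_exon_catalog(list(c1, c2))
  expect_identical(nrow(cat1), 3L)
  expect_identical(cat1$label, c("e1", "e2", "e3"))
  # overlapping-but-unequal interval stays distinct (alt splice site)
  c3 <- exon_chain("c", "chr", "+",
                   data.frame(start = c(0L, 100L), end = c(50L, 138L)))
  cat2 <- build_exon_catalog(list(c1, c3))
  expect_identical(nrow(cat2), 4L)
  expect_error(build_exon_catalog(list(
    c1, exon_chain("d", "chr2", "+", data.frame(start = 0L, end = 5L)))),
    "different chromosomes")
})

test_that("identical chains yield no events; roles swap symmetrically", {
  d <- toy_dataset(seed = 51, n_isoforms = 7)
  cat1 <- build_exon_catalog(d$chains)
  ref <- d$chains[["isoRef"]]
  expect_identical(nrow(classify_events(ref, ref, cat1)), 0L)
  for (id in setdiff(names(d$chains), "isoRef")) {
    ab <- classify_events(ref, d$chains[[id]], cat1)
    ba <- classify_events(d$chains[[id]], ref, cat1)
    expect_identical(sort(ab$event_type), sort(ba$event_type))
    expect_identical(ab$isoform_a, rep("isoRef", nrow(ab)))
    expect_identical(ba$isoform_a, rep(id, nrow(ba)))
  }
  expect_error(classify_events(
    ref, exon_chain("x", "other", "+", data.frame(start = 0L, end = 10L)),
    cat1), "different loci")
})

test_that("explicit skip is classified from first principles", {
  e <- data.frame(start = c(0L, 100L, 200L), end = c(50L, 150L, 250L))
  a <- exon_chain("a", "chr", "+", e)
  b <- exon_chain("b", "chr", "+", e[-2, ])
  cat1 <- build_exon_catalog(list(a, b))
  ev <- classify_events(a, b, cat1)
  expect_identical(ev$event_type, "exon_skipping")
  expect_identical(ev$exons, "100-150")
})

test_that("generator events are recovered for every class across seeds", {
  seen <- character()
  for (seed in 61:72) {
    d <- toy_dataset(seed = seed, n_isoforms = 9)
    cat1 <- build_exon_catalog(d$chains)
    ref <- d$chains[["isoRef"]]
    for (r in seq_len(nrow(d$events))) {
      id <- d$events$isoform[r]
      ev <- classify_events(ref, d$chains[[id]], cat1)
      expect_identical(nrow(ev), 1L)
      expect_identical(ev$event_type, d$events$event_type[r])
      seen <- union(seen, ev$event_type)
    }
  }
  # all six classes exercised somewhere in the seed sweep
  expect_setequal(seen, c("exon_skipping", "alt_5ss", "alt_3ss",
                          "mutually_exclusive", "intron_retention",
                          "complex"))
})

test_that("complex plants are never classified as elementary events", {
  for (seed in 81:90) {
    d <- toy_dataset(seed = seed, n_isoforms = 9)
    cx <- d$events$isoform[d$events$event_type == "complex"]
    if (!length(cx)) next
    cat1 <- build_exon_catalog(d$chains)
    for (id in cx) {
      ev <- classify_events(d$chains[["isoRef"]], d$chains[[id]], cat1)
      expect_identical(unique(ev$event_type), "complex")
    }
  }
})

test_that("minus-strand junction annotation reads the transcribed strand", {
  # forward genome carries CT..AC; transcribed (minus) strand reads GT..AG
  g <- seq_set("chr", paste0("AAATT", "CTGGGGGGAC", "CCTAA"))
  ch <- exon_chain("t", "chr", "-", data.frame(start = c(0L, 15L),
                                               end = c(5L, 20L)))
  j <- annotate_junctions(ch, g)
  expect_identical(j$donor_dinuc, "GT")
  expect_identical(j$acceptor_dinuc, "AG")
  expect_true(j$canonical)
})
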