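test_that("identical sequences of max length give one exact hit", {
  set.seed(3)
  s <- random_dna(16)
  h <- scan_homology(seq_set("q", s), seq_set("t", s),
                     scan_params("deregulated", orientations = "+/+"))
  expect_identical(nrow(h), 1L)
  expect_identical(h$length, 16L)
  expect_identical(h$mismatches, 0L)
  expect_identical(h$orientation, "+/+")
})

test_that("a planted reverse-complement 12-mer with one substitution is found", {
  set.seed(4)
  q <- random_dna(60)
  sub <- chars(reverse_complement(substr(q, 20, 31)))
  sub[5] <- setdiff(c("A", "C", "G", "T"), sub[5])[1]
  t <- paste0(random_dna(15), paste(sub, collapse = ""), random_dna(15))
  h <- scan_homology(seq_set("q", q), seq_set("t", t),
                     scan_params("deregulated"))
  pm <- h[h$orientation == "+/-", ]
  expect_gte(nrow(pm), 1L)
  # the planted 12-mer is inside one of the +/- hits, and the hit verifies
  best <- pm[which.max(pm$length), ]
  expect_lte(best$q_start, 19L)
  expect_gte(best$q_end, 31L)
  expect_identical(
    hamming(reverse_complement(substr(q, best$q_start + 1, best$q_end)),
            substr(t, best$t_start + 1, best$t_end)),
    best$mismatches)
})

test_that("scanner equals the brute-force oracle on random pairs", {
  set.seed(5)
  for (i in 1:25) {
    q <- seq_set("q", random_dna(sample(20:160, 1)))
    t <- seq_set("t", random_dna(sample(20:160, 1)))
    for (mode in c("deregulated", "utrdb")) {
      p <- scan_params(mode)
      expect_same_hits(scan_homology(q, t, p), scan_homology_naive(q, t, p))
    }
  }
})

test_that("orientation symmetry: scanning the reverse complement mirrors hits", {
  set.seed(6)
  q <- random_dna(90); t <- random_dna(90)
  p_fw <- scan_params("deregulated", orientations = "+/+")
  p_rc <- scan_params("deregulated", orientations = "+/-")
  a <- scan_homology(seq_set("q", q), seq_set("t", t), p_fw)
  b <- scan_homology(seq_set("q", reverse_complement(q)), seq_set("t", t),
                     p_rc)
  # same target intervals and mismatch multiset
  expect_identical(sort(paste(a$t_start, a$t_end, a$mismatches)),
                   sort(paste(b$t_start, b$t_end, b$mismatches)))
})

test_that("hit counts are monotone in mismatch budget and length window", {
  set.seed(8)
  q <- seq_set("q", random_dna(120)); t <- seq_set("t", random_dna(120))
  n0 <- nrow(scan_homology(q, t, scan_params("deregulated", max_mismatch = 0)))
  n1 <- nrow(scan_homology(q, t, scan_params("deregulated", max_mismatch = 1)))
  expect_gte(n1, n0)
  wide <- nrow(scan_homology(q, t, scan_params("deregulated")))
  narrow <- nrow(scan_homology(q, t, scan_params("deregulated",
                                                 min_len = 12, max_len = 14)))
  expect_gte(wide, narrow)
})

test_that("junction classification follows the overhang rule", {
  # 2-exon chain: boundary at transcript position 120
  chain <- exon_chain("tx", "chr", "+",
                      data.frame(start = c(0L, 500L), end = c(120L, 560L)))
  hit <- data.frame(query_id = "tx", q_start = 110L, q_end = 126L,
                    target_id = "u", t_start = 0L, t_end = 16L,
                    orientation = "+/+", length = 16L, mismatches = 0L)
  expect_identical(classify_location(hit, list(tx = chain))$location,
                   "junction")
  tight <- hit; tight$q_start <- 119L; tight$q_end <- 121L; tight$length <- 2L
  expect_identical(classify_location(tight, list(tx = chain),
                                     junction_min_overhang = 2)$location,
                   "exonic")
  expect_identical(classify_location(tight, list(tx = chain),
                                     junction_min_overhang = 1)$location,
                   "junction")
  # single-exon transcript: always exonic
  single <- exon_chain("tx", "chr", "+", data.frame(start = 0L, end = 200L))
  expect_identical(classify_location(hit, list(tx = single))$location,
                   "exonic")
  expect_error(classify_location(hit, list(other = chain)), "no exon chain")
})

test_that("deduplication collapses by query substring and summarizes", {
  set.seed(9)
  q <- random_dna(50)
  stretch <- substr(q, 10, 25)   # one max-length 16-mer, three UTRs
  utrs <- seq_set(paste0("u", 1:3), vapply(1:3, function(i)
    paste0(random_dna(12), stretch, random_dna(12)), character(1)))
  p <- scan_params("deregulated", orientations = "+/+")
  h <- scan_homology(seq_set("q", q), utrs, p)
  chain <- exon_chain("q", "chr", "+", data.frame(start = 0L, end = 50L))
  h <- classify_location(h, list(q = chain))
  dd <- dedupe_unique_stretches(h, seq_set("q", q))
  expect_identical(dd$summary$n_unique_stretches, 1L)
  expect_identical(dd$unique$n_hits, 3L)
  expect_identical(dd$summary$pct_exonic, 100)
})

test_that("summary percentages always sum to 100 within 0.01", {
  for (split in list(c(8, 2), c(7, 3), c(1, 2))) {
    n <- sum(split)
    hits <- data.frame(
      query_id = "q", q_start = seq_len(n) * 20L,
      q_end = seq_len(n) * 20L + 12L,
      target_id = paste0("u", seq_len(n)), t_start = 0L, t_end = 12L,
      orientation = "+/+", length = 12L, mismatches = 0L,
      location = rep(c("exonic", "junction"), split))
    q <- seq_set("q", random_dna(20 * n + 40))
    dd <- dedupe_unique_stretches(hits, q)
    expect_lte(abs(dd$summary$pct_exonic + dd$summary$pct_junction - 100),
               0.01)
  }
})

test_that("scan parameter validation rejects bad configs", {
  expect_error(scan_params("deregulated", min_len = 20, max_len = 10),
               "min_len")
  expect_error(scan_params("deregulated", max_mismatch = -1), "max_mismatch")
  expect_error(scan_params("deregulated", orientations = "x"), "orientations")
})
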