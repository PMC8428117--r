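make_ct <- function(test_target, test_ref, ctl_target, ctl_ref) {
  n <- length(test_target)
  data.frame(
    group = rep(c("test", "control"), each = 2 * n),
    replicate = rep(rep(seq_len(n), 2), 2),
    role = rep(rep(c("target", "reference"), each = n), 2),
    ct = c(test_target, test_ref, ctl_target, ctl_ref))
}

test_that("all-equal Cts give fold change 1", {
  ct <- make_ct(rep(20, 3), rep(20, 3), rep(20, 3), rep(20, 3))
  r <- livak(ct)
  expect_identical(r$delta_delta_ct, 0)
  expect_identical(r$fold_change, 1)
  expect_identical(r$fold_reduction, 1)
  expect_identical(r$p_value, 1)           # zero variance, equal means
})

test_that("the closed-form example gives ddCt 2 and fold 0.25", {
  ct <- make_ct(rep(22, 3), rep(20, 3), rep(20, 3), rep(20, 3))
  r <- livak(ct)
  expect_identical(r$delta_delta_ct, 2)
  expect_identical(r$fold_change, 0.25)
  expect_identical(r$fold_reduction, 4)
  expect_true(r$fold_reduction * r$fold_change == 1)
})

test_that("swapping groups returns the reciprocal fold change", {
  set.seed(101)
  ct <- make_ct(rnorm(4, 23), rnorm(4, 20), rnorm(4, 21), rnorm(4, 20))
  a <- livak(ct)
  sw <- ct
  sw$group <- ifelse(ct$group == "test", "control", "test")
  b <- livak(sw)
  expect_equal(a$fold_change * b$fold_change, 1, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
})

test_that("Welch statistics match the hand-written formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- ttest_unpaired(x, y)
  # closed form: means 2 and 5, each variance 1, n = 3
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (2 - 5) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(t_hand, df_hand), tolerance = 1e-12)
  expect_error(ttest_unpaired(1, y), ">= 2")
})

test_that("degenerate variance cases follow the stated conventions", {
  expect_identical(ttest_unpaired(c(1, 1), c(1, 1)),
                   list(t = 0, df = 2, p = 1))
  r <- ttest_unpaired(c(2, 2), c(1, 1))
  expect_identical(r$p, 0)
  expect_identical(r$t, Inf)
})

test_that("unpaired layouts fall back to group means with a warning", {
  ct <- make_ct(rep(22, 3), rep(20, 3), rep(20, 3), rep(20, 3))
  ct$replicate[ct$group == "test" & ct$role == "reference"] <- 4:6
  expect_warning(r <- livak(ct), "group-mean")
  expect_identical(r$fold_change, 0.25)
  expect_true(is.na(r$p_value))
})

test_that("malformed tables are rejected", {
  ct <- make_ct(rep(22, 2), rep(20, 2), rep(20, 2), rep(20, 2))
  bad <- ct[ct$role == "target", ]
  expect_error(livak(bad), "lacks")
  neg <- ct; neg$ct[1] <- -1
  expect_error(livak(neg), "positive")
  expect_error(livak(ct[, 1:3]), "columns")
  f <- tempfile(fileext = ".tsv")
  write.table(ct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(livak(read_ct_table(f))$fold_change, 0.25)
})

test_that("noise-free generator tables recover the fold to machine precision", {
  for (fold in c(1 / 3, 0.5, 2)) {
    cfg <- synth_config(seed = 102, ct_spec = list(true_fold_change = fold,
                                                   sd_noise = 0,
                                                   n_replicates = 4))
    expect_equal(livak(make_ct_table(cfg))$fold_change, fold,
                 tolerance = 1e-12)
  }
})
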