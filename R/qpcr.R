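#' Read a qPCR Ct table
#'
#' Expects a TSV with header columns `group` (`test`/`control`),
#' `replicate`, `role` (`target`/`reference`) and `ct`.
#'
#' @param path TSV file path.
#' @return validated Ct data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
  ct
}

validate_ct_table <- function(ct) {
  need <- c("group", "replicate", "role", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (!all(ct$group %in% c("test", "control")))
    stop("group must be 'test' or 'control'")
  if (!all(ct$role %in% c("target", "reference")))
    stop("role must be 'target' or 'reference'")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("ct values must be positive numbers")
  invisible(ct)
}

#' Relative quantification by the Livak 2^-ddCt method
#'
#' Computes per-replicate dCt = Ct(target) - Ct(reference), group means,
#' ddCt = mean dCt(test) - mean dCt(control), the fold change 2^-ddCt and
#' its reciprocal fold reduction, with an unpaired t-test on the replicate
#' dCt values (Welch by default). Assumes perfect doubling per cycle
#' (amplification efficiency 2), as the method does; no standard-curve
#' correction is applied.
#'
#' When replicate identifiers do not pair target and reference wells
#' within each group (e.g. pooled-cDNA layouts), dCt falls back to group
#' means with a warning and the t-test is suppressed.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param var_equal use Student's pooled-variance t-test instead of Welch.
#' @return object of class `livak_result`: `delta_ct_test`,
#'   `delta_ct_control` (group mean dCt), `delta_delta_ct`, `fold_change`,
#'   `fold_reduction`, `se` (standard error of the dCt difference),
#'   `t`, `df`, `p_value`, `n_test`, `n_control`.
#' @export
livak <- function(ct, var_equal = FALSE) {
  validate_ct_table(ct)
  dct <- list()
  paired <- TRUE
  for (grp in c("test", "control")) {
    g <- ct[ct$group == grp, , drop = FALSE]
    if (!nrow(g)) stop("missing sample group: ", grp)
    reps <- unique(g$replicate)
    ok <- vapply(reps, function(r) {
      sum(g$replicate == r & g$role == "target") == 1L &&
        sum(g$replicate == r & g$role == "reference") == 1L
    }, logical(1))
    if (all(ok)) {
      tg <- g[g$role == "target", ]
      rf <- g[g$role == "reference", ]
      dct[[grp]] <- tg$ct[order(tg$replicate)] - rf$ct[order(rf$replicate)]
    } else {
      paired <- FALSE
      if (!any(g$role == "target") || !any(g$role == "reference"))
        stop("group ", grp, " lacks a target or reference role")
      dct[[grp]] <- mean(g$ct[g$role == "target"]) -
        mean(g$ct[g$role == "reference"])
    }
  }
  if (!paired)
    warning("replicate ids do not pair target/reference wells; ",
            "using group-mean dCt, statistics suppressed")
  ddct <- mean(dct$test) - mean(dct$control)
  fold <- 2^(-ddct)
  nt <- length(dct$test); nc <- length(dct$control)
  se <- t <- df <- p <- NA_real_
  if (paired && nt >= 2L && nc >= 2L) {
    se <- sqrt(stats::var(dct$test) / nt + stats::var(dct$control) / nc)
    tt <- ttest_unpaired(dct$test, dct$control, var_equal = var_equal)
    t <- tt$t; df <- tt$df; p <- tt$p
  } else if (paired) {
    warning("fewer than 2 replicates per group; statistics suppressed")
  }
  structure(list(delta_ct_test = mean(dct$test),
                 delta_ct_control = mean(dct$control),
                 delta_delta_ct = ddct, fold_change = fold,
                 fold_reduction = 1 / fold, se = se, t = t, df = df,
                 p_value = p, n_test = nt, n_control = nc),
            class = "livak_result")
}

#' @export
print.livak_result <- function(x, ...) {
  cat(sprintf("Livak 2^-ddCt: ddCt = %.4g, fold change = %.4g (%.3g-fold %s)\n",
              x$delta_delta_ct, x$fold_change,
              ifelse(x$fold_change < 1, x$fold_reduction, x$fold_change),
              ifelse(x$fold_change < 1, "reduction", "increase")))
  if (is.finite(x$p_value))
    cat(sprintf("unpaired t-test on replicate dCt: t = %.4g, df = %.4g, p = %.4g\n",
                x$t, x$df, x$p_value))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (Welch by default, with the
#' Welch-Satterthwaite degrees of freedom; Student's pooled variant by
#' flag). When both groups have zero variance and equal means -- where the
#' statistic is 0/0 -- the result is `t = 0, p = 1` by convention.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance variant.
#' @return list `t`, `df`, `p`.
#' @export
ttest_unpaired <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
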