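#' Group summary statistics
#'
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(27.18, 5.33, 76)
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param x numeric vector of raw values.
#' @return `summarize_group()`: the `group_summary` of a raw vector.
#' @export
summarize_group <- function(x) {
  group_summary(mean(x), sd(x), length(x))
}

#' Two-tailed t-test from group summary statistics
#'
#' Computes the two-sample t statistic directly from (mean, sd, n) pairs,
#' as needed when only published summaries are available. Two variants are
#' provided: the classic pooled-variance Student test (`method = "student"`,
#' the default: it reproduces the demographic p-values printed in the
#' modelled study, whose groups have nearly equal SDs) and the
#' unequal-variance Welch test with Welch-Satterthwaite degrees of freedom
#' (`method = "welch"`, also exposed as `welch_t_from_summary()`). When both
#' SDs are zero the test degenerates: equal means give p = 1, unequal means
#' are rejected as having no sampling variability to test against.
#'
#' @param a,b [group_summary()] objects.
#' @param method "student" (pooled variance) or "welch".
#' @return List with `t`, `df` and two-tailed `p`.
#' @examples
#' t_from_summary(group_summary(27.18, 5.33, 76),
#'                group_summary(26.02, 5.32, 43))
#' @export
t_from_summary <- function(a, b, method = c("student", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    stop("degenerate: both groups have zero variance and unequal means")
  }
  if (method == "welch") {
    se2 <- va + vb
    t <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' @rdname t_from_summary
#' @export
welch_t_from_summary <- function(a, b) {
  t_from_summary(a, b, method = "welch")
}

#' Welch t-test on square-root transformed counts
#'
#' For count-valued demographic variables (gravidity, parity) the values are
#' square-root transformed before the two-sample comparison, stabilising the
#' variance of small counts.
#'
#' @param counts_a,counts_b non-negative numeric vectors of raw counts.
#' @return List with `t`, `df` and two-tailed `p` from the Welch test on the
#'   transformed values.
#' @examples
#' sqrt_count_test(c(0, 0, 4, 4), c(1, 1, 1, 1))
#' @export
sqrt_count_test <- function(counts_a, counts_b) {
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("counts must be non-negative")
  }
  tt <- t.test(sqrt(counts_a), sqrt(counts_b), var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Flag a p-value as statistically significant
#'
#' Strict inequality: p < alpha.
#'
#' @param p p-value in \[0, 1\].
#' @param alpha significance threshold (default 0.05).
#' @return Logical.
#' @examples
#' significance_flag(0.049)  # TRUE
#' significance_flag(0.05)   # FALSE (strict)
#' @export
significance_flag <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  p < alpha
}

#' Recompute demographic comparisons from a summary table
#'
#' Takes a per-variable summary table (columns variable, case_mean, case_sd,
#' case_n, control_mean, control_sd, control_n, transform, reported_p) and
#' recomputes the two-tailed t p-value for every variable whose test runs on
#' untransformed values. Variables tested after a square-root transform
#' cannot be recomputed from summaries (the transform precedes
#' summarisation), so their recomputed p is NA.
#'
#' @param summaries data.frame as above; defaults to the bundled study
#'   demographics ([pprom_demographics()]).
#' @param method passed to [t_from_summary()].
#' @return The input with columns `recomputed_p` and `significant` appended.
#' @examples
#' demographics_table()
#' @export
demographics_table <- function(summaries = pprom_demographics(),
                               method = "student") {
  p <- vapply(seq_len(nrow(summaries)), function(i) {
    if (summaries$transform[i] != "none") return(NA_real_)
    t_from_summary(
      group_summary(summaries$case_mean[i], summaries$case_sd[i],
                    summaries$case_n[i]),
      group_summary(summaries$control_mean[i], summaries$control_sd[i],
                    summaries$control_n[i]),
      method = method)$p
  }, numeric(1))
  summaries$recomputed_p <- p
  sig <- rep(NA, length(p))
  sig[!is.na(p)] <- significance_flag(p[!is.na(p)])
  summaries$significant <- sig
  summaries
}
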