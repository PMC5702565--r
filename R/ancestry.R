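#' Log-likelihood of an admixture proportion given AIMs genotypes
#'
#' Two-way admixture model with known ancestral allele frequencies: an
#' individual with proportion `theta` of ancestry from population A has
#' expected alt-allele frequency `p_m = theta * pA_m + (1 - theta) * pB_m`
#' at marker m, and the diploid dosage is Binomial(2, p_m). The
#' log-likelihood is the sum of binomial log-probabilities over markers with
#' a genotype call; missing genotypes contribute nothing. Ancestral
#' frequencies are treated as known constants; `clamp_eps` pulls frequencies
#' of exactly 0 or 1 into (0, 1) so that a single genotyping error cannot
#' drive the likelihood to -Inf (set it to 0 to evaluate the unsmoothed
#' model).
#'
#' @param theta admixture proportion toward population A, in \[0, 1\].
#' @param genotypes integer dosage vector (0/1/2, NA missing) aligned to the
#'   panel's markers.
#' @param panel an [aims_panel()].
#' @param clamp_eps clamp ancestral frequencies into
#'   \[clamp_eps, 1 - clamp_eps\]; default 1e-3.
#' @return The log-likelihood (may be -Inf if an observed genotype is
#'   impossible under the unsmoothed model).
#' @examples
#' p <- gen_panel(30, 0.7, seed = 1)
#' g <- gen_aims(0.6, p, seed = 2)[, 1]
#' admixture_loglik(0.6, g, p)
#' @export
admixture_loglik <- function(theta, genotypes, panel, clamp_eps = 1e-3) {
  if (!is.finite(theta) || theta < 0 || theta > 1) {
    stop("theta must be in [0, 1]")
  }
  stopifnot(length(genotypes) == nrow(panel))
  keep <- !is.na(genotypes)
  if (!any(keep)) stop("all marker genotypes are missing")
  pa <- pmin(pmax(panel$freq_popA[keep], clamp_eps), 1 - clamp_eps)
  pb <- pmin(pmax(panel$freq_popB[keep], clamp_eps), 1 - clamp_eps)
  p <- theta * pa + (1 - theta) * pb
  sum(dbinom(genotypes[keep], 2L, p, log = TRUE))
}

#' Maximum-likelihood admixture proportion for one individual
#'
#' Maximises [admixture_loglik()] over \[0, 1\]. The log-likelihood is
#' concave in theta (a sum of logs of affine functions of theta), so
#' bounded golden-section search ([stats::optimize()]) finds the global
#' maximum; the endpoints are checked explicitly so boundary maxima
#' (theta of exactly 0 or 1) are returned as converged estimates. A panel
#' with pA = pB at every marker carries no ancestry information; the
#' estimate is then flagged non-identifiable (`converged = FALSE`,
#' theta 0.5 by convention).
#'
#' @inheritParams admixture_loglik
#' @param tol convergence tolerance on theta (default 1e-6).
#' @return An object of class `ancestry_estimate`: list with theta, loglik,
#'   n_markers_used, converged.
#' @examples
#' p <- gen_panel(102, 0.733, seed = 1)
#' g <- gen_aims(0.7, p, seed = 2)[, 1]
#' estimate_theta(g, p)
#' @export
estimate_theta <- function(genotypes, panel, tol = 1e-6, clamp_eps = 1e-3) {
  keep <- !is.na(genotypes)
  if (!any(keep)) stop("all marker genotypes are missing")
  if (all(abs(panel$freq_popA[keep] - panel$freq_popB[keep]) < 1e-12)) {
    ll <- admixture_loglik(0.5, genotypes, panel, clamp_eps)
    return(structure(list(theta = 0.5, loglik = ll,
                          n_markers_used = sum(keep), converged = FALSE),
                     class = "ancestry_estimate"))
  }
  f <- function(th) admixture_loglik(th, genotypes, panel, clamp_eps)
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand_th <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, f(0), f(1))
  best <- which.max(cand_ll)
  structure(list(theta = cand_th[best], loglik = cand_ll[best],
                 n_markers_used = sum(keep), converged = TRUE),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf(
    "ancestry_estimate: theta = %.4f (loglik %.3f, %d markers%s)\n",
    x$theta, x$loglik, x$n_markers_used,
    if (x$converged) "" else ", NON-IDENTIFIABLE"))
  invisible(x)
}

#' Estimate admixture proportions for a cohort of individuals
#'
#' @param dosages integer matrix, markers x individuals (as from
#'   [gen_aims()] or [read_aims_dosage()]).
#' @inheritParams estimate_theta
#' @return data.frame with one row per individual: sample_id, theta, loglik,
#'   n_markers_used, converged.
#' @export
estimate_theta_cohort <- function(dosages, panel, tol = 1e-6,
                                  clamp_eps = 1e-3) {
  est <- lapply(seq_len(ncol(dosages)), function(j) {
    e <- estimate_theta(dosages[, j], panel, tol, clamp_eps)
    data.frame(sample_id = colnames(dosages)[j], theta = e$theta,
               loglik = e$loglik, n_markers_used = e$n_markers_used,
               converged = e$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, est)
}

#' Compare ancestry between cases and controls
#'
#' Summarises per-group admixture proportions (mean, SD, n) and tests the
#' group difference with a two-tailed Welch t-test, the ancestry-balance
#' check done before a case/control frequency comparison is interpreted.
#'
#' @param thetas numeric vector of admixture proportions.
#' @param status character vector, "case"/"control", aligned to `thetas`.
#' @return List with `summary` (per-group data.frame) and `t`, `df`, `p`.
#' @examples
#' th <- c(rnorm(30, 0.7, 0.08), rnorm(20, 0.7, 0.08))
#' st <- rep(c("case", "control"), c(30, 20))
#' ancestry_balance(th, st)
#' @export
ancestry_balance <- function(thetas, status) {
  stopifnot(length(thetas) == length(status))
  a <- thetas[status == "case"]
  b <- thetas[status == "control"]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 individuals")
  }
  tt <- welch_t_from_summary(group_summary(mean(a), sd(a), length(a)),
                             group_summary(mean(b), sd(b), length(b)))
  list(summary = data.frame(group = c("case", "control"),
                            mean = c(mean(a), mean(b)),
                            sd = c(sd(a), sd(b)),
                            n = c(length(a), length(b))),
       t = tt$t, df = tt$df, p = tt$p)
}
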