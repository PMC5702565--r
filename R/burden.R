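#' Per-group allele frequencies at one locus
#'
#' Alt-allele count and frequency per phenotype group, with missing
#' genotypes excluded from both numerator and denominator: the denominator
#' is 2 x (samples with a genotype call in that group).
#'
#' @param cohort a `cohort_genotypes` object.
#' @param variant_id locus identifier (a rowname of `cohort$geno`).
#' @return One-row data.frame of class `locus_freq_pair`: gene, variant_id,
#'   case_alt_count, case_called_chrom, case_freq, control_alt_count,
#'   control_called_chrom, control_freq.
#' @examples
#' ch <- gen_cohort(cohort_config(n_cases = 40, n_controls = 30, seed = 3))
#' locus_freq(ch, rownames(ch$geno)[1])
#' @export
locus_freq <- function(cohort, variant_id) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  if (!variant_id %in% rownames(cohort$geno)) {
    stop("locus not present in cohort: ", variant_id)
  }
  g <- cohort$geno[variant_id, ]
  out <- lapply(c(case = "case", control = "control"), function(grp) {
    gi <- g[cohort$samples$status == grp]
    called <- sum(!is.na(gi))
    if (called == 0) {
      stop("no called genotypes in group '", grp, "' at locus ", variant_id)
    }
    list(alt = sum(gi, na.rm = TRUE), chrom = 2L * called)
  })
  gene <- cohort$loci$gene[match(variant_id, cohort$loci$variant_id)]
  res <- data.frame(
    gene = gene, variant_id = variant_id,
    case_alt_count = out$case$alt, case_called_chrom = out$case$chrom,
    case_freq = out$case$alt / out$case$chrom,
    control_alt_count = out$control$alt,
    control_called_chrom = out$control$chrom,
    control_freq = out$control$alt / out$control$chrom,
    stringsAsFactors = FALSE)
  class(res) <- c("locus_freq_pair", "data.frame")
  res
}

#' @rdname locus_freq
#' @return `locus_freq_table()`: the per-locus frequency rows for every
#'   locus in the cohort, as one data.frame.
#' @export
locus_freq_table <- function(cohort) {
  rows <- lapply(rownames(cohort$geno), function(v) locus_freq(cohort, v))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Classify the case/control direction of a frequency pair
#'
#' @param case_freq,control_freq per-group alt-allele frequencies
#'   (vectorised).
#' @param similar_abs_tol absolute tolerance under which the pair is called
#'   "similar" (default 0: only exact equality is similar).
#' @return Character vector in {"case_higher", "control_higher", "similar"}.
#' @examples
#' classify_direction(c(0.036, 0.003, 0.007), c(0.026, 0.003, 0.012))
#' @export
classify_direction <- function(case_freq, control_freq, similar_abs_tol = 0) {
  d <- case_freq - control_freq
  ifelse(abs(d) <= similar_abs_tol, "similar",
         ifelse(d > 0, "case_higher", "control_higher"))
}

#' @rdname classify_direction
#' @param pairs data.frame with case_freq and control_freq columns.
#' @return `direction_tally()`: named integer vector of counts for the three
#'   directions.
#' @export
direction_tally <- function(pairs, similar_abs_tol = 0) {
  dir <- classify_direction(pairs$case_freq, pairs$control_freq,
                            similar_abs_tol)
  vapply(c(case_higher = "case_higher", control_higher = "control_higher",
           similar = "similar"),
         function(lv) sum(dir == lv), integer(1))
}

## round differences to kill float noise (0.374 - 0.376 must tie with 0.002)
.round_diffs <- function(diffs, digits = 12) round(diffs, digits)

#' Wilcoxon signed-rank statistic for paired differences
#'
#' Ranks absolute differences (midranks for ties) and sums the ranks of
#' positive differences. Under `zero_policy = "drop"` (the classical
#' convention) zero differences are removed before ranking; under `"pratt"`
#' zeros take part in the ranking but never contribute to the statistic.
#' Differences are rounded to 12 decimals first so that frequencies that
#' print as tied actually tie.
#'
#' @param diffs numeric vector of paired differences.
#' @param zero_policy "drop" or "pratt".
#' @return List with `w_plus`, `n_nonzero` and the `ranks` used (aligned to
#'   the non-dropped differences).
#' @examples
#' signed_rank_stat(c(1, 2, 3))     # w_plus 6
#' @export
signed_rank_stat <- function(diffs, zero_policy = c("drop", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(diffs) >= 1)
  d <- .round_diffs(diffs)
  if (all(d == 0)) {
    stop("signed-rank statistic undefined: all paired differences are zero")
  }
  if (zero_policy == "drop") d <- d[d != 0]
  r <- rank(abs(d))
  list(w_plus = sum(r[d > 0]), n_nonzero = sum(d != 0), ranks = r,
       diffs = d)
}

## exact distribution of W+ over independent sign flips of the given ranks:
## probability vector over 2*W+ (doubled so midranks are integers)
.signflip_dist <- function(ranks2) {
  probs <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) / 2 + shifted / 2
  }
  probs
}

#' Exact sign-flip p-value for the signed-rank statistic
#'
#' Enumerates the full permutation null of independent sign flips of the
#' nonzero paired differences (2^m equally likely patterns, computed by
#' dynamic programming over the rank values) and returns the exact tail
#' probability of the observed statistic. Serves as the oracle that
#' [permutation_test()] must converge to.
#'
#' @inheritParams signed_rank_stat
#' @param alternative "greater" (P(W+ >= observed)) or "two_sided" (double
#'   the smaller tail, capped at 1).
#' @return List with `p`, `w_plus`, `n_nonzero`.
#' @examples
#' exact_signflip_p(c(1, 2, 3), "greater")  # 1/8
#' @export
exact_signflip_p <- function(diffs, alternative = c("greater", "two_sided"),
                             zero_policy = c("drop", "pratt")) {
  alternative <- match.arg(alternative)
  zero_policy <- match.arg(zero_policy)
  s <- signed_rank_stat(diffs, zero_policy)
  if (s$n_nonzero > 20) {
    stop("exact enumeration limited to <= 20 nonzero differences")
  }
  flip_ranks <- s$ranks[s$diffs != 0]   # zeros never flip sign
  dist <- .signflip_dist(as.integer(round(2 * flip_ranks)))
  w2 <- as.integer(round(2 * s$w_plus))
  p_ge <- sum(dist[(w2 + 1):length(dist)])
  p_le <- sum(dist[1:(w2 + 1)])
  p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
  list(p = p, w_plus = s$w_plus, n_nonzero = s$n_nonzero)
}

#' Across-loci paired signed-rank burden test with a permutation null
#'
#' Treats loci as pairs: the paired difference at each locus is
#' `case_freq - control_freq`. The observed signed-rank statistic is
#' compared against a null generated by independent random sign flips of
#' the nonzero differences (exchangeable under no case/control difference),
#' with the add-one empirical p `(1 + r) / (n_perm + 1)` where r counts
#' permuted statistics as or more extreme than the observed one (so the
#' p-value is never exactly 0). Default alternative is "greater"
#' (overrepresentation in cases).
#'
#' @param pairs data.frame with `case_freq` and `control_freq` columns (e.g.
#'   from [locus_freq_table()] or a reported frequency table).
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed integer seed for the sign flips.
#' @inheritParams exact_signflip_p
#' @param similar_abs_tol tolerance used only for the reported direction
#'   tally, not the statistic.
#' @return An object of class `burden_test_result`: w_plus, n_nonzero,
#'   empirical_p, n_perm, seed, alternative, zero_policy, direction_tally.
#' @examples
#' res <- permutation_test(pprom_variants(), n_perm = 1000, seed = 1,
#'                         alternative = "two_sided")
#' res
#' @export
permutation_test <- function(pairs, n_perm = 10000, seed = 1,
                             alternative = c("greater", "two_sided"),
                             zero_policy = c("drop", "pratt"),
                             similar_abs_tol = 0) {
  alternative <- match.arg(alternative)
  zero_policy <- match.arg(zero_policy)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse empirical p")
  diffs <- pairs$case_freq - pairs$control_freq
  s <- signed_rank_stat(diffs, zero_policy)
  if (s$n_nonzero < 2) stop("need at least 2 nonzero paired differences")
  flip_ranks <- s$ranks[s$diffs != 0]
  m <- length(flip_ranks)
  set.seed(seed)
  pos <- matrix(runif(n_perm * m) < 0.5, n_perm, m)
  w_perm <- as.vector(pos %*% flip_ranks)
  r_ge <- sum(w_perm >= s$w_plus)
  r_le <- sum(w_perm <= s$w_plus)
  p_ge <- (1 + r_ge) / (n_perm + 1)
  p_le <- (1 + r_le) / (n_perm + 1)
  p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
  structure(list(w_plus = s$w_plus, n_nonzero = s$n_nonzero,
                 empirical_p = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), alternative = alternative,
                 zero_policy = zero_policy,
                 direction_tally = direction_tally(pairs, similar_abs_tol)),
            class = "burden_test_result")
}

#' @export
print.burden_test_result <- function(x, ...) {
  cat("Across-loci paired signed-rank burden test\n")
  cat(sprintf("  W+ = %g on %d nonzero paired differences (%s zeros)\n",
              x$w_plus, x$n_nonzero,
              if (x$zero_policy == "drop") "dropping" else "Pratt-ranking"))
  cat(sprintf("  empirical p = %.4f (%s, %d sign-flip permutations, seed %d)\n",
              x$empirical_p, x$alternative, x$n_perm, x$seed))
  cat(sprintf("  direction: %d case-higher, %d control-higher, %d similar\n",
              x$direction_tally[["case_higher"]],
              x$direction_tally[["control_higher"]],
              x$direction_tally[["similar"]]))
  invisible(x)
}

#' Probability of detecting an allele in a sequenced cohort
#'
#' The chance that at least one copy of an allele of population frequency
#' `allele_freq` appears among `n_chrom` independently sampled chromosomes:
#' `1 - (1 - f)^n`. Strictly increasing in both arguments.
#'
#' @param allele_freq allele frequency in \[0, 1\] (vectorised).
#' @param n_chrom number of chromosomes sampled (>= 1).
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_power(0.005, 304)   # ~0.78
#' @export
detection_power <- function(allele_freq, n_chrom) {
  stopifnot(all(allele_freq >= 0 & allele_freq <= 1), all(n_chrom >= 1))
  1 - (1 - allele_freq)^n_chrom
}

#' Carrier and homozygote tallies at one locus
#'
#' @inheritParams locus_freq
#' @return data.frame with one row per group: n (group size), n_called,
#'   het (dosage 1), hom (dosage 2), hom_pct (homozygotes as percent of the
#'   group).
#' @examples
#' ch <- gen_cohort(cohort_config(n_cases = 40, n_controls = 30, seed = 3))
#' carrier_tally(ch, "rs601338")
#' @export
carrier_tally <- function(cohort, variant_id) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  if (!variant_id %in% rownames(cohort$geno)) {
    stop("locus not present in cohort: ", variant_id)
  }
  g <- cohort$geno[variant_id, ]
  rows <- lapply(c("case", "control"), function(grp) {
    gi <- g[cohort$samples$status == grp]
    data.frame(group = grp, n = length(gi), n_called = sum(!is.na(gi)),
               het = sum(gi == 1, na.rm = TRUE),
               hom = sum(gi == 2, na.rm = TRUE),
               hom_pct = 100 * sum(gi == 2, na.rm = TRUE) / length(gi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Loci whose alt allele appears only in cases
#'
#' Filters frequency pairs to those with zero control alt alleles and at
#' least one case alt allele. Works from counts when present, otherwise
#' from frequencies.
#'
#' @param pairs data.frame of frequency pairs (rows of [locus_freq_table()]
#'   or a reported frequency table with case_freq/control_freq).
#' @return List with `variants` (the filtered rows) and `genes` (the
#'   deduplicated gene set, sorted).
#' @examples
#' case_only_loci(pprom_variants())$genes
#' @export
case_only_loci <- function(pairs) {
  if (all(c("case_alt_count", "control_alt_count") %in% names(pairs))) {
    keep <- pairs$control_alt_count == 0 & pairs$case_alt_count > 0
  } else {
    keep <- pairs$control_freq == 0 & pairs$case_freq > 0
  }
  variants <- pairs[keep, , drop = FALSE]
  list(variants = variants, genes = sort(unique(variants$gene)))
}

#' Samples carrying qualifying alleles at two or more loci
#'
#' @param cohort a `cohort_genotypes` object.
#' @param variant_ids loci to scan (default: all loci in the cohort); at
#'   least 2.
#' @return data.frame with one row per di-/multi-genic carrier: sample_id,
#'   status, n_loci and the comma-separated locus combination.
#' @examples
#' ch <- gen_cohort(cohort_config(seed = 3))
#' digenic_carriers(ch)
#' @export
digenic_carriers <- function(cohort, variant_ids = rownames(cohort$geno)) {
  stopifnot(inherits(cohort, "cohort_genotypes"), length(variant_ids) >= 2)
  g <- cohort$geno[variant_ids, , drop = FALSE]
  carries <- !is.na(g) & g > 0
  n_loci <- colSums(carries)
  hit <- which(n_loci >= 2)
  if (!length(hit)) {
    return(data.frame(sample_id = character(0), status = character(0),
                      n_loci = integer(0), loci = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    sample_id = colnames(g)[hit],
    status = cohort$samples$status[match(colnames(g)[hit],
                                         cohort$samples$sample_id)],
    n_loci = n_loci[hit],
    loci = vapply(hit, function(j) {
      paste(variant_ids[carries[, j]], collapse = ",")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
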