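make_cohort <- function(case_geno, control_geno, id = "v1") {
  g <- matrix(c(case_geno, control_geno), nrow = 1,
              dimnames = list(id, NULL))
  cohort_genotypes(g, rep(c("case", "control"),
                          c(length(case_geno), length(control_geno))))
}

test_that("locus frequencies use called chromosomes as denominators", {
  # 12 cases: 2 missing, 2 het + 1 hom among the 10 called -> 4/20
  ch <- make_cohort(c(1L, 1L, 2L, NA, NA, rep(0L, 7)), rep(0L, 5))
  fr <- locus_freq(ch, "v1")
  expect_equal(fr$case_alt_count, 4)
  expect_equal(fr$case_called_chrom, 20)
  expect_equal(fr$case_freq, 0.2)
  expect_equal(fr$control_freq, 0)
  # frequencies invariant to sample order
  perm <- sample(ncol(ch$geno))
  ch2 <- cohort_genotypes(ch$geno[, perm, drop = FALSE],
                          ch$samples$status[perm])
  expect_equal(locus_freq(ch2, "v1")$case_freq, fr$case_freq)
  # all genotypes missing in one group errors with group and locus
  ch3 <- make_cohort(c(NA_integer_, NA_integer_), c(0L, 1L))
  expect_error(locus_freq(ch3, "v1"), "case.*v1")
  expect_error(locus_freq(ch, "nope"), "not present")
})

test_that("direction classification follows sign with a similarity band", {
  expect_equal(classify_direction(0.036, 0.026), "case_higher")
  expect_equal(classify_direction(0.003, 0.003), "similar")
  expect_equal(classify_direction(0.007, 0.012), "control_higher")
  expect_equal(classify_direction(0.374, 0.376, similar_abs_tol = 0.005),
               "similar")
  tal <- direction_tally(published_pairs())
  expect_equal(unname(tal), c(10L, 3L, 1L))
})

test_that("signed-rank statistic uses midranks and drops zeros", {
  s <- signed_rank_stat(c(1, 2, 3))
  expect_equal(s$w_plus, 6)
  expect_equal(s$n_nonzero, 3)
  s <- signed_rank_stat(c(0, -1, 2, 2))
  expect_equal(s$n_nonzero, 3)
  expect_equal(s$w_plus, 2.5 + 2.5)  # midranks for the tied |2|s
  expect_error(signed_rank_stat(c(0, 0)), "all paired differences")
  # antisymmetry: flipping every sign maps W+ to n(n+1)/2 - W+
  set.seed(13)
  for (i in 1:25) {
    d <- round(rnorm(sample(3:15, 1)), 2)
    d <- d[d != 0]
    if (length(d) < 1) next
    a <- signed_rank_stat(d)
    b <- signed_rank_stat(-d)
    expect_equal(a$w_plus + b$w_plus, a$n_nonzero * (a$n_nonzero + 1) / 2)
  }
})

test_that("tied printed frequencies rank as ties despite float subtraction", {
  v <- published_pairs()
  s <- signed_rank_stat(v$case_freq - v$control_freq)
  expect_equal(s$w_plus, 79)
  expect_equal(s$n_nonzero, 13)
})

test_that("exact sign-flip enumeration matches closed forms and brute force", {
  expect_equal(exact_signflip_p(c(1, 2, 3), "greater")$p, 1 / 8)
  expect_equal(exact_signflip_p(1, "greater")$p, 1 / 2)
  expect_error(exact_signflip_p(seq_len(21), "greater"), "20")
  set.seed(17)
  for (i in 1:20) {
    d <- round(rnorm(sample(3:10, 1)), 1)
    if (all(round(d, 12) == 0)) next
    for (alt in c("greater", "two_sided")) {
      expect_equal(exact_signflip_p(d, alt)$p, brute_signflip_p(d, alt),
                   info = paste(alt, paste(d, collapse = ",")))
    }
  }
})

test_that("permutation p converges to the exact oracle and is seeded", {
  set.seed(23)
  d <- c(0.9, -0.4, 1.7, 0.2, 0.6, -1.1, 0.3, 1.2)
  pairs <- data.frame(case_freq = d, control_freq = 0)
  for (alt in c("greater", "two_sided")) {
    ex <- exact_signflip_p(d, alt)$p
    bt <- permutation_test(pairs, n_perm = 20000, seed = 3,
                           alternative = alt)
    mult <- if (alt == "two_sided") 2 else 1
    expect_lt(abs(bt$empirical_p - ex),
              mult * 3 * sqrt(ex * (1 - ex) / 20000) + 2 / 20000)
  }
  # reproducible given the seed
  b1 <- permutation_test(pairs, 500, seed = 11)
  b2 <- permutation_test(pairs, 500, seed = 11)
  expect_identical(b1$empirical_p, b2$empirical_p)
  # all-positive differences, m = 10: exact one-sided limit is 1/1024
  d10 <- seq_len(10)
  ex <- exact_signflip_p(d10, "greater")$p
  expect_equal(ex, 1 / 1024)
  bt <- permutation_test(data.frame(case_freq = d10, control_freq = 0),
                         n_perm = 100000, seed = 5)
  expect_lt(abs(bt$empirical_p - ex), 3 * sqrt(ex * (1 - ex) / 1e5) + 2e-5)
  # a statistic at the null median gives p about one half (up to the
  # discrete point mass at the median itself)
  dmed <- c(1, 1, -1, -1, 2, -2)
  ex <- exact_signflip_p(dmed, "greater")$p
  expect_lt(abs(ex - 0.5), 0.1)  # half the point mass at the median
  bt <- permutation_test(data.frame(case_freq = dmed, control_freq = 0),
                         n_perm = 4000, seed = 7)
  expect_lt(abs(bt$empirical_p - ex), 3 * sqrt(ex * (1 - ex) / 4000) + 1e-3)
  expect_warning(permutation_test(pairs, n_perm = 50, seed = 1), "coarse")
  expect_error(permutation_test(data.frame(case_freq = 0.1,
                                           control_freq = 0.1)),
               "zero")
})

test_that("the add-one correction keeps empirical p strictly positive", {
  d <- seq_len(12)
  bt <- permutation_test(data.frame(case_freq = d, control_freq = 0),
                         n_perm = 200, seed = 1)
  expect_gte(bt$empirical_p, 1 / 201)
})

test_that("detection power follows the at-least-one-copy formula", {
  expect_equal(detection_power(0, 100), 0)
  expect_equal(detection_power(1, 1), 1)
  expect_equal(detection_power(0.005, 304), 1 - 0.995^304)
  expect_equal(round(100 * detection_power(0.005, 304)), 78)
  # strictly increasing in both arguments (away from double saturation)
  f <- seq(0.001, 0.1, length.out = 50)
  expect_true(all(diff(detection_power(f, 100)) > 0))
  expect_true(all(diff(detection_power(0.01, c(10, 50, 100, 500))) > 0))
  expect_error(detection_power(1.5, 10), "allele_freq")
})

test_that("carrier tallies count het and hom per group", {
  case_g <- c(rep(2L, 16), rep(1L, 30), rep(0L, 30))   # 76 cases
  ctrl_g <- c(rep(2L, 4), rep(1L, 20), rep(0L, 19))    # 43 controls
  ch <- make_cohort(case_g, ctrl_g, id = "rs601338")
  tal <- carrier_tally(ch, "rs601338")
  expect_equal(tal$hom, c(16, 4))
  expect_equal(round(tal$hom_pct[1]), 21)
  expect_equal(round(tal$hom_pct[2], 1), 9.3)
  ch0 <- make_cohort(rep(0L, 5), rep(1L, 4))
  expect_equal(carrier_tally(ch0, "v1")$hom_pct, c(0, 0))
})

test_that("case-only filtering matches counts and frequencies", {
  res <- case_only_loci(published_pairs())
  expect_equal(nrow(res$variants), 6)
  expect_equal(res$genes,
               c("CARD6", "DEFB1", "FUT2", "MBL2", "NLRP10", "NOD2"))
  empty <- case_only_loci(data.frame(gene = character(0),
                                     case_freq = numeric(0),
                                     control_freq = numeric(0)))
  expect_equal(nrow(empty$variants), 0)
  both0 <- case_only_loci(data.frame(gene = "G", case_freq = 0,
                                     control_freq = 0))
  expect_equal(nrow(both0$variants), 0)
  # count columns take precedence when present
  counted <- case_only_loci(data.frame(gene = c("A", "B"),
                                       case_alt_count = c(2, 0),
                                       control_alt_count = c(0, 0),
                                       case_freq = c(0.1, 0),
                                       control_freq = c(0, 0)))
  expect_equal(counted$genes, "A")
})

test_that("di-genic carriers are recovered exactly from planted genotypes", {
  g <- rbind(v1 = c(1L, 0L, 1L, 0L, NA, 1L),
             v2 = c(0L, 0L, 1L, 0L, 1L, 2L),
             v3 = c(0L, 1L, 0L, 0L, 1L, 0L))
  colnames(g) <- paste0("s", 1:6)
  ch <- cohort_genotypes(g, rep(c("case", "control"), 3))
  dg <- digenic_carriers(ch)
  expect_equal(dg$sample_id, c("s3", "s5", "s6"))
  expect_equal(dg$loci, c("v1,v2", "v2,v3", "v1,v2"))
  expect_equal(dg$n_loci, c(2L, 2L, 2L))
  # no overlapping carriers -> empty
  g2 <- rbind(v1 = c(1L, 0L), v2 = c(0L, 1L))
  expect_equal(nrow(digenic_carriers(cohort_genotypes(
    g2, c("case", "control")))), 0)
  expect_error(digenic_carriers(ch, "v1"), "length")
})
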