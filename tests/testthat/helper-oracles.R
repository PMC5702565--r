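# Independent oracles used across the test files. Each deliberately avoids
# the code path it checks: translation uses a hand-built codon table (not
# Biostrings), the sign-flip oracle enumerates sign matrices (not the DP),
# the ancestry oracle is a dense grid search (not golden-section).

# standard genetic code, bases ordered T, C, A, G
.aa64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  setNames(.aa64, paste0(g$b1, g$b2, g$b3))
})
stopifnot(.codon_table[["ATG"]] == "M", .codon_table[["TGA"]] == "*",
          .codon_table[["TGG"]] == "W")

oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  paste(.codon_table[codons], collapse = "")
}

# same classification semantics as call_consequence, independent code
oracle_consequence <- function(tx, pos, ref, alt) {
  cds <- tx$cds
  L <- nchar(cds)
  if (pos < 1 || pos > L) return(list(effect = "noncoding",
                                      truncation_aa = NA_integer_))
  mut <- paste0(substr(cds, 1, pos - 1), alt,
                substr(cds, pos + nchar(ref), L))
  if (substr(mut, 1, 3) != "ATG") {
    return(list(effect = "start_loss", truncation_aa = NA_integer_))
  }
  p0 <- oracle_translate(cds)
  p1 <- oracle_translate(mut)
  k <- as.integer(regexpr("*", p1, fixed = TRUE))
  if ((nchar(alt) - nchar(ref)) %% 3 != 0) {
    return(list(effect = "frameshift",
                truncation_aa = if (k > 0) k else NA_integer_))
  }
  if (p1 == p0) return(list(effect = "synonymous",
                            truncation_aa = NA_integer_))
  if (k > 0 && k < tx$protein_length + (nchar(alt) - nchar(ref)) / 3 + 1) {
    return(list(effect = "nonsense", truncation_aa = k))
  }
  if (nchar(p1) == nchar(p0)) {
    return(list(effect = "missense", truncation_aa = NA_integer_))
  }
  list(effect = "inframe_indel", truncation_aa = NA_integer_)
}

# random variant on a transcript: SNV, anchored insertion, anchored deletion
random_variant <- function(tx) {
  L <- nchar(tx$cds)
  bases <- c("A", "C", "G", "T")
  type <- sample(c("snv", "ins", "del"), 1, prob = c(0.6, 0.2, 0.2))
  if (type == "snv") {
    pos <- sample(L, 1)
    ref <- substr(tx$cds, pos, pos)
    alt <- sample(setdiff(bases, ref), 1)
  } else if (type == "ins") {
    pos <- sample(L, 1)
    ref <- substr(tx$cds, pos, pos)
    alt <- paste0(ref, paste(sample(bases, sample(1:4, 1), TRUE),
                             collapse = ""))
  } else {
    dlen <- sample(1:4, 1)
    pos <- sample(L - dlen, 1)
    ref <- substr(tx$cds, pos, pos + dlen)
    alt <- substr(tx$cds, pos, pos)
  }
  list(pos = pos, ref = ref, alt = alt)
}

# dense grid-search maximiser of the admixture log-likelihood
grid_theta <- function(g, panel, step = 1e-4, clamp_eps = 1e-3) {
  keep <- !is.na(g)
  pa <- pmin(pmax(panel$freq_popA[keep], clamp_eps), 1 - clamp_eps)
  pb <- pmin(pmax(panel$freq_popB[keep], clamp_eps), 1 - clamp_eps)
  th <- seq(0, 1, by = step)
  m <- sum(keep)
  P <- th %o% (pa - pb) + matrix(pb, length(th), m, byrow = TRUE)
  G <- matrix(g[keep], length(th), m, byrow = TRUE)
  ll <- rowSums(dbinom(G, 2, P, log = TRUE))
  th[which.max(ll)]
}

# full enumeration of sign matrices (m <= 12), drop-zeros policy
brute_signflip_p <- function(diffs, alternative = "greater") {
  d <- round(diffs, 12)
  d <- d[d != 0]
  m <- length(d)
  stopifnot(m <= 12)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  stats <- as.vector(signs %*% r)
  obs <- sum(r[d > 0])
  pg <- mean(stats >= obs)
  pl <- mean(stats <= obs)
  if (alternative == "greater") pg else min(1, 2 * min(pg, pl))
}

published_pairs <- function() pprom_variants()
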