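#' Specify a planted variant locus
#'
#' Describes one biallelic locus to plant in a synthetic cohort: identifiers,
#' VCF-style coordinates and alleles, and the target alt-allele frequency in
#' each phenotype group. With `hwe = TRUE` genotypes are drawn as
#' Binomial(2, f) (Hardy-Weinberg, so homozygotes occur); with `hwe = FALSE`
#' every carrier is strictly heterozygous, the zygosity pattern of rare
#' damaging variants in the modelled study, which requires `f <= 0.5`.
#'
#' @param gene gene symbol.
#' @param variant_id variant identifier (e.g. an rsID).
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param ref,alt reference and alternate allele strings (VCF conventions,
#'   anchored-base indels); must differ.
#' @param case_freq,control_freq target alt-allele frequency per group, in
#'   \[0, 1\].
#' @param hwe logical; Hardy-Weinberg genotype draws (see above).
#' @return One-row data.frame; rbind rows to build a locus table.
#' @examples
#' planted_locus("DEFB1", "rs5743490", "8", 6870777, "C", "A", 0.011, 0)
#' @export
planted_locus <- function(gene, variant_id, chrom, pos, ref, alt,
                          case_freq, control_freq, hwe = FALSE) {
  stopifnot(is.character(ref), is.character(alt), nzchar(ref), nzchar(alt))
  if (ref == alt) stop("ref and alt alleles must differ")
  for (f in c(case_freq, control_freq)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      stop("allele frequencies must be finite and in [0, 1]")
    }
  }
  data.frame(gene = gene, variant_id = variant_id, chrom = as.character(chrom),
             pos = as.integer(pos), ref = ref, alt = alt,
             case_freq = case_freq, control_freq = control_freq, hwe = hwe,
             stringsAsFactors = FALSE)
}

#' Configure a synthetic case/control cohort
#'
#' Defaults mirror the combined discovery plus follow-up cohort of the
#' modelled study: 264 PPROM cases and 218 term controls genotyped at the 14
#' reported damaging loci (planted at the reported per-group frequencies),
#' with 2% of genotype calls missing completely at random.
#'
#' @param n_cases,n_controls group sizes (>= 1).
#' @param loci data.frame of planted loci ([planted_locus()] rows or
#'   [published_loci()]).
#' @param missing_rate per-genotype missing probability in \[0, 1).
#' @param seed integer seed; the generator is a pure function of config and
#'   seed.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_cases = 50, n_controls = 40, seed = 7)
#' @export
cohort_config <- function(n_cases = 264, n_controls = 218,
                          loci = published_loci(), missing_rate = 0.02,
                          seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  req <- c("gene", "variant_id", "chrom", "pos", "ref", "alt",
           "case_freq", "control_freq", "hwe")
  if (!all(req %in% names(loci))) {
    stop("loci must have columns: ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(loci$case_freq)) || any(!is.finite(loci$control_freq)) ||
      any(loci$case_freq < 0) || any(loci$case_freq > 1) ||
      any(loci$control_freq < 0) || any(loci$control_freq > 1)) {
    stop("planted frequencies must be finite and in [0, 1]")
  }
  bad <- !loci$hwe & (loci$case_freq > 0.5 | loci$control_freq > 0.5)
  if (any(bad)) {
    stop("heterozygous-only planting requires frequency <= 0.5: ",
         paste(loci$variant_id[bad], collapse = ", "))
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 loci = loci, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## genotype draws for one locus in one group
.draw_group <- function(n, f, hwe) {
  if (f == 0) return(integer(n))
  if (hwe) {
    rbinom(n, 2L, f)
  } else {
    # strictly heterozygous carriers: carrier probability 2f gives E[freq] = f
    rbinom(n, 1L, 2 * f)
  }
}

#' Generate a synthetic diploid case/control cohort
#'
#' Draws per-sample alt-allele dosages (0/1/2, NA for missing) at each
#' planted locus, per group, then masks genotypes missing completely at
#' random at the configured rate. Deterministic given the config (which
#' includes the seed).
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort_genotypes`: list with `geno` (integer
#'   matrix, loci x samples, rownames variant_id), `loci` (the locus table)
#'   and `samples` (data.frame sample_id, status).
#' @examples
#' ch <- gen_cohort(cohort_config(n_cases = 30, n_controls = 20, seed = 1))
#' table(ch$geno[1, ], useNA = "ifany")
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  nL <- nrow(config$loci)
  n <- config$n_cases + config$n_controls
  status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  ids <- c(sprintf("case_%04d", seq_len(config$n_cases)),
           sprintf("ctrl_%04d", seq_len(config$n_controls)))
  geno <- matrix(NA_integer_, nL, n, dimnames = list(config$loci$variant_id, ids))
  for (i in seq_len(nL)) {
    geno[i, status == "case"] <- .draw_group(
      config$n_cases, config$loci$case_freq[i], config$loci$hwe[i])
    geno[i, status == "control"] <- .draw_group(
      config$n_controls, config$loci$control_freq[i], config$loci$hwe[i])
  }
  if (config$missing_rate > 0) {
    geno[matrix(runif(nL * n) < config$missing_rate, nL, n)] <- NA_integer_
  }
  structure(list(geno = geno, loci = config$loci,
                 samples = data.frame(sample_id = ids, status = status,
                                      stringsAsFactors = FALSE)),
            class = "cohort_genotypes")
}

#' Assemble a cohort object from a raw genotype matrix
#'
#' Constructor for externally produced genotype data: a loci x samples
#' dosage matrix (0/1/2, NA for missing) plus per-sample case/control
#' labels.
#'
#' @param geno integer matrix, loci x samples; rownames are variant ids,
#'   colnames sample ids.
#' @param status character vector ("case"/"control") aligned to columns.
#' @param loci optional locus annotation data.frame with at least
#'   variant_id and gene columns; a minimal one is built from rownames if
#'   omitted.
#' @return An object of class `cohort_genotypes`.
#' @examples
#' g <- rbind(v1 = c(1L, 0L, NA, 2L))
#' colnames(g) <- paste0("s", 1:4)
#' cohort_genotypes(g, c("case", "case", "control", "control"))
#' @export
cohort_genotypes <- function(geno, status, loci = NULL) {
  stopifnot(is.matrix(geno), ncol(geno) == length(status),
            all(status %in% c("case", "control")),
            all(is.na(geno) | geno %in% 0:2))
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("locus_", seq_len(nrow(geno)))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("sample_%04d", seq_len(ncol(geno)))
  }
  storage.mode(geno) <- "integer"
  if (is.null(loci)) {
    loci <- data.frame(gene = rownames(geno), variant_id = rownames(geno),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(rownames(geno) %in% loci$variant_id))
  structure(list(geno = geno, loci = loci,
                 samples = data.frame(sample_id = colnames(geno),
                                      status = status,
                                      stringsAsFactors = FALSE)),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  tab <- table(x$samples$status)
  cat("cohort_genotypes:", nrow(x$geno), "loci x", ncol(x$geno), "samples (",
      tab[["case"]], "cases /", tab[["control"]], "controls ),",
      sprintf("%.1f%%", 100 * mean(is.na(x$geno))), "missing calls\n")
  invisible(x)
}

#' Build an AIMs panel object
#'
#' An ancestry-informative-marker panel holds, per marker, the alt-allele
#' frequency in each of the two ancestral source populations (A and B). Its
#' informativeness is summarised by delta, the mean absolute frequency
#' difference across markers.
#'
#' @param markers data.frame with columns marker_id, freq_popA, freq_popB.
#' @return An object of class `aims_panel` (the marker data.frame with a
#'   `delta` attribute).
#' @seealso [gen_panel()], [aims_delta()]
#' @export
aims_panel <- function(markers) {
  stopifnot(all(c("marker_id", "freq_popA", "freq_popB") %in% names(markers)))
  fr <- c(markers$freq_popA, markers$freq_popB)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("panel frequencies must be finite and in [0, 1]")
  }
  structure(markers, class = c("aims_panel", "data.frame"),
            delta = mean(abs(markers$freq_popA - markers$freq_popB)))
}

#' @rdname aims_panel
#' @param panel an `aims_panel`.
#' @return `aims_delta()`: the recomputed mean absolute ancestral frequency
#'   difference.
#' @export
aims_delta <- function(panel) {
  mean(abs(panel$freq_popA - panel$freq_popB))
}

#' Generate an AIMs panel with a target delta
#'
#' Draws per-marker ancestral frequency differences around `target_delta`,
#' rescales them so their mean hits the target, and places each pair
#' uniformly within \[0, 1\]. Defaults match the modelled study's panel:
#' 102 markers at delta = 0.733.
#'
#' @param n_markers number of markers.
#' @param target_delta desired mean absolute frequency difference, in (0, 1).
#' @param seed integer seed.
#' @return An [aims_panel()] whose delta is within 0.02 of the target.
#' @examples
#' p <- gen_panel(102, 0.733, seed = 1)
#' aims_delta(p)
#' @export
gen_panel <- function(n_markers = 102, target_delta = 0.733, seed = 1) {
  if (!is.finite(target_delta) || target_delta <= 0 || target_delta >= 1) {
    stop("target_delta must be in (0, 1)")
  }
  stopifnot(n_markers >= 1)
  set.seed(seed)
  spread <- min(0.1, target_delta / 2, (1 - target_delta) / 2)
  d <- runif(n_markers, target_delta - spread, target_delta + spread)
  d <- pmin(d * target_delta / mean(d), 1)
  d <- d * target_delta / mean(d)  # second pass fixes any clamping bias
  lo <- runif(n_markers, 0, 1 - d)
  a_high <- runif(n_markers) < 0.5
  pa <- ifelse(a_high, lo + d, lo)
  pb <- ifelse(a_high, lo, lo + d)
  aims_panel(data.frame(marker_id = sprintf("aim_%03d", seq_len(n_markers)),
                        freq_popA = pa, freq_popB = pb,
                        stringsAsFactors = FALSE))
}

#' Simulate AIMs genotypes under the two-way admixture model
#'
#' Forward simulation of the model the ancestry estimator inverts: an
#' individual with admixture proportion theta toward population A has, at
#' marker m, alt-allele dosage drawn Binomial(2, theta * pA_m +
#' (1 - theta) * pB_m).
#'
#' @param thetas vector of admixture proportions in \[0, 1\], one per
#'   individual.
#' @param panel an [aims_panel()].
#' @param seed integer seed.
#' @return Integer dosage matrix, markers x individuals (rownames from the
#'   panel).
#' @examples
#' p <- gen_panel(20, 0.7, seed = 2)
#' g <- gen_aims(c(0.6, 0.8), p, seed = 3)
#' @export
gen_aims <- function(thetas, panel, seed = 1) {
  if (any(!is.finite(thetas)) || any(thetas < 0) || any(thetas > 1)) {
    stop("admixture proportions must be in [0, 1]")
  }
  set.seed(seed)
  m <- nrow(panel)
  g <- vapply(thetas, function(th) {
    rbinom(m, 2L, th * panel$freq_popA + (1 - th) * panel$freq_popB)
  }, integer(m))
  g <- matrix(g, nrow = m,
              dimnames = list(panel$marker_id,
                              sprintf("ind_%04d", seq_along(thetas))))
  g
}

.STOPS <- c("TAA", "TAG", "TGA")

#' Generate a toy coding transcript
#'
#' Builds a random CDS for desk-scale testing: an ATG start, `n_codons - 2`
#' random sense codons (internal stops excluded) and a final stop codon,
#' optionally with non-overlapping named domains.
#'
#' @param gene gene identifier.
#' @param n_codons total codons including start and stop (>= 3).
#' @param n_domains number of non-overlapping domains to place.
#' @param seed integer seed.
#' @return A [transcript_model()].
#' @examples
#' tx <- gen_transcript("TOY1", n_codons = 12, n_domains = 2, seed = 5)
#' @export
gen_transcript <- function(gene, n_codons = 20, n_domains = 0, seed = 1) {
  stopifnot(n_codons >= 3)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- character(0)
  if (n_codons > 2) {
    repeat {
      codons <- replicate(n_codons - 2, paste(sample(bases, 3, TRUE),
                                              collapse = ""))
      if (!any(codons %in% .STOPS)) break
    }
  }
  cds <- paste0("ATG", paste(codons, collapse = ""), sample(.STOPS, 1))
  domains <- NULL
  plen <- n_codons - 1
  if (n_domains > 0) {
    cuts <- sort(sample(seq_len(plen), min(2 * n_domains, plen)))
    starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
    ends <- cuts[seq(2, length(cuts), by = 2)]
    domains <- data.frame(name = paste0("dom", seq_along(starts)),
                          start_aa = starts, end_aa = ends,
                          stringsAsFactors = FALSE)
  }
  transcript_model(gene, cds, domains)
}
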