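#' Bundled reference tables from the source PPROM candidate-gene study
#'
#' The package ships three small plain-text tables transcribed from the
#' published study it models: the 14 damaging variants with their reported
#' per-group minor-allele frequencies, the cohort demographic summary
#' statistics, and a set of reported headline figures (carrier counts,
#' permutation p, AIMs panel properties). These drive reproduction mode
#' ([reproduce_reported()]) and supply the default planted loci for
#' [gen_cohort()].
#'
#' @return `pprom_variants()`: a data.frame with one row per damaging
#'   variant (gene, variant_id, chrom, pos, ref, alt, effect, minor_allele,
#'   aa_position, case_freq, control_freq).
#' @examples
#' head(pprom_variants())
#' @export
pprom_variants <- function() {
  path <- system.file("extdata", "pprom_damaging_variants.tsv",
                      package = "ppromburden", mustWork = TRUE)
  read.delim(path, colClasses = c(pos = "integer"))
}

#' @rdname pprom_variants
#' @return `pprom_demographics()`: per-variable group summaries
#'   (mean, sd, n per group), the transform applied before testing, and the
#'   reported p-value (character; some are printed as "<0.001").
#' @export
pprom_demographics <- function() {
  path <- system.file("extdata", "pprom_demographics.tsv",
                      package = "ppromburden", mustWork = TRUE)
  read.delim(path, colClasses = c(reported_p = "character"))
}

#' @rdname pprom_variants
#' @return `pprom_reported()`: a named numeric vector of reported headline
#'   figures (cohort sizes, homozygote counts, permutation p, AIMs delta,
#'   group admixture means, per-variant case carrier counts).
#' @export
pprom_reported <- function() {
  path <- system.file("extdata", "pprom_reported_figures.tsv",
                      package = "ppromburden", mustWork = TRUE)
  tab <- read.delim(path)
  setNames(as.numeric(tab$value), tab$key)
}

#' Planted-locus table for the study's combined cohort
#'
#' Turns the bundled variant table into a planted-locus specification for
#' [gen_cohort()]: the reported case/control frequencies become the planting
#' frequencies, rare variants are planted with strictly heterozygous
#' carriers, and the common FUT2 stop variant (rs601338) under
#' Hardy-Weinberg genotype draws, matching the zygosity reported in the
#' study. Printed anchorless indel alleles ("-") are normalised to VCF
#' anchored-base form using a synthetic "A" anchor (the true flanking base
#' is not part of the printed table).
#'
#' @return A data.frame of planted loci accepted by [cohort_config()].
#' @examples
#' loci <- published_loci()
#' loci[loci$hwe, ]
#' @export
published_loci <- function() {
  v <- pprom_variants()
  ref <- v$ref
  alt <- v$alt
  pos <- v$pos
  ins <- ref == "-"
  del <- alt == "-"
  # anchorless insertion: synthetic anchor base prepended, position shifted
  ref[ins] <- "A"
  alt[ins] <- paste0("A", v$alt[ins])
  pos[ins] <- pos[ins] - 1L
  del_i <- which(del)
  ref[del_i] <- paste0("A", v$ref[del_i])
  alt[del_i] <- "A"
  pos[del_i] <- pos[del_i] - 1L
  data.frame(
    gene = v$gene,
    variant_id = v$variant_id,
    chrom = sub("[pq].*$", "", v$chrom),
    pos = pos,
    ref = ref,
    alt = alt,
    case_freq = v$case_freq,
    control_freq = v$control_freq,
    hwe = v$variant_id == "rs601338",
    stringsAsFactors = FALSE
  )
}
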