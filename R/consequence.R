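#' Define a coding transcript model
#'
#' A transcript model is the substrate of consequence calling: a complete
#' CDS (start codon through stop codon, in-frame, no internal stop) plus
#' optional named protein domain intervals. Protein length is the number of
#' encoded residues excluding the stop.
#'
#' @param gene gene identifier.
#' @param cds nucleotide string (A/C/G/T), length divisible by 3, beginning
#'   with ATG and ending with a stop codon.
#' @param domains optional data.frame (name, start_aa, end_aa), closed
#'   1-based amino-acid intervals within the protein.
#' @return An object of class `transcript_model` with fields gene, cds,
#'   protein_length and domains.
#' @examples
#' transcript_model("TOY", "ATGTGCGGATAA")
#' @export
transcript_model <- function(gene, cds, domains = NULL) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS may only contain A/C/G/T")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must begin with ATG")
  prot <- .translate_cds(cds)
  n <- nchar(prot)
  if (substr(prot, n, n) != "*") stop("CDS must end with a stop codon")
  if (grepl("\\*", substr(prot, 1, n - 1))) stop("CDS has an internal stop")
  protein_length <- n - 1L
  if (!is.null(domains)) {
    stopifnot(all(c("name", "start_aa", "end_aa") %in% names(domains)))
    ok <- domains$start_aa >= 1 & domains$start_aa <= domains$end_aa &
      domains$end_aa <= protein_length
    if (!all(ok)) {
      stop("domain interval(s) outside [1, protein_length]: ",
           paste(domains$name[!ok], collapse = ", "))
    }
  }
  structure(list(gene = gene, cds = cds,
                 protein_length = as.integer(protein_length),
                 domains = domains),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$gene, ":", nchar(x$cds), "nt CDS,",
      x$protein_length, "aa protein,",
      if (is.null(x$domains)) 0 else nrow(x$domains), "domain(s)\n")
  invisible(x)
}

## translate complete codons of a sequence; stops rendered "*"
.translate_cds <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     no.init.codon = TRUE))
}

#' Classify a variant's coding consequence
#'
#' Applies a replacement edit at a CDS position and classifies the effect by
#' comparing the mutated translation with the reference protein:
#' \itemize{
#'   \item position outside the CDS: `noncoding`;
#'   \item edit destroying the initiator ATG: `start_loss`;
#'   \item length change not divisible by 3: `frameshift`, with
#'     `truncation_aa` at the first stop codon encountered in the shifted
#'     frame (NA if none occurs before the CDS end);
#'   \item a premature stop in an in-frame edit: `nonsense` with
#'     `truncation_aa` at the new stop;
#'   \item otherwise `synonymous`, `missense` (with residue change) or
#'     `inframe_indel` by protein comparison.
#' }
#' Indels follow VCF anchored-base conventions (ref and alt both non-empty;
#' the edit replaces `ref` starting at `cds_pos` with `alt`). Only the
#' standard nuclear genetic code is used and only ATG is accepted as start.
#'
#' @param transcript a [transcript_model()].
#' @param cds_pos 1-based position in the CDS of the first replaced base.
#' @param ref,alt allele strings; `ref` must match the CDS at `cds_pos`.
#' @return An object of class `consequence_call`: list with effect,
#'   truncation_aa, aa_ref, aa_alt, codon_index.
#' @examples
#' tx <- transcript_model("TOY", "ATGTGCGGATAA")
#' call_consequence(tx, 6, "C", "A")   # TGC -> TGA: nonsense at codon 2
#' @export
call_consequence <- function(transcript, cds_pos, ref, alt) {
  stopifnot(inherits(transcript, "transcript_model"))
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(nzchar(ref), nzchar(alt))
  if (ref == alt) stop("ref and alt alleles must differ")
  cds <- transcript$cds
  L <- nchar(cds)
  out <- list(effect = NA_character_, truncation_aa = NA_integer_,
              aa_ref = NA_character_, aa_alt = NA_character_,
              codon_index = NA_integer_)
  class(out) <- "consequence_call"
  if (cds_pos < 1 || cds_pos > L) {
    out$effect <- "noncoding"
    return(out)
  }
  end <- cds_pos + nchar(ref) - 1L
  if (end > L) stop("ref allele extends beyond the CDS end")
  if (substr(cds, cds_pos, end) != ref) {
    stop("ref allele does not match the transcript CDS at position ", cds_pos)
  }
  mutated <- paste0(substr(cds, 1, cds_pos - 1), alt,
                    substr(cds, end + 1L, L))
  out$codon_index <- as.integer(ceiling(cds_pos / 3))
  if (substr(mutated, 1, 3) != "ATG") {
    out$effect <- "start_loss"
    out$codon_index <- 1L
    return(out)
  }
  shift <- (nchar(alt) - nchar(ref)) %% 3L
  prot_ref <- .translate_cds(cds)
  prot_mut <- .translate_cds(mutated)
  first_stop <- as.integer(regexpr("*", prot_mut, fixed = TRUE))
  if (shift != 0L) {
    out$effect <- "frameshift"
    out$truncation_aa <- if (first_stop > 0) first_stop else NA_integer_
    return(out)
  }
  if (prot_mut == prot_ref) {
    out$effect <- "synonymous"
    return(out)
  }
  # a stop is premature if it lands before where the (length-adjusted)
  # terminal stop of an in-frame edit would sit
  expected_stop <- transcript$protein_length +
    (nchar(alt) - nchar(ref)) / 3 + 1
  if (first_stop > 0 && first_stop < expected_stop) {
    out$effect <- "nonsense"
    out$truncation_aa <- first_stop
    return(out)
  }
  if (nchar(prot_mut) == nchar(prot_ref)) {
    d <- which(strsplit(prot_mut, "")[[1]] != strsplit(prot_ref, "")[[1]])[1]
    out$effect <- "missense"
    out$aa_ref <- substr(prot_ref, d, d)
    out$aa_alt <- substr(prot_mut, d, d)
    out$codon_index <- as.integer(d)
    return(out)
  }
  out$effect <- "inframe_indel"
  out
}

#' @export
print.consequence_call <- function(x, ...) {
  cat("consequence_call:", x$effect)
  if (!is.na(x$truncation_aa)) cat(", truncation at aa", x$truncation_aa)
  if (!is.na(x$aa_ref)) cat(sprintf(", p.%s%d%s", x$aa_ref, x$codon_index,
                                    x$aa_alt))
  cat("\n")
  invisible(x)
}

#' Partition protein domains by a truncation point
#'
#' A truncation at residue `truncation_aa` removes residues
#' `truncation_aa..protein_length`. A domain is retained iff it ends before
#' the truncation, lost iff it starts at or after it, and partial otherwise.
#'
#' @param protein_length protein length in residues.
#' @param truncation_aa truncation position, in \[1, protein_length\].
#' @param domains data.frame (name, start_aa, end_aa) of closed intervals.
#' @return List with character vectors `retained`, `lost`, `partial`; every
#'   domain appears in exactly one.
#' @examples
#' doms <- data.frame(name = c("A", "B"), start_aa = c(10, 600),
#'                    end_aa = c(100, 900))
#' domains_affected(1037, 560, doms)
#' @export
domains_affected <- function(protein_length, truncation_aa, domains) {
  stopifnot(truncation_aa >= 1, truncation_aa <= protein_length)
  if (is.null(domains) || nrow(domains) == 0) {
    return(list(retained = character(0), lost = character(0),
                partial = character(0)))
  }
  ok <- domains$start_aa >= 1 & domains$start_aa <= domains$end_aa &
    domains$end_aa <= protein_length
  if (!all(ok)) {
    stop("domain interval(s) outside [1, protein_length]: ",
         paste(domains$name[!ok], collapse = ", "))
  }
  retained <- domains$end_aa < truncation_aa
  lost <- domains$start_aa >= truncation_aa
  list(retained = domains$name[retained],
       lost = domains$name[lost],
       partial = domains$name[!retained & !lost])
}

#' Fraction of protein removed by a truncation
#'
#' @inheritParams domains_affected
#' @return `(protein_length - truncation_aa + 1) / protein_length`, in
#'   (0, 1\]: e.g. a stop at residue 211 of a 248-residue protein removes the
#'   38 terminal residues, fraction 38/248.
#' @examples
#' truncated_fraction(248, 211) * 248   # 38 residues removed
#' @export
truncated_fraction <- function(protein_length, truncation_aa) {
  stopifnot(protein_length >= 1)
  if (truncation_aa < 1 || truncation_aa > protein_length) {
    stop("truncation_aa must lie in [1, protein_length]")
  }
  (protein_length - truncation_aa + 1) / protein_length
}

.norm_label <- function(x) gsub("[ _]+", "_", tolower(trimws(x)))

#' Select damaging variants by effect class and prediction consensus
#'
#' Implements the study's inclusion rules. `truncating_only` keeps protein-
#' truncating classes (nonsense, frameshift, start_loss).
#' `truncating_plus_consensus_missense` additionally keeps missense variants
#' whose external predictions agree on the most deleterious category in both
#' tools: PolyPhen2 HumDiv "probably damaging" AND SIFT "damaging".
#'
#' @param calls data.frame with columns variant_id and effect.
#' @param labels data.frame (variant_id, polyphen_label, sift_label);
#'   required for every missense call in consensus mode. Labels are
#'   case-insensitive; spaces and underscores are equivalent.
#' @param mode selection rule (see above).
#' @return Character vector of included variant_ids (input order preserved).
#' @examples
#' calls <- data.frame(variant_id = c("v1", "v2"),
#'                     effect = c("nonsense", "missense"))
#' labs <- data.frame(variant_id = "v2", polyphen_label = "probably damaging",
#'                    sift_label = "damaging")
#' select_damaging(calls, labs, "truncating_plus_consensus_missense")
#' @export
select_damaging <- function(calls, labels = NULL,
                            mode = c("truncating_only",
                                     "truncating_plus_consensus_missense")) {
  mode <- match.arg(mode)
  stopifnot(all(c("variant_id", "effect") %in% names(calls)))
  truncating <- calls$effect %in% c("nonsense", "frameshift", "start_loss")
  keep <- truncating
  if (mode == "truncating_plus_consensus_missense") {
    mis <- calls$effect == "missense"
    if (any(mis)) {
      if (is.null(labels)) {
        stop("prediction labels required for missense variants: ",
             paste(calls$variant_id[mis], collapse = ", "))
      }
      idx <- match(calls$variant_id, labels$variant_id)
      unlabelled <- mis & is.na(idx)
      if (any(unlabelled)) {
        stop("missing prediction labels for missense variant(s): ",
             paste(calls$variant_id[unlabelled], collapse = ", "))
      }
      consensus <- .norm_label(labels$polyphen_label[idx]) ==
        "probably_damaging" & .norm_label(labels$sift_label[idx]) == "damaging"
      keep <- keep | (mis & !is.na(consensus) & consensus)
    }
  }
  calls$variant_id[keep]
}
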