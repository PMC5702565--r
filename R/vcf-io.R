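#' Write a cohort's genotypes as VCF 4.2
#'
#' Emits one biallelic record per locus with GT-only FORMAT: dosage 0 ->
#' "0/0", 1 -> "0/1", 2 -> "1/1", missing -> "./.". The gene symbol is
#' carried in INFO as `GENE=`.
#'
#' @param cohort a `cohort_genotypes` object.
#' @param path output file path (plain text `.vcf`).
#' @param phenotype_path optional path for a 2-column phenotype sheet
#'   (sample_id, status) written alongside the VCF.
#' @return `path`, invisibly.
#' @seealso [read_vcf()]
#' @export
write_vcf <- function(cohort, path, phenotype_path = NULL) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  gt <- matrix(c("0/0", "0/1", "1/1")[cohort$geno + 1L],
               nrow = nrow(cohort$geno))
  gt[is.na(gt)] <- "./."
  loci <- cohort$loci
  body <- cbind(loci$chrom, loci$pos, loci$variant_id, loci$ref, loci$alt,
                ".", "PASS", paste0("GENE=", loci$gene), "GT", gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ppromburden",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cohort$geno)), collapse = "\t"))
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  if (!is.null(phenotype_path)) {
    write_phenotype_sheet(cohort$samples, phenotype_path)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @param samples data.frame with columns sample_id and status.
#' @export
write_phenotype_sheet <- function(samples, path) {
  stopifnot(all(c("sample_id", "status") %in% names(samples)))
  write.table(samples[, c("sample_id", "status")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF plus phenotype sheet into a cohort
#'
#' Parses the VCF with `vcfR`, converts unphased or phased GT fields to
#' alt-allele dosages (missing calls "./."/"." become NA) and attaches
#' case/control labels from a 2-column TSV phenotype sheet. Every VCF sample
#' must appear in the sheet with status "case" or "control".
#'
#' @param path VCF file path.
#' @param phenotype_sheet path to the TSV (sample_id, status) or an
#'   equivalent data.frame.
#' @return A `cohort_genotypes` object.
#' @examples
#' ch <- gen_cohort(cohort_config(n_cases = 5, n_controls = 4, seed = 1))
#' f <- tempfile(fileext = ".vcf"); p <- tempfile(fileext = ".tsv")
#' write_vcf(ch, f, p)
#' ch2 <- read_vcf(f, p)
#' identical(ch$geno, ch2$geno)
#' @export
read_vcf <- function(path, phenotype_sheet) {
  pheno <- if (is.character(phenotype_sheet)) {
    read.delim(phenotype_sheet, colClasses = "character")
  } else {
    phenotype_sheet
  }
  stopifnot(all(c("sample_id", "status") %in% names(pheno)))
  bad_status <- setdiff(unique(pheno$status), c("case", "control"))
  if (length(bad_status)) {
    stop("phenotype status must be 'case' or 'control', found: ",
         paste(bad_status, collapse = ", "))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  missing_samples <- setdiff(colnames(gt_chr), pheno$sample_id)
  if (length(missing_samples)) {
    stop("sample(s) in VCF absent from phenotype sheet: ",
         paste(missing_samples, collapse = ", "))
  }
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
                   dimnames = dimnames(gt_chr))
  dosage[gt_chr %in% "0/0"] <- 0L
  dosage[gt_chr %in% c("0/1", "1/0")] <- 1L
  dosage[gt_chr %in% "1/1"] <- 2L
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gene <- ifelse(grepl("GENE=", fix$INFO),
                 sub(".*GENE=([^;]+).*", "\\1", fix$INFO), NA_character_)
  loci <- data.frame(gene = gene, variant_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  samples <- pheno[match(colnames(dosage), pheno$sample_id),
                   c("sample_id", "status")]
  rownames(samples) <- NULL
  structure(list(geno = dosage, loci = loci, samples = samples),
            class = "cohort_genotypes")
}

#' Read and write AIMs panel / dosage TSV files
#'
#' The panel TSV has columns marker_id, freq_popA, freq_popB; the dosage TSV
#' is markers x samples with marker ids in the first column.
#'
#' @param panel an [aims_panel()]; `path` a file path.
#' @return `read_panel()` returns an `aims_panel`;
#'   `read_aims_dosage()` an integer matrix.
#' @name panel_io
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @param path file path.
#' @export
read_panel <- function(path) {
  aims_panel(read.delim(path))
}

#' @rdname panel_io
#' @param dosages integer matrix, markers x samples.
#' @export
write_aims_dosage <- function(dosages, path) {
  write.table(data.frame(marker_id = rownames(dosages), dosages,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_aims_dosage <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  m
}
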