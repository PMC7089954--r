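#' Construct a genotype dataset
#'
#' The central container for a locus-wide variant panel: a variant map, a
#' minor-allele dosage matrix, and (optionally) phased haplotype alleles.
#' Dosages are oriented to the minor allele, determined once over all subjects
#' of the analysis set so effect directions are comparable across studies.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, `minor`, `maf`. Must be unique by (chrom, pos, ref, alt)
#'   and sorted by (chrom, pos).
#' @param subjects character vector of subject identifiers.
#' @param dosage integer matrix (variants x subjects) of minor-allele counts
#'   in \{0, 1, 2\}, `NA` for missing.
#' @param haplotypes optional 0/1 matrix (variants x 2*subjects) of phased
#'   alleles, 1 = minor allele; columns `2s - 1` and `2s` are subject `s`'s
#'   two chromosomes.
#' @param phase_prob optional per-subject phase confidence in \[0, 1\].
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(variants, subjects, dosage,
                             haplotypes = NULL, phase_prob = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt", "minor", "maf") %in%
                  names(variants)))
  if (any(variants$pos <= 0)) stop("variant positions must be positive")
  if (!all(variants$minor == variants$ref | variants$minor == variants$alt))
    stop("minor allele must be one of ref/alt")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) stop("variants must be unique by (chrom, pos, ref, alt)")
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants))))
    stop("variants must be sorted by (chrom, pos)")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(variants) || ncol(dosage) != length(subjects))
    stop("dosage dimensions inconsistent with variants/subjects")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (nrow(haplotypes) != nrow(variants) ||
        ncol(haplotypes) != 2L * length(subjects))
      stop("haplotype dimensions inconsistent")
    hsum <- haplotypes[, seq(1L, ncol(haplotypes), 2L), drop = FALSE] +
      haplotypes[, seq(2L, ncol(haplotypes), 2L), drop = FALSE]
    ok <- is.na(dosage) | (dosage == hsum)
    if (!all(ok)) stop("dosage must equal the sum of the two haplotype alleles")
  }
  if (!is.null(phase_prob)) {
    if (length(phase_prob) != length(subjects))
      stop("phase_prob must have one entry per subject")
    if (any(phase_prob < 0 | phase_prob > 1, na.rm = TRUE))
      stop("phase_prob must lie in [0, 1]")
  }
  rownames(dosage) <- variants$id
  colnames(dosage) <- subjects
  structure(list(variants = variants, subjects = as.character(subjects),
                 dosage = dosage, haplotypes = haplotypes,
                 phase_prob = phase_prob),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d variants x %d subjects (%s)\n",
              nrow(x$variants), length(x$subjects),
              if (is.null(x$haplotypes)) "unphased" else "phased"))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(nrow(x$variants), length(x$subjects))

#' Read a phenotype table
#'
#' Reads a tab-separated phenotype file with required columns `subject`,
#' `status` (case/control) and `study`. Optional columns: `age` (years at
#' diagnosis for cases, at screen for controls), clinical severity fields
#' (`stage`, `gleason_sum`, `psa_dx`, `prostatectomy`, `died_of_disease`),
#' and any numeric covariates named in `covariates` (e.g. ancestry principal
#' components).
#'
#' @param path path to a TSV file with a header.
#' @param covariates character vector of column names to treat as numeric
#'   model covariates; other unknown columns are carried along untouched.
#' @return data.frame of class `phenotype_table`, one row per subject, with
#'   attribute `covariates`.
#' @export
read_phenotypes <- function(path, covariates = character()) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("subject", "status", "study")
  miss <- setdiff(req, names(ph))
  if (length(miss)) stop("missing required phenotype columns: ",
                         paste(miss, collapse = ", "))
  ph$subject <- as.character(ph$subject)
  if (anyDuplicated(ph$subject))
    stop("duplicate subject ids: ",
         paste(unique(ph$subject[duplicated(ph$subject)]), collapse = ", "))
  bad <- which(!ph$status %in% c("case", "control"))
  if (length(bad))
    stop(sprintf("invalid status '%s' for subject '%s' (row %d)",
                 ph$status[bad[1]], ph$subject[bad[1]], bad[1]))
  for (cv in covariates) {
    if (!cv %in% names(ph)) stop("declared covariate not present: ", cv)
    ph[[cv]] <- as.numeric(ph[[cv]])
  }
  if ("age" %in% names(ph)) ph$age <- as.numeric(ph$age)
  attr(ph, "covariates") <- covariates
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Pair genotype datasets with phenotypes across studies
#'
#' A study collection maps study labels to (genotypes, phenotypes) pairs over
#' one shared variant map, the structure required by two-study replication
#' analyses.
#'
#' @param studies named list; each element a list with components `geno`
#'   (a [genotype_dataset]) and `pheno` (a phenotype data.frame).
#' @return object of class `study_collection`.
#' @export
study_collection <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1,
            !is.null(names(studies)), all(nzchar(names(studies))))
  ref <- studies[[1]]$geno$variants
  for (lab in names(studies)) {
    st <- studies[[lab]]
    if (!inherits(st$geno, "genotype_dataset"))
      stop("study '", lab, "' lacks a genotype_dataset")
    if (!identical(st$geno$variants$id, ref$id) ||
        !identical(st$geno$variants$pos, ref$pos))
      stop("study '", lab, "' has a different variant map")
    ph <- st$pheno
    if (!setequal(ph$subject, st$geno$subjects) ||
        nrow(ph) != length(st$geno$subjects))
      stop("study '", lab, "': phenotype rows do not match genotype subjects")
    # align phenotype rows to genotype subject order
    studies[[lab]]$pheno <- ph[match(st$geno$subjects, ph$subject), , drop = FALSE]
  }
  structure(list(studies = studies, variants = ref),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("study_collection: %d studies over %d variants\n",
              length(x$studies), nrow(x$variants)))
  for (lab in names(x$studies)) {
    ph <- x$studies[[lab]]$pheno
    cat(sprintf("  %s: %d cases / %d controls\n", lab,
                sum(ph$status == "case"), sum(ph$status == "control")))
  }
  invisible(x)
}

#' Case indicator aligned to a genotype dataset
#'
#' @param geno a [genotype_dataset].
#' @param pheno phenotype data.frame covering the dataset's subjects.
#' @return integer vector, 1 = case, 0 = control, in subject order.
#' @export
case_indicator <- function(geno, pheno) {
  idx <- match(geno$subjects, pheno$subject)
  if (anyNA(idx)) stop("phenotypes missing for some genotyped subjects")
  as.integer(pheno$status[idx] == "case")
}

#' Write any stage's result records as TSV
#'
#' Columns are written in their existing order; floating point values are
#' serialized at full precision (17 significant digits) so files round-trip
#' losslessly. P values are never written as 0: values below the documented
#' floor `1e-300` are written as `1e-300`.
#'
#' @param rows data.frame of results (may have zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- out[[j]]
      if (grepl("^p($|_)|^q($|_)|(_|\\b)p$", names(out)[j], ignore.case = TRUE))
        v <- pmax(v, 1e-300)
      out[[j]] <- sprintf("%.17g", v)
      out[[j]][is.na(v)] <- NA
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write results table: ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}
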