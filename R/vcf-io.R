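#' Read genotypes from a VCF file
#'
#' Parses bi-allelic SNVs from a VCF 4.2 file into a [genotype_dataset].
#' Dosages are oriented to the minor allele computed over all parsed subjects;
#' phased haplotype alleles are populated when every GT field uses the phased
#' `|` separator. Multi-allelic or non-SNV records and monomorphic variants
#' are skipped with a reported reason.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param phased_required if `TRUE`, an unphased GT is an error.
#' @return A [genotype_dataset]; attribute `skipped` is a data.frame of
#'   skipped records and reasons.
#' @export
read_genotypes_vcf <- function(path, phased_required = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  subjects <- colnames(gt)
  n <- nrow(fix)
  skipped <- list()
  keep <- logical(n)
  snv <- function(a) !is.na(a) & nchar(a) == 1 & a %in% c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    alt <- fix[i, "ALT"]
    if (is.na(alt) || grepl(",", alt)) {
      skipped[[length(skipped) + 1L]] <- c(i, "multi-allelic")
    } else if (!snv(fix[i, "REF"]) || !snv(alt)) {
      skipped[[length(skipped) + 1L]] <- c(i, "not a SNV")
    } else keep[i] <- TRUE
  }
  if (!any(keep)) stop("no bi-allelic SNV records in ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  sep_phased <- grepl("|", gt, fixed = TRUE)
  sep_unphased <- grepl("/", gt, fixed = TRUE)
  if (phased_required && any(sep_unphased & !is.na(gt)))
    stop("phased_required: unphased GT encountered")
  all_phased <- all(sep_phased[!is.na(gt)])

  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  dim(a1) <- dim(gt); dim(a2) <- dim(gt)
  alt_dose <- a1 + a2

  m <- nrow(gt)
  minor <- character(m); maf <- numeric(m)
  dosage <- matrix(NA_integer_, m, length(subjects))
  haps <- if (all_phased) matrix(NA_integer_, m, 2L * length(subjects)) else NULL
  poly <- logical(m)
  for (i in seq_len(m)) {
    ad <- alt_dose[i, ]
    af <- mean(ad, na.rm = TRUE) / 2
    if (is.nan(af) || af == 0 || af == 1) {
      skipped[[length(skipped) + 1L]] <- c(which(keep)[i], "monomorphic")
      next
    }
    poly[i] <- TRUE
    if (af <= 0.5) {
      minor[i] <- fix[i, "ALT"]; maf[i] <- af
      dosage[i, ] <- ad
      if (all_phased) {
        haps[i, seq(1, 2 * length(subjects), 2)] <- a1[i, ]
        haps[i, seq(2, 2 * length(subjects), 2)] <- a2[i, ]
      }
    } else {
      minor[i] <- fix[i, "REF"]; maf[i] <- 1 - af
      dosage[i, ] <- 2L - ad
      if (all_phased) {
        haps[i, seq(1, 2 * length(subjects), 2)] <- 1L - a1[i, ]
        haps[i, seq(2, 2 * length(subjects), 2)] <- 1L - a2[i, ]
      }
    }
  }
  if (!any(poly)) stop("all records monomorphic in ", path)
  variants <- data.frame(
    id = ifelse(is.na(fix[poly, "ID"]) | fix[poly, "ID"] == ".",
                paste0(fix[poly, "CHROM"], ":", fix[poly, "POS"]),
                fix[poly, "ID"]),
    chrom = fix[poly, "CHROM"],
    pos = as.integer(fix[poly, "POS"]),
    ref = fix[poly, "REF"], alt = fix[poly, "ALT"],
    minor = minor[poly], maf = maf[poly],
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(variants, subjects,
                         dosage[poly, , drop = FALSE],
                         haplotypes = if (all_phased) haps[poly, , drop = FALSE],
                         phase_prob = if (all_phased) rep(1, length(subjects)))
  skdf <- if (length(skipped)) {
    data.frame(record = as.integer(vapply(skipped, `[`, "", 1)),
               reason = vapply(skipped, `[`, "", 2))
  } else data.frame(record = integer(), reason = character())
  attr(ds, "skipped") <- skdf
  ds
}

#' Write a genotype dataset as a phased VCF
#'
#' Emits a minimal VCF 4.2 with GT fields. When phased haplotypes are present
#' they are written with the `|` separator (allele order preserved);
#' otherwise unphased `/` genotypes are derived from dosage.
#'
#' @param geno a [genotype_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_dataset"))
  va <- geno$variants
  ns <- length(geno$subjects)
  # convert minor-allele coding back to ref/alt coding
  flip <- va$minor == va$ref  # dosage counts ref copies at these sites
  if (!is.null(geno$haplotypes)) {
    h1 <- geno$haplotypes[, seq(1, 2 * ns, 2), drop = FALSE]
    h2 <- geno$haplotypes[, seq(2, 2 * ns, 2), drop = FALSE]
    h1[flip, ] <- 1L - h1[flip, , drop = FALSE]
    h2[flip, ] <- 1L - h2[flip, , drop = FALSE]
    gtm <- matrix(paste0(h1, "|", h2), nrow = nrow(va))
    gtm[is.na(h1) | is.na(h2)] <- ".|."
  } else {
    d <- geno$dosage
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
    gtm <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(va))
    gtm[is.na(d)] <- "./."
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=hapsentinel",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$subjects), collapse = "\t"))
  body <- paste(va$chrom, va$pos, va$id, va$ref, va$alt, ".", "PASS", ".",
                "GT", apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write phenotypes as TSV
#' @param pheno phenotype data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
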