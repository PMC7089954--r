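#' Squared dosage correlation (composite LD)
#'
#' r-squared between two variants' minor-allele dosage vectors over
#' pairwise-complete subjects. Computed on dosages rather than phased
#' haplotypes so it applies to unphased data; invariant under allele
#' recoding g -> 2 - g and under subject permutation.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return squared Pearson correlation in \[0, 1\]; 0 (with a warning) when
#'   either vector is constant over the complete pairs.
#' @export
dosage_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need at least 2 complete pairs")
  a <- a[ok]; b <- b[ok]
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) {
    warning("constant dosage vector; LD undefined, returning 0")
    return(0)
  }
  r <- stats::cor(a, b)
  min(r * r, 1)
}

#' Pairwise LD (r-squared) matrix
#'
#' @param geno a [genotype_dataset] or a dosage matrix (variants x subjects).
#' @param subjects optional subject subset (character ids or indices); by
#'   default all subjects enter the LD computation.
#' @return symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
r2_matrix <- function(geno, subjects = NULL) {
  d <- if (inherits(geno, "genotype_dataset")) geno$dosage else as.matrix(geno)
  if (!is.null(subjects)) {
    if (is.character(subjects)) {
      if (!inherits(geno, "genotype_dataset"))
        stop("character subject subset requires a genotype_dataset")
      subjects <- match(subjects, geno$subjects)
      if (anyNA(subjects)) stop("unknown subjects in subset")
    }
    if (!length(subjects)) stop("subject subset is empty")
    d <- d[, subjects, drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  m <- r * r
  m[m > 1] <- 1
  diag(m) <- 1
  dimnames(m) <- list(rownames(d), rownames(d))
  m
}
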