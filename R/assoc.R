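#' Single-variant association scan
#'
#' Fits the additive logistic model per variant, routing separated or
#' non-converged fits to the penalized-likelihood fallback test. Untestable
#' variants (monomorphic in the analyzed subjects, or unfittable) are
#' reported with a reason rather than dropped silently.
#'
#' @param geno a [genotype_dataset].
#' @param pheno phenotype data.frame covering the dataset's subjects.
#' @param covariates character vector of numeric covariate column names in
#'   `pheno` (e.g. ancestry principal components), or `NULL`.
#' @param scope label recorded in the `scope` column (defaults to the single
#'   study label in `pheno` if unique).
#' @return data.frame with one row per variant: `variant, scope, beta, se,
#'   or, ci_low, ci_high, p, test, n, direction, note`.
#' @export
scan_variants <- function(geno, pheno, covariates = NULL, scope = NULL) {
  status <- case_indicator(geno, pheno)
  if (is.null(scope)) {
    u <- unique(pheno$study)
    scope <- if (length(u) == 1) u else "combined"
  }
  cv <- NULL
  if (!is.null(covariates) && length(covariates)) {
    miss <- setdiff(covariates, names(pheno))
    if (length(miss)) stop("covariates not in phenotype table: ",
                           paste(miss, collapse = ", "))
    cv <- pheno[match(geno$subjects, pheno$subject), covariates, drop = FALSE]
  }
  m <- nrow(geno$variants)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    d <- geno$dosage[i, ]
    res <- tryCatch(fit_additive_logistic(d, status, cv),
                    error = function(e) e)
    note <- ""
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(variant = geno$variants$id[i], scope = scope,
                              beta = NA_real_, se = NA_real_, or = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_, test = "none", n = NA_integer_,
                              direction = NA_real_,
                              note = paste0("untestable: ",
                                            conditionMessage(res)),
                              stringsAsFactors = FALSE)
      next
    }
    if (res$separated) {
      res2 <- tryCatch(separation_fallback_test(d, status),
                       error = function(e) NULL)
      if (!is.null(res2)) { res <- res2; note <- "separation fallback" }
    }
    rows[[i]] <- data.frame(variant = geno$variants$id[i], scope = scope,
                            beta = res$beta, se = res$se, or = res$or_,
                            ci_low = res$ci95[1], ci_high = res$ci95[2],
                            p = res$p, test = res$test, n = res$n_used,
                            direction = res$direction, note = note,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted q-values, monotone non-decreasing in P-value rank.
#'
#' @param pvals vector of P values in (0, 1\].
#' @return vector of BH-adjusted q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of (possibly non-independent) tests.
#' @return list with `threshold = alpha/m` and `rendered`, the
#'   one-significant-figure value used for reporting.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  thr <- alpha / m
  list(threshold = thr, rendered = signif(thr, 1))
}

#' Two-study concordance (replication) filter
#'
#' Retains variants nominally significant in both studies separately
#' (`P <= alpha`, inclusive) with consistent direction of effect.
#'
#' @param results_a,results_b scan result data.frames over a shared variant
#'   map (as from [scan_variants()]).
#' @param alpha per-study significance level (default 0.05).
#' @return data.frame of retained variants with both studies' statistics
#'   (suffixes `_a`, `_b`).
#' @export
concordance_filter <- function(results_a, results_b, alpha = 0.05) {
  shared <- intersect(results_a$variant, results_b$variant)
  if (!length(shared)) stop("disjoint variant maps")
  a <- results_a[match(shared, results_a$variant), , drop = FALSE]
  b <- results_b[match(shared, results_b$variant), , drop = FALSE]
  keep <- !is.na(a$p) & !is.na(b$p) & a$p <= alpha & b$p <= alpha &
    !is.na(a$direction) & !is.na(b$direction) &
    a$direction == b$direction & a$direction != 0
  out <- data.frame(variant = shared, stringsAsFactors = FALSE)
  for (cl in c("scope", "beta", "or", "ci_low", "ci_high", "p", "test", "n",
               "direction"))
    out[[paste0(cl, "_a")]] <- a[[cl]]
  for (cl in c("scope", "beta", "or", "ci_low", "ci_high", "p", "test", "n",
               "direction"))
    out[[paste0(cl, "_b")]] <- b[[cl]]
  out[keep, , drop = FALSE]
}

#' Combined-study association scan
#'
#' Pools subjects of all member studies and fits the additive model per
#' variant, by default with a fixed study main effect guarding against
#' frequency drift between studies. Flags genome-wide significance at the
#' `P <= 5e-8` convention (inclusive).
#'
#' @param collection a [study_collection].
#' @param variants optional variant id subset (default: all).
#' @param genomewide_alpha genome-wide significance level.
#' @param study_covariate include a study indicator covariate (default TRUE).
#' @param covariates optional numeric covariate names present in every
#'   study's phenotype table.
#' @return scan data.frame with scope `"combined"` plus `genomewide` flag.
#' @export
combined_scan <- function(collection, variants = NULL,
                          genomewide_alpha = 5e-8, study_covariate = TRUE,
                          covariates = NULL) {
  stopifnot(inherits(collection, "study_collection"))
  labs <- names(collection$studies)
  dos <- do.call(cbind, lapply(collection$studies, function(s) s$geno$dosage))
  status <- unlist(lapply(collection$studies, function(s)
    case_indicator(s$geno, s$pheno)), use.names = FALSE)
  study <- factor(rep(labs, vapply(collection$studies,
                                   function(s) length(s$geno$subjects), 0L)),
                  levels = labs)
  ids <- collection$variants$id
  sel <- if (is.null(variants)) seq_along(ids) else match(variants, ids)
  if (anyNA(sel)) stop("unknown variants requested")
  cvdf <- NULL
  if (study_covariate) cvdf <- data.frame(study = study)
  if (!is.null(covariates) && length(covariates)) {
    cc <- do.call(rbind, lapply(collection$studies, function(s)
      s$pheno[, covariates, drop = FALSE]))
    cvdf <- if (is.null(cvdf)) cc else cbind(cvdf, cc)
  }
  rows <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    res <- tryCatch(fit_additive_logistic(dos[i, ], status, cvdf),
                    error = function(e) e)
    note <- ""
    if (!inherits(res, "error") && res$separated) {
      res2 <- tryCatch(separation_fallback_test(dos[i, ], status),
                       error = function(e) NULL)
      if (!is.null(res2)) { res <- res2; note <- "separation fallback" }
    }
    if (inherits(res, "error")) {
      rows[[k]] <- data.frame(variant = ids[i], scope = "combined",
                              beta = NA_real_, se = NA_real_, or = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_, test = "none", n = NA_integer_,
                              direction = NA_real_, genomewide = FALSE,
                              note = paste0("untestable: ",
                                            conditionMessage(res)),
                              stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- data.frame(variant = ids[i], scope = "combined",
                              beta = res$beta, se = res$se, or = res$or_,
                              ci_low = res$ci95[1], ci_high = res$ci95[2],
                              p = res$p, test = res$test, n = res$n_used,
                              direction = res$direction,
                              genomewide = !is.na(res$p) &&
                                res$p <= genomewide_alpha,
                              note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Association adjusted for a fixed variant list
#'
#' For each test variant, fits a multivariable model containing it plus all
#' adjustment-variant dosages concurrently, reporting the test variant's
#' adjusted OR/CI/P. Perfectly collinear adjustment variants (pairwise
#' r-squared 1) are deduplicated keeping the lowest position, with a warning.
#'
#' @param geno a [genotype_dataset] (or a study-pooled dosage matrix with a
#'   `variants` data.frame attribute is not supported; pool first).
#' @param pheno phenotype table covering the dataset.
#' @param test_variants variant ids to test.
#' @param adjustment_variants variant ids adjusted for; must not contain the
#'   variant under test.
#' @param covariates optional numeric covariate names in `pheno`.
#' @return data.frame (variant, beta_adj, se_adj, or_adj, ci_low_adj,
#'   ci_high_adj, p_adj, converged, n).
#' @export
adjusted_scan <- function(geno, pheno, test_variants, adjustment_variants,
                          covariates = NULL) {
  ids <- geno$variants$id
  if (any(!test_variants %in% ids) || any(!adjustment_variants %in% ids))
    stop("unknown variant ids")
  status <- case_indicator(geno, pheno)
  cv <- if (!is.null(covariates))
    pheno[match(geno$subjects, pheno$subject), covariates, drop = FALSE]
  # deduplicate perfect proxies within the adjustment set
  adj <- adjustment_variants
  if (length(adj) > 1) {
    r2 <- r2_matrix(geno$dosage[match(adj, ids), , drop = FALSE])
    pos <- geno$variants$pos[match(adj, ids)]
    drop <- logical(length(adj))
    for (i in seq_along(adj)) for (j in seq_along(adj)) {
      if (i < j && !drop[i] && !drop[j] && r2[i, j] >= 1 - 1e-12)
        drop[if (pos[i] <= pos[j]) j else i] <- TRUE
    }
    if (any(drop)) {
      warning("dropping perfectly collinear adjustment variants: ",
              paste(adj[drop], collapse = ", "))
      adj <- adj[!drop]
    }
  }
  rows <- vector("list", length(test_variants))
  for (k in seq_along(test_variants)) {
    tv <- test_variants[k]
    if (tv %in% adj) stop("test variant '", tv, "' is in the adjustment set")
    sub <- t(geno$dosage[match(c(tv, adj), ids), , drop = FALSE])
    colnames(sub) <- c(tv, adj)
    fit <- fit_joint_model(sub, status, cv)
    if (fit$converged) {
      r <- fit$results[fit$results$variant == tv, ]
      rows[[k]] <- data.frame(variant = tv, beta_adj = r$beta, se_adj = r$se,
                              or_adj = r$or_, ci_low_adj = r$ci_low,
                              ci_high_adj = r$ci_high, p_adj = r$p,
                              converged = TRUE, n = fit$n_used,
                              stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- data.frame(variant = tv, beta_adj = NA_real_,
                              se_adj = NA_real_, or_adj = NA_real_,
                              ci_low_adj = NA_real_, ci_high_adj = NA_real_,
                              p_adj = NA_real_, converged = FALSE,
                              n = fit$n_used, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
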