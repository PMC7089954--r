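# Clinical severity classification and genotype modifier tests.

# normalize a TNM-style stage string to its T level plus N1/M1 flags
parse_stage <- function(stage) {
  if (is.na(stage) || !nzchar(stage)) return(NULL)
  s <- toupper(gsub("\\s", "", stage))
  s <- sub("^P", "", s)  # pathologic prefix pT3 -> T3
  n1 <- grepl("N1", s); m1 <- grepl("M1", s)
  tm <- regmatches(s, regexpr("T[0-4][A-C]?", s))
  if (!length(tm) && !n1 && !m1) return(NA)  # unparseable
  tlevel <- if (length(tm)) as.integer(substr(tm, 2, 2)) else NA_integer_
  tsub <- if (length(tm) && nchar(tm) == 3) substr(tm, 3, 3) else NA_character_
  list(t = tlevel, sub = tsub, n1 = n1, m1 = m1)
}

#' Classify case severity from clinical fields
#'
#' Three-level classification by consortium-style clinical criteria,
#' evaluated aggressive first:
#' \itemize{
#'   \item aggressive: extra-prostatic stage at diagnosis (T3 or higher, N1,
#'     or M1), or Gleason sum >= 8, or PSA >= 20 ng/ml at diagnosis, or
#'     death from prostate cancer;
#'   \item insignificant: stage T1, or confined to one lobe (T2a) if
#'     prostatectomy was done, with no evidence of extra-prostatic disease,
#'     Gleason sum <= 6, PSA <= 4 ng/ml, and no death from prostate cancer;
#'   \item moderate: cases meeting neither rule.
#' }
#' Boundary values are inclusive exactly as stated. Records lacking the
#' fields required to decide are `unclassifiable`.
#'
#' @param stage TNM-style stage string (e.g. "T2a", "pT3", "T3aN1").
#' @param gleason_sum integer Gleason sum.
#' @param psa_dx PSA at diagnosis (ng/ml).
#' @param prostatectomy logical, prostatectomy done.
#' @param died_of_disease logical, death attributed to prostate cancer.
#' @return list with `category` (aggressive | moderate | insignificant |
#'   unclassifiable) and `rules`, the clauses that triggered it.
#' @export
classify_severity <- function(stage = NA, gleason_sum = NA, psa_dx = NA,
                              prostatectomy = NA, died_of_disease = NA) {
  st <- parse_stage(stage)
  unparseable <- length(st) == 1 && is.na(st[[1]])
  rules <- character(0)
  # aggressive clauses (any one suffices)
  if (!unparseable && !is.null(st)) {
    if (!is.na(st$t) && st$t >= 3) rules <- c(rules, "stage >= T3")
    if (st$n1) rules <- c(rules, "N1")
    if (st$m1) rules <- c(rules, "M1")
  }
  if (!is.na(gleason_sum) && gleason_sum >= 8) rules <- c(rules, "Gleason >= 8")
  if (!is.na(psa_dx) && psa_dx >= 20) rules <- c(rules, "PSA >= 20")
  if (isTRUE(died_of_disease)) rules <- c(rules, "lethal disease")
  if (length(rules))
    return(list(category = "aggressive", rules = rules))
  # insignificant: all clauses required
  if (is.null(st) || unparseable || is.na(gleason_sum) || is.na(psa_dx) ||
      is.na(died_of_disease))
    return(list(category = "unclassifiable",
                rules = "missing required fields"))
  organ_confined <- (!is.na(st$t) && st$t == 1) ||
    (!is.na(st$t) && st$t == 2 && identical(st$sub, "A") &&
       isTRUE(prostatectomy))
  if ((!is.na(st$t) && st$t == 2 && identical(st$sub, "A") &&
       is.na(prostatectomy)))
    return(list(category = "unclassifiable",
                rules = "missing required fields"))
  insig <- organ_confined && !st$n1 && !st$m1 && gleason_sum <= 6 &&
    psa_dx <= 4 && !isTRUE(died_of_disease)
  if (insig)
    return(list(category = "insignificant",
                rules = c("organ-confined", "Gleason <= 6", "PSA <= 4",
                          "not lethal")))
  list(category = "moderate", rules = "neither aggressive nor insignificant")
}

#' Classify severity for every case in a phenotype table
#'
#' @param pheno phenotype data.frame with clinical columns `stage`,
#'   `gleason_sum`, `psa_dx`, `prostatectomy`, `died_of_disease`.
#' @return character vector of categories (NA for controls).
#' @export
classify_severity_table <- function(pheno) {
  out <- rep(NA_character_, nrow(pheno))
  for (i in which(pheno$status == "case")) {
    out[i] <- classify_severity(pheno$stage[i], pheno$gleason_sum[i],
                                pheno$psa_dx[i], pheno$prostatectomy[i],
                                pheno$died_of_disease[i])$category
  }
  out
}

#' Age-at-diagnosis modifier test
#'
#' Two-sided Wilcoxon rank-sum test comparing age at diagnosis between
#' carriers (dosage >= 1) and non-carriers among cases; reports the mean age
#' difference (carriers minus non-carriers) in years. The exact distribution
#' is used for combined group sizes up to 50 (without ties), the normal
#' approximation with continuity correction above.
#'
#' @param dosage minor-allele dosage among cases.
#' @param age age at diagnosis (years) among the same cases.
#' @param coding `"carrier"` (default) dichotomizes at dosage >= 1;
#'   `"trend"` uses a rank correlation across the three dosage groups via a
#'   Kruskal-Wallis test.
#' @return list of class `modifier_result`: `comparison`, `statistic`, `p`,
#'   `effect` (mean age difference in years), `n` per group.
#' @export
age_at_diagnosis_test <- function(dosage, age, coding = c("carrier",
                                                          "trend")) {
  coding <- match.arg(coding)
  ok <- !is.na(dosage) & !is.na(age)
  dosage <- dosage[ok]; age <- age[ok]
  if (coding == "trend") {
    kt <- stats::kruskal.test(age, factor(dosage))
    return(structure(list(comparison = "age", statistic = unname(kt$statistic),
                          p = kt$p.value, effect = NA_real_,
                          n = table(dosage)), class = "modifier_result"))
  }
  carrier <- dosage >= 1
  n1 <- sum(carrier); n0 <- sum(!carrier)
  if (n1 < 2 || n0 < 2) stop("need >= 2 carriers and >= 2 non-carriers")
  exact <- (n1 + n0) <= 50
  wt <- suppressWarnings(stats::wilcox.test(age[carrier], age[!carrier],
                                            exact = exact, correct = TRUE))
  structure(list(comparison = "age", statistic = unname(wt$statistic),
                 p = wt$p.value,
                 effect = mean(age[carrier]) - mean(age[!carrier]),
                 n = c(carriers = n1, noncarriers = n0)),
            class = "modifier_result")
}

#' Dichotomized severity comparison
#'
#' Additive logistic regression of severity-group membership on dosage for
#' one of the three pairwise comparisons (aggressive vs insignificant,
#' moderate vs insignificant, aggressive vs moderate), optionally adjusted
#' for covariates (default unadjusted). Separated fits fall back to the
#' penalized-likelihood test.
#'
#' @param dosage minor-allele dosage among cases.
#' @param categories severity category per case (as from
#'   [classify_severity_table()]).
#' @param pair length-2 character: (group coded 1, group coded 0), e.g.
#'   `c("aggressive", "insignificant")`.
#' @param covariates optional numeric covariate data.frame.
#' @return `modifier_result` with OR of the first group per minor allele.
#' @export
severity_comparison <- function(dosage, categories, pair, covariates = NULL) {
  stopifnot(length(pair) == 2)
  sel <- categories %in% pair & !is.na(dosage)
  if (!any(categories[sel] == pair[1]) || !any(categories[sel] == pair[2]))
    stop("empty severity group in comparison ",
         paste(pair, collapse = " vs "))
  y <- as.integer(categories[sel] == pair[1])
  d <- dosage[sel]
  cv <- if (!is.null(covariates)) covariates[sel, , drop = FALSE]
  res <- fit_additive_logistic(d, y, cv)
  if (res$separated)
    res <- separation_fallback_test(d, y)
  structure(list(comparison = paste(pair, collapse = "-vs-"),
                 statistic = res$beta / res$se, p = res$p,
                 effect = res$or_, ci95 = res$ci95, test = res$test,
                 n = c(table(factor(categories[sel], levels = pair)))),
            class = "modifier_result")
}

#' @export
print.modifier_result <- function(x, ...) {
  cat(sprintf("%s: P = %.4g, effect = %.3f (n: %s)\n", x$comparison, x$p,
              x$effect, paste(x$n, collapse = "/")))
  invisible(x)
}
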