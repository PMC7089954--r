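# Logistic fitting machinery shared by the association, haplotype, sentinel
# and modifier stages. Single-variant additive fits with no continuous
# covariates are computed on the aggregated dosage-level binomial likelihood,
# which has the same MLE and Wald covariance as the subject-level fit but is
# independent of n once tabulated.

P_FLOOR <- 1e-300
BETA_OVERFLOW <- 10   # |log OR| beyond this is treated as a separated fit
SE_OVERFLOW <- 15

new_assoc_result <- function(variant = NA_character_, scope = NA_character_,
                             beta = NA_real_, se = NA_real_, p = NA_real_,
                             test = "wald", n_used = NA_integer_,
                             covariates_used = character(),
                             converged = FALSE, separated = FALSE) {
  or_ <- exp(beta)
  structure(list(variant = variant, scope = scope, beta = beta, se = se,
                 or_ = or_,
                 ci95 = if (test == "wald" && is.finite(se))
                   exp(beta + c(-1, 1) * 1.959963984540054 * se)
                 else c(NA_real_, NA_real_),
                 p = if (is.na(p)) NA_real_ else max(p, P_FLOOR),
                 test = test, n_used = n_used,
                 direction = sign(beta), covariates_used = covariates_used,
                 converged = converged, separated = separated),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s [%s] OR=%.3f (95%% CI %.3f-%.3f) P=%.3g test=%s n=%d\n",
              ifelse(is.na(x$variant), "<variant>", x$variant),
              ifelse(is.na(x$scope), "-", x$scope),
              x$or_, x$ci95[1], x$ci95[2], x$p, x$test, x$n_used))
  invisible(x)
}

# aggregated binomial fit of status ~ dosage (+ stratum dummies)
fit_dosage_aggregated <- function(dosage, status, strata = NULL) {
  if (is.null(strata)) strata <- factor(rep(1L, length(dosage)))
  key <- paste(dosage, as.integer(strata), sep = "\r")
  cases <- tapply(status, key, sum)
  tot <- tapply(status, key, length)
  lev <- do.call(rbind, strsplit(names(cases), "\r", fixed = TRUE))
  d <- as.numeric(lev[, 1])
  X <- cbind(`(Intercept)` = 1, dosage = d)
  if (nlevels(strata) > 1) {
    sf <- factor(as.integer(lev[, 2]), levels = seq_len(nlevels(strata)))
    mm <- stats::model.matrix(~sf)[, -1, drop = FALSE]
    colnames(mm) <- paste0("study", levels(strata)[-1])
    X <- cbind(X, mm)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, cbind(cases, tot - cases), family = stats::binomial()))
  list(fit = fit, X = X)
}

wald_from_glmfit <- function(fit, X) {
  beta <- fit$coefficients
  rank_ok <- fit$rank == ncol(X) && !anyNA(beta)
  se <- rep(NA_real_, length(beta))
  if (rank_ok) {
    w <- fit$weights
    xtwx <- crossprod(X * sqrt(w))
    cov <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(diag(cov))
  }
  names(se) <- colnames(X)
  list(beta = beta, se = se, rank_ok = rank_ok)
}

#' Single-variant additive logistic association
#'
#' Maximum-likelihood fit of `logit P(case) = alpha + beta * dosage`
#' (+ covariates), the multiplicative (additive on the logit scale) genetic
#' model. Significance by a two-sided Wald test; 95% CI as
#' `exp(beta +/- 1.96 SE)`. Separated or non-converged fits are flagged so
#' the caller can route to [separation_fallback_test()].
#'
#' @param dosage minor-allele dosage vector (0/1/2, `NA` allowed).
#' @param status case indicator (1/0, or "case"/"control").
#' @param covariates optional data.frame/matrix of covariates; a single
#'   factor/character column (e.g. study) keeps the fast aggregated path.
#' @return An `assoc_result` list: `beta`, `or_`, `ci95`, `p`, `test`,
#'   `n_used`, `direction`, `converged`, `separated`.
#' @export
fit_additive_logistic <- function(dosage, status, covariates = NULL) {
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  ok <- !is.na(dosage) & !is.na(status)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  d <- dosage[ok]; y <- status[ok]
  n <- length(d)
  if (sum(y) == 0 || sum(y) == n) stop("need at least one case and one control")
  if (length(unique(d)) < 2) stop("constant dosage")

  single_factor <- !is.null(covariates) && ncol(covariates) == 1 &&
    (is.factor(covariates[[1]]) || is.character(covariates[[1]]))
  if (is.null(covariates) || single_factor) {
    strata <- if (single_factor) factor(covariates[[1]][ok]) else NULL
    agg <- fit_dosage_aggregated(d, y, strata)
    fit <- agg$fit; X <- agg$X
    cov_used <- if (single_factor) names(covariates) else character()
  } else {
    cv <- covariates[ok, , drop = FALSE]
    mm <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    X <- cbind(`(Intercept)` = 1, dosage = d, mm)
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    cov_used <- names(covariates)
  }
  w <- wald_from_glmfit(fit, X)
  b <- unname(w$beta["dosage"]); se <- unname(w$se["dosage"])
  separated <- !fit$converged || !w$rank_ok || !is.finite(se) ||
    abs(b) > BETA_OVERFLOW || se > SE_OVERFLOW
  p <- if (separated) NA_real_ else 2 * stats::pnorm(-abs(b / se))
  new_assoc_result(beta = b, se = se, p = p, test = "wald", n_used = n,
                   covariates_used = cov_used,
                   converged = fit$converged && w$rank_ok,
                   separated = separated)
}

# Firth-penalized logistic regression (Jeffreys prior), intercept included
# in X. Accepts aggregated binomial rows (y successes of tot trials); the
# penalized estimates are identical to the subject-level fit.
firth_logistic <- function(X, y, tot = rep(1, length(y)), maxit = 60,
                           tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- tot * mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    cinfo <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(cinfo)) break
    hi <- rowSums((XW %*% chol2inv(cinfo)) * XW)  # leverage per row
    U <- crossprod(X, y - tot * mu + hi * (0.5 - mu))
    delta <- drop(chol2inv(cinfo) %*% U)
    # step-halving to keep the penalized log-likelihood increasing
    step <- 1
    repeat {
      bnew <- beta + step * delta
      etan <- drop(X %*% bnew)
      mun <- stats::plogis(etan)
      lln <- sum(y * log(pmax(mun, 1e-12)) +
                   (tot - y) * log(pmax(1 - mun, 1e-12)))
      wn <- tot * mun * (1 - mun)
      infon <- crossprod(X * sqrt(wn))
      detn <- determinant(infon, logarithm = TRUE)$modulus
      plln <- lln + 0.5 * detn
      if (plln >= loglik - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    moved <- max(abs(bnew - beta))
    beta <- bnew; loglik <- plln
    if (moved < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * sqrt(tot * mu * (1 - mu)))
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, se = sqrt(diag(cov)), penalized_loglik = as.numeric(loglik),
       converged = converged)
}

# Firth null fit with the slope constrained to zero but the Jeffreys
# penalty taken from the full two-parameter information (the standard
# penalized-likelihood-ratio construction)
firth_null_constrained <- function(X, y, tot) {
  pl <- function(alpha) {
    mu <- stats::plogis(alpha)
    w <- tot * mu * (1 - mu)
    ll <- sum(y * log(pmax(mu, 1e-12)) + (tot - y) * log(pmax(1 - mu,
                                                              1e-12)))
    info <- crossprod(X * sqrt(w))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  opt <- stats::optimize(pl, c(-15, 15), maximum = TRUE)
  as.numeric(opt$objective)
}

# penalized-likelihood LRT on aggregated counts (cases of tot at dosage d)
firth_fallback_counts <- function(d, cases, tot) {
  keep <- tot > 0
  d <- d[keep]; cases <- cases[keep]; tot <- tot[keep]
  if (length(unique(d)) < 2) return(NULL)
  X <- cbind(1, d)
  f1 <- firth_logistic(X, cases, tot)
  pl0 <- firth_null_constrained(X, cases, tot)
  stat <- max(0, 2 * (f1$penalized_loglik - pl0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(beta = f1$beta[2], se = f1$se[2], p = max(p, P_FLOOR),
       separated = TRUE)
}

#' Penalized-likelihood fallback test for separated data
#'
#' When genotype perfectly predicts case-control status (or the Wald fit
#' fails to converge), association is assessed by a likelihood-ratio
#' chi-squared test comparing the null and dosage models, both fitted by
#' Firth-penalized likelihood, which is finite under separation. The effect
#' is reported as the penalized estimate.
#'
#' @inheritParams fit_additive_logistic
#' @return An `assoc_result` with `test = "choi_lrt"` and a finite P.
#' @export
separation_fallback_test <- function(dosage, status) {
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  ok <- !is.na(dosage) & !is.na(status)
  d <- dosage[ok]; y <- status[ok]
  if (length(unique(d)) < 2) stop("constant dosage: untestable")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one case and one control")
  # aggregate by dosage level: identical penalized fit, faster
  lev <- sort(unique(d))
  cases <- vapply(lev, function(v) sum(y[d == v]), 0)
  tot <- vapply(lev, function(v) sum(d == v), 0)
  fb <- firth_fallback_counts(lev, cases, tot)
  res <- new_assoc_result(beta = fb$beta, se = fb$se, p = fb$p,
                          test = "choi_lrt", n_used = length(y),
                          converged = TRUE, separated = TRUE)
  res$ci95 <- exp(fb$beta + c(-1, 1) * 1.959963984540054 * fb$se)
  res
}

#' Multivariable additive logistic fit over a set of variants
#'
#' Regresses case status against all supplied variant dosages concurrently.
#' Convergence requires IRLS convergence, a full-rank design, finite standard
#' errors, and all |log OR| below an overflow bound; rank-deficient designs
#' (e.g. perfect duplicate variants) count as non-converged.
#'
#' @param X subjects x variants dosage matrix (column names = variant ids).
#' @param status case indicator.
#' @param covariates optional numeric covariate data.frame.
#' @return list with `converged` flag and, when converged, data.frame
#'   `results` (variant, beta, se, or, ci, p) plus `model_p` (LRT against the
#'   null model) and `lp` (linear predictor per subject).
#' @export
fit_joint_model <- function(X, status, covariates = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("empty variant list")
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  ok <- stats::complete.cases(X) & !is.na(status)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  Xc <- X[ok, , drop = FALSE]; y <- status[ok]
  vn <- colnames(Xc)
  if (is.null(vn)) vn <- paste0("v", seq_len(ncol(Xc)))
  D <- cbind(`(Intercept)` = 1, Xc)
  if (!is.null(covariates))
    D <- cbind(D, as.matrix(covariates[ok, , drop = FALSE]))
  fit <- suppressWarnings(stats::glm.fit(D, y, family = stats::binomial()))
  w <- wald_from_glmfit(fit, D)
  kv <- seq_len(ncol(Xc)) + 1L
  bad <- !fit$converged || !w$rank_ok || anyNA(w$se[kv]) ||
    any(!is.finite(w$se[kv])) || max(abs(w$beta[kv])) > BETA_OVERFLOW ||
    max(w$se[kv]) > SE_OVERFLOW
  if (bad)
    return(list(converged = FALSE, results = NULL, model_p = NA_real_,
                lp = NULL, n_used = sum(ok)))
  b <- w$beta[kv]; se <- w$se[kv]
  z <- b / se
  results <- data.frame(
    variant = vn, beta = unname(b), se = unname(se), or_ = exp(unname(b)),
    ci_low = exp(unname(b) - 1.959963984540054 * unname(se)),
    ci_high = exp(unname(b) + 1.959963984540054 * unname(se)),
    p = pmax(2 * stats::pnorm(-abs(unname(z))), P_FLOOR),
    stringsAsFactors = FALSE)
  lrt <- max(0, fit$null.deviance - fit$deviance)
  model_p <- stats::pchisq(lrt, df = ncol(Xc) +
                             if (is.null(covariates)) 0 else ncol(covariates),
                           lower.tail = FALSE)
  list(converged = TRUE, results = results,
       model_p = max(model_p, P_FLOOR),
       coefficients = w$beta, lp = drop(D %*% w$beta), n_used = sum(ok))
}
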