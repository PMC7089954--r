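#' Rank-based AUC
#'
#' Area under the ROC curve computed as all case-control pair concordance
#' (Mann-Whitney identity), with ties counted 0.5.
#'
#' @param scores risk score (linear predictor) per subject.
#' @param status case indicator (1 = case, or "case"/"control").
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, status) {
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  ok <- !is.na(scores) & !is.na(status)
  scores <- scores[ok]; status <- status[ok]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  r <- rank(scores)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the sentinel risk model
#'
#' Multivariable additive logistic regression of case status on sentinel
#' dosages. The linear predictor `alpha + sum beta_j dosage_j` is the risk
#' score. An empty sentinel set yields the intercept-only model, whose
#' constant score gives AUC 0.5 by convention.
#'
#' @param X subjects x sentinels dosage matrix (0 columns allowed).
#' @param status case indicator.
#' @return list of class `sentinel_fit`: `coefficients` (named, including
#'   intercept), `lp` (linear predictor), `converged`, `auc` (apparent).
#' @export
fit_sentinel_model <- function(X, status) {
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  X <- as.matrix(X)
  if (ncol(X) == 0) {
    n <- length(status)
    cf <- c(`(Intercept)` = stats::qlogis(mean(status)))
    return(structure(list(coefficients = cf, lp = rep(cf, n),
                          converged = TRUE, auc = 0.5),
                     class = "sentinel_fit"))
  }
  fit <- fit_joint_model(X, status)
  if (!fit$converged) {
    # report the unconverged fit; caller decides
    D <- cbind(1, X)
    g <- suppressWarnings(stats::glm.fit(D, status,
                                         family = stats::binomial()))
    cf <- g$coefficients; cf[is.na(cf)] <- 0
    names(cf) <- c("(Intercept)", colnames(X))
    lp <- drop(D %*% cf)
    return(structure(list(coefficients = cf, lp = lp, converged = FALSE,
                          auc = auc(lp, status)), class = "sentinel_fit"))
  }
  cf <- fit$coefficients
  names(cf) <- c("(Intercept)", colnames(X))
  structure(list(coefficients = cf, lp = fit$lp, converged = TRUE,
                 auc = auc(fit$lp, status)), class = "sentinel_fit")
}

#' Score subjects with previously fitted sentinel coefficients
#'
#' Applies training coefficients verbatim (no re-fit) to a dosage matrix.
#'
#' @param fit a `sentinel_fit`.
#' @param X subjects x sentinels dosage matrix with matching column names.
#' @return linear predictor vector.
#' @export
predict_sentinel <- function(fit, X) {
  cf <- fit$coefficients
  vars <- setdiff(names(cf), "(Intercept)")
  if (!length(vars)) return(rep(cf[["(Intercept)"]], nrow(as.matrix(X))))
  X <- as.matrix(X)[, vars, drop = FALSE]
  drop(cbind(1, X) %*% cf[c("(Intercept)", vars)])
}

#' Bootstrap bagged optimism of the sentinel model AUC
#'
#' For each replicate, subjects are resampled with replacement stratified by
#' case-control status (preserving the design's case:control margins), the
#' full RISSc algorithm is re-run on the replicate over the fixed original
#' candidate set, the sentinel model is fitted on the replicate (AUCboot),
#' and the replicate's coefficients are applied to the original data
#' (AUCreal). The replicate optimism is AUCboot - AUCreal; the bagged
#' optimism is the mean over usable replicates; the shrunken AUC is the
#' apparent AUC minus the bagged optimism. Replicates where RISSc returns no
#' sentinels or the fit fails are recorded and excluded from the mean.
#'
#' @param X subjects x candidates dosage matrix (the fixed candidate set).
#' @param status case indicator.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed controlling all resampling.
#' @param mark_alpha RISSc marking level.
#' @return object of class `optimism_report`: `apparent`, `replicates`
#'   (per-replicate AUCboot, AUCreal, optimism), `bagged_optimism`,
#'   `shrunken`, `B`, `n_failed`, `seed`.
#' @export
bootstrap_optimism <- function(X, status, B = 1000, seed = 1,
                               mark_alpha = 0.01) {
  if (B < 1) stop("B must be >= 1")
  X <- as.matrix(X)
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  set.seed(seed)
  orig <- run_rissc(X, status, mark_alpha = mark_alpha)
  ofit <- fit_sentinel_model(X[, orig$sentinel_idx, drop = FALSE], status)
  apparent <- ofit$auc
  caseix <- which(status == 1); ctrlix <- which(status == 0)
  reps <- data.frame(replicate = seq_len(B), auc_boot = NA_real_,
                     auc_real = NA_real_, optimism = NA_real_,
                     n_sentinels = NA_integer_, failed = FALSE)
  for (b in seq_len(B)) {
    ix <- c(sample(caseix, length(caseix), replace = TRUE),
            sample(ctrlix, length(ctrlix), replace = TRUE))
    Xb <- X[ix, , drop = FALSE]; yb <- status[ix]
    sm <- tryCatch(run_rissc(Xb, yb, mark_alpha = mark_alpha),
                   error = function(e) NULL)
    if (is.null(sm) || !length(sm$sentinels)) {
      reps$failed[b] <- TRUE
      reps$n_sentinels[b] <- if (is.null(sm)) NA_integer_ else 0L
      next
    }
    fb <- tryCatch(fit_sentinel_model(Xb[, sm$sentinel_idx, drop = FALSE],
                                      yb), error = function(e) NULL)
    if (is.null(fb)) { reps$failed[b] <- TRUE; next }
    lp_real <- predict_sentinel(fb, X[, sm$sentinel_idx, drop = FALSE])
    reps$auc_boot[b] <- fb$auc
    reps$auc_real[b] <- auc(lp_real, status)
    reps$optimism[b] <- reps$auc_boot[b] - reps$auc_real[b]
    reps$n_sentinels[b] <- length(sm$sentinels)
  }
  usable <- !reps$failed
  if (!any(usable)) stop("all bootstrap replicates failed")
  bagged <- mean(reps$optimism[usable])
  structure(list(apparent = apparent, replicates = reps,
                 bagged_optimism = bagged,
                 shrunken = apparent - bagged, B = B,
                 n_failed = sum(reps$failed), seed = seed,
                 sentinels = orig$sentinels),
            class = "optimism_report")
}

#' Shrunken (optimism-corrected) AUC
#'
#' The apparent AUC minus the bagged optimism, clamped to \[0, 1\] with a
#' warning if outside; negative bagged optimism (possible under sampling
#' noise) yields a shrunken estimate above the apparent one, with a warning.
#'
#' @param report an `optimism_report` from [bootstrap_optimism()].
#' @return the shrunken AUC.
#' @export
shrunken_auc <- function(report) {
  stopifnot(inherits(report, "optimism_report"))
  s <- report$apparent - report$bagged_optimism
  if (report$bagged_optimism < 0)
    warning("negative bagged optimism: shrunken AUC exceeds apparent AUC")
  if (s < 0 || s > 1) {
    warning("shrunken AUC outside [0, 1]; clamping")
    s <- min(max(s, 0), 1)
  }
  s
}

#' @export
print.optimism_report <- function(x, ...) {
  cat(sprintf(
    "optimism_report: apparent AUC %.4f, bagged optimism %.4f (B=%d, %d failed)\n  shrunken AUC %.4f\n",
    x$apparent, x$bagged_optimism, x$B, x$n_failed, x$shrunken))
  invisible(x)
}
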