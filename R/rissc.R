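# RISSc: recursively identified sentinel scoring. LD bins are formed at a
# descending r-squared schedule; within each bin the best-detecting variant
# (plus mutually significant bin members and mark-protected members) is kept
# and the rest permanently deleted; a global joint model then marks the
# survivors that remain significant under mutual adjustment. Sentinels are
# the variants still marked after the final step.

#' The descending r-squared threshold schedule
#'
#' Step 1 bins perfectly correlated variants (r-squared 1); step 2 starts at
#' 0.975 and each subsequent step subtracts 0.025, down to 0.025 at step 40.
#'
#' @param step integer step index in \[1, 40\].
#' @return the r-squared threshold for that step.
#' @export
threshold_schedule <- function(step) {
  if (any(step < 1 | step > 40) || any(step != floor(step)))
    stop("step must be an integer in [1, 40]")
  ifelse(step == 1, 1.0, 0.975 - 0.025 * (step - 2))
}

#' Partition candidates into LD bins at a threshold
#'
#' Deterministic greedy partition: repeatedly seed a bin with the unassigned
#' variant of smallest simple-logistic P (ties: larger |beta|, then lower
#' map position) and absorb every unassigned variant whose r-squared with
#' the seed is at least the threshold. Singleton bins are allowed.
#'
#' @param candidates integer indices into the r-squared matrix / simple
#'   results.
#' @param threshold r-squared threshold.
#' @param r2 full symmetric r-squared matrix.
#' @param simple data.frame with per-variant `p`, `beta`, `pos` aligned to
#'   the r-squared matrix rows.
#' @return list of integer vectors (bins), each headed by its seed.
#' @export
partition_bins <- function(candidates, threshold, r2, simple) {
  un <- candidates[order(simple$p[candidates],
                         -abs(simple$beta[candidates]),
                         simple$pos[candidates])]
  bins <- list()
  eps <- 1e-12
  while (length(un)) {
    seed <- un[1]
    members <- un[r2[seed, un] >= threshold - eps]
    bins[[length(bins) + 1L]] <- members
    un <- setdiff(un, members)
  }
  bins
}

#' Best-in-bin variant
#'
#' The bin member with the greatest simple-logistic association: smallest
#' P, ties broken by larger |beta|, then lower map position.
#'
#' @param bin integer indices.
#' @param simple per-variant simple results (`p`, `beta`, `pos`).
#' @return the winning index.
#' @export
best_in_bin <- function(bin, simple) {
  if (!length(bin)) stop("empty bin")
  bin[order(simple$p[bin], -abs(simple$beta[bin]), simple$pos[bin])[1]]
}

# simple per-candidate logistic results used for seeding and best-in-bin
rissc_simple_results <- function(X, status) {
  m <- ncol(X)
  p <- numeric(m); beta <- numeric(m)
  for (j in seq_len(m)) {
    res <- tryCatch(fit_additive_logistic(X[, j], status),
                    error = function(e) NULL)
    if (is.null(res)) { p[j] <- 1; beta[j] <- 0; next }
    if (res$separated) {
      res2 <- tryCatch(separation_fallback_test(X[, j], status),
                       error = function(e) NULL)
      if (!is.null(res2)) res <- res2
    }
    p[j] <- if (is.na(res$p)) 1 else res$p
    beta[j] <- if (is.na(res$beta)) 0 else res$beta
  }
  data.frame(p = p, beta = beta, pos = seq_len(m))
}

new_rissc_state <- function(surviving, marked, step, simple) {
  list(step = step, threshold = threshold_schedule(step),
       surviving = surviving, marked = marked,
       deleted = integer(0), simple = simple, last_converged = NA)
}

#' One RISSc recursion step
#'
#' Forms LD bins of the surviving candidates at the step's threshold. Per
#' bin, the best-in-bin variant, any bin member with mutually adjusted
#' `P <= mark_alpha` in the within-bin joint model, and any member marked at
#' the previous step are selected; all other bin members are permanently
#' deleted. A global joint model over all survivors then marks those with
#' `P <= mark_alpha` (previously marked variants that no longer meet the
#' threshold become unmarked); if the global model does not converge,
#' survivors keep only their previous-step marks.
#'
#' @param state RISSc state from the previous step.
#' @param X subjects x candidates dosage matrix.
#' @param status case indicator.
#' @param r2 candidate r-squared matrix.
#' @param mark_alpha marking significance level (default 0.01).
#' @return updated state (step incremented, deletions accumulated).
#' @export
rissc_step <- function(state, X, status, r2, mark_alpha = 0.01) {
  step <- state$step + 1L
  thr <- threshold_schedule(step)
  bins <- partition_bins(state$surviving, thr, r2, state$simple)
  keep <- integer(0); deleted <- state$deleted
  for (bin in bins) {
    if (length(bin) == 1) { keep <- c(keep, bin); next }
    bb <- best_in_bin(bin, state$simple)
    sel <- bb
    fit <- fit_joint_model(X[, bin, drop = FALSE], status)
    if (fit$converged) {
      sig <- bin[fit$results$p <= mark_alpha]
      sel <- union(sel, sig)
    }
    sel <- union(sel, intersect(bin, state$marked))
    deleted <- c(deleted, setdiff(bin, sel))
    keep <- c(keep, sel)
  }
  keep <- sort(unique(keep))
  # unchanged survivor set: the global refit would reproduce the previous
  # step's fit exactly, so marks carry over without recomputation
  if (identical(keep, state$surviving)) {
    state$step <- step
    state$threshold <- thr
    return(state)
  }
  gfit <- fit_joint_model(X[, keep, drop = FALSE], status)
  if (gfit$converged) {
    marked <- keep[gfit$results$p <= mark_alpha]
  } else {
    marked <- intersect(state$marked, keep)
  }
  list(step = step, threshold = thr, surviving = keep, marked = marked,
       deleted = sort(unique(deleted)), simple = state$simple,
       last_converged = gfit$converged)
}

#' Run the full RISSc sentinel-selection algorithm
#'
#' Step 1 collapses perfectly correlated bins to one representative each
#' (smallest simple P, then lowest position) and marks representatives
#' significant at `mark_alpha` in a global joint model; steps 2-40 then
#' apply [rissc_step()] at the descending threshold schedule. The sentinels
#' are the variants marked at step 40, reported with their mutually adjusted
#' estimates.
#'
#' @param X subjects x candidates dosage matrix (column names = ids);
#'   typically the genome-wide-significant variants of a combined scan.
#' @param status case indicator (1 = case).
#' @param mark_alpha marking significance level (default 0.01; relaxing to
#'   0.05 admits more sentinels).
#' @param r2 optional precomputed candidate r-squared matrix; by default
#'   computed over all supplied subjects.
#' @param trace if TRUE, keep a per-step audit table.
#' @return object of class `sentinel_model`: `sentinels` (ids), `results`
#'   (mutually adjusted beta/OR/CI/P), `model_p`, `r2_sentinels`,
#'   `mark_alpha`, `converged`, and `audit` when traced.
#' @export
run_rissc <- function(X, status, mark_alpha = 0.01, r2 = NULL, trace = FALSE) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("empty candidate set")
  ids <- colnames(X)
  if (is.null(ids)) ids <- colnames(X) <- paste0("v", seq_len(ncol(X)))
  if (is.character(status) || is.factor(status))
    status <- as.integer(as.character(status) == "case")
  if (is.null(r2)) r2 <- r2_matrix(t(X))
  simple <- rissc_simple_results(X, status)

  # Step 1: collapse perfect-proxy bins, keep one representative each
  bins1 <- partition_bins(seq_len(ncol(X)), 1.0, r2, simple)
  reps <- vapply(bins1, function(b)
    b[order(simple$p[b], simple$pos[b])[1]], 0L)
  deleted1 <- setdiff(seq_len(ncol(X)), reps)
  gfit <- fit_joint_model(X[, reps, drop = FALSE], status)
  marked <- if (gfit$converged) reps[gfit$results$p <= mark_alpha]
    else integer(0)
  state <- list(step = 1L, threshold = 1.0, surviving = sort(reps),
                marked = sort(marked), deleted = sort(deleted1),
                simple = simple, last_converged = gfit$converged)
  audit <- if (trace) list(data.frame(step = 1L, threshold = 1.0,
                                      n_surviving = length(reps),
                                      n_marked = length(marked),
                                      n_deleted = length(deleted1),
                                      converged = gfit$converged))
  while (state$step < 40L) {
    state <- rissc_step(state, X, status, r2, mark_alpha)
    if (trace)
      audit[[length(audit) + 1L]] <-
        data.frame(step = state$step, threshold = state$threshold,
                   n_surviving = length(state$surviving),
                   n_marked = length(state$marked),
                   n_deleted = length(state$deleted),
                   converged = isTRUE(state$last_converged))
  }
  sent <- sort(state$marked)
  if (length(sent)) {
    ffit <- fit_joint_model(X[, sent, drop = FALSE], status)
    results <- if (ffit$converged) ffit$results else NULL
    model_p <- ffit$model_p
    conv <- ffit$converged
    r2s <- r2[sent, sent, drop = FALSE]
    dimnames(r2s) <- list(ids[sent], ids[sent])
  } else {
    results <- NULL; model_p <- NA_real_; conv <- NA; r2s <- NULL
  }
  structure(list(sentinels = ids[sent], sentinel_idx = sent,
                 results = results, model_p = model_p,
                 r2_sentinels = r2s, mark_alpha = mark_alpha,
                 converged = conv,
                 audit = if (trace) do.call(rbind, audit)),
            class = "sentinel_model")
}

#' @export
print.sentinel_model <- function(x, ...) {
  cat(sprintf("sentinel_model: %d sentinels (mark_alpha = %g)\n",
              length(x$sentinels), x$mark_alpha))
  if (!is.null(x$results)) {
    cat(sprintf("  overall model P = %.3g\n", x$model_p))
    print(x$results, digits = 3)
  }
  invisible(x)
}
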