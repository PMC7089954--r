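#' Subset a genotype dataset to a variant index set
#'
#' @param geno a [genotype_dataset].
#' @param idx integer variant indices (map order preserved).
#' @return a [genotype_dataset] over the selected variants.
#' @export
subset_variants <- function(geno, idx) {
  idx <- sort(unique(as.integer(idx)))
  stopifnot(all(idx >= 1), all(idx <= nrow(geno$variants)))
  genotype_dataset(geno$variants[idx, , drop = FALSE], geno$subjects,
                   geno$dosage[idx, , drop = FALSE],
                   haplotypes = if (!is.null(geno$haplotypes))
                     geno$haplotypes[idx, , drop = FALSE],
                   phase_prob = geno$phase_prob)
}

#' Enumerate haplotypes of a window
#'
#' Reads off every distinct allele string observed in a window of phased
#' data and each subject's copy count (0/1/2). Subjects whose phase
#' confidence falls below `phase_threshold` are excluded from the window.
#'
#' @param geno a phased [genotype_dataset].
#' @param start first variant index of the window.
#' @param width window width (number of adjacent variants).
#' @param phase_threshold minimum per-subject phase probability (default 0.9).
#' @return list: `haps` character vector of observed allele strings (1 =
#'   minor), `chrom_count` chromosome counts per string, `copies` matrix
#'   (subjects x haplotypes) of copy counts, `included` logical per subject.
#' @export
enumerate_window_haplotypes <- function(geno, start, width,
                                        phase_threshold = 0.9) {
  if (is.null(geno$haplotypes)) stop("no phased haplotypes in dataset")
  m <- nrow(geno$variants)
  if (start < 1 || width < 1 || start + width - 1 > m)
    stop("window outside variant map")
  idx <- start:(start + width - 1)
  n <- length(geno$subjects)
  inc <- if (is.null(geno$phase_prob)) rep(TRUE, n)
    else !is.na(geno$phase_prob) & geno$phase_prob >= phase_threshold
  sub <- geno$haplotypes[idx, , drop = FALSE]
  w <- 2^(seq_along(idx) - 1)
  codes <- as.integer(drop(w %*% sub))        # one code per chromosome
  cm <- matrix(codes, nrow = 2)               # 2 x subjects
  cm <- cm[, inc, drop = FALSE]
  tab <- table(as.vector(cm))
  ucodes <- as.integer(names(tab))
  haps <- vapply(ucodes, function(cd)
    paste(as.integer(bitwAnd(cd, w) > 0), collapse = ""), "")
  copies <- vapply(ucodes, function(cd) as.integer(colSums(cm == cd)),
                   integer(sum(inc)))
  if (is.null(dim(copies))) copies <- matrix(copies, nrow = sum(inc))
  colnames(copies) <- haps
  list(haps = haps, chrom_count = as.integer(tab), copies = copies,
       included = inc)
}

# Newton fit of the additive logistic model on aggregated counts:
# cases[k] of tot[k] subjects at copy count d[k]. Same MLE/Wald SE as the
# subject-level fit; a handful of scalar ops per iteration.
fit_counts_additive <- function(d, cases, tot, maxit = 30, tol = 1e-10) {
  keep <- tot > 0
  d <- d[keep]; cases <- cases[keep]; tot <- tot[keep]
  if (length(unique(d)) < 2 || sum(cases) == 0 || sum(cases) == sum(tot))
    return(NULL)
  b0 <- stats::qlogis(sum(cases) / sum(tot)); b1 <- 0
  ok <- FALSE
  for (it in seq_len(maxit)) {
    eta <- b0 + b1 * d
    mu <- stats::plogis(eta)
    w <- tot * mu * (1 - mu)
    r <- cases - tot * mu
    s11 <- sum(w); s12 <- sum(w * d); s22 <- sum(w * d * d)
    det <- s11 * s22 - s12 * s12
    if (det <= 0) break
    u1 <- sum(r); u2 <- sum(r * d)
    db0 <- (s22 * u1 - s12 * u2) / det
    db1 <- (s11 * u2 - s12 * u1) / det
    b0 <- b0 + db0; b1 <- b1 + db1
    if (abs(db0) < tol && abs(db1) < tol) { ok <- TRUE; break }
    if (abs(b1) > 30) break
  }
  eta <- b0 + b1 * d
  mu <- stats::plogis(eta)
  w <- tot * mu * (1 - mu)
  s11 <- sum(w); s12 <- sum(w * d); s22 <- sum(w * d * d)
  det <- s11 * s22 - s12 * s12
  se <- if (det > 0) sqrt(s11 / det) else Inf
  separated <- !ok || !is.finite(se) || abs(b1) > BETA_OVERFLOW ||
    se > SE_OVERFLOW
  p <- if (separated) NA_real_ else 2 * stats::pnorm(-abs(b1 / se))
  list(beta = b1, se = se, p = p, separated = separated)
}

# fit a window-haplotype additive test, falling back under separation
fit_hap_test <- function(copies, status, strata = NULL) {
  res <- tryCatch(fit_additive_logistic(copies, status,
                                        if (!is.null(strata))
                                          data.frame(study = strata)),
                  error = function(e) NULL)
  if (is.null(res)) return(NULL)
  if (res$separated) {
    res <- tryCatch(separation_fallback_test(copies, status),
                    error = function(e) NULL)
  }
  res
}

#' Sliding-window haplotype association scan with two-study concordance
#'
#' Moves windows of each width along the variant map in single-variant
#' increments; every haplotype observed in a window with at least
#' `min_copies` total copies across studies is tested for association with
#' disease under the additive model (copy count 0/1/2, one-vs-rest), per
#' study. Haplotypes significant at `alpha` with consistent effect direction
#' in every study are retained and additionally tested in the pooled data
#' with a study covariate.
#'
#' @param collection a [study_collection] of phased studies.
#' @param widths integer window widths, each within \[2, 20\].
#' @param alpha per-study significance level.
#' @param min_copies minimum total haplotype copies for testing (default 5).
#' @param phase_threshold per-subject phase probability floor.
#' @param variants optional variant index subset defining the scanned map
#'   (defaults to the full map); windows run over consecutive entries.
#' @return data.frame of concordant window haplotypes: window coordinates,
#'   allele string, per-study case/control copy counts and statistics, and
#'   combined statistics. Attribute `n_tested` counts tested haplotypes;
#'   attribute `windows_checked` counts windows scanned.
#' @export
sliding_window_scan <- function(collection, widths = 2:20, alpha = 0.05,
                                min_copies = 5, phase_threshold = 0.9,
                                variants = NULL) {
  stopifnot(inherits(collection, "study_collection"))
  if (any(widths < 2 | widths > 20))
    stop("window widths must lie within [2, 20]")
  labs <- names(collection$studies)
  if (length(labs) < 2) stop("concordance scan requires >= 2 studies")
  genos <- lapply(collection$studies, function(s) {
    if (is.null(s$geno$haplotypes)) stop("all studies must be phased")
    if (!is.null(variants)) subset_variants(s$geno, variants) else s$geno
  })
  stats_y <- lapply(collection$studies, function(s)
    case_indicator(s$geno, s$pheno))
  m <- nrow(genos[[1]]$variants)
  map_pos <- if (is.null(variants)) seq_len(m) else sort(unique(variants))

  # per-study chromosome-level prework: phased matrix restricted to
  # phase-included subjects, case indicator per chromosome
  pre <- lapply(seq_along(labs), function(li) {
    g <- genos[[li]]
    n <- length(g$subjects)
    inc <- if (is.null(g$phase_prob)) rep(TRUE, n)
      else !is.na(g$phase_prob) & g$phase_prob >= phase_threshold
    cols <- rep(inc, each = 2)
    list(H = g$haplotypes[, cols, drop = FALSE],
         y = stats_y[[li]][inc], n = sum(inc))
  })

  n_tested <- 0L; windows_checked <- 0L
  out <- list()
  for (w in widths) {
    if (w > m) next
    pw2 <- 2^(seq_len(w) - 1)
    for (start in seq_len(m - w + 1)) {
      windows_checked <- windows_checked + 1L
      idx <- start:(start + w - 1)
      # per study: chromosome codes and count tables by status
      winfo <- lapply(pre, function(ps) {
        codes <- drop(pw2 %*% ps$H[idx, , drop = FALSE])
        cm1 <- codes[seq(1, length(codes), 2)]
        cm2 <- codes[seq(2, length(codes), 2)]
        list(cm1 = cm1, cm2 = cm2)
      })
      u <- sort(unique(unlist(lapply(winfo, function(z) c(z$cm1, z$cm2)))))
      cnt <- lapply(seq_along(labs), function(li) {
        z <- winfo[[li]]; y <- pre[[li]]$y
        i1 <- match(z$cm1, u); i2 <- match(z$cm2, u)
        nu <- length(u)
        chrom_case <- tabulate(i1[y == 1], nu) + tabulate(i2[y == 1], nu)
        chrom_ctrl <- tabulate(i1[y == 0], nu) + tabulate(i2[y == 0], nu)
        hom <- i1 == i2
        hom_case <- tabulate(i1[hom & y == 1], nu)
        hom_ctrl <- tabulate(i1[hom & y == 0], nu)
        list(chrom_case = chrom_case, chrom_ctrl = chrom_ctrl,
             hom_case = hom_case, hom_ctrl = hom_ctrl,
             n_case = sum(y == 1), n_ctrl = sum(y == 0))
      })
      tot <- Reduce(`+`, lapply(cnt, function(z) z$chrom_case + z$chrom_ctrl))
      test_ix <- which(tot >= min_copies)
      for (hix in test_ix) {
        n_tested <- n_tested + 1L
        per <- vector("list", length(labs))
        ok <- TRUE; dir0 <- NULL
        for (li in seq_along(labs)) {
          z <- cnt[[li]]
          # copy-count distribution by status for this haplotype
          n2ca <- z$hom_case[hix]; n1ca <- z$chrom_case[hix] - 2L * n2ca
          n0ca <- z$n_case - n1ca - n2ca
          n2co <- z$hom_ctrl[hix]; n1co <- z$chrom_ctrl[hix] - 2L * n2co
          n0co <- z$n_ctrl - n1co - n2co
          cases <- c(n0ca, n1ca, n2ca); tots <- cases + c(n0co, n1co, n2co)
          res <- fit_counts_additive(c(0, 1, 2), cases, tots)
          if (!is.null(res) && res$separated)
            res <- firth_fallback_counts(c(0, 1, 2), cases, tots)
          if (is.null(res) || is.na(res$p) || res$p > alpha) ok <- FALSE
          else {
            dr <- sign(res$beta)
            if (is.null(dir0)) dir0 <- dr
            else if (dr != dir0 || dir0 == 0) ok <- FALSE
          }
          per[[li]] <- list(res = res,
                            case_copies = z$chrom_case[hix],
                            ctrl_copies = z$chrom_ctrl[hix],
                            cases = cases, tots = tots)
          if (!ok) break
        }
        if (!ok) next
        # pooled fit with a study covariate on the aggregated counts
        nlev <- length(labs)
        dd <- rep(c(0, 1, 2), nlev)
        cc <- unlist(lapply(per, `[[`, "cases"))
        tt <- unlist(lapply(per, `[[`, "tots"))
        Xc <- cbind(1, dd)
        for (li in 2:nlev) {
          col <- numeric(3 * nlev); col[(3 * li - 2):(3 * li)] <- 1
          Xc <- cbind(Xc, col)
        }
        kp <- tt > 0
        gf <- suppressWarnings(stats::glm.fit(
          Xc[kp, , drop = FALSE], cbind(cc[kp], tt[kp] - cc[kp]),
          family = stats::binomial()))
        wl <- wald_from_glmfit(gf, Xc[kp, , drop = FALSE])
        bC <- unname(wl$beta[2]); seC <- unname(wl$se[2])
        if (!gf$converged || !wl$rank_ok || !is.finite(seC)) next
        pC <- 2 * stats::pnorm(-abs(bC / seC))
        hapstr <- paste(as.integer(bitwAnd(u[hix], pw2) > 0), collapse = "")
        row <- data.frame(start = map_pos[start],
                          end = map_pos[start + w - 1], width = w,
                          start_idx = start,
                          hap = hapstr, copies_total = tot[hix],
                          stringsAsFactors = FALSE)
        for (li in seq_along(labs)) {
          z <- per[[li]]
          row[[paste0("case_copies_", labs[li])]] <- z$case_copies
          row[[paste0("ctrl_copies_", labs[li])]] <- z$ctrl_copies
          row[[paste0("beta_", labs[li])]] <- z$res$beta
          row[[paste0("p_", labs[li])]] <- z$res$p
        }
        row$beta_combined <- bC
        row$or_combined <- exp(bC)
        row$ci_low_combined <- exp(bC - 1.959963984540054 * seC)
        row$ci_high_combined <- exp(bC + 1.959963984540054 * seC)
        row$p_combined <- max(pC, P_FLOOR)
        row$concordant <- TRUE
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), width = integer(),
               start_idx = integer(), hap = character(),
               copies_total = integer(),
               beta_combined = numeric(), or_combined = numeric(),
               ci_low_combined = numeric(), ci_high_combined = numeric(),
               p_combined = numeric(), concordant = logical())
  attr(res, "map_pos") <- map_pos
  attr(res, "n_tested") <- n_tested
  attr(res, "windows_checked") <- windows_checked
  attr(res, "study_labels") <- labs
  res
}

#' Assemble ancestral haplotype models from concordant windows
#'
#' Graph merge of retained window haplotypes: two are linked when their
#' windows overlap, their alleles agree on every shared variant, and no
#' other retained haplotype of either window carries the identical overlap
#' segment (the uniqueness rule behind "uniquely aligning"). Connected
#' components whose union is allele-consistent become ancestral haplotype
#' models; components with internal conflicts are reported unmerged.
#'
#' @param results concordant scan data.frame from [sliding_window_scan()].
#' @param collection optional [study_collection]; when given, per-study
#'   case/control carrier frequencies of each model are computed.
#' @param merge_ratio carrier-continuity floor: two window haplotypes are
#'   only linked when the smaller total copy count is at least this fraction
#'   of the larger (default 0.5), so allele runs shared by haplotypes of
#'   very different frequency are not chained into one model.
#' @return list of `ancestral_haplotype` models, each with `name`,
#'   `variants` (index vector), `alleles` (0/1 required alleles), `extent`,
#'   `members` (result row indices), `direction` (sign of the mean combined
#'   log OR), and carrier frequencies when computed. Attribute `ambiguous`
#'   lists unmerged component row sets.
#' @export
assemble_ancestral_haplotypes <- function(results, collection = NULL,
                                          merge_ratio = 0.5) {
  n <- nrow(results)
  if (!n) return(structure(list(), ambiguous = list()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  # all overlap arithmetic happens in scanned-map (submap) coordinates;
  # map_pos translates back to variant indices of the full map at the end
  map_pos <- attr(results, "map_pos")
  rs <- if (!is.null(results$start_idx)) results$start_idx else results$start
  if (is.null(map_pos)) map_pos <- seq_len(max(rs + results$width - 1))
  re <- rs + results$width - 1L
  rh <- results$hap
  seg <- function(k, lo, hi) substr(rh[k], lo - rs[k] + 1, hi - rs[k] + 1)
  key <- paste(rs, results$width)
  bykey <- split(seq_len(n), key)

  # candidate links: overlapping windows, allele-identical on the overlap,
  # overlap segment unique among each window's retained haplotypes
  wk <- unique(data.frame(s = rs, w = results$width))
  wk <- wk[order(wk$s, wk$w), , drop = FALSE]
  wrows <- lapply(seq_len(nrow(wk)), function(a)
    which(rs == wk$s[a] & results$width == wk$w[a]))
  cop <- results$copies_total
  edges <- list()
  for (a in seq_len(nrow(wk))) {
    ea <- wk$s[a] + wk$w[a] - 1L
    for (b in seq_len(nrow(wk))) {
      if (b <= a) next
      if (wk$s[b] > ea) break   # windows sorted by start: no more overlaps
      lo <- wk$s[b]; hi <- min(ea, wk$s[b] + wk$w[b] - 1L)
      ra <- wrows[[a]]; rb <- wrows[[b]]
      sa <- substr(rh[ra], lo - wk$s[a] + 1, hi - wk$s[a] + 1)
      sb <- substr(rh[rb], lo - wk$s[b] + 1, hi - wk$s[b] + 1)
      ua <- !(duplicated(sa) | duplicated(sa, fromLast = TRUE))
      ub <- !(duplicated(sb) | duplicated(sb, fromLast = TRUE))
      mi <- match(sa, sb)
      hit <- which(!is.na(mi) & ua)
      hit <- hit[ub[mi[hit]]]
      if (length(hit)) {
        # carrier continuity: the same ancestral haplotype shows a similar
        # copy count in overlapping windows; wildly different counts mean
        # different underlying haplotypes sharing an allele run
        ca <- cop[ra[hit]]; cb <- cop[rb[mi[hit]]]
        ratio_ok <- pmin(ca, cb) / pmax(ca, cb) >= merge_ratio
        hit <- hit[ratio_ok]
      }
      if (length(hit))
        edges[[length(edges) + 1L]] <-
          cbind(ra[hit], rb[mi[hit]], hi - lo + 1L)
    }
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    ei <- as.integer(em[, 1]); ej <- as.integer(em[, 2])
    elen <- as.integer(em[, 3])
  } else { ei <- integer(0); ej <- integer(0); elen <- integer(0) }
  # merge longest overlaps first (canonical order independent of input
  # order); a link whose union would assign conflicting alleles to a
  # variant is ambiguous and skipped
  ord <- order(-elen, rs[ei], results$width[ei], rh[ei],
               rs[ej], results$width[ej], rh[ej])
  comp_alleles <- lapply(seq_len(n), function(i) {
    bits <- as.integer(strsplit(rh[i], "")[[1]])
    names(bits) <- as.character(rs[i] + seq_along(bits) - 1L)
    bits
  })
  ambiguous <- list()
  for (e in ord) {
    ri <- find(ei[e]); rj <- find(ej[e])
    if (ri == rj) next
    ai <- comp_alleles[[ri]]; aj <- comp_alleles[[rj]]
    shared <- intersect(names(ai), names(aj))
    if (length(shared) && any(ai[shared] != aj[shared])) {
      ambiguous[[length(ambiguous) + 1L]] <- c(ei[e], ej[e])
      next
    }
    unite(ei[e], ej[e])
    comp_alleles[[min(ri, rj)]] <- c(ai, aj[setdiff(names(aj), names(ai))])
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), roots)
  models <- list()
  for (comp in comps) {
    alle <- comp_alleles[[find(comp[1])]]
    sidx <- sort(as.integer(names(alle)))
    vidx <- map_pos[sidx]
    models[[length(models) + 1L]] <- structure(list(
      name = NA_character_,
      variants = vidx,
      alleles = unname(alle[as.character(sidx)]),
      extent = range(vidx),
      members = comp,
      member_table = results[comp, , drop = FALSE],
      direction = sign(mean(results$beta_combined[comp]))),
      class = "ancestral_haplotype")
  }
  if (length(models)) {
    ord <- order(vapply(models, function(m) m$extent[1], 0L))
    models <- models[ord]
    for (k in seq_along(models)) models[[k]]$name <- paste0("H", k)
  }
  if (!is.null(collection)) for (k in seq_along(models))
    models[[k]]$carrier_freq <- model_carrier_freq(models[[k]], collection)
  structure(models, ambiguous = ambiguous)
}

# chromosomes matching a model's full allele signature
model_signature_match <- function(model, geno) {
  H <- geno$haplotypes[model$variants, , drop = FALSE]
  colSums(H == model$alleles) == length(model$alleles)
}

model_carrier_freq <- function(model, collection) {
  out <- list()
  for (lab in names(collection$studies)) {
    s <- collection$studies[[lab]]
    mm <- model_signature_match(model, s$geno)
    carrier <- mm[seq(1, length(mm), 2)] | mm[seq(2, length(mm), 2)]
    y <- case_indicator(s$geno, s$pheno)
    out[[lab]] <- c(cases = mean(carrier[y == 1]),
                    controls = mean(carrier[y == 0]))
  }
  out
}

#' @export
print.ancestral_haplotype <- function(x, ...) {
  cat(sprintf("ancestral haplotype %s: variants %d-%d (%d sites), %s, %d windows\n",
              x$name, x$extent[1], x$extent[2], length(x$variants),
              if (x$direction >= 0) "risk" else "protective",
              length(x$members)))
  invisible(x)
}

#' Peak-effect and peak-significance windows of a model
#'
#' @param model an `ancestral_haplotype` from
#'   [assemble_ancestral_haplotypes()].
#' @return list with `peak_effect` and `peak_significance`, each a one-row
#'   data.frame (combined OR and P). Ties are broken by wider window, then
#'   lower start index.
#' @export
peak_windows <- function(model) {
  tb <- model$member_table
  if (!nrow(tb)) stop("model has no member windows")
  eff <- abs(log(tb$or_combined))
  ord_eff <- order(-eff, -tb$width, tb$start)
  ord_sig <- order(tb$p_combined, -tb$width, tb$start)
  list(peak_effect = tb[ord_eff[1], , drop = FALSE],
       peak_significance = tb[ord_sig[1], , drop = FALSE])
}

#' Assign marking minor alleles to haplotype models
#'
#' A variant's minor allele marks model H when at least `theta` of the
#' chromosomes carrying the minor allele also carry H's full allele
#' signature, no other single model reaches `theta`, and the variant's
#' single-variant effect direction matches the model's. When no single model
#' reaches `theta` but the top two jointly do (each carrying more than 10%
#' of the minor-allele chromosomes), the allele is labeled shared between
#' them. Other alleles are unassigned.
#'
#' @param collection a [study_collection] (pooled chromosomes of all
#'   studies).
#' @param models list of models from [assemble_ancestral_haplotypes()].
#' @param scan_results combined single-variant scan (from [combined_scan()])
#'   supplying per-variant effect directions.
#' @param theta marking specificity threshold (default 0.8).
#' @param phase_threshold per-subject phase probability floor.
#' @return data.frame: `variant`, `model` (model name, `"shared:X+Y"`, or
#'   `NA`), and per-model carriage fractions.
#' @export
assign_marking_alleles <- function(collection, models, scan_results,
                                   theta = 0.8, phase_threshold = 0.9) {
  va <- collection$variants
  if (!length(models))
    return(data.frame(variant = va$id, model = NA_character_,
                      stringsAsFactors = FALSE))
  H <- do.call(cbind, lapply(collection$studies, function(s) {
    inc <- if (is.null(s$geno$phase_prob)) rep(TRUE, length(s$geno$subjects))
      else s$geno$phase_prob >= phase_threshold
    cols <- rep(inc, each = 2)
    s$geno$haplotypes[, cols, drop = FALSE]
  }))
  sig <- lapply(models, function(m)
    colSums(H[m$variants, , drop = FALSE] == m$alleles) ==
      length(m$variants))
  dirs <- scan_results$direction[match(va$id, scan_results$variant)]
  rows <- vector("list", nrow(va))
  for (v in seq_len(nrow(va))) {
    carriers <- H[v, ] == 1
    nc <- sum(carriers)
    frac <- vapply(sig, function(s) if (nc) mean(s[carriers]) else 0, 0)
    names(frac) <- vapply(models, `[[`, "", "name")
    assigned <- NA_character_
    if (nc > 0) {
      meets <- which(frac >= theta)
      dir_ok <- vapply(models, function(m)
        !is.na(dirs[v]) && dirs[v] == m$direction, TRUE)
      meets <- meets[dir_ok[meets]]
      if (length(meets) == 1) assigned <- names(frac)[meets]
      else if (length(meets) >= 2) {
        top <- order(-frac)[1:2]
        assigned <- paste0("shared:", paste(sort(names(frac)[top]),
                                            collapse = "+"))
      } else {
        top <- order(-frac)[seq_len(min(2, length(frac)))]
        if (length(top) == 2 && sum(frac[top]) >= theta &&
            all(frac[top] > 0.1) && all(dir_ok[top]))
          assigned <- paste0("shared:", paste(sort(names(frac)[top]),
                                              collapse = "+"))
      }
    }
    rows[[v]] <- data.frame(variant = va$id[v], model = assigned,
                            t(frac), stringsAsFactors = FALSE,
                            check.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Constrained secondary scan over a model's marking variants
#'
#' Re-runs the sliding-window scan on the submap restricted to the variants
#' whose minor alleles mark the haplotype of interest, and reports the new
#' peak windows among haplotypes consistent with the model's signature.
#'
#' @param model an `ancestral_haplotype`.
#' @param collection a [study_collection].
#' @param marking marking table from [assign_marking_alleles()].
#' @param ... passed to [sliding_window_scan()] (widths, alpha, min_copies).
#' @return list with `results` (concordant scan rows on the submap),
#'   `peak_effect` and `peak_significance` rows (NULL when nothing
#'   consistent was retained).
#' @export
constrained_scan <- function(model, collection, marking, ...) {
  ids <- collection$variants$id
  mv <- which(ids %in% marking$variant[!is.na(marking$model) &
                (marking$model == model$name |
                   grepl(paste0("(^|:|\\+)", model$name, "($|\\+)"),
                         marking$model))])
  if (length(mv) < 2) stop("model has fewer than 2 marking variants")
  dots <- list(...)
  maxw <- min(20, length(mv))
  if (is.null(dots$widths)) dots$widths <- 2:maxw
  res <- do.call(sliding_window_scan,
                 c(list(collection = collection, variants = mv), dots))
  if (!nrow(res)) return(list(results = res, peak_effect = NULL,
                              peak_significance = NULL))
  # keep haplotypes consistent with the model on the marking submap:
  # allele 1 required at marking sites inside the window
  consistent <- vapply(seq_len(nrow(res)), function(i) {
    span <- mv[mv >= res$start[i] & mv <= res$end[i]]
    # positions within the submap window
    sub_sorted <- sort(mv)
    win <- sub_sorted[sub_sorted >= res$start[i] & sub_sorted <= res$end[i]]
    bits <- as.integer(strsplit(res$hap[i], "")[[1]])
    req <- ifelse(win %in% model$variants,
                  model$alleles[match(win, model$variants)], NA)
    all(is.na(req) | bits == req)
  }, TRUE)
  keep <- res[consistent, , drop = FALSE]
  if (!nrow(keep)) return(list(results = res, peak_effect = NULL,
                               peak_significance = NULL))
  eff <- abs(log(keep$or_combined))
  pe <- keep[order(-eff, -keep$width, keep$start)[1], , drop = FALSE]
  ps <- keep[order(keep$p_combined, -keep$width, keep$start)[1], ,
             drop = FALSE]
  list(results = res, peak_effect = pe, peak_significance = ps)
}
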