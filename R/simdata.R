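#' Define a planted ancestral haplotype
#'
#' A planted haplotype is an allele configuration inserted into the simulated
#' population at frequency `freq` per chromosome, optionally carrying causal
#' per-allele effects at variants on its allele-1 set, an age-at-diagnosis
#' shift for carriers, and a clinical-severity shift.
#'
#' @param name short label (e.g. "A").
#' @param alleles 0/1 vector over the variant map; 1 = minor allele carried.
#' @param freq population haplotype frequency in (0, 1).
#' @param causal data.frame with columns `index` (variant index) and `beta`
#'   (per-allele log odds ratio); indices must lie on the allele-1 set.
#' @param age_shift years subtracted from carrier mean age at diagnosis.
#' @param severity_shift log-odds shift toward aggressive disease for
#'   carriers (cumulative, proportional-odds scale).
#' @return object of class `planted_haplotype`.
#' @export
planted_haplotype <- function(name, alleles, freq, causal = NULL,
                              age_shift = 0, severity_shift = 0) {
  stopifnot(freq > 0, freq < 1, all(alleles %in% 0:1))
  if (!is.null(causal)) {
    stopifnot(all(c("index", "beta") %in% names(causal)))
    if (any(alleles[causal$index] != 1))
      stop("causal variants must lie on the haplotype's allele-1 set")
  }
  structure(list(name = name, alleles = as.integer(alleles), freq = freq,
                 causal = causal, age_shift = age_shift,
                 severity_shift = severity_shift),
            class = "planted_haplotype")
}

default_planted <- function(n_variants) {
  stopifnot(n_variants >= 100)
  a1 <- integer(n_variants); a1[30:48] <- 1L
  a2 <- integer(n_variants); a2[70:88] <- 1L
  list(
    planted_haplotype("A", a1, freq = 0.02,
                      causal = data.frame(index = 39L, beta = log(4)),
                      age_shift = 2, severity_shift = 0),
    planted_haplotype("B", a2, freq = 0.10,
                      causal = data.frame(index = 79L, beta = log(1.8)),
                      age_shift = 0, severity_shift = 0))
}

#' Simulation configuration
#'
#' Defaults define the package's reference desk-scale study conditions: two
#' independent case-control studies of 1500 cases / 1500 controls each over a
#' 120-variant map with mosaic-founder LD, carrying one infrequent
#' higher-risk haplotype (frequency 0.02, per-allele OR 4) and one common
#' moderate-risk haplotype (frequency 0.10, OR 1.8).
#'
#' @param n_variants number of variants on the map.
#' @param n_founders number of founder haplotypes behind the mosaic LD.
#' @param maf_range range the per-site ancestral allele-1 frequency is drawn
#'   from (uniform).
#' @param recomb_switch_prob probability per adjacent interval that a mosaic
#'   chromosome switches founder template.
#' @param mutation_noise per-site allele flip probability on mosaics.
#' @param planted list of [planted_haplotype()] objects; `NULL` (default)
#'   plants the two reference haplotypes on maps of at least 100 variants
#'   and nothing on smaller maps. Allele-1 signature sites get ancestral
#'   frequency `planted_site_freq` so minor alleles there predominantly
#'   mark the planted haplotype.
#' @param planted_site_freq background ancestral frequency at planted
#'   signature sites.
#' @param beta0 baseline log-odds of disease.
#' @param n_cases,n_controls per-study quotas.
#' @param study_labels labels of the independent studies.
#' @param age_mean,age_sd age model (years), truncated to \[35, 90\].
#' @param severity_base baseline case probabilities of
#'   (insignificant, moderate, aggressive).
#' @param seed integer seed for [simulate_replicated_studies()].
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 120, n_founders = 8,
                       maf_range = c(0.05, 0.5),
                       recomb_switch_prob = 0.02, mutation_noise = 0.002,
                       planted = NULL,
                       planted_site_freq = 0.003,
                       beta0 = -0.1, n_cases = 1500, n_controls = 1500,
                       study_labels = c("studyA", "studyB"),
                       age_mean = 59, age_sd = 8,
                       severity_base = c(insignificant = 0.20,
                                         moderate = 0.55, aggressive = 0.25),
                       seed = 20260101) {
  if (is.null(planted))
    planted <- if (n_variants >= 100) default_planted(n_variants) else list()
  stopifnot(n_variants > 1, n_founders >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            recomb_switch_prob >= 0, recomb_switch_prob <= 1,
            mutation_noise >= 0, mutation_noise <= 1,
            n_cases > 0, n_controls > 0, length(study_labels) >= 1,
            abs(sum(severity_base) - 1) < 1e-8)
  if (length(planted)) {
    stopifnot(all(vapply(planted, inherits, TRUE, "planted_haplotype")))
    if (sum(vapply(planted, `[[`, 0, "freq")) >= 1)
      stop("planted haplotype frequencies must sum to < 1")
    if (any(vapply(planted, function(h) length(h$alleles), 0L) != n_variants))
      stop("planted allele vectors must span the variant map")
  }
  structure(list(n_variants = n_variants, n_founders = n_founders,
                 maf_range = maf_range,
                 recomb_switch_prob = recomb_switch_prob,
                 mutation_noise = mutation_noise, planted = planted,
                 planted_site_freq = planted_site_freq, beta0 = beta0,
                 n_cases = n_cases, n_controls = n_controls,
                 study_labels = study_labels, age_mean = age_mean,
                 age_sd = age_sd, severity_base = severity_base, seed = seed),
            class = "sim_config")
}

#' Build the founder haplotype pool
#'
#' Per-site allele-1 probabilities are drawn once from the MAF range and
#' shared by all founders, so founder mosaics exhibit blockwise LD. Sites on
#' any planted haplotype's allele-1 signature are assigned the low
#' `planted_site_freq` background frequency instead.
#'
#' @param config a [sim_config()].
#' @return list with `founders` (n_founders x n_variants 0/1 matrix) and
#'   `site_freq` (the ancestral per-site frequencies).
#' @export
build_founder_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  for (h in config$planted) p[h$alleles == 1L] <- config$planted_site_freq
  founders <- matrix(stats::rbinom(config$n_founders * m, 1, rep(p,
                     each = config$n_founders)),
                     nrow = config$n_founders, ncol = m)
  list(founders = founders, site_freq = p)
}

# draw n mosaic chromosomes (n x m matrix) from the founder pool
draw_mosaics <- function(n, pool, config) {
  m <- config$n_variants
  nf <- nrow(pool$founders)
  idx <- matrix(0L, n, m)
  cur <- sample.int(nf, n, replace = TRUE)
  idx[, 1] <- cur
  if (m > 1) for (j in 2:m) {
    sw <- stats::runif(n) < config$recomb_switch_prob
    if (any(sw)) cur[sw] <- sample.int(nf, sum(sw), replace = TRUE)
    idx[, j] <- cur
  }
  h <- matrix(pool$founders[cbind(as.vector(idx), rep(seq_len(m), each = n))],
              n, m)
  if (config$mutation_noise > 0) {
    flip <- matrix(stats::runif(n * m) < config$mutation_noise, n, m)
    h[flip] <- 1L - h[flip]
  }
  h
}

# draw n chromosomes: planted haplotype k with prob freq_k (mutually
# exclusive), else a founder mosaic; returns alleles and planted labels
draw_chromosomes <- function(n, pool, config) {
  m <- config$n_variants
  nh <- length(config$planted)
  lab <- integer(n)  # 0 = mosaic, k = planted k
  if (nh) {
    f <- vapply(config$planted, `[[`, 0, "freq")
    u <- stats::runif(n)
    cum <- cumsum(f)
    for (k in rev(seq_len(nh))) lab[u < cum[k]] <- k
  }
  h <- matrix(0L, n, m)
  nm <- sum(lab == 0L)
  if (nm) h[lab == 0L, ] <- draw_mosaics(nm, pool, config)
  if (nh) for (k in seq_len(nh)) {
    sel <- lab == k
    if (any(sel)) h[sel, ] <- matrix(config$planted[[k]]$alleles,
                                     sum(sel), m, byrow = TRUE)
  }
  list(alleles = h, label = lab)
}

rtruncnorm_clip <- function(n, mean, sd, lo = 35, hi = 90) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad) && tries < 50) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1
  }
  pmin(pmax(x, lo), hi)
}

severity_fields <- function(category) {
  # clinical fields consistent with the assigned severity category
  switch(category,
    aggressive = list(stage = sample(c("T2c", "T3", "T3a"), 1),
                      gleason_sum = sample(8:9, 1),
                      psa_dx = round(stats::runif(1, 6, 15), 1),
                      prostatectomy = TRUE, died_of_disease = FALSE),
    insignificant = list(stage = "T2a", gleason_sum = sample(5:6, 1),
                         psa_dx = round(stats::runif(1, 1, 3.9), 1),
                         prostatectomy = TRUE, died_of_disease = FALSE),
    moderate = list(stage = sample(c("T2b", "T2c"), 1), gleason_sum = 7L,
                    psa_dx = round(stats::runif(1, 5, 12), 1),
                    prostatectomy = TRUE, died_of_disease = FALSE))
}

#' Simulate one case-control study
#'
#' Each individual is two chromosomes, each a planted haplotype with its
#' population frequency (mutually exclusive draws) or a founder mosaic
#' otherwise. Disease probability follows the multiplicative model
#' `logit pi = beta0 + sum beta_c * dosage_c` over planted causal variants;
#' rejection sampling fills the case/control quotas exactly, preserving odds
#' ratios under retrospective sampling. Cases receive ages
#' `Normal(mean - sum age_shift * carrier, sd)` truncated to \[35, 90\] and a
#' three-level severity drawn from base probabilities shifted on the
#' cumulative log-odds scale for carriers. Emits phased data with phase
#' confidence 1.
#'
#' @param config a [sim_config()].
#' @param study_label label for this study.
#' @param pool founder pool from [build_founder_pool()]; built fresh if NULL.
#' @param orient_minor if TRUE (default), flip sites whose realized allele-1
#'   frequency exceeds 0.5 so dosages count minor alleles. Set FALSE when a
#'   caller orients jointly across studies.
#' @return list with `geno` ([genotype_dataset]), `pheno` (phenotype
#'   data.frame) and `truth` (list: per-subject planted copy counts matrix,
#'   per-variant causal beta, realized planted chromosome frequencies).
#' @export
simulate_study <- function(config, study_label = config$study_labels[1],
                           pool = NULL, orient_minor = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(pool)) pool <- build_founder_pool(config)
  m <- config$n_variants
  nh <- length(config$planted)
  ncase <- config$n_cases; nctrl <- config$n_controls
  causal_beta <- numeric(m)
  for (h in config$planted) if (!is.null(h$causal))
    causal_beta[h$causal$index] <- causal_beta[h$causal$index] + h$causal$beta
  cidx <- which(causal_beta != 0)

  acc_h1 <- acc_h2 <- list(); acc_l1 <- acc_l2 <- list(); acc_y <- list()
  got_case <- 0L; got_ctrl <- 0L; total_drawn <- 0L
  max_draw <- 400L * (ncase + nctrl)
  batch <- max(2L * (ncase + nctrl), 1000L)
  while ((got_case < ncase || got_ctrl < nctrl) && total_drawn < max_draw) {
    c1 <- draw_chromosomes(batch, pool, config)
    c2 <- draw_chromosomes(batch, pool, config)
    dose_c <- c1$alleles[, cidx, drop = FALSE] +
      c2$alleles[, cidx, drop = FALSE]
    eta <- config$beta0 + drop(dose_c %*% causal_beta[cidx])
    y <- stats::rbinom(batch, 1, stats::plogis(eta))
    need_case <- ncase - got_case; need_ctrl <- nctrl - got_ctrl
    take <- c(which(y == 1)[seq_len(min(need_case, sum(y == 1)))],
              which(y == 0)[seq_len(min(need_ctrl, sum(y == 0)))])
    take <- take[!is.na(take)]
    if (length(take)) {
      acc_h1[[length(acc_h1) + 1L]] <- c1$alleles[take, , drop = FALSE]
      acc_h2[[length(acc_h2) + 1L]] <- c2$alleles[take, , drop = FALSE]
      acc_l1[[length(acc_l1) + 1L]] <- c1$label[take]
      acc_l2[[length(acc_l2) + 1L]] <- c2$label[take]
      acc_y[[length(acc_y) + 1L]] <- y[take]
      got_case <- got_case + sum(y[take] == 1)
      got_ctrl <- got_ctrl + sum(y[take] == 0)
    }
    total_drawn <- total_drawn + batch
  }
  if (got_case < ncase || got_ctrl < nctrl)
    stop("case/control quotas unreachable after ", total_drawn,
         " draws; check beta0 and effect sizes")
  h1 <- do.call(rbind, acc_h1); h2 <- do.call(rbind, acc_h2)
  l1 <- unlist(acc_l1); l2 <- unlist(acc_l2); y <- unlist(acc_y)
  n <- length(y)
  ord <- order(-y)  # cases first, for readability
  h1 <- h1[ord, , drop = FALSE]; h2 <- h2[ord, , drop = FALSE]
  l1 <- l1[ord]; l2 <- l2[ord]; y <- y[ord]

  dosage <- t(h1 + h2)                      # variants x subjects
  haps <- matrix(0L, m, 2L * n)
  haps[, seq(1, 2 * n, 2)] <- t(h1)
  haps[, seq(2, 2 * n, 2)] <- t(h2)
  flip <- rep(FALSE, m)
  if (orient_minor) {
    af <- rowMeans(dosage) / 2
    flip <- af > 0.5
    dosage[flip, ] <- 2L - dosage[flip, , drop = FALSE]
    haps[flip, ] <- 1L - haps[flip, , drop = FALSE]
  }
  subjects <- sprintf("%s_S%04d", study_label, seq_len(n))
  variants <- data.frame(
    id = sprintf("var%03d", seq_len(m)), chrom = "8",
    pos = 128000000L + 5000L * seq_len(m),
    ref = "A", alt = "G",
    minor = ifelse(flip, "A", "G"),
    maf = rowMeans(dosage) / 2, stringsAsFactors = FALSE)
  geno <- genotype_dataset(variants, subjects, dosage, haplotypes = haps,
                           phase_prob = rep(1, n))

  # phenotypes
  carrier <- matrix(0L, n, max(nh, 1))
  if (nh) for (k in seq_len(nh)) carrier[, k] <- (l1 == k) + (l2 == k)
  age_shift <- if (nh)
    drop((carrier > 0) %*% vapply(config$planted, `[[`, 0, "age_shift"))
  else rep(0, n)
  mu <- ifelse(y == 1, config$age_mean - age_shift, config$age_mean)
  age <- round(rtruncnorm_clip(n, mu, config$age_sd), 1)

  sev <- rep(NA_character_, n)
  cum_base <- cumsum(config$severity_base)[1:2]  # P(<=insig), P(<=moderate)
  sshift <- if (nh)
    drop((carrier > 0) %*% vapply(config$planted, `[[`, 0, "severity_shift"))
  else rep(0, n)
  for (i in which(y == 1)) {
    g <- stats::plogis(stats::qlogis(cum_base) - sshift[i])
    u <- stats::runif(1)
    sev[i] <- if (u < g[1]) "insignificant" else if (u < g[2]) "moderate"
      else "aggressive"
  }
  clin <- data.frame(stage = NA_character_, gleason_sum = NA_integer_,
                     psa_dx = NA_real_, prostatectomy = NA,
                     died_of_disease = NA, stringsAsFactors = FALSE)
  clin <- clin[rep(1, n), ]
  for (i in which(y == 1)) {
    f <- severity_fields(sev[i])
    clin$stage[i] <- f$stage; clin$gleason_sum[i] <- f$gleason_sum
    clin$psa_dx[i] <- f$psa_dx; clin$prostatectomy[i] <- f$prostatectomy
    clin$died_of_disease[i] <- f$died_of_disease
  }
  pheno <- data.frame(subject = subjects,
                      status = ifelse(y == 1, "case", "control"),
                      study = study_label, age = age, clin,
                      row.names = NULL, stringsAsFactors = FALSE)

  colnames(carrier) <- if (nh) vapply(config$planted, `[[`, "", "name")
  truth <- list(
    carrier_copies = carrier,
    causal_beta = causal_beta,
    realized_freq = if (nh) colSums(carrier) / (2 * n) else numeric(0),
    planted = config$planted)
  list(geno = geno, pheno = pheno, truth = truth)
}

#' Simulate replicated independent studies
#'
#' Draws two (or more) independent studies with the same founders, variant
#' map and effects but independent subject sampling, orienting minor alleles
#' jointly over the combined subjects so effect directions are comparable.
#' Optionally writes per study a phased VCF, a phenotype TSV and a truth TSV.
#'
#' @param config a [sim_config()]; `config$seed` seeds all randomness.
#' @param out_dir optional directory to write `<label>.vcf`,
#'   `<label>.pheno.tsv` and `<label>.truth.tsv` per study.
#' @return list with `collection` (a [study_collection]) and `truth` (named
#'   per-study truth records).
#' @export
simulate_replicated_studies <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pool <- build_founder_pool(config)
  sims <- lapply(config$study_labels, function(lab)
    simulate_study(config, lab, pool, orient_minor = FALSE))
  names(sims) <- config$study_labels
  # joint minor-allele orientation over all studies
  tot <- Reduce(`+`, lapply(sims, function(s) rowSums(s$geno$dosage)))
  nsub <- sum(vapply(sims, function(s) length(s$geno$subjects), 0L))
  af <- tot / (2 * nsub)
  flip <- af > 0.5
  studies <- lapply(sims, function(s) {
    g <- s$geno
    g$dosage[flip, ] <- 2L - g$dosage[flip, , drop = FALSE]
    g$haplotypes[flip, ] <- 1L - g$haplotypes[flip, , drop = FALSE]
    g$variants$minor <- ifelse(flip, g$variants$ref, g$variants$alt)
    g$variants$maf <- rowMeans(g$dosage) / 2
    list(geno = g, pheno = s$pheno)
  })
  coll <- study_collection(studies)
  truth <- lapply(sims, `[[`, "truth")
  for (t in names(truth)) {
    truth[[t]]$flipped <- flip
    # planted allele vectors in the emitted minor-allele coding
    truth[[t]]$planted_minor <- lapply(config$planted, function(h)
      as.integer(xor(h$alleles == 1, flip)))
    names(truth[[t]]$planted_minor) <-
      vapply(config$planted, `[[`, "", "name")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lab in names(studies)) {
      write_genotypes_vcf(studies[[lab]]$geno,
                          file.path(out_dir, paste0(lab, ".vcf")))
      write_phenotypes(studies[[lab]]$pheno,
                       file.path(out_dir, paste0(lab, ".pheno.tsv")))
      tr <- truth[[lab]]
      tt <- data.frame(subject = studies[[lab]]$geno$subjects,
                       tr$carrier_copies, check.names = FALSE)
      utils::write.table(tt, file.path(out_dir, paste0(lab, ".truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(collection = coll, truth = truth)
}

#' Simulate a sentinel-selection candidate panel with LD proxies
#'
#' Generates a case-control dosage panel purpose-built for validating
#' LD-based sentinel selection: independent causal variants, each surrounded
#' by a block of LD proxies at controlled r-squared, plus optional
#' independent noise variants. Proxies are generated at the chromosome level
#' by copying the causal allele with probability `sqrt(r2)` and redrawing it
#' from the population frequency otherwise, which leaves allele frequencies
#' intact while hitting the target correlation in expectation.
#'
#' @param n_cases,n_controls sample quotas.
#' @param causal data.frame with columns `maf` and `beta` (log OR per
#'   allele); one row per independent causal variant. Use `NULL` for a
#'   pure-noise panel.
#' @param n_proxies proxies generated per causal variant.
#' @param r2_range target proxy r-squared range (uniform draw per proxy).
#' @param n_noise independent non-causal variants (maf uniform 0.1-0.4).
#' @param beta0 baseline log-odds.
#' @return list with `X` (subjects x variants dosage matrix), `status`
#'   (1 = case), `causal_ids`, `proxy_of` (named proxy-to-causal map) and
#'   `r2_target` per proxy.
#' @export
simulate_sentinel_panel <- function(n_cases, n_controls, causal = NULL,
                                    n_proxies = 0, r2_range = c(0.5, 0.99),
                                    n_noise = 0, beta0 = 0) {
  nc <- if (is.null(causal)) 0L else nrow(causal)
  # fixed proxy r2 targets (drawn once, part of the panel definition)
  qmat <- if (nc && n_proxies)
    matrix(sqrt(stats::runif(nc * n_proxies, r2_range[1], r2_range[2])),
           nc, n_proxies)
  noise_maf <- if (n_noise) stats::runif(n_noise, 0.1, 0.4)

  draw_panel <- function(n) {
    chrom <- function(p, n) stats::rbinom(n, 1, p)
    X <- NULL; nm <- character(0)
    eta <- rep(beta0, n)
    for (k in seq_len(nc)) {
      p <- causal$maf[k]
      x1 <- chrom(p, n); x2 <- chrom(p, n)
      X <- cbind(X, x1 + x2); nm <- c(nm, paste0("causal", k))
      eta <- eta + causal$beta[k] * (x1 + x2)
      for (j in seq_len(n_proxies)) {
        q <- qmat[k, j]
        y1 <- ifelse(stats::runif(n) < q, x1, chrom(p, n))
        y2 <- ifelse(stats::runif(n) < q, x2, chrom(p, n))
        X <- cbind(X, y1 + y2); nm <- c(nm, paste0("proxy", k, "_", j))
      }
    }
    for (v in seq_len(n_noise)) {
      p <- noise_maf[v]
      X <- cbind(X, chrom(p, n) + chrom(p, n))
      nm <- c(nm, paste0("noise", v))
    }
    colnames(X) <- nm
    list(X = X, y = stats::rbinom(n, 1, stats::plogis(eta)))
  }

  accX <- list(); accy <- list()
  got_case <- 0L; got_ctrl <- 0L; drawn <- 0L
  batch <- max(2L * (n_cases + n_controls), 1000L)
  while ((got_case < n_cases || got_ctrl < n_controls) &&
         drawn < 400L * (n_cases + n_controls)) {
    b <- draw_panel(batch)
    take <- c(which(b$y == 1)[seq_len(min(n_cases - got_case,
                                          sum(b$y == 1)))],
              which(b$y == 0)[seq_len(min(n_controls - got_ctrl,
                                          sum(b$y == 0)))])
    take <- take[!is.na(take)]
    if (length(take)) {
      accX[[length(accX) + 1L]] <- b$X[take, , drop = FALSE]
      accy[[length(accy) + 1L]] <- b$y[take]
      got_case <- got_case + sum(b$y[take] == 1)
      got_ctrl <- got_ctrl + sum(b$y[take] == 0)
    }
    drawn <- drawn + batch
  }
  if (got_case < n_cases || got_ctrl < n_controls)
    stop("quotas unreachable; check beta0/effects")
  X <- do.call(rbind, accX); y <- unlist(accy)
  causal_ids <- if (nc) paste0("causal", seq_len(nc)) else character(0)
  pr <- character(0)
  if (nc && n_proxies)
    for (k in seq_len(nc))
      pr[paste0("proxy", k, "_", seq_len(n_proxies))] <- paste0("causal", k)
  list(X = X, status = y, causal_ids = causal_ids, proxy_of = pr,
       r2_target = if (nc && n_proxies) as.vector(t(qmat^2)) else numeric(0))
}
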