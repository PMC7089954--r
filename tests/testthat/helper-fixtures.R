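# Shared fixture builders. Everything is generated in code; no stored data.

# minimal genotype dataset from a dosage matrix (variants x subjects),
# with consistent phased haplotypes when requested
toy_dataset <- function(dosage, phased = FALSE, chrom = "8") {
  m <- nrow(dosage); n <- ncol(dosage)
  variants <- data.frame(
    id = sprintf("v%02d", seq_len(m)), chrom = chrom,
    pos = 1000L * seq_len(m), ref = "A", alt = "G", minor = "G",
    maf = pmin(rowMeans(dosage, na.rm = TRUE) / 2, 0.5),
    stringsAsFactors = FALSE)
  haps <- NULL
  if (phased) {
    haps <- matrix(0L, m, 2 * n)
    for (s in seq_len(n)) for (v in seq_len(m)) {
      d <- dosage[v, s]
      if (is.na(d)) next
      haps[v, 2 * s - 1] <- as.integer(d >= 1)
      haps[v, 2 * s] <- as.integer(d == 2)
    }
  }
  genotype_dataset(variants, sprintf("S%03d", seq_len(n)), dosage,
                   haplotypes = haps,
                   phase_prob = if (phased) rep(1, n))
}

toy_phenotypes <- function(n, n_cases = n %/% 2, study = "study1",
                           age = NULL) {
  data.frame(subject = sprintf("S%03d", seq_len(n)),
             status = c(rep("case", n_cases), rep("control", n - n_cases)),
             study = study,
             age = if (is.null(age)) round(runif(n, 45, 80)) else age,
             stringsAsFactors = FALSE)
}

# null two-study collection: independent binomial dosages, no effects
null_collection <- function(n_variants, n_per_study, maf_range = c(0.1, 0.4),
                            phased = TRUE) {
  p <- runif(n_variants, maf_range[1], maf_range[2])
  studies <- list()
  for (lab in c("s1", "s2")) {
    h1 <- matrix(rbinom(n_variants * n_per_study, 1,
                        rep(p, n_per_study)), n_variants)
    h2 <- matrix(rbinom(n_variants * n_per_study, 1,
                        rep(p, n_per_study)), n_variants)
    dos <- h1 + h2
    haps <- matrix(0L, n_variants, 2 * n_per_study)
    haps[, seq(1, 2 * n_per_study, 2)] <- h1
    haps[, seq(2, 2 * n_per_study, 2)] <- h2
    variants <- data.frame(
      id = sprintf("v%03d", seq_len(n_variants)), chrom = "8",
      pos = 1000L * seq_len(n_variants), ref = "A", alt = "G", minor = "G",
      maf = rowMeans(dos) / 2, stringsAsFactors = FALSE)
    subj <- sprintf("%s_%04d", lab, seq_len(n_per_study))
    geno <- genotype_dataset(variants, subj, dos,
                             haplotypes = if (phased) haps,
                             phase_prob = if (phased) rep(1, n_per_study))
    pheno <- data.frame(subject = subj,
                        status = rep(c("case", "control"),
                                     length.out = n_per_study),
                        study = lab, stringsAsFactors = FALSE)
    studies[[lab]] <- list(geno = geno, pheno = pheno)
  }
  study_collection(studies)
}

# brute-force BH step-up adjustment, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(adj, 1)
  q
}

# all-pairs concordance AUC (ties 0.5)
auc_bruteforce <- function(scores, status) {
  ca <- scores[status == 1]; co <- scores[status == 0]
  s <- 0
  for (a in ca) for (b in co)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(ca) * length(co))
}

# exact two-sided Wilcoxon rank-sum P by enumeration of group assignments
wilcox_exact_enum <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  r <- rank(all)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(all), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- mean(ws)
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}
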