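make_result_rows <- function(starts, haps, copies = 50,
                             beta = 0.5, p = 0.01) {
  n <- length(starts)
  data.frame(start = starts, end = starts + nchar(haps) - 1,
             width = nchar(haps), start_idx = starts, hap = haps,
             copies_total = rep_len(copies, n),
             beta_combined = rep_len(beta, n),
             or_combined = exp(rep_len(beta, n)),
             ci_low_combined = NA_real_, ci_high_combined = NA_real_,
             p_combined = rep_len(p, n), concordant = TRUE,
             stringsAsFactors = FALSE)
}

test_that("window haplotype enumeration reads off phased alleles", {
  dos <- rbind(v1 = c(1L, 0L), v2 = c(2L, 1L))
  ds <- toy_dataset(dos, phased = TRUE)
  # subject 1 haplotypes: (1,1) and (0,1); subject 2: (0,1),(0,0)
  ew <- enumerate_window_haplotypes(ds, 1, 2)
  expect_setequal(ew$haps, c("11", "01", "00"))
  expect_equal(sum(ew$chrom_count), 2 * 2)
  i11 <- match("11", ew$haps); i01 <- match("01", ew$haps)
  expect_equal(unname(ew$copies[1, i11]), 1)
  expect_equal(unname(ew$copies[1, i01]), 1)
  # conservation: each subject contributes exactly two chromosomes
  expect_true(all(rowSums(ew$copies) == 2))
  expect_error(enumerate_window_haplotypes(ds, 2, 2), "outside")
})

test_that("subjects below the phase-probability threshold are excluded", {
  dos <- matrix(rbinom(40, 2, 0.4), nrow = 4)
  ds <- toy_dataset(dos, phased = TRUE)
  ds$phase_prob <- c(rep(1, 8), 0.85, 0.2)
  ew <- enumerate_window_haplotypes(ds, 1, 3)
  expect_equal(sum(ew$included), 8)
  expect_equal(sum(ew$chrom_count), 16)
  ew2 <- enumerate_window_haplotypes(ds, 1, 3, phase_threshold = 0.8)
  expect_equal(sum(ew2$included), 9)
})

test_that("copy counts are conserved across every scanned window", {
  set.seed(61)
  cfg <- sim_config(n_cases = 120, n_controls = 120, n_variants = 30,
                    seed = 61)
  sim <- simulate_replicated_studies(cfg)
  g <- sim$collection$studies$studyA$geno
  for (w in c(2, 5, 11, 20)) for (s in c(1, 30 - w + 1)) {
    ew <- enumerate_window_haplotypes(g, s, w)
    expect_equal(sum(ew$chrom_count), 2 * sum(ew$included))
    expect_true(all(rowSums(ew$copies) == 2))
  }
})

test_that("window widths outside [2, 20] are rejected", {
  set.seed(62)
  coll <- null_collection(10, 30)
  expect_error(sliding_window_scan(coll, widths = c(2, 25)), "\\[2, 20\\]")
  expect_error(sliding_window_scan(coll, widths = 1:3), "\\[2, 20\\]")
})

test_that("overlapping windows with agreeing alleles merge into one model", {
  rows <- make_result_rows(c(1, 3), c("11010", "01011"))
  models <- assemble_ancestral_haplotypes(rows)
  expect_length(models, 1)
  expect_equal(models[[1]]$variants, 1:7)
  expect_equal(models[[1]]$alleles, c(1L, 1L, 0L, 1L, 0L, 1L, 1L))
})

test_that("a shared overlap segment blocks the merge (uniqueness rule)", {
  # two retained haplotypes of window [3..7] share segment "010" on [3..5]
  rows <- make_result_rows(c(1, 3, 3), c("11010", "01011", "01000"))
  models <- assemble_ancestral_haplotypes(rows)
  expect_length(models, 3)  # nothing merges across the ambiguous overlap
})

test_that("assembly is invariant to input row order", {
  set.seed(63)
  rows <- make_result_rows(c(1, 3, 5, 9, 11), c("11010", "01011", "01100",
                                                "00110", "11000"),
                           copies = c(50, 50, 45, 60, 55))
  canon <- function(models) {
    sigs <- vapply(models, function(m)
      paste(m$variants, m$alleles, collapse = ";"), "")
    sort(sigs)
  }
  m1 <- assemble_ancestral_haplotypes(rows)
  for (i in 1:5) {
    m2 <- assemble_ancestral_haplotypes(rows[sample(nrow(rows)), ])
    expect_identical(canon(m2), canon(m1))
  }
})

test_that("carrier-continuity guard keeps different-frequency runs apart", {
  rows <- make_result_rows(c(1, 3), c("11010", "01011"),
                           copies = c(200, 20))
  expect_length(assemble_ancestral_haplotypes(rows), 2)
  rows2 <- make_result_rows(c(1, 3), c("11010", "01011"),
                            copies = c(200, 150))
  expect_length(assemble_ancestral_haplotypes(rows2), 1)
})

test_that("peak windows break ties by width then start", {
  rows <- make_result_rows(c(1, 3, 5), c("110", "0101", "01"),
                           beta = c(log(2), log(0.5), log(1.5)),
                           p = c(0.001, 0.001, 0.0005))
  model <- structure(list(name = "H1", variants = 1:6,
                          alleles = c(1L, 1L, 0L, 1L, 0L, 1L),
                          extent = c(1L, 6L), members = 1:3,
                          member_table = rows, direction = 1),
                     class = "ancestral_haplotype")
  pk <- peak_windows(model)
  # |log OR| ties between rows 1 and 2; wider window (row 2) wins
  expect_equal(pk$peak_effect$start, 3)
  expect_equal(pk$peak_significance$start, 5)
})

test_that("marking alleles honor specificity, sharing and direction", {
  # chromosomes: 40 carrying model H1 signature (variants 1:2 == 1),
  # 40 carrying H2 (variants 4:5 == 1), 120 background
  set.seed(64)
  n <- 100  # subjects per study
  build <- function(lab) {
    nh <- 2 * n
    H <- matrix(0L, 6, nh)
    h1 <- 1:20; h2 <- 21:40
    H[1:2, h1] <- 1L
    H[4:5, h2] <- 1L
    # v3: minor allele only on H1 chromosomes
    H[3, h1[1:15]] <- 1L
    # v6: split across H1 and H2
    H[6, c(h1[1:10], h2[1:10])] <- 1L
    dos <- H[, seq(1, nh, 2)] + H[, seq(2, nh, 2)]
    variants <- data.frame(id = sprintf("v%d", 1:6), chrom = "8",
                           pos = 1000L * (1:6), ref = "A", alt = "G",
                           minor = "G", maf = rowMeans(dos) / 2,
                           stringsAsFactors = FALSE)
    subj <- sprintf("%s_%03d", lab, 1:n)
    geno <- genotype_dataset(variants, subj, dos, haplotypes = H,
                             phase_prob = rep(1, n))
    pheno <- data.frame(subject = subj,
                        status = rep(c("case", "control"), length.out = n),
                        study = lab, stringsAsFactors = FALSE)
    list(geno = geno, pheno = pheno)
  }
  coll <- study_collection(list(a = build("a"), b = build("b")))
  mk_model <- function(name, variants, alleles, dir)
    structure(list(name = name, variants = variants, alleles = alleles,
                   extent = range(variants), members = 1L,
                   member_table = make_result_rows(variants[1], "11"),
                   direction = dir), class = "ancestral_haplotype")
  models <- list(mk_model("H1", 1:2, c(1L, 1L), 1),
                 mk_model("H2", 4:5, c(1L, 1L), 1))
  scan_res <- data.frame(variant = sprintf("v%d", 1:6),
                         direction = 1, stringsAsFactors = FALSE)
  mk <- assign_marking_alleles(coll, models, scan_res, theta = 0.8)
  expect_equal(mk$model[mk$variant == "v3"], "H1")
  expect_equal(mk$model[mk$variant == "v6"], "shared:H1+H2")
  # direction mismatch blocks assignment
  scan_res2 <- scan_res; scan_res2$direction <- -1
  mk2 <- assign_marking_alleles(coll, models, scan_res2, theta = 0.8)
  expect_true(is.na(mk2$model[mk2$variant == "v3"]))
})

test_that("constrained scan requires >= 2 marking variants and matches the primary scan on the full map", {
  set.seed(65)
  coll <- null_collection(8, 120)
  model <- structure(list(name = "H1", variants = 1:8,
                          alleles = rep(1L, 8), extent = c(1L, 8L),
                          members = 1L,
                          member_table = make_result_rows(1, "11"),
                          direction = 1), class = "ancestral_haplotype")
  marking_all <- data.frame(variant = coll$variants$id, model = "H1",
                            stringsAsFactors = FALSE)
  prim <- sliding_window_scan(coll, widths = 2:3)
  cons <- constrained_scan(model, coll, marking_all, widths = 2:3)
  expect_equal(cons$results, prim, ignore_attr = TRUE)

  marking_one <- data.frame(variant = coll$variants$id[1], model = "H1",
                            stringsAsFactors = FALSE)
  expect_error(constrained_scan(model, coll, marking_one),
               "fewer than 2 marking")
})
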