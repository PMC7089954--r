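test_that("additive logistic fit matches closed-form facts", {
  # exchangeable dosage distributions give OR = 1 exactly
  d <- c(0, 1, 2, 1, 0, 1, 2, 1)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  r <- fit_additive_logistic(d, y)
  expect_equal(r$beta, 0, tolerance = 1e-8)
  expect_equal(r$or_, 1, tolerance = 1e-8)

  # binary predictor: OR equals the 2x2 cross-product ratio
  d <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  y <- c(rep(1, 100), rep(0, 100))
  r <- fit_additive_logistic(d, y)
  expect_equal(r$or_, (30 * 90) / (10 * 70), tolerance = 1e-7)
  expect_equal(r$p, 2 * pnorm(-abs(r$beta / r$se)), tolerance = 1e-12)
  expect_equal(r$ci95, exp(r$beta + c(-1, 1) * qnorm(0.975) * r$se),
               tolerance = 1e-10)

  # aggregated fast path agrees with subject-level glm
  set.seed(10)
  d <- rbinom(400, 2, 0.3)
  y <- rbinom(400, 1, plogis(-0.3 + 0.4 * d))
  r <- fit_additive_logistic(d, y)
  g <- glm(y ~ d, family = binomial())
  expect_equal(r$beta, unname(coef(g)[2]), tolerance = 1e-7)
  expect_equal(r$se, unname(sqrt(diag(vcov(g)))[2]), tolerance = 1e-4)

  expect_error(fit_additive_logistic(rep(1, 10), rep(0:1, 5)), "constant")
  expect_error(fit_additive_logistic(0:9, rep(1, 10)), "case and one control")
})

test_that("separation is flagged and the penalized fallback gives finite P", {
  # all carriers are cases, some non-carrier cases exist
  d <- c(rep(1, 10), rep(0, 90), rep(0, 100))
  y <- c(rep(1, 100), rep(0, 100))
  r <- fit_additive_logistic(d, y)
  expect_true(r$separated)
  fb <- separation_fallback_test(d, y)
  expect_identical(fb$test, "choi_lrt")
  expect_true(is.finite(fb$p) && fb$p > 0)
  expect_lt(fb$p, 0.01)
  expect_true(is.finite(fb$beta))

  # no carriers at all -> untestable
  expect_error(separation_fallback_test(rep(0, 200), y), "constant")

  # non-separated data: fallback P close to Wald P in moderate-z settings
  set.seed(21)
  agree <- replicate(20, {
    d <- rbinom(500, 2, 0.3)
    y <- rbinom(500, 1, 0.5)
    w <- fit_additive_logistic(d, y)
    if (abs(w$beta / w$se) >= 2) return(NA)
    f <- separation_fallback_test(d, y)
    abs(f$p - w$p) / w$p
  })
  expect_lt(median(agree, na.rm = TRUE), 0.2)
})

test_that("covariate-adjusted fits accept numeric and factor columns", {
  set.seed(11)
  n <- 800
  d <- rbinom(n, 2, 0.3)
  pc1 <- rnorm(n); study <- factor(rep(c("a", "b"), n / 2))
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * d + 0.3 * pc1))
  r <- fit_additive_logistic(d, y, data.frame(pc1 = pc1, study = study))
  g <- glm(y ~ d + pc1 + study, family = binomial())
  expect_equal(r$beta, unname(coef(g)["d"]), tolerance = 1e-6)
  expect_false(r$separated)
  expect_setequal(r$covariates_used, c("pc1", "study"))
})

test_that("scan reports untestable variants and routes separated fits", {
  set.seed(5)
  dos <- rbind(v1 = rbinom(60, 2, 0.3),
               v2 = rep(0L, 60),           # monomorphic
               v3 = rbinom(60, 2, 0.4))
  dos["v2", 1] <- 0L
  ds <- toy_dataset(dos)
  ph <- toy_phenotypes(60)
  res <- scan_variants(ds, ph)
  expect_equal(nrow(res), 3)
  expect_match(res$note[res$variant == "v02"], "untestable")
  expect_true(all(is.finite(res$p[res$variant != "v02"])))
})

test_that("BH FDR matches the step-up definition", {
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bh_fdr(0.32), 0.32)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), bh_bruteforce(p))
  expect_error(bh_fdr(numeric(0)), "empty")
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_bruteforce(p))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in rank
  }
})

test_that("Bonferroni thresholds render at one significant figure", {
  expect_equal(bonferroni_threshold(0.05, 765)$rendered, 7e-5)
  expect_equal(bonferroni_threshold(0.05, 242)$rendered, 2e-4)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
})

test_that("concordance filter applies inclusive alpha and the direction rule", {
  mk <- function(p, beta) data.frame(
    variant = c("v1", "v2", "v3"), scope = "s", beta = beta,
    se = 0.1, or = exp(beta), ci_low = NA, ci_high = NA, p = p,
    test = "wald", n = 100, direction = sign(beta),
    stringsAsFactors = FALSE)
  a <- mk(c(0.04, 0.04, 0.05), c(0.5, 0.5, -0.2))
  b <- mk(c(0.04, 0.04, 0.01), c(0.5, -0.5, -0.3))
  out <- concordance_filter(a, b, 0.05)
  expect_setequal(out$variant, c("v1", "v3"))  # v2 dropped: opposite signs
  # P = 0.05 exactly is retained (inclusive)
  expect_true("v3" %in% out$variant)
  expect_error(concordance_filter(a, mk(0.1, 1)[0, ]), "disjoint")
})

test_that("combined scan pools studies and beats single-study power", {
  set.seed(31)
  # planted effect split across two studies
  ok <- replicate(10, {
    coll <- null_collection(1, 400)
    # inject an effect at the single variant in both studies
    for (lab in names(coll$studies)) {
      g <- coll$studies[[lab]]$geno
      y <- rbinom(400, 1, plogis(-0.2 + 0.45 * g$dosage[1, ]))
      coll$studies[[lab]]$pheno$status <-
        ifelse(y == 1, "case", "control")
    }
    if (any(vapply(coll$studies, function(s)
      length(unique(s$pheno$status)), 0L) < 2)) return(NA)
    sA <- scan_variants(coll$studies$s1$geno, coll$studies$s1$pheno)
    sB <- scan_variants(coll$studies$s2$geno, coll$studies$s2$pheno)
    cmb <- combined_scan(coll)
    cmb$p <= min(sA$p, sB$p)
  })
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
})

test_that("adjusted scan respects independence and collinearity", {
  set.seed(41)
  n <- 3000
  h <- rbinom(n, 2, 0.3)
  dos <- rbind(v1 = h,
               v2 = rbinom(n, 2, 0.25),     # independent of v1
               v3 = h)                       # perfect proxy of v1
  ds <- toy_dataset(dos)
  ph <- toy_phenotypes(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.3 * h))
  ph$status <- ifelse(y == 1, "case", "control")

  expect_error(adjusted_scan(ds, ph, "v01", c("v01", "v02")),
               "in the adjustment set")

  una <- scan_variants(ds, ph)
  adj <- adjusted_scan(ds, ph, "v01", "v02")
  expect_lt(abs(adj$beta_adj - una$beta[una$variant == "v01"]),
            una$se[una$variant == "v01"])

  # test variant that is a perfect proxy of an adjustment variant
  adj2 <- adjusted_scan(ds, ph, "v03", "v01")
  expect_false(isTRUE(adj2$converged))  # rank-deficient joint design

  # collinear adjusters deduplicated with a warning
  expect_warning(adjusted_scan(ds, ph, "v02", c("v01", "v03")),
                 "collinear")
})
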