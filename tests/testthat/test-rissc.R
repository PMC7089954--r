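test_that("the r-squared schedule descends exactly from 1.0 to 0.025", {
  expect_equal(threshold_schedule(1), 1.0)
  expect_equal(threshold_schedule(2), 0.975)
  expect_equal(threshold_schedule(40), 0.025)
  expect_equal(threshold_schedule(1:40),
               c(1.0, 0.975 - 0.025 * (0:38)), tolerance = 1e-12)
  expect_error(threshold_schedule(0), "\\[1, 40\\]")
  expect_error(threshold_schedule(41), "\\[1, 40\\]")
})

test_that("bin partition is exhaustive, disjoint, and threshold-faithful", {
  set.seed(71)
  simple <- data.frame(p = runif(8), beta = rnorm(8), pos = 1:8)
  # random but symmetric r2
  for (rep in 1:20) {
    A <- matrix(runif(64), 8)
    r2 <- (A + t(A)) / 2; diag(r2) <- 1
    thr <- runif(1)
    bins <- partition_bins(1:8, thr, r2, simple)
    all_members <- unlist(bins)
    expect_setequal(all_members, 1:8)
    expect_equal(anyDuplicated(all_members), 0L)
    for (b in bins) expect_true(all(r2[b[1], b] >= thr - 1e-12))
  }
  # threshold 0: one bin with everything
  bins0 <- partition_bins(1:8, 0, diag(8), simple)
  expect_length(bins0, 1)
  # threshold 1 with three identical variants and one independent
  r2 <- diag(4); r2[1:3, 1:3] <- 1
  bins1 <- partition_bins(1:4, 1, r2, data.frame(p = c(0.1, 0.2, 0.3, 0.4),
                                                 beta = 1:4, pos = 1:4))
  expect_setequal(lapply(bins1, sort), list(1:3, 4L))
})

test_that("best-in-bin uses P, then |beta|, then position", {
  simple <- data.frame(p = c(1e-6, 1e-3, 1e-6, 1e-6),
                       beta = c(0.3, 2, 0.9, 0.9), pos = 1:4)
  expect_equal(best_in_bin(c(1, 2), simple), 1)
  expect_equal(best_in_bin(c(1, 3), simple), 3)  # tie on P, larger |beta|
  expect_equal(best_in_bin(c(3, 4), simple), 3)  # full tie, lower position
  expect_equal(best_in_bin(2, simple), 2)
  expect_error(best_in_bin(integer(0), simple), "empty")
})

test_that("joint model flags rank deficiency and recovers two independent signals", {
  set.seed(72)
  n <- 4000
  x1 <- rbinom(n, 2, 0.2); x2 <- rbinom(n, 2, 0.2)
  y <- rbinom(n, 1, plogis(-0.5 + log(2) * x1 + log(2) * x2))
  fit <- fit_joint_model(cbind(a = x1, b = x2), y)
  expect_true(fit$converged)
  expect_true(all(fit$results$p <= 0.01))
  # duplicate columns: non-converged by the rank-deficiency policy
  fit2 <- fit_joint_model(cbind(a = x1, b = x1), y)
  expect_false(fit2$converged)
  expect_null(fit2$results)
})

test_that("the deleted set grows monotonically and never re-enters", {
  set.seed(73)
  pan <- simulate_sentinel_panel(600, 600,
                                 causal = data.frame(maf = 0.25,
                                                     beta = log(1.8)),
                                 n_proxies = 8, n_noise = 6)
  sm <- run_rissc(pan$X, pan$status, trace = TRUE)
  aud <- sm$audit
  expect_true(all(diff(aud$n_deleted) >= 0))
  expect_equal(aud$threshold, threshold_schedule(1:40))
  expect_true(all(sm$sentinel_idx %in%
                    setdiff(seq_len(ncol(pan$X)), integer(0))))
  # deleted variants are disjoint from the final sentinel set
  st <- list(step = 1, threshold = 1, surviving = seq_len(ncol(pan$X)),
             marked = integer(0), deleted = integer(0),
             simple = hapsentinel:::rissc_simple_results(pan$X, pan$status),
             last_converged = TRUE)
  r2 <- r2_matrix(t(pan$X))
  for (i in 2:40) {
    st_new <- rissc_step(st, pan$X, pan$status, r2)
    expect_true(all(st$deleted %in% st_new$deleted))
    expect_true(length(intersect(st_new$deleted, st_new$surviving)) == 0)
    expect_true(all(st_new$marked %in% st_new$surviving))
    st <- st_new
  }
})

test_that("mutually independent significant candidates are a fixed point", {
  set.seed(74)
  n <- 3000
  X <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3),
             c = rbinom(n, 2, 0.3))
  y <- rbinom(n, 1, plogis(-0.6 + 0.5 * X[, 1] + 0.5 * X[, 2] +
                             0.5 * X[, 3]))
  sm <- run_rissc(X, y)
  expect_setequal(sm$sentinels, c("a", "b", "c"))
  expect_true(all(sm$results$p <= 0.01))
})

test_that("a pure proxy is deleted while the stronger signal survives", {
  set.seed(75)
  ok <- replicate(10, {
    pan <- simulate_sentinel_panel(1500, 1500,
                                   causal = data.frame(maf = 0.25,
                                                       beta = log(2)),
                                   n_proxies = 1, r2_range = c(0.85, 0.95))
    sm <- run_rissc(pan$X, pan$status)
    length(sm$sentinels) == 1
  })
  expect_gte(mean(ok), 0.8)
})

test_that("a single strong candidate is returned as the sole sentinel", {
  set.seed(76)
  n <- 2000
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.4 + 0.6 * x))
  sm <- run_rissc(matrix(x, ncol = 1, dimnames = list(NULL, "v1")), y)
  expect_equal(sm$sentinels, "v1")
  expect_error(run_rissc(matrix(numeric(0), 10, 0), y), "empty candidate")
})

test_that("identical inputs produce identical sentinel sets", {
  set.seed(77)
  pan <- simulate_sentinel_panel(800, 800,
                                 causal = data.frame(maf = 0.2,
                                                     beta = log(1.6)),
                                 n_proxies = 5, n_noise = 5)
  s1 <- run_rissc(pan$X, pan$status)
  s2 <- run_rissc(pan$X, pan$status)
  expect_identical(s1$sentinels, s2$sentinels)
  expect_identical(s1$results, s2$results)
})
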