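test_that("exact signed-rank p-values match hand enumeration on the
           canonical cases", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  expect_equal(r$p, 0.0625)
  expect_equal(r$method, "exact")
  single <- wilcoxon_signed_rank(1)
  expect_equal(single$p, 1)
  anti <- wilcoxon_signed_rank(c(-2, 2))
  expect_equal(anti$p, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate")
})

test_that("exact signed-rank equals the 2^n enumeration oracle, with and
           without ties", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE) +
      sample(c(0, 0.5), n, replace = TRUE)
    for (alt in c("two.sided", "greater")) {
      mine <- wilcoxon_signed_rank(d, alternative = alt)
      oracle <- wilcoxon_enumeration_oracle(d, alternative = alt)
      expect_equal(mine$statistic, oracle$statistic)
      expect_equal(mine$p, oracle$p, tolerance = 1e-12)
    }
  }
  # independent cross-check against stats::wilcox.test where it is exact
  # (tie-free inputs: the reference falls back to an approximation on ties)
  set.seed(202)
  for (rep in 1:10) {
    d <- round(rnorm(8), 3)
    if (any(d == 0) || anyDuplicated(abs(d))) next
    ref <- wilcox.test(d, exact = TRUE)
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample approximation agrees with the reference
           implementation", {
  set.seed(9)
  x <- rnorm(60); y <- rnorm(60, 0.3)
  mine <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(mine$method, "approximate")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("positionwise tests find switching above clustering on
           MVT-consistent cohorts", {
  pol <- foraging_policy(p_fast_switch = 0, p_slow_cluster = 0,
                         noise_sd = 0.3)
  sc <- scored_sessions(14, pol, seed_base = 300)
  res <- test_position(sc, metric = "irtr")
  expect_true(all(res$mean_switching > res$mean_clustering))
  expect_true(all(res$p < 0.01))
  expect_true(all(res$mean_switching > 1))
  expect_true(all(res$mean_clustering < 1))
})

test_that("the ramping test is exact one-sided on uniform positive
           differences", {
  # 8 participants whose -1 IRTr exceeds -2 by construction
  sc <- do.call(rbind, lapply(1:8, function(i)
    scored_frame(irts = c(1, 1, 1.2 + 0.01 * i, 3),
                 meanings = c("A", "A", "A", "B"),
                 participant = sprintf("p%02d", i))))
  res <- ramping_test(sc, alternative = "greater")
  expect_equal(res$p, 1 / 2^8)
  expect_gt(res$mean_minus1, res$mean_minus2)
  flat <- do.call(rbind, lapply(1:4, function(i)
    scored_frame(irts = c(1, 1, 1, 3), meanings = c("A", "A", "A", "B"),
                 participant = sprintf("p%02d", i))))
  expect_error(ramping_test(flat), "degenerate")
})

test_that("zero-noise ramping puts position -1 strictly above -2", {
  pol <- foraging_policy(p_fast_switch = 0, p_slow_cluster = 0, noise_sd = 0,
                         ramp = 1.15)
  sc <- scored_sessions(5, pol, seed_base = 60)
  res <- ramping_test(sc, alternative = "greater")
  expect_gt(res$mean_minus1, res$mean_minus2)
})

test_that("optimality regression matches closed-form OLS", {
  r <- optimality_regression(x = c(0, 1, 2, 3), y = c(1, 3, 4, 8))
  expect_equal(r$slope, 2.2, tolerance = 1e-12)
  expect_equal(r$r_squared, 121 / 130, tolerance = 1e-10) # 0.93077
  coll <- optimality_regression(x = 0:2, y = 0:2)
  expect_equal(coll$slope, 1)
  expect_equal(coll$r_squared, 1)
  flat <- optimality_regression(x = c(0, 1, 2, 4), y = rep(2, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(optimality_regression(x = rep(1, 5), y = rnorm(5)),
               "zero variance")
})

test_that("regression R squared equals the squared Pearson correlation", {
  set.seed(4)
  for (rep in 1:5) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    r <- optimality_regression(x = x, y = y)
    expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-10)
    expect_equal(r$F, r$r_squared * 28 / (1 - r$r_squared),
                 tolerance = 1e-8)
  }
})

test_that("noiseless IRS dependence on IRT is recovered exactly", {
  set.seed(12)
  n <- 40
  dat <- tibble::tibble(
    participant = rep(sprintf("p%02d", 1:4), each = 10 * 2),
    cue = rep(rep(c("c1", "c2"), each = 10), 4),
    response_index = rep(1:10, 8),
    irt = runif(80, 1, 8))
  dat$irs <- -0.01 * dat$irt + 0.3
  dat$transition <- "clustering"
  res <- suppressWarnings(irt_irs_model(dat, "clustering"))
  est <- res$coefficients$estimate[res$coefficients$term == "irt"]
  expect_equal(est, -0.01, tolerance = 1e-6)
})

test_that("mixed model recovers a negative time-similarity coupling on
           synthetic clustering responses", {
  sc <- scored_sessions(12, foraging_policy(), seed_base = 410)
  res <- irt_irs_model(sc, "clustering")
  est <- res$coefficients$estimate[res$coefficients$term == "irt"]
  expect_lt(est, 0)
  expect_true(all(res$varcomp >= 0))
  expect_true(res$marginal_r2 >= 0 && res$marginal_r2 <= 1)
})

test_that("correlation battery handles monotone pairs and applies a monotone
           BH adjustment", {
  set.seed(3)
  x <- rnorm(20)
  counts <- tibble::tibble(up = x, down = -x)
  scores <- tibble::tibble(mono = sort(rnorm(20))[rank(x)],
                           noise = rnorm(20), const = rep(1, 20))
  res <- correlation_battery(counts, scores)
  expect_equal(res$rho[res$count == "up" & res$score == "mono"], 1)
  expect_equal(res$rho[res$count == "down" & res$score == "mono"], -1)
  expect_true(all(is.na(res$rho[res$score == "const"])))
  ok <- !is.na(res$p)
  expect_true(all(res$p_fdr[ok] >= res$p[ok] - 1e-15))
  # BH equals the step-up definition computed by hand
  p_raw <- sort(res$p[ok])
  by_hand <- rev(cummin(rev(p_raw * length(p_raw) / seq_along(p_raw))))
  expect_equal(sort(res$p_fdr[ok]), pmin(1, by_hand), tolerance = 1e-12)
})

test_that("one-sided battery mode matches the one-tailed protocol", {
  set.seed(5)
  x <- rnorm(25)
  counts <- tibble::tibble(v = x)
  scores <- tibble::tibble(w = x + rnorm(25, sd = 0.5))
  two <- correlation_battery(counts, scores)
  one <- correlation_battery(counts, scores, alternative = "greater")
  expect_lt(one$p, two$p)
})
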