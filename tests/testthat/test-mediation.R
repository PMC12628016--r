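test_that("the printed worked examples of the indirect product hold", {
  expect_equal(round(indirect_effect(0.371, 0.247), 3), 0.092)
  expect_equal(round(indirect_effect(0.50, 0.284), 3), 0.142)
  expect_equal(round(indirect_effect(0.50, 0.324), 3), 0.162)
  expect_equal(indirect_effect(0, 5), 0)
})

test_that("the identity chain gives a = 1, c = 1 and a null direct effect", {
  x <- rnorm(30)
  res <- fit_paths(x, x, x)
  expect_equal(res$a, 1, tolerance = 1e-10)
  expect_equal(res$c, 1, tolerance = 1e-10)
  expect_equal(res$c_prime, 0, tolerance = 1e-10)
  expect_equal(res$indirect, 1, tolerance = 1e-10)
})

test_that("c decomposes exactly into c' + a*b on arbitrary data", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    m <- 0.4 * x + rnorm(n)
    y <- 0.3 * m + 0.2 * x + rnorm(n)
    res <- fit_paths(x, m, y)
    expect_lt(abs(res$c - (res$c_prime + res$a * res$b)), 1e-10)
  }
})

test_that("standardization is idempotent", {
  set.seed(15)
  x <- rnorm(40); m <- 0.5 * x + rnorm(40); y <- 0.5 * m + rnorm(40)
  raw <- fit_paths(x, m, y)
  std <- fit_paths(as.numeric(scale(x)), as.numeric(scale(m)),
                   as.numeric(scale(y)))
  for (f in c("a", "b", "c", "c_prime", "indirect")) {
    expect_equal(raw[[f]], std[[f]], tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_paths(rep(1, 10), rnorm(10), rnorm(10)), "constant")
  expect_error(fit_paths(rnorm(3), rnorm(3), rnorm(3)), "at least 4")
})

test_that("bootstrap CIs are deterministic given the seed and exclude zero
           under a strong effect", {
  set.seed(23)
  n <- 150
  x <- rnorm(n); m <- 0.5 * x + sqrt(0.75) * rnorm(n)
  y <- 0.5 * m + sqrt(0.75) * rnorm(n)
  a <- bootstrap_ci(x, m, y, n_boot = 400, seed = 99)
  b <- bootstrap_ci(x, m, y, n_boot = 400, seed = 99)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_true(a$significant)
  expect_gt(a$ci_low, 0)
  expect_true(a$ci_low <= median(a$boot_indirect) &&
                median(a$boot_indirect) <= a$ci_high)
})

test_that("a null mediator path yields intervals covering zero in most
           replicates", {
  set.seed(31)
  cover <- vapply(1:10, function(rep) {
    n <- 200
    x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- bootstrap_ci(x, m, y, n_boot = 300, seed = rep)
    res$ci_low <= 0 && res$ci_high >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("direct-chain recovery at n = 300 lands within a tenth of truth", {
  set.seed(44)
  n <- 300
  x <- rnorm(n)
  m <- 0.4 * x + sqrt(1 - 0.16) * rnorm(n)
  y <- 0.4 * m + sqrt(1 - 0.16) * rnorm(n)
  res <- fit_paths(x, m, y)
  expect_lt(abs(res$a - 0.4), 0.1)
  expect_lt(abs(res$b - 0.4), 0.1)
  expect_lt(abs(res$indirect - 0.16), 0.07)
})

test_that("the table-driven wrapper validates its columns", {
  tab <- tibble::tibble(s = rnorm(20), cnt = rnorm(20), crea = rnorm(20))
  res <- mediate(tab, "s", "cnt", "crea", n_boot = 100, seed = 1)
  expect_s3_class(res, "mediation_result")
  expect_error(mediate(tab, "s", "missing", "crea"), "missing")
})
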