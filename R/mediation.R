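# Single-mediator mediation with percentile bootstrap: brain connectivity
# (predictor) -> memory search pattern (mediator) -> creativity (outcome).

#' Indirect effect as the product of paths a and b
#'
#' @param a regression coefficient of the mediator on the predictor.
#' @param b regression coefficient of the outcome on the mediator, controlling
#'   for the predictor.
#' @return `a * b`.
#' @examples
#' indirect_effect(0.371, 0.247)
#' @export
indirect_effect <- function(a, b) a * b

zscore <- function(v, name) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) {
    stop("`", name, "` is constant; mediation is degenerate", call. = FALSE)
  }
  (v - mean(v)) / s
}

fit_paths_raw <- function(x, m, y) {
  # x, m, y already standardized; closed-form OLS paths
  a <- stats::cov(x, m) / stats::var(x)
  fit_b <- stats::lm.fit(cbind(1, m, x), y)
  co <- fit_b$coefficients
  co[is.na(co)] <- 0 # aliased predictor under exact collinearity
  b <- co[2]
  c_prime <- co[3]
  c_total <- stats::cov(x, y) / stats::var(x)
  c(a = unname(a), b = unname(b), c_prime = unname(c_prime),
    c = unname(c_total))
}

#' Fit single-mediator mediation paths
#'
#' All variables are z-scored on the full sample, then the three nested OLS
#' models are fitted: path a from `m ~ x`, paths b and c' from `y ~ m + x`,
#' and the total effect c from `y ~ x`. The indirect effect is `a * b`; the
#' OLS identity `c = c' + a * b` holds exactly.
#'
#' @param x per-subject predictor (e.g. positive-network strength).
#' @param m per-subject mediator (e.g. Fast-Switching count).
#' @param y per-subject outcome (e.g. a creativity score).
#' @return an object of class `mediation_result`: list with `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `n`, per-path `p` values (OLS t tests), and `NA`
#'   CI fields to be filled by [bootstrap_ci()].
#' @export
fit_paths <- function(x, m, y) {
  keep <- stats::complete.cases(x, m, y)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("mediation needs at least 4 complete cases", call. = FALSE)
  x <- zscore(x, "x"); m <- zscore(m, "m"); y <- zscore(y, "y")
  paths <- fit_paths_raw(x, m, y)
  coef_p <- function(sm, term) {
    co <- sm$coefficients
    if (term %in% rownames(co)) co[term, 4] else NA_real_
  }
  p_a <- coef_p(summary(stats::lm(m ~ x)), "x")
  sm_b <- summary(stats::lm(y ~ m + x))
  p_c <- coef_p(summary(stats::lm(y ~ x)), "x")
  out <- list(a = paths[["a"]], b = paths[["b"]], c = paths[["c"]],
              c_prime = paths[["c_prime"]],
              indirect = indirect_effect(paths[["a"]], paths[["b"]]),
              p_a = p_a, p_b = coef_p(sm_b, "m"),
              p_c_prime = coef_p(sm_b, "x"),
              p_c = p_c, n = n,
              ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L,
              significant = NA, data = list(x = x, m = m, y = y))
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> n =", x$n, "\n",
      sprintf(" a = %.3f  b = %.3f  c = %.3f  c' = %.3f\n",
              x$a, x$b, x$c, x$c_prime),
      sprintf(" indirect (a*b) = %.3f", x$indirect))
  if (x$n_boot > 0) {
    cat(sprintf("  [%.3f, %.3f] (%d boots)%s", x$ci_low, x$ci_high,
                x$n_boot, if (isTRUE(x$significant)) " *" else ""))
  }
  cat("\n")
  invisible(x)
}

#' Percentile bootstrap CI for the indirect effect
#'
#' Variables are standardized once on the full sample; the bootstrap then
#' resamples the standardized rows with replacement, refits the paths per
#' resample, and takes the empirical 2.5th/97.5th percentiles of the `n_boot`
#' indirect effects (default 5000). The effect is flagged significant when
#' the interval excludes 0. Resamples in which a variable is constant are
#' redrawn (at most 10 retries each).
#'
#' @param x,m,y per-subject predictor, mediator, outcome.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed; the CI is deterministic given the seed.
#' @param conf confidence level (default 0.95).
#' @return a `mediation_result` with `ci_low`, `ci_high`, `n_boot`,
#'   `significant` and the bootstrap draws in `boot_indirect`.
#' @export
bootstrap_ci <- function(x, m, y, n_boot = 5000, seed = 1, conf = 0.95) {
  assert_count(n_boot, "n_boot", min = 100)
  res <- fit_paths(x, m, y)
  if (res$n < 10) {
    stop("bootstrap mediation needs at least 10 complete cases",
         call. = FALSE)
  }
  xs <- res$data$x; ms <- res$data$m; ys <- res$data$y
  n <- res$n
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (try in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(xs[idx]) > 0 && stats::sd(ms[idx]) > 0 &&
              stats::sd(ys[idx]) > 0) {
          p <- fit_paths_raw(xs[idx], ms[idx], ys[idx])
          return(p[["a"]] * p[["b"]])
        }
      }
      stop("bootstrap resample degenerate after 10 retries", call. = FALSE)
    }, numeric(1))
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  res$ci_low <- qs[1]
  res$ci_high <- qs[2]
  res$n_boot <- as.integer(n_boot)
  res$significant <- qs[1] > 0 || qs[2] < 0
  res$boot_indirect <- boot
  res
}

#' Run a configured mediation
#'
#' Convenience wrapper taking a merged per-participant table and column
#' names, mirroring the predictor = positive-network strength, mediator =
#' response-type count, outcome = creativity score design.
#'
#' @param table data.frame/tibble with one row per participant.
#' @param x,m,y column names of predictor, mediator, outcome.
#' @param n_boot,seed,conf passed to [bootstrap_ci()].
#' @return a `mediation_result`.
#' @export
mediate <- function(table, x, m, y, n_boot = 5000, seed = 1, conf = 0.95) {
  for (col in c(x, m, y)) {
    if (!col %in% names(table)) {
      stop("column not found in table: ", col, call. = FALSE)
    }
  }
  bootstrap_ci(table[[x]], table[[m]], table[[y]], n_boot = n_boot,
               seed = seed, conf = conf)
}
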