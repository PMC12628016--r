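# Tests of marginal-value-theorem adherence: paired signed-rank position
# tests, the optimality regression, the IRT->IRS mixed model, and the
# correlation battery with FDR control.

#' Paired Wilcoxon signed-rank test
#'
#' Exact version for small samples: zero differences are removed, absolute
#' differences are midranked, and the null distribution of the positive rank
#' sum is obtained by convolution over all 2^n sign assignments (equivalent to
#' exhaustive enumeration, including under ties). For `n > exact_threshold` a
#' normal approximation with continuity correction and tie-corrected variance
#' is used.
#'
#' @param x,y paired samples (or `y = NULL` to test differences `x` against 0).
#' @param alternative `"two.sided"`, `"greater"` (positive differences) or
#'   `"less"`.
#' @param exact_threshold sample-size bound for the exact null (default 25).
#' @return a list with `statistic` (positive rank sum W), `p`, `n` (pairs after
#'   zero removal) and `method` (`"exact"` or `"approximate"`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_threshold = 25) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  keep <- !is.na(d)
  d <- d[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero or missing; signed-rank test is ",
         "degenerate", call. = FALSE)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_threshold) {
    # exact null by convolution over sign assignments; midranks doubled so
    # all masses sit on integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dp <- c(1, rep(0, total))
    for (rk in r2) {
      shifted <- c(rep(0, rk), dp[seq_len(length(dp) - rk)])
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dp[seq_len(w2 + 1)])
    p_ge <- sum(dp[seq.int(w2 + 1, total + 1)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_num <- w - mu
    cc <- switch(alternative,
                 two.sided = sign(z_num) * 0.5,
                 greater = 0.5,
                 less = -0.5)
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    method <- "approximate"
  }
  list(statistic = w, p = p, n = n, method = method)
}

participant_position_means <- function(scored, positions, metric) {
  # mean of the metric per participant at each retrieval position,
  # averaged response -> cue -> participant, split by governing-switch speed
  skey <- paste(scored$participant, scored$cue, scored$response_index,
                sep = "\r")
  positions$value <- scored[[metric]][
    match(paste(positions$participant, positions$cue,
                positions$response_index, sep = "\r"), skey)]
  positions
}

position_mean_table <- function(positions, switch_subset) {
  if (switch_subset != "all") {
    positions <- positions[!is.na(positions$switch_speed) &
                             positions$switch_speed == switch_subset, ,
                           drop = FALSE]
  }
  if (!nrow(positions)) return(NULL)
  m <- cue_then_participant_mean(positions$value, positions$participant,
                                 positions$cue)
  tibble::tibble(participant = names(m), value = as.numeric(m))
}

#' Positionwise switching-vs-clustering signed-rank tests
#'
#' For each retrieval position (-2, -1, +1, +2) compares the per-participant
#' mean of the metric for clustering responses at that position against the
#' per-participant mean for the governing switching responses, with a paired
#' Wilcoxon signed-rank test across participants. Values are averaged response
#' level, then across cues, then tested across participants. The comparison
#' can be restricted to fast or slow switches.
#'
#' @param scored scored tibble from [score_responses()].
#' @param metric `"irtr"` (default) or `"irsr"` (or any scored column).
#' @param switch_subset `"all"`, `"fast"` or `"slow"` switches.
#' @param exact_threshold passed to [wilcoxon_signed_rank()].
#' @return a tibble with one row per position: position, switch_subset,
#'   metric, n (paired participants), W, p, mean/SE per condition.
#' @export
test_position <- function(scored, metric = "irtr",
                          switch_subset = c("all", "fast", "slow"),
                          exact_threshold = 25) {
  switch_subset <- match.arg(switch_subset)
  positions <- align_positions(scored)
  positions <- participant_position_means(scored, positions, metric)
  sw <- position_mean_table(positions[positions$position == "S", ,
                                      drop = FALSE], switch_subset)
  out <- list()
  for (pos in c("-2", "-1", "+1", "+2")) {
    cl <- position_mean_table(positions[positions$position == pos, ,
                                        drop = FALSE], switch_subset)
    if (is.null(cl) || is.null(sw)) next
    merged <- merge(cl, sw, by = "participant",
                    suffixes = c("_clustering", "_switching"))
    merged <- merged[stats::complete.cases(merged), , drop = FALSE]
    if (nrow(merged) < 2) next
    wt <- wilcoxon_signed_rank(merged$value_switching,
                               merged$value_clustering,
                               exact_threshold = exact_threshold)
    out[[pos]] <- tibble::tibble(
      position = pos, switch_subset = switch_subset, metric = metric,
      n = wt$n, W = wt$statistic, p = wt$p, method = wt$method,
      mean_clustering = mean(merged$value_clustering),
      se_clustering = stats::sd(merged$value_clustering) / sqrt(nrow(merged)),
      mean_switching = mean(merged$value_switching),
      se_switching = stats::sd(merged$value_switching) / sqrt(nrow(merged)))
  }
  if (!length(out)) {
    stop("no position with enough paired participants for subset '",
         switch_subset, "'", call. = FALSE)
  }
  do.call(rbind, out)
}

#' Pre-switch ramping test
#'
#' Paired signed-rank comparison of the metric at position -1 (last clustering
#' response before a switch) against position -2, testing whether retrieval
#' slows as the switch approaches; run for all switches or restricted to fast
#' or slow switch contexts.
#'
#' @inheritParams test_position
#' @param alternative passed to [wilcoxon_signed_rank()]; `"greater"` tests
#'   ramping up toward the switch.
#' @return a one-row tibble: switch_subset, metric, n, W, p, per-position
#'   means.
#' @export
ramping_test <- function(scored, metric = "irtr",
                         switch_subset = c("all", "fast", "slow"),
                         alternative = "two.sided", exact_threshold = 25) {
  switch_subset <- match.arg(switch_subset)
  positions <- align_positions(scored)
  positions <- participant_position_means(scored, positions, metric)
  m1 <- position_mean_table(positions[positions$position == "-1", ,
                                      drop = FALSE], switch_subset)
  m2 <- position_mean_table(positions[positions$position == "-2", ,
                                      drop = FALSE], switch_subset)
  if (is.null(m1) || is.null(m2)) {
    stop("no participants with both -1 and -2 positions for subset '",
         switch_subset, "'", call. = FALSE)
  }
  merged <- merge(m1, m2, by = "participant", suffixes = c("_m1", "_m2"))
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  if (nrow(merged) < 1) {
    stop("no participants with both -1 and -2 positions", call. = FALSE)
  }
  wt <- wilcoxon_signed_rank(merged$value_m1, merged$value_m2,
                             alternative = alternative,
                             exact_threshold = exact_threshold)
  tibble::tibble(switch_subset = switch_subset, metric = metric, n = wt$n,
                 W = wt$statistic, p = wt$p, method = wt$method,
                 mean_minus1 = mean(merged$value_m1),
                 mean_minus2 = mean(merged$value_m2))
}

#' Optimality regression: fluency on the pre-switch gap
#'
#' Ordinary least squares of fluency (total or mean responses retrieved, the
#' outcome) on the absolute distance between the pre-switch IRT and the
#' long-term IRT (the predictor). Under the marginal value theorem,
#' participants who leave clusters closer to their marginal value should
#' produce more responses, i.e. a negative slope.
#'
#' @param summaries participant summary tibble from
#'   [summarize_participants()], needing `polyft_fluency` and
#'   `pre_switch_gap` columns (or supply `x`/`y` directly).
#' @param x,y optional explicit predictor/outcome vectors overriding
#'   `summaries`.
#' @return a list with `slope`, `intercept`, `r_squared`, `F`, `df` (c(1,
#'   n-2)) and `p`.
#' @export
optimality_regression <- function(summaries = NULL, x = NULL, y = NULL) {
  if (is.null(x) || is.null(y)) {
    stopifnot(!is.null(summaries))
    x <- summaries$pre_switch_gap
    y <- summaries$polyft_fluency
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 participants with a defined pre-switch ",
                  "gap", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("predictor has zero variance; regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (is.nan(r2)) r2 <- 0 # constant outcome: no variance to explain
  Fstat <- if (is.null(sm$fstatistic) || is.na(sm$fstatistic[1])) {
    r2 * (n - 2) / max(1e-300, 1 - r2)
  } else unname(sm$fstatistic[1])
  p <- if (r2 == 0) 1 else stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, F = Fstat, df = c(1, n - 2), p = p)
}

#' Mixed model: does retrieval time predict retrieval similarity?
#'
#' Fits `irs ~ irt + response_index + (1 | participant) + (1 | cue)` by REML,
#' separately for clustering or switching responses, controlling for rank in
#' the sequence (time on task). On a singular fit the model falls back to a
#' fixed-effects-only OLS with `singular_fallback = TRUE`.
#'
#' @param scored scored tibble with `irt`, `irs`, `response_index`,
#'   `transition`.
#' @param transition_subset `"clustering"` or `"switching"`.
#' @return a list with `coefficients` (tibble: term, estimate, se, p),
#'   `varcomp` (named vector of random-intercept variances and residual
#'   variance), `marginal_r2` and `singular_fallback`.
#' @export
irt_irs_model <- function(scored,
                          transition_subset = c("clustering", "switching")) {
  transition_subset <- match.arg(transition_subset)
  dat <- scored[scored$transition == transition_subset &
                  !is.na(scored$irt) & !is.na(scored$irs), , drop = FALSE]
  if (length(unique(dat$participant)) < 2 || length(unique(dat$cue)) < 2) {
    stop("need data from at least 2 participants and 2 cues", call. = FALSE)
  }
  dat <- data.frame(irs = dat$irs, irt = dat$irt,
                    response_index = dat$response_index,
                    participant = factor(dat$participant),
                    cue = factor(dat$cue))
  fit <- tryCatch(
    lme4::lmer(irs ~ irt + response_index + (1 | participant) + (1 | cue),
               data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular && is.null(fit)) {
    return(irt_irs_ols(dat))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  # Wald z tests on the fixed effects
  z <- beta / se
  pvals <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  fixed_pred <- as.vector(stats::model.matrix(fit) %*% beta)
  marginal_r2 <- stats::var(fixed_pred) /
    (stats::var(fixed_pred) + sum(varcomp))
  if (singular) {
    warning("singular mixed-model fit; falling back to fixed-effects OLS",
            call. = FALSE)
    return(irt_irs_ols(dat))
  }
  list(coefficients = tibble::tibble(term = names(beta),
                                     estimate = unname(beta),
                                     se = unname(se), p = unname(pvals)),
       varcomp = varcomp, marginal_r2 = marginal_r2,
       singular_fallback = FALSE)
}

irt_irs_ols <- function(dat) {
  fit <- stats::lm(irs ~ irt + response_index, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = tibble::tibble(term = rownames(co),
                                     estimate = co[, 1], se = co[, 2],
                                     p = co[, 4]),
       varcomp = c(Residual = sm$sigma^2),
       marginal_r2 = sm$r.squared, singular_fallback = TRUE)
}

#' Spearman correlation battery with FDR control
#'
#' Correlates each response-type count column with each ability-score column
#' (Spearman rho with midranks for ties, pairwise deletion of missing values)
#' and applies a Benjamini-Hochberg adjustment within the declared family (all
#' computed pairs).
#'
#' @param counts tibble/data.frame of per-participant response-type counts
#'   (plus a `participant` column, ignored for correlation).
#' @param scores tibble/data.frame of per-participant ability scores.
#' @param alpha significance level applied to adjusted p-values.
#' @param alternative `"two.sided"` (default) or `"greater"`/`"less"` for the
#'   one-tailed replication protocol.
#' @return a tibble: count, score, n, rho, p, p_fdr, significant. Pairs with a
#'   constant column have `NA` rho and are excluded from the FDR family.
#' @export
correlation_battery <- function(counts, scores, alpha = 0.05,
                                alternative = "two.sided") {
  cnt <- counts[vapply(counts, is.numeric, logical(1))]
  sco <- scores[vapply(scores, is.numeric, logical(1))]
  out <- list()
  for (a in names(cnt)) {
    for (b in names(sco)) {
      x <- cnt[[a]]; y <- sco[[b]]
      keep <- !is.na(x) & !is.na(y)
      n <- sum(keep)
      if (n < 4 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        out[[paste(a, b)]] <- tibble::tibble(count = a, score = b, n = n,
                                             rho = NA_real_, p = NA_real_)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[keep], y[keep], method = "spearman",
                        alternative = alternative))
      out[[paste(a, b)]] <- tibble::tibble(count = a, score = b, n = n,
                                           rho = unname(ct$estimate),
                                           p = ct$p.value)
    }
  }
  res <- do.call(rbind, out)
  res$p_fdr <- NA_real_
  ok <- !is.na(res$p)
  res$p_fdr[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < alpha
  res
}

#' Full MVT adherence report
#'
#' Convenience wrapper running the positionwise signed-rank tests (overall and
#' split by switch speed), the ramping test, the optimality regression and,
#' when similarity data are present, the IRT-to-IRS mixed models.
#'
#' @param scored scored tibble from [score_responses()].
#' @param summaries participant summaries from [summarize_participants()]
#'   (recomputed when `NULL`).
#' @return a list of result tables: `position_tests`, `ramping`,
#'   `optimality`, `irt_irs` (or `NULL` if no IRS).
#' @export
mvt_report <- function(scored, summaries = NULL) {
  if (is.null(summaries)) {
    summaries <- suppressWarnings(summarize_participants(scored))
  }
  pos <- list()
  for (ss in c("all", "fast", "slow")) {
    pos[[ss]] <- tryCatch(test_position(scored, switch_subset = ss),
                          error = function(e) NULL)
  }
  ramp <- lapply(c("all", "fast", "slow"), function(ss) {
    tryCatch(ramping_test(scored, switch_subset = ss),
             error = function(e) NULL)
  })
  irt_irs <- NULL
  if ("irs" %in% names(scored) && any(!is.na(scored$irs))) {
    irt_irs <- list(
      clustering = tryCatch(irt_irs_model(scored, "clustering"),
                            error = function(e) NULL),
      switching = tryCatch(irt_irs_model(scored, "switching"),
                           error = function(e) NULL))
  }
  list(position_tests = do.call(rbind, Filter(Negate(is.null), pos)),
       ramping = do.call(rbind, Filter(Negate(is.null), ramp)),
       optimality = optimality_regression(summaries),
       irt_irs = irt_irs)
}
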