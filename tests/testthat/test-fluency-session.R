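space_small <- generate_semantic_space(n_cues = 1, n_meanings = 4,
                                       words_per_meaning = 12, dim = 16,
                                       within_sd = 0.25, seed = 42)

test_that("sessions are deterministic given the seed", {
  pol <- foraging_policy()
  a <- generate_fluency_session(space_small, pol, "cue01", seed = 11)
  b <- generate_fluency_session(space_small, pol, "cue01", seed = 11)
  expect_identical(a, b)
  c <- generate_fluency_session(space_small, pol, "cue01", seed = 12)
  expect_false(identical(a, c))
})

test_that("a zero time budget yields an empty log with a warning", {
  pol <- foraging_policy(trial_duration = 0)
  expect_warning(log <- generate_fluency_session(space_small, pol, "cue01",
                                                 seed = 1),
                 "no response")
  expect_equal(nrow(log), 0)
})

test_that("sessions respect the time budget and sample without replacement", {
  pol <- foraging_policy()
  for (seed in 1:5) {
    log <- generate_fluency_session(space_small, pol, "cue01", seed = seed)
    expect_true(all(log$onset <= pol$trial_duration))
    expect_false(any(duplicated(log$word)))
    expect_true(all(diff(log$onset) > 0))
  }
})

test_that("zero-noise MVT-consistent sessions separate exactly at IRTr = 1", {
  pol <- foraging_policy(p_fast_switch = 0, p_slow_cluster = 0, noise_sd = 0)
  sc <- scored_sessions(6, pol, space = space_small, cues = "cue01")
  expect_gt(sum(sc$transition == "switching"), 0)
  expect_true(all(sc$irtr[sc$transition == "switching"] > 1))
  expect_true(all(sc$irtr[sc$transition == "clustering"] < 1))
  # every switch IRT exceeds the session mean IRT, clustering IRTs sit below
  for (p in unique(sc$participant)) {
    rows <- sc[sc$participant == p, ]
    m <- mean(rows$irt, na.rm = TRUE)
    expect_true(all(rows$irt[rows$transition == "switching"] > m))
    expect_true(all(rows$irt[rows$transition == "clustering"] < m,
                    na.rm = TRUE))
  }
})

test_that("scoring recovers the generator's deviance rates", {
  # moderate grid here; the full 200-session grid runs in the acceptance suite
  for (rate in c(0, 0.2)) {
    pol <- foraging_policy(p_fast_switch = rate, p_slow_cluster = rate)
    logs <- lapply(1:60, function(i)
      generate_fluency_session(space_small, pol, "cue01", seed = 500 + i,
                               participant = sprintf("p%03d", i)))
    sc <- score_responses(do.call(rbind, logs), embeddings = space_small)
    est <- estimate_deviance_rates(sc)
    if (rate == 0) {
      expect_identical(est$n_fast_switches, 0L)
      expect_identical(est$n_slow_clusterings, 0L)
    } else {
      tol_f <- 2.576 * sqrt(rate * (1 - rate) / est$n_fast_opportunities)
      tol_s <- 2.576 * sqrt(rate * (1 - rate) / est$n_slow_opportunities)
      expect_lt(abs(est$p_fast_switch - rate), tol_f)
      expect_lt(abs(est$p_slow_cluster - rate), tol_s)
    }
  }
})

test_that("unknown cues and invalid policies are rejected", {
  expect_error(generate_fluency_session(space_small, foraging_policy(),
                                        "nope", seed = 1), "cue")
  expect_error(foraging_policy(mu_cluster = -1), "mu_cluster")
  expect_error(foraging_policy(p_fast_switch = 2), "probability")
  expect_error(foraging_policy(ramp = 0.5), "ramp")
})
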