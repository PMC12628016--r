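# Synthetic fluency sessions under a marginal-value-theorem foraging policy.

#' Construct a foraging policy
#'
#' Parameters of the simulated searcher. Within a cluster (one cue meaning),
#' retrieval times are lognormal with arithmetic mean
#' `mu_cluster * ramp^(k - 1)` for the k-th item of the cluster, so successive
#' within-cluster retrievals slow down (`ramp` >= 1). Before each retrieval the
#' agent draws the candidate time for the next within-cluster item and compares
#' it to the running mean of all inter-response times emitted so far (its
#' current estimate of the long-term IRT, the marginal value):
#'
#' * candidate above the running mean: the agent abandons the cluster — the
#'   emitted response is a switch with IRT = candidate + `switch_cost` — except
#'   that with probability `p_slow_cluster` it persists and emits the candidate
#'   as a (slow) clustering response;
#' * candidate at or below the running mean: the agent stays — the emitted
#'   response is a clustering response with IRT = candidate — except that with
#'   probability `p_fast_switch` it switches early, emitting a switch with
#'   IRT = candidate and no switch cost (a fast, deviant switch).
#'
#' With both deviance probabilities and `noise_sd` at zero every switch IRT
#' exceeds the session mean IRT and every clustering IRT falls below it, i.e.
#' scored IRT ratios separate exactly at 1.
#'
#' @param mu_cluster mean within-cluster IRT at cluster position 1 (seconds).
#' @param switch_cost additive IRT cost of a (non-deviant) cluster switch
#'   (seconds).
#' @param ramp multiplicative IRT growth per successive within-cluster item
#'   (>= 1).
#' @param p_fast_switch probability of switching although the candidate IRT is
#'   still below the running marginal value.
#' @param p_slow_cluster probability of persisting in the cluster although the
#'   candidate IRT exceeds the running marginal value.
#' @param noise_sd log-scale SD of retrieval-time noise (0 = deterministic).
#' @param trial_duration time budget per cue (seconds).
#' @param articulation fixed response articulation duration (seconds); offsets
#'   are onset + articulation.
#' @return a list of class `foraging_policy`.
#' @export
foraging_policy <- function(mu_cluster = 2.1, switch_cost = 2.2, ramp = 1.15,
                            p_fast_switch = 0.22, p_slow_cluster = 0.55,
                            noise_sd = 0.55, trial_duration = 60,
                            articulation = 0.4) {
  if (!is.numeric(mu_cluster) || mu_cluster <= 0) {
    stop("`mu_cluster` must be > 0", call. = FALSE)
  }
  if (!is.numeric(trial_duration) || trial_duration < 0) {
    stop("`trial_duration` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(ramp) || ramp < 1) stop("`ramp` must be >= 1", call. = FALSE)
  if (!is.numeric(switch_cost) || switch_cost < 0) {
    stop("`switch_cost` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  assert_prob(p_fast_switch, "p_fast_switch")
  assert_prob(p_slow_cluster, "p_slow_cluster")
  structure(list(mu_cluster = mu_cluster, switch_cost = switch_cost,
                 ramp = ramp, p_fast_switch = p_fast_switch,
                 p_slow_cluster = p_slow_cluster, noise_sd = noise_sd,
                 trial_duration = trial_duration, articulation = articulation),
            class = "foraging_policy")
}

#' @export
print.foraging_policy <- function(x, ...) {
  cat("<foraging_policy> mu_cluster =", x$mu_cluster,
      "ramp =", x$ramp, "switch_cost =", x$switch_cost, "\n",
      " p_fast_switch =", x$p_fast_switch,
      "p_slow_cluster =", x$p_slow_cluster,
      "noise_sd =", x$noise_sd, "trial_duration =", x$trial_duration, "\n")
  invisible(x)
}

#' Simulate one fluency session for one cue
#'
#' Samples words without replacement from the cue's lexicon under the foraging
#' policy (see [foraging_policy()] for the switch rule). Within a cluster the
#' agent retrieves the unused word most similar to the previous response, so
#' similarity decays as the cluster depletes while retrieval time ramps up;
#' on a switch it jumps to a uniformly chosen unused word of another meaning.
#' Generation stops when the next onset would exceed the trial duration or the
#' lexicon is exhausted.
#'
#' @param space a `semantic_space`.
#' @param policy a `foraging_policy`.
#' @param cue cue identifier present in `space$cues`.
#' @param seed integer seed; the session is deterministic given the seed.
#' @param participant participant identifier stamped on the rows.
#' @return a tibble of response-log rows: participant, cue, response_index,
#'   word, onset, offset, meaning. Empty (with a warning) when the time budget
#'   admits no response.
#' @export
generate_fluency_session <- function(space, policy, cue, seed,
                                     participant = "p001") {
  stopifnot(inherits(space, "semantic_space"),
            inherits(policy, "foraging_policy"))
  if (!cue %in% space$cues) stop("cue not present in space: ", cue,
                                 call. = FALSE)
  in_cue <- space$lexicon$cue == cue
  lex_word <- space$lexicon$word[in_cue]
  lex_meaning <- space$lexicon$meaning[in_cue]
  emb <- space$embeddings[lex_word, , drop = FALSE]
  empty <- tibble::tibble(participant = character(), cue = character(),
                          response_index = integer(), word = character(),
                          onset = double(), offset = double(),
                          meaning = character())
  with_seed(seed, {
    used <- logical(length(lex_word))
    pick_uniform <- function(meaning) {
      idx <- which(!used & lex_meaning == meaning)
      if (length(idx) == 1) idx else sample(idx, 1)
    }
    pick_nearest <- function(meaning, prev_idx) {
      idx <- which(!used & lex_meaning == meaning)
      sims <- emb[idx, , drop = FALSE] %*% emb[prev_idx, ]
      idx[which.max(sims)]
    }
    open_meanings <- function(exclude = NULL) {
      m <- unique(lex_meaning[!used])
      setdiff(m, exclude)
    }

    # first response: uniform meaning, uniform word; latency ~ mu_cluster
    m0 <- open_meanings()
    cur_meaning <- if (length(m0) == 1) m0 else sample(m0, 1)
    i0 <- pick_uniform(cur_meaning)
    onset <- rlnorm_mean(1, policy$mu_cluster, policy$noise_sd)
    if (onset > policy$trial_duration) {
      warning("time budget admits no response for cue ", cue, call. = FALSE)
      return(empty)
    }
    used[i0] <- TRUE
    max_n <- length(lex_word)
    word_idx <- integer(max_n); word_idx[1] <- i0
    mlab <- character(max_n); mlab[1] <- cur_meaning
    onsets <- double(max_n); onsets[1] <- onset
    n_out <- 1L
    prev_idx <- i0
    cluster_pos <- 1L
    irts <- double(0)
    prev_offset <- onset + policy$articulation

    repeat {
      cand <- rlnorm_mean(1, policy$mu_cluster * policy$ramp^cluster_pos,
                          policy$noise_sd)
      run_mean <- if (length(irts)) mean(irts) else NA_real_
      action <- if (is.na(run_mean)) {
        "stay"
      } else if (cand > run_mean) {
        if (stats::runif(1) < policy$p_slow_cluster) "stay" else "switch_slow"
      } else {
        if (stats::runif(1) < policy$p_fast_switch) "switch_fast" else "stay"
      }
      # feasibility: staying needs an unused word in the current meaning,
      # switching an unused word in some other meaning
      can_stay <- any(!used & lex_meaning == cur_meaning)
      other <- open_meanings(exclude = cur_meaning)
      if (action == "stay" && !can_stay) {
        # cluster exhausted: forced switch, charged the full switch cost
        action <- if (length(other)) "switch_slow" else "exhausted"
      } else if (action != "stay" && !length(other)) {
        action <- if (can_stay) "stay" else "exhausted"
      }
      if (action == "exhausted") break
      if (action == "stay") {
        irt <- cand
        idx <- pick_nearest(cur_meaning, prev_idx)
        cluster_pos <- cluster_pos + 1L
      } else {
        irt <- cand + if (action == "switch_slow") policy$switch_cost else 0
        cur_meaning <- if (length(other) == 1) other else sample(other, 1)
        idx <- pick_uniform(cur_meaning)
        cluster_pos <- 1L
      }
      onset <- prev_offset + irt
      if (onset > policy$trial_duration) break
      used[idx] <- TRUE
      n_out <- n_out + 1L
      word_idx[n_out] <- idx
      mlab[n_out] <- cur_meaning
      onsets[n_out] <- onset
      irts <- c(irts, irt)
      prev_idx <- idx
      prev_offset <- onset + policy$articulation
    }

    keep <- seq_len(n_out)
    tibble::new_tibble(list(
      participant = rep(participant, n_out), cue = rep(cue, n_out),
      response_index = keep, word = lex_word[word_idx[keep]],
      onset = onsets[keep],
      offset = onsets[keep] + policy$articulation,
      meaning = mlab[keep]), nrow = n_out)
  })
}

#' Recover deviance rates from scored sessions
#'
#' Reconstructs, from a scored sequence (see [score_responses()]) and the known
#' policy constants, every switch/stay opportunity the generating agent faced,
#' and estimates the deviant-switch and deviant-persistence probabilities.
#' The agent's running marginal value is recomputable from the scored IRTs;
#' under the generator's semantics a fast (deviant) switch satisfies
#' `irt <= running mean` while a slow switch satisfies
#' `irt > running mean + switch_cost`, so switches are separable by comparing
#' their IRT to the running mean (IRT values in the gap between the two bounds
#' arise only from a forced switch on cluster exhaustion and are binned as
#' slow).
#'
#' @param scored scored response tibble with `irt` and `transition` columns.
#' @return a list with `p_fast_switch` and `p_slow_cluster` estimates plus the
#'   opportunity counts `n_fast_opportunities`, `n_slow_opportunities` and the
#'   event counts `n_fast_switches`, `n_slow_clusterings`.
#' @export
estimate_deviance_rates <- function(scored) {
  stopifnot(all(c("participant", "cue", "response_index", "irt",
                  "transition") %in% names(scored)))
  scored <- scored[order(scored$participant, scored$cue,
                         scored$response_index), ]
  key <- paste(scored$participant, scored$cue, sep = "\r")
  n_fast_op <- 0L; n_slow_op <- 0L; n_fs <- 0L; n_sc <- 0L
  for (k in unique(key)) {
    rows <- which(key == k)
    irt <- scored$irt[rows]
    trans <- scored$transition[rows]
    seen <- double(0)
    for (i in seq_along(rows)) {
      if (is.na(irt[i])) next
      if (length(seen) >= 1 && trans[i] %in% c("clustering", "switching")) {
        rm_ <- mean(seen)
        if (trans[i] == "clustering") {
          if (irt[i] > rm_) { n_slow_op <- n_slow_op + 1L; n_sc <- n_sc + 1L }
          else n_fast_op <- n_fast_op + 1L
        } else {
          if (irt[i] <= rm_) { n_fast_op <- n_fast_op + 1L; n_fs <- n_fs + 1L }
          else n_slow_op <- n_slow_op + 1L
        }
      }
      seen <- c(seen, irt[i])
    }
  }
  list(p_fast_switch = if (n_fast_op) n_fs / n_fast_op else NA_real_,
       p_slow_cluster = if (n_slow_op) n_sc / n_slow_op else NA_real_,
       n_fast_opportunities = n_fast_op, n_slow_opportunities = n_slow_op,
       n_fast_switches = n_fs, n_slow_clusterings = n_sc)
}
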