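# Whole-cohort simulator: fluency sessions, embeddings, connectivity with
# planted effects, ability scores, and recorded ground truth.

#' Cohort configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 86
#' participants, three polysemous cues with five meanings each, one-minute
#' spoken trials, 200-node connectomes in 17 networks, and a mediated
#' brain -> search-pattern -> creativity structure.
#'
#' @param n_participants cohort size.
#' @param n_cues,n_meanings,words_per_meaning,embed_dim,within_sd semantic
#'   space parameters (see [generate_semantic_space()]).
#' @param policy baseline [foraging_policy()] shared by the cohort.
#' @param mu_sd between-participant SD of `mu_cluster` (seconds).
#' @param p_fast_sd,p_slow_sd between-participant SDs of the deviance
#'   probabilities (clamped to \[0.01, 0.6\]).
#' @param a_true target standardized path from planted network strength to
#'   the search-pattern counts.
#' @param b_true target standardized path from the counts to the creativity
#'   scores.
#' @param n_nodes,n_networks connectome size and number of network labels.
#' @param n_planted planted edges per sign per phenotype network.
#' @param beta planted edge effect per standardized trait unit.
#' @param conn_noise_sd background edge noise SD.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 86, n_cues = 3, n_meanings = 5,
                          words_per_meaning = 20, embed_dim = 50,
                          within_sd = 0.3, policy = foraging_policy(),
                          mu_sd = 0.35, p_fast_sd = 0.06, p_slow_sd = 0.07,
                          a_true = 0.4, b_true = 0.3, n_nodes = 200,
                          n_networks = 17, n_planted = 40, beta = 0.5,
                          conn_noise_sd = 0.1) {
  assert_count(n_participants, "n_participants")
  stopifnot(inherits(policy, "foraging_policy"))
  if (abs(a_true) > 1 || abs(b_true) > 1) {
    stop("`a_true` and `b_true` are standardized paths and must lie in ",
         "[-1, 1]", call. = FALSE)
  }
  out <- list(n_participants = n_participants, n_cues = n_cues,
              n_meanings = n_meanings, words_per_meaning = words_per_meaning,
              embed_dim = embed_dim, within_sd = within_sd, policy = policy,
              mu_sd = mu_sd, p_fast_sd = p_fast_sd, p_slow_sd = p_slow_sd,
              a_true = a_true, b_true = b_true, n_nodes = n_nodes,
              n_networks = n_networks, n_planted = n_planted, beta = beta,
              conn_noise_sd = conn_noise_sd)
  class(out) <- "cohort_config"
  out
}

sample_disjoint_edges <- function(n_nodes, n_sets, n_each) {
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  total <- n_sets * n_each
  if (total > nrow(ut)) {
    stop("not enough edges to plant ", total, " disjoint effects",
         call. = FALSE)
  }
  picked <- sample.int(nrow(ut), total)
  lapply(seq_len(n_sets), function(s) {
    idx <- picked[seq.int((s - 1) * n_each + 1, s * n_each)]
    unname(cbind(ut[idx, 1], ut[idx, 2]))
  })
}

mix_to_target <- function(target_cor, anchor, noise) {
  # returns a unit-variance variable with correlation target_cor to `anchor`
  target_cor * anchor + sqrt(1 - target_cor^2) * noise
}

#' Generate a full synthetic cohort
#'
#' Simulates, in order: (1) a semantic space; (2) per-participant foraging
#' policies (baseline policy plus participant-level variation in `mu_cluster`
#' and the two deviance probabilities); (3) one fluency session per
#' participant and cue; (4) scoring of those sessions with the package's own
#' scorer to obtain the realized Fast-Switching and Slow-Clustering counts;
#' (5) connectivity matrices in which two disjoint planted-edge networks
#' track traits built from the standardized counts (correlation `a_true`,
#' plus independent noise), so that the positive-network strength relates to
#' the measured phenotype at the configured path strength; (6) creativity
#' scores as `b_true * standardized count + noise` (CAT from Fast-Switching,
#' AUT fluency/uniqueness from Slow-Clustering) and executive scores with a
#' mild planted association to Slow-Switching. All stage seeds derive from
#' the master seed via [child_seed()].
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return a list of class `semforage_cohort` with elements `log` (response
#'   log tibble), `space` (`semantic_space`), `connectivity`
#'   (`connectivity_cohort`), `covariates` (per-participant tibble: motion,
#'   executive and creativity scores), `scored`, `summaries`, and
#'   `ground_truth` (policies, planted edge sets, traits, `a_true`,
#'   `b_true`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  base <- config$policy
  # all sub-seeds and all cohort-level noise come from one master stream so
  # no two stages share structurally related RNG states
  draws <- with_seed(seed, {
    rseed <- function(k = 1) sample.int(2147483646L, k)
    list(space_seed = rseed(), session_seeds = rseed(n * config$n_cues),
         conn_seed = rseed(), edge_seed = rseed(),
         mu = pmax(0.5, stats::rnorm(n, base$mu_cluster, config$mu_sd)),
         p_fast = pmin(0.6, pmax(0.01, stats::rnorm(
           n, base$p_fast_switch, config$p_fast_sd))),
         p_slow = pmin(0.6, pmax(0.01, stats::rnorm(
           n, base$p_slow_cluster, config$p_slow_sd))),
         eps_trait_fs = stats::rnorm(n), eps_trait_sc = stats::rnorm(n),
         eps_cat = stats::rnorm(n), eps_aut_flu = stats::rnorm(n),
         eps_aut_unq = stats::rnorm(n), eps_span = stats::rnorm(n),
         eps_tmt = stats::rnorm(n), eps_stroop = stats::rnorm(n))
  })
  space <- generate_semantic_space(
    n_cues = config$n_cues, n_meanings = config$n_meanings,
    words_per_meaning = config$words_per_meaning, dim = config$embed_dim,
    within_sd = config$within_sd, seed = draws$space_seed)

  policies <- tibble::tibble(
    participant = sprintf("p%03d", seq_len(n)),
    mu_cluster = draws$mu,
    p_fast_switch = draws$p_fast,
    p_slow_cluster = draws$p_slow)

  logs <- vector("list", n * config$n_cues)
  k <- 0L
  for (i in seq_len(n)) {
    pol <- foraging_policy(
      mu_cluster = policies$mu_cluster[i], switch_cost = base$switch_cost,
      ramp = base$ramp, p_fast_switch = policies$p_fast_switch[i],
      p_slow_cluster = policies$p_slow_cluster[i],
      noise_sd = base$noise_sd, trial_duration = base$trial_duration,
      articulation = base$articulation)
    for (ci in seq_len(config$n_cues)) {
      k <- k + 1L
      logs[[k]] <- generate_fluency_session(
        space, pol, space$cues[ci],
        seed = draws$session_seeds[(i - 1L) * config$n_cues + ci],
        participant = policies$participant[i])
    }
  }
  log <- do.call(rbind, logs)

  scored <- score_responses(log, embeddings = space, mode = "spoken")
  summaries <- suppressWarnings(summarize_participants(scored))
  summaries <- summaries[match(policies$participant, summaries$participant), ]

  std <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      stop("cohort config degenerate: a response-type count is constant",
           call. = FALSE)
    }
    (v - mean(v)) / s
  }
  m_fs <- std(summaries$n_fast_switching)
  m_sc <- std(summaries$n_slow_clustering)
  m_ss <- std(summaries$n_slow_switching)

  traits <- list(
    fast_switch = mix_to_target(config$a_true, m_fs, draws$eps_trait_fs),
    slow_cluster = mix_to_target(config$a_true, m_sc, draws$eps_trait_sc))

  edge_sets <- with_seed(draws$edge_seed, {
    sample_disjoint_edges(config$n_nodes, 4, config$n_planted)
  })
  names(edge_sets) <- c("pos_fast_switch", "neg_fast_switch",
                        "pos_slow_cluster", "neg_slow_cluster")

  # connectivity: two disjoint planted networks, one per phenotype
  conn_fs <- generate_connectivity(
    n, config$n_nodes, traits$fast_switch,
    planted_pos = edge_sets$pos_fast_switch,
    planted_neg = edge_sets$neg_fast_switch,
    beta = config$beta, noise_sd = config$conn_noise_sd,
    seed = draws$conn_seed, n_networks = config$n_networks)
  z_sc <- as.numeric(scale(traits$slow_cluster))
  mats <- conn_fs$matrices
  for (s in seq_len(n)) {
    m <- mats[[s]]
    m[edge_sets$pos_slow_cluster] <- m[edge_sets$pos_slow_cluster] +
      config$beta * z_sc[s]
    m[edge_sets$neg_slow_cluster] <- m[edge_sets$neg_slow_cluster] -
      config$beta * z_sc[s]
    lower <- cbind(edge_sets$pos_slow_cluster[, 2],
                   edge_sets$pos_slow_cluster[, 1])
    m[lower] <- m[cbind(edge_sets$pos_slow_cluster[, 1],
                        edge_sets$pos_slow_cluster[, 2])]
    lower <- cbind(edge_sets$neg_slow_cluster[, 2],
                   edge_sets$neg_slow_cluster[, 1])
    m[lower] <- m[cbind(edge_sets$neg_slow_cluster[, 1],
                        edge_sets$neg_slow_cluster[, 2])]
    mats[[s]] <- m
  }
  connectivity <- connectivity_cohort(mats, conn_fs$motion,
                                      subjects = policies$participant,
                                      node_labels = conn_fs$node_labels)

  b <- config$b_true
  covariates <- tibble::tibble(
    participant = policies$participant,
    motion = connectivity$motion,
    cat_cr = mix_to_target(b, m_fs, draws$eps_cat),
    aut_fluency = mix_to_target(b, m_sc, draws$eps_aut_flu),
    aut_uniqueness = mix_to_target(b, m_sc, draws$eps_aut_unq),
    backward_span = mix_to_target(0.25, m_ss, draws$eps_span),
    tmt_shifting = mix_to_target(-0.25, m_ss, draws$eps_tmt),
    stroop_interference = mix_to_target(-0.25, m_ss, draws$eps_stroop))

  ground_truth <- list(
    policies = policies, a_true = config$a_true, b_true = config$b_true,
    planted_edges = edge_sets, beta = config$beta,
    traits = traits,
    std_fast_switching = m_fs, std_slow_clustering = m_sc)

  out <- list(log = log, space = space, connectivity = connectivity,
              covariates = covariates, scored = scored,
              summaries = summaries, ground_truth = ground_truth,
              config = config, seed = seed)
  class(out) <- "semforage_cohort"
  out
}

#' @export
print.semforage_cohort <- function(x, ...) {
  cat("<semforage_cohort>", x$config$n_participants, "participants,",
      x$config$n_cues, "cues,", nrow(x$log), "responses,",
      x$config$n_nodes, "connectome nodes (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
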