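# Shared fixtures and independent oracles, all built in code.

# small spoken log: one participant, one cue, hand-set timing/meanings
tiny_log <- function(meanings = c("A", "A", "B"),
                     onsets = c(1, 12.5, 20),
                     offsets = onsets + 0.5,
                     words = paste0("w", seq_along(meanings)),
                     participant = "p01", cue = "c1") {
  tibble::tibble(participant = participant, cue = cue,
                 response_index = seq_along(meanings), word = words,
                 onset = onsets, offset = offsets, meaning = meanings)
}

# scored frame built directly (for summary-level hand traces)
scored_frame <- function(irts, meanings, participant = "p01", cue = "c1",
                         words = paste0("w", seq_along(meanings))) {
  log <- tibble::tibble(participant = participant, cue = cue,
                        response_index = seq_along(meanings), word = words,
                        meaning = meanings, irt = irts)
  log <- label_transitions(log)
  log <- compute_ratios(log)
  classify_speed(log)
}

# a small deterministic batch of sessions scored end to end
scored_sessions <- function(n_participants, policy, space = NULL,
                            seed_base = 100, cues = NULL) {
  if (is.null(space)) {
    space <- generate_semantic_space(n_cues = 3, n_meanings = 4,
                                     words_per_meaning = 12, dim = 16,
                                     within_sd = 0.25, seed = 42)
  }
  if (is.null(cues)) cues <- space$cues
  logs <- list()
  for (i in seq_len(n_participants)) {
    for (ci in seq_along(cues)) {
      logs[[length(logs) + 1]] <- generate_fluency_session(
        space, policy, cues[ci], seed = seed_base + 37 * i + ci,
        participant = sprintf("p%03d", i))
    }
  }
  score_responses(do.call(rbind, logs), embeddings = space)
}

# exhaustive 2^n sign-enumeration oracle for the paired signed-rank test
wilcoxon_enumeration_oracle <- function(d, alternative = "two.sided") {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge,
              less = p_le)
  list(statistic = w_obs, p = p, n = n)
}

# brute-force per-edge correlation selection oracle
select_edges_oracle <- function(cohort, behavior, alpha = 0.01) {
  pos <- neg <- list()
  p_nodes <- cohort$n_nodes
  for (i in seq_len(p_nodes - 1)) {
    for (j in seq.int(i + 1, p_nodes)) {
      vals <- vapply(cohort$matrices, function(m) m[i, j], numeric(1))
      if (stats::sd(vals) == 0) next
      ct <- stats::cor.test(vals, behavior)
      if (ct$p.value < alpha) {
        rec <- c(i, j)
        if (ct$estimate > 0) pos[[length(pos) + 1]] <- rec
        else neg[[length(neg) + 1]] <- rec
      }
    }
  }
  list(positive = do.call(rbind, pos), negative = do.call(rbind, neg))
}

mask_key <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0) return(character(0))
  if (is.matrix(mask)) sort(paste(mask[, 1], mask[, 2])) else
    sort(paste(mask$node_i, mask$node_j))
}

planted_mask <- function(edges) {
  tibble::tibble(node_i = edges[, 1], node_j = edges[, 2])
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
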