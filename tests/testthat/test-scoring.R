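test_that("spoken IRT is onset minus previous offset, undefined for the first
           response", {
  log <- tiny_log(onsets = c(1, 12.5, 20), offsets = c(10, 13, 20.5))
  sc <- compute_irt(log, mode = "spoken")
  expect_true(is.na(sc$irt[1]))
  expect_equal(sc$irt[2], 2.5)
  expect_equal(sc$irt[3], 7)
  bad <- tiny_log(onsets = c(1, 5, 20), offsets = c(10, 13, 20.5))
  expect_error(compute_irt(bad, mode = "spoken"), "negative IRT")
})

test_that("typed IRT adds thinking time from the fastest typing speed", {
  # r1 fixes the participant's fastest speed at 4 chars/s (20 chars in 5 s);
  # r2: raw 6 s, 12 chars typed in 5 s, theoretical 3 s -> thinking 2 -> 8 s
  log <- tibble::tibble(participant = "p01", cue = "c1",
                        response_index = 1:2, word = c("aaaa", "bbbb"),
                        meaning = c("A", "A"),
                        first_keypress = c(1, 12), validation = c(6, 17),
                        n_chars = c(20L, 12L))
  sc <- compute_irt(log, mode = "typed")
  expect_equal(sc$irt[1], 1) # raw 1 s, typing exactly at the fastest speed
  expect_equal(sc$irt[2], 8)
  expect_error(compute_irt(tiny_log(), mode = "typed"), "typed mode")
})

test_that("transitions label clustering and switching per the meaning
           sequence", {
  expect_equal(label_transitions(tiny_log(c("A", "A", "B")))$transition,
               c("initial", "clustering", "switching"))
  expect_equal(label_transitions(tiny_log(c("A", "B", "A")))$transition,
               c("initial", "switching", "switching"))
  expect_equal(sum(label_transitions(
    tiny_log(c("A", "A", "A")))$transition == "switching"), 0)
  nolab <- tiny_log(); nolab$meaning[2] <- NA
  expect_error(label_transitions(nolab), "meaning")
})

test_that("IRS is the cosine of consecutive embeddings", {
  emb <- rbind(w1 = c(1, 0), w2 = c(1, 0), w3 = c(0, 1), w4 = c(1, 1))
  log <- tiny_log(meanings = c("A", "A", "B", "B"),
                  onsets = c(1, 5, 9, 13), words = c("w1", "w2", "w3", "w4"))
  sc <- compute_irs(log, emb)
  expect_true(is.na(sc$irs[1]))
  expect_equal(sc$irs[2], 1)
  expect_equal(sc$irs[3], 0)
  expect_equal(sc$irs[4], 0.70711, tolerance = 1e-5)
  embz <- rbind(w1 = c(0, 0), w2 = c(1, 0))
  expect_error(compute_irs(tiny_log()[1:2, ], embz), "zero-norm")
})

test_that("missing embedding vectors leave IRS undefined with a report", {
  emb <- rbind(w1 = c(1, 0), w2 = c(0, 1))
  log <- tiny_log(meanings = c("A", "A", "B"))
  expect_message(sc <- compute_irs(log, emb), "1 response")
  expect_true(is.na(sc$irs[3]))
  expect_equal(sc$irs[2], 0)
})

test_that("marginal values are per-cue means, grand value a mean of cue
           means", {
  log <- rbind(
    tiny_log(meanings = c("A", "A", "A", "B"), onsets = c(1, 3.5, 8, 14.5),
             offsets = c(1.5, 4, 8.5, 15), cue = "c1"),
    tiny_log(meanings = c("A", "B"), onsets = c(1, 6.5),
             offsets = c(1.5, 7), cue = "c2"))
  sc <- compute_irt(log, mode = "spoken")
  m <- marginal_values(sc)
  expect_equal(m$per_cue$marginal_irt, c(4, 5)) # mean(2,4,6); single 5
  expect_equal(m$grand$long_term_irt, 4.5)
  one <- compute_irt(tiny_log(meanings = c("A", "A"), onsets = c(1, 4),
                              offsets = c(1.5, 4.5)),
                     mode = "spoken")
  expect_equal(marginal_values(one)$per_cue$marginal_irt, 2.5)
})

test_that("IRTr averages to exactly 1 per cue and classifies at the
           boundary", {
  sc <- scored_frame(irts = c(2, 4, 6), meanings = c("A", "A", "B"))
  expect_equal(sc$irtr, c(0.5, 1, 1.5))
  expect_equal(mean(sc$irtr), 1, tolerance = 1e-12)
  expect_equal(sc$speed, c("fast", "slow", "slow")) # irtr == 1 is slow
})

test_that("position labels follow the switch-adjacency rules", {
  p1 <- align_positions(scored_frame(irts = c(1, 1, 1, 2, 1, 1),
                                     meanings = c("A", "A", "A", "B",
                                                  "B", "B")))
  expect_equal(p1$position[order(p1$response_index)],
               c("-2", "-1", "S", "+1", "+2"))
  p2 <- align_positions(scored_frame(irts = c(1, 1, 2, 2),
                                     meanings = c("A", "A", "B", "C")))
  first_s <- p2[p2$switch_index == 3, ]
  expect_setequal(first_s$position, c("S", "-1"))  # +1 blocked by next switch
  p3 <- align_positions(scored_frame(irts = c(1, 2),
                                     meanings = c("A", "B")))
  expect_equal(p3$position, "S")
  # a clustering response between two switches one apart serves both roles
  p4 <- align_positions(scored_frame(irts = c(1, 2, 1, 2),
                                     meanings = c("A", "B", "B", "C")))
  both <- p4[p4$response_index == 3, ]
  expect_setequal(both$position, c("+1", "-1"))
})

test_that("participant summary matches the hand-traced toy example", {
  sc <- scored_frame(irts = c(2, 4, 6), meanings = c("A", "A", "B"))
  su <- summarize_participants(sc)
  expect_equal(su$switching_irt, 6)
  expect_equal(su$clustering_irt, 4)
  expect_equal(su$pre_switch_irt, 4)
  expect_equal(su$long_term_irt, 4)
  expect_equal(su$pre_switch_gap, 0)
  expect_equal(su$n_slow_clustering + su$n_slow_switching +
                 su$n_fast_clustering + su$n_fast_switching, su$n_labeled)
})

test_that("fluency counts case-folded unique words per cue", {
  log <- tiny_log(meanings = c("A", "A", "B"), words = c("Chat", "chien",
                                                         "chat"))
  sc <- score_responses(log)
  su <- summarize_participants(sc)
  expect_equal(su$polyft_fluency, 2)
})

test_that("participants without switches are flagged with undefined
           pre-switch fields", {
  sc <- scored_frame(irts = c(2, 4, 6), meanings = c("A", "A", "A"))
  expect_warning(su <- summarize_participants(sc), "without any switch")
  expect_true(su$no_switch_flag)
  expect_true(is.na(su$pre_switch_irt))
})

test_that("four-type counts partition labeled responses on generated
           cohorts", {
  sc <- scored_sessions(8, foraging_policy(), seed_base = 900)
  su <- suppressWarnings(summarize_participants(sc))
  expect_equal(su$n_fast_clustering + su$n_fast_switching +
                 su$n_slow_clustering + su$n_slow_switching, su$n_labeled)
  key <- paste(sc$participant, sc$cue)
  mean_irtr <- tapply(sc$irtr, key, mean, na.rm = TRUE)
  expect_true(all(abs(mean_irtr - 1) < 1e-9))
})

test_that("scoring is invariant to input row order", {
  pol <- foraging_policy()
  sc1 <- scored_sessions(3, pol, seed_base = 77)
  space <- generate_semantic_space(n_cues = 3, n_meanings = 4,
                                   words_per_meaning = 12, dim = 16,
                                   within_sd = 0.25, seed = 42)
  logs <- list()
  for (i in 1:3) {
    for (ci in seq_along(space$cues)) {
      logs[[length(logs) + 1]] <- generate_fluency_session(
        space, pol, space$cues[ci], seed = 77 + 37 * i + ci,
        participant = sprintf("p%03d", i))
    }
  }
  log <- do.call(rbind, logs)
  set.seed(1)
  shuffled <- log[sample(nrow(log)), ]
  sc2 <- score_responses(shuffled, embeddings = space)
  expect_equal(as.data.frame(sc1), as.data.frame(sc2))
})
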