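# Per-response foraging measures: inter-response times and similarities,
# clustering/switching transitions, marginal-value ratios, fast/slow classes,
# and switch-relative retrieval positions.

sort_log <- function(log) {
  log[order(log$participant, log$cue, log$response_index), , drop = FALSE]
}

split_keys <- function(log) paste(log$participant, log$cue, sep = "\r")

#' Compute inter-response times
#'
#' Spoken mode: the IRT of response k is the difference between the end
#' (offset) of response k-1 and the beginning (onset) of response k; the first
#' response of a cue has no IRT. Typed mode: the raw IRT is the delay between
#' the validation of the previous response (trial start, time 0, for the first
#' response) and the first keypress of the current one, plus a thinking-time
#' correction: measured typing duration (validation - first_keypress) minus
#' the theoretical duration (n_chars divided by the participant's fastest
#' typing speed over responses longer than four characters), floored at zero.
#'
#' @param log a response-log tibble (see [read_response_log()] for columns).
#' @param mode `"spoken"` or `"typed"`.
#' @return the log with an `irt` column (seconds; `NA` where undefined).
#' @export
compute_irt <- function(log, mode = c("spoken", "typed")) {
  mode <- match.arg(mode)
  log <- sort_log(log)
  key <- split_keys(log)
  first <- !duplicated(key)
  if (mode == "spoken") {
    prev_offset <- c(NA_real_, log$offset[-nrow(log)])
    irt <- log$onset - prev_offset
    irt[first] <- NA_real_
    bad <- which(!is.na(irt) & irt < 0)
    if (length(bad)) {
      stop("negative IRT for participant ", log$participant[bad[1]],
           ", cue ", log$cue[bad[1]], ", response ",
           log$response_index[bad[1]], call. = FALSE)
    }
  } else {
    needed <- c("first_keypress", "validation", "n_chars")
    missing_cols <- setdiff(needed, names(log))
    if (length(missing_cols)) {
      stop("typed mode requires columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    prev_validation <- c(NA_real_, log$validation[-nrow(log)])
    prev_validation[first] <- 0 # trial start
    raw <- log$first_keypress - prev_validation
    bad <- which(!is.na(raw) & raw < 0)
    if (length(bad)) {
      stop("negative raw IRT for participant ", log$participant[bad[1]],
           ", cue ", log$cue[bad[1]], ", response ",
           log$response_index[bad[1]], call. = FALSE)
    }
    measured <- log$validation - log$first_keypress
    speed <- ifelse(log$n_chars > 4, log$n_chars / measured, NA_real_)
    fastest <- tapply(speed, log$participant, max, na.rm = TRUE)
    fastest[!is.finite(fastest)] <- NA_real_
    fs <- as.numeric(fastest[log$participant])
    thinking <- pmax(0, measured - log$n_chars / fs)
    thinking[is.na(thinking)] <- 0 # no typing-speed estimate: no correction
    irt <- raw + thinking
  }
  log$irt <- irt
  log
}

#' Label clustering and switching transitions
#'
#' Per cue, the first response is `initial`; every later response is
#' `clustering` when it refers to the same meaning as the previous response
#' and `switching` otherwise.
#'
#' @param log response-log tibble with a `meaning` column.
#' @return the log with a `transition` column.
#' @export
label_transitions <- function(log) {
  if (!"meaning" %in% names(log) || anyNA(log$meaning)) {
    stop("every response needs a meaning label", call. = FALSE)
  }
  log <- sort_log(log)
  key <- split_keys(log)
  first <- !duplicated(key)
  prev_meaning <- c(NA_character_, log$meaning[-nrow(log)])
  log$transition <- ifelse(first, "initial",
                           ifelse(log$meaning == prev_meaning,
                                  "clustering", "switching"))
  log
}

#' Compute inter-response semantic similarities
#'
#' The IRS of response k is the cosine similarity between the embedding
#' vectors of responses k-1 and k; undefined for the first response of a cue
#' and whenever either word lacks a vector (the number of misses is reported
#' as a message).
#'
#' @param log response-log tibble.
#' @param embeddings a `semantic_space` or a numeric matrix with word rownames.
#' @return the log with an `irs` column (cosine in \[-1, 1\]; `NA` where
#'   undefined).
#' @export
compute_irs <- function(log, embeddings) {
  emb <- embedding_matrix(embeddings)
  norms <- sqrt(rowSums(emb^2))
  zero <- norms == 0
  if (any(zero)) {
    stop("zero-norm embedding vector for word: ",
         rownames(emb)[which(zero)[1]], call. = FALSE)
  }
  unit <- emb / norms
  log <- sort_log(log)
  key <- split_keys(log)
  first <- !duplicated(key)
  prev_word <- c(NA_character_, log$word[-nrow(log)])
  prev_word[first] <- NA_character_
  have <- log$word %in% rownames(unit)
  have_prev <- !is.na(prev_word) & prev_word %in% rownames(unit)
  ok <- have & have_prev
  irs <- rep(NA_real_, nrow(log))
  if (any(ok)) {
    irs[ok] <- rowSums(unit[log$word[ok], , drop = FALSE] *
                       unit[prev_word[ok], , drop = FALSE])
  }
  n_missing <- sum(!have)
  if (n_missing > 0) {
    message(n_missing, " response(s) without an embedding vector; ",
            "their IRS is undefined")
  }
  log$irs <- irs
  log
}

#' Per-cue marginal values and grand long-term IRT/IRS
#'
#' The per-cue marginal value is the arithmetic mean of that cue's defined
#' IRTs (respectively IRSs) for the participant; the grand long-term value is
#' the mean of the per-cue means (response level first, then across cues).
#' Cues with no defined IRT are dropped with a warning.
#'
#' @param scored tibble with `irt` (and optionally `irs`) columns.
#' @return a list with `per_cue` (participant, cue, marginal_irt, marginal_irs,
#'   n_irt) and `grand` (participant, long_term_irt, long_term_irs) tibbles.
#' @export
marginal_values <- function(scored) {
  scored <- sort_log(scored)
  if (!"irs" %in% names(scored)) scored$irs <- NA_real_
  key <- split_keys(scored)
  grp <- !duplicated(key)
  per_cue <- tibble::tibble(
    participant = scored$participant[grp],
    cue = scored$cue[grp],
    marginal_irt = as.numeric(tapply(scored$irt, key, mean, na.rm = TRUE)[key[grp]]),
    marginal_irs = as.numeric(tapply(scored$irs, key, mean, na.rm = TRUE)[key[grp]]),
    n_irt = as.integer(tapply(!is.na(scored$irt), key, sum)[key[grp]])
  )
  per_cue$marginal_irt[is.nan(per_cue$marginal_irt)] <- NA_real_
  per_cue$marginal_irs[is.nan(per_cue$marginal_irs)] <- NA_real_
  dropped <- per_cue$n_irt == 0
  if (any(dropped)) {
    warning(sum(dropped), " cue(s) with no defined IRT dropped from marginal ",
            "values", call. = FALSE)
    per_cue <- per_cue[!dropped, , drop = FALSE]
  }
  grand <- tibble::tibble(
    participant = unique(per_cue$participant),
    long_term_irt = as.numeric(tapply(per_cue$marginal_irt,
                                      per_cue$participant, mean,
                                      na.rm = TRUE)[unique(per_cue$participant)]),
    long_term_irs = as.numeric(tapply(per_cue$marginal_irs,
                                      per_cue$participant, mean,
                                      na.rm = TRUE)[unique(per_cue$participant)])
  )
  grand$long_term_irs[is.nan(grand$long_term_irs)] <- NA_real_
  list(per_cue = per_cue, grand = grand)
}

#' Compute marginal-value ratios IRTr and IRSr
#'
#' IRTr is each response's IRT divided by the participant's marginal (mean)
#' IRT for that cue, so the per-cue mean of IRTr is exactly 1; IRSr likewise
#' for similarity. IRSr is left undefined when the cue's marginal IRS is
#' within `epsilon` of zero.
#'
#' @param scored tibble with `irt`/`irs` columns.
#' @param marginals result of [marginal_values()]; recomputed when `NULL`.
#' @param epsilon guard for near-zero marginal IRS (default `1e-6`).
#' @return the tibble with `irtr` and `irsr` columns.
#' @export
compute_ratios <- function(scored, marginals = NULL, epsilon = 1e-6) {
  if (is.null(marginals)) marginals <- marginal_values(scored)
  scored <- sort_log(scored)
  per_cue <- marginals$per_cue
  bad <- which(!is.na(per_cue$marginal_irt) & per_cue$marginal_irt <= 0)
  if (length(bad)) {
    stop("non-positive marginal IRT for participant ",
         per_cue$participant[bad[1]], ", cue ", per_cue$cue[bad[1]],
         call. = FALSE)
  }
  key <- split_keys(scored)
  mkey <- paste(per_cue$participant, per_cue$cue, sep = "\r")
  m_irt <- per_cue$marginal_irt[match(key, mkey)]
  m_irs <- per_cue$marginal_irs[match(key, mkey)]
  scored$irtr <- scored$irt / m_irt
  if (!"irs" %in% names(scored)) scored$irs <- NA_real_
  irsr <- scored$irs / m_irs
  irsr[is.na(m_irs) | abs(m_irs) < epsilon] <- NA_real_
  scored$irsr <- irsr
  scored
}

#' Classify responses as fast or slow
#'
#' A response is `fast` when its IRTr is strictly below 1 (its IRT beat the
#' marginal value) and `slow` when IRTr is at or above 1. Crossed with the
#' transition label this yields the four response types (Fast-Clustering,
#' Fast-Switching, Slow-Clustering, Slow-Switching).
#'
#' @param scored tibble with an `irtr` column.
#' @return the tibble with a `speed` column (`NA` where IRTr is undefined).
#' @export
classify_speed <- function(scored) {
  scored$speed <- ifelse(is.na(scored$irtr), NA_character_,
                         ifelse(scored$irtr < 1, "fast", "slow"))
  scored
}

#' Switch-relative retrieval positions
#'
#' For each switching response S, the up-to-two clustering responses
#' immediately before it in the same cue receive positions -2 and -1, and the
#' up-to-two clustering responses immediately after it (before any further
#' switch) receive +1 and +2. A clustering response lying between two switches
#' one step apart serves as +1 for the earlier switch and -1 for the later
#' one; both assignments are retained in the long table.
#'
#' @param scored tibble with `transition` (and ideally `speed`) columns.
#' @return a long tibble with one row per (switch, position) assignment:
#'   participant, cue, response_index (of the assigned response), position
#'   (one of `"-2"`, `"-1"`, `"S"`, `"+1"`, `"+2"`), switch_index
#'   (response_index of the governing switch) and switch_speed (fast/slow
#'   class of that switch, `NA` if unclassified).
#' @export
align_positions <- function(scored) {
  stopifnot("transition" %in% names(scored))
  scored <- sort_log(scored)
  if (!"speed" %in% names(scored)) scored$speed <- NA_character_
  key <- split_keys(scored)
  groups <- unique(key)
  acc <- vector("list", length(groups))
  gi <- 0L
  for (k in groups) {
    gi <- gi + 1L
    rows <- which(key == k)
    trans <- scored$transition[rows]
    ridx <- scored$response_index[rows]
    speed <- scored$speed[rows]
    sw <- which(trans == "switching")
    if (!length(sw)) next
    pos <- character(5 * length(sw)); at <- integer(5 * length(sw))
    sidx <- integer(5 * length(sw)); m <- 0L
    for (j in sw) {
      put <- function(p, i) {
        m <<- m + 1L; pos[m] <<- p; at[m] <<- i; sidx[m] <<- j
      }
      put("S", j)
      if (j - 1 >= 1 && trans[j - 1] == "clustering") {
        put("-1", j - 1)
        if (j - 2 >= 1 && trans[j - 2] == "clustering") put("-2", j - 2)
      }
      if (j + 1 <= length(trans) && trans[j + 1] == "clustering") {
        put("+1", j + 1)
        if (j + 2 <= length(trans) && trans[j + 2] == "clustering") {
          put("+2", j + 2)
        }
      }
    }
    sel <- seq_len(m)
    acc[[gi]] <- list(participant = rep(scored$participant[rows[1]], m),
                      cue = rep(scored$cue[rows[1]], m),
                      response_index = ridx[at[sel]], position = pos[sel],
                      switch_index = ridx[sidx[sel]],
                      switch_speed = speed[sidx[sel]])
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  pull <- function(f, mode) {
    v <- unlist(lapply(acc, `[[`, f), use.names = FALSE)
    if (is.null(v)) vector(mode, 0) else v
  }
  tibble::new_tibble(list(
    participant = pull("participant", "character"),
    cue = pull("cue", "character"),
    response_index = pull("response_index", "integer"),
    position = pull("position", "character"),
    switch_index = pull("switch_index", "integer"),
    switch_speed = pull("switch_speed", "character")),
    nrow = length(pull("position", "character")))
}

#' Attach scalar position labels to a scored sequence
#'
#' Collapses the long position table of [align_positions()] to one label per
#' response (needed because a response may serve two switches): switching
#' responses are `"S"`; clustering responses take the role relative to their
#' nearest governing switch, preferring the pre-switch role on ties.
#' @noRd
scalar_positions <- function(scored, positions = NULL) {
  if (is.null(positions)) positions <- align_positions(scored)
  scored <- sort_log(scored)
  scored$position <- "none"
  scored$switch_speed_context <- NA_character_
  if (!nrow(positions)) return(scored)
  pr <- c("S" = 1, "-1" = 2, "+1" = 3, "-2" = 4, "+2" = 5)
  positions <- positions[order(pr[positions$position]), ]
  first <- !duplicated(positions[c("participant", "cue", "response_index")])
  positions <- positions[first, , drop = FALSE]
  key <- paste(scored$participant, scored$cue, scored$response_index,
               sep = "\r")
  pkey <- paste(positions$participant, positions$cue,
                positions$response_index, sep = "\r")
  hit <- match(key, pkey)
  scored$position[!is.na(hit)] <- positions$position[hit[!is.na(hit)]]
  scored$switch_speed_context[!is.na(hit)] <-
    positions$switch_speed[hit[!is.na(hit)]]
  scored
}

#' Score a response log end to end
#'
#' Runs the full per-response pipeline: IRT computation, transition labeling,
#' optional IRS computation, marginal values, IRTr/IRSr ratios, fast/slow
#' classification and switch-relative positions.
#'
#' @param log response-log tibble (validated and sorted).
#' @param embeddings optional `semantic_space` or embedding matrix for IRS.
#' @param mode `"spoken"` or `"typed"` timing convention.
#' @return a scored tibble; the per-cue/grand marginal values are attached as
#'   attribute `"marginals"`.
#' @export
score_responses <- function(log, embeddings = NULL,
                            mode = c("spoken", "typed")) {
  mode <- match.arg(mode)
  scored <- compute_irt(log, mode = mode)
  scored <- label_transitions(scored)
  if (!is.null(embeddings)) scored <- compute_irs(scored, embeddings)
  marg <- marginal_values(scored)
  scored <- compute_ratios(scored, marg)
  scored <- classify_speed(scored)
  scored <- scalar_positions(scored)
  attr(scored, "marginals") <- marg
  scored
}

cue_then_participant_mean <- function(value, participant, cue) {
  # response level -> cue -> participant averaging order
  ok <- !is.na(value)
  if (!any(ok)) return(NA_real_)
  cue_means <- tapply(value[ok], paste(participant[ok], cue[ok], sep = "\r"),
                      mean)
  pid <- sub("\r.*$", "", names(cue_means))
  out <- tapply(cue_means, pid, mean)
  out
}

#' Summarize a participant's foraging behavior
#'
#' Per-participant aggregates: fluency (mean count of case-folded unique words
#' per cue), long-term IRT/IRS (cue means averaged across cues), mean
#' IRT/IRS/IRTr/IRSr by transition type (response level, then cue, then
#' participant), the four response-type counts and percentages (over labeled
#' responses with a defined IRT), the pre-switch IRT (mean IRT at position -1)
#' and the pre-switch gap (absolute distance between pre-switch IRT and
#' long-term IRT). Participants who never switch have undefined pre-switch
#' fields and are flagged.
#'
#' @param scored a scored tibble from [score_responses()].
#' @return a tibble with one row per participant.
#' @export
summarize_participants <- function(scored) {
  needed <- c("participant", "cue", "response_index", "word", "irt",
              "transition", "irtr", "speed")
  stopifnot(all(needed %in% names(scored)))
  scored <- sort_log(scored)
  if (!"irs" %in% names(scored)) scored$irs <- NA_real_
  if (!"irsr" %in% names(scored)) scored$irsr <- NA_real_
  participants <- unique(scored$participant)
  marg <- marginal_values(scored)
  grand <- marg$grand

  # fluency: unique case-folded words per cue, averaged across cues
  ckey <- split_keys(scored)
  uniq <- tapply(tolower(scored$word), ckey, function(w) length(unique(w)))
  cue_pid <- sub("\r.*$", "", names(uniq))
  fluency <- tapply(as.numeric(uniq), cue_pid, mean)

  pick <- function(stat, pid) as.numeric(stat[pid])

  by_type <- function(trans_lab, col) {
    sel <- scored$transition == trans_lab & !is.na(scored[[col]])
    cue_then_participant_mean(ifelse(sel, scored[[col]], NA_real_),
                              scored$participant, scored$cue)
  }

  labeled <- scored$transition %in% c("clustering", "switching") &
    !is.na(scored$irt) & !is.na(scored$speed)
  type <- ifelse(labeled,
                 paste(scored$speed, scored$transition, sep = "_"),
                 NA_character_)
  count_type <- function(tt) {
    n <- tapply(!is.na(type) & type == tt, scored$participant, sum)
    n
  }
  n_fc <- count_type("fast_clustering"); n_fs <- count_type("fast_switching")
  n_sc <- count_type("slow_clustering"); n_ss <- count_type("slow_switching")
  n_lab <- tapply(labeled, scored$participant, sum)

  positions <- align_positions(scored)
  pre <- positions[positions$position == "-1", , drop = FALSE]
  pre_irt_val <- rep(NA_real_, nrow(pre))
  if (nrow(pre)) {
    skey <- paste(scored$participant, scored$cue, scored$response_index,
                  sep = "\r")
    pkey <- paste(pre$participant, pre$cue, pre$response_index, sep = "\r")
    pre_irt_val <- scored$irt[match(pkey, skey)]
  }
  pre_switch_irt <- if (nrow(pre)) {
    cue_then_participant_mean(pre_irt_val, pre$participant, pre$cue)
  } else numeric(0)

  n_switch <- tapply(scored$transition == "switching", scored$participant, sum)

  out <- tibble::tibble(
    participant = participants,
    polyft_fluency = pick(fluency, participants),
    long_term_irt = grand$long_term_irt[match(participants,
                                              grand$participant)],
    long_term_irs = grand$long_term_irs[match(participants,
                                              grand$participant)],
    clustering_irt = pick(by_type("clustering", "irt"), participants),
    switching_irt = pick(by_type("switching", "irt"), participants),
    clustering_irs = pick(by_type("clustering", "irs"), participants),
    switching_irs = pick(by_type("switching", "irs"), participants),
    clustering_irtr = pick(by_type("clustering", "irtr"), participants),
    switching_irtr = pick(by_type("switching", "irtr"), participants),
    clustering_irsr = pick(by_type("clustering", "irsr"), participants),
    switching_irsr = pick(by_type("switching", "irsr"), participants),
    n_fast_clustering = as.integer(pick(n_fc, participants)),
    n_fast_switching = as.integer(pick(n_fs, participants)),
    n_slow_clustering = as.integer(pick(n_sc, participants)),
    n_slow_switching = as.integer(pick(n_ss, participants)),
    n_labeled = as.integer(pick(n_lab, participants)),
    n_switches = as.integer(pick(n_switch, participants)),
    pre_switch_irt = if (length(pre_switch_irt)) {
      as.numeric(pre_switch_irt[participants])
    } else NA_real_
  )
  out$pct_fast_clustering <- 100 * out$n_fast_clustering / out$n_labeled
  out$pct_fast_switching <- 100 * out$n_fast_switching / out$n_labeled
  out$pct_slow_clustering <- 100 * out$n_slow_clustering / out$n_labeled
  out$pct_slow_switching <- 100 * out$n_slow_switching / out$n_labeled
  out$pre_switch_gap <- abs(out$pre_switch_irt - out$long_term_irt)
  out$no_switch_flag <- out$n_switches == 0
  if (any(out$no_switch_flag)) {
    warning(sum(out$no_switch_flag), " participant(s) without any switch; ",
            "pre-switch fields undefined", call. = FALSE)
  }
  out
}
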