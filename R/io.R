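# Readers and writers for the pipeline's plain-text formats: TSV tables,
# word2vec-style embeddings, whitespace-delimited square matrices, JSON
# results, YAML configuration.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read and validate a response log
#'
#' Expects a TSV with columns `participant`, `cue`, `response_index`, `word`,
#' `meaning` plus the timing columns of the declared mode (`onset`/`offset`
#' for spoken; `first_keypress`, `validation`, `n_chars` for typed; a typed
#' log may carry both sets). Validates per (participant, cue): strictly
#' increasing `response_index`, non-decreasing timing, `offset >= onset`, no
#' duplicate response index. Rows are returned sorted.
#'
#' @param path TSV file path.
#' @param mode `"spoken"` or `"typed"`.
#' @return a validated, sorted response-log tibble.
#' @export
read_response_log <- function(path, mode = c("spoken", "typed")) {
  mode <- match.arg(mode)
  timing <- if (mode == "spoken") c("onset", "offset") else
    c("first_keypress", "validation", "n_chars")
  log <- read_tsv_checked(path, c("participant", "cue", "response_index",
                                  "word", "meaning", timing),
                          "response log")
  log <- validate_response_log(log, mode)
  log
}

#' Validate a response log already in memory
#' @noRd
validate_response_log <- function(log, mode = "spoken") {
  log <- sort_log(log)
  key <- split_keys(log)
  dup <- duplicated(paste(key, log$response_index))
  if (any(dup)) {
    stop("duplicate (participant, cue, response_index) at row ",
         which(dup)[1], call. = FALSE)
  }
  first <- !duplicated(key)
  if (mode == "spoken") {
    if (any(log$offset < log$onset)) {
      bad <- which(log$offset < log$onset)[1]
      stop("offset before onset at row ", bad, " (participant ",
           log$participant[bad], ", cue ", log$cue[bad], ")", call. = FALSE)
    }
    prev_onset <- c(NA_real_, log$onset[-nrow(log)])
    non_mono <- !first & log$onset < prev_onset
    if (any(non_mono, na.rm = TRUE)) {
      bad <- which(non_mono)[1]
      stop("decreasing onset at row ", bad, " (participant ",
           log$participant[bad], ", cue ", log$cue[bad], ", response ",
           log$response_index[bad], ")", call. = FALSE)
    }
  } else {
    prev_val <- c(NA_real_, log$validation[-nrow(log)])
    non_mono <- !first & log$first_keypress < prev_val
    if (any(non_mono, na.rm = TRUE)) {
      bad <- which(non_mono)[1]
      stop("first keypress before previous validation at row ", bad,
           call. = FALSE)
    }
  }
  log
}

#' Write a table as TSV
#' @param x data.frame/tibble.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read word embeddings in word2vec text format
#'
#' Header line `"n_words dim"`, then one row per word: token followed by
#' `dim` whitespace-separated floats. Duplicate tokens keep the first
#' occurrence with a warning; a row with the wrong number of fields is an
#' error naming the line.
#'
#' @param path embeddings file.
#' @return numeric matrix, one unit row per token (rownames are tokens).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty embeddings file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2 || anyNA(suppressWarnings(as.integer(header)))) {
    stop("embeddings header must be 'n_words dim' (line 1)", call. = FALSE)
  }
  n_words <- as.integer(header[1]); dim <- as.integer(header[2])
  body <- lines[-1]
  if (length(body) != n_words) {
    stop("embeddings header declares ", n_words, " words but file has ",
         length(body), call. = FALSE)
  }
  toks <- strsplit(trimws(body), "\\s+")
  lens <- lengths(toks)
  bad <- which(lens != dim + 1)
  if (length(bad)) {
    stop("embeddings line ", bad[1] + 1, " has ", lens[bad[1]] - 1,
         " values, expected ", dim, call. = FALSE)
  }
  words <- vapply(toks, `[`, "", 1)
  vecs <- matrix(as.numeric(unlist(lapply(toks, `[`, -1))),
                 ncol = dim, byrow = TRUE)
  if (anyNA(vecs)) stop("non-numeric embedding value in ", path,
                        call. = FALSE)
  dupes <- duplicated(words)
  if (any(dupes)) {
    warning(sum(dupes), " duplicate token(s); first occurrence kept",
            call. = FALSE)
    vecs <- vecs[!dupes, , drop = FALSE]
    words <- words[!dupes]
  }
  rownames(vecs) <- words
  vecs
}

#' Write word embeddings in word2vec text format
#' @param embeddings numeric matrix with token rownames, or a
#'   `semantic_space`.
#' @param path output path.
#' @export
write_embeddings <- function(embeddings, path) {
  emb <- embedding_matrix(embeddings)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1, function(v)
                     paste(formatC(v, format = "g", digits = 8),
                           collapse = " "))), con)
  invisible(path)
}

#' Read per-subject connectivity matrices from a manifest
#'
#' The manifest TSV lists `subject_id`, `path` (whitespace-delimited square
#' matrix file, relative paths resolved against the manifest's directory) and
#' `motion`.
#'
#' @param manifest_path manifest TSV.
#' @param labels_path optional node-label TSV (`node_id`, `network`).
#' @return a `connectivity_cohort`.
#' @export
read_connectivity <- function(manifest_path, labels_path = NULL) {
  man <- read_tsv_checked(manifest_path, c("subject_id", "path", "motion"),
                          "manifest")
  base <- dirname(manifest_path)
  mats <- lapply(man$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(fp)) stop("matrix file not found: ", p, call. = FALSE)
    as.matrix(utils::read.table(fp))
  })
  mats <- lapply(mats, function(m) {
    dimnames(m) <- NULL
    m
  })
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read_tsv_checked(labels_path, c("node_id", "network"),
                               "node labels")
  }
  connectivity_cohort(mats, man$motion, subjects = man$subject_id,
                      node_labels = labels)
}

#' Write a connectivity cohort to a directory
#'
#' One whitespace-delimited square matrix file per subject, a manifest TSV
#' and a node-label TSV.
#' @param cohort a `connectivity_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_connectivity <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s_matrix.txt", cohort$subjects)
  for (i in seq_along(cohort$subjects)) {
    utils::write.table(format(cohort$matrices[[i]], digits = 8),
                       file.path(dir, paths[i]),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_tsv(tibble::tibble(subject_id = cohort$subjects, path = paths,
                           motion = cohort$motion),
            file.path(dir, "manifest.tsv"))
  write_tsv(cohort$node_labels, file.path(dir, "nodes.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Write a synthetic cohort to a directory
#'
#' Emits the response-log TSV, embeddings (word2vec text), connectivity
#' matrices + manifest + node labels, covariate TSV, and a ground-truth JSON.
#' @param cohort a `semforage_cohort` from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "semforage_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$log, file.path(dir, "responses.tsv"))
  write_embeddings(cohort$space, file.path(dir, "embeddings.txt"))
  write_connectivity(cohort$connectivity, file.path(dir, "connectivity"))
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  gt <- cohort$ground_truth
  gt$policies <- as.list(gt$policies)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or the fields directly. Required fields:
#' `log`, `out_dir`; optional: `embeddings`, `manifest`, `node_labels`,
#' `covariates`, `mode` (spoken/typed), `alpha_edges` (0.01), `alpha` (0.05),
#' `n_perm` (1000), `n_boot` (5000), `seed` (1), `cpm_behaviors` (count
#' columns to predict), `mediations` (list of x/m/y column triples).
#'
#' @param path YAML config path, or `NULL` when fields are given in `...`.
#' @param ... fields overriding/replacing the file contents.
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(mode = "spoken", alpha_edges = 0.01, alpha = 0.05,
                   n_perm = 1000, n_boot = 5000, seed = 1,
                   cpm_behaviors = c("n_fast_switching", "n_slow_clustering"),
                   mediations = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in c("log", "out_dir")) {
    if (is.null(cfg[[nm]])) stop("pipeline config needs `", nm, "`",
                                 call. = FALSE)
  }
  if (!cfg$mode %in% c("spoken", "typed")) {
    stop("mode must be 'spoken' or 'typed'", call. = FALSE)
  }
  for (nm in c("alpha_edges", "alpha")) assert_prob(cfg[[nm]], nm)
  for (p in c("log", "embeddings", "manifest", "node_labels", "covariates")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("configured path does not exist: ", cfg[[p]], call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Sequences scoring -> MVT tests -> CPM (one run per configured
#' response-type count, when connectivity inputs are configured) -> mediation
#' (configured x/m/y triples on the merged per-participant table). Every
#' output table is written to `out_dir` as TSV/JSON, stamped with the seed.
#' A mediation whose mediator's CPM permutation p exceeds `alpha` still runs
#' but is flagged `cpm_not_significant`.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return invisibly, a list with `scored`, `summaries`, `mvt`, `cpm`,
#'   `mediation`, `merged`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- read_response_log(config$log, mode = config$mode)
  embeddings <- if (!is.null(config$embeddings)) {
    read_embeddings(config$embeddings)
  }
  message("[score] ", nrow(log), " responses from ",
          length(unique(log$participant)), " participants")
  scored <- score_responses(log, embeddings = embeddings, mode = config$mode)
  summaries <- suppressWarnings(summarize_participants(scored))
  # cue-level exclusion: cues where more than 25% of participants never switch
  pkey <- paste(scored$participant, scored$cue)
  sw_by_cue <- tapply(scored$transition == "switching", pkey, sum)
  cue_of <- sub("^\\S+ ", "", names(sw_by_cue))
  frac_no_switch <- tapply(sw_by_cue == 0, cue_of, mean)
  flagged_cues <- names(frac_no_switch)[frac_no_switch > 0.25]
  if (length(flagged_cues)) {
    message("[score] cue(s) where >25% of participants never switch: ",
            paste(flagged_cues, collapse = ", "))
  }
  write_tsv(scored, file.path(config$out_dir, "scored.tsv"))
  write_tsv(summaries, file.path(config$out_dir, "summaries.tsv"))

  mvt <- mvt_report(scored, summaries)
  write_tsv(mvt$position_tests,
            file.path(config$out_dir, "position_tests.tsv"))
  write_tsv(mvt$ramping, file.path(config$out_dir, "ramping_tests.tsv"))

  merged <- summaries
  if (!is.null(config$covariates)) {
    cov <- read_tsv_checked(config$covariates, "participant", "covariates")
    merged <- merge(merged, cov, by = "participant", sort = TRUE)
  }

  cpm_results <- list()
  if (!is.null(config$manifest)) {
    cohort <- read_connectivity(config$manifest, config$node_labels)
    idx <- match(cohort$subjects, merged$participant)
    for (beh in config$cpm_behaviors) {
      if (!beh %in% names(merged)) next
      y <- merged[[beh]][idx]
      message("[cpm] predicting ", beh, " (n_perm = ", config$n_perm, ")")
      res <- cpm_permutation_test(cohort, y, alpha = config$alpha_edges,
                                  n_perm = config$n_perm,
                                  seed = child_seed(config$seed, "cpm_perm"))
      cpm_results[[beh]] <- res
      merged[[paste0("strength_pos_", beh)]] <-
        strength(cohort, res$final_masks$positive)[
          match(merged$participant, cohort$subjects)]
      net <- if (nrow(res$final_masks$positive)) {
        summarize_network(res$final_masks$positive, cohort$node_labels)
      }
      base <- file.path(config$out_dir, paste0("cpm_", beh))
      jsonlite::write_json(
        list(behavior = beh, rho = res$rho, p_parametric = res$p_parametric,
             p_permutation = res$p_permutation, n = res$n,
             seed = config$seed),
        paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
      write_tsv(rbind(res$final_masks$positive, res$final_masks$negative),
                paste0(base, "_masks.tsv"))
      if (!is.null(net)) {
        write_tsv(net$degrees, paste0(base, "_degrees.tsv"))
        write_tsv(net$pairs, paste0(base, "_network_pairs.tsv"))
      }
    }
  }

  mediation_results <- list()
  for (tri in config$mediations) {
    nm <- paste(tri$x, tri$m, tri$y, sep = "->")
    if (!all(c(tri$x, tri$m, tri$y) %in% names(merged))) {
      message("[mediate] skipping ", nm, ": missing column")
      next
    }
    message("[mediate] ", nm)
    res <- tryCatch(
      mediate(merged, tri$x, tri$m, tri$y, n_boot = config$n_boot,
              seed = child_seed(config$seed, "mediation")),
      error = function(e) {
        message("[mediate] ", nm, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    res$cpm_not_significant <-
      !is.null(cpm_results[[tri$m]]) &&
      cpm_results[[tri$m]]$p_permutation > config$alpha
    mediation_results[[nm]] <- res
    jsonlite::write_json(
      list(x = tri$x, m = tri$m, y = tri$y, a = res$a, b = res$b, c = res$c,
           c_prime = res$c_prime, indirect = res$indirect,
           ci_low = res$ci_low, ci_high = res$ci_high,
           n_boot = res$n_boot, significant = res$significant,
           cpm_not_significant = isTRUE(res$cpm_not_significant),
           seed = config$seed),
      file.path(config$out_dir,
                paste0("mediation_", gsub("[^A-Za-z0-9_]+", "_", nm),
                       ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_tsv(merged, file.path(config$out_dir, "merged.tsv"))
  invisible(list(scored = scored, summaries = summaries, mvt = mvt,
                 cpm = cpm_results, mediation = mediation_results,
                 merged = merged))
}
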