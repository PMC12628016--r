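# Synthetic semantic space: cue words with several abstract meanings, each
# meaning a cloud of word vectors around a random unit centroid.

#' Generate a synthetic semantic space
#'
#' Builds an abstract polysemous-cue lexicon: each cue has `n_meanings`
#' meanings, each meaning `words_per_meaning` words, and each word a unit-norm
#' embedding vector. Meaning centroids are drawn independently and uniformly on
#' the unit sphere; member vectors are the centroid plus isotropic Gaussian
#' noise (`within_sd` per coordinate), renormalized. With `within_sd = 0` all
#' words of a meaning share the identical vector, so within-meaning cosine
#' similarity is exactly 1.
#'
#' @param n_cues number of cue words.
#' @param n_meanings meanings per cue.
#' @param words_per_meaning words per meaning.
#' @param dim embedding dimensionality (>= 2).
#' @param within_sd within-meaning noise SD per coordinate (>= 0). Values below
#'   about 0.5 keep mean within-meaning cosine above mean between-meaning
#'   cosine for typical dimensions.
#' @param seed integer seed; output is deterministic given the seed.
#' @return an object of class `semantic_space`: a list with `cues` (character),
#'   `lexicon` (tibble: word, cue, meaning), `embeddings` (matrix, one row per
#'   word, rows unit-norm), and `dim`.
#' @examples
#' sp <- generate_semantic_space(n_cues = 1, n_meanings = 2,
#'                               words_per_meaning = 3, dim = 8,
#'                               within_sd = 0, seed = 1)
#' nrow(sp$lexicon)
#' @export
generate_semantic_space <- function(n_cues = 3, n_meanings = 5,
                                    words_per_meaning = 20, dim = 50,
                                    within_sd = 0.3, seed = 1) {
  assert_count(n_cues, "n_cues")
  assert_count(n_meanings, "n_meanings")
  assert_count(words_per_meaning, "words_per_meaning")
  assert_count(dim, "dim", min = 2)
  if (!is.numeric(within_sd) || length(within_sd) != 1 || within_sd < 0) {
    stop("`within_sd` must be a single non-negative number", call. = FALSE)
  }
  with_seed(seed, {
    cues <- sprintf("cue%02d", seq_len(n_cues))
    rows <- vector("list", n_cues * n_meanings)
    vecs <- vector("list", n_cues * n_meanings)
    k <- 0L
    for (ci in seq_len(n_cues)) {
      for (mi in seq_len(n_meanings)) {
        k <- k + 1L
        centroid <- stats::rnorm(dim)
        centroid <- centroid / sqrt(sum(centroid^2))
        words <- sprintf("%s_m%02d_w%02d", cues[ci], mi,
                         seq_len(words_per_meaning))
        v <- matrix(rep(centroid, each = words_per_meaning),
                    nrow = words_per_meaning)
        if (within_sd > 0) {
          v <- v + matrix(stats::rnorm(words_per_meaning * dim, sd = within_sd),
                          nrow = words_per_meaning)
        }
        v <- v / sqrt(rowSums(v^2))
        rownames(v) <- words
        rows[[k]] <- tibble::tibble(word = words, cue = cues[ci],
                                    meaning = sprintf("m%02d", mi))
        vecs[[k]] <- v
      }
    }
    out <- list(cues = cues,
                lexicon = do.call(rbind, rows),
                embeddings = do.call(rbind, vecs),
                dim = as.integer(dim))
    class(out) <- "semantic_space"
    out
  })
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("<semantic_space>", length(x$cues), "cues,",
      nrow(x$lexicon), "words, dim", x$dim, "\n")
  invisible(x)
}

#' Look up embedding vectors for words
#'
#' Accepts a `semantic_space` or a plain numeric matrix with one row per word
#' (words as rownames, e.g. from [read_embeddings()]).
#' @noRd
embedding_matrix <- function(embeddings) {
  if (inherits(embeddings, "semantic_space")) return(embeddings$embeddings)
  if (is.matrix(embeddings) && is.numeric(embeddings) &&
      !is.null(rownames(embeddings))) {
    return(embeddings)
  }
  stop("`embeddings` must be a semantic_space or a numeric matrix with ",
       "word rownames", call. = FALSE)
}

#' Mean within- and between-meaning cosine similarity of a semantic space
#'
#' Exhaustive pairwise means over all distinct word pairs, used to check that
#' the generated space places same-meaning words closer than different-meaning
#' words.
#' @param space a `semantic_space`.
#' @return a list with `within` and `between` mean cosines.
#' @export
space_cosine_summary <- function(space) {
  stopifnot(inherits(space, "semantic_space"))
  emb <- space$embeddings
  gram <- tcrossprod(emb) # rows are unit norm, so entries are cosines
  key <- paste(space$lexicon$cue, space$lexicon$meaning)
  same <- outer(key, key, "==")
  ut <- upper.tri(gram)
  list(within = mean(gram[ut & same]), between = mean(gram[ut & !same]))
}
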