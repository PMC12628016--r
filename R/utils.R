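# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do not
#' perturb the global RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Counter-based derivation: adding a new stage never perturbs the seeds of
#' earlier stages. Result is always a positive integer below 2^31 - 1.
#' @param seed master seed (integer).
#' @param stage stage counter (non-negative integer) or stage name known to the
#'   pipeline's fixed stage table.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(space = 1, policy = 2, sessions = 3, trait = 4,
                connectivity = 5, covariates = 6, cpm_perm = 7, mediation = 8)
    if (!stage %in% names(stages)) {
      stop("unknown stage name: ", stage, call. = FALSE)
    }
    stage <- stages[[stage]]
  }
  stopifnot(is.numeric(stage), length(stage) == 1, stage >= 0)
  m <- 2147483629 # largest prime < 2^31
  s <- (as.double(seed) %% m + 97561 * (as.double(stage) + 1)) %% m
  as.integer(s + 1)
}

#' @noRd
assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(as.double(x))
}

#' Lognormal draw with a prescribed arithmetic mean
#'
#' With `sdlog = 0` returns the mean exactly.
#' @noRd
rlnorm_mean <- function(n, mean, sdlog) {
  if (sdlog == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
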