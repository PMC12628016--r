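# Connectome-based predictive modeling: edge selection by behavioral
# correlation, positive/negative mask strengths, leave-one-out cross-validated
# prediction with a motion covariate, permutation inference, and predictive
# network summaries.

#' Assemble a connectivity cohort
#'
#' Bundles per-subject symmetric connectivity matrices with node/network
#' labels and a motion covariate into the container the CPM functions
#' operate on. Matrices must be square, of equal size and symmetric within
#' `1e-6` (they are symmetrized by averaging); the diagonal is ignored by all
#' edge operations.
#'
#' @param matrices list of node-by-node numeric matrices, one per subject.
#' @param motion numeric vector of mean framewise displacement (mm) per
#'   subject.
#' @param subjects subject identifiers (defaults to `s001`, ...).
#' @param node_labels tibble with columns `node_id` (1-based) and `network`;
#'   defaults to a single `"all"` network.
#' @return an object of class `connectivity_cohort`: list with `edge_matrix`
#'   (subjects x edges, strict upper triangle, column order column-major),
#'   `edge_pairs` (edges x 2 node indices), `n_nodes`, `motion`, `subjects`,
#'   `node_labels`, `matrices`.
#' @export
connectivity_cohort <- function(matrices, motion,
                                subjects = NULL, node_labels = NULL) {
  n <- length(matrices)
  stopifnot(n >= 1, length(motion) == n)
  p <- nrow(matrices[[1]])
  for (i in seq_len(n)) {
    m <- matrices[[i]]
    if (!is.matrix(m) || nrow(m) != p || ncol(m) != p) {
      stop("matrix ", i, " is not ", p, "x", p, call. = FALSE)
    }
    if (max(abs(m - t(m))) > 1e-6) {
      stop("matrix ", i, " is asymmetric beyond tolerance 1e-6",
           call. = FALSE)
    }
    matrices[[i]] <- (m + t(m)) / 2
  }
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(n))
  if (is.null(node_labels)) {
    node_labels <- tibble::tibble(node_id = seq_len(p), network = "all")
  }
  ut <- upper.tri(matrix(0, p, p))
  edge_pairs <- which(ut, arr.ind = TRUE)
  colnames(edge_pairs) <- c("node_i", "node_j")
  edge_matrix <- t(vapply(matrices, function(m) m[ut], numeric(sum(ut))))
  out <- list(edge_matrix = edge_matrix, edge_pairs = edge_pairs,
              n_nodes = p, motion = as.numeric(motion),
              subjects = subjects, node_labels = node_labels,
              matrices = matrices)
  class(out) <- "connectivity_cohort"
  out
}

#' @export
print.connectivity_cohort <- function(x, ...) {
  cat("<connectivity_cohort>", length(x$subjects), "subjects,",
      x$n_nodes, "nodes,", ncol(x$edge_matrix), "edges\n")
  invisible(x)
}

as_cohort <- function(bundles) {
  if (inherits(bundles, "connectivity_cohort")) return(bundles)
  stop("expected a connectivity_cohort (see connectivity_cohort() or ",
       "generate_connectivity())", call. = FALSE)
}

#' Generate synthetic connectivity matrices with planted trait effects
#'
#' Background edges are Normal(0, `noise_sd`); each planted positive edge adds
#' `+beta * z` and each planted negative edge `-beta * z`, where `z` is the
#' standardized trait of the subject. Matrices are exactly symmetric with a
#' unit diagonal; a per-subject motion covariate is drawn independently
#' (|Normal(0.15, 0.04)| mm, typical resting-state framewise displacement).
#'
#' @param n_subjects number of subjects.
#' @param n_nodes number of nodes.
#' @param trait numeric vector (length `n_subjects`) of the behavior the
#'   planted edges track.
#' @param planted_pos,planted_neg integer matrices (k x 2) of 1-based node
#'   pairs in the strict upper triangle (`node_i < node_j`); the two sets must
#'   be disjoint and off-diagonal.
#' @param beta planted effect size per standardized trait unit.
#' @param noise_sd SD of the background edge noise.
#' @param seed integer seed.
#' @param n_networks number of (contiguous, balanced) synthetic network
#'   labels to assign to the nodes.
#' @return a `connectivity_cohort`.
#' @export
generate_connectivity <- function(n_subjects, n_nodes, trait,
                                  planted_pos = NULL, planted_neg = NULL,
                                  beta = 0.3, noise_sd = 0.1, seed = 1,
                                  n_networks = min(17, n_nodes)) {
  assert_count(n_subjects, "n_subjects")
  assert_count(n_nodes, "n_nodes", min = 2)
  stopifnot(length(trait) == n_subjects)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be > 0", call. = FALSE)
  }
  check_edges <- function(e, name) {
    if (is.null(e)) return(matrix(integer(0), ncol = 2))
    e <- as.matrix(e)
    if (ncol(e) != 2) stop("`", name, "` must have two columns",
                           call. = FALSE)
    if (any(e[, 1] == e[, 2])) {
      stop("`", name, "` contains a diagonal (self) edge", call. = FALSE)
    }
    if (any(e < 1) || any(e > n_nodes)) {
      stop("`", name, "` contains a node outside 1..", n_nodes,
           call. = FALSE)
    }
    flip <- e[, 1] > e[, 2]
    e[flip, ] <- e[flip, 2:1]
    e
  }
  planted_pos <- check_edges(planted_pos, "planted_pos")
  planted_neg <- check_edges(planted_neg, "planted_neg")
  if (nrow(planted_pos) && nrow(planted_neg)) {
    key <- function(e) paste(e[, 1], e[, 2])
    if (length(intersect(key(planted_pos), key(planted_neg)))) {
      stop("planted positive and negative edge sets must be disjoint",
           call. = FALSE)
    }
  }
  z <- if (stats::sd(trait) > 0) as.numeric(scale(trait)) else trait * 0
  with_seed(seed, {
    mats <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      m <- matrix(0, n_nodes, n_nodes)
      ut <- upper.tri(m)
      vals <- stats::rnorm(sum(ut), sd = noise_sd)
      m[ut] <- vals
      if (nrow(planted_pos)) {
        m[planted_pos] <- m[planted_pos] + beta * z[s]
      }
      if (nrow(planted_neg)) {
        m[planted_neg] <- m[planted_neg] - beta * z[s]
      }
      m <- m + t(m)
      diag(m) <- 1
      mats[[s]] <- m
    }
    motion <- abs(stats::rnorm(n_subjects, 0.15, 0.04))
    labels <- tibble::tibble(
      node_id = seq_len(n_nodes),
      network = sprintf("N%02d", ceiling(seq_len(n_nodes) * n_networks /
                                           n_nodes)))
    connectivity_cohort(mats, motion, node_labels = labels)
  })
}

# internal vectorized edgewise Pearson correlation with behavior, leaving out
# one subject via precomputed sums
edge_cor_stats <- function(X) {
  list(Sx = colSums(X), Sxx = colSums(X^2), N = nrow(X))
}

edge_cor_loo <- function(X, stats_x, y, Sy, Syy, Sxy, leave_out = NULL) {
  if (is.null(leave_out)) {
    n <- stats_x$N
    sx <- stats_x$Sx; sxx <- stats_x$Sxx
    sy <- Sy; syy <- Syy; sxy <- Sxy
  } else {
    i <- leave_out
    n <- stats_x$N - 1
    sx <- stats_x$Sx - X[i, ]
    sxx <- stats_x$Sxx - X[i, ]^2
    sy <- Sy - y[i]
    syy <- Syy - y[i]^2
    sxy <- Sxy - X[i, ] * y[i]
  }
  denom2 <- (n * sxx - sx^2) * (n * syy - sy^2)
  r <- rep(NA_real_, length(sx))
  pos <- denom2 > 0
  r[pos] <- (n * sxy[pos] - sx[pos] * sy) / sqrt(denom2[pos])
  r[pos] <- pmin(1, pmax(-1, r[pos]))
  list(r = r, n = n)
}

edge_p_from_r <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  t2 <- r[ok]^2 * (n - 2) / pmax(1e-300, 1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-sqrt(t2), df = n - 2)
  p
}

mask_tibble <- function(cohort, idx, sign) {
  tibble::tibble(node_i = cohort$edge_pairs[idx, 1],
                 node_j = cohort$edge_pairs[idx, 2],
                 sign = rep(sign, length(idx)))
}

#' Select edges correlated with behavior
#'
#' Correlates each strict-upper-triangle edge (Pearson) with the behavior
#' across subjects; edges with `p < alpha` enter the positive or negative mask
#' according to the sign of the correlation. Constant edges are skipped.
#'
#' @param bundles a `connectivity_cohort`.
#' @param behavior per-subject numeric vector.
#' @param alpha edge-selection threshold (default 0.01).
#' @return a list with `positive` and `negative` mask tibbles (node_i,
#'   node_j, sign).
#' @export
select_edges <- function(bundles, behavior, alpha = 0.01) {
  cohort <- as_cohort(bundles)
  X <- cohort$edge_matrix
  stopifnot(length(behavior) == nrow(X))
  if (nrow(X) < 4) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(behavior) == 0) {
    stop("behavior is constant across subjects", call. = FALSE)
  }
  st <- edge_cor_stats(X)
  res <- edge_cor_loo(X, st, behavior, sum(behavior), sum(behavior^2),
                      as.vector(crossprod(X, behavior)))
  p <- edge_p_from_r(res$r, res$n)
  sel <- !is.na(p) & p < alpha
  list(positive = mask_tibble(cohort, which(sel & res$r > 0), "positive"),
       negative = mask_tibble(cohort, which(sel & res$r < 0), "negative"))
}

mask_to_index <- function(cohort, mask) {
  if (!nrow(mask)) return(integer(0))
  if (any(mask$node_i < 1 | mask$node_j > cohort$n_nodes |
            mask$node_i >= mask$node_j)) {
    stop("mask edges must satisfy 1 <= node_i < node_j <= n_nodes",
         call. = FALSE)
  }
  ekey <- paste(cohort$edge_pairs[, 1], cohort$edge_pairs[, 2])
  match(paste(mask$node_i, mask$node_j), ekey)
}

#' Network strength of a subject under an edge mask
#'
#' Sum of the subject's connectivity values over the mask edges, each
#' unordered pair counted once. An empty mask yields 0 with a warning.
#'
#' @param bundle a single symmetric connectivity matrix, or a
#'   `connectivity_cohort` (then a per-subject vector is returned).
#' @param mask a mask tibble (node_i, node_j) from [select_edges()].
#' @return numeric strength (or vector of strengths).
#' @export
strength <- function(bundle, mask) {
  if (!nrow(mask)) {
    warning("empty mask: strength is 0", call. = FALSE)
    if (inherits(bundle, "connectivity_cohort")) {
      return(rep(0, length(bundle$subjects)))
    }
    return(0)
  }
  if (inherits(bundle, "connectivity_cohort")) {
    idx <- mask_to_index(bundle, mask)
    return(as.vector(bundle$edge_matrix[, idx, drop = FALSE] %*%
                       rep(1, length(idx))))
  }
  stopifnot(is.matrix(bundle))
  sum(bundle[cbind(mask$node_i, mask$node_j)])
}

# single LOO pass over precomputed edge data; returns predictions and fold
# mask intersections. Used by both loocv_predict and the permutation test.
cpm_loocv_core <- function(X, motion, y, alpha, want_masks = TRUE) {
  n <- nrow(X); E <- ncol(X)
  st <- edge_cor_stats(X)
  Sy <- sum(y); Syy <- sum(y^2)
  Sxy <- as.vector(crossprod(X, y))
  pred <- numeric(n)
  pos_all <- rep(TRUE, E); neg_all <- rep(TRUE, E)
  any_empty <- FALSE
  for (i in seq_len(n)) {
    res <- edge_cor_loo(X, st, y, Sy, Syy, Sxy, leave_out = i)
    p <- edge_p_from_r(res$r, res$n)
    sel <- !is.na(p) & p < alpha
    pos <- sel & res$r > 0
    neg <- sel & res$r < 0
    if (want_masks) {
      pos_all <- pos_all & pos
      neg_all <- neg_all & neg
    }
    s_pos <- if (any(pos)) {
      rowSums(X[, pos, drop = FALSE])
    } else rep(0, n)
    s_neg <- if (any(neg)) {
      rowSums(X[, neg, drop = FALSE])
    } else rep(0, n)
    cols <- cbind(1, s_pos, s_neg, motion)
    keep_col <- c(TRUE, any(pos), any(neg), TRUE)
    if (!any(pos) && !any(neg)) any_empty <- TRUE
    fit <- stats::lm.fit(cols[-i, keep_col, drop = FALSE], y[-i])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred[i] <- sum(cols[i, keep_col] * beta)
  }
  list(pred = pred, pos_mask = which(pos_all), neg_mask = which(neg_all),
       any_empty_fold = any_empty)
}

#' Leave-one-out connectome-based prediction
#'
#' For each held-out subject, edges are selected on the remaining N-1
#' subjects, positive- and negative-mask strengths are computed, a linear
#' model `behavior ~ pos_strength + neg_strength + motion` is fitted on the
#' N-1 subjects, and the held-out subject's behavior is predicted. Prediction
#' quality is the Spearman correlation between predicted and observed
#' behavior; the final masks are the intersection of the fold masks (edges
#' selected in every loop).
#'
#' @param bundles a `connectivity_cohort`.
#' @param behavior per-subject numeric vector to predict.
#' @param alpha edge-selection threshold (default 0.01).
#' @return an object of class `cpm_result`: list with `predicted`,
#'   `observed`, `rho`, `p_parametric`, `p_permutation` (`NA` until
#'   [cpm_permutation_test()]), `final_masks` (list of positive/negative mask
#'   tibbles), `n`, `alpha`, `any_empty_fold`.
#' @export
loocv_predict <- function(bundles, behavior, alpha = 0.01) {
  cohort <- as_cohort(bundles)
  X <- cohort$edge_matrix
  n <- nrow(X)
  if (n < 10) stop("leave-one-out CPM needs a cohort of at least 10",
                   call. = FALSE)
  stopifnot(length(behavior) == n)
  if (stats::sd(behavior) == 0) {
    stop("behavior is constant across subjects", call. = FALSE)
  }
  core <- cpm_loocv_core(X, cohort$motion, behavior, alpha)
  if (core$any_empty_fold) {
    warning("at least one fold selected no edges; that fold predicts from ",
            "intercept and motion only", call. = FALSE)
  }
  rho <- stats::cor(core$pred, behavior, method = "spearman")
  ct <- suppressWarnings(stats::cor.test(core$pred, behavior,
                                         method = "spearman"))
  out <- list(predicted = core$pred, observed = behavior, rho = rho,
              p_parametric = ct$p.value, p_permutation = NA_real_,
              final_masks = list(
                positive = mask_tibble(cohort, core$pos_mask, "positive"),
                negative = mask_tibble(cohort, core$neg_mask, "negative")),
              n = n, alpha = alpha, any_empty_fold = core$any_empty_fold)
  class(out) <- "cpm_result"
  out
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("<cpm_result> n =", x$n, " rho =", round(x$rho, 3),
      " parametric p =", signif(x$p_parametric, 3), "\n",
      " permutation p =",
      if (is.na(x$p_permutation)) "(not run)" else
        signif(x$p_permutation, 3),
      " final masks:", nrow(x$final_masks$positive), "positive /",
      nrow(x$final_masks$negative), "negative edges\n")
  invisible(x)
}

#' Permutation test of the CPM prediction
#'
#' Randomly permutes the behavior vector across subjects `n_perm` times,
#' reruns the full leave-one-out CPM per permutation, and reports
#' `p = (1 + #\{null rho >= observed rho\}) / (n_perm + 1)`.
#'
#' @inheritParams loocv_predict
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutations.
#' @return a `cpm_result` (as [loocv_predict()]) with `p_permutation` filled
#'   and the null distribution in `null_rho`.
#' @export
cpm_permutation_test <- function(bundles, behavior, alpha = 0.01,
                                 n_perm = 1000, seed = 1) {
  assert_count(n_perm, "n_perm", min = 100)
  cohort <- as_cohort(bundles)
  obs <- loocv_predict(cohort, behavior, alpha)
  X <- cohort$edge_matrix
  null_rho <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yb <- sample(behavior)
      core <- cpm_loocv_core(X, cohort$motion, yb, alpha, want_masks = FALSE)
      stats::cor(core$pred, yb, method = "spearman")
    }, numeric(1))
  })
  obs$p_permutation <- (1 + sum(null_rho >= obs$rho)) / (n_perm + 1)
  obs$null_rho <- null_rho
  obs
}

#' Summarize a predictive network mask
#'
#' Node degrees (incident mask edges) and the symmetric network-pair edge
#' counts and percentages of the total mask edges, plus the node/link counts.
#'
#' @param mask mask tibble (node_i, node_j).
#' @param node_labels tibble with `node_id`, `network` covering all mask
#'   nodes.
#' @return list with `degrees` (tibble: node_id, network, degree), `pairs`
#'   (tibble: network_a, network_b, n_edges, pct), `n_nodes`, `n_links`.
#' @export
summarize_network <- function(mask, node_labels) {
  nodes <- sort(unique(c(mask$node_i, mask$node_j)))
  missing_nodes <- setdiff(nodes, node_labels$node_id)
  if (length(missing_nodes)) {
    stop("unlabeled node(s) in mask: ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  deg <- table(factor(c(mask$node_i, mask$node_j), levels = nodes))
  degrees <- tibble::tibble(
    node_id = as.integer(names(deg)),
    network = node_labels$network[match(as.integer(names(deg)),
                                        node_labels$node_id)],
    degree = as.integer(deg))
  net_i <- node_labels$network[match(mask$node_i, node_labels$node_id)]
  net_j <- node_labels$network[match(mask$node_j, node_labels$node_id)]
  a <- pmin(net_i, net_j); b <- pmax(net_i, net_j)
  tab <- table(paste(a, b, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- tibble::tibble(
    network_a = vapply(parts, `[`, "", 1),
    network_b = vapply(parts, `[`, "", 2),
    n_edges = as.integer(tab),
    pct = 100 * as.integer(tab) / max(1L, nrow(mask)))
  list(degrees = degrees, pairs = pairs,
       n_nodes = length(nodes), n_links = nrow(mask))
}
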