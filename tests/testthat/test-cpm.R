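test_that("edge selection equals the brute-force correlation oracle", {
  set.seed(21)
  for (rep in 1:5) {
    trait <- rnorm(12)
    cc <- generate_connectivity(12, 6, trait,
                                planted_pos = rbind(c(1, 2), c(3, 5)),
                                planted_neg = rbind(c(2, 6)),
                                beta = 0.5, noise_sd = 0.3, seed = 21 + rep)
    masks <- select_edges(cc, trait, alpha = 0.1)
    oracle <- select_edges_oracle(cc, trait, alpha = 0.1)
    expect_identical(mask_key(masks$positive), mask_key(oracle$positive))
    expect_identical(mask_key(masks$negative), mask_key(oracle$negative))
  }
})

test_that("an edge identical to the behavior lands in the matching mask", {
  beh <- rnorm(10)
  mats <- lapply(seq_len(10), function(s) {
    m <- matrix(0, 4, 4)
    m[1, 2] <- m[2, 1] <- beh[s]
    m[3, 4] <- m[4, 3] <- -beh[s]
    diag(m) <- 1
    m
  })
  cc <- connectivity_cohort(mats, motion = rep(0.1, 10))
  masks <- select_edges(cc, beh, alpha = 0.01)
  expect_true("1 2" %in% mask_key(masks$positive))
  expect_true("3 4" %in% mask_key(masks$negative))
})

test_that("null edges are selected at about the nominal alpha rate", {
  set.seed(77)
  counts <- vapply(1:10, function(rep) {
    trait <- rnorm(25)
    cc <- generate_connectivity(25, 46, trait, beta = 0, noise_sd = 0.2,
                                seed = 700 + rep) # 1035 edges
    masks <- select_edges(cc, trait, alpha = 0.01)
    nrow(masks$positive) + nrow(masks$negative)
  }, numeric(1))
  expect_gt(mean(counts), 4)   # ~10.35 expected
  expect_lt(mean(counts), 20)
})

test_that("strength sums each unordered mask edge once", {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- -0.3; diag(m) <- 1
  expect_equal(strength(m, tibble::tibble(node_i = 1, node_j = 2)), 0.5)
  expect_equal(strength(m, tibble::tibble(node_i = c(1, 2),
                                          node_j = c(2, 3))), 0.2,
               tolerance = 1e-12)
  expect_warning(s0 <- strength(m, tibble::tibble(node_i = integer(0),
                                                  node_j = integer(0))),
                 "empty mask")
  expect_equal(s0, 0)
})

test_that("generated matrices are exactly symmetric with planted effects of
           the right sign", {
  trait <- seq(-2, 2, length.out = 12)
  cc <- generate_connectivity(12, 8, trait, planted_pos = rbind(c(1, 2)),
                              planted_neg = rbind(c(3, 4)), beta = 5,
                              noise_sd = 0.05, seed = 3)
  for (m in cc$matrices) expect_identical(m, t(m))
  e_pos <- vapply(cc$matrices, function(m) m[1, 2], numeric(1))
  e_neg <- vapply(cc$matrices, function(m) m[3, 4], numeric(1))
  expect_gt(cor(e_pos, trait), 0.99)
  expect_lt(cor(e_neg, trait), -0.99)
  expect_error(generate_connectivity(5, 4, rnorm(5),
                                     planted_pos = rbind(c(2, 2))),
               "diagonal")
  expect_error(generate_connectivity(5, 4, rnorm(5),
                                     planted_pos = rbind(c(1, 2)),
                                     planted_neg = rbind(c(1, 2))),
               "disjoint")
})

test_that("leave-one-out prediction is strong under a planted effect and
           order-invariant", {
  set.seed(31)
  trait <- rnorm(24)
  planted <- rbind(c(1, 2), c(2, 3), c(4, 5), c(1, 6))
  cc <- generate_connectivity(24, 12, trait, planted_pos = planted,
                              beta = 1, noise_sd = 0.1, seed = 5)
  res <- loocv_predict(cc, trait)
  expect_gt(res$rho, 0.9)
  expect_equal(length(res$predicted), 24)
  # relabeling subjects leaves matched predictions unchanged
  perm <- sample(24)
  cc2 <- connectivity_cohort(cc$matrices[perm], cc$motion[perm])
  res2 <- loocv_predict(cc2, trait[perm])
  expect_equal(res2$predicted, res$predicted[perm], tolerance = 1e-10)
  # final masks are subsets of whole-cohort selection at the same alpha
  full <- select_edges(cc, trait, alpha = 0.01)
  expect_true(all(mask_key(res$final_masks$positive) %in%
                    mask_key(full$positive)))
  expect_true(all(mask_key(res$final_masks$negative) %in%
                    mask_key(full$negative)))
})

test_that("the permutation test flags a planted effect and spares an extreme
           null", {
  set.seed(41)
  trait <- rnorm(20)
  cc <- generate_connectivity(20, 10, trait,
                              planted_pos = rbind(c(1, 2), c(3, 4)),
                              beta = 1, noise_sd = 0.1, seed = 8)
  res <- cpm_permutation_test(cc, trait, n_perm = 199, seed = 2)
  expect_lte(res$p_permutation, 0.05)
  expect_equal(res$p_permutation,
               (1 + sum(res$null_rho >= res$rho)) / 200)
})

test_that("network summaries count degrees and normalize pair percentages", {
  labels <- tibble::tibble(node_id = 1:4,
                           network = c("DMN", "DMN", "FPN", "FPN"))
  mask <- tibble::tibble(node_i = c(1, 1), node_j = c(2, 3))
  s <- summarize_network(mask, labels)
  expect_equal(s$degrees$degree[s$degrees$node_id == 1], 2)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_links, 2)
  expect_equal(sum(s$pairs$pct), 100)
  within <- summarize_network(tibble::tibble(node_i = 1, node_j = 2), labels)
  expect_equal(within$pairs$pct, 100)
  expect_equal(within$pairs$network_a, "DMN")
  expect_error(summarize_network(tibble::tibble(node_i = 1, node_j = 9),
                                 labels), "unlabeled")
})
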