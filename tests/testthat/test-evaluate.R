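test_that("the alpha-vicinity criterion scores the +-20% band literally", {
  A <- matrix(1.0)
  expect_equal(edge_error_rate(A, matrix(0.81), alpha = 0.2), 0) # inside
  expect_equal(edge_error_rate(A, matrix(0.79), alpha = 0.2), 1) # outside
  expect_equal(edge_error_rate(A, A, alpha = 0.2), 0)
  # zero true edge: any nonzero estimate errs, an exact zero does not
  expect_equal(edge_error_rate(matrix(0), matrix(1e-9), alpha = 0.2), 1)
  expect_equal(edge_error_rate(matrix(0), matrix(0), alpha = 0.2), 0)
})

test_that("edge error agrees with an elementwise brute-force count and is scale-aware", {
  withr::with_seed(161, {
    tr <- matrix(rnorm(25), 5)
    tr[abs(tr) < 0.5] <- 0
    est <- tr + matrix(rnorm(25, 0, 0.3), 5)
    alpha <- 0.2
    brute <- 0
    for (i in 1:5) for (j in 1:5) {
      if (abs(tr[i, j] - est[i, j]) > alpha * abs(tr[i, j])) brute <- brute + 1
    }
    expect_equal(edge_error_rate(tr, est, alpha), brute / 25)
    for (c_scale in c(-3, 0.01, 7)) {
      expect_equal(edge_error_rate(c_scale * tr, c_scale * est, alpha),
                   edge_error_rate(tr, est, alpha))
    }
  })
})

test_that("confusion metrics satisfy their internal identities and degenerate limits", {
  A <- make_sparse_truth(8, 12, seed = 171)
  # perfect estimate
  cm <- confusion_metrics(A, A)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$precision, 1)
  # dense degenerate estimate: all edges called present
  cm2 <- confusion_metrics(A, matrix(1, 8, 8))
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 0)
  # identities on a noisy sequence
  withr::with_seed(172, {
    est <- lapply(1:3, function(k) A + matrix(rnorm(64, 0, 0.4), 8))
  })
  cm3 <- confusion_metrics(rep(list(A), 3), est)
  expect_equal(cm3$tp + cm3$tn + cm3$fp + cm3$fn, 100, tolerance = 1e-6)
  expect_equal(cm3$sensitivity, cm3$tp / (cm3$tp + cm3$fn), tolerance = 1e-9)
  expect_equal(cm3$specificity, cm3$tn / (cm3$tn + cm3$fp), tolerance = 1e-9)
  expect_equal(cm3$accuracy, (cm3$tp + cm3$tn) / 100, tolerance = 1e-9)
  expect_equal(cm3$precision, cm3$tp / (cm3$tp + cm3$fp), tolerance = 1e-9)
  # empty-denominator ratios are flagged, not NaN-propagated
  z <- matrix(0, 4, 4)
  cm4 <- confusion_metrics(z, z)
  expect_true(is.na(cm4$sensitivity))
  expect_true("sensitivity" %in% cm4$undefined)
  expect_equal(cm4$specificity, 1)
})

test_that("confusion metrics are invariant under a common gene relabelling", {
  withr::with_seed(173, {
    tr <- make_sparse_truth(7, 10, seed = 174)
    est <- tr + matrix(rnorm(49, 0, 0.5), 7)
    perm <- sample(7)
  })
  cm <- confusion_metrics(tr, est)
  cmp <- confusion_metrics(tr[perm, perm], est[perm, perm])
  expect_equal(cm$counts, cmp$counts)
})

test_that("degree trajectories count symmetrized above-threshold incident edges", {
  z <- matrix(0, 5, 5)
  expect_equal(degree_trajectories(list(z, z)), matrix(0L, 5, 2))
  e <- z
  e[2, 4] <- 0.8 # one directed edge -> degree 1 at both endpoints
  expect_equal(degree_trajectories(list(e, e))[, 1], c(0L, 1L, 0L, 1L, 0L))
  withr::with_seed(181, {
    A <- matrix(rnorm(36, 0, 0.5), 6)
    A[abs(A) < 0.4] <- 0
  })
  B <- (abs(A) > 1e-3) | t(abs(A) > 1e-3)
  diag(B) <- FALSE
  hand <- vapply(1:6, function(i) sum(B[i, ]), 1)
  expect_equal(degree_trajectories(A)[, 1], as.integer(hand))
})

test_that("discrete power-law MLE matches an independent fit and flags degenerate sequences", {
  # star on 50 nodes: hub degree 49, 49 leaves of degree 1
  star <- matrix(0, 50, 50)
  star[1, 2:50] <- 1
  alpha_hat <- powerlaw_exponent(star)
  ref <- igraph::fit_power_law(
    c(49, rep(1, 49)), xmin = 1, implementation = "R.mle"
  )
  expect_equal(alpha_hat, as.numeric(ref@coef), tolerance = 1e-3)

  # regular ring: single-valued degrees carry no slope information
  ring <- matrix(0, 8, 8)
  for (i in 1:8) ring[i, (i %% 8) + 1] <- 1
  expect_warning(expect_true(is.na(powerlaw_exponent(ring))), "degenerate")

  # heavy-tailed synthetic graph: agree with the independent MLE route
  g <- igraph::sample_pa(300, power = 1, m = 1, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  ref2 <- igraph::fit_power_law(igraph::degree(g), xmin = 1,
                                implementation = "R.mle")
  expect_equal(powerlaw_exponent(adj), as.numeric(ref2@coef), tolerance = 0.05)
})

test_that("clustering coefficient matches brute-force triangle counting", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  expect_equal(clustering_coefficient(tri), 1)
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- 1
  expect_equal(clustering_coefficient(star), 0)
  withr::with_seed(191, {
    A <- matrix(rbinom(100, 1, 0.3), 10) * runif(100, 0.5, 1)
  })
  B <- ((abs(A) > 1e-3) | t(abs(A) > 1e-3)) * 1L
  diag(B) <- 0L
  expect_equal(clustering_coefficient(A), oracle_clustering(B), tolerance = 1e-12)
})

test_that("reducing observations never helps: error at m = p is near zero and decreases in m", {
  # identifiable noiseless limit at m = p with a static network
  sw <- sweep_observation_count(
    p = 8, m_values = 8, reps = 2, seed = 201, n_epochs = 3,
    obs_noise_sd = 1e-4, rewire_fraction = 0, sparsity = 0.15
  )
  expect_lt(sw$mean_error, 0.1)
  # paired comparison on matched seeds: more observations, less error
  sw2 <- sweep_observation_count(p = 12, m_values = c(3, 12), reps = 3, seed = 202)
  expect_lte(sw2$mean_error[sw2$m == 12], sw2$mean_error[sw2$m == 3])
})
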