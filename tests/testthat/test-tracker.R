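test_that("prediction keeps the state and inflates the covariance additively", {
  s <- gene_track_state(a = c(1, -2), P = diag(2), Q = diag(0, 2), R = 1)
  s1 <- kalman_predict(s)
  expect_identical(s1$a, s$a)
  expect_equal(s1$P, diag(2))

  s <- gene_track_state(a = c(0, 0), P = diag(2), Q = diag(0.1, 2), R = 1)
  expect_equal(kalman_predict(s)$P, diag(1.1, 2))

  # k predictions with no updates: P = P0 + k Q
  s <- gene_track_state(a = c(0, 0), P = diag(0.5, 2), Q = diag(0.2, 2), R = 1)
  for (k in 1:4) s <- kalman_predict(s)
  expect_equal(s$P, diag(0.5 + 4 * 0.2, 2))
})

test_that("measurement update matches hand-computed scalar case and degenerate limits", {
  # scalar: p = m = 1, P = 1, H = 1, R = 1, a = 0, y = 2 -> a = 1, P = 0.5
  s <- gene_track_state(a = 0, P = matrix(1), Q = matrix(0), R = matrix(1))
  s1 <- kalman_update(s, matrix(1), 2)
  expect_equal(s1$a, 1)
  expect_equal(s1$P, matrix(0.5))

  # perfectly known state: P = 0 -> zero gain, estimate unchanged
  s <- gene_track_state(a = c(3, -1), P = diag(0, 2), Q = diag(0, 2), R = 1)
  s1 <- kalman_update(s, diag(2), c(100, 100))
  expect_equal(s1$a, c(3, -1))

  # full observation, vanishing noise: the measurement is trusted fully
  s <- gene_track_state(a = c(0, 0, 0), P = diag(3), Q = diag(0, 3), R = 1e-12)
  s1 <- kalman_update(s, diag(3), c(1, -2, 0.5))
  expect_equal(s1$a, c(1, -2, 0.5), tolerance = 1e-9)

  # singular innovation: P = 0 and R = 0 makes S = 0
  s <- gene_track_state(a = 0, P = matrix(0), Q = matrix(0), R = matrix(0))
  expect_error(kalman_update(s, matrix(1), 1, epoch = 3), "singular innovation")
})

test_that("covariance constructors enforce symmetry and positive semi-definiteness", {
  asym <- matrix(c(1, 0.5, 0, 1), 2)
  expect_error(gene_track_state(c(0, 0), P = asym, Q = diag(2), R = 1), "symmetric")
  neg <- diag(c(1, -0.5))
  expect_error(gene_track_state(c(0, 0), P = neg, Q = diag(2), R = 1), "PSD")
})

test_that("lasso projection equals the soft-threshold closed form and a brute-force solve", {
  # frozen example: threshold lambda / 2 = 0.25
  expect_equal(lasso_project(c(1.0, -0.2, 0.05), lambda = 0.5), c(0.75, 0, 0))
  # lambda = 0: unconstrained limit, exact identity
  a <- c(0.3, -2, 0, 1e-9)
  expect_identical(lasso_project(a, lambda = 0), a)
  # lambda -> Inf: exactly the zero vector
  expect_identical(lasso_project(c(1e6, -3, 0.1), lambda = Inf), c(0, 0, 0))

  withr::with_seed(11, {
    for (rep in 1:20) {
      v <- rnorm(12, sd = 2)
      lam <- runif(1, 0, 4)
      closed <- sign(v) * pmax(abs(v) - lam / 2, 0)
      expect_equal(lasso_project(v, lambda = lam), closed, tolerance = 1e-12)
      expect_equal(lasso_project(v, lambda = lam), oracle_lasso_project(v, lam),
                   tolerance = 1e-8)
      # iterative solver behind the same interface agrees
      expect_equal(
        lasso_project(v, lambda = lam, opts = track_options(method = "ista")),
        closed, tolerance = 1e-8
      )
    }
  })
})

test_that("projected support is non-increasing in lambda", {
  withr::with_seed(12, {
    v <- rnorm(30)
    lams <- sort(runif(15, 0, 3))
    nnz <- vapply(lams, function(l) sum(lasso_project(v, lambda = l) != 0), 1L)
    expect_true(all(diff(nnz) <= 0))
  })
})

test_that("the lambda = 0 filter agrees with an information-form textbook Kalman filter", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      p <- sample(2:8, 1)
      n <- sample(2:6, 1)
      A <- make_sparse_truth(p, max(1, round(0.3 * p * (p - 1))), seed = rep)
      obs <- make_static_instance(A, n, m = sample(2:(p + 2), 1),
                                  noise_sd = 0.3, seed = 100 + rep)
      for (i in seq_len(p)) {
        probs <- extract_gene_problem(obs, i)
        opts <- track_options(lambda = 0, q_scale = 0.01, r_scale = 0.2,
                              p0_scale = 2)
        mine <- filter_gene(probs, opts, a0 = rep(0, p))
        ref <- oracle_kalman_filter(probs, 0.01, 0.2, 2, rep(0, p))
        for (k in seq_len(n)) {
          expect_equal(mine$filtered[[k]], ref[[k]]$a, tolerance = 1e-10)
          expect_equal(mine$filtered_cov[[k]], ref[[k]]$P, tolerance = 1e-10)
        }
      }
    }
  })
})

test_that("a consistent start with noiseless data stays at the truth", {
  A <- make_sparse_truth(6, 8, seed = 31)
  obs <- make_static_instance(A, n_epochs = 1, m = 6, noise_sd = 0, seed = 32)
  probs <- extract_gene_problem(obs, 2)
  traj <- filter_gene(probs, track_options(lambda = 0), a0 = A[2, ])
  expect_equal(traj$filtered[[1]], A[2, ], tolerance = 1e-8)
})

test_that("covariances stay symmetric PSD along a constrained filter run", {
  A <- make_sparse_truth(6, 8, seed = 41)
  obs <- make_static_instance(A, n_epochs = 5, m = 3, noise_sd = 0.2, seed = 42)
  traj <- smooth_gene(extract_gene_problem(obs, 1),
                      track_options(lambda = 0.3), a0 = rep(0, 6))
  for (P in c(traj$filtered_cov, traj$smoothed_cov)) {
    expect_lt(max(abs(P - t(P))), 1e-10)
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("noiseless overdetermined epochs with lambda = 0 recover the true row to 1e-6", {
  p <- 7
  A <- make_sparse_truth(p, 10, seed = 51)
  obs <- make_static_instance(A, n_epochs = 4, m = p + 2, noise_sd = 0, seed = 52)
  # noise covariances are "known": match the zero-noise experiment
  opts <- track_options(lambda = 0, q_scale = 0, r_scale = 1e-9)
  for (i in seq_len(p)) {
    traj <- filter_gene(extract_gene_problem(obs, i), opts, a0 = rep(0, p))
    expect_equal(traj$filtered[[4]], A[i, ], tolerance = 1e-6)
  }
})

test_that("a sparse row is support-recovered by the constrained filter at the final epoch", {
  # two nonzero incoming edges in p = 10, seven observations per epoch,
  # five epochs, moderate fixed sparsity weight
  p <- 10
  A <- matrix(0, p, p)
  A[1, 3] <- 1.2
  A[1, 7] <- -0.9
  obs <- make_static_instance(A, n_epochs = 5, m = 7, noise_sd = 0.1, seed = 61)
  traj <- filter_gene(extract_gene_problem(obs, 1),
                      track_options(lambda = 0.3), a0 = rep(0, p))
  est <- traj$filtered[[5]]
  expect_identical(which(est != 0), c(3L, 7L))
  expect_equal(sign(est[c(3, 7)]), c(1, -1))
})

test_that("single-epoch fusion with symmetric initialization returns the filtered state", {
  # the backward pass sees the same single epoch from the same prior, so the
  # information-weighted combination must reproduce the filtered estimate
  A <- make_sparse_truth(5, 5, seed = 71)
  obs <- make_static_instance(A, n_epochs = 1, m = 4, noise_sd = 0.1, seed = 72)
  opts <- track_options(lambda = 0, p0_scale = 3, p0_scale_backward = 3)
  probs <- extract_gene_problem(obs, 1)
  traj <- smooth_gene(probs, opts, a0 = rep(0, 5))
  expect_equal(traj$smoothed[[1]], traj$filtered[[1]], tolerance = 1e-8)
  # and the fused covariance halves (information doubles)
  expect_equal(traj$smoothed_cov[[1]], traj$filtered_cov[[1]] / 2, tolerance = 1e-8)
})

test_that("static truth with zero noise gives an epoch-constant smoothed estimate", {
  p <- 5
  A <- make_sparse_truth(p, 5, seed = 81)
  obs <- make_static_instance(A, n_epochs = 4, m = p + 1, noise_sd = 0, seed = 82)
  opts <- track_options(lambda = 0, q_scale = 0, r_scale = 1e-9)
  traj <- smooth_gene(extract_gene_problem(obs, 2), opts, a0 = rep(0, p))
  for (k in 2:4) {
    expect_equal(traj$smoothed[[k]], traj$smoothed[[1]], tolerance = 1e-6)
  }
})

test_that("smoothing reduces posterior variance relative to filtering", {
  inst <- simulate_instance(sim_config(seed = 91))
  mean_diag_f <- 0
  mean_diag_s <- 0
  for (i in seq_len(inst$obs$p)) {
    traj <- smooth_gene(extract_gene_problem(inst$obs, i),
                        track_options(lambda = 0.1), a0 = rep(0, 10))
    for (k in seq_along(traj$filtered_cov)) {
      df <- diag(traj$filtered_cov[[k]])
      ds <- diag(traj$smoothed_cov[[k]])
      expect_true(all(ds <= df + 1e-8)) # per-coordinate, every epoch
      mean_diag_f <- mean_diag_f + mean(df)
      mean_diag_s <- mean_diag_s + mean(ds)
    }
  }
  expect_lt(mean_diag_s, mean_diag_f)
})

test_that("track_network equals independent per-gene smoothing and is worker-invariant", {
  inst <- simulate_instance(sim_config(p = 4, n_epochs = 3, m_per_epoch = 5, seed = 101))
  opts <- track_options(lambda = 0.2)
  traj1 <- track_network(inst$obs, opts, workers = 1)
  traj4 <- track_network(inst$obs, opts, workers = 4)
  expect_identical(traj1$smoothed, traj4$smoothed)
  expect_identical(traj1$filtered, traj4$filtered)
  for (i in 1:4) {
    solo <- smooth_gene(extract_gene_problem(inst$obs, i), opts, NULL, i)
    for (k in 1:3) {
      expect_identical(traj1$smoothed[[k]][i, ], solo$smoothed[[k]])
    }
  }
})

test_that("the l1 projection yields a sparser network than the classical filter at every epoch", {
  inst <- simulate_instance(sim_config(seed = 111)) # ten genes, five epochs, m = 7
  con <- track_network(inst$obs, track_options(lambda = 0.3))
  kal <- track_network(inst$obs, track_options(lambda = 0))
  for (k in 1:5) {
    expect_lt(sum(con$smoothed[[k]] != 0), sum(kal$smoothed[[k]] != 0))
  }
})
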