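# Independent reference implementations used as oracles. These deliberately
# take different computational routes than the package code.

# Textbook Kalman filter in information form: covariance update via
# P_post = (P_prior^-1 + H' R^-1 H)^-1 instead of the gain form.
oracle_kalman_filter <- function(problems, q_scale, r_scale, p0_scale, a0) {
  p <- length(a0)
  a <- a0
  P <- diag(p0_scale, p)
  out <- vector("list", length(problems))
  for (k in seq_along(problems)) {
    P <- P + diag(q_scale, p)
    H <- problems[[k]]$design
    y <- problems[[k]]$response
    P_inv <- solve(P)
    P_post <- solve(P_inv + crossprod(H) / r_scale)
    a <- drop(P_post %*% (P_inv %*% a + crossprod(H, y) / r_scale))
    P <- (P_post + t(P_post)) / 2
    out[[k]] <- list(a = a, P = P)
  }
  out
}

# Brute-force solve of min ||a_tilde - x||_2^2 + lambda ||x||_1 by
# per-coordinate optimality conditions: the objective is separable and
# convex, so each coordinate is either at the kink (0, when the subgradient
# interval there contains zero) or at a numerically located root of the
# smooth derivative on the corresponding half-line.
oracle_lasso_project <- function(a_tilde, lambda) {
  vapply(a_tilde, function(v) {
    if (abs(2 * v) <= lambda) return(0) # 0 in subgradient [-lambda, lambda] + 2(0 - v)
    if (v > 0) {
      g <- function(x) 2 * (x - v) + lambda # derivative for x > 0
      stats::uniroot(g, c(0, v + lambda), tol = 1e-13)$root
    } else {
      g <- function(x) 2 * (x - v) - lambda # derivative for x < 0
      stats::uniroot(g, c(v - lambda, 0), tol = 1e-13)$root
    }
  }, numeric(1))
}

# Brute-force mean local clustering coefficient by triangle counting.
oracle_clustering <- function(B) {
  p <- nrow(B)
  cc <- numeric(p)
  for (i in seq_len(p)) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k >= 2) {
      links <- 0
      for (u in nb) for (v in nb) if (u < v && B[u, v] > 0) links <- links + 1
      cc[i] <- 2 * links / (k * (k - 1))
    }
  }
  mean(cc)
}

# A static instance of the observation model: fixed truth A, noiseless or
# noisy observations, n epochs of m columns each.
make_static_instance <- function(A, n_epochs, m, noise_sd = 0, seed = 1) {
  p <- nrow(A)
  withr::with_seed(seed, {
    epochs <- lapply(seq_len(n_epochs), function(k) {
      X <- matrix(rnorm(p * m), p, m)
      V <- if (noise_sd > 0) matrix(rnorm(p * m, 0, noise_sd), p, m) else 0
      list(X = X, Y = A %*% X + V)
    })
    obs <- epoch_observations(epochs)
    attr(obs, "truth") <- rep(list(A), n_epochs)
    obs
  })
}

# Sparse truth matrix with given nonzero off-diagonal count.
make_sparse_truth <- function(p, nnz_offdiag, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(0, p, p)
    off <- which(row(A) != col(A))
    pos <- sample(off, nnz_offdiag)
    A[pos] <- runif(nnz_offdiag, 0.5, 1.5) * sample(c(-1, 1), nnz_offdiag, TRUE)
    diag(A) <- runif(p, -1, -0.1)
    A
  })
}
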