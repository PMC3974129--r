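#' Tracking options for the LASSO-Kalman filter/smoother
#'
#' Noise covariances are parametrized as scalar multiples of the identity:
#' process noise `Q = q_scale * I(p)` (how fast edge weights are allowed to
#' drift between epochs), observation noise `R = r_scale * I(m_k)`, and the
#' forward prior covariance `P0 = p0_scale * I(p)`. The backward pass starts
#' from a diffuse prior `p0_scale_backward * I(p)` at the last epoch so that
#' its estimate is driven by the data rather than the (unknown) terminal
#' state.
#'
#' @param lambda nonnegative sparsity weight of the l1 projection; scalar, or
#'   one value per gene when passed to [track_network()]. `0` disables the
#'   projection (classical Kalman filter).
#' @param q_scale nonnegative process-noise scale (default 1e-3: slow drift).
#' @param r_scale positive observation-noise scale (default 0.1).
#' @param p0_scale positive forward prior covariance scale (default 1).
#' @param p0_scale_backward positive diffuse prior scale for the backward
#'   filter (default 1e3).
#' @param lasso_tol convergence tolerance of the iterative projection solver.
#' @param lasso_max_iter iteration cap of the iterative projection solver.
#' @param method `"closed_form"` solves the projection exactly by
#'   soft-thresholding; `"ista"` runs the proximal-gradient iteration to
#'   `lasso_tol` behind the same interface.
#' @return list of class `track_options`.
#' @export
track_options <- function(lambda = 0, q_scale = 1e-3, r_scale = 0.1,
                          p0_scale = 1, p0_scale_backward = 1e3,
                          lasso_tol = 1e-8, lasso_max_iter = 1000L,
                          method = c("closed_form", "ista")) {
  method <- match.arg(method)
  stopifnot(
    all(lambda >= 0), all(is.finite(lambda)),
    q_scale >= 0, is.finite(q_scale),
    r_scale > 0, is.finite(r_scale),
    p0_scale > 0, p0_scale_backward > 0,
    lasso_tol > 0, lasso_max_iter >= 1
  )
  structure(
    list(
      lambda = lambda, q_scale = q_scale, r_scale = r_scale,
      p0_scale = p0_scale, p0_scale_backward = p0_scale_backward,
      lasso_tol = lasso_tol, lasso_max_iter = as.integer(lasso_max_iter),
      method = method
    ),
    class = "track_options"
  )
}

#' Construct a per-gene track state
#'
#' State of the random-walk model for one gene: `a` is the incoming-edge
#' vector (length `p`), `P` its error covariance, `Q` the process-noise
#' covariance. `R` may be a full `m_k` by `m_k` observation-noise covariance
#' or a positive scalar interpreted as `R = r * I(m_k)` (the epoch sizes may
#' vary). Symmetry is checked to 1e-8 and eigenvalues are required to be
#' above -1e-8.
#'
#' @param a numeric state vector (length `p`).
#' @param P numeric `p` by `p` covariance.
#' @param Q numeric `p` by `p` process-noise covariance.
#' @param R observation-noise covariance (matrix) or positive scalar scale.
#' @param gene_index optional gene label carried through error messages.
#' @return list of class `gene_track_state`.
#' @export
gene_track_state <- function(a, P, Q, R, gene_index = NA_integer_) {
  a <- as.numeric(a)
  p <- length(a)
  check_cov <- function(M, name) {
    if (!is.matrix(M) || nrow(M) != ncol(M)) stop(sprintf("%s must be square", name))
    if (max(abs(M - t(M))) > 1e-8) stop(sprintf("%s is not symmetric (tol 1e-8)", name))
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop(sprintf("%s is not PSD (min eigenvalue %.3g)", name, min(ev)))
    (M + t(M)) / 2
  }
  P <- check_cov(P, "P")
  Q <- check_cov(Q, "Q")
  if (nrow(P) != p || nrow(Q) != p) stop("P and Q must be p x p")
  if (is.matrix(R)) R <- check_cov(R, "R") else stopifnot(length(R) == 1, R > 0)
  structure(
    list(a = a, P = P, Q = Q, R = R, gene_index = gene_index),
    class = "gene_track_state"
  )
}

symmetrize <- function(M) (M + t(M)) / 2

#' Kalman prediction step (random-walk transition)
#'
#' The state transition is the identity plus zero-mean Gaussian drift, so
#' prediction leaves the estimate unchanged and inflates the covariance:
#' `a <- a`, `P <- P + Q`.
#'
#' @param state a [gene_track_state()].
#' @return updated `gene_track_state`.
#' @export
kalman_predict <- function(state) {
  state$P <- symmetrize(state$P + state$Q)
  state
}

#' Kalman measurement update
#'
#' Standard minimum-mean-square update for the observation `response =
#' design %*% a + v`, `v ~ N(0, R)`: gain `K = P H' (H P H' + R)^{-1}` with
#' `H = design`, then `a <- a + K (response - H a)` and `P <- (I - K H) P`
#' (symmetrized). The innovation system is solved with a linear solver, never
#' an explicit inverse.
#'
#' @param state a [gene_track_state()].
#' @param design numeric `m_k` by `p` matrix.
#' @param response numeric length-`m_k` vector.
#' @param epoch optional epoch label used in error messages.
#' @return updated `gene_track_state`.
#' @export
kalman_update <- function(state, design, response, epoch = NA) {
  H <- as.matrix(design)
  y <- as.numeric(response)
  m <- nrow(H)
  p <- length(state$a)
  if (ncol(H) != p || length(y) != m) stop("design/response dimensions inconsistent with state")
  R <- if (is.matrix(state$R)) state$R else diag(state$R, m)
  if (nrow(R) != m) stop(sprintf("R is %d x %d but epoch has m = %d", nrow(R), ncol(R), m))
  HP <- H %*% state$P
  S <- HP %*% t(H) + R
  Kt <- tryCatch(
    solve(S, HP),
    error = function(e) {
      stop(sprintf(
        "singular innovation matrix in Kalman update (gene %s, epoch %s): %s",
        state$gene_index, epoch, conditionMessage(e)
      ), call. = FALSE)
    }
  )
  K <- t(Kt)
  state$a <- state$a + drop(K %*% (y - drop(H %*% state$a)))
  state$P <- symmetrize(state$P - K %*% HP)
  state
}

#' Project an estimate onto sparse vectors (l1 proximal operator)
#'
#' Returns the exact minimizer of `||a_tilde - a||_2^2 + lambda * ||a||_1`.
#' The objective is separable, so the minimizer is elementwise
#' soft-thresholding at `lambda / 2`:
#' `a_j = sign(a_tilde_j) * max(|a_tilde_j| - lambda / 2, 0)`.
#' The covariance, when supplied, is passed through unmodified: the
#' projection constrains the state only. `method = "ista"` solves the same
#' problem by proximal-gradient iteration (kept behind the identical
#' interface for covariance-weighted variants of the objective).
#'
#' @param a_unconstrained numeric vector, the unconstrained estimate.
#' @param cov ignored (accepted for interface stability).
#' @param lambda nonnegative sparsity weight; `Inf` yields the zero vector.
#' @param opts [track_options()] controlling the solver.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' lasso_project(c(1, -0.2, 0.05), lambda = 0.5)  # 0.75 0 0
lasso_project <- function(a_unconstrained, cov = NULL, lambda,
                          opts = track_options()) {
  stopifnot(lambda >= 0)
  a <- as.numeric(a_unconstrained)
  if (lambda == 0) return(a)
  thr <- lambda / 2
  if (opts$method == "closed_form" || !is.finite(thr)) {
    return(sign(a) * pmax(abs(a) - thr, 0))
  }
  # ISTA on f(x) = ||a - x||^2 + lambda ||x||_1; Lipschitz constant of the
  # smooth part is 2, so the step is 1/2 and each iteration is
  # x <- soft(x - (x - a), lambda/4 * 2) = soft(a, lambda/2); converges in one
  # step here but the loop is kept for non-identity quadratic weights.
  x <- a
  for (it in seq_len(opts$lasso_max_iter)) {
    v <- x - (x - a)
    x_new <- sign(v) * pmax(abs(v) - thr, 0)
    if (max(abs(x_new - x)) < opts$lasso_tol) {
      return(x_new)
    }
    x <- x_new
  }
  x
}

#' Run the constrained (LASSO-)Kalman filter for one gene
#'
#' For epochs `k = 1..n`: predict under the random walk, update with the
#' epoch's observations, then project the estimate onto sparse vectors with
#' [lasso_project()]. With `lambda = 0` this is the classical Kalman filter.
#'
#' @param problems per-epoch `(design, response)` list from
#'   [extract_gene_problem()].
#' @param opts [track_options()]; `opts$lambda` must be a scalar here.
#' @param a0 initial state vector (length `p`); defaults to zeros.
#' @param gene_index optional label for error messages.
#' @return list of class `gene_trajectory` with `filtered` (list of `n` state
#'   vectors) and `filtered_cov` (list of `n` covariances); `smoothed` fields
#'   are `NULL`.
#' @export
filter_gene <- function(problems, opts = track_options(), a0 = NULL,
                        gene_index = NA_integer_) {
  n <- length(problems)
  if (n < 1) stop("need at least one epoch")
  p <- ncol(problems[[1]]$design)
  if (is.null(a0)) a0 <- rep(0, p)
  if (length(a0) != p) stop(sprintf("a0 has length %d, expected %d", length(a0), p))
  state <- gene_track_state(
    a = a0, P = diag(opts$p0_scale, p), Q = diag(opts$q_scale, p),
    R = opts$r_scale, gene_index = gene_index
  )
  filtered <- vector("list", n)
  filtered_cov <- vector("list", n)
  for (k in seq_len(n)) {
    state <- kalman_predict(state)
    state <- kalman_update(state, problems[[k]]$design, problems[[k]]$response,
                           epoch = k)
    state$a <- lasso_project(state$a, state$P, opts$lambda, opts)
    filtered[[k]] <- state$a
    filtered_cov[[k]] <- state$P
  }
  structure(
    list(filtered = filtered, filtered_cov = filtered_cov,
         smoothed = NULL, smoothed_cov = NULL, gene_index = gene_index),
    class = "gene_trajectory"
  )
}

# Invert a PSD covariance; regularize by +1e-10 I with a warning when the
# Cholesky route fails.
inv_psd <- function(M, what = "covariance") {
  out <- tryCatch(chol2inv(chol(symmetrize(M))), error = function(e) NULL)
  if (is.null(out)) {
    warning(sprintf("%s not invertible; regularizing with 1e-10 * I", what),
            call. = FALSE)
    out <- chol2inv(chol(symmetrize(M) + diag(1e-10, nrow(M))))
  }
  symmetrize(out)
}

#' Run the LASSO-Kalman forward-backward smoother for one gene
#'
#' Runs the constrained filter forward over epochs `1..n` and a second
#' constrained filter backward over epochs `n..1` (same equations, reversed
#' epoch order, diffuse prior `p0_scale_backward * I` and zero initial state),
#' then fuses the two per epoch by inverse-covariance (information)
#' weighting: `P_s = (P_f^-1 + P_b^-1)^-1`,
#' `a_s = P_s (P_f^-1 a_f + P_b^-1 a_b)`. The l1 projection is applied inside
#' each pass and once more to the fused estimate, so the smoothed snapshot is
#' exactly sparse; the price is a second shrinkage of the surviving weights
#' by `lambda / 2`. The fused covariance diagonal never exceeds the filtered
#' one.
#'
#' @inheritParams filter_gene
#' @return `gene_trajectory` with `filtered`, `filtered_cov`, `smoothed`,
#'   `smoothed_cov`, each of length `n`.
#' @export
smooth_gene <- function(problems, opts = track_options(), a0 = NULL,
                        gene_index = NA_integer_) {
  n <- length(problems)
  p <- ncol(problems[[1]]$design)
  fwd <- filter_gene(problems, opts, a0, gene_index)
  opts_b <- opts
  opts_b$p0_scale <- opts$p0_scale_backward
  bwd <- filter_gene(rev(problems), opts_b, rep(0, p), gene_index)
  smoothed <- vector("list", n)
  smoothed_cov <- vector("list", n)
  for (k in seq_len(n)) {
    kb <- n - k + 1L
    i_f <- inv_psd(fwd$filtered_cov[[k]], "forward covariance")
    i_b <- inv_psd(bwd$filtered_cov[[kb]], "backward covariance")
    P_s <- inv_psd(i_f + i_b, "fused information")
    a_s <- drop(P_s %*% (i_f %*% fwd$filtered[[k]] + i_b %*% bwd$filtered[[kb]]))
    smoothed[[k]] <- lasso_project(a_s, P_s, opts$lambda, opts)
    smoothed_cov[[k]] <- P_s
  }
  structure(
    list(filtered = fwd$filtered, filtered_cov = fwd$filtered_cov,
         smoothed = smoothed, smoothed_cov = smoothed_cov,
         gene_index = gene_index),
    class = "gene_trajectory"
  )
}

#' Track a whole network: per-gene smoothing stacked into A(k)
#'
#' Runs [smooth_gene()] (or [filter_gene()] when `smoothing = FALSE`)
#' independently for every gene and stacks gene `i`'s estimate at epoch `k`
#' into row `i` of the connectivity matrix `A(k)`. Genes are independent, so
#' the loop is parallelizable; results are identical for any worker count.
#' Per-gene failures are collected and the corresponding rows are `NA`.
#'
#' @param obs an [epoch_observations()] object.
#' @param opts [track_options()]. `opts$lambda` may be a scalar or one value
#'   per gene.
#' @param init optional `p` by `p` matrix of initial states (row `i` is gene
#'   `i`'s `a0`); zeros when absent. See [initial_condition()].
#' @param smoothing run the forward-backward smoother (default) or the
#'   forward filter only.
#' @param workers number of parallel workers (forked processes; 1 = serial).
#' @return object of class `network_trajectory`: list with `smoothed` and
#'   `filtered` (each a list of `n` signed `p` by `p` matrices; `smoothed` is
#'   `NULL` when `smoothing = FALSE`), `p`, `n_epochs`, `lambda` (per-gene
#'   vector) and `failures` (named list of error messages, empty on success).
#' @export
track_network <- function(obs, opts = track_options(), init = NULL,
                          smoothing = TRUE, workers = 1L) {
  stopifnot(inherits(obs, "epoch_observations"))
  p <- obs$p
  n <- obs$n_epochs
  lambda <- opts$lambda
  if (length(lambda) == 1) lambda <- rep(lambda, p)
  if (length(lambda) != p) stop("opts$lambda must be scalar or length p")
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (!all(dim(init) == c(p, p))) stop("init must be a p x p matrix")
  }
  run_one <- function(i) {
    o <- opts
    o$lambda <- lambda[i]
    a0 <- if (is.null(init)) NULL else init[i, ]
    probs <- extract_gene_problem(obs, i)
    tryCatch(
      if (smoothing) smooth_gene(probs, o, a0, i) else filter_gene(probs, o, a0, i),
      error = function(e) structure(conditionMessage(e), class = "track_failure")
    )
  }
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(p), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(p), run_one)
  }
  failures <- list()
  stack <- function(field) {
    lapply(seq_len(n), function(k) {
      A <- matrix(NA_real_, p, p)
      for (i in seq_len(p)) {
        if (!inherits(results[[i]], "track_failure")) {
          A[i, ] <- results[[i]][[field]][[k]]
        }
      }
      A
    })
  }
  for (i in seq_len(p)) {
    if (inherits(results[[i]], "track_failure")) {
      failures[[as.character(i)]] <- unclass(results[[i]])
    }
  }
  structure(
    list(
      smoothed = if (smoothing) stack("smoothed") else NULL,
      filtered = stack("filtered"),
      p = p, n_epochs = n, lambda = lambda, failures = failures
    ),
    class = "network_trajectory"
  )
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf(
    "<network_trajectory> p = %d, %d epochs, %s%s\n",
    x$p, x$n_epochs,
    if (is.null(x$smoothed)) "filtered only" else "smoothed + filtered",
    if (length(x$failures)) sprintf(" (%d gene failures)", length(x$failures)) else ""
  ))
  invisible(x)
}
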