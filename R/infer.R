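#' Infer a time-varying network end to end
#'
#' Convenience wrapper tying the pieces together for one data set: per gene,
#' pool all epochs into the static regression, select the sparsity weight by
#' two-step GCV (unless `lambda` is fixed), build the static l1-penalized
#' initial state, and run the constrained Kalman smoother (or filter). The
#' same per-gene lambda is used for the static initial fit and for the
#' projection at every epoch.
#'
#' The GCV-selected weight lives on the scale of the pooled regression, whose
#' quadratic term has curvature `X'X ~ N I` for `N` pooled samples, while the
#' per-epoch projection objective `||a_tilde - a||_2^2 + lambda ||a||_1` has
#' identity curvature. For an orthonormalized design the regression LASSO
#' soft-thresholds the least-squares coefficients at `lambda / (2N)`, so the
#' regression penalty `lambda*` is converted to its projection-scale
#' equivalent `lambda* / N` before tracking; the static initial fit keeps the
#' regression scale. A `lambda` supplied by the user is taken on the
#' projection scale and converted the other way (`N * lambda`) for the
#' initial fit.
#'
#' @param obs an [epoch_observations()] object.
#' @param lambda `NULL` (default) selects lambda per gene by GCV; a
#'   nonnegative scalar fixes it for all genes; a length-`p` vector fixes it
#'   per gene. Fixed values are on the projection scale (threshold
#'   `lambda / 2`).
#' @param smoothing run the forward-backward smoother (default) or the
#'   forward filter only.
#' @param init `"ml"` (default) starts each gene from the static l1-penalized
#'   estimate at its lambda; `"zero"` starts from the origin; a `p` by `p`
#'   matrix supplies explicit initial states.
#' @param opts [track_options()] for the noise scales; its `lambda` field is
#'   overridden by the selection above.
#' @param workers parallel workers for the per-gene loop.
#' @return a [track_network()] `network_trajectory`.
#' @export
#' @examples
#' inst <- simulate_instance(sim_config(p = 6, n_epochs = 3, seed = 7))
#' traj <- infer_network(inst$obs)
#' traj$smoothed[[3]]
infer_network <- function(obs, lambda = NULL, smoothing = TRUE, init = "ml",
                          opts = track_options(), workers = 1L) {
  stopifnot(inherits(obs, "epoch_observations"))
  p <- obs$p
  n_pooled <- sum(obs$m)
  if (is.null(lambda)) {
    lambda_reg <- vapply(seq_len(p), function(i) {
      pooled <- pool_gene_problem(extract_gene_problem(obs, i))
      select_lambda(pooled$design, pooled$response)$lambda_star
    }, numeric(1))
    lambda <- lambda_reg / n_pooled
  } else {
    if (length(lambda) == 1) lambda <- rep(lambda, p)
    lambda_reg <- lambda * n_pooled
  }
  if (length(lambda) != p) stop("lambda must be NULL, scalar, or length p")
  init_mat <- if (is.matrix(init)) {
    init
  } else if (identical(init, "ml")) {
    initial_condition(obs, lambda_init = lambda_reg)
  } else if (identical(init, "zero")) {
    NULL
  } else {
    stop('init must be "ml", "zero", or a p x p matrix')
  }
  opts$lambda <- lambda
  track_network(obs, opts, init = init_mat, smoothing = smoothing,
                workers = workers)
}
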