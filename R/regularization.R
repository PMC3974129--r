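# Sparsity-weight selection by generalized cross-validation and the static
# l1-penalized initial condition.

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("lassokalman.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
}

#' Smallest lambda giving the all-zero LASSO solution
#'
#' For the objective `||y - X b||_2^2 + lambda ||b||_1` the zero vector is
#' optimal iff `lambda >= 2 * max |X' y|`.
#'
#' @param design numeric `N` by `p` matrix.
#' @param response numeric length-`N` vector.
#' @return nonnegative scalar.
#' @export
lambda_max <- function(design, response) {
  2 * max(abs(crossprod(design, response)))
}

# Fit the LASSO min ||y - X b||^2 + lambda ||b||_1 at one or more lambda
# values; returns a p x length(lambda) coefficient matrix (columns in the
# order of `lambda`). glmnet minimizes RSS/(2N) + lambda_glmnet ||b||_1, so
# lambda_glmnet = lambda / (2N). lambda = 0 falls back to (min-norm) least
# squares; lambda >= lambda_max short-circuits to zero.
lasso_fit <- function(design, response, lambda, thresh = 1e-11) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  N <- nrow(X)
  p <- ncol(X)
  out <- matrix(0, p, length(lambda))
  lmax <- lambda_max(X, y)
  trivial <- lambda >= lmax | !is.finite(lambda)
  ls_cols <- lambda == 0
  if (any(ls_cols)) {
    b <- if (N >= p) {
      qr.coef(qr(X), y)
    } else {
      # min-norm solution of the underdetermined system
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-12
      sv$v[, pos, drop = FALSE] %*% ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    }
    b[is.na(b)] <- 0
    out[, ls_cols] <- b
  }
  todo <- which(!trivial & !ls_cols)
  if (length(todo) > 0) {
    if (N < 2) stop("LASSO fit at 0 < lambda < lambda_max needs at least 2 samples")
    lam <- lambda[todo]
    # decreasing path anchored at lambda_max for warm starts
    path <- sort(unique(c(lmax * 0.999, lam)), decreasing = TRUE)
    fit <- glmnet::glmnet(
      X, y, family = "gaussian", alpha = 1,
      lambda = path / (2 * N), standardize = FALSE, intercept = FALSE,
      thresh = thresh, maxit = 10^6
    )
    beta <- as.matrix(fit$beta)
    idx <- match(lam / (2 * N), fit$lambda)
    # match with tolerance: glmnet stores the given sequence, but guard
    # against representation drift
    if (anyNA(idx)) {
      idx <- vapply(lam / (2 * N), function(l) which.min(abs(fit$lambda - l)), 1L)
    }
    out[, todo] <- beta[, idx, drop = FALSE]
  }
  out
}

#' Generalized cross-validation statistic for a LASSO fit
#'
#' Fits the LASSO of `response` on `design` at `lambda` and returns
#' `GCV(lambda) = (RSS / N) / (1 - d / N)^2`, where the effective number of
#' parameters `d` is the number of nonzero fitted coefficients. When
#' `d >= N` the statistic is `+Inf` (the saturated guard; never a division
#' by zero).
#'
#' @param design numeric `N` by `p` matrix.
#' @param response numeric length-`N` vector.
#' @param lambda nonnegative scalar.
#' @return scalar GCV value (possibly `Inf`).
#' @export
gcv_statistic <- function(design, response, lambda) {
  gcv_path(design, response, lambda)
}

# Vectorized GCV over a lambda grid (one glmnet path call).
gcv_path <- function(design, response, lambdas) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  N <- nrow(X)
  if (N < 1) stop("need at least one sample")
  beta <- lasso_fit(X, y, lambdas)
  resid <- y - X %*% beta
  rss <- colSums(resid^2)
  d <- colSums(beta != 0)
  gcv <- ifelse(d >= N, Inf, (rss / N) / (1 - d / N)^2)
  if (any(d >= N)) {
    log_info("GCV saturated (d >= N) at %d of %d lambda values", sum(d >= N), length(lambdas))
  }
  unname(gcv)
}

#' Two-step coarse/fine GCV search for the sparsity weight
#'
#' Evaluates the GCV statistic on a coarse lambda grid to locate the
#' neighbourhood of the optimum, then on a fine grid spanning the two coarse
#' neighbours of the coarse minimizer, and returns the fine minimizer. Ties
#' are broken toward the larger lambda (the sparser solution).
#'
#' @param design numeric `N` by `p` matrix.
#' @param response numeric length-`N` vector.
#' @param coarse_grid strictly increasing nonnegative lambda grid; default is
#'   20 logarithmically spaced values on `[1e-4 * lambda_max, lambda_max]`.
#' @param refine_factor number of fine-grid points (default 20).
#' @return object of class `gcv_result`: list with `lambda_grid_coarse`,
#'   `gcv_coarse`, `lambda_grid_fine`, `gcv_fine`, `lambda_star`.
#' @export
select_lambda <- function(design, response, coarse_grid = NULL,
                          refine_factor = 20L) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  refine_factor <- as.integer(refine_factor)
  stopifnot(refine_factor >= 1)
  if (is.null(coarse_grid)) {
    lmax <- lambda_max(X, y)
    if (lmax <= 0) lmax <- 1 # degenerate response: every lambda fits zero
    coarse_grid <- exp(seq(log(1e-4 * lmax), log(lmax), length.out = 20))
  }
  if (length(coarse_grid) < 1 || any(coarse_grid < 0) ||
      is.unsorted(coarse_grid, strictly = length(coarse_grid) > 1)) {
    stop("coarse_grid must be nonempty, nonnegative and strictly increasing")
  }
  argmin_tie_large <- function(g) {
    fin <- is.finite(g)
    if (!any(fin)) return(NA_integer_)
    mn <- min(g[fin])
    tol <- max(1e-12, abs(mn) * 1e-10)
    max(which(g <= mn + tol))
  }
  g_coarse <- gcv_path(X, y, coarse_grid)
  i <- argmin_tie_large(g_coarse)
  if (is.na(i)) stop("GCV is infinite on the whole grid; data cannot support lambda selection")
  lo <- coarse_grid[max(i - 1L, 1L)]
  hi <- coarse_grid[min(i + 1L, length(coarse_grid))]
  fine_grid <- if (hi > lo) {
    if (lo > 0) {
      exp(seq(log(lo), log(hi), length.out = refine_factor))
    } else {
      seq(lo, hi, length.out = refine_factor)
    }
  } else {
    coarse_grid[i]
  }
  # keep the coarse minimizer in play so refinement can never do worse
  fine_grid <- sort(unique(c(fine_grid, coarse_grid[i])))
  g_fine <- gcv_path(X, y, fine_grid)
  j <- argmin_tie_large(g_fine)
  if (is.na(j)) { # saturated fine pass: fall back to the coarse minimizer
    fine_grid <- coarse_grid[i]
    g_fine <- g_coarse[i]
    j <- 1L
  }
  structure(
    list(
      lambda_grid_coarse = coarse_grid, gcv_coarse = g_coarse,
      lambda_grid_fine = fine_grid, gcv_fine = g_fine,
      lambda_star = fine_grid[j]
    ),
    class = "gcv_result"
  )
}

#' @export
print.gcv_result <- function(x, ...) {
  cat(sprintf(
    "<gcv_result> lambda* = %.5g (coarse grid [%g, %g], %d fine points)\n",
    x$lambda_star, min(x$lambda_grid_coarse), max(x$lambda_grid_coarse),
    length(x$lambda_grid_fine)
  ))
  invisible(x)
}

#' Static l1-penalized initial network estimate
#'
#' Pools the observation columns of every epoch into one static regression
#' per gene (design: all samples by `p`; response: the gene's pooled
#' perturbation-corrected derivatives) and solves the l1-penalized
#' least-squares estimate at `lambda_init`. Row `i` of the returned matrix is
#' the initial state `a0` for gene `i`'s tracker; starting from this educated
#' guess instead of zeros makes the filter converge within the few available
#' epochs.
#'
#' @param obs an [epoch_observations()] object.
#' @param lambda_init nonnegative penalty for the static fit; `0` gives
#'   (min-norm) least squares; a vector gives one value per gene.
#' @return numeric `p` by `p` matrix.
#' @export
initial_condition <- function(obs, lambda_init = 0) {
  stopifnot(inherits(obs, "epoch_observations"))
  p <- obs$p
  if (sum(obs$m) < 1) stop("need at least one pooled sample")
  lambda_init <- if (length(lambda_init) == 1) rep(lambda_init, p) else lambda_init
  if (length(lambda_init) != p) stop("lambda_init must be scalar or length p")
  A0 <- matrix(0, p, p)
  for (i in seq_len(p)) {
    pooled <- pool_gene_problem(extract_gene_problem(obs, i))
    A0[i, ] <- lasso_fit(pooled$design, pooled$response, lambda_init[i])[, 1]
  }
  A0
}
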