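#' Construct an expression time series
#'
#' Container for a genes-by-samples expression matrix, its time labels and an
#' optional known external perturbation. The perturbation enters the linear
#' expression model as `b[i] * u(t)`: `u` is the shared perturbation signal
#' over time and `b` the per-gene response coefficient, and it is subtracted
#' from the expression derivative when observations are built (see
#' [build_observations()]).
#'
#' Rows with missing values are rejected rather than imputed; drop incomplete
#' genes upstream.
#'
#' @param values numeric matrix, `p` genes (rows) by `T` samples (columns),
#'   `p >= 2`, `T >= 2`, no missing values.
#' @param time_labels length-`T` vector of time labels. Numeric labels must be
#'   strictly increasing and are used as actual time points for derivative
#'   estimation; non-numeric labels imply unit spacing.
#' @param perturbation_u optional length-`T` numeric perturbation signal.
#' @param perturbation_b optional length-`p` numeric per-gene perturbation
#'   coefficients; required when `perturbation_u` is given.
#' @return An object of class `expression_series` with elements `values`,
#'   `time_labels`, `times` (numeric times or `NULL`), `perturbation_u`,
#'   `perturbation_b`.
#' @seealso [estimate_derivatives()], [build_observations()],
#'   [read_expression_tsv()]
#' @export
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)
#' es <- expression_series(x, time_labels = 1:5)
expression_series <- function(values, time_labels = NULL,
                              perturbation_u = NULL, perturbation_b = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  p <- nrow(values)
  n_t <- ncol(values)
  if (p < 2) stop("expression matrix must have at least 2 genes (rows)")
  if (n_t < 2) stop("expression matrix must have at least 2 samples (columns)")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "missing/non-finite expression value at gene %d, sample %d; drop incomplete rows before ingestion",
      bad[1], bad[2]
    ))
  }
  if (is.null(time_labels)) time_labels <- colnames(values)
  if (is.null(time_labels)) time_labels <- seq_len(n_t)
  if (length(time_labels) != n_t) {
    stop(sprintf("time_labels has length %d, expected %d", length(time_labels), n_t))
  }
  times <- suppressWarnings(as.numeric(as.character(time_labels)))
  if (anyNA(times)) {
    times <- NULL
  } else {
    bad <- which(diff(times) <= 0)
    if (length(bad) > 0) {
      stop(sprintf(
        "numeric time labels must be strictly increasing; violated at index %d (%g followed by %g)",
        bad[1] + 1, times[bad[1]], times[bad[1] + 1]
      ))
    }
  }
  if (!is.null(perturbation_u)) {
    if (is.null(perturbation_b)) {
      stop("perturbation_b must be supplied together with perturbation_u")
    }
    if (length(perturbation_u) != n_t) {
      stop(sprintf("perturbation_u has length %d, expected %d", length(perturbation_u), n_t))
    }
    if (length(perturbation_b) != p) {
      stop(sprintf("perturbation_b has length %d, expected %d", length(perturbation_b), p))
    }
    perturbation_u <- as.numeric(perturbation_u)
    perturbation_b <- as.numeric(perturbation_b)
  } else if (!is.null(perturbation_b)) {
    stop("perturbation_u must be supplied together with perturbation_b")
  }
  structure(
    list(
      values = values, time_labels = time_labels, times = times,
      perturbation_u = perturbation_u, perturbation_b = perturbation_b
    ),
    class = "expression_series"
  )
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf(
    "<expression_series> %d genes x %d samples%s%s\n",
    nrow(x$values), ncol(x$values),
    if (is.null(x$times)) " (non-numeric time labels, unit spacing)" else "",
    if (is.null(x$perturbation_u)) "" else ", with perturbation signal"
  ))
  invisible(x)
}

#' Estimate expression derivatives by forward differences
#'
#' Approximates the rate of change of each gene's expression with first-order
#' forward differences, `(x[, k + 1] - x[, k]) / dt[k]`, using the actual time
#' spacing when the series carries numeric time labels and unit spacing
#' otherwise. The last sample has no forward neighbour, so the result has one
#' column fewer than the input.
#'
#' @param series an [expression_series()].
#' @return numeric matrix, `p` by `T - 1`, derivative estimates at the first
#'   `T - 1` sample times.
#' @export
#' @examples
#' es <- expression_series(rbind(0:3, (0:3)^2), time_labels = 0:3)
#' estimate_derivatives(es)  # rows: 1 1 1 and 1 3 5
estimate_derivatives <- function(series) {
  stopifnot(inherits(series, "expression_series"))
  v <- series$values
  n_t <- ncol(v)
  dt <- if (!is.null(series$times)) diff(series$times) else rep(1, n_t - 1)
  d <- (v[, -1, drop = FALSE] - v[, -n_t, drop = FALSE]) /
    matrix(dt, nrow = nrow(v), ncol = n_t - 1, byrow = TRUE)
  rownames(d) <- rownames(v)
  d
}

#' Group samples into per-epoch observation matrices
#'
#' Builds, for each epoch `k`, the design matrix `X(k)` (expression snapshots
#' in columns) and response matrix `Y(k)` (perturbation-corrected expression
#' derivatives) of the linear observation model `Y(k) = A(k) X(k) + V(k)`.
#' Sample `j` contributes column `x[, j]` to its epoch's `X` and
#' `xdot[, j] - b * u[j]` to its epoch's `Y`. Because the forward-difference
#' derivative loses the final sample, only the first `T - 1` samples are
#' usable.
#'
#' @param series an [expression_series()].
#' @param epoch_assignment integer vector of length `T - 1` assigning each
#'   usable sample to an epoch; must be non-decreasing, contiguous and start
#'   at 1. `NULL` groups samples into consecutive blocks of `m_per_epoch`
#'   (a short remainder is merged into the final epoch).
#' @param m_per_epoch block size for the default uniform grouping. The default
#'   3 matches grouping a developmental time course into one network per three
#'   consecutive samples.
#' @return An `epoch_observations` object: list with `epochs` (each a list
#'   with matrices `X` and `Y`, both `p` by `m_k`), `p`, `n_epochs`, `m` (the
#'   per-epoch counts).
#' @export
build_observations <- function(series, epoch_assignment = NULL, m_per_epoch = 3) {
  stopifnot(inherits(series, "expression_series"))
  xdot <- estimate_derivatives(series)
  n_use <- ncol(xdot)
  if (is.null(epoch_assignment)) {
    m_per_epoch <- as.integer(m_per_epoch)
    if (m_per_epoch < 1) stop("m_per_epoch must be >= 1")
    n_ep <- max(1L, n_use %/% m_per_epoch)
    epoch_assignment <- pmin(((seq_len(n_use) - 1L) %/% m_per_epoch) + 1L, n_ep)
  }
  epoch_assignment <- as.integer(epoch_assignment)
  if (length(epoch_assignment) != n_use) {
    stop(sprintf(
      "epoch_assignment has length %d; expected one id per usable sample (%d)",
      length(epoch_assignment), n_use
    ))
  }
  if (epoch_assignment[1] != 1L || any(diff(epoch_assignment) < 0L)) {
    stop("epoch ids must form a non-decreasing sequence starting at 1")
  }
  if (any(diff(epoch_assignment) > 1L)) {
    stop("epoch ids must be contiguous (no empty epochs)")
  }
  n_ep <- epoch_assignment[n_use]
  correction <- if (!is.null(series$perturbation_u)) {
    outer(series$perturbation_b, series$perturbation_u[seq_len(n_use)])
  } else {
    0
  }
  y_all <- xdot - correction
  x_all <- series$values[, seq_len(n_use), drop = FALSE]
  epochs <- lapply(seq_len(n_ep), function(k) {
    j <- which(epoch_assignment == k)
    list(X = x_all[, j, drop = FALSE], Y = y_all[, j, drop = FALSE])
  })
  epoch_observations(epochs)
}

#' Construct an epoch observation set
#'
#' Low-level constructor validating a list of per-epoch `(X, Y)` matrix pairs.
#' Normally produced by [build_observations()] or [generate_observations()].
#'
#' @param epochs list; each element a list with numeric matrices `X` and `Y`
#'   of identical dimension `p` by `m_k`, `m_k >= 1`.
#' @return `epoch_observations` object.
#' @export
epoch_observations <- function(epochs) {
  if (length(epochs) < 1) stop("need at least one epoch")
  p <- nrow(epochs[[1]]$X)
  m <- integer(length(epochs))
  for (k in seq_along(epochs)) {
    e <- epochs[[k]]
    if (is.null(e$X) || is.null(e$Y)) stop(sprintf("epoch %d lacks X or Y", k))
    if (!identical(dim(e$X), dim(e$Y))) {
      stop(sprintf("epoch %d: X and Y dimensions differ", k))
    }
    if (nrow(e$X) != p) stop(sprintf("epoch %d: gene count differs from epoch 1", k))
    if (ncol(e$X) < 1) stop(sprintf("epoch %d is empty (m_k must be >= 1)", k))
    m[k] <- ncol(e$X)
  }
  structure(
    list(epochs = epochs, p = p, n_epochs = length(epochs), m = m),
    class = "epoch_observations"
  )
}

#' @export
print.epoch_observations <- function(x, ...) {
  cat(sprintf(
    "<epoch_observations> p = %d genes, %d epochs, m = [%s]\n",
    x$p, x$n_epochs, paste(x$m, collapse = ", ")
  ))
  invisible(x)
}

#' Extract the per-gene tracking problem
#'
#' The network observation model decomposes into `p` independent per-gene
#' regressions: row `i` of `Y(k)` equals `a_i(k)' X(k)` plus noise, where
#' `a_i(k)` is gene `i`'s incoming-edge vector. This returns, per epoch, the
#' design matrix `t(X(k))` (samples by genes) and the response vector (row
#' `gene_index` of `Y(k)`) consumed by [filter_gene()] and [smooth_gene()].
#'
#' @param obs an [epoch_observations()] object.
#' @param gene_index integer in `1..p`.
#' @return list of length `n_epochs`; each element a list with `design`
#'   (`m_k` by `p` matrix) and `response` (length `m_k` vector).
#' @export
extract_gene_problem <- function(obs, gene_index) {
  stopifnot(inherits(obs, "epoch_observations"))
  gene_index <- as.integer(gene_index)
  if (gene_index < 1L || gene_index > obs$p) {
    stop(sprintf("gene_index %d out of range 1..%d", gene_index, obs$p))
  }
  lapply(obs$epochs, function(e) {
    list(design = t(e$X), response = as.numeric(e$Y[gene_index, ]))
  })
}

# Pool all epochs of one gene's problem into one static regression
# (design: sum(m_k) x p; response: pooled y). Used by GCV selection and the
# static initial condition.
pool_gene_problem <- function(problems) {
  design <- do.call(rbind, lapply(problems, `[[`, "design"))
  response <- unlist(lapply(problems, `[[`, "response"), use.names = FALSE)
  list(design = design, response = response)
}
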