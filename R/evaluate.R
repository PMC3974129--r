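# Evaluation machinery: alpha-vicinity edge error, presence/absence
# confusion metrics, simulation sweeps, and temporal topology statistics.

#' Edge-prediction error rate under the alpha-vicinity criterion
#'
#' An estimated edge is counted correct iff it lies within
#' `alpha * |a_ij|` of the true edge value, i.e. an error is scored when
#' `|a_ij - ahat_ij| > alpha * |a_ij|`. Applied literally at `a_ij = 0` the
#' vicinity degenerates to a point: any nonzero estimate of a zero edge is an
#' error and an exact zero is correct.
#'
#' @param true_A,est_A numeric matrices of identical shape.
#' @param alpha nonnegative tolerance fraction; default 0.2 (a +-20% band
#'   around the true value).
#' @return fraction of entries in error, in \[0, 1\].
#' @export
edge_error_rate <- function(true_A, est_A, alpha = 0.2) {
  stopifnot(all(dim(true_A) == dim(est_A)), alpha >= 0)
  mean(abs(true_A - est_A) > alpha * abs(true_A))
}

#' Presence/absence confusion metrics over a network sequence
#'
#' Binarizes truth and estimate at `|entry| > presence_threshold`, pools all
#' epochs and matrix entries, and reports the confusion counts as percentages
#' of all scored edges together with sensitivity, specificity, accuracy and
#' precision. Sign and strength of interactions are ignored. A ratio whose
#' denominator is empty is returned as `NA` and named in `undefined`.
#'
#' @param true_seq,est_seq equal-length lists of equal-shape matrices (or
#'   single matrices).
#' @param presence_threshold absolute strength below which an edge counts as
#'   absent; default 1e-3.
#' @return object of class `confusion_report`: `tp`, `tn`, `fp`, `fn`
#'   (percentages summing to 100), `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, `n_edges` (pooled count), `undefined` (character vector).
#' @export
confusion_metrics <- function(true_seq, est_seq, presence_threshold = 1e-3) {
  if (is.matrix(true_seq)) true_seq <- list(true_seq)
  if (is.matrix(est_seq)) est_seq <- list(est_seq)
  stopifnot(length(true_seq) == length(est_seq), length(true_seq) >= 1)
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (k in seq_along(true_seq)) {
    stopifnot(all(dim(true_seq[[k]]) == dim(est_seq[[k]])))
    tr <- abs(true_seq[[k]]) > presence_threshold
    es <- abs(est_seq[[k]]) > presence_threshold
    counts["tp"] <- counts["tp"] + sum(tr & es)
    counts["tn"] <- counts["tn"] + sum(!tr & !es)
    counts["fp"] <- counts["fp"] + sum(!tr & es)
    counts["fn"] <- counts["fn"] + sum(tr & !es)
  }
  confusion_report_from_counts(counts)
}

confusion_report_from_counts <- function(counts) {
  total <- sum(counts)
  pct <- 100 * counts / total
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(counts["tp"], counts["tp"] + counts["fn"])
  spec <- ratio(counts["tn"], counts["tn"] + counts["fp"])
  prec <- ratio(counts["tp"], counts["tp"] + counts["fp"])
  acc <- ratio(counts["tp"] + counts["tn"], total)
  undefined <- c("sensitivity", "specificity", "precision", "accuracy")[
    is.na(c(sens, spec, prec, acc))
  ]
  structure(
    list(
      tp = unname(pct["tp"]), tn = unname(pct["tn"]),
      fp = unname(pct["fp"]), fn = unname(pct["fn"]),
      sensitivity = unname(sens), specificity = unname(spec),
      accuracy = unname(acc), precision = unname(prec),
      n_edges = unname(total), undefined = undefined,
      counts = counts
    ),
    class = "confusion_report"
  )
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<confusion_report> %d scored edges\n",
      "  TP %.2f%%  TN %.2f%%  FP %.2f%%  FN %.2f%%\n",
      "  sensitivity %.3f  specificity %.3f  accuracy %.3f  precision %.3f\n"
    ),
    x$n_edges, x$tp, x$tn, x$fp, x$fn,
    x$sensitivity, x$specificity, x$accuracy, x$precision
  ))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Benchmark the three tracker variants on a simulated ensemble
#'
#' Simulates `n_networks` independent instances of the standard benchmark
#' condition (see [scenario_table1()]), tracks each with (a) the smoothed
#' LASSO-Kalman (GCV-selected lambda, static l1 initial condition), (b) the
#' unsmoothed (filter-only) LASSO-Kalman from the same run, and (c) the
#' classical Kalman filter (lambda = 0, least-squares initial condition), and
#' pools presence/absence confusion counts across all networks, epochs and
#' entries. One instance is materialized at a time.
#'
#' @param n_networks ensemble size.
#' @param seed integer base seed.
#' @param presence_threshold binarization threshold (default 1e-3).
#' @param alpha tolerance of the edge-error criterion also accumulated per
#'   variant.
#' @param opts [track_options()] noise scales.
#' @param workers parallel workers forwarded to the per-gene loop.
#' @param ... overrides forwarded to [sim_config()] (e.g. `p`, `m_per_epoch`).
#' @return list with one [confusion_metrics()] `confusion_report` per variant
#'   (`smoothed`, `filtered`, `classical`), a matching `edge_error` vector of
#'   mean alpha-vicinity error rates, and `n_networks`.
#' @export
benchmark_tracking <- function(n_networks, seed = 1L, presence_threshold = 1e-3,
                               alpha = 0.2, opts = track_options(),
                               workers = 1L, ...) {
  cfgs <- scenario_table1(n_networks, seed = seed, ...)
  variants <- c("smoothed", "filtered", "classical")
  counts <- lapply(variants, function(v) c(tp = 0, tn = 0, fp = 0, fn = 0))
  names(counts) <- variants
  err_sum <- c(smoothed = 0, filtered = 0, classical = 0)
  for (cfg in cfgs) {
    inst <- simulate_instance(cfg)
    traj <- infer_network(inst$obs, lambda = NULL, smoothing = TRUE,
                          init = "ml", opts = opts, workers = workers)
    classical <- infer_network(inst$obs, lambda = 0, smoothing = FALSE,
                               init = "ml", opts = opts, workers = workers)
    est <- list(
      smoothed = traj$smoothed,
      filtered = traj$filtered,
      classical = classical$filtered
    )
    for (v in variants) {
      rep_v <- confusion_metrics(inst$networks, est[[v]], presence_threshold)
      counts[[v]] <- counts[[v]] + rep_v$counts
      err_sum[v] <- err_sum[v] + mean(vapply(
        seq_along(inst$networks),
        function(k) edge_error_rate(inst$networks[[k]], est[[v]][[k]], alpha),
        numeric(1)
      ))
    }
  }
  out <- lapply(counts, confusion_report_from_counts)
  out$edge_error <- err_sum / length(cfgs)
  out$n_networks <- length(cfgs)
  out
}

#' Mean edge error as a function of network size
#'
#' For each size `p`, simulates `reps` instances with
#' `m = round(obs_fraction * p)` observation columns per epoch, infers the
#' network with the smoothed tracker (GCV lambda, static l1 initial
#' condition) and scores the alpha-vicinity error averaged over epochs.
#'
#' @param sizes integer vector of network sizes (each >= 2).
#' @param obs_fraction observations per epoch as a fraction of `p`
#'   (default 0.7).
#' @param reps replicates per size.
#' @param seed integer base seed.
#' @param alpha edge-error tolerance (default 0.2).
#' @param n_epochs epochs per instance (default 5).
#' @param opts,workers forwarded to [infer_network()].
#' @param ... further [sim_config()] overrides.
#' @return data.frame with columns `size`, `mean_error`, `sd_error`, `reps`.
#' @export
sweep_network_size <- function(sizes, obs_fraction = 0.7, reps = 5, seed = 1L,
                               alpha = 0.2, n_epochs = 5L,
                               opts = track_options(), workers = 1L, ...) {
  stopifnot(all(sizes >= 2))
  counter <- 0L
  rows <- lapply(sizes, function(p) {
    errs <- vapply(seq_len(reps), function(r) {
      counter <<- counter + 1L
      cfg <- sim_config(
        p = p, n_epochs = n_epochs,
        m_per_epoch = max(1L, round(obs_fraction * p)),
        seed = as.integer(seed) + 2L * counter, ...
      )
      mean_instance_error(cfg, alpha, opts, workers)
    }, numeric(1))
    data.frame(size = p, mean_error = mean(errs), sd_error = stats::sd(errs),
               reps = reps)
  })
  do.call(rbind, rows)
}

#' Mean edge error as a function of the observation count
#'
#' Fixed network size `p`, varying number of observation columns per epoch.
#'
#' @param p network size.
#' @param m_values integer vector of per-epoch observation counts (each
#'   >= 1).
#' @inheritParams sweep_network_size
#' @return data.frame with columns `m`, `mean_error`, `sd_error`, `reps`.
#' @export
sweep_observation_count <- function(p, m_values, reps = 5, seed = 1L,
                                    alpha = 0.2, n_epochs = 5L,
                                    opts = track_options(), workers = 1L, ...) {
  stopifnot(all(m_values >= 1))
  counter <- 0L
  rows <- lapply(m_values, function(m) {
    errs <- vapply(seq_len(reps), function(r) {
      counter <<- counter + 1L
      cfg <- sim_config(
        p = p, n_epochs = n_epochs, m_per_epoch = m,
        seed = as.integer(seed) + 2L * counter, ...
      )
      mean_instance_error(cfg, alpha, opts, workers)
    }, numeric(1))
    data.frame(m = m, mean_error = mean(errs), sd_error = stats::sd(errs),
               reps = reps)
  })
  do.call(rbind, rows)
}

mean_instance_error <- function(cfg, alpha, opts, workers) {
  inst <- simulate_instance(cfg)
  traj <- infer_network(inst$obs, lambda = NULL, smoothing = TRUE,
                        init = "ml", opts = opts, workers = workers)
  mean(vapply(seq_along(inst$networks), function(k) {
    edge_error_rate(inst$networks[[k]], traj$smoothed[[k]], alpha)
  }, numeric(1)))
}

# Symmetrized binarized adjacency (undirected presence graph, no self loops).
presence_graph <- function(est, presence_threshold) {
  B <- (abs(est) > presence_threshold) | (t(abs(est)) > presence_threshold)
  diag(B) <- FALSE
  B * 1L
}

#' Degree of every gene across epochs
#'
#' Per epoch, the degree of gene `i` is the number of above-threshold edges
#' incident to it in the symmetrized, binarized network snapshot.
#'
#' @param est_seq list of estimated `p` by `p` matrices (or a single matrix).
#' @param presence_threshold binarization threshold (default 1e-3).
#' @return integer matrix, genes by epochs.
#' @export
degree_trajectories <- function(est_seq, presence_threshold = 1e-3) {
  if (is.matrix(est_seq)) est_seq <- list(est_seq)
  out <- vapply(est_seq, function(A) {
    rowSums(presence_graph(A, presence_threshold))
  }, numeric(nrow(est_seq[[1]])))
  dn <- if (is.null(rownames(est_seq[[1]]))) NULL else list(rownames(est_seq[[1]]), NULL)
  matrix(as.integer(out), nrow = nrow(est_seq[[1]]), dimnames = dn)
}

#' Power-law exponent of the degree distribution
#'
#' Maximum-likelihood exponent of the discrete power law
#' `P(d) = d^-alpha / zeta(alpha)` fitted to the positive degrees of the
#' symmetrized binarized snapshot with `xmin = 1`. The likelihood is
#' maximized numerically (the zeta function evaluated by truncated series).
#' Degenerate degree sequences (fewer than two distinct positive degrees)
#' yield `NA` with a warning: a single-valued (regular) degree sequence pins
#' the fit to the boundary and carries no slope information.
#'
#' @param est estimated `p` by `p` matrix.
#' @param presence_threshold binarization threshold (default 1e-3).
#' @return scalar exponent estimate, or `NA` for a degenerate sequence.
#' @export
powerlaw_exponent <- function(est, presence_threshold = 1e-3) {
  d <- rowSums(presence_graph(est, presence_threshold))
  d <- d[d > 0]
  if (length(unique(d)) < 2) {
    warning("degenerate degree sequence: need >= 2 distinct positive degrees",
            call. = FALSE)
    return(NA_real_)
  }
  sum_log_d <- sum(log(d))
  n <- length(d)
  zeta_trunc <- function(a) sum(seq_len(20000)^(-a))
  nll <- function(a) n * log(zeta_trunc(a)) + a * sum_log_d
  stats::optimize(nll, interval = c(1.0001, 25))$minimum
}

#' Mean local clustering coefficient
#'
#' Average, over all nodes, of the local clustering coefficient of the
#' symmetrized binarized snapshot; nodes with degree < 2 contribute 0
#' (cliquishness is undefined there and treated as absent).
#'
#' @param est estimated `p` by `p` matrix.
#' @param presence_threshold binarization threshold (default 1e-3).
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(est, presence_threshold = 1e-3) {
  B <- presence_graph(est, presence_threshold)
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  mean(cc)
}
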