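# Synthetic generator for sparse, slowly rewiring networks observed through
# the linear expression model Y(k) = A(k) X(k) + V(k).

#' Simulation configuration
#'
#' Defaults describe the benchmark condition used throughout: ten-gene
#' networks over five epochs with seven observation columns per epoch,
#' off-diagonal edges present with probability 0.2, edge magnitudes uniform
#' on \[0.5, 1.5\] with random sign, 20% of the edges rewired between
#' consecutive epochs, observation noise sd 0.1. Diagonal entries model
#' self-degradation and are drawn negative uniform on \[-1, -0.1\]; they
#' persist across epochs.
#'
#' @param p number of genes (>= 2).
#' @param n_epochs number of network snapshots (>= 1).
#' @param m_per_epoch observation columns per epoch (>= 1).
#' @param sparsity expected fraction of nonzero off-diagonal entries, in
#'   (0, 1].
#' @param edge_low,edge_high magnitude range of off-diagonal edge weights.
#' @param rewire_fraction fraction of present edges deleted and re-created
#'   elsewhere between consecutive epochs, in \[0, 1\].
#' @param obs_noise_sd sd of the additive observation noise `V(k)`.
#' @param state_noise_sd sd of Gaussian drift added to surviving edge weights
#'   between epochs (0 = weights change only by rewiring).
#' @param diag_low,diag_high range of the (negative) self-degradation
#'   diagonal.
#' @param seed integer RNG seed; the network sequence uses `seed` and the
#'   observations `seed + 1`, so one config reproducibly defines both.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(p = 10L, n_epochs = 5L, m_per_epoch = 7L,
                       sparsity = 0.2, edge_low = 0.5, edge_high = 1.5,
                       rewire_fraction = 0.2, obs_noise_sd = 0.1,
                       state_noise_sd = 0, diag_low = -1, diag_high = -0.1,
                       seed = 1L) {
  p <- as.integer(p); n_epochs <- as.integer(n_epochs)
  m_per_epoch <- as.integer(m_per_epoch); seed <- as.integer(seed)
  stopifnot(
    p >= 2, n_epochs >= 1, m_per_epoch >= 1,
    sparsity > 0, sparsity <= 1,
    edge_low <= edge_high, edge_low >= 0,
    rewire_fraction >= 0, rewire_fraction <= 1,
    obs_noise_sd >= 0, state_noise_sd >= 0,
    diag_low <= diag_high, diag_high <= 0
  )
  structure(
    list(
      p = p, n_epochs = n_epochs, m_per_epoch = m_per_epoch,
      sparsity = sparsity, edge_low = edge_low, edge_high = edge_high,
      rewire_fraction = rewire_fraction, obs_noise_sd = obs_noise_sd,
      state_noise_sd = state_noise_sd, diag_low = diag_low,
      diag_high = diag_high, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> p = %d, %d epochs x m = %d, sparsity %.2f, rewire %.2f, obs sd %.2g, seed %d\n",
    x$p, x$n_epochs, x$m_per_epoch, x$sparsity, x$rewire_fraction,
    x$obs_noise_sd, x$seed
  ))
  invisible(x)
}

# sample() without the length-1 surprise
sample_from <- function(x, size) x[sample.int(length(x), size)]

#' Generate a sequence of sparse, slowly rewiring true networks
#'
#' The first epoch's matrix has each off-diagonal entry nonzero with
#' probability `sparsity`, magnitude uniform on
#' `[edge_low, edge_high]` and equiprobable sign; diagonal entries (the
#' self-degradation rates) are negative uniform on `[diag_low, diag_high]`.
#' Each subsequent epoch copies the previous one and rewires
#' `round(rewire_fraction * nnz)` off-diagonal edges: the chosen edges are
#' deleted and the same number of new edges with fresh random weights appear
#' at previously empty positions. When `state_noise_sd > 0`, surviving
#' off-diagonal weights additionally drift by N(0, state_noise_sd^2).
#' Fully reproducible from `cfg$seed`; the caller's RNG state is untouched.
#'
#' @param cfg a [sim_config()].
#' @return list of `n_epochs` numeric `p` by `p` matrices.
#' @export
generate_network_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    p <- cfg$p
    off <- which(row(diag(p)) != col(diag(p)))
    A <- matrix(0, p, p)
    present <- off[stats::runif(length(off)) < cfg$sparsity]
    A[present] <- draw_weights(length(present), cfg)
    diag(A) <- stats::runif(p, cfg$diag_low, cfg$diag_high)
    nets <- vector("list", cfg$n_epochs)
    nets[[1]] <- A
    for (k in seq_len(cfg$n_epochs - 1L)) {
      A <- nets[[k]]
      nz <- off[A[off] != 0]
      n_rw <- round(cfg$rewire_fraction * length(nz))
      if (n_rw > 0 && length(nz) > 0) {
        empty <- off[A[off] == 0]
        n_rw <- min(n_rw, length(nz), length(empty))
        drop_idx <- sample_from(nz, n_rw)
        add_idx <- sample_from(empty, n_rw)
        A[drop_idx] <- 0
        A[add_idx] <- draw_weights(n_rw, cfg)
      }
      if (cfg$state_noise_sd > 0) {
        keep <- off[A[off] != 0]
        A[keep] <- A[keep] + stats::rnorm(length(keep), 0, cfg$state_noise_sd)
      }
      nets[[k + 1L]] <- A
    }
    nets
  })
}

draw_weights <- function(n, cfg) {
  if (n == 0) return(numeric(0))
  stats::runif(n, cfg$edge_low, cfg$edge_high) *
    sample(c(-1, 1), n, replace = TRUE)
}

#' Generate noisy observations from a network sequence
#'
#' Per epoch `k`, draws `m_per_epoch` expression snapshot columns of `X(k)`
#' i.i.d. standard normal and sets `Y(k) = A(k) X(k) + V(k)` with `V` entries
#' N(0, obs_noise_sd^2). Seeded with `cfg$seed + 1` (distinct from the
#' network stream) and leaves the caller's RNG state untouched. The true
#' networks are attached as attribute `"truth"` for downstream scoring.
#'
#' @param networks list of `p` by `p` matrices (see
#'   [generate_network_sequence()]).
#' @param cfg the [sim_config()] used to generate them.
#' @return [epoch_observations()] with attribute `truth`.
#' @export
generate_observations <- function(networks, cfg) {
  stopifnot(inherits(cfg, "sim_config"), length(networks) >= 1)
  p <- nrow(networks[[1]])
  withr::with_seed(cfg$seed + 1L, {
    epochs <- lapply(networks, function(A) {
      X <- matrix(stats::rnorm(p * cfg$m_per_epoch), p, cfg$m_per_epoch)
      V <- if (cfg$obs_noise_sd > 0) {
        matrix(stats::rnorm(p * cfg$m_per_epoch, 0, cfg$obs_noise_sd),
               p, cfg$m_per_epoch)
      } else {
        0
      }
      list(X = X, Y = A %*% X + V)
    })
    obs <- epoch_observations(epochs)
    attr(obs, "truth") <- networks
    obs
  })
}

#' Simulate one complete instance (networks plus observations)
#'
#' @param cfg a [sim_config()].
#' @return list with `networks` (true matrices) and `obs`
#'   ([epoch_observations()] carrying the truth attribute).
#' @export
simulate_instance <- function(cfg) {
  networks <- generate_network_sequence(cfg)
  list(networks = networks, obs = generate_observations(networks, cfg))
}

#' Benchmark-ensemble specification: ten genes, five epochs, seven columns
#'
#' Returns `n_networks` independent simulation configs for the standard
#' benchmark condition (p = 10, 5 epochs, m = 7 observation columns per
#' epoch, simulator defaults otherwise). Instance `i` uses seeds
#' `seed + 2 (i - 1)` and `seed + 2 (i - 1) + 1`, so the ensemble can be
#' materialized one instance at a time with bounded memory.
#'
#' @param n_networks ensemble size (>= 1).
#' @param seed integer base seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return list of `n_networks` [sim_config()] objects.
#' @export
scenario_table1 <- function(n_networks, seed = 1L, ...) {
  n_networks <- as.integer(n_networks)
  stopifnot(n_networks >= 1)
  lapply(seq_len(n_networks), function(i) {
    sim_config(seed = as.integer(seed) + 2L * (i - 1L), ...)
  })
}
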