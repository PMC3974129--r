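# Readers, writers, run configuration and the end-to-end pipeline.

#' Read a gene expression matrix from tab-delimited text
#'
#' Expects a header row of time labels and a first column of gene
#' identifiers; the remaining cells must be numeric. Ragged rows, non-numeric
#' cells and duplicate gene identifiers are rejected with the offending
#' (row, column) coordinates.
#'
#' @param path file path.
#' @param perturbation_path optional two-column TSV (time, u) with a header,
#'   giving the external perturbation signal; requires `perturbation_b`.
#' @param perturbation_b optional length-`p` per-gene perturbation
#'   coefficients.
#' @return an [expression_series()].
#' @export
read_expression_tsv <- function(path, perturbation_path = NULL,
                                perturbation_b = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3) stop("expression table needs a header and at least 2 gene rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  for (r in seq_along(fields)[-1]) {
    if (length(fields[[r]]) != width) {
      stop(sprintf("ragged row %d: %d fields, expected %d", r, length(fields[[r]]), width))
    }
  }
  time_labels <- fields[[1]][-1]
  ids <- vapply(fields[-1], `[[`, "", 1)
  dup <- anyDuplicated(ids)
  if (dup > 0) {
    stop(sprintf("duplicate gene identifier '%s' at row %d", ids[dup], dup + 1))
  }
  p <- length(ids)
  values <- matrix(NA_real_, p, width - 1L, dimnames = list(ids, time_labels))
  for (r in seq_len(p)) {
    cells <- fields[[r + 1L]][-1]
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
      c0 <- which(is.na(num))[1]
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   r + 1L, c0 + 1L, cells[c0]))
    }
    values[r, ] <- num
  }
  u <- NULL
  if (!is.null(perturbation_path)) {
    tab <- utils::read.delim(perturbation_path, header = TRUE)
    if (ncol(tab) < 2) stop("perturbation file must have two columns (time, u)")
    if (nrow(tab) != ncol(values)) {
      stop(sprintf("perturbation file has %d rows, expected %d", nrow(tab), ncol(values)))
    }
    u <- as.numeric(tab[[2]])
  }
  expression_series(values, time_labels = time_labels,
                    perturbation_u = u, perturbation_b = perturbation_b)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_tsv()]: header row of time labels, first
#' column of gene identifiers, full precision.
#'
#' @param series an [expression_series()] or a numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(series, path) {
  values <- if (inherits(series, "expression_series")) series$values else as.matrix(series)
  labels <- if (inherits(series, "expression_series")) series$time_labels else colnames(values)
  if (is.null(labels)) labels <- seq_len(ncol(values))
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(values)))
  header <- paste(c("gene", as.character(labels)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(r) {
    paste(c(ids[r], format(values[r, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export network snapshots as adjacency TSVs and SIF edge lists
#'
#' Per epoch `k` (1-based labels in file names) writes: the full signed
#' adjacency matrix `adjacency_epoch_<k>.tsv`; the thresholded edge list
#' `edges_epoch_<k>.sif` with one `source interaction target` line per edge,
#' tagged `activates` for positive and `represses` for negative weights
#' (row `i` holds gene `i`'s incoming edges, so the source is the column
#' gene); and `edge_attrs_epoch_<k>.tsv` with the corresponding weights.
#'
#' @param traj a `network_trajectory` (see [track_network()]) or a list of
#'   `p` by `p` matrices.
#' @param out_dir output directory (created if needed).
#' @param presence_threshold edges with absolute strength at or below this
#'   are omitted from the SIF output (default 1e-3); the adjacency TSV is
#'   always full precision and unthresholded.
#' @param gene_names optional gene names; defaults to `g1..gp`.
#' @return character vector of written paths, invisibly.
#' @export
write_network_snapshots <- function(traj, out_dir, presence_threshold = 1e-3,
                                    gene_names = NULL) {
  mats <- if (inherits(traj, "network_trajectory")) {
    if (!is.null(traj$smoothed)) traj$smoothed else traj$filtered
  } else {
    traj
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir))
  }
  p <- nrow(mats[[1]])
  if (is.null(gene_names)) gene_names <- sprintf("g%d", seq_len(p))
  paths <- character(0)
  for (k in seq_along(mats)) {
    A <- mats[[k]]
    dimnames(A) <- list(gene_names, gene_names)
    adj_path <- file.path(out_dir, sprintf("adjacency_epoch_%02d.tsv", k))
    write_expression_tsv(A, adj_path)
    idx <- which(abs(A) > presence_threshold, arr.ind = TRUE)
    # source = regulator (column), target = regulated gene (row)
    sif_lines <- if (nrow(idx) > 0) {
      ord <- order(idx[, 2], idx[, 1])
      idx <- idx[ord, , drop = FALSE]
      sprintf("%s\t%s\t%s",
              gene_names[idx[, 2]],
              ifelse(A[idx] > 0, "activates", "represses"),
              gene_names[idx[, 1]])
    } else {
      character(0)
    }
    sif_path <- file.path(out_dir, sprintf("edges_epoch_%02d.sif", k))
    writeLines(sif_lines, sif_path)
    attr_path <- file.path(out_dir, sprintf("edge_attrs_epoch_%02d.tsv", k))
    attr_lines <- c("source\ttarget\tweight",
                    if (nrow(idx) > 0) {
                      sprintf("%s\t%s\t%s", gene_names[idx[, 2]], gene_names[idx[, 1]],
                              format(A[idx], digits = 17, trim = TRUE))
                    })
    writeLines(attr_lines, attr_path)
    paths <- c(paths, adj_path, sif_path, attr_path)
  }
  invisible(paths)
}

#' Read back an adjacency TSV written by [write_network_snapshots()]
#'
#' @param path file path.
#' @return numeric matrix with gene dimnames.
#' @export
read_adjacency_tsv <- function(path) {
  es <- read_expression_tsv(path)
  m <- es$values
  colnames(m) <- rownames(m)
  m
}

#' Assemble a run configuration
#'
#' All knobs of the end-to-end pipeline in one serializable list. Exactly one
#' of `input` (an expression TSV to track) or `simulate = TRUE` (generate a
#' synthetic instance, track it and score it against the known truth) must be
#' chosen.
#'
#' @param input path to an expression TSV, or `NULL` for simulation mode.
#' @param simulate logical, simulation mode.
#' @param out_dir output directory.
#' @param m_per_epoch epoch block size for real data / observation columns
#'   per epoch for simulation.
#' @param lambda fixed sparsity weight, or `NULL` for per-gene GCV selection.
#' @param smoothing forward-backward smoothing (default) or filter only.
#' @param presence_threshold export/binarization threshold.
#' @param alpha edge-error tolerance used when truth is available.
#' @param workers parallel workers.
#' @param seed integer seed (simulation mode).
#' @param p,n_epochs,sparsity,rewire_fraction,obs_noise_sd simulator fields,
#'   see [sim_config()].
#' @param q_scale,r_scale,p0_scale tracker noise scales, see
#'   [track_options()].
#' @param perturbation_path,perturbation_b optional perturbation inputs for
#'   real data, see [read_expression_tsv()].
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = is.null(input),
                       out_dir = "lassokalman_run",
                       m_per_epoch = if (simulate) 7L else 3L,
                       lambda = NULL, smoothing = TRUE,
                       presence_threshold = 1e-3, alpha = 0.2,
                       workers = 1L, seed = 1L,
                       p = 10L, n_epochs = 5L, sparsity = 0.2,
                       rewire_fraction = 0.2, obs_noise_sd = 0.1,
                       q_scale = 1e-3, r_scale = 0.1, p0_scale = 1,
                       perturbation_path = NULL, perturbation_b = NULL) {
  if (is.null(input) && !simulate) stop("either supply input or set simulate = TRUE")
  if (!is.null(input) && simulate) stop("input and simulate are mutually exclusive")
  cfg <- list(
    input = input, simulate = simulate, out_dir = out_dir,
    m_per_epoch = as.integer(m_per_epoch), lambda = lambda,
    smoothing = smoothing, presence_threshold = presence_threshold,
    alpha = alpha, workers = as.integer(workers), seed = as.integer(seed),
    p = as.integer(p), n_epochs = as.integer(n_epochs), sparsity = sparsity,
    rewire_fraction = rewire_fraction, obs_noise_sd = obs_noise_sd,
    q_scale = q_scale, r_scale = r_scale, p0_scale = p0_scale,
    perturbation_path = perturbation_path, perturbation_b = perturbation_b
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys map one-to-one onto [run_config()] arguments; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' Run the full pipeline: ingest/simulate, track, evaluate, export
#'
#' Executes ingest (or simulation), observation building, per-gene GCV
#' lambda selection (unless fixed), static initial condition, network
#' tracking, evaluation against the truth when available, and export of the
#' network snapshots plus a JSON manifest (full configuration, seed, package
#' and R versions) sufficient to reproduce the run. Output is deterministic
#' given the configuration, independent of the worker count.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `trajectory`, `report` (confusion metrics
#'   and edge error; `NULL` without truth), `paths` (written files) and
#'   `manifest_path`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  gene_names <- NULL
  if (cfg$simulate) {
    sim <- sim_config(
      p = cfg$p, n_epochs = cfg$n_epochs, m_per_epoch = cfg$m_per_epoch,
      sparsity = cfg$sparsity, rewire_fraction = cfg$rewire_fraction,
      obs_noise_sd = cfg$obs_noise_sd, seed = cfg$seed
    )
    inst <- simulate_instance(sim)
    obs <- inst$obs
    truth <- inst$networks
  } else {
    series <- read_expression_tsv(cfg$input, cfg$perturbation_path,
                                  cfg$perturbation_b)
    gene_names <- rownames(series$values)
    obs <- build_observations(series, m_per_epoch = cfg$m_per_epoch)
  }
  opts <- track_options(q_scale = cfg$q_scale, r_scale = cfg$r_scale,
                        p0_scale = cfg$p0_scale)
  traj <- infer_network(obs, lambda = cfg$lambda, smoothing = cfg$smoothing,
                        init = "ml", opts = opts, workers = cfg$workers)
  if (length(traj$failures) > 0) {
    warning(sprintf("%d gene(s) failed to track; their rows are NA",
                    length(traj$failures)), call. = FALSE)
  }
  est <- if (cfg$smoothing) traj$smoothed else traj$filtered
  paths <- write_network_snapshots(traj, cfg$out_dir,
                                   presence_threshold = cfg$presence_threshold,
                                   gene_names = gene_names)
  report <- NULL
  if (!is.null(truth)) {
    cm <- confusion_metrics(truth, est, cfg$presence_threshold)
    err <- mean(vapply(seq_along(truth), function(k) {
      edge_error_rate(truth[[k]], est[[k]], cfg$alpha)
    }, numeric(1)))
    report <- list(confusion = unclass(cm)[c("tp", "tn", "fp", "fn",
                                             "sensitivity", "specificity",
                                             "accuracy", "precision")],
                   mean_edge_error = err)
    report_path <- file.path(cfg$out_dir, "evaluation.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, report_path)
  }
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    lambda_per_gene = traj$lambda,
    failures = traj$failures,
    package_version = as.character(utils::packageVersion("lassokalman")),
    r_version = as.character(getRversion())
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(trajectory = traj, report = report, paths = paths,
                 manifest_path = manifest_path))
}
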