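# End-to-end orchestration: simulate/load -> PCA -> coupling -> surfaces ->
# reports, with validated config, deterministic CSV output and a digest
# manifest.

pipeline_defaults <- function() {
  list(seed = NULL, out_dir = NULL,
       n_frames = 5000L, n_bins = 100L, temperature = 310,
       depth_threshold = 0.5, n_pcs = 5L,
       selection = "name CA", fit_selection = NULL,
       topology_path = NULL, trajectory_path = NULL,
       trajectory_format = "frames-text",
       pairs = "A:309-316,B:295-316")
}

config_error <- function(msg) {
  stop(structure(class = c("confcouple_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a pipeline configuration
#'
#' Accepts a named list, or a path to a flat `key = value` text file (lines
#' starting with `#` are comments) or a `.json` file with the same keys.
#' Unknown keys are rejected; `seed` and `out_dir` are required.  When
#' `trajectory_path`/`topology_path` are given they must exist (otherwise
#' the run is synthetic, driven by the seed).
#'
#' @param config Named list or file path.
#' @return The completed config list (defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(paste("config file not found:", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      lines <- readLines(config)
      lines <- lines[!grepl("^\\s*(#|$)", lines)]
      kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
      bad <- vapply(kv, length, integer(1)) != 3L
      if (any(bad)) config_error(paste("unparseable config line:", lines[bad][1]))
      stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
    }
  }
  if (!is.list(config)) config_error("config must be a named list or a file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    config_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  for (k in c("seed", "n_frames", "n_bins", "n_pcs"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("temperature", "depth_threshold"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if (is.null(cfg$seed) || is.na(cfg$seed)) config_error("config key 'seed' is required")
  if (is.null(cfg$out_dir)) config_error("config key 'out_dir' is required")
  if (cfg$n_frames < 2L) config_error("n_frames must be at least 2")
  if (!is.null(cfg$trajectory_path) && !file.exists(cfg$trajectory_path))
    config_error(paste("trajectory path not found:", cfg$trajectory_path))
  if (!is.null(cfg$trajectory_path) && is.null(cfg$topology_path))
    config_error("trajectory_path requires topology_path")
  if (!is.null(cfg$topology_path) && !file.exists(cfg$topology_path))
    config_error(paste("topology path not found:", cfg$topology_path))
  cfg
}

parse_pair_spec <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*([A-Za-z0-9]+):([0-9]+)-([0-9]+)\\s*$", p))[[1]]
    if (length(m) != 4L) config_error(paste("bad pair spec:", p))
    list(chain = m[2], res_a = as.integer(m[3]), res_b = as.integer(m[4]))
  })
}

fmt9 <- function(x) {
  if (is.numeric(x)) sprintf("%.9g", x) else as.character(x)
}

write_csv9 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt9), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  basename(path)
}

#' Run the conformational-coupling pipeline
#'
#' Simulates (or loads) a trajectory, performs essential-dynamics PCA over
#' the configured selection, computes aromatic pair distances, their
#' correlations with the leading components, two free-energy surfaces (PC1
#' vs the first pair; first pair vs second pair when present) with basin
#' detection and a compensation score, and writes every result as CSV to the
#' output directory together with the serialized config and an md5 manifest.
#' All floating-point output is formatted at 9 significant digits, so
#' re-running with the stored config reproduces the files byte for byte.
#'
#' @param config Named list or config-file path; see [validate_config()].
#' @return Invisibly, a list with `status` (0 on success), `out_dir` and
#'   `manifest` (data frame of file names and md5 digests).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- character(0)

  pair_specs <- parse_pair_spec(cfg$pairs)
  if (is.null(cfg$trajectory_path)) {
    sim <- generate_coupled_trajectory(n_frames = cfg$n_frames, seed = cfg$seed)
    traj <- sim$trajectory
  } else {
    topo <- read_structure(cfg$topology_path)
    traj <- read_trajectory(topo, cfg$trajectory_path, cfg$trajectory_format)
  }

  sel <- select_atoms(traj$topology, cfg$selection)
  fit <- if (is.null(cfg$fit_selection)) sel else
    select_atoms(traj$topology, cfg$fit_selection)
  pca <- compute_pca(traj, sel, fit_selection = fit)

  k <- min(cfg$n_pcs, ncol(pca$modes))
  eig <- data.frame(mode = seq_along(pca$eigenvalues),
                    lambda = pca$eigenvalues,
                    cumulative_fraction = cumsum(pca$eigenvalues) /
                      sum(pca$eigenvalues))
  produced <- c(produced, write_csv9(eig, file.path(cfg$out_dir, "eigenvalues.csv")))

  prof <- displacement_along_pc(pca, 1L, topology = traj$topology)
  produced <- c(produced,
                write_csv9(prof$per_atom,
                           file.path(cfg$out_dir, "displacement_profile.csv")))

  proj <- as.data.frame(pca$projections[, seq_len(k), drop = FALSE])
  names(proj) <- paste0("PC", seq_len(k))
  proj <- cbind(frame = seq_len(nrow(proj)), proj)
  produced <- c(produced, write_csv9(proj, file.path(cfg$out_dir, "projections.csv")))

  series <- lapply(pair_specs, function(ps)
    pair_distance_series(traj,
                         cluster_member(ps$chain, ps$res_a),
                         cluster_member(ps$chain, ps$res_b)))
  dist_df <- data.frame(frame = seq_len(n_frames(traj)))
  for (s in series) dist_df[[attr(s, "label")]] <- as.numeric(s)
  produced <- c(produced, write_csv9(dist_df, file.path(cfg$out_dir, "distances.csv")))

  corr <- distance_pc_correlation(series, pca, n_pcs = k)
  produced <- c(produced,
                write_csv9(corr$ranking, file.path(cfg$out_dir, "correlations.csv")))

  fes_rows <- function(fes) {
    occ <- which(fes$counts >= 0, arr.ind = TRUE)
    data.frame(x_center = fes$x_centers[occ[, 1]],
               y_center = fes$y_centers[occ[, 2]],
               count = fes$counts[occ],
               free_energy = ifelse(is.finite(fes$free_energy[occ]),
                                    fes$free_energy[occ], NA),
               masked = fes$counts[occ] == 0L)
  }
  basins_all <- NULL
  fes1 <- free_energy_surface(pca$projections[, 1L], as.numeric(series[[1L]]),
                              n_bins = cfg$n_bins, temperature = cfg$temperature,
                              labels = c("PC1", attr(series[[1L]], "label")))
  produced <- c(produced,
                write_csv9(fes_rows(fes1), file.path(cfg$out_dir, "fes_pc1_pair1.csv")))
  b1 <- find_basins(fes1, cfg$depth_threshold)
  if (nrow(b1) > 0L) basins_all <- cbind(surface = "pc1_pair1", b1)

  if (length(series) >= 2L) {
    fes2 <- free_energy_surface(as.numeric(series[[1L]]), as.numeric(series[[2L]]),
                                n_bins = cfg$n_bins, temperature = cfg$temperature,
                                labels = c(attr(series[[1L]], "label"),
                                           attr(series[[2L]], "label")))
    produced <- c(produced,
                  write_csv9(fes_rows(fes2),
                             file.path(cfg$out_dir, "fes_pair1_pair2.csv")))
    b2 <- find_basins(fes2, cfg$depth_threshold)
    if (nrow(b2) > 0L)
      basins_all <- rbind(basins_all, cbind(surface = "pair1_pair2", b2))
    comp <- compensation_score(series[[1L]], series[[2L]])
  } else {
    comp <- NA_real_
  }
  if (is.null(basins_all))
    basins_all <- data.frame(surface = character(0), x = numeric(0),
                             y = numeric(0), free_energy = numeric(0),
                             depth = numeric(0))
  produced <- c(produced, write_csv9(basins_all, file.path(cfg$out_dir, "basins.csv")))

  summary_df <- data.frame(
    quantity = c("n_frames", "n_atoms", "lambda1", "compensation_score"),
    value = c(n_frames(traj), dim(traj$coords)[2], pca$eigenvalues[1L], comp))
  produced <- c(produced, write_csv9(summary_df, file.path(cfg$out_dir, "summary.csv")))

  # serialize the effective config
  set_keys <- names(cfg)[!vapply(cfg, is.null, logical(1))]
  cfg_lines <- vapply(set_keys, function(k) sprintf("%s = %s", k, fmt9(cfg[[k]])),
                      character(1))
  writeLines(cfg_lines, file.path(cfg$out_dir, "config.txt"))
  produced <- c(produced, "config.txt")

  digests <- tools::md5sum(file.path(cfg$out_dir, produced))
  manifest <- data.frame(file = produced, md5 = unname(digests),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(status = 0L, out_dir = cfg$out_dir, manifest = manifest))
}
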