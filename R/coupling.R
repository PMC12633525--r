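# Aromatic-pair distances, their coupling to principal components,
# free-energy surfaces and basin detection.

# Boltzmann constant in kcal mol^-1 K^-1
KB_KCAL <- 0.0019872041

#' Default aromatic ring-atom rule
#'
#' "Center-to-center" distances in this package are distances between
#' unweighted centroids of ring heavy atoms.  The default ring sets are
#' Phe/Tyr `{CG, CD1, CD2, CE1, CE2, CZ}`, the Trp six-membered ring
#' `{CD2, CE2, CE3, CZ2, CZ3, CH2}`, and His `{CG, ND1, CD2, CE1, NE2}`.
#' Override by passing a modified list wherever a `ring_rule` is accepted.
#'
#' @return Named list mapping residue name to ring atom names.
#' @export
default_ring_rule <- function() {
  list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
       TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
       TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
       HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
}

#' Describe one aromatic cluster member
#'
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @param resname Optional 3-letter residue name; when `NULL` it is resolved
#'   from the topology.
#' @return List of class `cluster_member`.
#' @export
cluster_member <- function(chain, resno, resname = NULL) {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 resname = resname), class = "cluster_member")
}

member_label <- function(member) {
  sprintf("PRO%s:%d", member$chain, member$resno)
}

# Resolve the ring atom indices of a member within a topology.
ring_atom_indices <- function(topology, member, ring_rule = default_ring_rule()) {
  at <- topology$atoms
  in_res <- at$chain == member$chain & at$resno == member$resno
  if (!any(in_res))
    stop(sprintf("residue %s %d not found in topology", member$chain,
                 member$resno))
  resname <- member$resname
  if (is.null(resname)) resname <- at$resid[which(in_res)[1L]]
  ring <- ring_rule[[resname]]
  if (is.null(ring))
    stop("no ring_rule entry for residue name '", resname, "'")
  idx <- vapply(ring, function(nm) {
    i <- which(in_res & at$elety == nm)
    if (length(i) != 1L)
      stop(sprintf("ring atom %s missing in residue %s %s %d", nm, resname,
                   member$chain, member$resno))
    i
  }, integer(1))
  unname(idx)
}

#' Ring centroid of an aromatic residue in one frame
#'
#' Unweighted mean of the ring heavy-atom coordinates.
#'
#' @param topology A [structure_model()] naming the atoms.
#' @param coords `n_atoms x 3` coordinate matrix for the frame (defaults to
#'   the topology's own coordinates).
#' @param member A [cluster_member()].
#' @param ring_rule Mapping residue name -> ring atom names
#'   ([default_ring_rule()]).
#' @return Length-3 numeric centroid (Angstrom).
#' @export
ring_centroid <- function(topology, member, coords = topology$xyz,
                          ring_rule = default_ring_rule()) {
  idx <- ring_atom_indices(topology, member, ring_rule)
  colMeans(coords[idx, , drop = FALSE])
}

#' Centroid-to-centroid distance series for an aromatic pair
#'
#' Euclidean ring-centroid distance per frame.  No superposition is applied:
#' internal distances are invariant under global rotation and translation.
#'
#' @param traj A [trajectory()].
#' @param a,b [cluster_member()]s (a warning is raised if identical).
#' @param ring_rule See [default_ring_rule()].
#' @return Object of class `distance_series`: numeric per-frame distances
#'   (Angstrom) with a `label` attribute such as `"PROA:309-316"`.
#' @export
pair_distance_series <- function(traj, a, b, ring_rule = default_ring_rule()) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- ring_atom_indices(traj$topology, a, ring_rule)
  ib <- ring_atom_indices(traj$topology, b, ring_rule)
  if (identical(a$chain, b$chain) && identical(a$resno, b$resno))
    warning("pair members are the same residue; distance is identically zero")
  d2 <- 0
  for (dim_i in 1:3) {
    ca <- rowMeans(traj$coords[, ia, dim_i, drop = FALSE])
    cb <- rowMeans(traj$coords[, ib, dim_i, drop = FALSE])
    d2 <- d2 + (ca - cb)^2
  }
  label <- if (identical(a$chain, b$chain))
    sprintf("PRO%s:%d-%d", a$chain, a$resno, b$resno)
  else
    sprintf("%s-%s", member_label(a), member_label(b))
  structure(sqrt(d2), label = label, class = "distance_series")
}

#' Correlation between distance series and principal components
#'
#' Pearson correlation between each per-frame distance series and each of the
#' first `n_pcs` PC projection series, on raw (unsmoothed) values.  Both the
#' signed r and |r| are reported; ranking uses |r| while the sign is
#' retained.  A zero-variance series yields `NA` entries (undefined, reported
#' as missing rather than 0).
#'
#' @param series List of [pair_distance_series()] results (or plain numeric
#'   vectors; names/labels become row names).
#' @param pca A [compute_pca()] result over the same frames.
#' @param n_pcs Number of components to correlate against.
#' @return Object of class `correlation_matrix`: list with `r` and `abs_r`
#'   (pairs x PCs matrices) and `ranking` (data frame of pair, pc, r, abs_r
#'   sorted by |r| descending).
#' @export
distance_pc_correlation <- function(series, pca, n_pcs = 10L) {
  stopifnot(inherits(pca, "pca_result"))
  if (inherits(series, "distance_series") || is.numeric(series))
    series <- list(series)
  n_pcs <- min(as.integer(n_pcs), ncol(pca$projections))
  if (n_pcs < 1L) stop("n_pcs must be at least 1")
  nf <- nrow(pca$projections)
  labels <- vapply(seq_along(series), function(i) {
    lb <- attr(series[[i]], "label")
    if (is.null(lb)) lb <- names(series)[i]
    if (is.null(lb) || is.na(lb) || lb == "") lb <- sprintf("series%d", i)
    lb
  }, character(1))
  r <- matrix(NA_real_, nrow = length(series), ncol = n_pcs,
              dimnames = list(labels, paste0("PC", seq_len(n_pcs))))
  for (i in seq_along(series)) {
    s <- as.numeric(series[[i]])
    if (length(s) != nf)
      stop("series '", labels[i], "' length does not match the number of frames")
    if (stats::var(s) <= 0) {
      warning("series '", labels[i], "' has zero variance; correlations undefined")
      next
    }
    for (j in seq_len(n_pcs))
      r[i, j] <- stats::cor(s, pca$projections[, j])
  }
  ranking <- data.frame(pair = rep(labels, times = n_pcs),
                        pc = rep(seq_len(n_pcs), each = length(series)),
                        r = as.vector(r))
  ranking$abs_r <- abs(ranking$r)
  ranking <- ranking[order(-ranking$abs_r, ranking$pair, ranking$pc), ]
  rownames(ranking) <- NULL
  structure(list(r = r, abs_r = abs(r), ranking = ranking),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix (signed Pearson r):\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Two-dimensional free-energy surface from two collective variables
#'
#' Bins the paired series on a regular 2D grid and converts occupancy to free
#' energy, `F(bin) = -kB * T * ln(count / max_count)` in kcal/mol
#' (`kB = 0.0019872041` kcal/mol/K), so the most-occupied bin has `F = 0`
#' exactly and empty bins are masked at `+Inf`.
#'
#' @param x,y Equal-length numeric series (e.g. a PC projection and a pair
#'   distance).
#' @param n_bins Integer 2-vector of bin counts (default `c(100, 100)`).
#' @param temperature Temperature in Kelvin (default 310, the simulated
#'   ensemble temperature).
#' @param ranges Optional list with `x` and `y` 2-vectors of axis limits;
#'   default is the data range padded by 2%.
#' @param labels Character 2-vector of axis labels.
#' @return Object of class `fes_grid`: list with `x_edges`, `y_edges`,
#'   `x_centers`, `y_centers`, `counts`, `free_energy` (both `n_bins`
#'   matrices, x indexing rows), `temperature`, `labels`.
#' @export
free_energy_surface <- function(x, y, n_bins = c(100L, 100L),
                                temperature = 310, ranges = NULL,
                                labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y series must have equal length")
  if (length(x) < 1L) stop("empty series")
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  n_bins <- rep(as.integer(n_bins), length.out = 2L)
  if (any(n_bins < 2L)) stop("need at least 2 bins per axis")
  pad_range <- function(v, lim) {
    if (!is.null(lim)) return(as.numeric(lim))
    r <- range(v)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1) * 0.01
    r + c(-1, 1) * 0.02 * w
  }
  xr <- pad_range(x, ranges$x)
  yr <- pad_range(y, ranges$y)
  x_edges <- seq(xr[1], xr[2], length.out = n_bins[1] + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = n_bins[2] + 1L)
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  inside <- x >= xr[1] & x <= xr[2] & y >= yr[1] & y <= yr[2]
  counts <- matrix(0L, n_bins[1], n_bins[2])
  tab <- table(factor(ix[inside], levels = seq_len(n_bins[1])),
               factor(iy[inside], levels = seq_len(n_bins[2])))
  counts[] <- as.integer(tab)
  if (max(counts) == length(x))
    warning("all points fall in a single bin; the surface is degenerate")
  f <- matrix(Inf, n_bins[1], n_bins[2])
  occ <- counts > 0L
  f[occ] <- -KB_KCAL * temperature * log(counts[occ] / max(counts))
  structure(list(x_edges = x_edges, y_edges = y_edges,
                 x_centers = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
                 y_centers = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
                 counts = counts, free_energy = f,
                 temperature = temperature, labels = labels),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %d x %d bins, T = %g K, %d occupied, F range [0, %.3g] kcal/mol\n",
              nrow(x$counts), ncol(x$counts), x$temperature,
              sum(x$counts > 0), max(x$free_energy[is.finite(x$free_energy)])))
  invisible(x)
}

#' Detect basins on a free-energy surface
#'
#' Finds local minima over the 8-connected occupied neighbourhood of the
#' grid, using a watershed-by-flooding pass over occupied bins in order of
#' increasing free energy.  When two growing basins first touch, the
#' shallower one is assigned a depth equal to its lowest saddle minus its
#' minimum and merged; basins that never merge take their depth from the
#' highest occupied level of their connected component.  Basins with depth
#' below `depth_threshold` are discarded.
#'
#' @param fes A [free_energy_surface()] result.
#' @param depth_threshold Minimum basin depth in kcal/mol (default 0.5,
#'   roughly 0.8 kT at 310 K; the choice of metastability cut-off is a
#'   documented heuristic).
#' @return Data frame with one row per retained basin: `x`, `y` (bin centre
#'   coordinates of the minimum), `free_energy`, `depth`, sorted by
#'   `free_energy` ascending.
#' @export
find_basins <- function(fes, depth_threshold = 0.5) {
  stopifnot(inherits(fes, "fes_grid"))
  f <- fes$free_energy
  occ <- which(is.finite(f), arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("free-energy surface has no occupied bin")
  ord <- order(f[occ], occ[, 1], occ[, 2])
  occ <- occ[ord, , drop = FALSE]
  nx <- nrow(f); ny <- ncol(f)
  # basin id per grid cell (0 = unassigned)
  cell_basin <- matrix(0L, nx, ny)
  basin_parent <- integer(0)   # union-find
  basin_min_f <- numeric(0)
  basin_min_cell <- list()
  basin_depth <- numeric(0)    # NA until finalized by a merge
  find_root <- function(b) {
    while (basin_parent[b] != b) b <- basin_parent[b]
    b
  }
  for (i in seq_len(nrow(occ))) {
    r <- occ[i, 1]; cidx <- occ[i, 2]
    fv <- f[r, cidx]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- cidx + dc
      if (rr < 1L || rr > nx || cc < 1L || cc > ny) next
      b <- cell_basin[rr, cc]
      if (b > 0L) nb <- c(nb, find_root(b))
    }
    nb <- unique(nb)
    if (length(nb) == 0L) {
      basin_parent <- c(basin_parent, length(basin_parent) + 1L)
      basin_min_f <- c(basin_min_f, fv)
      basin_min_cell[[length(basin_parent)]] <- c(r, cidx)
      basin_depth <- c(basin_depth, NA_real_)
      cell_basin[r, cidx] <- length(basin_parent)
    } else if (length(nb) == 1L) {
      cell_basin[r, cidx] <- nb
    } else {
      # merge event: the current level is the saddle
      survivor <- nb[which.min(basin_min_f[nb])]
      for (b in setdiff(nb, survivor)) {
        basin_depth[b] <- fv - basin_min_f[b]
        basin_parent[b] <- survivor
      }
      cell_basin[r, cidx] <- survivor
    }
  }
  # surviving roots: depth relative to the top of their component
  roots <- which(basin_parent == seq_along(basin_parent) & is.na(basin_depth))
  if (length(roots) > 0L) {
    comp_max <- vapply(roots, function(b) {
      cells <- which(apply_root(cell_basin, basin_parent) == b)
      max(f[cells])
    }, numeric(1))
    basin_depth[roots] <- comp_max - basin_min_f[roots]
  }
  keep <- which(basin_depth >= depth_threshold)
  out <- data.frame(
    x = vapply(keep, function(b) fes$x_centers[basin_min_cell[[b]][1]], numeric(1)),
    y = vapply(keep, function(b) fes$y_centers[basin_min_cell[[b]][2]], numeric(1)),
    free_energy = basin_min_f[keep],
    depth = basin_depth[keep])
  out <- out[order(out$free_energy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map every assigned cell to its root basin id
apply_root <- function(cell_basin, basin_parent) {
  root_of <- seq_along(basin_parent)
  for (b in seq_along(basin_parent)) {
    r <- b
    while (basin_parent[r] != r) r <- basin_parent[r]
    root_of[b] <- r
  }
  out <- cell_basin
  nz <- cell_basin > 0L
  out[nz] <- root_of[cell_basin[nz]]
  out
}

#' Compensation score between two distance series
#'
#' Pearson correlation between the two per-frame pair distances; a negative
#' score indicates a compensating relationship (one pair opens as the other
#' closes, as across protomers in a half-sites arrangement).
#'
#' @param a,b Equal-length [pair_distance_series()] results (or numeric
#'   vectors) with nonzero variance.
#' @return Signed score in `[-1, 1]`; `NA` (with a warning) if either series
#'   has zero variance.
#' @export
compensation_score <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("series must have equal lengths")
  if (stats::var(a) <= 0 || stats::var(b) <= 0) {
    warning("zero-variance series; compensation score undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
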