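# Superposition and essential-dynamics principal component analysis.

#' Kabsch rigid-body superposition
#'
#' Finds the optimal rotation + translation (no reflection) least-squares fit
#' of `mobile` onto `reference` over `fit_selection`, applies it to all atoms
#' of `mobile`, and reports the RMSD over the fit selection.
#'
#' @param mobile Numeric `n_atoms x 3` coordinate matrix.
#' @param reference Numeric `n_atoms x 3` coordinate matrix (same atom set).
#' @param fit_selection An [atom_selection()] (or integer indices) over which
#'   the fit is computed.  Defaults to all atoms.
#' @return List with `coords` (aligned copy of `mobile`) and `rmsd`
#'   (Angstrom, over the fit selection).
#' @export
kabsch_superpose <- function(mobile, reference, fit_selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be equal-sized n x 3 matrices")
  sel <- if (is.null(fit_selection)) seq_len(nrow(mobile)) else as.integer(fit_selection)
  if (length(sel) == 0L) stop("fit selection is empty")
  p <- mobile[sel, , drop = FALSE]
  q <- reference[sel, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2L, pc); q0 <- sweep(q, 2L, qc)
  # degenerate if the fit atoms are coincident or collinear (rotation about
  # the line is unresolved)
  sv_p <- svd(p0, nu = 0, nv = 0)$d
  if (length(sel) < 3L || sv_p[2] <= 1e-8 * max(sv_p[1], 1e-12))
    stop("degenerate fit selection: atoms are coincident or collinear")
  h <- crossprod(p0, q0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- sweep(sweep(mobile, 2L, pc) %*% t(rot), 2L, qc, FUN = "+")
  diff <- aligned[sel, , drop = FALSE] - reference[sel, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums(diff^2)))
  list(coords = aligned, rmsd = rmsd)
}

# Align every frame of a coordinate array to `ref` over `fit`; returns the
# aligned array.  The degeneracy check is done once on the reference; the
# per-frame rotation solve is inlined for speed.
align_frames <- function(coords, ref, fit) {
  nf <- dim(coords)[1]
  q <- ref[fit, , drop = FALSE]
  qc <- colMeans(q)
  q0 <- sweep(q, 2L, qc)
  sv_q <- svd(q0, nu = 0, nv = 0)$d
  if (length(fit) < 3L || sv_q[2] <= 1e-8 * max(sv_q[1], 1e-12))
    stop("degenerate fit selection: atoms are coincident or collinear")
  out <- coords
  for (f in seq_len(nf)) {
    m <- matrix(coords[f, , ], ncol = 3L)
    p <- m[fit, , drop = FALSE]
    pc <- colMeans(p)
    s <- svd(crossprod(sweep(p, 2L, pc), q0))
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    out[f, , ] <- sweep(sweep(m, 2L, pc) %*% t(rot), 2L, qc, FUN = "+")
  }
  out
}

#' Essential-dynamics PCA of selected atoms
#'
#' Frames are optionally superposed (Kabsch, over `fit_selection`) onto a
#' reference, then the selected atoms' coordinates are mean-centred and
#' decomposed.  The covariance is the population covariance (divide by
#' `n_frames`) of the aligned 3N coordinate vectors; no mass weighting is
#' applied.  Modes are orthonormal with descending eigenvalues (Angstrom^2)
#' and each mode is oriented so its largest-magnitude component is positive
#' (ties broken by lowest coordinate index), making downstream signs
#' reproducible.
#'
#' @param traj A [trajectory()] with at least two frames.
#' @param selection [atom_selection()] of analysis atoms (e.g. C-alpha plus
#'   ligand heavy atoms).
#' @param fit_selection [atom_selection()] used for superposition; defaults
#'   to `selection`.
#' @param align Superpose frames before the decomposition (default `TRUE`).
#' @param reference `"mean-iterative"` (fit to the first frame, recompute the
#'   mean and re-fit, twice) or `"first-frame"`.
#' @return Object of class `pca_result` with fields `selection`,
#'   `fit_selection`, `mean_coords` (3N vector), `eigenvalues`, `modes`
#'   (3N x K, columns orthonormal), `projections` (n_frames x K, Angstrom),
#'   `reference_coords` (full-topology matrix used as the alignment
#'   reference) and `align`.
#' @export
compute_pca <- function(traj, selection, fit_selection = selection,
                        align = TRUE,
                        reference = c("mean-iterative", "first-frame")) {
  reference <- match.arg(reference)
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("PCA requires at least 2 frames")
  sel <- as.integer(selection)
  if (length(sel) == 0L) stop("empty analysis selection")
  fit <- as.integer(fit_selection)

  coords <- traj$coords
  ref <- matrix(coords[1L, , ], ncol = 3L)
  if (align) {
    for (iter in 1:2) {
      aligned <- align_frames(coords, ref, fit)
      ref <- apply(aligned, c(2L, 3L), mean)
    }
    coords <- align_frames(coords, ref, fit)
  }

  # n_frames x 3N matrix of the selected atoms, coordinate-major per atom
  x <- flatten_selection(coords, sel)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  k <- min(nf - 1L, ncol(xc), length(sv$d))
  lambda <- (sv$d^2) / nf
  modes <- sv$v
  proj <- xc %*% modes
  # deterministic sign convention
  for (j in seq_len(ncol(modes))) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) {
      modes[, j] <- -modes[, j]
      proj[, j] <- -proj[, j]
    }
  }
  res <- list(selection = selection,
              fit_selection = fit_selection,
              mean_coords = mu,
              eigenvalues = lambda,
              modes = modes,
              projections = proj,
              reference_coords = if (align) ref else NULL,
              align = align,
              reference = reference)
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("pca_result: %d atoms, %d frames, total variance %.4g A^2\n",
              length(x$selection), nrow(x$projections), tot))
  for (j in seq_len(k))
    cat(sprintf("  PC%d: lambda = %.4g A^2 (%.1f%%)\n", j, x$eigenvalues[j],
                100 * x$eigenvalues[j] / max(tot, .Machine$double.eps)))
  invisible(x)
}

# frames x atoms x 3 array -> frames x 3N matrix (x1,y1,z1,x2,...)
flatten_selection <- function(coords, sel) {
  nf <- dim(coords)[1]
  sub <- coords[, sel, , drop = FALSE]
  out <- matrix(NA_real_, nf, 3L * length(sel))
  for (j in seq_along(sel)) out[, (3L * j - 2L):(3L * j)] <- sub[, j, ]
  out
}

#' Per-atom displacement profile along one principal component
#'
#' The displacement of atom i along mode k is
#' `d_i = sqrt(lambda_k) * ||(e_k)_i||` where `(e_k)_i` is the atom's
#' 3-vector block of the (orthonormal) mode: the RMS displacement that mode k
#' contributes to that atom.  Atoms outside the analysis selection have zero
#' displacement by construction and are omitted from the table.
#'
#' @param pca A [compute_pca()] result.
#' @param k Mode index (1-based).
#' @param topology Optional [structure_model()]; when given, residue number
#'   and chain columns are attached and a per-residue aggregation (max over
#'   the residue's selected atoms) is included.
#' @return List of class `displacement_profile` with `per_atom` (data frame:
#'   `atom_index`, `displacement`, plus `resno`/`chain` when a topology is
#'   supplied) and `per_residue` (or `NULL`).
#' @export
displacement_along_pc <- function(pca, k, topology = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  if (k < 1L || k > ncol(pca$modes)) stop("mode index k out of range")
  sel <- as.integer(pca$selection)
  block <- matrix(pca$modes[, k], ncol = 3L, byrow = TRUE)
  d <- sqrt(pca$eigenvalues[k]) * sqrt(rowSums(block^2))
  per_atom <- data.frame(atom_index = sel, displacement = d)
  per_residue <- NULL
  if (!is.null(topology)) {
    at <- topology$atoms[sel, , drop = FALSE]
    per_atom$resno <- at$resno
    per_atom$chain <- at$chain
    key <- paste(at$chain, at$resno)
    agg <- tapply(d, key, max)
    first <- !duplicated(key)
    per_residue <- data.frame(chain = at$chain[first], resno = at$resno[first])
    per_residue$displacement <- as.numeric(agg[paste(per_residue$chain,
                                                     per_residue$resno)])
  }
  structure(list(per_atom = per_atom, per_residue = per_residue, mode = k),
            class = "displacement_profile")
}

#' Project trajectory frames onto a principal component
#'
#' Frames are aligned with the PCA's stored reference (when the PCA was
#' aligned), mean-centred with the PCA mean, and projected onto mode `k`.
#' For the defining trajectory this reproduces the stored projections.
#'
#' @param pca A [compute_pca()] result.
#' @param traj A [trajectory()] with the same atom universe.
#' @param k Mode index.
#' @return Numeric vector of per-frame projections (Angstrom).
#' @export
project_frames <- function(pca, traj, k) {
  stopifnot(inherits(pca, "pca_result"), inherits(traj, "trajectory"))
  if (k < 1L || k > ncol(pca$modes)) stop("mode index k out of range")
  sel <- as.integer(pca$selection)
  if (dim(traj$coords)[2] < max(sel))
    stop("trajectory is not atom-compatible with the PCA selection")
  coords <- traj$coords
  if (pca$align)
    coords <- align_frames(coords, pca$reference_coords,
                           as.integer(pca$fit_selection))
  x <- flatten_selection(coords, sel)
  as.numeric(sweep(x, 2L, pca$mean_coords) %*% pca$modes[, k])
}
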