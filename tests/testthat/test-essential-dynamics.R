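test_that("Kabsch superposition removes rigid motion and flags degeneracy", {
  set.seed(1)
  ref <- matrix(rnorm(12, sd = 3), 4, 3)
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)

  rot90z <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- sweep(ref %*% t(rot90z), 2, c(5, 0, 0), FUN = "+")
  fit2 <- kabsch_superpose(moved, ref)
  expect_lt(fit2$rmsd, 1e-10)
  expect_lt(max(abs(fit2$coords - ref)), 1e-10)

  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch RMSD matches an independent least-squares fit", {
  set.seed(42)
  ref <- matrix(rnorm(12, sd = 3), 4, 3)
  mobile <- ref
  mobile[4, ] <- mobile[4, ] + c(1.0, -0.5, 0.25)
  rot <- random_rotation()
  mobile <- sweep(mobile %*% t(rot), 2, c(2, -1, 3), FUN = "+")
  ours <- kabsch_superpose(mobile, ref)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                           mobile = as.vector(t(mobile)),
                           fixed.inds = 1:12, mobile.inds = 1:12)
  oracle_rmsd <- bio3d::rmsd(as.vector(t(ref)), fitted)
  expect_equal(ours$rmsd, oracle_rmsd, tolerance = 1e-3) # bio3d rounds xyz
})

test_that("PCA reproduces the hand-computed single-atom example", {
  topo <- make_ca_protein(1L)
  traj <- make_traj(topo, list(cbind(0, 0, 0), cbind(2, 0, 0)))
  pca <- compute_pca(traj, atom_selection(1L), align = FALSE)
  expect_equal(pca$mean_coords, c(1, 0, 0))
  expect_equal(pca$eigenvalues[1], 1)               # population covariance
  expect_equal(pca$modes[, 1], c(1, 0, 0))          # sign convention
  expect_equal(as.numeric(pca$projections[, 1]), c(-1, 1))
})

test_that("constant trajectories have zero eigenvalues and displacements", {
  topo <- make_ca_protein(3L)
  frame <- topo$xyz
  traj <- make_traj(topo, list(frame, frame, frame))
  pca <- compute_pca(traj, select_atoms(topo, "name CA"), align = FALSE)
  expect_true(all(abs(pca$eigenvalues) < 1e-12))
  prof <- displacement_along_pc(pca, 1)
  expect_true(all(prof$per_atom$displacement < 1e-9))
  expect_error(compute_pca(make_traj(topo, list(frame)), atom_selection(1:3)),
               "at least 2 frames")
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(9)
  topo <- make_random_topology(5L, 9)
  frames <- lapply(1:50, function(i) topo$xyz + matrix(rnorm(15), 5, 3))
  traj <- make_traj(topo, frames)
  sel <- atom_selection(1:5)

  for (use_align in c(FALSE, TRUE)) {
    pca <- compute_pca(traj, sel, align = use_align)
    # rebuild the aligned frame matrix independently
    x <- t(vapply(seq_len(n_frames(traj)), function(f) {
      m <- frame_coords(traj, f)
      if (use_align) m <- kabsch_superpose(m, pca$reference_coords, sel)$coords
      as.vector(t(m))
    }, numeric(15)))
    xc <- sweep(x, 2, colMeans(x))
    cov_pop <- crossprod(xc) / nrow(x)
    eig <- eigen(cov_pop, symmetric = TRUE)
    k <- 10L
    expect_equal(pca$eigenvalues[1:k], eig$values[1:k], tolerance = 1e-8)
    # compare mode directions only where the spectrum is well separated
    # (alignment empties the rigid-body subspace, leaving degenerate tails)
    gaps <- abs(diff(eig$values[1:(k + 1)]))
    for (j in 1:k) {
      sep <- min(if (j > 1) gaps[j - 1] else Inf, gaps[j])
      if (sep < 1e-3 * eig$values[1]) next
      expect_equal(abs(sum(pca$modes[, j] * eig$vectors[, j])), 1,
                   tolerance = 1e-8)
    }
    # variance conservation
    expect_equal(sum(pca$eigenvalues), sum(xc^2) / nrow(x), tolerance = 1e-6)
    # orthonormal modes, centred and uncorrelated projections
    gram <- crossprod(pca$modes)
    expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
    expect_lt(max(abs(colMeans(pca$projections))), 1e-8)
    cv <- crossprod(pca$projections) / nrow(x)
    off <- abs(cv[upper.tri(cv)])
    lim <- 1e-6 * sqrt(outer(pca$eigenvalues, pca$eigenvalues))[upper.tri(cv)]
    expect_true(all(off <= pmax(lim, 1e-12)))
  }
})

test_that("eigenvalues are invariant under per-frame global rotations", {
  set.seed(11)
  topo <- make_random_topology(6L, 11)
  frames <- lapply(1:40, function(i) topo$xyz + matrix(rnorm(18, sd = 0.5), 6, 3))
  traj <- make_traj(topo, frames)
  sel <- atom_selection(1:6)
  pca1 <- compute_pca(traj, sel, align = TRUE)
  rotated <- lapply(frames, function(m) {
    sweep(m %*% t(random_rotation()), 2, rnorm(3, sd = 10), FUN = "+")
  })
  pca2 <- compute_pca(make_traj(topo, rotated), sel, align = TRUE)
  expect_equal(pca1$eigenvalues, pca2$eigenvalues, tolerance = 1e-6)
})

test_that("frame projection is self-consistent and linear", {
  set.seed(13)
  topo <- make_random_topology(4L, 13)
  frames <- lapply(1:30, function(i) topo$xyz + matrix(rnorm(12, sd = 0.5), 4, 3))
  traj <- make_traj(topo, frames)
  sel <- atom_selection(1:4)

  pca_a <- compute_pca(traj, sel, align = TRUE)
  expect_lt(max(abs(project_frames(pca_a, traj, 1) - pca_a$projections[, 1])),
            1e-10)

  pca <- compute_pca(traj, sel, align = FALSE)
  mean_frame <- matrix(pca$mean_coords, ncol = 3, byrow = TRUE)
  expect_lt(abs(project_frames(pca, make_traj(topo, list(mean_frame)), 1)), 1e-10)
  shifted <- mean_frame + 2.5 * matrix(pca$modes[, 1], ncol = 3, byrow = TRUE)
  expect_equal(project_frames(pca, make_traj(topo, list(shifted)), 1), 2.5,
               tolerance = 1e-8)
  expect_error(project_frames(pca, traj, 99), "out of range")
})

test_that("displacement profiles localise motion and scale as sqrt(lambda)", {
  topo <- make_ca_protein(1L)
  traj <- make_traj(topo, list(cbind(0, 0, 0), cbind(2, 0, 0)))
  pca <- compute_pca(traj, atom_selection(1L), align = FALSE)
  prof <- displacement_along_pc(pca, 1)
  expect_equal(prof$per_atom$displacement, 1.0)   # sqrt(1) * ||(1,0,0)||

  topo2 <- make_ca_protein(2L)
  frames <- list(topo2$xyz, topo2$xyz + rbind(c(0, 0, 0), c(0, 1, 0)))
  pca2 <- compute_pca(make_traj(topo2, frames), atom_selection(1:2),
                      align = FALSE)
  prof2 <- displacement_along_pc(pca2, 1, topology = topo2)
  expect_lt(prof2$per_atom$displacement[1], 1e-10)
  expect_gt(prof2$per_atom$displacement[2], 0.4)
  expect_equal(nrow(prof2$per_residue), 2L)
  expect_error(displacement_along_pc(pca2, 10), "out of range")
})

test_that("a planted slow mode is recovered from a long synthetic trajectory", {
  sim <- generate_coupled_trajectory(n_frames = 20000L, seed = 7L)
  sel <- select_atoms(sim$trajectory$topology, "name CA")
  pca <- compute_pca(sim$trajectory, sel)
  overlap <- abs(sum(pca$modes[, 1] * sim$truth$mode_ca))
  expect_gte(overlap, 0.99)
  planted_var <- sim$truth$mode_variance + sim$truth$noise_sigma^2
  expect_lt(abs(pca$eigenvalues[1] - planted_var) / planted_var, 0.10)
})
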