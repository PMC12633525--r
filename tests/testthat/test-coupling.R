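test_that("ring centroids equal the planted centres", {
  st <- generate_toy_structure(
    data.frame(resname = "PHE", chain = "A", resno = 10L, x = 0, y = 0, z = 0),
    include_ca = FALSE)
  expect_equal(ring_centroid(st, cluster_member("A", 10)), c(0, 0, 0),
               tolerance = 1e-12)

  st2 <- generate_toy_structure(
    data.frame(resname = "PHE", chain = "A", resno = 10L, x = 3, y = 4, z = 0),
    include_ca = FALSE)
  expect_equal(ring_centroid(st2, cluster_member("A", 10)), c(3, 4, 0),
               tolerance = 1e-12)

  # hand-placed six-membered Trp ring: centroid is the arithmetic mean
  coords <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 1.2, 0),
                  c(1.4, 2.4, 0), c(0, 2.4, 0), c(-0.7, 1.2, 0.6))
  atoms <- data.frame(eleno = 1:6,
                      elety = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                      elesy = "C", resno = 5L, resid = "TRP", chain = "A",
                      insert = "", is_heavy = TRUE, stringsAsFactors = FALSE)
  trp <- structure_model(atoms, coords)
  expect_equal(ring_centroid(trp, cluster_member("A", 5)), colMeans(coords))

  broken <- structure_model(atoms[-1, ] |> transform(eleno = 1:5), coords[-1, ])
  expect_error(ring_centroid(broken, cluster_member("A", 5)), "CD2")
  expect_error(ring_centroid(trp, cluster_member("A", 99)), "not found")
})

test_that("pair distances track planted separations and rigid invariance", {
  a <- generate_toy_structure(
    data.frame(resname = "PHE", chain = "A", resno = c(1L, 2L),
               x = c(0, 3), y = c(0, 4), z = 0), include_ca = FALSE)
  traj <- make_traj(a, list(a$xyz, a$xyz))
  d <- pair_distance_series(traj, cluster_member("A", 1), cluster_member("A", 2))
  expect_equal(as.numeric(d), c(5, 5))
  expect_equal(attr(d, "label"), "PROA:1-2")
  expect_warning(
    same <- pair_distance_series(traj, cluster_member("A", 1),
                                 cluster_member("A", 1)), "zero")
  expect_equal(as.numeric(same), c(0, 0))

  # planted sinusoid separation: move ring 2's centroid to (s, 0, 0)
  sep <- 5 + sin(seq(0, 2 * pi, length.out = 20))
  base <- a$xyz
  ring2 <- which(a$atoms$resno == 2L)
  frames <- lapply(sep, function(s) {
    m <- base
    shift <- c(s, 0, 0) - colMeans(base[ring2, , drop = FALSE])
    m[ring2, ] <- sweep(base[ring2, , drop = FALSE], 2, shift, FUN = "+")
    m
  })
  traj2 <- make_traj(a, frames)
  d2 <- pair_distance_series(traj2, cluster_member("A", 1), cluster_member("A", 2))
  expect_lt(max(abs(as.numeric(d2) - sep)), 1e-9)

  # global rigid motion per frame leaves distances unchanged
  set.seed(4)
  moved <- lapply(frames, function(m)
    sweep(m %*% t(random_rotation()), 2, rnorm(3, sd = 20), FUN = "+"))
  d3 <- pair_distance_series(make_traj(a, moved), cluster_member("A", 1),
                             cluster_member("A", 2))
  expect_lt(max(abs(as.numeric(d3) - as.numeric(d2))), 1e-9)
})

test_that("distance/PC correlations match the textbook Pearson formula", {
  # one atom moving along x: PC1 projection is the centred x series
  topo <- make_ca_protein(1L)
  y <- c(2, 1, 4, 3, 5)
  traj <- make_traj(topo, lapply(y, function(v) cbind(v, 0, 0)))
  pca <- compute_pca(traj, atom_selection(1L), align = FALSE)
  expect_equal(as.numeric(pca$projections[, 1]), y - mean(y))

  x <- c(1, 2, 3, 4, 5)
  cm <- distance_pc_correlation(list(series = x), pca, n_pcs = 1)
  expect_equal(unname(cm$r[1, 1]), pearson_oracle(x, y))
  expect_equal(unname(cm$r[1, 1]), 0.8)   # hand-computed direct sums

  perfect <- 2 * pca$projections[, 1] + 3
  cm2 <- distance_pc_correlation(list(p = perfect, m = -pca$projections[, 1]),
                                 pca, n_pcs = 1)
  expect_equal(unname(cm2$r[, 1]), c(1, -1), tolerance = 1e-12)

  expect_warning(cm3 <- distance_pc_correlation(list(z = rep(1, 5)), pca, 1),
                 "zero variance")
  expect_true(is.na(cm3$r[1, 1]))
})

test_that("free-energy surfaces follow the Boltzmann closed form", {
  # two occupied bins with counts 3 and 1 at 310 K
  x <- c(0.1, 0.2, 0.15, 0.9)
  y <- rep(0, 4)
  fes <- free_energy_surface(x, y, n_bins = c(2, 2), temperature = 310,
                             ranges = list(x = c(0, 1), y = c(-0.5, 0.5)))
  occupied <- fes$free_energy[is.finite(fes$free_energy)]
  expect_equal(sum(fes$counts), 4L)
  expect_equal(min(occupied), 0)
  delta <- 0.0019872041 * 310 * log(3)
  expect_equal(max(occupied) - min(occupied), delta, tolerance = 1e-12)
  expect_equal(sort(unique(as.vector(fes$counts))), c(0L, 1L, 3L))

  # doubling every count leaves F unchanged
  fes2 <- free_energy_surface(c(x, x), c(y, y), n_bins = c(2, 2),
                              temperature = 310,
                              ranges = list(x = c(0, 1), y = c(-0.5, 0.5)))
  expect_equal(fes2$free_energy, fes$free_energy)

  # degenerate single-bin surface warns; F = 0 there, all else masked
  expect_warning(one <- free_energy_surface(rep(1, 10), rep(2, 10),
                                            n_bins = c(5, 5)), "single bin")
  expect_equal(sum(is.finite(one$free_energy)), 1L)
  expect_equal(one$free_energy[is.finite(one$free_energy)], 0)
  expect_error(free_energy_surface(1:3, 1:3, temperature = -1), "positive")

  # re-binning with identical edges is idempotent and conserves counts
  set.seed(6)
  xs <- rnorm(500); ys <- rnorm(500)
  f1 <- free_energy_surface(xs, ys, n_bins = c(20, 20))
  f2 <- free_energy_surface(xs, ys, n_bins = c(20, 20),
                            ranges = list(x = range(f1$x_edges),
                                          y = range(f1$y_edges)))
  expect_equal(f1$counts, f2$counts)
  expect_equal(sum(f1$counts), 500L)
})

test_that("basin detection finds single minima and ignores flat surfaces", {
  # paraboloid-shaped occupancy: one basin at the most occupied cell
  centers <- seq(-1, 1, length.out = 9)
  pts_x <- c(); pts_y <- c()
  for (i in seq_along(centers)) for (j in seq_along(centers)) {
    n <- round(400 * exp(-(centers[i]^2 + centers[j]^2) / 0.3))
    pts_x <- c(pts_x, rep(centers[i], n)); pts_y <- c(pts_y, rep(centers[j], n))
  }
  fes <- free_energy_surface(pts_x, pts_y, n_bins = c(9, 9),
                             ranges = list(x = c(-1.1, 1.1), y = c(-1.1, 1.1)))
  basins <- find_basins(fes, depth_threshold = 0.5)
  expect_equal(nrow(basins), 1L)
  expect_lt(abs(basins$x[1]), 0.2)
  expect_lt(abs(basins$y[1]), 0.2)
  expect_equal(basins$free_energy[1], 0)

  # flat occupied grid has no basins at a positive threshold
  gx <- rep(centers, each = 9); gy <- rep(centers, times = 9)
  flat <- free_energy_surface(gx, gy, n_bins = c(9, 9),
                              ranges = list(x = c(-1.1, 1.1), y = c(-1.1, 1.1)))
  expect_equal(nrow(find_basins(flat, depth_threshold = 0.1)), 0L)
})

test_that("compensation scores sign anti-coupled series", {
  set.seed(8)
  a <- rnorm(1000, 10)
  expect_equal(compensation_score(a, -a + 20), -1, tolerance = 1e-12)
  expect_equal(compensation_score(a, a), 1, tolerance = 1e-12)
  set.seed(9)
  ind1 <- rnorm(10000); ind2 <- rnorm(10000)
  expect_lt(abs(compensation_score(ind1, ind2)), 0.05)  # ~3/sqrt(n) bound
  expect_warning(na_score <- compensation_score(rep(1, 5), 1:5), "zero")
  expect_true(is.na(na_score))
})
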