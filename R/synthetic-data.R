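# Synthetic-data generators with analytic ground truth.
#
# Every generator is deterministic under a fixed seed.  A single user seed
# derives independent per-stream sub-seeds (see derive_seed), so adding a
# later draw never perturbs earlier streams.

# Documented sub-seed derivation: stays inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647) * 1103 + stream * 7919) %% 2147483647L
}

# Remove the rigid-body (3 translation + 3 rotation) components of a 3N
# displacement vector defined at reference coordinates `ref` (n x 3).
project_out_rigid <- function(vec, ref) {
  n <- nrow(ref)
  centred <- sweep(ref, 2L, colMeans(ref))
  basis <- matrix(0, 3L * n, 6L)
  for (d in 1:3) basis[seq(d, 3L * n, by = 3L), d] <- 1
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  for (d in 1:3) {
    axis <- c(0, 0, 0); axis[d] <- 1
    basis[, 3L + d] <- as.vector(apply(centred, 1L, function(x) cross(axis, x)))
  }
  q <- qr.Q(qr(basis))
  as.vector(vec - q %*% crossprod(q, vec))
}

non_aromatic_letters <- function() {
  c("A", "L", "I", "V", "S", "T", "K", "E", "D", "G", "N", "Q", "R", "M", "P")
}

#' Describe one planted coupled aromatic pair
#'
#' A coupled pair is two aromatic rings whose centroid separation follows
#' the latent two-state mode: `d(t) = base + amplitude * s(t)` plus thermal
#' noise, with `s(t)` the 0/1 telegraph state.  Specify either `amplitude`
#' (Angstrom; negative values anti-couple the pair, giving a compensating
#' relationship) or `rho` (target Pearson correlation between the pair
#' distance and the PC1 projection; the required amplitude is derived
#' analytically, see [generate_coupled_trajectory()]).
#'
#' @param res_a,res_b Residue numbers of the two rings.
#' @param chain Chain identifier for both rings.
#' @param base Centroid separation (Angstrom) in state 0.
#' @param amplitude Separation change (Angstrom) in state 1, or `NULL`.
#' @param rho Target distance/PC1 correlation in `[-1, 1]`, or `NULL`.
#' @return List of class `coupled_pair`.
#' @export
coupled_pair <- function(res_a, res_b, chain = "A", base = 4,
                         amplitude = NULL, rho = NULL) {
  if (is.null(amplitude) == is.null(rho))
    stop("specify exactly one of amplitude or rho")
  if (!is.null(rho) && abs(rho) > 1) stop("|rho| must be <= 1")
  if (base <= 0) stop("base separation must be positive")
  structure(list(res_a = as.integer(res_a), res_b = as.integer(res_b),
                 chain = as.character(chain), base = base,
                 amplitude = amplitude, rho = rho),
            class = "coupled_pair")
}

#' Default coupled pairs
#'
#' Two pairs emulating the study conditions: an intra-protomer pair (chain A,
#' 309-316) switching between a ~4 Angstrom closed contact and a ~14 Angstrom
#' open separation, and an opposing-protomer pair (chain B, 295-316)
#' anti-coupled to it (14 -> 4 Angstrom), producing the compensating,
#' L-shaped joint occupancy.
#'
#' @return List of two [coupled_pair()]s.
#' @export
default_coupled_pairs <- function() {
  list(coupled_pair(309L, 316L, chain = "A", base = 4, amplitude = 10),
       coupled_pair(295L, 316L, chain = "B", base = 14, amplitude = -10))
}

# ring atom coordinates: regular polygon of the residue's ring atoms around
# `center`, lying in the plane perpendicular to `normal`.
make_ring_coords <- function(resname, center, normal = c(0, 0, 1),
                             bond = 1.39, rule = default_ring_rule()) {
  atoms <- rule[[resname]]
  if (is.null(atoms)) stop("no ring rule for residue name '", resname, "'")
  k <- length(atoms)
  # circumradius of a regular k-gon with the given edge length
  radius <- bond / (2 * sin(pi / k))
  normal <- normal / sqrt(sum(normal^2))
  seed_axis <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed_axis - sum(seed_axis * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  theta <- 2 * pi * (seq_len(k) - 1) / k
  xyz <- t(vapply(theta, function(a)
    center + radius * (cos(a) * u + sin(a) * v), numeric(3)))
  list(names = atoms, xyz = xyz)
}

#' Build a toy structure with planted ring geometry
#'
#' Emits regular aromatic rings (default C-C bond 1.39 Angstrom) whose
#' centroids equal the requested centers exactly, plus an optional CA marker
#' atom per residue, and returns the structure (optionally writing a PDB).
#' This is a synthetic fixture generator: the geometry is planted, not taken
#' from any experimental structure.
#'
#' @param rings Data frame with columns `resname`, `chain`, `resno`, `x`,
#'   `y`, `z` (centroid, Angstrom).  Duplicate (chain, resno) keys error.
#' @param path Optional PDB output path.
#' @param include_ca Also place a CA atom 2 Angstrom above each ring centre
#'   (handy for selection tests); default `TRUE`.
#' @param ring_rule See [default_ring_rule()].
#' @return A [structure_model()] (written to `path` when given).
#' @export
generate_toy_structure <- function(rings, path = NULL, include_ca = TRUE,
                                   ring_rule = default_ring_rule()) {
  stopifnot(is.data.frame(rings),
            all(c("resname", "chain", "resno", "x", "y", "z") %in% names(rings)))
  key <- paste(rings$chain, rings$resno)
  if (anyDuplicated(key)) stop("duplicate residue keys in ring table")
  rows <- list()
  xyz <- NULL
  for (i in seq_len(nrow(rings))) {
    center <- c(rings$x[i], rings$y[i], rings$z[i])
    ring <- make_ring_coords(rings$resname[i], center, rule = ring_rule)
    nm <- ring$names
    coords <- ring$xyz
    if (include_ca) {
      nm <- c("CA", nm)
      coords <- rbind(center + c(0, 0, 2), coords)
    }
    rows[[i]] <- data.frame(elety = nm,
                            elesy = substr(nm, 1L, 1L),
                            resno = rings$resno[i],
                            resid = rings$resname[i],
                            chain = rings$chain[i],
                            insert = "",
                            stringsAsFactors = FALSE)
    xyz <- rbind(xyz, coords)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$is_heavy <- atoms$elesy != "H"
  out <- structure_model(atoms, xyz)
  if (!is.null(path)) write_structure(out, path)
  out
}

#' Planted-geometry aromatic cluster structure
#'
#' A five-ring synthetic structure whose centroid distance matrix spans
#' exactly 3.9 to 9.5 Angstrom, mirroring the centre-to-centre range of the
#' crystallographic aromatic cluster; residue numbers follow the
#' *D. radiodurans* cluster (295, 302, 303, 309, 316 on chain A).
#'
#' @param path Optional PDB output path.
#' @return List with `structure` ([structure_model()]), `cluster`
#'   ([cluster_spec()]) and `truth` (the planted centroid matrix and its
#'   min/max of 3.9 and 9.5 Angstrom).
#' @export
synthetic_cluster_structure <- function(path = NULL) {
  centers <- rbind(c(0, 0, 0),
                   c(3.9, 0, 0),
                   c(9.5, 0, 0),
                   c(4.75, 5, 0),
                   c(4.75, 2.5, 4.33))
  rings <- data.frame(resname = c("TYR", "PHE", "PHE", "TYR", "PHE"),
                      chain = "A",
                      resno = c(295L, 302L, 303L, 309L, 316L),
                      x = centers[, 1], y = centers[, 2], z = centers[, 3])
  st <- generate_toy_structure(rings, path = path)
  spec <- cluster_spec(data.frame(chain = rings$chain, resno = rings$resno,
                                  resname = rings$resname))
  dmat <- as.matrix(stats::dist(centers))
  off <- dmat[upper.tri(dmat)]
  list(structure = st, cluster = spec,
       truth = list(distances = dmat, min = min(off), max = max(off)))
}

#' Generate a trajectory with one slow coupled mode and known ground truth
#'
#' The latent state `s(t)` is a two-state (0/1) telegraph process with
#' per-frame switch probabilities `rate_up`/`rate_down`.  A set of backbone
#' CA atoms is displaced by `mode_amplitude * s(t)` along a unit 3N mode
#' vector, each coupled aromatic ring pair changes its centroid separation
#' by `amplitude * s(t)`, and isotropic Gaussian noise of width
#' `noise_sigma` is added to every coordinate of every frame.
#'
#' For a pair specified by target correlation `rho` (against the PC1
#' projection of the CA atoms), the amplitude is derived from the analytic
#' small-displacement model: with `q = p(1-p)` the stationary state variance
#' factor, the distance/state correlation is
#' `rho_d = a*sqrt(q) / sqrt(a^2*q + sigma_eta^2)` with ring-centroid
#' distance noise `sigma_eta = noise_sigma * sqrt(1/6 + 1/6)`, and the
#' PC1-projection/state correlation is
#' `rho_proj = A*sqrt(q) / sqrt(A^2*q + noise_sigma^2)` for mode amplitude
#' `A`; the planted distance/PC1 correlation is their product, so the
#' generator solves `a` from `rho_d = rho / rho_proj`.  Values of `rho`
#' beyond the attainable bound `rho_proj` error out, reporting the bound.
#'
#' @param n_frames Number of frames (default 20000).
#' @param n_ca Number of backbone CA atoms carrying the global mode.
#' @param mode_amplitude State-1 displacement amplitude along the mode
#'   (Angstrom, default 3).
#' @param rate_up,rate_down Per-frame switch probabilities in (0, 1)
#'   (default 0.005 each: dwell times of ~200 frames, slow against the frame
#'   rate yet well-mixed over the default trajectory length).
#' @param coupled_pairs List of [coupled_pair()]s
#'   (default [default_coupled_pairs()]).
#' @param noise_sigma Thermal noise width per coordinate (Angstrom,
#'   default 0.1).
#' @param mode_vector Optional length `3 * n_ca` mode direction (normalised
#'   internally); default a seeded random unit vector.
#' @param frame_interval Informational frame spacing in ps (default 4).
#' @param seed Integer seed fixing the full output.
#' @return List with `trajectory` (a [trajectory()]; CA atoms are chain A
#'   residues 1..n_ca, rings are PHE residues per the pair specs) and
#'   `truth`: `state_series`, `state_prob`, `mode_ca` (unit planted mode on
#'   the CA atoms), `mode_variance` (analytic PC1 signal variance
#'   `A^2 * p(1-p)`), `rho_proj`, and `pairs` (data frame with label, base,
#'   amplitude, expected_r and the two state separations).
#' @export
generate_coupled_trajectory <- function(n_frames = 20000L, n_ca = 20L,
                                        mode_amplitude = 3,
                                        rate_up = 0.005, rate_down = 0.005,
                                        coupled_pairs = default_coupled_pairs(),
                                        noise_sigma = 0.1,
                                        mode_vector = NULL,
                                        frame_interval = 4,
                                        seed = 1L) {
  if (rate_up <= 0 || rate_up >= 1 || rate_down <= 0 || rate_down >= 1)
    stop("switch rates must lie in (0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  n_frames <- as.integer(n_frames)
  p <- rate_up / (rate_up + rate_down)      # stationary P(state = 1)
  q <- p * (1 - p)
  rho_proj <- if (noise_sigma == 0) 1 else
    mode_amplitude * sqrt(q) /
      sqrt(mode_amplitude^2 * q + noise_sigma^2)
  sigma_eta <- noise_sigma * sqrt(1 / 6 + 1 / 6)

  # resolve pair amplitudes
  pair_tab <- lapply(coupled_pairs, function(cp) {
    stopifnot(inherits(cp, "coupled_pair"))
    amp <- cp$amplitude
    if (is.null(amp)) {
      rho <- cp$rho
      if (rho == 0) {
        amp <- 0
      } else if (noise_sigma == 0) {
        if (abs(rho) != 1)
          stop("with noise_sigma = 0 only rho in {-1, 0, 1} is attainable")
        amp <- sign(rho) * 1
      } else {
        rho_d <- rho / rho_proj
        if (abs(rho_d) >= 1)
          stop(sprintf(
            "target rho = %.3f exceeds the attainable bound %.4f for this noise level",
            rho, rho_proj))
        amp <- sign(rho_d) * abs(rho_d) * sigma_eta /
          (sqrt(q) * sqrt(1 - rho_d^2))
      }
    }
    rho_d_eff <- if (amp == 0) 0 else if (noise_sigma == 0) sign(amp) else
      amp * sqrt(q) / sqrt(amp^2 * q + sigma_eta^2)
    c(cp, list(amplitude_eff = amp, expected_r = rho_d_eff * rho_proj))
  })

  # topology: CA backbone (chain A, residues 1..n_ca) + one PHE ring pair
  # per coupled pair, rings facing each other along x
  ca_xyz <- cbind(3.8 * seq_len(n_ca), 2 * sin(seq_len(n_ca)),
                  2 * cos(seq_len(n_ca)))
  atoms <- data.frame(elety = rep("CA", n_ca), elesy = "C",
                      resno = seq_len(n_ca), resid = "GLY", chain = "A",
                      insert = "", stringsAsFactors = FALSE)
  xyz <- ca_xyz
  disp <- matrix(0, n_ca, 3L)
  ring_rule <- default_ring_rule()
  keys <- character(0)
  for (j in seq_along(pair_tab)) {
    cp <- pair_tab[[j]]
    y0 <- 40 * j
    for (side in 1:2) {
      resno <- if (side == 1L) cp$res_a else cp$res_b
      key <- paste(cp$chain, resno)
      if (key %in% keys) stop("duplicate residue key in coupled pairs: ", key)
      keys <- c(keys, key)
      cx <- (if (side == 1L) -1 else 1) * cp$base / 2
      ring <- make_ring_coords("PHE", c(cx, y0, 0), normal = c(1, 0, 0),
                               rule = ring_rule)
      atoms <- rbind(atoms, data.frame(elety = ring$names, elesy = "C",
                                       resno = resno, resid = "PHE",
                                       chain = cp$chain, insert = "",
                                       stringsAsFactors = FALSE))
      xyz <- rbind(xyz, ring$xyz)
      shift <- (if (side == 1L) -1 else 1) * cp$amplitude_eff / 2
      disp <- rbind(disp, matrix(rep(c(shift, 0, 0), each = nrow(ring$xyz)),
                                 ncol = 3L))
    }
  }
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$is_heavy <- TRUE
  topology <- structure_model(atoms, xyz)
  na <- nrow(atoms)

  # planted global mode on the CA atoms: an internal mode, i.e. orthogonal
  # to the rigid-body subspace (net translation/rotation), since
  # superposition removes that subspace before PCA
  set.seed(derive_seed(seed, 1L))
  if (is.null(mode_vector)) mode_vector <- stats::rnorm(3L * n_ca)
  if (length(mode_vector) != 3L * n_ca)
    stop("mode_vector must have length 3 * n_ca")
  mode_vector <- project_out_rigid(mode_vector, ca_xyz)
  mode_vector <- mode_vector / sqrt(sum(mode_vector^2))
  disp[seq_len(n_ca), ] <- mode_amplitude *
    matrix(mode_vector, ncol = 3L, byrow = TRUE)

  # telegraph state
  set.seed(derive_seed(seed, 2L))
  s <- integer(n_frames)
  s[1L] <- stats::rbinom(1L, 1L, p)
  if (rate_up == rate_down) {
    flips <- stats::runif(n_frames - 1L) < rate_up
    s <- (s[1L] + c(0L, cumsum(flips))) %% 2L
  } else {
    u <- stats::runif(n_frames - 1L)
    for (f in 2:n_frames) {
      pr <- if (s[f - 1L] == 0L) rate_up else rate_down
      s[f] <- if (u[f - 1L] < pr) 1L - s[f - 1L] else s[f - 1L]
    }
  }

  set.seed(derive_seed(seed, 3L))
  coords <- array(NA_real_, dim = c(n_frames, na, 3L))
  for (d in 1:3) {
    noise <- if (noise_sigma > 0)
      matrix(stats::rnorm(n_frames * na, 0, noise_sigma), n_frames, na)
    else 0
    coords[, , d] <- outer(s, disp[, d]) + noise +
      matrix(xyz[, d], n_frames, na, byrow = TRUE)
  }

  pairs_df <- do.call(rbind, lapply(pair_tab, function(cp) data.frame(
    label = sprintf("PRO%s:%d-%d", cp$chain, cp$res_a, cp$res_b),
    chain = cp$chain, res_a = cp$res_a, res_b = cp$res_b,
    base = cp$base, amplitude = cp$amplitude_eff,
    expected_r = cp$expected_r,
    d_state0 = cp$base, d_state1 = cp$base + cp$amplitude_eff,
    stringsAsFactors = FALSE)))

  list(trajectory = trajectory(topology, coords, frame_interval),
       truth = list(state_series = s, state_prob = p,
                    mode_ca = mode_vector,
                    mode_amplitude = mode_amplitude,
                    mode_variance = mode_amplitude^2 * q,
                    rho_proj = rho_proj,
                    noise_sigma = noise_sigma,
                    pairs = pairs_df))
}

#' Generate an alignment fixture with planted aromatic counts
#'
#' Builds a gapless alignment whose scan with [scan_msa_aromatics()]
#' reproduces `counts` exactly: within the window columns each sequence
#' carries its requested number of aromatic letters (drawn from F/Y/W) at
#' seeded random positions, all other columns hold non-aromatic letters.
#'
#' @param counts Named integer vector: aromatic count per sequence
#'   (default [default_homolog_counts()], the 16-homolog emulation).
#' @param windows [motif_windows()] for the fixture (default spoon 11-40,
#'   fork 41-55 on a 60-column alignment).
#' @param n_columns Alignment width.
#' @param seed Integer seed.
#' @return List with `msa` (an [msa()]) and `truth` (`counts`, `windows`).
#' @export
generate_msa_fixture <- function(counts = default_homolog_counts(),
                                 windows = NULL, n_columns = 60L,
                                 seed = 1L) {
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts must be a named vector")
  if (is.null(windows))
    windows <- motif_windows(spoon = c(11L, 40L), fork = c(41L, 55L))
  cols <- window_columns(windows)
  if (max(cols) > n_columns) stop("windows exceed the alignment width")
  if (any(counts > length(cols)))
    stop("impossible spec: a count exceeds the total window width")
  if (any(counts < 0)) stop("counts must be non-negative")
  set.seed(derive_seed(seed, 11L))
  bg <- non_aromatic_letters()
  seqs <- vapply(seq_along(counts), function(i) {
    row <- sample(bg, n_columns, replace = TRUE)
    k <- counts[[i]]
    if (k > 0) {
      at <- if (length(cols) == 1L) cols else sample(cols, k)
      row[at] <- sample(c("F", "Y", "W"), k, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1))
    }
    paste(row, collapse = "")
  }, character(1))
  list(msa = msa(names(counts), seqs),
       truth = list(counts = counts, windows = windows))
}

#' Aromatic counts of the 16-homolog emulation
#'
#' The four counts of the named homologs (Ec 3, Dr 5, Pa 2, Mtb 1) plus
#' twelve synthetic homologs chosen so that exactly 9 of the 16 sequences
#' carry three aromatic residues, the modal configuration.  The
#' twelve extra assignments are an emulation, not homolog data.
#'
#' @return Named integer vector of length 16.
#' @export
default_homolog_counts <- function() {
  c(Ec = 3L, Dr = 5L, Pa = 2L, Mtb = 1L,
    Kp = 3L, St = 3L, Vc = 3L, Hi = 3L, Yp = 3L, Ab = 3L, Se = 3L, Ng = 3L,
    Bs = 2L, Sa = 4L, Lm = 4L, Ct = 2L)
}

#' Generate Michaelis-Menten initial-velocity data
#'
#' @param vmax,km True parameters.
#' @param S Substrate concentrations (default a 7-point series spanning
#'   `km/8` to `~13*km`).
#' @param sigma Gaussian noise width on velocities (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `data` (data frame `S`, `v`) and `truth`.
#' @export
generate_mm_data <- function(vmax = 0.083, km = 39,
                             S = c(5, 10, 25, 50, 100, 250, 500),
                             sigma = 0, seed = 1L) {
  if (vmax <= 0 || km <= 0) stop("vmax and km must be positive")
  v <- mm_velocity(vmax, km, S)
  if (sigma > 0) {
    set.seed(derive_seed(seed, 21L))
    v <- v + stats::rnorm(length(S), 0, sigma)
  }
  list(data = data.frame(S = S, v = v),
       truth = list(vmax = vmax, km = km, sigma = sigma))
}

#' Generate a logistic CD222 melt curve
#'
#' `cd222 = baseline + amplitude / (1 + exp(-(T - tm) / slope))`: the
#' first-derivative maximum of the noiseless curve sits exactly at `tm`.
#'
#' @param tm Midpoint (deg C, default 74, a WT-like apparent Tm).
#' @param slope Transition width parameter (deg C).
#' @param amplitude Signal change across the transition (mdeg).
#' @param baseline Pre-transition CD222 (mdeg).
#' @param temperature Sampling temperatures (default 20-88 deg C by 1).
#' @param sigma Gaussian noise width (mdeg).
#' @param seed Integer seed.
#' @return List with `data` (data frame `temperature`, `cd222`) and `truth`.
#' @export
generate_melt_curve <- function(tm = 74, slope = 2, amplitude = 15,
                                baseline = -20,
                                temperature = seq(20, 88, by = 1),
                                sigma = 0, seed = 1L) {
  if (slope <= 0) stop("slope must be positive")
  cd <- baseline + amplitude / (1 + exp(-(temperature - tm) / slope))
  if (sigma > 0) {
    set.seed(derive_seed(seed, 22L))
    cd <- cd + stats::rnorm(length(cd), 0, sigma)
  }
  list(data = data.frame(temperature = temperature, cd222 = cd),
       truth = list(tm = tm, slope = slope))
}

#' Generate an exponential CD timecourse
#'
#' Formation: `baseline + amplitude * (1 - exp(-rate * t))` (adduct
#' build-up); depletion: `baseline + amplitude * exp(-rate * t)`.
#'
#' @param mode `"formation"` or `"depletion"`.
#' @param amplitude Signal amplitude (mdeg).
#' @param rate First-order rate constant (s^-1, positive).
#' @param baseline Baseline signal (mdeg).
#' @param times Sampling times (s, default every 10 s over 13 min).
#' @param sigma Gaussian noise width (mdeg).
#' @param seed Integer seed.
#' @return List with `data` (data frame `time`, `cd313`) and `truth`
#'   (including `t95`, the time to 95% completion).
#' @export
generate_cd_timecourse <- function(mode = c("formation", "depletion"),
                                   amplitude = 3.6, rate = log(20) / 60,
                                   baseline = 0, times = seq(0, 780, by = 10),
                                   sigma = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (rate <= 0) stop("rate constant must be positive")
  cd <- if (mode == "formation")
    baseline + amplitude * (1 - exp(-rate * times))
  else baseline + amplitude * exp(-rate * times)
  if (sigma > 0) {
    set.seed(derive_seed(seed, 23L))
    cd <- cd + stats::rnorm(length(cd), 0, sigma)
  }
  list(data = data.frame(time = times, cd313 = cd),
       truth = list(mode = mode, amplitude = amplitude, rate = rate,
                    t95 = time_to_fraction(rate, 0.95)))
}

#' Time to reach a fraction of an exponential amplitude
#'
#' For first-order formation `A * (1 - exp(-k t))`, the time to reach
#' fraction `f` of the final amplitude is `t_f = -ln(1 - f) / k`
#' (e.g. `t95 = ln(20) / k`).
#'
#' @param rate First-order rate constant (positive).
#' @param fraction Fraction of the final amplitude in (0, 1).
#' @return Time in the rate constant's inverse units.
#' @export
time_to_fraction <- function(rate, fraction = 0.95) {
  if (rate <= 0) stop("rate constant must be positive")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  -log(1 - fraction) / rate
}
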