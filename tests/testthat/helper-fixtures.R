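# Fixture builders used across the suite; everything is generated in code.

# Minimal CA-only protein: one CA atom per residue on a line.
make_ca_protein <- function(n_res = 3L, chain = "A") {
  atoms <- data.frame(
    eleno = seq_len(n_res), elety = "CA", elesy = "C",
    resno = seq_len(n_res), resid = "GLY", chain = chain, insert = "",
    is_heavy = TRUE, stringsAsFactors = FALSE)
  structure_model(atoms, cbind(3.8 * seq_len(n_res), 0, 0))
}

# Protein + PLT ligand with 5 heavy atoms and 2 hydrogens.
make_ligand_system <- function() {
  prot <- make_ca_protein(3L)
  lig <- data.frame(
    eleno = 1:7,
    elety = c("C1", "C2", "O1", "N1", "P1", "H1", "H2"),
    elesy = c("C", "C", "O", "N", "P", "H", "H"),
    resno = 900L, resid = "PLT", chain = "A", insert = "",
    is_heavy = c(rep(TRUE, 5), FALSE, FALSE), stringsAsFactors = FALSE)
  atoms <- rbind(prot$atoms, lig)
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms, rbind(prot$xyz, matrix(runif(21, 10, 12), 7, 3)))
}

# Random toy topology for selection-algebra property tests.
make_random_topology <- function(n_atoms, seed) {
  set.seed(seed)
  elesy <- sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
  atoms <- data.frame(
    eleno = seq_len(n_atoms),
    elety = paste0(elesy, sample(1:3, n_atoms, replace = TRUE)),
    elesy = elesy,
    resno = sort(sample(1:8, n_atoms, replace = TRUE)),
    resid = sample(c("ALA", "PHE", "PLT"), n_atoms, replace = TRUE),
    chain = sample(c("A", "B"), n_atoms, replace = TRUE),
    insert = "", is_heavy = elesy != "H", stringsAsFactors = FALSE)
  structure_model(atoms, matrix(rnorm(3 * n_atoms, sd = 5), n_atoms, 3))
}

# A trajectory built directly from a list of coordinate matrices.
make_traj <- function(topology, frames) {
  coords <- array(NA_real_, dim = c(length(frames), n_atoms_of(topology), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(topology, coords)
}

n_atoms_of <- function(topology) nrow(topology$atoms)

# Uniformly random 3x3 rotation matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Textbook Pearson correlation from direct sums (independent oracle).
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Ring atoms of one residue in a generated toy structure (CA marker excluded).
ring_atom_indices_for_test <- function(st, chain, resno) {
  which(st$atoms$chain == chain & st$atoms$resno == resno &
          st$atoms$elety != "CA")
}

# Minimal PDB text writer for hand-crafted read_structure fixtures.
pdb_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          eleno, paste0(" ", elety), alt, resid, chain, resno, x, y, z, occ, 0)
}
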