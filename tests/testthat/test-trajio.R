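test_that("read_structure parses single records and selects models", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3), "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(unname(st$xyz[1, ]), c(1, 2, 3))
  expect_equal(st$atoms$elety, "CA")
  expect_true(st$atoms$is_heavy)

  two <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
               "ENDMDL",
               "MODEL     2",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 5, 6, 7),
               "ENDMDL", "END"), two)
  expect_equal(unname(read_structure(two, model_index = 2)$xyz[1, ]), c(5, 6, 7))
  expect_equal(unname(read_structure(two, model_index = 1)$xyz[1, ]), c(0, 0, 0))
  expect_error(read_structure(two, model_index = 3), "out of range")
  expect_error(read_structure(file.path(tempdir(), "absent.pdb")), "not found")
})

test_that("altloc resolution keeps the highest occupancy, tie goes to A", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
               pdb_atom_line(2, "CA", "GLY", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
               pdb_atom_line(3, "CB", "GLY", "A", 1, 1, 1, 1, occ = 0.5, alt = "A"),
               pdb_atom_line(4, "CB", "GLY", "A", 1, 8, 8, 8, occ = 0.5, alt = "B"),
               "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 2L)
  expect_equal(unname(st$xyz[st$atoms$elety == "CA", ]), c(9, 9, 9)) # occupancy wins
  expect_equal(unname(st$xyz[st$atoms$elety == "CB", ]), c(1, 1, 1)) # tie -> A
})

test_that("structure write/read round trip reproduces the atom table", {
  cl <- synthetic_cluster_structure()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cl$structure, path)
  st2 <- read_structure(path)
  expect_identical(st2$atoms$elety, cl$structure$atoms$elety)
  expect_identical(st2$atoms$resno, cl$structure$atoms$resno)
  expect_identical(st2$atoms$resid, cl$structure$atoms$resid)
  expect_identical(st2$atoms$chain, cl$structure$atoms$chain)
  expect_lt(max(abs(st2$xyz - cl$structure$xyz)), 5e-4) # 3-decimal precision
})

test_that("frames-text trajectories read, convert units and round-trip", {
  topo <- make_ca_protein(1L)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "0.0 0.0 0.0", "1.0 2.0 3.0"), path)
  traj <- read_trajectory(topo, path, "frames-text")
  expect_equal(n_frames(traj), 2L)
  expect_equal(unname(traj$coords[2, 1, ]), c(1, 2, 3))

  nmfile <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 nm", "0.5 0.0 0.0"), nmfile)
  expect_equal(read_trajectory(topo, nmfile, "frames-text")$coords[1, 1, 1], 5.0)

  trunc <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2", "0 0 0"), trunc)
  expect_error(read_trajectory(make_ca_protein(2L), trunc, "frames-text"),
               "truncated")
  expect_error(read_trajectory(make_ca_protein(2L), path, "frames-text"),
               "mismatch")
  expect_error(read_trajectory(topo, path, "xtc"), "XTC")

  sim <- generate_coupled_trajectory(
    n_frames = 4L, n_ca = 4L, seed = 3L,
    coupled_pairs = list(coupled_pair(9L, 16L, base = 4, amplitude = 2)))
  out <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(sim$trajectory, out)
  back <- read_trajectory(sim$trajectory$topology, out, "frames-text")
  expect_lt(max(abs(back$coords - sim$trajectory$coords)), 5e-4)
})

test_that("nm-based and Angstrom-based text encodings agree (unit law)", {
  sim <- generate_coupled_trajectory(
    n_frames = 3L, n_ca = 4L, seed = 5L,
    coupled_pairs = list(coupled_pair(9L, 16L, base = 4, amplitude = 2)))
  fa <- withr::local_tempfile(); fn <- withr::local_tempfile()
  # write in full precision in both unit systems to probe the conversion,
  # not the 3-decimal text rounding
  m <- sim$trajectory$coords
  writeLines(c(paste(dim(m)[2], "angstrom"),
               apply(matrix(aperm(m, c(3, 2, 1)), nrow = 3), 2,
                     function(v) paste(sprintf("%.8f", v), collapse = " "))), fa)
  writeLines(c(paste(dim(m)[2], "nm"),
               apply(matrix(aperm(m, c(3, 2, 1)), nrow = 3) / 10, 2,
                     function(v) paste(sprintf("%.9f", v), collapse = " "))), fn)
  ta <- read_trajectory(sim$trajectory$topology, fa, "frames-text")
  tn <- read_trajectory(sim$trajectory$topology, fn, "frames-text")
  expect_lt(max(abs(ta$coords - tn$coords)), 1e-6)
})

test_that("multi-model PDB files read as trajectories", {
  topo <- make_ca_protein(1L)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0), "ENDMDL",
               "MODEL     2",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 1, 1), "ENDMDL",
               "END"), path)
  traj <- read_trajectory(topo, path, "multi-model-pdb")
  expect_equal(n_frames(traj), 2L)
  expect_equal(unname(traj$coords[2, 1, ]), c(1, 1, 1))
})

test_that("selection grammar picks named atoms, residues and heavies", {
  prot <- make_ca_protein(3L)
  expect_equal(as.integer(select_atoms(prot, "name CA")), 1:3)

  sys <- make_ligand_system()
  expect_equal(length(select_atoms(sys, "resname PLT and heavy")), 5L)
  both <- select_atoms(sys, "name CA or (resname PLT and heavy)")
  manual <- sort(union(which(sys$atoms$elety == "CA"),
                       which(sys$atoms$resid == "PLT" & sys$atoms$is_heavy)))
  expect_equal(as.integer(both), manual)
  expect_equal(length(select_atoms(sys, "resnum 1-2")), 2L)
  expect_error(select_atoms(sys, "resname XXX"), "empty selection")
  expect_error(select_atoms(sys, "frobnicate CA"), "syntax")
  expect_error(select_atoms(sys, "name CA or"), "syntax|unexpected end")
})

test_that("selection algebra matches set union and intersection", {
  for (seed in 1:5) {
    topo <- make_random_topology(40L, seed)
    a <- "resname PHE"; b <- "chain B and heavy"
    mask_a <- topo$atoms$resid == "PHE"
    mask_b <- topo$atoms$chain == "B" & topo$atoms$is_heavy
    if (!any(mask_a) || !any(mask_b) || !any(mask_a & mask_b)) next
    expect_equal(as.integer(select_atoms(topo, paste(a, "or", b))),
                 sort(union(which(mask_a), which(mask_b))))
    expect_equal(as.integer(select_atoms(topo, paste(a, "and", b))),
                 sort(intersect(which(mask_a), which(mask_b))))
  }
})

test_that("alignments read from FASTA and Clustal with invariants enforced", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDEFGHIKL", ">s2", "acdefg-ikl"), fa)
  aln <- read_msa(fa, "fasta")
  expect_equal(aln$n_columns, 10L)
  expect_equal(aln$ids, c("s1", "s2"))
  expect_equal(aln$seqs[2], "ACDEFG-IKL") # case-normalised

  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1    ACDEFGHIKL", "s2    ACDEFG-IKL"), cl)
  aln2 <- read_msa(cl, "clustal")
  expect_equal(aln2$seqs, aln$seqs)

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDEF", ">s2", "ACD"), ragged)
  expect_error(read_msa(ragged, "fasta"))
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_msa(empty, "fasta"), "empty")

  fx <- generate_msa_fixture(seed = 2L)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_msa(fx$msa, out)
  back <- read_msa(out, "fasta")
  expect_equal(length(back$ids), 16L)
  expect_identical(back$seqs, fx$msa$seqs)
})
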