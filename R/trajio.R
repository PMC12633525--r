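# Structure, trajectory, selection and alignment input/output.
#
# Conventions used throughout the package:
#   * atom indices are 1-based and follow file order;
#   * author (file) residue numbering is preserved verbatim, never renumbered;
#   * all coordinates are Angstrom internally; all distances are reported in
#     Angstrom.

#' Construct a structure model
#'
#' A `structure_model` is the atom universe every other module works on.  It
#' holds one conformation of a molecular system: an atom table (file order,
#' author residue numbering) and an `n_atoms x 3` coordinate matrix in
#' Angstrom.
#'
#' @param atoms Data frame with columns `eleno` (1-based atom index, file
#'   order), `elety` (atom name), `elesy` (element symbol), `resno`
#'   (author-assigned residue number), `resid` (3-letter residue name),
#'   `chain` (chain identifier), `insert` (insertion code, `""` if none) and
#'   `is_heavy` (logical, `TRUE` unless the element is hydrogen).
#' @param xyz Numeric matrix, `nrow(atoms)` rows and 3 columns, Angstrom.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  required <- c("eleno", "elety", "elesy", "resno", "resid", "chain",
                "insert", "is_heavy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("structure has no atoms")
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L)
    stop("coordinate matrix must be n_atoms x 3")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in structure")
  if (!identical(as.integer(atoms$eleno), seq_len(nrow(atoms))))
    stop("atom indices must be unique and contiguous from 1 in file order")
  atoms$is_heavy <- atoms$elesy != "H"
  obj <- list(atoms = atoms, xyz = xyz)
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chain(s) %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

# Element symbol from a PDB atom name when the element column is blank.
# Digit-leading hydrogen names ("1HB") and two-character organics are handled;
# metal disambiguation (CA calcium vs C-alpha) is out of scope for protein use.
guess_element <- function(elety) {
  stripped <- gsub("[^A-Za-z]", "", elety)
  first <- toupper(substr(stripped, 1L, 1L))
  ifelse(first == "", "X", first)
}

#' Read a structure from a PDB file
#'
#' Parses `ATOM`/`HETATM` records (via \pkg{bio3d}) preserving file order and
#' author residue numbering.  Hydrogens are retained and flagged, never
#' dropped; selections decide what to keep.  When several alternate locations
#' are present for an atom, the highest-occupancy conformer is kept, with ties
#' broken in favour of altloc `A`.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model to take from a multi-model file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models)
    stop(sprintf("model_index %d out of range (file has %d model(s))",
                 model_index, n_models))
  at <- pdb$atom
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
  elesy <- ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety),
                  toupper(trimws(at$elesy)))
  atoms <- data.frame(
    eleno = seq_len(nrow(at)),
    elety = trimws(at$elety),
    elesy = elesy,
    resno = as.integer(at$resno),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    is_heavy = elesy != "H",
    stringsAsFactors = FALSE)
  structure_model(atoms, xyz)
}

# Keep one altloc per atom site: highest occupancy, tie -> 'A' (then first).
resolve_altloc <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (all(alt == "")) return(rep(TRUE, nrow(at)))
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[occ[idx] == max(occ[idx])]
    if (length(best) > 1L && any(alt[best] == "A")) best <- best[alt[best] == "A"]
    keep[setdiff(idx, best[1L])] <- FALSE
  }
  keep
}

#' Write a structure to a PDB file
#'
#' @param structure A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   resno = at$resno, resid = at$resid,
                   eleno = at$eleno, elety = at$elety,
                   chain = ifelse(at$chain == "", NA, at$chain),
                   insert = ifelse(at$insert == "", NA, at$insert),
                   elesy = at$elesy)
  invisible(path)
}

#' Construct a trajectory
#'
#' @param topology A [structure_model()] describing the atoms.
#' @param coords Numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param frame_interval Time per saved frame in ps (informational).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, frame_interval = NA_real_) {
  stopifnot(inherits(topology, "structure_model"))
  coords <- unclass(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != n_atoms(topology) ||
      dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array matching the topology")
  if (dim(coords)[1] < 1L) stop("trajectory must have at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  obj <- list(topology = topology, coords = coords,
              frame_interval = frame_interval)
  class(obj) <- "trajectory"
  obj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms (frame interval %s ps)\n",
              n_frames(x), dim(x$coords)[2],
              ifelse(is.na(x$frame_interval), "?", format(x$frame_interval))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a coordinate trajectory
#'
#' Supported formats:
#' \describe{
#'   \item{`frames-text`}{Plain-text dialect defined by this package so the
#'     full pipeline is testable with zero binary-format dependencies.  The
#'     header line is `n_atoms` optionally followed by a unit token
#'     (`angstrom`, the default, or `nm`); then each frame is `n_atoms` lines
#'     of `x y z`.  nm input is converted to Angstrom on read.}
#'   \item{`multi-model-pdb`}{Each `MODEL` block is one frame.}
#'   \item{`dcd`}{CHARMM/NAMD binary trajectories, via \pkg{bio3d}.}
#'   \item{`xtc`}{Not supported: no XTC reader is available to R here.
#'     Requesting it raises an error suggesting the DCD or frames-text routes
#'     (frames-text accepts nm units, covering XTC-style input after a text
#'     dump).}
#' }
#'
#' @param topology A [structure_model()]; the frame atom count must match.
#' @param path Path to the trajectory file.
#' @param format One of `"frames-text"`, `"multi-model-pdb"`, `"dcd"`, `"xtc"`.
#' @param frame_interval Time per saved frame in ps (informational).
#' @return A [trajectory()] with coordinates in Angstrom.
#' @export
read_trajectory <- function(topology, path,
                            format = c("frames-text", "multi-model-pdb",
                                       "dcd", "xtc"),
                            frame_interval = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  na <- n_atoms(topology)
  if (format == "frames-text") {
    header <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
    file_atoms <- suppressWarnings(as.integer(header[1L]))
    if (is.na(file_atoms)) stop("frames-text header must start with the atom count")
    unit <- if (length(header) >= 2L) tolower(header[2L]) else "angstrom"
    scale <- switch(unit, angstrom = 1, a = 1, nm = 10,
                    stop("unknown unit in frames-text header: ", unit))
    if (file_atoms != na)
      stop(sprintf("atom-count mismatch: topology has %d, file declares %d",
                   na, file_atoms))
    vals <- scan(path, what = double(), skip = 1L, quiet = TRUE)
    if (length(vals) == 0L) stop("frames-text file contains no frames")
    if (length(vals) %% (3L * na) != 0L)
      stop("truncated frame: coordinate count is not a multiple of 3 * n_atoms")
    nf <- length(vals) %/% (3L * na)
    # file layout: frames stacked, one atom per line => fill rows of (x,y,z)
    per_frame <- matrix(vals, ncol = 3L, byrow = TRUE) * scale
    coords <- array(NA_real_, dim = c(nf, na, 3L))
    for (f in seq_len(nf))
      coords[f, , ] <- per_frame[((f - 1L) * na + 1L):(f * na), , drop = FALSE]
  } else if (format == "multi-model-pdb") {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
    xyz <- pdb$xyz
    if (ncol(xyz) != 3L * na)
      stop(sprintf("atom-count mismatch: topology has %d, file has %d",
                   na, ncol(xyz) %/% 3L))
    nf <- nrow(xyz)
    coords <- array(NA_real_, dim = c(nf, na, 3L))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  } else if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3L * na)
      stop(sprintf("atom-count mismatch: topology has %d, file has %d",
                   na, ncol(xyz) %/% 3L))
    nf <- nrow(xyz)
    coords <- array(NA_real_, dim = c(nf, na, 3L))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  } else {
    stop("no XTC reader is available; convert the trajectory to DCD or to ",
         "the frames-text dialect (which accepts nm units in its header)")
  }
  trajectory(topology, coords, frame_interval)
}

#' Write a trajectory in the frames-text dialect
#'
#' Coordinates are written with 3 decimals (the dialect's declared precision);
#' `units = "nm"` divides by 10 on output and declares `nm` in the header.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  scale <- if (units == "nm") 0.1 else 1
  na <- dim(traj$coords)[2]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(na, units), con)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f) * scale
    writeLines(sprintf("%.3f %.3f %.3f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selections

#' Select atoms with a small selection grammar
#'
#' The grammar supports `name <atom-name>`, `resname <3-letter-code>`,
#' `resnum <a>` / `resnum <a>-<b>` / `resnum <a>,<b>,...`, `chain <id>`,
#' `heavy`, combined with `and`, `or` and parentheses (`and` binds tighter
#' than `or`).  Matching is case-sensitive on the atom table as read.
#'
#' @param topology A [structure_model()].
#' @param spec Selection expression, e.g.
#'   `"name CA or (resname PLT and heavy)"`.
#' @return An `atom_selection`: an increasing integer vector of 1-based atom
#'   indices with attributes `label` (the expression) carried along.
#' @export
select_atoms <- function(topology, spec) {
  stopifnot(inherits(topology, "structure_model"))
  tokens <- tokenize_selection(spec)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  mask <- parse_sel_or(state, topology$atoms)
  if (state$pos <= length(state$tokens))
    stop("selection syntax error near '", state$tokens[state$pos], "'")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty selection: '", spec, "'")
  atom_selection(idx, label = spec, topology = topology)
}

#' Construct an atom selection from explicit indices
#'
#' @param indices Strictly increasing 1-based atom indices.
#' @param label Text label.
#' @param topology Optional [structure_model()] to validate against.
#' @return An `atom_selection`.
#' @export
atom_selection <- function(indices, label = "", topology = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("empty selection")
  if (is.unsorted(indices, strictly = TRUE))
    stop("selection indices must be strictly increasing")
  if (!is.null(topology) && (min(indices) < 1L || max(indices) > n_atoms(topology)))
    stop("selection indices out of range for topology")
  structure(indices, label = label, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n", attr(x, "label"), length(x)))
  invisible(x)
}

tokenize_selection <- function(spec) {
  spaced <- gsub("([()])", " \\1 ", spec)
  tokens <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  if (length(tokens) == 0L || identical(tokens, ""))
    stop("selection syntax error: empty expression")
  tokens
}

sel_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}
sel_take <- function(state) {
  tok <- sel_peek(state)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  state$pos <- state$pos + 1L
  tok
}

parse_sel_or <- function(state, atoms) {
  mask <- parse_sel_and(state, atoms)
  while (!is.na(sel_peek(state)) && sel_peek(state) == "or") {
    sel_take(state)
    mask <- mask | parse_sel_and(state, atoms)
  }
  mask
}

parse_sel_and <- function(state, atoms) {
  mask <- parse_sel_primary(state, atoms)
  while (!is.na(sel_peek(state)) && sel_peek(state) == "and") {
    sel_take(state)
    mask <- mask & parse_sel_primary(state, atoms)
  }
  mask
}

parse_sel_primary <- function(state, atoms) {
  tok <- sel_take(state)
  if (tok == "(") {
    mask <- parse_sel_or(state, atoms)
    if (sel_take(state) != ")") stop("selection syntax error: expected ')'")
    return(mask)
  }
  switch(tok,
    heavy = atoms$is_heavy,
    name = atoms$elety == sel_take(state),
    resname = atoms$resid == sel_take(state),
    chain = atoms$chain == sel_take(state),
    resnum = atoms$resno %in% parse_resnum_values(sel_take(state)),
    stop("selection syntax error: unknown token '", tok, "'"))
}

parse_resnum_values <- function(value) {
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      out <- c(out, seq.int(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("selection syntax error: bad resnum value '", p, "'")
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Multiple sequence alignments

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of record identifiers.
#' @param seqs Character vector of equal-length gapped sequences (upper case
#'   is enforced).
#' @return An object of class `msa` with fields `ids`, `seqs`, `n_columns`.
#' @export
msa <- function(ids, seqs) {
  if (length(ids) != length(seqs) || length(ids) == 0L)
    stop("alignment must have at least one record, with one id per sequence")
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  if (any(grepl("[^A-Z.-]", seqs)))
    stop("alignment contains characters outside the amino-acid + gap alphabet")
  obj <- list(ids = as.character(ids), seqs = seqs,
              n_columns = widths[1L])
  class(obj) <- "msa"
  obj
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids), x$n_columns))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads an existing alignment (FASTA or Clustal) via \pkg{Biostrings};
#' building alignments is out of scope.  Record order is preserved and
#' sequences are upper-cased.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An [msa()].
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("cannot read ", format, " alignment '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  seqs <- as.character(aln)
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  msa(names(seqs), unname(seqs))
}

#' Write an alignment as aligned FASTA
#'
#' @param x An [msa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  set <- Biostrings::AAStringSet(stats::setNames(x$seqs, x$ids))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a delimited assay table
#'
#' Reads a CSV (or TSV, by file extension) table with a header row, as used
#' for substrate/velocity pairs, CD timecourses, melt curves and densitometry
#' values.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @return A data frame.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(out) < 1L || nrow(out) < 1L) stop("empty assay table: ", path)
  out
}
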