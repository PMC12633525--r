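# Static aromatic-cluster geometry and MSA aromatic-conservation scanning.

#' Specify an aromatic cluster
#'
#' @param members Data frame with columns `chain`, `resno` and optionally
#'   `resname` (resolved from the structure when absent); or a list of
#'   [cluster_member()]s.
#' @param ring_rule Residue name -> ring atom names ([default_ring_rule()]).
#' @return Object of class `cluster_spec`.
#' @export
cluster_spec <- function(members, ring_rule = default_ring_rule()) {
  if (is.data.frame(members)) {
    members <- lapply(seq_len(nrow(members)), function(i)
      cluster_member(members$chain[i], members$resno[i],
                     if ("resname" %in% names(members)) members$resname[i] else NULL))
  }
  if (length(members) < 2L)
    stop("a cluster requires at least 2 members")
  structure(list(members = members, ring_rule = ring_rule),
            class = "cluster_spec")
}

#' Aromatic-cluster geometry report
#'
#' All pairwise ring-centroid distances of the cluster in one static
#' structure, with per-protomer (chain) and overall minima and maxima.
#'
#' @param structure A [structure_model()] resolving every cluster residue.
#' @param cluster A [cluster_spec()].
#' @return Object of class `cluster_geometry_report`: list with `distances`
#'   (symmetric labelled matrix, Angstrom), `min_distance`, `max_distance`
#'   (overall, off-diagonal), and `per_protomer` (data frame of chain, min,
#'   max over within-chain pairs).
#' @export
cluster_geometry <- function(structure, cluster) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(cluster, "cluster_spec"))
  members <- cluster$members
  cent <- t(vapply(members, function(m)
    ring_centroid(structure, m, ring_rule = cluster$ring_rule), numeric(3)))
  labels <- vapply(members, member_label, character(1))
  dmat <- as.matrix(stats::dist(cent))
  dimnames(dmat) <- list(labels, labels)
  off <- dmat[upper.tri(dmat)]
  chains <- vapply(members, function(m) m$chain, character(1))
  per_protomer <- do.call(rbind, lapply(unique(chains), function(ch) {
    i <- which(chains == ch)
    if (length(i) < 2L)
      return(data.frame(chain = ch, min = NA_real_, max = NA_real_))
    sub <- dmat[i, i][upper.tri(dmat[i, i])]
    data.frame(chain = ch, min = min(sub), max = max(sub))
  }))
  structure(list(distances = dmat,
                 min_distance = min(off), max_distance = max(off),
                 per_protomer = per_protomer),
            class = "cluster_geometry_report")
}

#' @export
print.cluster_geometry_report <- function(x, ...) {
  cat(sprintf("cluster_geometry_report: %d members, centre-to-centre %.1f-%.1f A\n",
              nrow(x$distances), x$min_distance, x$max_distance))
  print(round(x$distances, 2))
  invisible(x)
}

#' Define motif windows on an alignment
#'
#' Named inclusive 1-based alignment-column intervals, e.g. the "spoon" and
#' "fork" mobile regions flanking the active site.
#'
#' @param ... Named length-2 integer vectors, e.g.
#'   `spoon = c(10, 40), fork = c(41, 60)`.
#' @param msa Optional [msa()] to validate the intervals against.
#' @param allow_overlap Set `TRUE` to permit overlapping windows.
#' @return Object of class `motif_windows` (named list of intervals).
#' @export
motif_windows <- function(..., msa = NULL, allow_overlap = FALSE) {
  w <- list(...)
  if (length(w) == 1L && is.list(w[[1]]) && is.null(names(w)[1]))
    w <- w[[1]]
  if (length(w) == 0L || is.null(names(w)) || any(names(w) == ""))
    stop("windows must be named intervals")
  for (nm in names(w)) {
    iv <- as.integer(w[[nm]])
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1L)
      stop("window '", nm, "' must be an increasing positive interval")
    if (!is.null(msa) && iv[2] > msa$n_columns)
      stop("window '", nm, "' exceeds the alignment width")
    w[[nm]] <- iv
  }
  cols <- unlist(lapply(w, function(iv) seq.int(iv[1], iv[2])))
  if (!allow_overlap && anyDuplicated(cols))
    stop("windows overlap; pass allow_overlap = TRUE to permit this")
  structure(w, class = "motif_windows")
}

window_columns <- function(windows) {
  sort(unique(unlist(lapply(windows, function(iv) seq.int(iv[1], iv[2])))))
}

#' Count aromatic residues within motif windows of an alignment
#'
#' Per sequence, counts aromatic letters falling in the window columns; gaps
#' are ignored.  The default aromatic set is `{F, Y, W}` -- His is excluded
#' by default but can be added via `aromatic_set`.
#'
#' @param x An [msa()].
#' @param windows A [motif_windows()] object valid for `x`.
#' @param aromatic_set Character vector of one-letter codes counted as
#'   aromatic (default `c("F", "Y", "W")`).
#' @return Object of class `aromatic_count_table`: list with `table` (data
#'   frame of `id`, `count`), `columns` (list of the matching alignment
#'   columns per sequence) and `distribution` (named integer vector: how many
#'   sequences carry each count).
#' @export
scan_msa_aromatics <- function(x, windows, aromatic_set = c("F", "Y", "W")) {
  stopifnot(inherits(x, "msa"))
  if (!inherits(windows, "motif_windows"))
    windows <- motif_windows(windows, msa = x)
  cols <- window_columns(windows)
  if (max(cols) > x$n_columns) stop("window out of range for this alignment")
  aromatic_set <- toupper(aromatic_set)
  hits <- lapply(x$seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]][cols]
    cols[ch %in% aromatic_set]
  })
  counts <- vapply(hits, length, integer(1))
  distribution <- table(factor(counts, levels = 0:max(counts)))
  structure(list(table = data.frame(id = x$ids, count = counts,
                                    stringsAsFactors = FALSE),
                 columns = stats::setNames(hits, x$ids),
                 distribution = c(distribution)),
            class = "aromatic_count_table")
}

#' @export
print.aromatic_count_table <- function(x, ...) {
  cat("aromatic_count_table:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Map an alignment column to an ungapped residue index
#'
#' Returns the 1-based residue index (count of non-gap characters up to and
#' including the column) of `column` in sequence `id`; errors if the position
#' is a gap in that sequence.
#'
#' @param x An [msa()].
#' @param id Sequence identifier.
#' @param column Alignment column (1-based).
#' @return Integer residue index.
#' @export
map_column_to_residue <- function(x, id, column) {
  stopifnot(inherits(x, "msa"))
  i <- match(id, x$ids)
  if (is.na(i)) stop("sequence '", id, "' not in alignment")
  column <- as.integer(column)
  if (column < 1L || column > x$n_columns) stop("column out of range")
  ch <- strsplit(x$seqs[i], "", fixed = TRUE)[[1]]
  gap <- ch %in% c("-", ".")
  if (gap[column])
    stop(sprintf("column %d is a gap in sequence '%s'", column, id))
  sum(!gap[seq_len(column)])
}

#' Approximate default spoon/fork motif residue ranges
#'
#' Ships the residue ranges used in the narrative around the conserved
#' aromatic cluster: the *D. radiodurans* spoon (292-306) and fork (307-319)
#' motifs, and the *E. coli* cluster residues Y288/F298/F304 within the
#' ~287-313 region.  These are residue numbers of the respective proteins,
#' *not* alignment columns; map them onto a given alignment before use.
#' They are approximate, documented defaults -- supply explicit alignment
#' columns for any quantitative scan.
#'
#' @return Named list of residue-number intervals.
#' @export
default_motif_residues <- function() {
  list(Dr_spoon = c(292L, 306L),
       Dr_fork = c(307L, 319L),
       Ec_cluster_region = c(287L, 313L))
}
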