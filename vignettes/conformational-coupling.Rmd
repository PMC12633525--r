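---
title: "Conformational coupling analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational coupling analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confcouple)
```

## The scientific question

1-deoxy-D-xylulose 5-phosphate synthase (DXPS) is a thiamin
diphosphate-dependent enzyme whose catalytic cycle is gated by a global
open/close conformational equilibrium.  Two mobile loops flanking the active
site -- the "spoon" and "fork" motifs -- order in the closed state, and a
cluster of conserved aromatic side chains within them is thought to
stabilize that state and hold the catalytic histidine in place while the
pre-decarboxylation intermediate (C2-alpha-lactyl-ThDP) persists.
`confcouple` packages the analyses used to interrogate this model from three
directions:

1. **Trajectory analysis** -- does the geometry of the aromatic cluster
   couple to the dominant collective motion of the enzyme?
2. **Sequence and structure** -- is the cluster conserved across homologs,
   and how tightly packed is it in a closed-state structure?
3. **Assay mathematics** -- the kinetic, spectroscopic and densitometric
   calculations used to quantify what cluster-disrupting substitutions do.

## Essential dynamics

PCA is performed on the Cartesian coordinates of a user-selected atom set
(typically protein C-alpha atoms plus cofactor/ligand heavy atoms).  Frames
are first superposed by the Kabsch algorithm (rotation + translation, no
reflection) over a fit selection that may differ from the analysis
selection.  Choices the method leaves open, fixed here and exposed as
arguments:

* **Weighting** -- none.  Unweighted coordinates are the common
  essential-dynamics default for C-alpha/heavy-atom sets.
* **Alignment reference** -- `"mean-iterative"`: fit to the first frame,
  recompute the mean, re-fit (two passes).  This reduces the bias of an
  arbitrary first-frame reference; `"first-frame"` is available.
* **Covariance normalisation** -- population covariance (divide by
  `n_frames`).  All test oracles assume this convention.
* **Mode sign** -- each eigenvector is oriented so its largest-magnitude
  component is positive (ties broken by lowest coordinate index).  Signs of
  principal components are otherwise arbitrary, and a fixed convention makes
  projections, correlations and plots reproducible run to run.
* **Degeneracy** -- eigenvalues equal within numerical tolerance are
  reported in stable (index) order; tests avoid asserting directions of
  degenerate modes.

The per-atom displacement profile along mode *k* is
`d_i = sqrt(lambda_k) * ||(e_k)_i||`, the RMS displacement mode *k*
contributes to atom *i*.  An alternative reading of "displacement along a
component" -- the peak-to-peak span between extreme projections -- is not
implemented as the default because it is noise-dominated at the extremes;
the RMS form is the quantity tested here.

## Coupling analysis

Aromatic pair geometry uses **ring centroids**: the unweighted mean of the
ring heavy atoms (Phe/Tyr `CG,CD1,CD2,CE1,CE2,CZ`; the six-membered Trp
ring; the His imidazole).  "Center-to-center" is not defined more precisely
by common usage, so the rule is explicit and overridable (`ring_rule`).
Distances are computed per frame without superposition (they are invariant
under rigid motion), and frames with unresolved ring atoms abort rather
than interpolate.

Coupling between a pair distance and a principal component is the Pearson
correlation of the raw per-frame series -- no smoothing -- reported signed,
with |r| used for ranking.  Zero-variance series yield missing values, not
zeros.

Two-dimensional **free-energy surfaces** are built from 2D histograms of
two collective coordinates:

\[ F(\mathrm{bin}) = -k_B T \ln \frac{n_{\mathrm{bin}}}{n_{\mathrm{max}}} \]

with `kB = 0.0019872041` kcal/mol/K, `T = 310` K by default (the simulated
ensemble temperature), 100 x 100 bins over the data range padded by 2%, and
empty bins masked at infinity.  Normalising by the most-occupied bin pins
the occupied minimum at exactly zero, which makes surfaces from different
trajectories comparable without an absolute reference.

**Basins** are local minima over the 8-connected occupied neighbourhood,
found by a watershed-by-flooding pass in order of increasing F.  A basin's
depth is measured to its lowest saddle (or, for basins that never merge, to
the top of their connected component), and basins shallower than
`depth_threshold` are discarded.  The default threshold of 0.5 kcal/mol is
roughly 0.8 kT at 310 K: deep enough to ignore single-bin noise pockets in
a 20 000-frame histogram, shallow enough to keep genuinely metastable
states.  It is a documented heuristic, not a statistical test.

The **compensation score** between two pair-distance series is their
Pearson correlation; values near -1 indicate that one contact closes as the
other opens, the signature expected of half-sites behaviour across a
homodimer.

## The synthetic trajectory generator

The real object of study -- a multi-microsecond trajectory of a ~600-residue
dimer -- is not reproducible at desk scale, so every dynamics claim in this
package is validated on synthetic trajectories with planted, analytically
known structure.  `generate_coupled_trajectory()` emulates:

* a **slow two-state latent mode** `s(t)`: a 0/1 telegraph process with
  per-frame switch probabilities (default 0.005 each way, i.e. dwell times
  of ~200 frames -- slow against the frame rate, as an open/close transition
  is, yet mixed well enough over 20 000 frames that occupancy sampling
  noise is small);
* a **global displacement** of `n_ca` backbone atoms by
  `mode_amplitude * s(t)` (default 3 Angstrom) along a random unit mode
  vector that is projected onto the complement of the rigid-body subspace
  -- a purely internal mode, since superposition removes net
  translation/rotation;
* **coupled aromatic pairs**: rings whose centroid separation is
  `base + amplitude * s(t)`, with amplitude either given directly (the
  two-state 4 Angstrom / 14 Angstrom demo) or derived from a target
  distance/PC1 correlation `rho`;
* **isotropic Gaussian thermal noise** (default 0.1 Angstrom per
  coordinate).

For a target correlation the generator inverts the analytic
small-displacement model.  Writing `q = p(1-p)` for the stationary state
variance factor, the distance/state correlation of a pair with amplitude `a`
is `rho_d = a sqrt(q) / sqrt(a^2 q + sigma_eta^2)` where
`sigma_eta = noise_sigma * sqrt(1/6 + 1/6)` is the centroid-distance noise
of two six-atom rings, and the PC1-projection/state correlation is
`rho_proj = A sqrt(q) / sqrt(A^2 q + noise_sigma^2)`.  The planted
distance/PC1 correlation is the product `rho_d * rho_proj`, so the
attainable bound is `rho_proj`; requesting more errors out and reports the
bound.  Recovered correlations match planted values of 0, 0.5 and 0.8
within +/- 0.05 at 20 000 frames (the sampling scale of the Pearson
estimator is ~1/sqrt(n) inflated by the telegraph autocorrelation).

A telegraph process, rather than an Ornstein-Uhlenbeck process, was chosen
deliberately: it produces genuinely bimodal joint histograms -- two basins
with an empty saddle -- which is the regime the basin detector must handle.

What the generator does **not** emulate: anharmonic multi-state landscapes
beyond two states, correlated (coloured) thermal noise, solvent effects,
side-chain rotamer jumps, or any force-field physics.  Passing tests
demonstrate that the estimators recover planted structure under realistic
noise, not that any particular biological trajectory has that structure.

## Sequence and structure module

`scan_msa_aromatics()` counts aromatic letters (default `{F, Y, W}`;
histidine excluded by default because the clusters of interest are Tyr/Phe,
toggleable) within named alignment-column windows, skipping gaps.  Motif
windows are user input: alignment columns for the spoon/fork regions
depend on the alignment at hand, so the shipped residue-number defaults
(`default_motif_residues()`) are labelled approximate and all quantitative
tests use generated fixtures whose counts are planted.  The 16-homolog
fixture plants the four named homolog counts (Ec 3, Dr 5, Pa 2, Mtb 1) and
fills the remaining twelve so that exactly 9 of 16 sequences carry three
aromatics; the fill is an emulation, documented as such.

`cluster_geometry()` reports all pairwise ring-centroid distances of a
cluster specification, grouped per protomer by chain ID.
`synthetic_cluster_structure()` plants five rings whose distance matrix
spans exactly 3.9-9.5 Angstrom -- a typical closed-state packing range -- so the
geometry pipeline is testable without any structure download.

## Assay calculations

* **Extinction coefficients**: `5690 * nTrp + 1280 * nTyr` (M^-1 cm^-1),
  exact integer arithmetic.
* **Michaelis-Menten fits**: Levenberg-Marquardt nonlinear least squares
  with a deterministic start (`Vmax0 = max(v)`; `Km0` from linear
  interpolation to the half-maximal velocity).  The commercial software
  normally used for such fits does not document its algorithm; fixing the
  start rule and solver makes results reproducible.  Standard errors come
  from the Jacobian; non-positive estimates and non-convergence are errors,
  not silent results.
* **Slope-based efficiency** (`kcat/Km`): free-intercept OLS over the
  initial linear region.  "Linear region" is not a defined term; the
  default takes the three lowest substrate concentrations, and a threshold
  (e.g. `Km/10`) can be supplied.  Note the first-order expansion of the
  saturation curve biases the slope low by roughly `S/Km` at the largest
  point used, so data for this estimator should sit well below `Km`.
* **Initial velocities**: OLS slope over a time window times a
  user-supplied signal-to-concentration factor.  For NADPH-coupled assays a
  factor of `-1/(6220 * path) * 1e6` converts an A340 slope to uM/s; the
  extinction coefficient and plate path length are inputs, stated
  assumptions rather than constants.
* **IP signal change**: the default (`"from-full"`) convention measures
  depletion relative to the fully formed signal and reads -100% at t = 0
  and 0% at full signal; the alternative `"from-start"` convention
  (`(CD(t) - CD(0)) / delta * 100`) reads 0% at t = 0.  Both are
  implemented and differ by exactly 100 for all inputs.
* **Apparent Tm**: maximum of the first derivative of CD222 vs temperature.
  The derivative scheme (central differences plus 3-point quadratic
  refinement of the discrete peak) is a numerical choice; it recovers
  logistic midpoints across transition widths of 1-5 degrees C within
  0.2 degrees C on 1-degree sampling.  Monotone or flat curves raise a
  "no transition detected" error rather than returning a boundary value.
* **Fold changes**: `reference/variant` (decrease) or `variant/reference`
  (increase), with optional nearest-integer rounding for narrative
  comparisons.

```{r assay-example}
extinction_coefficient(4, 19)       # 4 Trp + 19 Tyr per monomer
fit <- fit_michaelis_menten(
  S = c(5, 10, 25, 50, 100, 250, 500),
  v = mm_velocity(0.083, 39, c(5, 10, 25, 50, 100, 250, 500)),
  enzyme_conc = 0.1)
fit
melt <- generate_melt_curve(tm = 74, slope = 2)
melting_temperature(melt$data$temperature, melt$data$cd222)
```

## Numerical conventions and degenerate inputs

* Coordinates are Angstrom everywhere; the frames-text trajectory dialect
  declares its units (`angstrom` or `nm`) in the header and is written with
  3 decimals, its declared precision.
* Author (file) residue numbering is preserved verbatim and never
  renumbered; whether a given analysis should renumber a grafted or
  engineered region is left to the user, who supplies residue numbers.
* Altloc handling on PDB input keeps the highest-occupancy conformer, ties
  resolved toward altloc A.  Hydrogens are read and flagged, never dropped;
  selections decide.
* Degenerate superpositions (coincident or collinear fit atoms), empty
  selections, ragged alignments, zero-variance series, all-in-one-bin
  histograms and non-positive rate constants are all explicit errors or
  warnings with named causes.
* All randomness flows from a single integer seed; generators derive
  per-stream sub-seeds so adding a draw never perturbs earlier streams, and
  identical seeds give bit-identical files.

## Problem sizes

The test suite and the acceptance script use 20 000-frame synthetic
trajectories of ~40-50 atoms for recovery claims (correlations, basins,
mode overlap), 100-frame/10-atom instances for exact PCA oracle
comparisons, and 69-point melt curves -- sizes at which every planted
quantity is measurable with comfortable margin while the whole suite runs
in about a minute.  The demonstration pipeline default is 5 000 frames.

## Known limitations

* No XTC reader: binary trajectory support is DCD (plus multi-model PDB and
  the frames-text dialect).  The nm-to-Angstrom conversion of XTC-style
  data is handled by the frames-text header.
* No reweighting of biased trajectories, no kinetics between basins, no
  block-averaged error bars on free-energy surfaces.
* The correlation analysis is linear (Pearson); strongly nonlinear
  couplings would be under-reported.
* The synthetic trajectory is a two-state caricature: conclusions about
  estimator behaviour on multi-state or drifting systems require their own
  fixtures.
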