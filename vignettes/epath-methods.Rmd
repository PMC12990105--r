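---
title: "Path collective variables in the RMSD plane: methods and design"
author: "epathcv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path collective variables in the RMSD plane: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epathcv)
```

## The problem

Large conformational transitions — the canonical example being class A
GPCR activation between an experimentally determined inactive and an
active structure — are too slow for brute-force molecular dynamics.
Enhanced-sampling methods need a small number of collective variables
(CVs) that resolve the transition.  Path CVs describe it with a
*progress* variable $s$ and a *deviation* variable $z$ defined over a
sequence of $N$ milestones connecting the two end states.

`epathcv` implements two flavours of this idea, the machinery around
them (engine input generation, COLVAR parsing, reweighting to
free-energy surfaces), and an entropy-based analysis of conformational
heterogeneity along the path.

## The two path flavours

**RPATH** (structure-based).  Milestones are full reference structures
$X_i$ and distances are optimal-superposition RMSDs $R[X - X_i]$:

$$ s(X) = \frac{\sum_{i=1}^{N} i\, e^{-\lambda R[X - X_i]}}
               {\sum_{i=1}^{N} e^{-\lambda R[X - X_i]}}, \qquad
   z(X) = -\frac{1}{\lambda} \ln \sum_{i=1}^{N} e^{-\lambda R[X - X_i]}. $$

The exponent is linear in $R$ (so $\lambda$ has units nm$^{-1}$);
`rpath_definition(squared = TRUE)` switches to a squared-deviation
exponent for engines that use the mean-square convention, with
$\lambda$ in nm$^{-2}$.

**EPATH** (Euclidean).  Every configuration is first encoded as a
point $M = (\mathrm{RMSD}_\mathrm{inactive}(M),
\mathrm{RMSD}_\mathrm{active}(M))$ in the plane spanned by the RMSDs
to the two end-state structures.  Milestones $M_i$ are points of that
plane, and the distance is simply Euclidean,

$$ d(M, M_i) = \left[ (\mathrm{RMSD}_\mathrm{inact.}(M) -
   \mathrm{RMSD}_\mathrm{inact.}(M_i))^2 + (\mathrm{RMSD}_\mathrm{act.}(M)
   - \mathrm{RMSD}_\mathrm{act.}(M_i))^2 \right]^{1/2}, $$

with $d^2$ replacing $R$ in the expressions above ($\lambda$ in
nm$^{-2}$).  The decisive practical advantage: only the two end
milestones correspond to real structures, so no intermediate
conformations have to be guessed, curated or refined, and only two
RMSD evaluations are needed per step instead of $N$.

Both implementations share one numerical contract: the exponential
weights are computed after subtracting the largest exponent
(max-shift), so $s$ and $z$ remain exact to machine precision at
arbitrarily large $\lambda$ where the naive sum would underflow to
$0/0$.  The deviation is reconstructed as
$z = -(m + \ln\sum e^{e_i - m})/\lambda$ with $m$ the shift.

## The arched milestone path

`build_arched_path(D, N, arch)` places milestones between the anchors
$M_1 = (0, D)$ and $M_N = (D, 0)$, where $D$ is the superposed RMSD
between the two end states.  Interior milestones lie on a quadratic
Bézier curve whose control point sits on the diagonal, chosen so that
the *apex* of the curve is at $((1+\mathrm{arch})D/2)\,(1,1)$: `arch`
is directly the fractional height of the path above the midpoint of
the straight chord.  `arch = 0` degenerates to the chord.  The bow
away from the origin reflects how transitions of this kind actually
travel: through an entropic basin of configurations that are far from
*both* references at once, so for every milestone
$\mathrm{RMSD}_\mathrm{inactive} + \mathrm{RMSD}_\mathrm{active} \ge D$.

Milestones are placed at equal arc-length intervals, computed from a
dense numeric parameterization of the curve (20 001 grid points;
equal-arc positions are then interpolated, accurate to well below the
10$^{-4}$ nm level the tests assert).  The construction is symmetric
under swapping the two RMSD axes and reversing milestone order.

Defaults: $N = 8$ milestones and `arch = 0.3`, the configuration used
for receptor-activation work in the literature this package follows.

## Choosing λ

$\lambda$ interpolates between two regimes: very large values tie $s$
rigidly to the closest milestone (stepwise dynamics), very small
values wash $s$ out over many milestones.  Two use cases call for
different points on that axis:

* **Biasing.**  `suggest_lambda()` returns
  $\ln 2 / \overline{d^2}$ (EPATH) or $\ln 2 / \overline{R}$ (RPATH),
  the choice that gives a neighbouring milestone a weight of one half
  — a smooth, differentiable progress variable suitable for driving a
  bias.  This is the constructor default.
* **State assignment / analysis.**  When frames are *projected* onto a
  path to be classified (free-energy basins, entropy profiling), a
  crisper $\lambda$ is appropriate; the package's own analyses use
  $\ln 100 / \overline{d^2}$, i.e. a neighbour weight of 0.01, for
  which a frame sitting exactly on an end milestone maps to $s$ within
  0.01 of its index.  With the biasing default it would map to
  $s \approx 1.4$ — correct, but deliberately smooth.

## Restraints

Intermediate regions of activation pathways contain kinetic traps;
practical setups therefore add parabolic restraints on auxiliary CVs
(microswitch distances such as PIF or NPxxY — handled here as generic
named scalars) that act *only on intermediates, never on the end
states*, so the end-state free-energy difference is unaffected.
`restraint_energy()` implements $w(s)\,\kappa (x - x_0)^2$ with a
smooth bump $w(s)$: zero outside the progress window
$[s_\mathrm{lo}, s_\mathrm{hi}]$, one on the interior plateau, with
half-cosine ramps of width `taper` (default 0.25 s-units, clipped to
half the window).  Deviation control uses a one-sided wall
$\kappa_z \max(0, z - z_\mathrm{max})^2$, active everywhere (a loose
leash on $z$, not a window).

## Engine input and COLVAR I/O

`write_epath_plumed()` emits deterministic PLUMED-dialect text: two
`RMSD TYPE=OPTIMAL` variables against reference PDBs written by
`write_reference_pdb()` (occupancy column = alignment weights, beta
column = measure weights), and explicit `CUSTOM` arithmetic for $s$
and $z$ built from `exp`/`log` only.  Milestone constants are embedded
with 6 significant digits; the round-trip tests therefore compare the
emitted expression against `epath_sz()` on the path *as emitted*
(constants quantized identically), which isolates the expression
generation from the quantization.  Emission is byte-identical across
runs for identical inputs.

`read_colvar()` parses `#! FIELDS` tables, skips `#! SET` lines,
accepts repeated identical `FIELDS` headers from restarts, and
resolves duplicated time stamps (restart overlaps) by keeping the last
occurrence.  `write_colvar()` prints 12 significant digits so a
round trip is lossless at that precision.

## Reweighting

Samples recorded under bias potentials $V_b$ are reweighted with the
static weights $w = e^{\sum_b V_b / kT}$ (the bias columns to include
are an explicit argument).  `reweight_fes()` histograms $w$ over a 1D
or 2D grid and reports $F = -kT \ln H$, min-shifted to zero; empty
bins are flagged unobserved, never assigned $F = 0$.  Two exact
invariants pin the estimator down: with zero bias it reduces
*identically* to the plain histogram estimator, and adding any
constant to a bias column leaves $F$ unchanged (the max-shift inside
the weight computation makes this exact, not approximate).

`deltag_trace()` tracks
$\Delta G(t) = -kT \ln( W_\mathrm{active}(\le t) /
W_\mathrm{inactive}(\le t) )$ over cumulative reweighted populations
of two disjoint windows of the progress variable (defaults in the
basin sense: $s \in [1, 1.5]$ vs $[N-0.5, N]$ style windows supplied
by the caller).  Uncertainty comes from a block bootstrap
(`deltag_bootstrap()`, 20 contiguous blocks, 200 resamples by
default), which is robust to the autocorrelation of Markov-chain
samples.  `replica_average()` reports the pointwise mean and $n-1$
standard deviation across replicas on a shared time grid
(`resample_trace()` interpolates onto one).

Time-dependent normalization corrections of on-the-fly biasing
schemes are out of scope: the package assumes quasi-static recorded
bias energies, the regime in which a convergence-focused replica is
analysed.  kT defaults to 310 K (0.616 kcal/mol).

## Clustering and the entropy profile

`gromos_cluster()` is the classic greedy RMSD-cutoff algorithm: the
unassigned frame with the most unassigned neighbours within the
cutoff becomes the next cluster centre, taking its neighbours with it;
ties break to the lowest frame index, clusters are reported by
decreasing size, and the default cutoff is 0.14 nm (1.4 Å) on the
C$\alpha$ selection.  Conformational heterogeneity is summarized by
the Shannon entropy of the fractional cluster populations,
$S/k_B = -\sum_i p_i \ln p_i$.

`entropy_profile()` groups frames by milestone interval of their
projected $s$, clusters each interval *independently* (matching how
per-interval heterogeneity is usually visualized; a global clustering
then split by interval answers a different question), and reports the
per-interval entropy.  For a two-state system the expected signature
is a low-entropy (well-defined) pair of terminal basins and a
high-entropy middle.

## The synthetic generators

The package is fully testable without external data:

* `make_toy_endstates()` — a 20-atom helix-like C$\alpha$ chain and a
  copy with its terminal half bent 60° about a hinge: a minimal
  two-state system with a well-defined end-to-end RMSD (~0.3 nm).
* `make_transition_trajectory()` — linear interpolation between the
  superposed end states, an optional mid-path `detour` bulge along a
  fixed random displacement field (emulating the entropic basin far
  from both references), and Gaussian coordinate noise (default
  0.02 nm, the simplest perturbation that produces RMSD spread).
  `noise_scaling = "midpath"` scales the noise s.d. with
  $\sin(\pi t)$, giving tight end basins and a diffuse middle — the
  fixture used for the entropy-profile analyses, since spatially
  uniform noise makes every interval equally heterogeneous.
* `make_biased_samples()` — Metropolis Monte-Carlo from
  $e^{-(U+V)/kT}$ on the double well
  $U(x) = 5\,[(x/1)^2 - 1]^2$ kcal/mol with the scaling bias
  $V = -0.8\,U$, recording $V$ so that reweighting recovers $U$.
  Metropolis (rather than Langevin) sampling makes the stationary law
  exact, so reweighting tests compare against adaptive quadrature of
  the Boltzmann integral with no discretization caveat.  Default
  2×10⁵ samples, proposal s.d. 0.35 (acceptance ≈ 0.7).

What these fixtures deliberately do *not* emulate: membrane and
solvent environments, the dynamics of on-the-fly bias deposition,
multi-replica ladders, and the sheer dimensionality of a receptor.
Green tests demonstrate the correctness of the estimators and
geometry on systems where ground truth is computable — not that a
particular receptor's activation free energy is reproduced; headline
numbers from production GPCR simulations (tens of kcal/mol over
microseconds) require the original MD data and are expressly out of
scope.

## Numerical choices and degenerate inputs

* Superposition excludes reflections (determinant-corrected proper
  rotation), preserving chirality; fewer than 3 alignment atoms or a
  collinear alignment set is a geometry error, not a silent fallback.
* Coordinates are stored in nm; PDB I/O converts Å at the boundary
  (fixed-width PDB quantizes at 10⁻⁴ nm — relevant to round-trip
  expectations).  GRO files are already in nm.
* `extract_milestones()` minimizes the variance of consecutive
  milestone RMSD gaps exhaustively for ≤ 20 frames; beyond that a
  cumulative-RMSD arc-length quantile heuristic is used.
* No tie-breaking is needed in $s$ itself: it is a smooth weighted
  mean, and at finite $\lambda$ no argmax is taken.
* Cluster populations are validated to sum to 1 (renormalized with a
  warning beyond 10⁻⁹); entropy of an empty path interval is `NA` and
  flagged, never 0.

## Problem sizes used in the shipped analyses

The package's own test and acceptance analyses run at deliberately
modest scale — 4–20-atom structures, 60-frame trajectories, 2×10⁵
Monte-Carlo samples, 10³–10⁵-rotation search oracles — sizes at which
every reference quantity (rotation-search optimum, exhaustive
subsequence optimum, quadrature free energies, exhaustive greedy
clustering) is computable exactly, so agreement is a sharp statement
rather than a statistical one.

## Known limitations

* Only static-bias reweighting; no WHAM/MBAR multi-ensemble
  combination and no kinetics.
* No secondary-structure detection: the C$\alpha$ selection is either
  everything or user-supplied residue ranges.
* No periodic-boundary handling; inputs are assumed whole.
* Binary trajectory formats are not read natively; any multi-frame
  source must be converted to multi-MODEL PDB (the `cv_trajectory()`
  constructor accepts in-memory coordinate arrays from any origin).
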