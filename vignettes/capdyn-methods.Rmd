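---
title: "Methods: brain-state extraction, temporal dynamics, and control energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-state extraction, temporal dynamics, and control energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdyn)
```

This vignette documents the models behind `capdyn`, the assumptions they
make, the parameters that matter, and the design choices taken where more
than one defensible convention exists. It states no empirical result that
the package's test suite and acceptance script do not themselves compute.

## 1. The state model

Each fMRI frame is treated as a point in the regional activation space
$\mathbb{R}^N$. Per subject, every ROI's time series is z-scored across time
(mean 0, sd 1) before frames are concatenated into the $N \times T$ matrix
$X$; z-scoring removes inter-subject amplitude differences so that
clustering sees only co-activation topography. We use the *population*
standard deviation (denominator $T$). The correlation distance between
frames, $d = 1 - r$, is invariant to this choice, so it affects nothing
downstream; it is fixed for reproducibility. Constant ROI rows (flat-lined
channels) are zeroed with a warning rather than rejected, so one degraded
ROI cannot abort a cohort run.

### k-medoids under correlation distance

Frames are clustered by k-medoids so that each cluster center is an actual
frame — a real BOLD configuration — rather than an arithmetic mean, and so
that an arbitrary metric (here $d = 1 - r$) can be used. The variant is PAM:
greedy BUILD initialization followed by a swap phase. The objective (total
within-cluster distance to medoids) descends monotonically across swaps;
this is asserted at every iteration. Restart 1 starts from BUILD and
further restarts from random medoid sets, so restarts explore genuinely
different basins; the restart with the *minimum* total within-cluster
distance is kept. ("Maximum inertia" appears in parts of the literature as
the selection rule, which conflicts with inertia being a minimization
objective; we read it as a wording slip. `kmedoids(final = "max")` provides
the literal reading for anyone who wants it.)

PAM needs the full $T \times T$ distance matrix. A concatenated cohort at
the default design (76 subjects $\times$ 286 frames, $T = 21{,}736$) makes
that matrix impractical, so for large $T$ `kmedoids()` switches to an
**alternating (Voronoi) refinement** that is still exact in both of its
steps: frames are assigned to their nearest medoid, and each cluster's
medoid is recomputed exactly using the identity
$\sum_{o \in C} d(o, j) = |C| - z_j \cdot \sum_{o \in C} z_o$
for unit-normalized frames $z$, which costs $O(NT)$ instead of $O(T^2)$.
Each restart is initialized by running full PAM on a random 2000-frame
subsample. Like all alternating k-medoids schemes it can stop in a local
optimum PAM's swap would escape, which is why multiple restarts are the
default and why PAM remains the reference path on every instance small
enough to enumerate (the test suite proves PAM equal to exhaustive search
for $T \le 12$).

Frames are reported with nearest-medoid labels; the per-state patterns used
everywhere downstream are the **cluster means** of those labels' frames
(states as average configurations), with medoid frames available as an
alternative representation.

### Choosing K

`k_selection_report()` scans a contiguous range of K (the study design scans
2–17; the ceiling comes from requiring $K^2$ possible transitions to be
observable within one $\approx$10-minute scan of 286 frames,
`k_scan_ceiling(286) = 17`) and tabulates:

- **explained variance** $1 - \sum_o d(o, m_o)^2 / \sum_o d(o, g)^2$, with
  $m_o$ the frame's medoid and $g$ the grand medoid (the frame minimizing
  total squared distance). EV is 0 at $K = 1$ by definition and 1 when
  every frame is its own medoid. Squared distances are used so the ratio
  mirrors a variance decomposition; any monotone variant would rank K the
  same way.
- **variance gain** $EV(K) - EV(K-1)$, with the elbow rule
  "gain $< 0.01$";
- **mean medoid silhouette** $s = (d_2 - d_1)/\max(d_1, d_2)$ over the
  nearest and second-nearest *medoids* (Van der Laan/Schubert convention;
  the $0/0$ case is defined as 0);
- **state-absence fraction**: subjects in which at least one state never
  occurs;
- **maximum centroid correlation**: spatial overlap between states.

`select_k()` returns the smallest K passing all four criteria (gain tapering
below 0.01, silhouette locally maximal or within 0.02 of its successor,
absence fraction $\le 0.25$, centroid correlation $\le 0.5$); if none does,
the best compromise is returned flagged non-conclusive. The thresholds are
exposed as arguments.

Supporting evidence comes from `split_half_stability()` (cluster random
halves, match centroids, record matched correlations) and
`match_states()`, which solves the assignment problem between two centroid
sets by the Hungarian method — deterministic and order-independent, unlike
greedy row-max matching (the package carries its own $O(K^3)$ solver,
verified against enumeration).

### Null model

`phase_randomize()` builds surrogates per ROI by rotating every
positive-frequency Fourier coefficient by an independent uniform phase,
mirroring conjugates, and keeping DC (and the Nyquist bin for even $T$)
untouched. This preserves each ROI's amplitude spectrum exactly — hence its
autocorrelation function, variance and mean — while destroying temporal
alignment across ROIs. "Independent" phases per ROI are the default
because the quantity under test is co-activation structure; a phase-locked
mode preserving zero-lag cross-correlation is available
(`mode = "locked"`). Surrogates are generated per subject *before*
concatenation so subject boundaries match the real pipeline.
`compare_cluster_quality()` reruns the identical clustering pipeline on
surrogate cohorts and reports the real-minus-null silhouette difference
with an empirical p-value. Note that phase randomization does not force
cross-ROI correlations to zero in finite samples: two ROIs sharing a
dominant frequency retain a $\cos(\Delta\phi)$ correlation under random
relative phase; the comparison is therefore always real-versus-null, never
against an absolute zero.

## 2. Temporal dynamics

Per subject (`state_sequence`; metrics never cross subject boundaries):

- **dwell time**: mean maximal-run length $\times$ TR, in seconds. States
  never visited are *missing, not zero*, so they do not drag group means
  toward zero; group tests simply exclude them.
- **fractional occupancy**: percent of frames per state; sums to 100.
- **transition probabilities**: self-transitions are removed first
  ("removing state autocorrelations" read as discarding unchanged frame
  pairs), then $P(i \to j) = N(i \to j) / N_\text{switches}$ — joint
  normalization over *all* switches, not per-row. Under row normalization
  every state's exit probability is identically $1/(K-1)$ and carries no
  subject information; joint normalization is the only convention under
  which per-state exit/enter probabilities can differ between groups, which
  is the phenomenon of interest. Both conventions are implemented
  (`normalize = "joint"` / `"row"`); joint is the default.
- **exit/enter probabilities**: means of a state's outgoing/incoming
  off-diagonal probabilities.
- **permutation null** (`permutation_null_transitions()`): the order of the
  sequence's maximal runs is permuted, preserving the run-length multiset
  and per-state occupancy exactly — the statistic is conditioned on
  everything except which state follows which. Permuting frames instead
  would destroy the run-length structure that dwell times are made of, and
  permuting subject labels tests a different (between-subject) hypothesis.
  Sequences with fewer than 3 runs are skipped. Empirical p-values use the
  add-one convention $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$.

## 3. Control energies on connectomes

The connectome $A$ (symmetric, nonnegative, zero diagonal — validated, with
ROI order checked by label equality against the time series) defines linear
dynamics after stabilization:
$$A_\text{norm} = \frac{A}{\lambda_\text{max}(A) + c} - I, \qquad c = 1,$$
placing the spectrum in $[-2, 0)$. This is the prevailing convention in the
continuous-time network-control literature; $c$ is exposed (`norm_c`).
Because $c$ is an absolute offset the result is not invariant to rescaling
$A$, so connectomes should enter on a common weight scale; energies are in
arbitrary units regardless.

The steering problem from pattern $x_0$ to $x_f$ minimizes
$$\int_0^T \left[(x - x_f)^\top S (x - x_f) + \rho\, u^\top u\right] dt,
\quad \dot x = A_\text{norm} x + B u,\; x(0) = x_0,\; x(T) = x_f,$$
with defaults $T = 1$, $\rho = 1$, $B = I$ (uniform full control set) and
$S = I$. The solution is computed exactly from the Hamiltonian system: with
costate $p$ and $u^* = -B^\top p / (2\rho)$, the boundary-value problem is
solved via the matrix exponential of the augmented block system, the
costate's initial value obtained by enforcing $x(T) = x_f$, and the
trajectory propagated by a fixed-step exponential integrator (exact for a
linear system). This is preferred over shooting or collocation because it
is deterministic, has no convergence failures, and is fast at $N = 85$.
A numerically singular boundary block (unreachable target) is an explicit
error reporting the reciprocal condition number.

Numerical settings: `n_time_steps = 1001` trajectory samples; nodal energy
$\int u_i^2\,dt$ by composite trapezoid; both configurable. The terminal
constraint is a *hard gate*: $\lVert x(T) - x_f\rVert \le 10^{-6}(1 +
\lVert x_f\rVert)$ or the solve errors out — no energy is ever reported
from a trajectory that missed its target. An independent check,
`discretized_control_energy()`, re-solves the problem by direct
minimization over piecewise-constant controls (exact zero-order-hold
propagation, KKT system); the suite requires agreement within 0.5%
relative on systems small enough for the discretization to be run densely.

States enter as cluster-mean centroids in z-units, unrescaled
(`state_scale = "raw"`); since energy scales quadratically with pattern
magnitude, a unit-norm option exists for cross-study comparisons.
Diagonal entries (self-maintenance of a nonzero pattern against the
stable drift) are computed but excluded from exit/enter means.
`exit_enter_energies()` classifies `exit > enter` as sink-like (local
minimum: costly to leave, cheap to enter) and the reverse as source-like,
with `depth_rank` ordering states by mean energy.

## 4. The synthetic cohort generator

`generate_cohort()` emulates exactly the statistical structure the analysis
assumes: per-subject BOLD emitted from $K$ planted centroid patterns via a
Markov state sequence, with AR(1) ROI noise; group-specific transition
matrices; modular weighted connectomes; clinical scores linearly coupled to
planted fractional occupancy. Defaults mirror the study design the package
targets: 38 + 38 subjects, 286 frames at TR 2.1 s, $N = 85$ ROIs over 8
networks, $K = 4$.

Choices and their rationale:

- **AR(1) noise, coefficient 0.45, innovation sd 0.8 (z-units).** AR(1) is
  the minimal model consistent with validating against an
  autocorrelation-preserving null; resting BOLD at TR $\approx$ 2 s shows
  lag-1 autocorrelation broadly in this range, and an innovation sd of 0.8
  against unit-variance centroids gives frame-level state separability
  comparable to what makes CAP analysis workable on real data (states
  recoverable, but individual frames noisy). The generator makes no claim
  that real noise is AR(1); surrogate tests only require matched lag
  structure, not a matched spectrum shape.
- **Initial Markov state from the stationary distribution**, so sequences
  are stationary from frame 1 and short scans carry no burn-in bias;
  overridable by simulating longer and trimming.
- **Planted group contrast** (for $K = 4$): the control group prefers
  $1 \leftrightarrow 4$ switching, the patient group prefers the
  $2 \leftrightarrow 3$ loop with a shallower self-transition for state 3
  (shorter dwell, higher turnover). Effect sizes are set so that the
  contrast is comfortably detectable at $n = 38$ per group — these are
  recovery tests of machinery, not power analyses.
- **Clinical coupling targets fractional occupancy** of a designated state
  (state 3 by default), the strongest and simplest dynamical correlate to
  plant; scores are linear in the subject's planted occupancy plus
  Gaussian noise.
- **Connectomes**: log-normal weights, denser and stronger within modules
  (the 8 networks double as modules), symmetric, hollow; disconnected
  realizations are regenerated with an incremented seed and logged.

What the generator does *not* emulate — hemodynamic responses, head motion,
physiological noise, scanner drift, spatial autocorrelation within
networks, realistic streamline-count distributions — bounds what passing
tests show: the pipeline recovers the truth *under its own generative
assumptions*. Results on real data additionally depend on preprocessing
choices outside this package's scope (it consumes already-extracted ROI
time series and connectomes).

## 5. Validation scale

The test suite and `scripts/acceptance.R` exercise: the full default cohort
($T = 21{,}736$ frames) for state recovery and K selection; exhaustive
clustering oracles at $T \le 12$; control-energy oracles at $N \le 3$ with
500–2000 control segments and the full 16-pair terminal gate at $N = 85$;
100-seed surrogate checks; 2000-replicate t-test calibration on
15-per-group null cohorts; and 20-seed recovery runs for couplings and
null-vs-real silhouette. These sizes were chosen so the whole battery runs
in minutes on one CPU while keeping every Monte-Carlo margin (e.g.
$\pm 0.01$ on a 0.05 rejection rate at 2000 replicates) meaningfully wider
than its standard error.

## 6. Known limitations

- The alternating large-$T$ clustering path trades PAM's swap guarantees
  for scalability; with few restarts on weakly structured data it can
  return a locally optimal solution.
- Energies depend on the spectral normalization constant and on centroid
  scale; only comparisons holding both fixed are meaningful.
- The run-order permutation null conditions on the run-length multiset;
  it does not test dwell-time structure itself.
- `select_k()` thresholds are heuristics; on data without planted
  structure it deliberately returns a flagged, non-conclusive choice
  rather than an answer.
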