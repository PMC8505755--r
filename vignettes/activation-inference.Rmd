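---
title: "Inferring ventricular activation properties: models, discrepancies and the SMC-ABC engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ventricular activation properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

The ventricular activation sequence in sinus rhythm is governed by a small
set of properties: where the Purkinje network first excites the endocardium
(the *root nodes*, discrete) and how fast the excitation wavefront travels
through the tissue (four *conduction speeds*, continuous).  Neither is
measurable non-invasively, but both leave a signature in data that *is*
accessible: the QRS complex of the 12-lead ECG, and epicardial activation
time maps (ATMs) as produced by electrocardiographic imaging.  `cardioinfer`
implements a simulation-based Bayesian procedure that inverts this
relationship: given a biventricular anatomy and a target QRS or ATM, it
infers a population of plausible root-node configurations and speed sets,
and aggregates them into a single solution with error metrics.

Because the ground truth is unobservable in humans, the package evaluates
the method on *virtual subjects*: synthetic anatomies paired with known
parameters whose simulated data (optionally contaminated with 20 dB white
Gaussian noise) serve as targets.

# Forward model

## Graph-Eikonal activation

Activation times are first-arrival times of an anisotropic wavefront.  On a
tetrahedral mesh this is approximated by shortest paths on a graph: each
edge with displacement $e$ (cm) inside the myocardium costs

$$ t(e) = 1000\,\sqrt{e^\top M e}\ \text{ms}, \qquad
   M = \frac{ff^\top}{v_f^2} + \frac{ss^\top}{v_s^2} +
       \frac{nn^\top}{v_n^2}, $$

where $(f, s, n)$ is the local orthonormal fibre / sheet / sheet-normal
frame and $(v_f, v_s, v_n)$ the corresponding speeds in cm/s.  Edges whose
two endpoints lie on the same endocardial surface instead use the isotropic
fast-layer rule $t(e) = 1000\,|e|/v_\mathrm{endo}$, emulating the rapid
spread of the Purkinje network over the inner wall.  All active root nodes
fire at $t = 0$ (inter-root delays of the order of 10 ms reported in ex-vivo
data are deliberately not modelled), and a multi-source Dijkstra solve
(compiled, priority queue ordered by (time, node index) for bitwise
determinism) yields the activation map.

**Graph construction.** Shortest paths restricted to element edges
over-estimate travel times (metrication error).  The propagation graph
therefore contains all tetrahedron edges *plus* neighbour-of-neighbour node
pairs; on a regular isotropic lattice this brings graph distances within a
few percent of Euclidean ones (the property suite asserts a 16 % worst-case
bound at the test lattice resolution, approached from above).  Per-edge
frames are the volume-weighted average of the frames of elements touching
either endpoint, re-orthonormalised by Gram–Schmidt.  A second-order edge
can in principle shortcut across a cavity rim; at the default edge lengths
this error is well below the metrication error it removes.

## Pseudo-ECG

Potentials at an electrode position $x$ are computed with the current-source
integral
$$ \phi(t) = -K \sum_\mathrm{elements} \nabla v_m(t)\big\rvert_e \cdot
   \nabla\!\left(\tfrac{1}{r}\right)_e \mathrm{Vol}_e , $$
with $r$ the element-centroid-to-electrode distance and $\nabla v_m$ the
linear (P1) gradient of the transmembrane-potential surrogate
$v_m(t) = \tfrac12\!\left(1 + \tanh\frac{t - \mathrm{AT}}{\tau}\right)$.
Choices made here, and why:

* **Upstroke constant** $\tau = 1$ ms.  Only the depolarisation upstroke
  shapes the QRS; $\tau$ controls temporal smoothing.  1 ms matches the
  1 kHz sampling and keeps the QRS-width scaling law exact to within one
  sample.
* **$K = 1$ and an infinite homogeneous volume conductor.**  Each lead is
  standardised by the maximum absolute amplitude across all 12 leads
  (joint normalisation preserves inter-lead amplitude ratios, which the
  morphology matching uses; per-lead normalisation is the documented
  alternative), so the absolute scale and torso inhomogeneities are
  irrelevant by construction.
* The recording is trimmed to the samples where any lead exceeds 1 % of the
  peak; the trimmed extent defines the QRS width in ms.

Limb leads follow Einthoven, augmented leads Goldberger, precordial leads
subtract the Wilson central terminal; the linear identities (III = II − I,
etc.) are asserted to 1e−9 before standardisation.

# Discrepancies

* **ATM targets:** root-mean-square error in ms over the epicardial nodes.
* **ECG targets:** a constrained dynamic-time-warping cost averaged over the
  eight linearly independent leads (I, II, V1–V6; the other four are linear
  combinations and would double count), plus a QRS-width penalty.

The DTW dynamic programme aligns two leads monotonically with common start
and end.  Constraints and defaults:

* **Warping-slope constraint:** at most two consecutive off-diagonal steps
  in the same direction, so 1 ms of one signal can absorb at most 3 ms of
  the other; a 3× integer stretch is feasible, 4× is flagged infeasible
  (sentinel = largest finite double).
* **Parallelogram band:** tight half-width of 2 samples at the start,
  opening linearly to 25 % of the target length at the end — early QRS
  samples reflect the root-node pattern and should not warp, while
  activation-sequence differences accumulate towards the end.
* **Off-diagonal penalty:** decays linearly along the path from
  0.2 × (target lead amplitude range) to 0.  The magnitudes are not
  published; they were fixed once on a single calibration subject and left
  untouched, mirroring the single-subject calibration philosophy of the
  source method.
* **Local cost** is the absolute sample difference (squared difference is
  the recorded alternative).  The programme minimises the *total*
  accumulated cost; the reported cost is that optimum divided by the
  optimal path length so that leads of different lengths are comparable.
  (Normalising inside the recursion would break optimal substructure.)
* **Width penalty:** `0.05 · |Δwidth|` (per ms).  Standardised amplitudes
  are ≤ 1, so typical morphology costs are ~0.1; at weight 0.05 a 20 ms
  width error doubles the discrepancy, which implements the intended
  division of labour — morphology identifies roots, width identifies the
  overall speed scale.

All DTW behaviour is verified against exhaustive enumeration of admissible
paths on series up to length 12.

# The SMC-ABC engine

A population of 512 (default) parameter-sets is drawn by Latin hypercube
sampling over $[100,200] \times [25,90]^3$ cm/s — the three myocardial
coordinates sorted descending to enforce $v_f \ge v_s \ge v_n$ — with 6–10
active root nodes drawn uniformly from the candidate set.  Each iteration:

1. simulate and evaluate every member (order-independent, embarrassingly
   parallel by contract);
2. mark the $\lceil 0.125\,N \rceil$ highest-discrepancy members for
   replacement; the *cut-off* is the highest discrepancy among survivors
   (the value that separates the rejected 12.5 %);
3. replace each marked member by a mutated copy of a uniformly chosen
   survivor if the mutant beats the cut-off, else by the unmodified
   survivor copy;
4. stop when every member matches the target within tolerance (`MATCHED`),
   or when more than 50 % of members are exact duplicates of another
   (`COLLAPSED`), or after `max_iterations` (safety bound, default 100 —
   the source algorithm has none).

**Mutation kernel.** Speeds receive truncated-Gaussian perturbations
(σ = 5 cm/s endocardial, 2.5 cm/s myocardial; ordering restored by a
descending sort).  With probability 0.5 the root subset is modified by
either toggling one candidate or relocating one active root to an inactive
candidate within 2 cm (uniform choice between the two moves); proposals
leaving the 6–10 count range are re-drawn up to 10 times, then the original
subset is kept.  One mutation per replacement, not a chain.  These values
were calibrated on one designated virtual subject and then frozen.

**Tolerance.** The default is the mean discrepancy between the clean target
and ten independent 20 dB noise realisations of it — i.e. the distortion
the noise protocol itself introduces, below which further matching is
meaningless for noisy targets.  For *noiseless* targets this rationale
yields a zero distortion scale, so clean-target experiments run with
tolerance 0 and terminate by population collapse; stopping a clean-target
run at the noise-scale tolerance leaves the population an under-converged
truncated prior.

**Duplicates** are bitwise-equal full parameter vectors — the strictest
definition that is testable, since the published criterion does not define
equality.

# Synthetic geometry and the virtual cohort

The geometry generator replaces patient-derived meshes (not redistributable)
with an idealised biventricular anatomy: the LV is a truncated thick-walled
ellipsoid (apex-to-base axis = z, base truncated at 70° colatitude, apex at
170°), and the RV is a crescent cavity carved into an outward bulge of the
wall on the anterior (+x) side.  A structured longitude × latitude ×
transmural grid is split into five tetrahedra per cell with parity
alternation (conformal, deterministic, bitwise reproducible).  Derived
fields:

* **Transmural coordinate:** distance ratio
  $d_\mathrm{endo} / (d_\mathrm{endo} + d_\mathrm{epi})$ to the labelled
  surfaces — 0 on both endocardial surfaces, 1 on the epicardium.  The
  source model assumes such a coordinate exists but does not define one;
  the distance ratio is the simplest construction satisfying the boundary
  anchoring.
* **Fibre frames:** helix angle $\alpha(d) = 60° - 120°\,d$ rotating the
  circumferential axis towards the longitudinal axis about the transmural
  axis; sheet = transmural; sheet-normal completes the right-handed triple.
* **Root-node candidates:** greedy farthest-point sampling per endocardial
  surface until every node has a same-ventricle candidate within 2.5 cm
  (low resolution) or 1.5 cm (high); hybrid = low-RV + high-LV.  The
  original low-resolution placement used image-registration-dependent
  AHA-17 segment centres, which cannot be replicated without those images;
  only the coverage bounds are normative and they hold exactly by
  construction.  Minimal farthest-point sets are smaller (9–17 candidates)
  than the published 27–38.
* **Electrodes:** fixed anatomical proportions of a torso box scaled around
  the heart (limb electrodes at corners, V1–V6 on a left-anterior arc);
  placement is a stand-in for torso-informed positions and is deterministic
  and scale-linear.
* **Anatomy presets:** four sizes calibrated once, on geometry alone, to
  myocardial volumes of ≈ 82/112/150/169 cm³, inside the 74–171 cm³ range
  of the reference cohort.  Crossed with the five canonical speed
  configurations (Normal 150/50/32/29; Slow-endo 120/...; Fast-endo 179/...;
  Fast-endo+myo 179/88/49/45; Slow-endo-fast-myo 120/88/49/45 cm/s) this
  gives the twenty-subject virtual cohort.

**What the generator does *not* emulate** — and hence what a green test
does not establish: real CMR-derived anatomical variability (papillary
muscles, trabeculation, valve plane obliquity), torso conductor
inhomogeneity, inter-root activation delays, and bidomain/ionic-model
electrophysiology.  Green tests establish that the *inference machinery*
recovers parameters of the package's own forward model under its stated
noise protocol; they are silent on model-to-reality transfer.

Noise contamination adds i.i.d. Gaussian noise with variance
(signal power) / 10^(SNR/10); signal power is the mean square over all
epicardial nodes (ATM) or all samples of all leads (QRS) — the power window
is not defined in the source and this choice is asserted by the empirical
20 ± 0.5 dB check.

# Aggregation and evaluation

The final population is collapsed to a single solution: component-wise
median speeds (medians of ordered tuples preserve the ordering), and
k-means centroids of the pooled active-root coordinates.  k and the initial
centroids come from the modal root configuration (the most frequent exact
configuration), which is guaranteed spread-out and representative; when all
configurations are unique, k falls back to the modal root *count* with
initialisation from the lowest-discrepancy member (logged).  Lloyd
iterations stop when assignments stabilise or after 300 rounds, and the
objective is asserted non-increasing at every step.

Error metrics: signed speed error $100\,(S' - S)/S$ (absolute values in
summaries); per-ventricle mean ± SD of the Euclidean distance from each
true root to the nearest *same-ventricle* centroid (the reference reports
LV/RV rows separately; surface-geodesic distance is the noted alternative,
unspecified in the source); absolute per-ventricle count error; and Pearson
correlation between prediction and target (per-lead average for ECG).

# Numerical and degenerate-input conventions

* Lengths cm, time ms, speeds cm/s; $t\,[\mathrm{ms}] = 1000\,L/v$.
* Node indices are 0-based in every file format, 1-based inside R.
* Frame orthonormality is enforced to 1e−9; speed-ordering ties to 1e−9.
* Dijkstra tie-break: (time, node index).  DTW ties resolve to the first
  minimising predecessor in state order (diagonal preferred).
* Degenerate inputs fail loudly: zero-length edges, unreachable nodes
  (reported by node id), all-zero potentials, zero-power signals,
  wall thickness ≥ semi-axis, empty endocardial surfaces.
* Population capacity: sampling more members than distinct root
  configurations is refused (relevant for very coarse candidate sets).

# Known limitations

* The crescent RV is an idealisation; RV candidate sets on small anatomies
  are sparse (as few as 2 low-resolution candidates), which limits
  root-count identifiability in the RV.
* Clean-target inference at population 128 shows the expected residual
  trade-off between endocardial speed and root count; endocardial errors of
  10–20 % at low candidate resolution match the reference's own reported
  scale, and high resolution improves them — the recovery acceptance test
  runs at high resolution for this reason.
* The DTW cost is normalised by the optimal path's length *after*
  optimisation; a path-length-aware optimum could differ on pathological
  inputs.
* No parallel evaluation is implemented; the evaluation contract
  (order-independence) permits it.
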