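---
title: "Methods: probabilistic metastable substates and whole-brain Hopf models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic metastable substates and whole-brain Hopf models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the model, its assumptions, the parameters that matter, the synthetic
data that stands in for empirical recordings, and the numerical choices
made where the design was genuinely open. Everything quantitative stated
here is computed by the test suite or by `scripts/acceptance.R`; nothing
is quoted from elsewhere.

## From time series to a brain state

A *brain state* is operationalized as a probabilistic metastable substate
(PMS) space. The chain, implemented in `run_leida()`, is:

1. `bandpass_filter()` — per-region demeaning and a zero-phase
   second-order Butterworth band-pass, default 0.02–0.1 Hz. The band
   isolates slow hemodynamic fluctuations; zero-phase (forward–backward)
   filtering matters because everything downstream is phase-based.
2. `compute_phases()` — the analytic signal of each region via the FFT
   construction (negative frequencies nulled, positive doubled), giving
   instantaneous phase and amplitude. The transform is unreliable at the
   series edges, so `trim` samples (default 3) at each end are excluded
   from every later computation. The `signal` port used for filtering has
   no Hilbert transform, so the analytic signal is built in-package; it is
   the textbook frequency-domain construction and is exercised against
   closed-form phase relationships in the tests.
3. `phase_coherence_tensor()` — `dFC(n, p, t) = cos(θ(n,t) − θ(p,t))`:
   1 for co-oscillating regions, 0 at 90°, −1 in anti-phase. Each slice
   is symmetric with unit diagonal by construction.
4. `leading_eigenvectors()` — each slice is reduced to the unit
   eigenvector of its largest-magnitude eigenvalue, the best rank-1
   summary of the instantaneous coherence pattern.
5. `cluster_states()` — k-means over the pooled eigenvectors of all
   subjects and conditions (pooling both conditions into one clustering
   is the default, so that two states are described over a common
   substate vocabulary). Occupancy probabilities and the switching matrix
   are then computed per the labels.

**Eigenvector sign convention.** Eigenvectors are defined up to sign, and
clustering needs a consistent orientation. Each vector is flipped so the
majority of elements are negative; exact ties flip so the
largest-magnitude element is negative. The convention is arbitrary but
fixed; the test suite asserts it holds for 100% of rows. One practical
consequence, found while building the label-recovery fixture: patterns
with exactly balanced signs sit on the tie boundary, and under noise
their orientation is unstable. Real phase-coherence patterns are
essentially never balanced; synthetic fixtures should avoid exact balance.

**k-means settings.** Euclidean distance, best of 20 restarts
(`stats::kmeans`, Hartigan–Wong), up to 100 iterations, clusters
relabeled by decreasing size so labels are stable across reruns. Restart
count, not seeding strategy, is what buys stability at these sample
sizes. `select_k()` reports the mean silhouette width per k
(`cluster::silhouette`) with the argmax as recommendation.

**Transitions across sessions.** Switching matrices count consecutive
label pairs within a session only; concatenation boundaries contribute
nothing. Substates never visited yield `NA` rows flagged in an attribute
rather than silently uniform rows.

**Between-condition testing.** `permutation_paired_test()` uses the
paired t statistic with a null built from independent within-pair sign
flips (default 1000 permutations, α = 0.05, add-one p-value). Constant
nonzero differences produce a degenerate ±Inf statistic and the correct
small p; constant zero differences give p = 1.

## The whole-brain model

`simulate_hopf()` integrates N Stuart–Landau oscillators (the normal form
of a supercritical Hopf bifurcation) coupled by difference coupling
through the connectome, with additive Gaussian noise of SD β (default
0.02) in both coordinates of every node. For an uncoupled, noise-free
node the closed forms are exact test oracles: radius √a and frequency
ω/2π for a > 0, decay to the fixed point for a < 0, threshold at a = 0.

**Integrator.** Stochastic Heun: a forward-Euler predictor, drift
averaged between current and predicted state, Euler–Maruyama noise scaled
by √dt, default dt = 0.1 s. Plain Euler was rejected because its
effective limit-cycle radius is inflated by ≈ dt·ω²/2 — about 6% at
dt = 0.1 s and 0.05 Hz — which violates the 1% radius accuracy the
closed-form checks demand; the Heun corrector removes the bias at
unchanged step size (measured error ≤ 0.2%, and halving dt moves the mean
radius by < 0.5%).

**Working point.** Fitted (unperturbed) models place every node at
a = 0, the bifurcation edge between noise-driven and oscillatory
dynamics — the regime the model is designed to express; it is an explicit
argument everywhere. Output is the x channel only, decimated to the
sampling period `tr_s` after discarding a transient (default 60 s;
closed-form decay checks use longer transients because relaxation at
|a| small is slow — algebraic, ~1/√t, exactly at a = 0). No hemodynamic
convolution is applied: x is treated as the BOLD-like observable, and the
LEiDA band-pass follows anyway.

**Intrinsic frequencies.** `estimate_intrinsic_frequencies()` takes the
per-region peak of the subject-averaged power spectrum inside a band
(default 0.04–0.07 Hz, the usual narrowband range of slow hemodynamic
oscillations); broadband input therefore clamps to the band by design.

## Fitting a model to a state

`evaluate_model()` runs the LEiDA chain on simulated series and assigns
the eigenvectors to the *empirical* centroids, so simulated and empirical
probabilities refer to the same substates. Assignment is nearest-centroid
under the clustering's Euclidean distance, ties to the lowest index.
Measures:

- `pms_kl()` — symmetrized KL with natural logs. Probabilities are
  floored at 1e−6 and renormalized first: an unvisited substate would
  otherwise make the distance infinite, and a sweep must stay finite at
  every grid point. Natural log is used throughout entropy and KL for
  internal consistency.
- `fcd_ks()` — two-sample KS statistic (`stats::ks.test`) between pooled
  upper-triangular entries of the FCD matrices (cosine similarity between
  the vectorized upper triangles of dFC slices at all time-point pairs).
- `fc_fit()` — Pearson correlation of upper-triangular static FC.
- `entropy_distance()` — absolute difference of Markov entropy rates.
  The stationary distribution is the eigenvector of the transposed
  switching matrix at eigenvalue 1, with a power-iteration fallback when
  the eigensolver residual exceeds 1e−8; reducible chains are an error
  naming the unreachable states. When a short simulation leaves a
  substate unvisited, the entropy distance is reported as `NA` rather
  than fabricated.

`sweep_coupling()` scores a grid of G (n_runs simulations pooled per
point) and reports the PMS optimum (argmin KL) and the FCD optimum
(argmin KS) separately — the two criteria need not agree, and only the
PMS criterion is treated as the selection rule.

`optimize_ec()` iterates simulate → grand-average phase FC → update
`C_ij ← C_ij + ε (FC_emp − FC_mod)` on all off-diagonal entries (learning
rate ε = 0.01), clamped at 0 and symmetrized by averaging each step. The
objective is the Frobenius distance between phase-FC matrices — the
quantity the update descends. Because the objective is evaluated on
stochastic simulations it fluctuates around its descent path, so
convergence uses patience (default 10 no-progress iterations) rather
than a pointwise test, divergence ("objective doubled from its minimum")
is tested on a 5-iteration running mean so single-run spikes cannot
trigger it, and the final iterate is returned. EC entries are not
re-normalized to the structural-connectome scale after updates; the
learned matrix is allowed to drift from it.

## Forcing transitions

A stimulation site is one homotopic pair, perturbed identically on both
sides (bilateral stimulation); pairs come from the connectome's declared
table, keeping the scheme parcellation-agnostic. The perturbation is
tonic — `apply_perturbation()` shifts `a` for the whole simulation, with
Δa > 0 the synchronization protocol and Δa < 0 the noise protocol.
Default scan grids (0 to 0.2 by 0.02 for synchronization, 0 to −0.6 by
−0.05 for noise) bracket the usual working intensities.

`transition_scan()` evaluates every pair × intensity cell with the *same*
run seeds (common random numbers), and the unperturbed baseline with the
same budget, so all KL comparisons are like-for-like. `greedy_multisite()`
adds one pair per step, keeping the pair that minimizes KL to the target;
candidates within a step share seeds, ties go to the lowest index, and
the trace records target-KL, source-KL and substate probabilities from
step 0 (unperturbed) onward. The scans use the fitted source model as-is;
whether that model is SC-based or EC-optimized is the caller's choice.

## What the synthetic data emulates — and what it does not

`generate_connectome()` builds a symmetric, non-negative, zero-diagonal
modular network with explicit homotopic edges, normalized so the mean
off-diagonal weight is exactly 0.2 — the scale at which the model is
operated. Between-module background weights are drawn 20× weaker than
within-module ones: with a stronger background the network synchronizes
almost completely by G ≈ 0.2 and the occupancy statistics stop changing
over the swept coupling range, which would make any coupling-recovery
experiment uninformative. Ground truth (G, a, ω, β, seeds) travels in a
sidecar record so recovery experiments never re-derive parameters from
file names. All randomness flows from one explicit integer seed per call.

The recovery experiments define their study conditions once:

- **Coupling recovery** (tests): 20 regions, 2 modules, module-linked
  frequencies 0.04/0.065 Hz, data generated at G = 0.5 with β = 0.02;
  6 subjects × 660 s at TR = 2 s; swept grid 0 to 1 by 0.1 with 3 runs ×
  660 s per point. Heterogeneous frequencies are essential: with
  identical node frequencies the network's substate structure collapses
  to a single dominant pattern and occupancies barely depend on G.
- **EC recovery** (tests): the same system with 5 randomly chosen links
  strengthened by +0.3; the target phase FC is averaged over 3 × 660 s
  runs; 120 update iterations at ε = 0.01, 2 × 500 s runs per iteration.
  Success is a recovered-vs-true correlation above the structural
  baseline — the update spreads noise across all links, so the
  improvement is real but modest by design of the measure.
- **Perturbation recovery** (tests): 16 regions, single module, weak
  working-point coupling G = 0.02, and *pair-tagged* frequencies
  (`generate_pair_frequencies()`): the three planted pairs share
  0.055 Hz while background pairs sit at 0.036–0.042 and 0.068–0.070 Hz.
  Two design facts came out of explicit experimentation and are worth
  recording. First, site identity only survives into the leading
  eigenvector at weak coupling: by G ≈ 0.1 a single strongly oscillating
  pair entrains the whole network and every stimulation looks global.
  Second, a target generated by stimulating several pairs is only
  reachable by single-site stimulation if those sites are mutually
  coherent (the shared tag frequency); otherwise each planted site owns
  a private substate that single-site stimulation at full intensity
  over-expresses, and the site ranking inverts. The noise-protocol
  asymmetry — no KL improvement in the wrong direction, worsening with
  intensity — emerges robustly in this design. In the greedy experiment
  the source-KL curve rises monotonically (within Monte-Carlo tolerance)
  up to the target optimum and can fall again once heavy multi-site
  stimulation pushes occupancies past the target; the tests therefore
  assert monotonicity up to the optimum, not beyond.

The generator emulates the model's own statistical structure only: no
motion or physiological artifacts, no scanner drift, no hemodynamic
convolution, no parcellation error. Passing recovery tests therefore
demonstrates the correctness and sensitivity of the pipeline under the
model's assumptions — not robustness to the nuisance structure of real
recordings.

## Numerical choices and degenerate inputs

- Band edges must satisfy 0 < low < high < Nyquist; violations report the
  achievable band for the given TR.
- Coherence slices asymmetric beyond 1e−8 are an error, not silently
  symmetrized.
- Occupancies are exact rational counts (sum exactly 1); KL clamping
  floor 1e−6; probability vectors read from disk must satisfy their
  simplex/row-stochastic invariants or are rejected.
- Assignment ties take the lowest centroid index; greedy ties take the
  lowest pair index (both documented rules, both tested).
- Simulation overflow (non-finite or |x| > 1e6) reports the failing step
  and suggests a smaller dt.
- Sampling-period metadata is always read from sidecars, never inferred.
- A top-level seed spawns per-stage seeds deterministically
  (`sample.int` under the seeded RNG, all below 2³¹), so any stage can be
  reproduced in isolation; no function mutates the caller's RNG state.

## Problem sizes

The shipped experiments run at 16–20 regions with sessions of roughly
260–1100 s at TR = 0.5–2 s, sizes chosen so the full suite completes in a
few minutes on one CPU while every recovery experiment retains a clear
margin over its decision threshold. The pipeline itself is
dimension-agnostic; nothing in the code assumes these sizes.

## Known limitations

- Occupancy-based KL is a low-dimensional summary; very different
  dynamical regimes can occasionally produce similar occupancy vectors
  (this is why the perturbation experiments were designed around
  pattern-identifiable substates).
- The EC update learns a symmetric effective connectivity; directed
  effective connectivity is out of scope.
- k is chosen by silhouette over a small range (2–8 by default); no
  model-order criteria beyond that.
- On-disk formats are TSV/JSON only; the containers are plain R matrices,
  adequate at whole-brain parcellation scale (~100 regions) but not
  for voxel-level data.
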