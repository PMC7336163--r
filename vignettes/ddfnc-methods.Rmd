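---
title: "Methods: decentralized dFNC, its assumptions, and its tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decentralized dFNC, its assumptions, and its tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices, and
the design decisions taken where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The problem and the model

Dynamic functional network connectivity (dFNC) characterizes how the
correlation structure among brain networks changes over minutes of
resting-state fMRI: component timecourses are windowed, each window's
correlation matrix is computed, and the windows are clustered into a small
number of recurring "states". The standard pipeline needs all subjects in
one place. In a consortium where sites cannot share voxel data, every
stage must instead be computed from exchanged statistics.

The generative model is linear spatial ICA on temporally concatenated
subjects: site $i$ holds $X_i = A S_i \in \mathbb{R}^{d \times N_i}$, with
common spatial maps $A \in \mathbb{R}^{d\times r}$ whose columns are
statistically independent across voxels, and subject-specific timecourses.
Identifiability requires non-Gaussian spatial sources; infomax with a
logistic nonlinearity assumes they are super-Gaussian, which holds for the
sparse, peaked spatial maps typical of fMRI components and for the
Laplacian sources the generator plants.

## 2. Decentralized PCA: why subspace merging works, and when exactly

`local_pca` returns the eigen package $P = U^{(k)}\Sigma^{(k)}$, which
satisfies $PP^\top = X X^\top$ whenever $k$ reaches the rank of $X$. The
round-robin merge reduces $[P'\;P_{\text{prev}}]$, whose outer product is
the *sum* of the site covariance approximations — so the merged subspace
tracks the pooled covariance. Two regimes matter:

* **Exact regime.** If the global data have rank at most the working rank
  $k$ at every hop, no information is truncated and the final span equals
  the pooled SVD span to machine precision. The test suite asserts
  principal angles $< 10^{-6}$ over 20 seeded low-rank instances, for the
  serial and the recursive parallel variant alike, and bit-identical
  serial/parallel results when the cluster size equals the site count.
* **Truncating regime.** With full-rank (flat-spectrum) data, each hop
  keeps only the local top-$k$ subspace. The algorithm caps the working
  rank at $\min(k, \operatorname{rank}(X_i))$, so feeding it a pure
  $100\times100$ Gaussian matrix split over 10 thin sites truncates
  $20\to10$ columns at every hop, and the trailing pooled components —
  whose singular values are nearly degenerate — are not recovered
  per-component (we measured mean matched $|\rho| \approx 0.6$ against
  the pooled-SVD oracle). This is a property of the algorithm and of
  ill-conditioned inputs, not a defect: fMRI covariance spectra decay
  steeply. The equivalence experiment therefore defaults to a
  rank-10-signal-plus-5%-noise matrix, where matched correlations exceed
  0.99; `flat = TRUE` reproduces the raw Gaussian protocol as a
  diagnostic.

The working rank $k_2 = 5r$ (with $r = 100$ the field's convention,
$k_1 = 120$ at the subject level for 162-volume acquisitions) keeps the
retained subspace generous enough that the final truncation to $r$ is the
only aggressive one. A warning fires whenever $k_2 < 5r$.

## 3. Infomax ICA at the aggregator

The aggregator whitens the global eigenvectors (symmetric ZCA, retained
with its inverse for round-trips) and runs natural-gradient infomax with
the logistic nonlinearity: $W \leftarrow W + \eta\,(I + (1-2y)u^\top)W$
over shuffled blocks of rows, rows being voxel samples, so "independence"
is spatial. The cited description fixes no hyperparameters; ours are:
initial rate $\eta_0 = 0.015/\ln r$, annealing by 0.9 whenever successive
updates differ by more than 60°, block size $\lceil\sqrt{n/3}\rceil$,
at most 1000 passes, convergence at relative weight change $10^{-6}$.
Everything is driven by one seed; results are bit-reproducible. When the
pass cap is hit the result is *flagged* (a warning and
`converged = FALSE`), not discarded — at small sample sizes the stochastic
block noise floors the weight change without harming separation quality.
Separation needs samples: at $r = 6$, infomax reaches Amari ISI $< 0.05$
against planted mixing around $d \approx 2000$ voxels but not at
$d = 800$ (measured ≈ 0.1–0.3 there, pooled and decentralized alike), so
recovery tests run at $d \ge 2000$. A kurtosis fixed-point backend is
registered alongside infomax for backend comparisons.

## 4. Windows, exemplars, and their conventions

Window $w$ spans timepoints $w..w{+}t$ ($t+1$ samples, $N-t$ windows),
the only reading under which a 162-volume run with $t=22$ yields the
conventional 140 windows — asserted exactly. Windows are rectangular (no
taper), Pearson correlation across time, vectorized strict upper
triangle, 1-based indices user-facing. A zero-variance component inside a
window contributes correlation 0 and flags the window. The exemplar rule
computes, at each window, the variance of the correlation values *across
component pairs* and keeps strict local maxima (endpoints excluded); a
monotone or constant variance course falls back to the single global
argmax. A flag (`standardize_pairs`) z-scores each pair across windows
first, the main alternative reading of the exemplar heuristic. Dropping
initial timepoints is a config-gated no-op meant for real acquisitions.

## 5. Decentralized K-means

All distances are correlation distance $1-\rho$, everywhere (assignment,
merging, silhouettes), with ties broken toward the lowest centroid index.

* **Multishot Lloyd's.** Sites send per-cluster local sums and counts;
  the aggregator's count-weighted average *is* the pooled centroid
  update, so with a shared initialization the decentralized label
  trajectory is identical to pooled Lloyd's — asserted bit-for-bit over
  20 seeds and on the acceptance dataset. Globally empty clusters are
  re-seeded from the globally farthest point (sites offer their local
  candidate; deterministic).
* **Multishot gradient descent.** Sites send count-weighted objective
  gradients $g_j = c_j - \bar{x}_j^{\text{local}}$; the aggregator steps
  $C \leftarrow C - \eta g$ (at $\eta = 1$ this is Lloyd's). Five
  consecutive genuine inertia increases halve $\eta$ with a warning;
  convergence is a step-norm threshold, since assignments freeze before
  the centroids finish drifting toward the cluster means.
* **Single-shot merging.** Sites run local K-means to convergence
  (deterministic farthest-first initialization from a seeded start) and
  the aggregator runs count-weighted K-means on the pooled local
  centroids; sites label locally afterwards.
* **Two-stage protocol.** Stage 1 clusters exemplar windows from
  `n_init` initializations drawn uniformly from local exemplars (the
  drawn rows travel as centroids, which the message whitelist already
  permits); runs are scored by the count-weighted mean of *per-site*
  silhouettes — a pooled silhouette would require sharing windows — and
  the winner seeds stage 2 over all windows. The field default is
  `n_init = 200`; tests use 20.

One caveat is documented rather than asserted away: under correlation
distance the member mean is not the exact minimizer of within-cluster
distance, so inertia can rise by parts in $10^4$ near convergence. The
test asserts near-monotonicity (increases below 0.1 % of the initial
inertia) and overall decrease.

## 6. The synthetic world

`gen_state_dataset` plants: independent unit-variance Laplacian spatial
maps (columns of $A$); per-subject hidden state sequences with geometric
segment lengths (mean `dwell`, default 60 timepoints — comfortably above
the 23-sample window so most windows are state-pure); within a segment,
timecourses $L_c z_t$ with $L_c$ the Cholesky factor of that state's
planted correlation matrix; i.i.d. Gaussian sensor noise (`noise_sd = 1`,
i.e. roughly 10:1 signal-to-noise power at $r=10$ — deliberately benign).
State centroids are drawn from a two-factor-plus-diagonal model and
redrawn until pairwise correlation distances reach `min_sep` (0.5).

What a green test establishes, and what it does not: the generator
produces block-stationary connectivity with exactly recurring states and
spatially i.i.d. super-Gaussian maps. Real fMRI has hemodynamic
autocorrelation, spatial smoothness, scanner drift, motion, and states
that are at best approximately recurring — none of which are emulated, so
equivalence results here certify the *decentralization* (decentralized ≡
pooled on the same data), not clinical validity of dFNC itself. Clustering
identifiability at small scale needed longer windows (31 samples), longer
dwell (70), and `min_sep = 0.8` in the unit-test fixture; with the
field-standard 23-sample windows even clustering from the *planted*
centroids misses ~22 % of window labels at $r=5$, because a 10-pair
correlation vector from 16 samples is simply that noisy. The acceptance
dataset ($r=10$, 45 pairs) does not have this problem. Paper-scale
real-data behaviour (e.g. ~8 exemplar windows per subject) is tracked as
a diagnostic only; the generator yields ~30.

## 7. Privacy accounting

The channel is the only inter-site path used by the algorithms; it
refuses any message kind outside {eigen_package, unmixing_maps,
centroids, gradients, counts, scalar_stats} and logs every transfer with
its payload. `audit_privacy` then checks (a) no payload exceeds the
largest legitimate statistics width and (b) no payload column equals any
raw subject column up to sign and scale. Centroids drawn from local
windows are deliberately shared — they are derived connectivity
statistics, and the protocol's initialization step requires it. Final
label vectors are gathered outside the channel purely for reporting; in a
deployment they would stay local. This is "plausible privacy": nothing
quantifies leakage, and differential privacy is out of scope.

## 8. Numerical choices and degenerate inputs

Rank detection uses a relative singular-value cutoff of $10^{-10}$; SVDs
switch to the Gram-matrix eigendecomposition when both dimensions exceed
512 (halving precision, irrelevant above the rank cutoff, and necessary
for voxel-scale speed). Singular-vector signs follow the
largest-magnitude-entry-positive convention; component matching is
therefore sign-agnostic (cost $1-|\rho|$) with signs reconciled after
matching. Back-reconstruction uses normal equations with an SVD
pseudo-inverse fallback and warnings on rank deficiency. Group contrasts
use pooled-variance two-sample t by default (Welch behind a flag), with
*no* multiple-comparison correction — the maps are raw, as conventional
for state-difference displays. All-zero matrices, zero-norm columns,
zero-variance vectors, empty consortia, too-short timecourses, and
non-identifiable generator setups raise immediate errors.

## 9. Known limitations

Input is flat voxels × timepoints text matrices; no NIfTI reader is
bundled (none is available in the supported dependency set), so masking
happens upstream. The single-shot "merging error" variant and
decentralized K-means++ initialization are registry slots, not
implementations. Runtime comparisons between serial and parallel PCA are
reported, never asserted — they are hardware-dependent. The in-process
simulation ignores transport latency, asynchrony, and site failure.
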