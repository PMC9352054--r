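---
title: "Quantifying Ciona larval swimming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Ciona larval swimming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cionaswim)
```

# Overview

`cionaswim` quantifies the swimming behavior of *Ciona intestinalis* larvae
from tracked midline skeletons: 49 ordered points per frame at 30 frames per
second, with 49 contour widths and a per-frame validity flag, as produced by
upstream trackers of the Tierpsy family. The package covers the full
analysis chain:

1. **Posture featurization** — neck detection, a seven-segment body
   partition, signed curvature, relative tangent angles, quirkiness and
   segment speeds (25 features per frame).
2. **Eigenposture decomposition** — PCA of the curvature covariance into
   "eigencionas" and per-frame eigencoefficients EC1–EC6.
3. **Motif mining** — multidimensional matrix profile over the 7
   segment-curvature channels, motif extraction under a distance threshold,
   and time-series k-means clustering.
4. **Behavioral states** — a 10-state full-covariance Gaussian hidden
   Markov model over `[EC1..EC6, quirkiness]` with Viterbi decoding,
   per-condition state usage and transition matrices.
5. **Behavioral space** — Morlet wavelet features (180 dimensions),
   speed-weighted frame sampling, a composite 4-D t-SNE embedding, density
   clustering into stereotyped regions and a k-nearest-neighbor assigner.
6. **Statistics** — standardized median differences (SMD), Shapiro–Wilk
   normality screening, Wilcoxon signed-rank and Mann–Whitney U batteries
   with Bonferroni correction, per-video usage comparisons, and
   light-stimulus event-window analysis.
7. **Synthetic data** — a larval-swim generator with full ground truth
   (regimes, planted motifs, planted stimulus responses) so every stage is
   testable without external data.

All indices in the R API are 1-based (point 1 = head tip, point 49 = tail
tip); the CSV interchange columns `x0..x48` follow the upstream 0-based
naming.

# Posture features

**Neck detection.** The neck is the sharp constriction where the wide trunk
meets the narrow tail. The width profile is smoothed with a 5-point moving
average and the first difference is minimized over the admissible anterior
range (points 5–23, 1-based). Ties break toward the anterior. The smoothing
width and the tie rule are package conventions; the admissible range is
anatomical.

**Segments.** Head (tip to two points before the neck), a 3-point neck
segment centered on the neck point, and five contiguous tail blocks —
tail base, pre-mid, mid, post-mid and tip — of as-equal-as-possible size.
The integer-division remainder goes to the most posterior blocks and the
midpoint of an even-sized block is its lower-middle index; both conventions
are arbitrary but fixed and tested.

**Curvature.** The midline is treated as a differentiable curve; curvature
is the rate of change of the tangent angle with arc length,
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$, with derivatives over point
index estimated by a Savitzky–Golay filter of window 15 and polynomial
order 2. Units are 1/pixel. The sign convention (positive = leftward bend
along head-to-tail traversal, in image coordinates with y pointing down) is
a package choice. Per-frame speed-up: the filter is linear, so it is applied
as a cached 49×49 operator to all valid frames at once; this is exactly
equivalent to filtering each frame.

**Relative tangent angles.** Each segment's tangent is the four-quadrant
angle of the chord joining its end points; subtracting the head segment's
angle expresses posture in the animal's own frame. Angles are wrapped into
$(-\pi, \pi]$.

**Quirkiness.** $q = \sqrt{1 - (b/a)^2}$ where $a \ge b$ are the extents of
the skeleton point cloud along its two principal axes. A straight body has
$q = 1$; a body whose principal-axis bounding box is square approaches
$q = 0$. The principal-axis (rather than image-axis) box makes the measure
rotation invariant. This eccentricity form is the only reading of the
"ratio of the axes" description consistent with both stated extremes, and
matches the definition used by the upstream tracker.

**Segment speeds.** Per-point Euclidean displacement between adjacent
frames (pixels/frame), averaged over each segment's points. The first frame
and frames adjacent to invalid frames are masked, never interpolated.
Multiply by `um_per_pixel * fps` for µm/s; the bundled calibration is
1,330.61 µm ≙ 115.10 px (11.56 µm/px).

# Eigenposture decomposition

The 49×49 sample covariance of curvature (denominator $n-1$) is
eigendecomposed; eigenvectors are sorted by descending eigenvalue and
sign-fixed so each one's largest-magnitude entry is positive, making the
basis bit-reproducible for a fixed input order. Projections subtract the
training mean curvature by default (`center = FALSE` is available for
sensitivity checks, since deposited coefficient sets may have been computed
either way). On wild-type-like data six modes capture ≈97% of curvature
variance, so `k = 6` is the default; the residual on the training sample
equals the discarded eigenvalue mass (a tested identity).

# Motif discovery

The 7 segment-midpoint curvature channels are smoothed with a centered
10-frame rolling mean (edges truncated) and scanned with a multidimensional
matrix profile: for every window start, the minimum over all other starts of
the mean across channels of the z-normalized Euclidean distance, with a
trivial-match exclusion zone of $\lceil m/2 \rceil$ frames around self. The
implementation uses a diagonal-traversal sliding-dot-product recurrence
(O(channels·T²), exact); the test suite compares it against an independent
brute-force oracle to 1e-6 on instances up to T = 500.

Numerical choices: window variances are floored at 1e-8 before
z-normalization (near-constant windows otherwise divide by ~0); windows
covering invalid frames neither give nor receive matches; motif onsets are
local profile minima below the threshold (default 8), accepted greedily in
ascending profile order with an exclusion of one window length between
accepted starts, so extracted motifs never overlap. The greedy rule and the
exclusion are package conventions — the deposited motif counts from the
original screen are therefore not expected to be matched exactly.

A practical note on the threshold: the maximum possible z-normalized
distance grows like $2\sqrt{m}$, so a fixed threshold of 8 is selective for
5-second windows ($m = 150$, background pairs sit near
$\sqrt{2m} \approx 17$) but admits most background at 1-second windows
($\sqrt{60} \approx 7.7$). Recall of planted motifs is therefore
demonstrated at the 5-second window; at 1-second windows the threshold
functions as a weak filter and clustering carries the structure.

Motifs are clustered with Euclidean k-means on the flattened, un-normalized
m×7 matrices (amplitude is informative — active and idle motifs differ by
scale), with a fixed seed and multiple starts. The cluster count (default
15) can be checked with the elbow rule: the k at the maximum discrete second
difference of the inertia curve, ties to the smallest k.

# Behavioral states (Gaussian HMM)

A 10-state Gaussian HMM with full covariance is fit to
`[EC1..EC6, quirkiness]` by Baum–Welch over a pooled set of sequences.
Recordings are split at invalid-frame gaps into contiguous segments before
fitting and decoding, since the chain needs uninterrupted observations; the
filter keeping recordings with at least 80% valid frames mirrors the
upstream selection rule for model fitting.

Initialization and stopping are explicit: k-means on the pooled frames with
the given seed supplies initial means, within-cluster covariances and
label-sequence transition counts (+1 smoothing); EM stops when the
log-likelihood gain falls below 1e-3 or at 200 iterations; covariance
diagonals are floored at 1e-6. Identical seeds give identical fits. State
labels are arbitrary, so all cross-model comparisons align states first by
Hungarian matching on state means (an exact O(K³) assignment solver is
included and tested against brute-force enumeration).

`selection_report()` fits candidate state counts (6, 8, 10, 12, 15) and
covariance structures and reports, per model, the log-likelihood and the
number of states used in less than 1% of decoded frames — the
over-segmentation symptom that argues against too many states.
`stability_protocol()` refits on the full data under several seeds and on
mutually exclusive random and condition-balanced splits, reporting
state-mean correlations after alignment.

Per-condition empirical transition matrices pool transition counts within a
condition but never across recording boundaries; unobserved rows are set
uniform and flagged. Exported edge lists keep transitions above 0.001 and
label those above 0.01, matching the conventions of the transition graphs.

# Behavioral space

**Wavelet features.** Each eigencoefficient channel is transformed with an
analytic Morlet wavelet (center parameter $\omega_0 = 5$) at 30 uniformly
spaced frequencies in 1–30 Hz, computed in the Fourier domain with
reflective padding; the modulus is taken and normalized per scale by
$s^{-1/2}$ so responses are comparable across frequencies. Six channels ×
30 scales = 180 features per frame. Frequencies above the 15 Hz Nyquist
limit of 30 fps data are retained for fidelity to the original design; they
carry attenuated spectral leakage rather than independent information.

**Sampling.** Training frames are sampled with probability proportional to
$0.5\,s_N + 0.1\,(s_{TB}+s_{TprM}+s_{TM}+s_{TpoM}+s_{TT})$, emphasizing
active swimming. Draws are without replacement unless more frames are
requested than exist (then with replacement, flagged); all-zero weights fall
back to uniform with a warning.

**Embedding.** Three planar t-SNE embeddings are fit, each with PCA
initialization (scaled to a tight spread) and a cosine metric (implemented
as Euclidean distance on unit-normalized rows, a monotone transform), an
early-exaggeration phase (factor 12) and a main phase: perplexity 500 with
final exaggeration 1, perplexity 250 with exaggeration 3, and perplexity
750 with exaggeration 2. The composite behavioral space is
`[e1.x, e1.y, e2.x, e3.y]`; e2.y and e3.x are computed and discarded. The
t-SNE itself is an exact implementation: perplexity-calibrated sparse input
similarities over a k-nearest-neighbor graph (k = 3·perplexity) and dense
pairwise repulsive forces, deterministic given the initialization. When
fewer than 3·max(perplexity) points are supplied, all perplexities are
scaled down proportionally and the factor is recorded in the fitted object.
This quadratic-cost implementation is intended for desk-scale samples
(≈10⁴ points); the package's own analyses and tests use roughly 10³–10⁴
training frames with 190–450 gradient iterations.

**Clustering and assignment.** DBSCAN over the 4-D composite coordinates
yields the stereotyped regions plus an outlier class (label 0). The radius
`eps` is not a universal constant; when unset it is tuned by a geometric
grid sweep targeting six clusters (the number of stereotyped regions in the
original analysis), choosing the middle of the plateau that achieves the
target; the sweep is kept in the fitted object for inspection. New frames
are labeled by a distance-weighted 200-nearest-neighbor vote in the
180-dimensional wavelet feature space against the labeled training frames —
this space is well-defined for unseen frames without re-embedding, which is
why it is the default assignment space; an exact feature match inherits its
neighbor's label, so training frames reproduce their own labels.

**Occupancy maps.** 2-D histograms of the first embedding's plane are
Gaussian-smoothed and clipped at 0.8% of the smoothed maximum — the printed
rendering convention, implemented literally (`saturation = 0.008`) with the
level exposed because a 80% reading is also plausible. Cluster-transition
matrices drop outlier frames and bridge across them (the transition joins
the surrounding labeled frames), while invalid frames break the chain.

# Statistics

**SMD.** $(\mathrm{median}_1 - \mathrm{median}_2)/s_p$ with
$s_p = \sqrt{(s_1^2+s_2^2)/2}$ and $s = 1.4826\,\mathrm{MAD}$ by default —
a robust scale consistent with the median-based numerator and the heavy
tails of posture features; a classical-SD variant sits behind `scale =
"sd"` since the original screen's exact scale is not printed.

**Test battery.** Shapiro–Wilk at α = 0.05 screens normality (samples above
the test's 5,000-value limit are thinned deterministically); posture
features fail it, so comparisons are nonparametric. Across body segments
(dependent values along one animal) the Wilcoxon signed-rank test is used;
zero differences are dropped (signed-rank convention), exact null for small
tie-free samples, normal approximation with tie correction otherwise.
Drug-versus-control feature comparisons use Mann–Whitney U with effect size
$U/(n_1 n_2)$ and Bonferroni-corrected α = 0.05/25 = 0.002 for the
25-feature panel. Usage comparisons work on per-video percentages of frames
in a state/cluster at uncorrected α = 0.05. Both small-sample tests are
verified against exhaustive null enumeration in the test suite, and the
usage comparison's type-I error is checked against its nominal level over
1,000 null simulations.

**Light stimuli.** A 60-s stimulus window starting at the 30th second
defines four analysis windows: 10 s immediately before each of the ON and
OFF events and 2.5 s starting 0.5 s after each event (the post-event skip
is applied at both events; the design is symmetric). At 30 fps the ON
windows are frames [600, 900) and [915, 990), half-open and 0-based.
Event responses are after-minus-before SMDs per panel feature.

# The synthetic swim generator

The generator is first-class, tested code that defines the package's study
conditions; it emulates what the pipeline measures, not hydrodynamics.

**Posture model.** The curvature field is
$\kappa(s,t) = \sum_{i=1}^{6} a_i\,\alpha(r_t)\, b_i(s)\,
\sin(h_i\,\phi_t + (i-1)\,\psi) + \mathrm{asym}(r_t)\,b_1(s) + \epsilon$,
with relative mode amplitudes $a = (1, 0.8, 0.6, 0.5, 0.4, 0.3)$, regime
amplitude $\alpha$, phase $\phi_t$ advancing at the regime's tail-beat
frequency, quadrature phase lag $\psi = \pi/2$, and harmonic multipliers
$h = (1, 1, 1.5, 1.5, 2, 2)$. Two design points deserve explanation:

* *Why harmonics:* a pure traveling wave makes all six mode coefficients
  linear combinations of $(\sin\phi, \cos\phi)$ — a temporally rank-2
  signal that cannot ground-truth a 6-mode decomposition. Driving mode
  pairs in quadrature at three distinct frequencies gives all six shapes
  independent variance.
* *Why these basis shapes:* the measurement chain (skeleton synthesis by
  tangent integration, then Savitzky–Golay curvature) is a strong spatial
  low-pass. Raw orthogonal polynomials of degree 4–5 are distorted enough
  that the re-extracted eigenmodes no longer span the planted subspace.
  The generator therefore uses the orthonormalized leading eigenshapes of
  the linearized measurement operator restricted to the tail
  (`curvature_mode_basis()`): smooth, polynomial-like bends that the
  measurement transmits nearly unchanged (transmission gains ≈0.91 down to
  ≈0.23). Subspace-recovery checks compare tail-restricted subspaces,
  because the filter spreads ~1–3% of mode energy across the neck boundary
  into head indices — a measurement artifact, not a posture feature.

Skeletons are reconstructed by integrating the tangent angle along arc
length at fixed spacing (115.10 px body length / 48 gaps), so arc spacing
is constant by construction. The head is rigid: modes are zero through the
neck, and only observation noise bends it.

**Kinematics.** Six regimes — dwell, beat, glide, clockwise and
counter-clockwise turns, startle — follow a per-frame Markov chain whose
default transition matrix produces intermittent beat-and-glide locomotion
with rare startles (dwell self-transition 0.985, bout lifetimes of a few
hundred ms to seconds at 30 fps). Propelled regimes move head-first at
`gain × amplitude × frequency / fps` pixels per frame (default gain 18
gives ≈3 px/frame ≈ 1 mm/s during beats — the observed order of magnitude
for larval swimming); glide and dwell speeds decay exponentially with time
constants 0.5 s and 0.15 s. Turns add ±2 rad/s heading drift and an
asymmetric bend offset; startle is a brief high-amplitude, high-frequency
(7 Hz) burst. Amplitude scale: `base_curvature_amp = 0.09` 1/px yields tail
deflections up to roughly a half turn and quirkiness excursions below 0.97
during full beats — moderate, realistic bends. The 7 Hz startle frequency
keeps the highest harmonic (2 × 7 = 14 Hz) under the 15 Hz Nyquist limit.

**Noise and dropouts.** Observation noise is additive on the curvature
field, i.i.d. per point and frame, with sd expressed as a fraction of the
recording's maximum noiseless curvature (default 5%); it propagates through
skeleton synthesis exactly as segmentation jitter would. Note one
consequence: even motionless larvae show a noise floor in measured segment
speeds (≈0.4 px/frame at default settings), as real tracking data do.
Dropout frames are invalid with missing coordinates, exercising every
stage's gap policy.

**Planting.** `plant_motif()` overwrites stretches of a recording with a
7-channel segment-curvature template (spline-interpolated to 49 points,
resynthesized with the frame's original head position and heading), so all
plant sites carry identical shapes up to optional noise. `
plant_stimulus_response()` scales whole-body translation during the
stimulus window while leaving shapes untouched, planting a pure speed
effect with known sign.

**What the generator does not emulate.** No hydrodynamics (propulsion is a
kinematic gain), no contour re-estimation errors, no tracker-specific
artifacts (head/tail flips, segmentation failures correlated with posture),
no arena walls or interactions, and real larvae do not follow Gaussian
emission or first-order Markov dynamics exactly. Passing tests on this
generator therefore demonstrate the *correctness of the computations* and
the *recoverability of planted structure* — not that real data satisfy the
models' assumptions.

# Problem sizes and reproducibility

Every random stage takes an explicit seed; fixed seeds give bit-identical
recordings, fits and embeddings. The package's own verification runs at
desk scale, chosen as the smallest sizes at which each property is
comfortably demonstrated: ≈54,000 frames for the eigenposture variance
twin; T ≤ 500 for oracle-exact matrix-profile comparisons; 10⁵ frames for
4-state HMM parameter recovery (transition entries within 0.05, Viterbi
accuracy ≥ 90%); ≈900 training frames with proportionally reduced
perplexities for the behavioral-map twin (six planted regimes, adjusted
Rand ≥ 0.8, assigner fidelity 100% on training frames); 1,000 replicates
for the type-I error check. The original screen's full scale (≈2.9 million
frames, 200,000-frame embeddings) is orders of magnitude larger; nothing in
the code depends on the reduced sizes, and `scripts/acceptance.R` recomputes
the headline quantity from scratch at the sizes above.

# Known limitations

* The tierpsy-HDF5 dialect is declared but not readable here; recordings
  arrive via the documented CSV interchange (one row per frame:
  `frame_index`, `valid`, `x0..x48`, `y0..y48`, `w0..w48`).
* The exact t-SNE is quadratic in sample size; it is not intended for
  10⁵-point embeddings.
* Motif extraction at 1-second windows under threshold 8 is permissive (see
  above); deposited motif counts are not reproduced exactly because the
  dip-detection and overlap rules are package conventions.
* DBSCAN's `eps` depends on embedding geometry; the automatic sweep targets
  a cluster count rather than fixing a radius.
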