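---
title: "Methods: synthetic cortico-cerebellar theta analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cortico-cerebellar theta analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`corticocereb` re-implements, over fully synthetic data with known ground
truth, a source-level EEG analysis of cortico-cerebellar theta-band (3–8 Hz)
dynamics during social interaction: a high-density EEG protocol with
resting-state baselines and a coordination task, band-pass filtering and
epoch cleaning, shrinkage noise covariance and eLORETA/minimum-norm source
reconstruction on a labelled cortex+cerebellum source graph, Welch
cross-spectra with coherence, symmetric orthogonalization and the weighted
phase lag index, Z-scored condition contrasts, and cluster-based permutation
statistics with TFCE and FDR-corrected region-pair tests.

Real clinical recordings of this kind are typically not shareable, so the
package's first-class citizen is a generator whose injected effects the
pipeline must recover. Every analysis step is an exported function; the
numbered scripts under `analysis/` are thin drivers over them.

# The synthetic generator

## Head model

The head is a homogeneous conducting unit sphere. Electrodes are placed
quasi-uniformly on the upper hemisphere by a golden-angle spiral, plus an
inferior-posterior patch (1/8 of the montage, at least 8 electrodes) over
the cerebellum — without such coverage cerebellar sources are essentially
invisible to the inverse. Twelve bilateral regions (frontal, sensorimotor,
temporal, temporo-parietal junction, occipital, cerebellum) each receive
`nodes_per_region` source nodes scattered around fixed centroid directions.
Cortical nodes sit at eccentricity 0.85, cerebellar nodes deeper at 0.70,
so inverse tests genuinely exercise the depth asymmetry that makes
cerebellar sources harder to localize. Dipole orientations are radial
(scalar sources).

The forward solution is the exact potential of a current dipole in a
homogeneous sphere with an insulated boundary, evaluated by the Legendre
expansion of the Neumann Green function summed to a 1e-13 relative
tolerance (geometric convergence in eccentricity^n). The test suite checks
it against the independent closed form for radial dipoles and against
superposition/symmetry identities. The leadfield is average-referenced and
scaled so clean sensor signals land in a realistic tens-of-microvolts
range. Source adjacency is a symmetric k-nearest-neighbour graph built
separately within the cortical and cerebellar node groups; cerebello-
cortical edges exist only when configured explicitly.

## Signals

Each source node carries:

* a pink (1/f power) background, generated by spectral shaping with a flat
  floor below 0.5 Hz, unit variance;
* a theta oscillation (centre 5.37 Hz, slow phase drift) of amplitude 4 at
  every node; during the interaction condition the amplitude at the
  configured regions (default: both cerebellar and both frontal regions) is
  multiplied by `theta_gain` (default 2, i.e. a 4x band-power increase);
* an alpha oscillation (10.23 Hz, amplitude 3) at occipital nodes, doubled
  when eyes are closed;
* a mu oscillation (11.61 Hz, amplitude 2) at sensorimotor nodes, halved
  during interaction (mu suppression).

Centre frequencies are deliberately non-commensurate with the 1 s epoch
grid. Half-integer frequencies are phase-locked to integer-second epoch
onsets, which manufactures a spurious "evoked" structure across epochs and
corrupts any epoch-mean-based statistic; this was observed directly during
development and is the reason for the odd-looking values.

Zero-lag (or configurably lagged) cerebello-cortical coupling is built from
a shared theta phase process: member nodes of a coupled pair follow a
common drifting phase, offset by the configured lag, plus independent
wrapped-Gaussian phase jitter with standard deviation `(1 - strength) * pi`
radians. The jitter is low-passed at 4 Hz — faster than the shared 1 Hz
drift — so that at zero lag the residual imaginary cross-spectrum changes
sign across Welch segments. This choice is load-bearing: with slower
jitter, the sign of Im S_xy persists across the two segments of an epoch
and the small-sample wPLI estimator saturates, destroying the
coherence-up/wPLI-flat dissociation that distinguishes genuine lagged
coupling from zero-lag (volume-conduction-like) coupling.

Sensor data are leadfield-projected sources plus white noise scaled to an
amplitude signal-to-noise ratio (default 5). Artifacts are 200 ms pulses of
`artifact_amplitude` (default 500 uV) injected on 1–3 random channels in a
randomly chosen fraction (`artifact_rate`) of 1 s windows; every injected
window is recorded so that rejection quality can be scored against ground
truth.

## Protocol

The event schedule mirrors the study design: resting state as eyes-open
then eyes-closed blocks of 30 s repeated three times; the coordination task
as 4 blocks x 10 trials with the in-phase/anti-phase instruction
alternating across blocks, each trial being 3 s of metronome warm-up, a 1 s
transient, ~15 s of interaction and a closing 1 s transient. Only the
interaction segments carry task labels and are epoched — the transients
exist precisely to keep non-stationary switches out of the analysis. The
analysis drivers and acceptance runs use shortened blocks (15 s resting
blocks twice, 2 task blocks of 5 trials, 10 s interactions) so a full
18-participant cohort completes in minutes; all sizes are plain
configuration fields.

# Preprocessing

The order is fixed: zero-phase FIR band-pass (0.5–48 Hz, Hamming design,
3.3/transition-width rule), average-reference projection, 1 s epoching,
decimation by 4 (1000 -> 250 Hz; the band-pass guarantees the new Nyquist),
then peak-to-peak rejection fitted on the pooled resting + task epochs and
applied to all of them. Zero-phase filtering applies the squared magnitude
response in the frequency domain with reflection padding — exactly the
forward–backward FIR result, with doubled stop-band attenuation and no net
group delay.

## Rejection: what the cross-validated objective can and cannot do

Thresholds are per-channel peak-to-peak limits chosen from a candidate grid
(pooled peak-to-peak deciles plus percentile resolution above the 90th) by
k-fold cross-validation of a simplified Autoreject objective: the RMS
distance between the mean of threshold-surviving training epochs and the
per-sample median of held-out epochs.

Two properties of this objective on *non-evoked* data were measured during
development and shaped the final rule. First, because resting/oscillatory
epochs have no common waveform, both the train mean and the test median
estimate zero, and the objective degenerates into a variance minimizer: it
rewards excluding loud-but-clean epochs (e.g. eyes-closed alpha), with a
smooth shallow error gradient toward aggressive rejection. Second, a single
500 uV artifact epoch among a hundred shifts the cross-validated error by
far less than one fold standard error, so sparse artifacts are invisible to
it. The selection rule therefore (a) walks the grid downward from full
retention and accepts a smaller threshold only on an *abrupt* improvement
larger than one cross-validation standard error — the signature of
excluding genuine artifact epochs, which smooth variance gradients never
produce — and (b) caps each channel's threshold with a robust Tukey-style
fence, Q3 + 4·IQR of that channel's peak-to-peak distribution. The fence
multiplier 4 places the cap far outside the bulk of clean epochs (roughly
seven standard deviations for light-tailed peak-to-peak distributions)
while quartiles tolerate up to 25% contamination.

Epochs with no channel above threshold are kept; epochs whose bad-channel
fraction is at most the consensus fraction `kappa` (default 0.1) are
repaired by inverse-distance-weighted averaging of the nearest good
channels; worse epochs are rejected. Repaired channels are logged per
epoch.

# Source reconstruction

The noise covariance comes from the eyes-open resting epochs with shrinkage
`C = (1 - s) C_emp + s (tr/n) I` (default s = 0.1); a variant low-passes
the epochs at 8 Hz first so intrinsic alpha is not modelled as noise.
Leadfield and data are whitened with the pseudo-inverse square root of C.

eLORETA uses the scalar fixed-point iteration: diagonal weights
`w_i <- sqrt(l_i' (L W^-1 L' + alpha I)^+ l_i)` until the largest relative
weight change falls below the tolerance (default 1e-6; non-convergence is
an error carrying the change trace). The minimum-norm operator is the
Tikhonov solution. In both, `alpha = lambda tr(G)/n_channels` with
`lambda = 1/9` by default (the usual assumed-SNR-of-3 heuristic); the
amount of regularization is a config value because no principled value is
available without real data. Pseudo-inverses use an eigendecomposition with
a 1e-12 relative cutoff (the average reference makes sensor-space matrices
rank-deficient by one).

eLORETA's defining property — exact localization of noiseless point
sources — is verified over every node of the fixture model; minimum-norm
localization is held to two hops on the source graph, a bound measured on
the fixture and dominated by the depth bias at cerebellar nodes.

ROI time courses are arithmetic means over member nodes (no sign-flip
alignment, following the literal averaging choice; a pair of
equal-and-opposite nodes cancels — a documented limitation of unsigned
averaging).

# Spectra, connectivity and contrasts

Welch cross-spectra use 125-sample segments with 62-sample overlap (at the
250 Hz decimated rate a 1 s epoch yields exactly two segments starting at
samples 0 and 63, and 2 Hz bins), Hann taper, mean detrending, one-sided
density scaling. Coherence is `|<S_xy>| / sqrt(<S_xx><S_yy>)` with the
standard square-rooted denominator; wPLI is `|<Im S_xy>| / <|Im S_xy|>`
with an epsilon guard of 1e-15 for degenerate denominators. "Overlap 62" is
read as 62 samples (~50% of 125), not percent. Segment averages pool epochs
and segments jointly within a condition for the pooled estimates; the Z
contrast uses per-epoch values (segments averaged within epoch), which is
the logged interpretation of the per-epoch ambiguity. Both metrics are
verified to 1e-10 against direct-DFT brute-force oracles on 8-sample toy
segments (interior frequency bins; DC is exactly zeroed by detrending and
the imaginary part at Nyquist is exactly zero for real signals, so both are
0/0 ratios there).

Symmetric orthogonalization takes, per epoch, the orthonormal polar factor
of the time x ROI matrix — the closest orthonormal set in least squares —
rescaled to each ROI's original norm; rank-deficient inputs are an error.
It removes zero-lag (leakage-like) correlation, and the suite asserts the
resulting coherence drop on an instantaneous-mixing fixture.

The condition contrast is `Z = (mu_A - mu_B) / sigma_B` after band
averaging (band edges inclusive), with A the interaction epochs and B the
eyes-open baseline; `sigma_B = 0` is an explicit error naming the unit.
Cohen's d uses the pooled n-1-weighted standard deviation.

# Statistics

Cluster-based permutation tests form supra-threshold connected components
on the source (or electrode) graph, scored by mass (sum of t). The
cluster-forming threshold defaults to the two-sided p = 0.05 critical t for
the design's degrees of freedom. The null distribution of the maximum
cluster mass uses sign flips of participant maps for the one-sample
(within-group) design — the standard one-sample analogue of exchanging
participant labels — and group-label exchange for the two-sample design,
with the +1 finite-permutation correction. Connected components in the
permutation loop use a hand-rolled BFS (hot path); the test suite
cross-checks memberships against igraph. Type-I calibration is asserted
empirically: over 500 null replicates at 200 permutations, the family false
positive rate must fall inside the 95% binomial interval around 0.05, on
both the source graph and the sensor graph.

TFCE integrates `e(v,h)^E h^H dh` over thresholds with E = 0.5, H = 2 and
`dh = max|t|/50` by default; negative values are enhanced on the negated
map and re-signed. On integer maps with dh = 1 the implementation equals
exhaustive threshold enumeration, checked over all 4^5 maps on several
5-node graphs.

Region-pair analyses test the per-participant coherence Z values for the
12 cerebello-cortical pairs (each cerebellar hemisphere against frontal,
sensorimotor and temporo-parietal regions bilaterally): one-sample t within
group, two-sample t between groups, each family Benjamini–Hochberg
corrected across pairs. Participants whose Cohen's d maps have more than 5%
of sources above 10 are excluded before group statistics (strict
"more than" on the fraction).

The power helper uses the noncentral t distribution
(`df = n1 + n2 - 2`, noncentrality `d sqrt(n1 n2/(n1+n2))`); at d = 0.5
with groups of 107 and 33 it reproduces the published design power of 0.7.

# What the synthetic cohort shows — and what it cannot

On the seeded default cohort (12 affected-like participants with injected
theta gain and zero-lag coupling, 6 null control-like participants), the
pipeline reports significant within-group theta clusters covering the
injected cerebellar and frontal nodes, recovers the injected pairs in the
coherence contrast with no significant pairs in the control group, and
shows the dissociation: strongly positive coherence contrasts with wPLI
contrasts that are not significantly positive at zero lag. Injected
coupling can also *redistribute* baseline leakage coherence, producing
genuine negative contrasts at neighbouring pairs; the tests therefore
constrain spurious positives, not all side effects. Spectral leakage from
the boosted theta peak can likewise reach the 10 Hz bin at
cerebellar-patch electrodes, so the sensor-level mu-suppression check is
asserted over central electrodes where it belongs.

Passing these tests shows the machinery is correct and calibrated under
the generator's assumptions — stationary 1/f-plus-oscillation sources, a
spherical homogeneous head, white sensor noise, pulse artifacts. It does
not certify performance on real EEG, whose artifacts are broadband and
spatially correlated, whose anatomy is not spherical, and whose effects
are far smaller than the injected ones.

# Numerical choices

* FIR design: Hamming window, order `ceil(3.3 fs / transition width)`,
  transition `min(max(low_cut, 0.5), 2)` Hz; recordings must exceed three
  filter lengths.
* Pseudo-inverse cutoff 1e-12 (relative); eLORETA tolerance 1e-6, cap 100
  iterations.
* wPLI epsilon 1e-15; band edges inclusive; TFCE dh = max|t|/50.
* Permutation p floor `1/(n_permutations + 1)`; all permutation streams and
  cohort members draw seeds deterministically from the master seed via a
  32-bit-safe linear derivation.
* EDF export quantizes to 16 bits over each channel's physical range (one
  data record per second); round-trip error is bounded by range/65535.
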