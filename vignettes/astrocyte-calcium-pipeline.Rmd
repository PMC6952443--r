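---
title: "Methods: astrocyte Ca2+ imaging and hemodynamic response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: astrocyte Ca2+ imaging and hemodynamic response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Astrocytes respond to acute drops in cerebral perfusion pressure
(CPP = MAP − ICP) with elevations in intracellular Ca2+, and this response
can be read out in vivo by two-photon imaging of a Ca2+ indicator (e.g.
OGB) together with an astrocyte-selective structural marker (e.g. SR101),
while ICP, arterial pressure and sympathetic nerve activity are recorded
simultaneously. Turning such recordings into per-compartment event
statistics requires a chain of non-trivial steps — motion correction,
time-varying baseline estimation, denoising/detection, segmentation, event
statistics — each with failure modes that are invisible without ground
truth. `astroca` implements that chain and pairs it with a synthetic-data
generator that plants every quantity the chain is supposed to recover, so
each stage is tested against known truth.

## Synthetic data: what is emulated, and what is not

`generate_movie()` builds a two-channel movie as

    functional = [baseline drift] x (1 + planted transients), warped, + noise
    structural = static marker texture, warped by the same fields, + noise

* **Geometry.** Somas are filled ellipses (radii 4–8 px), processes are
  thick curved polylines (2–3 px wide), endfeet are annular arcs hugging a
  smooth synthetic vessel path. Structures are painted disjoint with a
  2 px separation, and soma/process bodies stay out of a 4 px perivascular
  margin (that interface belongs to endfeet): the scored compartments in a
  real field of view are individually resolvable, and classification by
  vessel adjacency is only meaningful if non-endfoot structures do not
  graze the vessel.
* **Transients.** Difference-of-exponentials kinetics (default rise 0.5 s,
  decay 2 s), normalized to unit peak, multiplicative on the baseline,
  with Poisson event timing (default 1.5 events/min per ROI). A frame
  counts as planted-active when the transient sum exceeds half the peak
  amplitude (FWHM convention); the same convention is used when measuring
  event durations downstream, which keeps "active time" well defined
  without reference to any detector threshold.
* **Drift.** A sum of `drift_rank` (default 3) separable components —
  smooth random spatial maps times sub-cycle temporal sinusoids — scaled
  to a default 10% of baseline intensity. The planted baseline therefore
  has matrix rank at most `drift_rank + 1` by construction, making the
  low-rank assumption of the baseline stage true exactly.
* **Motion.** Rigid shifts follow a smoothed, centered random walk (peak
  2 px by default); non-rigid displacement is a low-frequency separable
  sinusoid field (peak 0.75 px), with temporal modes centered so the
  ground-truth reference geometry coincides with the temporal mean — the
  alignment target a template-based corrector can actually estimate.
* **Noise.** Gaussian with intensity-independent SD by default (keeps the
  noise-SD ground truth exact for detector calibration); a Poisson mode is
  available for shot-noise realism.

Not emulated: vessel diameter dynamics, z-motion, bleaching chemistry,
indicator saturation, inter-animal variability, and spatially correlated
("structured") noise. Passing tests on these movies therefore demonstrate
correctness of the algorithms under their stated assumptions, not
performance on every pathology of real data.

`generate_physio()` plants a minutes-long ICP step (default 12 mmHg for
5 min, linear 5 s ramps), a delayed pressor response (default +21 mmHg MAP
and +49 bpm starting 32 s after stimulus onset, decaying linearly to
baseline 120 s after offset), an arterial pulse wave at the instantaneous
heart rate, and a raw sympathetic signal modeled as amplitude-modulated
white noise whose envelope follows the pressor response at 1.9% of resting
activity per mmHg. `generate_traces()` is the trace-level counterpart used
for long-duration event statistics, with an optional within-stimulus event
rate multiplier (inhomogeneous Poisson).

## Motion correction

Rigid shifts are estimated per frame by FFT cross-correlation against the
temporal median frame (robust to transients), with Hann windowing — the
shared border content otherwise acts as a spurious zero-shift component
and biases the peak — and ×10 upsampled-DFT subpixel refinement. The dense
stage minimizes the combined local–global (CLG) optical-flow energy: a
structure-tensor data term smoothed over an integration scale `rho`
(default 2 px) plus a Horn–Schunck smoothness term with weight `lambda`
(default 40), solved by fixed-point iteration (default 60 per level, two
warp sweeps) on a 3-level coarse-to-fine pyramid. The structural channel
drives all estimates; both channels are resampled identically (bilinear,
edge-replicated). The regularization weight, pyramid depth and
template choice are engineering defaults — flagged as configurable because
no canonical values exist for this data class.

Displacement convention, used everywhere: fields store content
displacement in (row, col) = (y, x); `moving(y + dy, x + dx)` aligns the
moving frame to the fixed frame. Template-referenced rigid shifts are
re-centered to zero mean — registration is defined only up to a constant,
and the temporal mean position is the gauge that minimizes total
resampling (it is also the generator's ground-truth reference).

## Baseline F0(t) and dF/F0

The frames-by-pixels matrix F is decomposed by truncated SVD; the first
`r = 20` temporal components are smoothed by asymmetric iteratively
reweighted penalized least squares and projected back, giving a slow
low-rank trend; local deviations are then corrected in small overlapping
windows (16 × 16 px, 50% overlap, 30-frame smoothing) blended with
raised-cosine weights normalized to unit total weight. dF/F0 =
(F − F0) / max(F0, floor), floor = 1% of the global mean.

Three numerical choices deserve explanation:

* **Upswing flagging is morphological, not residual-based.** The IRLS
  smoother flags upswing samples where the trace exceeds its temporal
  opening (rolling min-then-max, 31 samples) by two fast-noise SDs, and
  only those samples are down-weighted (weight `p = 0.1`, refined by a
  bisquare factor each iteration). Reweighting by the sign of the evolving
  residual — the textbook asymmetric scheme — is unstable here: wherever
  curvature leaves a small positive residual the fit sags, the sag grows
  the residual, and the iteration ratchets smooth peaks away.
* **Transient power is clipped before the SVD.** Each pixel trace is
  clipped at its temporal opening plus `clip_k = 2` noise SDs. Without
  this, transient components can carry larger singular values than the
  slow drift (many ROIs, sizeable amplitudes), and because one SVD
  component mixes ROIs with spatial loadings of either sign, transients
  appear in its temporal signal as both up- and down-swings — beyond what
  any purely asymmetric temporal weighting can reject.
* **The smoothness penalty** (second differences, `lambda = 1e4`) has an
  effective bandwidth of roughly `lambda^(1/4) ≈ 10` frames: transients of
  a few frames are crushed, drift components with periods of hundreds of
  frames pass nearly unattenuated.

The local correction spatially averages the residual per window, clips it
at its temporal opening plus half a noise SD (same upswing logic), and
smooths with a running median — so windows dominated by a single active
soma do not leak transients into F0.

## Selective averaging and transient detection

In each 16 × 16 window (stride 8), per-pixel dF/F0 traces are projected
onto the first 5 principal components, k-means-clustered, and the cluster
containing the window's center pixel is averaged; member pixels accumulate
that average with weight 1/(1e-6 + distance to the cluster centroid in PC
space). Overlapping windows give most pixels several estimates, aggregated
by weight-normalized averaging; pixels never co-clustered with a center
keep their own trace at unit weight so coverage is total. Clustering uses
a deterministic quantile initialization (no RNG), so results are exactly
reproducible.

Two deliberate departures from the simplest reading:

* **Traces are whitened before the projection** (divided by their robust
  noise SD). Dim background pixels carry several-fold larger dF/F0 noise
  than bright ROI pixels; unwhitened PCA lets that noise dominate the
  components and thin processes merge into background clusters, diluting
  their signal below the detection threshold at low SNR.
* **Five clusters per window** (not three): a window can plausibly contain
  background plus several distinct compartments, and the cluster count
  must give each a chance to separate.

Detection thresholds the temporally smoothed (Gaussian, 3-frame width),
running-median-detrended trace at `threshold_sd = 2` times the robust
noise SD (`mad(diff)/sqrt(2)`, insensitive to sparse transients and slow
trends). Detrending (31-frame window) exists because residual baseline
errors of ~1% dF/F0 are slow but larger than the post-averaging noise
floor; without it the 2-SD rule fires on baseline wiggle, not noise. The
Monte-Carlo null used in the calibration tests applies exactly the same
rule to white noise.

For event statistics, each detected run is refined to half-prominence
extent (FWHM) with greedy multi-peak splitting: the raw 2-SD mask spans a
transient's full tail and merges closely spaced events, which would
overstate active time severalfold and undercount frequency at
physiological rates.

## Segmentation and compartment classification

Per frame, foreground = pixel > (sliding 11 × 11 local mean +
`contrast_floor`), additionally requiring the temporal-mean image to
exceed a global Otsu cut — bright structures adjacent to dark regions
(endfeet against the vessel lumen) otherwise pass their blur halo through
the purely local test. Pixels foreground in strictly more than 50% of
frames are labeled into 8-connected components and filtered by a 6 px
minimum area. Classification is a shape heuristic (no published criteria
exist): endfoot if within 3 px of the vessel mask; soma if compact
(solidity ≥ 0.85, area ≥ 30 px, eccentricity ≤ 0.92); process otherwise.
Marker-negative cells are never inferred — they are accepted only as
externally supplied masks.

## Event statistics and physiology

Active time is 100 × active frames / total frames; frequency counts events
whose start lies in the epoch per minute; epochs default to the stimulus
window, an equal-length pre-onset baseline, and an equal-length post
window. A ROI is called a responder when it has at least one stimulus
event, stimulus frequency at least 1.2 × baseline, mean duration not
shrunk below 0.8 × baseline, and a one-sided exact conditional binomial
test on the event counts significant at 0.05 — the count test is what
holds the false-positive rate on null data below 10%; a pure relative-
increase rule does not. Published work does not define its responder
criterion, so this rule is a package convention and its outputs should not
be read as reproducing any published responder fraction.

Peristimulus averages resample each trace onto a common axis around its
alignment time (onset and offset both supported, matching the two response
peaks such protocols produce) and report mean ± SEM (n − 1 denominator).

On the physiology side: CPP = MAP − ICP (an optional CVP trace replaces
ICP by max(ICP, CVP)); MAP is a 2 s sliding mean of the arterial wave; HR
comes from systolic peaks of the low-passed (~20 ms) pulse with a
refractory period of 0.25 × the median interbeat interval, bootstrapped
from a high-threshold first pass. Rectified nerve activity is smoothed by
a first-order exponential filter (time constant 100 ms) and normalized
between the post-blockade floor (0%) and resting activity (100%). The
response-onset rule — first crossing of baseline mean + max(2 SD,
`min_delta`) sustained for `m` samples — defaults to the pure SD rule for
`response_delay()`; `response_summary()` sets the sustained run to the
2 s MAP window and `min_delta = 1` mmHg, because baseline SD of a heavily
smoothed trace is far below its autocorrelated ripple and the raw rule
false-triggers. Both epoch-mean and peak changes are reported; the peak
change is the better estimator of a planted pressor amplitude when the
response onset is delayed within the stimulus epoch.

## Problem sizes and reproducibility

The test suite and the acceptance script exercise the chain on
128 × 128 × 300-frame movies (1 Hz) for baseline, motion, detection and
segmentation; 64 × 64 movies for the statistics-recovery checks;
hour-long traces for event rates; and 50/20-seed Monte-Carlo repeats for
the physiological delay and pressor recovery — sizes chosen so the whole
chain runs on a laptop-class single core in minutes. All randomness flows
from explicit integer seeds; `run_pipeline()` fans a single master seed
out to per-stage seeds by stable hashing, and two runs with the same
configuration produce bit-identical statistics tables.

## Known limitations

* The CLG solver estimates flow poorly in large textureless regions
  (information arrives only by smoothness diffusion); the synthetic
  background carries weak texture, as does real neuropil, but flow
  accuracy in dark corners is limited.
* Events closer together than the temporal smoothing scale (~3–4 s at
  1 Hz) are unresolvable and are counted once; at high event rates this
  compresses frequency ratios between epochs.
* The compartment classifier is a shape heuristic; its thresholds were
  chosen against the generator's geometry and will need adjustment for
  other markers or magnifications.
* Baseline estimation assumes transients are sparse in time per pixel;
  a pixel active most of the recording will have its baseline biased
  upward by any method of this family.
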