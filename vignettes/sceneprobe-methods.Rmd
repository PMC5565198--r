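---
title: "sceneprobe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sceneprobe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When an observer reconstructs a locally corrupted patch of a natural scene
(here: judging whether an oriented probe is aligned with or orthogonal to
the local scene structure), two very different descriptions of the scene
could control performance. A *bottom-up* description scores each location
by its physical edge energy; a *top-down* description scores it by how
consistently human annotators mark it as an object boundary. The package
implements the full computational apparatus needed to study which
description controls local reconstruction: map construction, categorized
probe placement, probe synthesis with orientation noise, global scene
manipulations, model observers, reverse-correlation psychometrics,
double-pass internal-noise estimation, and a lateralized ERP analysis —
all drivable end-to-end by synthetic data, so every stage can be validated
against known ground truth.

# Scene maps and insertion points

**Geometry.** Scenes are calibrated so the smaller image side spans 13
degrees of visual angle; luminances live in 4–60 cd/m² around a 32 cd/m²
background. Sizes in the code are given in degrees and converted through
`scene_geometry()`.

**Bottom-up map.** A 3×3 Sobel gradient pair, squared gradient magnitude
pooled by its root mean square over a disc of 0.9° diameter (the operator's
active area), then divided by its maximum. The two-stage construction
(canonical Sobel + RMS pooling) is one consistent realization of an
edge-energy operator with that active area. Convolutions are done by exact
shift-and-add rather than FFT: the final max-normalization would amplify
FFT round-off into visible structure on near-constant scenes.

**Top-down map.** Each annotator's boundary drawing is thickened by
morphological dilation with a 0.5°-diameter disc (for binary inputs this is
equivalent to blur-and-threshold), and the map value is the proportion of
annotators covering the pixel — exact multiples of 1/K.

**Elongation.** Described as a half-focal separation bounded in [0, 1],
which only holds after normalizing by the semi-major axis; we therefore use
the eccentricity `sqrt(1 - b²/a²)` of the second-moment ellipse. Windowed
elongation over 1.6° squares is computed from box-filtered moment sums.

**Insertion-point selection.** Eligible pixels are nonzero on the top-down
map, elongation ≥ 0.9, bottom-up ≥ 0.1, and ≥ 2° from the image edge.
Top-down "rich" means full consensus (value exactly 1). The four slots are
filled in the order rich/poor, poor/poor, poor/rich, rich/rich
(top-down/bottom-up): minimum bottom-up value v among TD-rich; TD-poor
closest to v; maximum bottom-up value V among TD-poor; TD-rich closest to
V. The 1.6° pairwise-spacing constraint interacts with the per-slot
optima; we resolve it by depth-first search in slot order with candidates
sorted by each slot's criterion (ties broken row-major), so the first
complete assignment preserves per-slot optimality as the primary
criterion and the result is deterministic. A fixed work budget (200,000
candidate visits) bounds pathological backtracking on near-infeasible
scenes; exhausting it excludes the scene, exactly as a genuinely
infeasible scene would be excluded.

# Probe and orientation noise

The probe sums 16 cosine-carrier Gabor wavelets ("pseudo-Gabors" realized
as standard Gabors sharing one compound envelope: a flat disc of 1.6°
diameter with a Gaussian skirt of 0.1° SD), one per orientation channel at
spacing π/16, each with a random phase drawn from `phase_seed`. Channel 5
is the congruent channel; channel 13 is orthogonal to it. Contrasts are
fractions of the background luminance (L = 32·(1 + c)). The target vector
puts intensity ρ on channel 5 (congruent trials) or 13 (incongruent
trials); noise adds i.i.d. Gaussian contrast (mean 3%, SD 0.7%, clipped at
±4 SD) to every channel. Noise is applied to carrier amplitude before
envelope multiplication. Grafting blends by the envelope:
`env·32·(1+patch) + (1-env)·scene`, clipped to the display range (clipped
pixel counts are kept as an attribute).

# Scene manipulations — numerical choices

* **Lowpass**: power × 0.3 (amplitude × √0.3) above 0.5 cycles/degree.
  **Highpass**: power attenuation ramps log-linearly in frequency from 10%
  at 7 cpd to 100% at 0.5 cpd (the endpoints are stated; the log-linear
  ramp is our choice), untouched above 7 cpd. The DC component is kept in
  both modes so mean luminance is preserved.
* **Preserved probe region**: a 3.1°-diameter disc around the probe is
  blended back with a raised-cosine taper of 0.25° (taper widths are
  unspecified upstream; raised-cosine over 0.25° is used for every taper
  in the package — preserved discs and gap edges).
* **Warping**: 40 lattice points spanning the scene, minus those within
  3.2° of the probe; each center is randomly a swirl (rotation by
  `swirl_peak`·G(r), default 0.5 rad) or a lens (radial stretch
  `exp(ln(lens_exponent)·G(r))`, default 1.5), with Gaussian window G of
  SD 0.6° (weak) or 1.2° (strong). Magnitudes are configurable; the
  mechanism and extents are fixed. Displacements are additionally
  suppressed within 3.2° of the probe so that region is bit-stable.
* **Cut-out / lines**: boundaries are the thickened top-down map
  thresholded at zero. Lines paints them at 60 cd/m²; cut-out fills each
  connected region with a value from a seeded permutation of a uniform
  grid spanning 4–60 cd/m² (no two regions share a value), boundary
  pixels taking the nearest region's value.
* **Scrambling**: a seeded white-noise image supplies the replacement
  phase (power-only) or amplitude (phase-only) spectrum; Hermitian
  symmetry keeps the output real, and the scene's DC is kept. Phase-only
  amplitudes are rescaled to the scene's contrast energy. Phase
  preservation is exact for the construction; clipping the whitened image
  to the display range (as any displayed stimulus is) perturbs it
  slightly, so `clip = FALSE` exposes the pure construction.
* **Gap stimuli**: a background-luminance annulus from the probe edge to
  `multiple`×probe-diameter, raised-cosine tapered into the scene. A
  multiple of 1 is the identity.

# Model observers

**Gain-control (retuning) model.** A stimulus patch is processed by
quadrature pairs of Gabor filters along the congruent and incongruent
axes; the decision variable is r₁/(r₁+r₀) and the criterion is the mean
decision variable over 8,000 calibration trials (half congruent). The
filter "broadness multiples" (Poor: f₁ = 4, f₀ = 21; Rich: f₁ = 1,
f₀ = 3) are realized by shrinking the signal-matched Gaussian envelope
isotropically (σ₀/f on both axes). We tried scaling only the bar-axis
extent first, but orientation selectivity then survives through the
frequency-tuning route and the f₀ = 21 filter stays visibly tuned,
erasing the Poor/Rich kernel difference; isotropic shrinking broadens
both routes together, so a large multiple is genuinely untuned and the
narrative Poor→Rich sharpening emerges (a spatial-frequency-mismatch
reading remains available via `broadness_mode = "frequency"`). Model
simulations use ρ = 0.06 — half the experimental ~12% contrast — as the
"lower SNR" regime; internal noise, when used, is added to the decision
variable (late noise). The batch simulator works in the carrier basis
(the rendered patch is linear in `s_k cos φ_k` and `s_k sin φ_k`, so
Frobenius products reduce to 32-vector algebra); this is exactly the
image-domain computation, factored.

**Template observer.** A channel-domain surrogate for large-N
psychometrics: decision variable `template·s + σ_int·z` against a fixed
criterion. Its d′ has a closed form, which the test suite checks against
simulation.

# Psychometrics

* d′ and criterion use hit/false-alarm rates clipped to
  [1/(2N), 1−1/(2N)] (standard correction; the correction rule is not
  specified upstream). Log-ratios use the natural log; estimates with
  d′ ≤ 0 are excluded (NA).
* The reverse-correlation tuning function is
  `p = <n[1,1]> + <n[0,0]> − <n[1,0]> − <n[0,1]>`; symmetrization averages
  entries mirrored about channels 5 and 13 (one permutation handles both
  centers since they are 8 channels apart) and is idempotent. The
  retuning index is `(p[13] − p[5])² / Σp²`.
* **Double-pass internal noise.** The forward model: a unit-SD external
  decision variable shared between passes (mixture N(0,1) / N(μ,1)),
  independent internal noise of SD σ_int per pass, fixed criterion c. The
  inversion solves (μ, c) exactly from percent correct and the observed
  yes-rate (H = pc + p_yes − 1/2, F = p_yes − pc + 1/2), then searches
  σ_int to match percent agreement, computed by deterministic numerical
  integration over the external variable (the same two-pass model one
  would Monte-Carlo; integration removes grid-node sampling error). With
  only (pc, pa) the three-parameter model is unidentifiable, which is why
  the yes-rate enters; without it an unbiased criterion c = μ/2 is
  assumed. pa = 1 returns σ_int = 0 exactly; non-attainable (pc, pa)
  pairs are flagged with the nearest attainable agreement.
* Group-level effects use two-tailed Wilcoxon signed-rank tests (exact
  for n ≤ 25) with pseudo-median confidence intervals.

# Lateralized ERP analysis

Epochs are 1 s at 256 Hz starting 200 ms before stimulus onset. The
pre-stimulus baseline is subtracted first, then causal filtering is
applied (baseline-first keeps a constant epoch exactly zero and avoids
baselining filter transients). Causal filtering uses an order-2
Butterworth highpass and an order-6 Butterworth lowpass applied twice,
forward only. An order-4 bandpass leaves a 50 Hz tone at ~49% RMS under
the 0.5/40 Hz regime; the steeper cascade brings it to ~6% while passing
10 Hz at ~98%, which is what a band edge at 40 Hz should mean in
practice. Trials can be linearly rescaled by the probe's distance from
the vertical meridian (weighting strongly lateralized probes).

Per homologue pair, trial-averaged traces per probe side are normalized
to unit RMS per electrode (making the contrast invariant to
per-electrode gain), assigned to contralateral/ipsilateral roles, and
differenced. The modulation map stores (rich − poor) of the
contra-minus-ipsi difference per subject — the sign convention is chosen
so the expected top-down effect is positive — and the across-subject Z
is mean/SE. With S subjects this Z is a t statistic with S−1 degrees of
freedom: with 7 subjects about 9% of null bins exceed |Z| = 2, so null
calibration checks are phrased against that t behaviour rather than a
Gaussian 95% band. Window pooling sums per-subject modulation over an
electrode-group × time rectangle (early occipital window: 0–100 ms).

# Synthetic data: what it emulates, and what it does not

**Scenes.** Seeded jittered-lattice Voronoi tessellations with 1/f
per-region texture (α = 1). Each boundary independently draws a top-down
type (consensus: marked by all K = 5 annotators; weak: marked with
p = 0.6) and a bottom-up type (tapered luminance step of 18 or 5 cd/m²
across the boundary), making the two dimensions orthogonal *by
construction*; annotators add ±1 px positional jitter. The default
configuration yields a full 2×2 insertion quadruple for ≥ 90% of scenes.
These scenes exercise the algorithms' input contracts (consensus
structure, controllable edge energy, elongated boundaries); they do not
emulate natural-image statistics, occlusion, or annotator biases beyond
marking probability and jitter — so passing tests validate the pipeline's
computations, not claims about natural scenes.

**Cohorts.** Template observers with a sharp Rich-state template
(σ_w = 0.8 channels) at top-down-rich insertions and a broad Poor-state
template (σ_w = 2.5) elsewhere, internal noise set per state to land at
target sensitivities d′ = 1.6 (Rich) and 0.9 (Poor) — the study targeted
threshold performance per observer, and the implied log-ratio
ln(1.6/0.9) ≈ 0.58 sits inside the reported effect range — with 10%
lognormal between-subject jitter. The headline pattern this produces
(top-down log-ratio > 0, bottom-up ≈ 0) is generator-set ground truth
for validating the analysis, not a reproduction of empirical values.
Double-pass blocks follow the 50 + 50 structure (second half a seeded
permutation of the first). Because the template surrogate is a
near-ideal observer of the 16 noise entries, threshold performance
implies an internal/external noise ratio far above the human range;
double-pass analysis of these cohorts is therefore structural, and the
internal-noise estimator is validated against its own forward model
instead.

**Kernel-recovery conditions.** Classical kernel recovery needs adequate
kernel SNR: at 20,000 trials a threshold-level observer (d′ ≈ 1.3) yields
recovered-kernel correlations near 0.93 regardless of implementation, so
the recovery check uses a smooth template (σ_w = 1.5) and a d′ ≈ 2
observer, for which the correlation exceeds 0.95 across seeds.

**ERP cohorts.** Per trial: a shared evoked response (P1-like +5 µV at
100 ms, N1-like −7 µV at 170 ms; posterior-weighted), a contralateral
posterior probe component (130 ms, scaled by meridian distance), an
optional top-down-rich-specific occipital component at 60 ms, and 1/f
noise of 15 µV RMS — literature-typical scales. The modulation amplitude
(2 µV) was set by the prescribed power-calibration run so the default
cohort (7 subjects, 500 trials/condition) detects the pooled occipital
effect (Z > 2) with ≥ 90% probability; the bottom-up axis carries no
injected effect and serves as the built-in null.

# Problem sizes

The test suite and acceptance script use: 100 generated scenes for the
orthogonality/yield checks and 40 for the acceptance run; cohorts of 8
observers × 4,000 trials (2,000 per observer minimum guaranteed); 100
null-cohort replicates; 8,000 calibration + 20,000 test trials per
observer state for the retuning model; 10,000 trial pairs per
internal-noise recovery point; one default-size ERP cohort plus 6
reduced null cohorts. These sizes put Monte-Carlo error comfortably
inside each check's tolerance.

# Known limitations

* The bottom-up operator is one reading of a "Sobel-like filter with a
  0.9° active area"; other kernel/pooling splits would change map values
  (not the selection logic).
* Zooming (thin-plate-spline) stimuli, cue rendering, artifact
  rejection, raw EEG formats, and third-party segmentation algorithms
  are out of scope; `median_split_labels()` supports external model maps
  classified by median split.
* The insertion-point search is exact on the scales tested; on scenes
  with vastly larger eligible sets the work budget may exclude a scene
  that exhaustive search would keep.
* The synthetic generators are validation instruments. Effect sizes,
  internal-noise magnitudes and ERP amplitudes are configurable inputs,
  and no quantitative human result should be read off them.
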