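---
title: "Methods: from synthetic soundscapes to occurrence statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synthetic soundscapes to occurrence statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pamscape` re-creates, at desk scale and on fully synthetic data, the
analysis chain of a semi-automated passive-acoustic survey of a rare vocal
primate: scheduled recorders produce soundscapes; a convolutional detector
proposes call windows; a reviewer verifies every proposal; verified
detections are coded into 7-day detection histories; and the resulting
presence/absence drives landscape occurrence statistics. This vignette
documents the models, the generator's stated world, the numerical choices,
and what a passing test suite does and does not establish.

## 1. The synthetic soundscape

**Call model.** The target call is rendered as a linear FM arc of the
fundamental (default 700 → 3500 Hz over 0.5–1 s) with 2–4 harmonics at
1/k amplitude, 8–12 Hz sinusoidal amplitude tremolo, and a raised-cosine
onset/offset. These values follow published descriptions of the
spider-monkey whinny and keep all partials far under Nyquist at the 48 kHz
default rate (the source material's "48 000 kHz" is read as a typo for
48 kHz). Harmonics that would cross Nyquist at low test rates are silently
dropped. Confounders are the same machinery with the sweep direction
reversed or the band shifted, so negatives are acoustically adjacent to
positives rather than trivially distinguishable.

**Background.** Pink noise (1/f-shaped white noise), narrowband insect
tones with slow amplitude drift, and sparse decaying broadband transients.
The mixture is normalized so its RMS equals the root-sum-square of the
enabled component levels. Each synthetic site gets its own insect band so
that site-independent data splits are meaningful: a detector could, in
principle, key on the site signature, which is exactly what the splitting
strategy must defend against.

**Mixing and SNR.** A call is scaled so that its band-limited RMS (default
band 0.5–4 kHz, clipped to Nyquist) sits `snr_db` decibels above the
band-limited RMS of the local background segment. Mixing keeps ≥ 3 dBFS of
headroom in the rendered calls, and any mix that would exceed 0 dBFS raises
an error instead of saturating — silent clipping would corrupt the SNR
bookkeeping that the review simulation depends on.

**Schedule.** The default daily schedule is 05.00–09.30, 14.00–18.30 and
21.00–03.00 (the night window is written 21–27 h), i.e. 15 h/day; a "day"
is the scheduled block attributed to its starting calendar date, since the
night window crosses midnight and the attribution is otherwise ambiguous.
Tests render this schedule at very low sample rates (e.g. 8 Hz), which
exercises the duration arithmetic without creating gigabytes of audio.

**What the generator does not emulate:** realistic call-type diversity,
reverberation and distance-dependent spectral colouring, overlapping
vocalisations, rain and wind nonstationarity, and recorder transfer
functions. A green detector test therefore establishes that the
architecture can learn a band-limited FM cue over structured noise under a
site-independent split — not field-grade performance.

## 2. Frontend and detector

Waveforms become log-Mel spectrograms: Hann-windowed STFT (25 ms frames,
10 ms hop), triangular Mel filterbank (64 bands, 100 Hz–12 kHz, capped at
Nyquist), and `log(power + 1e-10)`; the floor maps digital silence to a
finite constant instead of −∞. Long recordings are cut into 3 s windows
with 1.5 s hop (one window always covers a ≤ 2 s call); a final partial
window is zero-padded and flagged.

The detector is a compact CNN: 3×3 convolutions (default 16/32/64/64
channels), ReLU, a squeeze-and-excitation block after every convolutional
layer (global average squeeze per channel, bottleneck of width
channels/4, sigmoid gate multiplied back onto the channels), 2×2
max-pooling, then multi-head attention pooling over the frame axis: each
head learns a scoring vector, scores are softmax-normalized over frames,
and the per-head weighted sums are concatenated into one fixed vector that
feeds a sigmoid classifier. Training is Adam (1e-3) on binary
cross-entropy, batch 16, up to 30 epochs, dropout 0.2 on the pooled
vector, all randomness from one run seed; the checkpoint with the best
validation UAR is kept, ties resolved in favour of the earlier epoch.
The original architecture's exact hyperparameters are not public, so these
desk-scale defaults preserve the described mechanisms at CPU-trainable
size; tests use even smaller stacks (e.g. 8/16 channels, 32 Mel bands at a
4 kHz clip rate).

Implementation note: convolution is im2col + BLAS matrix multiplication
with a hand-written backward pass. The test suite checks every parameter
block against central finite differences, and checks two structural
identities: saturating the SE gate reproduces the SE-free network, and
forcing uniform attention reproduces mean pooling.

**Metrics.** With a semi-automated design the operating point favours
recall over precision, so metrics are reported class-unweighted: UAR is the
mean of positive and negative recall, precision is the mean of the
per-class precisions, and the headline F1 is the harmonic mean of those two
averages (this composition reproduces the published 62 % from 75 % recall
and 53 % precision; per-class F1 is also returned). Detection emission is
monotone in the threshold by construction.

## 3. Review, histories, occupancy coding

Every emitted detection must carry exactly one verdict before ecological
coding; in unattended runs the verdict is simulated from the event
manifest (true positive iff the window overlaps a whinny event in the same
file). True positives are tallied per site and day; a day codes 1 iff its
tally is positive; sites with fewer than 7 recorded days are excluded
rather than imputed, mirroring the recorder-malfunction rule; site
occurrence is the OR of the 7 days; naive occupancy is the occupied
fraction.

## 4. Landscape generator

Sites are rejection-sampled uniformly with a 500 m minimum spacing
(matching a home-range radius) and stratified over six land-use classes by
largest-remainder rounding. The forest raster thresholds a smooth random
surface plus per-site Gaussian "pulls" (+ for forest-stratum sites, − for
open strata, bandwidth 500 m), which guarantees a wide forest-cover
gradient across site buffers; a 60 m disc of each site's own class is
painted so all classes exist on the map without making small buffers
single-valued. Primary roads are region-crossing jittered polylines,
secondary roads shorter random segments, buildings rectangle clusters near
primary roads. The default raster cell is 25 m rather than the source
map's 5 m — a 25× cost saving with quantization error far below the
effects of interest (tests on half-plane rasters bound it at ~1 cell); the
cell size is configurable down to 5 m.

Occurrence truth: a logistic model on forest cover centred at a threshold
(default 80 % cover, where the probability crosses 1/2), optionally a hard
floor (no occupancy below threshold, for tipping-point recovery), a hard
exclusion wherever primary-road density in the 1 km buffer is positive
(this deliberately manufactures complete separation), an optional
zero-mean Gaussian field with exponential covariance added on the logit
scale (the real residual covariance is uncharacterized; exponential-range
is the simplest mechanism that produces the reported residual
autocorrelation), and i.i.d. daily detection probability p = 0.68 at
occupied sites with structural zeros elsewhere.

## 5. Buffer covariates

All geometry is planar Euclidean in a metric projection. Forest cover uses
the cell-centre rule (% of in-disc cell centres whose code is a forest
code). Road length is exact segment–disc clipping via the quadratic
intersection. Building area is the exact disc–polygon intersection by an
arc decomposition of Green's theorem: each polygon edge is split at its
circle crossings; interior sub-segments contribute triangle terms
cross(P,Q)/2 and exterior sub-segments circular-sector terms r²θ/2. The
suite validates this against closed forms (chords, half-discs, containment)
and a 10⁶-point Monte-Carlo oracle at 1 % tolerance. Self-intersecting
polygons are rejected. Buffers may overlap between nearby sites; each site
is computed independently.

## 6. Occurrence statistics

**Logistic fits.** IRLS to a 1e-8 score tolerance. Separation is declared
when any coefficient exceeds 15 on the standardized scale or the fit fails
to converge in 100 iterations — the symptom the source analysis reports
(exploding standard errors) made explicit as a programmatic detector.
**Firth fits** maximize ℓ(β) + ½log|I(β)| by modified scoring
(hat-value-adjusted score), with two numerical safeguards: the Fisher step
is capped at 2 per coordinate (vanishing weights otherwise produce
astronomically long steps on separated data) and step-halving enforces
monotone penalized likelihood. On any 2×2 single-binary-covariate design
this reproduces the add-½-to-each-cell estimator exactly, which the suite
sweeps over 50 random tables including zero cells.

**Scale of effect** fits one single-covariate logistic model per radius
(degree-2 orthogonal polynomial for forest cover — the reported
relationship is nonlinear — linear otherwise), records McFadden's
pseudo-R² and selects the argmax, ties to the smallest radius. The choice
of pseudo-R² is genuinely open (the source never names its R²), so it is
isolated behind `pseudo_r2()` with Tjur's D as a one-line alternative;
absolute R² values are consequently never asserted, only recovery of the
true radius.

**Contrasts** between land-use levels are Wald contrasts on the dummy
coding with Bonferroni adjustment min(1, m·p). **Prediction intervals**
are delta-method on the logit scale, transformed, so they always lie in
(0,1); the suite checks the SE against a 1000-draw parametric bootstrap at
10 %. **Tipping points** are empirical boundaries (minimum covariate among
presences for presence-above), not fitted changepoints — that is how such
thresholds are stated in the field — reported together with the count of
absences beyond the boundary.

**Spatial diagnostics.** Moran's I uses the textbook cross-product form
with inverse-distance weights (global, not thresholded, matching a
"distance-based weight matrix"; row standardization optional),
expectation −1/(n−1), normality-assumption variance, and two-sided normal
p. Response residuals (observed − fitted probability) are the diagnostic
residuals. The autocovariate is the inverse-distance weighted average of
neighbouring responses within a per-site radius
max(210 m, nearest-neighbour distance), so no site is neighbourless. One
practical caveat discovered in testing and worth stating: with ≥ 400–500 m
site spacing, the 210 m floor reduces the neighbourhood to the single
nearest site, and such a one-neighbour autocovariate often cannot absorb a
field whose range is kilometres. The absorption property is therefore
demonstrated (and should be used in practice) with the neighbourhood
radius matched to the expected autocorrelation range — the operation's
default stays at 210 m because that is the documented method contract.

**Variance partitioning** fits all 2^k predictor subsets (k ≤ 6 guard) and
computes each predictor's independent contribution as its Shapley value
over goodness-of-fit gains, which is algebraically the
hierarchical-partitioning average-over-hierarchies; conservation
Σ independent = full-model gof is asserted to 1e-10. If any subset
separates, the entire hierarchy is refit on the bias-reduced path for
comparability. Aliased (exactly collinear) predictor columns are dropped
per subset, so duplicated predictors split their contribution symmetrically
instead of crashing the fit. Negative independent or joint contributions
can occur (a known property of the method) and are reported as-is.

**Null occupancy model.** The likelihood ψ p^{d_i}(1−p)^{J−d_i} for
detected sites and ψ(1−p)^J + (1−ψ) for undetected ones is maximized on
the logit scale with BFGS; standard errors come from the numerical Hessian
by the delta method. ψ̂ ≥ naive occupancy always; the suite checks the
optimum against a 200×200 grid at 1e-4. Covariate occupancy models are out
of scope by design: on this data they fail by complete separation, which
is the source analysis's own reported reason for stopping at the null
model. All-zero history matrices make ψ unidentifiable and raise an error.

## 7. Reproducibility and configuration

Every generator and the trainer take explicit seeds; per-clip and
per-replicate seeds are derived from a single run seed. The pipeline
persists its effective configuration as JSON next to the outputs; configs
are JSON (the environment carries no YAML parser) with a flat
`key: value` text form accepted for scalar overrides. Artifact formats are
deliberately plain: WAV (PCM16 mono), CSV with JSON sidecars, GeoJSON for
vector layers, and a text raster with a JSON georeferencing header.

## 8. Known limitations

- The detector is desk-scale: no augmentation, no mixup, no PCEN, and it
  has never seen real rainforest audio; its acceptance bar is solvability
  of a stated synthetic world, not field performance.
- The whinny model is a caricature (one FM arc, fixed tremolo family);
  fine acoustic realism was explicitly traded away for controllability.
- Geometry is planar; no geodesy, no DEM-corrected distances, no raster
  reprojection.
- Moran inference uses the normal approximation, not permutation, though
  the permutation mean is property-tested.
- The occupancy model is single-season, constant-ψ, constant-p only.
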