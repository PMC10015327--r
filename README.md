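# pamscape

Passive acoustic monitoring (PAM) is one of the few survey methods that
scales to rare, elusive, but vocally active species: unattended recorders
collect thousands of hours of audio, an automated detector proposes call
events, a human verifies them, and the verified detections become
presence/absence data for landscape-scale occurrence modelling. `pamscape`
implements that entire workflow for a spider-monkey-like target call (a
frequency-modulated "whinny") at desk scale, with every stage driven by
synthetic data with known ground truth, so the full chain — soundscape →
detector → detection histories → occurrence statistics — is testable on one
CPU with no field data.

The package is aimed at quantitative ecologists and bioacoustics methods
developers who want a self-contained, fully seeded reference implementation
of the statistical machinery around semi-automated acoustic surveys.

## What is implemented

**Audio and detection**

- Synthetic soundscapes: FM harmonic whinnies (fundamental ~700→3500 Hz,
  2–4 harmonics, 8–12 Hz tremolo), bird-like confounder sweeps, pink-noise +
  insect + transient backgrounds, scheduled recordings
  (05.00–09.30, 14.00–18.30, 21.00–03.00 = 15 h/day) with calls mixed at a
  requested SNR, and labelled clip sets with round-robin site assignment.
  Plain 16-bit PCM WAV I/O is built in.
- Log-Mel spectrogram frontend and overlapping analysis windows.
- A compact convolutional detector with a **squeeze-and-excitation** (SE)
  recalibration after each convolutional layer and **multi-head attention
  pooling** of the frame sequence into a fixed vector, trained with Adam on
  binary cross-entropy. Forward and backward passes are implemented in the
  package (im2col convolutions on BLAS) and verified against numerical
  gradients. Site-independent data splits, thresholded inference, and
  unweighted-average metrics (UAR = mean of per-class recalls; F1 = harmonic
  mean of unweighted-average precision and recall) follow the semi-automated
  survey design, as does CSV + clipped-WAV export of all positives.

**Ecology and statistics**

- Review bookkeeping: every detection gets a verdict (simulated from the
  event manifest in unattended runs), true positives are tallied per site
  and day, coded into 7-day detection histories
  (day = 1 iff ≥ 1 verified call; site occurrence = OR of days), and naive
  occupancy.
- Synthetic landscapes: stratified site networks with ≥ 500 m spacing,
  forest/land-use raster, road polylines, building polygons, and occurrence
  truth with a forest-cover threshold (default 80 %), hard exclusion near
  primary roads, an exponential-covariance Gaussian field on the logit, and
  daily detection probability p (default 0.68) at occupied sites.
- Buffer covariates: % forest cover (cell-centre rule), road density (exact
  segment–disc clipping, km) and building area (exact polygon–disc
  intersection via an arc decomposition, km²) at radius grids of
  100–5000 m (forest) and 100–1000 m (roads/buildings).
- Scale of effect: per-radius logistic fits (quadratic cover term),
  McFadden pseudo-R², argmax radius.
- Occurrence GLMs: hand-rolled IRLS logistic regression with explicit
  complete-separation detection, **Firth bias-reduced** fits (Jeffreys
  penalty; exactly the add-½ estimator on 2×2 designs), Bonferroni-corrected
  pairwise land-use contrasts, delta-method prediction intervals, and
  empirical tipping-point boundaries.
- Spatial statistics: Moran's I (brute-force-verified, with
  normal-approximation inference), inverse-distance weights, empirical
  variogram, and the distance-weighted **autocovariate** with a 210 m
  minimum neighbour distance.
- Hierarchical (all-subsets, Shapley) variance partitioning whose
  independent contributions sum exactly to the full-model fit, and the
  constant-ψ constant-p **null occupancy model** MLE separating site
  occupancy from daily detection probability.

## Worked example

The statistics-only pipeline on a 120-site synthetic landscape:

```r
library(pamscape)
cfg <- default_config(seed = 1, out_dir = "runs/demo",
                      n_sites = 120, region = c(14000, 14000))
cfg$landscape$cell <- 50
rep <- run_pipeline(cfg)
print(rep)
print(rep$scale)
```

prints (elapsed: a few seconds):

```
pamscape pipeline report; stages run: synth-landscape, metrics, scale, fit, spatial, partition, occupancy
scale of effect: 500 m
Moran's I on residuals: 0.0063 (p = 0.165)
null occupancy: psi 0.500, p 0.664 (naive 0.500)
Scale-of-effect profile (mcfadden pseudo-R2, degree 2)
 radius     r2       method selected
    100 0.4387           ML    FALSE
    200 0.4426 bias-reduced    FALSE
    500 0.4539           ML     TRUE
   1000 0.3288           ML    FALSE
selected radius: 500 m
```

Reading the output: forest cover predicts occurrence most strongly at the
500 m radius on this draw; the occurrence model's residuals show no
remaining spatial autocorrelation once the autocovariate is included
(Moran p = 0.165); and the null occupancy model recovers a daily detection
probability of 0.664 against the generating value 0.68. The report also
carries the variance partition (forest cover dominating, 79.5 % of the
summed independent contributions on this draw) and the empirical
tipping-point boundary (77.5 % cover against the generating 80 % threshold).

Training the detector on a separable synthetic clip set (about 12 s of CPU):

```r
clips <- make_clipset(n_pos = 60, n_neg = 60, hard_negative_fraction = 0,
                      n_sites = 6, clip_length = 1.2, rate = 4000,
                      snr_range = c(20, 30), seed = 11)
ml  <- logmel_config(n_mels = 32, fmax = 1999)
sp  <- split_site_independent(clips, seed = 1)
mdl <- build_model(detector_config(conv_channels = c(8, 16), epochs = 8,
                                   seed = 2), n_mels = 32)
mdl <- train_detector(mdl, sp$train, sp$validation, ml)
tail(mdl$log, 3)
```

```
  epoch train_loss val_uar
6     6  0.3026533       1
7     7  0.2232031       1
8     8  0.1600967       1
```

Validation UAR reaches 1.0 on the held-out sites; the site-independent split
guarantees the model is not keying on per-site background characteristics.

## Command line

```sh
Rscript inst/cli/pamscape pipeline --seed 1 --out runs/demo
```

See `vignettes/methods.Rmd` for the model descriptions, the generator's
stated world, numerical choices, and known limitations.
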