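# orientfree

Orientation-invariant preprocessing for accelerometer-based human
activity recognition (HAR).

## The problem

HAR systems classify activities (walking, jogging, sitting, ...) from
body-worn tri-axial accelerometers.  The signal lives in the *sensor's*
axes: wear the device in a different orientation and the same movement
produces a different signal, so a classifier trained on well-oriented
data degrades badly in the wild.  `orientfree` is for signal-processing
and digital-health researchers who need HAR pipelines that survive
sensor mis-orientation.

## The method

At every sample the package estimates a consistent, body-referenced
orthonormal triad and re-expresses the acceleration in it:

1. gravity `g(t)` = 5 s sliding mean of the acceleration (movement
   averages away, the gravity reaction remains);
2. horizontal acceleration `h = a − (a·ĝ)ĝ`; forward direction
   `f` = 5 s sliding mean of `h`;
3. third axis `û_cross = û_fwd × û_grav` (right-handed triad);
4. transform: `a_new = M a`, where the rows of `M` are
   `(û_fwd, û_grav, û_cross)` — orthonormal, norm-preserving, inverted
   by its transpose.

Every step is exactly equivariant under a fixed rotation `R` of the
sensor, so the transformed signal is *identical* for any mounting —
the orientation nuisance cancels.  Static postures carry no forward
motion; they instead get the gravity-direction component subtracted
(`h` itself), whose norm is rotation-invariant.  A 2-class CNN routes
each window to the right branch.  Downstream, overlapped 5 s Hanning
windows yield per-axis FFT magnitude spectra feeding a compact 1-D CNN
(conv–pool–dropout ×2, dense ReLU, softmax; RMSprop, cross-entropy),
evaluated with subject-wise 10-fold cross-validation:
accuracy `= 100·Σ P_ii / N` with 95% interval
`±1.96·sqrt(acc(100−acc)/N)`.

## Worked example

```r
library(orientfree)

# synthetic benchmark: 20 subjects, 50 Hz, five activities with known
# ground truth (3 movements, 2 postures)
cfg <- synth_config(n_subjects = 2, duration_s = 30, seed = 1)
ds  <- generate_dataset(cfg)
rec <- ds$recordings[[1]]
rec
#> <triaxial_recording> subject S01: 7500 samples at 50 Hz (150.0 s)
#>   labels: jog, sit, stairs, stand, walk

# the headline property: preprocessing is invariant to sensor rotation
seg <- generate_movement(cfg, "S01", "walk")
R45 <- rotation_matrix("y", 45)
p0 <- preprocess_segment(seg$x,            cfg$fs, mode = "movement")
p1 <- preprocess_segment(seg$x %*% t(R45), cfg$fs, mode = "movement")
both <- p0$provenance == "frame" & p1$provenance == "frame"
max(abs(p0$x[both, ] - p1$x[both, ]))
#> [1] 1.887379e-14
```

The rotated and unrotated recordings become the same signal after the
transform — deviations are at floating-point level, far below the 1e-6
invariance requirement.  The full four-setup experiment (baseline;
rotated; rotated + algorithm; rotated + per-type algorithm with a
learned movement/posture router):

```r
report <- run_benchmark(seed = 1)   # ~13 min on one CPU
report
#> <eval_report> subject-wise 10 fold CV, 11600 windows, 5 classes
#>   baseline             99.36 +- 0.14 %   (movements 99.02, postures 99.87)
#>   rotated              82.80 +- 0.69 %   (movements 71.39, postures 99.91)
#>   rotated_algorithm    92.59 +- 0.48 %   (movements 93.10, postures 91.81)
#>   rotated_per_type     95.61 +- 0.37 %   (movements 92.70, postures 99.98)
#>   type classifier     100.00 +- 0.00 %
```

Reading: random per-subject 45° rotations cost the plain system 16.6
accuracy points (movements suffer most — the forward/vertical amplitude
ratio that separates walking from stairs lives in exactly the axes a
rotation scrambles).  Applying the consistent reference frame everywhere
recovers 9.8 points; routing movements through the frame transform and
postures through gravity subtraction recovers 12.8 of the 16.6 (posture
accuracy returns to baseline exactly; movements retain a residual gap
because the estimated forward axis carries noise — see the vignette for
why, and for what the estimator provably can and cannot recover).

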