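---
title: "Methods: the wrist muscle-to-force null-space pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the wrist muscle-to-force null-space pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullreach)
```

## The model

Four wrist muscles (FCR, FCU, ECRL, ECU) act on two mechanical degrees of
freedom (flexion–extension = X, radial–ulnar deviation = Y). Under an
isometric, quasi-static linear assumption, the rectified-and-smoothed EMG
envelope vector $\alpha \in \mathbb{R}^4_{\ge 0}$ maps to planar force via a
*pulling matrix* $H \in \mathbb{R}^{2\times 4}$:

$$ f = H\,\alpha. $$

Because there are four muscles and two force axes, the kernel of $H$ is a
two-dimensional *muscle-to-force null-space*: activation patterns that
produce no net force (co-contraction lives here). The pipeline builds an
interpretable coordinate system on that null-space in four steps:

1. **Basis.** $N \in \mathbb{R}^{2\times 4}$ has orthonormal rows spanning
   the kernel of $H$ ($N H^\top = 0$, $N N^\top = I$), computed from the SVD
   of $H$.
2. **Scaling.** $\tilde N = \kappa N$ with
   $\kappa = \max(\lVert h_1\rVert, \lVert h_2\rVert)$, the larger row norm
   of $H$. This makes null coordinates force-comparable: a null coordinate
   of magnitude $\beta$ demands a muscle-activity level similar to producing
   $\beta$ N of force along the stronger principal force direction. The
   package tests this as an exact identity: a unit activation along the
   dominant pulling row's normalized direction produces the same number of
   newtons along that axis as the null magnitude $\lVert\tilde N \alpha\rVert$
   produced by a kernel activation of equal Euclidean norm.
3. **Offset.** $n_0 = \tilde N \bar\alpha_{\text{rest}}$, the mean projected
   envelope of a dedicated rest trial, so the displayed coordinate is zero
   at rest. The offset is estimated from the rest trial rather than from the
   least-squares rest target, because the two play different roles: the rest
   target anchors the force origin of the (intercept-free) regression, while
   $n_0$ absorbs the tonic envelope bias.
4. **Alignment.** $n_c$ is the mean of $\tilde N \bar\alpha$ over the six
   co-contraction calibration repetitions minus $n_0$, and
   $R_c$ is the proper rotation taking $n_c$ to the $+X$ axis. The working
   coordinate is $n = R_c(\tilde N \alpha - n_0)$.

Muscles only pull, so with $\alpha \ge 0$ the reachable set
$\{R_c(\tilde N\alpha - n_0) : \alpha \ge 0\}$ is not the whole plane but an
affine cone with apex $-R_c n_0$ whose directions are the conical hull of
the four column images $R_c \tilde N e_j$.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| high-pass cut-off | 20 | Hz | removes motion artifact/DC before rectification |
| low-pass cut-off | 5 | Hz | envelope smoothing after rectification |
| trajectory smoothing cut-off | 3 | Hz | pre-filter for correction counting |
| MVF directions | 16 every 22.5° | deg | maximum-voluntary-force schedule, anticlockwise from flexion (180°) |
| calibration targets | 1 rest + 16 at 0.2·sMVF | N | pulling-matrix fitting points |
| calibration rounds | 6 initial / 4 post | — | 102 / 68 fitting points |
| co-contraction ring | $\lVert\tilde n\rVert = 3$ | null units | natural co-contraction calibration level |
| NSTR trials | 80 × 7 s | — | null-space target reaching session |
| NSTR tolerance | 0.4 | null units | in-target criterion |
| NSTR force threshold | 0.04·sMVF | N | "without producing force" criterion |
| NSTR initial target / step | [2, 0] / 5° anticlockwise | null units / deg | adaptive progression |
| progression window | 10 trials, 80% | — | consistency criterion |
| CTR trials | 90 × 7 s | — | 9 positions × 2 sizes (3, 6) |
| hold | 1 | s | success requires an uninterrupted hold |
| sampling rate | 1000 | Hz | all evaluation at the native rate |

## Design choices where the protocol was open

- **Causal filtering.** Whether envelope filtering was causal or zero-phase
  is not specified by the protocol; the package defaults to causal
  single-pass filters, matching the real-time feedback context, and exposes
  `zero_phase = TRUE` for offline work. The first 0.5 s of every envelope
  recording is flagged as filter warm-up and excluded from calibration
  averages, so zero-state transients cannot bias 2-s hold windows.
- **Envelope clipping.** Low-pass ringing can dip slightly negative after
  rectification; envelopes are clipped at zero. Non-negativity is
  load-bearing: the reachable-cone computation assumes $\alpha \ge 0$
  exactly.
- **No regression intercept.** The force model is strictly $f = H\alpha$;
  the rest calibration target anchors the origin and rest-envelope bias is
  handled by $n_0$, keeping the force map and the null-space offset
  consistent rather than splitting bias between an intercept and $n_0$.
- **Basis orientation.** SVD kernel rows are sign-ambiguous. Rows are first
  signed so their largest-magnitude entry is positive; when the model is
  assembled, the first row is flipped if needed so the pre-rotation
  co-contraction coordinate has a non-negative first component, and $R_c$
  absorbs the remaining alignment. Serialized models are therefore
  reproducible across runs.
- **Cone feasibility with closure.** The reachable set is defined with
  strict positivity of $\alpha$, which is not decidable numerically;
  membership is implemented on the closure $\alpha \ge 0$. With a fixed
  required force the stacked system (two force rows, two scaled-null rows)
  has four independent rows for four unknowns, so feasibility reduces to a
  unique linear solve plus a non-negativity check at tolerance $10^{-7}$ in
  scaled units; with the force unconstrained it is decided by non-negative
  least squares on the null-coordinate equations.
- **Progression-window semantics.** "80% of a moving window of ten trials"
  is counted over successes *at the current target* within the last ten
  trials, evaluated from the first trial at that target, so eight
  consecutive successes suffice. This is the unique reading under which an
  ideal agent attempts exactly ten target locations in eighty trials, which
  is the protocol's stated best case.
- **CTR tolerances.** Position and size tolerances are not printed in the
  protocol. The defaults reuse the printed NSTR thresholds — 0.04 (sMVF
  fraction) for position, 0.4 null units for size — and are overridable in
  `ctr_config()`; logs record the values used.
- **CTR size coordinate.** The cursor radius is driven by the unrotated
  magnitude $\lVert\tilde n\rVert = \lVert\tilde N\alpha\rVert$ (the
  quantity the size rings 3 and 6 are defined on), not by the rotated
  first coordinate; the rotated frame matters only for NSTR positions.
- **Violations outside the hold.** Force-threshold or tolerance violations
  during a trial do not abort it; only the hold window must be
  violation-free, since the success definition attaches its conditions to
  the hold.
- **Correction counting.** The peak finder on the 3-Hz-smoothed speed
  profile requires peaks above 5% of the trial's maximum speed with at
  least 100 ms separation. A generic peak finder is underspecified; these
  two criteria suppress numerical micro-peaks and are exposed as arguments.
- **Movement onset** (for concurrency Phase 1) is likewise unstated; the
  evaluator uses the entry time of the continuous in-tolerance run that
  leads into the successful hold, separately for the task-space and
  null-space conditions.
- **Reaching range** is a circular span: 360° minus the largest angular gap
  between sorted reached angles (binned at 1°), which is well defined for
  wrap-around angle sets. Reached angles are samples whose null magnitude
  is within 0.4 of the target radius 2; the band reuses the target
  tolerance since no separate band is printed.
- **Concurrency baselines.** For CTR positions T1–T8 the baseline
  unintentional null activity is the mean $\lVert\tilde n\rVert$ over the
  matching calibration target's final 2-s hold; the origin target T9 uses
  the offset-corrected rest level (≈ 0). Trials whose required null
  movement is below 15% of the target size are excluded as too small to
  measure robustly.
- **Co-contraction averaging.** The offset is subtracted after averaging
  the six repetitions (equivalent to subtracting before, for means).

## The synthetic participant

No human recordings ship with the package; every stage is exercised on
synthetic participants with known ground truth.

- `make_wrist_geometry()` draws a 2×4 pulling matrix around anatomically
  plausible pulling directions (flexors toward −X, extensors toward +X,
  with radial/ulnar components), jittered per seed, scaled so the sMVF
  lands near 10 N (task targets near 2 N). The four columns positively span
  the force plane, and a non-negative kernel pattern provides the natural
  co-contraction direction. Because the cone's angular headroom around the
  natural co-contraction direction is asymmetric, the generator orients the
  geometry (mirroring the radial/ulnar assignment when needed) so the
  anticlockwise NSTR progression arc lies on the covered side — emulating
  the study condition that requested targets were always inside the cone.
- `simulate_calibration_session()` emits envelope-level recordings for all
  calibration stages (MVF ramps, 17-target holds whose noiseless means obey
  $f = H\alpha$, rest, six co-contraction repetitions on the
  $\lVert\tilde n\rVert = 3$ ring). Noise is additive Gaussian on the
  envelope (clipped at zero), optionally with a signal-dependent component
  proportional to activation; the protocol prescribes no noise model, so
  both parameters are explicit.
- `simulate_raw_recording()` synthesizes raw-style EMG as 20–450 Hz
  band-limited noise amplitude-modulated by a target envelope, so the
  filter chain itself can be exercised; envelope-level simulation bypasses
  it for speed.
- `simulate_session()` closes the loop: an ideal policy plans activation
  endpoints by inverting the stacked force/null system (non-negative least
  squares) and ramps with a minimum-jerk profile after a 0.3-s reaction
  time; noisy, biased and co-contraction-locked policies reproduce the
  failure modes of interest (drift, a consistent null-direction bias,
  inability to redirect co-contraction). In CTR, when the natural null
  activity of the force solution already exceeds the requested size, no
  non-negative activation can reduce it along the natural curve; the
  simulated participant then overshoots, which is the characteristic
  failure mode for large unintentional null activity.

What the generator does *not* emulate: posture-dependent changes of the
pulling vectors, nonlinear EMG-to-force saturation, electrode cross-talk,
fatigue and slow drift of the co-contraction direction, and trial-to-trial
motor variability structure beyond stationary envelope noise. Passing tests
therefore validate the pipeline's algebra, task logic and metric
definitions — not claims about human behaviour.

## Numerical choices

- Equality constraints in feasibility checks: $10^{-7}$ (scaled units);
  witness round-trips verified to $10^{-8}$ in tests.
- Basis orthonormality and annihilation: $10^{-10}$ in model validation.
- Rotation construction via `atan2`; degenerate ($n_c = 0$) rejected.
- Degenerate cones (all column images collinear) are flagged single-ray;
  when the column images positively span the plane the cone is reported as
  the full plane rather than as rays.
- Zero path length makes motion efficiency undefined (`NA` with warning);
  zero-variance force axes make $R^2$ undefined (flagged).
- Collinear envelope channels are rejected by the fitter, naming the
  channels involved.

## Problem sizes

The test suite and acceptance script run closed-loop sessions at the native
1000 Hz for the protocol-level checks (80-trial NSTR) and at 50–250 Hz for
oracle-equivalence sweeps, where the sampling rate is a free parameter of
the evaluator rather than part of the claim being checked. The pulling-
matrix recovery study uses the full 6-round, 102-point calibration over 20
seeds at 5% envelope noise. The membership oracle uses a 201×201 grid over
kernel coefficients against 10,000 random targets sampled away from the
cone boundary by twice the grid resolution (decisions within a band
narrower than the grid cannot be attributed to either method).

## Known limitations

- The API asserts a two-dimensional null-space (four muscles, two force
  DoFs); higher-dimensional generalization is future work.
- Bayesian hypothesis testing of behavioural differences is out of scope;
  summaries are descriptive (medians, IQRs).
- The closed-loop policies are kinematic activation planners, not
  biomechanical muscle models (no activation dynamics or Hill-type
  behaviour).
- Metrics assume trajectories sampled on a uniform grid at a known rate.
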