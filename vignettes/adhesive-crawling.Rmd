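---
title: "Modelling adhesive crawling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adhesive crawling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balicrawl)
```

This vignette is the package's own account of its models: the assumptions
behind the two-sucker gait simulator and the ratcheting friction model, the
parameters that matter and how their defaults were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
decisions made where the biology left the design open.

## The gait model

The crawling body is reduced to two rigid adhesive discs — the anterior
(pectoral) sucker and the posterior (pelvic) sucker — joined by an
inextensible spine of length `spine_length` (default 15 mm on a 50 mm
fish). Each disc carries a left and a right fin. A fin's state sets the
lateral friction of its side of the disc: abducted fins anchor (high
coefficient `mu_abducted`), adducted fins slide (`mu_adducted <
mu_abducted`). Both suckers stay attached at all times; every simulated
frame carries `TRUE` contact flags, and the spine constraint is enforced to
machine precision rather than approximately.

The dynamics are *quasi-static and kinematic*: we do not integrate forces.
Instead, each displacement phase applies the minimal mechanism consistent
with the observed behaviour — the abducted-fin side of a sucker acts as a
pivot (an effectively infinite-friction anchor), the adducted side slides,
so the actively pulled sucker rotates by the stage rotation about its
pivot, and the other sucker's rotation about *its* pivot is solved
(1-D root find, tolerance 1e-13) so the spine length is preserved exactly.
Quasi-static force magnitudes (`F1`, `F2`, `Fs2`) are book-kept for
inspection but play no role in the kinematics.

One forward cycle has two mirrored stages. In stage 1 the left girdle
muscle contracts, the posterior sucker rotates negatively (clockwise in
ventral view) about its right abducted pelvic fin, the anterior sucker
follows positively about its left abducted pectoral fin, and all four fin
states swap during the rotation. Stage 2 mirrors it. Backward crawling has
four quarters: fin-state swaps with no displacement (quarters 1 and 3)
alternate with rotations during which fin states hold (quarters 2 and 4).
Because the pivots land on the opposite sides, the same actuator parameters
move the body the other way: swapping only the protocol reverses the sign
of the net axial displacement. Fin states are diagonally coupled (RF with
LH, LF with RH) and the two girdle muscles are exactly antagonistic, so the
left/right muscle-length correlation of a noiseless simulation is -1 by
construction — a property the analysis pipeline must recover, and does.

Sign convention: positive rotation is counter-clockwise in ventral view
with the x-axis along the initial direction of travel (the source
observations never fix a convention, so the package does).

## Actuation, easing and the phase structure

Within each phase, motion follows a cosine easing confined to the central
`active_fraction` (default 0.7) of the phase, so the body pauses briefly at
stage boundaries and its velocity accelerates and decelerates twice per
cycle. The stage rotation is geared linearly to the girdle-muscle stroke:

```
theta = rotation_per_stage * muscle_contraction_amplitude / 2 mm
```

so a zero stroke produces zero displacement, while `rotation_per_stage`
remains the rotation realized at the default 2 mm stroke.

Two defaults are *calibrations*, fixed once against the observed
performance of crawling fish and not revisited:

- `rotation_per_stage = 0.44` rad with `pivot_offset = 10` mm, so that a
  16-cycle bout covers about 134 mm (observed bouts exceed 130 mm).
- the lateral amplitude envelope (below), so that the kinematics pipeline
  reports a peak lateral velocity of 7.8 BL/s at the 80%-BL landmark.

## Midline, fin and muscle synthesis

The 20 digitized midline points are synthesized per frame as a straight
body line through the two sucker frames plus a lateral C-bend offset field
`env(s) * q(t)`, where `q` is the phase-locked fin wave (±1 at stage
boundaries) and the envelope

```
env(s) = amp_env_tail * (0.08 + 0.92 * s^2)      # s = arc fraction, head = 0
```

grows from about 0.5 mm at the head to `amp_env_tail = 6.47` mm at the
caudal peduncle, reproducing the tail-dominant amplitude profile (largest
amplitude more than seven times the head's). Because the body is
(approximately) inextensible, lateral bending foreshortens the chord; the
free ends beyond the anchored suckers are pulled toward their suckers by
the accumulated foreshortening integral. This term is what gives the tail
its axial whip: without it the maximum axial velocity would sit at the
head, contradicting the tail-dominant axial profile of real crawling.

Fin polygons are fans of `n_pectoral_rays = 24` / `n_pelvic_rays = 20` rim
vertices whose shoelace area follows the abduction/adduction waveform
between the adducted and abducted areas (defaults 30–80 mm² pectoral,
25–70 mm² pelvic). Girdle-muscle endpoint pairs are placed on the
girdle-to-girdle line separated by exactly `rest ± amp/2 * q(t)`; the
suckers themselves move near-rigidly, so endpoints derived purely from the
sucker frames could not shorten — the synthesized endpoints represent the
digitized soft-tissue insertion extremes. Optional Gaussian landmark
jitter (`noise_sigma`, seeded) is applied to every landmark kind.

What the generator does **not** emulate: out-of-plane motion and camera
distortion, tracking error correlated along the body (jitter is i.i.d.),
sucker detachment or failure, the tail-powered escape launch, and
fatigue/variability across cycles (every cycle is identical up to noise).
Passing the pipeline's tests on synthetic recordings therefore validates
the *computations*, not the digitizing process; and one known shape
mismatch remains by design — the simulated maximum lateral velocity grows
monotonically to the tail tip, whereas real crawling peaks at the 80%-BL
landmark, which is the point the calibration targets.

## The ratcheting friction model

Pulling tests on an adhering fish are modelled as a massless block on a
spring (`spring_stiffness`, default 30 mN/mm) whose anchor moves at
`pull_speed` (0.1 mm/s). While stuck, force grows at `k*v`; at the stick
limit `mu_static * N` a rapid slip relaxes the force to `mu_sliding * N`.
Above `angle_threshold_force` (60 mN) a slip also increases the fin-ray
angles (`angle_per_slip = 3` deg/mm) and adhesion grows with angle
(`angle_gain = 1` mN/deg), so the contact re-arrests and the stick limit
ratchets upward — a rising sawtooth of force with plateaued, stepwise
displacement. Below the threshold nothing strengthens the contact during
sliding, so the block slides on quasi-statically at exactly
`mu_sliding * N`: a flat plateau. This single re-arrest rule reproduces
both observed regimes (stable sliding plateaus in the coefficient tests;
rising stick-slip in the ratchet test) without introducing inertia.

Units: applied adhesion is given in gram-force and converted at 9.80665
mN/gf. The default single-pull adhesion (3.331 gf) is chosen so the stick
limit equals the observed 65 mN force at which fin-ray angles begin to
rise; the threshold detector reports the maximum force attained up to the
first time the smoothed (Savitzky-Golay, window 11, order 3) mean angle
exceeds its initial value by 2°, which is exactly the "fitting force
reached" reading and coincides with the naive reading on monotone traces.

Coefficient estimation extracts, per trace, the maximum force before the
displacement first exceeds 0.05 mm (static) and the median force over the
post-onset stable window (sliding), then fits each against adhesion by OLS
*through the origin* — the coefficient is defined as the proportionality
slope, and the origin-anchored fit matches that definition; an intercept
option exists but is off by default. The 0.05 mm movement threshold and
the window definition are implementation choices, small relative to the
~10 mm excursions of real tests. All twelve traces (4 levels x 3 reps)
enter the fit individually rather than as per-level means; with the
default noise (0.05 mN SD) the two give indistinguishable slopes.

## The analysis pipeline

Midline resampling fits natural cubic splines to the 20 points under
chord-length parameterization and inverts the arc-length map on a dense
subdivision (8001 points), yielding 101 points equally spaced in arc
length; 11 landmarks (every 10th point) divide the body into 10 segments
of 10% body length. The direction of travel is the principal axis
(total least squares) of the anterior head point's path, oriented by net
displacement, falling back to the head-axis direction below 0.1 mm of net
motion. Segment angles are folded to [0°, 90°] since the reported maxima
are unsigned. The straight reference midline for amplitudes — never
defined operationally in the source observations — is taken as the
travel-direction line through the mean head position. Velocities are
central differences of Savitzky-Golay-smoothed positions (window 11,
order 3, both exposed); axial/lateral components are projections onto the
travel frame, reported in mm/s and BL/s.

Fin state is classified from the normalized area range: >= 70% abducted,
<= 30% adducted, transition between (both thresholds exposed; the
observers' original scoring rule is unknown, and the two-threshold scheme
reproduces transition bands of finite width). Cycles run between
successive completed transitions of the right pectoral fin into abduction;
each variable is linearly interpolated at 20 phase increments including
both endpoints and aggregated as pointwise mean ± sample SD over cycles.
Correlations are Pearson (the coupled waveforms are near-linear), computed
over whole cycles only.

## Problem sizes and degenerate inputs

The packaged analyses use 5-cycle (325-frame) and 10-cycle (650-frame)
bouts at 500 Hz and 20-30 s pulling traces at 100 Hz — one forward bout
resolves each gait phase with ~32 frames, and a trace comfortably contains
the onset and plateau at every adhesion level. Degenerate inputs fail
loudly rather than silently: duplicate midline points, self-intersecting
fin polygons, coincident muscle endpoints, stationary heads, constant area
series, traces without movement and single-level fits all raise typed
errors or flagged sentinels (`NA` with a `reason`, never propagated NaN).

## Reproducibility

A single integer seed drives every stochastic component (landmark jitter,
force noise); identical configurations give byte-identical outputs, which
`run_pipeline()` certifies by writing md5 hashes into its manifest. All
tolerances and thresholds live in `run_config()`; there are no hidden
numeric constants in the pipeline stages.
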