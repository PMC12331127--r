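---
title: "The ICR digital laboratory: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ICR digital laboratory: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrlab)
```

## The problem

Joint kinematics — the temporomandibular joint is the motivating case —
is often summarized by an *instantaneous center (axis) of rotation*: the
single axis about which a pure rotation would carry the body from one
observed pose to the next. Real motions are rarely pure rotations. The
moment a small translational component rides on the rotation, the
registered ICR is no longer "approximately the anatomical hinge axis": it
is displaced by a factor that diverges as the rotation angle shrinks.
`icrlab` provides a controlled, noise-free digital environment in which
both sides of that coin are measured:

* **Transition experiment (Setup 1).** How far, and in which direction,
  does a perpendicular translation of magnitude $|t_e|$ push the
  registered axis?
* **Axis-error experiment (Setup 2).** If the axis used for articulation
  is *wrong* by a known amount and direction, how wrong does the
  resulting motion become, at best?

## Model and exact relations

A proper rigid motion is $v \mapsto Rv + t$. Every such motion with a
nonzero rotation angle has a unique finite helical (screw) axis: rotation
by $\alpha$ about an axis plus a slide along it. With the translation
perpendicular to the rotation axis the slide is zero and the screw axis
is the 3D ICR. `screw_axis()` extracts it in closed form: the angle from
the rotation-matrix trace, the direction from the skew part (with the
dominant-column fallback near half-turns), and the axis anchor from

$$c = \tfrac{1}{2} b + \frac{u \times b}{2\tan(\alpha/2)},$$

where $b$ is the in-plane translation component — the 3D form of the
classical planar Reuleaux perpendicular-bisector construction, which is
kept in the package (`reuleaux_2d()`) as an independent oracle and
cross-checked against the 3D route in the tests.

For rotation $\alpha$ about the original axis followed by a perpendicular
translation $t_e$:

* $|d_{axis}| = |t_e| / (2\sin(\alpha/2))$ (isosceles triangle between
  the two centers; at $\alpha = 180°$ this degenerates to $|t_e|/2$);
* the displacement direction lies $90° - \alpha/2$ from $t_e$, in the
  rotation's own sense (at $\alpha = 180°$, along $t_e$ itself);
* the registered angle equals the applied one, the axes stay parallel,
  and the substitute rotation reproduces the end pose exactly.

Angles are accepted in $(0°, 360°)$; values above $180°$ are re-expressed
as opposite-sense rotations of $360° - \alpha$, and multiples of $360°$
raise an explicit error (the motion is then a pure translation and the
ICR recedes to infinity — this is precisely the small-angle sensitivity
that makes clinical ICR registration fragile). The EcD ratio
$1/(2\sin(\alpha/2))$ is taken as ground truth throughout;
`ecd_curve()` exposes the *empirical* power-law summary
$a/\alpha^b + c$ separately, with the reference coefficients as
defaults.

### A note on the reference curve coefficients

The reference power-law coefficients are exactly what one obtains by
refitting $a/\alpha^b + c$ to the EcD table rounded at two decimals over
the eight study angles — `fit_ecd_curve()` reproduces them to seven
significant digits, which is how the package validates its fitting
routine. Those same coefficients do **not** reproduce the six-decimal
curve tabulation often quoted alongside them (they differ in the third
decimal, by up to 0.0125), and no standard refit we tried
(full-precision ratios, alternative weightings, inclusion of the
comparison block) generates that tabulation. The package therefore
treats the coefficient equation as the authoritative curve and reports
its own evaluations of it; the six-decimal tabulation is regarded as
reproducible only to ±0.013. The
curve stays within 0.02 of the exact relation over the fitted range
either way, which is the property that matters in use.

## Conventions (the free choices, fixed)

The geometry leaves several conventions open; the package fixes them
once:

* **Frame.** Right-handed, mm and degrees at every API boundary. The
  Setup 1 rotation axis is parallel to $+x$; the plane perpendicular to
  it is the "sagittal plane", with direction labels $f = +y$, $b = -y$,
  $u = +z$, $d = -z$ and the four 45° diagonals.
* **Rotation sense.** Right-hand rule about the stored direction.
  `screw_axis()` orients the recovered direction so its angle is positive
  in $(0°, 180°]$; line-level metrics canonicalize the direction (first
  nonzero component positive) so they are sign-invariant.
* **Axis reporting.** An axis is reported at the foot of the
  perpendicular from the body's gravity point, advanced 100 mm along the
  canonical direction — advancing canonically resolves the
  forward/backward ambiguity reproducibly.
* **Axis placement.** The default hinge sits 40 mm above the arch
  centroid in $+z$, the order of magnitude of a condylar axis over a
  lower arch. EcD is provably position-independent, so this only sets
  the scene (and the tests assert the independence).
* **Tolerances.** 1e−10 absolute for orthonormality and rigidity
  checks; rotation angles below 1e−9° are treated as pure translation
  (an explicit error beats a numerically enormous axis).

## Setup 1 pipeline

`run_transition_experiment()` sweeps the full study grid by default — 8
angles $\times$ 6 magnitudes $\times$ 8 directions $= 384$ cases — and
registers each case by least-squares rigid fit (Kabsch/orthogonal
Procrustes with the proper-rotation correction) followed by screw-axis
decomposition. Correspondence is strictly by vertex index: the poses are
the *same* body moved, so nearest-neighbour matching would only add an
error source the design excludes. Registration failures become flagged
rows, not crashes. The `rms_after` column re-applies the registered
screw motion to the original pose and measures the residual against the
target pose — the "substitution property" that the single rotation
really does stand in for the combined motion (at or below 1e−13 mm here;
the package asserts ≤ 1e−7 mm, treating that level as a numerical
contract, not a target).

## Setup 2 pipeline

`build_error_set()` constructs the 20 misplaced axes of a set: ±5/10/15
mm along the gravity-point line (negative = toward the body), the same
amounts along the perpendicular path (oriented toward $+z$, ties toward
$+y$), and ±3/6/9/12° swings about the gravity-point axis parallel to
the central one (positive toward the positive perpendicular side). All
three modifications keep the modified axis parallel to the central one.
The axis error of a circular modification is the line-to-line distance
$2r\sin(\beta/2)$ — the chord swept by the axis' foot point — which is
the natural metric when the displacement is itself a rotation.

`build_groups()` replicates that structure at the group level: the
original axis, six parallel groups stepped 10 mm outward, six
perpendicular groups stepped 10 mm to alternating sides, eight circular
groups at 15° steps in alternating senses, and a secondary series (six
perpendicular + eight circular) re-rooted at the farthest parallel axis
— 21 + 14 = 35 groups. Group lattices like this are sometimes labelled
with single letters; the package uses descriptive ids (`origin`,
`par_+10`, `F_circ_-45`, ...) instead, since no result depends on the
naming. Step sizes are a free choice; 10 mm / 15° keep the intergroup scale comparable to the
in-set error scale, and only orderings and trends — never absolute AEcFE
values, which depend on the body's shape — are asserted.

`best_fit_rotation()` minimizes rms over the rotation angle about the
wrong axis. Because every vertex moves on a circle about that axis, the
squared objective is a *single sinusoid* $K + 2E_c\cos\theta +
2E_s\sin\theta$ whose three coefficients are accumulated once in
$O(n)$; the minimizer then follows the prescribed route — coarse scan
over the nominal angle ±2° at 0.01° (widening and flagging if the
minimum lands on the bracket edge), Brent refinement, and a final
stationary-point polish $\theta^* = \operatorname{atan2}(-E_s, -E_c)$
that the sinusoid form makes exact. The reported `rms_star` is
re-evaluated from the actual rotated geometry, because the accumulated
statistics cancel catastrophically exactly where the true residual is
near zero. The tests compare $\theta^*$ against a brute-force grid scan
that rotates the vertices directly. `AEcFE` is `axis_error_mm /
rms_star`; degenerate cases with zero residual report `NA` rather than infinity.

On the synthetic arch the tolerance structure comes out as the theory
predicts: parallel errors are the most tolerated and become more so with
distance from the body (the error then barely changes the lever arm
direction, only its length); perpendicular and circular errors are least
tolerated and nearly constant across magnitudes. AEcFE is *not*
constant across parallel magnitudes — the error changes the lever arm
itself, so tolerance grows monotonically from the toward-the-body side
to the away side — and the tests assert that monotonicity rather than a
constancy the geometry does not support.

## The synthetic bodies

`generate_arch()` builds a parabolic horseshoe band of vertices
(occlusal plane $x$–$y$, height $z$) with tooth-like sinusoidal bumps
and a small seeded jitter (±0.05 mm) that breaks the exact grid
symmetry the way scan roughness would, then centres the centroid and
triangulates the grid. Defaults — 60 × 50 mm footprint, 10 mm band, 14
teeth, 2 mm bumps, 2000 vertices — match a lower dental arch
dimensionally. Two stock specs (`arch_spec_primary()`,
`arch_spec_control()`) mirror the two-scan control design: anything
claimed body-independent is asserted on both. Generation is
deterministic per seed and leaves the caller's RNG state untouched.

What the synthetic arch does *not* emulate: scanner noise fields,
segmentation artifacts, soft-tissue deformation, or a clinically
realistic occlusal surface. That is deliberate. The Setup 1 results are
provably independent of the body, so passing tests there transfer to
real scans exactly. Setup 2 residuals *do* depend on the body's shape
and vertex distribution, so its tests assert orderings and trends, which
are geometry-driven, not the absolute AEcFE magnitudes one would measure
on clinical meshes.

## Problem sizes used in the tests

Module tests run on 520–600-vertex bodies and reduced grids; the
acceptance suite runs the full 384-case transition grid at 2000 vertices
and the full 35-group axis-error layout at 1000 vertices with all six
set rotations (4200 optimizations), sizes at which the whole suite
completes in a few minutes on a single core while exercising every
default condition.

## Known limitations

* ICR estimation from noisy sparse landmark trajectories (SCoRE-style
  center fitting) is out of scope; registration is index-corresponded
  and noise-free by design.
* The binary STL writer quantizes to 32-bit floats (the format's own
  limit); OBJ round-trips at full double precision.
* `exec_time` columns are recorded for report parity but are
  hardware-dependent and never asserted.
* Non-rigid deformation, scaling and reflections are rejected, not
  modelled.
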