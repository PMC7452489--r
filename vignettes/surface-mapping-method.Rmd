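---
title: "Surface mapping of the patella: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface mapping of the patella: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patmap)
```

## The estimation problem

The patella is a sesamoid bone floating in the quadriceps tendon; its
six-degree-of-freedom pose relative to the lower leg is clinically
interesting (patellar tracking) but hard to measure without biplane
fluoroscopy. The surface-mapping approach implemented here uses only
two widely available inputs: a bone surface mesh segmented from CT, and
the positions of reflective markers attached to the skin of the
anterior knee, captured by an ordinary motion-capture system.

The key observation is that CT delivers, once and for all, the
*soft-tissue thickness* over every bone-surface triangle: the distance
`eps_i` from face `i`'s centroid along its outward unit normal to the
skin surface, measured in the CT frame. During a static trial, a
candidate pose `Q = (px, py, pz, thx, thy, thz)` places the bone among
the captured markers; each analysis face then measures the signed
projection `d_i` of its nearest marker onto its posed normal ray (the
*vertical distance*). If the pose is right, markers sit where the skin
was in CT, so `d_i` should reproduce `eps_i`. The pose estimate
minimizes the surface mapping error

$$ S(Q, M, E) \;=\; \sum_{i=1}^{N} \lvert d_i - \varepsilon_i \rvert $$

over the analysis area of `N` faces.

Assumptions worth keeping in mind: the skin does not move relative to
the bone between CT and capture (the method's dominant error source in
practice), soft tissue is not deformed by muscle contraction, and the
trial is static.

## Pipeline and parameters

`register()` runs the stages in order; each can also be called alone.

| parameter | default | units | role |
|---|---|---|---|
| `target_edge` | 3 | mm | isotropic remeshing edge length for the bone; 2–4 mm is the sensible band (finer is slow, coarser distorts the shape) |
| `thickness_range` | c(0, 20) | mm | analysis-area band on `eps`; narrower bands shrink the area until the mapping becomes degenerate, wider bands admit posterior faces that markers cannot constrain |
| `marker_min_distance` | 10 | mm | minimum pairwise distance for generated virtual markers; 10 mm matches what can be physically attached |
| `h` | 0.5 | mm or deg | fixed descent step; also the resolution floor of the estimate |
| `max_sweeps` | 10000 | – | sweep cap; convergence is a full sweep with no accepted move |
| `update` | sequential | – | whether accepted moves apply immediately (sequential) or per-sweep (simultaneous) |

The defaults are the selected working condition of the factorial
parameter study (minimum total rank score; see
`condition_total_scores()` and `select_best()`).

### Numerical conventions

* Right-handed frames, millimetres, degrees. Cardan sequence x-y-z
  about the moving axes, so `R = Rx(thx) Ry(thy) Rz(thz)`; angles are
  reported in (−180, 180], and at gimbal lock (`|thy| = 90`) `thz` is
  fixed to 0 with the remainder folded into `thx`.
* Face and vertex indices are 1-based in memory, following R
  convention; PLY keeps its native 0-based indices on disk and OBJ its
  1-based ones.
* `eps` is cast from the face **centroid** (not the vertices) along the
  outward face normal; the first skin intersection wins; faces whose
  ray misses the skin are undefined and never enter the analysis area.
* `d_i` selects the marker nearest the outward normal **ray** — not the
  infinite line. With the infinite line, a lateral face can "select" a
  marker lying near the line's backward extension on the far side of
  the knee, which poisons the objective; the half-line reading is the
  one under which the noiseless identity `d_i = eps_i` actually holds.
* Correspondence is recomputed at every objective evaluation, since the
  normal rays move with the pose (the alternative — freezing the
  initial correspondence — biases the estimate toward the initial
  guess).
* In the descent rule, ties between the three trial values keep the
  current coordinate: deterministic and conservative.
* Sequential update is the default because each accepted move strictly
  decreases `S`, making the per-sweep error trace provably monotone
  non-increasing; simultaneous update is available as a configuration
  switch for fidelity comparisons but can cycle.
* The initial-pose perturbation used in simulation-style validation is
  independent uniform on ±magnitude per DOF.
* Remeshing is the classic split/collapse/flip/tangential-relax loop:
  edges longer than 4/3 of the target split at their midpoint, edges
  shorter than 4/5 collapse (guarded by the link condition and a
  normal-flip check), flips drive vertex valence toward 6, and vertices
  relax only within their tangent plane so the surface barely moves.
  The contract is statistical — mean edge length within roughly 50% of
  the target, bounded surface deviation — not an exact edge length,
  which no remesher can deliver.

## The synthetic phantom

`make_phantom()` builds a fully known scene so that every stage of the
estimator can be validated without CT or motion-capture data:

* **bone** — a superellipsoid of semi-axes 20 × 22.5 × 10 mm
  (envelope ≈ 40 × 45 × 20 mm), tapered 45% along the proximodistal
  axis (wide proximally, apex distally) and carrying a 4-mm anterior
  median ridge. The taper and ridge are what make rotation about the
  anteroposterior axis observable at all; a symmetric envelope would
  leave it free.
* **skin** — a heightfield over a 100 × 108 mm elliptical footprint
  that follows the top of the posed bone plus a soft-tissue thickness
  profile, smoothly blended into a background dome away from the bone.
  The profile combines a radial growth term (thin over the apex,
  thicker laterally, spanning roughly 3.5–20 mm) with low-frequency
  lumps (amplitude 2 mm, wavelength 28 mm) emulating the spatial
  inhomogeneity of real prepatellar tissue. The lumps double as
  registration texture: a perfectly radial profile admits alternative
  poses with near-identical error.
* **markers** — by default a 10-mm grid projected onto the skin
  (about 80 markers, emulating the 79-marker experimental layout), or
  Poisson-disk samples at a minimum distance.
* **true poses** — a prescribed glide-and-tilt model maps each
  knee-flexion angle (0/30/60/90 degrees) to a distinct pose; the
  coefficients are fixtures chosen for smooth, recoverable variation,
  not claims about real patellofemoral kinematics.
* **noise** — `add_noise()` jitters markers isotropically and/or biases
  the thickness, emulating skin movement; the four lower-leg markers
  exist in both a CT and a synthetic motion-capture frame linked by a
  known transform, so the frame-transfer stage is testable end to end.

What the phantom does *not* emulate: anatomical bone detail, skin
deformation under muscle contraction, marker-attachment error, and the
CT segmentation itself. Passing tests on the phantom therefore
demonstrate the estimator's internal correctness and its behaviour
under controlled geometry and noise — not clinical accuracy on real
knees.

## What the estimator can and cannot resolve

Two structural facts dominate the accuracy picture, and both are
visible in the test suite's measurements rather than assumed:

1. **A discretization floor.** With markers ~10 mm apart on curved
   skin, the marker nearest a face's normal ray sits several
   millimetres from the ray's skin intersection; over the patellar
   margin (local curvature radii of 5–10 mm) this mis-sampling
   contributes a mean `|d − eps|` of roughly a millimetre per face even
   at the true pose. On the constructed scene whose markers lie exactly
   at `eps` along the normals the floor vanishes and the truth is an
   exact fixed point of the optimizer; on the realistic scene the
   fixed-step search can wander within its quantization band around
   the truth.
2. **Weak observability of some DOFs.** Translation along the
   anteroposterior axis is strongly constrained (every face's `d`
   responds directly); in-plane translations are moderately
   constrained; rotations — above all rotation about the
   anteroposterior axis — move the surface by only ~0.3 mm per degree
   at the relevant lever arms, below the floor, so the objective is
   nearly flat there and the fixed-step descent stalls within a few
   degrees of the truth. Local minima in which no single (or paired)
   ±h move improves `S` exist and trap a substantial fraction of
   strongly perturbed starts. This mirrors the method's published
   real-data accuracy envelope (errors approaching 10 mm / 10 degrees)
   and the open status of its local-minimum risk; the acceptance test
   records the measured recovery statistics as-is instead of relaxing
   its bar.

## Problem sizes

The shipped validation workloads are sized for a single CPU: the
default phantom uses a 1280-face bone (remeshed to ~1000 faces at
3 mm, ~500 in the analysis band), a ~2300-face skin and ~80 markers;
recovery experiments use 20 perturbed starts; the optimizer-contract
checks use a coarser 320-face bone over 100 starts; the live factorial
smoke test runs an 8-condition × 1-angle × 2-repetition subset, with
the full 3×3×3×4×10 design exercised as an enumeration. One
registration on the default phantom takes well under a second; the
whole validation suite runs in a few minutes.

## Known limitations

* Static trials only; no tracking across frames.
* The thickness map is trusted as measured; muscle contraction or skin
  slide between CT and capture violates this silently (use
  `add_noise()` to bound the effect).
* The optimizer is local with a fixed step: no restarts, no step decay,
  accuracy floor of `h` per DOF, and a real local-minimum rate from
  strongly perturbed starts.
* Remeshing assumes a closed, manifold bone mesh; the skin may be an
  open patch but must be seen by the anterior bone normals.
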