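# patmap

Estimation of the three-dimensional pose of the patella (kneecap) from
skin-surface markers and a CT-derived bone mesh — the setting where a
motion-capture system and a CT scan are available but biplane
fluoroscopy is not.

## The method

The patella's local coordinate system is described by six degrees of
freedom

    Q = (px, py, pz, thx, thy, thz)

with positions in mm and Cardan x-y-z angles in degrees. Two per-face
quantities connect the bone to the skin:

* **soft-tissue thickness** `eps_i` — measured once from CT-frame
  geometry as the distance from bone face `i`'s centroid, along its
  outward normal, to the skin surface;
* **vertical distance** `d_i` — at a candidate pose, the signed
  projection onto that (posed) normal of the skin marker closest to the
  normal ray.

Only faces whose thickness falls inside a configured band (the
*analysis area*, default 0–20 mm) contribute. The pose estimate
minimizes the **surface mapping error**

    S(Q, M, E) = sum_i | d_i − eps_i |

over the analysis area, using a fixed-step derivative-free coordinate
descent: every sweep tries `q_i`, `q_i + h` and `q_i − h` for each DOF
(`h` = 0.5 mm or degree) and keeps the best, until a full sweep accepts
no move. Around the estimator the package provides:

* isotropic remeshing of the bone mesh to a target edge length
  (default 3 mm);
* grid and Poisson-disk (minimum-distance) marker generation on a skin
  mesh;
* least-squares (Kabsch) rigid fitting for the motion-capture → CT
  frame transfer from four lower-leg markers;
* a full-factorial parameter-selection study (edge length × thickness
  threshold × marker distance over knee angles and repetitions) with
  rank-based scoring, where each condition's total score is the sum of
  its six per-DOF error ranks and the minimum total wins;
* a synthetic knee phantom — tapered, ridged superellipsoid bone under
  a heightfield skin with an inhomogeneous soft-tissue profile — with
  known true poses per knee-flexion angle, for validation without any
  CT or motion-capture data;
* STL/PLY/OBJ mesh and CSV/TRC marker input and output, plus a small
  command line (`inst/cli/patmap`).

## Worked example

```r
library(patmap)
scene <- make_phantom(knee_angle = 30, seed = 7)   # synthetic knee at 30 deg flexion
scene
#> phantom_scene: knee 30 deg, 1280 bone faces, 2346 skin faces, 83 markers
#> pose6: p = (0.900, -2.400, -0.600) mm, theta = (3.600, 1.200, -0.900) deg

model <- build_surface_model(scene$bone, scene$skin, scene$true_pose,
                             mapping_params())
model
#> surface_model: 1000 bone faces, 504 in analysis area
#>   soft-tissue thickness 3.6-19.8 mm (median 6.0)

res <- register_scene(scene, perturb = 10, seed = 42, model = model)
res
#> registration_result: S = 582.255 mm after 22 sweeps (converged)
#> pose6: p = (0.831, -2.564, -0.777) mm, theta = (2.258, 1.963, 1.383) deg
#> errors vs truth:
#> pose6: p = (-0.063, -0.176, -0.168) mm, theta = (-1.353, 0.743, 2.254) deg
```

The first block builds a phantom whose true pose is known (shown under
the scene). `build_surface_model` remeshes the bone to 3 mm, measures
per-face soft-tissue thickness and keeps the 504 faces inside the
0–20 mm band. `register_scene` starts from a pose perturbed by up to
±10 mm/deg, descends in 0.5-unit steps and converges after 22 sweeps;
the last line gives the signed per-DOF errors of the estimate against
the truth — positions recover to a fraction of a millimetre here, while
the angles (especially rotation about the anteroposterior axis, the
weakly observable DOF at 10-mm marker spacing) carry a degree or two.

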