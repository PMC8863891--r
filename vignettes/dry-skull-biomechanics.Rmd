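---
title: "Dry-skull bite forces and muscle-constrained gape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dry-skull bite forces and muscle-constrained gape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryskull)
```

## The model

`dryskull` implements the classic *dry-skull method* for estimating bite
force from skeletal material, plus a kinematic model of how muscle strain
limits gape. The chain has three algebraic stages and one kinematic stage.

**1. Contraction force.** A muscle's force-generating capacity is
proportional to its physiological cross-sectional area, approximated as
reconstructed volume over length, times an assumed isometric muscle stress
$\sigma$:

$$F_{mus} = \frac{V}{L}\,\sigma\,c \times \begin{cases}2 & \text{bilateral}\\ 1 & \text{unilateral}\end{cases}$$

with $\sigma = 0.3\ \mathrm{N\,mm^{-2}}$ and a correction factor $c = 1.5$
compensating for the systematic underestimate of CSA when pennation is not
modelled. Because the bite is produced by both sides of the skull, forces
are doubled here — once, at this stage, and never again downstream.

**2. Resultant force on the mandible.** The contraction force acts along
the muscle's line of action; only its vertical component adducts the jaw.
With $\alpha$ the deviation of the line of action from vertical in the
sagittal plane and $\beta$ the same in the coronal plane,

$$F_{res} = F_{mus}\cos\alpha\cos\beta .$$

**3. Bite force.** The mandible is a third-class lever rotating about the
jaw joint. A muscle inserting at moment arm $L_{in}$ delivers, at a bite
point with moment arm $L_{out}$,

$$F_{bite} = F_{res}\,\frac{L_{in}}{L_{out}} .$$

Per-bite-point totals are sums over the eight adductors; the depressor
(`mDM`) is carried through the tables but excluded from all adduction sums.
Mechanical advantage is defined as $MA = \sum F_{bite} / \sum F_{res}$,
i.e. the $F_{res}$-weighted mean of the lever ratios. This definition (and
not a single in/out ratio) is what reproduces published MA tables in which
the numerator and denominator come from different tables.

**4. Gape limits.** Jaw opening is a rigid rotation of the mandible about
the axis through the two jaw-joint centres. Each muscle is proxied by one
or two straight cylinders joining the anteriormost ("1") and posteriormost
("2") extents of origin (cranium-fixed) and insertion (mandible-fixed).
Strain is length at gape $\theta$ over length at the resting gape.
Sarcomere cross-bridge overlap limits tension: full tetanic force is
possible up to ~130% of resting length and any tension up to ~170%. The
*optimal* and *maximum* gape limits are the first sampled angles at which
any adductor cylinder reaches those strains.

## Assumptions

* All adductors are simultaneously and fully active; no activation
  dynamics, no force–length curve beyond the two strain thresholds.
* Pennation enters only through the scalar correction $c$.
* Muscle lines of action are straight. Curved wrapping paths are
  deliberately not modelled during opening: their stretch cannot be
  measured objectively, and straight chords give a conservative,
  reproducible strain.
* The craniomandibular joint is a pure hinge; anteroposterior (palinal)
  translation, present in some of the taxa this method is applied to, is
  out of scope.
* Lever arms are straight-line 3D distances from the joint centre. The
  alternative (sagittal-projected) reading is supported by projecting
  coordinates before measurement; for tables of published levers the
  distinction is moot because levers are inputs there.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `stress_sigma` | 0.3 | N/mm² | isometric muscle stress |
| `correction_factor` | 1.5 | — | dry-skull underestimation correction; 1 = uncorrected |
| `bilateral` | TRUE | — | sum forces over both sides |
| `resting_gape` | 5 | deg | pose at which strains are 1; small open angle required by the length–tension relation |
| `step` | 0.5 | deg | opening-cycle sampling increment (one animation frame) |
| `optimal`, `maximum` | 1.3, 1.7 | — | strain limits of optimal / any tension |

## Numerical choices

* **Grid detection, no interpolation.** Gape limits are reported as the
  first sampled angle at or above threshold, mirroring keyframe-based
  opening cycles; published angles are multiples of 0.5°. The convention
  "first frame at/above" can differ by one step from "last frame below";
  halving the step never moves an estimate by more than the coarser step
  (property-tested).
* **Ties** between cylinders crossing on the same frame are all reported,
  sorted lexicographically.
* **Opening sense** is auto-detected as the rotation direction that
  lengthens the adductor set; geometry for which both directions shorten
  it (e.g. a planar cylinder at 180°) is rejected or, in the synthetic
  planar constructor, flagged `non_adductor`.
* **Mesh volumes** use the divergence theorem on closed, consistently
  oriented triangle meshes. Closedness is enforced (every directed
  half-edge paired with its reverse), not repaired; the error names the
  offending edges. Volume is orientation-normalised to be non-negative.
* **Angles** are folded into [0, 90]: downstream only cosines are used, so
  sign carries no information. A line of action orthogonal to a projection
  plane yields a 0° angle flagged as degenerate.
* **Degenerate inputs** error early with the offending record named:
  non-positive lengths or outlevers, missing inlevers, zero resultant-force
  totals in MA, coincident joint points.

## The synthetic generator

`make_taxon()` emulates the geometric and statistical structure the
analysis consumes — nothing more: a bilateral jaw with a mediolateral
rotation axis, eight (configurable) adductors with insertions low on the
mandible and origins high in the adductor chamber, three bite points with
outlevers strictly decreasing anterior to posterior, anterior/posterior
cylinder pairs per muscle, and a retroarticular depressor that shortens on
opening. Muscle volumes are assigned so the pipeline recovers any force
targets exactly (the linearity of the chain in volume makes this an exact
inverse, used by the round-trip tests at 10⁻⁶ relative). Default dimensions
(100 mm skull, 20 mm joint separation) sit in the size range of the small
theropod skulls this method is typically applied to, and the default
geometry yields optimal gapes of roughly 20–30°, matching published
estimates for herbivorous theropods. All randomness flows from one seed
through a private RNG stream; the caller's RNG state is untouched.

What the generator does **not** emulate: anatomical muscle shapes (only
V, L, α, β and anchor points matter to the chain), CT volumes, taphonomic
deformation, curved muscle paths, or measurement error in landmark
placement. Passing round-trip tests therefore demonstrates the chain's
internal consistency, not the accuracy of any particular reconstruction.

`make_planar_gape_model()` is the analytic scaffold for the kinematics: a
single cylinder in the sagittal plane whose strain obeys the law of
cosines, $l(\theta)^2 = r_o^2 + r_i^2 - 2 r_o r_i \cos(\phi_0 + \theta -
\theta_{rest})$, so exact crossing angles come from `planar_strain_crossing()`
by inversion and the grid scan can be checked against a closed form.

## Fixtures and reproduction tolerances

`oviraptor_fixtures()` ships published measurement tables for four
oviraptorosaurian taxa (*Incisivosaurus*, *Citipati*, *Khaan*,
*Conchoraptor*) exactly as printed, at 1 decimal place. Two tolerances
apply when reproducing them:

* single-step recomputations from printed inputs of the same magnitude
  agree to about the print quantum (±0.05 N);
* cross-table chains inherit the rounding of their printed inputs; totals
  agree to ≈0.1% for three taxa.

Two known limitations of the printed sources, found during verification and
reproduced honestly rather than patched:

* printed per-muscle forces carry the rounding of their printed inputs, so
  recomputed values deviate by up to ≈0.4 N at the largest taxon's
  magnitudes (≈0.15% relative) — larger than the print quantum;
* the *Citipati* bite-force table is not internally consistent with its
  force table: the printed per-muscle bite forces imply resultant forces
  2–6% below the printed ones, so the recomputed chain gives totals ≈3.4%
  above the printed sums (e.g. 516.0 vs 499.0 N posteriorly). The package
  reports the recomputed values; the fixture stores the printed ones.

Published gape angles for these taxa were derived from deposited 3D
attachment coordinates that are not shipped here; the kinematic stage is
instead validated by the analytic planar oracle (200 randomized cases),
resting-strain, ordering and step-halving properties. Users with the
deposited geometry can export landmarks and reproduce the printed angles
via `jaw_model_from_landmarks()` + `find_gape_limits()`.

## Problem sizes

The test suite and acceptance script run entirely at desk scale: 4 taxa ×
8 muscles × 3 bite points for the force chain; 200 randomized planar
models (plus 20 step-halving pairs) for the kinematics; icospheres up to 4
subdivisions (5120 triangles) for mesh volumetrics; 8-muscle synthetic
taxa for round trips. A full run takes well under a minute.

## A worked example

```{r example}
fx <- oviraptor_fixtures()
ft <- force_table(fx$Incisivosaurus$muscle_table[, 1:5])
bt <- bite_table(ft, fx$Incisivosaurus$levers$inlever,
                 fx$Incisivosaurus$levers$outlever)
round(bt$totals, 1)
round(mechanical_advantage(bt), 3)
```

```{r gape-example}
m <- make_planar_gape_model(30, 20, 60)
find_gape_limits(m)
planar_strain_crossing(30, 20, 60, 1.3)  # exact crossing, off-grid
```
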