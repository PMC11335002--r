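---
title: "Digital bending experiments: models, constraints and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital bending experiments: models, constraints and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vertbend)
```

## The model

An intervertebral joint is modelled as two rigid vertebral meshes articulated
about a fixed centre of rotation (COR). For amphicoelous or acoelous centra
the COR is the midpoint of the intervertebral space — the midpoint between the
caudal endplate centroid of the anterior vertebra and the cranial endplate
centroid of the posterior one, each centroid being the mean of the four
extreme endplate landmarks (dorsal, ventral, left, right). For procoelous
(ball-and-socket) centra it is the centre of a least-squares sphere fitted to
points on the condyle. The joint frame is a right-handed orthonormal triad at
the COR: +x caudal (axial rotation), +y dorsal (lateral bending), +z
anatomical left (sagittal bending). Positive z rotation is dorsiflexion,
positive y rotation left lateroflexion, positive x rotation left axial
rotation; only the axis-to-motion assignment is anatomically fixed, the signs
are package conventions.

A bending experiment rotates the posterior vertebra about one frame axis in
0.5 degree increments, to a cap of 90 degrees in every direction, and records
the largest angle at which no constraint is violated. Three constraint
families are evaluated at every pose:

* **bone** — the volume of the boolean intersection of the two meshes,
  normalized by the mean enclosed volume of the two vertebrae, must not
  exceed the intersection threshold. A small positive threshold is allowed so
  that slightly inflated (smoothed, wrapped) surfaces can slide past one
  another.
* **disc** — the relative length change `(d - d0)/d0` of each endplate
  locator pair (dorsal, ventral, left, right extremes of the facing
  endplates) must stay within the strain allowance, in both tension and
  compression by default (`disc_mode = "tension"` restricts discs to
  tension-only).
* **capsule** — likewise for the zygapophyseal locator pairs, which join the
  cranial and caudal extremes of the articulating post- and prezygapophyseal
  facets on each undamaged side; tension and compression are always both
  limited, since zygapophyseal joints are reported limited by either.

Joint translations are not modelled. Epaxial musculature and interspinous
ligaments are likewise outside the model: they are poorly constrained in
fossils, which is the population of specimens the pipeline targets.

Reconstruction uncertainty is explored with a full factorial grid of 27
variants: joint spacing multiplier {0.9, 1.0, 1.1} (optimal spacing ±10%),
intersection threshold {0.25%, 0.5%, 0.75%} of the mean vertebral measure,
and strain allowance 0.5 scaled by {0.9, 1.0, 1.1} — i.e. {0.45, 0.50, 0.55}.
"Optimal spacing" itself is an input: the synthetic generator emits it and
real-data manifests must supply it, because articulating real scans is an
interactive judgement that the pipeline deliberately consumes rather than
reproduces.

Disarticulation — the loss of all projected overlap between left and right
facet pairs, projected along the facet normal at neutral — is detected and
recorded per sweep but does not stop the sweep; it is diagnostic information
used downstream (the 0.75% threshold variants are dropped before
aggregation, because permissive bony thresholds let joints disarticulate in
axial rotation before the threshold binds).

## Post-processing and statistics

Per joint, lateroflexion and axial rotation are averaged across left and
right and doubled (full amplitude); with asymmetric damage the intact side
alone is doubled. Sagittal ROM is the sum of dorsiflexion and ventroflexion —
the two sagittal directions are anatomically distinct, so they add rather
than average. Variants at the 0.75% threshold are removed first (27 to 18),
and the surviving variants are aggregated by their mean. Ternary mobility
proportions divide each direction's processed ROM by their sum; the
sagittal–lateral class is "sagittal-dominant" when sagittal/(sagittal +
lateral) exceeds 0.5, with ties assigned to lateral-dominant (the
sagittal-dominant region is defined by a strict inequality); `dominant` is
the argmax of the three proportions. Regions split anterior/posterior at the
diaphragmatic joint (mammals) or at floor(n/2) (other groups).

Relative stiffness in a bending plane is the bending-moment proxy (lever arm
times centrum area, mm³) divided by the cube of the mean centrum length and
by the ROM in that plane. The cubic size correction makes the quantity
dimensionless per degree and invariant under isotropic scaling — the property
the correction exists to provide; the exponent is exposed as a parameter
(`size_exponent`) since only relative comparisons are meaningful. The
sagittal lever runs from the COR to the arch apex of the anterior vertebra
(the joint's namesake), the lateral lever is the mean COR-to-lateral-endplate
distance of the two facing endplates.

Inference uses a permutation MANOVA with randomization of residuals (RRPP):
sequential (type-I) term entry in formula order; for each term the reduced
model with the preceding terms is fitted, its residuals are permuted as whole
rows, and the trace-based pseudo-F
`(tr(SSCP_term)/df_term)/(tr(SSCP_resid)/df_res)` is recomputed;
`p = (1 + #{F* >= F_obs})/(1 + n_perm)` with 10 000 permutations by default
and a mandatory, recorded seed. The trace statistic was chosen for its
robustness and its exact equivalence, on Euclidean responses, to the
sums-of-squares decomposition of distance-based permutation MANOVA (the test
suite cross-checks the observed SS, R² and F against `vegan::adonis2`).
Nested factors (species within group) are written with the standard formula
operators; the dummy coding of a nested design is rank-deficient, so aliased
columns are dropped left-to-right (preserving sequential order) and only a
term losing *all* of its columns is an error.

## Numerical design

**Contact semantics.** A pose violates the bone constraint when the overlap
fraction strictly exceeds the threshold. At threshold zero this reduces to
"do the surfaces intersect?", which is decided exactly by bounding-box-pruned
triangle–triangle tests plus a containment probe. This makes the analytic
oracles exact: a flat-endplate cylinder joint with radius r and gap g is
bone-limited at exactly `2*atan(g/(2r))`, and the swept ROM equals
`floor(2*atan(g/(2r))/step)*step` (asserted over r in {5,10,20} mm and g in
{1,2,4} mm).

**Intersection volumes.** When the surfaces do cross, the intersection volume
is estimated by counting deterministic grid-cell centres inside both meshes,
on a grid spanning the axis-aligned bounding box of the *surface-crossing
region* (padded by 25%), not of the whole meshes. Tracking the penetration
lens keeps the estimate accurate at shallow contact and — importantly for
paired structure-removal designs — independent of geometry far from the
contact, so adding or removing a distant structure cannot perturb the
estimate. Inside/outside queries use parity ray casting with fixed
"irrational" ray directions and automatic fallback directions on grazing
hits; meshes are rigid groups of closed components (a merged mesh behaves as
the union of its parts). The accuracy bar the package holds itself to — grid
agreement with the exact boolean within 2% on axis-aligned box pairs at a
pitch of 1/50 of the box edge — is asserted in the tests.

**Mesh measures.** Single closed components use the exact divergence-theorem
volume; rigid groups with overlapping components use the deterministic grid
(union) volume; groups with disjoint components sum the exact per-component
volumes. In paired experiments (spines removed, intercentra merged/absent)
the overlap normalization and lever arms are kept at the values of the intact
vertebrae, so ROM differences isolate contact geometry.

**Shared sweeps.** Pose metrics (overlap, strains, disarticulation) do not
depend on the threshold or allowance, so each joint is swept once per spacing
multiplier and direction and the 9 threshold-allowance variants are read off
the recorded profile; a sweep stops as soon as the most permissive variant is
violated. Reruns are byte-identical.

**Degenerate inputs.** Meshes are repaired on load (exact duplicate-vertex
weld, degenerate-face drop, unreferenced-vertex drop, connected-component
recovery); empty or fully collinear inputs are errors. Coincident endplate
centroids trigger a zero-spacing warning; coplanar condyle points are an
ill-conditioned-fit error; a constraint violated at neutral yields ROM 0 with
a warning; joints that fail assembly inside `run_experiment` are recorded as
missing and the run continues.

## The synthetic columns

The generator builds vertebrae from analytic primitives — an
elliptical-section centrum (lathe about x) with paraboloid endplate dimples
approximating shallow spherical concavity (depth 10% of the centrum height by
default), box arch and spine, and flat zygapophyseal facet plates — so every
landmark, contact angle and strain limit has a closed form. Default
dimensions (centrum 20 x 14 mm section, 30 mm long, 4 mm joint space) are
those of a mid-sized tetrapod trunk vertebra. A vertebra's prezygapophyses
articulate with the preceding vertebra's postzygapophyses and therefore take
the preceding position's facet angle, so every joint has a geometrically
consistent facet pair and the per-position angle profile acts per joint.
Facet capsule clearance defaults to `2 - 1.2 sin(angle)` mm: horizontal
thoracic-style facets have loose, "open" capsules, vertical lumbar-style
facets are tightly apposed, which is what gives horizontal facets their
axial-rotation permissiveness in the model.

The presets encode the mechanics behind the comparative contrasts, designed
from the closed forms before any sweep was run:

* `mammal_like` — sigmoid facet-angle profile, ~5 deg (horizontal) anteriorly
  to ~85 deg (vertical) behind the mid-column diaphragmatic position. With
  the default geometry the anterior disc limit is ~14.3 deg/side in lateral
  bending (allowance x gap / centrum half-width) while horizontal facets
  leave axial rotation disc-limited near 25 deg/side, so anterior joints are
  axial-dominant; vertical posterior facets block axial rotation at a few
  degrees and cap lateral bending below the sagittal capsule limit, so
  posterior joints are sagittal-dominant.
* `reptile_like` — uniform 45 deg facets placed high and medial with tight
  (0.8 mm) capsules and a round centrum: the narrower centrum relaxes the
  lateral disc limit while the oblique facets' bone contact restricts axial
  rotation, yielding lateral dominance throughout.
* `cynodont_like` — horizontal anterior facets with posterior joint spacing
  reduced to 60%: anterior axial rotation with posterior lateral
  stabilization via the tighter disc.
* `sailback` — neural spines elongated up to 15x at mid-column and fanned
  craniocaudally (rake -35 to +35 deg); the fan keeps the analytic tip
  contact angle above the joints' dorsiflexion ROM, so the sail does not
  limit motion — the joint itself does.
* `tuatara_like` — long (6 mm) notochordal joint spaces, staggered facets
  with a compliant sagittal capsule, and a crescent intercentrum at every
  joint. The crescent's caudal face is tilted 6 deg so a ventroflexing
  posterior endplate meets it nearly face-on: overlap then grows with a large
  contact area and crosses the bony thresholds well before the disc limit,
  whereas in lateral bending only a corner of the crescent engages and the
  threshold is never reached. This is what makes intercentra block
  ventroflexion specifically.

What the generator does *not* emulate: real endplate curvature and rugosity,
non-planar interlocking facet surfaces, ribs, asymmetric taphonomic
distortion beyond whole-side zygapophysis loss, and scan noise
(non-manifold meshes, holes). Passing the end-to-end tests therefore shows
that the engine recovers the functional consequences of idealized facet
orientation, spacing and accessory structures — not that it reproduces any
particular specimen's ROM.

## Problem sizes and reproducibility

The test suite and the acceptance script use short columns (2–6 vertebrae at
24 lathe segments), the 3 x 3 x 3 grid, 40 to 500 replicates with 199 to 999
permutations for the statistical calibrations, and 10 000 permutations where
the default count itself is the quantity of interest. All randomness (MANOVA
permutations, simulated responses, optional landmark noise) sits behind
explicit integer seeds; the geometry pipeline is fully deterministic.

## Known limitations

* The intersection-volume estimator is a grid method: fractions within ~1–2%
  of a threshold can resolve one 0.5 deg step differently at a different
  `grid_n`. The contact decision at threshold 0 is exact.
* Planar cut capping uses a centroid fan, correct for the convex
  cross-sections the generator and spine-truncation produce; strongly
  non-convex cut sections would need constrained triangulation.
* Locator strain is purely geometric (length change), with no
  force-deformation model; stiffness is relative, never N·mm/deg.
* Coupled multi-axis rotations and joint translations are out of scope, as
  is continuous-angle root finding: the experiment is defined incrementally.
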