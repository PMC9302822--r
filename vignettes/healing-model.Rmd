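---
title: "A coupled finite-element / fuzzy-logic model of secondary fracture healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled finite-element / fuzzy-logic model of secondary fracture healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`callusim` simulates secondary (callus-mediated) bone healing in a plated
diaphyseal segment as a daily feedback loop between mechanics and biology:

1. **Mechanics.** A linear-elastic, small-strain tet4 finite-element solve
   of the whole construct (bone, callus, plate, screws) under a static
   2.1 kN load tilted 10 degrees in the frontal and sagittal planes, with
   the distal end fixed.  Each callus element yields two stimuli from its
   principal strains: the hydrostatic strain
   $\varepsilon_{hyd} = (\varepsilon_1+\varepsilon_2+\varepsilon_3)/3$
   (signed volumetric change) and the distortional strain
   $\varepsilon_{dis} = \tfrac{1}{\sqrt2}\,[(\varepsilon_1-\varepsilon_2)^2
   +(\varepsilon_2-\varepsilon_3)^2+(\varepsilon_3-\varepsilon_1)^2]^{1/2}$
   (shape change).

2. **Biology.** A Mamdani fuzzy controller maps seven inputs per callus
   element — the two strain stimuli (in percent), local blood perfusion,
   neighbour perfusion, local bone and cartilage concentration, neighbour
   bone concentration — through 19 linguistic rules (angiogenesis,
   intramembranous ossification, chondrogenesis, cartilage calcification,
   endochondral ossification, tissue destruction) to three daily changes:
   perfusion, bone and cartilage, each in percent per day.  Inference is
   classical Mamdani: min AND, $1-\mu$ negation, clipping implication, max
   aggregation, centroid defuzzification on a 1001-point uniform grid of
   the $[-10, 10]$ %/day output universe.

3. **State update.** Per element the deltas are added, perfusion/bone/
   cartilage are clamped to $[0,100]$, bone+cartilage are rescaled
   proportionally if they exceed 100, and connective tissue is the
   remainder, so the three tissue fractions always sum to 100%.

4. **Material update.** Each callus element's stiffness follows the tissue
   mixture $E = 4000\,c_{bone} + 40\,c_{cart} + 3\,c_{conn}$ MPa and
   $\nu = 0.3\,c_{bone} + 0.45\,c_{cart} + 0.3\,c_{conn}$ (weights as
   fractions of one).  The loop then repeats; one iteration represents one
   day and the default run is 60 days.

The state lives on the callus only; cortical bone, the cancellous core and
the stainless-steel implant keep fixed properties (16,700 / 155 / 193,000
MPa; an optional transversely isotropic cortical variant uses 10,000 MPa).
The mixture deliberately uses a 40 MPa cartilage coefficient although the
base-material table lists 200 MPa for standalone fibrocartilage; the two
values come from different sources in the constitutive literature and are
not reconciled — the mixture coefficients are overridable.

## Synthetic geometry

Because the healing dynamics depend on the strain field and the rules, not
on anatomical curvature, the model replaces a real femur by an idealized
straight segment: a hollow cortical cylinder (outer radius 13.5 mm, wall
5 mm) with a cancellous core, a 20 mm transverse gap, an ellipsoidal
callus envelope (semi-axes 30 mm axial, 25 mm radial) filling the gap and
collaring both fragment ends, and a lateral plate (12 x 5 mm section)
connected by four transcortical screws (radius 2.25 mm at z = -40, -25,
+25, +40 mm from the gap centre).

Meshing is voxel-based: feature planes (fracture faces, plate faces, screw
columns, segment ends) are inserted exactly into a structured grid, every
interval is subdivided to the target edge length, and each cell splits
into six tetrahedra sharing a diagonal, which is always conforming and
positively oriented.  Curved boundaries are staircase approximations
classified by a 3x3x3 sub-cell majority vote, which keeps region volumes
accurate at coarse resolution (the callus volume test against the analytic
ellipsoid-minus-bone volume passes within 5% at the default density).  The
coarse preset (4.5 mm edges, roughly 12,000 tets, of which about half are
callus) was chosen as the smallest density whose region volumes and strain
fields are stable enough for the qualitative healing sequence; 1.0 mm is
the medium preset for convergence studies.  Two runs with identical
parameters produce bit-identical meshes.

**What the voxel geometry does not emulate:** anatomic curvature, the
trochanter and femoral head, screw threads and plate holes (threads are
abstracted to a pretension slice, holes to node-to-node interfaces), and
smooth curved surfaces.  Passing tests on this geometry demonstrate the
coupled dynamics and orderings, not patient-specific strain magnitudes.

## Fixation mechanisms

* **LP (locked plate):** every interface shares nodes (bonded), and the
  plate stands off the bone by `plate_offset` (default 0.5 mm, a minimal
  clinical elevation).  No contact computation.
* **DCP (dynamic compression plate):** the plate sits flush; the
  plate-bone interface and the distal (dynamic) screws are duplicated-node
  penalty contact pairs with Coulomb friction ($\mu = 0.3$): unilateral
  normal contact at the plate-bone plane, head bearing along the screw
  axis plus zero-clearance radial shaft bearing at the plate hole, and
  radial contact at the near-cortex shaft passage.  Thread engagement in
  the far cortex stays bonded — without resolved threads the screw needs
  an axial anchor or the 500 N pretension could not equilibrate.  The
  pretension is applied as equal-and-opposite axial force pairs across one
  element slice of each distal screw shaft (the "first thread" location,
  mid-near-cortex).

The load is applied on the proximal end face along the tilted direction,
together with the couple of the resultant acting 20 mm medial of the shaft
axis (`head_offset`).  The lever arm stands in for the femoral head: it
restores the physiological bending so the periosteal surface strain of the
intact cortex is about 0.15%, the level real femora see during stance.  A
purely axial centroid load on a straight cylinder leaves the periosteum at
~0.04% strain, an order of magnitude below any mechanoregulatory band, and
the collar then never ossifies.

## Fuzzy calibration

The rule table is shipped verbatim (`inst/extdata/tissue_rules.tsv`); "-"
means the variable is absent from a rule and "Not" negates a term.  The
membership functions are trapezoids.  Their breakpoints are calibration
parameters, not measurements; all are overridable via the `[fuzzy]` config
section:

* distortional strain (%): zero up to ~2, low 2-10 (the callus-friendly
  window), destructive beyond 10-15;
* hydrostatic strain (%): destructive beyond |5-8|, medium -8..-1,
  compression-biased as in Claes-Heigele-type diagrams.  The inner edges
  of the osteogenic "low" bands reach down to a disuse threshold of
  0.005-0.02% hydrostatic strain (about 400-1500 microstrain axial, a
  mechanostat-type cutoff).  This inner edge is the single most sensitive
  calibration choice: hydrostatic strain is only ~13% of axial strain in a
  near-uniaxial state, so periosteal collar tissue on intact cortex tops
  out near 0.05-0.1% hydrostatic.  If the osteogenic band starts at 0.1%,
  well-perfused tissue on bone surfaces is classified as quiescent, the
  collar never mineralizes and the run freezes far short of bony union —
  contradicting the biology the rules encode (intramembranous apposition
  on existing bone under good perfusion and low strain).  Raising the
  threshold also delays or caps the endpoint ossification; lowering it
  towards zero removes the quiescent hole entirely and lets fully
  unloaded tissue ossify, which is equally wrong.
* concentrations and perfusion (%): low below ~30, medium 10-90, high
  above 70;
* outputs (%/day): decrease (-10,-10,-5,0) and increase (0,5,10,10) on
  [-10,10], implying single-digit daily changes.

Where the table leaves room, the package reads it conservatively: "About
zero" on distortional strain is the "zero" term; the destruction rules use
the same "decrease" consequent as every other rule; if no rule fires the
element does not change (quiescence).

## Neighbour topology and perfusion boundaries

Callus elements interact through face adjacency plus ghost sources: faces
shared with cortical elements contribute 100% bone and the cortex band's
perfusion (100% away from the gap, 0% within a 5 mm avascular band at the
fragment ends); exterior callus faces carry the 30% extraosseous periphery
supply; faces towards the cancellous core carry the 30% medullary supply
from day 10.  Neighbour values aggregate by maximum (configurable to
mean), which makes vascularisation and ossification propagate as fronts
from the boundaries inward.  Because the front advances element-by-element
per day, coarse meshes heal proportionally faster than fine ones; the
60-day coarse run compresses the real 8-week sequence, and day indices
should be read as ordinal stages rather than calendar days when comparing
against finer models.

## Numerical choices

* Sparse symmetric assembly with a constant sparsity pattern; the
  lambda/mu split of each element stiffness is precomputed so the daily
  material update only rescales two vectors; the symbolic Cholesky
  factorization is computed once and refreshed numerically per day.
* Contact: node-to-node penalty springs (normal 1e5 N/mm, tangential
  1e3 N/mm per pair), permanent 1e-2 N/mm stabilization springs so
  separated bodies stay non-singular and the sparsity pattern constant.
  Stick/slip by active-set iteration: sticking pairs carry tangential
  springs, slipping pairs get under-relaxed applied Coulomb forces
  (relaxation 0.7, halved every 15 stalled iterations), warm-started from
  the previous day; at most 50 iterations to a 1e-3 N force tolerance,
  otherwise the run aborts.  The tangential penalty is kept an order of
  magnitude below the normal one because the stick/slip fixed point
  contracts at a rate governed by the tangential stiffness.
* Strain invariants per element (constant in a tet4), no nodal smoothing;
  principal strains by the closed-form trigonometric symmetric-3x3
  eigenvalue method with the `acos` argument clamped to [-1, 1]; the
  degenerate isotropic case returns three equal eigenvalues.
* Centroid defuzzification on a 1001-point grid; a zero aggregated area
  returns 0 %/day.  Trapezoid evaluation treats infinite outer breakpoints
  as open shoulders and zero-width ramps as step edges.
* The tissue update clamps each field to [0,100] first and then rescales
  bone+cartilage proportionally if their sum exceeds 100 (the alternative
  bone-priority clamp is noted but not used); connective tissue is floored
  at zero against rounding.

## Limitations

Static full weight-bearing over the whole healing time; no bone
resorption or remodelling after bridging; the callus envelope is fixed (no
growth); linear elasticity without poroelastic or viscoelastic soft-tissue
behaviour; isotropic cortical bone by default.  The voxel geometry
reproduces construct-level stiffness only approximately, so absolute
interfragmentary movements are indicative; the package's comparative
statements (LP vs DCP orderings, the healing sequence) are the quantities
the tests and the acceptance script actually compute.

The most consequential limitation is the resolution coupling described
above: neighbour-gated fronts advance per element per day, so at the
coarse preset the construct stiffens — and the strain stimuli fade — after
roughly three weeks, before the full callus volume has passed through the
chondrogenic/osteogenic window.  The coarse 60-day run therefore
understates the endpoint ossified fraction and the cartilage peak relative
to a fine-mesh simulation of the same rules; the acceptance script reports
the endpoint the model actually computes, and the comparative orderings
between fixation modes are unaffected.

## Running

```{r}
library(callusim)
cfg <- default_config()
cfg$run$iterations <- 60L
res <- run_healing(cfg)
summarize_healing(res)
```

The same run is available from the shell:

```sh
Rscript inst/scripts/callusim run --config run.yaml --out results/
Rscript inst/scripts/callusim compare --config run.yaml
```
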