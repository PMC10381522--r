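---
title: "Measuring enamel thickness on tooth-crown meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring enamel thickness on tooth-crown meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelmap)
```

## The measurement problem

Average enamel thickness (AET) is a standard comparative quantity in dental
morphology and palaeontology: the enamel volume of a crown (or part of it)
divided by a reference surface area. Classically the reference is the
enamel-dentine junction (EDJ) area, which is ontogenetically motivated — all
enamel is secreted by ameloblasts sitting on the EDJ. For worn teeth, however,
the measured enamel is the *residue* of secretion and wear, bounded by two
irregular surfaces: the EDJ on the inside and the outer enamel surface (OES)
on the outside. `enamelmap` therefore reports the modified sector parameters

$$\mathrm{SAET3D} = \frac{SV}{SAA}, \qquad
  SAA = \frac{SA_{edj} + SA_{oes}}{2},$$

and, in a bucco-lingual cross-section,

$$\mathrm{SAET2D} = \frac{SA}{SACL}, \qquad
  SACL = \frac{SCL_{edj} + SCL_{oes}}{2},$$

where $SV$ is the sector enamel volume, $SA_{edj}$/$SA_{oes}$ the sector
areas of the two bounding surfaces, $SA$ the sectional enamel area and
$SCL_{edj}$/$SCL_{oes}$ the sectional contour lengths. When the two bounding
surfaces coincide in size the denominators reduce to the classical ones
(`saet3d(..., classical = TRUE)` reports the EDJ-only value alongside).

The sectors themselves are anchored in occlusal morphology rather than in an
external coordinate system: the *occlusal surface* (bounded by the marginal
and cusp ridges) is delineated on the OES, projected onto the EDJ, and split
by the *midline* — the mesio-distally running chain of per-section deepest
points — into the inner slopes of the buccal and lingual cusps.

## Pipeline

Starting from a triangulated enamel-cap mesh (STL/PLY/OBJ, µm or mm) that
contains both the OES and the EDJ sheets:

1. **Repair and centre.** Perforations (CT segmentation artefacts, pits)
   below a perimeter threshold are triangulated shut; the coordinate origin
   moves to the area-weighted surface centroid.
2. **Surface segmentation.** Each face is seeded *outer* or *inner* by the
   sign of the dot product between its outward normal and the ray from the
   mass centre to the face centroid, then labels are refined over
   edge-connected components: all but the two largest components are absorbed
   into the neighbour with the longest shared border. This uses exactly the
   two ingredients available on a raw mesh — point position and normal
   direction — and the component pass makes the result robust at the cervix,
   where the radial direction degenerates.
3. **Orientation.** The cervical edge — the closed borderline where the two
   classes meet — defines the tooth's own frame: origin at its
   arc-length-weighted centroid, z along the total-least-squares plane
   normal (signed toward the crown), x along the major principal axis of the
   projected edge, later re-aligned to the occlusal contour's principal axis.
4. **Occlusal contour.** After a cotangent-Laplacian mean-curvature analysis,
   cusp apices are detected as separated curvature maxima high on the crown;
   one crest candidate is chosen per angular sector around the apex midpoint
   (the outermost convex crest, scored by $\max(0,H)\,r^2$), and candidates
   are joined by minimal-cost paths with edge cost
   $\ell/(\varepsilon + \max(0, H))$, $\varepsilon = 10^{-3}\,\mathrm{mm^{-1}}$.
   Manual override points take precedence and are joined along geodesics —
   mirroring the semi-automatic practice on worn, pitted material.
5. **Sections and midline.** The cap is cut by `n_sections = 80` planes
   normal to the mesio-distal axis (bin midpoints over the occlusal
   contour's x-extent; `span = "crown"` covers the whole crown instead).
   Per section the deepest OES point inside the contour's y-interval becomes
   a midline vertex; ties within 1 µm resolve toward the previous section's
   ordinate (first section: toward y = 0).
6. **Sectors and report.** OES faces inside the contour are split by the
   midline; the same happens on the EDJ with the projected contours. Areas,
   volumes and SAET3D are reported per sector with slope-vs-occlusal
   percentage columns rounded half-up to two decimals.
7. **Topographic map.** Per-OES-vertex thickness as the unsigned distance to
   the nearest EDJ point, exported as a colour-mapped PLY.

## Numerical choices

* **Sector volume by prismatic columns.** A sector's enamel volume is
  integrated as $\iint (z_{OES} - z_{EDJ})\,dx\,dy$ over the sector's plan
  domain, evaluated per OES patch triangle with the EDJ sampled by vertical
  ray casting. Compared with closing each sector with ruled side-walls and
  applying the divergence theorem, the column integral has no wall
  self-intersection failure mode and makes buccal + lingual = occlusal hold
  exactly, which the report asserts as a leak check. Its assumption — that
  the occlusal enamel is single-valued over the crown plan — holds for the
  basins and inner slopes that the sectors measure.
* **Boundary faces by subdivision.** Faces straddling the contour or midline
  are partitioned by three levels of 4-way midpoint subdivision with
  centroid-rule assignment, rather than exact polyline cutting: fragments
  partition their parent exactly (so additivity is preserved to machine
  precision) and the residual boundary error falls by 8x per level.
* **Deepest-point search margin.** Midline candidates exclude 5% of the
  y-interval at each end: the interval endpoints are on the marginal-ridge
  crest itself, and mesh-resolution wiggles of the contour would otherwise
  let a crest or outer-wall vertex masquerade as a basin point.
* **Pit robustness.** With `pit_filter = TRUE`, candidates whose mean
  curvature falls below the 10th percentile of the section's candidates are
  suppressed before the minimum-z search — sharp concave outliers are pits,
  not groove floor.
* **Winding and welding.** STL input is triangle soup: vertices are welded on
  a 1 µm grid, winding is repaired by propagation over face adjacency, and
  components are oriented outward (a component nested inside another — the
  inner sheet of a closed shell — is oriented inward so that the signed
  volume of the enamel is positive).
* **Hole filling** closes boundary loops below 10% of the bounding-box
  diagonal (fan to the loop centroid); larger openings, such as the cervical
  rim of a single-surface model, are reported, not sealed.
* **Curvature sign and areas.** Mean curvature uses the cotangent Laplacian
  with barycentric vertex areas, positive on convex regions; boundary
  vertices are flagged and excluded from crest logic. At irregular-valence
  vertices (the icosphere's twelve seeds) the barycentric area is least
  accurate; crest detection is quantile-based and insensitive to this.

## The synthetic-tooth generator

Scan data of the studied molars is not redistributable, so the package
generates crowns with analytic ground truth. The default `tooth_spec()`
emulates a primate lower second molar at realistic scale: an elliptical
footprint of 11 x 9 mm, a flat-topped dome with steep cervical walls
(exponent 16, wall height 4 mm), two Gaussian cusps (height 1.2 mm,
s.d. 1.5 mm) at y = ±2.2 mm, a mesio-distal central groove (depth 0.8 mm,
s.d. 0.9 mm) whose floor — the analytic valley locus — lies exactly on
y = 0, and a uniform enamel thickness of 0.5 mm built by offsetting the OES
inward along the analytic surface normal, tapering to zero at the cervical
rim so the cap closes there, as real enamel does. Wear is a horizontal facet
truncating the cusp tips (exposing the EDJ if it cuts below it); perforations
are punched holes that exercise hole filling and the pit filter. Sphere-shell
fixtures (`make_sphere_shell`) provide closed-form oracles for areas, volume
and the thin-shell identity
$\mathrm{SAET3D} = \tfrac{2}{3}(R^3 - r^3)/(R^2 + r^2)$.

What the generator does *not* emulate: scanning noise, segmentation
artefacts beyond circular perforations, enamel thickness gradients, more
than two cusps, crown tilt relative to the cervical plane, and real
cervical-margin chipping. Passing tests therefore demonstrate the geometric
correctness and invariances of the algorithms, not their behaviour on every
pathology of fossil material — which is precisely why the contour and
midline accept manual overrides.

## Problem sizes and determinism

The test-suite and acceptance fixtures use a 0.25 mm target edge length for
crowns (~15,000 faces) and ~41,000 faces for the concentric shell; these
sizes keep the full suite in the minutes range while leaving discretization
errors an order of magnitude below the asserted tolerances. All randomness
(pit placement, displacement angles) sits behind explicit integer seeds;
identical input and configuration reproduce byte-identical reports.

## Worked example

```{r example, eval = FALSE}
fx <- make_two_cusp_crown(tooth_spec(thickness = 0.5, resolution = 0.25))
res <- run_pipeline(fx$cap$mesh, pipeline_config(n_sections = 80))
res$report
#> <tooth_report> synthetic
#>                                         quantity parameter  occlusal ...
#> 1                 Outer enamel surface area, mm2     SAoes 62.802988
#> 2              Enamel-dentine junction area, mm2     SAedj 65.228929
#> 3                             Enamel volume, mm3        SV 31.858092
#> 4 Three-dimensional average enamel thickness, mm    SAET3D  0.497659
```

The recovered SAET3D of 0.4977 mm differs from the construction thickness of
0.5 mm by 0.5%: the averaged-area denominator cancels the first-order
curvature effect of measuring a shell between two offset surfaces.

## Known limitations

* The published per-tooth thickness values cannot be reproduced from their
  own printed sector volumes and areas through the defining ratio (the
  occlusal row yields 0.715 mm, not the printed 0.751 mm); the package
  implements the definition literally, and its acceptance checks therefore
  target the internally consistent percentage columns and synthetic oracles.
* Direct delineation of the occlusal contour on the EDJ (rather than by
  projection) is intentionally not implemented.
* Mesio-distal axis *direction* (which end is mesial) is not derivable from
  geometry alone; the sign convention is deterministic but anatomically
  unlabelled, and a `frame_override` accepts user metadata.
* The column-integral volume assumes no occlusal overhang; strongly
  overhanging cusp walls would require the ruled-wall closure instead.
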