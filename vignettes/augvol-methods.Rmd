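---
title: "Measuring grafted bone volume from surface scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring grafted bone volume from surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(augvol)
```

This vignette documents the science and the engineering decisions behind
`augvol`: the measurement model, what every tunable parameter means and why
its default is what it is, what the synthetic phantoms do and do not emulate,
and the numerical corner cases the implementation has to handle. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The measurement model

An intraoral scanner observes only the outer surface of the anatomy, as a
triangle mesh in millimetres with no topology guarantees: vertices are
duplicated per facet, normals are unreliable, and each scan lives in its own
coordinate frame. The quantity of interest is the volume enclosed between
the baseline surface and the post-augmentation surface of the same anatomy.
`augvol` estimates it in five stages.

**Registration.** The post-augmentation scan is first aligned coarsely by
three corresponding landmarks (Kabsch on three points, no scaling), then
refined by weighted point-to-point ICP: weighted moving vertices are
corresponded to their closest points on the fixed surface (closest point on
triangle through a uniform spatial grid, not vertex-to-vertex, because the
two scans tessellate the surface differently), and each iteration solves the
weighted least-squares rigid transform in closed form via the SVD of the
weighted cross-covariance with determinant correction. Point-to-point ICP is
used rather than point-to-plane because the closed-form Kabsch solution *is*
the point-to-point step; the refinement must not be driven by the graft
itself, so vertices on and around the augmented region carry weight zero
(graded weights are supported; a binary mask is the special case). Visual
confirmation of the match is replaced by a numeric gate: the final weighted
RMS must fall below a threshold (default 0.5 mm) or a registration-quality
warning is raised and recorded.

**Solidification.** Enclosed volume is only defined for a closed surface.
After trimming the scan to the neighbourhood of the region of interest (only
faces with all three vertices inside the kept region survive), the patch has
exactly one boundary loop. That loop is extruded by a fixed depth along the
closing direction — by default the negated area-weighted mean normal of the
patch, i.e. straight into the body being scanned — side walls are built from
the loop edges, and the displaced loop is capped.

**Dual region of interest.** Subtracting one solidified scan from the other
directly would leave slivers wherever their walls and caps nearly coincide.
Instead an ROI solid (an axis-aligned box, or any watertight mesh) is
intersected with the baseline solid, and a copy scaled about its volume
centroid by a factor $s<1$ is intersected with the augmented solid. Because
the augmented solid then ends strictly inside the baseline solid's walls,
the Boolean difference contains only the graft plus, possibly, disconnected
debris. Free-floating fragments — real particulate graft material produces
them — are removed by face-adjacency connected-component filtering, by
default keeping the single largest-volume component ("largest"); a
"threshold" policy keeps all components above a volume fraction, for grafts
that legitimately split into several attached pieces.

**Volume.** For a closed, consistently oriented mesh the divergence theorem
gives $V = \tfrac16\left|\sum_f v_0\cdot(v_1\times v_2)\right|$. The
implementation orients each connected component outward and takes absolute
values per component, so a stray inverted component cannot cancel volume. A
second, deliberately different computation mirrors the manual gold standard:
parallel planes spaced 0.25 mm apart cut the solid, each cross-section's
area is accumulated from the oriented plane–mesh intersection segments
(Green's theorem over the oriented contour, which realizes the even–odd rule
without chaining segments), and the areas are summed times the thickness.
The agreement of the two routes on every measured difference mesh is the
geometric analogue of the equivalence between manual and semiautomatic
measurement, and is checked in the test suite.

**Statistics.** The study design this package serves compares two
measurement methods on paired specimens and reads each scan twice. The
statistical layer therefore provides: paired TOST (two one-sided t tests
against margins $\pm 0.15$ cm³, $\alpha = 0.05$; equivalence is declared
exactly when the 90% CI of the mean difference lies inside the margins, and
the TOST p value is the larger of the two one-sided p values) together with
the standard paired NHST t test; the two-way mixed-effects single-measure
intraclass correlation for test–retest reliability, with absolute agreement
ICC(A,1) as the default (the appropriate choice when the same rater
re-measures the same quantity; consistency ICC(C,1) is available via a
flag), 95% CIs by the F-distribution method with Satterthwaite degrees of
freedom, and interpretation on the conventional bands (poor < 0.5 ≤ moderate
< 0.75 ≤ good < 0.9 ≤ excellent); and the Wilcoxon signed-rank test for the
paired, non-normal timing comparisons. The signed-rank null distribution is
computed exactly for up to 25 non-zero differences by a generating-function
convolution over doubled mid-ranks — exact even under ties, where textbook
exact methods do not apply — with zeros dropped and counted, and a
tie-corrected normal approximation with continuity correction beyond that.
Pairs missing one side are excluded and counted (complete-case analysis).

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| vertex merge tolerance | 1e-6 | mm | STL duplicates vertices per facet; scanner exports are far coarser than this, so merging is safe and restores shared edges. Configurable because export precision varies. |
| ICP max iterations / RMS tolerance | 200 / 1e-6 | – / mm | Point-to-point ICP converges slowly along surface-sliding directions; residual misalignment of even ~0.01 mm biases the measured volume by ~1% at the studied volume scales, so the defaults favour convergence over speed. |
| ICP point budget | 3000 | vertices | A deterministic stride subsample of the positively weighted vertices; beyond a few thousand points accuracy is limited by residual misalignment, not sampling. |
| ICP correspondence cap | 5 | mm | Discards spurious matches when overlap is partial. |
| registration quality gate | 0.5 | mm | Replaces visual confirmation; scans that cannot be aligned below this RMS are flagged rather than silently measured. |
| solidify depth | 5 | mm | Cancels in the subtraction (both solids are closed the same way) but must exceed registration residuals; the test suite checks the measured volume is invariant to the ROI scale and the acceptance phantoms pass at this depth. |
| ROI scale s | 0.98 | – | "Slightly smaller": must exceed the registration-residual and lattice scales but stay close to 1. A property test verifies the measured volume is invariant (±0.5%) over s ∈ {0.95, 0.98, 0.99}. |
| lattice pitch | 0.1 | mm | Boolean resolution. The discretization error on the studied volumes is well below the 1% acceptance band; halving the pitch multiplies time and memory by 8. |
| slice thickness | 0.25 | mm | The manual protocol's slice spacing. |
| TOST margin | 0.15 | cm³ | The smallest volume difference considered clinically meaningful in this setting. |

## The phantom generator

Real scan pairs cannot be shipped, so the package generates its own study
conditions. A baseline scan is a height field over a rectangular domain: a
rounded-trapezoid ridge profile (crest plateau with cosine shoulders, 16 mm
wide and 8 mm high by default, 36 mm long) plus a low-frequency seeded
undulation, tessellated at 0.2 mm — the density of an intraoral scan — with
three reproducible landmarks outside the augmentation zone. An augmentation
adds a technique-specific height field on top: a super-elliptic plateau for
the solid block (B), a boxier plateau with small seeded surface ripples for
the thinned plate over particulate (S1), and an elliptic dome with ripples
for the curved shell (S2). Modelling the *visible envelope* is the right
abstraction because a surface scanner cannot see the particulate filler
under the plate — only the outer surface contributes to the measured volume.
The peak height is calibrated by 0.05 mm quadrature so the added volume hits
the per-technique target, drawn per specimen around the studied scales
(0.35 ± 0.085, 0.76 ± 0.15, 0.82 ± 0.17 cm³). Scanner noise is i.i.d.
vertex displacement along local normals; the augmented scan is emitted in a
perturbed frame (a known random rigid pose, default 5° / 2 mm) with jittered
landmarks; optional free-floating spheres near the graft emulate loose
particles. A hemispherical bump variant provides a fully analytic truth
$\tfrac23\pi r^3$ for oracle tests.

Ground truth is the exact prism integral of the piecewise-linear, noise-free
added-height surface — machinery disjoint from registration, solidification
and the lattice CSG — so pipeline agreement with the truth is evidence, not
tautology.

What the phantoms do **not** emulate: real mandible anatomy (no teeth,
undercuts or concave overhangs — the surfaces are height fields), correlated
scanner noise, stitching artefacts, blood or saliva, and the true geometry of
packed particulate grafts. Passing tests therefore demonstrate that the
measurement machinery is correct on ridge-like geometry under the studied
noise and misalignment scales; they do not certify accuracy on pathological
scan quality or strongly re-entrant anatomy.

## Numerical choices and degenerate inputs

*Lattice CSG.* No robust exact mesh-Boolean engine is available to this
package, and scanner meshes would strain one anyway; the Boolean backend
rasterizes each watertight input by vertical ray parity at voxel centers on
a lattice whose origin is snapped to multiples of the pitch. Snapping makes
chained operations on the same lattice exact and keeps axis-aligned fixtures
(unit cubes, slabs) bit-exact. Rays through shared projected edges or
vertices are counted exactly once by a rasterization-style ownership rule
(the triangle whose edge runs downward, or leftward when horizontal, owns
the boundary), with edge functions within a scale-aware epsilon snapped to
zero so the two incident triangles agree despite round-off — without this,
symmetric geometry (extrusion caps, scaled copies of the same mesh) loses
entire parity intervals. Vertical triangles are tangent to the ray and are
skipped. An unpaired trailing crossing (degenerate tangency) is dropped.

*Watertight vs closed.* `mesh_summary()` reports strict watertightness
(every edge shared by exactly two faces). Volume computation requires the
weaker, sufficient condition that every directed edge is balanced by its
reverse — lattice-extracted surfaces can carry even-incidence edges at
diagonal voxel contacts, where the divergence theorem still holds. Both
flags are reported.

*Cap triangulation.* The displaced boundary loop is capped by a fan from its
centroid. For the near-rectangular loops produced by box cropping the fan is
deterministic, watertight by construction, and robust to the non-planar
loops a ridge crop produces; an ear-clipping triangulation was rejected
because collinear boundary runs (ubiquitous on grid-tessellated crops)
degenerate it, and its failure modes are quadratic-time and silent. Strongly
non-star-shaped crop boundaries could make the fan self-fold; the pipeline's
box crops cannot produce them, and the watertightness and positive-volume
checks after assembly fail loudly if assumptions are violated.

*Degenerate inputs.* Collinear landmark triples, rank-deficient Kabsch
covariances (collinear point sets), meshes with no faces after validation,
empty crops, multi-loop patches, non-manifold boundaries, zero-variance
TOST differences (zero-width CI), all-zero signed-rank differences and
incomplete ICC designs all raise structured errors with specific messages
rather than propagating NaNs. Equal-volume component ties in fragment
filtering are broken deterministically by the lexicographically smallest
minimum vertex coordinate, with a 1e-9 relative tolerance so the rule
actually triggers under floating point.

*Margin failure.* A graft reaching the open border of the trimmed scan
cannot be measured — the scan edge clips it. The pipeline detects a kept
difference component approaching the scan's boundary loop (within twice the
lattice pitch plus 0.05 mm) and reports a structured `margin_failure` for
that scan instead of a volume, while other scans continue.

*Re-measurement variability.* The study design reads each scan twice. In a
fully deterministic pipeline the second reading would be identical, so
`run_study()` emulates independent sessions by jittering the ROI placement
(normal, 0.3 mm sd) and the registration initialization (up to 0.5° / 0.3 mm)
on runs after the first — the scriptable analogue of a human re-placing the
ROI cube and re-seeding the alignment.

## Problem sizes

The test suite and the acceptance script run phantoms at the full scan-like
tessellation (0.2 mm pitch, ≈29 000 triangles per scan) with the default
0.1 mm Boolean lattice. The acceptance study uses five specimens per
technique measured twice — enough to exercise every stage, the reliability
analysis and the equivalence decision at the studied volume scales — and the
statistical simulations use 1000 replicates. These sizes are the package's
own choice of a thorough-but-routine desk check; all of them scale up by
changing one argument.

## Known limitations

- Point-to-point ICP needs a sane landmark initialization; there is no
  global registration, non-rigid deformation or scale estimation.
- The Boolean backend is lattice-based: volumes carry a discretization error
  that shrinks with the pitch but is never exactly zero on curved geometry;
  the extracted difference meshes are axis-aligned staircase surfaces.
- Solidification handles exactly one boundary loop and does not attempt
  general hole filling or self-intersection repair.
- The slice oracle and the divergence volume share the input mesh; they
  cross-validate the volume computation, not the registration.
- Statistics cover the paired two-method, two-timepoint design; multi-rater
  designs beyond two occasions are out of scope.
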