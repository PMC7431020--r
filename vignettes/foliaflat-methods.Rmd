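---
title: "Reconstructing and flattening folded cortical sheets: methods and design"
author: "foliaflat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and flattening folded cortical sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`foliaflat` measures the total surface area of a thin, doubly folded
cortical sheet — the cerebellar cortex is the motivating case — from a pair
of co-registered ex vivo MRI volumes: a short-TE proton-density-weighted
(PD) image and a long-TE T2\*-weighted image on the same isotropic grid.
The cerebellar sheet folds at two nested scales: large lobules (centimeter
wavelength) carry small folia (a few millimeters), and voxels that are not
substantially smaller than a folium blend opposing gray-matter banks into
one another (partial-volume effect), which is why historical area estimates
from coarser scans were severe underestimates. The package provides the
complete chain: image preparation, white-matter segmentation, tessellation,
deformable refinement into gray/white and pial surfaces, inflation with
dual-scale folding maps, cutting and flattening, shrinkage-corrected area
reports, and a voxel-size resolution-loss analysis. Because real specimens
are not distributable test assets, a synthetic phantom with *exactly known*
surface area is a first-class component, and every quantitative claim in
the test suite is checked against that ground truth.

# The phantom

`PhantomSpec`/`generatePhantom` build a folded-sheet specimen as the graph

$$ S(x, y) = z_0 + A_l \sin(2\pi x/\lambda_l)
   + A_f \sin(2\pi y/\lambda_f)\,\mathrm{env}(x), $$

with the gray sheet occupying a vertical band of thickness $t$ around the
mid-surface (granule layer below, molecular layer above), white matter
filling the interior below, and a low-signal background outside.
`env(x)` is a smoothstep taper that switches the folium amplitude off
within one folium wavelength of the sheet's x-edges so the offset layers
cannot self-intersect at the rim; independently, a spec whose half
thickness exceeds the mid-surface's minimum curvature radius
($\tfrac{t}{2}\,\kappa_{\max} \ge 1$) is rejected outright. Because the
gray layers are *vertical* offsets of a graph, the gray/white, mid and pial
reference areas all equal the same quadrature integral
$\iint \sqrt{1 + S_x^2 + S_y^2}\,dx\,dy$, which `sheetReferenceArea`
evaluates from the analytic gradient by midpoint rule at a spacing of
$\lambda_f/40$ — far denser than the folium frequency. Slab, spherical
shell and cylindrical shell variants carry closed-form areas and serve as
calibration shapes.

Echo synthesis assigns each tissue class a mean intensity per echo,
multiplies both echoes by one shared smooth random polynomial bias field
(mapped into [0.6, 1.6]; the phantom analog of the coil receive profile),
and adds white Gaussian noise. The default class means make the combined,
inverted image decrease monotonically from white matter outward (white >
granule > molecular > background) with a clear molecular/background step,
matching the appearance of a specimen in a signal-free embedding medium.
Defaults — voxel width 0.25 mm, sheet thickness 1 mm, lobules
$\lambda_l = 20$ mm / $A_l = 3.5$ mm, folia $\lambda_f = 4$ mm /
$A_f = 0.6$ mm, noise SD 0.01 (1% of the white PD mean, consistent with a
heavily averaged ex vivo acquisition), bias order 2 — were chosen once as a
realistic miniature of the tissue geometry; the grids they generate
(roughly $176 \times 136 \times 78$ voxels) keep a full end-to-end run in
tens of seconds. One integer seed drives a single RNG stream, so identical
spec + seed gives bit-identical volumes.

What the phantom does *not* emulate: overhanging (non-graph) folds, true
MR physics (relaxation, flip angles), Rician noise (additive Gaussian is
used; at this SNR the distinction is immaterial for geometry), spatially
varying cortical thickness, and anatomical boundary conditions such as cut
peduncles. Passing tests therefore demonstrate correct recovery of
graph-like doubly folded sheets under realistic contrast and noise, not
performance on a real specimen.

# Image preparation

`combineEchoes` divides T2\* by PD voxelwise; a multiplicative field shared
by both echoes cancels exactly. The denominator guard defaults to
$10^{-3}\times$ the median foreground PD. The background of the ratio image
is noise-over-noise and heavy-tailed; all later stages are written to be
robust to it (quantile-clipped histograms for Otsu thresholds, clipped
samples for the k-means class levels).

`flattenAndInvert` fits a low-order 3D polynomial (default order 2) to the
log intensity over the foreground and divides it out. The fit is
segmentation-coupled: the log image is modelled as tissue-class offsets
plus a smooth field, and the algorithm alternates a 1-D k-means clustering
of the residuals (k = 3, the foreground tissue classes, deterministic
quantile initialization) with a least-squares refit on offset-corrected
data. This matters because a plain fit soaks up the anatomy itself — on a
spherical phantom an order-2 polynomial represents the radial class layout
almost perfectly and catastrophically distorts the image after division —
while simple robust (M-estimator) fits stay biased whenever the class
spread is comparable to the bias range. The alternating fit recovers the
field exactly in both regimes, the same idea mixture-model bias-correction
methods use. Inversion then
maps `v` to `q001 + q999 − v` using extreme foreground quantiles as anchors
(identical to max/min on clean images, stable under noise). Two final
robustness measures, documented here because they shape the pipeline's
behavior: intensities are clamped to the observed tissue range plus a
quarter-span of slack, and voxels outside the PD-defined foreground are
pinned to the dark floor — the analog of masking out the signal-free
embedding medium, which otherwise injects ratio noise into the pial
boundary.

`orientedSmooth` implements the oriented anisotropic filter: at every voxel
the structure tensor (Gaussian-integrated outer product of central-difference
gradients, integration scale 1.5 voxels) defines the plane of least
brightness variation as the span of its two smallest-eigenvalue
eigenvectors; the image is averaged over a 7×7×7 neighborhood with a 2D
Gaussian of FWHM 2.5 *voxels* restricted to that plane, sampled by trilinear
interpolation with weights normalized to one. FWHM is fixed in voxels
rather than millimeters so the filter is resolution-portable. Where the
eigenvalue ratio falls below 1.2 the tensor is treated as isotropic and a
3D Gaussian of the same FWHM is used. The filter runs once by default
(`passes` exposes iteration). The property that justifies filtering before
tessellation is tested directly: on a noisy slab phantom it reduces
within-sheet variance at least threefold while moving the sub-voxel edge
position by under 0.2 voxel.

# Segmentation, tessellation, refinement

`segmentWhite` thresholds the prepared image (white matter brightest). The
default is two-stage Otsu — background vs. tissue, then gray vs. white
within tissue — because the four-class histogram defeats single Otsu. The
largest 6-connected component is kept and interior cavities are filled, the
automated stand-in for the manual clean-up a real specimen receives.

`tessellate` emits one quad (two triangles) per boundary voxel face, with
vertices on voxel corners, wound outward. Voxel pairs touching only along
an edge or a corner would make that surface non-manifold; a thickening rule
fills one voxel of the offending pair (repeatedly, until clean), so the
output is always a closed, consistently wound 2-manifold. A digitized
sphere tessellates to about 1.5× its true area — the Manhattan
(staircase) inflation — which is exactly what refinement must remove.

`refineSurfaces` deforms the tessellation with per-vertex updates: a step
along the vertex normal proportional to a saturating function of the
intensity error against the target isovalue (clamped at a quarter voxel),
tangential Laplacian smoothing (weight 0.3), and a small normal
curvature-spring term (weight 0.1) that damps noise-driven wrinkling.
Because the prepared image decreases monotonically outward, positive error
always means "move outward", and the iteration is globally stable. The
gray/white surface targets the white/granule isovalue; the pial run
continues from it toward the molecular/background isovalue. Isovalues are
estimated from the data: the white level is the median inside the eroded
mask, and the flanking granule/molecular/background levels are k-means
centers (k = 3, deterministic quantile initialization) of the intensities
in a 6-voxel shell outside the mask — the midpoint rule on medians alone
cannot see the molecular/background split. The pial run adds
self-intersection avoidance: a spatial-hash search for the nearest
*facing* (normal-opposed) vertex outside the 2-ring freezes outward motion
below one voxel of gap and backs off below 0.6 voxel; normal opposition is
what distinguishes an approaching opposite bank from the surface's own
neighborhood, which on voxel meshes sits within a voxel of itself. Residual
local fold-overs (adjacent-triangle crossings left by noise) are repaired
by relaxing exactly the vertices of intersecting pairs until an exact
triangle–triangle test (uniform spatial hash + segment–triangle tests;
coplanar overlaps are not flagged) reports zero.

On the default folded-sheet phantom this chain recovers the pial area to
within 3% of quadrature ground truth, and on a digitized sphere-shell
phantom (radius 10 mm, 0.5 mm voxels) both surfaces land within 2% of
their closed forms, removing the 1.5× voxelization inflation.

# Folding maps: curv and sulc

`vertexCurvature` measures the local convexity from the relative positions
of neighboring vertices: the uniform-weight umbrella vector projected on
the outward normal, scaled by $2/\overline{|e|^2}$. The scale is calibrated
by the sphere, where every chord satisfies
$(p_j - p)\cdot n = -|p_j - p|^2/2R$ exactly, so the measure returns
$-1/R$ at *any* neighborhood size; on a cylinder it returns half that, the
mean curvature. Convex crowns are negative, concave fissures positive. On
voxel-derived surfaces the one-ring estimate mostly measures sub-voxel
jaggedness, so the support is widened to a few rings (`rings = 4` for the
default phantom, roughly one millimeter) — wide enough to see a fissure
whose floor the voxel grid flattened, narrow enough not to blur folia into
lobules.

`inflateSurface` smooths the surface (uniform Laplacian, weight 0.5)
against a metric-preservation spring (weight 0.1) restoring 1-ring edge
lengths, rescales about the centroid after every iteration so total area
stays pinned, and accumulates each vertex's displacement projected on its
current normal as the average convexity ("sulc"): fissure depths move
outward (positive), crowns inward (negative). Two numerical choices
matter. First, heavy-ball momentum (0.9) on the update: the mesh edge
(0.25 mm) is two orders of magnitude finer than the lobule wavelength
(20 mm), and plain umbrella iteration would need many thousands of
iterations to erase lobule-scale folds; momentum brings that within the
default 500-iteration budget. Second, the uniform-weight scheme has a
genuine equilibrium displacement on irregular meshes — on the icosphere the
valence-5 vertices settle about 2% of the radius away from their start —
so sulc values within about 2–3% of the object radius are the scheme's
noise floor, and sulc contrasts are interpreted against it (the two-lobe
peanut fixture separates waist from crowns by more than an order of
magnitude above that floor). Sulc is not mean-centered by default;
`center = TRUE` provides the centered variant. On the default phantom,
thresholding sulc at zero classifies lobule crowns vs. fissures at ≥ 90%
against the analytic lobule phase while thresholding curv does the same
for the folium phase — the operational meaning of the two hierarchical
folding scales.

# Cutting and flattening

`applyCuts` duplicates vertices along edge paths by partitioning each path
vertex's triangle fan into the groups still connected through non-cut
edges; open path endpoints stay single (slits), paths may meet mesh
boundary or each other, and the pieces come back with a vertex provenance
map so scalar maps transfer. A per-vertex piece labelling is accepted as
the alternative cut description. The standard topology checks hold by
construction: a meridian slit turns a sphere into a disk, an axial cut
unrolls a tube, the two canonical loops open a torus.

`flattenPiece` requires a topological disk (Euler characteristic 1) and
refuses anything else with advice to cut further — a surface with leftover
intrinsic curvature cannot flatten without severe distortion. The map is
initialized by a boundary-fixed Tutte embedding (flip-free by construction)
and relaxed with free boundary by as-rigid-as-possible local/global
iteration: per-triangle best-fit rotations of isometric 2D rest shapes
(closed-form 2×2 polar factor), then one prefactored sparse least-squares
solve for all positions. ARAP was adopted after free-boundary quasi-Newton
descent of the edge-spring energy alone proved unable to unroll
accordion-folded strips from the disk start (it stalls half-unrolled with
thousands of fold-overs); ARAP preserves orientation strongly and unrolls a
2.7-period folded strip to its exact developable rectangle. A
spring-energy polish (`polishIter`) sharpens edge lengths afterwards; the
polish also runs from a second, independent start — the projection onto
the piece's principal plane, the better basin for gently curved cap-like
pieces, while the ARAP route wins for multiply folded ones — and the
lower-energy solution is kept. Any flipped triangles are then repaired by
local untangling with the residual count flagged in the result rather than
hidden — on clean parametric surfaces the count is zero; on voxel-derived
phantoms a ~1% residue of degenerate micro-triangles may remain flagged.
Convergence: relative position change below $10^{-7}$ of the piece scale,
cap 300 local/global iterations. Distortion is reported as the per-vertex log ratio of 1-ring
areas, 2D over 3D: zero for developables (cylinder: median |log| under
0.01, total area within 1%), strictly positive and growing with cap angle
for spherical caps.

# Resolution analysis

`downsampleVolume` box-averages onto a coarser grid with exact separable
overlap integrals — the physical model of partial-volume formation — and
conserves intensity mass on exact covers; trailing slabs that do not fill a
whole output voxel are dropped. `areaRecoveryCurve` degrades the
*synthesized* echoes (the closest analog of degrading a final processed
dataset), re-runs the entire pipeline at each width with all parameters
held fixed, and reports recovered pial area as a fraction of the
native-width recovery. On a folia-scale phantom the fraction is monotone
non-increasing in voxel width (Spearman ρ ≤ −0.9 over six widths from 0.2
to 1.0 mm); on a foldless slab control it stays above 0.97 at every width —
area loss is a folding phenomenon, not a resampling artifact. The published
loss percentages at specific voxel sizes depend on the real specimen's
folia geometry and are deliberately not targets.

# Area reports

`meshArea` sums triangle areas with optional vertex-flag exclusion (the
analog of removing surface over cut peduncles). `correctShrinkage` applies
the isotropic fixation-shrinkage correction: volume shrinkage by fraction
f means measured areas are multiplied by $(1/(1-f))^{2/3}$; at the default
f = 0.03 the multiplier is 1.02051. The alternative reading (in vivo
volume = 1.03 × fixed) would give 1.0199, a 0.06% difference; the first
reading is adopted and documented. `buildAreaReport` assembles named areas,
applies shrinkage per entry (ex vivo structures only; literature in vivo
comparison values enter as given), optionally scales gray/white areas by
the 1.2× gray/white-to-pial factor, and reports pairwise ratios both in
full precision and as integer percent, rounded half away from zero.

# Reproducing the results

`scripts/acceptance.R` re-runs the full chain from scratch — worked-example
ratios from the published areas, the default folded-sheet phantom through
reconstruction, folding maps, flattening, and the resolution experiment on
the folia phantom and slab control — and writes every quantity to JSON.
The problem sizes used there (the default ~1.9M-voxel sheet phantom, the
~0.8M-voxel folia phantom, six widths) are the package's standard
demonstration conditions. The test suite asserts the same contracts at the
tolerances stated above.

# Known limitations

* The phantom sheet is a graph: no overhanging folds, so the
  self-intersection machinery is exercised mainly by fissure banks, not by
  truly re-entrant geometry.
* Uniform-weight operators trade accuracy on irregular meshes for
  robustness on voxel-derived ones; the sulc noise floor and the few-ring
  curvature support are the visible costs.
* The flattening flip count on voxel-derived pieces is flagged, not forced
  to zero; areas read off such flat maps remain accurate to well under 2%.
* No lobule parcellation, no spherical registration, no hand-editing hook;
  phantom noise levels are chosen so morphological cleanup suffices.
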