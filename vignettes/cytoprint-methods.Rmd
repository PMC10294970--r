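---
title: "From confocal z-stacks to dismountable 3D-printed cell models: methods"
author: "cytoprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From confocal z-stacks to dismountable 3D-printed cell models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoprint)
```

## The problem

Confocal laser scanning microscopy images cultured cells as z-stacks:
series of 2D optical sections with sub-micrometre in-plane pixels and a
coarser axial step. Selective fluorescent stains separate subcellular
structures into channels — DAPI marks nuclei, phalloidin-TRITC the f-actin
cytoskeleton, and an anti-alpha-SMA antibody the contractile actin isoform
of myofibroblasts. `cytoprint` turns such stacks into physical,
dismountable models for FDM (fused deposition modeling) printing: the
cytoskeleton-defined cell surface becomes a solid printable part, the
nucleus a separate part that fits into a cavity carved with positive
clearance, so the printed "cell" can be taken apart and reassembled.

Because micrometre-scale structures sit far below printer resolution, the
model is magnified by a factor `M` (printed length / original length,
typically 200–10000). The pipeline keeps all geometry in specimen
micrometres until an explicit scale step converts to model millimetres,
and reports the specimen-scale feature size represented by one printed
layer, `layer_height * 1e3 / M` µm.

## Pipeline stages and their models

### Segmentation

Masks are produced by inclusive grey-value thresholding
(`gv_min <= I <= gv_max`) or seeded region growing (the 26-connected
component of the threshold band containing the seed). Components are
separated with 26-connectivity in 3D and 8-connectivity in 2D slices —
the common default in segmentation suites, and the choice that does not
sever thin diagonal actin fibers. Cortical staining leaves membrane
holes, so masks are closed with a Euclidean-ball morphological closing
(default radius 2 voxels, comparable to the PSF width of the bundled
phantoms) followed by a 3D hole fill; a per-slice 2D fill is available
for stacks whose gaps are confined to single planes. Both modes are
extensive and idempotent. Grey-value bands are never hard-coded: they are
configuration inputs, with known-good values shipped in the presets.
Interactive mask brushing is replaced by deterministic ROI-based edits
(all set regions, then all clear regions), trading interactivity for
reproducibility.

### Surface extraction

Iso-surfaces are extracted by marching tetrahedra: each grid cube is
decomposed into the six tetrahedra sharing its main diagonal, whose
face diagonals agree between neighbouring cubes, so the triangulation is
crack-free and closed regions give watertight, consistently oriented
meshes with vertices shared through grid-edge keys. Marching tetrahedra
was chosen over the classic 256-case marching cubes table because it has
no ambiguous configurations and a far smaller, verifiable case table;
the contract (iso-level 0.5 on the binary grid, anisotropic spacing in
µm) is the same.

Binary masks are extracted on a 2x-refined copy of the grid, which makes
the mesh wrap the voxel extents: a single 1 µm³ voxel yields a closed
mesh of volume ~0.84 µm³ (a unit cube with chamfered corners), and the
enclosed volume of a digitized ball at 0.5 µm voxels matches the analytic
volume to ~0.1%. For grids above ~3M voxels the refinement is skipped —
objects there span hundreds of voxels and the midpoint surface is
equally accurate — keeping the largest preset (512x512x33) tractable.

Smoothing is Taubin's two-step lambda/mu scheme (defaults 0.5/−0.53, 10
iterations): surface area relaxes monotonically while enclosed volume
changes by well under 1%, which matters because parts must still fit
after smoothing. Decimation re-voxelizes the mesh on a coarser grid and
re-extracts, preserving watertightness by construction; if no coarsening
reaches the requested face budget (e.g. a tetrahedron), the input is
returned unchanged.

### Solidification, splitting and clearance fits

Printable solids are built on a signed-distance voxel engine. Meshes are
voxelized by parity ray casting along voxel columns; the signed distance
field (SDF) combines exact point-to-triangle distances within a narrow
band (3 voxels) of the surface with a half-voxel-corrected distance
transform in the far field. CSG is done on the fields (`min`/`max`), and
results are re-extracted with interpolated marching tetrahedra, which
places offset surfaces and flat caps with subvoxel accuracy:

* `solidify(filled)` extracts `thickness − sdf > 0` — the outward offset
  with the interior filled (volume error ~1% on an analytic sphere);
* `solidify(shell)` extracts `min(sdf, thickness − sdf) > 0` — a wall of
  nominal thickness bounded by the original and offset surfaces
  (volume within 5%; the wall's outer face sits in the far field, so
  shell mode defaults to a finer pitch, thickness/8);
* `plane_split` intersects the part field with the two half-space fields
  of a datum plane (default: horizontal plane through the volume
  centroid, separating an adherent cell into upper and lower halves);
  the two extractions are complementary, so the halves' volumes sum to
  the whole to ~0.01%;
* `subtract_insert` removes `sdf_insert <= clearance` from the host, the
  cavity the printed insert drops into. Clearance defaults to 0.3 mm, a
  typical FDM fit tolerance. Cavity volume agrees with the analytic
  nested-cube case to <1% and shrinks strictly as clearance grows.

The working pitch follows the quarter-of-smallest-feature rule,
`min(thickness, clearance)/4`, bounded below so the longest grid axis
stays near 192 cells (config-exposed); the problem sizes actually run are
~190x190x80 cells for the epithelial model and smaller for the others.
Open (non-watertight) input surfaces are handled by offsetting the
surface sheet itself — parity inside/outside is undefined, but the
thickened sheet is always a watertight solid, which is also how holes in
reconstructed membranes are closed.

Cut faces are capped flat; no pins or joints are added by default.
Printability is assessed by inward ray casting from ~200 sampled faces:
the wall thickness at a sample is the distance to the triangle the ray
exits through (grazing hits on neighbouring surface bumps, whose normals
oppose the ray, are ignored), and the reported minimum wall is the 5th
percentile of sampled thicknesses — a robust minimum on faceted
surfaces. Parts are flagged stable at the 1 mm FDM wall threshold.

### Morphometry

Cell and nucleus diameters are measured on the z-maximum projection
(adherent cultured cells are flat, so the conventional D1/D2 are
in-plane): D1 is the maximum caliper (Feret) diameter of the convex hull
of foreground pixel centres, D2 the minimum caliper via rotating
calipers over hull edges, and Davg = (D1 + D2)/2 — the definition
consistent with reported nucleus averages (e.g. (18.8 + 13.7)/2 = 16.25
vs a printed 16.2). Davg is still computed for highly elongated objects
but flagged for suppression above an elongation ratio D1/D2 > 3, since a
mean diameter is not meaningful for spindle-shaped fibroblasts.

### Scaling and the print report

`make_scale_map` stores the magnification from a key length (e.g. a
"1 cm printed : 10 µm original" scale bar gives M = 1000); applying and
inverting it round-trips coordinates to 1e-9 relative, guarded by unit
tags against double scaling. The print report records the FDM
configuration (layer 0.2 mm, triangular infill 10%, supports on — a fast
PLA profile), the bounding box against a 330x240x300 mm build volume
(config-overridable; typical large desktop FDM), and the original-scale
resolution. Slicing and G-code are out of scope by design.

## The phantom generator

Real stained stacks are not redistributable, so validation runs on
synthetic phantoms with exact ground truth. A phantom cell is a rotated
ellipsoid body, optionally with capsule protrusions (neuron-like cells);
the cortical f-actin channel is the body minus an inward offset by the
shell thickness (thin protrusions stay filled, as bundled actin does);
the nucleus is an interior ellipsoid whose outline can be perturbed by
low-order angular lobes to mimic irregular nuclear shapes; an optional
fiber channel holds capsule tubes (alpha-SMA). Channels are blurred with
an anisotropic Gaussian PSF (defaults sigma_z = 1.0 µm, sigma_xy =
0.3 µm — axial blur dominates in confocal imaging) and degraded with
Gaussian or Poisson detector noise under a fixed seed; generation is
bit-reproducible and never perturbs the caller's RNG stream.

The three presets reproduce the study conditions of the modeled
archetypes: an epithelial cell (in-plane diameters 44.6/35.9 µm, nucleus
18.8/13.7 µm, 16 planes over 15 µm at 0.25 µm/pixel, M = 1000), two
contacting spindle-shaped fibroblasts (D1 195.5 µm, nuclei 44.1/17.2 µm,
33 planes over 16 µm at 0.5 µm/pixel on a 512x512 grid, with an
alpha-SMA channel, M = 200), and a neuron-like cell (16.5 µm tip-to-tip
across two opposed protrusions, body width 9.7 µm, nucleus 6.4/5.9 µm,
36 planes over 10 µm at 0.1 µm/pixel, M = 10000). Where the archetype
geometry is not fully determined by the reported diameters (axial
semi-axes, nucleus offsets, fiber layout, staining intensities), values
were chosen once to look like adherent cultured cells at these
magnifications and are not tuned thereafter.

What the phantoms do not emulate: photon-accurate noise statistics,
spectral bleed-through, stage drift, refractive-index depth aberrations,
or textured intensity within structures. Passing tests therefore
demonstrate the geometric fidelity of the reconstruction chain under
idealized imaging, not robustness to every real acquisition artifact;
on real stacks the threshold bands and fill radii are the parameters
that absorb those differences.

## Numerical choices and degenerate inputs

* Field values exactly at the iso-level are treated as outside;
  interpolation parameters are clamped away from 0/1 so cut vertices stay
  distinct.
* Voxel columns are jittered by ~1e-4 voxel during parity voxelization so
  rays avoid grazing triangle edges of meshes built on round coordinates;
  columns with an odd crossing count (numerically degenerate) drop their
  last crossing.
* Grid origins are placed half a pitch off the bounding box so
  axis-aligned faces fall exactly between voxel centres, making the
  half-voxel EDT correction exact on flat geometry.
* Watertightness is defined as every undirected edge being shared by
  exactly two faces, once in each direction; `solid_part` re-orients
  inward-wound meshes and rejects open or degenerate ones.
* Empty masks, empty meshes, seeds outside the intensity band, ROIs out
  of bounds, planes missing a part, and offsets that collapse a surface
  all raise immediate, stage-named errors; the pipeline retains partial
  outputs on failure.

## Design choices where the design was open

* TIFF carries no axial spacing, so voxel sizes follow the precedence
  explicit override > in-plane resolution tags > error; silent defaults
  would corrupt every physical measurement downstream.
* Channel-interleaved pages are the default layout, overridable to
  z-fastest; both occur in exported confocal TIFFs.
* The Boolean/offset engine is voxel-based throughout rather than using
  exact mesh Booleans: marching-cubes-style meshes routinely break exact
  predicates, while distance-field CSG is unconditionally robust, and
  interpolated re-extraction keeps the accuracy loss at the tolerances
  quoted above.
* The CLI (`inst/cli/cytoprint.R`) is a thin Rscript over the exported
  functions with subcommands for each stage; the package functions are
  the primary interface.

## Limitations

Engine accuracy is bounded by the voxel pitch: clearances below ~4 voxel
pitches are not resolved, and the ray-cast wall estimate is a sampled
statistic, not a guaranteed minimum. Morphometry is 2D-projected (no 3D
Feret diameters). Touching cells are not instance-split (no watershed);
the mesenchymal preset deliberately reconstructs two contacting cells as
one cytoskeleton part. Printing itself — slicing, supports, G-code — is
delegated to the user's slicer, configured from the emitted report.
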