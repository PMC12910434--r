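---
title: "The nuclear drop model and its morphometric readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nuclear drop model and its morphometric readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleodrop)
```

## The model

The nucleus is modelled as a pressurized drop bounded by a nearly
inextensible lamina. Its shape changes occur at constant volume
$V_{nuc}$ and constant lamina area $A_{nuc}$; when the lamina is taut it
carries an in-plane tension balanced by nuclear pressure, so free portions
of the nuclear surface take constant mean curvature (Laplace). The cell
cortex is a minimal-area surface pinned at the adhesion perimeter and
enclosing a fixed cell volume $V_{cell}$. The limiting nuclear shape in a
spread cell is therefore purely geometric — no elastic moduli enter, only
$(V_{cell,0},\,V_{nuc,0},\,A_{nuc,0})$ and the footprint.

Both surfaces are triangulated meshes, and the equilibrium is found by
minimizing

$$E_{tot} = E_{cell} + E_{nuc}
 + \gamma\left(\tfrac{A_{nuc}}{A_{nuc,0}}-1\right)^2
 + \beta_{nuc}\left(\tfrac{V_{nuc}}{V_{nuc,0}}-1\right)^2
 + \beta_{cell}\left(\tfrac{V_{cell}}{V_{cell,0}}-1\right)^2,$$

where $E_{cell}$ is the cortex area (normalized by $A_{nuc,0}$) plus a small
mesh-quality regularizer and $E_{nuc}$ is the mesh-quality regularizer only:
the lamina area appears exclusively as a constraint, never as an objective,
so the nucleus has no spurious drive toward the sphere. The regularizer is
the centroidal-Voronoi-tessellation (CVT) energy
$\sum_i \int_{v_i}\lVert x-x_i\rVert^2\,dA$ over barycentric dual cells
$v_i$; it is minimized per unit area when every vertex sits at its dual-cell
centroid, i.e. for near-equilateral triangles. Dual cells are barycentric,
not geodesic-Voronoi: the standard convergent approximation. The energy
integral is evaluated exactly per face with the three-edge-midpoint rule
(exact for quadratics).

### Assumptions

* Quasi-static and purely geometric: no viscoelasticity, chromatin
  elasticity, actomyosin force generation, or flow-structure coupling.
* The substrate is a rigid plane at $z = 0$; the basal disk of the cell
  surface is held fixed on it together with the adhesion perimeter (with a
  rigid substrate underneath, pinning the basal facet is mechanically
  equivalent to pinning only the perimeter ring, and it keeps the cell
  surface closed so volume bookkeeping is exact).
* Contact transmits only normal push, no adhesion: vertices crossing a
  boundary are reflected to the nearest admissible point.

## The solver

`solve_equilibrium()` runs damped gradient descent with a backtracking line
search over an outer loop of stiffness stages. Choices that matter:

* **Stiffness schedule** — $\gamma,\beta$ rise tenfold per stage from
  $10^2$ to $10^8$ (dimensionless; energies are normalized by $A_{nuc,0}$
  and the CVT terms by their initial-mesh magnitude). Converged nuclear
  $A$ and $V$ are insensitive to the schedule (tested to within $2\times$
  the residual tolerance against a $4\times$-shifted schedule). The outer
  loop stops early once all residuals sit below half the tolerance and the
  stage has stalled.
* **Step control** — the step is scaled so the largest vertex moves at most
  `step_frac` (default 0.2) of the mean edge length, then halved until the
  energy, evaluated *after* all contact projections, does not increase.
  Monotone descent is thus enforced by construction and is asserted in the
  tests from the recorded per-sweep trace.
* **Stall tolerance** — a stage is abandoned when the relative energy
  decrease per sweep falls below `stall_tol` ($10^{-8}$); the descent is
  deliberately cut before polishing soft tangential modes that do not move
  the residuals.
* **Contact ordering** — in `enforce_no_overlap()` the cortex yields first
  (cell vertices inside the nucleus are pushed out) and the nucleus is
  clipped to the updated cortex second. The order matters: clipping the
  nucleus first makes contact one-way and the pair deadlocks with the
  nucleus unable to press the cortex outward; cortex-first transmits the
  contact force while still returning an overlap-free state.
* **Edge flipping** — every fifth accepted sweep, interior edges whose two
  opposite angles sum above $\pi$ (tolerance $10^{-8}$ rad; ties are not
  flipped) are flipped to the other diagonal; flips that would duplicate an
  existing edge are skipped. Vertex positions and topology are untouched.
* **Micropost stepping** — `indent_with_post()` moves the cylinder in steps
  of at most half the mean nuclear edge length with 40 relaxation sweeps
  per step. Slow stepping is not cosmetic: at double the step and a third
  of the sweeps, the displaced surface area piles up beside the post and
  freezes into a blister that survives withdrawal (a metastable
  near-constant-curvature feature), degrading shape recovery from ~0.5 % to
  ~2.3 % Hausdorff/diameter.
* **Confining plate** — a rigid ceiling (`ceiling=`) complements the
  substrate. Pressing it down quasi-statically until the residuals can no
  longer be met yields the limiting pancake height for given $(A, V)$; the
  tests compare this against an independent 1D constant-mean-curvature
  shooting oracle (`pancake_height_for_area()` in the test helpers) and
  agree to ~4 % at 0.15-µm press decrements.

### Worked configuration

The monolayer-cell runs use $V_{cell,0} = 2800$ µm³, $V_{nuc,0} = 800$ µm³
and 37 % excess lamina area ($A_{nuc,0} = 571.7$ µm²) over a 20-µm-radius
footprint. The printed companion pairing of $A = 1543$ µm² with "37 %
excess" is internally inconsistent — 1543 µm² is 270 % excess over the
sphere area for 800 µm³ — so `drop_config()` accepts either an explicit
`A_nuc0` or an `excess_area_pct` and never silently reconciles the two; the
worked runs use the excess-area reading, which is the physically sensible
one for a mildly wrinkled nucleus. The footprint radius matters
qualitatively: a free cortex cap over a small footprint (≤ ~18 µm at this
cell volume) is taller than the nucleus and never touches it; the spread
configuration (r = 20 µm, mean cell height 2.2 µm) produces the
apical-contact, curved-rim, flat-base shape.

Problem sizes: nuclei at 700–2400 faces, cells at ~1000–1700; the
isoperimetric control runs at ~2400 faces. The discrete isoperimetric gap
of a polyhedral sphere sets a residual floor of order $10^{-3}$ near 300
faces, which is why the constraint tolerance of $10^{-3}$ needs $\gtrsim
10^3$ faces.

## Morphometrics

* **EFC ratio** — contours are decomposed into harmonic ellipses in the
  uniform-parameter convention (Fourier coefficients of the $x(t),y(t)$
  sequences over the contour parameter), under which an exact ellipse is a
  pure first harmonic. An arc-length parameterization would instead spread
  an ellipse across odd harmonics; since traced contours are sampled
  near-uniformly along the outline, the two conventions differ negligibly
  for the ratio readout. The ratio
  $(a_1+b_1)/\sum_{n=2}^{15}(a_n+b_n)$ is capped at $10^3$ because it is
  unbounded for a true ellipse; the cap keeps statistics finite without
  disturbing the ordering. It is invariant to translation, rotation,
  uniform scaling and traversal direction, and strictly decreasing in
  wrinkle amplitude.
* **Sub-pixel lamina tracing** — the intensity maximum along the local
  outward normal (probe ±1.5 µm, quarter-pixel sampling) is localized by a
  least-squares parabola over a ±0.3 µm window re-centered on the running
  peak estimate for three passes. The windowed, re-centered fit is what
  achieves ~0.005 px accuracy; a plain 3-point parabola on bilinear samples
  is biased by interpolation kinks to ~0.3 px.
* **Nuclear height** — per-plane in-mask mean lamin intensity against
  background mean + 3 SD from a cell-free region (border frame by default).
  Known limitation: single wrinkle lobes poking above the envelope
  contribute a tiny in-plane cross-section; their planes stay below the
  criterion, so heights of strongly wrinkled nuclei are biased low by
  several z-planes (visible in `results/morphometrics_recovery.csv`),
  while taut nuclei recover to within half a plane.
* **Surface area and volume** — volume is the voxel count times voxel
  volume of the solid mask built per plane from the traced sub-pixel
  contour (rasterized with the even-odd rule), which places the boundary on
  the lamina ridge; bulk thresholding alone would put it on the outer edge
  of the band (+6–7 % volume). Surface area comes from a marching-tetrahedra
  isosurface of the mask after Gaussian smoothing of 1 voxel per axis — the
  minimal anti-aliasing scale: unsmoothed staircase area overshoots a ball
  by 27 %, 1-voxel smoothing brings it to 0.4 % while eroding only ~2 % of
  genuine wrinkle area (1.5 voxels erodes ~3.4 %).
* **Height maps** — channels are summed, Otsu-binarized, apical−basal
  distance per column, 2-µm edge crop, uncovered columns filled by iterated
  neighbor means, block-averaged (factor 4); roughness is the SD of the
  final grid.
* **Gates** — FA particles keep area ∈ [0.5, 15] µm² and circularity
  $4\pi A/P^2 \in [0.1, 1]$ with the perimeter from EBImage's boundary-pixel
  convention (stated because perimeter estimators shift the 0.1 gate);
  components touching the ROI edge are excluded.

## Synthetic data: what it does and does not emulate

Generators produce wrinkled/taut closed surfaces with prescribed volume and
excess area (band-limited spherical-harmonic radial fields, degrees 4–8 by
default, amplitude set by bisection to 1 % of the target excess and volume
rescaled exactly); lamin-shell or solid renders at the 130-nm z-step with
Gaussian PSF and Poisson-Gaussian noise; Voronoi-tessellated monolayers
with a controllable tall-cell fraction; YAP scenes whose N/C contrast is
exact by construction; and power-diagram detachment series. They emulate
the geometry and first-order photon statistics of confocal stacks — not
depth-dependent aberrations, bleaching, chromatic shifts, nucleoplasmic
background structure, or segmentation failures of crowded real monolayers.
Passing round-trip tests therefore demonstrates correctness of the
measurement code under the stated imaging model, not robustness to every
artifact of real data.

Realism choices made once: lamin staining peak of 300 counts over a
10-count background (bright but routine confocal staining; the plane-mean
height criterion needs the mid-plane ring to clear background + 3 SD),
PSF σ = 0.2 µm, shell thickness 0.25 µm centered on the surface, monolayer
base height 3 µm with 8-µm domes.

## Statistics

The roughness contrast uses a two-sample permutation test on the difference
of group means of per-image roughness SDs, two-sided, with the add-one rule
$p = (1 + \#\{|T^\ast| \ge |T|\})/(n_{perm}+1)$ and a fixed seed (the
global RNG state is saved and restored). The permutation unit is the image,
matching how roughness is measured. Calibration (type-I error at
$\alpha=0.05$ over 1000 null replicates, super-uniformity at several
levels) and power (3-SD gap, n = 8/group) are exercised in the test suite.
The Mann-Whitney U test is deliberately a thin pass-through to
`stats::wilcox.test` and is recorded alongside, never instead.

## Known limitations

* Gradient descent finds local minima: frozen wrinkle configurations are
  metastable, so limiting-shape runs should start from smooth initial
  surfaces (the press protocol above), and indentation must be stepped
  slowly.
* The residual floor scales with mesh resolution; below ~10³ faces the
  $10^{-3}$ criterion may be unreachable for area-tight configurations.
* Nuclear height of strongly wrinkled nuclei is biased low by the
  plane-mean criterion (see above).
* The equilibrium is translation-degenerate in the plane; shape recovery is
  judged by Hausdorff distance, reported relative to the nuclear diameter.
* Exact geodesic Voronoi diagrams, adaptive refinement and
  self-intersection repair are out of scope; meshes are validated, not
  repaired.
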