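# nucleodrop

Equilibrium cell and nuclear shapes under the nuclear drop model, with the
image-quantification pipeline used to test that model in sheared endothelial
monolayers — for cell-mechanics and mechanobiology groups who want the
computational side of the story as reusable, tested R code.

## The science

The nuclear drop model treats the interphase nucleus as a pressurized liquid
drop bounded by a nearly inextensible lamina: nuclear shape changes occur at
constant nuclear volume `V_nuc` and constant lamina surface area `A_nuc`.
Excess area over the equal-volume sphere (`100·(A/A_sphere(V) − 1)` %) is
stored as wrinkles when the nucleus rounds up and unfolds as the nucleus
flattens; once the lamina is taut it carries surface tension and the free
nuclear surface takes constant mean curvature. In an endothelial monolayer
the limiting nuclear shape is then purely geometric: the minimal-area cell
cortex over a fixed adhesion footprint, at fixed cell volume, confines a
nucleus of fixed `V_nuc` and `A_nuc`.

`nucleodrop` computes these shapes by minimizing

```
E_tot(X_cell, X_nuc) = E_cell(X_cell) + E_nuc(X_nuc)
                     + γ (A_nuc/A_nuc,0 − 1)²
                     + β_nuc (V_nuc/V_nuc,0 − 1)²
                     + β_cell (V_cell/V_cell,0 − 1)²
```

over triangulated surfaces, where `E_cell` is the (normalized) cortex area
plus a small mesh-quality regularizer and `E_nuc` is the mesh-quality
(centroidal-Voronoi-tessellation) regularizer alone — the lamina area is
constrained, not minimized. The stiffnesses γ, β are raised over an outer
schedule until all three residuals `|V_nuc/V_nuc,0 − 1|`, `|A_nuc/A_nuc,0 − 1|`,
`|V_cell/V_cell,0 − 1|` fall below 10⁻³. Contact (substrate plane,
cortex/nucleus, rigid microposts, optional confining plate) is handled by
reflecting penetrating vertices to the nearest admissible point, and the
Delaunay property of the meshes is maintained by edge flipping.

The morphometrics side quantifies what the model predicts: elliptical
Fourier (EFC) ratio of sub-pixel-traced lamina contours (higher = smoother),
nuclear height/surface area/volume from confocal z-stacks (130-nm z-step),
monolayer height maps and roughness SD, YAP nuclear-to-cytoplasmic ratios,
focal-adhesion density with size/circularity gates, pMLC intensity per area,
and area-over-time detachment traces — plus a seeded two-sample permutation
test for the roughness contrast. A synthetic-data module generates all of
these inputs with known ground truth.

## Worked example

The monolayer-cell configuration (cell volume 2800 µm³ over a 20-µm-radius
footprint; nuclear volume 800 µm³; lamina area 37 % in excess of the
equal-volume sphere):

```r
library(nucleodrop)

cfg <- drop_config(V_nuc0 = 800, excess_area_pct = 37, V_cell0 = 2800)
a <- 8.9; cz <- 3 * 800 / (4 * pi * a^2)
nuc  <- make_initial_mesh(list(type = "ellipsoid", semiaxes = c(a, a, cz)), 1.0)
nuc$vertices[, 3] <- nuc$vertices[, 3] + cz + 0.05
cell <- make_initial_mesh(list(type = "capped", radius = 20, height = 6.5), 1.9)

res <- solve_equilibrium(cfg, cell, nuc)
res
#> solve_result: converged after 3 stages; E = 4.5853
#>   residuals: |V_nuc/V0-1| = 3.25e-06, |A_nuc/A0-1| = 1.09e-06, |V_cell/V0-1| = 1.08e-05

drop_shape_metrics(res$nucleus)[c("height", "basal_z_range")]
#> $height        4.51      # um: flattened nucleus under the cortex
#> $basal_z_range 0.085     # um: flat substrate-contact face
```

The converged nucleus shows the drop-model signature: a flattened apical
contact under the cortex (apical mean curvature ≈ 0.067× the free-rim
curvature), a highly curved free rim, and a flat basal face. Driving a
1-µm-diameter micropost 2 µm into the rim and withdrawing it returns the
shape to within 0.5 % (Hausdorff / nuclear diameter) of the pre-indentation
equilibrium — the drop recovers.

Wrinkling quantification on a lobed contour family `r = R(1 + ε cos 5θ)`:

```r
th <- seq(0, 2 * pi, length.out = 257)[-257]
sapply(c(0.05, 0.1, 0.2), function(eps) {
  r <- 10 * (1 + eps * cos(5 * th))
  efc_ratio(elliptical_fourier(closed_contour(cbind(r * cos(th), r * sin(th)))))
})
#> [1] 20 10  5      # EFC ratio falls as wrinkle amplitude grows
```

And the vessel-chip operating point:

```r
wall_shear_stress(Q_uL_min = 10, eta_mPa_s = 0.8, w_um = 200, h_um = 200)
#> [1] 1             # dyne/cm^2
```

## Analysis workflow

The `analysis/` scripts run the full study on synthetic data and write
tables and meshes under `results/`:

| script | what it does |
|---|---|
| `01_synthesize.R` | wrinkled (37 % excess) vs taut (3 %) nuclei at V = 800 µm³, rendered lamin stacks, YAP scene, detachment series |
| `02_solve_drop_shapes.R` | free-drop isoperimetric control and the confined monolayer-cell equilibrium |
| `03_indentation.R` | micropost indentation/withdrawal round trip |
| `04_morphometrics.R` | measures the rendered stacks against ground truth (V, A, height, EFC, YAP, FA, detachment) |
| `05_stats.R` | roughness of 8 static-like vs 8 shear-like monolayers; permutation and rank tests |

Run them in order from the repository root (`Rscript analysis/01_synthesize.R`, …).

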