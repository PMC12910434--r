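#!/usr/bin/env Rscript
# Micropost indentation control: drive a 1-um-diameter rigid post 2 um into
# the rim of the converged nucleus from 02, then withdraw it along the same
# path. A drop with an intact (surface-tension-bearing) lamina must recover
# its pre-indentation shape; the Hausdorff distance quantifies recovery.
# Requires: results/meshes/confined_state.rds from 02_solve_drop_shapes.R.

suppressPackageStartupMessages({
  library(nucleodrop)
  library(jsonlite)
})
fig <- readRDS("results/meshes/confined_state.rds")
cfg <- fig$cfg

nuc0 <- fig$nucleus
cen <- colMeans(nuc0$vertices)
R <- max(sqrt((nuc0$vertices[, 1] - cen[1])^2 +
                (nuc0$vertices[, 2] - cen[2])^2))
d_final <- R + 0.5 - 2
d_start <- R + 1.0

post_in <- obstacle(center_xy = c(cen[1] + d_final, cen[2]),
                    radius = 0.5, height = 5)
ind <- indent_with_post(fig, post_in, cfg,
                        path_from = c(cen[1] + d_start, cen[2]))
write_mesh_off(ind$nucleus, "results/meshes/indented_nucleus.off")

post_out <- obstacle(center_xy = c(cen[1] + d_start, cen[2]),
                     radius = 0.5, height = 5)
wd <- indent_with_post(ind, post_out, cfg,
                       path_from = c(cen[1] + d_final, cen[2]),
                       final_sweeps = 300)
write_mesh_off(wd$nucleus, "results/meshes/recovered_nucleus.off")

hd <- hausdorff_distance(wd$nucleus, nuc0)
report <- list(
  indented_residuals = as.list(ind$residuals),
  recovered_residuals = as.list(wd$residuals),
  hausdorff_um = hd,
  hausdorff_pct_of_diameter = 100 * hd / (2 * R),
  post_radius_um = 0.5,
  indent_depth_um = 2
)
write_json(report, "results/indentation.json", auto_unbox = TRUE, digits = NA)
message(sprintf(
  "indentation round trip: Hausdorff %.3f um (%.2f%% of nuclear diameter)",
  hd, report$hausdorff_pct_of_diameter
))
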