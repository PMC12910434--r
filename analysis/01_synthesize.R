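#!/usr/bin/env Rscript
# Build the synthetic study material: wrinkled vs taut nuclear surfaces at
# fixed volume, their rendered confocal stacks, monolayer fields with and
# without tall cells, and a YAP scene with known nuclear/cytoplasmic
# contrast. Everything downstream (02-05) measures these objects.

suppressPackageStartupMessages(library(nucleodrop))
dir.create("results", showWarnings = FALSE)
dir.create("results/meshes", showWarnings = FALSE)
seed <- 1L

# Nuclear surfaces: one wrinkled (rounded phenotype, 37% excess lamina area)
# and one taut (spread/sheared phenotype, 3% excess), same volume.
specs <- data.frame(label = c("wrinkled", "taut"),
                    excess = c(37, 3))
truth <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
  ns <- make_nucleus_surface(800, specs$excess[i], seed = seed + i)
  ns$surface$vertices[, 3] <-
    ns$surface$vertices[, 3] - min(ns$surface$vertices[, 3]) + 1
  write_mesh_off(ns$surface,
                 file.path("results/meshes",
                           paste0("nucleus_", specs$label[i], ".off")))
  rs <- render_stack(ns$surface, voxel_size = c(0.15, 0.15, 0.13),
                     signal = "shell", peak = 300, seed = seed + 10 + i)
  write_stack_tiff(rs$stack,
                   file.path("results",
                             paste0("stack_", specs$label[i], ".tif")))
  data.frame(label = specs$label[i],
             volume_um3 = ns$volume, area_um2 = ns$area,
             excess_pct = ns$excess_pct,
             height_um = diff(range(ns$surface$vertices[, 3])),
             amplitude = ns$amplitude)
}))
write.csv(truth, "results/nuclei_truth.csv", row.names = FALSE)
message("nuclear surfaces: ")
print(truth)

# YAP scene: four cells spanning cytoplasmic to strongly nuclear YAP.
sc <- make_yap_scene(nc_ratios = c(0.5, 1, 2, 4), noise_frac = 0.1,
                     seed = seed)
write_stack_tiff(sc$img, "results/yap_scene.tif")
write.csv(sc$truth, "results/yap_truth.csv", row.names = FALSE)

# Detachment time series (shear removes a rounding cell; neighbours fill in).
ser <- make_detachment_series(n_frames = 10, detach_frame = 7, seed = seed)
write.csv(ser$truth, "results/detachment_truth.csv", row.names = FALSE)

message("synthesis complete; ground truth under results/")
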