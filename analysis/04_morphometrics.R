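#!/usr/bin/env Rscript
# Measure the synthetic material from 01 with the image-analysis pipeline
# and compare against ground truth: nuclear volume/surface area/height and
# 3-plane EFC ratio from the lamin stacks; YAP nuclear-to-cytoplasmic
# ratios; FA density on a constructed vinculin field; detachment flags from
# the mask time series.
# Requires: outputs of 01_synthesize.R under results/.

suppressPackageStartupMessages(library(nucleodrop))
seed <- 1L

truth <- read.csv("results/nuclei_truth.csv")
rows <- lapply(seq_len(nrow(truth)), function(i) {
  st <- read_stack_tiff(file.path("results",
                                  paste0("stack_", truth$label[i], ".tif")))
  m <- measure_nuclei(st)$records
  data.frame(
    label = truth$label[i],
    volume_err_pct = 100 * abs(m$volume / truth$volume_um3[i] - 1),
    area_err_pct = 100 * abs(m$surface_area / truth$area_um2[i] - 1),
    height_err_planes = abs(m$height - truth$height_um[i]) / 0.13,
    efc_mean = m$efc_mean
  )
})
rec <- do.call(rbind, rows)
write.csv(rec, "results/morphometrics_recovery.csv", row.names = FALSE)
message("nuclear morphometrics recovery:")
print(rec)
message("EFC ordering (wrinkled < taut): ",
        rec$efc_mean[rec$label == "wrinkled"] <
          rec$efc_mean[rec$label == "taut"])

# YAP: rebuild the identical scene (same seed) for the exact masks.
sc <- make_yap_scene(nc_ratios = c(0.5, 1, 2, 4), noise_frac = 0.1,
                     seed = seed)
yap <- data.frame(
  cell = 1:4,
  true_ratio = sc$truth$nc_ratio,
  measured = vapply(1:4, function(i)
    yap_nc_ratio(sc$img, sc$nuc_labels == i, sc$cell_labels == i,
                 sc$bg_mask), numeric(1))
)
yap$err_pct <- 100 * abs(yap$measured / yap$true_ratio - 1)
write.csv(yap, "results/yap_recovery.csv", row.names = FALSE)
message("YAP N/C recovery (max err ", sprintf("%.2f", max(yap$err_pct)), "%):")
print(yap)

# FA density on a constructed 20-spot field (~1000 um^2).
px <- 0.2; n_side <- 159
img <- matrix(0, n_side, n_side)
rws <- matrix(rep(seq_len(n_side), n_side), n_side)
cls <- matrix(rep(seq_len(n_side), each = n_side), n_side)
centers <- expand.grid(r = seq(20, 140, length.out = 5),
                       c = seq(20, 140, length.out = 4))
for (i in seq_len(nrow(centers))) {
  d <- sqrt((rws - centers$r[i])^2 + (cls - centers$c[i])^2)
  img[d <= 4] <- 100
}
fa <- fa_density(image_stack(img, c(px, px, 0.13), "vinculin"))
message(sprintf("FA field: %d of %d spots detected, density %.4f /um^2",
                fa$count, nrow(centers), fa$density))

# Detachment flags from the time series.
ser <- make_detachment_series(n_frames = 10, detach_frame = 7, seed = seed)
at <- area_traces(ser$masks, pixel_size = c(0.5, 0.5))
write.csv(at$traces, "results/area_traces.csv", row.names = FALSE)
ok <- identical(at$status$detached, ser$truth$detached)
message("detachment flags match construction: ", ok)
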