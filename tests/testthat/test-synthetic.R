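test_that("nucleus generator hits prescribed volume and excess area", {
  ns <- make_nucleus_surface(800, 37, seed = 2)
  expect_lt(abs(ns$excess_pct / 37 - 1), 0.01)
  expect_lt(abs(ns$volume / 800 - 1), 1e-3)
  expect_equal(ns$area, surface_area(ns$surface))
  expect_silent(validate_tri_surface(ns$surface))

  # excess 0: a sphere within 0.5% radial deviation
  s0 <- make_nucleus_surface(800, 0, seed = 2)
  rr <- sqrt(rowSums(s0$surface$vertices^2))
  expect_lt(max(abs(rr / mean(rr) - 1)), 0.005)

  # determinism: same seed, identical mesh; different seed, different phase
  a <- make_nucleus_surface(500, 20, seed = 7)
  b <- make_nucleus_surface(500, 20, seed = 7)
  c2 <- make_nucleus_surface(500, 20, seed = 8)
  expect_identical(a$surface$vertices, b$surface$vertices)
  expect_false(isTRUE(all.equal(a$surface$vertices, c2$surface$vertices)))
  expect_lt(abs(c2$volume / a$volume - 1), 1e-6)
  expect_lt(abs(c2$excess_pct / a$excess_pct - 1), 0.02)

  # unreachable excess errors out
  expect_error(make_nucleus_surface(800, 500, wrinkle_orders = 2,
                                    max_amplitude = 0.2), "infeasible")
})

test_that("rendered stacks carry the surface geometry and noise model", {
  s <- make_initial_mesh(list(type = "sphere", radius = 3), 0.5)
  s$vertices[, 3] <- s$vertices[, 3] + 4
  # noiseless, unblurred shell: ring cross-sections at mid-height
  rs <- render_stack(s, voxel_size = c(0.2, 0.2, 0.13), signal = "shell",
                     psf_sigma_um = 0, background = 0, read_sd = 0, peak = 1,
                     seed = 1)
  kmid <- round(dim(rs$shell_mask)[3] / 2)
  plane <- rs$shell_mask[, , kmid]
  inner <- rs$solid_mask[, , kmid] - plane
  expect_gt(sum(plane), 0)
  expect_gt(sum(inner > 0), 0)       # hollow interior: it is a ring
  # solid mask volume matches the mesh volume
  vol <- sum(rs$solid_mask) * prod(c(0.2, 0.2, 0.13))
  expect_lt(abs(vol / enclosed_volume(s) - 1), 0.03)

  # empty-field background level
  rs2 <- render_stack(s, voxel_size = c(0.25, 0.25, 0.26), signal = "shell",
                      peak = 0, background = 12, read_sd = 0, seed = 2)
  expect_lt(abs(mean(rs2$stack$data) - 12), 0.5)

  # same seed bit-reproducible
  ra <- render_stack(s, signal = "solid", voxel_size = c(0.3, 0.3, 0.26), seed = 5)
  rb <- render_stack(s, signal = "solid", voxel_size = c(0.3, 0.3, 0.26), seed = 5)
  expect_identical(ra$stack$data, rb$stack$data)
})

test_that("monolayer generator produces flat fields and dome-raised roughness", {
  flat <- make_monolayer(field_um = c(40, 40), n_cells = 12,
                         tall_cell_fraction = 0, seed = 3)
  expect_true(all(flat$true_height == 3))
  hm <- monolayer_height_map(flat$stack, crop_margin = 2, downsample = 4)
  expect_lt(hm$roughness_sd, 0.13)
  expect_lt(abs(mean(hm$grid) - 3), 0.13)

  tall <- make_monolayer(field_um = c(40, 40), n_cells = 12,
                         tall_cell_fraction = 0.25, tall_height = 8, seed = 3)
  expect_gt(max(tall$true_height), 6)
  hm_t <- monolayer_height_map(tall$stack, crop_margin = 2, downsample = 4)
  expect_gt(hm_t$roughness_sd, hm$roughness_sd)
  expect_gt(max(hm_t$grid), 6)       # the dome is visible in the map

  # reproducibility and the error contracts
  again <- make_monolayer(field_um = c(40, 40), n_cells = 12,
                          tall_cell_fraction = 0.25, tall_height = 8, seed = 3)
  expect_identical(tall$stack$data, again$stack$data)
  expect_error(monolayer_height_map(flat$stack, crop_margin = 50), "entire")
})

test_that("yap scenes realize requested contrast exactly and under noise", {
  sc <- make_yap_scene(nc_ratios = c(0.5, 1, 2, 4), noise_frac = 0, seed = 2)
  for (i in 1:4) {
    r <- yap_nc_ratio(sc$img, sc$nuc_labels == i, sc$cell_labels == i,
                      sc$bg_mask)
    expect_equal(r, sc$truth$nc_ratio[i], tolerance = 1e-6)
  }
  # with 10% noise, recovery within 15%
  scn <- make_yap_scene(nc_ratios = c(0.5, 1, 2, 4), noise_frac = 0.1, seed = 2)
  for (i in 1:4) {
    r <- yap_nc_ratio(scn$img, scn$nuc_labels == i, scn$cell_labels == i,
                      scn$bg_mask)
    expect_lt(abs(r / scn$truth$nc_ratio[i] - 1), 0.15)
  }
  # ratios constructed to rise with spread area give a positive correlation
  sc2 <- make_yap_scene(nc_ratios = 1 + order(order(
    make_yap_scene(nc_ratios = rep(1, 6), seed = 9)$truth$spread_area_um2
  )) * 0.4, seed = 9)
  meas <- vapply(1:6, function(i)
    yap_nc_ratio(sc2$img, sc2$nuc_labels == i, sc2$cell_labels == i,
                 sc2$bg_mask), numeric(1))
  expect_gt(cor(meas, sc2$truth$spread_area_um2), 0)
})

test_that("detachment series construction matches its contracts", {
  ser <- make_detachment_series(n_frames = 8, detach_frame = 5, seed = 4)
  areas <- vapply(ser$masks, function(m) sum(m == 1), numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_identical(areas[5], 0)
  expect_gt(areas[1], 0)
  # coverage never decreases
  cov <- vapply(ser$masks, function(m) sum(m > 0), numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_error(make_detachment_series(n_frames = 5, detach_frame = 6), "<")
})

test_that("stack TIFF round trip preserves data and metadata", {
  s <- make_initial_mesh(list(type = "sphere", radius = 2), 0.6)
  s$vertices[, 3] <- s$vertices[, 3] + 3
  rs <- render_stack(s, voxel_size = c(0.3, 0.3, 0.26), signal = "solid",
                     seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(rs$stack, path)
  rt <- read_stack_tiff(path)
  expect_equal(rt$voxel_size, rs$stack$voxel_size)
  expect_identical(rt$channel, rs$stack$channel)
  expect_lt(max(abs(rt$data - rs$stack$data)) / max(rs$stack$data), 2e-4)
})
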