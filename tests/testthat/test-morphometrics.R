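# A tiny synthetic lamin scene: bright rings on a dark background.
ring_image <- function(centers, r_in = 6, r_out = 8, dims = c(96, 96),
                       value = 100) {
  img <- matrix(0, dims[1], dims[2])
  for (cc in centers) {
    rows <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
    cols <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
    d <- sqrt((rows - cc[1])^2 + (cols - cc[2])^2)
    img[d >= r_in & d <= r_out] <- value
  }
  img
}

test_that("bulk segmentation finds disjoint nuclei and applies exclusion rules", {
  img <- ring_image(list(c(25, 25), c(25, 70), c(70, 48)))
  seg <- segment_nuclei_bulk(image_stack(img, c(0.2, 0.2, 0.13), "lamin"))
  expect_identical(length(setdiff(unique(as.vector(seg$labels)), 0L)), 3L)
  expect_identical(nrow(seg$exclusions), 0L)

  # a ring touching the frame edge is excluded
  img2 <- ring_image(list(c(8, 25), c(60, 60)))  # first ring hits row 1
  seg2 <- segment_nuclei_bulk(image_stack(img2, c(0.2, 0.2, 0.13), "lamin"))
  expect_true("edge" %in% seg2$exclusions$rule)
  expect_identical(length(setdiff(unique(as.vector(seg2$labels)), 0L)), 1L)

  # overlapping (touching) nuclei are excluded
  img3 <- ring_image(list(c(40, 40), c(40, 54)))
  seg3 <- segment_nuclei_bulk(image_stack(img3, c(0.2, 0.2, 0.13), "lamin"))
  expect_true(all(seg3$exclusions$rule == "overlap"))

  # uniform image yields no labels (with a warning)
  expect_warning(
    seg4 <- segment_nuclei_bulk(image_stack(matrix(5, 40, 40),
                                            c(0.2, 0.2, 0.13), "lamin")),
    "foreground|uniform"
  )
  expect_identical(max(seg4$labels), 0L)
})

test_that("sub-pixel tracing recovers a Gaussian ridge to within 0.1 px", {
  # Gaussian ridge ring of known radius, pixel size 0.2 um
  px <- 0.2
  dims <- c(120, 120)
  r_true <- 8.3          # um
  cen <- c(60, 60)       # pixel indices
  rows <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  cols <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  d_um <- sqrt((rows - cen[1])^2 + (cols - cen[2])^2) * px
  img <- 100 * exp(-(d_um - r_true)^2 / (2 * 0.3^2))
  # bulk contour deliberately offset by ~0.4 px in radius
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  bulk <- closed_contour(cbind((cen[2] - 1) * px + (r_true + 0.4 * px) * cos(th),
                               (cen[1] - 1) * px + (r_true + 0.4 * px) * sin(th)))
  traced <- trace_lamina_subpixel(img, bulk, probe_len = 1.5, pixel_size = c(px, px))
  r_traced <- sqrt(rowSums(sweep(traced$points, 2,
                                 c((cen[2] - 1) * px, (cen[1] - 1) * px))^2))
  expect_lt(max(abs(r_traced - r_true)), 0.1 * px)

  # flat intensity: bulk points are retained and flagged
  flat <- matrix(7, dims[1], dims[2])
  tf <- trace_lamina_subpixel(flat, bulk, probe_len = 1.5, pixel_size = c(px, px))
  expect_true(all(attr(tf, "fallback")))
  expect_equal(tf$points, bulk$points)

  # ridge shifted 1 px outward -> traced radius follows by 1 px
  img_shift <- 100 * exp(-(d_um - (r_true + px))^2 / (2 * 0.3^2))
  ts <- trace_lamina_subpixel(img_shift, bulk, probe_len = 1.5,
                              pixel_size = c(px, px))
  r_shift <- sqrt(rowSums(sweep(ts$points, 2,
                                c((cen[2] - 1) * px, (cen[1] - 1) * px))^2))
  expect_lt(max(abs(r_shift - (r_true + px))), 0.1 * px)
})

test_that("nuclear height finds onset/offset planes against background", {
  # synthetic stack: planes 10..40 carry in-mask signal, dz = 0.13
  dims <- c(40, 40); nz <- 50
  arr <- array(0, c(dims, nz))
  mask <- matrix(FALSE, dims[1], dims[2]); mask[15:25, 15:25] <- TRUE
  set.seed(5)
  arr[] <- rpois(length(arr), 5)                       # background
  for (k in 10:40) arr[, , k][mask] <- arr[, , k][mask] + 80
  st <- image_stack(arr, c(0.2, 0.2, 0.13), "lamin")
  nh <- nuclear_height(st, mask)
  expect_equal(nh$height, 3.9, tolerance = 2 * 0.13 / 3.9)
  expect_lte(abs(nh$onset - 10), 2)
  expect_lte(abs(nh$offset - 40), 2)

  # doubling dz doubles the height
  st2 <- image_stack(arr, c(0.2, 0.2, 0.26), "lamin")
  expect_equal(nuclear_height(st2, mask)$height, 2 * nh$height)

  # all-background stack: height 0 with a warning
  bgonly <- image_stack(array(rpois(prod(dims) * 5, 5), c(dims, 5)),
                        c(0.2, 0.2, 0.13), "lamin")
  expect_warning(h0 <- nuclear_height(bgonly, mask), "background")
  expect_identical(h0$height, 0)
})

test_that("3-plane EFC averaging behaves on constructed stacks", {
  # identical cross-sections: efc_mean equals the single-plane value
  px <- 0.2; dims <- c(100, 100); nz <- 30
  rows <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  cols <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  d_um <- sqrt((rows - 50)^2 + (cols - 50)^2) * px
  ring <- 100 * exp(-(d_um - 6)^2 / (2 * 0.3^2))
  arr <- array(2, c(dims, nz))
  for (k in 8:24) arr[, , k] <- arr[, , k] + ring
  st <- image_stack(arr, c(px, px, 0.13), "lamin")
  mask <- d_um <= 6.5
  res <- nucleus_efc_3plane(st, mask)
  expect_false(res$flag)
  expect_identical(length(res$per_plane), 3L)
  expect_lt(diff(range(res$per_plane)) / mean(res$per_plane), 0.01)
  expect_equal(res$efc_mean, mean(res$per_plane))

  # wrinkled vs smooth cross-sections order correctly
  r_l <- 6 * (1 + 0.18 * cos(5 * atan2(rows - 50, cols - 50)))
  ring_l <- 100 * exp(-(d_um - r_l)^2 / (2 * 0.3^2))
  arr_l <- array(2, c(dims, nz))
  for (k in 8:24) arr_l[, , k] <- arr_l[, , k] + ring_l
  st_l <- image_stack(arr_l, c(px, px, 0.13), "lamin")
  res_l <- nucleus_efc_3plane(st_l, d_um <= 8)
  expect_lt(res_l$efc_mean, res$efc_mean)
})

test_that("surface/volume from binary regions converge and scale with voxel size", {
  # voxelized ball r = 5 at (0.1, 0.1, 0.13)
  dx <- 0.1; dz <- 0.13
  xs <- seq(-6, 6, by = dx); zs <- seq(-6, 6, by = dz)
  mask <- array(0, c(length(xs), length(xs), length(zs)))
  for (k in seq_along(zs)) {
    mask[, , k] <- (outer(xs^2, xs^2, "+") + zs[k]^2 <= 25) * 1
  }
  sv <- nuclear_surface_volume(mask, c(dx, dx, dz))
  expect_lt(abs(sv$volume / (4 / 3 * pi * 125) - 1), 0.03)
  expect_lt(abs(sv$surface_area / (4 * pi * 25) - 1), 0.05)

  # doubling all voxel sizes: V x8, A x4 (same binary grid)
  sv2 <- nuclear_surface_volume(mask, 2 * c(dx, dx, dz))
  expect_equal(sv2$volume / sv$volume, 8)
  expect_equal(sv2$surface_area / sv$surface_area, 4, tolerance = 1e-6)

  expect_identical(nuclear_surface_volume(array(0, c(4, 4, 4)))$volume, 0)
})

test_that("YAP N/C ratio implements the background-subtracted formula", {
  img <- matrix(50, 60, 60)
  cell <- matrix(FALSE, 60, 60); cell[20:40, 20:40] <- TRUE
  nuc <- matrix(FALSE, 60, 60); nuc[27:33, 27:33] <- TRUE
  bg <- matrix(FALSE, 60, 60); bg[1:10, 1:10] <- TRUE
  img[cell] <- 100
  img[nuc] <- 200
  st <- image_stack(img, c(0.2, 0.2, 0.13), "yap")
  expect_equal(yap_nc_ratio(st, nuc, cell, bg), 3.0)

  # uniform image -> ratio undefined (cytoplasm at background)
  uni <- image_stack(matrix(80, 60, 60), c(0.2, 0.2, 0.13), "yap")
  expect_warning(r <- yap_nc_ratio(uni, nuc, cell, bg), "undefined")
  expect_true(is.na(r))

  expect_error(yap_nc_ratio(st, cell, nuc, bg), "inside")
})

test_that("FA density applies the size and circularity gates", {
  px <- 0.2
  img <- matrix(0, 200, 200)
  # 12 round spots of area ~2 um^2 (radius ~4 px)
  centers <- expand.grid(r = c(40, 80, 120, 160), c = c(50, 100, 150))
  rows <- matrix(rep(1:200, 200), 200)
  cols <- matrix(rep(1:200, each = 200), 200)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((rows - centers$r[i])^2 + (cols - centers$c[i])^2)
    img[d <= 4] <- 100
  }
  # a sub-gate speck (area ~0.12 um^2) and a 1-px-wide filament
  img[20, 20] <- 100; img[20, 21] <- 100; img[21, 20] <- 100
  img[180, 30:120] <- 100
  st <- image_stack(img, c(px, px, 0.13), "vinculin")
  fa <- fa_density(st)
  expect_identical(fa$count, 12L)
  expect_equal(fa$density, 12 / (200 * 200 * px^2))
  expect_true(all(fa$particles$area_um2 >= 0.5 & fa$particles$area_um2 <= 15))

  # spots touching the ROI edge are excluded
  roi <- c(36, 84, 46, 104)  # contains spot (40,50) fully, cuts others
  fa2 <- fa_density(st, roi)
  expect_lt(fa2$count, 4L)
})

test_that("pMLC intensity per area normalizes by ROI area", {
  st <- image_stack(array(10, c(50, 50, 4)), c(0.2, 0.2, 0.13), "pmlc")
  # uniform 10 over a 10x10 um ROI -> 10 / 100
  expect_equal(pmlc_per_area(st, roi = c(1, 50, 1, 50)), 10 / 100)
  # doubling the ROI area halves the value
  st2 <- image_stack(array(10, c(50, 100, 4)), c(0.2, 0.2, 0.13), "pmlc")
  expect_equal(pmlc_per_area(st2), 10 / 200)
  expect_error(pmlc_per_area(st, roi = c(2, 1, 2, 1)), "ROI")
})

test_that("cell area and aspect ratio come from the second-moment ellipse", {
  m <- matrix(FALSE, 60, 60); m[10:19, 10:19] <- TRUE
  ca <- cell_area_aspect(m, c(0.5, 0.5))
  expect_equal(ca$area, 25)
  expect_equal(ca$aspect_ratio, 1, tolerance = 1e-6)

  m2 <- matrix(FALSE, 80, 80); m2[10:49, 10:19] <- TRUE  # 40 x 10 px
  ca2 <- cell_area_aspect(m2, c(0.5, 0.5))
  expect_equal(ca2$aspect_ratio, 4, tolerance = 0.05)
  # rotation by 90 degrees leaves both outputs unchanged
  ca3 <- cell_area_aspect(t(m2), c(0.5, 0.5))
  expect_equal(ca3$area, ca2$area)
  expect_equal(ca3$aspect_ratio, ca2$aspect_ratio)
})

test_that("area traces flag the constructed detaching object only", {
  ser <- make_detachment_series(n_frames = 10, detach_frame = 7, seed = 3)
  at <- area_traces(ser$masks, pixel_size = c(0.5, 0.5))
  expect_identical(at$status$detached, ser$truth$detached)
  # the detaching object's trace declines monotonically to zero
  a1 <- at$traces$area_um2[at$traces$object == 1]
  expect_true(all(diff(a1) <= 0))
  expect_identical(a1[10], 0)
  # neighbours fill in: total covered area is constant
  tot <- tapply(at$traces$area_um2, at$traces$frame, sum)
  expect_true(all(abs(tot - tot[1]) < 1e-9))
  # a retained neighbour grows after the detachment
  a2 <- at$traces$area_um2[at$traces$object == 2]
  expect_gt(a2[10], a2[1])

  # zero-detachment series: no flags
  ser0 <- make_detachment_series(n_frames = 6, detach_frame = NA, seed = 3)
  at0 <- area_traces(ser0$masks)
  expect_false(any(at0$status$detached))
})
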