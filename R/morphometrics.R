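norm01 <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m)
  m / mx
}

#' Segment nuclei from a lamin stack (bulk masks)
#'
#' Otsu threshold on the max-intensity projection of the lamin channel,
#' connected-component labelling, then exclusion of components touching the
#' image edge and of components that overlap others (touching after a
#' one-pixel dilation). Excluded labels are reported, not silently dropped.
#'
#' @param lamin_stack an [image_stack()] (lamin channel).
#' @return list with `labels` (integer matrix, 0 = background; labels are
#'   the original component ids), and `exclusions` (data.frame of label and
#'   the rule that fired: `edge` or `overlap`).
#' @export
segment_nuclei_bulk <- function(lamin_stack) {
  mp <- max_projection(lamin_stack)
  mn <- norm01(mp)
  if (max(mn) == 0 || diff(range(mn)) == 0) {
    warning("empty foreground: uniform image")
    return(list(labels = matrix(0L, nrow(mp), ncol(mp)),
                exclusions = data.frame(label = integer(), rule = character())))
  }
  th <- EBImage::otsu(EBImage::Image(mn))
  bw <- mn > th
  if (!any(bw)) {
    warning("empty foreground after thresholding")
    return(list(labels = matrix(0L, nrow(mp), ncol(mp)),
                exclusions = data.frame(label = integer(), rule = character())))
  }
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(mp), ncol(mp))
  excl <- data.frame(label = integer(), rule = character())
  # edge exclusion
  edge_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  edge_ids <- setdiff(edge_ids, 0L)
  if (length(edge_ids)) {
    excl <- rbind(excl, data.frame(label = edge_ids, rule = "edge"))
  }
  # overlap exclusion: labels whose one-pixel dilation touches another label
  ids <- setdiff(unique(as.vector(lab)), 0L)
  overlap_ids <- integer()
  if (length(ids) > 1L) {
    br <- EBImage::makeBrush(3, "box")
    for (id in ids) {
      d <- EBImage::dilate(lab == id, br)
      neigh <- unique(lab[d > 0])
      if (any(!neigh %in% c(0L, id))) overlap_ids <- c(overlap_ids, id)
    }
  }
  overlap_ids <- setdiff(overlap_ids, edge_ids)
  if (length(overlap_ids)) {
    excl <- rbind(excl, data.frame(label = overlap_ids, rule = "overlap"))
  }
  lab[lab %in% excl$label] <- 0L
  list(labels = lab, exclusions = excl)
}

# Bilinear sampling of a matrix at fractional (row, col) positions (1-based);
# NA outside.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  r0 <- pmin(floor(row[ok]), nr - 1L); c0 <- pmin(floor(col[ok]), nc - 1L)
  fr <- row[ok] - r0; fc <- col[ok] - c0
  out[ok] <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}

#' Boundary contour of one labelled mask in physical units
#'
#' @param labels integer matrix (or logical mask).
#' @param id label to trace (ignored for logical masks).
#' @param pixel_size `(dx, dy)` um.
#' @return a [closed_contour()] (x = column direction, y = row direction).
#' @export
mask_to_contour <- function(labels, id = 1L, pixel_size = c(0.1, 0.1)) {
  m <- if (is.logical(labels)) labels else labels == id
  if (!any(m)) stop("empty mask for label ", id)
  oc <- EBImage::ocontour(EBImage::Image(m * 1))[[1]]
  # EBImage returns (first-dim index, second-dim index), 0-based
  x_um <- oc[, 2] * pixel_size[1]
  y_um <- oc[, 1] * pixel_size[2]
  closed_contour(cbind(x_um, y_um), source = "bulk")
}

#' Sub-pixel lamina tracing along contour normals
#'
#' Refines a bulk nuclear contour by sampling the image along the local
#' outward normal at each contour point over `+/- probe_len` and placing
#' the refined point at the parabolically interpolated intensity maximum
#' (3-point fit around the discrete peak). Probes that exit the image, or
#' flat intensity profiles, leave the bulk point unchanged (flagged).
#'
#' @param plane 2D [image_stack()] (or matrix with `pixel_size` given).
#' @param bulk_contour a [closed_contour()] in um.
#' @param probe_len half-length of the normal probe (um).
#' @param pixel_size `(dx, dy)` um; taken from `plane` when it is a stack.
#' @param step probe sampling step (um); default a quarter pixel.
#' @return a [closed_contour()] with `source = "subpixel"` and attribute
#'   `fallback` (logical vector marking retained bulk points).
#' @export
trace_lamina_subpixel <- function(plane, bulk_contour, probe_len = 1.5,
                                  pixel_size = NULL, step = NULL) {
  if (inherits(plane, "image_stack")) {
    pixel_size <- plane$voxel_size[1:2]
    img <- plane$data[, , 1]
  } else {
    img <- plane
    if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
  }
  if (is.null(step)) step <- 0.25 * min(pixel_size)
  pts <- bulk_contour$points
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  tang <- nxt - prv
  tl <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(tl, .Machine$double.eps)
  nrm <- cbind(tang[, 2], -tang[, 1])        # outward for CCW traversal
  if (polygon_area(pts) < 0) nrm <- -nrm     # CW input
  ss <- seq(-probe_len, probe_len, by = step)
  out <- pts
  fallback <- rep(FALSE, n)
  for (i in seq_len(n)) {
    px <- pts[i, 1] + ss * nrm[i, 1]
    py <- pts[i, 2] + ss * nrm[i, 2]
    vals <- bilinear_sample(img, py / pixel_size[2] + 1, px / pixel_size[1] + 1)
    if (anyNA(vals) || diff(range(vals)) < 1e-12) { fallback[i] <- TRUE; next }
    j <- which.max(vals)
    if (j == 1L || j == length(vals)) { fallback[i] <- TRUE; next }
    # least-squares parabola over a window recentered on the running peak
    # estimate; the window smooths interpolation kinks that bias a plain
    # 3-point fit, and recentering removes the window-asymmetry bias
    s_hat <- ss[j]
    wlen <- max(2 * step, 0.3)
    ok_fit <- FALSE
    for (pass in 1:3) {
      idx <- which(abs(ss - s_hat) <= wlen)
      if (length(idx) < 5L) break
      fit <- stats::lm.fit(cbind(1, ss[idx] - s_hat, (ss[idx] - s_hat)^2),
                           vals[idx])
      a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
      if (!is.finite(a2) || a2 >= 0) break
      s_hat <- s_hat - a1 / (2 * a2)
      ok_fit <- TRUE
    }
    if (!ok_fit) { fallback[i] <- TRUE; next }
    s_hat <- min(max(s_hat, ss[max(1L, j - 2L)]), ss[min(length(ss), j + 2L)])
    out[i, ] <- pts[i, ] + s_hat * nrm[i, ]
  }
  res <- closed_contour(out, plane_z = bulk_contour$plane_z, source = "subpixel")
  attr(res, "fallback") <- fallback
  res
}

# Background intensity statistics from a cell-free region: by default a
# border frame of the max projection, 0.8 um wide (kept physical so coarse
# pixel grids do not push the frame into the signal).
background_stats <- function(stack, bg_mask = NULL, border_um = 0.8) {
  mp <- max_projection(stack)
  if (is.null(bg_mask)) {
    border_px <- max(2L, floor(border_um / min(stack$voxel_size[1:2])))
    bg_mask <- matrix(FALSE, nrow(mp), ncol(mp))
    bg_mask[c(seq_len(border_px), nrow(mp) - seq_len(border_px) + 1L), ] <- TRUE
    bg_mask[, c(seq_len(border_px), ncol(mp) - seq_len(border_px) + 1L)] <- TRUE
  }
  per_plane <- apply(stack$data, 3, function(pl) pl[bg_mask])
  c(mean = mean(per_plane), sd = stats::sd(as.vector(per_plane)))
}

#' Nuclear height from the z-profile of lamin intensity
#'
#' The mean in-mask lamin intensity is computed per z-plane; the onset and
#' offset planes are the first and last whose mean exceeds the background
#' criterion (background mean + 3 background SD, estimated from a cell-free
#' border region unless `bg_mask` is given). Height is the onset-offset
#' plane distance times the z-step.
#'
#' @param lamin_stack an [image_stack()].
#' @param mask 2D logical mask of the nucleus (xy footprint).
#' @param bg_mask optional logical matrix marking cell-free background.
#' @param k_sd background SD multiplier (default 3).
#' @return list with `height` (um), `onset`, `offset` (plane indices) and
#'   `profile` (per-plane means).
#' @export
nuclear_height <- function(lamin_stack, mask, bg_mask = NULL, k_sd = 3) {
  prof <- apply(lamin_stack$data, 3, function(pl) mean(pl[mask]))
  bg <- background_stats(lamin_stack, bg_mask)
  thr <- bg["mean"] + k_sd * bg["sd"]
  above <- which(prof > thr)
  if (!length(above)) {
    warning("no plane above background: height 0")
    return(list(height = 0, onset = NA_integer_, offset = NA_integer_,
                profile = prof))
  }
  onset <- min(above); offset <- max(above)
  list(height = (offset - onset) * lamin_stack$voxel_size[3],
       onset = onset, offset = offset, profile = prof)
}

#' Mean EFC ratio over three fractional-height planes
#'
#' Extracts sub-pixel lamina contours at the z-planes nearest 25%, 50% and
#' 75% of the nuclear height and averages their EFC ratios. Nuclei spanning
#' fewer than 3 planes fall back to the single available mid-plane (with
#' `flag = TRUE`).
#'
#' @param lamin_stack an [image_stack()].
#' @param mask 2D logical bulk mask of the nucleus.
#' @param probe_len normal probe half-length (um) for sub-pixel tracing.
#' @param bg_mask optional background mask for the height criterion.
#' @return list with `efc_mean`, `per_plane` (ratios), `planes` (indices),
#'   `flag`.
#' @export
nucleus_efc_3plane <- function(lamin_stack, mask, probe_len = 1.5,
                               bg_mask = NULL) {
  nh <- nuclear_height(lamin_stack, mask, bg_mask)
  if (is.na(nh$onset)) stop("nucleus has no planes above background")
  span <- nh$offset - nh$onset
  if (span + 1L < 3L) {
    mid <- nh$onset + span %/% 2L
    bc <- mask_to_contour(mask, pixel_size = lamin_stack$voxel_size[1:2])
    tc <- trace_lamina_subpixel(
      image_stack(lamin_stack$data[, , mid, drop = FALSE],
                  lamin_stack$voxel_size, lamin_stack$channel),
      bc, probe_len
    )
    r <- efc_ratio(elliptical_fourier(tc))
    return(list(efc_mean = r, per_plane = r, planes = mid, flag = TRUE))
  }
  planes <- nh$onset + round(c(0.25, 0.5, 0.75) * span)
  bc <- mask_to_contour(mask, pixel_size = lamin_stack$voxel_size[1:2])
  ratios <- vapply(planes, function(pz) {
    pl <- image_stack(lamin_stack$data[, , pz, drop = FALSE],
                      lamin_stack$voxel_size, lamin_stack$channel)
    tc <- trace_lamina_subpixel(pl, bc, probe_len)
    efc_ratio(elliptical_fourier(tc))
  }, numeric(1))
  list(efc_mean = mean(ratios), per_plane = ratios, planes = planes,
       flag = FALSE)
}

#' Nuclear surface area and volume from a 3D binary region
#'
#' Volume is the voxel count times the voxel volume; surface area comes
#' from a marching-tetrahedra triangulated isosurface of the (lightly
#' smoothed) binary region with the anisotropic voxel spacing. Both
#' converge to the analytic values for voxelized smooth bodies.
#'
#' @param mask 3D logical/0-1 array (`[y, x, z]`) of the nuclear region.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param smooth_sigma_vox Gaussian pre-smoothing scale in voxels (applied
#'   per axis, so the estimate depends only on the binary grid and scales
#'   exactly with the voxel size). One voxel is the minimal anti-aliasing
#'   scale: it suppresses the voxel staircase (which otherwise biases the
#'   area high) while eroding little genuine wrinkle area; 0 disables.
#' @return list with `surface_area` (um^2) and `volume` (um^3).
#' @export
nuclear_surface_volume <- function(mask, voxel_size = c(0.1, 0.1, 0.13),
                                   smooth_sigma_vox = 1.0) {
  mask <- (mask > 0) * 1.0
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (sum(mask) == 0) return(list(surface_area = 0, volume = 0))
  vol <- sum(mask) * prod(voxel_size)
  f <- mask
  if (smooth_sigma_vox > 0) {
    f <- smooth_gaussian3(mask, rep(smooth_sigma_vox, 3))
  }
  area <- marching_tet_area(f, c(voxel_size[1], voxel_size[2], voxel_size[3]))
  list(surface_area = area, volume = vol)
}

# Even-odd scanline rasterization of a closed polygon (um coords) onto the
# pixel grid; pixel (r, c) center is at ((c-1)*dx, (r-1)*dy).
rasterize_polygon <- function(poly, pixel_size, dims) {
  nr <- dims[1]; nc <- dims[2]
  dx <- pixel_size[1]; dy <- pixel_size[2]
  out <- matrix(FALSE, nr, nc)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  for (r in seq_len(nr)) {
    yy <- (r - 1) * dy
    crosses <- (y1 <= yy & y2 > yy) | (y2 <= yy & y1 > yy)
    if (!any(crosses)) next
    xs <- x1[crosses] + (yy - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xs <- sort(xs)
    np <- (length(xs) %/% 2) * 2
    for (p in seq_len(np %/% 2)) {
      c0 <- ceiling(xs[2 * p - 1] / dx) + 1L
      c1 <- floor(xs[2 * p] / dx) + 1L
      if (c1 >= c0) out[r, max(1L, c0):min(nc, c1)] <- TRUE
    }
  }
  out
}

#' Solid 3D nuclear mask from a lamin (shell) stack
#'
#' Per z-plane: Otsu threshold (whole-stack), hole filling of the lamina
#' ring, then sub-pixel ridge tracing of the lamina along the bulk contour
#' and even-odd rasterization of the traced polygon, so the mask boundary
#' sits on the lamina ridge rather than the outer edge of the thresholded
#' band. Planes whose cross-section is too small to trace fall back to the
#' filled bulk mask.
#'
#' @param lamin_stack an [image_stack()].
#' @param mask optional 2D footprint to restrict to.
#' @param probe_len normal probe half-length (um) for the ridge tracing.
#' @return 3D 0/1 array.
#' @export
solid_mask_from_lamin <- function(lamin_stack, mask = NULL, probe_len = 0.8) {
  d <- norm01(lamin_stack$data)
  vx <- lamin_stack$voxel_size
  th <- EBImage::otsu(EBImage::Image(as.vector(d), dim = c(length(d), 1)))
  shell <- d > th
  out <- array(0, dim(d))
  for (k in seq_len(dim(d)[3])) {
    bw <- EBImage::fillHull(shell[, , k])
    if (!is.null(mask)) bw <- bw & mask
    if (!any(bw)) next
    filled <- as.numeric(bw)
    # keep the largest component only (stray specks break the contour)
    lab <- EBImage::bwlabel(bw)
    if (max(lab) > 1L) {
      sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
      bw <- lab == which.max(sizes)
      filled <- as.numeric(bw)
    }
    if (sum(bw) < 25) { out[, , k] <- filled; next }
    traced <- tryCatch({
      bc <- mask_to_contour(bw, pixel_size = vx[1:2])
      tc <- trace_lamina_subpixel(lamin_stack$data[, , k], bc, probe_len,
                                  pixel_size = vx[1:2])
      rasterize_polygon(tc$points, vx[1:2], dim(bw))
    }, error = function(e) NULL)
    out[, , k] <- if (is.null(traced)) filled else as.numeric(traced)
  }
  out
}

#' YAP nuclear-to-cytoplasmic intensity ratio
#'
#' `[(nuclear mean) - (background mean)] / [(cytoplasmic mean) -
#' (background mean)]` on the max projection; the cytoplasm is the cell
#' mask minus the nuclear mask. An undefined ratio (cytoplasmic mean at or
#' below background) is reported as `NA` with a warning.
#'
#' @param yap_img an [image_stack()] (YAP channel).
#' @param nuc_mask,cell_mask 2D logical masks, nucleus inside cell.
#' @param bg_mask 2D logical mask of a cell-free region.
#' @return dimensionless ratio (or `NA`).
#' @export
yap_nc_ratio <- function(yap_img, nuc_mask, cell_mask, bg_mask) {
  if (any(nuc_mask & !cell_mask)) stop("nuc_mask must lie inside cell_mask")
  if (any(bg_mask & cell_mask)) stop("bg_mask must be disjoint from the cell")
  mp <- max_projection(yap_img)
  cyto <- cell_mask & !nuc_mask
  b <- mean(mp[bg_mask])
  nm <- mean(mp[nuc_mask]) - b
  cm <- mean(mp[cyto]) - b
  if (cm <= 0) {
    warning("cytoplasmic mean at or below background: ratio undefined")
    return(NA_real_)
  }
  nm / cm
}

#' Focal adhesion density in a region of interest
#'
#' Otsu threshold on the vinculin image inside the ROI, connected
#' components, then particle gates: area in `[0.5, 15]` um^2 and
#' circularity `4 pi A / P^2` in `[0.1, 1]`, excluding components touching
#' the ROI edge; the surviving count is divided by the ROI area.
#'
#' @param vinculin_img an [image_stack()]; the max projection is analyzed.
#' @param roi integer vector `(row0, row1, col0, col1)` (1-based,
#'   inclusive); default whole image.
#' @param area_gate particle area bounds (um^2).
#' @param circ_gate circularity bounds.
#' @return list with `density` (count/um^2), `count`, `roi_area_um2`,
#'   `particles` (data.frame of area/circularity of retained particles).
#' @export
fa_density <- function(vinculin_img, roi = NULL,
                       area_gate = c(0.5, 15), circ_gate = c(0.1, 1.0)) {
  mp <- max_projection(vinculin_img)
  px <- vinculin_img$voxel_size[1:2]
  if (is.null(roi)) roi <- c(1L, nrow(mp), 1L, ncol(mp))
  sub <- mp[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  roi_area <- prod(dim(sub)) * px[1] * px[2]
  mn <- norm01(sub)
  if (max(mn) == 0) {
    return(list(density = 0, count = 0L, roi_area_um2 = roi_area,
                particles = data.frame(area_um2 = numeric(),
                                       circularity = numeric())))
  }
  th <- EBImage::otsu(EBImage::Image(mn))
  lab <- EBImage::bwlabel(mn > th)
  if (max(lab) == 0) {
    return(list(density = 0, count = 0L, roi_area_um2 = roi_area,
                particles = data.frame(area_um2 = numeric(),
                                       circularity = numeric())))
  }
  fs <- EBImage::computeFeatures.shape(lab)
  labm <- matrix(as.integer(lab), nrow(sub), ncol(sub))
  edge_ids <- setdiff(unique(c(labm[1, ], labm[nrow(labm), ],
                               labm[, 1], labm[, ncol(labm)])), 0L)
  area_um2 <- fs[, "s.area"] * px[1] * px[2]
  # perimeter in physical units (isotropic pixels assumed for the gate)
  per_um <- fs[, "s.perimeter"] * mean(px)
  circ <- 4 * pi * area_um2 / pmax(per_um^2, .Machine$double.eps)
  circ <- pmin(circ, 1)  # discrete perimeters can nudge above 1 for tiny blobs
  ids <- seq_len(nrow(fs))
  keep <- area_um2 >= area_gate[1] & area_um2 <= area_gate[2] &
    circ >= circ_gate[1] & circ <= circ_gate[2] &
    !(ids %in% edge_ids)
  list(density = sum(keep) / roi_area, count = sum(keep),
       roi_area_um2 = roi_area,
       particles = data.frame(area_um2 = area_um2[keep],
                              circularity = circ[keep]))
}

#' Mean pMLC intensity per unit area
#'
#' Average-intensity z-projection over the monolayer planes, then the mean
#' gray value in the ROI divided by the ROI area.
#'
#' @param pmlc_stack an [image_stack()].
#' @param roi `(row0, row1, col0, col1)` 1-based inclusive; default whole
#'   image.
#' @param planes z planes containing the monolayer (default all).
#' @return intensity per area (a.u./um^2).
#' @export
pmlc_per_area <- function(pmlc_stack, roi = NULL, planes = NULL) {
  pr <- mean_projection(pmlc_stack, planes)
  if (is.null(roi)) roi <- c(1L, nrow(pr), 1L, ncol(pr))
  if (roi[2] < roi[1] || roi[4] < roi[3]) stop("empty ROI")
  sub <- pr[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  px <- pmlc_stack$voxel_size[1:2]
  mean(sub) / (prod(dim(sub)) * px[1] * px[2])
}

#' Cell spreading area and aspect ratio from a mask
#'
#' Area is the pixel count times the pixel area; the aspect ratio is the
#' major/minor axis ratio of the second-moment (best-fit) ellipse, always
#' >= 1 and invariant to rotation.
#'
#' @param cell_mask 2D logical mask.
#' @param pixel_size `(dx, dy)` um.
#' @return list with `area` (um^2) and `aspect_ratio`.
#' @export
cell_area_aspect <- function(cell_mask, pixel_size = c(0.1, 0.1)) {
  idx <- which(cell_mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  area <- nrow(idx) * pixel_size[1] * pixel_size[2]
  xy <- cbind(idx[, 2] * pixel_size[1], idx[, 1] * pixel_size[2])
  if (nrow(idx) < 3) return(list(area = area, aspect_ratio = 1))
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE)$values
  ev <- pmax(ev, .Machine$double.eps)
  list(area = area, aspect_ratio = sqrt(ev[1] / ev[2]))
}

#' Per-object area traces over time with detachment flags
#'
#' Computes per-frame areas for each labelled object across a time series of
#' label masks. An object is flagged detached when it disappears (area
#' reaches 0) after a window of monotone area decline; objects present in
#' the last frame are retained. Identity gaps (an object vanishing and
#' reappearing) split the trace with a warning.
#'
#' @param mask_series list of integer label matrices (consistent ids).
#' @param pixel_size `(dx, dy)` um.
#' @param decline_window frames of monotone decline required before the
#'   disappearance counts as detachment.
#' @return list with `traces` (data.frame: object, frame, area_um2) and
#'   `status` (data.frame: object, detached, last_frame).
#' @export
area_traces <- function(mask_series, pixel_size = c(0.1, 0.1),
                        decline_window = 2L) {
  n_fr <- length(mask_series)
  ids <- sort(setdiff(unique(unlist(lapply(mask_series, unique))), 0L))
  pxa <- pixel_size[1] * pixel_size[2]
  tr <- expand.grid(object = ids, frame = seq_len(n_fr))
  tr$area_um2 <- mapply(function(id, fr) sum(mask_series[[fr]] == id) * pxa,
                        tr$object, tr$frame)
  status <- do.call(rbind, lapply(ids, function(id) {
    a <- tr$area_um2[tr$object == id]
    present <- a > 0
    if (any(diff(present) == 1L) && which.max(present) > 1L) {
      warning("object ", id, " has an identity gap; trace split")
    }
    last <- max(which(present))
    detached <- FALSE
    if (last < n_fr) {
      w <- max(1L, last - decline_window + 1L):last
      detached <- length(w) >= decline_window && all(diff(a[w]) <= 0)
    }
    data.frame(object = id, detached = detached, last_frame = last)
  }))
  list(traces = tr, status = status)
}

#' Measure all nuclei in a lamin stack
#'
#' End-to-end per-nucleus morphometrics: bulk segmentation, nuclear height,
#' 3-plane EFC ratio, 3D surface area and volume, xy spread area and aspect
#' ratio. Every retained label yields exactly one record; exclusions are
#' returned with the rule that fired.
#'
#' @param lamin_stack an [image_stack()].
#' @param bg_mask optional cell-free background mask.
#' @param probe_len sub-pixel tracing probe half-length (um).
#' @return list with `records` (data.frame, one row per nucleus) and
#'   `exclusions` (from [segment_nuclei_bulk()]).
#' @export
measure_nuclei <- function(lamin_stack, bg_mask = NULL, probe_len = 1.5) {
  seg <- segment_nuclei_bulk(lamin_stack)
  ids <- sort(setdiff(unique(as.vector(seg$labels)), 0L))
  px <- lamin_stack$voxel_size
  rows <- lapply(ids, function(id) {
    mask <- seg$labels == id
    nh <- nuclear_height(lamin_stack, mask, bg_mask)
    ef <- tryCatch(nucleus_efc_3plane(lamin_stack, mask, probe_len, bg_mask),
                   error = function(e) list(efc_mean = NA_real_, flag = TRUE))
    solid <- solid_mask_from_lamin(lamin_stack, mask)
    sv <- nuclear_surface_volume(solid, px)
    ca <- cell_area_aspect(mask, px[1:2])
    data.frame(
      nucleus_id = id,
      height = nh$height,
      surface_area = sv$surface_area,
      volume = sv$volume,
      efc_mean = ef$efc_mean,
      efc_flag = isTRUE(ef$flag),
      spread_area = ca$area,
      aspect_ratio = ca$aspect_ratio
    )
  })
  list(records = do.call(rbind, rows), exclusions = seg$exclusions)
}
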