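# Evaluate a function with a temporary RNG state.
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Real spherical-harmonic band signal at unit directions `dir` (n x 3):
# sum over degrees l in `orders`, m = 0..l, with standard-normal weights.
sph_harm_signal <- function(dir, orders, seed) {
  theta <- acos(pmin(1, pmax(-1, dir[, 3])))
  phi <- atan2(dir[, 2], dir[, 1])
  ct <- cos(theta)
  with_seed(seed, {
    g <- numeric(nrow(dir))
    for (l in orders) {
      P <- pracma::legendre(l, ct)   # (l+1) x n, rows m = 0..l
      for (m in 0:l) {
        w1 <- stats::rnorm(1)
        base <- P[m + 1, ]
        if (m == 0) {
          g <- g + w1 * base
        } else {
          w2 <- stats::rnorm(1)
          # normalize the associated Legendre magnitude to keep degrees
          # comparable before random weighting
          nrm <- sqrt(2 * factorial(l - m) / factorial(l + m))
          g <- g + nrm * base * (w1 * cos(m * phi) + w2 * sin(m * phi))
        }
      }
    }
    g
  })
}

#' Synthetic wrinkled nuclear surface with prescribed volume and excess area
#'
#' Radial spherical-harmonic perturbation of a sphere,
#' `r(dir) = r0 (1 + a g(dir))` with `g` a band-limited random field over
#' the requested degrees. The amplitude `a` is tuned by bisection until the
#' mesh-measured excess area matches `excess_area_pct` within 1% (relative),
#' then the mesh is rescaled to the target volume (exactly, up to float
#' round-off). The same seed reproduces the same mesh; different seeds give
#' a different wrinkle phase at the same (V, A).
#'
#' @param volume target volume (um^3).
#' @param excess_area_pct target percent excess area over the equal-volume
#'   sphere (>= 0).
#' @param wrinkle_orders spherical-harmonic degrees of the wrinkles.
#' @param seed integer seed for the wrinkle phase.
#' @param mesh_edge target mesh edge length (um); default r0/8.
#' @param max_amplitude feasibility cap on the relative radial amplitude.
#' @return list with `surface` (a [tri_surface()]), `volume`, `area`
#'   (mesh-measured ground truth), `excess_pct`, `amplitude`.
#' @export
make_nucleus_surface <- function(volume, excess_area_pct,
                                 wrinkle_orders = 4:8, seed = 1L,
                                 mesh_edge = NULL, max_amplitude = 0.75) {
  if (volume <= 0) stop("volume must be positive")
  if (excess_area_pct < 0) stop("excess_area_pct must be >= 0")
  r0 <- (3 * volume / (4 * pi))^(1 / 3)
  if (is.null(mesh_edge)) mesh_edge <- r0 / 8
  s0 <- make_initial_mesh(list(type = "sphere", radius = r0), mesh_edge)
  dir <- s0$vertices / rownorm(s0$vertices)
  base_excess <- excess_area_percent(surface_area(s0), enclosed_volume(s0))
  shape_at <- function(a) {
    s <- s0
    s$vertices <- dir * (r0 * (1 + a * gsig))
    s
  }
  if (excess_area_pct <= max(base_excess, 0.25)) {
    out <- s0
    amp <- 0
  } else {
    gsig <- sph_harm_signal(dir, wrinkle_orders, seed)
    gsig <- (gsig - mean(gsig)) / stats::sd(gsig)
    excess_at <- function(a) {
      s <- shape_at(a)
      excess_area_percent(surface_area(s), enclosed_volume(s))
    }
    lo <- 0; hi <- 0.05
    while (excess_at(hi) < excess_area_pct) {
      lo <- hi
      hi <- hi * 1.6
      if (hi > max_amplitude) {
        stop("infeasible spec: excess area unreachable with the given orders")
      }
    }
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (excess_at(mid) < excess_area_pct) lo <- mid else hi <- mid
      if (abs(excess_at(mid) / excess_area_pct - 1) < 1e-3) break
    }
    amp <- (lo + hi) / 2
    out <- shape_at(amp)
  }
  sc <- (volume / enclosed_volume(out))^(1 / 3)
  out$vertices <- out$vertices * sc
  list(surface = out,
       volume = enclosed_volume(out),
       area = surface_area(out),
       excess_pct = excess_area_percent(surface_area(out), enclosed_volume(out)),
       amplitude = amp)
}

# Separable box erosion / dilation of a 0/1 array: removes (adds) n voxels
# per side per axis.
erode_box3 <- function(arr, n_vox) {
  for (ax in 1:3) {
    n <- n_vox[ax]
    if (n <= 0) next
    out <- arr
    for (j in seq_len(n)) {
      out <- pmin(out, shift_replicate(arr, ax, j), shift_replicate(arr, ax, -j))
    }
    arr <- out
  }
  arr
}

dilate_box3 <- function(arr, n_vox) {
  for (ax in 1:3) {
    n <- n_vox[ax]
    if (n <= 0) next
    out <- arr
    for (j in seq_len(n)) {
      out <- pmax(out, shift_replicate(arr, ax, j), shift_replicate(arr, ax, -j))
    }
    arr <- out
  }
  arr
}

#' Render a surface into a synthetic confocal stack
#'
#' Voxelizes the closed surface on an anisotropic grid (column parity
#' fill), paints either a thin shell around the surface (lamin-like) or the
#' solid interior (DNA-like), applies Gaussian PSF blur and Poisson-Gaussian
#' noise over a constant background, and returns the ground-truth masks
#' alongside the stack.
#'
#' @param surface a closed [tri_surface()].
#' @param voxel_size `(dx, dy, dz)` um (dz defaults to the 0.13-um z-step).
#' @param signal `"shell"` or `"solid"`.
#' @param shell_thickness_um shell half-band thickness for `"shell"`.
#' @param psf_sigma_um Gaussian PSF sigma (um); 0 disables blur.
#' @param peak signal amplitude in photon counts (SNR at the peak is about
#'   `sqrt(peak)` for pure shot noise).
#' @param background constant background level (counts).
#' @param read_sd Gaussian read-noise SD (counts); 0 disables.
#' @param margin_um empty margin around the surface bounding box.
#' @param seed noise seed.
#' @return list with `stack` (an [image_stack()]), `solid_mask`,
#'   `shell_mask` (0/1 arrays), `origin` (um coordinates of voxel
#'   `[1, 1, 1]` center), `truth` (list `volume`, `area` of the surface).
#' @export
render_stack <- function(surface, voxel_size = c(0.1, 0.1, 0.13),
                         signal = c("shell", "solid"),
                         shell_thickness_um = 0.25,
                         psf_sigma_um = 0.2, peak = 100, background = 10,
                         read_sd = 2, margin_um = 1, seed = 1L) {
  signal <- match.arg(signal)
  v <- surface$vertices
  dx <- voxel_size[1]; dy <- voxel_size[2]; dz <- voxel_size[3]
  x0 <- min(v[, 1]) - margin_um; x1 <- max(v[, 1]) + margin_um
  y0 <- min(v[, 2]) - margin_um; y1 <- max(v[, 2]) + margin_um
  z0 <- min(v[, 3]) - margin_um; z1 <- max(v[, 3]) + margin_um
  xs <- seq(x0, x1, by = dx); ys <- seq(y0, y1, by = dy); zs <- seq(z0, z1, by = dz)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  solid <- array(0, c(ny, nx, nz))
  grid <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  cr <- cpp_column_crossings(surface$vertices, surface$faces,
                             xs[grid$x] + 1e-7, ys[grid$y] + 2e-7)
  for (i in seq_along(cr)) {
    z <- cr[[i]]
    if (length(z) < 2) next
    np <- (length(z) %/% 2) * 2
    for (p in seq(1, np, by = 2)) {
      inside <- zs >= z[p] & zs <= z[p + 1]
      if (any(inside)) solid[grid$y[i], grid$x[i], inside] <- 1
    }
  }
  if (signal == "shell") {
    # band centered on the surface: half the thickness inward, half outward
    nv <- pmax(1L, round(0.5 * shell_thickness_um / c(dy, dx, dz)))
    shell <- dilate_box3(solid, nv) - erode_box3(solid, nv)
  } else {
    shell <- solid
  }
  img <- (if (signal == "shell") shell else solid) * peak
  if (psf_sigma_um > 0) {
    img <- smooth_gaussian3(img, psf_sigma_um / c(dy, dx, dz))
  }
  img <- img + background
  img <- with_seed(seed, {
    shot <- array(stats::rpois(length(img), lambda = img), dim(img))
    if (read_sd > 0) shot <- shot + array(stats::rnorm(length(img), 0, read_sd), dim(img))
    pmax(shot, 0)
  })
  list(
    stack = image_stack(img, voxel_size,
                        channel = if (signal == "shell") "lamin" else "dna"),
    solid_mask = solid,
    shell_mask = shell,
    origin = c(x0, y0, z0),
    truth = list(volume = enclosed_volume(surface),
                 area = surface_area(surface))
  )
}

#' Synthetic endothelial monolayer with a controllable tall-cell fraction
#'
#' Tessellates the field into cell footprints (Voronoi regions of seeded
#' points), gives a chosen fraction of cells a dome profile rising to
#' `tall_height`, renders a 3D stack (voxels below the local height are
#' signal), and returns the true per-pixel height grid.
#'
#' @param field_um `(width, height)` of the field (um).
#' @param n_cells number of cells.
#' @param base_height flat monolayer height (um).
#' @param tall_cell_fraction fraction of cells given domes (0..1).
#' @param tall_height dome peak height (um).
#' @param pixel_size `(dx, dy, dz)` um.
#' @param peak,background,read_sd rendering intensities (counts).
#' @param seed seed for cell positions, tall-cell choice and noise.
#' @return list with `stack` (an [image_stack()], tag `mixed`),
#'   `true_height` (matrix, um), `labels` (cell footprint labels),
#'   `tall_cells` (ids).
#' @export
make_monolayer <- function(field_um = c(60, 60), n_cells = 30L,
                           base_height = 3, tall_cell_fraction = 0,
                           tall_height = 8,
                           pixel_size = c(0.4, 0.4, 0.13),
                           peak = 100, background = 5, read_sd = 2,
                           seed = 1L) {
  stopifnot(tall_cell_fraction >= 0, tall_cell_fraction <= 1)
  dx <- pixel_size[1]; dy <- pixel_size[2]; dz <- pixel_size[3]
  xs <- seq(0, field_um[1], by = dx); ys <- seq(0, field_um[2], by = dy)
  nx <- length(xs); ny <- length(ys)
  res <- with_seed(seed, {
    sx <- stats::runif(n_cells, 0, field_um[1])
    sy <- stats::runif(n_cells, 0, field_um[2])
    n_tall <- round(tall_cell_fraction * n_cells)
    tall <- if (n_tall > 0) sample.int(n_cells, n_tall) else integer()
    list(sx = sx, sy = sy, tall = tall)
  })
  px <- matrix(rep(xs, each = ny), ny, nx)
  py <- matrix(rep(ys, nx), ny, nx)
  lab <- matrix(1L, ny, nx)
  best <- (px - res$sx[1])^2 + (py - res$sy[1])^2
  if (n_cells > 1) for (i in 2:n_cells) {
    d2 <- (px - res$sx[i])^2 + (py - res$sy[i])^2
    upd <- d2 < best
    lab[upd] <- i
    best[upd] <- d2[upd]
  }
  hgrid <- matrix(base_height, ny, nx)
  for (i in res$tall) {
    inr <- lab == i
    if (!any(inr)) next
    d <- sqrt((px - res$sx[i])^2 + (py - res$sy[i])^2)
    rmax <- max(d[inr])
    prof <- base_height + (tall_height - base_height) *
      pmax(0, 1 - (d / rmax)^2)
    hgrid[inr] <- prof[inr]
  }
  nz <- ceiling((max(hgrid) + 1) / dz)
  stack <- array(0, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    stack[, , k] <- (((k - 0.5) * dz) <= hgrid) * peak
  }
  stack <- stack + background
  stack <- with_seed(seed + 1L, {
    out <- array(stats::rpois(length(stack), stack), dim(stack))
    if (read_sd > 0) out <- out + array(stats::rnorm(length(out), 0, read_sd), dim(out))
    pmax(out, 0)
  })
  list(
    stack = image_stack(stack, pixel_size, "mixed"),
    true_height = hgrid,
    labels = lab,
    tall_cells = res$tall
  )
}

#' Synthetic YAP scene with known nuclear/cytoplasmic contrast
#'
#' Lays out disjoint elliptical cells on a grid, each with a concentric
#' nuclear region; intensities realize the requested N/C ratios exactly
#' over a known background before optional Gaussian noise. Masks are exact.
#'
#' @param nc_ratios per-cell true nuclear/cytoplasmic ratios (> 0); one
#'   cell per value.
#' @param noise_frac Gaussian noise SD as a fraction of the cytoplasmic
#'   contrast (0 disables).
#' @param pixel_size `(dx, dy)` um.
#' @param cell_radius_um mean cell radius; individual radii vary 20%
#'   (seeded), giving a spread-area range.
#' @param background background intensity.
#' @param contrast cytoplasmic intensity above background.
#' @param seed seed for radii and noise.
#' @return list with `img` (an [image_stack()], yap), `nuc_labels`,
#'   `cell_labels` (integer matrices), `bg_mask`, `truth` (data.frame:
#'   cell, nc_ratio, spread_area_um2).
#' @export
make_yap_scene <- function(nc_ratios, noise_frac = 0, pixel_size = c(0.2, 0.2),
                           cell_radius_um = 8, background = 50,
                           contrast = 100, seed = 1L) {
  if (any(nc_ratios <= 0)) stop("nc_ratios must be positive")
  n <- length(nc_ratios)
  ngrid <- ceiling(sqrt(n))
  pitch <- 2.6 * cell_radius_um
  W <- ngrid * pitch
  dx <- pixel_size[1]; dy <- pixel_size[2]
  xs <- seq(0, W, by = dx); ys <- seq(0, W, by = dy)
  nx <- length(xs); ny <- length(ys)
  px <- matrix(rep(xs, each = ny), ny, nx)
  py <- matrix(rep(ys, nx), ny, nx)
  img <- matrix(background, ny, nx)
  nucl <- matrix(0L, ny, nx)
  celll <- matrix(0L, ny, nx)
  radii <- with_seed(seed, cell_radius_um * stats::runif(n, 0.8, 1.2))
  truth <- data.frame(cell = seq_len(n), nc_ratio = nc_ratios,
                      spread_area_um2 = NA_real_)
  for (i in seq_len(n)) {
    gx <- ((i - 1) %% ngrid + 0.5) * pitch
    gy <- ((i - 1) %/% ngrid + 0.5) * pitch
    d2 <- (px - gx)^2 + (py - gy)^2
    cellm <- d2 <= radii[i]^2
    nucm <- d2 <= (0.45 * radii[i])^2
    img[cellm] <- background + contrast
    img[nucm] <- background + nc_ratios[i] * contrast
    celll[cellm] <- i
    nucl[nucm] <- i
    truth$spread_area_um2[i] <- sum(cellm) * dx * dy
  }
  if (noise_frac > 0) {
    img <- with_seed(seed + 1L, {
      pmax(img + matrix(stats::rnorm(length(img), 0, noise_frac * contrast),
                        ny, nx), 0)
    })
  }
  list(
    img = image_stack(array(img, c(ny, nx, 1)), c(pixel_size, 0.13), "yap"),
    nuc_labels = nucl, cell_labels = celll,
    bg_mask = celll == 0L,
    truth = truth
  )
}

#' Synthetic detachment time series of labelled cell masks
#'
#' A power-diagram tessellation in which one chosen object shrinks
#' monotonically and vanishes at `detach_frame`; its neighbours expand to
#' fill the vacated area, so total coverage never decreases.
#'
#' @param n_frames number of frames.
#' @param detach_frame frame at which the shrinking object's area reaches 0
#'   (none detaches if `NA`).
#' @param n_cells number of objects.
#' @param field_px square field size in pixels.
#' @param seed seed for the seed-point layout.
#' @return list with `masks` (list of integer label matrices) and `truth`
#'   (data.frame: object, detached).
#' @export
make_detachment_series <- function(n_frames = 10L, detach_frame = 7L,
                                   n_cells = 4L, field_px = 80L, seed = 1L) {
  if (!is.na(detach_frame) && detach_frame >= n_frames) {
    stop("detach_frame must be < n_frames")
  }
  pts <- with_seed(seed, cbind(stats::runif(n_cells, 0.15, 0.85) * field_px,
                               stats::runif(n_cells, 0.15, 0.85) * field_px))
  px <- matrix(rep(seq_len(field_px), each = field_px), field_px, field_px)
  py <- matrix(rep(seq_len(field_px), field_px), field_px, field_px)
  d2 <- lapply(seq_len(n_cells), function(i)
    (px - pts[i, 1])^2 + (py - pts[i, 2])^2)
  # margin: how negative object 1's power weight must get before it vanishes
  others <- Reduce(pmin, d2[-1])
  margin <- max(others - d2[[1]]) * 1.02
  masks <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    w1 <- if (is.na(detach_frame)) 0 else -margin * min(1, (t - 1) / (detach_frame - 1))
    lab <- matrix(1L, field_px, field_px)
    best <- d2[[1]] - w1
    for (i in 2:n_cells) {
      upd <- d2[[i]] < best
      lab[upd] <- i
      best[upd] <- d2[[i]][upd]
    }
    masks[[t]] <- lab
  }
  list(
    masks = masks,
    truth = data.frame(object = seq_len(n_cells),
                       detached = if (is.na(detach_frame)) rep(FALSE, n_cells)
                       else seq_len(n_cells) == 1L)
  )
}
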