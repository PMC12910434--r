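# Shift a 3D array along one axis with edge replication.
shift_replicate <- function(arr, axis, by) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable 3D Gaussian smoothing; sigma per axis in voxel units.
smooth_gaussian3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r):r)^2 / (2 * s^2))
    w <- w / sum(w)
    out <- arr * w[r + 1L]
    for (j in seq_len(r)) {
      out <- out + w[r + 1L + j] * (shift_replicate(arr, ax, j) +
                                      shift_replicate(arr, ax, -j))
    }
    arr <- out
  }
  arr
}

# Surface area of the `level` isosurface of a 3D scalar field by marching
# tetrahedra (each grid cell split into 6 tetrahedra, linear interpolation
# along edges). Only mixed cells (straddling the level) are visited.
# spacing = (dx, dy, dz) physical voxel size; field indexed [y, x, z].
marching_tet_area <- function(field, spacing, level = 0.5) {
  d <- dim(field)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  if (nx < 2 || ny < 2 || nz < 2) return(0)
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  # cell corner offsets (unit cube), v0..v7
  corner <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  # 6 tetrahedra around the v0-v6 diagonal
  tets <- rbind(
    c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
    c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
  )
  # corner field values for all cells, gathered lazily for mixed cells only
  cy <- seq_len(ny - 1L); cx <- seq_len(nx - 1L); cz <- seq_len(nz - 1L)
  # locate mixed cells via min/max over the 8 corners
  sub <- function(oy, ox, oz) field[cy + oy, cx + ox, cz + oz, drop = FALSE]
  fmin <- fmax <- sub(0L, 0L, 0L)
  for (ci in 2:8) {
    s <- sub(corner[ci, 2], corner[ci, 1], corner[ci, 3])  # (y offset, x offset, z offset)
    fmin <- pmin(fmin, s); fmax <- pmax(fmax, s)
  }
  mixed <- which(fmin < level & fmax >= level)
  if (!length(mixed)) return(0)
  dmc <- c(ny - 1L, nx - 1L, nz - 1L)
  iy <- (mixed - 1L) %% dmc[1] + 1L
  ixz <- (mixed - 1L) %/% dmc[1]
  ix <- ixz %% dmc[2] + 1L
  iz <- ixz %/% dmc[2] + 1L
  # physical coords and values of the 8 corners of each mixed cell
  vals <- matrix(0, length(mixed), 8)
  px <- matrix(0, length(mixed), 8)
  py <- matrix(0, length(mixed), 8)
  pz <- matrix(0, length(mixed), 8)
  for (ci in 1:8) {
    yy <- iy + corner[ci, 2]; xx <- ix + corner[ci, 1]; zz <- iz + corner[ci, 3]
    vals[, ci] <- field[cbind(yy, xx, zz)]
    px[, ci] <- (xx - 1L) * dx
    py[, ci] <- (yy - 1L) * dy
    pz[, ci] <- (zz - 1L) * dz
  }
  interp <- function(ia, ib) {
    t <- (level - vals[, ia]) / (vals[, ib] - vals[, ia])
    cbind(px[, ia] + t * (px[, ib] - px[, ia]),
          py[, ia] + t * (py[, ib] - py[, ia]),
          pz[, ia] + t * (pz[, ib] - pz[, ia]))
  }
  tri_area <- function(p1, p2, p3, rows) {
    if (!length(rows)) return(0)
    u <- p2[rows, , drop = FALSE] - p1[rows, , drop = FALSE]
    v <- p3[rows, , drop = FALSE] - p1[rows, , drop = FALSE]
    cx_ <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy_ <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz_ <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    sum(sqrt(cx_^2 + cy_^2 + cz_^2)) / 2
  }
  total <- 0
  for (tt in seq_len(nrow(tets))) {
    tv <- tets[tt, ]
    above <- (vals[, tv[1]] >= level) + 2L * (vals[, tv[2]] >= level) +
      4L * (vals[, tv[3]] >= level) + 8L * (vals[, tv[4]] >= level)
    # single-corner cases: corner j isolated -> triangle on its 3 edges
    singles <- list(`1` = 1L, `2` = 2L, `4` = 3L, `8` = 4L,
                    `14` = 1L, `13` = 2L, `11` = 3L, `7` = 4L)
    for (cs in names(singles)) {
      rows <- which(above == as.integer(cs))
      if (!length(rows)) next
      j <- singles[[cs]]
      oth <- setdiff(1:4, j)
      e1 <- interp(tv[j], tv[oth[1]])
      e2 <- interp(tv[j], tv[oth[2]])
      e3 <- interp(tv[j], tv[oth[3]])
      total <- total + tri_area(e1, e2, e3, rows)
    }
    # two-corner cases: corners {j,k} above -> quad from the 4 crossing edges
    pairs <- list(`3` = c(1L, 2L), `5` = c(1L, 3L), `9` = c(1L, 4L),
                  `6` = c(2L, 3L), `10` = c(2L, 4L), `12` = c(3L, 4L))
    for (cs in names(pairs)) {
      rows <- which(above == as.integer(cs))
      if (!length(rows)) next
      jk <- pairs[[cs]]
      oth <- setdiff(1:4, jk)
      # quad vertices in strip order: (j-o1, j-o2, k-o1, k-o2)
      q1 <- interp(tv[jk[1]], tv[oth[1]])
      q2 <- interp(tv[jk[1]], tv[oth[2]])
      q3 <- interp(tv[jk[2]], tv[oth[1]])
      q4 <- interp(tv[jk[2]], tv[oth[2]])
      total <- total + tri_area(q1, q2, q3, rows) + tri_area(q2, q4, q3, rows)
    }
  }
  total
}
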