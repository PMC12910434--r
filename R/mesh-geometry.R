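cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(m) sqrt(rowSums(m * m))

face_corner_coords <- function(s) {
  list(a = s$vertices[s$faces[, 1], , drop = FALSE],
       b = s$vertices[s$faces[, 2], , drop = FALSE],
       c = s$vertices[s$faces[, 3], , drop = FALSE])
}

#' Per-face triangle areas
#' @param s a [tri_surface()].
#' @return numeric vector of face areas (um^2).
#' @export
face_areas <- function(s) {
  fc <- face_corner_coords(s)
  0.5 * rownorm(cross3(fc$b - fc$a, fc$c - fc$a))
}

#' Per-face unit normals (outward for consistently oriented closed surfaces)
#' @param s a [tri_surface()].
#' @export
face_normals <- function(s) {
  fc <- face_corner_coords(s)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  n / rownorm(n)
}

#' Total surface area
#'
#' Sum of triangle areas; converges to the analytic area under mesh
#' refinement.
#'
#' @param s a [tri_surface()].
#' @return area in um^2.
#' @export
surface_area <- function(s) sum(face_areas(s))

#' Enclosed volume of a closed surface
#'
#' Divergence-theorem signed volume (sum of signed origin tetrahedra);
#' positive for outward orientation. For open surfaces whose boundary lies
#' in a plane `z = 0` (the substrate), the same sum taken with a reference
#' point in that plane equals the volume between the surface and the plane;
#' pass `ref` to use this convention, otherwise open surfaces are an error.
#'
#' @param s a [tri_surface()].
#' @param ref optional reference point (length-3) for open, planar-boundary
#'   surfaces.
#' @return volume in um^3 (signed).
#' @export
enclosed_volume <- function(s, ref = NULL) {
  if (is.null(ref) && !is_closed_surface(s)) {
    stop("enclosed_volume requires a closed surface (or an explicit ref ",
         "point in the boundary plane)")
  }
  fc <- face_corner_coords(s)
  if (!is.null(ref)) {
    ref <- matrix(rep(as.numeric(ref), each = nrow(fc$a)), ncol = 3)
    fc$a <- fc$a - ref; fc$b <- fc$b - ref; fc$c <- fc$c - ref
  }
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

# Exact integral of |x - p|^2 over triangle (p1,p2,p3), p broadcast per row.
# Midpoint (three-edge-midpoint) quadrature is exact for quadratics.
tri_second_moment <- function(p1, p2, p3, p) {
  area <- 0.5 * rownorm(cross3(p2 - p1, p3 - p1))
  m12 <- (p1 + p2) / 2; m23 <- (p2 + p3) / 2; m13 <- (p1 + p3) / 2
  (area / 3) * (rowSums((m12 - p)^2) + rowSums((m23 - p)^2) +
                  rowSums((m13 - p)^2))
}

# Per-face CVT contribution: for each corner vertex x_i the barycentric dual
# region inside the face is the quad (x_i, edge midpoint, centroid, edge
# midpoint); integrate |x - x_i|^2 over it exactly.
cvt_face_energy <- function(a, b, c) {
  g <- (a + b + c) / 3
  mab <- (a + b) / 2; mbc <- (b + c) / 2; mca <- (c + a) / 2
  e <- tri_second_moment(a, mab, g, a) + tri_second_moment(a, g, mca, a)
  e <- e + tri_second_moment(b, mbc, g, b) + tri_second_moment(b, g, mab, b)
  e + tri_second_moment(c, mca, g, c) + tri_second_moment(c, g, mbc, c)
}

#' Centroidal-Voronoi-tessellation energy of a mesh
#'
#' The mesh-quality regularizer: the sum over vertices of the second moment
#' of their barycentric dual cell about the vertex,
#' `sum_i int_{v_i} |x - x_i|^2 dA`. It is minimized (per area) when every
#' vertex sits at the centroid of its dual cell, i.e. for a centroidal
#' Voronoi layout of near-equilateral triangles. Units um^4; scales as the
#' fourth power of linear size.
#'
#' @param s a [tri_surface()].
#' @return energy in um^4.
#' @export
cvt_energy <- function(s) {
  fc <- face_corner_coords(s)
  sum(cvt_face_energy(fc$a, fc$b, fc$c))
}

#' Per-face aspect-ratio quality
#'
#' Longest edge over `2*sqrt(3)` times the inradius, normalized so an
#' equilateral triangle scores 1; larger is worse.
#'
#' @param s a [tri_surface()].
#' @export
per_face_quality <- function(s) {
  fc <- face_corner_coords(s)
  la <- rownorm(fc$b - fc$c); lb <- rownorm(fc$a - fc$c); lc <- rownorm(fc$a - fc$b)
  smax <- pmax(la, lb, lc)
  sp <- (la + lb + lc) / 2
  area <- face_areas(s)
  rin <- area / sp
  smax / (2 * sqrt(3) * rin)
}

#' Minimum interior angle over all faces (radians)
#' @param s a [tri_surface()].
#' @export
min_triangle_angle <- function(s) {
  fc <- face_corner_coords(s)
  ang <- function(p, q, r) {  # angle at p
    u <- q - p; v <- r - p
    acos(pmin(1, pmax(-1, rowSums(u * v) / (rownorm(u) * rownorm(v)))))
  }
  min(ang(fc$a, fc$b, fc$c), ang(fc$b, fc$c, fc$a), ang(fc$c, fc$a, fc$b))
}

#' Mean edge length
#' @param s a [tri_surface()].
#' @export
mean_edge_length <- function(s) {
  e <- mesh_edges(s)
  mean(rownorm(s$vertices[e$v2, , drop = FALSE] - s$vertices[e$v1, , drop = FALSE]))
}

#' Summary of mesh energies and quality
#'
#' @param s a [tri_surface()].
#' @return list with `surface_area` (um^2), `enclosed_volume` (um^3, `NA`
#'   for open surfaces), `cvt_energy` (um^4), `per_face_quality`.
#' @export
mesh_energy_report <- function(s) {
  list(
    surface_area = surface_area(s),
    enclosed_volume = if (is_closed_surface(s)) enclosed_volume(s) else NA_real_,
    cvt_energy = cvt_energy(s),
    per_face_quality = per_face_quality(s)
  )
}

# ---- Edge flipping ---------------------------------------------------------

#' Enforce the Delaunay-like local criterion by edge flipping
#'
#' Scans interior edges and flips any whose two opposite angles sum to more
#' than pi (within `tol`), replacing the shared diagonal of the adjacent
#' triangle pair by the other diagonal. Vertex positions are untouched;
#' topology (Euler characteristic, boundary) is preserved. Flips that would
#' duplicate an existing edge are skipped. Iterates to a fixed point.
#'
#' @param s a [tri_surface()].
#' @param tol angular tolerance in radians; an angle sum of exactly pi (to
#'   within `tol`) is not flipped.
#' @param max_sweeps safety cap on full-mesh sweeps.
#' @return list with elements `surface` (flipped [tri_surface()]) and
#'   `n_flips` (total flips applied).
#' @export
flip_edges <- function(s, tol = 1e-8, max_sweeps = 50L) {
  v <- s$vertices
  f <- s$faces
  total <- 0L
  vang <- function(p, u, w) {  # angle at vertex p opposite edge (u, w), vectorized
    a1 <- v[u, , drop = FALSE] - v[p, , drop = FALSE]
    a2 <- v[w, , drop = FALSE] - v[p, , drop = FALSE]
    acos(pmin(1, pmax(-1, rowSums(a1 * a2) / (rownorm(a1) * rownorm(a2)))))
  }
  for (sweep in seq_len(max_sweeps)) {
    e <- mesh_edges(tri_surface(v, f, s$fixed, validate = FALSE))
    ie <- e[!is.na(e$f2), , drop = FALSE]
    if (!nrow(ie)) break
    p <- rowSums(f[ie$f1, , drop = FALSE]) - ie$v1 - ie$v2
    q <- rowSums(f[ie$f2, , drop = FALSE]) - ie$v1 - ie$v2
    asum <- vang(p, ie$v1, ie$v2) + vang(q, ie$v1, ie$v2)
    cand <- which(asum > pi + tol)
    if (!length(cand)) break
    cand <- cand[order(asum[cand], decreasing = TRUE)]
    nvv <- nrow(v)
    ekey <- unique(e$v1 * (nvv + 1) + e$v2)  # existing undirected edges
    touched <- rep(FALSE, nrow(f))
    flips <- 0L
    for (i in cand) {
      f1 <- ie$f1[i]; f2 <- ie$f2[i]
      if (touched[f1] || touched[f2]) next
      u <- ie$v1[i]; w <- ie$v2[i]
      pp <- p[i]; qq <- q[i]
      nk <- min(pp, qq) * (nvv + 1) + max(pp, qq)
      if (nk %in% ekey) next  # flip would duplicate an existing edge; skip
      t1 <- f[f1, ]
      uw <- if (any(t1 == u & c(t1[2], t1[3], t1[1]) == w)) c(u, w) else c(w, u)
      a <- uw[1]; b <- uw[2]     # f1 = (a, b, p), f2 = (b, a, q)
      newf1 <- c(a, qq, pp)
      newf2 <- c(b, pp, qq)
      ar1 <- 0.5 * sqrt(sum(crossprod_vec(v[newf1[2], ] - v[newf1[1], ],
                                          v[newf1[3], ] - v[newf1[1], ])^2))
      ar2 <- 0.5 * sqrt(sum(crossprod_vec(v[newf2[2], ] - v[newf2[1], ],
                                          v[newf2[3], ] - v[newf2[1], ])^2))
      if (ar1 <= 1e-12 || ar2 <= 1e-12) next
      f[f1, ] <- newf1
      f[f2, ] <- newf2
      touched[f1] <- TRUE; touched[f2] <- TRUE
      ekey <- c(ekey, nk)
      flips <- flips + 1L
    }
    total <- total + flips
    if (flips == 0L) break
  }
  list(surface = tri_surface(v, f, s$fixed, validate = FALSE), n_flips = total)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Discrete per-vertex mean curvature
#'
#' Magnitude of the cotangent-Laplacian mean-curvature normal,
#' `|sum_j (cot a_ij + cot b_ij)(x_j - x_i)| / (4 A_i)` with barycentric
#' vertex areas; equals `1/R` on a sphere of radius `R` up to discretization
#' error. Boundary vertices are returned as `NA`.
#'
#' @param s a [tri_surface()].
#' @return numeric vector of curvatures (1/um).
#' @export
vertex_mean_curvature <- function(s) {
  v <- s$vertices; f <- s$faces
  nv <- nrow(v)
  fc <- face_corner_coords(s)
  areas <- face_areas(s)
  cot_at <- function(p, q, r) { # cot of angle at p
    u <- q - p; w <- r - p
    rowSums(u * w) / rownorm(cross3(u, w))
  }
  ca <- cot_at(fc$a, fc$b, fc$c)
  cb <- cot_at(fc$b, fc$c, fc$a)
  cc <- cot_at(fc$c, fc$a, fc$b)
  lap <- matrix(0, nv, 3)
  acc <- function(lap, i, j, w) {
    d <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    for (dd in 1:3) lap[, dd] <- lap[, dd] + tabulate2(i, w * d[, dd], nv)
    lap
  }
  # edge (b,c) is opposite corner a (cot weight ca), etc.
  lap <- acc(lap, f[, 2], f[, 3], ca); lap <- acc(lap, f[, 3], f[, 2], ca)
  lap <- acc(lap, f[, 3], f[, 1], cb); lap <- acc(lap, f[, 1], f[, 3], cb)
  lap <- acc(lap, f[, 1], f[, 2], cc); lap <- acc(lap, f[, 2], f[, 1], cc)
  va <- (tabulate2(f[, 1], areas, nv) + tabulate2(f[, 2], areas, nv) +
           tabulate2(f[, 3], areas, nv)) / 3
  h <- rownorm(lap) / (4 * pmax(va, .Machine$double.eps))
  h[boundary_vertices(s)] <- NA_real_
  h
}
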