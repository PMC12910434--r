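icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# Subdivide each icosahedron face into k^2 triangles on a barycentric grid,
# project to the unit sphere, dedupe shared edge/corner vertices exactly.
icosphere <- function(k) {
  ico <- icosahedron()
  verts <- list(); vkey <- new.env(hash = TRUE)
  faces <- list()
  nv <- 0L
  get_vid <- function(p) {
    key <- paste(sprintf("%.15a", p), collapse = ",")
    id <- vkey[[key]]
    if (is.null(id)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      vkey[[key]] <- nv
      id <- nv
    }
    id
  }
  for (fi in seq_len(nrow(ico$faces))) {
    A <- ico$vertices[ico$faces[fi, 1], ]
    B <- ico$vertices[ico$faces[fi, 2], ]
    C <- ico$vertices[ico$faces[fi, 3], ]
    # grid ids: row i = 0..k (towards C), positions j = 0..k-i along A->B
    ids <- matrix(NA_integer_, k + 1, k + 1)
    for (i in 0:k) for (j in 0:(k - i)) {
      p <- (j * B + i * C + (k - i - j) * A) / k
      p <- p / sqrt(sum(p^2))
      ids[i + 1, j + 1] <- get_vid(p)
    }
    for (i in 0:(k - 1)) for (j in 0:(k - i - 1)) {
      faces[[length(faces) + 1L]] <- c(ids[i + 1, j + 1], ids[i + 1, j + 2], ids[i + 2, j + 1])
      if (j < k - i - 1) {
        faces[[length(faces) + 1L]] <- c(ids[i + 1, j + 2], ids[i + 2, j + 2], ids[i + 2, j + 1])
      }
    }
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  s <- tri_surface(v, f, validate = FALSE)
  if (enclosed_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

# Tangential Lloyd-style smoothing with projection back to a surface given by
# a projection function; a light equilibration pass in the spirit of spring
# relaxation meshing.
relax_on_surface <- function(s, project, n_iter = 5L) {
  e <- mesh_edges(s)
  for (it in seq_len(n_iter)) {
    v <- s$vertices
    acc <- matrix(0, nrow(v), 3)
    cnt <- numeric(nrow(v))
    for (col in 1:2) {
      i <- if (col == 1) e$v1 else e$v2
      j <- if (col == 1) e$v2 else e$v1
      acc[, 1] <- acc[, 1] + tabulate2(i, v[j, 1], nrow(v))
      acc[, 2] <- acc[, 2] + tabulate2(i, v[j, 2], nrow(v))
      acc[, 3] <- acc[, 3] + tabulate2(i, v[j, 3], nrow(v))
      cnt <- cnt + tabulate(i, nbins = nrow(v))
    }
    mean_nb <- acc / pmax(cnt, 1)
    free <- !s$fixed
    v[free, ] <- v[free, ] + 0.5 * (mean_nb[free, , drop = FALSE] - v[free, , drop = FALSE])
    v[free, ] <- project(v[free, , drop = FALSE])
    s$vertices <- v
  }
  s
}

tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  rs <- rowsum(w, bin)
  out[as.integer(rownames(rs))] <- rs
  out
}

# Bridge two concentric closed rings of vertex indices into a consistent
# triangle strip, advancing by polar angle.
bridge_rings <- function(inner_idx, outer_idx, inner_ang, outer_ang) {
  ni <- length(inner_idx); no <- length(outer_idx)
  faces <- matrix(0L, ni + no, 3)
  i <- 1L; o <- 1L; nf <- 0L
  adv_i <- 0L; adv_o <- 0L
  nexta <- function(ang, pos, n, adv) ang[(pos %% n) + 1L] + 2 * pi * ((pos + adv) %/% n)
  while (adv_i < ni || adv_o < no) {
    ai_next <- if (adv_i < ni) inner_ang[(i %% ni) + 1L] + 2 * pi * (i %/% ni) else Inf
    ao_next <- if (adv_o < no) outer_ang[(o %% no) + 1L] + 2 * pi * (o %/% no) else Inf
    nf <- nf + 1L
    if (ai_next <= ao_next) {
      faces[nf, ] <- c(inner_idx[(i - 1L) %% ni + 1L],
                       outer_idx[(o - 1L) %% no + 1L],
                       inner_idx[i %% ni + 1L])
      i <- i + 1L; adv_i <- adv_i + 1L
    } else {
      faces[nf, ] <- c(inner_idx[(i - 1L) %% ni + 1L],
                       outer_idx[(o - 1L) %% no + 1L],
                       outer_idx[o %% no + 1L])
      o <- o + 1L; adv_o <- adv_o + 1L
    }
  }
  faces[seq_len(nf), , drop = FALSE]
}

# Resample a closed polygon to n points by arc length.
polygon_resample <- function(poly, n) {
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  t_out <- seq(0, total, length.out = n + 1)[-(n + 1)]
  x <- approx(cs, p[, 1], xout = t_out)$y
  y <- approx(cs, p[, 2], xout = t_out)$y
  cbind(x, y)
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  a <- polygon_area(poly)
  cr <- x * ys - xs * y
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Triangulated planar disk shaped like `poly` (closed polygon, star-shaped
# about its centroid), built from concentric scaled rings. Returns surface
# with boundary vertices flagged fixed. Orientation: +z normal.
disk_mesh_from_polygon <- function(poly, target_edge) {
  cen <- polygon_centroid(poly)
  radii <- sqrt(rowSums(sweep(poly, 2, cen)^2))
  rmean <- mean(radii)
  nr <- max(2L, round(rmean / target_edge))
  verts <- matrix(cen, 1, 2)
  ring_ids <- list()
  ring_angs <- list()
  for (j in seq_len(nr)) {
    frac <- j / nr
    npts <- max(6L, round(2 * pi * rmean * frac / target_edge))
    ring <- polygon_resample(poly, npts)
    ring <- sweep(sweep(ring, 2, cen, "-") * frac, 2, cen, "+")
    idx <- nrow(verts) + seq_len(npts)
    verts <- rbind(verts, ring)
    rel <- sweep(ring, 2, cen)
    ang <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
    # rings from polygon_resample are ordered; rotate to start near angle 0
    o <- order(ang)
    ring_ids[[j]] <- idx[o]
    ring_angs[[j]] <- ang[o]
  }
  faces <- list()
  # innermost fan
  id1 <- ring_ids[[1]]
  n1 <- length(id1)
  for (t in seq_len(n1)) {
    faces[[length(faces) + 1L]] <- c(1L, id1[t], id1[t %% n1 + 1L])
  }
  if (nr >= 2) {
    for (j in 2:nr) {
      faces[[length(faces) + 1L]] <-
        bridge_rings(ring_ids[[j - 1]], ring_ids[[j]],
                     ring_angs[[j - 1]], ring_angs[[j]])
    }
  }
  f <- do.call(rbind, faces)
  v3 <- cbind(verts, 0)
  fixed <- rep(FALSE, nrow(v3))
  fixed[ring_ids[[nr]]] <- TRUE
  # ensure +z orientation
  s <- tri_surface(v3, f, fixed, validate = FALSE)
  nz <- face_normals(s)[, 3]
  if (mean(nz) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

# Closed "capped" cell-like surface over a footprint polygon: a flat basal
# disk at z = 0 plus a dome of stacked, shrinking footprint rings. All basal
# vertices are flagged fixed (adhesion footprint on a rigid substrate).
capped_mesh_from_polygon <- function(poly, height, target_edge) {
  base <- disk_mesh_from_polygon(poly, target_edge)
  # base normals must point down (outward from the enclosed body)
  base$faces <- base$faces[, c(1, 3, 2)]
  cen <- polygon_centroid(poly)
  radii <- sqrt(rowSums(sweep(poly, 2, cen)^2))
  rmean <- mean(radii)
  # dome rings: parameter u in (0,1], scale cos(u*pi/2), lift sin(u*pi/2)
  arc <- sqrt((pi / 2)^2 * (rmean^2 + height^2) / 2) # rough meridian length
  nu <- max(2L, round(arc / target_edge / (pi / 2)))
  verts <- base$vertices
  fixed <- rep(TRUE, nrow(verts))  # whole basal disk pinned
  e <- mesh_edges(base)
  bidx <- boundary_vertices(base)
  rel <- sweep(base$vertices[bidx, 1:2, drop = FALSE], 2, cen)
  bang <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  o <- order(bang)
  prev_ids <- bidx[o]; prev_ang <- bang[o]
  faces <- list(base$faces)
  for (ju in seq_len(nu)) {
    u <- ju / nu
    sc <- cos(u * pi / 2)
    z <- height * sin(u * pi / 2)
    if (ju == nu) {
      apex <- c(cen, z)
      verts <- rbind(verts, apex)
      fixed <- c(fixed, FALSE)
      aid <- nrow(verts)
      np <- length(prev_ids)
      for (t in seq_len(np)) {
        faces[[length(faces) + 1L]] <- c(prev_ids[t], prev_ids[t %% np + 1L], aid)
      }
    } else {
      npts <- max(6L, round(2 * pi * rmean * sc / target_edge))
      ring <- polygon_resample(poly, npts)
      ring <- sweep(sweep(ring, 2, cen, "-") * sc, 2, cen, "+")
      relr <- sweep(ring, 2, cen)
      ang <- atan2(relr[, 2], relr[, 1]) %% (2 * pi)
      oo <- order(ang)
      ids <- nrow(verts) + seq_len(npts)
      verts <- rbind(verts, cbind(ring, z))
      fixed <- c(fixed, rep(FALSE, npts))
      ids <- ids[oo]; ang <- ang[oo]
      faces[[length(faces) + 1L]] <-
        bridge_rings(ids, prev_ids, ang, prev_ang)
      prev_ids <- ids; prev_ang <- ang
    }
  }
  f <- do.call(rbind, faces)
  s <- tri_surface(verts, f, fixed, validate = FALSE)
  if (enclosed_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

#' Generate an initial triangulated mesh
#'
#' Builds a near-equilateral starting mesh for the drop solver. Spheres and
#' ellipsoids come from a geodesic subdivision of the icosahedron followed by
#' a few spring-relaxation sweeps projected back onto the target surface;
#' planar disks and capped (cell-like) surfaces are built from concentric
#' rings of the footprint polygon. Boundary/basal vertices of open or capped
#' shapes are flagged `fixed`.
#'
#' @param shape a list describing the target shape, one of
#'   `list(type = "sphere", radius = r)`,
#'   `list(type = "ellipsoid", semiaxes = c(a, b, c))`,
#'   `list(type = "disk", radius = r)` or
#'   `list(type = "disk", footprint = <k x 2 polygon>)`,
#'   `list(type = "capped", footprint = <k x 2 polygon>, height = h)`
#'   (a `radius` may replace `footprint` for a circular cell).
#' @param target_edge_length requested mean edge length (um); must be small
#'   enough that the mesh has at least 50 faces.
#' @param relax_iter spring-relaxation sweeps for curved shapes.
#' @return a [tri_surface()].
#' @export
make_initial_mesh <- function(shape, target_edge_length, relax_iter = 5L) {
  if (!is.list(shape) || is.null(shape$type)) {
    stop("shape must be a list with a 'type' field")
  }
  if (target_edge_length <= 0) stop("target_edge_length must be > 0")
  s <- switch(shape$type,
    sphere = {
      r <- shape$radius
      if (is.null(r) || r <= 0) stop("sphere requires radius > 0")
      k <- max(2L, round(1.0515 * r / target_edge_length))
      m <- icosphere(k)
      m$vertices <- m$vertices * r
      if (!is.null(shape$center)) {
        m$vertices <- sweep(m$vertices, 2, as.numeric(shape$center), "+")
      }
      if (relax_iter > 0) {
        cen <- if (is.null(shape$center)) c(0, 0, 0) else as.numeric(shape$center)
        proj <- function(p) {
          q <- sweep(p, 2, cen)
          sweep(q * (r / sqrt(rowSums(q^2))), 2, cen, "+")
        }
        m <- relax_on_surface(m, proj, relax_iter)
      }
      m
    },
    ellipsoid = {
      ax <- shape$semiaxes
      if (is.null(ax) || length(ax) != 3 || any(ax <= 0)) {
        stop("ellipsoid requires three positive semiaxes")
      }
      rg <- prod(ax)^(1 / 3)
      k <- max(2L, round(1.0515 * rg / target_edge_length))
      m <- icosphere(k)
      m$vertices <- sweep(m$vertices, 2, ax, "*")
      m
    },
    disk = {
      poly <- shape$footprint
      if (is.null(poly)) {
        r <- shape$radius
        if (is.null(r) || r <= 0) stop("disk requires radius > 0 or a footprint")
        th <- seq(0, 2 * pi, length.out = 65)[-65]
        poly <- cbind(r * cos(th), r * sin(th))
      }
      disk_mesh_from_polygon(poly, target_edge_length)
    },
    capped = {
      poly <- shape$footprint
      if (is.null(poly)) {
        r <- shape$radius
        if (is.null(r) || r <= 0) stop("capped requires radius > 0 or a footprint")
        th <- seq(0, 2 * pi, length.out = 65)[-65]
        poly <- cbind(r * cos(th), r * sin(th))
      }
      h <- shape$height
      if (is.null(h) || h <= 0) stop("capped requires height > 0")
      capped_mesh_from_polygon(poly, h, target_edge_length)
    },
    stop("unknown shape type: ", shape$type)
  )
  if (nrow(s$faces) < 50L) {
    stop("target_edge_length too large: mesh has fewer than 50 faces")
  }
  validate_tri_surface(s)
  s
}
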