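#' Triangulated surface
#'
#' A `tri_surface` is a triangulated surface embedded in 3D: an `n x 3`
#' vertex matrix (micrometres), an `m x 3` integer face matrix of 1-based
#' vertex indices with consistent counter-clockwise (outward) orientation,
#' and a per-vertex logical `fixed` mask marking pinned vertices (used for
#' the adhesion-perimeter boundary condition of the drop solver).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in um.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param fixed logical vector of length `nrow(vertices)`; `TRUE` pins a
#'   vertex during energy minimization.
#' @param validate if `TRUE` (default) run [validate_tri_surface()].
#' @return an object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, fixed = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (is.null(fixed)) fixed <- rep(FALSE, nrow(vertices))
  fixed <- as.logical(fixed)
  if (length(fixed) != nrow(vertices)) {
    stop("fixed mask length must equal the number of vertices")
  }
  s <- structure(
    list(vertices = vertices, faces = faces, fixed = fixed),
    class = "tri_surface"
  )
  if (validate) validate_tri_surface(s)
  s
}

#' Validate a triangulated surface
#'
#' Checks the structural invariants: every face references three distinct
#' valid vertex indices, every face has positive area, orientation is
#' consistent (each interior edge traversed once in each direction), and the
#' surface is either closed (every edge shared by two faces) or has a
#' boundary whose edges belong to exactly one face.
#'
#' @param s a [tri_surface()].
#' @param tol area tolerance below which a triangle counts as degenerate.
#' @return `s`, invisibly; errors describe the first violated invariant.
#' @export
validate_tri_surface <- function(s, tol = 1e-12) {
  v <- s$vertices; f <- s$faces
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3])) {
    stop("face with repeated vertex index")
  }
  if (any(face_areas(s) <= tol)) stop("degenerate (zero-area) triangle")
  ed <- directed_edges(f)
  key <- paste(ed[, 1], ed[, 2])
  if (anyDuplicated(key)) stop("inconsistent orientation: repeated directed edge")
  ukey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(ukey)
  if (any(cnt > 2L)) stop("non-manifold edge (shared by > 2 faces)")
  invisible(s)
}

directed_edges <- function(f) {
  rbind(f[, c(1, 2), drop = FALSE],
        f[, c(2, 3), drop = FALSE],
        f[, c(3, 1), drop = FALSE])
}

#' Edge table of a surface
#'
#' @param s a [tri_surface()].
#' @return data.frame with undirected edge endpoints `v1 < v2`, adjacent face
#'   ids `f1`, `f2` (`f2 = NA` on the boundary).
#' @export
mesh_edges <- function(s) {
  f <- s$faces
  nf <- nrow(f)
  ed <- directed_edges(f)
  face_id <- rep(seq_len(nf), times = 3L)
  a <- pmin(ed[, 1], ed[, 2]); b <- pmax(ed[, 1], ed[, 2])
  key <- a * (nrow(s$vertices) + 1) + b
  o <- order(key)
  a <- a[o]; b <- b[o]; face_id <- face_id[o]; key <- key[o]
  first <- !duplicated(key)
  idx <- cumsum(first)
  f1 <- rep(NA_integer_, max(idx)); f2 <- rep(NA_integer_, max(idx))
  f1[idx[first]] <- face_id[first]
  dupe <- !first
  f2[idx[dupe]] <- face_id[dupe]
  data.frame(v1 = a[first], v2 = b[first], f1 = f1, f2 = f2)
}

#' Is the surface closed?
#' @param s a [tri_surface()].
#' @return `TRUE` when every edge is shared by exactly two faces.
#' @export
is_closed_surface <- function(s) {
  !anyNA(mesh_edges(s)$f2)
}

#' Boundary vertex indices of an open surface (empty for closed surfaces).
#' @param s a [tri_surface()].
#' @export
boundary_vertices <- function(s) {
  e <- mesh_edges(s)
  sort(unique(c(e$v1[is.na(e$f2)], e$v2[is.na(e$f2)])))
}

#' Euler characteristic V - E + F
#' @param s a [tri_surface()].
#' @export
euler_characteristic <- function(s) {
  nrow(s$vertices) - nrow(mesh_edges(s)) + nrow(s$faces)
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf(
    "tri_surface: %d vertices, %d faces, %d fixed, %s\n",
    nrow(x$vertices), nrow(x$faces), sum(x$fixed),
    if (is_closed_surface(x)) "closed" else "open (boundary)"
  ))
  invisible(x)
}

# ---- ASCII mesh I/O (OFF and PLY) -----------------------------------------

#' Write a surface to an ASCII OFF file
#' @param s a [tri_surface()].
#' @param path output file path.
#' @export
write_mesh_off <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nrow(s$vertices), nrow(s$faces), 0L), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     s$vertices[, 1], s$vertices[, 2], s$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     s$faces[, 1] - 1L, s$faces[, 2] - 1L, s$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a surface from an ASCII OFF file
#' @param path input file path.
#' @return a [tri_surface()].
#' @export
read_mesh_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vl <- ln[3:(2 + nv)]
  fl <- ln[(3 + nv):(2 + nv + nf)]
  v <- matrix(as.numeric(unlist(strsplit(vl, "\\s+"))), ncol = 3, byrow = TRUE)
  fparts <- strsplit(fl, "\\s+")
  f <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
  tri_surface(v, f)
}

#' Write a surface to an ASCII PLY file
#' @param s a [tri_surface()].
#' @param path output file path.
#' @export
write_mesh_ply <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(s$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(s$faces)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     s$vertices[, 1], s$vertices[, 2], s$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     s$faces[, 1] - 1L, s$faces[, 2] - 1L, s$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a surface from an ASCII PLY file
#' @param path input file path.
#' @return a [tri_surface()].
#' @export
read_mesh_ply <- function(path) {
  ln <- trimws(readLines(path))
  if (ln[1] != "ply") stop("not a PLY file")
  end <- match("end_header", ln)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)))
  vl <- ln[(end + 1):(end + nv)]
  fl <- ln[(end + nv + 1):(end + nv + nf)]
  v <- matrix(as.numeric(unlist(strsplit(vl, "\\s+"))), ncol = 3, byrow = TRUE)
  fparts <- strsplit(fl, "\\s+")
  f <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
  tri_surface(v, f)
}
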