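test_that("initial sphere meshes are valid, closed and metrically accurate", {
  s <- make_initial_mesh(list(type = "sphere", radius = 1), 0.3)
  expect_silent(validate_tri_surface(s))
  expect_true(is_closed_surface(s))
  expect_identical(euler_characteristic(s), 2L)
  expect_gt(min_triangle_angle(s), 20 * pi / 180)
  expect_lt(abs(mean_edge_length(s) / 0.3 - 1), 0.2)

  # sphere sized for V = 800 um^3
  r <- (3 * 800 / (4 * pi))^(1 / 3)
  s800 <- make_initial_mesh(list(type = "sphere", radius = r), 0.45)
  expect_lt(abs(enclosed_volume(s800) / 800 - 1), 0.02)

  # fine sphere: area within 1% of 4 pi at >= 2000 faces
  sf <- make_initial_mesh(list(type = "sphere", radius = 1), 0.065)
  expect_gte(nrow(sf$faces), 2000)
  expect_lt(abs(surface_area(sf) / (4 * pi) - 1), 0.01)
  expect_lt(abs(enclosed_volume(sf) / (4 * pi / 3) - 1), 0.01)

  expect_error(make_initial_mesh(list(type = "sphere", radius = 0), 0.1),
               "radius")
  expect_error(make_initial_mesh(list(type = "disk", radius = 10), 8),
               "50 faces")
})

test_that("disk footprints flag boundary vertices as fixed", {
  d <- make_initial_mesh(list(type = "disk", radius = 10), 1)
  expect_false(is_closed_surface(d))
  bv <- boundary_vertices(d)
  expect_true(all(d$fixed[bv]))
  expect_true(all(which(d$fixed) %in% bv))
  expect_lt(abs(surface_area(d) / (pi * 100) - 1), 0.02)
})

test_that("surface area and volume are exact on polyhedra and sign-aware", {
  cube <- unit_cube_mesh()
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)
  # single triangle area
  tr <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  expect_equal(surface_area(tr), 0.5)
  # inward-oriented cube has signed volume -1
  inward <- cube
  inward$faces <- inward$faces[, c(1, 3, 2)]
  expect_equal(enclosed_volume(inward), -1)
  # open surface refuses a volume without a reference point
  opened <- tri_surface(cube$vertices, cube$faces[-1, ], validate = FALSE)
  expect_error(enclosed_volume(opened), "closed")
})

test_that("area/volume converge to analytic sphere values with refinement", {
  errs <- vapply(c(0.5, 0.25, 0.125), function(h) {
    s <- make_initial_mesh(list(type = "sphere", radius = 1), h)
    abs(surface_area(s) / (4 * pi) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # observed order >= 1 in edge length (errors drop at least ~2x per halving)
  expect_gt(errs[1] / errs[2], 2)
  expect_gt(errs[2] / errs[3], 2)
})

test_that("cvt energy scales as length^4, penalizes jitter, matches quadrature", {
  s <- make_initial_mesh(list(type = "sphere", radius = 1), 0.25)
  e1 <- cvt_energy(s)
  s2 <- s; s2$vertices <- 2 * s2$vertices
  expect_equal(cvt_energy(s2) / e1, 16, tolerance = 1e-10)
  sj <- jitter_radially(s, 0.02, seed = 3)
  expect_gt(cvt_energy(sj), e1)

  # flat unit square, 2 vs 8 triangles: compare with dense grid quadrature
  sq2 <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  quad_oracle <- function(s) {
    # integrate |x - x_i|^2 over barycentric dual cells on a fine grid
    n <- 400
    gx <- (seq_len(n) - 0.5) / n
    pts <- cbind(rep(gx, each = n), rep(gx, n), 0)
    total <- 0
    fc <- list(a = s$faces[, 1], b = s$faces[, 2], c = s$faces[, 3])
    for (f in seq_len(nrow(s$faces))) {
      tri <- s$vertices[s$faces[f, ], 1:2]
      # barycentric coords of grid points wrt this face
      m <- cbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      uv <- t(solve(m, t(sweep(pts[, 1:2], 2, tri[1, ]))))
      inside <- uv[, 1] >= 0 & uv[, 2] >= 0 & rowSums(uv) <= 1
      if (!any(inside)) next
      w <- cbind(1 - rowSums(uv[inside, , drop = FALSE]),
                 uv[inside, 1], uv[inside, 2])
      owner <- max.col(w)  # nearest corner in barycentric terms
      vi <- s$faces[f, owner]
      d2 <- rowSums((pts[inside, 1:2, drop = FALSE] -
                       s$vertices[vi, 1:2, drop = FALSE])^2)
      total <- total + sum(d2) / n^2
    }
    total
  }
  expect_lt(abs(cvt_energy(sq2) / quad_oracle(sq2) - 1), 0.01)
})

test_that("edge flipping enforces the opposite-angle criterion and is a fixed point", {
  # skewed planar quad triangulated on the wrong diagonal
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0.2, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  s <- tri_surface(v, f)
  fl <- flip_edges(s)
  expect_identical(fl$n_flips, 1L)
  # the new shared edge is 2-4 (the short diagonal)
  e <- mesh_edges(fl$surface)
  inner <- e[!is.na(e$f2), ]
  expect_identical(c(inner$v1, inner$v2), c(2L, 4L))
  # vertex positions untouched
  expect_identical(fl$surface$vertices, v)
  # flipping again is a no-op
  expect_identical(flip_edges(fl$surface)$n_flips, 0L)

  # already-Delaunay sphere mesh: unchanged; Euler characteristic preserved
  sp <- make_initial_mesh(list(type = "sphere", radius = 1), 0.3)
  expect_identical(flip_edges(sp)$n_flips, 0L)
  spj <- jitter_radially(sp, 0.15, seed = 9)
  flj <- flip_edges(spj)
  expect_identical(euler_characteristic(flj$surface), 2L)
  expect_identical(flj$surface$vertices, spj$vertices)
})

test_that("mesh I/O round-trips through OFF and PLY", {
  s <- make_initial_mesh(list(type = "sphere", radius = 2), 0.6)
  for (fmt in c("off", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "off") write_mesh_off(s, path) else write_mesh_ply(s, path)
    r <- if (fmt == "off") read_mesh_off(path) else read_mesh_ply(path)
    expect_equal(r$vertices, s$vertices, tolerance = 1e-5)
    expect_identical(r$faces, s$faces)
  }
})

test_that("validation rejects malformed surfaces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_surface(v, rbind(c(1, 1, 2))), "repeated")
  expect_error(tri_surface(v, rbind(c(1, 2, 4))), "out of range")
  # inconsistent orientation: two faces traversing the shared edge identically
  v4 <- rbind(v, c(1, 1, 0))
  expect_error(tri_surface(v4, rbind(c(1, 2, 3), c(2, 3, 4))),
               "orientation")
})

test_that("mean curvature matches 1/R on spheres", {
  for (r in c(2, 5)) {
    s <- make_initial_mesh(list(type = "sphere", radius = r), r / 7)
    H <- vertex_mean_curvature(s)
    expect_lt(abs(mean(H) * r - 1), 0.02)
  }
})
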