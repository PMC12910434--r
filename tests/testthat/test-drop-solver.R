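test_that("wall shear stress matches the vessel-chip operating point and scaling laws", {
  expect_equal(wall_shear_stress(10, 0.8, 200, 200), 1.0, tolerance = 1e-12)
  expect_identical(wall_shear_stress(0, 0.8, 200, 200), 0)
  t1 <- wall_shear_stress(5, 0.8, 200, 100)
  expect_equal(wall_shear_stress(5, 0.8, 200, 200) / t1, 1 / 4)  # h doubling
  expect_equal(wall_shear_stress(10, 0.8, 200, 200),
               2 * wall_shear_stress(5, 0.8, 200, 200))          # linear in Q
  expect_equal(wall_shear_stress(10, 1.6, 200, 200),
               2 * wall_shear_stress(10, 0.8, 200, 200))         # linear in eta
  expect_error(wall_shear_stress(10, 0.8, -1, 200), "positive")
})

test_that("excess area percent follows its closed form", {
  expect_equal(excess_area_percent(4 * pi, 4 * pi / 3), 0, tolerance = 1e-9)
  A37 <- 1.37 * sphere_area_for_volume(800)
  expect_equal(excess_area_percent(A37, 800), 37, tolerance = 1e-9)
  # the printed-table pairing (A = 1543, V = 800) evaluates as stated
  expect_equal(excess_area_percent(1543, 800),
               100 * (1543 / ((36 * pi)^(1 / 3) * 800^(2 / 3)) - 1),
               tolerance = 1e-12)
  expect_warning(excess_area_percent(100, 800), "below")
  expect_error(excess_area_percent(-1, 800), "positive")
})

test_that("drop_config validates its invariants", {
  expect_error(drop_config(V_nuc0 = 800, A_nuc0 = 100), "below the sphere")
  expect_error(drop_config(V_nuc0 = 800, excess_area_pct = 10, V_cell0 = 700),
               "exceed")
  expect_error(drop_config(V_nuc0 = 800, excess_area_pct = 10,
                           gamma_schedule = c(10, 5, 20),
                           beta_nuc_schedule = c(1, 2, 3),
                           beta_cell_schedule = c(1, 2, 3)), "increasing")
  cfg <- drop_config(V_nuc0 = 800, excess_area_pct = 37)
  expect_equal(cfg$A_nuc0, 1.37 * sphere_area_for_volume(800))
})

test_that("total energy decomposes into its stated terms", {
  V0 <- 4 * pi / 3
  cfg <- drop_config(V_nuc0 = V0, A_nuc0 = 4 * pi * 1.05, V_cell0 = 10 * V0,
                     cvt_weight = 0.05)
  nuc <- make_initial_mesh(list(type = "sphere", radius = 1), 0.3)
  cell <- make_initial_mesh(list(type = "sphere", radius = 3), 0.8)
  # term-by-term oracle computed independently from the primitives
  scales <- nucleodrop:::energy_scales(cfg, cell, nuc)
  for (k in c(1L, 3L)) {
    gam <- cfg$gamma_schedule[k]
    bn <- cfg$beta_nuc_schedule[k]; bc <- cfg$beta_cell_schedule[k]
    expected <- surface_area(cell) / cfg$A_nuc0 +
      0.05 * cvt_energy(cell) / scales$cvt_cell0 +
      0.05 * cvt_energy(nuc) / scales$cvt_nuc0 +
      gam * (surface_area(nuc) / cfg$A_nuc0 - 1)^2 +
      bn * (enclosed_volume(nuc) / V0 - 1)^2 +
      bc * (enclosed_volume(cell) / (10 * V0) - 1)^2
    expect_equal(total_energy(cell, nuc, cfg, k), expected,
                 tolerance = 1e-9)
  }
  # doubling gamma with a nonzero area residual strictly increases E_tot
  e1 <- total_energy(cell, nuc, cfg, 1)
  cfg2 <- cfg; cfg2$gamma_schedule <- 2 * cfg$gamma_schedule
  expect_gt(total_energy(cell, nuc, cfg2, 1), e1)
  # zero residuals: E_tot = E_cell + E_nuc exactly, penalty-free
  cfg0 <- drop_config(V_nuc0 = enclosed_volume(nuc),
                      A_nuc0 = surface_area(nuc),
                      V_cell0 = enclosed_volume(cell))
  e0 <- total_energy(cell, nuc, cfg0, 1)
  expect_equal(e0, surface_area(cell) / cfg0$A_nuc0 +
                 0.05 + 0.05, tolerance = 1e-9)
  expect_error(total_energy(cell, nuc, cfg, 99L), "schedule")
})

test_that("overlap enforcement reflects vertices to the admissible side", {
  cell <- make_initial_mesh(list(type = "sphere", radius = 3), 0.5)
  nuc <- make_initial_mesh(list(type = "sphere", radius = 1.5), 0.4)
  # fully inside: both unchanged
  ov <- enforce_no_overlap(cell, nuc)
  expect_identical(ov$n_moved_cell + ov$n_moved_nucleus, 0L)
  expect_identical(ov$nucleus$vertices, nuc$vertices)

  # one nuclear vertex displaced outside a rigid spherical cell:
  # closest-point oracle for a sphere is radial projection
  cell$fixed <- rep(TRUE, nrow(cell$vertices))
  nuc2 <- nuc
  i <- which.max(nuc2$vertices[, 1])
  dir <- nuc2$vertices[i, ] / sqrt(sum(nuc2$vertices[i, ]^2))
  nuc2$vertices[i, ] <- dir * 3.1
  ov2 <- enforce_no_overlap(cell, nuc2)
  expect_identical(ov2$n_moved_nucleus, 1L)
  moved <- ov2$nucleus$vertices[i, ]
  r_moved <- sqrt(sum(moved^2))
  expect_lt(r_moved, 3.0)           # strictly inside
  expect_gt(r_moved, 2.9)           # near the surface, not bounced far
  # displacement along the inward radial direction (sphere normal)
  expect_gt(sum((moved / r_moved) * dir), 0.99)

  # substrate plane: vertex below z = 0 clipped to the plane
  nuc3 <- nuc
  nuc3$vertices[, 3] <- nuc3$vertices[, 3] - 1.4  # dips below z = 0
  pr <- nucleodrop:::project_substrate(nuc3)
  expect_gte(min(pr$vertices[, 3]), 0)
  untouched <- nuc3$vertices[, 3] >= 0
  expect_identical(pr$vertices[untouched, ], nuc3$vertices[untouched, ])
})

test_that("free nucleus with spherical target area relaxes to a sphere", {
  V0 <- 150
  r0 <- (3 * V0 / (4 * pi))^(1 / 3)
  s <- make_initial_mesh(list(type = "sphere", radius = r0), r0 / 8)
  v <- s$vertices
  s$vertices <- v * (1 + 0.1 * sin(2 * v[, 1]) * cos(3 * v[, 2]))
  cfg <- drop_config(V_nuc0 = V0, A_nuc0 = sphere_area_for_volume(V0),
                     gamma_schedule = 10^(2:6),
                     beta_nuc_schedule = 10^(2:6),
                     beta_cell_schedule = 10^(2:6))
  res <- solve_equilibrium(cfg, NULL, s, substrate = FALSE, max_inner = 130)
  expect_true(res$converged)
  expect_true(all(res$residuals < 1e-3))
  vv <- res$nucleus$vertices
  rr <- sqrt(rowSums(sweep(vv, 2, colMeans(vv))^2))
  expect_lt(max(abs(rr / mean(rr) - 1)), 0.02)
  # descent energy is non-increasing within stages between flip events
  tr <- res$trace
  by_stage <- split(tr, tr$stage)
  for (st in by_stage) {
    expect_true(all(st$energy_post <= st$energy_pre + 1e-12))
  }
})

test_that("converged nuclear A and V are robust to the penalty schedule", {
  V0 <- 150
  r0 <- (3 * V0 / (4 * pi))^(1 / 3)
  s <- make_initial_mesh(list(type = "sphere", radius = r0), r0 / 4)
  s <- jitter_radially(s, 0.05, seed = 11)
  out <- lapply(list(10^(2:6), 4 * 10^(2:6)), function(sch) {
    cfg <- drop_config(V_nuc0 = V0, A_nuc0 = 1.1 * sphere_area_for_volume(V0),
                       gamma_schedule = sch, beta_nuc_schedule = sch,
                       beta_cell_schedule = sch)
    res <- solve_equilibrium(cfg, NULL, s, substrate = FALSE, max_inner = 60)
    c(A = surface_area(res$nucleus), V = enclosed_volume(res$nucleus))
  })
  expect_lt(abs(out[[1]]["A"] / out[[2]]["A"] - 1), 2e-3)
  expect_lt(abs(out[[1]]["V"] / out[[2]]["V"] - 1), 2e-3)
})

test_that("plate confinement reaches the axisymmetric pancake limit", {
  # quasi-static press of a smooth drop with 37% excess area between the
  # substrate and a descending plate; the smallest feasible gap is the
  # limiting height, compared against the 1D constant-mean-curvature oracle
  V0 <- 800
  A0 <- 1.37 * sphere_area_for_volume(V0)
  h_star <- pancake_height_for_area(A0, V0)
  cfg <- drop_config(V_nuc0 = V0, A_nuc0 = A0)
  a <- 8.0; cz <- 3 * V0 / (4 * pi * a^2)
  nuc <- make_initial_mesh(list(type = "ellipsoid", semiaxes = c(a, a, cz)), 0.95)
  nuc$vertices[, 3] <- nuc$vertices[, 3] + cz + 0.02
  scales <- nucleodrop:::energy_scales(cfg, NULL, nuc)
  res <- solve_equilibrium(cfg, NULL, nuc, ceiling = 2 * cz + 0.05,
                           max_inner = 60)
  expect_true(res$converged)
  h_ok <- NA_real_
  for (h in seq(2 * cz, 3.0, by = -0.15)) {
    res <- nucleodrop:::solve_single_stage(
      cfg, NULL, res$nucleus, res$stiffness_index, scales,
      obstacles = list(), substrate = TRUE, max_inner = 80, ceiling = h
    )
    if (all(res$residuals < cfg$residual_tol)) h_ok <- h else break
  }
  expect_lt(abs(h_ok / h_star - 1), 0.05)
})

test_that("micropost machinery rejects infeasible or ill-prepared setups", {
  expect_error(obstacle(c(0, 0), radius = 0), "radius")
  cfg <- drop_config(V_nuc0 = 800, excess_area_pct = 37, V_cell0 = 900)
  fake <- structure(list(cell = NULL, nucleus = NULL), class = "solve_result")
  big <- obstacle(c(0, 0), radius = 6, height = 5)
  expect_error(indent_with_post(fake, big, cfg), "infeasible")
})
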