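closest_point_mesh <- function(points, s) {
  cpp_closest_point_mesh(points, s$vertices, s$faces)
}

points_inside_mesh <- function(points, s, jitter = 1e-9) {
  cpp_points_inside(points, s$vertices, s$faces, jitter)
}

#' Reflect interpenetrating vertices of the cell/nucleus surface pair
#'
#' Any nuclear vertex lying outside the cell surface is moved to the nearest
#' point on the cell surface and nudged strictly inside; symmetrically, any
#' cell vertex lying inside the nucleus is moved just outside it. Fixed
#' vertices are never moved. This is the reflecting-boundary treatment of
#' cortex/nucleus contact, applied once per descent sweep by the solver.
#'
#' @param cell closed cell-cortex [tri_surface()].
#' @param nucleus closed nuclear [tri_surface()].
#' @param eps separation margin (um) left after reflection.
#' @return list with elements `cell`, `nucleus`, and counts `n_moved_cell`,
#'   `n_moved_nucleus`.
#' @export
enforce_no_overlap <- function(cell, nucleus, eps = 1e-4) {
  moved_n <- 0L; moved_c <- 0L
  # cortex yields first: cell vertices inside the nucleus are pushed just
  # outside it, so an expanding nucleus can transmit contact force ...
  free_c <- which(!cell$fixed)
  if (length(free_c)) {
    pc <- cell$vertices[free_c, , drop = FALSE]
    inside <- points_inside_mesh(pc, nucleus)
    bad <- which(inside)
    if (length(bad)) {
      cp <- closest_point_mesh(pc[bad, , drop = FALSE], nucleus)
      dir <- cp$point - pc[bad, , drop = FALSE]
      nn <- rownorm(dir)
      fn <- face_normals(nucleus)[cp$face, , drop = FALSE]
      use_norm <- nn < eps
      dir <- dir / pmax(nn, .Machine$double.eps)
      dir[use_norm, ] <- fn[use_norm, , drop = FALSE]
      cell$vertices[free_c[bad], ] <- cp$point + eps * dir
      moved_c <- length(bad)
    }
  }
  # ... then the nucleus is clipped to the (updated) cell, so the returned
  # pair is overlap-free with the nucleus strictly inside
  free_n <- which(!nucleus$fixed)
  if (length(free_n)) {
    pn <- nucleus$vertices[free_n, , drop = FALSE]
    inside <- points_inside_mesh(pn, cell)
    bad <- which(!inside)
    if (length(bad)) {
      cp <- closest_point_mesh(pn[bad, , drop = FALSE], cell)
      dir <- cp$point - pn[bad, , drop = FALSE]
      nn <- rownorm(dir)
      # on-surface points: push along inward face normal instead
      fn <- face_normals(cell)[cp$face, , drop = FALSE]
      use_norm <- nn < eps
      dir <- dir / pmax(nn, .Machine$double.eps)
      dir[use_norm, ] <- -fn[use_norm, , drop = FALSE]
      nucleus$vertices[free_n[bad], ] <- cp$point + eps * dir
      moved_n <- length(bad)
    }
  }
  list(cell = cell, nucleus = nucleus,
       n_moved_cell = moved_c, n_moved_nucleus = moved_n)
}

# Substrate half-space: free vertices reflected to z >= 0.
project_substrate <- function(s) {
  free <- !s$fixed
  z <- s$vertices[, 3]
  bad <- free & z < 0
  s$vertices[bad, 3] <- 0
  s
}

# Rigid top plate: free vertices reflected to z <= ceiling.
project_ceiling <- function(s, ceiling) {
  if (!is.finite(ceiling)) return(s)
  free <- !s$fixed
  bad <- free & s$vertices[, 3] > ceiling
  s$vertices[bad, 3] <- ceiling
  s
}

# Micropost exclusion: vertices inside the cylinder are reflected to the
# nearest point on its surface (radial wall or top cap).
project_obstacle <- function(s, obs, center_xy = obs$center_xy, eps = 1e-4) {
  v <- s$vertices
  dx <- v[, 1] - center_xy[1]
  dy <- v[, 2] - center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  inside <- !s$fixed & r < obs$radius & v[, 3] >= 0 & v[, 3] < obs$height
  if (!any(inside)) return(s)
  wall_d <- obs$radius - r[inside]
  top_d <- obs$height - v[inside, 3]
  to_wall <- wall_d <= top_d
  i_wall <- which(inside)[to_wall]
  i_top <- which(inside)[!to_wall]
  if (length(i_wall)) {
    rr <- pmax(r[i_wall], .Machine$double.eps)
    sc <- (obs$radius + eps) / rr
    v[i_wall, 1] <- center_xy[1] + dx[i_wall] * sc
    v[i_wall, 2] <- center_xy[2] + dy[i_wall] * sc
  }
  if (length(i_top)) v[i_top, 3] <- obs$height + eps
  s$vertices <- v
  s
}

n_vertices_in_obstacle <- function(s, obs, center_xy = obs$center_xy) {
  v <- s$vertices
  r <- sqrt((v[, 1] - center_xy[1])^2 + (v[, 2] - center_xy[2])^2)
  sum(r < obs$radius & v[, 3] >= 0 & v[, 3] < obs$height)
}

# Apply the active reflecting boundaries for the given configuration.
project_state <- function(cell, nucleus, obstacles, substrate,
                          ceiling = Inf) {
  if (substrate) {
    nucleus <- project_substrate(nucleus)
    if (!is.null(cell)) cell <- project_substrate(cell)
  }
  if (is.finite(ceiling)) {
    nucleus <- project_ceiling(nucleus, ceiling)
    if (!is.null(cell)) cell <- project_ceiling(cell, ceiling)
  }
  for (obs in obstacles) {
    nucleus <- project_obstacle(nucleus, obs)
    if (!is.null(cell)) cell <- project_obstacle(cell, obs)
  }
  if (!is.null(cell)) {
    ov <- enforce_no_overlap(cell, nucleus)
    cell <- ov$cell; nucleus <- ov$nucleus
  }
  list(cell = cell, nucleus = nucleus)
}

#' Solve for equilibrium cell and nuclear shapes
#'
#' Minimizes the total drop-model energy ([total_energy()]) by damped
#' gradient descent with backtracking line search, over an outer loop that
#' progressively increases the area/volume penalty stiffnesses until the
#' constraint residuals fall below `cfg$residual_tol`. Each accepted sweep
#' applies the reflecting boundaries (substrate plane, optional micropost
#' obstacles, cortex/nucleus non-overlap) and re-establishes the local
#' Delaunay property by edge flipping. Step acceptance requires the energy
#' after projection not to increase, so the per-stage energy trace is
#' non-increasing between flip events.
#'
#' @param cfg a [drop_config()].
#' @param init_cell initial cell-cortex [tri_surface()] (closed, basal
#'   vertices fixed), or `NULL` for a nucleus-only solve.
#' @param init_nucleus initial nuclear [tri_surface()] (closed), inside the
#'   cell if one is given.
#' @param obstacles list of [obstacle()]s held fixed during the solve.
#' @param substrate if `FALSE`, no substrate plane is imposed (free drop).
#' @param ceiling optional rigid top plate height (um); `Inf` disables.
#'   Together with the substrate this imposes plate confinement.
#' @param max_inner maximum descent sweeps per stiffness stage.
#' @param flip_every apply [flip_edges()] every this many accepted sweeps.
#' @param step_frac initial step as a fraction of mean edge length.
#' @param stall_tol relative energy decrease below which a stage is
#'   declared stalled.
#' @param verbose print per-stage progress.
#' @return a `solve_result`: list with `cell`, `nucleus`, `residuals`
#'   (named `V_nuc`, `A_nuc`, `V_cell`), `total_energy`, `converged`,
#'   `outer_iterations`, and a per-sweep `trace` data.frame.
#' @export
solve_equilibrium <- function(cfg, init_cell, init_nucleus,
                              obstacles = list(), substrate = TRUE,
                              ceiling = Inf,
                              max_inner = 120L, flip_every = 5L,
                              step_frac = 0.2, stall_tol = 1e-8,
                              verbose = FALSE) {
  cell <- init_cell
  nucleus <- init_nucleus
  scales <- energy_scales(cfg, cell, nucleus)
  n_stage <- length(cfg$gamma_schedule)
  l_nuc <- mean_edge_length(nucleus)
  l_ref <- if (!is.null(cell)) min(l_nuc, mean_edge_length(cell)) else l_nuc
  trace <- list()
  outer_done <- 0L
  proj <- function(cl, nu) project_state(cl, nu, obstacles, substrate, ceiling)
  st <- proj(cell, nucleus)
  cell <- st$cell; nucleus <- st$nucleus
  for (k in seq_len(n_stage)) {
    et <- drop_energy_terms(cell, nucleus, cfg, k, scales)
    E0 <- et$total
    stalled <- FALSE
    for (it in seq_len(max_inner)) {
      g <- drop_energy_gradient(cell, nucleus, cfg, k, scales)
      gmax <- max(rownorm(g$nucleus),
                  if (!is.null(g$cell)) rownorm(g$cell) else 0)
      if (!is.finite(gmax) || gmax < 1e-14) { stalled <- TRUE; break }
      step <- step_frac * l_ref / gmax
      accepted <- FALSE
      for (bt in 1:25) {
        cand_n <- nucleus
        cand_n$vertices <- nucleus$vertices - step * g$nucleus
        cand_c <- cell
        if (!is.null(cell)) cand_c$vertices <- cell$vertices - step * g$cell
        stc <- proj(cand_c, cand_n)
        etc <- drop_energy_terms(stc$cell, stc$nucleus, cfg, k, scales)
        if (is.finite(etc$total) && etc$total <= E0 * (1 + 1e-12) + 1e-14) {
          if (etc$total < E0) accepted <- TRUE
          cell <- stc$cell; nucleus <- stc$nucleus
          E_new <- etc$total
          et <- etc
          break
        }
        step <- step / 2
      }
      if (!accepted) { stalled <- TRUE; break }
      flipped <- 0L
      if (it %% flip_every == 0L) {
        fn <- flip_edges(nucleus)
        nucleus <- fn$surface
        flipped <- fn$n_flips
        if (!is.null(cell)) {
          fcl <- flip_edges(cell)
          cell <- fcl$surface
          flipped <- flipped + fcl$n_flips
        }
        if (flipped > 0L) {
          et <- drop_energy_terms(cell, nucleus, cfg, k, scales)
        }
      }
      trace[[length(trace) + 1L]] <- data.frame(
        stage = k, iter = it, energy_pre = E0, energy_post = E_new,
        flips = flipped,
        r_Vnuc = et$residuals[["V_nuc"]], r_Anuc = et$residuals[["A_nuc"]],
        r_Vcell = et$residuals[["V_cell"]]
      )
      rel <- (E0 - et$total) / max(abs(E0), 1e-30)
      E0 <- et$total
      if (rel < stall_tol && flipped == 0L) { stalled <- TRUE; break }
    }
    outer_done <- k
    if (verbose) {
      message(sprintf(
        "stage %d (gamma=%g): E=%.6g residuals V_nuc=%.2e A_nuc=%.2e V_cell=%.2e%s",
        k, cfg$gamma_schedule[k], E0,
        et$residuals[["V_nuc"]], et$residuals[["A_nuc"]], et$residuals[["V_cell"]],
        if (stalled) " [stalled]" else ""
      ))
    }
    if (all(et$residuals < cfg$residual_tol / 2) && stalled) break
  }
  et <- drop_energy_terms(cell, nucleus, cfg, outer_done, scales)
  res <- structure(list(
    cell = cell, nucleus = nucleus,
    residuals = et$residuals,
    total_energy = et$total,
    converged = all(et$residuals < cfg$residual_tol),
    outer_iterations = outer_done,
    stiffness_index = outer_done,
    cfg = cfg,
    scales = scales,
    substrate = substrate,
    obstacles = obstacles,
    trace = do.call(rbind, trace)
  ), class = "solve_result")
  res
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(
    "solve_result: %s after %d stages; E = %.5g\n",
    if (x$converged) "converged" else "NOT converged",
    x$outer_iterations, x$total_energy
  ))
  cat(sprintf("  residuals: |V_nuc/V0-1| = %.2e, |A_nuc/A0-1| = %.2e, |V_cell/V0-1| = %.2e\n",
              x$residuals[["V_nuc"]], x$residuals[["A_nuc"]], x$residuals[["V_cell"]]))
  invisible(x)
}

#' Quasi-static micropost indentation
#'
#' Steps a rigid cylindrical obstacle along an approach path; at each step,
#' nuclear (and cell) vertices crossing the post boundary are reflected to
#' its surface, then descent continues at the final stiffness stage so that
#' near-equilibrium is maintained throughout. Step length along the path is
#' bounded by the mean nuclear edge length.
#'
#' @param result converged [solve_equilibrium()] result to start from.
#' @param obs an [obstacle()]; its `approach_path` (or `path_from`) defines
#'   the stepping. The path must start outside the nucleus.
#' @param cfg the [drop_config()] used for `result`.
#' @param path_from optional xy start position; a straight path to
#'   `obs$center_xy` is built with steps of at most one mean edge length.
#' @param relax_sweeps descent sweeps after each path step.
#' @param final_sweeps descent sweeps after the last step.
#' @return a `solve_result` at the final post position (with the obstacle
#'   recorded in `obstacles`).
#' @export
indent_with_post <- function(result, obs, cfg, path_from = NULL,
                             relax_sweeps = 40L, final_sweeps = 200L) {
  cell <- result$cell
  nucleus <- result$nucleus
  # feasibility: the post cannot displace more volume than the cell holds
  # beyond the nucleus
  cyl_vol <- pi * obs$radius^2 * obs$height
  if (!is.na(cfg$V_cell0) && cyl_vol >= cfg$V_cell0 - cfg$V_nuc0) {
    stop("infeasible obstacle: cylinder volume exceeds cell/nucleus slack")
  }
  l_nuc <- mean_edge_length(nucleus)
  path <- obs$approach_path
  if (is.null(path)) {
    if (is.null(path_from)) stop("need approach_path or path_from")
    d <- sqrt(sum((obs$center_xy - path_from)^2))
    n_steps <- max(2L, ceiling(d / (0.5 * l_nuc)))
    tt <- seq(0, 1, length.out = n_steps + 1L)
    path <- cbind(path_from[1] + tt * (obs$center_xy[1] - path_from[1]),
                  path_from[2] + tt * (obs$center_xy[2] - path_from[2]))
  }
  # path steps must not exceed one mean nuclear edge length
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  if (any(seg > l_nuc * 1.5)) {
    stop("approach path step exceeds the mean nuclear edge length")
  }
  obs0 <- obstacle(path[1, ], obs$radius, obs$height)
  if (n_vertices_in_obstacle(nucleus, obs0) > 0) {
    stop("approach path must begin outside the nucleus")
  }
  k <- max(result$stiffness_index, 1L)
  scales <- result$scales
  cur <- result
  for (i in seq_len(nrow(path))) {
    obs_i <- obstacle(path[i, ], obs$radius, obs$height)
    sweeps <- if (i == nrow(path)) final_sweeps else relax_sweeps
    cfg_i <- cfg
    # hold stiffness at the reached stage: restrict schedules to stage k
    cfg_i$gamma_schedule <- cfg$gamma_schedule[seq_len(k)]
    cfg_i$beta_nuc_schedule <- cfg$beta_nuc_schedule[seq_len(k)]
    cfg_i$beta_cell_schedule <- cfg$beta_cell_schedule[seq_len(k)]
    cur <- solve_single_stage(cfg_i, cur$cell, cur$nucleus, k, scales,
                              obstacles = list(obs_i),
                              substrate = result$substrate,
                              max_inner = sweeps)
  }
  cur$obstacles <- list(obstacle(path[nrow(path), ], obs$radius, obs$height))
  cur
}

# One-stage descent used during obstacle stepping: same inner loop as
# solve_equilibrium but pinned at stiffness stage k.
solve_single_stage <- function(cfg, cell, nucleus, k, scales, obstacles,
                               substrate, max_inner, flip_every = 5L,
                               step_frac = 0.2, stall_tol = 1e-8,
                               ceiling = Inf) {
  l_nuc <- mean_edge_length(nucleus)
  l_ref <- if (!is.null(cell)) min(l_nuc, mean_edge_length(cell)) else l_nuc
  st <- project_state(cell, nucleus, obstacles, substrate, ceiling)
  cell <- st$cell; nucleus <- st$nucleus
  et <- drop_energy_terms(cell, nucleus, cfg, k, scales)
  E0 <- et$total
  for (it in seq_len(max_inner)) {
    g <- drop_energy_gradient(cell, nucleus, cfg, k, scales)
    gmax <- max(rownorm(g$nucleus),
                if (!is.null(g$cell)) rownorm(g$cell) else 0)
    if (!is.finite(gmax) || gmax < 1e-14) break
    step <- step_frac * l_ref / gmax
    accepted <- FALSE
    for (bt in 1:25) {
      cand_n <- nucleus
      cand_n$vertices <- nucleus$vertices - step * g$nucleus
      cand_c <- cell
      if (!is.null(cell)) cand_c$vertices <- cell$vertices - step * g$cell
      stc <- project_state(cand_c, cand_n, obstacles, substrate, ceiling)
      etc <- drop_energy_terms(stc$cell, stc$nucleus, cfg, k, scales)
      if (is.finite(etc$total) && etc$total < E0) {
        accepted <- TRUE
        cell <- stc$cell; nucleus <- stc$nucleus
        et <- etc
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    if (it %% flip_every == 0L) {
      nucleus <- flip_edges(nucleus)$surface
      if (!is.null(cell)) cell <- flip_edges(cell)$surface
      et <- drop_energy_terms(cell, nucleus, cfg, k, scales)
    }
    rel <- (E0 - et$total) / max(abs(E0), 1e-30)
    E0 <- et$total
    if (rel >= 0 && rel < stall_tol) break
  }
  structure(list(
    cell = cell, nucleus = nucleus,
    residuals = et$residuals,
    total_energy = et$total,
    converged = all(et$residuals < cfg$residual_tol),
    outer_iterations = k,
    stiffness_index = k,
    cfg = cfg, scales = scales,
    substrate = substrate, obstacles = obstacles,
    trace = NULL
  ), class = "solve_result")
}

#' Symmetric Hausdorff distance between two surfaces
#'
#' Max over both directions of the largest vertex-to-surface distance; used
#' for the indentation round-trip (drop-recovery) check.
#'
#' @param s1,s2 [tri_surface()] objects.
#' @return distance in um.
#' @export
hausdorff_distance <- function(s1, s2) {
  d12 <- max(closest_point_mesh(s1$vertices, s2)$dist)
  d21 <- max(closest_point_mesh(s2$vertices, s1)$dist)
  max(d12, d21)
}

#' Geometric diagnostics of a converged nuclear shape
#'
#' Splits the nuclear surface into a basal patch (central bottom), an apical
#' patch (central top) and a lateral rim, and reports the height variation of
#' the basal patch and mean curvatures of the apical patch and rim. A
#' confined drop-model nucleus shows a flat basal face (small height
#' variation), a flattened apical contact (apical curvature well below rim
#' curvature) and a highly curved free rim.
#'
#' @param nucleus a closed [tri_surface()] resting on the substrate.
#' @param central_frac radial fraction defining the apical/basal patches.
#' @param rim_frac radial fraction beyond which vertices count as rim.
#' @return list with `height`, `radius`, `basal_z_range`,
#'   `apical_mean_curvature`, `rim_mean_curvature`, and the patch sizes.
#' @export
drop_shape_metrics <- function(nucleus, central_frac = 0.55, rim_frac = 0.9) {
  v <- nucleus$vertices
  cen <- colMeans(v)
  rxy <- sqrt((v[, 1] - cen[1])^2 + (v[, 2] - cen[2])^2)
  R <- max(rxy)
  z <- v[, 3]
  h <- max(z) - min(z)
  H <- vertex_mean_curvature(nucleus)
  basal <- rxy < central_frac * R & z < min(z) + 0.5 * h
  apical <- rxy < central_frac * R & z > min(z) + 0.5 * h
  rim <- rxy > rim_frac * R
  list(
    height = h,
    radius = R,
    basal_z_range = diff(range(z[basal])),
    apical_mean_curvature = mean(H[apical], na.rm = TRUE),
    rim_mean_curvature = mean(H[rim], na.rm = TRUE),
    n_basal = sum(basal), n_apical = sum(apical), n_rim = sum(rim)
  )
}
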