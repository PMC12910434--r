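# Analytic gradient of total surface area with respect to vertex positions.
# For triangle (a, b, c): dA/da = 0.5 * (b - c) x n_hat.
grad_surface_area <- function(s) {
  v <- s$vertices; f <- s$faces
  fc <- face_corner_coords(s)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  nh <- n / rownorm(n)
  g <- matrix(0, nrow(v), 3)
  add <- function(g, idx, contrib) {
    for (d in 1:3) g[, d] <- g[, d] + tabulate2(idx, contrib[, d], nrow(g))
    g
  }
  g <- add(g, f[, 1], 0.5 * cross3(fc$b - fc$c, nh))
  g <- add(g, f[, 2], 0.5 * cross3(fc$c - fc$a, nh))
  g <- add(g, f[, 3], 0.5 * cross3(fc$a - fc$b, nh))
  g
}

# Analytic gradient of enclosed (signed) volume: dV/da = (b x c) / 6.
grad_enclosed_volume <- function(s) {
  v <- s$vertices; f <- s$faces
  fc <- face_corner_coords(s)
  g <- matrix(0, nrow(v), 3)
  add <- function(g, idx, contrib) {
    for (d in 1:3) g[, d] <- g[, d] + tabulate2(idx, contrib[, d], nrow(g))
    g
  }
  g <- add(g, f[, 1], cross3(fc$b, fc$c) / 6)
  g <- add(g, f[, 2], cross3(fc$c, fc$a) / 6)
  g <- add(g, f[, 3], cross3(fc$a, fc$b) / 6)
  g
}

# Gradient of the CVT energy by per-face central differences: the face
# contribution is an explicit polynomial of its three corners, so perturbing
# one corner coordinate of every face simultaneously gives the full gradient
# in 18 vectorized evaluations.
grad_cvt_energy <- function(s, h = NULL) {
  v <- s$vertices; f <- s$faces
  if (is.null(h)) h <- 1e-5 * mean(sqrt(face_areas(s)))
  fc <- face_corner_coords(s)
  g <- matrix(0, nrow(v), 3)
  corners <- list(fc$a, fc$b, fc$c)
  for (slot in 1:3) {
    for (d in 1:3) {
      cp <- corners; cm <- corners
      cp[[slot]][, d] <- cp[[slot]][, d] + h
      cm[[slot]][, d] <- cm[[slot]][, d] - h
      de <- (cvt_face_energy(cp[[1]], cp[[2]], cp[[3]]) -
               cvt_face_energy(cm[[1]], cm[[2]], cm[[3]])) / (2 * h)
      g[, d] <- g[, d] + tabulate2(f[, slot], de, nrow(v))
    }
  }
  g
}

# Normalization scales fixed at solve start: energies are divided by A_ref
# (the target lamina area) and CVT terms by their initial-mesh magnitude so
# the regularizer starts at cvt_weight regardless of mesh resolution.
energy_scales <- function(cfg, cell, nucleus) {
  list(
    A_ref = cfg$A_nuc0,
    cvt_nuc0 = cvt_energy(nucleus),
    cvt_cell0 = if (!is.null(cell)) cvt_energy(cell) else NA_real_
  )
}

drop_energy_terms <- function(cell, nucleus, cfg, stiffness_index, scales) {
  k <- stiffness_index
  if (k < 1L || k > length(cfg$gamma_schedule)) {
    stop("stiffness_index out of schedule range")
  }
  gam <- cfg$gamma_schedule[k]
  bn <- cfg$beta_nuc_schedule[k]
  bc <- cfg$beta_cell_schedule[k]
  A_nuc <- surface_area(nucleus)
  V_nuc <- enclosed_volume(nucleus)
  E_nuc <- cfg$cvt_weight * cvt_energy(nucleus) / scales$cvt_nuc0
  r_area <- A_nuc / cfg$A_nuc0 - 1
  r_vnuc <- V_nuc / cfg$V_nuc0 - 1
  if (!is.null(cell)) {
    A_cell <- surface_area(cell)
    V_cell <- enclosed_volume(cell)
    E_cell <- A_cell / scales$A_ref +
      cfg$cvt_weight * cvt_energy(cell) / scales$cvt_cell0
    r_vcell <- V_cell / cfg$V_cell0 - 1
  } else {
    A_cell <- NA_real_; V_cell <- NA_real_; E_cell <- 0; r_vcell <- 0
  }
  pen <- gam * r_area^2 + bn * r_vnuc^2 + bc * r_vcell^2
  list(
    total = E_cell + E_nuc + pen,
    E_cell = E_cell, E_nuc = E_nuc,
    penalty = pen,
    A_nuc = A_nuc, V_nuc = V_nuc, A_cell = A_cell, V_cell = V_cell,
    residuals = c(V_nuc = abs(r_vnuc), A_nuc = abs(r_area), V_cell = abs(r_vcell))
  )
}

#' Total drop-model energy
#'
#' `E_cell + E_nuc + gamma (A_nuc/A_nuc0 - 1)^2 + beta_nuc (V_nuc/V_nuc0 - 1)^2
#'  + beta_cell (V_cell/V_cell0 - 1)^2`, where `E_cell` is the (normalized)
#' cell cortex area plus a small mesh-quality regularizer and `E_nuc` is the
#' nuclear mesh-quality (CVT) regularizer only — the lamina area is
#' constrained, not minimized. Stiffnesses are taken at `stiffness_index` of
#' the configured schedules.
#'
#' @param cell cell-cortex [tri_surface()], or `NULL` for nucleus-only.
#' @param nucleus nuclear [tri_surface()].
#' @param cfg a [drop_config()].
#' @param stiffness_index 1-based position in the stiffness schedules.
#' @return energy value (dimensionless; see Details in the vignette).
#' @export
total_energy <- function(cell, nucleus, cfg, stiffness_index) {
  scales <- energy_scales(cfg, cell, nucleus)
  drop_energy_terms(cell, nucleus, cfg, stiffness_index, scales)$total
}

# Gradient of the total energy with respect to free vertices; returns a list
# with matrices `cell` and `nucleus` (rows of fixed vertices zeroed).
drop_energy_gradient <- function(cell, nucleus, cfg, k, scales) {
  gam <- cfg$gamma_schedule[k]
  bn <- cfg$beta_nuc_schedule[k]
  bc <- cfg$beta_cell_schedule[k]
  A_nuc <- surface_area(nucleus)
  V_nuc <- enclosed_volume(nucleus)
  g_nuc <- cfg$cvt_weight * grad_cvt_energy(nucleus) / scales$cvt_nuc0 +
    (2 * gam * (A_nuc / cfg$A_nuc0 - 1) / cfg$A_nuc0) * grad_surface_area(nucleus) +
    (2 * bn * (V_nuc / cfg$V_nuc0 - 1) / cfg$V_nuc0) * grad_enclosed_volume(nucleus)
  g_nuc[nucleus$fixed, ] <- 0
  g_cell <- NULL
  if (!is.null(cell)) {
    V_cell <- enclosed_volume(cell)
    g_cell <- grad_surface_area(cell) / scales$A_ref +
      cfg$cvt_weight * grad_cvt_energy(cell) / scales$cvt_cell0 +
      (2 * bc * (V_cell / cfg$V_cell0 - 1) / cfg$V_cell0) * grad_enclosed_volume(cell)
    g_cell[cell$fixed, ] <- 0
  }
  list(cell = g_cell, nucleus = g_nuc)
}
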