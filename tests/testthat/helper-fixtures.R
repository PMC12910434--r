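# Shared fixtures, built in code at load time. Mesh sizes are kept small so
# the whole suite stays fast; convergence-order checks refine locally.

unit_cube_mesh <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),          # bottom (z = 0), outward -z
    c(5, 6, 7), c(5, 7, 8),          # top, outward +z
    c(1, 2, 6), c(1, 6, 5),          # y = 0
    c(2, 3, 7), c(2, 7, 6),          # x = 1
    c(3, 4, 8), c(3, 8, 7),          # y = 1
    c(4, 1, 5), c(4, 5, 8)           # x = 0
  )
  tri_surface(v, f)
}

jitter_radially <- function(s, frac, seed = 1) {
  set.seed(seed)
  r <- sqrt(rowSums(s$vertices^2))
  s$vertices <- s$vertices * (1 + frac * stats::runif(nrow(s$vertices), -1, 1))
  s
}

circle_contour <- function(r = 10, n = 256, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

lobed_contour <- function(R = 10, eps = 0.1, order = 5, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R * (1 + eps * cos(order * th))
  cbind(r * cos(th), r * sin(th))
}

# Dense-quadrature elliptical Fourier oracle: same parametric definition,
# evaluated by numerical integration of the continuous curve (independent of
# the summation path in the implementation).
efc_quadrature_oracle <- function(xy_fun, n_harmonics = 15, n_quad = 8192) {
  tt <- seq(0, 2 * pi, length.out = n_quad + 1)[-(n_quad + 1)]
  xy <- xy_fun(tt)
  semi <- matrix(0, n_harmonics, 2)
  for (h in seq_len(n_harmonics)) {
    a <- 2 * mean(xy[, 1] * cos(h * tt))
    b <- 2 * mean(xy[, 1] * sin(h * tt))
    cc <- 2 * mean(xy[, 2] * cos(h * tt))
    d <- 2 * mean(xy[, 2] * sin(h * tt))
    semi[h, ] <- svd(matrix(c(a, b, cc, d), 2, 2, byrow = TRUE))$d
  }
  colnames(semi) <- c("major", "minor")
  semi
}

# Axisymmetric fixed-(A, V) pancake oracle: a drop squeezed between
# non-adhesive plates has flat top/bottom contact discs and a free rim of
# constant mean curvature. With H = 1 fixed, the family is parameterized by
# the equatorial radius r_eq; the rim profile follows the Young-Laplace
# meridian ODE (dr/ds = cos phi, dz/ds = sin phi, dphi/ds = 2H - sin phi/r)
# from the equator (phi = pi/2) to plate tangency (phi = pi). Global scaling
# then matches the target volume. Independent 1D integration, no meshes.
pancake_shape_h1 <- function(r_eq, ds = 5e-4) {
  state <- c(r = r_eq, z = 0, phi = pi / 2)
  deriv <- function(s) c(cos(s[3]), sin(s[3]), 2 - sin(s[3]) / s[1])
  pts <- list(state)
  for (i in seq_len(20000L)) {
    k1 <- deriv(state)
    k2 <- deriv(state + ds / 2 * k1)
    k3 <- deriv(state + ds / 2 * k2)
    k4 <- deriv(state + ds * k3)
    nxt <- state + ds / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (nxt[3] >= pi) {
      # interpolate the fraction of the last step to phi = pi exactly
      fr <- (pi - state[3]) / (nxt[3] - state[3])
      nxt <- state + fr * (nxt - state)
      pts[[length(pts) + 1L]] <- nxt
      break
    }
    state <- nxt
    pts[[length(pts) + 1L]] <- state
  }
  p <- do.call(rbind, pts)
  dsr <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  rmid <- (p[-1, 1] + p[-nrow(p), 1]) / 2
  r_c <- p[nrow(p), 1]
  gap <- 2 * p[nrow(p), 2]
  A <- 2 * sum(2 * pi * rmid * dsr) + 2 * pi * r_c^2
  V <- 2 * abs(sum(pi * rmid^2 * diff(p[, 2])))
  list(gap = gap, A = A, V = V, r_c = r_c)
}

# Limiting pancake height for a drop of volume V and fixed lamina area A:
# squeezing increases area, so the limiting gap solves A(gap) = A_target
# along the scaled family.
pancake_height_for_area <- function(A_target, V_target) {
  excess_at <- function(r_eq) {
    sh <- pancake_shape_h1(r_eq)
    s <- (V_target / sh$V)^(1 / 3)
    s^2 * sh$A - A_target
  }
  r_eq <- stats::uniroot(excess_at, c(1.001, 60), tol = 1e-8)$root
  sh <- pancake_shape_h1(r_eq)
  s <- (V_target / sh$V)^(1 / 3)
  s * sh$gap
}
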