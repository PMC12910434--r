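#' Surface area of a sphere of given volume
#' @param V volume (um^3).
#' @return area (um^2).
#' @export
sphere_area_for_volume <- function(V) {
  (36 * pi)^(1 / 3) * V^(2 / 3)
}

#' Percent excess surface area over the equal-volume sphere
#'
#' The drop model's primary shape parameter: how much lamina area the
#' nucleus carries beyond the minimum (spherical) area for its volume,
#' `100 * (A / A_sphere(V) - 1)`. Negative values indicate sub-spherical
#' area, which is geometrically impossible for a real closed surface and is
#' flagged with a warning.
#'
#' @param A surface area (um^2).
#' @param V volume (um^3).
#' @return percent excess area.
#' @export
excess_area_percent <- function(A, V) {
  if (any(A <= 0) || any(V <= 0)) stop("A and V must be positive")
  pct <- 100 * (A / sphere_area_for_volume(V) - 1)
  if (any(pct < 0)) {
    warning("surface area below the equal-volume sphere: invalid as a lamina area")
  }
  pct
}

#' Wall shear stress in a shallow rectangular channel
#'
#' `tau = 6 Q eta / (w h^2)` for fully developed laminar flow, the standard
#' vessel-chip estimate; linear in flow rate and viscosity.
#'
#' @param Q_uL_min flow rate in uL/min.
#' @param eta_mPa_s dynamic viscosity in mPa*s (water ~0.7, culture medium
#'   ~0.8 at 37 C).
#' @param w_um channel width in um.
#' @param h_um channel height in um.
#' @return wall shear stress in dyne/cm^2.
#' @export
wall_shear_stress <- function(Q_uL_min, eta_mPa_s, w_um, h_um) {
  if (any(c(eta_mPa_s, w_um, h_um) <= 0) || any(Q_uL_min < 0)) {
    stop("viscosity and channel dimensions must be positive, Q nonnegative")
  }
  Q <- Q_uL_min * 1e-9 / 60      # m^3/s
  eta <- eta_mPa_s * 1e-3        # Pa*s
  w <- w_um * 1e-6               # m
  h <- h_um * 1e-6               # m
  tau_pa <- 6 * Q * eta / (w * h^2)
  tau_pa * 10                    # Pa -> dyne/cm^2
}

#' Drop-model configuration
#'
#' Target volumes and lamina area for the constrained shape solve, the
#' penalty stiffness schedules, and the convergence tolerance. The lamina
#' area may be given directly (`A_nuc0`) or as percent excess area over the
#' equal-volume sphere (`excess_area_pct`); both are stored, neither is
#' silently reconciled against the other.
#'
#' @param V_nuc0 target nuclear volume (um^3).
#' @param A_nuc0 target lamina (nuclear surface) area (um^2); mutually
#'   exclusive with `excess_area_pct`.
#' @param excess_area_pct percent excess area; `A_nuc0` is derived as
#'   `(1 + pct/100) * sphere_area_for_volume(V_nuc0)`.
#' @param V_cell0 target cell volume (um^3); `NA` for nucleus-only solves.
#' @param gamma_schedule strictly increasing area-penalty stiffnesses
#'   (dimensionless; energies are normalized by `A_nuc0`).
#' @param beta_nuc_schedule,beta_cell_schedule volume-penalty stiffness
#'   schedules, same length as `gamma_schedule`.
#' @param residual_tol convergence criterion on all of
#'   `|V_nuc/V_nuc0 - 1|`, `|A_nuc/A_nuc0 - 1|`, `|V_cell/V_cell0 - 1|`.
#' @param footprint optional closed polygon (k x 2 matrix, um) of the cell
#'   adhesion perimeter; informational (initial cell meshes carry the pinned
#'   vertices).
#' @param cvt_weight weight of the mesh-quality (CVT) regularizer relative
#'   to its initial-mesh scale.
#' @return a `drop_config` object.
#' @export
drop_config <- function(V_nuc0, A_nuc0 = NULL, excess_area_pct = NULL,
                        V_cell0 = NA_real_,
                        gamma_schedule = 10^(2:8),
                        beta_nuc_schedule = 10^(2:8),
                        beta_cell_schedule = 10^(2:8),
                        residual_tol = 1e-3,
                        footprint = NULL,
                        cvt_weight = 0.05) {
  if (V_nuc0 <= 0) stop("V_nuc0 must be positive")
  if (!is.na(V_cell0) && V_cell0 <= V_nuc0) stop("V_cell0 must exceed V_nuc0")
  if (is.null(A_nuc0) == is.null(excess_area_pct)) {
    stop("give exactly one of A_nuc0 or excess_area_pct")
  }
  if (is.null(A_nuc0)) {
    if (excess_area_pct < 0) stop("excess_area_pct must be >= 0")
    A_nuc0 <- (1 + excess_area_pct / 100) * sphere_area_for_volume(V_nuc0)
  } else {
    if (A_nuc0 < sphere_area_for_volume(V_nuc0) * (1 - 1e-9)) {
      stop("A_nuc0 is below the sphere area for V_nuc0: infeasible lamina")
    }
    excess_area_pct <- 100 * (A_nuc0 / sphere_area_for_volume(V_nuc0) - 1)
  }
  ns <- length(gamma_schedule)
  if (length(beta_nuc_schedule) != ns || length(beta_cell_schedule) != ns) {
    stop("stiffness schedules must have equal length")
  }
  chk <- function(x, nm) {
    if (any(x <= 0) || any(diff(x) <= 0)) {
      stop(nm, " must be a strictly increasing positive sequence")
    }
  }
  chk(gamma_schedule, "gamma_schedule")
  chk(beta_nuc_schedule, "beta_nuc_schedule")
  chk(beta_cell_schedule, "beta_cell_schedule")
  if (residual_tol <= 0) stop("residual_tol must be positive")
  structure(list(
    V_nuc0 = V_nuc0, A_nuc0 = A_nuc0, excess_area_pct = excess_area_pct,
    V_cell0 = V_cell0,
    gamma_schedule = gamma_schedule,
    beta_nuc_schedule = beta_nuc_schedule,
    beta_cell_schedule = beta_cell_schedule,
    residual_tol = residual_tol,
    footprint = footprint,
    cvt_weight = cvt_weight
  ), class = "drop_config")
}

#' @export
print.drop_config <- function(x, ...) {
  cat(sprintf(
    "drop_config: V_nuc0 = %.4g um^3, A_nuc0 = %.4g um^2 (%.3g%% excess), V_cell0 = %.4g um^3\n",
    x$V_nuc0, x$A_nuc0, x$excess_area_pct, x$V_cell0
  ))
  cat(sprintf("  %d penalty stages, residual_tol = %g\n",
              length(x$gamma_schedule), x$residual_tol))
  invisible(x)
}

#' Cylindrical micropost obstacle
#'
#' A rigid vertical cylinder (the PDMS micropost) standing on the substrate,
#' with an approach path of xy center positions used for quasi-static
#' stepping during indentation.
#'
#' @param center_xy final cylinder center, length-2 (um).
#' @param radius cylinder radius (um); the paper's lateral indentation uses
#'   a 1-um-diameter post (radius 0.5).
#' @param height cylinder height above the substrate (um); microposts are
#'   ~5 um tall.
#' @param approach_path optional k x 2 matrix of xy positions ending at
#'   `center_xy`; if omitted, built by [indent_with_post()] from a start
#'   point with steps bounded by the nuclear mesh edge length.
#' @return an `obstacle` object.
#' @export
obstacle <- function(center_xy, radius, height = 5, approach_path = NULL) {
  if (radius <= 0) stop("obstacle radius must be positive")
  if (height <= 0) stop("obstacle height must be positive")
  structure(list(
    center_xy = as.numeric(center_xy), radius = radius, height = height,
    approach_path = approach_path
  ), class = "obstacle")
}
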