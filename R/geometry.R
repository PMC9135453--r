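#' Build a filament table of rigid spherocylinders
#'
#' Filaments are rigid spherocylinders: a centerline segment of length
#' `length` (um) swept by a sphere of diameter `diameter`, so the tip-to-tip
#' extent is `length + diameter`. Orientation is stored as a unit quaternion
#' `(qw, qx, qy, qz)`; the director (unit vector from the minus end at arc
#' coordinate `-length/2` to the plus end at `+length/2`) is the rotation of
#' the reference axis (0, 0, 1).
#'
#' @param center Matrix or data frame of centers (um), one row per filament.
#' @param director Matrix or data frame of direction vectors (normalized
#'   internally), or `NULL` together with `quaternion`.
#' @param quaternion Optional 4-column matrix `(qw, qx, qy, qz)`; overrides
#'   `director`.
#' @param length,diameter Filament dimensions (um), recycled.
#' @param mobile Logical, recycled; immobile filaments have a zero mobility
#'   block and act as static obstacles/substrates.
#' @return A filament tibble with columns `id`, `x`, `y`, `z`, `qw`, `qx`,
#'   `qy`, `qz`, `length`, `diameter`, `mobile` and periodic image counters
#'   `ix`, `iy`, `iz`.
#' @export
#' @examples
#' spherocylinders(center = rbind(c(0, 0, 0)), director = rbind(c(1, 0, 0)),
#'                 length = 1, diameter = 0.025)
spherocylinders <- function(center, director = NULL, quaternion = NULL,
                            length = 1, diameter = 0.025, mobile = TRUE) {
  center <- .as_xyz(center)
  n <- nrow(center)
  if (is.null(quaternion)) {
    if (is.null(director)) abort("provide `director` or `quaternion`")
    director <- .as_xyz(director)
    quaternion <- t(apply(director, 1, quat_from_director))
  }
  stopifnot(ncol(quaternion) == 4)
  length <- rep_len(length, n)
  diameter <- rep_len(diameter, n)
  if (any(length <= 0) || any(diameter <= 0)) {
    abort("filament length and diameter must be positive")
  }
  nq <- sqrt(rowSums(quaternion^2))
  quaternion <- quaternion / nq
  tibble::tibble(
    id = seq_len(n),
    x = center[, 1], y = center[, 2], z = center[, 3],
    qw = quaternion[, 1], qx = quaternion[, 2],
    qy = quaternion[, 3], qz = quaternion[, 4],
    length = length, diameter = diameter,
    mobile = rep_len(mobile, n),
    ix = 0L, iy = 0L, iz = 0L
  )
}

#' Quaternion representing the rotation from (0,0,1) to a direction
#'
#' Deterministic minimal rotation; the antipodal direction (0,0,-1) maps to a
#' 180-degree rotation about the x-axis.
#'
#' @param p Direction 3-vector (normalized internally).
#' @return Numeric length-4 `(qw, qx, qy, qz)`.
#' @export
quat_from_director <- function(p) {
  p <- p / sqrt(sum(p^2))
  ez <- c(0, 0, 1)
  c_ <- sum(ez * p)
  if (c_ > 1 - 1e-14) return(c(1, 0, 0, 0))
  if (c_ < -1 + 1e-14) return(c(0, 1, 0, 0))
  axis <- c(ez[2] * p[3] - ez[3] * p[2],
            ez[3] * p[1] - ez[1] * p[3],
            ez[1] * p[2] - ez[2] * p[1])
  axis <- axis / sqrt(sum(axis^2))
  half <- acos(c_) / 2
  c(cos(half), sin(half) * axis)
}

#' Filament directors
#'
#' @param filaments Filament tibble.
#' @return Tibble with columns `id`, `px`, `py`, `pz` (unit directors,
#'   minus end to plus end).
#' @export
director <- function(filaments) {
  q <- cbind(filaments$qw, filaments$qx, filaments$qy, filaments$qz)
  p <- cpp_directors(q)
  tibble::tibble(id = filaments$id, px = p[, 1], py = p[, 2], pz = p[, 3])
}

#' Endpoint coordinates of filaments
#'
#' @inheritParams director
#' @param end `"minus"` (arc coordinate -L/2) or `"plus"` (+L/2).
#' @return Tibble `id`, `x`, `y`, `z`.
#' @export
filament_ends <- function(filaments, end = c("minus", "plus")) {
  end <- match.arg(end)
  s <- if (end == "minus") -0.5 else 0.5
  p <- director(filaments)
  tibble::tibble(
    id = filaments$id,
    x = filaments$x + s * filaments$length * p$px,
    y = filaments$y + s * filaments$length * p$py,
    z = filaments$z + s * filaments$length * p$pz
  )
}

#' Minimal distance between two spherocylinders
#'
#' Computes the surface-to-surface signed separation: the centerline
#' segment-segment distance minus the sum of the radii. Negative values mean
#' overlap. Exactly parallel centerlines are resolved deterministically at
#' the midpoint of the projected overlap interval. With a periodic boundary
#' the minimum-image displacement of the centers is applied first.
#'
#' @param f1,f2 Single-row filament tibbles (or rows of one).
#' @param boundary Boundary for minimum-image resolution
#'   (default [boundary_free()]).
#' @return A list with `sep` (um), arc coordinates `s1`, `s2` of the closest
#'   centerline points, and `n`, the unit normal pointing from `f2`'s closest
#'   point toward `f1`'s.
#' @export
min_distance <- function(f1, f2, boundary = boundary_free()) {
  v <- function(f) c(f$x, f$y, f$z, f$qw, f$qx, f$qy, f$qz,
                     f$length, f$diameter)
  cpp_min_distance(v(f1), v(f2), .boundary_code(boundary))
}

#' Slender-body drag coefficients
#'
#' Translational drags along (`zeta_par`) and perpendicular
#' (`zeta_perp = 2 zeta_par`) to the filament axis, and the rotational drag
#' about the center (`zeta_rot`), from slender-body theory:
#' `zeta_par = 2 pi eta L / log(2 L / D)`,
#' `zeta_rot = pi eta L^3 / (3 log(2 L / D))`. The combined drag relevant to
#' the crosslink-spring relaxation rate of parallel filaments is
#' `zeta_perp = 4 pi eta L / log(2 L / D)`.
#'
#' @inheritParams director
#' @param eta Solvent viscosity (pN s / um^2).
#' @return Tibble `id`, `zeta_par`, `zeta_perp`, `zeta_rot`.
#' @export
mobility_coefficients <- function(filaments, eta) {
  stopifnot(eta > 0)
  lg <- log(2 * filaments$length / filaments$diameter)
  zpar <- 2 * pi * eta * filaments$length / lg
  tibble::tibble(id = filaments$id, zeta_par = zpar, zeta_perp = 2 * zpar,
                 zeta_rot = pi * eta * filaments$length^3 / (3 * lg))
}

#' Apply the mobility map U = M F
#'
#' Maps a stack of forces and torques to translational and angular
#' velocities using the anisotropic slender-body drag of each filament.
#' The mobility is block-diagonal; the axial spin of a spherocylinder is a
#' null mode and is projected out of the angular velocity. Immobile
#' filaments have a zero block.
#'
#' @inheritParams director
#' @param eta Solvent viscosity (pN s / um^2).
#' @param wrench Matrix (n x 6) or tibble with columns `fx, fy, fz, tx, ty,
#'   tz` (pN, pN um).
#' @return Tibble `id`, `vx, vy, vz` (um/s), `wx, wy, wz` (rad/s).
#' @export
mobility_apply <- function(filaments, eta, wrench) {
  if (is.data.frame(wrench)) {
    wrench <- cbind(wrench$fx, wrench$fy, wrench$fz,
                    wrench$tx, wrench$ty, wrench$tz)
  }
  stopifnot(all(is.finite(wrench)))
  U <- cpp_mobility_apply(.fil_matrix(filaments), eta, wrench)
  tibble::tibble(id = filaments$id, vx = U[, 1], vy = U[, 2], vz = U[, 3],
                 wx = U[, 4], wy = U[, 5], wz = U[, 6])
}

#' Advance filament configuration by one kinematic update
#'
#' Translates centers by `h * v` and rotates quaternions by the exponential
#' map of `h * omega`, then renormalizes and applies periodic wrapping
#' (image counters are updated). Lengths and diameters are preserved
#' exactly.
#'
#' @inheritParams director
#' @param velocity Matrix (n x 6) or tibble `vx..wz` as returned by
#'   [mobility_apply()].
#' @param h Timestep (s).
#' @param eta Viscosity used to refresh cached drag coefficients.
#' @param boundary Boundary for wrapping.
#' @return The updated filament tibble.
#' @export
advance_configuration <- function(filaments, velocity, h,
                                  boundary = boundary_free(), eta = 0.01) {
  if (h <= 0) abort("h must be positive")
  if (is.data.frame(velocity)) {
    velocity <- cbind(velocity$vx, velocity$vy, velocity$vz,
                      velocity$wx, velocity$wy, velocity$wz)
  }
  out <- cpp_advance_configuration(.fil_matrix(filaments),
                                   .img_matrix(filaments), velocity, h, eta,
                                   .boundary_code(boundary))
  .fils_from_matrix(out$fil, out$img, filaments)
}
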