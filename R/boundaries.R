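#' Domain boundary specifications
#'
#' A boundary specification determines periodic wrapping, minimum-image
#' displacements, and which static walls generate one-sided collision
#' constraints. Impermeable walls (cylinder surface, sphere, shell) confine
#' both filaments -- through complementarity constraints against the wall --
#' and unbound motors, which are reflected.
#'
#' * `boundary_free()`: unbounded space, no wrapping.
#' * `boundary_periodic_box(lx, ly, lz)`: fully periodic box centred on the
#'   origin (coordinates live in `[-l/2, l/2)` per axis).
#' * `boundary_cylinder_x(diameter, period)`: impermeable cylinder of the
#'   given diameter whose axis is the x-axis, periodic along x.
#' * `boundary_sphere(radius)`: impermeable sphere centred on the origin.
#' * `boundary_spherical_shell(r_in, r_out)`: the space between two
#'   concentric impermeable spheres (`r_out > r_in`).
#'
#' @param lx,ly,lz Box edge lengths (um).
#' @param diameter Cylinder diameter (um).
#' @param period Cylinder repeat length along x (um).
#' @param radius Sphere radius (um).
#' @param r_in,r_out Inner and outer shell radii (um).
#' @return An object of class `fm_boundary`.
#' @name boundaries
NULL

new_boundary <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "fm_boundary")
}

#' @rdname boundaries
#' @export
boundary_free <- function() new_boundary("free")

#' @rdname boundaries
#' @export
boundary_periodic_box <- function(lx, ly = lx, lz = lx) {
  stopifnot(lx > 0, ly > 0, lz > 0)
  new_boundary("periodic_box", lx = lx, ly = ly, lz = lz)
}

#' @rdname boundaries
#' @export
boundary_cylinder_x <- function(diameter, period) {
  stopifnot(diameter > 0, period > 0)
  new_boundary("cylinder_x", radius = diameter / 2, period = period)
}

#' @rdname boundaries
#' @export
boundary_sphere <- function(radius) {
  stopifnot(radius > 0)
  new_boundary("sphere", radius = radius)
}

#' @rdname boundaries
#' @export
boundary_spherical_shell <- function(r_in, r_out) {
  if (!(r_out > r_in && r_in > 0)) {
    abort("spherical shell requires r_out > r_in > 0")
  }
  new_boundary("spherical_shell", r_in = r_in, r_out = r_out)
}

#' @export
print.fm_boundary <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<boundary:", x$kind,
      if (length(pars)) paste0("| ", paste(names(pars), unlist(pars),
                                           sep = " = ", collapse = ", ")),
      ">\n")
  invisible(x)
}

# numeric encoding consumed by the C++ engine
.boundary_code <- function(b) {
  switch(b$kind,
    free = c(0),
    periodic_box = c(1, b$lx, b$ly, b$lz),
    cylinder_x = c(2, b$period, b$radius),
    sphere = c(3, b$radius),
    spherical_shell = c(4, b$r_in, b$r_out),
    abort(paste0("unsupported boundary kind: ", b$kind))
  )
}

#' Wrap points into the primary cell
#'
#' Applies periodic wrapping for the boundary's periodic axes; coordinates on
#' non-periodic axes are returned unchanged.
#'
#' @param points A data frame with columns `x`, `y`, `z`, or a 3-column
#'   matrix.
#' @param boundary An [fm_boundary][boundaries] object.
#' @return A tibble with wrapped `x`, `y`, `z`.
#' @export
wrap_points <- function(points, boundary) {
  m <- .as_xyz(points)
  w <- cpp_wrap_points(m, .boundary_code(boundary))
  tibble::tibble(x = w[, 1], y = w[, 2], z = w[, 3])
}

#' Minimum-image displacement vectors
#'
#' @param d Displacement vectors (data frame with `x`, `y`, `z` or 3-column
#'   matrix).
#' @inheritParams wrap_points
#' @return A tibble of minimum-image displacements.
#' @export
minimum_image <- function(d, boundary) {
  m <- .as_xyz(d)
  w <- cpp_min_image(m, .boundary_code(boundary))
  tibble::tibble(x = w[, 1], y = w[, 2], z = w[, 3])
}

.as_xyz <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    return(p)
  }
  cbind(p$x, p$y, p$z)
}

#' Signed gaps between a filament and the domain walls
#'
#' For impermeable boundaries, returns the signed separation of the filament
#' surface from each wall it can touch (both endcap spheres for convex
#' containment walls, the closest centerline point for the inner shell
#' sphere). Negative separations indicate wall penetration. Periodic and free
#' boundaries have no walls and give zero rows.
#'
#' @param filaments A filament tibble (see [spherocylinders()]); one row per
#'   filament.
#' @inheritParams wrap_points
#' @return A tibble with columns `id`, `sep` (um), contact point `cx, cy, cz`
#'   and inward unit normal `nx, ny, nz`.
#' @export
wall_gap <- function(filaments, boundary) {
  code <- .boundary_code(boundary)
  res <- lapply(seq_len(nrow(filaments)), function(i) {
    f <- filaments[i, ]
    g <- cpp_wall_gaps(c(f$x, f$y, f$z, f$qw, f$qx, f$qy, f$qz,
                         f$length, f$diameter), code)
    if (nrow(g) == 0) return(NULL)
    tibble::tibble(id = f$id, sep = g[, 1], cx = g[, 2], cy = g[, 3],
                   cz = g[, 4], nx = g[, 5], ny = g[, 6], nz = g[, 7])
  })
  dplyr::bind_rows(res)
}
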