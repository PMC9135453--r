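# Scenario generators: deterministic, seedable builders of the study's
# initial conditions. All are pure functions of their arguments plus `seed`
# (R's RNG state is saved and restored).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Volume of a spherocylinder
#'
#' Cylinder of centerline length `length` plus two hemispherical caps.
#'
#' @param length Centerline length (um).
#' @param diameter Diameter (um).
#' @export
spherocylinder_volume <- function(length, diameter) {
  r <- diameter / 2
  pi * r^2 * length + 4 / 3 * pi * r^3
}

#' Motor parameter presets
#'
#' Editable parameter sets for the motor species used by the scenario
#' generators. Only a few of these numbers are pinned by direct
#' measurements (unloaded speeds: 1.0 um/s for the gliding Kinesin-1 motors
#' and 46 nm/s for the NCD-like tube motors); the remaining kinetic
#' constants are literature-typical reconstructions for kinesin-family
#' motors and are documented as such in the methods vignette. Adjust freely
#' via [motor_species()].
#'
#' * `kinesin1_params()`: surface-anchored gliding-assay motor. Head A is
#'   permanently anchored (to the substrate rod) and inert; head B walks to
#'   the plus end and detaches there. `active` toggles the walking head
#'   (inactive = rigor crosslinker).
#' * `ncd_params()`: kinesin-14-like antiparallel-sliding motor: one
#'   minus-end-directed walking motor domain (46 nm/s) and one passive
#'   tail domain that grips the partner filament (rigor crosslink), as in
#'   NCD/XCTK2; detaches at the end.
#' * `aster_motor_params()`: minus-end-directed end-pausing motor (pauses at
#'   the minus end until unbinding) with rest length 53 nm; drives aster
#'   formation.
#' * `dynein_params()`: one head permanently attached to its carrier
#'   filament, the other walks to the minus end at 1 um/s and detaches
#'   there (bundling scenario).
#'
#' @param active Is the walking head motile?
#' @param vm Override the walking speed (um/s).
#' @return A one-row species tibble.
#' @name motor_presets
NULL

#' @rdname motor_presets
#' @export
kinesin1_params <- function(active = TRUE, vm = 1.0) {
  motor_species(
    name = if (active) "kinesin1" else "kinesin1_inactive",
    kappa = 100, ell0 = 0.05, vm = if (active) vm else 0, fstall = 5,
    ko_s = 1, ko_d = 1, ka = 5e-4, ke = 25, lambda = 0.5, rc = 0.1,
    eps = 400, d_motor = 0,
    direction = c("plus", "plus"),
    active = c(FALSE, active),
    end_behavior = c("pause", "detach"),
    permanent = c(TRUE, FALSE),
    bind_mobile_only = TRUE
  )
}

#' @rdname motor_presets
#' @export
ncd_params <- function(vm = 0.046) {
  motor_species(
    name = "ncd", kappa = 100, ell0 = 0.053, vm = vm, fstall = 1,
    ko_s = 1, ko_d = 0.5, ka = 5e-4, ke = 5, lambda = 0.5, rc = 0.1,
    eps = 400, d_motor = 1, direction = "minus",
    active = c(TRUE, FALSE),  # motor domain + passive tail (kinesin-14)
    end_behavior = "detach"
  )
}

#' @rdname motor_presets
#' @export
aster_motor_params <- function(vm = 0.1) {
  motor_species(
    name = "aster_kinesin", kappa = 100, ell0 = 0.053, vm = vm, fstall = 1,
    ko_s = 1, ko_d = 0.5, ka = 5e-4, ke = 5, lambda = 0.5, rc = 0.1,
    eps = 400, d_motor = 1, direction = "minus", active = TRUE,
    end_behavior = "pause"
  )
}

#' @rdname motor_presets
#' @export
dynein_params <- function(vm = 1.0) {
  motor_species(
    name = "dynein", kappa = 100, ell0 = 0.05, vm = vm, fstall = 5,
    ko_s = 1, ko_d = 1, ka = 5e-4, ke = 5, lambda = 0.5, rc = 0.1,
    eps = 400, d_motor = 0, direction = c("minus", "minus"),
    active = c(FALSE, TRUE), end_behavior = c("pause", "detach"),
    permanent = c(TRUE, FALSE)
  )
}

#' Surface gliding assay
#'
#' One microtubule above a plane of surface-anchored motors. The surface is
#' modeled as an immobile substrate rod spanning the (x-)periodic box, so
#' anchored heads reuse the standard attachment bookkeeping; `n` motors are
#' anchored at uniform random positions along it with their free heads
#' facing the filament, and `n_active` of them are motile (the rest are
#' rigor crosslinkers with `vm = 0`). The microtubule starts one tether
#' rest length above the substrate surface with its plus end along +x.
#' The default period gives a dense lawn (~65 motors/um); sparse lawns can
#' lose the filament, since in the athermal assay only bound tethers hold
#' it within binding reach.
#'
#' @param n Total motor count.
#' @param n_active Number of active motors (`0 <= n_active <= n`).
#' @param fil_length Microtubule length (um).
#' @param diameter Filament and substrate-rod diameter (um).
#' @param period Periodic box length along x (um).
#' @param vm Active-motor walking speed (um/s).
#' @param seed RNG seed.
#' @param n_rails,rail_spacing The lawn is a set of parallel immobile
#'   rails at z = 0 spaced `rail_spacing` (um) apart in y; the box is
#'   periodic in y with period `n_rails * rail_spacing`, so the rails tile
#'   into an unbounded lawn the filament cannot slide off. The default
#'   spacing keeps neighboring rails just outside binding reach of a
#'   centered filament: anchors then hold it at the tether rest length
#'   (near-zero tether energy, calm unbinding kinetics), while a filament
#'   wandering sideways is caught by the next rail.
#' @return A [system_state()]; the last filament is the transported
#'   microtubule, the others are substrate rails.
#' @export
scenario_gliding_assay <- function(n = 100, n_active = n, fil_length = 1,
                                   diameter = 0.025, period = 1.5,
                                   n_rails = 3, rail_spacing = 0.15,
                                   vm = 1.0, seed = 1) {
  stopifnot(n_active >= 0, n_active <= n)
  .with_seed(seed, {
    species <- dplyr::bind_rows(kinesin1_params(active = TRUE, vm = vm),
                                kinesin1_params(active = FALSE))
    ell0 <- species$ell0[1]
    ys <- (seq_len(n_rails) - (n_rails + 1) / 2) * rail_spacing
    y_period <- n_rails * rail_spacing
    fil <- spherocylinders(
      center = rbind(cbind(0, ys, 0), c(0, 0, diameter + ell0)),
      director = matrix(rep(c(1, 0, 0), n_rails + 1), ncol = 3,
                        byrow = TRUE),
      length = c(rep(period, n_rails), fil_length), diameter = diameter,
      mobile = c(rep(FALSE, n_rails), TRUE))
    s_anchor <- runif(n, -period / 2, period / 2)
    rail <- sample.int(n_rails, n, replace = TRUE)
    which_active <- sample(n) <= n_active
    motors <- crosslinkers(n = n,
                           species = ifelse(which_active, 1L, 2L),
                           state = "SA", fil_a = rail, s_a = s_anchor)
    motors$s_a <- s_anchor
    system_state(fil, motors, species,
                 boundary = boundary_periodic_box(period, y_period, 2),
                 eta = 0.001, seed = seed)
  })
}

#' Antiparallel nematic tube
#'
#' Densely packed filaments aligned along +/-x (exact polarity balance)
#' inside an x-periodic cylinder, crosslinked by minus-end-directed sliding
#' motors (initially unbound, uniform). The tube length is set by the
#' requested volume fraction; initial overlaps are resolved by a short
#' athermal relaxation with collisions only.
#'
#' @param n_fil Filament count.
#' @param fil_length,diameter Filament dimensions (um).
#' @param vol_frac Target filament volume fraction in the tube.
#' @param tube_diameter Tube diameter (um).
#' @param motors_per_fil Motors per filament.
#' @param vm Motor walking speed (um/s).
#' @param relax Athermal relaxation time (s) before motors are considered.
#' @param seed RNG seed.
#' @return A [system_state()].
#' @export
scenario_nematic_tube <- function(n_fil = 300, fil_length = 0.5,
                                  diameter = 0.025, vol_frac = 0.3,
                                  tube_diameter = 0.5, motors_per_fil = 20,
                                  vm = 0.046, relax = 0.3, seed = 1) {
  .with_seed(seed, {
    R <- tube_diameter / 2
    vf <- spherocylinder_volume(fil_length, diameter)
    period <- n_fil * vf / (vol_frac * pi * R^2)
    if (period < fil_length) abort("packing infeasible: tube too short")
    # centers uniform in the cross-section disc (clear of the wall) and x
    rmax <- R - diameter / 2
    rr <- rmax * sqrt(runif(n_fil))
    th <- runif(n_fil, 0, 2 * pi)
    centers <- cbind(runif(n_fil, -period / 2, period / 2),
                     rr * cos(th), rr * sin(th))
    sign_x <- rep(c(1, -1), length.out = n_fil)[sample(n_fil)]
    dirs <- cbind(sign_x, 0, 0)
    fil <- spherocylinders(centers, dirs, length = fil_length,
                           diameter = diameter)
    species <- ncd_params(vm = vm)
    n_mot <- n_fil * motors_per_fil
    rrm <- R * sqrt(runif(n_mot))
    thm <- runif(n_mot, 0, 2 * pi)
    motors <- crosslinkers(
      x = cbind(runif(n_mot, -period / 2, period / 2),
                rrm * cos(thm), rrm * sin(thm)),
      species = 1L, state = "U")
    st <- system_state(fil, motors, species,
                       boundary = boundary_cylinder_x(tube_diameter, period),
                       eta = 0.01, seed = seed)
    .relax_overlaps(st, relax)
  })
}

# athermal, motor-free relaxation pass used by the dense generators
.relax_overlaps <- function(state, relax, h = 1e-4) {
  if (relax <= 0) return(state)
  motors <- state$motors
  state$motors <- crosslinkers(0)
  cfg <- step_config(h = h, brownian = FALSE)
  state <- timestep(state, cfg, n = as.integer(round(relax / h)))
  state$motors <- motors
  state$time <- 0
  state$step <- 0
  state
}

#' Bulk isotropic suspension
#'
#' Uniform filament centers with isotropic orientations in a fully periodic
#' box; motors start unbound and uniform. The default motor preset is the
#' end-pausing minus-end-directed species that drives aster formation.
#'
#' @param n_fil,n_motor Object counts.
#' @param fil_length,diameter Filament dimensions (um).
#' @param box Periodic box edge (um).
#' @param species Motor species tibble.
#' @param seed RNG seed.
#' @return A [system_state()].
#' @export
scenario_bulk_isotropic <- function(n_fil = 500, n_motor = 1000,
                                    fil_length = 0.5, diameter = 0.025,
                                    box = 3, species = aster_motor_params(),
                                    seed = 1) {
  .with_seed(seed, {
    centers <- matrix(runif(3 * n_fil, -box / 2, box / 2), n_fil, 3)
    dirs <- .isotropic_directions(n_fil)
    fil <- spherocylinders(centers, dirs, length = fil_length,
                           diameter = diameter)
    motors <- crosslinkers(
      x = matrix(runif(3 * n_motor, -box / 2, box / 2), n_motor, 3),
      species = 1L, state = "U")
    system_state(fil, motors, species,
                 boundary = boundary_periodic_box(box), eta = 0.01,
                 seed = seed)
  })
}

.isotropic_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Filaments confined between concentric spherical shells
#'
#' Centers at mid-gap radius, uniform over the sphere, with directors along
#' +/- the local meridian tangent (tangential alignment); a relaxation pass
#' resolves initial overlaps. Motors start unbound, uniform in the gap.
#'
#' @param n_fil,n_motor Object counts.
#' @param fil_length,diameter Filament dimensions (um).
#' @param r_in,r_out Shell radii (um).
#' @param species Motor species tibble.
#' @param relax Athermal relaxation time (s).
#' @param seed RNG seed.
#' @return A [system_state()].
#' @export
scenario_spherical_shell <- function(n_fil = 400, n_motor = 800,
                                     fil_length = 0.25, diameter = 0.025,
                                     r_in = 1.5, r_out = 1.602,
                                     species = ncd_params(vm = 1),
                                     relax = 0.2, seed = 1) {
  stopifnot(r_out - r_in > diameter)
  .with_seed(seed, {
    rmid <- (r_in + r_out) / 2
    u <- .isotropic_directions(n_fil)   # radial unit vectors
    centers <- rmid * u
    # meridian tangent e_theta at each point, random sign
    eth <- .meridian_tangent(u)
    sgn <- sample(c(-1, 1), n_fil, replace = TRUE)
    fil <- spherocylinders(centers, eth * sgn, length = fil_length,
                           diameter = diameter)
    um <- .isotropic_directions(n_motor)
    rm_ <- runif(n_motor, r_in, r_out)
    motors <- crosslinkers(x = um * rm_, species = 1L, state = "U")
    st <- system_state(fil, motors, species,
                       boundary = boundary_spherical_shell(r_in, r_out),
                       eta = 0.01, seed = seed)
    .relax_overlaps(st, relax)
  })
}

.meridian_tangent <- function(u) {
  # e_theta = d r_hat / d theta for polar axis z
  rho <- sqrt(u[, 1]^2 + u[, 2]^2)
  eth <- cbind(ifelse(rho > 1e-9, u[, 3] * u[, 1] / rho, 1),
               ifelse(rho > 1e-9, u[, 3] * u[, 2] / rho, 0),
               -rho)
  eth / sqrt(rowSums(eth^2))
}

#' Axially aligned filaments in a confining cylinder
#'
#' Uniformly distributed filaments aligned along +/-x with an exact
#' polarity split, confined in an x-periodic cylinder whose period is set
#' by the requested packing fraction; motors start unbound.
#'
#' @param n_fil,n_motor Object counts.
#' @param fil_length,diameter Filament dimensions (um).
#' @param cyl_diameter Cylinder diameter (um).
#' @param packing Filament packing fraction.
#' @param species Motor species tibble.
#' @param relax Athermal relaxation time (s).
#' @param seed RNG seed.
#' @return A [system_state()].
#' @export
scenario_confined_cylinder <- function(n_fil = 300, n_motor = 900,
                                       fil_length = 0.25, diameter = 0.025,
                                       cyl_diameter = 0.25, packing = 0.16,
                                       species = aster_motor_params(),
                                       relax = 0.2, seed = 1) {
  stopifnot(cyl_diameter > diameter)
  .with_seed(seed, {
    R <- cyl_diameter / 2
    vf <- spherocylinder_volume(fil_length, diameter)
    period <- n_fil * vf / (packing * pi * R^2)
    rmax <- R - diameter / 2
    rr <- rmax * sqrt(runif(n_fil))
    th <- runif(n_fil, 0, 2 * pi)
    centers <- cbind(runif(n_fil, -period / 2, period / 2),
                     rr * cos(th), rr * sin(th))
    sign_x <- rep(c(1, -1), length.out = n_fil)[sample(n_fil)]
    fil <- spherocylinders(centers, cbind(sign_x, 0, 0),
                           length = fil_length, diameter = diameter)
    rrm <- R * sqrt(runif(n_motor))
    thm <- runif(n_motor, 0, 2 * pi)
    motors <- crosslinkers(
      x = cbind(runif(n_motor, -period / 2, period / 2),
                rrm * cos(thm), rrm * sin(thm)),
      species = 1L, state = "U")
    st <- system_state(fil, motors, species,
                       boundary = boundary_cylinder_x(cyl_diameter, period),
                       eta = 0.01, seed = seed)
    .relax_overlaps(st, relax)
  })
}
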