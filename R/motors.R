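#' Define a crosslinking-motor species
#'
#' A motor is a Hookean tether of stiffness `kappa` and rest length `ell0`
#' connecting two binding heads A and B. Each head is either unbound or
#' attached to a filament at an arc coordinate; the four motor states are
#' U (both unbound), SA / SB (one head bound) and D (doubly bound, which
#' creates a bilateral spring constraint between the two filaments).
#'
#' Tether length convention: the tether spans the gap between filament
#' surfaces, `ell_f = |r_A - r_B| - (D_A + D_B)/2` (clamped at zero), where
#' `r_A`, `r_B` are the centerline attachment points. The tether energy is
#' `E = kappa (ell_f - ell0)^2 / 2`.
#'
#' Binding kinetics (rates in 1/s; `beta = 1/kbt`):
#' * U -> S: `ko_s * (3 eps ka / (4 pi rc^3)) * sum_i L_in,i(x)` with
#'   `L_in,i` the centerline arclength of filament i inside the capture
#'   sphere of radius `rc` around the motor.
#' * S -> U: `ko_s` (independent of tether deformation).
#' * S -> D: `ko_d * eps * ke * sum_j int ds exp[-(1 - lambda) beta E]`.
#' * D -> S: `ko_d * exp[lambda beta E]`. Note the Boltzmann exponent here
#'   carries `beta` so that the S<->D equilibrium constant recovers
#'   `exp(-beta E)` for every `lambda`; a rate written without `beta` would
#'   not be dimensionally consistent with the energy.
#'
#' Active heads walk along their filament toward the end given by
#' `direction` at the load-dependent speed
#' `v_F = vm * max(0, min(1, 1 + F_proj / fstall))`, where `F_proj` is the
#' tether-force projection on the stepping direction (positive =
#' assisting).
#'
#' @param name Species label.
#' @param kappa Tether stiffness (pN/um).
#' @param ell0 Tether rest length (um).
#' @param vm Unloaded stepping speed per head (um/s).
#' @param fstall Stall force (pN).
#' @param ko_s Singly-bound off rate (1/s); also scales the U->S on rate.
#' @param ko_d Doubly-bound force-independent off rate (1/s).
#' @param ka U<->S association constant (um^3).
#' @param ke S<->D association constant (dimensionless).
#' @param lambda Energy-partition factor in `[0, 1]` splitting the tether
#'   energy between the S->D and D->S rates.
#' @param rc Capture radius for U->S binding (um).
#' @param eps Linear density of binding sites along a filament (1/um).
#' @param d_motor Diffusivity of the unbound motor (um^2/s).
#' @param direction Stepping direction per head: `"plus"` or `"minus"`,
#'   length 1 or 2 (head A, head B).
#' @param active Logical per head: does the head step when bound?
#' @param end_behavior `"pause"` (clamp at the filament end) or `"detach"`,
#'   length 1 or 2.
#' @param permanent Logical per head: permanently bound heads never unbind
#'   (used e.g. for surface-anchored motors).
#' @param allow_same_fil May both heads bind the same filament?
#' @param bind_mobile_only Free heads bind only mobile filaments (used for
#'   surface-anchored motors whose free head must not grip the substrate).
#' @return A one-row species tibble.
#' @export
motor_species <- function(name = "motor", kappa = 100, ell0 = 0.05, vm = 1,
                          fstall = 5, ko_s = 1, ko_d = 1, ka = 5e-4, ke = 5,
                          lambda = 0.5, rc = 0.1, eps = 400, d_motor = 1,
                          direction = "minus", active = TRUE,
                          end_behavior = "detach", permanent = FALSE,
                          allow_same_fil = FALSE,
                          bind_mobile_only = FALSE) {
  direction <- rep_len(direction, 2)
  active <- rep_len(active, 2)
  end_behavior <- rep_len(end_behavior, 2)
  permanent <- rep_len(permanent, 2)
  stopifnot(all(direction %in% c("plus", "minus")),
            all(end_behavior %in% c("pause", "detach")),
            kappa >= 0, ell0 >= 0, ko_s >= 0, ko_d >= 0, ka >= 0, ke >= 0,
            rc > 0, eps >= 0, lambda >= 0, lambda <= 1, vm >= 0)
  if (any(active) && vm > 0 && fstall <= 0) {
    abort("active motors require a positive stall force")
  }
  tibble::tibble(
    name = name, kappa = kappa, ell0 = ell0, vm = vm, fstall = fstall,
    ko_s = ko_s, ko_d = ko_d, ka = ka, ke = ke, lambda = lambda, rc = rc,
    eps = eps, d_motor = d_motor,
    dir_a = ifelse(direction[1] == "plus", 1L, -1L),
    dir_b = ifelse(direction[2] == "plus", 1L, -1L),
    active_a = active[1], active_b = active[2],
    end_pause_a = end_behavior[1] == "pause",
    end_pause_b = end_behavior[2] == "pause",
    permanent_a = permanent[1], permanent_b = permanent[2],
    allow_same_fil = allow_same_fil, bind_mobile_only = bind_mobile_only
  )
}

#' Build a crosslinker population table
#'
#' @param n Number of crosslinkers (ignored if `x` is given).
#' @param species Species index (row of the state's species table),
#'   recycled.
#' @param x Positions of unbound motors: data frame/matrix with `x, y, z`,
#'   or `NULL` for all-at-origin.
#' @param state Initial state, recycled: `"U"`, `"SA"`, `"SB"` or `"D"`.
#' @param fil_a,s_a,fil_b,s_b Attachments (filament id and arc coordinate)
#'   for bound heads; `NA` when unbound.
#' @return A crosslinker tibble.
#' @export
crosslinkers <- function(n = NULL, species = 1L, x = NULL, state = "U",
                         fil_a = NA_integer_, s_a = NA_real_,
                         fil_b = NA_integer_, s_b = NA_real_) {
  if (is.null(x)) {
    stopifnot(!is.null(n))
    x <- matrix(0, n, 3)
  } else {
    x <- .as_xyz(x)
    n <- nrow(x)
  }
  xs <- x
  tibble::tibble(
    id = seq_len(n),
    species = rep_len(as.integer(species), n),
    state = rep_len(state, n),
    x = xs[, 1], y = xs[, 2], z = xs[, 3],
    fil_a = rep_len(as.integer(fil_a), n), s_a = rep_len(s_a, n),
    fil_b = rep_len(as.integer(fil_b), n), s_b = rep_len(s_b, n)
  )
}

#' Tether deformation energy
#'
#' `E(ell_f) = kappa (ell_f - ell0)^2 / 2` in pN um.
#'
#' @param ell_f Tether length (um), `>= 0`.
#' @param kappa Stiffness (pN/um).
#' @param ell0 Rest length (um).
#' @export
tether_energy <- function(ell_f, kappa, ell0) {
  stopifnot(all(ell_f >= 0))
  0.5 * kappa * (ell_f - ell0)^2
}

#' Load-dependent stepping velocity
#'
#' Clamped linear force-velocity relation
#' `v_F = vm * max(0, min(1, 1 + f_proj / fstall))`: assisting load
#' saturates at `vm`, hindering load stalls the head at
#' `f_proj = -fstall`.
#'
#' @param f_proj Tether-force projection on the stepping direction (pN);
#'   positive assists stepping.
#' @param vm Unloaded speed (um/s).
#' @param fstall Stall force (pN), positive.
#' @export
step_velocity <- function(f_proj, vm, fstall) {
  stopifnot(fstall > 0)
  vm * pmax(0, pmin(1, 1 + f_proj / fstall))
}

#' U -> S binding rate at a point
#'
#' Evaluates `ko_s * 3 eps ka / (4 pi rc^3) * sum_i L_in,i(x)` where
#' `L_in,i` is the centerline arclength of filament `i` inside the capture
#' sphere of radius `rc` about `x`.
#'
#' @param x Motor position (length-3 numeric).
#' @param filaments Filament tibble.
#' @param species One-row species tibble.
#' @param boundary Boundary (minimum image applied to filament centers).
#' @return List with `rate` (1/s) and the per-filament captured lengths
#'   `lin` (um).
#' @export
rate_u_to_s <- function(x, filaments, species, boundary = boundary_free()) {
  cpp_rate_u2s(as.numeric(x), .fil_matrix(filaments),
               as.numeric(.species_matrix(species)[1, ]),
               .boundary_code(boundary))
}

#' S -> D binding rate for a singly bound head
#'
#' Integrates the Boltzmann-weighted binding density
#' `exp[-(1 - lambda) beta E(ell_f(s))]` over candidate filaments within
#' reach of the bound head's attachment point, on a fixed midpoint grid
#' (`nodes` quadrature nodes over the admissible arc window where
#' `beta E <= ecut`). The same discretized density is used for
#' inverse-transform sampling of the binding site.
#'
#' @param attachment Length-3 point: the bound head's attachment position.
#' @param rad_attached Radius of the filament the head is attached to (um),
#'   used in the surface-to-surface tether length.
#' @param filaments Candidate filament tibble.
#' @param species One-row species tibble.
#' @param exclude Filament ids excluded from the integral (normally the one
#'   the head is attached to).
#' @param kbt Thermal energy (pN um).
#' @param boundary Boundary.
#' @param nodes Quadrature nodes per candidate filament.
#' @param ecut Dimensionless energy cutoff `beta E` beyond which the weight
#'   is treated as zero.
#' @return List with `rate` (1/s) and `grids`, one record per candidate
#'   filament with node coordinates and densities.
#' @export
rate_s_to_d <- function(attachment, rad_attached, filaments, species,
                        exclude = integer(), kbt = kbt_room,
                        boundary = boundary_free(), nodes = 256, ecut = 20) {
  cpp_rate_s2d(as.numeric(attachment), rad_attached, as.integer(exclude),
               .fil_matrix(filaments),
               as.numeric(.species_matrix(species)[1, ]),
               .boundary_code(boundary), kbt, as.integer(nodes), ecut)
}

#' D -> S unbinding rate
#'
#' `ko_d * exp(lambda * beta * E(ell_f))`. Together with the S -> D density
#' this satisfies detailed balance: the site-wise equilibrium constant is
#' `eps * ke * exp(-beta E)` independent of `lambda`.
#'
#' @param ell_f Tether length (um).
#' @param species One-row species tibble.
#' @param kbt Thermal energy (pN um).
#' @export
rate_d_to_s <- function(ell_f, species, kbt = kbt_room) {
  e <- tether_energy(ell_f, species$kappa, species$ell0)
  species$ko_d * exp(species$lambda * e / kbt)
}

#' Tether geometry of doubly bound crosslinkers
#'
#' For each D-state crosslinker, computes the attachment points, the
#' surface-to-surface tether length
#' `ell_f = |r_A - r_B|_minimage - (D_A + D_B)/2` and the unit direction
#' from head B's attachment toward head A's.
#'
#' @param state A system state (see [system_state()]).
#' @return Tibble with one row per doubly bound crosslinker: `id`, `ell_f`,
#'   direction `ux, uy, uz`, and attachment coordinates.
#' @export
tether_geometry <- function(state) {
  m <- state$motors[state$motors$state == "D", ]
  if (nrow(m) == 0) {
    return(tibble::tibble(id = integer(), ell_f = numeric(), ux = numeric(),
                          uy = numeric(), uz = numeric()))
  }
  fil <- state$filaments
  bad_a <- abs(m$s_a) > fil$length[m$fil_a] / 2 + 1e-12
  bad_b <- abs(m$s_b) > fil$length[m$fil_b] / 2 + 1e-12
  if (any(bad_a | bad_b)) abort("attachment arc coordinate outside filament")
  p <- director(fil)
  pa <- cbind(fil$x[m$fil_a] + m$s_a * p$px[m$fil_a],
              fil$y[m$fil_a] + m$s_a * p$py[m$fil_a],
              fil$z[m$fil_a] + m$s_a * p$pz[m$fil_a])
  pb <- cbind(fil$x[m$fil_b] + m$s_b * p$px[m$fil_b],
              fil$y[m$fil_b] + m$s_b * p$py[m$fil_b],
              fil$z[m$fil_b] + m$s_b * p$pz[m$fil_b])
  d <- as.matrix(minimum_image(pa - pb, state$boundary))
  ptdist <- sqrt(rowSums(d^2))
  rad <- (fil$diameter[m$fil_a] + fil$diameter[m$fil_b]) / 2
  u <- d / ifelse(ptdist > 0, ptdist, 1)
  tibble::tibble(
    id = m$id, ell_f = pmax(0, ptdist - rad),
    ux = u[, 1], uy = u[, 2], uz = u[, 3],
    ax = pa[, 1], ay = pa[, 2], az = pa[, 3],
    bx = pb[, 1], by = pb[, 2], bz = pb[, 3]
  )
}

#' Advance bound motor heads along their filaments
#'
#' Task one of the timestep: attachments co-move with their filament (arc
#' coordinates are material coordinates, so this is implicit), then active
#' singly bound heads advance by `vm * h` toward their preferred end and
#' active doubly bound heads by `v_F(F_proj) * h` with the tether-force
#' projection evaluated at the current geometry. Heads reaching a filament
#' end pause (clamp) or detach according to the species' end behavior.
#'
#' @param state A system state.
#' @param h Timestep (s).
#' @return The updated state.
#' @export
move_bound_heads <- function(state, h) {
  .engine_call(state, step_config(h = h), tasks = "move")
}

#' Sample binding and unbinding events for one timestep
#'
#' Task two of the timestep: every head independently fires its candidate
#' transition with probability `1 - exp(-R(0) h)`, with all rates evaluated
#' at start-of-step geometry (first-order truncation of the inhomogeneous
#' Poisson process); at most one transition per head and per crosslinker is
#' applied per step, so U and D are never connected in a single step.
#' Unbound motors take an isotropic diffusion step first.
#'
#' @param state A system state.
#' @param cfg A [step_config()]; `h`, `kbt`, `binding_nodes` and the seed
#'   stream are taken from it.
#' @return The updated state (the state's step counter advances its RNG
#'   stream).
#' @export
sample_events <- function(state, cfg = step_config()) {
  .engine_call(state, cfg, tasks = "kmc")
}

#' Relaxation time of a crosslink-bridged filament pair
#'
#' When N identical crosslinkers of stiffness `kappa` bridge two parallel
#' filaments, the tether length relaxes as
#' `d(ell_f)/dt = -(ell_f - ell0)/tau` with `tau = zeta / (N kappa)`, where
#' `zeta` is the relevant slender-body drag (for perpendicular approach of
#' a 1 um microtubule in water, `zeta = 4 pi eta L / log(2L/D) ~ 0.003
#' pN s/um`, giving `tau ~ 3e-6 s`). Explicit timesteppers are limited to
#' `h < 2 tau`; the implicit constraint solve is not.
#'
#' @param n_crosslinkers Number of bridging crosslinkers.
#' @param kappa Tether stiffness (pN/um).
#' @param zeta Drag coefficient of the relative coordinate (pN s/um).
#' @return Relaxation time (s).
#' @export
spring_relaxation_time <- function(n_crosslinkers, kappa, zeta) {
  stopifnot(n_crosslinkers > 0, kappa > 0, zeta > 0)
  zeta / (n_crosslinkers * kappa)
}
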