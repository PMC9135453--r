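#' Assemble a system state
#'
#' The state is the single source of truth advanced by [timestep()]: the
#' filament table, the crosslinker table, their species parameters, the
#' boundary, the solvent viscosity, simulation time, and the RNG
#' bookkeeping (`seed` and the step counter define the random stream, so a
#' run is reproducible and independent of how steps are chunked).
#'
#' @param filaments Filament tibble from [spherocylinders()].
#' @param motors Crosslinker tibble from [crosslinkers()], or `NULL`.
#' @param species Species tibble ([motor_species()] rows bound together);
#'   required when motors are present.
#' @param boundary An [fm_boundary][boundaries] object.
#' @param eta Solvent viscosity (pN s/um^2); default 0.01, ten times water,
#'   typical for cytoplasmic extracts.
#' @param time Simulation time (s).
#' @param step Step counter (indexes the counter-based RNG stream).
#' @param seed Integer seed.
#' @return An object of class `fm_state`.
#' @export
system_state <- function(filaments, motors = NULL, species = NULL,
                         boundary = boundary_free(), eta = 0.01, time = 0,
                         step = 0, seed = 1) {
  if (is.null(motors)) motors <- crosslinkers(0)
  if (is.null(species)) species <- motor_species()
  if (nrow(motors) > 0 &&
      any(motors$species < 1 | motors$species > nrow(species))) {
    abort("motor species index outside the species table")
  }
  st <- structure(
    list(filaments = filaments, motors = motors, species = species,
         boundary = boundary, eta = eta, time = time, step = step,
         seed = seed),
    class = "fm_state"
  )
  validate_state(st)
  st
}

#' Validate a system state
#'
#' Checks quaternion normalization, positive dimensions, and that motor
#' head bookkeeping matches the declared state (U: no attachments; SA/SB:
#' exactly one; D: two with arc coordinates inside the filament).
#'
#' @param state An `fm_state`.
#' @return The state, invisibly; aborts with an informative message
#'   otherwise.
#' @export
validate_state <- function(state) {
  f <- state$filaments
  qn <- sqrt(f$qw^2 + f$qx^2 + f$qy^2 + f$qz^2)
  if (any(abs(qn - 1) > 1e-6)) abort("non-unit quaternion in filament table")
  if (any(f$length <= 0) || any(f$diameter <= 0)) {
    abort("filament length and diameter must be positive")
  }
  m <- state$motors
  if (nrow(m) > 0) {
    a_ok <- ifelse(m$state %in% c("SA", "D"), !is.na(m$fil_a), is.na(m$fil_a))
    b_ok <- ifelse(m$state %in% c("SB", "D"), !is.na(m$fil_b), is.na(m$fil_b))
    if (!all(a_ok & b_ok)) {
      abort("motor attachments inconsistent with declared state")
    }
    for (hd in c("a", "b")) {
      fl <- m[[paste0("fil_", hd)]]
      s <- m[[paste0("s_", hd)]]
      sel <- !is.na(fl)
      if (any(abs(s[sel]) > f$length[fl[sel]] / 2 + 1e-9)) {
        abort("bound arc coordinate outside the filament")
      }
    }
  }
  invisible(state)
}

#' @export
print.fm_state <- function(x, ...) {
  cat("<fm_state> ", nrow(x$filaments), " filaments, ", nrow(x$motors),
      " crosslinkers (", paste(names(table(x$motors$state)),
                               table(x$motors$state), collapse = ", "),
      "), t = ", signif(x$time, 6), " s\n", sep = "")
  invisible(x)
}

#' Integration settings for the implicit timestep
#'
#' @param h Timestep (s). The linearized implicit-Euler constraint solve is
#'   stable far beyond the explicit stability limit of the stiffest tether
#'   spring, so `h` is set by kinetics and accuracy rather than stiffness;
#'   1e-4 s is the working default.
#' @param kbt Thermal energy (pN um): sets Brownian kick amplitudes and the
#'   `beta` in all Boltzmann factors of the binding kinetics.
#' @param brownian Include thermal forces on filaments? (Binding kinetics
#'   keep their Boltzmann factors either way.)
#' @param buffer Collision detection buffer (um): constraints are seeded for
#'   pairs closer than this so the implicit step can prevent overlap before
#'   it happens. `NULL` = 0.3 x smallest filament diameter.
#' @param tol Relative tolerance of the projected-gradient stopping rule
#'   (scaled by `max(1, |q|_inf)`).
#' @param maxit BBPGD iteration cap.
#' @param pgs_sweeps Projected Gauss-Seidel smoothing sweeps run before the
#'   BBPGD solve (cheap local relaxation of the disturbances left by
#'   binding/unbinding between steps); 0 disables smoothing.
#' @param binding_nodes Quadrature nodes per candidate filament in the
#'   S -> D integral.
#' @param ecut Dimensionless cutoff `beta E` for the S -> D integration
#'   window (weight below `exp(-20)` is dropped).
#' @param cache_binding Reuse each singly bound head's S -> D integral
#'   across steps. Only valid while the geometry seen by bound heads is
#'   static (immobile filaments, unchanged attachments); used by
#'   equilibrium kinetics studies such as the detailed-balance checks.
#' @return A `fm_step_config` list.
#' @export
step_config <- function(h = 1e-4, kbt = kbt_room, brownian = TRUE,
                        buffer = NULL, tol = 1e-6, maxit = 5000,
                        pgs_sweeps = 20, binding_nodes = 256, ecut = 20,
                        cache_binding = FALSE) {
  stopifnot(h > 0, kbt >= 0, tol > 0, maxit > 0, binding_nodes > 1,
            pgs_sweeps >= 0)
  structure(list(h = h, kbt = kbt, brownian = brownian, buffer = buffer,
                 tol = tol, maxit = maxit, pgs_sweeps = pgs_sweeps,
                 binding_nodes = binding_nodes, ecut = ecut,
                 cache_binding = cache_binding),
            class = "fm_step_config")
}

.cfg_list <- function(state, cfg) {
  buffer <- cfg$buffer %||% (0.3 * min(state$filaments$diameter))
  list(eta = state$eta, h = cfg$h, kbt = cfg$kbt, brownian = cfg$brownian,
       buffer = buffer, tol = cfg$tol, maxit = as.integer(cfg$maxit),
       pgs_sweeps = as.integer(cfg$pgs_sweeps %||% 20),
       cache_binding = isTRUE(cfg$cache_binding),
       nodes = as.integer(cfg$binding_nodes), ecut = cfg$ecut,
       seed = as.double(state$seed), step = as.double(state$step),
       time = state$time)
}

# run selected tasks of a single step through the engine
.engine_call <- function(state, cfg, tasks) {
  out <- cpp_step_tasks(
    .fil_matrix(state$filaments), .img_matrix(state$filaments),
    .motor_matrix(state$motors), .species_matrix(state$species),
    .boundary_code(state$boundary), .cfg_list(state, cfg),
    "move" %in% tasks, "kmc" %in% tasks, "filament" %in% tasks
  )
  state$filaments <- .fils_from_matrix(out$fil, out$img, state$filaments)
  state$motors <- .motors_from_matrix(out$motors, state$motors)
  if ("kmc" %in% tasks) state$step <- state$step + 1
  if ("filament" %in% tasks) {
    attr(state, "diagnostics") <- out[c(
      "n_unilateral", "n_bilateral", "iterations", "pg_residual",
      "comp_residual", "bil_residual", "min_separation")]
    attr(state, "gamma") <- out$gamma
    attr(state, "constraints") <- .cons_tibble(out$constraints)
  }
  state
}

#' Advance the system by one full timestep
#'
#' Executes the three per-step tasks in order: (1) bound motor heads co-move
#' and step along their filaments, (2) kinetic Monte Carlo binding and
#' unbinding, (3) constraint collection, the convex QP solve for collision
#' and tether forces, the mobility solve `U = M (F_u + F_b + F_nc)`, and
#' the configuration advance. Thermal forces, when enabled, enter as
#' non-constraint forces so steric constraints resist them within the same
#' implicit solve.
#'
#' @param state An [system_state()].
#' @param cfg A [step_config()].
#' @param n Number of steps to take.
#' @return The advanced state; solver diagnostics of the last step are in
#'   `attr(state, "diagnostics")`.
#' @export
timestep <- function(state, cfg = step_config(), n = 1) {
  out <- cpp_run(
    .fil_matrix(state$filaments), .img_matrix(state$filaments),
    .motor_matrix(state$motors), .species_matrix(state$species),
    .boundary_code(state$boundary), .cfg_list(state, cfg),
    as.integer(n), 0L, FALSE, FALSE, 0
  )
  state$filaments <- .fils_from_matrix(out$fil, out$img, state$filaments)
  state$motors <- .motors_from_matrix(out$motors, state$motors)
  state$step <- out$step
  state$time <- out$time
  lg <- out$log
  k <- length(lg$step)
  attr(state, "diagnostics") <- list(
    n_unilateral = lg$n_unilateral[k], n_bilateral = lg$n_bilateral[k],
    iterations = lg$iterations[k], pg_residual = lg$pg_residual[k],
    comp_residual = lg$comp_residual[k], bil_residual = lg$bil_residual[k],
    min_separation = lg$min_separation[k])
  state
}

#' Run a simulation and record a trajectory
#'
#' Steps the state for `duration / cfg$h` steps (rounded), recording a
#' frame every `record_every` seconds plus the initial state, together with
#' per-step solver diagnostics and, per frame, the virial stress tensors of
#' collision and crosslinker constraints.
#'
#' @param state Initial [system_state()].
#' @param cfg [step_config()].
#' @param duration Simulated time (s).
#' @param record_every Frame cadence (s); coerced to a whole number of
#'   steps, minimum one.
#' @param record_motors Record the crosslinker table in each frame?
#' @param record_events Keep a log of every binding/unbinding event? (Can be
#'   large; capped by `max_events`.)
#' @param max_events Event-log capacity.
#' @return A list with `state` (final) and `trajectory`
#'   (class `fm_trajectory`).
#' @export
simulate_run <- function(state, cfg = step_config(), duration,
                         record_every = duration / 50, record_motors = TRUE,
                         record_events = FALSE, max_events = 2e6) {
  nsteps <- max(1L, as.integer(round(duration / cfg$h)))
  cadence <- max(1L, as.integer(round(record_every / cfg$h)))
  out <- cpp_run(
    .fil_matrix(state$filaments), .img_matrix(state$filaments),
    .motor_matrix(state$motors), .species_matrix(state$species),
    .boundary_code(state$boundary), .cfg_list(state, cfg),
    nsteps, cadence, record_motors, record_events, max_events
  )
  final <- state
  final$filaments <- .fils_from_matrix(out$fil, out$img, state$filaments)
  final$motors <- .motors_from_matrix(out$motors, state$motors)
  final$step <- out$step
  final$time <- out$time
  traj <- new_trajectory(out, state, cfg)
  if (record_events) {
    ev <- out$events
    if (isTRUE(out$events_overflow)) {
      warn("event log reached capacity; later events were dropped")
    }
    traj$events <- tibble::tibble(
      step = ev[, 1], motor = as.integer(ev[, 2]),
      event = c("bind_us", "unbind_su", "bind_sd", "unbind_ds",
                "end_detach")[ev[, 3]],
      head = c("A", "B")[ev[, 4]], fil = as.integer(ev[, 5]), s = ev[, 6],
      ell_f = ev[, 7])
  }
  list(state = final, trajectory = traj)
}

new_trajectory <- function(out, state0, cfg) {
  frames <- tibble::tibble(
    step = vapply(out$frames, `[[`, 0, "step"),
    time = vapply(out$frames, `[[`, 0, "time"),
    filaments = lapply(out$frames, function(fr) {
      f <- fr$fil
      tibble::tibble(id = state0$filaments$id, x = f[, 1], y = f[, 2],
                     z = f[, 3], qw = f[, 4], qx = f[, 5], qy = f[, 6],
                     qz = f[, 7], ix = fr$img[, 1], iy = fr$img[, 2],
                     iz = fr$img[, 3])
    }),
    motors = lapply(out$frames, function(fr) {
      if (is.null(fr$motors)) return(NULL)
      .motors_from_matrix(fr$motors, state0$motors)
    }),
    sigma_col = lapply(out$frames, function(fr) {
      matrix(fr$sigma_col, 3, 3, byrow = TRUE)
    }),
    sigma_xl = lapply(out$frames, function(fr) {
      matrix(fr$sigma_xl, 3, 3, byrow = TRUE)
    })
  )
  structure(
    list(frames = frames, log = tibble::as_tibble(out$log),
         filaments = state0$filaments[, c("id", "length", "diameter",
                                          "mobile")],
         species = state0$species, boundary = state0$boundary,
         eta = state0$eta, h = cfg$h, kbt = cfg$kbt, seed = state0$seed),
    class = "fm_trajectory"
  )
}

#' @export
print.fm_trajectory <- function(x, ...) {
  cat("<fm_trajectory> ", nrow(x$frames), " frames, ",
      nrow(x$filaments), " filaments, t = [",
      signif(min(x$frames$time), 4), ", ", signif(max(x$frames$time), 4),
      "] s, h = ", x$h, " s\n", sep = "")
  invisible(x)
}

.cons_tibble <- function(cm) {
  if (is.null(cm) || nrow(cm) == 0) {
    return(tibble::tibble(
      type = character(), fil1 = integer(), fil2 = integer(),
      phi = numeric(), rest = numeric(), kinv = numeric(),
      nx = numeric(), ny = numeric(), nz = numeric(),
      r1x = numeric(), r1y = numeric(), r1z = numeric(),
      r2x = numeric(), r2y = numeric(), r2z = numeric(),
      dx = numeric(), dy = numeric(), dz = numeric(), motor = integer()))
  }
  tibble::tibble(
    type = ifelse(cm[, 1] != 0, "bilateral", "unilateral"),
    fil1 = as.integer(cm[, 2]),
    fil2 = ifelse(cm[, 3] == 0, NA_integer_, as.integer(cm[, 3])),
    phi = cm[, 4], rest = cm[, 5], kinv = cm[, 6],
    nx = cm[, 7], ny = cm[, 8], nz = cm[, 9],
    r1x = cm[, 10], r1y = cm[, 11], r1z = cm[, 12],
    r2x = cm[, 13], r2y = cm[, 14], r2z = cm[, 15],
    dx = cm[, 16], dy = cm[, 17], dz = cm[, 18],
    motor = ifelse(cm[, 19] == 0, NA_integer_, as.integer(cm[, 19]))
  )
}
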