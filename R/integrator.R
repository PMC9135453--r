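#' Thermal kick as an effective non-constraint force
#'
#' Draws, per mobile filament, the random displacement and rotation of one
#' timestep with covariance `2 kbt M h` in the body frame (anisotropic
#' translation along/perpendicular to the axis; two rotational components,
#' axial spin excluded) and converts them to an equivalent wrench
#' `F = M^-1 dx / h`. Delivering the kick as a force lets steric and tether
#' constraints resist thermal motion inside the same implicit solve.
#'
#' Draws come from the state's counter-based RNG stream at its current step
#' index, so the kick is exactly the one [timestep()] would apply.
#'
#' @param state A [system_state()].
#' @param cfg A [step_config()]; `kbt = 0` or `brownian = FALSE` gives a
#'   zero wrench.
#' @return Wrench tibble `id`, `fx..fz` (pN), `tx..tz` (pN um).
#' @export
brownian_kick <- function(state, cfg = step_config()) {
  Fm <- cpp_brownian_wrench(.fil_matrix(state$filaments),
                            .img_matrix(state$filaments),
                            .boundary_code(state$boundary),
                            .cfg_list(state, cfg))
  tibble::tibble(id = state$filaments$id, fx = Fm[, 1], fy = Fm[, 2],
                 fz = Fm[, 3], tx = Fm[, 4], ty = Fm[, 5], tz = Fm[, 6])
}

#' Per-filament frame table of a trajectory
#'
#' @param x An `fm_trajectory`.
#' @param unwrap Add unwrapped coordinates (`xu`, `yu`, `zu`) using the
#'   periodic image counters -- use these for displacement and velocity
#'   fits.
#' @param ... Unused.
#' @return A tibble with one row per filament and frame: `step`, `time`,
#'   `id`, positions, image counts, and director components `px, py, pz`.
#' @export
tidy.fm_trajectory <- function(x, unwrap = TRUE, ...) {
  per <- .period_vector(x$boundary)
  out <- tidyr::unnest(
    dplyr::select(x$frames, "step", "time", "filaments"), "filaments")
  q <- cbind(out$qw, out$qx, out$qy, out$qz)
  p <- cpp_directors(q)
  out$px <- p[, 1]; out$py <- p[, 2]; out$pz <- p[, 3]
  if (unwrap) {
    out$xu <- out$x + out$ix * per[1]
    out$yu <- out$y + out$iy * per[2]
    out$zu <- out$z + out$iz * per[3]
  }
  out
}

.period_vector <- function(b) {
  switch(b$kind,
    periodic_box = c(b$lx, b$ly, b$lz),
    cylinder_x = c(b$period, 0, 0),
    c(0, 0, 0))
}

#' Trajectory summary
#'
#' One-row overview: frame count, simulated time span, filament and motor
#' counts, the peak solver iteration count, and the worst complementarity
#' and bilateral residuals over the run.
#'
#' @param x An `fm_trajectory`.
#' @param ... Unused.
#' @export
glance.fm_trajectory <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$frames),
    n_filaments = nrow(x$filaments),
    t_start = min(x$frames$time), t_end = max(x$frames$time),
    h = x$h,
    max_iterations = max(x$log$iterations, 0),
    max_comp_residual = max(x$log$comp_residual, 0),
    max_bil_residual = max(x$log$bil_residual, 0),
    min_separation = min(x$log$min_separation, Inf)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Fit the transport velocity of filaments
#'
#' `method = "slope"`: least-squares slope of unwrapped displacement versus
#' time, per filament (the gliding-assay readout); `r_squared` reports the
#' linearity of the trajectory. `method = "windows"`: the median over
#' non-overlapping windows of `|displacement| / window` -- a robust
#' transport-speed estimate when trajectories contain occasional stall or
#' reorientation episodes. The fit uses frames with `time >= t_min`.
#'
#' @param trajectory An `fm_trajectory`.
#' @param axis Displacement axis (`"x"`, `"y"`, `"z"`).
#' @param t_min Discard the initial transient before this time (s).
#' @param ids Filament ids to fit (default: all mobile filaments).
#' @param method `"slope"` or `"windows"`.
#' @param window Window length (s) for `method = "windows"`.
#' @return Tibble `id`, `velocity` (um/s, signed), `speed`, `r_squared`
#'   (`NA` for the windowed method).
#' @export
fit_transport_velocity <- function(trajectory, axis = "x", t_min = 0,
                                   ids = NULL,
                                   method = c("slope", "windows"),
                                   window = 1) {
  method <- match.arg(method)
  td <- tidy(trajectory)
  if (is.null(ids)) {
    ids <- trajectory$filaments$id[trajectory$filaments$mobile]
  }
  col <- paste0(axis, "u")
  td <- td[td$id %in% ids & td$time >= t_min, ]
  res <- lapply(split(td, td$id), function(d) {
    if (method == "slope") {
      fit <- lm(d[[col]] ~ d$time)
      r2 <- summary(fit)$r.squared
      tibble::tibble(id = d$id[1], velocity = unname(coef(fit)[2]),
                     speed = abs(unname(coef(fit)[2])), r_squared = r2)
    } else {
      ws <- transport_window_speeds(d$time, d[[col]], window)
      tibble::tibble(id = d$id[1], velocity = stats::median(ws$v),
                     speed = stats::median(abs(ws$v)), r_squared = NA_real_)
    }
  })
  dplyr::bind_rows(res)
}

#' Per-window velocities of a displacement series
#'
#' @param time,x Time (s) and unwrapped coordinate (um) samples.
#' @param window Window length (s).
#' @return Tibble `t0`, `v` (signed window velocity).
#' @export
transport_window_speeds <- function(time, x, window = 1) {
  t0s <- seq(min(time), max(time) - window, by = window)
  v <- vapply(t0s, function(t0) {
    i0 <- which.min(abs(time - t0))
    i1 <- which.min(abs(time - (t0 + window)))
    (x[i1] - x[i0]) / (time[i1] - time[i0])
  }, 0)
  tibble::tibble(t0 = t0s, v = v)
}
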