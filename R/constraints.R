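#' Collect collision (unilateral) constraints
#'
#' One constraint per filament pair whose surface separation is below
#' `buffer`, plus one per filament-wall contact for impermeable boundaries.
#' Seeding constraints slightly before touching lets the implicit step
#' prevent overlap rather than repair it.
#'
#' @param state A [system_state()].
#' @param buffer Detection buffer (um); default 0.3 x smallest diameter.
#' @return A constraint tibble (`type = "unilateral"`, signed gap `phi`,
#'   unit normal `nx..nz` pointing from `fil2`'s closest point toward
#'   `fil1`'s, lever arms `r1*`, `r2*`, and the application-point
#'   displacement `dx..dz`). Wall contacts have `fil2 = NA`.
#' @export
collect_collisions <- function(state,
                               buffer = 0.3 * min(state$filaments$diameter)) {
  stopifnot(buffer >= 0)
  cm <- cpp_collect_collisions(.fil_matrix(state$filaments),
                               .boundary_code(state$boundary), buffer)
  .cons_tibble(cm)
}

#' Collect tether (bilateral) constraints
#'
#' One Hookean spring constraint per doubly bound crosslinker, with
#' geometry from [tether_geometry()].
#'
#' @param state A [system_state()].
#' @return A constraint tibble (`type = "bilateral"`, `phi = ell_f`,
#'   `rest = ell0`, `kinv = 1/kappa`).
#' @export
collect_tethers <- function(state) {
  cm <- cpp_collect_tethers(.fil_matrix(state$filaments),
                            .motor_matrix(state$motors),
                            .species_matrix(state$species),
                            .boundary_code(state$boundary))
  .cons_tibble(cm)
}

.cons_matrix <- function(constraints) {
  cm <- cbind(
    as.numeric(constraints$type == "bilateral"),
    constraints$fil1,
    ifelse(is.na(constraints$fil2), 0, constraints$fil2),
    constraints$phi, constraints$rest, constraints$kinv,
    constraints$nx, constraints$ny, constraints$nz,
    constraints$r1x, constraints$r1y, constraints$r1z,
    constraints$r2x, constraints$r2y, constraints$r2z,
    constraints$dx, constraints$dy, constraints$dz,
    ifelse(is.na(constraints$motor), 0, constraints$motor)
  )
  matrix(cm, nrow = nrow(constraints))
}

#' Assemble the per-step convex quadratic program
#'
#' Builds the QP `min 1/2 g' M g + q' g` over constraint force magnitudes
#' `g = (g_u, g_b)` subject to `g_u >= 0`, where
#' `M = D' M D + diag(0, K^-1 / h)` and
#' `q = (Phi_u / h + D_u' M F_nc, (Phi_b - Phi_b0)/h + D_b' M F_nc)`.
#' `D` maps force magnitudes to equal-and-opposite wrenches on the two
#' filaments of each constraint, and `M` is the block-diagonal slender-body
#' mobility. The rigid-joint limit `K^-1 -> 0` (a constraint row with
#' `kinv = 0`) is supported.
#'
#' Unilateral rows are ordered first; the returned object carries the dense
#' `M` (suitable for direct inspection and for small systems -- the
#' production path inside [timestep()] is matrix-free).
#'
#' @param state A [system_state()].
#' @param constraints Constraint tibble (rows from [collect_collisions()]
#'   and/or [collect_tethers()]).
#' @param h Timestep (s).
#' @param f_nc Non-constraint wrench matrix (n x 6), e.g. from
#'   [brownian_kick()]; defaults to zero.
#' @return An `fm_qp` list with `M`, `q`, `n_unilateral`, `h`, and the
#'   reordered constraint tibble.
#' @export
assemble_qp <- function(state, constraints, h, f_nc = NULL) {
  stopifnot(h > 0)
  if (any(constraints$type == "bilateral" & !is.finite(constraints$kinv))) {
    abort("bilateral constraint with non-finite compliance")
  }
  ord <- order(constraints$type == "bilateral")
  constraints <- constraints[ord, ]
  nu <- sum(constraints$type == "unilateral")
  n <- nrow(state$filaments)
  if (is.null(f_nc)) f_nc <- matrix(0, n, 6)
  dn <- cpp_qp_dense(.fil_matrix(state$filaments), state$eta,
                     .cons_matrix(constraints), h, f_nc)
  structure(list(M = dn$M, q = dn$q, n_unilateral = nu, h = h,
                 constraints = constraints),
            class = "fm_qp")
}

#' Solve a constraint QP with Barzilai-Borwein projected gradient descent
#'
#' Minimizes `1/2 g' M g + q' g` subject to nonnegativity of the first
#' `n_unilateral` components (collision force magnitudes); bilateral tether
#' magnitudes are unconstrained. The first iteration takes a small fixed
#' step scaled by an operator-norm estimate; subsequent steps alternate the
#' two Barzilai-Borwein step sizes. Convergence is declared when the
#' projected-gradient infinity norm falls below
#' `tol * max(1, |q|_inf)`.
#'
#' @param qp An `fm_qp` from [assemble_qp()], or a plain list with `M`,
#'   `q`, `n_unilateral`.
#' @param tol Relative tolerance.
#' @param max_iter Iteration cap; a convergence warning reports the residual
#'   if reached.
#' @return List with `gamma`, `iterations`, `residual`, `converged`.
#' @export
bbpgd_solve <- function(qp, tol = 1e-6, max_iter = 5000) {
  tol_abs <- tol * max(1, max(abs(qp$q), 0))
  out <- cpp_bbpgd_dense(qp$M, qp$q, as.integer(qp$n_unilateral), tol_abs,
                         as.integer(max_iter))
  if (!out$converged) {
    warn(sprintf(
      "BBPGD reached %d iterations (projected-gradient residual %.3e)",
      max_iter, out$resid))
  }
  list(gamma = out$gamma, iterations = out$iters, residual = out$resid,
       converged = out$converged)
}

#' Constraint forces and torques from solved magnitudes
#'
#' Expands `F = D gamma`: each constraint applies `+gamma n` at its point
#' on `fil1` and `-gamma n` on `fil2` (action-reaction), with the matching
#' torques. Wall constraints push only the filament.
#'
#' @param state A [system_state()].
#' @param constraints Constraint tibble (same ordering as `gamma`).
#' @param gamma Solved force magnitudes (pN).
#' @return Tibble `id`, `fx..fz` (pN), `tx..tz` (pN um).
#' @export
constraint_forces <- function(state, constraints, gamma) {
  Fm <- cpp_constraint_forces(.fil_matrix(state$filaments),
                              .cons_matrix(constraints), gamma)
  tibble::tibble(id = state$filaments$id, fx = Fm[, 1], fy = Fm[, 2],
                 fz = Fm[, 3], tx = Fm[, 4], ty = Fm[, 5], tz = Fm[, 6])
}
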