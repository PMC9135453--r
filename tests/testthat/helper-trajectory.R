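# build a synthetic fm_trajectory from a function giving centers over time
# (directors fixed); used by observable tests that need known kinematics
make_test_trajectory <- function(times, centers_fun, directors, length = 0.5,
                                 diameter = 0.025,
                                 boundary = filamotor::boundary_free()) {
  n <- nrow(directors)
  quats <- t(apply(directors, 1, filamotor::quat_from_director))
  frames <- tibble::tibble(
    step = seq_along(times) - 1,
    time = times,
    filaments = lapply(times, function(t) {
      ctr <- centers_fun(t)
      tibble::tibble(id = seq_len(n), x = ctr[, 1], y = ctr[, 2],
                     z = ctr[, 3], qw = quats[, 1], qx = quats[, 2],
                     qy = quats[, 3], qz = quats[, 4],
                     ix = 0L, iy = 0L, iz = 0L)
    }),
    motors = lapply(times, function(t) NULL),
    sigma_col = lapply(times, function(t) matrix(0, 3, 3)),
    sigma_xl = lapply(times, function(t) matrix(0, 3, 3))
  )
  structure(
    list(frames = frames,
         log = tibble::tibble(step = numeric(), time = numeric(),
                              n_unilateral = numeric(),
                              n_bilateral = numeric(),
                              iterations = numeric(),
                              pg_residual = numeric(),
                              comp_residual = numeric(),
                              bil_residual = numeric(),
                              min_separation = numeric(),
                              tol_abs = numeric()),
         filaments = tibble::tibble(id = seq_len(n),
                                    length = rep(length, n),
                                    diameter = rep(diameter, n),
                                    mobile = TRUE),
         species = filamotor::motor_species(),
         boundary = boundary, eta = 0.01, h = 1e-4,
         kbt = filamotor::kbt_room, seed = 1),
    class = "fm_trajectory"
  )
}
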