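test_that("collision collection matches a brute-force all-pairs oracle", {
  # far pair: nothing
  st <- system_state(spherocylinders(rbind(c(0, 0, 0), c(5, 0, 0)),
                                     rbind(c(0, 0, 1), c(0, 0, 1)),
                                     length = 1, diameter = 0.025))
  expect_equal(nrow(collect_collisions(st)), 0)
  # overlapping pair: one constraint with negative gap
  st2 <- system_state(spherocylinders(rbind(c(0, 0, 0), c(0.02, 0, 0)),
                                      rbind(c(0, 0, 1), c(0, 1, 0)),
                                      length = 1, diameter = 0.025))
  cc <- collect_collisions(st2)
  expect_equal(nrow(cc), 1)
  expect_lt(cc$phi[1], 0)

  # random rods: the detected pair set equals the oracle's pair set and the
  # reported gaps match recomputed minimal distances
  set.seed(12)
  n <- 60
  fil <- spherocylinders(matrix(runif(3 * n, -0.8, 0.8), n, 3),
                         matrix(rnorm(3 * n), n, 3),
                         length = 0.5, diameter = 0.05)
  st3 <- system_state(fil)
  buffer <- 0.015
  cc3 <- collect_collisions(st3, buffer = buffer)
  got <- unique(paste(cc3$fil1, cc3$fil2))
  want <- character()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      md <- min_distance(fil[i, ], fil[j, ])
      if (md$sep < buffer) want <- c(want, paste(i, j))
    }
  }
  expect_setequal(got, want)
  for (k in seq_len(nrow(cc3))) {
    md <- min_distance(fil[cc3$fil1[k], ], fil[cc3$fil2[k], ])
    # manifold constraints sit at or above the true minimal separation
    expect_gte(cc3$phi[k], md$sep - 1e-9)
  }
  # and the minimal gap per pair is represented
  agg <- tapply(cc3$phi, paste(cc3$fil1, cc3$fil2), min)
  for (nm in names(agg)) {
    ij <- as.integer(strsplit(nm, " ")[[1]])
    md <- min_distance(fil[ij[1], ], fil[ij[2], ])
    expect_equal(agg[[nm]], md$sep, tolerance = 1e-9)
  }
})

test_that("tether collection mirrors the doubly bound population", {
  st <- scenario_bulk_isotropic(n_fil = 30, n_motor = 100, box = 1.5,
                                seed = 3)
  expect_equal(nrow(collect_tethers(st)), 0)
  st2 <- timestep(st, step_config(h = 5e-4, binding_nodes = 64), n = 200)
  ct <- collect_tethers(st2)
  expect_equal(nrow(ct), sum(st2$motors$state == "D"))
  expect_true(all(ct$type == "bilateral"))
  tg <- tether_geometry(st2)
  expect_equal(sort(ct$phi), sort(tg$ell_f), tolerance = 1e-12)
})

test_that("QP assembly matches the dense oracle", {
  set.seed(14)
  n <- 6
  fil <- spherocylinders(matrix(runif(3 * n, -0.3, 0.3), n, 3),
                         matrix(rnorm(3 * n), n, 3),
                         length = 0.6, diameter = 0.06)
  sp <- motor_species(kappa = 120, ell0 = 0.04, d_motor = 0)
  motors <- crosslinkers(n = 3, state = "D",
                         fil_a = c(1L, 2L, 4L), s_a = c(0.1, -0.2, 0),
                         fil_b = c(3L, 5L, 6L), s_b = c(0, 0.25, -0.1))
  st <- system_state(fil, motors, sp)
  cons <- dplyr::bind_rows(collect_collisions(st, buffer = 0.1),
                           collect_tethers(st))
  expect_gt(sum(cons$type == "unilateral"), 0)
  h <- 1e-4
  f_nc <- matrix(rnorm(6 * n), n, 6)
  qp <- assemble_qp(st, cons, h, f_nc)
  ora <- qp_dense_oracle(st, qp$constraints, h, f_nc)
  expect_equal(qp$M, ora$M, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(qp$q, ora$q, tolerance = 1e-12, ignore_attr = TRUE)
  # symmetric positive semidefinite
  expect_equal(qp$M, t(qp$M), tolerance = 1e-12)
  for (i in 1:20) {
    x <- rnorm(nrow(qp$M))
    expect_gte(sum(x * (qp$M %*% x)), -1e-10 * sum(x^2))
  }
  # empty problem
  qp0 <- assemble_qp(st, cons[0, ], h)
  expect_equal(dim(qp0$M), c(0L, 0L))
})

test_that("single mid-length contact gives the scalar 2/zeta_perp", {
  # two identical free rods touching at mid-length: lever arms vanish and
  # the QP matrix reduces to n' (M1 + M2) n = 2/zeta_perp
  fil <- spherocylinders(rbind(c(0, 0, 0), c(0.03, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 1, 0)),
                         length = 1, diameter = 0.04)
  st <- system_state(fil, eta = 0.01)
  cons <- collect_collisions(st, buffer = 0.02)
  expect_equal(nrow(cons), 1)
  qp <- assemble_qp(st, cons, h = 1e-4)
  zperp <- mobility_coefficients(fil, 0.01)$zeta_perp[1]
  expect_equal(qp$M[1, 1], 2 / zperp, tolerance = 1e-12)
})

test_that("a resting bilateral spring contributes a zero q row", {
  st <- two_rod_spring_state(gap = 0.075, n_links = 1, kappa = 100,
                             ell0 = 0.05)  # lf = 0.075 - 0.025 = ell0
  cons <- collect_tethers(st)
  qp <- assemble_qp(st, cons, h = 1e-4)
  expect_equal(qp$q, 0)
})

test_that("BBPGD solves trivial and closed-form problems", {
  # q >= 0 with only unilateral rows: gamma = 0 is the stationary point
  out <- bbpgd_solve(list(M = diag(3), q = c(1, 2, 0.5), n_unilateral = 3))
  expect_equal(out$gamma, c(0, 0, 0))
  # 1D unilateral: M = m, q = -phi/h -> gamma = phi/(h m)
  m <- 4; phi <- 0.02; h <- 1e-4
  out1 <- bbpgd_solve(list(M = matrix(m), q = -phi / h, n_unilateral = 1),
                      tol = 1e-12)
  expect_equal(out1$gamma, phi / (h * m), tolerance = 1e-8)
})

test_that("BBPGD matches exact active-set solutions on random SPSD QPs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:9, 1)
    nu <- sample(1:n, 1)
    qp <- random_spsd_qp(n, nu, rank = sample(2:n, 1))
    ora <- qp_active_set_oracle(qp$M, qp$q, qp$nu)
    out <- bbpgd_solve(list(M = qp$M, q = qp$q, n_unilateral = qp$nu),
                       tol = 1e-8, max_iter = 50000)
    val <- 0.5 * sum(out$gamma * (qp$M %*% out$gamma)) +
      sum(qp$q * out$gamma)
    expect_lt(abs(val - ora$value), 1e-8 * max(1, abs(ora$value)))
  }
})

test_that("BBPGD agrees with an independent QP library solver", {
  skip_if_not_installed("pracma")
  set.seed(123)
  for (i in 1:10) {
    n <- 20; nu <- 12
    A <- matrix(rnorm(n * n), n)
    M <- crossprod(A) + 0.5 * diag(n)
    q <- rnorm(n)
    # pracma::quadprog: min 1/2 x'Cx + d'x subject to A x <= b
    Amat <- -diag(n)[seq_len(nu), , drop = FALSE]
    ref <- pracma::quadprog(M, q, A = Amat, b = rep(0, nu))
    out <- bbpgd_solve(list(M = M, q = q, n_unilateral = nu), tol = 1e-10,
                       max_iter = 50000)
    val <- 0.5 * sum(out$gamma * (M %*% out$gamma)) + sum(q * out$gamma)
    ref_val <- 0.5 * sum(ref$xmin * (M %*% ref$xmin)) + sum(q * ref$xmin)
    expect_lt(abs(val - ref_val), 1e-8 * max(1, abs(ref_val)))
  }
})

test_that("constraint forces obey action-reaction and momentum conservation", {
  set.seed(15)
  n <- 20
  fil <- spherocylinders(matrix(runif(3 * n, -0.4, 0.4), n, 3),
                         matrix(rnorm(3 * n), n, 3),
                         length = 0.5, diameter = 0.06)
  st <- system_state(fil)
  cons <- collect_collisions(st, buffer = 0.05)
  expect_gt(nrow(cons), 2)
  # zero magnitudes, zero forces
  F0 <- constraint_forces(st, cons, rep(0, nrow(cons)))
  expect_true(all(unlist(F0[, -1]) == 0))
  # single contact: +n on filament 1, -n on filament 2
  c1 <- cons[1, ]
  F1 <- constraint_forces(st, c1, 1)
  expect_equal(unlist(F1[c1$fil1, c("fx", "fy", "fz")]),
               c(fx = c1$nx, fy = c1$ny, fz = c1$nz))
  expect_equal(unlist(F1[c1$fil2, c("fx", "fy", "fz")]),
               -c(fx = c1$nx, fy = c1$ny, fz = c1$nz))
  # random magnitudes: net force vanishes; net torque about the origin too
  gam <- rnorm(nrow(cons))
  Fr <- constraint_forces(st, cons, gam)
  expect_lt(max(abs(colSums(Fr[, c("fx", "fy", "fz")]))), 1e-10)
  tau <- cbind(Fr$tx, Fr$ty, Fr$tz) +
    t(sapply(seq_len(n), function(i) {
      pracma::cross(c(fil$x[i], fil$y[i], fil$z[i]),
                    c(Fr$fx[i], Fr$fy[i], Fr$fz[i]))
    }))
  expect_lt(max(abs(colSums(tau))), 1e-10)
})

test_that("implicit tether springs follow the closed-form recurrence", {
  # two parallel mobile rods bridged by N identical springs at matching arc
  # coordinates: per step (lf - ell0) contracts by 1/(1 + h N kappa (2/zp))
  for (n_links in c(1, 10)) {
    st <- two_rod_spring_state(gap = 0.2, n_links = n_links, kappa = 100,
                               ell0 = 0.05)
    zp <- mobility_coefficients(st$filaments, st$eta)$zeta_perp[1]
    h <- 1e-4
    fac <- 1 / (1 + h * n_links * 100 * (2 / zp))
    lf <- 0.2 - 0.025
    cfg <- step_config(h = h, brownian = FALSE, tol = 1e-10, maxit = 50000)
    s <- st
    for (k in 1:5) {
      s <- timestep(s, cfg)
      lf <- 0.05 + (lf - 0.05) * fac
      gap_k <- s$filaments$x[2] - s$filaments$x[1]
      expect_equal(gap_k - 0.025, lf, tolerance = 1e-10)
    }
  }
})

test_that("the rigid-joint limit pins the tether at its rest length", {
  st <- two_rod_spring_state(gap = 0.2, n_links = 1)
  cons <- collect_tethers(st)
  cons$kinv <- 0  # K^-1 -> 0: non-compliant joint
  qp <- assemble_qp(st, cons, h = 1e-4)
  sol <- bbpgd_solve(qp, tol = 1e-10, max_iter = 10000)
  # linearized post-step tether length equals the rest length
  ora <- qp_dense_oracle(st, qp$constraints, 1e-4)
  u <- ora$Mmob %*% (ora$D %*% sol$gamma)
  phi_lin <- qp$constraints$phi + 1e-4 * as.vector(t(ora$D) %*% u)
  expect_equal(phi_lin, qp$constraints$rest, tolerance = 1e-8)
})

test_that("per-step solver residuals stay within tolerance in a live run", {
  st <- scenario_bulk_isotropic(n_fil = 60, n_motor = 150, box = 1.5,
                                seed = 21)
  cfg <- step_config(h = 2e-4, binding_nodes = 64, tol = 1e-4,
                     maxit = 20000)
  res <- simulate_run(st, cfg, duration = 0.2, record_every = 0.2,
                      record_motors = FALSE)
  lg <- res$trajectory$log
  # every step converged: complementarity and bilateral residuals within
  # the stopping tolerance of that step's problem
  expect_true(all(lg$comp_residual <= lg$tol_abs + 1e-12))
  expect_true(all(lg$bil_residual <= lg$tol_abs + 1e-12))
  expect_true(all(lg$iterations < 20000))
})
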