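test_that("tether energy and force-velocity relation follow their formulas", {
  expect_equal(tether_energy(0.05, 100, 0.05), 0)
  expect_equal(tether_energy(0.06, 100, 0.05), 0.005)
  expect_equal(tether_energy(0.04, 100, 0.05), tether_energy(0.06, 100, 0.05))

  expect_equal(step_velocity(0, vm = 1, fstall = 5), 1)     # unloaded
  expect_equal(step_velocity(-5, vm = 1, fstall = 5), 0)    # stalled
  expect_equal(step_velocity(10, vm = 1, fstall = 5), 1)    # saturated
  set.seed(1)
  v <- step_velocity(rnorm(1000, sd = 20), vm = 0.8, fstall = 3)
  expect_true(all(v >= 0 & v <= 0.8))
})

test_that("U->S rate integrates captured arclength inside the capture sphere", {
  sp <- motor_species(ko_s = 1, ka = 1, eps = 1, rc = 0.5)
  # no filament within reach
  far <- spherocylinders(rbind(c(10, 0, 0)), rbind(c(0, 0, 1)), length = 1)
  expect_equal(rate_u_to_s(c(0, 0, 0), far, sp)$rate, 0)
  # single filament with captured length 0.5 um (rod through the center,
  # length 0.5 < sphere diameter): rate = ko_s * 3*0.5/(4 pi 0.5^3)
  rod <- spherocylinders(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)), length = 0.5)
  r <- rate_u_to_s(c(0, 0, 0), rod, sp)
  expect_equal(r$lin, 0.5)
  expect_equal(r$rate, 3 * 0.5 / (4 * pi * 0.5^3), tolerance = 1e-12)
  # captured arclength vs quadrature for a chord crossing the sphere
  set.seed(31)
  for (i in 1:20) {
    x <- runif(3, -0.3, 0.3)
    p <- rnorm(3); p <- p / sqrt(sum(p^2))
    fil <- spherocylinders(rbind(x), rbind(p), length = 1.4)
    s <- seq(-0.7, 0.7, length.out = 100001)
    pts <- cbind(x[1] + s * p[1], x[2] + s * p[2], x[3] + s * p[3])
    inside <- rowSums(pts^2) < 0.5^2
    oracle <- sum(inside) * (s[2] - s[1])
    expect_equal(rate_u_to_s(c(0, 0, 0), fil, sp)$lin, oracle,
                 tolerance = 1e-4)
  }
})

test_that("S->D rate matches an adaptive quadrature oracle", {
  sp <- motor_species(kappa = 100, ell0 = 0.05, ko_d = 2, ke = 3, eps = 400,
                      lambda = 0.3)
  beta <- 1 / kbt_room
  # no candidate within reach
  far <- spherocylinders(rbind(c(5, 0, 0)), rbind(c(0, 1, 0)), length = 1)
  expect_equal(rate_s_to_d(c(0, 0, 0), 0.0125, far, sp)$rate, 0)
  # flat integrand when kappa = 0: rate = ko_d * eps * ke * L
  sp0 <- motor_species(kappa = 0, ko_d = 2, ke = 3, eps = 400)
  near <- spherocylinders(rbind(c(0.05, 0, 0)), rbind(c(0, 1, 0)),
                          length = 0.8)
  expect_equal(rate_s_to_d(c(0, 0, 0), 0.0125, near, sp0,
                           nodes = 64)$rate, 2 * 400 * 3 * 0.8,
               tolerance = 1e-12)
  # perpendicular rod at fixed offset vs integrate()
  a <- c(0, 0, 0)
  rod <- spherocylinders(rbind(c(0.06, 0, 0)), rbind(c(0, 1, 0)),
                         length = 1, diameter = 0.025)
  rad_sum <- 0.0125 + 0.0125
  dens <- function(s) {
    lf <- pmax(0, sqrt(0.06^2 + s^2) - rad_sum)
    exp(-(1 - sp$lambda) * beta * 0.5 * sp$kappa * (lf - sp$ell0)^2)
  }
  oracle <- integrate(dens, -0.5, 0.5, rel.tol = 1e-10)$value *
    sp$ko_d * sp$eps * sp$ke
  r <- rate_s_to_d(a, 0.0125, rod, sp, nodes = 4096)
  expect_equal(r$rate, oracle, tolerance = 1e-6 * oracle)
  # the production discretization (256 nodes) is within 0.1%
  r256 <- rate_s_to_d(a, 0.0125, rod, sp, nodes = 256)
  expect_equal(r256$rate, oracle, tolerance = 1e-3 * oracle)
})

test_that("S<->D rates satisfy detailed balance site by site", {
  beta <- 1 / kbt_room
  for (lam in c(0, 0.5, 1)) {
    sp <- motor_species(kappa = 80, ell0 = 0.053, ko_d = 1.5, ke = 2,
                        eps = 100, lambda = lam)
    rod <- spherocylinders(rbind(c(0.07, 0, 0)), rbind(c(0, 1, 0)),
                           length = 1, diameter = 0.025)
    r <- rate_s_to_d(c(0, 0, 0), 0.0125, rod, sp, nodes = 128)
    g <- r$grids[[1]]
    lf <- pmax(0, sqrt(0.07^2 + g$s^2) - 0.025)
    off <- rate_d_to_s(lf, sp)
    # on-density / off-rate proportional to the Boltzmann factor,
    # independent of lambda
    ratio <- (g$density * sp$ko_d * sp$eps * sp$ke / off) /
      exp(-beta * tether_energy(lf, sp$kappa, sp$ell0))
    expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-10)
  }
  # trivial D->S cases
  sp <- motor_species(lambda = 0, ko_d = 3)
  expect_equal(rate_d_to_s(c(0.01, 0.2, 1), sp), rep(3, 3))
  sp2 <- motor_species(lambda = 0.7, ko_d = 3, ell0 = 0.05)
  expect_equal(rate_d_to_s(0.05, sp2), 3)
})

test_that("tether geometry uses the surface-to-surface convention", {
  # heads at the same point: zero length
  fil <- spherocylinders(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 0, 1)), length = 1,
                         diameter = 0.025)
  sp <- motor_species()
  m <- crosslinkers(n = 1, state = "D", fil_a = 1L, s_a = 0.2, fil_b = 2L,
                    s_b = 0.2)
  st <- system_state(fil, m, sp)
  tg <- tether_geometry(st)
  # parallel rods offset 0.05: point distance 0.05, minus both radii
  expect_equal(tg$ell_f, 0.05 - 0.025)
  expect_equal(unname(c(tg$ux, tg$uy, tg$uz)), c(-1, 0, 0))

  set.seed(17)
  for (i in 1:20) {
    x2 <- runif(3, -0.3, 0.3)
    p2 <- rnorm(3); p2 <- p2 / sqrt(sum(p2^2))
    fil2 <- spherocylinders(rbind(c(0, 0, 0), x2),
                            rbind(c(0, 0, 1), p2), length = 1,
                            diameter = c(0.025, 0.04))
    sa <- runif(1, -0.5, 0.5); sb <- runif(1, -0.5, 0.5)
    st2 <- system_state(fil2, crosslinkers(n = 1, state = "D", fil_a = 1L,
                                           s_a = sa, fil_b = 2L, s_b = sb),
                        sp)
    tg2 <- tether_geometry(st2)
    pa <- c(0, 0, sa)
    pb <- x2 + sb * p2
    expect_equal(tg2$ell_f,
                 max(0, sqrt(sum((pa - pb)^2)) - (0.025 + 0.04) / 2),
                 tolerance = 1e-12)
  }
})

test_that("bound heads step with load-dependent velocity and end behavior", {
  h <- 1e-4
  # unloaded singly bound minus-directed head: ds = -vm h
  fil <- spherocylinders(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)), length = 1,
                         diameter = 0.025)
  sp <- motor_species(vm = 1, direction = "minus", end_behavior = "pause",
                      d_motor = 0)
  m <- crosslinkers(n = 1, state = "SA", fil_a = 1L, s_a = 0.1)
  st <- system_state(fil, m, sp)
  st2 <- move_bound_heads(st, h)
  expect_equal(st2$motors$s_a, 0.1 - 1e-4)
  # clamped at the minus end under pause
  m2 <- crosslinkers(n = 1, state = "SA", fil_a = 1L, s_a = -0.5)
  st3 <- move_bound_heads(system_state(fil, m2, sp), h)
  expect_equal(st3$motors$s_a, -0.5)
  # detach at the end
  spd <- motor_species(vm = 1, direction = "minus",
                       end_behavior = "detach", d_motor = 0)
  st4 <- move_bound_heads(system_state(fil, m2, spd), h)
  expect_equal(st4$motors$state, "U")

  # doubly bound antiparallel pair under symmetric load: both heads step at
  # v_F computed from the same tether force with opposite projections
  fil2 <- spherocylinders(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                          rbind(c(0, 0, 1), c(0, 0, -1)), length = 1,
                          diameter = 0.025)
  spv <- motor_species(vm = 1, fstall = 2, kappa = 30, ell0 = 0.15,
                       direction = "minus", end_behavior = "pause",
                       d_motor = 0)
  # heads walking away from each other: symmetric sub-stall hindering load
  md <- crosslinkers(n = 1, state = "D", fil_a = 1L, s_a = -0.1, fil_b = 2L,
                     s_b = -0.1)
  std <- system_state(fil2, md, spv)
  tg <- tether_geometry(std)
  fmag <- spv$kappa * (tg$ell_f - spv$ell0)
  # force on head A along the tether toward B; A's stepping direction is
  # -z (minus end of filament 1), B's is +z (minus end of flipped rod 2)
  u_a <- -c(tg$ux, tg$uy, tg$uz)  # unit vector from A toward B
  fproj_a <- fmag * sum(u_a * c(0, 0, -1))
  fproj_b <- fmag * sum(-u_a * c(0, 0, 1))
  va <- step_velocity(fproj_a, spv$vm, spv$fstall)
  vb <- step_velocity(fproj_b, spv$vm, spv$fstall)
  st5 <- move_bound_heads(std, h)
  expect_equal(st5$motors$s_a, -0.1 - va * h, tolerance = 1e-12)
  expect_equal(st5$motors$s_b, -0.1 - vb * h, tolerance = 1e-12)
  expect_equal(fproj_a, fproj_b, tolerance = 1e-12)  # symmetric load
  expect_gt(va, 0)
  expect_lt(va, spv$vm)  # hindered but not stalled
})

test_that("event sampling fires with probability 1 - exp(-R h)", {
  # motor anchored next to a filament; binding probability of the free head
  # in one step checked against the binomial expectation over many motors
  sp <- motor_species(kappa = 100, ell0 = 0.05, ko_s = 0, ko_d = 5,
                      ke = 0.5, eps = 40, d_motor = 0,
                      permanent = c(TRUE, FALSE))
  fil <- spherocylinders(rbind(c(0, 0, 0), c(0.06, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 0, 1)), length = 1,
                         diameter = 0.025)
  n <- 4000
  m <- crosslinkers(n = n, state = "SA", fil_a = 1L,
                    s_a = rep(0, n))
  st <- system_state(fil, m, sp)
  h <- 1e-3
  r <- rate_s_to_d(c(0, 0, 0), 0.0125, fil[2, ], sp,
                   nodes = 256)
  p_expect <- 1 - exp(-r$rate * h)
  reps <- 25
  fired <- 0
  for (k in seq_len(reps)) {
    st$seed <- k
    st2 <- sample_events(st, step_config(h = h, binding_nodes = 256))
    fired <- fired + sum(st2$motors$state == "D")
  }
  ntrial <- n * reps
  se <- sqrt(ntrial * p_expect * (1 - p_expect))
  expect_lt(abs(fired - ntrial * p_expect), 3 * se)
  # zero rate: nothing fires
  sp0 <- motor_species(ko_s = 0, ko_d = 0, d_motor = 0,
                       permanent = c(TRUE, FALSE))
  st0 <- system_state(fil, m, sp0)
  expect_equal(sample_events(st0, step_config(h = h))$motors$state,
               rep("SA", n))
})

test_that("kMC conserves motors and never jumps U<->D in one step", {
  st <- scenario_bulk_isotropic(n_fil = 50, n_motor = 200, box = 1.5,
                                fil_length = 0.5, seed = 8)
  cfg <- step_config(h = 5e-4, binding_nodes = 64)
  res <- simulate_run(st, cfg, duration = 0.25, record_every = 0.25,
                      record_motors = TRUE, record_events = TRUE)
  expect_equal(nrow(res$state$motors), 200)
  ev <- res$trajectory$events
  # reconstruct state codes per motor and check the transition graph
  code <- c(U = 0, SA = 1, SB = 1, D = 2)
  lvl <- setNames(rep(0L, 200), seq_len(200))
  for (k in seq_len(nrow(ev))) {
    mtr <- as.character(ev$motor[k])
    delta <- switch(ev$event[k], bind_us = 1L, bind_sd = 1L,
                    unbind_su = -1L, unbind_ds = -1L, end_detach = -1L)
    lvl[mtr] <- lvl[mtr] + delta
    expect_gte(lvl[[mtr]], 0)
    expect_lte(lvl[[mtr]], 2)
  }
  expect_equal(unname(lvl[as.character(res$state$motors$id)]),
               unname(code[res$state$motors$state]))
})
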