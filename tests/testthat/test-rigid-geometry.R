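test_that("director matches the quaternion rotation of the reference axis", {
  expect_equal(unlist(director(spherocylinders(
    rbind(c(0, 0, 0)), quaternion = rbind(c(1, 0, 0, 0))))[, 2:4]),
    c(px = 0, py = 0, pz = 1))
  # 180 degrees about x flips the director
  expect_equal(unlist(director(spherocylinders(
    rbind(c(0, 0, 0)), quaternion = rbind(c(0, 1, 0, 0))))[, 2:4]),
    c(px = 0, py = 0, pz = -1))
  set.seed(42)
  for (i in 1:50) {
    q <- random_unit_quaternion()
    fil <- spherocylinders(rbind(c(0, 0, 0)), quaternion = rbind(q))
    p <- unlist(director(fil)[, 2:4])
    expect_equal(unname(p), as.vector(quat_to_matrix(q) %*% c(0, 0, 1)),
                 tolerance = 1e-12)
  }
})

test_that("non-unit quaternions are rejected", {
  fil <- spherocylinders(rbind(c(0, 0, 0)), quaternion = rbind(c(1, 0, 0, 0)))
  fil$qw <- 2
  expect_error(director(fil), "not normalized")
})

test_that("quat_from_director round-trips through director", {
  set.seed(7)
  for (i in 1:30) {
    p <- rnorm(3)
    p <- p / sqrt(sum(p^2))
    fil <- spherocylinders(rbind(c(0, 0, 0)),
                           quaternion = rbind(quat_from_director(p)))
    expect_equal(unname(unlist(director(fil)[, 2:4])), p, tolerance = 1e-12)
  }
  # antipodal special case
  expect_equal(quat_from_director(c(0, 0, -1)), c(0, 1, 0, 0))
})

test_that("min_distance handles parallel, overlapping and skew pairs", {
  f <- function(x, p) spherocylinders(rbind(x), rbind(p), length = 1,
                                      diameter = 0.025)
  a <- f(c(0, 0, 0), c(0, 0, 1))
  b <- f(c(0.05, 0, 0), c(0, 0, 1))
  r <- min_distance(a, b)
  expect_equal(r$sep, 0.025)
  # fully coincident centerlines: overlap equals the diameter
  expect_equal(min_distance(a, a)$sep, -0.025)

  set.seed(11)
  for (i in 1:25) {
    c1 <- runif(3, -0.5, 0.5); c2 <- runif(3, -0.5, 0.5)
    p1 <- rnorm(3); p1 <- p1 / sqrt(sum(p1^2))
    p2 <- rnorm(3); p2 <- p2 / sqrt(sum(p2^2))
    L1 <- runif(1, 0.3, 1.5); L2 <- runif(1, 0.3, 1.5)
    fa <- spherocylinders(rbind(c1), rbind(p1), length = L1,
                          diameter = 0.025)
    fb <- spherocylinders(rbind(c2), rbind(p2), length = L2,
                          diameter = 0.03)
    r <- min_distance(fa, fb)
    ora <- segment_distance_oracle(c1, p1, L1 / 2, c2, p2, L2 / 2)
    expect_equal(r$sep, ora$dist - (0.025 + 0.03) / 2, tolerance = 1e-6)
  }
})

test_that("min_distance is symmetric and bounded by the center distance", {
  set.seed(3)
  for (i in 1:200) {
    c1 <- runif(3, -1, 1); c2 <- runif(3, -1, 1)
    p1 <- rnorm(3); p1 <- p1 / sqrt(sum(p1^2))
    p2 <- rnorm(3); p2 <- p2 / sqrt(sum(p2^2))
    fa <- spherocylinders(rbind(c1), rbind(p1), length = 0.8,
                          diameter = 0.05)
    fb <- spherocylinders(rbind(c2), rbind(p2), length = 1.2,
                          diameter = 0.05)
    r1 <- min_distance(fa, fb)
    r2 <- min_distance(fb, fa)
    expect_equal(r1$sep, r2$sep, tolerance = 1e-12)
    expect_equal(r1$s1, r2$s2, tolerance = 1e-9)
    expect_equal(r1$n, -r2$n, tolerance = 1e-9)
    # segment distance never exceeds the center-center distance
    expect_lte(r1$sep, sqrt(sum((c1 - c2)^2)) - 0.05 + 1e-12)
  }
})

test_that("min_distance applies the minimum image convention", {
  b <- boundary_periodic_box(2, 2, 2)
  a <- spherocylinders(rbind(c(-0.95, 0, 0)), rbind(c(0, 0, 1)),
                       length = 0.5, diameter = 0.02)
  c_ <- spherocylinders(rbind(c(0.95, 0, 0)), rbind(c(0, 0, 1)),
                        length = 0.5, diameter = 0.02)
  expect_equal(min_distance(a, c_, b)$sep, 0.1 - 0.02)
})

test_that("mobility obeys the slender-body drag formulas", {
  # filament whose parallel drag equals 0.003 pN s/um (1 um microtubule in
  # water-like solvent): axial unit force moves it at 1/0.003 = 333.3 um/s
  L <- 1; D <- 0.025
  eta <- 0.003 * log(2 * L / D) / (2 * pi * L)
  fil <- spherocylinders(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)), length = L,
                         diameter = D)
  mc <- mobility_coefficients(fil, eta)
  expect_equal(mc$zeta_par, 0.003, tolerance = 1e-12)
  expect_equal(mc$zeta_perp, 0.006, tolerance = 1e-12)
  U <- mobility_apply(fil, eta, cbind(0, 0, 1, 0, 0, 0))
  expect_equal(U$vz, 1 / 0.003, tolerance = 1e-12)
  expect_equal(c(U$vx, U$vy), c(0, 0))
  # perpendicular force: velocity parallel to the force, magnitude f/zperp
  U2 <- mobility_apply(fil, eta, cbind(2, 0, 0, 0, 0, 0))
  expect_equal(U2$vx, 2 / mc$zeta_perp)
  expect_equal(c(U2$vy, U2$vz), c(0, 0))
  # zero force, zero velocity
  expect_true(all(unlist(mobility_apply(fil, eta,
                                        cbind(0, 0, 0, 0, 0, 0))[, -1]) == 0))
})

test_that("per-filament mobility block is symmetric PSD and linear", {
  set.seed(5)
  q <- random_unit_quaternion()
  fil <- spherocylinders(rbind(c(0, 0, 0)), quaternion = rbind(q),
                         length = 0.7, diameter = 0.03)
  eta <- 0.01
  Mb <- sapply(1:6, function(k) {
    w <- rep(0, 6); w[k] <- 1
    unlist(mobility_apply(fil, eta, rbind(w))[, -1])
  })
  expect_equal(Mb, t(Mb), tolerance = 1e-14, ignore_attr = TRUE)
  ev <- eigen(Mb, symmetric = TRUE, only.values = TRUE)$values
  # PSD with exactly one null mode: the axial spin of the spherocylinder
  expect_true(all(ev > -1e-12))
  expect_equal(sum(ev < 1e-10), 1)
  # linearity
  w1 <- rnorm(6); w2 <- rnorm(6)
  u12 <- unlist(mobility_apply(fil, eta, rbind(w1 + 2 * w2))[, -1])
  u1 <- unlist(mobility_apply(fil, eta, rbind(w1))[, -1])
  u2 <- unlist(mobility_apply(fil, eta, rbind(w2))[, -1])
  expect_equal(u12, u1 + 2 * u2, tolerance = 1e-12)
  # matches the dense oracle
  p <- unlist(director(fil)[, 2:4])
  expect_equal(unname(Mb), unname(mobility_block_oracle(p, 0.7, 0.03, eta)),
               tolerance = 1e-13)
})

test_that("advance_configuration integrates rigid kinematics exactly", {
  fil <- spherocylinders(rbind(c(0, 0, 0)), rbind(c(1, 0, 0)), length = 1,
                         diameter = 0.025)
  h <- 1e-3
  # zero velocity: unchanged
  same <- advance_configuration(fil, cbind(0, 0, 0, 0, 0, 0), h)
  expect_equal(as.data.frame(same), as.data.frame(fil))
  # rotation by pi about z flips an x-director
  rot <- advance_configuration(fil, cbind(0, 0, 0, 0, 0, pi / h), h)
  expect_equal(unname(unlist(director(rot)[, 2:4])), c(-1, 0, 0),
               tolerance = 1e-12)
  # translation is linear: two half steps equal one full step
  v <- cbind(0.3, -0.2, 0.5, 0, 0, 0)
  one <- advance_configuration(fil, v, h)
  two <- advance_configuration(advance_configuration(fil, v, h / 2), v,
                               h / 2)
  expect_equal(c(two$x, two$y, two$z), c(one$x, one$y, one$z),
               tolerance = 1e-14)
  # shape and quaternion norm preserved under arbitrary motion
  set.seed(9)
  st <- fil
  for (i in 1:20) {
    st <- advance_configuration(st, rbind(rnorm(6, sd = 10)), h)
  }
  expect_equal(st$length, fil$length)
  expect_equal(st$diameter, fil$diameter)
  expect_equal(st$qw^2 + st$qx^2 + st$qy^2 + st$qz^2, 1, tolerance = 1e-12)
  # non-finite velocities abort
  expect_error(advance_configuration(fil, cbind(NaN, 0, 0, 0, 0, 0), h),
               "non-finite")
})
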