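test_that("local nematic order spans aligned, isolated and isotropic limits", {
  # all directors identical and mutually crosslinked: S = 1
  n <- 8
  fil <- spherocylinders(cbind(seq_len(n) * 0.05, 0, 0),
                         matrix(rep(c(0, 0, 1), each = n), n, 3),
                         length = 0.5)
  links <- tibble::tibble(fil1 = rep(1L, n - 1), fil2 = 2:n)
  s <- local_nematic_order(fil, links)
  expect_equal(s$s_local[1], 1, tolerance = 1e-12)
  expect_equal(s$nd[1], n)
  # isolated filament: self-average gives exactly 1
  s0 <- local_nematic_order(fil, links[0, ])
  expect_equal(s0$s_local, rep(1, n))
  expect_equal(s0$nd, rep(1L, n))
  # a large isotropic neighborhood decays to O(1e-2)
  set.seed(33)
  m <- 10000
  iso <- spherocylinders(matrix(runif(3 * m), m, 3),
                         matrix(rnorm(3 * m), m, 3), length = 0.1)
  big <- tibble::tibble(fil1 = rep(1L, m - 1), fil2 = 2:m)
  siso <- local_nematic_order(iso, big)
  expect_lt(siso$s_local[1], 0.05)
  # range property
  expect_true(all(s$s_local >= 0 & s$s_local <= 1 + 1e-12))
})

test_that("local nematic order derives neighborhoods from D-state motors", {
  fil <- spherocylinders(rbind(c(0, 0, 0), c(0.05, 0, 0), c(0.1, 0, 0)),
                         rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1)),
                         length = 0.5)
  m <- crosslinkers(n = 1, state = "D", fil_a = 1L, s_a = 0, fil_b = 2L,
                    s_b = 0)
  st <- system_state(fil, m, motor_species())
  s <- local_nematic_order(st)
  # filaments 1 and 2 are perpendicular partners, 3 is isolated
  expect_equal(s$nd, c(2L, 2L, 1L))
  expect_equal(s$s_local[3], 1)
  expect_lt(s$s_local[1], 1)
})

test_that("axial order profile weights by in-window centerline length", {
  breaks <- seq(-0.5, 0.5, by = 0.25)
  # all along x: s_x = 1 everywhere covered
  fx <- spherocylinders(rbind(c(-0.25, 0, 0), c(0.25, 0, 0)),
                        rbind(c(1, 0, 0), c(-1, 0, 0)), length = 0.4)
  px <- axial_order_profile(fx, breaks)
  expect_equal(px$s_x[!is.na(px$s_x)],
               rep(1, sum(!is.na(px$s_x))), tolerance = 1e-12)
  # perpendicular: -1/2
  fy <- spherocylinders(rbind(c(-0.1, 0, 0)), rbind(c(0, 1, 0)),
                        length = 0.4)
  py <- axial_order_profile(fy, breaks)
  expect_equal(py$s_x[2], -0.5)
  # empty windows are NA, not zero
  expect_true(any(is.na(py$s_x)))
  # isotropic ensemble averages to ~0
  set.seed(5)
  n <- 6000
  fi <- spherocylinders(cbind(runif(n, -0.5, 0.5), 0, 0),
                        matrix(rnorm(3 * n), n, 3), length = 0.2)
  pi_ <- axial_order_profile(fi, breaks)
  expect_true(all(abs(pi_$s_x) < 0.05))
  # range
  expect_true(all(pi_$s_x >= -0.5 - 1e-12 & pi_$s_x <= 1 + 1e-12))
})

test_that("minus-end RDF is normalized and matches brute force", {
  set.seed(6)
  b <- boundary_periodic_box(2)
  n <- 400
  pts <- tibble::tibble(x = runif(n, -1, 1), y = runif(n, -1, 1),
                        z = runif(n, -1, 1))
  rdf <- rdf_minus_ends(pts, bin_width = 0.05, r_max = 0.9, boundary = b,
                        volume = 8)
  # ideal gas: g ~ 1 across bins (weighted mean exactly 1 by construction
  # of the pair count; allow sampling noise per bin)
  expect_equal(sum(rdf$count), sum(rdf$count[rdf$g > 0]))
  expect_lt(abs(weighted.mean(rdf$g, 4 / 3 * pi * diff(seq(0, 0.9,
    by = 0.05)^3)) - 1), 0.05)
  expect_true(all(abs(rdf$g[-(1:4)] - 1) < 0.5))
  # normalization conservation: expected counts sum to observed total
  expect_equal(sum(rdf$count),
               sum(rdf$g * (n * (n - 1) / 2) * 4 / 3 * pi *
                     diff(seq(0, 0.9, by = 0.05)^3) / 8))

  # simple cubic lattice: sharp peak at the lattice constant
  g0 <- expand.grid(x = (0:4) * 0.4 - 0.8, y = (0:4) * 0.4 - 0.8,
                    z = (0:4) * 0.4 - 0.8)
  rl <- rdf_minus_ends(g0, bin_width = 0.02, r_max = 0.5, boundary = b,
                       volume = 8)
  expect_lt(abs(rl$r[which.max(rl$g)] - 0.40), 0.011)

  # brute-force histogram identical (dist() as the independent pair count)
  d <- as.vector(dist(as.matrix(pts)))
  # free boundary comparison (no images): use a huge box
  rdf2 <- rdf_minus_ends(pts, bin_width = 0.05, r_max = 0.9,
                         boundary = boundary_free(), volume = 8)
  cnt <- tabulate(findInterval(d[d < 0.9], seq(0, 0.9, by = 0.05)),
                  nbins = 18)
  expect_equal(rdf2$count, cnt)
  # r_max guard
  expect_error(rdf_minus_ends(pts, r_max = 1.5, boundary = b), "half")
})

test_that("virial stress signs distinguish extensile and contractile parts", {
  # no constraints: zero stress
  s0 <- virial_stress(tibble::tibble(type = character(), fil1 = integer(),
                                     fil2 = integer(), phi = numeric(),
                                     rest = numeric(), kinv = numeric(),
                                     nx = numeric(), ny = numeric(),
                                     nz = numeric(), r1x = numeric(),
                                     r1y = numeric(), r1z = numeric(),
                                     r2x = numeric(), r2y = numeric(),
                                     r2z = numeric(), dx = numeric(),
                                     dy = numeric(), dz = numeric(),
                                     motor = integer()),
                     numeric(0), volume = 1)
  expect_equal(s0$sigma_col, matrix(0, 3, 3))

  # stretched tether along x: contractile (negative sigma_xx)
  st <- two_rod_spring_state(gap = 0.2, n_links = 1, kappa = 100,
                             ell0 = 0.05)
  cons <- collect_tethers(st)
  gam <- -100 * (cons$phi - cons$rest)  # spring law, stretched -> negative
  sx <- virial_stress(cons, gam, volume = 1)
  expect_lt(sx$sigma_xl[1, 1], 0)
  expect_lt(sx$pressure_xl, 0)
  expect_equal(sx$sigma_xl, t(sx$sigma_xl), tolerance = 1e-12)

  # overlapping pair pushed apart: extensile collision pressure
  fil <- spherocylinders(rbind(c(0, 0, 0), c(0.02, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 1, 0)), length = 1,
                         diameter = 0.025)
  st2 <- system_state(fil)
  cc <- collect_collisions(st2)
  sc <- virial_stress(cc, rep(2, nrow(cc)), volume = 1)
  expect_gt(sc$pressure_col, 0)

  # invariance under global translation
  st3 <- st2
  st3$filaments$x <- st3$filaments$x + 3
  st3$filaments$y <- st3$filaments$y - 1
  cc3 <- collect_collisions(st3)
  sc3 <- virial_stress(cc3, rep(2, nrow(cc3)), volume = 1)
  expect_equal(sc3$sigma_col, sc$sigma_col, tolerance = 1e-12)
})

test_that("sampling-plane straining velocity recovers known kinematics", {
  # two polarity groups translating at +/- v: Vx = 2v in every window
  n <- 40
  set.seed(8)
  y0 <- runif(n, -0.05, 0.05); z0 <- runif(n, -0.05, 0.05)
  x0 <- runif(n, -0.5, 0.5)
  dirs <- cbind(rep(c(1, -1), n / 2), 0, 0)
  v <- 0.02
  vel <- v * dirs[, 1]
  traj <- make_test_trajectory(
    times = seq(0, 12, by = 1),
    centers_fun = function(t) cbind(x0 + vel * t, y0, z0),
    directors = dirs)
  sv <- plane_straining_velocity(traj, plane_x = c(-0.2, 0, 0.2),
                                 points = cbind(0, 0), window = 0.2,
                                 averaging = 10)
  expect_gt(nrow(sv), 0)
  expect_equal(sv$vx, rep(2 * v, nrow(sv)), tolerance = 1e-12)
  expect_true(all(abs(sv$px_mean) <= 1))

  # static filaments: no moving groups, no samples
  traj0 <- make_test_trajectory(
    times = seq(0, 12, by = 1),
    centers_fun = function(t) cbind(x0, y0, z0),
    directors = dirs)
  sv0 <- plane_straining_velocity(traj0, plane_x = 0, points = cbind(0, 0),
                                  averaging = 10)
  expect_equal(nrow(sv0), 0)

  # drift + noise: recovered within the standard error
  set.seed(9)
  noise <- function(t) matrix(rnorm(3 * n, sd = 0.002), n, 3)
  trajn <- make_test_trajectory(
    times = seq(0, 12, by = 1),
    centers_fun = function(t) cbind(x0 + vel * t, y0, z0) + noise(t),
    directors = dirs)
  svn <- plane_straining_velocity(trajn, plane_x = c(-0.2, 0, 0.2),
                                  points = cbind(0, 0), window = 0.2,
                                  averaging = 10)
  expect_lt(abs(mean(svn$vx) - 2 * v), 3 * sd(svn$vx) / sqrt(nrow(svn)) +
              2e-3)
})

test_that("polarity divergence is zero for uniform and positive for source", {
  sp <- 0.2
  g <- expand.grid(x = seq(0.1, 1.9, by = sp), y = seq(0.1, 1.9, by = sp),
                   z = seq(0.1, 1.9, by = sp))
  uniform <- tibble::tibble(g, px = 1, py = 0, pz = 0)
  du <- polarity_divergence(uniform, sp, length_scale = 0.5)
  expect_equal(du$div_p, rep(0, nrow(du)), tolerance = 1e-12)

  # radial source p = r_hat about the grid center: div p = 2/r > 0
  ctr <- c(1, 1, 1)
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  r[r == 0] <- 1e-9
  rad <- tibble::tibble(g, px = (g$x - ctr[1]) / r, py = (g$y - ctr[2]) / r,
                        pz = (g$z - ctr[3]) / r)
  dr <- polarity_divergence(rad, sp, length_scale = 0.5)
  interior <- with(dr, x > 0.2 & x < 1.8 & y > 0.2 & y < 1.8 &
                     z > 0.2 & z < 1.8 & r > 0.3)
  expect_true(all(dr$div_p[interior] > 0))
  # against the analytic divergence 2/r (finite-difference error allowed)
  expect_equal(dr$div_p[interior], 0.5 * 2 / r[interior], tolerance = 0.2)
})

test_that("stress series integrates recorded tensors", {
  st <- two_rod_spring_state(gap = 0.2, n_links = 3)
  cfg <- step_config(h = 1e-4, brownian = FALSE)
  res <- simulate_run(st, cfg, duration = 0.005, record_every = 1e-3)
  ss <- stress_series(res$trajectory, volume = 1)
  # stretched tethers: contractile crosslink pressure while relaxing
  expect_lt(ss$pressure_xl[2], 0)
  expect_equal(ss$pressure_col[2], 0)  # no contacts
})
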