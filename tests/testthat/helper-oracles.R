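# Independent oracles used across the test suite. These deliberately avoid
# the package's computational paths: rotation matrices instead of
# quaternions, grid search instead of closed-form closest points, dense
# linear algebra instead of matrix-free operators, and exhaustive
# active-set enumeration instead of projected gradients.

# quaternion (w, x, y, z) -> 3x3 rotation matrix
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_unit_quaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# brute-force minimal distance between two segments by grid search with
# recursive refinement (accurate to ~1e-9 um)
segment_distance_oracle <- function(c1, p1, h1, c2, p2, h2,
                                    n = 201, levels = 5) {
  lo1 <- -h1; hi1 <- h1; lo2 <- -h2; hi2 <- h2
  best <- c(0, 0)
  for (lev in seq_len(levels)) {
    s <- seq(lo1, hi1, length.out = n)
    t <- seq(lo2, hi2, length.out = n)
    pts1 <- outer(s, p1)  # n x 3 via outer on each component
    a1 <- cbind(c1[1] + s * p1[1], c1[2] + s * p1[2], c1[3] + s * p1[3])
    a2 <- cbind(c2[1] + t * p2[1], c2[2] + t * p2[2], c2[3] + t * p2[3])
    d2 <- outer(rowSums(a1^2), rep(1, n)) + outer(rep(1, n), rowSums(a2^2)) -
      2 * a1 %*% t(a2)
    idx <- arrayInd(which.min(d2), dim(d2))
    best <- c(s[idx[1]], t[idx[2]])
    ds <- (hi1 - lo1) / (n - 1)
    dt <- (hi2 - lo2) / (n - 1)
    lo1 <- max(-h1, best[1] - 2 * ds); hi1 <- min(h1, best[1] + 2 * ds)
    lo2 <- max(-h2, best[2] - 2 * dt); hi2 <- min(h2, best[2] + 2 * dt)
  }
  p_a <- c1 + best[1] * p1
  p_b <- c2 + best[2] * p2
  list(dist = sqrt(sum((p_a - p_b)^2)), s1 = best[1], s2 = best[2])
}

# dense mobility matrix (6x6 per filament, block diagonal) built from the
# drag formulas directly
mobility_block_oracle <- function(p, L, D, eta, mobile = TRUE) {
  if (!mobile) return(matrix(0, 6, 6))
  lg <- log(2 * L / D)
  zpar <- 2 * pi * eta * L / lg
  zperp <- 2 * zpar
  zrot <- pi * eta * L^3 / (3 * lg)
  P <- outer(p, p)
  Mt <- P / zpar + (diag(3) - P) / zperp
  Mr <- (diag(3) - P) / zrot
  rbind(cbind(Mt, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), Mr))
}

# dense QP assembly oracle: explicit D matrix and block mobility
qp_dense_oracle <- function(state, constraints, h, f_nc = NULL) {
  fil <- state$filaments
  n <- nrow(fil)
  p <- filamotor::director(fil)
  nc <- nrow(constraints)
  Dm <- matrix(0, 6 * n, nc)
  for (k in seq_len(nc)) {
    i <- constraints$fil1[k]
    nv <- c(constraints$nx[k], constraints$ny[k], constraints$nz[k])
    ri <- c(constraints$r1x[k], constraints$r1y[k], constraints$r1z[k])
    Dm[(6 * i - 5):(6 * i - 3), k] <- nv
    Dm[(6 * i - 2):(6 * i), k] <- pracma::cross(ri, nv)
    j <- constraints$fil2[k]
    if (!is.na(j)) {
      rj <- c(constraints$r2x[k], constraints$r2y[k], constraints$r2z[k])
      Dm[(6 * j - 5):(6 * j - 3), k] <- Dm[(6 * j - 5):(6 * j - 3), k] - nv
      Dm[(6 * j - 2):(6 * j), k] <- Dm[(6 * j - 2):(6 * j), k] -
        pracma::cross(rj, nv)
    }
  }
  Mm <- matrix(0, 6 * n, 6 * n)
  for (i in seq_len(n)) {
    idx <- (6 * i - 5):(6 * i)
    Mm[idx, idx] <- mobility_block_oracle(
      c(p$px[i], p$py[i], p$pz[i]), fil$length[i], fil$diameter[i],
      state$eta, fil$mobile[i])
  }
  K <- diag(ifelse(constraints$type == "bilateral", constraints$kinv / h, 0),
            nc, nc)
  Mqp <- t(Dm) %*% Mm %*% Dm + K
  if (is.null(f_nc)) f_nc <- matrix(0, n, 6)
  phi0 <- ifelse(constraints$type == "bilateral",
                 constraints$phi - constraints$rest, constraints$phi)
  q <- phi0 / h + as.vector(t(Dm) %*% (Mm %*% as.vector(t(f_nc))))
  list(M = Mqp, q = q, D = Dm, Mmob = Mm)
}

# exact solver for min 1/2 g'Mg + q'g s.t. g[1:nu] >= 0 by enumerating
# active sets (exponential; for small problems only)
qp_active_set_oracle <- function(M, q, nu) {
  n <- length(q)
  best <- NULL
  best_val <- Inf
  for (mask in 0:(2^nu - 1)) {
    active <- which(bitwAnd(mask, 2^(seq_len(nu) - 1)) > 0)  # gamma = 0
    free <- setdiff(seq_len(n), active)
    g <- numeric(n)
    if (length(free) > 0) {
      sol <- tryCatch(solve(M[free, free, drop = FALSE], -q[free]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      g[free] <- sol
    }
    if (any(g[seq_len(nu)] < -1e-10)) next
    grad <- as.vector(M %*% g) + q
    if (length(active) > 0 && any(grad[active] < -1e-8)) next
    val <- 0.5 * sum(g * (M %*% g)) + sum(q * g)
    if (val < best_val) {
      best_val <- val
      best <- g
    }
  }
  list(gamma = best, value = best_val)
}

random_spsd_qp <- function(n, nu, rank = n) {
  A <- matrix(rnorm(n * rank), rank, n)
  M <- crossprod(A) + 1e-3 * diag(n)
  q <- rnorm(n)
  list(M = M, q = q, nu = nu)
}

# minimal two-rod system used by several solver tests: parallel rods along
# z at x = 0 and x = gap, bridged by `n_links` permanent doubly bound motors
two_rod_spring_state <- function(gap = 0.2, n_links = 1, kappa = 100,
                                 ell0 = 0.05, L = 1, D = 0.025,
                                 eta = 0.001, mobile = c(TRUE, TRUE)) {
  fil <- filamotor::spherocylinders(
    center = rbind(c(0, 0, 0), c(gap, 0, 0)),
    director = rbind(c(0, 0, 1), c(0, 0, 1)),
    length = L, diameter = D, mobile = mobile)
  sp <- filamotor::motor_species(
    name = "link", kappa = kappa, ell0 = ell0, vm = 0, fstall = 1,
    ko_s = 0, ko_d = 0, d_motor = 0, permanent = c(TRUE, TRUE),
    end_behavior = "pause")
  s_att <- if (n_links == 1) 0 else seq(-0.2, 0.2, length.out = n_links) * L
  motors <- filamotor::crosslinkers(
    n = n_links, species = 1L, state = "D",
    fil_a = 1L, s_a = s_att, fil_b = 2L, s_b = s_att)
  filamotor::system_state(fil, motors, sp, eta = eta)
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         tolerance = tol)
}
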