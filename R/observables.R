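#' Local nematic order over crosslink neighborhoods
#'
#' For each filament i, averages the tensor `Q = <p p'> - I/3` over the
#' neighborhood consisting of the filament itself plus every filament
#' directly crosslinked to it (doubly bound motors), and reports
#' `S_local = sqrt(3/2 Q:Q)` together with the neighborhood size `Nd`.
#' An isolated filament has `S_local = 1` (self-average).
#'
#' @param state A [system_state()], or a filament tibble when `links` is
#'   given.
#' @param links Optional crosslink pairs (tibble with columns `fil1`,
#'   `fil2`); defaults to the D-state motors of the state.
#' @return Tibble `id`, `s_local`, `nd`.
#' @export
local_nematic_order <- function(state, links = NULL) {
  if (inherits(state, "fm_state")) {
    fil <- state$filaments
    if (is.null(links)) {
      m <- state$motors[state$motors$state == "D", ]
      links <- tibble::tibble(fil1 = m$fil_a, fil2 = m$fil_b)
    }
  } else {
    fil <- state
    links <- links %||% tibble::tibble(fil1 = integer(), fil2 = integer())
  }
  p <- director(fil)
  pm <- cbind(p$px, p$py, p$pz)
  n <- nrow(fil)
  nbr <- lapply(seq_len(n), function(i) i)
  if (nrow(links) > 0) {
    for (k in seq_len(nrow(links))) {
      a <- links$fil1[k]; b <- links$fil2[k]
      if (a != b) {
        nbr[[a]] <- c(nbr[[a]], b)
        nbr[[b]] <- c(nbr[[b]], a)
      }
    }
  }
  s_local <- numeric(n)
  nd <- integer(n)
  for (i in seq_len(n)) {
    idx <- unique(nbr[[i]])
    nd[i] <- length(idx)
    pp <- pm[idx, , drop = FALSE]
    Q <- crossprod(pp) / nrow(pp) - diag(3) / 3
    s_local[i] <- sqrt(1.5 * sum(Q * Q))
  }
  tibble::tibble(id = fil$id, s_local = s_local, nd = nd)
}

#' Axial nematic order profile along x
#'
#' Each filament contributes `(3 cos^2(theta) - 1) / 2` -- theta its angle
#' to the x-axis -- weighted by the fraction of its centerline length
#' falling inside each window. Windows with zero total weight are reported
#' as `NA`, not zero.
#'
#' @param state A [system_state()] or filament tibble.
#' @param breaks Window edges along x (um), increasing.
#' @param boundary Boundary (for periodic unwrapping of window membership);
#'   taken from the state when available.
#' @return Tibble `x` (window center), `s_x` (axial order in `[-1/2, 1]`),
#'   `weight` (summed centerline length, um).
#' @export
axial_order_profile <- function(state, breaks, boundary = NULL) {
  fil <- if (inherits(state, "fm_state")) state$filaments else state
  boundary <- boundary %||%
    (if (inherits(state, "fm_state")) state$boundary else boundary_free())
  per <- .period_vector(boundary)[1]
  p <- director(fil)
  half_dx <- 0.5 * fil$length * abs(p$px)
  contrib <- 0.5 * (3 * p$px^2 - 1)
  shifts <- if (per > 0) c(-per, 0, per) else 0
  nb <- length(breaks) - 1
  wsum <- numeric(nb)
  ssum <- numeric(nb)
  for (sh in shifts) {
    cx <- fil$x + sh
    xmin <- cx - half_dx
    xmax <- cx + half_dx
    for (k in seq_len(nb)) {
      ov <- pmax(0, pmin(breaks[k + 1], xmax) - pmax(breaks[k], xmin))
      w <- ifelse(half_dx > 1e-12,
                  fil$length * ov / (2 * half_dx),
                  fil$length * (cx >= breaks[k] & cx < breaks[k + 1]))
      wsum[k] <- wsum[k] + sum(w)
      ssum[k] <- ssum[k] + sum(w * contrib)
    }
  }
  tibble::tibble(
    x = (head(breaks, -1) + tail(breaks, -1)) / 2,
    s_x = ifelse(wsum > 0, ssum / wsum, NA_real_),
    weight = wsum
  )
}

#' Radial distribution function of filament minus ends
#'
#' Standard pair-distance histogram under the minimum-image convention,
#' normalized by the ideal-gas expectation, so an uncorrelated uniform
#' system gives `g(r) = 1`.
#'
#' @param state A [system_state()], or a point tibble/matrix (`x`, `y`,
#'   `z`) together with an explicit `boundary` and `volume`.
#' @param bin_width Histogram bin width (um).
#' @param r_max Maximum distance (um); must not exceed half the shortest
#'   periodic edge.
#' @param boundary,volume Override for non-state inputs.
#' @return Tibble `r` (bin centers), `g`, `count`.
#' @export
rdf_minus_ends <- function(state, bin_width = 0.002, r_max = 0.25,
                           boundary = NULL, volume = NULL) {
  if (inherits(state, "fm_state")) {
    pts <- filament_ends(state$filaments, "minus")
    boundary <- boundary %||% state$boundary
  } else {
    m_ <- .as_xyz(state)
    pts <- tibble::tibble(x = m_[, 1], y = m_[, 2], z = m_[, 3])
    boundary <- boundary %||% boundary_free()
  }
  if (boundary$kind == "periodic_box") {
    volume <- volume %||% (boundary$lx * boundary$ly * boundary$lz)
    if (r_max > min(boundary$lx, boundary$ly, boundary$lz) / 2) {
      abort("r_max exceeds half the shortest box edge")
    }
  } else if (is.null(volume)) {
    abort("supply `volume` for non-periodic boundaries")
  }
  m <- cbind(pts$x, pts$y, pts$z)
  n <- nrow(m)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  d <- m[ii, , drop = FALSE] - m[jj, , drop = FALSE]
  d <- as.matrix(minimum_image(d, boundary))
  r <- sqrt(rowSums(d^2))
  breaks <- seq(0, r_max, by = bin_width)
  if (max(breaks) < r_max) breaks <- c(breaks, max(breaks) + bin_width)
  counts <- tabulate(findInterval(r[r < max(breaks)], breaks),
                     nbins = length(breaks) - 1)
  shell <- 4 / 3 * pi * diff(breaks^3)
  npairs <- n * (n - 1) / 2
  expected <- npairs * shell / volume
  tibble::tibble(
    r = (head(breaks, -1) + tail(breaks, -1)) / 2,
    g = counts / expected,
    count = counts
  )
}

#' Locate local maxima of g(r)
#'
#' Peak finder with a topographic prominence filter: a bin is a peak when
#' it exceeds both neighbors, its height passes `min_g`, and it rises by at
#' least `min_prominence` above the highest saddle separating it from
#' taller terrain on either side. The prominence filter suppresses the
#' Poisson noise bumps of sparse histograms while keeping genuine
#' structural maxima.
#'
#' @param rdf Tibble from [rdf_minus_ends()].
#' @param min_g Minimum peak height.
#' @param min_prominence Minimum prominence (same units as `g`).
#' @return Tibble of peak rows ordered by `r`, with a `prominence` column.
#' @export
rdf_peaks <- function(rdf, min_g = 1.5, min_prominence = 0) {
  g <- rdf$g
  n <- length(g)
  idx <- integer(0)
  prom <- numeric(0)
  for (i in seq(2, n - 1)) {
    if (!(g[i] >= g[i - 1] && g[i] >= g[i + 1] && g[i] >= min_g &&
          (g[i] > g[i - 1] || g[i] > g[i + 1]))) next
    # saddle toward taller terrain on each side (edge counts as terrain 0)
    left <- g[seq_len(i - 1)]
    right <- g[seq(i + 1, n)]
    # lowest point between the peak and the nearest taller bin per side
    taller <- which(left >= g[i])
    lp <- if (length(taller) == 0) 0 else min(left[max(taller):(i - 1)])
    taller_r <- which(right >= g[i])
    rp <- if (length(taller_r) == 0) 0 else
      min(right[seq_len(min(taller_r))])
    p <- g[i] - max(lp, rp)
    if (p >= min_prominence) {
      idx <- c(idx, i)
      prom <- c(prom, p)
    }
  }
  out <- rdf[idx, ]
  out$prominence <- prom
  out
}

#' Virial stress of the current constraint forces
#'
#' `sigma = (1/V) sum_c f_c (x) d_c`, where `f_c = gamma_c n_c` is the force
#' the constraint applies to its first filament and `d_c` the minimum-image
#' vector between the two application points (contact points for
#' collisions, attachment points for tethers). Collision and crosslinker
#' contributions are reported separately; wall constraints are external and
#' excluded. With this convention overlapping pairs pushed apart give
#' positive (extensile) collision pressure and stretched tethers negative
#' (contractile) crosslinker pressure, `Pi = tr(sigma) / 3`.
#'
#' @param constraints Constraint tibble (ordering must match `gamma`).
#' @param gamma Solved force magnitudes (pN).
#' @param volume System volume V (um^3).
#' @return An `fm_stress` list: `sigma_col`, `sigma_xl` (3x3, pN/um^2),
#'   `pressure_col`, `pressure_xl`, `volume`.
#' @export
virial_stress <- function(constraints, gamma, volume) {
  sig <- function(rows) {
    s <- matrix(0, 3, 3)
    if (!any(rows)) return(s)
    f <- gamma[rows] * cbind(constraints$nx[rows], constraints$ny[rows],
                             constraints$nz[rows])
    d <- cbind(constraints$dx[rows], constraints$dy[rows],
               constraints$dz[rows])
    (t(f) %*% d) / volume
  }
  internal <- !is.na(constraints$fil2)
  uni <- constraints$type == "unilateral" & internal
  bil <- constraints$type == "bilateral" & internal
  s_col <- sig(uni)
  s_xl <- sig(bil)
  structure(list(sigma_col = s_col, sigma_xl = s_xl,
                 pressure_col = sum(diag(s_col)) / 3,
                 pressure_xl = sum(diag(s_xl)) / 3, volume = volume),
            class = "fm_stress")
}

#' Stress and pressure time series of a trajectory
#'
#' @param trajectory An `fm_trajectory` recorded by [simulate_run()].
#' @param volume System volume (um^3).
#' @return Tibble `time`, `pressure_col`, `pressure_xl`, and the diagonal
#'   stress components per frame.
#' @export
stress_series <- function(trajectory, volume) {
  fr <- trajectory$frames
  tibble::tibble(
    time = fr$time,
    pressure_col = vapply(fr$sigma_col, function(s) sum(diag(s)),
                          0) / (3 * volume),
    pressure_xl = vapply(fr$sigma_xl, function(s) sum(diag(s)),
                         0) / (3 * volume),
    sxx_col = vapply(fr$sigma_col, function(s) s[1, 1], 0) / volume,
    sxx_xl = vapply(fr$sigma_xl, function(s) s[1, 1], 0) / volume
  )
}

#' Sampling-plane straining velocity
#'
#' Emulates a photobleached-line velocity measurement: square sampling
#' windows (edge `window`) are drawn around sample points on planes
#' orthogonal to x. For each window and sampling time, `Px` is the mean
#' director x-component over filaments whose centerline crosses the window,
#' and the window's straining velocity is `Vx = V+x - V-x`, the difference
#' of the mean velocities of the +x- and -x-moving crossing filaments,
#' with velocities measured as unwrapped displacement over `averaging`
#' seconds. Windows missing either polarity group are dropped.
#'
#' @param trajectory An `fm_trajectory`.
#' @param plane_x Plane positions along x (um).
#' @param points Sample points in the plane: tibble/matrix with `y`, `z`;
#'   default: plane center plus four symmetric points at half the cylinder
#'   radius (requires a cylindrical boundary).
#' @param window Window edge length (um).
#' @param averaging Velocity averaging time (s).
#' @return Tibble with one row per (time, plane, point): `px_mean`, `vx`
#'   (um/s), and group sizes `n_plus`, `n_minus`.
#' @export
plane_straining_velocity <- function(trajectory, plane_x = NULL,
                                     points = NULL, window = 0.2,
                                     averaging = 10) {
  b <- trajectory$boundary
  per <- .period_vector(b)[1]
  if (is.null(plane_x)) {
    plane_x <- if (per > 0) seq(-per / 2, per / 2, length.out = 7)[-7]
               else stop("supply plane_x for aperiodic boundaries")
  }
  if (is.null(points)) {
    r2 <- if (b$kind == "cylinder_x") b$radius / 2 else window / 2
    points <- rbind(c(0, 0), c(r2, 0), c(-r2, 0), c(0, r2), c(0, -r2))
  }
  points <- as.matrix(points)
  td <- tidy(trajectory)
  times <- sort(unique(td$time))
  t0s <- times[times + averaging <= max(times) + 1e-9]
  out <- vector("list", 0)
  L <- trajectory$filaments$length
  for (t0 in t0s) {
    t1 <- times[which.min(abs(times - (t0 + averaging)))]
    d0 <- td[td$time == t0, ]
    d1 <- td[td$time == t1, ]
    vel <- (d1$xu - d0$xu) / (t1 - t0)
    for (xp in plane_x) {
      # arc coordinate where the centerline crosses the plane
      dx <- xp - d0$x
      if (per > 0) dx <- dx - per * round(dx / per)
      s <- ifelse(abs(d0$px) > 1e-12, dx / d0$px, Inf)
      hit0 <- abs(s) <= L / 2
      yc <- d0$y + s * d0$py
      zc <- d0$z + s * d0$pz
      for (k in seq_len(nrow(points))) {
        hit <- hit0 & abs(yc - points[k, 1]) <= window / 2 &
          abs(zc - points[k, 2]) <= window / 2
        if (!any(hit)) next
        vplus <- vel[hit & vel > 0]
        vminus <- vel[hit & vel < 0]
        if (length(vplus) == 0 || length(vminus) == 0) next
        out[[length(out) + 1]] <- tibble::tibble(
          time = t0, plane_x = xp, point = k,
          px_mean = mean(d0$px[hit]),
          vx = mean(vplus) - mean(vminus),
          n_plus = length(vplus), n_minus = length(vminus))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Windowed polarity field on a regular grid
#'
#' Assigns each filament center to a cubic cell of edge `spacing` and
#' averages directors per cell; also counts motors per cell.
#'
#' @param state A [system_state()].
#' @param spacing Cell edge (um).
#' @return Tibble `x, y, z` (cell centers), mean polarity `px, py, pz`,
#'   `n_fil`, `n_motor`.
#' @export
polarity_field <- function(state, spacing) {
  fil <- state$filaments
  p <- director(fil)
  cell <- function(v) floor(v / spacing)
  key <- paste(cell(fil$x), cell(fil$y), cell(fil$z))
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      key = key, cx = cell(fil$x), cy = cell(fil$y), cz = cell(fil$z),
      px = p$px, py = p$py, pz = p$pz), .data$key, .data$cx, .data$cy,
      .data$cz),
    px = mean(.data$px), py = mean(.data$py), pz = mean(.data$pz),
    n_fil = dplyr::n(), .groups = "drop")
  mpos <- .motor_positions(state)
  mkey <- paste(cell(mpos$x), cell(mpos$y), cell(mpos$z))
  cnt <- table(mkey)
  agg$n_motor <- as.integer(cnt[agg$key])
  agg$n_motor[is.na(agg$n_motor)] <- 0L
  tibble::tibble(
    x = (agg$cx + 0.5) * spacing, y = (agg$cy + 0.5) * spacing,
    z = (agg$cz + 0.5) * spacing,
    px = agg$px, py = agg$py, pz = agg$pz,
    n_fil = agg$n_fil, n_motor = agg$n_motor
  )
}

.motor_positions <- function(state) {
  m <- state$motors
  fil <- state$filaments
  p <- director(fil)
  pos <- cbind(m$x, m$y, m$z)
  bound_a <- !is.na(m$fil_a)
  pos[bound_a, 1] <- fil$x[m$fil_a[bound_a]] +
    m$s_a[bound_a] * p$px[m$fil_a[bound_a]]
  pos[bound_a, 2] <- fil$y[m$fil_a[bound_a]] +
    m$s_a[bound_a] * p$py[m$fil_a[bound_a]]
  pos[bound_a, 3] <- fil$z[m$fil_a[bound_a]] +
    m$s_a[bound_a] * p$pz[m$fil_a[bound_a]]
  only_b <- is.na(m$fil_a) & !is.na(m$fil_b)
  pos[only_b, 1] <- fil$x[m$fil_b[only_b]] +
    m$s_b[only_b] * p$px[m$fil_b[only_b]]
  pos[only_b, 2] <- fil$y[m$fil_b[only_b]] +
    m$s_b[only_b] * p$py[m$fil_b[only_b]]
  pos[only_b, 3] <- fil$z[m$fil_b[only_b]] +
    m$s_b[only_b] * p$pz[m$fil_b[only_b]]
  tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Divergence of a polarity field
#'
#' Central-difference divergence of the windowed mean polarity,
#' non-dimensionalized by the filament length: `L * div(p)`. Input must be
#' a complete regular grid (as from [polarity_field()] on a dense system or
#' any tibble with `x, y, z, px, py, pz` at spacing `spacing`); boundary
#' cells lacking a neighbor use one-sided differences.
#'
#' @param field Grid tibble with `x, y, z, px, py, pz`.
#' @param spacing Grid spacing (um).
#' @param length_scale Filament length L (um).
#' @return The field tibble with a `div_p` column added.
#' @export
polarity_divergence <- function(field, spacing, length_scale = 1) {
  # keys on half-integer multiples of the spacing must stay distinct
  key <- function(x, y, z) paste(round(2 * x / spacing),
                                 round(2 * y / spacing),
                                 round(2 * z / spacing))
  idx <- setNames(seq_len(nrow(field)), key(field$x, field$y, field$z))
  comp_deriv <- function(col, axis) {
    sh <- c(x = 0, y = 0, z = 0)
    vapply(seq_len(nrow(field)), function(i) {
      up <- sh; up[axis] <- spacing
      dn <- sh; dn[axis] <- -spacing
      iu <- idx[key(field$x[i] + up["x"], field$y[i] + up["y"],
                    field$z[i] + up["z"])]
      id <- idx[key(field$x[i] + dn["x"], field$y[i] + dn["y"],
                    field$z[i] + dn["z"])]
      if (!is.na(iu) && !is.na(id)) {
        (field[[col]][iu] - field[[col]][id]) / (2 * spacing)
      } else if (!is.na(iu)) {
        (field[[col]][iu] - field[[col]][i]) / spacing
      } else if (!is.na(id)) {
        (field[[col]][i] - field[[col]][id]) / spacing
      } else NA_real_
    }, 0)
  }
  field$div_p <- length_scale *
    (comp_deriv("px", "x") + comp_deriv("py", "y") + comp_deriv("pz", "z"))
  field
}
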