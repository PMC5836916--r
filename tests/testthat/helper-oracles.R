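# Independent oracles used across the test files.

# Brute-force distance from a point to the RBC membrane: direct
# minimization over the surface of every periodic image (dense surface
# seed, then local polish of the best candidate patch).
bf_membrane_distance <- function(cell, point) {
  r <- cell$cyl_diameter / 2
  hh <- cell$cyl_height / 2
  lx <- cell$cell_xy
  lz <- cell$cell_z
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  zs <- seq(-hh, hh, length.out = 41)
  rs <- seq(0, r, length.out = 41)
  lat <- cbind(rep(r * cos(th), length(zs)), rep(r * sin(th), length(zs)),
               rep(zs, each = length(th)))
  capg <- cbind(rep(rs, each = length(th)) * cos(th),
                rep(rs, each = length(th)) * sin(th), 0)
  surf <- rbind(lat,
                cbind(capg[, 1], capg[, 2], hh),
                cbind(capg[, 1], capg[, 2], -hh))
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    p <- point - c(ix * lx, iy * lx, iz * lz)
    d2 <- (surf[, 1] - p[1])^2 + (surf[, 2] - p[2])^2 + (surf[, 3] - p[3])^2
    th0 <- atan2(p[2], p[1])
    # polish by bounded minimization over each smooth surface patch
    lat_obj <- function(par)
      sum((c(r * cos(par[1]), r * sin(par[1]), par[2]) - p)^2)
    cap_obj <- function(par, zc)
      sum((c(par[2] * cos(par[1]), par[2] * sin(par[1]), zc) - p)^2)
    o1 <- stats::optim(c(th0, min(hh, max(-hh, p[3]))), lat_obj,
                       method = "L-BFGS-B",
                       lower = c(th0 - pi, -hh), upper = c(th0 + pi, hh),
                       control = list(factr = 1))
    o2 <- stats::optim(c(th0, min(r, sqrt(p[1]^2 + p[2]^2))),
                       cap_obj, zc = hh, method = "L-BFGS-B",
                       lower = c(th0 - pi, 0), upper = c(th0 + pi, r),
                       control = list(factr = 1))
    o3 <- stats::optim(c(th0, min(r, sqrt(p[1]^2 + p[2]^2))),
                       cap_obj, zc = -hh, method = "L-BFGS-B",
                       lower = c(th0 - pi, 0), upper = c(th0 + pi, r),
                       control = list(factr = 1))
    best <- min(best, sqrt(min(d2)), sqrt(o1$value), sqrt(o2$value),
                sqrt(o3$value))
  }
  best
}

# Independent b-value quadrature: build the effective waveform from the
# switch times, integrate q(t) numerically on a grid containing every
# switch time, then Simpson-integrate q^2 per subinterval.
bf_b_value <- function(profile, g = 1, gamma = 1, n_grid = 4096) {
  t <- profile$t
  grid <- sort(unique(c(seq(t[1], t[length(t)], length.out = n_grid), t)))
  gmid <- numeric(length(grid) - 1)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  for (k in seq_len(profile$K))
    gmid[mids > t[k] & mids < t[k + 1]] <- g * profile$signs[k]
  dtg <- diff(grid)
  qn <- c(0, cumsum(gmid * dtg))       # exact: G constant per subinterval
  qa <- qn[-length(qn)]
  qb <- qn[-1]
  qm <- qa + gmid * dtg / 2
  gamma^2 * sum(dtg / 6 * (qa^2 + 4 * qm^2 + qb^2))   # Simpson, exact for q^2
}

# Minimal walk_record wrapper around hand-built center-of-mass arrays,
# for testing the phase computation on analytic trajectories.
fake_record <- function(x_cm_list, profiles) {
  structure(list(
    x_cm = x_cm_list, profiles = profiles,
    dt = NA, ds_p = NA, ds_e = NA, n_steps = NA,
    n_particles = dim(x_cm_list[[1]])[1], TE = profiles[[1]]$TE
  ), class = "walk_record")
}

# Reference cell constants shared by several files
ref_cell <- function() build_unit_cell(0.43, 87.7)
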