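#' Build the periodic blood unit cell
#'
#' Constructs the periodic cuboid unit cell containing a single centered
#' red blood cell (RBC), modelled as an oblate cylinder of reference
#' diameter 8.00 um and height 1.75 um, scaled isotropically so that its
#' volume equals the mean corpuscular volume `mcv`. The cuboid is sized so
#' that the RBC volume fraction equals the hematocrit `hct`, with the same
#' plasma gap `g` along all three axes: `(d + g)^2 * (h + g) = mcv / hct`.
#'
#' The coordinate frame is cell-centered: origin at the cylinder centroid,
#' cylinder axis along z, periodic wrapping into `[-L/2, L/2)` per axis.
#' All lengths are in micrometers.
#'
#' @param hct Hematocrit, the RBC volume fraction, in (0, 1).
#' @param mcv Mean corpuscular volume in fL (= um^3).
#' @param membrane Logical; `FALSE` builds a membrane-free control cell with
#'   identical dimensions in which the whole volume behaves as plasma.
#' @return An object of class `blood_unit_cell`: a list with fields `hct`,
#'   `mcv`, `cyl_diameter`, `cyl_height`, `cell_xy`, `cell_z`, `gap`,
#'   `surface_to_volume` (of the scaled RBC, in 1/um) and `membrane`.
#' @examples
#' cell <- build_unit_cell(hct = 0.43, mcv = 87.7)
#' cell$gap                 # ~0.857 um shortest plasma gap
#' cell$surface_to_volume   # ~1.64 1/um
#' @export
build_unit_cell <- function(hct, mcv, membrane = TRUE) {
  if (!is.numeric(hct) || length(hct) != 1L || !is.finite(hct) ||
      hct <= 0 || hct >= 1)
    stop("'hct' must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(mcv) || length(mcv) != 1L || !is.finite(mcv) || mcv <= 0)
    stop("'mcv' must be a single positive number (fL)", call. = FALSE)

  ref_d <- 8.00
  ref_h <- 1.75
  v_ref <- pi * (ref_d / 2)^2 * ref_h
  s <- (mcv / v_ref)^(1 / 3)
  d <- ref_d * s
  h <- ref_h * s

  # equal-gap cubic: (d+g)^2 (h+g) = mcv/hct, one sign change => unique
  # positive root
  target <- mcv / hct
  fg <- function(g) (d + g)^2 * (h + g) - target
  if (fg(0) >= 0)
    stop(sprintf(paste0("no positive plasma gap exists: hct = %.3f exceeds ",
                        "the packing limit pi/4 ~ 0.785 of the equal-gap ",
                        "cylinder-in-cuboid construction"), hct),
         call. = FALSE)
  upper <- max(2, (target)^(1 / 3)) * 2
  while (fg(upper) < 0) upper <- upper * 2
  root <- stats::uniroot(fg, c(0, upper), tol = 1e-14)
  g <- refine_gap(d, h, target, root$root)
  if (!is.finite(g) || g <= 0)
    stop("no positive real gap solves the unit-cell volume constraint",
         call. = FALSE)

  surf <- 2 * pi * (d / 2)^2 + pi * d * h
  structure(list(
    hct = hct,
    mcv = mcv,
    cyl_diameter = d,
    cyl_height = h,
    cell_xy = d + g,
    cell_z = h + g,
    gap = g,
    surface_to_volume = surf / mcv,
    membrane = isTRUE(membrane)
  ), class = "blood_unit_cell")
}

# Newton polish of the gap root to full double precision
refine_gap <- function(d, h, target, g) {
  for (i in 1:6) {
    f <- (d + g)^2 * (h + g) - target
    fp <- 2 * (d + g) * (h + g) + (d + g)^2
    g <- g - f / fp
  }
  g
}

#' @export
print.blood_unit_cell <- function(x, ...) {
  cat("Periodic blood unit cell (oblate-cylinder RBC)\n")
  cat(sprintf("  HCT %.3f, MCV %.1f fL%s\n", x$hct, x$mcv,
              if (x$membrane) "" else "  [membrane-free control]"))
  cat(sprintf("  cylinder d x h: %.4f x %.4f um\n",
              x$cyl_diameter, x$cyl_height))
  cat(sprintf("  cuboid: %.4f x %.4f x %.4f um, gap %.4f um\n",
              x$cell_xy, x$cell_xy, x$cell_z, x$gap))
  cat(sprintf("  RBC surface-to-volume: %.4f 1/um\n", x$surface_to_volume))
  invisible(x)
}

#' Compartment membership of a point
#'
#' Determines whether a point (after periodic wrapping into the primary
#' cell) lies inside the RBC cylinder or in plasma. Membrane-free control
#' cells report `"plasma"` everywhere.
#'
#' @param cell A [build_unit_cell()] object.
#' @param point Numeric 3-vector (um) or an n x 3 matrix of points.
#' @return Character vector, `"erythrocyte"` or `"plasma"` per point.
#' @export
locate <- function(cell, point) {
  p <- as_points(point)
  if (!cell$membrane) return(rep("plasma", nrow(p)))
  w <- wrap_points(p, cell)
  r2 <- (cell$cyl_diameter / 2)^2
  inside <- (w[, 1]^2 + w[, 2]^2 <= r2) & (abs(w[, 3]) <= cell$cyl_height / 2)
  ifelse(inside, "erythrocyte", "plasma")
}

#' Shortest distance to the RBC membrane
#'
#' Shortest Euclidean distance from a point to the surface of the RBC
#' cylinder, taking the nearest periodic image into account. Zero if and
#' only if the point lies on the membrane.
#'
#' @param cell A [build_unit_cell()] object.
#' @param point Numeric 3-vector (um) or an n x 3 matrix of points.
#' @return Numeric vector of nonnegative distances (um).
#' @export
distance_to_membrane <- function(cell, point) {
  p <- as_points(point)
  w <- wrap_points(p, cell)
  r <- cell$cyl_diameter / 2
  hh <- cell$cyl_height / 2
  lx <- cell$cell_xy
  lz <- cell$cell_z
  out <- rep(Inf, nrow(w))
  # the wrapped point is nearest to the primary image or one of its 26
  # neighbors; scan all
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    x <- w[, 1] - ix * lx
    y <- w[, 2] - iy * lx
    z <- w[, 3] - iz * lz
    out <- pmin(out, cylinder_surface_distance(x, y, z, r, hh))
  }
  out
}

# distance from (x,y,z) to the surface of a finite cylinder centered at the
# origin, axis z, radius r, half-height hh
cylinder_surface_distance <- function(x, y, z, r, hh) {
  rho <- sqrt(x^2 + y^2)
  drho <- rho - r
  dz <- abs(z) - hh
  outside_both <- drho > 0 & dz > 0
  d <- numeric(length(x))
  d[outside_both] <- sqrt(drho[outside_both]^2 + dz[outside_both]^2)
  lat <- drho > 0 & dz <= 0
  d[lat] <- drho[lat]
  cap <- drho <= 0 & dz > 0
  d[cap] <- dz[cap]
  ins <- drho <= 0 & dz <= 0
  d[ins] <- pmin(-drho[ins], -dz[ins])
  d
}

as_points <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3)
    storage.mode(point) <- "double"
    point
  } else {
    stopifnot(length(point) == 3)
    matrix(as.double(point), nrow = 1)
  }
}

wrap_points <- function(p, cell) {
  l <- c(cell$cell_xy, cell$cell_xy, cell$cell_z)
  for (j in 1:3) p[, j] <- p[, j] - l[j] * floor(p[, j] / l[j] + 0.5)
  p
}

#' Fraction of blood water residing in erythrocytes
#'
#' With free-water concentrations `c_p` (plasma) and `c_e` (erythrocyte),
#' the fraction of all blood water inside RBCs is
#' `f = c_e * hct / (c_e * hct + c_p * (1 - hct))`.
#'
#' @param hct Hematocrit in \[0, 1\].
#' @param c_p,c_e Free-water concentrations (dimensionless volume
#'   fractions), both positive.
#' @return Intracellular water fraction `f` in \[0, 1\].
#' @examples
#' intracellular_water_fraction(0.43, 0.95, 0.70)  # ~0.357
#' @export
intracellular_water_fraction <- function(hct, c_p = 0.95, c_e = 0.70) {
  stopifnot(all(hct >= 0 & hct <= 1), c_p > 0, c_e > 0)
  c_e * hct / (c_e * hct + c_p * (1 - hct))
}

#' Membrane permeability from the intracellular pre-exchange lifetime
#'
#' The mean residence time `tau_e` of a water molecule inside the RBC sets
#' the membrane permeability seen from inside, `kappa_e = (V/S) / tau_e`,
#' with `S/V` the surface-to-volume ratio of the RBC. Stationary
#' compartment concentrations then require
#' `kappa_p = kappa_e * c_e / c_p` for the plasma side.
#'
#' @param cell A [build_unit_cell()] object (provides `S/V` of the RBC).
#' @param tau_e Intracellular pre-exchange lifetime in ms, positive.
#' @param c_p,c_e Free-water concentrations.
#' @return List with `kappa_e` and `kappa_p` in um/ms.
#' @export
permeability_from_lifetime <- function(cell, tau_e, c_p = 0.95, c_e = 0.70) {
  if (!is.numeric(tau_e) || length(tau_e) != 1L || !is.finite(tau_e) ||
      tau_e <= 0)
    stop("'tau_e' must be a single positive number (ms)", call. = FALSE)
  kappa_e <- (1 / cell$surface_to_volume) / tau_e
  list(kappa_e = kappa_e, kappa_p = kappa_e * c_e / c_p)
}

#' Bundle compartment parameters
#'
#' Collects the diffusivities, water concentrations and exchange
#' parameters of the two-compartment blood model and derives the membrane
#' permeabilities and the intracellular water fraction for a given cell.
#' Defaults are the model's literature values: plasma diffusivity
#' `D_p = 2.75 um^2/ms` and erythrocyte diffusivity `D_e = 1.00 um^2/ms`
#' at 37 degrees C, concentrations `c_p = 0.95`, `c_e = 0.70`, and
#' pre-exchange lifetime `tau_e = 12 ms`.
#'
#' @param cell A [build_unit_cell()] object.
#' @param D_p,D_e Compartment diffusivities in um^2/ms.
#' @param c_p,c_e Free-water concentrations.
#' @param tau_e Intracellular pre-exchange lifetime in ms.
#' @return An object of class `compartment_params` with fields `D_p`,
#'   `D_e`, `c_p`, `c_e`, `tau_e`, `kappa_e`, `kappa_p`, `f`.
#' @export
compartment_params <- function(cell, D_p = 2.75, D_e = 1.00,
                               c_p = 0.95, c_e = 0.70, tau_e = 12) {
  stopifnot(D_p > 0, D_e > 0, c_p > 0, c_e > 0)
  k <- permeability_from_lifetime(cell, tau_e, c_p, c_e)
  structure(list(
    D_p = D_p, D_e = D_e, c_p = c_p, c_e = c_e, tau_e = tau_e,
    kappa_e = k$kappa_e, kappa_p = k$kappa_p,
    f = intracellular_water_fraction(cell$hct, c_p, c_e)
  ), class = "compartment_params")
}

#' @export
print.compartment_params <- function(x, ...) {
  cat("Two-compartment blood parameters\n")
  cat(sprintf("  D_p %.3f, D_e %.3f um^2/ms; c_p %.2f, c_e %.2f\n",
              x$D_p, x$D_e, x$c_p, x$c_e))
  cat(sprintf("  tau_e %.1f ms -> kappa_e %.4f, kappa_p %.4f um/ms\n",
              x$tau_e, x$kappa_e, x$kappa_p))
  cat(sprintf("  intracellular water fraction f = %.4f\n", x$f))
  invisible(x)
}
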