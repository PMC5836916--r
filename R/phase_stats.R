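#' Random directions for isotropic diffusion weighting
#'
#' Draws `n` unit vectors uniformly on the sphere (normalized Gaussian
#' triples). Directions are shared across particles so that ensemble
#' statistics average coherently.
#'
#' @param n Number of directions.
#' @param seed Optional integer seed.
#' @return n x 3 matrix of unit vectors.
#' @export
isotropic_directions <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Diffusion-encoded phases from a walk record
#'
#' For each particle, the accumulated phase under a piecewise-constant
#' effective gradient of amplitude `g` along direction `u` is
#' `phi = gamma * g * sum_k dt_k * (-1)^k * (x_cm_k . u)`. Since `phi` is
#' proportional to `g` and hence to `sqrt(b)`, the ensemble is stored in
#' normalized form `phi' = phi / sqrt(b)`, which is independent of the
#' b-value used to set the amplitude.
#'
#' The ensemble is kept factorized: the per-particle encoded displacement
#' moment `w_i = sum_k dt_k (-1)^k x_cm_k` (n x 3) and the direction set,
#' with `phi'_(i,d) = (w_i . u_d) / sqrt(a T^3)` where `a` is the
#' profile's dimensionless b coefficient.
#'
#' @param record A [simulate_walk()] record.
#' @param profile One of the profiles the record was accumulated against
#'   (index or `sequence_profile` object).
#' @param directions Direction matrix from [isotropic_directions()].
#' @param b_s_mm2 b-value in s/mm^2 at which signals are evaluated
#'   (default 400).
#' @return Object of class `phase_ensemble` with fields `w`, `directions`,
#'   `scale` (phi' per unit projection), `b` (ms/um^2), `profile`.
#' @export
phases <- function(record, profile, directions, b_s_mm2 = 400) {
  stopifnot(inherits(record, "walk_record"))
  if (is.numeric(profile) && length(profile) == 1L) {
    idx <- as.integer(profile)
    if (idx < 1L || idx > length(record$profiles))
      stop("profile index out of range", call. = FALSE)
    profile <- record$profiles[[idx]]
  } else {
    idx <- match_profile(record, profile)
  }
  xcm <- record$x_cm[[idx]]
  K <- dim(xcm)[2]
  if (K != profile$K)
    stop("record interval grid does not match this profile", call. = FALSE)
  w <- matrix(0, nrow = dim(xcm)[1], ncol = 3)
  for (k in seq_len(K))
    w <- w + profile$dt[k] * profile$signs[k] * xcm[, k, ]
  a <- b_coefficient(profile)
  structure(list(
    w = w,
    directions = as_points(directions),
    scale = 1 / sqrt(a * profile$T^3),
    b = b_s_mm2 * 1e-3,
    profile = profile
  ), class = "phase_ensemble")
}

match_profile <- function(record, profile) {
  stopifnot(inherits(profile, "sequence_profile"))
  for (i in seq_along(record$profiles)) {
    p <- record$profiles[[i]]
    if (p$kind == profile$kind && isTRUE(all.equal(p$t, profile$t)))
      return(i)
  }
  stop("record was not accumulated against this profile's interval grid",
       call. = FALSE)
}

#' Normalized phase matrix of an ensemble
#'
#' Materializes `phi'` as an `n_particles x n_directions` matrix, in
#' units of `(ms/um^2)^(-1/2)`.
#' @param ensemble A [phases()] object.
#' @return Numeric matrix.
#' @export
phase_matrix <- function(ensemble) {
  ensemble$scale * (ensemble$w %*% t(ensemble$directions))
}

#' ADC and apparent kurtosis from a phase ensemble
#'
#' From the normalized phase distribution `phi'` the estimators are:
#' `ADC_b = -(1/b) log |< exp(i phi' sqrt(b)) >|` (the ADC a two-point
#' measurement at b and b = 0 would yield), the small-b limit
#' `ADC_0 = <phi'^2> / 2` (Gaussian phase approximation), and the
#' apparent excess kurtosis `K_app = <phi'^4> / <phi'^2>^2 - 3`. The
#' complex signal is averaged over particles and directions jointly;
#' standard errors come from a percentile bootstrap over particles only
#' (directions are a variance-reduction device, not independent samples).
#'
#' @param ensemble A [phases()] object (or a numeric matrix/vector of
#'   normalized phases, in which case `b` must be given).
#' @param b b-value in ms/um^2; defaults to the ensemble's.
#' @param n_boot Bootstrap resamples (default 200).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param chunk Directions processed per block (memory control).
#' @return Object of class `diffusion_stats`: list with `adc_b`, `adc_0`,
#'   `k_app`, raw moments `m2`, `m4`, `m6`, standard errors `se_adc_b`,
#'   `se_adc_0`, `se_k_app`, `b`, `n_particles`, `n_directions`.
#' @export
adc_from_phases <- function(ensemble, b = NULL, n_boot = 200,
                            boot_seed = 1L, chunk = 2000L) {
  if (is.numeric(ensemble)) {
    phi <- if (is.matrix(ensemble)) ensemble else matrix(ensemble, ncol = 1)
    if (is.null(b)) stop("'b' required for a raw phase matrix", call. = FALSE)
    nd <- ncol(phi)
    s2 <- rowSums(phi^2)
    s4 <- rowSums(phi^4)
    s6 <- rowSums(phi^6)
    cr <- rowSums(cos(phi * sqrt(b)))
    ci <- rowSums(sin(phi * sqrt(b)))
  } else {
    stopifnot(inherits(ensemble, "phase_ensemble"))
    if (is.null(b)) b <- ensemble$b
    n <- nrow(ensemble$w)
    nd <- nrow(ensemble$directions)
    s2 <- s4 <- s6 <- cr <- ci <- numeric(n)
    sqb <- sqrt(b)
    for (j0 in seq(1L, nd, by = chunk)) {
      j1 <- min(nd, j0 + chunk - 1L)
      phi <- ensemble$scale *
        (ensemble$w %*% t(ensemble$directions[j0:j1, , drop = FALSE]))
      s2 <- s2 + rowSums(phi^2)
      s4 <- s4 + rowSums(phi^4)
      s6 <- s6 + rowSums(phi^6)
      cr <- cr + rowSums(cos(phi * sqb))
      ci <- ci + rowSums(sin(phi * sqb))
    }
  }
  n <- length(s2)
  if (n < 2) stop("need at least 2 phase samples", call. = FALSE)
  stat <- function(idx) {
    m2 <- sum(s2[idx]) / (length(idx) * nd)
    m4 <- sum(s4[idx]) / (length(idx) * nd)
    sig <- sqrt(sum(cr[idx])^2 + sum(ci[idx])^2) / (length(idx) * nd)
    if (sig <= 0) stop("signal magnitude vanished; ADC_b undefined",
                       call. = FALSE)
    c(adc_b = -log(sig) / b, adc_0 = m2 / 2, k_app = m4 / m2^2 - 3)
  }
  est <- stat(seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(boot_seed)
  bt <- vapply(seq_len(n_boot),
               function(i) stat(sample.int(n, n, replace = TRUE)),
               numeric(3))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  se <- apply(bt, 1, stats::sd)
  structure(list(
    adc_b = unname(est["adc_b"]), adc_0 = unname(est["adc_0"]),
    k_app = unname(est["k_app"]),
    m2 = sum(s2) / (n * nd), m4 = sum(s4) / (n * nd),
    m6 = sum(s6) / (n * nd),
    se_adc_b = unname(se[1]), se_adc_0 = unname(se[2]),
    se_k_app = unname(se[3]),
    b = b, n_particles = n, n_directions = nd, n_boot = n_boot
  ), class = "diffusion_stats")
}

#' @export
print.diffusion_stats <- function(x, ...) {
  cat(sprintf("Diffusion statistics at b = %g ms/um^2 (%d particles x %d directions)\n",
              x$b, x$n_particles, x$n_directions))
  cat(sprintf("  ADC_b  = %.4f +/- %.4f um^2/ms\n", x$adc_b, x$se_adc_b))
  cat(sprintf("  ADC_0  = %.4f +/- %.4f um^2/ms\n", x$adc_0, x$se_adc_0))
  cat(sprintf("  K_app  = %.4f +/- %.4f\n", x$k_app, x$se_k_app))
  invisible(x)
}

#' Consistency of ADC_b with the kurtosis expansion
#'
#' The cumulant expansion links the estimators as
#' `ADC_b = ADC_0 - (b/6) ADC_0^2 K_app + O(b^2)`. Returns the absolute
#' residual of this relation together with the magnitude of the next
#' (b^2) term estimated from the sixth moment of the same ensemble
#' (`b^2 kappa_6' / 720`, with `kappa_6' = m6 - 15 m4 m2 + 30 m2^3` for a
#' symmetric distribution).
#'
#' @param stats A [adc_from_phases()] object.
#' @param b b-value in ms/um^2; defaults to the one in `stats`.
#' @return List with `residual` and `b2_scale`.
#' @export
kurtosis_expansion_check <- function(stats, b = NULL) {
  stopifnot(inherits(stats, "diffusion_stats"))
  if (is.null(b)) b <- stats$b
  resid <- abs(stats$adc_b -
               (stats$adc_0 - (b / 6) * stats$adc_0^2 * stats$k_app))
  k6 <- stats$m6 - 15 * stats$m4 * stats$m2 + 30 * stats$m2^3
  list(residual = resid, b2_scale = abs(b^2 * k6 / 720))
}

#' Hematocrit / diffusion-time / profile sweep
#'
#' Runs the full simulation chain over a grid of hematocrit values and
#' diffusion times for both gradient profiles, at fixed TE, and returns
#' one row of diffusion statistics per condition. One trajectory set per
#' hematocrit serves every (profile, T) combination: the walker
#' accumulates interval centers of mass against all requested grids in a
#' single pass.
#'
#' @param hct Vector of hematocrit values.
#' @param T_mp,T_fc Diffusion times (ms) for the MP and FC profiles.
#' @param mcv Mean corpuscular volume (fL).
#' @param TE_ms Echo time / simulated duration (ms).
#' @param b_s_mm2 b-value in s/mm^2.
#' @param n_particles Trajectories per hematocrit.
#' @param step_fraction Plasma step length as a fraction of the gap.
#' @param n_directions Diffusion-encoding directions.
#' @param seed Base seed; hematocrit index and direction sampling derive
#'   sub-seeds deterministically.
#' @param params_fn Function `cell -> compartment_params`, by default the
#'   literature defaults.
#' @param verbose Print progress lines.
#' @return Data frame with columns `profile`, `hct`, `T_ms`, `TE_ms`,
#'   `b_s_mm2`, `adc_b`, `adc_0`, `k_app`, `se_adc_b`, `se_adc_0`,
#'   `se_k_app`.
#' @export
adc_sweep <- function(hct = c(0.36, 0.43, 0.47),
                      T_mp = c(40, 100), T_fc = c(70, 100),
                      mcv = 87.7, TE_ms = 120, b_s_mm2 = 400,
                      n_particles = 2500, step_fraction = 0.05,
                      n_directions = 4000, seed = 1L,
                      params_fn = compartment_params,
                      verbose = FALSE) {
  dirs <- isotropic_directions(n_directions, seed = seed)
  grid <- rbind(
    if (length(T_mp)) data.frame(kind = "MP", T = T_mp),
    if (length(T_fc)) data.frame(kind = "FC", T = T_fc)
  )
  profiles <- lapply(seq_len(nrow(grid)), function(i)
    switch_times(grid$kind[i], grid$T[i], TE_ms))
  out <- list()
  for (i in seq_along(hct)) {
    cell <- build_unit_cell(hct[i], mcv)
    params <- params_fn(cell)
    if (verbose)
      message(sprintf("HCT %.2f: %d particles, %d profiles ...",
                      hct[i], n_particles, length(profiles)))
    rec <- simulate_walk(cell, params, profiles,
                         n_particles = n_particles, TE_ms = TE_ms,
                         step_fraction = step_fraction,
                         seed = seed + 104729 * i)
    for (j in seq_along(profiles)) {
      ens <- phases(rec, j, dirs, b_s_mm2 = b_s_mm2)
      st <- adc_from_phases(ens, boot_seed = seed + j)
      out[[length(out) + 1L]] <- data.frame(
        profile = grid$kind[j], hct = hct[i], T_ms = grid$T[j],
        TE_ms = TE_ms, b_s_mm2 = b_s_mm2,
        adc_b = st$adc_b, adc_0 = st$adc_0, k_app = st$k_app,
        se_adc_b = st$se_adc_b, se_adc_0 = st$se_adc_0,
        se_k_app = st$se_k_app
      )
    }
  }
  do.call(rbind, out)
}
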