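#' Effective diffusion-gradient switch times
#'
#' Builds a `sequence_profile` describing the effective (post-refocusing
#' sign-flipped) diffusion-gradient waveform of a spin-echo sequence with a
#' diffusion-weighting block of duration `T` centered on `TE/2`.
#'
#' Monopolar (MP) encoding has two intervals of constant gradient with
#' switch times `t_k = TE/2 + (k - 1) * T/2`, k = 0..2. Flow-compensated
#' (FC) encoding has four intervals with
#' `t_k = TE/2 + (T/4) * sgn(k - 2) * sqrt(2)^abs(k - 2)`, k = 0..4
#' (`sgn(0) = 0`, so the middle switch sits at the refocusing pulse). The
#' FC interval pattern `(T(2-sqrt(2))/4, sqrt(2)T/4, sqrt(2)T/4,
#' T(2-sqrt(2))/4)` nulls both the zeroth and the first moment of the
#' effective waveform, removing phase from constant velocity.
#'
#' @param kind `"MP"` or `"FC"`.
#' @param T_ms Duration of the diffusion-weighting block in ms.
#' @param TE_ms Echo time in ms; must satisfy `TE >= T` so the waveform,
#'   symmetric about `TE/2`, fits before the echo.
#' @return Object of class `sequence_profile`: list with `kind`, `TE`,
#'   `T`, `t` (switch times, ms), `dt` (interval durations), `signs`
#'   (`(-1)^k`, k = 1..K), `K`.
#' @examples
#' switch_times("MP", T_ms = 40, TE_ms = 120)$t  # 40 60 80
#' @export
switch_times <- function(kind = c("MP", "FC"), T_ms, TE_ms) {
  kind <- match.arg(toupper(kind), c("MP", "FC"))
  stopifnot(is.numeric(T_ms), length(T_ms) == 1L, T_ms > 0,
            is.numeric(TE_ms), length(TE_ms) == 1L)
  if (TE_ms < T_ms)
    stop("TE must be >= T: the diffusion block is symmetric about TE/2",
         call. = FALSE)
  mid <- TE_ms / 2
  if (kind == "MP") {
    k <- 0:2
    t <- mid + (k - 1) * T_ms / 2
  } else {
    k <- 0:4
    t <- mid + (T_ms / 4) * sign(k - 2) * sqrt(2)^abs(k - 2)
  }
  K <- length(t) - 1L
  structure(list(
    kind = kind, TE = TE_ms, T = T_ms,
    t = t, dt = diff(t), signs = (-1)^seq_len(K), K = K
  ), class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("%s diffusion-gradient profile: T = %g ms, TE = %g ms\n",
              x$kind, x$T, x$TE))
  cat("  switch times (ms):", paste(signif(x$t, 6), collapse = ", "), "\n")
  cat("  interval signs:", paste(ifelse(x$signs > 0, "+", "-"),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Numeric b-value of a profile
#'
#' Computes `b = gamma^2 * integral q(t)^2 dt` where `q(t)` is the running
#' integral of the effective gradient waveform with amplitude `g`. The
#' waveform is piecewise constant, so `q` is piecewise linear and the
#' integral is evaluated in closed form per segment. The result equals
#' `a * gamma^2 * g^2 * T^3` with a dimensionless coefficient `a` that
#' depends only on the profile kind: `a = 1/12` for MP and
#' `a = sqrt(2)/8 - 1/6 ~ 0.010110` for FC.
#'
#' Internal units are um/ms: `gamma` in rad/(ms T), `g` in T/um, giving
#' `b` in ms/um^2 (multiply by 1000 for s/mm^2).
#'
#' @param profile A [switch_times()] object.
#' @param g Gradient amplitude (T/um), nonnegative.
#' @param gamma Gyromagnetic ratio in rad/(ms T); proton default.
#' @return b-value in ms/um^2.
#' @export
b_value_numeric <- function(profile, g, gamma = gamma_proton()) {
  stopifnot(inherits(profile, "sequence_profile"), g >= 0)
  # q at segment ends: cumulative sum of sign * duration
  qk <- c(0, cumsum(profile$signs * profile$dt))
  acc <- sum(profile$dt * (qk[-length(qk)]^2 +
                           qk[-length(qk)] * qk[-1] + qk[-1]^2) / 3)
  gamma^2 * g^2 * acc
}

#' Dimensionless b-value coefficient of a profile kind
#'
#' @param profile A [switch_times()] object.
#' @return `a = b / (gamma^2 g^2 T^3)`.
#' @export
b_coefficient <- function(profile) {
  b_value_numeric(profile, g = 1, gamma = 1) / profile$T^3
}

#' Gradient amplitude producing a target b-value
#'
#' Inverts [b_value_numeric()]: since `b` scales as `g^2`, the amplitude
#' is `g = sqrt(b / (a gamma^2 T^3))`.
#'
#' @param profile A [switch_times()] object.
#' @param b_s_mm2 Target b-value in s/mm^2 (converted internally by 1e-3
#'   to ms/um^2), nonnegative.
#' @param gamma Gyromagnetic ratio in rad/(ms T).
#' @return Gradient amplitude `g` in T/um.
#' @export
amplitude_for_b <- function(profile, b_s_mm2, gamma = gamma_proton()) {
  stopifnot(b_s_mm2 >= 0)
  b <- b_s_mm2 * 1e-3
  sqrt(b / (b_coefficient(profile) * gamma^2 * profile$T^3))
}

#' Zeroth and first moments of the effective waveform
#'
#' `M0 = integral G_eff dt` and `M1 = integral (t - TE/2) G_eff dt`,
#' taken about the waveform midpoint. Spin-echo refocusing forces `M0 = 0`
#' for both kinds; the FC profile additionally nulls `M1` (flow
#' compensation), while MP retains `|M1| = g T^2 / 4` (its sign follows
#' the `(-1)^k` interval polarity, whose first interval is negative).
#'
#' @param profile A [switch_times()] object.
#' @param g Gradient amplitude (default 1).
#' @return List with `M0` and `M1`.
#' @export
gradient_moments <- function(profile, g = 1) {
  t0 <- profile$t[-length(profile$t)]
  t1 <- profile$t[-1]
  mid <- profile$TE / 2
  m0 <- sum(profile$signs * (t1 - t0)) * g
  m1 <- sum(profile$signs * ((t1 - mid)^2 - (t0 - mid)^2) / 2) * g
  list(M0 = m0, M1 = m1)
}

#' Proton gyromagnetic ratio
#'
#' 2.6752218744e8 rad/(s T) expressed in the package's internal ms time
#' base, i.e. 2.6752218744e5 rad/(ms T).
#' @return Numeric scalar.
#' @export
gamma_proton <- function() 2.6752218744e5

#' Piecewise-constant segment table of a profile
#'
#' @param profile A [switch_times()] object.
#' @param g Gradient amplitude.
#' @return Data frame with columns `t_start`, `t_end`, `sign`,
#'   `amplitude`.
#' @export
profile_segments <- function(profile, g = 1) {
  data.frame(
    t_start = profile$t[-length(profile$t)],
    t_end = profile$t[-1],
    sign = profile$signs,
    amplitude = g * profile$signs
  )
}
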