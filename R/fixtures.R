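#' Specification for a synthetic diffusion-signal table
#'
#' Describes the acquisition a [generate_signals()] table emulates: a
#' three-b-value (0, 50, 400 s/mm^2), six-direction, spin-echo protocol
#' with sum-of-squares multi-channel magnitude reconstruction. The noise
#' model operates at the channel level: each accessible channel receives
#' the attenuated signal scaled by its gain plus complex Gaussian noise
#' of total variance `sigma^2` per channel (so the sum-of-squares noise
#' floor is `n_channels * sigma^2`). The default gain pattern mirrors a
#' head coil whose lower elements return roughly half the signal of the
#' upper ones; gains are normalized so the noiseless magnitude equals the
#' ideal signal.
#'
#' @param adc True ADC(s) in um^2/ms: either a single number or a data
#'   frame with columns `profile`, `T_ms`, `adc`.
#' @param t2 True T2 in ms.
#' @param s0 Ideal signal at b = 0, TE = 0.
#' @param sigma Per-channel noise RMS (same units as `s0`).
#' @param gains Relative channel gains (default 3 upper at 1, 3 lower at
#'   0.5, then normalized to unit sum of squares).
#' @param b_s_mm2 b-values acquired.
#' @param n_directions Diffusion directions per nonzero b.
#' @param n_b0 Repeats of the unweighted scan.
#' @param TE_ms,T_grid Echo times and diffusion times of the grid; `T_grid`
#'   is a data frame with columns `profile`, `T_ms` (default: the MP and
#'   FC minimum diffusion times 40 and 70 ms).
#' @return List of class `signal_fixture_spec`.
#' @export
signal_fixture_spec <- function(adc = 1.30, t2 = 120, s0 = 100,
                                sigma = 1, gains = c(1, 1, 1, 0.5, 0.5, 0.5),
                                b_s_mm2 = c(0, 50, 400),
                                n_directions = 6, n_b0 = 2,
                                TE_ms = 120,
                                T_grid = data.frame(
                                  profile = c("MP", "FC"),
                                  T_ms = c(40, 70))) {
  stopifnot(all(gains >= 0), length(gains) >= 1, sigma >= 0, s0 > 0, t2 > 0,
            length(b_s_mm2) >= 1, nrow(T_grid) >= 1)
  structure(list(adc = adc, t2 = t2, s0 = s0, sigma = sigma,
                 gains = gains / sqrt(sum(gains^2)),
                 b_s_mm2 = b_s_mm2, n_directions = n_directions,
                 n_b0 = n_b0, TE_ms = TE_ms, T_grid = T_grid),
            class = "signal_fixture_spec")
}

true_adc_for <- function(spec, profile, T_ms) {
  if (is.data.frame(spec$adc)) {
    hit <- spec$adc$profile == profile & spec$adc$T_ms == T_ms
    if (!any(hit)) stop("no true ADC declared for this (profile, T)",
                        call. = FALSE)
    spec$adc$adc[hit][1]
  } else spec$adc
}

#' Generate a synthetic multi-channel diffusion-signal table
#'
#' For every row of the acquisition grid the noiseless complex channel
#' signals `gain_ch * S0 * exp(-b * ADC - TE/T2)` receive i.i.d. complex
#' Gaussian noise (per-channel variance `sigma^2`, i.e. `sigma/sqrt(2)`
#' per real component) and are combined by sum-of-squares magnitude. The
#' exact ground truth is attached as attribute `"truth"`, so recovery
#' tests never rely on hidden state.
#'
#' @param spec A [signal_fixture_spec()].
#' @param sample_id Label written into the `sample_id` column.
#' @param seed Integer seed; identical seed and spec give identical
#'   tables.
#' @return Data frame with columns `sample_id`, `profile`, `TE_ms`,
#'   `T_ms`, `b_s_mm2`, `direction`, `rep`, `S_m`, `sigma`; attribute
#'   `"truth"` holds the spec's ground-truth parameters.
#' @export
generate_signals <- function(spec, sample_id = "S1", seed = 1L) {
  stopifnot(inherits(spec, "signal_fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(spec$T_grid))) {
    prof <- spec$T_grid$profile[i]
    T_ms <- spec$T_grid$T_ms[i]
    adc <- true_adc_for(spec, prof, T_ms)
    for (te in spec$TE_ms) {
      for (b in spec$b_s_mm2) {
        dirs <- if (b == 0) 0L else seq_len(spec$n_directions)
        reps <- if (b == 0) seq_len(spec$n_b0) else 1L
        for (rp in reps) for (dn in dirs) {
          s_true <- spec$s0 * exp(-b * 1e-3 * adc - te / spec$t2)
          ch <- spec$gains * s_true +
            complex(real = stats::rnorm(length(spec$gains),
                                        sd = spec$sigma / sqrt(2)),
                    imaginary = stats::rnorm(length(spec$gains),
                                             sd = spec$sigma / sqrt(2)))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, profile = prof, TE_ms = te, T_ms = T_ms,
            b_s_mm2 = b, direction = dn, rep = rp,
            S_m = sqrt(sum(Mod(ch)^2)), sigma = spec$sigma)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(adc = spec$adc, t2 = spec$t2, s0 = spec$s0,
                             sigma = spec$sigma, gains = spec$gains,
                             n_channels = length(spec$gains),
                             noise_floor_factor = length(spec$gains),
                             seed = seed)
  out
}

#' Named reference unit cells
#'
#' Canned geometries used throughout the tests: the reference blood cell
#' (HCT 0.43, MCV 87.7 fL), a low-HCT (0.36) and a high-HCT (0.47)
#' variant, and a membrane-free control with the reference dimensions in
#' which all water diffuses as plasma.
#'
#' @return Named list of [build_unit_cell()] objects: `reference`,
#'   `low_hct`, `high_hct`, `control`.
#' @export
toy_geometries <- function() {
  list(
    reference = build_unit_cell(0.43, 87.7),
    low_hct = build_unit_cell(0.36, 87.7),
    high_hct = build_unit_cell(0.47, 87.7),
    control = build_unit_cell(0.43, 87.7, membrane = FALSE)
  )
}
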