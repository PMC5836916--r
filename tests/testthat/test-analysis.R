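test_that("noise-floor correction is exact, monotone and scale-equivariant", {
  expect_identical(as.numeric(noise_correct(10, 0)), 10)
  expect_equal(as.numeric(noise_correct(10, 1)), sqrt(94), tolerance = 1e-14)
  expect_equal(as.numeric(noise_correct(10, 1)), 9.695, tolerance = 1e-4)
  # floor case flagged, not an error
  low <- noise_correct(1, 1)
  expect_identical(as.numeric(low), 0)
  expect_true(attr(low, "floored"))
  # monotone in S_m
  s <- noise_correct(seq(3, 20, by = 0.5), 1)
  expect_true(all(diff(s) > 0))
  # common rescaling of signal and noise commutes
  expect_equal(as.numeric(noise_correct(7 * 10, 7 * 1)),
               7 * as.numeric(noise_correct(10, 1)), tolerance = 1e-12)
})

test_that("low-SNR exclusion applies the sqrt(60) sigma rule at b = 400", {
  sig <- 2
  mk <- function(id, s400) {
    data.frame(sample_id = id, profile = "MP", T_ms = 40, TE_ms = 120,
               b_s_mm2 = c(0, 50, 400), direction = 1,
               S_m = c(50, 40, sqrt(s400^2 + 6) * sig), sigma = sig)
  }
  # corrected b=400 signals of 8 sigma (kept) and 7 sigma (excluded)
  rows <- rbind(mk("keep", 8), mk("drop", 7))
  out <- exclude_low_snr(rows)
  expect_equal(out$snr_threshold, sqrt(10), tolerance = 1e-14)
  expect_equal(out$snr_threshold, 3.2, tolerance = 0.02)
  expect_setequal(unique(out$kept$sample_id), "keep")
  expect_setequal(unique(out$excluded$sample_id), "drop")
  rep <- out$report
  expect_equal(rep$S_c_b400[rep$sample_id == "keep"], 8 * sig,
               tolerance = 1e-12)
  expect_false(rep$excluded[rep$sample_id == "keep"])
  expect_true(rep$excluded[rep$sample_id == "drop"])
  # sqrt(60) sigma is the boundary in signal units
  expect_gt(8, sqrt(60))  # 8 sigma retained
  expect_lt(7, sqrt(60))  # 7 sigma excluded
  expect_error(exclude_low_snr(rows[rows$b_s_mm2 != 400, ]), "400")
})

test_that("ADC fit is exact on noiseless mono-exponential signals", {
  b <- c(0, 0, 50, 400)
  s <- 100 * exp(-b * 1e-3 * 1.5)
  fit <- fit_adc(b, s)
  expect_equal(fit$adc, 1.5, tolerance = 1e-12)
  expect_equal(fit$s0, 100, tolerance = 1e-10)
  # direction averaging is a no-op on identical directions
  b6 <- rep(c(0, 50, 400), each = 6)
  s6 <- 100 * exp(-b6 * 1e-3 * 1.5)
  fit6 <- fit_adc(b6, s6, direction = rep(1:6, 3))
  expect_equal(fit6$adc, 1.5, tolerance = 1e-12)
  expect_error(fit_adc(c(0, 50), c(10, -1)), "usable")
})

test_that("T2 fit is exact on noiseless decays and flags degenerate input", {
  te <- seq(60, 200, by = 20)
  s <- 80 * exp(-te / 80)
  fit <- fit_t2(te, s)
  expect_equal(fit$t2, 80, tolerance = 1e-12)
  expect_false(fit$flagged)
  flat <- fit_t2(te, rep(5, length(te)))
  expect_true(flat$flagged)
  expect_identical(flat$t2, Inf)
  expect_error(fit_t2(c(60, 80), c(10, 9)), "3 echo")
})

test_that("T2 recovery on noisy fixture signals matches the oracle rate", {
  # channel-SNR 30 at the shortest echo; unweighted log-linear estimator
  te <- seq(60, 160, by = 20)
  t2 <- 45
  s0 <- 100
  sigma <- s0 * exp(-min(te) / t2) / 30
  set.seed(61)
  n_rep <- 300
  hits <- 0
  for (i in seq_len(n_rep)) {
    spec <- signal_fixture_spec(adc = 1.3, t2 = t2, s0 = s0, sigma = sigma,
                                b_s_mm2 = 0, n_b0 = 1, TE_ms = te,
                                T_grid = data.frame(profile = "MP",
                                                    T_ms = 40))
    tab <- generate_signals(spec, seed = 7000 + i)
    sc <- noise_correct(tab$S_m, tab$sigma)
    keep <- sc > sqrt(60) * tab$sigma
    if (sum(keep) >= 3) {
      est <- fit_t2(tab$TE_ms[keep], sc[keep])
      if (is.finite(est$t2) && abs(est$t2 - t2) / t2 < 0.10) hits <- hits + 1
    }
  }
  expect_gt(hits / n_rep, 0.80)
})

test_that("critical r matches the exact null distribution of Pearson r", {
  # the t-transform critical value against the Beta law of r^2 under H0
  for (df in 3:30) {
    x <- seq_len(df + 2)
    y <- c(seq_len(df + 1), df)  # arbitrary non-collinear data
    res <- correlate_and_regress(rnorm(df + 2), rnorm(df + 2))
    expect_equal(res$r_crit, sqrt(stats::qbeta(0.95, 1 / 2, df / 2)),
                 tolerance = 1e-10)
  }
  set.seed(71)
  res7 <- correlate_and_regress(rnorm(9), rnorm(9))
  expect_equal(res7$df, 7)
  expect_equal(res7$r_crit, 0.666, tolerance = 1e-3)
  res8 <- correlate_and_regress(rnorm(10), rnorm(10))
  expect_equal(res8$r_crit, 0.632, tolerance = 1e-3)
})

test_that("regression is gated on |r| > r_crit and exact when collinear", {
  x <- c(0.36, 0.39, 0.42, 0.45, 0.48)
  y <- 1.545 + (0.42 - x) * 2.169
  res <- correlate_and_regress(y, x)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$slope, -2.169, tolerance = 1e-10)
  expect_equal(res$intercept, 1.545 + 0.42 * 2.169, tolerance = 1e-10)
  # uncorrelated noise: usually below the gate
  set.seed(81)
  res0 <- correlate_and_regress(rnorm(9), rnorm(9))
  if (!res0$significant) expect_true(is.na(res0$slope))
  expect_error(correlate_and_regress(rep(1, 5), 1:5), "variance")
  # p-value agrees with cor.test
  set.seed(82)
  a <- rnorm(12); b <- a + rnorm(12)
  res1 <- correlate_and_regress(b, a)
  ct <- stats::cor.test(a, b)
  expect_equal(res1$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(res1$pearson_r, unname(ct$estimate), tolerance = 1e-12)
})

test_that("paired MP/FC comparison controls type-I error and detects shifts", {
  expect_true(compare_profiles(c(1, 2, 3), c(1, 2, 3))$degenerate)
  # constant shift + small noise: decisive
  set.seed(91)
  mp <- rnorm(10, 1.30, 0.02)
  res <- compare_profiles(mp, mp + 0.24 + rnorm(10, 0, 0.02))
  expect_lt(res$p, 1e-6)
  expect_gt(res$mean_diff, 0.2)
  # simulated null: rejection rate ~ alpha
  set.seed(92)
  n <- 10
  reps <- 1000
  d <- matrix(rnorm(n * reps), nrow = n)
  tstat <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n))
  pvals <- vapply(seq_len(reps), function(j)
    compare_profiles(rep(0, n), d[, j])$p, numeric(1))
  expect_equal(pvals, 2 * stats::pt(-abs(tstat), n - 1), tolerance = 1e-10)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("blood-count calibration returns the recommended D_b values", {
  expect_equal(predict_Db("FC", hct = 0.42), 1.545, tolerance = 1e-12)
  expect_equal(predict_Db("MP", hct = 0.42), 1.307, tolerance = 1e-12)
  expect_equal(predict_Db("FC", hgb = 14.5), 1.551, tolerance = 1e-12)
  expect_equal(predict_Db("MP", hgb = 14.5), 1.312, tolerance = 1e-12)
  expect_equal(predict_Db("FC", hct = 0.47), 1.545 - 0.05 * 2.169,
               tolerance = 1e-10)
  expect_equal(predict_Db("FC", hct = 0.47), 1.437, tolerance = 1e-3)
  d_mp <- predict_Db("MP")
  expect_equal(as.numeric(d_mp), 1.30)
  expect_equal(attr(d_mp, "spread"), 0.18)
  d_fc <- predict_Db("FC")
  expect_equal(as.numeric(d_fc), 1.54)
  expect_equal(attr(d_fc, "spread"), 0.12)
  expect_error(predict_Db("XX", hct = 0.4))
  expect_warning(predict_Db("FC", hct = 0.9), "plausible")
})

test_that("blood_count validates plausible ranges as warnings only", {
  expect_silent(blood_count("a", 0.43, 87.7, 14.5))
  expect_warning(blood_count("a", 0.1, 87.7, 14.5), "hematocrit")
  expect_warning(blood_count("a", 0.43, 150, 14.5), "MCV")
})
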