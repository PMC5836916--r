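test_that("isotropic directions are unit, reproducible and balanced", {
  d1 <- isotropic_directions(1, seed = 9)
  d2 <- isotropic_directions(1, seed = 9)
  expect_identical(d1, d2)
  d <- isotropic_directions(10000, seed = 4)
  expect_equal(rowSums(d^2), rep(1, 10000), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(d)^2)), 0.02)
  # second moments ~ isotropic
  expect_equal(crossprod(d) / 10000, diag(3) / 3, tolerance = 0.02)
})

test_that("static and constant-velocity particles accrue the right phase", {
  mp <- switch_times("MP", 40, 120)
  fc <- switch_times("FC", 70, 120)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))

  static_cm <- function(prof, x0) {
    a <- array(0, dim = c(1, prof$K, 3))
    for (k in seq_len(prof$K)) a[1, k, ] <- x0
    a
  }
  rec <- fake_record(list(static_cm(mp, c(1, 2, 3)),
                          static_cm(fc, c(1, 2, 3))), list(mp, fc))
  expect_equal(max(abs(phase_matrix(phases(rec, 1, dirs, 400)))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(phase_matrix(phases(rec, 2, dirs, 400)))), 0,
               tolerance = 1e-12)

  # constant velocity: interval center of mass = v * interval midpoint
  v <- c(0.02, -0.01, 0.005)     # um/ms
  vel_cm <- function(prof) {
    a <- array(0, dim = c(1, prof$K, 3))
    for (k in seq_len(prof$K))
      a[1, k, ] <- v * (prof$t[k] + prof$t[k + 1]) / 2
    a
  }
  rec_v <- fake_record(list(vel_cm(mp), vel_cm(fc)), list(mp, fc))
  # FC: flow compensation nulls the phase
  expect_equal(max(abs(phase_matrix(phases(rec_v, 2, dirs, 400)))), 0,
               tolerance = 1e-10)
  # MP: phi = gamma g (v . u) T^2 / 4, i.e. phi' = (v.u) T^2/4 / sqrt(a T^3)
  ens <- phases(rec_v, 1, dirs, 400)
  want_phi <- (dirs %*% v) * mp$T^2 / 4 / sqrt(b_coefficient(mp) * mp$T^3)
  expect_equal(as.numeric(phase_matrix(ens)), as.numeric(t(want_phi)),
               tolerance = 1e-12)
})

test_that("normalized phases are independent of the chosen b-value", {
  mp <- switch_times("MP", 40, 120)
  set.seed(11)
  a <- array(rnorm(5 * mp$K * 3), dim = c(5, mp$K, 3))
  rec <- fake_record(list(a), list(mp))
  dirs <- isotropic_directions(7, seed = 2)
  expect_equal(phase_matrix(phases(rec, 1, dirs, 400)),
               phase_matrix(phases(rec, 1, dirs, 50)), tolerance = 1e-14)
})

test_that("ADC estimators recover Gaussian and two-point phase laws", {
  # Gaussian phi' with variance 2D: adc_0 = D, k_app = 0, adc_b = D
  D <- 1.8
  set.seed(21)
  phi <- matrix(rnorm(60000, sd = sqrt(2 * D)), ncol = 1)
  st <- adc_from_phases(phi, b = 0.4)
  expect_lt(abs(st$adc_0 - D), 3 * st$se_adc_0)
  expect_lt(abs(st$k_app), 3 * st$se_k_app)
  expect_lt(abs(st$adc_b - D), 3 * st$se_adc_b)

  # two-point distribution phi = +/- phi0: enumeration closed form
  phi0 <- 0.9
  b <- 0.4
  phi2 <- matrix(c(rep(phi0 * sqrt(1 / b), 500),
                   rep(-phi0 * sqrt(1 / b), 500)), ncol = 1)
  st2 <- adc_from_phases(phi2, b = b)
  expect_equal(st2$adc_b, -log(cos(phi0)) / b, tolerance = 1e-10)
  expect_equal(st2$k_app, -2, tolerance = 1e-10)
})

test_that("adc_b approaches adc_0 as b goes to zero", {
  set.seed(33)
  # non-Gaussian mixture so adc_b != adc_0 at finite b
  phi <- matrix(c(rnorm(40000, sd = sqrt(2 * 0.5)),
                  rnorm(40000, sd = sqrt(2 * 3.0))), ncol = 1)
  s_big <- adc_from_phases(phi, b = 0.4)
  s_small <- adc_from_phases(phi, b = 0.004)
  expect_lt(abs(s_small$adc_b - s_small$adc_0),
            abs(s_big$adc_b - s_big$adc_0) / 50)
  # departure tracks the kurtosis term of the expansion
  expect_equal(s_big$adc_0 - s_big$adc_b,
               0.4 / 6 * s_big$adc_0^2 * s_big$k_app, tolerance = 0.25)
})

test_that("kurtosis expansion residual vanishes for Gaussian phases and scales as b^2", {
  set.seed(44)
  phi_g <- matrix(rnorm(50000, sd = sqrt(2 * 1.5)), ncol = 1)
  st <- adc_from_phases(phi_g, b = 0.4)
  chk <- kurtosis_expansion_check(st)
  expect_lt(chk$residual, 0.02)

  # unequal-weight Gaussian mixture (an equal-weight one has kappa_6 = 0
  # identically, which would leave no leading b^2 term to observe)
  phi <- matrix(c(rnorm(45000, sd = 1), rnorm(15000, sd = sqrt(6))),
                ncol = 1)
  r1 <- kurtosis_expansion_check(adc_from_phases(phi, b = 0.10))
  r2 <- kurtosis_expansion_check(adc_from_phases(phi, b = 0.05))
  expect_equal(r1$residual / r2$residual, 4, tolerance = 0.15)
  # residual agrees with the sixth-moment scale estimate
  expect_lt(r1$residual, 2 * r1$b2_scale)
  expect_gt(r1$residual, r1$b2_scale / 2)
})

test_that("ADC statistics are invariant under rotation of the direction set", {
  mp <- switch_times("MP", 40, 120)
  set.seed(55)
  a <- array(rnorm(400 * mp$K * 3, sd = 2), dim = c(400, mp$K, 3))
  rec <- fake_record(list(a), list(mp))
  dirs <- isotropic_directions(500, seed = 6)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s1 <- adc_from_phases(phases(rec, 1, dirs, 400))
  s2 <- adc_from_phases(phases(rec, 1, dirs %*% R, 400))
  expect_equal(s1$adc_0, s2$adc_0, tolerance = 0.02)
  expect_equal(s1$adc_b, s2$adc_b, tolerance = 0.02)
})

test_that("a small sweep returns one tidy row per condition", {
  res <- adc_sweep(hct = 0.43, T_mp = 40, T_fc = 100, n_particles = 150,
                   step_fraction = 0.1, n_directions = 300, seed = 3)
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 2)
  expect_setequal(res$profile, c("MP", "FC"))
  expect_true(all(res$adc_b > 0 & res$adc_b < 2.75))
  expect_true(all(res$se_adc_b > 0))
})
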