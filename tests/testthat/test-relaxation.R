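test_that("Stokes-Einstein arithmetic and scalings are exact", {
  tum <- stokes_einstein(300, 1.0e-3, 1.0)
  expect_equal(tum$d_rot, 1.648e8, tolerance = 1e-3)
  expect_equal(tum$tau_r_ns, 1.011, tolerance = 1e-3)
  expect_equal(stokes_einstein(300, 1e-3, 2.0)$d_rot, tum$d_rot / 8)
  expect_equal(stokes_einstein(600, 1e-3, 1.0)$d_rot, tum$d_rot * 2)
  expect_error(stokes_einstein(-1, 1e-3, 1),
               class = "nanosite_parameter_error")
})

test_that("the hydrodynamic radius is 1.1 times the radius of gyration", {
  expect_equal(hydrodynamic_radius(1.73), 1.903)
  expect_equal(hydrodynamic_radius(1.0), 1.1)
  expect_true(hydrodynamic_radius(2) > hydrodynamic_radius(1.9))
  expect_error(hydrodynamic_radius(0), class = "nanosite_parameter_error")
})

test_that("an exact biexponential internal ACF is recovered", {
  t <- seq(0, 2000, by = 2)
  truth <- list(s2 = 0.7, a1 = 0.2, a2 = 0.1, tau1 = 20, tau2 = 300)
  acf <- tibble::tibble(lag_ps = t,
                        acf = truth$s2 + truth$a1 * exp(-t / truth$tau1) +
                          truth$a2 * exp(-t / truth$tau2))
  fit <- fit_internal_acf(acf)
  expect_equal(fit$s2, truth$s2, tolerance = 1e-4)
  taus <- sort(c(fit$tau1_ps, fit$tau2_ps))
  expect_equal(taus, c(truth$tau1, truth$tau2), tolerance = 1e-3)
  expect_equal(sort(c(fit$a1, fit$a2)), c(truth$a2, truth$a1),
               tolerance = 1e-4)
  expect_equal(fit$s2 + fit$a1 + fit$a2, 1, tolerance = 1e-6)
})

test_that("a single-exponential ACF leaves one amplitude near zero", {
  t <- seq(0, 1000, by = 2)
  acf <- tibble::tibble(lag_ps = t, acf = 0.6 + 0.4 * exp(-t / 50))
  fit <- fit_internal_acf(acf)
  expect_equal(fit$s2, 0.6, tolerance = 1e-3)
  expect_lt(min(fit$a1, fit$a2), 0.02)
  expect_error(fit_internal_acf(acf[1:5, ]),
               class = "nanosite_insufficient_data_error")
})

test_that("generator ACFs yield the planted order parameter and time", {
  v <- generate_tumbling_vectors(0, 0.8, 50, dt = 2, n_frames = 4000,
                                 seed = 2, n_vectors = 30)
  fit <- fit_internal_acf(p2_acf(v, dt = 2, max_lag = 1500))
  expect_equal(fit$s2, 0.8, tolerance = 0.05)
  tau_eff <- (fit$a1 * fit$tau1_ps + fit$a2 * fit$tau2_ps) /
    max(fit$a1 + fit$a2, 1e-12)
  expect_equal(tau_eff, 50, tolerance = 0.2 * 50)
})

test_that("the spectral density matches its closed forms and quadrature", {
  tum <- stokes_einstein(300, 8.5e-4, 1.9)
  tau_r <- tum$tau_r_ns * 1e-9
  rigid <- list(s2 = 1, a1 = 0, a2 = 0, tau1_ps = 1, tau2_ps = 1)
  w <- 2 * pi * 100.61e6
  expect_equal(spectral_density(rigid, tum, w),
               2 / 5 * tau_r / (1 + (w * tau_r)^2), tolerance = 1e-12)
  fit <- list(s2 = 0.8, a1 = 0.15, a2 = 0.05, tau1_ps = 50, tau2_ps = 500)
  taup <- 1 / (1 / tau_r + 1 / c(50e-12, 500e-12))
  expect_equal(spectral_density(fit, tum, 0),
               2 / 5 * (0.8 * tau_r + sum(c(0.15, 0.05) * taup)),
               tolerance = 1e-12)
  # quadrature oracle: trapezoidal Fourier cosine transform of the product ACF
  tg <- seq(0, 80 * tau_r, length.out = 400000)
  ct <- exp(-tg / tau_r) * (0.8 + 0.15 * exp(-tg / 50e-12) +
                              0.05 * exp(-tg / 500e-12))
  for (om in c(w, 2 * pi * 400.13e6)) {
    jq <- 2 / 5 * sum((ct * cos(om * tg))[-1] + (ct * cos(om * tg))[-length(tg)]) /
      2 * (tg[2] - tg[1])
    expect_equal(spectral_density(fit, tum, om), jq, tolerance = 1e-3)
  }
  # monotone decreasing in omega
  ws <- 10^seq(6, 10, length.out = 30)
  expect_true(all(diff(spectral_density(fit, tum, ws)) < 0))
})

test_that("T1 reduces to the extreme-narrowing closed form", {
  # fast tumbling: all omega*tau << 1 so 1/T1 -> n_h d^2 tau_c
  tum <- stokes_einstein(300, 1e-4, 0.2)  # tau_r ~ 1 ps
  rigid <- list(s2 = 1, a1 = 0, a2 = 0, tau1_ps = 1, tau2_ps = 1)
  r_ch <- 0.109
  d <- 1e-7 * 1.054571817e-34 * 267.52218744e6 * 67.2828e6 / (r_ch * 1e-9)^3
  tau_c <- tum$tau_r_ns * 1e-9
  for (nh in 1:2) {
    t1 <- t1_13c(rigid, tum, n_h = nh, r_ch = r_ch)
    expect_equal(1 / t1$t1_s, nh * d^2 * tau_c, tolerance = 1e-3)
  }
  # n_h linearity: two hydrogens halve T1
  expect_equal(t1_13c(rigid, tum, n_h = 2)$t1_s,
               t1_13c(rigid, tum, n_h = 1)$t1_s / 2, tolerance = 1e-12)
  expect_warning(t1_13c(rigid, tum, n_h = 1, r_ch = 0.15), regexp = "0.09")
})

test_that("T1 against a brute-force numerical spectral density", {
  tum <- stokes_einstein(300, 8.5e-4, 1.9)
  rigid <- list(s2 = 1, a1 = 0, a2 = 0, tau1_ps = 1, tau2_ps = 1)
  t1 <- t1_13c(rigid, tum, n_h = 1, b0_proton_mhz = 400.13)
  w_h <- 2 * pi * 400.13e6
  w_c <- w_h * 67.2828e6 / 267.52218744e6
  expect_equal(t1$freq_13c_mhz, 100.63, tolerance = 1e-4)
  tau_r <- tum$tau_r_ns * 1e-9
  tg <- seq(0, 80 * tau_r, length.out = 400000)
  jnum <- function(om) {
    ct <- exp(-tg / tau_r)
    2 / 5 * sum((ct * cos(om * tg))[-1] + (ct * cos(om * tg))[-length(tg)]) /
      2 * (tg[2] - tg[1])
  }
  d <- 1e-7 * 1.054571817e-34 * 267.52218744e6 * 67.2828e6 / (0.109e-9)^3
  r1 <- d^2 / 4 * (jnum(w_h - w_c) + 3 * jnum(w_c) + 6 * jnum(w_h + w_c))
  expect_equal(t1$t1_s, 1 / r1, tolerance = 1e-3)
})

test_that("T1 traces the textbook minimum near omega tau of order one", {
  rigid <- list(s2 = 1, a1 = 0, a2 = 0, tau1_ps = 1, tau2_ps = 1)
  w_c <- 2 * pi * 100.61e6
  taus <- 10^seq(-10.5, -7.5, length.out = 40)
  t1s <- vapply(taus, function(tau) {
    tum <- structure(list(d_rot = 1 / (6 * tau), tau_r_ns = tau * 1e9),
                     class = "nanosite_tumbling")
    t1_13c(rigid, tum, n_h = 1)$t1_s
  }, numeric(1))
  i_min <- which.min(t1s)
  expect_gt(i_min, 1); expect_lt(i_min, length(taus))
  expect_equal(w_c * taus[i_min], 1, tolerance = 0.8)
})

test_that("end-to-end T1 prediction recovers the analytic model-free value", {
  d_rot <- 1.65e8; s2 <- 0.8; tau_e <- 50
  v <- generate_tumbling_vectors(0, s2, tau_e, dt = 2, n_frames = 5000,
                                 seed = 12, n_vectors = 30)
  fit <- fit_internal_acf(p2_acf(v, dt = 2, max_lag = 1500))
  tum <- structure(list(d_rot = d_rot, tau_r_ns = 1 / (6 * d_rot) * 1e9),
                   class = "nanosite_tumbling")
  t1_pred <- t1_13c(fit, tum, n_h = 1)$t1_s
  t1_true <- nanosite:::.analytic_t1(d_rot, s2, tau_e, n_h = 1)
  expect_lt(abs(t1_pred - t1_true) / t1_true, 0.10)
  expect_gt(t1_pred, 0)
})
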