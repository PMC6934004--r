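# Background gradients, echo selection, sinc correction, decay fitting.

test_that("constructed linear phase field is recovered to machine precision", {
  p <- default_protocol()
  gz <- 50e-6  # 50 uT/m
  ser <- constructed_series(c(16, 16, 12), p, gz = gz, phi0 = 0)
  gr <- estimate_background_gradients(ser, phi0_subtract = TRUE)
  expect_lt(max(abs(gr$gz - gz)), 1e-12 * abs(gz) + 1e-18)
  expect_lt(max(abs(gr$gx)), 1e-15)
  expect_lt(max(abs(gr$gy)), 1e-15)
  expect_true(all(gr$valid))
  # uniform phase -> zero gradients in both modes
  ser0 <- constructed_series(c(12, 12, 8), p, gz = 0, phi0 = 0.7)
  for (mode in c(TRUE, FALSE)) {
    g0 <- estimate_background_gradients(ser0, phi0_subtract = mode)
    expect_lt(max(abs(g0$gz)), 1e-15)
  }
})

test_that("phi0 subtraction removes the receive-phase contamination of the literal estimator", {
  p <- default_protocol()
  dims <- c(12, 12, 10)
  a <- 0.05  # phi0 step per z voxel, radians
  phi0 <- array(rep(a * seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims)
  ser <- constructed_series(dims, p, t2star = 60, gz = 0, phi0 = phi0)
  # subtraction mode: exact zero
  g_sub <- estimate_background_gradients(ser, phi0_subtract = TRUE)
  expect_lt(max(abs(g_sub$gz)), 1e-15)
  # literal per-echo mode: bias equals the analytic contamination
  # a / (gamma * dz) * mean(1 / TE_n) over magnitude-qualified echoes
  g_lit <- estimate_background_gradients(ser, phi0_subtract = FALSE)
  te_s <- p$te_ms / 1000
  included <- exp(-p$te_ms / 60) >= 0.5 * exp(-p$te_ms[1] / 60)
  predicted <- a / (p$gamma * 1.5e-3) * mean(1 / te_s[included])
  inner_z <- 2:(dims[3] - 1)
  expect_equal(mean(g_lit$gz[, , inner_z]), predicted, tolerance = 1e-10)
})

test_that("gradient error shrinks roughly as 1/sqrt(n_echoes) under phase noise", {
  p32 <- default_protocol(32L)
  p8 <- default_protocol(8L)
  gz <- 30e-6
  set.seed(21)
  err <- sapply(list(p8, p32), function(p) {
    ser <- constructed_series(c(10, 10, 10), p, t2star = 1e5, gz = gz)
    ser$phase <- wrap_phase(ser$phase + array(rnorm(length(ser$phase), sd = 0.05),
                                              dim = dim(ser$phase)))
    g <- estimate_background_gradients(ser, phi0_subtract = FALSE)
    sd(g$gz - gz)
  })
  expect_lt(err[2], err[1])  # 32 echoes beat 8
})

test_that("echo selection follows the 0.8*pi dephasing rule", {
  p <- default_protocol(32L)
  ser <- constructed_series(c(6, 6, 4), p)
  z <- array(0, dim = c(6, 6, 4))
  expect_true(all(select_echoes(ser, z) == 32L))
  # |gz| placing the limit between TE_12 (48.75 ms) and TE_13 (52.83 ms):
  # te_max = 50 ms  =>  gz = 0.8*pi / (gamma * dz * 50 ms)
  gz_val <- 0.8 * pi / (p$gamma * 1.5e-3 * 0.050)
  expect_true(all(select_echoes(ser, z + gz_val) == 12L))
  expect_true(all(select_echoes(ser, z + 1) == 0L))      # huge gradient
  expect_true(all(select_echoes(ser, z + gz_val, max_echoes = 5) == 5L))
  # monotone: echo count never increases with |gz|
  gzs <- seq(0, 5e-4, length.out = 40)
  counts <- vapply(gzs, function(g) select_echoes(ser, z + g)[1], integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mono-exponential fit is exact on noiseless decays and handles edge cases", {
  p <- default_protocol(32L)
  sig <- 80 * exp(-p$te_ms / 50)
  for (mode in c("intensity2", "uniform")) {
    fit <- fit_monoexponential(p$te_ms, sig, weights_mode = mode)
    expect_equal(fit$s0, 80, tolerance = 1e-10)
    expect_equal(fit$t2star, 50, tolerance = 1e-10)
    expect_true(fit$valid)
    expect_lt(fit$rss, 1e-20)
  }
  # flat signal: T2* capped, fit still valid
  flat <- fit_monoexponential(p$te_ms, rep(7, 32))
  expect_equal(flat$t2star, 2000)
  expect_true(flat$valid)
  expect_true(flat$capped)
  # non-positive signals are excluded; < 3 left invalidates
  bad <- fit_monoexponential(c(4, 8, 12, 16), c(10, -1, 0, 5))
  expect_false(bad$valid)
  # nls refinement agrees with the log-linear route on noiseless data
  ref <- fit_monoexponential(p$te_ms, sig, refine = "nls")
  expect_equal(ref$t2star, 50, tolerance = 5e-4)
  expect_equal(ref$s0, 80, tolerance = 5e-4)
})

test_that("log-linear fit is accurate under Rician noise at SNR 97 (Monte Carlo)", {
  p <- default_protocol(32L)
  n_rep <- 3000
  s0 <- 80; t2 <- 50
  clean <- s0 * exp(-p$te_ms / t2)
  sdn <- clean[1] / 97
  set.seed(33)
  re <- matrix(rep(clean, each = n_rep), n_rep) + rnorm(n_rep * 32, sd = sdn)
  im <- matrix(rnorm(n_rep * 32, sd = sdn), n_rep)
  S <- sqrt(re^2 + im^2)
  fit <- watermap:::fit_loglinear_core(S, p$te_ms, matrix(TRUE, n_rep, 32))
  expect_lt(abs(median(fit$t2star) - t2) / t2, 0.01)
  expect_lt(abs(median(fit$s0) - s0) / s0, 0.01)
})

test_that("sinc-corrected fit exactly undoes simulated through-slice modulation", {
  p <- default_protocol(32L)
  gz <- 6e-5; dz <- 1.5
  fac <- sinc(p$gamma / 2 * gz * dz / 1000 * p$te_ms / 1000)
  sig <- 80 * exp(-p$te_ms / 50) * fac
  fit <- sinc_corrected_fit(p$te_ms, sig, gz, dz)
  expect_equal(fit$s0, 80, tolerance = 1e-10)
  expect_equal(fit$t2star, 50, tolerance = 1e-10)
  # gz = 0 falls back to the plain fit
  f0 <- sinc_corrected_fit(p$te_ms, 80 * exp(-p$te_ms / 50), 0, dz)
  f1 <- fit_monoexponential(p$te_ms, 80 * exp(-p$te_ms / 50))
  expect_identical(f0$t2star, f1$t2star)
})

test_that("fit_volume recovers the noiseless phantom exactly and keeps invariants", {
  truth <- small_brain(phi0_field = FALSE)
  p <- default_protocol(12L)
  ser <- simulate_echo_series(truth, p, noise_sd = 0)
  dm <- fit_volume(ser, correct_gradients = TRUE)
  obj <- truth$label_map > 0
  f_map <- steady_state_factor(10, truth$t1_map, 72)
  s0_expect <- 1000 * truth$water_map / 100 * f_map * sin(pi / 180 * 72)
  expect_lt(max(abs(dm$s0[obj] / s0_expect[obj] - 1)), 1e-6)
  expect_lt(max(abs(dm$t2star[obj] / truth$t2star_map[obj] - 1)), 1e-6)
  expect_true(all(dm$valid[obj]))
  expect_equal(dm$r2star[obj] * dm$t2star[obj], rep(1000, sum(obj)))
  expect_true(all(dm$echoes_used[obj] >= 3))
  # T2* class means by construction
  expect_equal(mean(dm$t2star[truth$label_map == 1]), 50.0, tolerance = 1e-8)
  expect_equal(mean(dm$t2star[truth$label_map == 2]), 55.7, tolerance = 1e-8)
})

test_that("fitting CSF with the full echo train beats a short-subset fit (Monte Carlo)", {
  # slow CSF decay (T2* 200 ms): the spec of precision for calibration
  p <- default_protocol(32L)
  n_rep <- 1500
  clean <- 900 * exp(-p$te_ms / 200)
  sdn <- clean[1] / 97
  set.seed(44)
  re <- matrix(rep(clean, each = n_rep), n_rep) + rnorm(n_rep * 32, sd = sdn)
  im <- matrix(rnorm(n_rep * 32, sd = sdn), n_rep)
  S <- sqrt(re^2 + im^2)
  all32 <- watermap:::fit_loglinear_core(S, p$te_ms, matrix(TRUE, n_rep, 32))
  sub12 <- watermap:::fit_loglinear_core(S[, 1:12], p$te_ms[1:12],
                                         matrix(TRUE, n_rep, 12))
  rmse <- function(x) sqrt(mean((x - 200)^2))
  expect_lt(rmse(all32$t2star), 0.5 * rmse(sub12$t2star))
})

test_that("whole-tissue T2* distribution reflects configured spread on a noisy phantom", {
  truth <- small_brain(grid = c(32L, 32L, 16L))
  p <- default_protocol()
  nsd <- noise_sd_for_snr(truth, p, 97)
  ser <- simulate_echo_series(truth, p, noise_sd = nsd, seed = 6)
  dm <- fit_volume(ser)
  wm <- truth$label_map == 1 & dm$valid
  t2 <- dm$t2star[wm]
  expect_equal(median(t2), 50, tolerance = 0.02 * 50)
  # roughly symmetric, unimodal spread
  expect_lt(abs(mean(t2) - median(t2)), sd(t2))
})
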