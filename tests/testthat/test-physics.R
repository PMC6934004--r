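# Spoiled-GRE steady-state physics and protocol optimization.

test_that("steady_state_factor matches closed forms and published protocol values", {
  # CSF factor at the 3T protocol: TR 10 s, T1 4.3 s, 0.8 x 90 deg
  expect_equal(round(steady_state_factor(10, 4.3, 0.8 * 90), 2), 0.93)
  # at 90 deg the factor is exactly 1 - E1
  expect_equal(steady_state_factor(10, 2, 90), 1 - exp(-5), tolerance = 1e-12)
  # TR >> T1 limit
  expect_equal(steady_state_factor(1000, 1, 72), 1, tolerance = 1e-12)
  expect_error(steady_state_factor(-1, 2, 90), "tr")
  expect_error(steady_state_factor(10, 0, 90), "t1")
})

test_that("saturation_level reproduces the protocol design numbers", {
  s <- saturation_level(10, 2, 90)
  expect_equal(s, exp(-5), tolerance = 1e-12)
  expect_lt(s, 0.007)                       # below 0.7%
  # at the printed TR = 9.2 s the level is 1% (1.005% exactly: exp(-4.6))
  expect_equal(saturation_level(9.2, 2, 90), 0.0100, tolerance = 1e-2)
  # flip -> 0 limit: saturation vanishes
  expect_lt(saturation_level(3, 2, 1e-4), 1e-8)
})

test_that("steady-state invariants hold over a parameter sweep", {
  set.seed(42)
  for (i in 1:50) {
    tr <- runif(1, 1, 20); t1 <- runif(1, 0.3, 5); fl <- runif(1, 5, 90)
    f <- steady_state_factor(tr, t1, fl)
    expect_gt(f, 0); expect_lte(f, 1)
    # non-increasing in t1 (strictly, up to double-precision saturation at 1)
    f2 <- steady_state_factor(tr, t1 * 1.3, fl)
    expect_lte(f2, f)
    if (f < 1 - 1e-9) expect_lt(f2, f)
    # saturation bounded by E1 (maximum at 90 deg)
    expect_lte(saturation_level(tr, t1, fl), exp(-tr / t1) + 1e-12)
  }
})

test_that("tr_for_saturation agrees with closed forms and a grid oracle", {
  # 1% saturation at 90 deg, T1 = 2 s: closed form 2*ln(100) = 9.2103
  expect_equal(tr_for_saturation(0.01, 2, 90), 2 * log(100), tolerance = 1e-4)
  expect_equal(round(tr_for_saturation(0.01, 2, 90), 1), 9.2)
  expect_equal(tr_for_saturation(0.5, 1.7, 90), 1.7 * log(2), tolerance = 1e-4)
  # 0.5%: the formula gives 2*ln(200) = 10.597
  expect_equal(tr_for_saturation(0.005, 2, 90), 2 * log(200), tolerance = 1e-4)
  # arbitrary flip angle: dense-grid brute force oracle
  trs <- seq(0.5, 30, by = 1e-3)
  oracle <- trs[which(saturation_level(trs, 1.5, 60) <= 0.01)[1]]
  expect_equal(tr_for_saturation(0.01, 1.5, 60), oracle, tolerance = 2e-3)
  expect_error(tr_for_saturation(0, 2, 90), "level")
})

test_that("flip_max_for_saturation matches the protocol choice and a grid oracle", {
  # at TR 10 s / T1 2 s even 90 deg stays below 0.7%
  expect_equal(flip_max_for_saturation(10, 2, 0.007), 90)
  expect_equal(flip_max_for_saturation(1e4, 2, 0.007), 90)
  # shorter TR forces a lower flip; check the bound brackets the level
  fm <- flip_max_for_saturation(7, 2, 0.007)
  expect_gt(fm, 0); expect_lt(fm, 90)
  expect_lte(saturation_level(7, 2, fm - 0.01), 0.007)
  expect_gt(saturation_level(7, 2, fm + 0.01), 0.007)
  # dense grid scan oracle
  grid <- seq(0.01, 90, by = 0.01)
  oracle <- max(grid[saturation_level(7, 2, grid) <= 0.007])
  expect_equal(fm, oracle, tolerance = 0.02)
})

test_that("SNR per unit time peaks between TR 9 and 10 s for T1 = 2 s", {
  trs <- seq(5, 11, by = 0.25)
  flips <- vapply(trs, flip_max_for_saturation, numeric(1), t1 = 2, level = 0.007)
  snr <- mapply(snr_per_unit_time, trs, 2, flips)
  best <- trs[which.max(snr)]
  expect_gte(best, 9); expect_lte(best, 10)
  # absolute signal (numerator) increases with TR toward the plateau
  sig <- steady_state_factor(trs, 2, 90) * sin(pi / 2)
  expect_true(all(diff(sig) > 0))
  expect_equal(snr_per_unit_time(10, 2, 1e-9), 0, tolerance = 1e-10)
})

test_that("signal_model composes steady state, sinc dephasing and decay", {
  tiss <- tissue_params(100, 1e-3, 50, label = "custom")  # T1 << TR => f ~ 1
  # single early echo, everything at unity
  p1 <- acq_protocol(te_ms = 1e-9, voxel_mm = c(1, 1, 1.5), cal_factor = 1)
  s <- signal_model(42, p1, tiss)
  expect_equal(Mod(s), 42, tolerance = 1e-6)
  # TE = T2* = 50 ms gives m0/e
  p2 <- acq_protocol(te_ms = 50, voxel_mm = c(1, 1, 1.5), cal_factor = 1)
  expect_equal(Mod(signal_model(10, p2, tiss)), 10 / exp(1), tolerance = 1e-5)
  # sinc factor divides out exactly
  p3 <- default_protocol()
  tiss2 <- tissue_params(80, 1.2, 45)
  gz <- 8e-5
  with_g <- Mod(signal_model(10, p3, tiss2, gz = gz))
  no_g <- Mod(signal_model(10, p3, tiss2, gz = 0))
  fac <- sinc(p3$gamma / 2 * gz * 1.5e-3 * p3$te_ms / 1000)
  expect_equal(with_g / abs(fac), no_g, tolerance = 1e-12)
  # gz = 0: log-magnitude is linear in TE with slope -1/T2*
  lm_fit <- stats::lm(log(no_g) ~ p3$te_ms)
  expect_equal(unname(coef(lm_fit)[2]), -1 / 45, tolerance = 1e-10)
  # phase evolves as phi0 + 2 pi df TE
  tiss3 <- tissue_params(80, 1.2, 45, freq_offset_ppm = 0.5)
  ph <- Arg(signal_model(10, p3, tiss3, phi0 = 0.2))
  df <- 0.5e-6 * p3$gamma / (2 * pi) * 3.0
  expect_equal(wrap_phase(ph - (0.2 + 2 * pi * df * p3$te_ms / 1000)),
               rep(0, length(ph)), tolerance = 1e-8)
})

test_that("protocol sidecar round-trips through JSON", {
  p <- default_protocol(12L)
  f <- withr::local_tempfile(fileext = ".json")
  write_protocol(p, f)
  q <- read_protocol(f)
  expect_equal(q$te_ms, p$te_ms)
  expect_equal(q$tr_s, p$tr_s)
  expect_equal(flip_effective(q), 72)
  expect_error(acq_protocol(te_ms = c(5, 4, 6)))  # not increasing
})
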