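# Mixture-model segmentation with bias-field estimation.

make_biased_s0 <- function(grid = c(32L, 32L, 16L), log_sd = 0.05, seed = 5,
                           jitter = c(WM = 1.2, GM = 2.1), noise_seed = 3) {
  truth <- small_brain(grid = grid, jitter_sd = jitter,
                       bias_transmit = field_spec("dct", log_sd = log_sd / 2,
                                                  seed = seed),
                       bias_receive = field_spec("dct", log_sd = log_sd,
                                                 seed = seed + 13L))
  p <- default_protocol(12L)
  nsd <- noise_sd_for_snr(truth, p, 97)
  ser <- simulate_echo_series(truth, p, noise_sd = nsd, seed = noise_seed)
  dm <- fit_volume(ser)
  s0 <- dm$s0; s0[!dm$valid] <- 0
  list(truth = truth, protocol = p, s0 = s0)
}

test_that("identity field: estimated bias stays within 1% of 1", {
  # noiseless, delta classes: nothing for the field to explain
  truth <- small_brain(phi0_field = FALSE)
  p <- default_protocol(12L)
  ser <- simulate_echo_series(truth, p, noise_sd = 0)
  dm <- fit_volume(ser, correct_gradients = FALSE)
  s0 <- dm$s0; s0[!dm$valid] <- 0
  seg <- suppressWarnings(segment_and_debias(s0, n_classes = 3, seed = 1))
  expect_lt(max(abs(seg$bias[seg$foreground] - 1)), 0.01)
  # with noise and within-class jitter the field stays near flat
  truth2 <- small_brain(jitter_sd = c(WM = 1.2, GM = 2.1))
  ser2 <- simulate_echo_series(truth2, p,
                               noise_sd = noise_sd_for_snr(truth2, p, 97),
                               seed = 2)
  dm2 <- fit_volume(ser2)
  s02 <- dm2$s0; s02[!dm2$valid] <- 0
  seg2 <- segment_and_debias(s02, n_classes = 3, seed = 1)
  expect_lt(max(abs(seg2$bias[seg2$foreground] - 1)), 0.02)
})

test_that("known exp-DCT bias field is recovered (log-bias correlation >= 0.98)", {
  fix <- make_biased_s0(grid = c(48L, 48L, 16L))
  seg <- segment_and_debias(fix$s0, n_classes = 3, seed = 1)
  eff <- effective_bias_field(fix$truth, fix$protocol)
  fg <- seg$foreground
  expect_gt(cor(log(eff[fg]), log(seg$bias[fg])), 0.98)
  # post-correction within-class spread is close to the never-biased case
  s0c <- apply_bias_correction(fix$s0, seg)
  truth_flat <- small_brain(grid = c(48L, 48L, 16L),
                            jitter_sd = c(WM = 1.2, GM = 2.1))
  ser_flat <- simulate_echo_series(truth_flat, fix$protocol,
                                   noise_sd = noise_sd_for_snr(truth_flat,
                                                               fix$protocol, 97),
                                   seed = 3)
  dm_flat <- fit_volume(ser_flat)
  wm <- fix$truth$label_map == 1
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(s0c[wm]), 1.2 * cv(dm_flat$s0[wm]))
})

test_that("EM log-likelihood is non-decreasing and the result is seed-deterministic", {
  fix <- make_biased_s0(grid = c(24L, 24L, 12L))
  seg <- segment_and_debias(fix$s0, n_classes = 3, seed = 4)
  tr <- seg$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  seg2 <- segment_and_debias(fix$s0, n_classes = 3, seed = 4)
  expect_identical(seg$class_params, seg2$class_params)
  expect_identical(seg$bias, seg2$bias)
  # probabilities sum to 1 inside the fitted region
  psum <- apply(seg$prob, 1:3, sum)
  expect_lt(max(abs(psum[seg$foreground] - 1)), 1e-6)
  # class means strictly ordered (proton-density contrast)
  expect_true(all(diff(seg$class_params$mean) > 0))
  expect_true(all(seg$bias > 0))
})

test_that("gauge invariance: global intensity scaling moves class means, not the bias", {
  fix <- make_biased_s0(grid = c(24L, 24L, 12L))
  seg1 <- segment_and_debias(fix$s0, n_classes = 3, seed = 4)
  seg2 <- segment_and_debias(fix$s0 * 3.7, n_classes = 3, seed = 4)
  expect_equal(seg2$class_params$mean, 3.7 * seg1$class_params$mean,
               tolerance = 1e-6)
  expect_equal(seg2$bias, seg1$bias, tolerance = 1e-6)
  # unit geometric mean of the field over the fitted region
  expect_lt(abs(mean(log(seg1$bias[seg1$fit_region]))), 1e-10)
})

test_that("brain mask follows the 0.25 any-tissue rule", {
  prob <- array(0, dim = c(2, 2, 1, 4))
  prob[1, 1, 1, ] <- c(0.5, 0.3, 0.1, 0.1)   # WM 0.3 > 0.25 -> in
  prob[1, 2, 1, ] <- c(0.4, 0.2, 0.2, 0.2)   # all tissues <= 0.25 -> out
  prob[2, 1, 1, ] <- c(0, 0, 0, 0)           # background -> out
  prob[2, 2, 1, ] <- c(0.7, 0.1, 0.1, 0.26)  # CSF 0.26 -> in
  m <- brain_mask(prob)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("tissue masks implement the exclusive 0.98 rule in all permutations", {
  prob <- array(0, dim = c(3, 1, 1, 3))
  prob[1, 1, 1, ] <- c(0.99, 0.005, 0.005)   # WM only
  prob[2, 1, 1, ] <- c(0.98, 0.98, 0)        # ambiguous -> none
  prob[3, 1, 1, ] <- c(0.5, 0.5, 0)          # none
  m <- tissue_masks(prob)
  expect_identical(as.vector(m$WM), c(TRUE, FALSE, FALSE))
  expect_false(any(m$GM))
  expect_false(any(m$CSF))
})

test_that("coil-independence surrogate: two receive fields give matching water maps", {
  p <- default_protocol(12L)
  res <- list()
  for (coil in 1:2) {
    truth <- small_brain(grid = c(48L, 48L, 16L),
                         jitter_sd = c(WM = 1.2, GM = 2.1),
                         bias_receive = field_spec("dct", log_sd = 0.05,
                                                   seed = 100 + coil * 7L))
    ser <- simulate_echo_series(truth, p,
                                noise_sd = noise_sd_for_snr(truth, p, 97),
                                seed = 50 + coil)
    res[[coil]] <- map_water(ser, n_classes = 3, seg_seed = 1)$stats$classes
  }
  for (cls in c("WM", "GM")) {
    m1 <- res[[1]]$mean[res[[1]]$class == cls]
    m2 <- res[[2]]$mean[res[[2]]$class == cls]
    expect_lt(abs(m1 - m2), 1)   # < 1 percent unit between "coils"
  }
})

test_that("revolver: bias removal preserves tube contrast", {
  spec <- phantom_spec("revolver", grid_shape = c(48, 48, 16),
                       bias_receive = field_spec("dct", log_sd = 0.05, seed = 9))
  truth <- make_revolver_phantom(spec)
  p <- default_protocol(12L)
  ser <- simulate_echo_series(truth, p, noise_sd = noise_sd_for_snr(truth, p, 97),
                              seed = 4)
  dm <- fit_volume(ser)
  s0 <- dm$s0; s0[!dm$valid] <- 0
  seg <- segment_and_debias(s0, n_classes = 6, seed = 1)
  s0c <- apply_bias_correction(s0, seg)
  assigned <- seq(10, 100, 10)
  measured <- sapply(1:10, function(k) mean(s0c[truth$label_map == k + 1]))
  # contrast is not absorbed into the field: slope of the (scaled) ladder
  sl <- coef(lm(measured / mean(measured[10] / 100) ~ 0 + assigned))[[1]]
  expect_gt(sl, 0.9)
  # values inside each tube constant within ~2% after correction
  cvs <- sapply(1:10, function(k) {
    v <- s0c[truth$label_map == k + 1]; sd(v) / mean(v)
  })
  expect_lt(median(cvs), 0.05)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(segment_and_debias(array(0, dim = c(8, 8, 8))), "positive")
  s0 <- array(rep(c(10, 20), each = 512), dim = c(8, 8, 16))
  expect_warning(seg <- segment_and_debias(s0, n_classes = 2, basis_order = 2L,
                                           max_iter = 50, estimate_bias = FALSE),
                 "variance|converge")
})
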