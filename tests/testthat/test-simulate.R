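test_that("sample_path draws exponential dwells and is seed-deterministic", {
  m <- two_state_model(100, 50)
  p <- sample_path(m, 100, seed = 1)
  open_d <- p$duration[p$class == "O" & p$start + p$duration < 100]
  se <- 1 / 50 / sqrt(length(open_d))
  expect_lt(abs(mean(open_d) - 1 / 50), 3 * se)
  expect_identical(sample_path(m, 5, seed = 9), sample_path(m, 5, seed = 9))
  # all-zero rates: single dwell spanning the duration, flagged absorbing
  frozen <- gating_model(
    tibble::tibble(state = c("C", "O"), class = c("C", "O")),
    tibble::tibble(from = c("C", "O"), to = c("O", "C"), rate = c(0, 0)))
  pf <- sample_path(frozen, 3, initial_state = "C", seed = 2)
  expect_equal(nrow(pf), 1L)
  expect_equal(pf$duration, 3)
  expect_true(attr(pf, "absorbed"))
})

test_that("render_trace maps classes to conductance x voltage with left-closed samples", {
  m <- two_state_model()
  p <- sample_path(m, 0.2, initial_state = "O", seed = 3)
  tr <- render_trace(p, m, voltage = 30, fs = 1e4)
  expect_equal(nrow(tr), 2000L)
  lv <- unique(round(tr$current, 9))
  expect_true(all(lv %in% round(c(0, 199 * 30e-3), 9)))
  expect_equal(max(tr$current), 199 * 30e-3, tolerance = 1e-12)
  expect_true(all(render_trace(p, m, voltage = 0, fs = 1e4)$current == 0))
  # left-closed: the first sample takes the state at t = 0
  expect_equal(tr$current[1], 199 * 30e-3)
})

test_that("gaussian_filter has unit DC gain, -3 dB at fc, the erf rise time, and is linear", {
  fs <- 1e5
  fc <- 1e3
  const <- new_trace_for_test(rep(2.5, 5000), fs)
  expect_lt(max(abs(gaussian_filter(const, fc)$current - 2.5)), 1e-9)
  # -3 dB attenuation of a sinusoid at fc
  tt <- (0:(fs / 10)) / fs
  sine <- new_trace_for_test(sin(2 * pi * fc * tt), fs)
  amp <- max(gaussian_filter(sine, fc)$current[2000:8000])
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.02)
  # 10-90% rise time of a step: 2.5631 sigma_t with sigma_t = 0.1325/fc
  step <- new_trace_for_test(c(rep(0, 3000), rep(1, 3000)), fs)
  y <- gaussian_filter(step, fc)$current
  seg <- y[2500:3500]
  t10 <- approx(seg, seq_along(seg), xout = 0.1, ties = "ordered")$y
  t90 <- approx(seg, seq_along(seg), xout = 0.9, ties = "ordered")$y
  rise <- (t90 - t10) / fs
  expect_equal(rise, 2.5631 * 0.1325 / fc, tolerance = 0.02)
  # linearity
  x1 <- stats::rnorm(4000)
  x2 <- stats::rnorm(4000)
  f1 <- gaussian_filter(new_trace_for_test(x1, fs), fc)$current
  f2 <- gaussian_filter(new_trace_for_test(x2, fs), fc)$current
  f12 <- gaussian_filter(new_trace_for_test(2 * x1 - 3 * x2, fs), fc)$current
  expect_lt(max(abs(f12 - (2 * f1 - 3 * f2))), 1e-9)
  expect_error(gaussian_filter(new_trace_for_test(x1, fs), 6e4), "Nyquist")
})

test_that("resample_trace decimates by picking and round-trips through upsampling", {
  x <- stats::rnorm(1000)
  tr <- new_trace_for_test(x, 1e5)
  dn <- resample_trace(tr, 1e4)
  expect_identical(dn$current, x[seq(1, 1000, by = 10)])
  expect_identical(resample_trace(tr, 1e5)$current, x)
  up <- resample_trace(dn, 1e5)
  expect_identical(resample_trace(up, 1e4)$current, dn$current)
  expect_error(resample_trace(tr, 3e4), "integer")
})

test_that("baseline noise has the requested SD and is reproducible", {
  tr <- new_trace_for_test(rep(0, 2e5), 1e4)
  expect_identical(add_baseline_noise(tr, 0)$current, tr$current)
  y <- add_baseline_noise(tr, 1, seed = 4)$current
  expect_equal(stats::sd(y), 1, tolerance = 0.008)
  expect_identical(y, add_baseline_noise(tr, 1, seed = 4)$current)
})

test_that("fast-gating chain turns unresolved flicker into the duty-cycle level", {
  beta <- 21583
  m <- fast_couplet_model(beta)
  p <- sample_path(m, 3, seed = 21)
  tr <- acquisition_chain(p, m, 30, mode = "fast_gating", noise_sd = 0, seed = 22)
  lvl <- mean(tr$current)
  expect_equal(lvl, 199 * 30e-3 * beta / (5e4 + beta), tolerance = 0.02)
  # trace histories record the full chain
  ops <- vapply(trace_history(tr), function(h) h$op, character(1))
  expect_equal(ops, c("render", "gaussian_filter", "resample",
                      "baseline_noise", "gaussian_filter", "resample"))
})

test_that("slow gating gives the same apparent levels through either chain", {
  m <- two_state_model(20, 20)
  p <- sample_path(m, 4, seed = 31)
  t_std <- acquisition_chain(p, m, 30, mode = "standard", noise_sd = 0, seed = 1)
  t_fast <- acquisition_chain(p, m, 30, mode = "fast_gating", noise_sd = 0, seed = 1)
  expect_equal(mean(t_std$current), mean(t_fast$current), tolerance = 0.01)
  expect_equal(trace_fs(t_std), 1e4)
  expect_equal(trace_fs(t_fast), 1e4)
})

test_that("simulate_to_stationarity converges and respects tol = Inf", {
  m <- two_state_model(200, 200)
  tr <- simulate_to_stationarity(m, 30, chunk = 2, tol = Inf, seed = 5)
  expect_equal(attr(tr, "chunks"), 1L)
  tr2 <- simulate_to_stationarity(m, 30, chunk = 2, tol = 0.02, seed = 5,
                                  max_chunks = 20)
  po_hat <- mean(tr2$current > 199 * 30e-3 / 2)
  expect_equal(po_hat, 0.5, tolerance = 0.05)
})
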