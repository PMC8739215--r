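test_that("zero drive amplitude gives a flat response at the autonomous level", {
  p <- model_parameters(c_py_ei = 0.76)
  fr <- frequency_sweep(p, "sensory", c(1, 3, 5), amp = 0, inherit = FALSE)
  auto <- compute_features(simulate_model(p))$ptp
  expect_equal(fr$response$ptp, rep(auto, 3), tolerance = 1e-8)
})

test_that("jump detection stays quiet on a linear second-order resonance", {
  f <- seq(0.1, 5, by = 0.05)
  f0 <- 2; zeta <- 0.3
  amp <- 1 / sqrt((f0^2 - f^2)^2 + (2 * zeta * f0 * f)^2)
  expect_equal(nrow(detect_jumps(fake_freqresp(f, amp))), 0)
  # an explicit absolute tolerance works as an override
  expect_equal(nrow(detect_jumps(fake_freqresp(f, amp), jump_tol = 10)), 0)
})

test_that("jump detection flags a genuine discontinuity at its midpoint", {
  f <- seq(1, 2, by = 0.05)
  amp <- c(rep(0.02, 10), rep(0.06, 11))   # step between 1.45 and 1.50
  j <- detect_jumps(fake_freqresp(f, amp))
  expect_equal(nrow(j), 1)
  expect_equal(j$freq, 1.475)
  expect_equal(j$delta, 0.04)
})

test_that("resonance detection finds interior peaks and boundary maxima", {
  f <- seq(0.5, 8, by = 0.05)
  # lightly damped resonance: amplitude peak at f0 * sqrt(1 - 2 zeta^2)
  peak <- 1 / sqrt((4.7^2 - f^2)^2 + (2 * 0.05 * 4.7 * f)^2)
  r <- detect_resonance(fake_freqresp(f, peak))
  expect_equal(r$freq[1], 4.7 * sqrt(1 - 2 * 0.05^2), tolerance = 0.03)
  # monotone decreasing curve: only the boundary peak
  mono <- detect_resonance(fake_freqresp(f, 1 / (1 + f)))
  expect_equal(mono$freq, f[1])
})

test_that("the interictal state responds linearly in the drive amplitude", {
  p <- model_parameters(c_py_ei = 0.76)
  for (fq in c(2, 4.5)) {
    r1 <- frequency_sweep(p, "sensory", fq, amp = 0.01)$response$ptp
    r2 <- frequency_sweep(p, "sensory", fq, amp = 0.02)$response$ptp
    expect_equal(r2 / r1, 2, tolerance = 0.1)
  }
})

test_that("the near-onset state breaks amplitude proportionality at the jump", {
  p <- model_parameters(c_py_ei = 0.748)
  # at 1.3 Hz the 0.02-amplitude drive sits past the resonance jump
  r1 <- frequency_sweep(p, "cortical", 1.3, amp = 0.01)$response$ptp
  r2 <- frequency_sweep(p, "cortical", 1.3, amp = 0.02)$response$ptp
  expect_gt(abs(r2 / r1 - 2), 0.2)
})

test_that("the state-switch protocol shows a reversible amplitude transition", {
  sw <- state_switch_protocol(model_parameters())
  expect_length(sw$epoch_features, 3)
  ptps <- vapply(sw$epoch_features, `[[`, numeric(1), "ptp")
  expect_gt(ptps[2], 2 * ptps[3])   # excursion and return
  expect_lt(ptps[3], ptps[1] + 1e-3)
  # drive phase continuity across epochs: uniform time grid throughout
  expect_equal(diff(sw$times), rep(sw$dt, length(sw$times) - 1))
  # a constant schedule stays uniformly low-amplitude
  flat <- state_switch_protocol(
    model_parameters(),
    schedule = data.frame(c_py_ei = c(0.76, 0.76), duration = c(20, 20)))
  fptp <- vapply(flat$epoch_features, `[[`, numeric(1), "ptp")
  expect_lt(max(fptp), 0.05)
  expect_error(state_switch_protocol(
    model_parameters(),
    schedule = data.frame(c_py_ei = 0.1, duration = 10)), "0.3")
})

test_that("response tables round-trip through CSV", {
  p <- model_parameters(c_py_ei = 0.76)
  fr <- frequency_sweep(p, "sensory", c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  response_table(fr, path)
  back <- utils::read.csv(path)
  expect_equal(back$ptp, fr$response$ptp, tolerance = 1e-12)
})
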