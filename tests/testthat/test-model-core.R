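test_that("sigmoid matches its closed form and is overflow-safe", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1, 250000), 1 / (1 + 1 / 250000))
  x <- seq(-3, 3, by = 0.25)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(is.finite(sigmoid(c(-50, 50)))))
  expect_true(all(diff(sigmoid(seq(-2, 2, by = 0.01))) > 0))
  expect_error(sigmoid(NaN), "finite")
  expect_error(sigmoid(0, epsilon = 1), "> 1")
})

test_that("sigmoid_derivative agrees with a central finite difference", {
  expect_equal(sigmoid_derivative(0), log(250000) / 4)
  h <- 1e-6
  for (x in c(-2, -0.5, 0.5, 2)) {
    fd <- (sigmoid(x + h) - sigmoid(x - h)) / (2 * h)
    expect_equal(sigmoid_derivative(x), fd, tolerance = 1e-6)
  }
  expect_lt(sigmoid_derivative(40), 1e-10)
  expect_lt(sigmoid_derivative(-40), 1e-10)
})

test_that("drive_value implements the biased sinusoids", {
  d0 <- drive_spec()
  v <- drive_value(d0, c(0, 1, 2.5))
  expect_equal(v$Npy, rep(0.7, 3))
  expect_equal(v$Ntc, rep(0.1, 3))
  d <- drive_spec(a_py = 0.02, fpy = 1)
  expect_equal(drive_value(d, 0.25)$Npy, 0.72)
  # input gains scale the whole drive
  p <- model_parameters(c_Npy_py = 2)
  expect_equal(drive_value(d, 0.25, p)$Npy, 1.44)
})

test_that("decoupled vector field reduces to pure relaxation", {
  p <- decoupled_params()
  h <- c(p$h_py, p$h_i1, p$h_i2, p$h_ei, p$h_tc, p$h_re)
  expect_equal(unname(vector_field(h, p)), rep(0, 6))
  # off the fixed point the relaxation rates are the taus
  s <- h + 1
  tau <- c(p$tau_1, p$tau_2, p$tau_3, p$tau_4, p$tau_5, p$tau_6)
  expect_equal(unname(vector_field(s, p)), -tau)
  expect_error(vector_field(c(NA, 0, 0, 0, 0, 0), p), "finite")
})

test_that("simulation is deterministic and reports the cortical mean", {
  p <- model_parameters()
  r1 <- simulate_model(p, duration = 5)
  r2 <- simulate_model(p, duration = 5)
  expect_identical(r1$output, r2$output)
  expect_identical(r1$states, r2$states)
  expect_equal(r1$output,
               unname(rowMeans(r1$states[, c("PY", "I1", "I2", "EI")])))
  expect_equal(diff(r1$times), rep(0.0039, length(r1$times) - 1))
})

test_that("EI ablation freezes the population and renormalizes the output", {
  p <- model_parameters(ei_enabled = FALSE)
  r <- simulate_model(p, duration = 5)
  expect_true(all(r$states[, "EI"] == 0))
  expect_equal(r$output,
               unname(rowMeans(r$states[, c("PY", "I1", "I2")])))
})

test_that("a state started at an equilibrium stays there for 60 s", {
  p <- model_parameters()
  eq <- find_equilibria(p)
  stable <- Filter(function(e) startsWith(e$stability, "stable"), eq)
  expect_gte(length(stable), 1)
  s0 <- stable[[1]]$state
  r <- simulate_model(p, duration = 60, s0 = s0)
  dev <- max(abs(sweep(r$states, 2, s0)))
  expect_lt(dev, 1e-6)
})

test_that("integrator shows fourth-order convergence on the full model", {
  p <- model_parameters()
  # dt chosen so every step count divides the duration exactly
  end_state <- function(dt) {
    r <- simulate_model(p, duration = 1.024, dt = dt)
    r$states[nrow(r$states), ]
  }
  ref <- end_state(0.004 / 8)
  e1 <- max(abs(end_state(0.004) - ref))
  e2 <- max(abs(end_state(0.004 / 2) - ref))
  expect_gt(e1 / e2, 10)   # ~16 for a fourth-order scheme
  expect_lt(e1 / e2, 24)
})

test_that("the divergence guard names the failing step", {
  p <- model_parameters(c_py_py = 1e7)   # pins PY at ~1e7, beyond the guard
  err <- tryCatch(simulate_model(p, duration = 5),
                  tc_divergence = function(e) e)
  expect_s3_class(err, "tc_divergence")
  expect_match(conditionMessage(err), "step")
})

test_that("driven output is periodic at the drive period after transient", {
  p <- model_parameters(c_py_ei = 0.76)
  r <- simulate_model(p, drive_spec(a_tc = 0.02, ftc = 2), duration = 60)
  seg <- analysis_window(r, 2)
  lag <- round(1 / (2 * r$dt))
  x <- seg - mean(seg)
  n <- length(x)
  ac <- sum(x[1:(n - lag)] * x[(lag + 1):n]) /
    sqrt(sum(x[1:(n - lag)]^2) * sum(x[(lag + 1):n]^2))
  expect_gt(ac, 0.95)
})

test_that("trajectories round-trip through CSV", {
  r <- simulate_model(model_parameters(), duration = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(r, path)
  back <- utils::read.csv(path)
  expect_named(back, c("t", "PY", "I1", "I2", "EI", "TC", "RE", "output"))
  expect_equal(back$output, r$output, tolerance = 1e-12)
  expect_equal(nrow(back), length(r$times))
})

test_that("parameter constructor validates and rejects unknowns", {
  expect_error(model_parameters(c_bogus = 1), "unknown parameter")
  expect_error(model_parameters(tau_2 = -1), "positive")
  expect_error(model_parameters(epsilon = 0.5), "exceed 1")
  expect_error(model_parameters(c_py_py = -2), "non-negative")
  p <- model_parameters(c_tc_ei = 3.5)
  expect_equal(p$c_tc_ei, 3.5)
  expect_equal(p$c_py_py, 1.89)
})
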