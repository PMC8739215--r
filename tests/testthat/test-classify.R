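fake_features <- function(DF, Pmax1 = NA, Pmax2 = NA, Pmin1 = NA,
                          Pmin2 = NA, mean_level = 0, ptp = NULL,
                          oscillatory = !is.na(Pmax1)) {
  if (is.null(ptp))
    ptp <- if (oscillatory) Pmax1 - Pmin2 else 0
  structure(list(DF = DF, Pmax1 = Pmax1, Pmax2 = Pmax2, Pmin1 = Pmin1,
                 Pmin2 = Pmin2, ptp = ptp, mean_level = mean_level,
                 n_max_clusters = if (oscillatory) 1L else 0L,
                 oscillatory = oscillatory),
            class = "tc_features")
}

test_that("the rule table reproduces the regime prototypes", {
  # fixed point at a high output level -> normal background
  expect_equal(as.character(classify_state(fake_features(0, mean_level = 0.2))),
               "normal")
  # fixed point at a depressed level -> slow rhythmic
  expect_equal(as.character(classify_state(fake_features(0, mean_level = -0.4))),
               "slow_rhythmic")
  # fast spiking, single minimum level -> tonic
  f <- fake_features(16, 0.2, 0.15, -0.1, -0.105)
  expect_equal(as.character(classify_state(f)), "tonic")
  # 3 Hz spike-and-wave with well-separated minima -> typical absence
  f <- fake_features(3, 0.4, 0.4, -0.1, -0.4)
  expect_equal(as.character(classify_state(f)), "typical_absence")
  # same structure outside the 2-4 Hz band -> atypical absence
  f <- fake_features(5, 0.3, 0.3, -0.1, -0.12)
  expect_equal(as.character(classify_state(f)), "atypical_absence")
  # low-amplitude two-level spikes below 3.5 Hz -> preictal
  f <- fake_features(2.5, 0.06, 0.02, -0.02, -0.05)
  expect_equal(as.character(classify_state(f)), "preictal")
  # large simple slow cycle -> clonic
  f <- fake_features(4, 0.25, 0.2499, -0.3, -0.301)
  expect_equal(as.character(classify_state(f)), "clonic")
})

test_that("every finite feature set receives exactly one label", {
  set.seed(42)
  for (i in 1:300) {
    osc <- runif(1) > 0.2
    if (osc) {
      mx <- sort(runif(2, -1, 1), decreasing = TRUE)
      mn <- sort(runif(2, -1, min(mx)), decreasing = TRUE)
      f <- fake_features(runif(1, 0, 20), mx[1], mx[2], mn[1], mn[2],
                         mean_level = runif(1, -1, 1))
    } else {
      f <- fake_features(0, mean_level = runif(1, -2, 1))
    }
    lab <- classify_state(f)
    expect_length(lab, 1)
    expect_false(is.na(lab))
    expect_true(as.character(lab) %in% state_labels())
  }
})

test_that("canned fixture feature sets classify to their intended types", {
  fx <- generate_fixtures()
  for (nm in names(fx$feature_sets)) {
    f <- fx$feature_sets[[nm]]
    expect_equal(as.character(classify_state(f)), attr(f, "expected"),
                 label = paste("fixture", nm))
  }
})

test_that("synthetic series classify consistently with their construction", {
  fx <- generate_fixtures()
  f_swd <- compute_features(fx$series$swd3hz, dt = fx$dt)
  expect_equal(as.character(classify_state(f_swd)), "typical_absence")
  f_damp <- compute_features(fx$series$damped_neg[300:513], dt = fx$dt)
  expect_equal(as.character(classify_state(f_damp)), "slow_rhythmic")
  f_const <- compute_features(fx$series$constant, dt = fx$dt)
  expect_equal(as.character(classify_state(f_const)), "normal")
})

test_that("simulations across the GABAergic sweep hit the named regimes", {
  # representative points inside each regime of the EI-inhibition diagram
  expected <- list(`0.3` = "normal", `0.36` = "preictal", `0.4` = "clonic",
                   `0.62` = "slow_rhythmic", `0.8` = "tonic")
  for (v in names(expected)) {
    p <- fig_gaba_params(c_i1_ei = as.numeric(v))
    lab <- as.character(classify_state(compute_features(simulate_model(p))))
    expect_equal(lab, expected[[v]], label = paste("c_i1_ei =", v))
  }
  # the bistable window hosts spike-and-wave (absence) discharges
  p <- fig_gaba_params(c_i1_ei = 0.48)
  lab <- as.character(classify_state(compute_features(simulate_model(p))))
  expect_true(lab %in% c("typical_absence", "atypical_absence"))
})
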