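fake_diagram <- function(values, n_max, ptp = 0.3) {
  features <- data.frame(value = values, DF = 3, Pmax1 = 0.2, Pmax2 = 0.1,
                         Pmin1 = -0.1, Pmin2 = -0.2, ptp = ptp,
                         mean_level = 0, n_max_clusters = n_max,
                         oscillatory = ptp >= 1e-3, label = "clonic")
  structure(list(param = "c_i1_ei", values = values, direction = "forward",
                 features = features,
                 max_levels = lapply(seq_along(values), function(i) 0.2),
                 min_levels = lapply(seq_along(values), function(i) -0.2),
                 equilibrium = NULL,
                 events = data.frame(type = character(0),
                                     location = numeric(0),
                                     direction = character(0)),
                 final_states = matrix(0, length(values), 6),
                 amp_tol = 1e-3, level_tol = 1e-3, ei_enabled = TRUE),
            class = "tc_bifurcation")
}

test_that("a one-point sweep yields a single column and no events", {
  bd <- sweep_1d(model_parameters(), "c_i1_ei", 0.3,
                 track_equilibrium = FALSE)
  expect_equal(nrow(bd$features), 1)
  expect_equal(nrow(bd$events), 0)
  expect_equal(as.character(bd$features$label), "normal")
})

test_that("period doubling is read off the maxima-level counts", {
  bd <- fake_diagram(seq(0.1, 0.5, by = 0.1), c(1, 1, 2, 2, 4))
  pd <- detect_period_doubling(bd)
  expect_equal(pd$location, c(0.25, 0.45))
  expect_equal(pd$from_levels, c(1L, 2L))
  # constant level count: no events
  expect_equal(nrow(detect_period_doubling(
    fake_diagram(seq(0.1, 0.5, by = 0.1), rep(1, 5)))), 0)
  # non-oscillatory points cannot carry a doubling
  quiet <- fake_diagram(seq(0.1, 0.3, by = 0.1), c(1, 2, 2), ptp = 1e-5)
  expect_equal(nrow(detect_period_doubling(quiet)), 0)
})

test_that("identical forward and backward sweeps give no bistable window", {
  fw <- fake_diagram(seq(0.1, 0.5, by = 0.1), rep(1, 5))
  bw <- fake_diagram(rev(seq(0.1, 0.5, by = 0.1)), rep(1, 5))
  bw$direction <- "backward"
  expect_equal(nrow(detect_bistable_windows(fw, bw)), 0)
})

test_that("differing attractor branches delimit a bistable window", {
  vals <- seq(0.1, 0.7, by = 0.1)
  fw <- fake_diagram(vals, rep(1, 7))
  bw <- fake_diagram(rev(vals), rep(1, 7))
  bw$direction <- "backward"
  # backward branch sits 0.3 higher over the middle three grid points
  for (i in 3:5) {
    j <- length(vals) + 1 - i
    bw$max_levels[[j]] <- 0.5
    bw$min_levels[[j]] <- 0.1
  }
  win <- detect_bistable_windows(fw, bw, tol = 0.02)
  expect_equal(nrow(win), 1)
  expect_equal(win$lower, 0.25)
  expect_equal(win$upper, 0.55)
  expect_equal(win$n_points, 3L)
})

test_that("sweep events agree with the eigenvalue-based Hopf location", {
  p <- fig_gaba_params()
  bd <- sweep_1d(p, "c_i1_ei", seq(0.33, 0.37, by = 0.002))
  hopf <- subset(bd$events, type == "hopf")
  expect_equal(nrow(hopf), 1)
  # oscillation onset column within one grid step of the refined event
  onset <- bd$values[which(bd$features$ptp >= 1e-3)[1]]
  expect_lt(abs(onset - hopf$location), 0.004 + 1e-9)
  # and the first period doubling follows within the scanned range
  pd <- subset(bd$events, type == "period_doubling")
  expect_gte(nrow(pd), 1)
  expect_gt(min(pd$location), hopf$location)
})

test_that("forward and backward sweeps agree away from bistability", {
  grid <- seq(0.30, 0.34, by = 0.002)   # stable fixed-point territory
  fw <- sweep_1d(fig_gaba_params(), "c_i1_ei", grid,
                 track_equilibrium = FALSE)
  bw <- sweep_1d(fig_gaba_params(), "c_i1_ei", rev(grid),
                 track_equilibrium = FALSE)
  expect_equal(nrow(detect_bistable_windows(fw, bw, tol = 0.02)), 0)
})

test_that("single-cell and small state maps classify totally", {
  m1 <- map_2d(model_parameters(), 0.8, 0.3, c_tc_ei = 4.5)
  expect_equal(dim(m1$labels), c(1, 1))
  expect_equal(m1$labels[1, 1], "normal")
  m <- map_2d(model_parameters(), c(0.3, 0.8), c(0.3, 0.8), c_tc_ei = 4.5)
  expect_true(all(m$labels %in% state_labels()))
  expect_equal(dim(m$DF), c(2, 2))
})

test_that("diagram tables combine extrema and equilibrium branches", {
  bd <- sweep_1d(fig_gaba_params(), "c_i1_ei", seq(0.34, 0.36, by = 0.01))
  df <- diagram_table(bd)
  expect_true(all(c("extremum", "equilibrium") %in% df$kind))
  expect_true(all(df$value >= 0.34 & df$value <= 0.36))
})
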