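#' One-dimensional bifurcation sweep
#'
#' Simulates the model at each value of a parameter grid (60 s per point by
#' default), extracts the steady-state features of the trailing window and
#' continues the tracked equilibrium branch alongside.  With attractor
#' inheritance (`inherit = TRUE`, the default) the final state of each run
#' seeds the next grid point, so the sweep follows an attractor through
#' bistable regions; a backward grid then exposes hysteresis.
#'
#' @param p a [model_parameters()] object.
#' @param param name of the swept parameter.
#' @param grid monotone numeric grid of parameter values.
#' @param d a constant [drive_spec()].
#' @param inherit logical; inherit the final state between grid points.
#' @param duration,dt,window simulation settings per grid point.
#' @param s0 initial state for the first grid point (all zeros by
#'   default; with `inherit = FALSE`, for every grid point).
#' @param level_tol,amp_tol feature-extraction tolerances, see
#'   [compute_features()].
#' @param track_equilibrium logical; continue the equilibrium branch and
#'   attach its leading complex eigenvalue real part plus refined Hopf
#'   event locations.
#' @return A `tc_bifurcation` object: `param`, `values`, `direction`,
#'   `features` (data frame, one row per grid value, with the regime
#'   `label`), `max_levels`/`min_levels` (lists of clustered extremum
#'   levels for diagram plotting), `equilibrium` (data frame with state,
#'   leading complex real part, stability), `events` (data frame
#'   `type, location, direction`), `final_states`.
#' @examples
#' \donttest{
#' bd <- sweep_1d(model_parameters(), "c_i1_ei", seq(0.2, 0.9, 0.002))
#' subset(bd$events, type == "hopf")
#' }
#' @export
sweep_1d <- function(p, param, grid, d = drive_spec(), inherit = TRUE,
                     duration = 60, dt = 0.0039, window = 2,
                     s0 = rep(0, 6), level_tol = 1e-3, amp_tol = 1e-3,
                     track_equilibrium = TRUE) {
  stopifnot(inherits(p, "tc_params"), param %in% names(p),
            is.numeric(grid), length(grid) >= 1)
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("'grid' must be strictly monotone")
  if (!is_constant_drive(d))
    stop("sweep_1d requires constant inputs")
  direction <- if (length(grid) > 1 && grid[2] < grid[1]) "backward"
               else "forward"
  n <- length(grid)
  feats <- vector("list", n)
  max_levels <- min_levels <- vector("list", n)
  finals <- matrix(NA_real_, n, 6, dimnames = list(NULL, .state_names))
  s <- check_state(s0)
  for (i in seq_len(n)) {
    p[[param]] <- grid[i]
    r <- tryCatch(simulate_model(p, d, duration, dt, s0 = s),
                  tc_divergence = function(e) NULL)
    if (is.null(r)) {                       # divergent point: record gap
      feats[[i]] <- NULL
      if (!inherit) s <- check_state(s0)
      next
    }
    seg <- analysis_window(r, window)
    f <- compute_features(seg, dt = dt, level_tol = level_tol,
                          amp_tol = amp_tol)
    ex <- if (f$oscillatory) extract_extrema(seg, level_tol)
          else list(max_levels = numeric(0), min_levels = numeric(0))
    feats[[i]] <- cbind(as.data.frame(f),
                        label = as.character(classify_state(f)))
    max_levels[[i]] <- ex$max_levels
    min_levels[[i]] <- ex$min_levels
    finals[i, ] <- r$states[nrow(r$states), ]
    if (inherit) s <- finals[i, ] else s <- check_state(s0)
  }
  missing <- vapply(feats, is.null, logical(1))
  if (all(missing))
    stop("every grid point diverged; no bifurcation diagram to build")
  template <- feats[!missing][[1]]
  for (i in which(missing)) {
    feats[[i]] <- template
    feats[[i]][1, ] <- NA
    feats[[i]]$label <- "unclassified"
  }
  features <- do.call(rbind, c(feats, list(make.row.names = FALSE)))
  features <- cbind(value = grid, features)
  features$label <- factor(features$label, levels = .state_labels)
  bd <- structure(list(param = param, values = grid, direction = direction,
                       features = features, max_levels = max_levels,
                       min_levels = min_levels, equilibrium = NULL,
                       events = data.frame(type = character(0),
                                           location = numeric(0),
                                           direction = character(0)),
                       final_states = finals, amp_tol = amp_tol,
                       level_tol = level_tol, ei_enabled = p$ei_enabled),
                  class = "tc_bifurcation")
  if (track_equilibrium && n > 1)
    bd <- attach_equilibria(bd, p, d)
  pd <- detect_period_doubling(bd)
  if (nrow(pd))
    bd$events <- rbind(bd$events,
                       data.frame(type = "period_doubling",
                                  location = pd$location,
                                  direction = direction))
  bd
}

## Continue the tracked equilibrium along the sweep grid and refine the
## zero crossings of its leading complex eigenvalue pair into Hopf events.
attach_equilibria <- function(bd, p, d) {
  grid <- bd$values
  dv <- drive_value(d, 0, p)
  ## start from the first non-divergent simulated end state
  i0 <- which(apply(is.finite(bd$final_states), 1, all))[1]
  if (is.na(i0)) return(bd)
  p[[bd$param]] <- grid[i0]
  s <- reacquire_equilibrium(bd$final_states[i0, ], p, dv$Npy, dv$Ntc)
  if (is.null(s)) return(bd)
  n <- length(grid)
  lead_re <- rep(NA_real_, n)
  stab <- rep(NA_character_, n)
  states <- matrix(NA_real_, n, 6, dimnames = list(NULL, .state_names))
  order_idx <- c(seq(i0, n), if (i0 > 1) seq(i0 - 1, 1))
  s_dir <- list(up = s, down = s)
  for (i in order_idx) {
    prev <- if (i >= i0) s_dir$up else s_dir$down
    p[[bd$param]] <- grid[i]
    si <- reacquire_equilibrium(prev, p, dv$Npy, dv$Ntc)
    if (is.null(si)) next
    if (i >= i0) s_dir$up <- si else s_dir$down <- si
    states[i, ] <- si
    ev <- eigen(tc_jacobian_cpp(si, par_vector(p)), only.values = TRUE)$values
    lead_re[i] <- leading_complex_re(ev)
    stab[i] <- stability_class(ev)
  }
  bd$equilibrium <- data.frame(value = grid, states, lead_re = lead_re,
                               stability = stab)
  ## refine sign changes by bisection
  sgn <- sign(lead_re)
  for (i in which(diff(sgn) != 0 & is.finite(sgn[-n]) & is.finite(sgn[-1]))) {
    loc <- tryCatch(
      locate_hopf(p, bd$param, grid[i], grid[i + 1], d,
                  s0 = states[i, ]),
      error = function(e) mean(grid[i + 0:1]))
    bd$events <- rbind(bd$events,
                       data.frame(type = "hopf", location = as.numeric(loc),
                                  direction = bd$direction))
  }
  bd
}

#' Detect period-doubling events in a bifurcation sweep
#'
#' A period-doubling event is placed at the midpoint between consecutive
#' grid values where the number of distinct local-maximum levels of the
#' steady-state output doubles (1 to 2, or 2 to 4), both points being
#' oscillatory.  This waveform-based reading matches how the two-amplitude
#' preictal spike pattern is identified in the reference diagrams; no
#' Floquet analysis is performed.
#'
#' @param bd a `tc_bifurcation` from [sweep_1d()] (built with
#'   `inherit = TRUE`).
#' @return Data frame with columns `location` and `from_levels`.
#' @export
detect_period_doubling <- function(bd) {
  stopifnot(inherits(bd, "tc_bifurcation"))
  f <- bd$features
  n <- nrow(f)
  out <- data.frame(location = numeric(0), from_levels = integer(0))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    a <- f$n_max_clusters[i]; b <- f$n_max_clusters[i + 1]
    if (is.na(a) || is.na(b)) next
    osc <- isTRUE(f$ptp[i] >= bd$amp_tol) && isTRUE(f$ptp[i + 1] >= bd$amp_tol)
    if (osc && a >= 1 && b == 2 * a && a <= 2)
      out <- rbind(out, data.frame(location = mean(bd$values[i + 0:1]),
                                   from_levels = a))
  }
  out
}

#' Detect bistable windows from a forward/backward sweep pair
#'
#' Compares the steady-state attractors reached by forward and backward
#' sweeps (both with attractor inheritance) over the same grid.  Grid
#' values where the two extrema sets differ by more than `tol` form
#' bistable windows; the window edges approximate fold-limit-cycle and
#' subcritical-Hopf boundaries of the hysteresis loops.
#'
#' @param forward,backward `tc_bifurcation` objects over the same grid,
#'   opposite directions.
#' @param tol amplitude tolerance for calling two attractors different.
#' @return Data frame with one row per window: `lower`, `upper` (interval
#'   midpoint edges) and `n_points`.
#' @export
detect_bistable_windows <- function(forward, backward, tol = 0.02) {
  stopifnot(inherits(forward, "tc_bifurcation"),
            inherits(backward, "tc_bifurcation"))
  gf <- forward$values
  gb <- rev(backward$values)
  if (length(gf) != length(gb) || max(abs(gf - gb)) > 1e-12)
    stop("forward and backward sweeps must share one grid")
  idx_b <- rev(seq_along(gb))
  differ <- vapply(seq_along(gf), function(i) {
    attractor_distance(forward$max_levels[[i]],
                       backward$max_levels[[idx_b[i]]],
                       forward$min_levels[[i]],
                       backward$min_levels[[idx_b[i]]]) > tol
  }, logical(1))
  runs <- rle(differ)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(lower = numeric(0), upper = numeric(0),
                    n_points = integer(0))
  for (k in which(runs$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    lower <- if (i1 > 1) mean(gf[(i1 - 1):i1]) else gf[1]
    upper <- if (i2 < length(gf)) mean(gf[i2:(i2 + 1)]) else gf[length(gf)]
    out <- rbind(out, data.frame(lower = lower, upper = upper,
                                 n_points = i2 - i1 + 1L))
  }
  out
}

## Hausdorff-style distance between the extrema-level sets of two
## attractors; empty vs non-empty counts as the other set's amplitude span.
attractor_distance <- function(max_a, max_b, min_a, min_b) {
  set_d <- function(a, b) {
    if (!length(a) && !length(b)) return(0)
    if (!length(a) || !length(b))
      return(max(abs(range(c(a, b)))))
    max(max(vapply(a, function(x) min(abs(x - b)), numeric(1))),
        max(vapply(b, function(x) min(abs(x - a)), numeric(1))))
  }
  max(set_d(max_a, max_b), set_d(min_a, min_b))
}

#' Two-dimensional state map over the EI coupling plane
#'
#' Simulates the model on a grid of `(c_py_ei, c_i1_ei)` values at a fixed
#' thalamus-to-EI coupling, classifies each cell and records its dominant
#' frequency.  Every cell starts from the same initial state (all zeros by
#' default), so the map shows the attractor reached from a fixed
#' condition.
#'
#' @param p a [model_parameters()] object.
#' @param grid_py_ei,grid_i1_ei numeric grids for the two couplings.
#' @param c_tc_ei fixed thalamus-to-EI coupling.
#' @param d a constant [drive_spec()].
#' @param duration,dt,window,s0,level_tol,amp_tol as in [sweep_1d()].
#' @return A `tc_statemap`: `labels` (factor matrix, rows = `grid_py_ei`),
#'   `DF` matrix, the two grids and `c_tc_ei`.  Divergent cells get the
#'   label `unclassified` and `NA` frequency.
#' @examples
#' \donttest{
#' m <- map_2d(model_parameters(), seq(0.1, 0.9, length = 40),
#'             seq(0.2, 0.9, length = 40), c_tc_ei = 4.5)
#' table(m$labels)
#' }
#' @export
map_2d <- function(p, grid_py_ei, grid_i1_ei, c_tc_ei = 4.5,
                   d = drive_spec(), duration = 60, dt = 0.0039,
                   window = 2, s0 = rep(0, 6), level_tol = 1e-3,
                   amp_tol = 1e-3) {
  stopifnot(inherits(p, "tc_params"), is.numeric(grid_py_ei),
            is.numeric(grid_i1_ei))
  if (!is_constant_drive(d)) stop("map_2d requires constant inputs")
  p$c_tc_ei <- c_tc_ei
  nx <- length(grid_py_ei); ny <- length(grid_i1_ei)
  labels <- matrix(NA_character_, nx, ny)
  DF <- matrix(NA_real_, nx, ny)
  s0 <- check_state(s0)
  for (i in seq_len(nx)) {
    p$c_py_ei <- grid_py_ei[i]
    for (j in seq_len(ny)) {
      p$c_i1_ei <- grid_i1_ei[j]
      r <- tryCatch(simulate_model(p, d, duration, dt, s0 = s0),
                    tc_divergence = function(e) NULL)
      if (is.null(r)) { labels[i, j] <- "unclassified"; next }
      f <- compute_features(r, window, level_tol = level_tol,
                            amp_tol = amp_tol)
      labels[i, j] <- as.character(classify_state(f))
      DF[i, j] <- f$DF
    }
  }
  structure(list(labels = labels, DF = DF, grid_py_ei = grid_py_ei,
                 grid_i1_ei = grid_i1_ei, c_tc_ei = c_tc_ei),
            class = "tc_statemap")
}

#' @export
print.tc_statemap <- function(x, ...) {
  cat(sprintf("<tc_statemap> %d x %d cells, c_tc_ei = %g\n",
              length(x$grid_py_ei), length(x$grid_i1_ei), x$c_tc_ei))
  print(table(factor(x$labels, levels = .state_labels)))
  invisible(x)
}

#' Export a bifurcation diagram as long-format CSV
#'
#' One row per plotted element: extremum levels (`kind = "extremum"`) and
#' equilibrium output levels (`kind = "equilibrium"`, with stability).
#'
#' @param bd a `tc_bifurcation`.
#' @param path optional output CSV path.
#' @return The long-format data frame, invisibly when written.
#' @export
diagram_table <- function(bd, path = NULL) {
  stopifnot(inherits(bd, "tc_bifurcation"))
  rows <- list()
  for (i in seq_along(bd$values)) {
    lv <- c(bd$max_levels[[i]], bd$min_levels[[i]])
    if (length(lv))
      rows[[length(rows) + 1L]] <-
        data.frame(param = bd$param, value = bd$values[i],
                   kind = "extremum", y = lv, stability = NA_character_)
  }
  if (!is.null(bd$equilibrium)) {
    eq <- bd$equilibrium
    y <- if (isTRUE(bd$ei_enabled)) (eq$PY + eq$I1 + eq$I2 + eq$EI) / 4
         else (eq$PY + eq$I1 + eq$I2) / 3
    rows[[length(rows) + 1L]] <-
      data.frame(param = bd$param, value = eq$value, kind = "equilibrium",
                 y = y, stability = eq$stability)
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
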