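#' Sigmoidal firing-rate transfer function
#'
#' `f(x) = 1 / (1 + epsilon^(-x))`, the population transfer function mapping
#' mean membrane potential to normalized firing rate.  Overflow-safe for
#' large `|x|`.
#'
#' @param x potential (numeric, finite; vectorized).
#' @param epsilon steepness base, must exceed 1.  Default is the model's
#'   reference value 250000.
#' @return Values in (0, 1).
#' @seealso [sigmoid_derivative()]
#' @export
sigmoid <- function(x, epsilon = 250000) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 1)
    stop("'epsilon' must be a single number > 1")
  stats::plogis(log(epsilon) * x)
}

#' Derivative of the sigmoidal transfer function
#'
#' `f'(x) = log(epsilon) * f(x) * (1 - f(x))`, used to assemble the analytic
#' Jacobian of the vector field.
#'
#' @inheritParams sigmoid
#' @return Non-negative slopes; `log(epsilon)/4` at `x = 0`, tending to 0 as
#'   `|x|` grows.
#' @export
sigmoid_derivative <- function(x, epsilon = 250000) {
  f <- sigmoid(x, epsilon)
  log(epsilon) * f * (1 - f)
}

check_state <- function(s) {
  if (!is.numeric(s) || length(s) != 6L || any(!is.finite(s)))
    stop("state must be a finite numeric vector of length 6 (PY, I1, I2, EI, TC, RE)")
  s <- as.numeric(s)
  names(s) <- .state_names
  s
}

#' Right-hand side of the model ODEs
#'
#' Evaluates the six population derivatives at a state, for given constant
#' drive values.  The cortical drive `Npy` is added to the PY equation and
#' the sensory drive `Ntc` to the TC equation, both outside the time-scale
#' multiplier.  With `ei_enabled = FALSE` the EI derivative is zero and all
#' EI source terms are dropped.
#'
#' @param s state vector `(PY, I1, I2, EI, TC, RE)`.
#' @param p a [model_parameters()] object.
#' @param Npy,Ntc drive values (already including any input gain is not
#'   expected here: the gains `c_Npy_py`, `c_Ntc_tc` are applied by
#'   [drive_value()] / [simulate()]; pass plain values for direct use).
#' @return Numeric length-6 derivative vector.
#' @export
vector_field <- function(s, p, Npy = 0, Ntc = 0) {
  s <- check_state(s)
  stopifnot(inherits(p, "tc_params"), is.finite(Npy), is.finite(Ntc))
  ds <- tc_field_cpp(s, par_vector(p), Npy, Ntc)
  names(ds) <- .state_names
  ds
}

#' Simulate the model with fixed-step RK4
#'
#' Integrates the six-population model with the classic fourth-order
#' Runge-Kutta scheme at a fixed step, under constant or sinusoidal drives.
#' The run is fully deterministic: identical arguments give bit-identical
#' trajectories.  Default duration (60 s) and step (0.0039 s) match the
#' reference analysis protocol.
#'
#' @param p a [model_parameters()] object.
#' @param d a [drive_spec()]; defaults to constant inputs 0.7 / 0.1.
#' @param duration simulated time in seconds.
#' @param dt integration step in seconds.
#' @param s0 initial state; default all zeros.
#' @param t0 start time in seconds.  Chained runs (see
#'   [state_switch_protocol()]) pass the previous end time so sinusoidal
#'   drives stay phase-continuous.
#' @return A `tc_sim` object: list with `times`, `states`
#'   (matrix, columns PY, I1, I2, EI, TC, RE), `output` (cortical mean,
#'   `(PY+I1+I2+EI)/4`, or the three-population mean under EI ablation),
#'   `dt`, `params`, `drive`.
#' @examples
#' r <- simulate_model(model_parameters(), duration = 2)
#' range(r$output)
#' @export
simulate_model <- function(p, d = drive_spec(), duration = 60, dt = 0.0039,
                           s0 = rep(0, 6), t0 = 0) {
  stopifnot(inherits(p, "tc_params"), inherits(d, "tc_drive"),
            duration > 0, dt > 0)
  n <- as.integer(round(duration / dt))
  if (n < 2) stop("duration/dt must be at least 2 steps")
  s0 <- check_state(s0)
  res <- tc_rk4_cpp(s0, t0, n, dt, par_vector(p), drive_vector(d))
  if (res$diverged >= 0)
    stop(structure(class = c("tc_divergence", "error", "condition"),
                   list(message = sprintf(
                     "simulation diverged (|state| > 1e6) at step %d (t = %.4f s)",
                     res$diverged, t0 + res$diverged * dt),
                     call = sys.call(-1), step = res$diverged)))
  states <- res$states
  colnames(states) <- .state_names
  structure(list(times = t0 + dt * (0:n), states = states,
                 output = res$output, dt = dt, params = p, drive = d),
            class = "tc_sim")
}

#' @export
print.tc_sim <- function(x, ...) {
  cat(sprintf("<tc_sim> %d steps, dt = %g s, t in [%g, %g] s\n",
              length(x$times) - 1L, x$dt, x$times[1],
              x$times[length(x$times)]))
  cat(sprintf("  output range [%.4f, %.4f]\n", min(x$output), max(x$output)))
  invisible(x)
}

#' @export
as.data.frame.tc_sim <- function(x, ...) {
  data.frame(t = x$times, x$states, output = x$output)
}

#' Write a simulated trajectory to CSV
#'
#' One row per step with header `t,PY,I1,I2,EI,TC,RE,output`, full double
#' precision.
#'
#' @param r a `tc_sim` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(r, path) {
  stopifnot(inherits(r, "tc_sim"))
  utils::write.csv(as.data.frame(r), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
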