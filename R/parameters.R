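## Canonical parameter ordering shared with src/model.cpp.
.coupling_names <- c(
  "c_py_py", "c_py_i1", "c_i1_py", "c_re_re", "c_tc_re", "c_re_tc",
  "c_py_tc", "c_py_re", "c_tc_py", "c_py_i2", "c_tc_i1", "c_tc_i2",
  "c_ei_i1", "c_ei_py", "c_i2_py", "c_i2_i1", "c_i1_i2", "c_py_ei",
  "c_i1_ei", "c_tc_ei")
.gain_names <- c("c_Npy_py", "c_Ntc_tc")
.h_names <- c("h_py", "h_i1", "h_i2", "h_ei", "h_tc", "h_re")
.tau_names <- c("tau_1", "tau_2", "tau_3", "tau_4", "tau_5", "tau_6")
.par_order <- c(.coupling_names, .gain_names, .h_names, .tau_names,
                "epsilon", "ei_enabled")

.state_names <- c("PY", "I1", "I2", "EI", "TC", "RE")

#' Model parameters of the thalamocortical circuit
#'
#' Construct the full parameter set of the six-population neural mass model:
#' pyramidal (PY), fast and slow inhibitory interneurons (I1, I2), excitatory
#' interneurons / spiny stellate cells (EI), thalamic relay (TC) and thalamic
#' reticular (RE) populations.  Coupling strengths follow the
#' `c_SOURCE_TARGET` convention: `c_i1_ei` is the coefficient of `f(I1)` in
#' the EI equation, i.e. the GABAergic inhibition received by EI.
#'
#' Defaults are the published reference parameterization of the circuit,
#' with the three EI input couplings at their baseline (interictal) values
#' `c_py_ei = 0.8`, `c_i1_ei = 0.3`, `c_tc_ei = 4.5`.
#'
#' @param ... named overrides of any parameter, e.g. `c_i1_ei = 0.36`.
#'   Unknown names are an error.
#' @param ei_enabled logical; when `FALSE` the EI population is ablated:
#'   its state is frozen at zero, every term with EI as source is dropped,
#'   and the model output becomes the mean of the three remaining cortical
#'   populations.
#'
#' @return An object of class `tc_params`: a named list with the 20 coupling
#'   strengths, two input gains (`c_Npy_py`, `c_Ntc_tc`), six input offsets
#'   `h_*`, six time scales `tau_1..tau_6` (1/s), the sigmoid steepness
#'   `epsilon` and the `ei_enabled` flag.
#' @examples
#' p <- model_parameters(c_i1_ei = 0.36)
#' p$c_i1_ei
#' @export
model_parameters <- function(..., ei_enabled = TRUE) {
  p <- list(
    c_py_py = 1.89, c_py_i1 = 4, c_i1_py = 1.8, c_re_re = 0.01,
    c_tc_re = 10, c_re_tc = 1.4, c_py_tc = 3, c_py_re = 1.4,
    c_tc_py = 1, c_py_i2 = 1.5, c_tc_i1 = 0.05, c_tc_i2 = 0.05,
    c_ei_i1 = 0.05, c_ei_py = 0.442, c_i2_py = 0.05, c_i2_i1 = 0.1,
    c_i1_i2 = 0.5, c_py_ei = 0.8, c_i1_ei = 0.3, c_tc_ei = 4.5,
    c_Npy_py = 1, c_Ntc_tc = 1,
    h_py = -0.4, h_i1 = -3.4, h_i2 = -2, h_ei = -1, h_tc = -2.5,
    h_re = -3.2,
    tau_1 = 21.5, tau_2 = 31.5, tau_3 = 0.1, tau_4 = 4.5, tau_5 = 3.8,
    tau_6 = 3.9,
    epsilon = 250000, ei_enabled = isTRUE(ei_enabled))
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_parameters(p)
  structure(p, class = "tc_params")
}

validate_parameters <- function(p) {
  num <- setdiff(.par_order, "ei_enabled")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  for (nm in .tau_names)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be positive")
  if (p$epsilon <= 1) stop("parameter 'epsilon' must exceed 1")
  for (nm in c(.coupling_names, .gain_names))
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  if (!is.logical(p$ei_enabled) || length(p$ei_enabled) != 1L ||
      is.na(p$ei_enabled))
    stop("'ei_enabled' must be TRUE or FALSE")
  invisible(p)
}

## Flatten a tc_params into the numeric vector consumed by the C++ kernels.
par_vector <- function(p) {
  v <- vapply(.par_order, function(nm) {
    if (nm == "ei_enabled") as.numeric(p[[nm]]) else p[[nm]]
  }, numeric(1))
  names(v) <- .par_order
  v
}

#' Sinusoidal cortical and sensory drive specification
#'
#' The pyramidal population receives the cortical input
#' `Npy = B_Npy + a_py * sin(2*pi*fpy*t)` and the thalamic relay nucleus the
#' sensory input `Ntc = B_Ntc + a_tc * sin(2*pi*ftc*t)`.  Constant-input
#' mode (used for all autonomous bifurcation analyses) is `a_py = a_tc = 0`,
#' which is the default.
#'
#' @param B_Npy,B_Ntc constant bias of the cortical / sensory input.
#' @param a_py,a_tc sinusoid amplitudes (non-negative).
#' @param fpy,ftc drive frequencies in Hz (non-negative).
#' @return An object of class `tc_drive`.
#' @examples
#' drive_spec()                      # constant inputs 0.7 / 0.1
#' drive_spec(a_tc = 0.02, ftc = 4)  # 4 Hz sensory stimulation
#' @export
drive_spec <- function(B_Npy = 0.7, a_py = 0, fpy = 0,
                       B_Ntc = 0.1, a_tc = 0, ftc = 0) {
  d <- list(B_Npy = B_Npy, a_py = a_py, fpy = fpy,
            B_Ntc = B_Ntc, a_tc = a_tc, ftc = ftc)
  for (nm in names(d))
    if (!is.numeric(d[[nm]]) || length(d[[nm]]) != 1L || !is.finite(d[[nm]]))
      stop("drive field '", nm, "' must be a single finite number")
  if (d$a_py < 0 || d$a_tc < 0) stop("drive amplitudes must be >= 0")
  if (d$fpy < 0 || d$ftc < 0) stop("drive frequencies must be >= 0")
  structure(d, class = "tc_drive")
}

drive_vector <- function(d) {
  c(d$B_Npy, d$a_py, d$fpy, d$B_Ntc, d$a_tc, d$ftc)
}

is_constant_drive <- function(d) d$a_py == 0 && d$a_tc == 0

#' Evaluate the drives at a time point
#'
#' @param d a [drive_spec()].
#' @param t time in seconds (vectorized, must be non-negative).
#' @param p optional [model_parameters()] supplying the input gains
#'   `c_Npy_py` and `c_Ntc_tc` (both default 1).
#' @return A list with numeric components `Npy` and `Ntc`.
#' @export
drive_value <- function(d, t, p = NULL) {
  stopifnot(inherits(d, "tc_drive"), is.numeric(t), all(t >= 0))
  g_py <- if (is.null(p)) 1 else p$c_Npy_py
  g_tc <- if (is.null(p)) 1 else p$c_Ntc_tc
  list(Npy = g_py * (d$B_Npy + d$a_py * sin(2 * pi * d$fpy * t)),
       Ntc = g_tc * (d$B_Ntc + d$a_tc * sin(2 * pi * d$ftc * t)))
}

#' @export
print.tc_params <- function(x, ...) {
  cat("<tc_params> thalamocortical neural mass parameters\n")
  cat("  EI couplings: c_py_ei =", x$c_py_ei, " c_i1_ei =", x$c_i1_ei,
      " c_tc_ei =", x$c_tc_ei, "\n")
  cat("  EI population:", if (x$ei_enabled) "enabled" else "ablated", "\n")
  defaults <- model_parameters(ei_enabled = x$ei_enabled)
  changed <- Filter(function(nm) !identical(x[[nm]], defaults[[nm]]),
                    setdiff(.par_order, "ei_enabled"))
  if (length(changed))
    cat("  non-default:",
        paste(sprintf("%s = %g", changed,
                      unlist(x[changed], use.names = FALSE)),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.tc_drive <- function(x, ...) {
  cat(sprintf("<tc_drive> Npy = %g + %g sin(2pi %g t);  Ntc = %g + %g sin(2pi %g t)\n",
              x$B_Npy, x$a_py, x$fpy, x$B_Ntc, x$a_tc, x$ftc))
  invisible(x)
}
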