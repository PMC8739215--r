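#' Trailing analysis window of a simulation
#'
#' Steady-state analysis uses the final stretch of the output series
#' (default 2 s, i.e. 512 samples at the default step), discarding the
#' transient.
#'
#' @param r a `tc_sim` object.
#' @param window window length in seconds (default 2).
#' @return Numeric vector: the last `floor(window/dt)` output samples.
#' @export
analysis_window <- function(r, window = 2) {
  stopifnot(inherits(r, "tc_sim"), window > 0)
  n <- length(r$output)
  k <- floor(window / r$dt)
  if (k > n) stop("analysis window is longer than the simulation")
  r$output[(n - k + 1L):n]
}

#' Local extrema of a series, with level clustering
#'
#' Interior extrema are strict sign changes of the first difference.
#' Extremum values are grouped into levels: after sorting, a gap larger
#' than `level_tol` starts a new level.  Level counts distinguish e.g. a
#' single-amplitude limit cycle (one maximum level) from the two-amplitude
#' pattern that emerges after a period doubling.
#'
#' @param segment numeric series (length >= 3).
#' @param level_tol clustering tolerance in amplitude units.
#' @return List with `maxima`, `minima` (raw extremum values),
#'   `max_levels`, `min_levels` (cluster representatives, one mean value
#'   per level).  A constant segment yields empty vectors.
#' @export
extract_extrema <- function(segment, level_tol = 1e-3) {
  stopifnot(is.numeric(segment), length(segment) >= 3)
  d <- diff(segment)
  sg <- sign(d)
  ## strict sign changes only: plateaus (sign 0) break any extremum
  idx <- which(sg[-length(sg)] * sg[-1] < 0) + 1L
  maxima <- segment[idx][sg[idx - 1L] > 0]
  minima <- segment[idx][sg[idx - 1L] < 0]
  list(maxima = maxima, minima = minima,
       max_levels = cluster_levels(maxima, level_tol),
       min_levels = cluster_levels(minima, level_tol))
}

## one representative (mean) per group of values closer than tol
cluster_levels <- function(v, tol) {
  if (!length(v)) return(numeric(0))
  v <- sort(v)
  grp <- cumsum(c(1, diff(v) > tol))
  as.numeric(tapply(v, grp, mean))
}

#' Dominant frequency of a series
#'
#' Frequency of the maximum-power bin of the mean-removed FFT periodogram,
#' over strictly positive frequencies.  A segment whose peak-to-peak
#' amplitude is below `amp_tol` is treated as non-oscillatory and assigned
#' 0 Hz.
#'
#' @param segment numeric series (length >= 16).
#' @param dt sampling step in seconds.
#' @param amp_tol no-oscillation threshold on peak-to-peak amplitude.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(segment, dt, amp_tol = 1e-3) {
  stopifnot(is.numeric(segment), length(segment) >= 16, dt > 0)
  if (diff(range(segment)) < amp_tol) return(0)
  n <- length(segment)
  pw <- Mod(stats::fft(segment - mean(segment)))^2
  ks <- 2:(n %/% 2 + 1L)                 # positive frequencies up to Nyquist
  (ks[which.max(pw[ks])] - 1L) / (n * dt)
}

#' Feature set of a simulated output window
#'
#' Composes [analysis_window()], [extract_extrema()] and
#' [dominant_frequency()] into the feature vector used for regime
#' classification: dominant frequency `DF`, the largest and smallest local
#' maxima (`Pmax1 >= Pmax2`), the largest and smallest local minima
#' (`Pmin1 >= Pmin2`), peak-to-peak amplitude `ptp`, the window mean
#' `mean_level`, and the number of distinct maximum levels
#' `n_max_clusters`.
#'
#' When `ptp < amp_tol` the window counts as non-oscillatory: `DF = 0`,
#' the extrema fields are `NA` and `n_max_clusters = 0`.
#'
#' @param r a `tc_sim` object, or a plain numeric series (then `dt` must be
#'   given).
#' @param window trailing window in seconds (ignored for a plain series).
#' @param dt sampling step, required when `r` is a plain series.
#' @param level_tol extremum level clustering tolerance.
#' @param amp_tol no-oscillation peak-to-peak threshold.
#' @return An object of class `tc_features` (named list).
#' @export
compute_features <- function(r, window = 2, dt = NULL, level_tol = 1e-3,
                             amp_tol = 1e-3) {
  if (inherits(r, "tc_sim")) {
    segment <- analysis_window(r, window)
    dt <- r$dt
  } else {
    if (is.null(dt)) stop("'dt' is required for a plain numeric series")
    segment <- as.numeric(r)
  }
  ptp <- diff(range(segment))
  oscillatory <- ptp >= amp_tol
  if (!oscillatory) {
    f <- list(DF = 0, Pmax1 = NA_real_, Pmax2 = NA_real_,
              Pmin1 = NA_real_, Pmin2 = NA_real_, ptp = ptp,
              mean_level = mean(segment), n_max_clusters = 0L,
              oscillatory = FALSE)
    return(structure(f, class = "tc_features"))
  }
  ex <- extract_extrema(segment, level_tol)
  f <- list(
    DF = dominant_frequency(segment, dt, amp_tol),
    Pmax1 = if (length(ex$maxima)) max(ex$maxima) else NA_real_,
    Pmax2 = if (length(ex$maxima)) min(ex$maxima) else NA_real_,
    Pmin1 = if (length(ex$minima)) max(ex$minima) else NA_real_,
    Pmin2 = if (length(ex$minima)) min(ex$minima) else NA_real_,
    ptp = ptp, mean_level = mean(segment),
    n_max_clusters = length(ex$max_levels), oscillatory = TRUE)
  structure(f, class = "tc_features")
}

#' @export
print.tc_features <- function(x, ...) {
  cat(sprintf("<tc_features> DF = %.2f Hz, ptp = %.4g, %d max level(s)\n",
              x$DF, x$ptp, x$n_max_clusters))
  if (x$oscillatory)
    cat(sprintf("  Pmax1 = %.4f  Pmax2 = %.4f  Pmin1 = %.4f  Pmin2 = %.4f\n",
                x$Pmax1, x$Pmax2, x$Pmin1, x$Pmin2))
  invisible(x)
}

#' @export
as.data.frame.tc_features <- function(x, ...) {
  data.frame(DF = x$DF, Pmax1 = x$Pmax1, Pmax2 = x$Pmax2,
             Pmin1 = x$Pmin1, Pmin2 = x$Pmin2, ptp = x$ptp,
             mean_level = x$mean_level, n_max_clusters = x$n_max_clusters)
}
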