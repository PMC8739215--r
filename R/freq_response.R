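#' Frequency-response sweep of a sinusoidal drive
#'
#' Drives one input channel (`"sensory"` = thalamic relay, `"cortical"` =
#' pyramidal) with a sinusoid of fixed amplitude while the other channel
#' stays constant, across a grid of drive frequencies.  Each frequency is
#' simulated for `duration` seconds and the steady-state peak-to-peak
#' amplitude, dominant frequency and extrema of the trailing window are
#' recorded.  With `inherit = TRUE` the end state of one frequency seeds
#' the next, which preserves the attractor branch across the grid and is
#' what makes hysteresis-type amplitude jumps observable.
#'
#' An optional refinement pass re-samples the neighbourhood of the
#' amplitude maximum at a finer step, so resonance peaks are located at
#' `refine_step` resolution without paying for a fine global grid.
#'
#' A frequency is flagged `chaotic` when the trailing window fails to be
#' periodic at the drive period: the normalized autocorrelation of the
#' window at one drive-period lag falls below 0.9.  (A proxy for
#' aperiodicity; no Lyapunov exponents are computed.)
#'
#' @param p a [model_parameters()] object.
#' @param channel `"sensory"` or `"cortical"`.
#' @param freqs strictly increasing frequency grid in Hz.
#' @param amp drive amplitude (default 0.02, the reference stimulation
#'   amplitude).
#' @param B_Npy,B_Ntc input biases.
#' @param inherit carry the final state across frequencies.
#' @param duration,dt,window,s0 simulation settings per frequency.
#' @param refine logical; refine around the amplitude peak.
#' @param refine_step fine step in Hz for the refinement pass.
#' @param window_mode `"drive_period"` (default) widens the analysis
#'   window to at least one full drive period, the correct steady-state
#'   measure for slow drives; `"fixed"` always uses exactly `window`
#'   seconds, the historical last-2-s reading, which attenuates and
#'   phase-modulates the response below `1/window` Hz.
#' @return A `tc_freqresp` object with `channel`, `response` (data frame
#'   `freq, ptp, DF, n_max_clusters, chaotic`, refined points merged in
#'   order), and the simulation settings.
#' @examples
#' \donttest{
#' fr <- frequency_sweep(model_parameters(c_py_ei = 0.76), "sensory",
#'                       seq(0.5, 8, by = 0.25))
#' detect_resonance(fr)
#' }
#' @export
frequency_sweep <- function(p, channel = c("sensory", "cortical"), freqs,
                            amp = 0.02, B_Npy = 0.7, B_Ntc = 0.1,
                            inherit = TRUE, duration = 60, dt = 0.0039,
                            window = 2, s0 = rep(0, 6), refine = FALSE,
                            refine_step = 0.01,
                            window_mode = c("drive_period", "fixed")) {
  channel <- match.arg(channel)
  window_mode <- match.arg(window_mode)
  stopifnot(inherits(p, "tc_params"), is.numeric(freqs), amp >= 0)
  if (length(freqs) > 1 && !(all(diff(freqs) > 0) || all(diff(freqs) < 0)))
    stop("'freqs' must be strictly monotone")
  run_grid <- function(fgrid, s_init) {
    s <- check_state(s_init)
    rows <- vector("list", length(fgrid))
    finals <- matrix(NA_real_, length(fgrid), 6)
    for (i in seq_along(fgrid)) {
      d <- if (channel == "sensory")
        drive_spec(B_Npy = B_Npy, B_Ntc = B_Ntc, a_tc = amp,
                   ftc = fgrid[i])
      else
        drive_spec(B_Npy = B_Npy, B_Ntc = B_Ntc, a_py = amp,
                   fpy = fgrid[i])
      r <- tryCatch(simulate_model(p, d, duration, dt, s0 = s),
                    tc_divergence = function(e) NULL)
      if (is.null(r)) {
        rows[[i]] <- data.frame(freq = fgrid[i], ptp = NA_real_,
                                DF = NA_real_, n_max_clusters = NA_integer_,
                                chaotic = NA, diverged = TRUE)
        if (!inherit) s <- check_state(s_init)
        next
      }
      ## the steady-state swing of a driven response is only visible over
      ## at least one full drive period, so widen the window for slow drives
      win <- if (window_mode == "drive_period")
        min(max(window, 1 / fgrid[i]), duration / 2) else window
      seg <- analysis_window(r, win)
      f <- compute_features(seg, dt = dt)
      rows[[i]] <- data.frame(freq = fgrid[i], ptp = f$ptp, DF = f$DF,
                              n_max_clusters = f$n_max_clusters,
                              chaotic = is_aperiodic(seg, dt, fgrid[i]),
                              diverged = FALSE)
      finals[i, ] <- r$states[nrow(r$states), ]
      if (inherit) s <- finals[i, ] else s <- check_state(s_init)
    }
    list(df = do.call(rbind, rows), finals = finals)
  }
  base <- run_grid(freqs, s0)
  df <- base$df
  if (refine && any(is.finite(df$ptp))) {
    i_pk <- which.max(df$ptp)
    lo <- freqs[max(1L, i_pk - 1L)]
    hi <- freqs[min(length(freqs), i_pk + 1L)]
    fine <- setdiff(round(seq(lo, hi, by = refine_step), 10), freqs)
    if (length(fine)) {
      s_init <- if (inherit && i_pk > 1L && all(is.finite(base$finals[i_pk - 1L, ])))
        base$finals[i_pk - 1L, ] else s0
      ref <- run_grid(fine, s_init)
      df <- rbind(df, ref$df)
      df <- df[order(df$freq), ]
      rownames(df) <- NULL
    }
  }
  structure(list(channel = channel, response = df, amp = amp,
                 duration = duration, dt = dt, window = window),
            class = "tc_freqresp")
}

## periodicity check: normalized autocorrelation at one drive-period lag
is_aperiodic <- function(segment, dt, freq, threshold = 0.9) {
  if (freq <= 0) return(NA)
  lag <- as.integer(round(1 / (freq * dt)))
  n <- length(segment)
  if (lag < 1 || lag > n / 2) return(NA)
  x <- segment - mean(segment)
  denom <- sum(x^2)
  if (denom < 1e-20) return(FALSE)
  ac <- sum(x[1:(n - lag)] * x[(lag + 1):n]) /
    sqrt(sum(x[1:(n - lag)]^2) * sum(x[(lag + 1):n]^2))
  ac < threshold
}

#' Detect resonance peaks in a frequency response
#'
#' Local maxima of the (lightly smoothed) amplitude curve whose prominence
#' exceeds a fraction of the curve's range, including boundary maxima;
#' sorted by peak amplitude, largest first.
#'
#' @param fr a `tc_freqresp`.
#' @param smooth odd moving-average length (1 disables smoothing).
#' @param prominence minimal peak prominence as a fraction of the
#'   amplitude range.
#' @return Data frame `freq, ptp, prominence`, ordered by `ptp`.
#' @export
detect_resonance <- function(fr, smooth = 5, prominence = 0.05) {
  stopifnot(inherits(fr, "tc_freqresp"))
  df <- fr$response[is.finite(fr$response$ptp), ]
  y <- df$ptp
  n <- length(y)
  if (n < 3) stop("response curve too short")
  if (smooth > 1) {
    k <- min(smooth, n - (1 - n %% 2))
    y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    y[is.na(y)] <- df$ptp[is.na(y)]
  }
  is_peak <- c(y[1] > y[2],
               y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               y[n] > y[n - 1])
  rng <- diff(range(y))
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(i) {
    sides <- c(if (i > 1) min(y[1:i]), if (i < n) min(y[i:n]))
    y[i] - max(sides)
  }, numeric(1))
  keep <- prom >= prominence * rng
  out <- data.frame(freq = df$freq[peaks[keep]], ptp = df$ptp[peaks[keep]],
                    prominence = prom[keep])
  out[order(-out$ptp), , drop = FALSE]
}

#' Detect amplitude jumps in a frequency response
#'
#' A jump -- the signature of non-linear resonance -- is an
#' adjacent-grid-point amplitude difference exceeding `factor` times the
#' median adjacent difference of the curve.  Reported at the midpoint of
#' the jumping interval.
#'
#' @param fr a `tc_freqresp`.
#' @param jump_tol absolute amplitude threshold overriding the
#'   median-based rule when supplied.
#' @param factor multiple of the median adjacent difference (default 5).
#' @return Data frame `freq, delta`, ordered by frequency.
#' @export
detect_jumps <- function(fr, jump_tol = NULL, factor = 5) {
  stopifnot(inherits(fr, "tc_freqresp"))
  df <- fr$response[is.finite(fr$response$ptp), ]
  dy <- abs(diff(df$ptp))
  thr <- if (!is.null(jump_tol)) jump_tol else factor * stats::median(dy)
  idx <- which(dy > thr & dy > 0)
  data.frame(freq = (df$freq[idx] + df$freq[idx + 1]) / 2, delta = dy[idx])
}

#' Piecewise-constant parameter switch protocol
#'
#' Simulates the model while `c_py_ei` follows a piecewise-constant
#' schedule under a fixed sinusoidal drive, chaining the epochs with state
#' and drive-phase continuity.  The default schedule
#' `0.76 -> 0.748 -> 0.76` moves the model from its normal (interictal)
#' state into the preictal configuration and back, which under a 1 Hz
#' drive elicits a reversible transition into high-amplitude
#' absence-type discharges.
#'
#' @param p a [model_parameters()] object (its `c_py_ei` is overridden).
#' @param schedule data frame with columns `c_py_ei` and `duration`
#'   (seconds); values must lie in \[0.3, 0.9\].
#' @param d a [drive_spec()] providing the fixed drive (default: 1 Hz
#'   cortical sinusoid of amplitude 0.02, silent sensory channel).
#' @param dt integration step.
#' @param window trailing window for the per-epoch features.
#' @param s0 initial state.
#' @return A `tc_switch` object: combined `times`/`output`, `epoch` index
#'   per sample, the schedule, and `epoch_features` (list of
#'   `tc_features`, one per epoch) plus `epoch_labels`.
#' @export
state_switch_protocol <- function(p,
                                  schedule = data.frame(
                                    c_py_ei = c(0.76, 0.748, 0.76),
                                    duration = c(20, 20, 20)),
                                  d = drive_spec(a_py = 0.02, fpy = 1),
                                  dt = 0.0039, window = 2,
                                  s0 = rep(0, 6)) {
  stopifnot(inherits(p, "tc_params"), is.data.frame(schedule),
            all(c("c_py_ei", "duration") %in% names(schedule)),
            all(schedule$duration > 0))
  if (any(schedule$c_py_ei < 0.3 | schedule$c_py_ei > 0.9))
    stop("schedule values must lie within [0.3, 0.9]")
  s <- check_state(s0)
  t0 <- 0
  times <- numeric(0); output <- numeric(0); epoch <- integer(0)
  feats <- vector("list", nrow(schedule))
  labels <- character(nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    p$c_py_ei <- schedule$c_py_ei[k]
    r <- simulate_model(p, d, schedule$duration[k], dt, s0 = s, t0 = t0)
    keep <- if (k == 1) seq_along(r$times) else -1L   # drop duplicated joint
    times <- c(times, r$times[keep])
    output <- c(output, r$output[keep])
    epoch <- c(epoch, rep.int(k, length(r$times[keep])))
    feats[[k]] <- compute_features(r, window)
    labels[k] <- as.character(classify_state(feats[[k]]))
    s <- r$states[nrow(r$states), ]
    t0 <- r$times[length(r$times)]
  }
  structure(list(times = times, output = output, epoch = epoch,
                 schedule = schedule, epoch_features = feats,
                 epoch_labels = labels, drive = d, dt = dt),
            class = "tc_switch")
}

#' @export
print.tc_switch <- function(x, ...) {
  cat("<tc_switch>", nrow(x$schedule), "epochs\n")
  for (k in seq_len(nrow(x$schedule)))
    cat(sprintf("  epoch %d: c_py_ei = %g for %g s -> %s (ptp %.3f)\n",
                k, x$schedule$c_py_ei[k], x$schedule$duration[k],
                x$epoch_labels[k], x$epoch_features[[k]]$ptp))
  invisible(x)
}

#' Export a frequency response as CSV
#'
#' @param fr a `tc_freqresp`.
#' @param path output path; when `NULL`, returns the data frame only.
#' @return The response data frame.
#' @export
response_table <- function(fr, path = NULL) {
  stopifnot(inherits(fr, "tc_freqresp"))
  if (!is.null(path))
    utils::write.csv(fr$response, path, row.names = FALSE, quote = FALSE)
  fr$response
}
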