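#' Deterministic synthetic test signals and canned feature sets
#'
#' Generates the synthetic series used to exercise the feature extractor
#' and classifier without running the full model: pure sinusoids, a
#' two-amplitude spike train (the waveform signature of a
#' period-doubled cycle), a damped oscillation settling at a depressed
#' level (slow-rhythmic proxy), a constant series, and one canned
#' `tc_features` object per activity type with values inside that type's
#' defining ranges.  Everything is reproducible from `seed`.
#'
#' @param seed integer seed for the small amplitude/phase jitter.
#' @param dt sampling step of the series (default 1/256 s).
#' @param duration series length in seconds.
#' @return List with `series` (named list of numeric vectors), `dt`, and
#'   `feature_sets` (named list of `tc_features`, one per label, each
#'   carrying the expected label as attribute `"expected"`).
#' @export
generate_fixtures <- function(seed = 1, dt = 1 / 256, duration = 2) {
  set.seed(seed)
  t <- seq(0, duration, by = dt)
  jitter <- stats::runif(1, -0.01, 0.01)
  series <- list(
    sine3hz = sin(2 * pi * 3 * t),
    sine5hz_mix = 0.3 * sin(2 * pi * 2 * t) + (1 + jitter) * sin(2 * pi * 5 * t),
    two_amp_spikes = two_amplitude_train(t, f = 3, a1 = 1.0, a2 = 0.6),
    swd3hz = swd_train(t, f = 3, depth2 = 0.95),
    damped_neg = -0.4 + 0.5 * exp(-8 * t) * cos(2 * pi * 2 * t),
    constant = rep(0.2, length(t)))
  canned <- function(DF, Pmax1, Pmax2, Pmin1, Pmin2, mean_level, expected) {
    f <- structure(list(DF = DF, Pmax1 = Pmax1, Pmax2 = Pmax2,
                        Pmin1 = Pmin1, Pmin2 = Pmin2,
                        ptp = if (is.na(Pmax1)) 0 else Pmax1 - Pmin2,
                        mean_level = mean_level,
                        n_max_clusters = if (is.na(Pmax1)) 0L
                                         else if (Pmax1 - Pmax2 > 1e-3) 2L
                                         else 1L,
                        oscillatory = !is.na(Pmax1)),
                   class = "tc_features")
    attr(f, "expected") <- expected
    f
  }
  feature_sets <- list(
    normal = canned(0, NA, NA, NA, NA, mean_level = 0.2,
                    expected = "normal"),
    preictal = canned(2.5, Pmax1 = 0.06, Pmax2 = 0.02, Pmin1 = -0.02,
                      Pmin2 = -0.05, mean_level = 0.02,
                      expected = "preictal"),
    slow_rhythmic = canned(0, NA, NA, NA, NA, mean_level = -0.4,
                           expected = "slow_rhythmic"),
    typical_absence = canned(3, Pmax1 = 0.4, Pmax2 = 0.1, Pmin1 = -0.1,
                             Pmin2 = -0.4, mean_level = 0,
                             expected = "typical_absence"),
    atypical_absence = canned(5, Pmax1 = 0.3, Pmax2 = 0.1, Pmin1 = -0.1,
                              Pmin2 = -0.3, mean_level = 0,
                              expected = "atypical_absence"),
    clonic = canned(4, Pmax1 = 0.25, Pmax2 = 0.2499, Pmin1 = -0.3,
                    Pmin2 = -0.301, mean_level = 0, expected = "clonic"),
    tonic = canned(16, Pmax1 = 0.2, Pmax2 = 0.15, Pmin1 = -0.1,
                   Pmin2 = -0.105, mean_level = 0, expected = "tonic"))
  list(series = series, dt = dt, feature_sets = feature_sets)
}

## spike train whose consecutive peaks alternate between two amplitudes
two_amplitude_train <- function(t, f, a1, a2) {
  base <- sin(2 * pi * f * t)
  cycle <- floor(t * f)
  amp <- ifelse(cycle %% 2 == 0, a1, a2)
  ifelse(base > 0, amp * base, 0.3 * base)
}

## spike-and-wave proxy: troughs alternate between depths 1 and depth2,
## giving two distinct minimum levels (gap 1 - depth2) at a single spike
## amplitude
swd_train <- function(t, f, depth2) {
  y <- sin(2 * pi * f * t)
  odd <- floor(t * f) %% 2 == 1
  ifelse(y < 0 & odd, depth2 * y, y)
}
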