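.state_labels <- c("normal", "preictal", "slow_rhythmic", "typical_absence",
                   "atypical_absence", "clonic", "tonic", "unclassified")
.state_types <- c(normal = 1L, preictal = 2L, slow_rhythmic = 3L,
                  typical_absence = 4L, atypical_absence = 5L,
                  clonic = 6L, tonic = 7L, unclassified = NA_integer_)

#' Activity-regime labels
#'
#' The seven activity types the model produces, plus `unclassified`:
#' normal background firing (Type 1), preictal spikes (Type 2), slow
#' rhythmic activity (Type 3), typical absence seizure (Type 4), atypical
#' absence seizure (Type 5), clonic seizure (Type 6) and tonic seizure
#' (Type 7).
#'
#' @return Character vector of the eight label names in type order.
#' @export
state_labels <- function() .state_labels

#' Classify a feature set into an activity regime
#'
#' Rule-based mapping from a [compute_features()] result to one of the
#' seven activity types.  Rules are applied in a fixed precedence order,
#' narrower conditions first, so the overlapping frequency/amplitude
#' ranges of the regimes resolve deterministically.  Writing
#' `dmax = Pmax1 - Pmax2` and `dmin = Pmin1 - Pmin2`:
#'
#' 1. tonic: `DF >= 14` and `dmin < 0.01` -- fast spiking at a single
#'    minimum level;
#' 2. non-oscillatory window: slow rhythmic if the mean output level lies
#'    in (-0.8, -0.1) (stable focus at depressed level), else normal;
#' 3. preictal: `DF < 3.5`, `dmin < 0.2`, `dmax < 0.12` and
#'    `ptp < 0.15` -- the low-amplitude spike activity between seizure
#'    onset and the full seizure, covering both the small cycle born at
#'    the supercritical Hopf and the two-amplitude pattern after the
#'    first period doubling;
#' 4. typical absence: `DF` in (2, 4) and `dmin > 0.004` -- the
#'    spike-and-wave double minimum at absence frequency;
#' 5. atypical absence: (`DF > 4` or `DF < 2`) and `dmin > 0.01` --
#'    spike-and-wave structure outside the typical band;
#' 6. clonic: `DF` in \[2, 7\] and `dmin < 0.15` -- large simple
#'    slow-wave cycling;
#' 7. otherwise unclassified.
#'
#' The function is total: every finite feature set receives exactly one
#' label; conditions on missing extrema simply fail.  See the methods
#' vignette for how these rules operationalize the published regime
#' descriptions for exactly converged attractors.
#'
#' @param f a `tc_features` object.
#' @return A one-element factor with levels [state_labels()], with
#'   attribute `"type"` giving the type number (1-7, `NA` for
#'   unclassified).
#' @examples
#' r <- simulate_model(model_parameters())   # baseline: normal background
#' classify_state(compute_features(r))
#' @export
classify_state <- function(f) {
  stopifnot(inherits(f, "tc_features"))
  dmax <- f$Pmax1 - f$Pmax2
  dmin <- f$Pmin1 - f$Pmin2
  ok <- function(x) isTRUE(x)   # NA-safe condition
  label <-
    if (ok(f$DF >= 14) && ok(dmin < 0.01)) "tonic"
    else if (!f$oscillatory) {
      if (f$mean_level > -0.8 && f$mean_level < -0.1) "slow_rhythmic"
      else "normal"
    }
    else if (ok(f$DF < 3.5) && ok(dmin < 0.2) && ok(dmax < 0.12) &&
             ok(f$ptp < 0.15)) "preictal"
    else if (ok(f$DF > 2) && ok(f$DF < 4) && ok(dmin > 0.004))
      "typical_absence"
    else if ((ok(f$DF > 4) || ok(f$DF < 2)) && ok(dmin > 0.01))
      "atypical_absence"
    else if (ok(f$DF >= 2) && ok(f$DF <= 7) && ok(dmin < 0.15)) "clonic"
    else "unclassified"
  structure(factor(label, levels = .state_labels),
            type = .state_types[[label]])
}

## vectorized helper: classify each row of a feature data.frame
classify_feature_rows <- function(df, amp_tol = 1e-3) {
  labs <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    f <- structure(as.list(df[i, ]), class = "tc_features")
    if (is.null(f$oscillatory)) f$oscillatory <- f$ptp >= amp_tol
    labs[i] <- as.character(classify_state(f))
  }
  factor(labs, levels = .state_labels)
}
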