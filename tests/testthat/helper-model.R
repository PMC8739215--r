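# Shared configurations for the bifurcation-analysis tests.

# GABAergic sweep setup: c_py_ei = 0.8, c_tc_ei = 4.5, c_i1_ei varied
fig_gaba_params <- function(...) model_parameters(...)

# glutamatergic sweep setup: c_i1_ei = 0.3, c_py_ei varied
fig_glut_params <- function(...) model_parameters(c_i1_ei = 0.3, ...)

# thalamic sweep setup: c_tc_re varied
fig_thal_params <- function(...)
  model_parameters(c_py_ei = 0.75, c_i1_ei = 0.33, c_tc_ei = 4.2, ...)

# a decoupled parameter set: every coupling and both gains zero
decoupled_params <- function() {
  p <- model_parameters()
  for (nm in grep("^c_", names(p), value = TRUE)) p[[nm]] <- 0
  p
}

# fake frequency-response container for the detector unit tests
fake_freqresp <- function(freq, ptp) {
  structure(list(channel = "cortical",
                 response = data.frame(freq = freq, ptp = ptp,
                                       DF = NA_real_,
                                       n_max_clusters = NA_integer_,
                                       chaotic = NA, diverged = FALSE),
                 amp = 0.02, duration = 60, dt = 0.0039, window = 2),
            class = "tc_freqresp")
}

# collapse a sweep's label column to its regime sequence: first-appearance
# order, unclassified dropped, both absence flavours merged
regime_sequence <- function(bd) {
  labs <- as.character(bd$features$label)
  labs[labs %in% c("typical_absence", "atypical_absence")] <- "absence"
  labs <- labs[labs != "unclassified"]
  unique(labs)
}
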