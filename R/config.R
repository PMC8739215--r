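.sim_keys <- c("duration", "dt", "window")
.drive_keys <- c("B_Npy", "a_py", "fpy", "B_Ntc", "a_tc", "ftc")

#' Load a run configuration
#'
#' Reads a flat YAML key-value file of model-parameter, drive and
#' simulation-setting overrides, validates it and fills every missing key
#' with the package defaults.  An empty file therefore yields the full
#' reference parameterization.  Unknown keys and out-of-range values are
#' errors naming the offending key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `tc_config`: list with `params` ([model_parameters()]),
#'   `drive` ([drive_spec()]) and `sim` (list `duration`, `dt`,
#'   `window`).
#' @examples
#' cfg <- load_config(NULL)
#' cfg$sim$dt
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a key-value mapping")
  known <- c(.par_order, .drive_keys, .sim_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  par_over <- raw[intersect(names(raw), .par_order)]
  params <- do.call(model_parameters, par_over)
  drive <- do.call(drive_spec, raw[intersect(names(raw), .drive_keys)])
  sim <- list(duration = 60, dt = 0.0039, window = 2)
  for (k in intersect(names(raw), .sim_keys)) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config key '", k, "' must be a single positive number")
    sim[[k]] <- v
  }
  if (sim$window > sim$duration)
    stop("config key 'window' must not exceed 'duration'")
  structure(list(params = params, drive = drive, sim = sim),
            class = "tc_config")
}

#' Write a run configuration to YAML
#'
#' Serializes a `tc_config` (or its pieces) as a flat key-value file that
#' [load_config()] reads back to an identical configuration.
#'
#' @param cfg a `tc_config`, or `NULL` to start from defaults.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tc_config"))
  flat <- c(unclass(cfg$params)[setdiff(.par_order, "ei_enabled")],
            list(ei_enabled = cfg$params$ei_enabled),
            unclass(cfg$drive), cfg$sim)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @export
print.tc_config <- function(x, ...) {
  cat("<tc_config>\n")
  print(x$params)
  print(x$drive)
  cat(sprintf("  simulation: %g s at dt = %g s, window %g s\n",
              x$sim$duration, x$sim$dt, x$sim$window))
  invisible(x)
}
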