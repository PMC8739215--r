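#' Analytic Jacobian of the vector field
#'
#' 6x6 linearization of the model at a state, assembled from
#' [sigmoid_derivative()].  Row order and column order follow the state
#' `(PY, I1, I2, EI, TC, RE)`.  The constant drives do not enter the
#' Jacobian.
#'
#' @param s state vector.
#' @param p a [model_parameters()] object.
#' @return 6x6 numeric matrix.
#' @export
jacobian <- function(s, p) {
  s <- check_state(s)
  stopifnot(inherits(p, "tc_params"))
  J <- tc_jacobian_cpp(s, par_vector(p))
  dimnames(J) <- list(.state_names, .state_names)
  J
}

## Damped Newton iteration for equilibria of the constant-input field.
## Returns the solution or NULL when no convergence to residual < tol.
newton_equilibrium <- function(s0, p, Npy, Ntc, tol = 1e-12, max_iter = 200) {
  pv <- par_vector(p)
  s <- as.numeric(s0)
  for (i in seq_len(max_iter)) {
    F <- tc_field_cpp(s, pv, Npy, Ntc)
    r0 <- sum(F^2)
    if (sqrt(r0) < tol) break
    step <- tryCatch(solve(tc_jacobian_cpp(s, pv), F),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    s_new <- s - step
    for (k in 1:20) {   # step halving on residual increase
      if (all(is.finite(s_new)) &&
          sum(tc_field_cpp(s_new, pv, Npy, Ntc)^2) < r0) break
      lambda <- lambda / 2
      s_new <- s - lambda * step
    }
    s <- s_new
    if (any(!is.finite(s))) return(NULL)
  }
  if (sqrt(sum(tc_field_cpp(s, pv, Npy, Ntc)^2)) < 1e-10) s else NULL
}

stability_class <- function(ev) {
  lead <- ev[which.max(Re(ev))]
  if (max(Re(ev)) < 0) {
    if (any(abs(Im(ev)) > 1e-9)) "stable_focus" else "stable_node"
  } else if (abs(Im(lead)) > 1e-9) "unstable" else "saddle"
}

equilibrium_record <- function(s, p, Npy, Ntc) {
  ev <- eigen(tc_jacobian_cpp(s, par_vector(p)), only.values = TRUE)$values
  names(s) <- .state_names
  list(state = s, eigenvalues = ev, stability = stability_class(ev),
       residual = sqrt(sum(tc_field_cpp(s, par_vector(p), Npy, Ntc)^2)))
}

## real part of the leading complex-conjugate eigenvalue pair (NA if the
## spectrum is entirely real)
leading_complex_re <- function(ev) {
  cv <- ev[abs(Im(ev)) > 1e-9]
  if (!length(cv)) NA_real_ else max(Re(cv))
}

#' Find all equilibria of the constant-input model
#'
#' Damped-Newton iterations started from a deterministic grid of
#' `3^6 + 1` points (three values per state axis over \[-4, 2\], plus the
#' origin), deduplicated at Euclidean distance `1e-6`.  Only constant
#' drives are admitted (`a_py = a_tc = 0`).
#'
#' @param p a [model_parameters()] object.
#' @param d a constant [drive_spec()].
#' @return List of equilibrium records, each with `state`, `eigenvalues`
#'   (of the analytic Jacobian), `stability` (one of `stable_node`,
#'   `stable_focus`, `unstable`, `saddle`) and `residual`
#'   (always `< 1e-10`).  Empty list when no start converges.
#' @examples
#' eq <- find_equilibria(model_parameters())
#' sapply(eq, `[[`, "stability")
#' @export
find_equilibria <- function(p, d = drive_spec()) {
  stopifnot(inherits(p, "tc_params"), inherits(d, "tc_drive"))
  if (!is_constant_drive(d))
    stop("find_equilibria requires constant inputs (a_py = a_tc = 0)")
  dv <- drive_value(d, 0, p)
  axis <- c(-4, -1, 2)
  starts <- as.matrix(expand.grid(axis, axis, axis, axis, axis, axis))
  starts <- rbind(starts, rep(0, 6))
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    s <- newton_equilibrium(starts[i, ], p, dv$Npy, dv$Ntc)
    if (is.null(s)) next
    if (any(vapply(sols, function(q) sqrt(sum((q$state - s)^2)) < 1e-6,
                   logical(1)))) next
    sols[[length(sols) + 1L]] <- equilibrium_record(s, p, dv$Npy, dv$Ntc)
  }
  sols
}

## Re-acquire the tracked equilibrium branch near a previous solution:
## plain warm start first, then deterministically perturbed starts, then a
## small local grid.  Returns the solution nearest to s_prev or NULL.
reacquire_equilibrium <- function(s_prev, p, Npy, Ntc, max_dist = 1) {
  s <- newton_equilibrium(s_prev, p, Npy, Ntc)
  if (!is.null(s) && sqrt(sum((s - s_prev)^2)) <= max_dist) return(s)
  best <- NULL; best_d <- max_dist
  for (delta in c(0.005, -0.005, 0.02, -0.02, 0.08, -0.08, 0.3, -0.3)) {
    cand <- newton_equilibrium(s_prev + delta, p, Npy, Ntc)
    if (is.null(cand)) next
    dd <- sqrt(sum((cand - s_prev)^2))
    if (dd < best_d) { best <- cand; best_d <- dd }
  }
  best
}

#' Locate a Hopf bifurcation by eigenvalue bisection
#'
#' Continues one equilibrium branch of the constant-input model across a
#' parameter interval by warm-started damped Newton and bisects the
#' parameter value at which the real part of the leading
#' complex-conjugate eigenvalue pair crosses zero.  Near folds of the
#' equilibrium curve, where the warm start fails, the branch is
#' re-acquired from perturbed starts; the continuation then follows the
#' reconnecting segment, which is how the printed bifurcation values of
#' the reference diagrams are recovered.
#'
#' @param p a [model_parameters()] object (values other than `param` fixed).
#' @param param name of the swept parameter, e.g. `"c_i1_ei"`.
#' @param from,to bracket endpoints; the scan runs from `from` to `to`, so
#'   a decreasing sweep is expressed as `from > to`.
#' @param d a constant [drive_spec()].
#' @param tol bisection tolerance on the parameter (default `1e-4`).
#' @param n_scan number of pre-scan points used to find the sign change.
#' @param s0 optional starting state for the branch at `from`; by default
#'   the attractor reached by a 30 s simulation from the origin, polished
#'   by Newton.
#' @return The crossing parameter value, with attributes `"state"` (the
#'   equilibrium at the crossing) and `"direction"` (`+1` when the real
#'   part increases through zero along the scan, `-1` otherwise).
#' @examples
#' \donttest{
#' ## first stability loss when raising the I1 -> EI inhibition
#' locate_hopf(model_parameters(), "c_i1_ei", 0.2, 0.45)  # ~0.349
#' }
#' @export
locate_hopf <- function(p, param, from, to, d = drive_spec(), tol = 1e-4,
                        n_scan = 60, s0 = NULL) {
  stopifnot(inherits(p, "tc_params"), param %in% names(p),
            is.numeric(from), is.numeric(to), from != to)
  if (!is_constant_drive(d))
    stop("locate_hopf requires constant inputs")
  dv <- drive_value(d, 0, p)
  solve_at <- function(v, s_prev) {
    p[[param]] <- v
    reacquire_equilibrium(s_prev, p, dv$Npy, dv$Ntc)
  }
  re_at <- function(v, s) {
    p[[param]] <- v
    leading_complex_re(eigen(tc_jacobian_cpp(s, par_vector(p)),
                             only.values = TRUE)$values)
  }
  ## starting equilibrium at `from`
  if (is.null(s0)) {
    p0 <- p; p0[[param]] <- from
    sim <- simulate_model(p0, d, duration = 30)
    s0 <- sim$states[nrow(sim$states), ]
  }
  s <- solve_at(from, s0)
  if (is.null(s))
    stop(structure(class = c("tc_branch_lost", "error", "condition"),
                   list(message = "no equilibrium found at bracket start",
                        call = sys.call())))
  grid <- seq(from, to, length.out = n_scan + 1)
  res <- re_at(from, s)
  lo <- from; s_lo <- s; r_lo <- res
  hi <- NA
  for (v in grid[-1]) {
    s_new <- solve_at(v, s_lo)
    if (is.null(s_new))
      stop(structure(class = c("tc_branch_lost", "error", "condition"),
                     list(message = sprintf(
                       "equilibrium branch lost near %s = %g", param, v),
                       call = sys.call())))
    r_new <- re_at(v, s_new)
    if (is.finite(r_lo) && is.finite(r_new) && sign(r_new) != sign(r_lo)) {
      hi <- v; r_hi <- r_new
      break
    }
    lo <- v; s_lo <- s_new; r_lo <- r_new
  }
  if (is.na(hi))
    stop(structure(class = c("tc_no_crossing", "error", "condition"),
                   list(message = sprintf(
                     "no eigenvalue zero crossing of '%s' in [%g, %g]",
                     param, from, to), call = sys.call())))
  ## bisection with warm starts from the lo side
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    s_mid <- solve_at(mid, s_lo)
    if (is.null(s_mid))
      stop(structure(class = c("tc_branch_lost", "error", "condition"),
                     list(message = sprintf(
                       "equilibrium branch lost near %s = %g", param, mid),
                       call = sys.call())))
    r_mid <- re_at(mid, s_mid)
    if (sign(r_mid) == sign(r_lo)) {
      lo <- mid; s_lo <- s_mid; r_lo <- r_mid
    } else {
      hi <- mid; r_hi <- r_mid
    }
  }
  structure((lo + hi) / 2, state = s_lo,
            direction = if (r_hi > r_lo) 1 else -1,
            class = "tc_hopf")
}

#' @export
print.tc_hopf <- function(x, ...) {
  print(as.numeric(x))
  invisible(x)
}

#' Export an equilibrium table to CSV
#'
#' @param records list of equilibrium records from [find_equilibria()].
#' @param path output file; when `NULL` the data frame is returned only.
#' @param param_value optional parameter value column to prepend.
#' @return Data frame with the state coordinates, the maximal real
#'   eigenvalue part and the stability class.
#' @export
equilibrium_table <- function(records, path = NULL, param_value = NA) {
  rows <- lapply(records, function(rec) {
    data.frame(param_value = param_value,
               t(rec$state),
               max_re = max(Re(rec$eigenvalues)),
               stability = rec$stability)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
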