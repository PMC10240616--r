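# Integration of the fuzzy ODE system to steady state under node clamps.

#' Clamp set: nodes held at constant values
#'
#' Clamping models exogenous cytokines held at a microenvironment
#' concentration, and constant genetic perturbations of transcription
#' factors. A clamped node has zero derivative throughout
#' integration and its state equals the clamp value exactly.
#'
#' @param ... named values in `[0, 1]`, or a single named list/vector.
#' @return named numeric vector of class `clamp_set`.
#' @export
clamp_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  v <- unlist(args)
  if (length(v) == 0L) {
    return(structure(setNames(numeric(0), character(0)), class = "clamp_set"))
  }
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    stop("clamp values must be named by node", call. = FALSE)
  }
  if (any(v < 0 | v > 1)) stop("clamp values must lie in [0, 1]", call. = FALSE)
  structure(v, class = "clamp_set")
}

#' Simulation configuration
#'
#' @param t_max integration horizon in units of 1/alpha (default 500; with
#'   alpha = 1 the natural relaxation timescale is 1, and the generous
#'   horizon covers slow passages near saddle-node ghosts in scans).
#' @param convergence_tol infinity-norm tolerance on the right-hand side
#'   below which a state counts as converged (default 1e-6).
#' @param monitor_dt spacing of the monitor/trajectory grid (default 1).
#' @param rtol,atol solver tolerances passed to deSolve.
#' @param recurrence_tol infinity-norm tolerance for oscillation detection on
#'   a densely sampled terminal window (default 1e-2).
#' @param seed integer seed for any randomized component (recorded in run
#'   metadata; the integrator itself is deterministic).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(t_max = 500, convergence_tol = 1e-6, monitor_dt = 1,
                       rtol = 1e-8, atol = 1e-10, recurrence_tol = 1e-2,
                       seed = 1L) {
  stopifnot(t_max > 0, convergence_tol > 0, monitor_dt > 0)
  structure(list(t_max = t_max, convergence_tol = convergence_tol,
                 monitor_dt = monitor_dt, rtol = rtol, atol = atol,
                 recurrence_tol = recurrence_tol, seed = as.integer(seed)),
            class = "sim_config")
}

#' Apply clamps to a fuzzy ODE system
#'
#' Returns a system in which the clamped nodes have zero derivative and are
#' held at the clamp value; all other equations are unchanged. Clamps
#' accumulate over repeated application (later values win).
#'
#' @param system a `fuzzy_ode_system`.
#' @param clamps a [clamp_set()] (possibly empty).
#' @return clamped `fuzzy_ode_system`.
#' @export
apply_clamps <- function(system, clamps) {
  stopifnot(inherits(system, "fuzzy_ode_system"))
  if (length(clamps) == 0L) return(system)
  unknown <- setdiff(names(clamps), system$node_names)
  if (length(unknown)) {
    stop(sprintf("clamp references unknown node '%s'", unknown[1]), call. = FALSE)
  }
  merged <- system$clamps
  merged[names(clamps)] <- as.numeric(clamps)
  out <- system
  out$clamps <- merged
  # rebind rhs so its closure sees the new clamp set
  out$rhs <- local({
    sys <- out
    inner <- system
    index <- setNames(seq_along(sys$node_names), sys$node_names)
    function(t, q) {
      dq <- inner$rhs(t, q)
      dq[index[names(sys$clamps)]] <- 0
      dq
    }
  })
  out
}

#' Integrate a fuzzy ODE system to steady state
#'
#' Integrates from `q0` with the given clamps until the infinity norm of the
#' right-hand side over unclamped nodes falls below `cfg$convergence_tol`
#' (detected by the solver's root-finding), or until `cfg$t_max`. If the
#' horizon is reached without convergence, the terminal segment of the
#' trajectory is compared against earlier states: recurrence within
#' `cfg$recurrence_tol` at a nonzero lag classifies the run as `cyclic`,
#' otherwise `undetermined`.
#'
#' @param system a `fuzzy_ode_system`.
#' @param q0 initial state: named numeric vector in `[0,1]` (missing nodes
#'   default to 0), or `NULL` for the all-zero monocyte state.
#' @param clamps a [clamp_set()]; clamp values override `q0`.
#' @param cfg a [sim_config()].
#' @param keep_trajectory keep the monitor-grid trajectory in the result.
#' @return object of class `steady_state`: fields `q` (named state vector),
#'   `converged`, `residual`, `classification` (`"fixed_point"`, `"cyclic"`
#'   or `"undetermined"`), `time`, `clamps`, and optionally `trajectory`
#'   (matrix of monitor-grid states).
#' @export
integrate_to_steady_state <- function(system, q0 = NULL, clamps = clamp_set(),
                                      cfg = sim_config(),
                                      keep_trajectory = FALSE) {
  stopifnot(inherits(system, "fuzzy_ode_system"))
  sys <- apply_clamps(system, clamps)
  nn <- sys$node_names
  q <- setNames(rep(0, length(nn)), nn)
  if (!is.null(q0)) {
    if (is.null(names(q0))) {
      if (length(q0) != length(nn)) stop("unnamed q0 must have full dimension",
                                         call. = FALSE)
      q[] <- as.numeric(q0)
    } else {
      unknown <- setdiff(names(q0), nn)
      if (length(unknown)) stop(sprintf("q0 references unknown node '%s'",
                                        unknown[1]), call. = FALSE)
      q[names(q0)] <- as.numeric(q0)
    }
  }
  if (any(q < 0 | q > 1)) stop("q0 must lie in [0, 1]^n", call. = FALSE)
  if (length(sys$clamps)) q[names(sys$clamps)] <- sys$clamps

  free_tf <- setdiff(sys$tf_nodes, names(sys$clamps))
  free_idx <- match(free_tf, nn)
  residual_of <- function(state) {
    if (length(free_idx) == 0L) return(0)
    max(abs(sys$rhs(0, state)[free_idx]))
  }

  finish <- function(state, time, residual, classification, traj = NULL) {
    if (length(sys$clamps)) state[names(sys$clamps)] <- sys$clamps
    out <- structure(list(
      q = state, converged = classification == "fixed_point",
      residual = residual, classification = classification, time = time,
      clamps = sys$clamps), class = "steady_state")
    if (keep_trajectory && !is.null(traj)) out$trajectory <- traj
    out
  }

  r0 <- residual_of(q)
  if (r0 <= cfg$convergence_tol) {
    return(finish(q, 0, r0, "fixed_point"))
  }

  times <- seq(0, cfg$t_max, by = cfg$monitor_dt)
  if (times[length(times)] < cfg$t_max) times <- c(times, cfg$t_max)
  deriv <- function(t, y, parms) list(unname(sys$rhs(t, setNames(y, nn))))
  rootfn <- function(t, y, parms) {
    residual_of(setNames(y, nn)) - cfg$convergence_tol
  }
  sol <- tryCatch(
    deSolve::lsodar(y = unname(q), times = times, func = deriv, parms = NULL,
                    rootfunc = rootfn, rtol = cfg$rtol, atol = cfg$atol),
    error = function(e) stop(sprintf("ODE solver failure: %s", conditionMessage(e)),
                             call. = FALSE))
  troot <- attr(sol, "troot")
  last <- setNames(as.numeric(sol[nrow(sol), -1]), nn)
  t_end <- sol[nrow(sol), 1]
  res_end <- residual_of(last)
  traj <- sol[, -1, drop = FALSE]
  colnames(traj) <- nn

  if (!is.null(troot) && length(troot) > 0) {
    return(finish(last, t_end, res_end, "fixed_point", traj))
  }
  if (res_end <= cfg$convergence_tol) {
    return(finish(last, t_end, res_end, "fixed_point", traj))
  }
  # oscillation diagnostics: integrate a dense terminal window and look for a
  # recurrence of the final state at a nonzero lag; a slow monotone drift has
  # negligible amplitude over the window and stays "undetermined"
  window <- min(40, cfg$t_max / 2)
  wt <- seq(0, window, by = 0.01)
  dense <- deSolve::lsoda(y = unname(last), times = wt, func = deriv,
                          parms = NULL, rtol = cfg$rtol, atol = cfg$atol)
  wtraj <- dense[, -1, drop = FALSE]
  final <- wtraj[nrow(wtraj), ]
  lagged <- wt <= window - 0.5
  dist <- apply(wtraj[lagged, , drop = FALSE], 1, function(s) max(abs(s - final)))
  amplitude <- max(apply(wtraj, 2, function(v) diff(range(v))))
  classification <- if (min(dist) <= cfg$recurrence_tol &&
                        amplitude >= 5 * cfg$recurrence_tol) "cyclic"
                    else "undetermined"
  last <- setNames(as.numeric(final), nn)
  finish(last, t_end + window, residual_of(last), classification, traj)
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): residual %.3g at t = %g%s\n",
              x$classification, x$residual, x$time,
              if (x$converged) "" else " [not converged]"))
  print(round(x$q, 4))
  invisible(x)
}

#' Tidy data.frame view of a steady state
#'
#' @param x a `steady_state`.
#' @param ... unused.
#' @return data.frame with one row per node: `node`, `value`, `clamped`,
#'   `residual`, `classification`.
#' @export
as.data.frame.steady_state <- function(x, ...) {
  data.frame(node = names(x$q), value = unname(x$q),
             clamped = names(x$q) %in% names(x$clamps),
             residual = x$residual, classification = x$classification,
             stringsAsFactors = FALSE)
}

#' Export a trajectory in tidy long format
#'
#' @param state a `steady_state` computed with `keep_trajectory = TRUE`.
#' @return data.frame with columns `time`, `node`, `value`.
#' @export
trajectory_long <- function(state) {
  if (is.null(state$trajectory)) {
    stop("steady state was computed without keep_trajectory = TRUE", call. = FALSE)
  }
  tr <- state$trajectory
  times <- seq(0, by = 1, length.out = nrow(tr))
  data.frame(
    time = rep(times, times = ncol(tr)),
    node = rep(colnames(tr), each = nrow(tr)),
    value = as.numeric(tr), stringsAsFactors = FALSE)
}

#' Run metadata as JSON
#'
#' Records the reproducibility-relevant settings of a simulation: fuzzy
#' parameters, clamps, initial state and tolerances.
#'
#' @param system a `fuzzy_ode_system`.
#' @param state a `steady_state`.
#' @param cfg the [sim_config()] used.
#' @param q0 the initial state used (named vector or `NULL`).
#' @param path optional output file.
#' @return JSON string, invisibly when written to `path`.
#' @export
run_metadata_json <- function(system, state, cfg, q0 = NULL, path = NULL) {
  meta <- list(
    b = system$params$b, omega_thr = system$params$omega_thr,
    alpha = unname(system$params$alpha[1]),
    clamps = as.list(state$clamps),
    q0 = if (is.null(q0)) "M0 (all zeros)" else as.list(q0),
    t_max = cfg$t_max, convergence_tol = cfg$convergence_tol,
    seed = cfg$seed,
    converged = state$converged, residual = state$residual,
    classification = state$classification)
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
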