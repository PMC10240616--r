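# Fuzzy-logic transformation: continuous rule composition, sigmoid
# characteristic function, and assembly of the ODE right-hand side.

#' Parameters of the fuzzy ODE transformation
#'
#' @param b sigmoid steepness (dimensionless, > 0). Controls how sharply a
#'   node saturates from unexpressed to expressed as the fuzzy truth value of
#'   its rule crosses the threshold. The package default (25) reproduces the
#'   fixture's published dose-response thresholds; see the vignette.
#' @param omega_thr activation threshold in (0, 1) at which the
#'   characteristic function equals 1/2. Default 0.5.
#' @param alpha per-node decay rate (1/time), scalar recycled over nodes or a
#'   named vector. Default 1 everywhere, so a node's steady-state expression
#'   equals the characteristic value of its rule.
#' @return object of class `fuzzy_params`.
#' @export
fuzzy_params <- function(b = 25, omega_thr = 0.5, alpha = 1) {
  stopifnot(is.numeric(b), length(b) == 1L, b > 0,
            is.numeric(omega_thr), length(omega_thr) == 1L,
            omega_thr > 0, omega_thr < 1,
            is.numeric(alpha), all(alpha > 0))
  structure(list(b = b, omega_thr = omega_thr, alpha = alpha),
            class = "fuzzy_params")
}

#' Sigmoid characteristic function
#'
#' `phi(omega) = 1 / (1 + exp(-b * (omega - omega_thr)))`: maps the fuzzy
#' truth value of a node's rule to its activation drive. Strictly increasing
#' in `omega`, equal to 1/2 at `omega = omega_thr` for every steepness `b`,
#' and confined to (0, 1).
#'
#' @param omega numeric vector of fuzzy truth values.
#' @param params a [fuzzy_params()] object (or anything with fields `b`,
#'   `omega_thr`).
#' @return numeric vector of activation levels in (0, 1).
#' @export
characteristic <- function(omega, params = fuzzy_params()) {
  1 / (1 + exp(-params$b * (omega - params$omega_thr)))
}

#' Build the fuzzy ODE system of a regulatory network
#'
#' For every transcription-factor node i the equation is
#' `dq_i/dt = phi(omega_i(q)) - alpha_i * q_i`, where `omega_i` is the
#' fuzzified Boolean rule of node i. Extracellular nodes are carried as state
#' components with zero derivative, so the state dimension equals the node
#' count (29 for the macrophage fixture) and inputs stay constant at their
#' clamped values.
#'
#' @param network a `regulatory_network`.
#' @param params a [fuzzy_params()] object.
#' @return object of class `fuzzy_ode_system` with fields
#'   \describe{
#'     \item{network, params}{as supplied (alpha expanded per node)}
#'     \item{node_names}{state vector layout}
#'     \item{omega}{`function(q)` returning the named vector of fuzzy truth
#'       values of all transcription-factor rules}
#'     \item{rhs}{`function(t, q)` returning the full derivative vector}
#'     \item{clamps}{named numeric vector of permanently clamped nodes
#'       (empty here; see [apply_clamps()])}
#'   }
#' @export
build_ode_system <- function(network, params = fuzzy_params()) {
  stopifnot(inherits(network, "regulatory_network"))
  node_names <- network$nodes$name
  n <- length(node_names)
  index <- setNames(seq_len(n), node_names)
  tf <- network$nodes$name[network$nodes$klass == "transcription_factor"]
  tf_idx <- index[tf]

  alpha <- params$alpha
  if (length(alpha) == 1L) alpha <- setNames(rep(alpha, n), node_names)
  else {
    a <- setNames(rep(1, n), node_names)
    a[names(alpha)] <- alpha
    alpha <- a
  }

  # compile all omega_i into a single expression c(e_1, ..., e_m) over x
  exprs <- lapply(network$rules[tf], function(r) compile_fuzzy_expr(r$expr, index))
  omega_call <- as.call(c(quote(c), exprs))
  omega_env <- new.env(parent = baseenv())
  omega_fn <- function(q) {
    x <- as.numeric(q)
    assign("x", x, envir = omega_env)
    setNames(eval(omega_call, omega_env), tf)
  }

  b <- params$b; thr <- params$omega_thr
  sys <- structure(list(
    network = network, params = params, node_names = node_names,
    tf_nodes = tf, tf_idx = unname(tf_idx), alpha = alpha,
    omega = omega_fn, clamps = setNames(numeric(0), character(0))),
    class = "fuzzy_ode_system")

  sys$rhs <- function(t, q) {
    dq <- numeric(n)
    w <- sys$omega(q)
    phi <- 1 / (1 + exp(-b * (w - thr)))
    dq[sys$tf_idx] <- phi - alpha[sys$tf_idx] * as.numeric(q)[sys$tf_idx]
    if (length(sys$clamps)) dq[index[names(sys$clamps)]] <- 0
    setNames(dq, node_names)
  }
  sys
}

#' @export
print.fuzzy_ode_system <- function(x, ...) {
  cat(sprintf("Fuzzy ODE system: %d state variables (%d dynamic equations), b = %g, omega_thr = %g\n",
              length(x$node_names), length(x$tf_nodes),
              x$params$b, x$params$omega_thr))
  if (length(x$clamps)) {
    cat("  clamped:", paste(sprintf("%s=%g", names(x$clamps), x$clamps),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export the generated equations as human-readable text
#'
#' One line per transcription-factor node of the form
#' `dSTAT1/dt = phi[ <fuzzy expression> ] - 1 * STAT1`, for audit against an
#' external rule listing.
#'
#' @param system a `fuzzy_ode_system`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return character vector of equation lines, invisibly when written.
#' @export
export_equations <- function(system, path = NULL) {
  fuzzy_text <- function(e) {
    switch(e$op,
      var = e$name,
      const = as.character(e$value),
      not = sprintf("(1 - %s)", fuzzy_text(e$arg)),
      and = sprintf("(%s * %s)", fuzzy_text(e$lhs), fuzzy_text(e$rhs)),
      or = {
        a <- fuzzy_text(e$lhs); b <- fuzzy_text(e$rhs)
        sprintf("(%s + %s - %s * %s)", a, b, a, b)
      })
  }
  lines <- vapply(system$tf_nodes, function(nm) {
    sprintf("d%s/dt = phi[ %s ] - %g * %s", nm,
            fuzzy_text(system$network$rules[[nm]]$expr),
            system$alpha[[nm]], nm)
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
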