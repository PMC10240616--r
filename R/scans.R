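# Experiment families: 1D dose scans, microenvironment scans, constant
# perturbation (TGEM) scans, and 2D phenotype-space maps.

#' Specification of a 1D dose scan
#'
#' One or more extracellular nodes are clamped together at each value of a
#' grid; the system is integrated from the same initial state at every grid
#' point (independent conditions, no continuation), and each terminal state
#' is labeled.
#'
#' @param scan_nodes character vector of nodes clamped jointly to the grid
#'   value.
#' @param from,to,step grid definition within `[0, 1]` (defaults 0, 1, 0.025;
#'   the published transition thresholds are multiples of 0.025).
#' @param values optional explicit grid (overrides from/to/step); values must
#'   lie in `[0, 1]`.
#' @param q0 initial state: `NULL` (monocyte M0), a named phenotype (resolved
#'   via [make_initial_state()]), or a named numeric vector.
#' @param extra_clamps additional [clamp_set()] applied at every grid point
#'   (e.g. a constant genetic perturbation).
#' @return object of class `scan_spec_1d`.
#' @export
scan_spec_1d <- function(scan_nodes, from = 0, to = 1, step = 0.025,
                         values = NULL, q0 = NULL, extra_clamps = clamp_set()) {
  if (is.null(values)) {
    stopifnot(step > 0, from >= 0, to <= 1, from <= to)
    values <- seq(from, to, by = step)
  }
  if (any(values < 0 | values > 1)) stop("grid must lie within [0, 1]", call. = FALSE)
  stopifnot(length(scan_nodes) >= 1)
  structure(list(scan_nodes = scan_nodes, grid = values, q0 = q0,
                 extra_clamps = extra_clamps),
            class = "scan_spec_1d")
}

resolve_q0 <- function(network, q0) {
  if (is.null(q0)) return(NULL)
  if (is.character(q0) && length(q0) == 1L) return(make_initial_state(network, q0))
  q0
}

scan_point <- function(system, clamps, q0, markers, cfg) {
  st <- integrate_to_steady_state(system, q0 = q0, clamps = clamps, cfg = cfg)
  lab <- label_state(st, markers)
  tf <- system$tf_nodes
  d <- distance_to_initial(st, if (is.null(q0)) numeric(0) else q0, nodes = tf)
  list(state = st, label = lab$label, distance = as.numeric(d))
}

#' Extract label transitions from a labeled grid
#'
#' @param grid numeric grid values.
#' @param labels character labels, same length.
#' @return data.frame with columns `value`, `label_before`, `label_after`,
#'   one row per consecutive label change.
#' @export
extract_transitions <- function(grid, labels) {
  stopifnot(length(grid) == length(labels))
  ch <- which(labels[-1] != labels[-length(labels)])
  data.frame(value = grid[ch + 1L],
             label_before = labels[ch],
             label_after = labels[ch + 1L],
             stringsAsFactors = FALSE)
}

#' Maximal NoLabel intervals of a labeled grid
#'
#' @param grid numeric grid values.
#' @param labels character labels, same length.
#' @return data.frame with columns `start`, `end` (grid values bounding each
#'   maximal run of `"NoLabel"` rows).
#' @export
uncertainty_bands <- function(grid, labels) {
  r <- rle(labels == "NoLabel")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = grid[starts[keep]], end = grid[ends[keep]])
}

build_scan_result <- function(spec, grid, points, markers, kind) {
  labels <- vapply(points, `[[`, character(1), "label")
  rows <- data.frame(
    value = grid,
    label = labels,
    distance = vapply(points, `[[`, numeric(1), "distance"),
    residual = vapply(points, function(p) p$state$residual, numeric(1)),
    converged = vapply(points, function(p) p$state$converged, logical(1)),
    classification = vapply(points, function(p) p$state$classification,
                            character(1)),
    stringsAsFactors = FALSE)
  mk <- do.call(rbind, lapply(points, function(p) p$state$q[markers$marker]))
  colnames(mk) <- markers$marker
  structure(list(
    spec = spec, rows = cbind(rows, as.data.frame(mk)),
    states = lapply(points, function(p) p$state$q),
    transitions = extract_transitions(grid, labels),
    uncertainty_bands = uncertainty_bands(grid, labels),
    kind = kind), class = "scan_result")
}

#' 1D exogenous dose scan
#'
#' For each grid value v the scan nodes are clamped to v (plus any extra
#' clamps), the system is integrated from the specified initial state, and
#' the steady state is labeled. Non-convergence at a grid point is recorded
#' in that row (label `"Cyclic"` or classification `"undetermined"`), never
#' fatal.
#'
#' @param system a `fuzzy_ode_system`.
#' @param spec a [scan_spec_1d()].
#' @param markers a [marker_table()].
#' @param cfg a [sim_config()].
#' @return object of class `scan_result`: `rows` (one per grid value: clamp
#'   value, label, distance to initial state over TF nodes, residual,
#'   per-marker steady values), `states`, `transitions`,
#'   `uncertainty_bands`.
#' @export
dose_scan_1d <- function(system, spec, markers = default_marker_table(),
                         cfg = sim_config()) {
  stopifnot(inherits(spec, "scan_spec_1d"))
  unknown <- setdiff(spec$scan_nodes, system$node_names)
  if (length(unknown)) stop(sprintf("unknown scan node '%s'", unknown[1]),
                            call. = FALSE)
  q0 <- resolve_q0(system$network, spec$q0)
  points <- lapply(spec$grid, function(v) {
    cl <- clamp_set(c(setNames(rep(v, length(spec$scan_nodes)), spec$scan_nodes),
                      spec$extra_clamps))
    scan_point(system, cl, q0, markers, cfg)
  })
  build_scan_result(spec, spec$grid, points, markers, "dose_scan_1d")
}

#' Microenvironment scan from a named phenotype state
#'
#' Identical contract to [dose_scan_1d()] with all environment nodes clamped
#' jointly to the common grid value and the initial state set to a registered
#' phenotype attractor (e.g. `"M1"`). Used to probe the robustness of a
#' polarized macrophage against a changing cytokine milieu.
#'
#' @param system a `fuzzy_ode_system`.
#' @param env_nodes nonempty character vector of extracellular nodes scanned
#'   jointly (see [microenvironment_presets()]).
#' @param q0 named phenotype (character) or state vector.
#' @param markers a [marker_table()].
#' @param cfg a [sim_config()].
#' @param ... grid arguments forwarded to [scan_spec_1d()].
#' @return a `scan_result`.
#' @export
microenvironment_scan <- function(system, env_nodes, q0,
                                  markers = default_marker_table(),
                                  cfg = sim_config(), ...) {
  stopifnot(length(env_nodes) >= 1)
  spec <- scan_spec_1d(env_nodes, q0 = q0, ...)
  res <- dose_scan_1d(system, spec, markers, cfg)
  res$kind <- "microenvironment_scan"
  res
}

#' Constant-perturbation (TGEM) scan
#'
#' Dose scan under a theoretically genetically modified macrophage: selected
#' transcription factors are clamped as constant perturbations (by default
#' NFkB held active at 1 and HIF1a held inactive at 0) while an extracellular
#' environment is scanned.
#'
#' @param system a `fuzzy_ode_system`.
#' @param env_nodes extracellular nodes scanned jointly.
#' @param markers a [marker_table()].
#' @param cfg a [sim_config()].
#' @param perturbation [clamp_set()] of constant TF perturbations.
#' @param q0 initial state (default monocyte).
#' @param ... grid arguments forwarded to [scan_spec_1d()].
#' @return a `scan_result`.
#' @export
tgem_scan <- function(system, env_nodes, markers = default_marker_table(),
                      cfg = sim_config(),
                      perturbation = clamp_set(NFkB = 1, HIF1a = 0),
                      q0 = NULL, ...) {
  unknown <- setdiff(names(perturbation), system$node_names)
  if (length(unknown)) stop(sprintf("perturbation references unknown node '%s'",
                                    unknown[1]), call. = FALSE)
  spec <- scan_spec_1d(env_nodes, q0 = q0, extra_clamps = perturbation, ...)
  res <- dose_scan_1d(system, spec, markers, cfg)
  res$kind <- "tgem_scan"
  res
}

#' Specification of a 2D phenotype-space map
#'
#' Each axis varies one node either as an initial value (competition between
#' endogenous transcription factors) or as a clamp, on its own grid; a fixed
#' environment clamp set applies to every cell.
#'
#' @param axis1,axis2 lists with fields `node`, `role`
#'   (`"initial_value"` or `"clamp"`), and `grid` (numeric in `[0,1]`).
#' @param environment a [clamp_set()] applied everywhere.
#' @param q0 initial-state template (`NULL`, phenotype name, or named vector);
#'   axis `initial_value` entries override it per cell.
#' @return object of class `map_spec_2d`.
#' @export
map_spec_2d <- function(axis1, axis2, environment = clamp_set(), q0 = NULL) {
  for (ax in list(axis1, axis2)) {
    stopifnot(is.list(ax), all(c("node", "role", "grid") %in% names(ax)))
    if (!ax$role %in% c("initial_value", "clamp")) {
      stop("axis role must be 'initial_value' or 'clamp'", call. = FALSE)
    }
    if (any(ax$grid < 0 | ax$grid > 1)) stop("axis grid must lie in [0, 1]",
                                             call. = FALSE)
  }
  if (identical(axis1$node, axis2$node)) {
    stop("the two axes must reference distinct nodes", call. = FALSE)
  }
  structure(list(axis1 = axis1, axis2 = axis2, environment = environment,
                 q0 = q0), class = "map_spec_2d")
}

#' 2D phenotype-space map
#'
#' For every `(v1, v2)` cell the initial state and clamps are assembled
#' according to the axis roles, the system is integrated, and the steady
#' state labeled. Returns the label matrix (axis1 along rows) plus per-cell
#' steady states.
#'
#' @param system a `fuzzy_ode_system`.
#' @param spec a [map_spec_2d()].
#' @param markers a [marker_table()].
#' @param cfg a [sim_config()].
#' @return object of class `phenotype_map`: `labels` (matrix with axis-1
#'   values as rows), `states` (list-matrix of steady states), `spec`.
#' @export
phenotype_map_2d <- function(system, spec, markers = default_marker_table(),
                             cfg = sim_config()) {
  stopifnot(inherits(spec, "map_spec_2d"))
  q0base <- resolve_q0(system$network, spec$q0)
  n1 <- length(spec$axis1$grid); n2 <- length(spec$axis2$grid)
  labels <- matrix(NA_character_, n1, n2,
                   dimnames = list(format(spec$axis1$grid, trim = TRUE),
                                   format(spec$axis2$grid, trim = TRUE)))
  states <- vector("list", n1 * n2)
  dim(states) <- c(n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    q0 <- if (is.null(q0base)) {
      setNames(rep(0, length(system$node_names)), system$node_names)
    } else {
      full <- setNames(rep(0, length(system$node_names)), system$node_names)
      full[names(q0base)] <- q0base
      full
    }
    cl <- as.list(spec$environment)
    for (k in 1:2) {
      ax <- spec[[paste0("axis", k)]]
      v <- ax$grid[if (k == 1) i else j]
      if (ax$role == "clamp") cl[[ax$node]] <- v else q0[[ax$node]] <- v
    }
    st <- integrate_to_steady_state(system, q0 = q0,
                                    clamps = clamp_set(cl), cfg = cfg)
    labels[i, j] <- label_state(st, markers)$label
    states[[i, j]] <- st$q
  }
  structure(list(labels = labels, states = states, spec = spec),
            class = "phenotype_map")
}

#' Locate a labeled transition threshold in a scan
#'
#' Returns the smallest grid value whose label equals `to_label` such that
#' the last differing label before it equals `from_label`; intervening
#' `"NoLabel"` rows are attributed to the transition and reported as its
#' uncertainty band.
#'
#' @param result a `scan_result`.
#' @param from_label,to_label label strings.
#' @return list with `value` (threshold grid value) and `band`
#'   (`c(start, end)` of the attributed NoLabel rows, or `NULL`), or `NULL`
#'   when no such transition occurs.
#' @export
find_transition_threshold <- function(result, from_label, to_label) {
  rows <- result$rows
  labs <- rows$label
  for (i in seq_along(labs)[-1]) {
    if (labs[i] != to_label) next
    j <- i - 1L
    band_idx <- integer(0)
    while (j >= 1L && labs[j] == "NoLabel" && to_label != "NoLabel") {
      band_idx <- c(j, band_idx)
      j <- j - 1L
    }
    if (j >= 1L && labs[j] == from_label && labs[j + 1L] != from_label) {
      band <- if (length(band_idx)) c(rows$value[band_idx[1]],
                                      rows$value[band_idx[length(band_idx)]])
              else NULL
      return(list(value = rows$value[i], band = band))
    }
  }
  NULL
}

#' Named microenvironment presets
#'
#' Vendored sets of extracellular nodes clamped jointly in the published
#' experiments: one pro-phenotype environment per macrophage subtype, plus
#' four simplified breast-cancer microenvironments.
#'
#' @return named list of character vectors of node names.
#' @export
microenvironment_presets <- function() {
  list(
    "pro-M1a" = c("IFNG", "IFNB"),
    "pro-M1"  = c("TNFAe", "IL1B"),
    "pro-M2a" = c("IL4e", "TGFB"),
    "pro-M2b" = c("IgG", "GCGCR"),
    "pro-M2c" = c("IL10e", "MCSF", "IL6e"),
    "pro-M2d" = c("A2a", "Hypoxia", "GCGCR"),
    "bc-immune-complex" = c("IgG", "A2a"),
    "bc-anti-inflammatory" = c("IL10e", "TGFB"),
    "bc-cytokine-storm" = c("IL1B", "IL6e", "IFNG"),
    "bc-hypoxic" = c("Hypoxia", "GCGCR"))
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("%s over {%s}: %d grid points\n", x$kind,
              paste(x$spec$scan_nodes, collapse = ", "), nrow(x$rows)))
  r <- rle(x$rows$label)
  cat("  labels:", paste(sprintf("%s x%d", r$values, r$lengths), collapse = " | "), "\n")
  if (nrow(x$transitions)) {
    cat("  transitions at:",
        paste(sprintf("%g (%s -> %s)", x$transitions$value,
                      x$transitions$label_before, x$transitions$label_after),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.scan_result <- function(x, ...) x$rows
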