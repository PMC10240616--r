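# Phenotype labeling of steady states from marker transcription factors.

canonical_tags <- c("M1", "M1a", "M2a", "M2b", "M2c", "M2d")

#' Marker table: transcription factors defining each phenotype tag
#'
#' The default maps NFkB to M1, STAT1 to M1a, STAT6 to M2a, ERK to M2b,
#' STAT3 to M2c and HIF1a to M2d, with the canonical tag order
#' M1 < M1a < M2a < M2b < M2c < M2d used to assemble hybrid labels.
#'
#' @param markers character vector of marker node names.
#' @param tags phenotype tag for each marker.
#' @param tag_order total order over tags used for canonical label assembly.
#' @return data.frame of class `marker_table` with columns `marker`, `tag`.
#' @export
marker_table <- function(markers = c("NFkB", "STAT1", "STAT6", "ERK", "STAT3", "HIF1a"),
                         tags = canonical_tags,
                         tag_order = canonical_tags) {
  stopifnot(length(markers) == length(tags))
  if (anyDuplicated(markers)) stop("duplicate marker", call. = FALSE)
  if (!all(tags %in% tag_order)) stop("tag not present in tag_order", call. = FALSE)
  structure(data.frame(marker = as.character(markers), tag = as.character(tags),
                       stringsAsFactors = FALSE),
            tag_order = tag_order, class = c("marker_table", "data.frame"))
}

#' Load a marker-signature file
#'
#' Accepts a CSV with columns `marker` and `tag`, or a JSON object with
#' fields `markers` (array of `{marker, tag}`) and optional `tag_order`.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return a [marker_table()].
#' @export
load_marker_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(path)
    m <- js$markers
    order <- if (!is.null(js$tag_order)) js$tag_order else canonical_tags
    return(marker_table(m$marker, m$tag, order))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "tag") %in% names(df))) {
    stop("marker file needs columns 'marker' and 'tag'", call. = FALSE)
  }
  marker_table(df$marker, df$tag)
}

#' The default macrophage marker table shipped with the package
#'
#' @return a [marker_table()].
#' @export
default_marker_table <- function() {
  load_marker_table(system.file("extdata", "macrophage_markers.csv",
                                package = "macpol", mustWork = TRUE))
}

#' Label a steady state with a macrophage phenotype
#'
#' A marker is active when its steady-state value is `>= activation` (0.75)
#' and inactive when `<= inactivation` (0.25). If any marker lies strictly
#' between the thresholds the state is in the range of uncertainty and the
#' label is `"NoLabel"`. With no active marker and none uncertain the label
#' is `"M0"` (monocyte). Otherwise the label concatenates the active tags in
#' canonical order; when both the M1 and M1a markers are active the pair
#' collapses to the single tag `"M1"` (both are M1-type transcription
#' factors). Non-fixed-point states are labeled `"Cyclic"`.
#'
#' @param state a `steady_state`, or a named numeric vector of node values
#'   (then assumed to be a fixed point).
#' @param markers a [marker_table()].
#' @param activation,inactivation thresholds (inclusive).
#' @param collapse_m1 apply the M1/M1a collapse rule (default TRUE).
#' @return object of class `phenotype_label`: fields `label`,
#'   `active_markers`, `marker_values`.
#' @export
label_state <- function(state, markers = default_marker_table(),
                        activation = 0.75, inactivation = 0.25,
                        collapse_m1 = TRUE) {
  if (inherits(state, "steady_state")) {
    if (state$classification != "fixed_point") {
      return(structure(list(label = "Cyclic", active_markers = character(0),
                            marker_values = NULL), class = "phenotype_label"))
    }
    q <- state$q
  } else {
    q <- state
  }
  missing <- setdiff(markers$marker, names(q))
  if (length(missing)) {
    stop(sprintf("marker '%s' absent from state vector", missing[1]),
         call. = FALSE)
  }
  v <- q[markers$marker]
  tag_order <- attr(markers, "tag_order")
  uncertain <- v > inactivation & v < activation
  active <- v >= activation
  label <- if (any(uncertain)) {
    "NoLabel"
  } else if (!any(active)) {
    "M0"
  } else {
    tags <- markers$tag[active]
    if (collapse_m1 && all(c("M1", "M1a") %in% tags)) tags <- setdiff(tags, "M1a")
    paste(tags[order(match(tags, tag_order))], collapse = "")
  }
  structure(list(label = label,
                 active_markers = markers$marker[active],
                 marker_values = v),
            class = "phenotype_label")
}

#' @export
print.phenotype_label <- function(x, ...) {
  cat(x$label, "\n")
  if (!is.null(x$marker_values)) print(round(x$marker_values, 3))
  invisible(x)
}

#' Distance between a steady state and its initial state
#'
#' Euclidean norm of the difference over transcription-factor nodes (clamped
#' inputs are excluded: they carry no polarization information). This is the
#' summary statistic plotted against clamp concentration in dose scans.
#'
#' @param state a `steady_state` or named numeric vector.
#' @param q0 initial state, named numeric vector (missing nodes count as 0).
#' @param nodes nodes over which to take the norm; defaults to the
#'   transcription-factor nodes recorded in `state` when it is a
#'   `steady_state` over a network system, otherwise all shared nodes.
#' @return nonnegative scalar, with the per-node difference vector attached
#'   as attribute `"diff"`.
#' @export
distance_to_initial <- function(state, q0, nodes = NULL) {
  q <- if (inherits(state, "steady_state")) state$q else state
  if (is.null(nodes)) nodes <- names(q)
  miss <- setdiff(nodes, names(q))
  if (length(miss)) stop(sprintf("node '%s' absent from state", miss[1]),
                         call. = FALSE)
  q0full <- setNames(rep(0, length(nodes)), nodes)
  if (length(q0) == 0L) {
    # empty initial state: the all-zero monocyte
  } else if (!is.null(names(q0))) {
    shared <- intersect(names(q0), nodes)
    q0full[shared] <- as.numeric(q0[shared])
  } else {
    if (length(q0) != length(nodes)) stop("dimension mismatch", call. = FALSE)
    q0full[] <- as.numeric(q0)
  }
  d <- q[nodes] - q0full
  structure(sqrt(sum(d^2)), diff = d)
}
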