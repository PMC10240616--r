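# Random Boolean regulatory networks and the exhaustive synchronous Boolean
# attractor oracle used as ground truth in tests.

#' Specification of a random Boolean regulatory network
#'
#' Emulates the structural class the analysis assumes: signed Boolean
#' networks with clamp-only extracellular input nodes and internal
#' transcription-factor nodes, each governed by an AND/OR/NOT rule.
#'
#' @param n_tf number of transcription-factor nodes (>= 1).
#' @param n_input number of extracellular input nodes (>= 0).
#' @param k maximum number of regulators per rule.
#' @param p_not probability that a literal is negated.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tf, n_input = 0L, k = 2L, p_not = 0.3, seed = 1L) {
  stopifnot(n_tf >= 1, n_input >= 0, k >= 1, k <= n_tf + n_input,
            p_not >= 0, p_not <= 1)
  structure(list(n_tf = as.integer(n_tf), n_input = as.integer(n_input),
                 k = as.integer(k), p_not = p_not, seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random AND/OR tree over the given literals (depth <= 3 by construction:
# literals are folded in pairs, then pairs of pairs)
random_rule_tree <- function(regulators, p_not) {
  leaves <- lapply(regulators, function(r) {
    leaf <- list(op = "var", name = r)
    if (stats::runif(1) < p_not) list(op = "not", arg = leaf) else leaf
  })
  while (length(leaves) > 1L) {
    op <- sample(c("and", "or"), 1L)
    merged <- list(op = op, lhs = leaves[[1L]], rhs = leaves[[2L]])
    leaves <- c(list(merged), leaves[-(1:2)])
  }
  leaves[[1L]]
}

#' Generate a random Boolean regulatory network
#'
#' Each transcription-factor node receives a random AND/OR rule over up to
#' `k` distinct regulators, with literals negated with probability `p_not`.
#' Generation is deterministic given the spec's seed (integer-only sampling
#' path), and the caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated `regulatory_network` with inputs named `E1..` and
#'   transcription factors named `G1..`.
#' @export
random_boolean_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  inputs <- if (spec$n_input > 0) paste0("E", seq_len(spec$n_input)) else character(0)
  tfs <- paste0("G", seq_len(spec$n_tf))
  all_nodes <- c(inputs, tfs)
  rules <- with_seed(spec$seed, {
    lapply(setNames(tfs, tfs), function(g) {
      k1 <- sample.int(spec$k, 1L)
      regs <- sample(all_nodes, k1)
      structure(list(target = g, expr = random_rule_tree(regs, spec$p_not)),
                class = "boolean_rule")
    })
  })
  nodes <- data.frame(
    name = all_nodes,
    klass = c(rep("extracellular", length(inputs)),
              rep("transcription_factor", length(tfs))),
    stringsAsFactors = FALSE)
  regulatory_network(nodes, rules)
}

#' Exhaustive synchronous Boolean attractors
#'
#' Enumerates all `2^n` transcription-factor states (inputs held at a fixed
#' 0/1 assignment), applies the synchronous Boolean update, and partitions
#' the state space into attractor basins. Basin sizes sum to `2^n`.
#'
#' @param network a `regulatory_network`.
#' @param input_assignment named 0/1 vector over the extracellular nodes
#'   (missing inputs default to 0).
#' @return list with components
#'   \describe{
#'     \item{attractors}{list of 0/1 matrices (one row per state in the
#'       attractor; a single row is a fixed point), columns named by TF}
#'     \item{basin_sizes}{integer vector aligned with `attractors`}
#'     \item{fixed_points}{matrix of all fixed-point states (possibly 0 rows)}
#'     \item{n_states}{`2^n`}
#'   }
#' @export
boolean_attractors_synchronous <- function(network, input_assignment = NULL) {
  tf <- network_nodes(network, "transcription_factor")
  ext <- network_nodes(network, "extracellular")
  n <- length(tf)
  if (n > 20L) stop("state space too large for exhaustive enumeration (n_tf > 20)",
                    call. = FALSE)
  n_states <- 2L^n
  # vectorized state table: one logical vector of length 2^n per node
  state <- list()
  for (e in ext) state[[e]] <- rep(FALSE, n_states)
  if (!is.null(input_assignment)) {
    unknown <- setdiff(names(input_assignment), ext)
    if (length(unknown)) stop(sprintf("'%s' is not an extracellular node",
                                      unknown[1]), call. = FALSE)
    for (e in names(input_assignment)) {
      state[[e]] <- rep(as.logical(input_assignment[[e]]), n_states)
    }
  }
  idx <- 0:(n_states - 1L)
  for (i in seq_len(n)) state[[tf[i]]] <- bitwAnd(idx, bitwShiftL(1L, i - 1L)) > 0L
  succ <- rep(0L, n_states)
  for (i in seq_len(n)) {
    bit <- as.logical(boolean_evaluate(network$rules[[tf[i]]], state))
    succ <- succ + bitwShiftL(1L, i - 1L) * as.integer(bit)
  }
  succ <- succ + 1L  # 1-based

  # attractor detection on the functional graph
  attractor_id <- rep(0L, n_states)   # 0 = unassigned
  attractors <- list()
  for (s in seq_len(n_states)) {
    if (attractor_id[s] > 0L) next
    path <- integer(0)
    on_path <- rep(FALSE, n_states)
    cur <- s
    while (attractor_id[cur] == 0L && !on_path[cur]) {
      on_path[cur] <- TRUE
      path <- c(path, cur)
      cur <- succ[cur]
    }
    if (attractor_id[cur] > 0L) {
      id <- attractor_id[cur]
    } else {
      # new cycle: cur is on the current path
      cstart <- match(cur, path)
      cyc <- path[cstart:length(path)]
      id <- length(attractors) + 1L
      attractors[[id]] <- cyc
    }
    attractor_id[path] <- id
  }
  basin_sizes <- tabulate(attractor_id, nbins = length(attractors))

  decode <- function(codes) {
    m <- matrix(0L, nrow = length(codes), ncol = n, dimnames = list(NULL, tf))
    for (i in seq_len(n)) {
      m[, i] <- as.integer(bitwAnd(codes - 1L, bitwShiftL(1L, i - 1L)) > 0L)
    }
    m
  }
  att_states <- lapply(attractors, decode)
  fp <- att_states[vapply(att_states, nrow, integer(1)) == 1L]
  fixed_points <- if (length(fp)) do.call(rbind, fp)
                  else matrix(0L, 0L, n, dimnames = list(NULL, tf))
  list(attractors = att_states, basin_sizes = basin_sizes,
       fixed_points = fixed_points, n_states = n_states)
}

# Named phenotype embeddings for the macrophage fixture: each tag's marker
# transcription factor plus the nodes its activation directly sustains.
phenotype_node_sets <- list(
  M1  = c("NFkB", "AP1", "SOCS3"),
  M1a = "STAT1",
  M2a = c("STAT6", "SOCS1"),
  M2b = "ERK",
  M2c = "STAT3",
  M2d = "HIF1a")

#' Build an initial state vector
#'
#' `"M0"` is the all-zero monocyte state. Phenotype names (`"M1"`, `"M1a"`,
#' `"M2a"`..`"M2d"`, or concatenated hybrids such as `"M1M2b"`) are embedded
#' as 0/1 vectors over the corresponding marker transcription factors and
#' their directly sustained partners (for `"M1"`, the self-sustaining
#' NFkB/AP1/SOCS3 loop, which is a synchronous Boolean fixed point of the
#' fixture under zero inputs). A 0/1 Boolean attractor row (named or
#' full-length) is embedded as-is.
#'
#' @param network a `regulatory_network`.
#' @param phenotype character phenotype name, or numeric 0/1 (or `[0,1]`)
#'   vector.
#' @return named numeric state vector over all nodes of the network.
#' @export
make_initial_state <- function(network, phenotype) {
  nn <- network$nodes$name
  q <- setNames(rep(0, length(nn)), nn)
  if (is.numeric(phenotype)) {
    if (is.null(names(phenotype))) {
      m <- length(phenotype)
      tf <- network_nodes(network, "transcription_factor")
      if (m == length(nn)) q[] <- phenotype
      else if (m == length(tf)) q[tf] <- phenotype
      else stop("attractor vector length matches neither all nodes nor TF nodes",
                call. = FALSE)
    } else {
      unknown <- setdiff(names(phenotype), nn)
      if (length(unknown)) stop(sprintf("unknown node '%s'", unknown[1]),
                                call. = FALSE)
      q[names(phenotype)] <- phenotype
    }
    return(q)
  }
  stopifnot(is.character(phenotype), length(phenotype) == 1L)
  if (phenotype == "M0") return(q)
  rest <- phenotype
  tags <- character(0)
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr("^(M1a|M1|M2[abcd])", rest))
    if (length(m) == 0L) stop(sprintf("unknown phenotype name '%s'", phenotype),
                              call. = FALSE)
    tags <- c(tags, m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  nodes <- unique(unlist(phenotype_node_sets[tags]))
  missing <- setdiff(nodes, nn)
  if (length(missing)) {
    stop(sprintf("phenotype '%s' needs node '%s', absent from this network",
                 phenotype, missing[1]), call. = FALSE)
  }
  q[nodes] <- 1
  q
}
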