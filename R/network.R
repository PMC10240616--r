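# Regulatory network container, file I/O and the vendored macrophage fixture.

#' Construct a regulatory network
#'
#' A network couples a node table (name + class) with one Boolean update rule
#' per transcription-factor node. Extracellular nodes are pure inputs: they
#' carry no rule and are only ever set exogenously (clamped).
#'
#' @param nodes data.frame with columns `name` and `klass`
#'   (`"extracellular"` or `"transcription_factor"`).
#' @param rules named list of `boolean_rule` objects, one per
#'   transcription-factor node (names are the target nodes).
#' @return object of class `regulatory_network` with fields `nodes`, `rules`
#'   and the derived signed `edges` table.
#' @export
regulatory_network <- function(nodes, rules) {
  stopifnot(is.data.frame(nodes), all(c("name", "klass") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  nodes$klass <- as.character(nodes$klass)
  if (anyDuplicated(nodes$name)) {
    stop(sprintf("duplicate node name: %s",
                 nodes$name[duplicated(nodes$name)][1]), call. = FALSE)
  }
  bad <- setdiff(nodes$klass, c("extracellular", "transcription_factor"))
  if (length(bad)) stop(sprintf("unknown node class '%s'", bad[1]), call. = FALSE)

  tf <- nodes$name[nodes$klass == "transcription_factor"]
  ext <- nodes$name[nodes$klass == "extracellular"]
  if (length(setdiff(names(rules), tf))) {
    off <- setdiff(names(rules), tf)[1]
    if (off %in% ext) {
      stop(sprintf("extracellular node '%s' must not have a rule", off),
           call. = FALSE)
    }
    stop(sprintf("rule for undeclared node '%s'", off), call. = FALSE)
  }
  if (length(setdiff(tf, names(rules)))) {
    stop(sprintf("transcription_factor node '%s' has no rule",
                 setdiff(tf, names(rules))[1]), call. = FALSE)
  }
  for (target in names(rules)) {
    refs <- rule_inputs(rules[[target]])
    unknown <- setdiff(refs, nodes$name)
    if (length(unknown)) {
      stop(sprintf("rule for '%s' references undeclared node '%s'",
                   target, unknown[1]), call. = FALSE)
    }
    rules[[target]]$target <- target
  }
  net <- structure(list(nodes = nodes, rules = rules[tf]),
                   class = "regulatory_network")
  net$edges <- network_edges(net)
  net
}

#' Derived signed interaction list of a network
#'
#' `(source, target)` is an edge iff `source` appears in `target`'s rule.
#' The sign is `"+"` if every occurrence sits under an even number of NOTs,
#' `"-"` if odd, `"+-"` if mixed.
#'
#' @param network a `regulatory_network`.
#' @return data.frame with columns `source`, `target`, `sign`.
#' @export
network_edges <- function(network) {
  out <- lapply(network$rules, function(r) {
    s <- rule_signs(r)
    if (nrow(s) == 0L) return(NULL)
    data.frame(source = s$source, target = r$target, sign = s$sign,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(source = character(0), target = character(0),
                      sign = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Node names of a network
#'
#' @param network a `regulatory_network`.
#' @param klass optional filter, `"extracellular"` or `"transcription_factor"`.
#' @return character vector of node names, in declaration order.
#' @export
network_nodes <- function(network, klass = NULL) {
  n <- network$nodes
  if (!is.null(klass)) n <- n[n$klass == klass, , drop = FALSE]
  n$name
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "Regulatory network: %d nodes (%d transcription factors, %d extracellular), %d interactions\n",
    nrow(x$nodes),
    sum(x$nodes$klass == "transcription_factor"),
    sum(x$nodes$klass == "extracellular"),
    nrow(x$edges)))
  for (r in x$rules) cat("  ", format(r), "\n", sep = "")
  invisible(x)
}

#' Load a network-definition file
#'
#' Plain-text format, one line per node:
#' `<name>, <klass>, <rule-or-dash>`; `klass` is `extracellular` (alias
#' `input`) or `transcription_factor` (alias `tf`); extracellular nodes use
#' `-` in the rule column. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a validated `regulatory_network`.
#' @export
load_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nodes <- data.frame(name = character(0), klass = character(0))
  rules <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("malformed network line (need 'name, klass, rule'): '%s'", ln),
           call. = FALSE)
    }
    name <- trimws(parts[1])
    klass <- trimws(parts[2])
    rule_text <- trimws(paste(parts[-(1:2)], collapse = ","))
    klass <- switch(klass,
      input = , extracellular = "extracellular",
      tf = , transcription_factor = "transcription_factor",
      stop(sprintf("unknown node class '%s' for node '%s'", klass, name),
           call. = FALSE))
    nodes <- rbind(nodes, data.frame(name = name, klass = klass,
                                     stringsAsFactors = FALSE))
    if (klass == "transcription_factor") {
      if (rule_text == "-") {
        stop(sprintf("transcription_factor node '%s' has no rule", name),
             call. = FALSE)
      }
      rules[[name]] <- parse_rule(rule_text, target = name)
    } else if (rule_text != "-") {
      stop(sprintf("extracellular node '%s' must not have a rule", name),
           call. = FALSE)
    }
  }
  regulatory_network(nodes, rules)
}

#' Serialize a network to the network-definition format
#'
#' Inverse of [load_network()] modulo whitespace and comments.
#'
#' @param network a `regulatory_network`.
#' @param path file path, or `NULL` to return the lines invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_network <- function(network, path = NULL) {
  lines <- vapply(seq_len(nrow(network$nodes)), function(i) {
    name <- network$nodes$name[i]
    klass <- network$nodes$klass[i]
    rule <- if (klass == "transcription_factor") {
      deparse_rule(network$rules[[name]])
    } else "-"
    sprintf("%s, %s, %s", name, klass, rule)
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a BoolNet-style rule file
#'
#' Interoperability reader for the `targets, factors` format used by the
#' BoolNet family of tools: a header line `targets, factors` followed by one
#' `target, expression` line per node, with `&`, `|`, `!` as AND, OR, NOT.
#' Nodes that appear only as regulators (never as targets) are declared
#' extracellular; a self-copy rule `A, A` is also treated as an input
#' declaration.
#'
#' @param path file path.
#' @return a validated `regulatory_network`.
#' @export
read_boolnet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^targets\\s*,\\s*factors$", lines[1],
                             ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  targets <- character(0)
  exprs <- character(0)
  for (ln in lines) {
    m <- regexpr(",", ln, fixed = TRUE)
    if (m < 0) stop(sprintf("malformed BoolNet line: '%s'", ln), call. = FALSE)
    targets <- c(targets, trimws(substr(ln, 1, m - 1)))
    exprs <- c(exprs, trimws(substr(ln, m + 1, nchar(ln))))
  }
  to_infix <- function(s) {
    s <- gsub("&", " AND ", s, fixed = TRUE)
    s <- gsub("|", " OR ", s, fixed = TRUE)
    s <- gsub("!", " NOT ", s, fixed = TRUE)
    s
  }
  rules <- list()
  tf <- character(0)
  for (i in seq_along(targets)) {
    if (identical(exprs[i], targets[i])) next  # self-copy: input declaration
    rules[[targets[i]]] <- parse_rule(to_infix(exprs[i]), target = targets[i])
    tf <- c(tf, targets[i])
  }
  regs <- unique(unlist(lapply(rules, rule_inputs)))
  all_nodes <- unique(c(targets, regs))
  nodes <- data.frame(
    name = all_nodes,
    klass = ifelse(all_nodes %in% tf, "transcription_factor", "extracellular"),
    stringsAsFactors = FALSE)
  regulatory_network(nodes, rules)
}

# Variant spellings occurring in the literature, normalized to the fixture's
# identifiers (Greek letters transliterated).
node_alias_map <- c(
  "NFKB" = "NFkB", "NF-KB" = "NFkB", "NFKAPPAB" = "NFkB",
  "HIF1ALPHA" = "HIF1a", "HIF1-ALPHA" = "HIF1a", "HIF-1A" = "HIF1a",
  "HIF1A" = "HIF1a",
  "IFN-G" = "IFNG", "IFNGAMMA" = "IFNG", "IFN-B" = "IFNB", "IFNBETA" = "IFNB",
  "TNFA" = "TNFAe", "TNF-A" = "TNFAe", "TNFALPHA" = "TNFAe",
  "IL10" = "IL10e", "IL-10" = "IL10e", "IL4" = "IL4e", "IL-4" = "IL4e",
  "IL13" = "IL13e", "IL-13" = "IL13e", "IL6" = "IL6e", "IL-6" = "IL6e",
  "IL1BETA" = "IL1B", "IL-1B" = "IL1B",
  "TGFBETA" = "TGFB", "TGF-B" = "TGFB",
  "ADENOSINE" = "A2a", "ADENOSINES" = "A2a",
  "GC" = "GCGCR", "GLUCOCORTICOID" = "GCGCR",
  "SMAD2/3" = "SMAD23", "AP-1" = "AP1", "PPAR-G" = "PPARG", "PPARGAMMA" = "PPARG",
  "ERK1/2" = "ERK"
)

#' Normalize a node name to the fixture's spelling
#'
#' Case-sensitive identifiers are kept as-is; known variant spellings
#' (Greek letters, hyphenation) are mapped to the vendored network's
#' transliterated names.
#'
#' @param name character vector of node names.
#' @return character vector of normalized names.
#' @export
normalize_node_name <- function(name) {
  key <- toupper(name)
  hit <- unname(node_alias_map[key])
  ifelse(is.na(hit), name, hit)
}

#' The vendored 29-node macrophage polarization network
#'
#' Loads the transcriptional regulatory network of macrophage polarization
#' shipped with the package: 29 nodes (14 transcription factors, 15
#' extracellular cytokines/metabolic byproducts) and 60 signed interactions.
#' The rule set is a reconstruction from the published network description
#' (see the package vignette); the file itself is data, and every analysis
#' function accepts any conforming network.
#'
#' @return a `regulatory_network`.
#' @export
macrophage_network <- function() {
  load_network(system.file("extdata", "macrophage_trn.txt", package = "macpol",
                           mustWork = TRUE))
}
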