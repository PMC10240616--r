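# Toy networks built in code, shared across test files.

toy_network <- function(node_lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(node_lines, f)
  on.exit(unlink(f))
  load_network(f)
}

# mutual inhibition toggle: two TFs repressing each other
toggle_network <- function() {
  regulatory_network(
    data.frame(name = c("A", "B"), klass = "transcription_factor"),
    list(A = parse_rule("NOT B", "A"), B = parse_rule("NOT A", "B")))
}

# one input driving one TF
relay_network <- function() {
  regulatory_network(
    data.frame(name = c("A", "B"),
               klass = c("extracellular", "transcription_factor")),
    list(B = parse_rule("A", "B")))
}

# self-copy TF (two Boolean fixed points)
selfcopy_network <- function() {
  regulatory_network(
    data.frame(name = "A", klass = "transcription_factor"),
    list(A = parse_rule("A", "A")))
}

random_specs <- function(n, seed_offset = 0L) {
  lapply(seq_len(n), function(i) {
    synthetic_spec(
      n_tf = 3L + (i %% 8L),
      n_input = i %% 3L,
      k = min(3L, 3L + (i %% 8L)),
      p_not = 0.3,
      seed = 1000L + seed_offset + i)
  })
}

# all 0/1 assignments over k variables as a list of named vectors
bool_grid <- function(vars) {
  k <- length(vars)
  lapply(0:(2^k - 1), function(code) {
    setNames(as.numeric(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0), vars)
  })
}
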