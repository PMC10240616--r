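test_that("a clamped input drives its target to the closed-form fixed point", {
  sys <- build_ode_system(relay_network(), fuzzy_params(b = 10))
  st <- integrate_to_steady_state(sys, q0 = c(A = 1, B = 0),
                                  clamps = clamp_set(A = 1))
  expect_true(st$converged)
  expect_equal(st$classification, "fixed_point")
  expect_equal(unname(st$q["B"]), 0.993307149075715, tolerance = 1e-5)
})

test_that("integration from a fixed point is idempotent", {
  sys <- build_ode_system(relay_network(), fuzzy_params(b = 10))
  qstar <- c(A = 1, B = 0.993307149075715)
  st <- integrate_to_steady_state(sys, q0 = qstar, clamps = clamp_set(A = 1))
  expect_true(st$converged)
  expect_equal(st$time, 0)
  expect_equal(unname(st$q["B"]), unname(qstar["B"]), tolerance = 1e-9)
})

test_that("the mutual-inhibition toggle has the symmetric balanced state", {
  # q = phi(1 - q) is solved exactly by q = 1/2 when omega_thr = 1/2
  sys <- build_ode_system(toggle_network(), fuzzy_params(b = 10))
  st <- integrate_to_steady_state(sys, q0 = c(A = 0.5, B = 0.5))
  expect_true(st$converged)
  expect_equal(unname(st$q), c(0.5, 0.5), tolerance = 1e-6)
  # asymmetric starts break toward the stable committed states
  st2 <- integrate_to_steady_state(sys, q0 = c(A = 0.9, B = 0.1))
  expect_gt(st2$q[["A"]], 0.9)
  expect_lt(st2$q[["B"]], 0.1)
})

test_that("clamped coordinates are held bit-identically", {
  net <- macrophage_network()
  sys <- build_ode_system(net)
  cl <- clamp_set(IFNG = 0.6, NFkB = 1, HIF1a = 0)
  st <- integrate_to_steady_state(sys, clamps = cl, keep_trajectory = TRUE)
  expect_identical(unname(st$q["IFNG"]), 0.6)
  expect_identical(unname(st$q["NFkB"]), 1)
  expect_identical(unname(st$q["HIF1a"]), 0)
  # and the derivative of a clamped node is zero throughout
  dq <- apply_clamps(sys, cl)$rhs(0, st$q)
  expect_equal(unname(dq[c("IFNG", "NFkB", "HIF1a")]), c(0, 0, 0))
})

test_that("apply_clamps leaves unclamped equations untouched", {
  sys <- build_ode_system(macrophage_network())
  expect_identical(apply_clamps(sys, clamp_set())$clamps, sys$clamps)
  cl_sys <- apply_clamps(sys, clamp_set(IFNG = 0.3))
  q <- setNames(runif(29), sys$node_names)
  free <- setdiff(sys$node_names, "IFNG")
  expect_equal(cl_sys$rhs(0, q)[free], sys$rhs(0, q)[free])
  expect_error(apply_clamps(sys, clamp_set(NOPE = 1)), "unknown node")
})

test_that("trajectories never leave the unit box and converge consistently", {
  # forward invariance: phi in (0,1) and alpha = 1 push the flow inward
  eps <- 1e-9
  count <- 0
  for (spec in random_specs(10)) {
    net <- random_boolean_network(spec)
    sys <- build_ode_system(net, fuzzy_params(b = 10))
    set.seed(spec$seed)
    for (rep in 1:10) {
      q0 <- setNames(runif(length(sys$node_names)), sys$node_names)
      st <- integrate_to_steady_state(sys, q0 = q0, cfg = sim_config(t_max = 60),
                                      keep_trajectory = TRUE)
      count <- count + 1
      expect_true(all(st$trajectory >= -eps & st$trajectory <= 1 + eps))
      if (st$converged) {
        # fixed-point consistency with alpha = 1: q = phi(omega(q))
        w <- sys$omega(st$q)
        phi <- characteristic(w, sys$params)
        free <- setdiff(sys$tf_nodes, names(st$clamps))
        expect_lte(max(abs(st$q[free] - phi[free])), 1e-5)
      }
    }
  }
  expect_equal(count, 100)
})

test_that("identical inputs give identical terminal states", {
  sys <- build_ode_system(macrophage_network())
  cfg <- sim_config()
  s1 <- integrate_to_steady_state(sys, clamps = clamp_set(IL6e = 0.5), cfg = cfg)
  s2 <- integrate_to_steady_state(sys, clamps = clamp_set(IL6e = 0.5), cfg = cfg)
  expect_identical(s1$q, s2$q)
})

test_that("continuous dynamics respect Boolean fixed points at high steepness", {
  for (spec in random_specs(8, seed_offset = 300L)) {
    net <- random_boolean_network(spec)
    ext <- network_nodes(net, "extracellular")
    assign0 <- setNames(rep(0, length(ext)), ext)
    oracle <- boolean_attractors_synchronous(net, assign0)
    if (nrow(oracle$fixed_points) == 0) next
    sys <- build_ode_system(net, fuzzy_params(b = 50))
    for (i in seq_len(nrow(oracle$fixed_points))) {
      q0 <- make_initial_state(net, oracle$fixed_points[i, ])
      st <- integrate_to_steady_state(sys, q0 = q0, cfg = sim_config(t_max = 100))
      expect_lte(max(abs(st$q - q0)), 0.01)
    }
  }
})

test_that("a genuine limit cycle is classified cyclic, slow drift is not", {
  # three-node repressor ring: the canonical oscillator of this model class
  ring <- regulatory_network(
    data.frame(name = c("A", "B", "C"), klass = "transcription_factor"),
    list(A = parse_rule("NOT C", "A"), B = parse_rule("NOT A", "B"),
         C = parse_rule("NOT B", "C")))
  sys <- build_ode_system(ring, fuzzy_params(b = 50))
  st <- integrate_to_steady_state(sys, q0 = c(A = 1, B = 0, C = 0.2),
                                  cfg = sim_config(t_max = 300))
  expect_false(st$converged)
  expect_equal(st$classification, "cyclic")
  # a truncated slow relaxation stays undetermined rather than cyclic
  sys2 <- build_ode_system(relay_network(), fuzzy_params(b = 25))
  st2 <- integrate_to_steady_state(sys2, q0 = c(A = 0.42, B = 0),
                                   clamps = clamp_set(A = 0.42),
                                   cfg = sim_config(t_max = 3))
  expect_false(st2$converged)
  expect_equal(st2$classification, "undetermined")
})

test_that("invalid initial states and clamps are rejected with diagnostics", {
  sys <- build_ode_system(relay_network())
  expect_error(integrate_to_steady_state(sys, q0 = c(A = 2, B = 0)), "\\[0, 1\\]")
  expect_error(integrate_to_steady_state(sys, q0 = c(Z = 1)), "unknown node")
  expect_error(clamp_set(A = 1.5), "\\[0, 1\\]")
  expect_error(clamp_set(0.5), "named")
})

test_that("steady states export to tidy tables and JSON metadata", {
  sys <- build_ode_system(relay_network())
  cfg <- sim_config()
  st <- integrate_to_steady_state(sys, clamps = clamp_set(A = 1), cfg = cfg,
                                  keep_trajectory = TRUE)
  df <- as.data.frame(st)
  expect_equal(nrow(df), 2)
  expect_true(df$clamped[df$node == "A"])
  long <- trajectory_long(st)
  expect_equal(sort(unique(long$node)), c("A", "B"))
  js <- jsonlite::fromJSON(run_metadata_json(sys, st, cfg))
  expect_equal(js$b, sys$params$b)
  expect_equal(js$clamps$A, 1)
  expect_true(js$converged)
})
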