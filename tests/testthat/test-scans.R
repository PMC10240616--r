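# Machinery tests on small grids; the full-grid fixture scans reproducing the
# published thresholds live in test-acceptance.R.

fast_cfg <- sim_config(t_max = 200)

test_that("transition thresholds and uncertainty bands are extracted exactly", {
  mkres <- function(grid, labels) {
    structure(list(rows = data.frame(value = grid, label = labels,
                                     stringsAsFactors = FALSE)),
              class = "scan_result")
  }
  r <- mkres(c(0.50, 0.525, 0.55, 0.575), c("M0", "M0", "NoLabel", "M1a"))
  hit <- find_transition_threshold(r, "M0", "M1a")
  expect_equal(hit$value, 0.575)
  expect_equal(hit$band, c(0.55, 0.55))
  expect_null(find_transition_threshold(mkres(c(0, 1), c("M0", "M0")),
                                        "M0", "M1a"))
  expect_equal(find_transition_threshold(mkres(c(0, 1), c("M0", "M1a")),
                                         "M0", "M1a")$value, 1)
  # bands
  b <- uncertainty_bands(seq(0, 1, 0.25),
                         c("M0", "NoLabel", "NoLabel", "M1", "NoLabel"))
  expect_equal(b$start, c(0.25, 1.0))
  expect_equal(b$end, c(0.5, 1.0))
  tr <- extract_transitions(c(1, 2, 3), c("M0", "M0", "M1"))
  expect_equal(tr$value, 3)
  expect_equal(tr$label_before, "M0")
})

test_that("scanning a disconnected input never polarizes the cell", {
  net <- regulatory_network(
    data.frame(name = c("I", "A"), klass = c("extracellular", "transcription_factor")),
    list(A = parse_rule("A", "A")))
  sys <- build_ode_system(net)
  mk <- marker_table("A", "M1")
  res <- dose_scan_1d(sys, scan_spec_1d("I", step = 0.25), mk, fast_cfg)
  expect_true(all(res$rows$label == "M0"))
  expect_equal(nrow(res$transitions), 0)
  expect_equal(nrow(res$uncertainty_bands), 0)
})

test_that("scan rows are independent of grid evaluation order", {
  sys <- build_ode_system(macrophage_network())
  vals <- c(0.45, 0.5, 0.55)
  a <- dose_scan_1d(sys, scan_spec_1d("IFNG", values = vals), cfg = fast_cfg)
  b <- dose_scan_1d(sys, scan_spec_1d("IFNG", values = rev(vals)), cfg = fast_cfg)
  bb <- b$rows[order(b$rows$value), ]
  rownames(bb) <- NULL
  expect_equal(bb, a$rows)
})

test_that("scan rows carry states, distances and marker values", {
  sys <- build_ode_system(macrophage_network())
  res <- dose_scan_1d(sys, scan_spec_1d("IFNG", values = c(0, 0.55)),
                      cfg = fast_cfg)
  expect_equal(nrow(res$rows), 2)
  expect_true(all(c("distance", "residual", "STAT1", "NFkB") %in% names(res$rows)))
  expect_equal(res$rows$distance[1], 0, tolerance = 1e-4)
  expect_gt(res$rows$distance[2], 0.5)
  expect_length(res$states, 2)
  expect_true(all(as.data.frame(res)$converged))
})

test_that("a microenvironment scan from M1 keeps its phenotype in interferon", {
  sys <- build_ode_system(macrophage_network())
  res <- microenvironment_scan(sys, microenvironment_presets()[["pro-M1a"]],
                               q0 = "M1", values = c(0, 0.25, 0.75, 1),
                               cfg = fast_cfg)
  expect_true(all(res$rows$label == "M1"))
  # degenerate single-point grid equals the label of the settled q0
  res0 <- microenvironment_scan(sys, "IL4e", q0 = "M1", values = 0,
                                cfg = fast_cfg)
  st <- integrate_to_steady_state(sys, q0 = make_initial_state(sys$network, "M1"),
                                  cfg = fast_cfg)
  expect_equal(res0$rows$label, label_state(st)$label)
})

test_that("the M1 state destabilizes in a regulatory milieu", {
  # wound-healing environment flips the pro-inflammatory loop off
  sys <- build_ode_system(macrophage_network())
  res <- microenvironment_scan(sys, microenvironment_presets()[["pro-M2a"]],
                               q0 = "M1", values = c(0.1, 0.8), cfg = fast_cfg)
  expect_equal(res$rows$label[1], "M1")
  expect_false(res$rows$label[2] %in% c("M1", "NoLabel"))
  expect_gte(res$rows[2, "HIF1a"], 0.75)  # tumor-associated program on
  expect_lte(res$rows[2, "NFkB"], 0.25)   # pro-inflammatory program off
})

test_that("constant TGEM perturbations hold through every scan row", {
  sys <- build_ode_system(macrophage_network())
  res <- tgem_scan(sys, c("Hypoxia", "GCGCR"), values = c(0, 0.4, 0.8),
                   cfg = fast_cfg)
  for (q in res$states) {
    expect_identical(unname(q["NFkB"]), 1)
    expect_identical(unname(q["HIF1a"]), 0)
  }
  # hypoxia/glucocorticoid environment never moves the modified macrophage
  expect_true(all(res$rows$label == "M1"))
  expect_equal(nrow(res$transitions), 0)
  # immune complexes + adenosine recruit the regulatory M2b arm above 0.6
  res2 <- tgem_scan(sys, c("IgG", "A2a"), values = c(0.2, 0.625, 0.8),
                    cfg = fast_cfg)
  expect_equal(res2$rows$label, c("M1", "M1M2b", "M1M2b"))
})

test_that("2D phenotype maps cover the grid and honor axis roles", {
  net <- macrophage_network()
  sys <- build_ode_system(net)
  spec <- map_spec_2d(
    axis1 = list(node = "STAT1", role = "initial_value", grid = c(0, 0.5, 1)),
    axis2 = list(node = "IL13e", role = "clamp", grid = c(0, 1)),
    q0 = "M1a")
  m <- phenotype_map_2d(sys, spec, cfg = fast_cfg)
  expect_equal(dim(m$labels), c(3, 2))
  expect_equal(length(m$states), 6)
  # clamped axis value is exact in every cell of its column
  expect_identical(unname(m$states[[1, 2]]["IL13e"]), 1)
  expect_error(map_spec_2d(
    axis1 = list(node = "A", role = "clamp", grid = 0),
    axis2 = list(node = "A", role = "clamp", grid = 0)), "distinct")
})

test_that("a degenerate 2D map reproduces the corresponding 1D scan", {
  sys <- build_ode_system(macrophage_network())
  vals <- c(0.45, 0.5, 0.55)
  spec <- map_spec_2d(
    axis1 = list(node = "IFNG", role = "clamp", grid = vals),
    axis2 = list(node = "IL13e", role = "clamp", grid = 0))
  m <- phenotype_map_2d(sys, spec, cfg = fast_cfg)
  res <- dose_scan_1d(sys, scan_spec_1d("IFNG", values = vals), cfg = fast_cfg)
  expect_equal(unname(m$labels[, 1]), res$rows$label)
})

test_that("an axis clamping a disconnected input leaves rows identical", {
  net <- regulatory_network(
    data.frame(name = c("I", "J", "A"),
               klass = c("extracellular", "extracellular", "transcription_factor")),
    list(A = parse_rule("I", "A")))
  sys <- build_ode_system(net)
  mk <- marker_table("A", "M1")
  spec <- map_spec_2d(
    axis1 = list(node = "I", role = "clamp", grid = c(0, 0.5, 1)),
    axis2 = list(node = "J", role = "clamp", grid = c(0, 0.5, 1)))
  m <- phenotype_map_2d(sys, spec, mk, fast_cfg)
  expect_true(all(m$labels[, 1] == m$labels[, 2] & m$labels[, 2] == m$labels[, 3]))
})

test_that("microenvironment presets list the published cytokine sets", {
  p <- microenvironment_presets()
  net <- macrophage_network()
  ext <- network_nodes(net, "extracellular")
  expect_true(all(unlist(p) %in% ext))
  expect_equal(p[["pro-M2c"]], c("IL10e", "MCSF", "IL6e"))
  expect_equal(p[["bc-hypoxic"]], c("Hypoxia", "GCGCR"))
})
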