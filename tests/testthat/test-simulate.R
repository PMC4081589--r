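test_that("config validation enforces the report horizon", {
  expect_error(simulation_config(horizon = 20,
                                 report_times = c(21, 42)), "report time")
  expect_error(simulation_config(report_times = c(42, 21)),
               "increasing")
})

test_that("a zero-horizon run returns the initial hematoma state", {
  cfg <- small_config(horizon = 0, report_times = numeric(0))
  tc <- run_healing(cfg)
  expect_equal(tc$report$v_bo, 0)
  expect_equal(tc$report$ci, 1)
  expect_false(tc$report$bridged)
  h <- tc$mesh$region == "HEALING"
  expect_true(all(tc$state$c_conn[h] == 1))
  expect_true(all(tc$state$t_age[h] == 0))
  # hematoma modulus at age 0
  sm <- callusmap:::state_materials(tc$state, tc$mesh, material_table(),
                                    maturation_curve())
  expect_equal(unname(sm$E[h]), rep(0.1, sum(h)), tolerance = 0.02)
  # initial vascularity confined to the healing-domain boundary sources
  expect_true(all(tc$state$v[tc$mesh$source_elements] == 1))
  interior <- h & !(seq_along(h) %in% tc$mesh$source_elements)
  expect_true(all(tc$state$v[interior] == 0))
})

test_that("identical configurations give identical timecourses", {
  cfg <- small_config(horizon = 6, report_times = c(3, 6))
  a <- run_healing(cfg)
  b <- run_healing(cfg)
  expect_identical(a$report, b$report)
  expect_identical(a$traces, b$traces)
  expect_identical(a$state, b$state)
})

test_that("forced intramembranous ossification fills the healing region", {
  # wide low-strain window, no gating: the whole domain converts to bone
  rules <- rule_parameters(resting_strain = 1e-9, gamma_low = 0.999,
                           eps_low = 0.999, gamma_eo = 0.9999,
                           gamma_mid = 0.99999, eps_mid = 0.999,
                           gamma_max = 1 - 1e-6, eps_max = 1 - 1e-6,
                           r_io = 0.3, appositional = FALSE,
                           ossification_requires_vascularity = FALSE)
  cfg <- small_config(ka = 1e6, ks = 1e6, horizon = 28,
                      report_times = 28, rules = rules)
  tc <- run_healing(cfg)
  h <- tc$mesh$region == "HEALING"
  expect_gt(min(tc$state$c_bone[h]), 0.99)
  expect_true(tc$report$bridged)
  expect_equal(tc$report$v_bo, 100)
})

test_that("bone volume is non-decreasing when nothing is destroyed", {
  tc <- run_healing(small_config(ka = 5000, ks = 500, horizon = 42,
                                 report_times = c(21, 42)))
  expect_true(all(diff(tc$traces$bone_vol) >= -1e-9))
})

test_that("bridging detection matches a graph-connectivity oracle", {
  skip_if_not_installed("igraph")
  mesh <- small_mesh()
  nel <- nrow(mesh$elems)
  oracle <- function(state, thr) {
    allowed <- mesh$region == "CORTEX" |
      (mesh$region == "HEALING" & state$c_bone >= thr)
    nb <- mesh$neighbors
    edges <- c()
    for (e in which(allowed)) for (n in nb[e, ]) {
      if (n > 0 && n > e && allowed[n]) edges <- c(edges, e, n)
    }
    g <- igraph::make_empty_graph(n = nel, directed = FALSE)
    g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    zc <- mesh$centroids[, 3]
    dist_c <- which(mesh$region == "CORTEX" & zc < 0)
    prox_c <- which(mesh$region == "CORTEX" & zc > 0)
    any(comp[dist_c] %in% comp[prox_c])
  }
  state <- initial_tissue_state(mesh)
  expect_false(detect_bridging(state, mesh))
  expect_identical(detect_bridging(state, mesh), oracle(state, 0.5))
  # fully ossified healing region bridges
  state$c_bone[mesh$region == "HEALING"] <- 1
  expect_true(detect_bridging(state, mesh))
  # randomized fields agree with the oracle
  set.seed(11)
  for (i in 1:12) {
    s <- initial_tissue_state(mesh)
    s$c_bone[mesh$region == "HEALING"] <-
      rbinom(sum(mesh$region == "HEALING"), 1, 0.25)
    expect_identical(detect_bridging(s, mesh), oracle(s, 0.5))
  }
  # a single one-element-wide ossified periosteal arc bridges
  s <- initial_tissue_state(mesh)
  grid <- mesh$grid
  ring <- which(mesh$region == "HEALING" & grid$it == 1)
  arc_r <- min(grid$ir[ring][mesh$extracortical[ring]])
  arc <- ring[grid$ir[ring] == arc_r | !mesh$extracortical[ring]]
  # keep only the extracortical arc plus nothing intercortical
  arc <- ring[grid$ir[ring] == arc_r]
  s$c_bone[arc] <- 1
  expect_identical(detect_bridging(s, mesh), oracle(s, 0.5))
  expect_true(detect_bridging(s, mesh))
})
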