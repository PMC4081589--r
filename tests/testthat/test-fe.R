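test_that("uniform-strain patch fields are reproduced exactly", {
  bm <- box_model(2, 2, 2, 2, 2, 2, centered = FALSE)
  A <- matrix(c(0.01, 0, 0.003, 0, -0.002, 0.001,
                0.003, 0.001, -0.004), 3, 3, byrow = TRUE)
  u <- bm$mesh$nodes %*% t((A + t(A)) / 2)
  st <- element_strains(as.numeric(t(u)), bm$model)
  expect_equal(st$exx, rep(0.01, nrow(st)), tolerance = 1e-12)
  expect_equal(st$ezz, rep(-0.004, nrow(st)), tolerance = 1e-12)
  expect_equal(st$gxz, rep(2 * 0.003, nrow(st)), tolerance = 1e-12)
})

test_that("rigid-body motion produces zero strain invariants", {
  bm <- box_model(2, 2, 2, 2, 2, 2)
  n <- bm$mesh$nodes
  u_rb <- cbind(1 - 0.2 * n[, 2], 0.5 + 0.2 * n[, 1], -0.3)
  st <- element_strains(as.numeric(t(u_rb)), bm$model)
  expect_equal(max(abs(st$gamma)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$eps_vol)), 0, tolerance = 1e-12)
})

test_that("strain invariants match hand formulas", {
  bm <- box_model(2, 2, 2, 2, 2, 2)
  n <- bm$mesh$nodes
  nu <- 0.3; eps <- 0.01
  # uniaxial z strain with lateral contraction
  u <- cbind(-nu * eps * n[, 1], -nu * eps * n[, 2], eps * n[, 3])
  st <- element_strains(as.numeric(t(u)), bm$model)
  expect_equal(st$eps_vol, rep(eps * (1 - 2 * nu), nrow(st)),
               tolerance = 1e-10)
  expect_equal(st$gamma, rep(2 * sqrt(2) / 3 * eps * (1 + nu), nrow(st)),
               tolerance = 1e-10)
  # hydrostatic compression: deviator vanishes
  uh <- -0.01 * n
  sth <- element_strains(as.numeric(t(uh)), bm$model)
  expect_equal(max(sth$gamma), 0, tolerance = 1e-12)
  expect_true(all(sth$eps_vol < 0))
})

test_that("intact tube cantilever matches the Euler-Bernoulli closed form", {
  # slender configuration (L/D ~ 10) where the closed form is valid
  geom <- osteotomy_geometry(fragment_length = 100)
  mesh <- generate_mesh(geom)
  model <- fe_model(mesh)
  k <- intact_bending_reference(model)
  EI <- 15750 * pi / 64 * (20^4 - 13^4)
  expect_equal(k, EI, tolerance = 0.05)
})

test_that("assembly validates materials and reports the element", {
  mesh <- small_mesh()
  model <- fe_model(mesh)
  E <- rep(1000, model$nel)
  bad <- which(mesh$region == "HEALING")[1]
  E[bad] <- NA
  expect_error(assemble_system(model, E, 0.3), as.character(bad))
  E[bad] <- 0
  expect_error(assemble_system(model, E, 0.3), "non-positive")
})

test_that("loads, springs and solutions behave physically", {
  mesh <- small_mesh()
  model <- fe_model(mesh)
  E <- numeric(model$nel); nu <- rep(0.33, model$nel)
  E[mesh$region == "CORTEX"] <- 15750
  nu[mesh$region == "CORTEX"] <- 0.325
  E[mesh$region == "HEALING"] <- 0.1
  sys <- assemble_system(model, E, nu)
  expect_error(apply_boundary_and_loads(sys, list(k_axial = 0, k_shear = 1),
                                        load_case()), "positive")

  # zero loads -> zero displacements
  s0 <- apply_boundary_and_loads(sys, fixation_config(1000, 400),
                                 load_case(0, 0))
  expect_equal(max(abs(solve_system(s0)$u_full)), 0, tolerance = 1e-12)

  # rigid fixation limit -> vanishing IFM
  sr <- apply_boundary_and_loads(sys, fixation_config(1e9, 1e9),
                                 load_case())
  ifm <- interfragmentary_movement(solve_system(sr), model)
  expect_lt(abs(ifm[["axial"]]), 1e-4)
  expect_lt(abs(ifm[["shear"]]), 1e-4)

  # axial-only load: shear IFM vanishes by mirror symmetry
  sa <- apply_boundary_and_loads(sys, fixation_config(1000, 400),
                                 load_case(F_axial = 840, F_shear = 0))
  ifa <- interfragmentary_movement(solve_system(sa), model)
  expect_lt(abs(ifa[["shear"]]), 1e-8 + 1e-4 * abs(ifa[["axial"]]))
  expect_gt(ifa[["axial"]], 0)  # compression closes the gap

  # linearity: doubling loads doubles displacements
  s1 <- apply_boundary_and_loads(sys, fixation_config(1000, 400),
                                 load_case(840, 200))
  s2 <- apply_boundary_and_loads(sys, fixation_config(1000, 400),
                                 load_case(1680, 400))
  u1 <- solve_system(s1)$u_full
  u2 <- solve_system(s2)$u_full
  expect_equal(u2, 2 * u1, tolerance = 1e-9)
})

test_that("axial IFM tracks the two-spring oracle for soft callus", {
  mesh <- small_mesh()
  model <- fe_model(mesh)
  geom <- mesh$geom
  E <- numeric(model$nel); nu <- rep(0.33, model$nel)
  E[mesh$region == "CORTEX"] <- 15750
  E[mesh$region == "HEALING"] <- 0.1
  k_callus <- 0.1 * geom$cortical_area / geom$gap_size
  sys <- assemble_system(model, E, nu)
  for (k in c(100, 1000, 10000)) {
    s <- apply_boundary_and_loads(sys, fixation_config(k, k), load_case())
    ifm <- interfragmentary_movement(solve_system(s), model)
    expect_equal(ifm[["axial"]], 840 / (k + k_callus), tolerance = 0.10)
  }
})

test_that("bending stiffness is monotone in callus stiffness and self-normalizes", {
  mesh <- small_mesh()
  model <- fe_model(mesh)
  mats <- material_table()
  k_int <- intact_bending_reference(model, mats)
  bt_self <- bending_stiffness(
    model,
    E = ifelse(mesh$region == "CORTEX" | mesh$intercortical,
               mats$E[mats$tissue == "cortical"], 0),
    nu = mats$nu[mats$tissue == "cortical"], k_intact = k_int)
  expect_equal(bt_self$k_bend_rel, 100, tolerance = 1e-9)

  E_woven <- numeric(model$nel); nu <- rep(0.33, model$nel)
  E_woven[mesh$region == "CORTEX"] <- 15750
  E_woven[mesh$region == "HEALING"] <- 538
  E_conn <- E_woven
  E_conn[mesh$region == "HEALING"] <- 1.4
  k_woven <- bending_stiffness(model, E_woven, nu)$k_bend
  k_conn <- bending_stiffness(model, E_conn, nu)$k_bend
  expect_gt(k_woven, k_conn)
  expect_gt(k_conn, 0)   # unbridged soft construct: small but positive
})
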