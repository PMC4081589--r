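#' Healing simulation configuration
#'
#' Bundles all inputs of one healing simulation: geometry, fixation
#' stiffness, loads, materials, rule engine, maturation, time stepping and
#' mesh resolution.
#'
#' @param geometry An [osteotomy_geometry()].
#' @param fixation A [fixation_config()].
#' @param loads A [load_case()].
#' @param materials A [material_table()].
#' @param rules A [rule_parameters()].
#' @param maturation A [maturation_curve()].
#' @param horizon Simulated time, days (default 84 = 12 weeks; daily
#'   steps).
#' @param report_times Days at which the virtual bending test and outcome
#'   metrics are evaluated (default weeks 3, 6, 9, 12).  Must not exceed
#'   `horizon`.
#' @param resolution,n_theta Mesh controls passed to [generate_mesh()].
#' @param bend_every_step Run the virtual bending test every day instead of
#'   only at report times (slower; the per-step trace then carries
#'   `k_bend_rel`).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(geometry = osteotomy_geometry(),
                              fixation = fixation_config(1500, 400),
                              loads = load_case(),
                              materials = material_table(),
                              rules = rule_parameters(),
                              maturation = maturation_curve(),
                              horizon = 84,
                              report_times = c(21, 42, 63, 84),
                              resolution = NULL,
                              n_theta = 16,
                              bend_every_step = FALSE) {
  if (horizon < 0) stop("`horizon` must be >= 0 days.", call. = FALSE)
  if (length(report_times) && horizon < max(report_times)) {
    stop("`horizon` (", horizon, " d) is smaller than the last report time (",
         max(report_times), " d).", call. = FALSE)
  }
  if (is.unsorted(report_times, strictly = TRUE)) {
    stop("`report_times` must be strictly increasing.", call. = FALSE)
  }
  cfg <- list(geometry = geometry, fixation = fixation, loads = loads,
              materials = materials, rules = rules, maturation = maturation,
              horizon = horizon, report_times = report_times,
              resolution = resolution, n_theta = n_theta,
              bend_every_step = bend_every_step)
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Healing simulation: gap %g mm, k_fix (axial %g, shear %g) N/mm,\n",
    x$geometry$gap_size, x$fixation$k_axial, x$fixation$k_shear))
  cat(sprintf("  loads %g N axial + %g N shear, horizon %d d, reports at %s\n",
              x$loads$F_axial, x$loads$F_shear, x$horizon,
              paste(x$report_times, collapse = ", ")))
  invisible(x)
}

# Per-element materials for a tissue state (cortex fixed, healing mixed,
# void excluded).
state_materials <- function(state, mesh, materials, curve) {
  nel <- length(state$c_conn)
  E <- numeric(nel)
  nu <- rep(0.3, nel)
  cortex <- mesh$region == "CORTEX"
  cort <- materials[materials$tissue == "cortical", ]
  E[cortex] <- cort$E
  nu[cortex] <- cort$nu
  h <- which(mesh$region == "HEALING")
  mixed <- mix_materials(
    list(c_conn = state$c_conn[h], c_cart = state$c_cart[h],
         c_bone = state$c_bone[h]),
    table = materials, t_age = state$t_age[h], curve = curve)
  E[h] <- mixed$E
  nu[h] <- mixed$nu
  list(E = E, nu = nu)
}

# Cached-factorization solver for repeated solves on a fixed mesh with
# changing materials.  Reuses the supernodal Cholesky analysis across
# steps (the sparsity pattern is constant during a healing run).
heal_solver <- function(model) {
  env <- new.env(parent = emptyenv())
  env$chL <- NULL
  env$chB <- NULL
  m <- model$master_idx

  reduced <- function(E, nu) {
    lc <- lame_constants(E, nu)
    reduce_stiffness(model, lc$lambda, lc$mu)
  }

  solve_load <- function(K_red, fixation, loads) {
    sp <- Matrix::sparseMatrix(
      i = m[c("tx", "tz")], j = m[c("tx", "tz")],
      x = c(fixation$k_shear, fixation$k_axial),
      dims = dim(K_red), symmetric = TRUE)
    K <- K_red + sp
    if (is.null(env$keepL)) {
      env$keepL <- setdiff(which(Matrix::diag(K) > 0),
                           m[c("rx", "ry", "rz")])
      env$fL <- numeric(model$n_red)
      env$fL[m["tz"]] <- -loads$F_axial
      env$fL[m["tx"]] <- loads$F_shear
      env$fLk <- env$fL[env$keepL]
    }
    Kk <- K[env$keepL, env$keepL, drop = FALSE]
    if (is.null(env$chL)) {
      env$chL <- Matrix::Cholesky(Kk, LDL = FALSE, perm = TRUE,
                                  super = TRUE)
    } else {
      env$chL <- Matrix::update(env$chL, Kk)
    }
    uk <- as.numeric(Matrix::solve(env$chL, env$fLk, system = "A"))
    u_red <- numeric(model$n_red)
    u_red[env$keepL] <- uk
    u_full <- as.numeric(model$T %*% u_red)
    structure(list(u = matrix(u_full, ncol = 3, byrow = TRUE),
                   u_full = u_full, u_red = u_red,
                   master = u_red[model$master_idx]),
              class = "fe_solution")
  }

  solve_bend <- function(K_red, u_bend) {
    p <- m[["tx"]]
    if (is.null(env$keepB)) {
      env$keepB <- setdiff(which(Matrix::diag(K_red) > 0), p)
    }
    Kff <- K_red[env$keepB, env$keepB, drop = FALSE]
    kfp <- as.numeric(K_red[env$keepB, p])
    if (is.null(env$chB)) {
      env$chB <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE,
                                  super = TRUE)
    } else {
      env$chB <- Matrix::update(env$chB, Kff)
    }
    uf <- as.numeric(Matrix::solve(env$chB, -kfp * u_bend, system = "A"))
    F_bend <- sum(kfp * uf) + as.numeric(K_red[p, p]) * u_bend
    F_bend * model$L^3 / (3 * u_bend)
  }

  list(reduced = reduced, solve_load = solve_load, solve_bend = solve_bend)
}

#' Run the iterative healing simulation
#'
#' Daily loop: (1) mix per-element materials from the current tissue state,
#' (2) solve the fixed-and-loaded linear-elastic model, (3) clamp and
#' classify the centroid strain stimuli, (4) advance vascularity, then
#' tissue composition, (5) at report times run the virtual cantilever
#' bending test and the callus metrics.  Everything is deterministic:
#' identical configurations yield identical timecourses.
#'
#' @param config A [simulation_config()].
#' @param mesh Optional pre-built mesh (else generated from the config).
#' @param progress Print a one-line per-step record (day, max stimulus,
#'   bone volume, IFM).
#' @return A `healing_timecourse`: list with `report` (one row per report
#'   time: IFM, absolute and relative bending stiffness, extracortical
#'   callus volume `v_bo`, callus index `ci`, `bridged`), `traces` (per-day
#'   IFM, peak stimulus, tissue volumes), `state` (final tissue state),
#'   `mesh`, `config` and the intact reference rigidity `k_intact`
#'   (N mm^2).
#' @export
run_healing <- function(config, mesh = NULL, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(mesh)) {
    mesh <- generate_mesh(config$geometry, resolution = config$resolution,
                          n_theta = config$n_theta)
  }
  model <- fe_model(mesh)
  rules <- config$rules
  curve <- config$maturation
  mats <- config$materials
  state <- initial_tissue_state(mesh)
  solver <- heal_solver(model)
  k_intact <- intact_bending_reference(model, mats)
  healing <- mesh$region == "HEALING"

  report_rows <- list()
  trace_rows <- list()
  report_metrics <- function(day, K_red, ifm) {
    kb <- solver$solve_bend(K_red, 0.1)
    data.frame(
      day = day, week = day / 7,
      ifm_axial = ifm[["axial"]], ifm_shear = ifm[["shear"]],
      k_bend = kb, k_bend_rel = 100 * kb / k_intact,
      v_bo = callus_volume_fraction(state, mesh, rules$bone_threshold),
      ci = callus_index(state, mesh, rules$bone_threshold),
      bridged = detect_bridging(state, mesh, rules$bone_threshold))
  }

  if (config$horizon == 0) {
    sm <- state_materials(state, mesh, mats, curve)
    K_red <- solver$reduced(sm$E, sm$nu)
    sol <- solver$solve_load(K_red, config$fixation, config$loads)
    ifm <- interfragmentary_movement(sol, model)
    rep0 <- report_metrics(0, K_red, ifm)
    return(structure(list(report = rep0,
                          traces = rep0[0, ], state = state, mesh = mesh,
                          config = config, k_intact = k_intact),
                     class = "healing_timecourse"))
  }

  for (day in seq_len(config$horizon)) {
    sm <- state_materials(state, mesh, mats, curve)
    K_red <- solver$reduced(sm$E, sm$nu)
    sol <- solver$solve_load(K_red, config$fixation, config$loads)
    ifm <- interfragmentary_movement(sol, model)
    st <- element_strains(sol, model)

    signal <- rep("NONE", model$nel)
    uncommitted <- mesh$extracortical &
      (state$c_cart + state$c_bone) < rules$commit_fraction
    signal[healing] <- classify_stimulus(
      st$gamma[healing], st$eps_vol[healing], rules,
      periosteal = uncommitted[healing])
    destroyed <- healing & signal == "DESTRUCTION"
    state <- update_vascularity(state, mesh, rules,
                                destruction = destroyed)
    state <- update_composition(state, signal, mesh, rules)

    trace_rows[[day]] <- data.frame(
      day = day,
      ifm_axial = ifm[["axial"]], ifm_shear = ifm[["shear"]],
      max_gamma = max(st$gamma[healing]),
      bone_vol = sum(state$c_bone[healing] * mesh$volumes[healing]),
      cart_vol = sum(state$c_cart[healing] * mesh$volumes[healing]),
      mean_vascularity = mean(state$v[healing]),
      k_bend_rel = NA_real_)
    if (config$bend_every_step) {
      sm2 <- state_materials(state, mesh, mats, curve)
      trace_rows[[day]]$k_bend_rel <-
        100 * solver$solve_bend(solver$reduced(sm2$E, sm2$nu), 0.1) /
        k_intact
    }
    if (day %in% config$report_times) {
      sm2 <- state_materials(state, mesh, mats, curve)
      K2 <- solver$reduced(sm2$E, sm2$nu)
      report_rows[[length(report_rows) + 1L]] <-
        report_metrics(day, K2, ifm)
    }
    if (progress) {
      cat(sprintf(
        "day %3d: max gamma %.3f, bone vol %.0f mm^3, IFM (%.3f, %.3f) mm\n",
        day, max(st$gamma[healing]),
        sum(state$c_bone[healing] * mesh$volumes[healing]),
        ifm[["axial"]], ifm[["shear"]]))
    }
  }

  structure(list(report = do.call(rbind, report_rows),
                 traces = do.call(rbind, trace_rows),
                 state = state, mesh = mesh, config = config,
                 k_intact = k_intact),
            class = "healing_timecourse")
}

#' @export
print.healing_timecourse <- function(x, ...) {
  cat("Healing timecourse\n")
  cfg <- x$config
  cat(sprintf("  gap %g mm, k_fix (%g, %g) N/mm, %d days\n",
              cfg$geometry$gap_size, cfg$fixation$k_axial,
              cfg$fixation$k_shear, cfg$horizon))
  if (!is.null(x$report) && nrow(x$report)) {
    print(transform(x$report,
                    k_bend = signif(k_bend, 4),
                    k_bend_rel = round(k_bend_rel, 1),
                    v_bo = round(v_bo, 1), ci = round(ci, 2),
                    ifm_axial = signif(ifm_axial, 3),
                    ifm_shear = signif(ifm_shear, 3)),
          row.names = FALSE)
  }
  invisible(x)
}
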