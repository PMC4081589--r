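#' Precompute the finite-element operator for a healing mesh
#'
#' Builds everything about the linear-elastic problem that does not depend
#' on the (evolving) material distribution: per-element stiffness
#' decompositions, global triplet indices, centroid strain-displacement
#' operators, the rigid end-plate constraint at the proximal end and the
#' clamped distal end.
#'
#' The isotropic element stiffness separates as
#' `Ke = lambda * KeL + mu * KeM` (Lame constants), so reassembly under new
#' tissue moduli is a vectorized triplet update.  The proximal end plate is
#' a rigid multi-point constraint with six master degrees of freedom (three
#' translations, three rotations); the distal end is fully clamped.
#'
#' @param mesh A [generate_mesh()] mesh (or any list with `nodes`, `elems`,
#'   `node_sets`).
#' @return An object of class `fe_model` used by [assemble_system()],
#'   [element_strains()], [interfragmentary_movement()] and
#'   [bending_stiffness()].
#' @export
fe_model <- function(mesh) {
  nodes <- mesh$nodes; elems <- mesh$elems
  nel <- nrow(elems); nn <- nrow(nodes); nfull <- 3L * nn

  dN_gp <- lapply(seq_len(8), function(g) {
    hex8_dN(hex8_gauss[g, 1], hex8_gauss[g, 2], hex8_gauss[g, 3])
  })
  dN0 <- hex8_dN(0, 0, 0)
  m6 <- c(1, 1, 1, 0, 0, 0)
  dmu_sqrt <- sqrt(c(2, 2, 2, 1, 1, 1))

  VL <- matrix(0, 576, nel)
  VM <- matrix(0, 576, nel)
  B0 <- matrix(0, nel, 144)            # centroid B, row-major per element
  vol <- numeric(nel)
  B_of <- function(dNdx) {
    B <- matrix(0, 6, 24)
    ix <- 3 * (seq_len(8) - 1)
    B[1, ix + 1] <- dNdx[, 1]
    B[2, ix + 2] <- dNdx[, 2]
    B[3, ix + 3] <- dNdx[, 3]
    B[4, ix + 1] <- dNdx[, 2]; B[4, ix + 2] <- dNdx[, 1]
    B[5, ix + 2] <- dNdx[, 3]; B[5, ix + 3] <- dNdx[, 2]
    B[6, ix + 1] <- dNdx[, 3]; B[6, ix + 3] <- dNdx[, 1]
    B
  }
  for (e in seq_len(nel)) {
    xe <- nodes[elems[e, ], , drop = FALSE]
    KeL <- matrix(0, 24, 24); KeM <- matrix(0, 24, 24)
    ve <- 0
    for (g in seq_len(8)) {
      J <- crossprod(dN_gp[[g]], xe)   # J[i, j] = dx_j / dxi_i
      dJ <- det(J)
      dNdx <- dN_gp[[g]] %*% solve(t(J))
      B <- B_of(dNdx)
      bm <- drop(crossprod(B, m6))
      KeL <- KeL + tcrossprod(bm) * dJ
      KeM <- KeM + crossprod(B * dmu_sqrt) * dJ
      ve <- ve + dJ
    }
    VL[, e] <- KeL
    VM[, e] <- KeM
    vol[e] <- ve
    J0 <- crossprod(dN0, xe)
    B0[e, ] <- as.vector(B_of(dN0 %*% solve(t(J0))))
  }

  gdof <- cbind(3L * elems[, 1] - 2L)  # placeholder; build full 24-col
  gdof <- matrix(0L, nel, 24)
  for (a in seq_len(8)) {
    gdof[, 3 * a - 2] <- 3L * elems[, a] - 2L
    gdof[, 3 * a - 1] <- 3L * elems[, a] - 1L
    gdof[, 3 * a]     <- 3L * elems[, a]
  }
  ridx <- rep(seq_len(24), times = 24)
  cidx <- rep(seq_len(24), each = 24)
  II <- t(gdof[, ridx, drop = FALSE])  # 576 x nel
  JJ <- t(gdof[, cidx, drop = FALSE])
  ii <- as.integer(II); jj <- as.integer(JJ)
  ee <- rep(seq_len(nel), each = 576L)

  ## constraints: distal clamp + proximal rigid plate with 6 master dofs
  ns <- mesh$node_sets
  fixed_nodes <- ns$DISTAL_END
  slave_nodes <- ns$PROXIMAL_END
  fixed_dofs <- as.integer(outer(c(-2L, -1L, 0L), 3L * fixed_nodes, `+`))
  slave_dofs <- as.integer(outer(c(-2L, -1L, 0L), 3L * slave_nodes, `+`))
  master_pos <- c(0, 0, max(nodes[, 3]))
  normal_dofs <- setdiff(seq_len(nfull), c(fixed_dofs, slave_dofs))
  n_red <- length(normal_dofs) + 6L
  red_of <- integer(nfull)
  red_of[normal_dofs] <- seq_along(normal_dofs)
  master_idx <- length(normal_dofs) + 1:6
  names(master_idx) <- c("tx", "ty", "tz", "rx", "ry", "rz")

  ti <- normal_dofs; tj <- red_of[normal_dofs]; tx <- rep(1, length(ti))
  for (n in slave_nodes) {
    dx <- nodes[n, 1] - master_pos[1]
    dy <- nodes[n, 2] - master_pos[2]
    dz <- nodes[n, 3] - master_pos[3]
    d <- 3L * n
    ti <- c(ti, d - 2L, d - 2L, d - 2L, d - 1L, d - 1L, d - 1L, d, d, d)
    tj <- c(tj, master_idx[c("tx", "ry", "rz", "ty", "rx", "rz",
                             "tz", "rx", "ry")])
    tx <- c(tx, 1, dz, -dy, 1, -dz, dx, 1, dy, -dx)
  }
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(nfull, n_red))

  model <- list(
    mesh = mesh, nel = nel, n_nodes = nn, nfull = nfull, n_red = n_red,
    VL = as.numeric(VL), VM = as.numeric(VM),
    ii = ii, jj = jj, ee = ee,
    B0 = B0, gdof = gdof, volumes = vol,
    T = T, master_idx = master_idx,
    fixed_dofs = fixed_dofs, slave_dofs = slave_dofs,
    master_pos = master_pos,
    L = max(nodes[, 3]) - min(nodes[, 3])
  )
  class(model) <- "fe_model"
  model
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("FE model: %d elements, %d nodes (%d dofs, %d reduced)\n",
              x$nel, x$n_nodes, x$nfull, x$n_red))
  invisible(x)
}

lame_constants <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu     = E / (2 * (1 + nu)))
}

#' Assemble the linear-elastic system for a material distribution
#'
#' @param model An [fe_model()].
#' @param E Per-element Young's modulus (MPa); use 0 for excluded (void)
#'   elements.  Every element with a region tag other than `VOID` must have
#'   `E > 0`.
#' @param nu Per-element Poisson's ratio.
#' @return An object of class `fe_system` carrying the reduced (constraint-
#'   eliminated) symmetric stiffness matrix.  Pass it to
#'   [apply_boundary_and_loads()] and [solve_system()].
#' @export
assemble_system <- function(model, E, nu) {
  stopifnot(inherits(model, "fe_model"))
  E <- rep_len(E, model$nel); nu <- rep_len(nu, model$nel)
  region <- model$mesh$region
  if (!is.null(region)) {
    bad <- which(region != "VOID" & (!is.finite(E) | E <= 0))
    if (length(bad)) {
      stop("missing/non-positive Young's modulus on non-void element(s): ",
           paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ...", call. = FALSE)
    }
  }
  E[!is.finite(E) | E < 0] <- 0
  lc <- lame_constants(E, nu)
  K_red <- reduce_stiffness(model, lc$lambda, lc$mu)
  structure(list(model = model, K_red = K_red, E = E, nu = nu,
                 springs = NULL, f_red = NULL),
            class = "fe_system")
}

# lambda/mu per element -> reduced symmetric stiffness
reduce_stiffness <- function(model, lambda, mu) {
  x <- lambda[model$ee] * model$VL + mu[model$ee] * model$VM
  K <- Matrix::sparseMatrix(i = model$ii, j = model$jj, x = x,
                            dims = c(model$nfull, model$nfull))
  Matrix::forceSymmetric(Matrix::crossprod(model$T, K %*% model$T))
}

#' Attach fixation springs and physiological loads
#'
#' The distal end is clamped; the proximal rigid end plate is loaded by the
#' axial compressive force (along -z) and the translational shear force
#' (along +x), and is connected to ground by two uncoupled springs: the
#' axial fixation stiffness acting along z and the shear fixation stiffness
#' along x.  End-plate rotations are locked (the device is idealized as
#' rigid in bending and torsion; its compliance is fully described by the
#' two translational stiffness values).
#'
#' @param system An [assemble_system()] result.
#' @param fixation A [fixation_config()].
#' @param loads A [load_case()].
#' @return The constrained `fe_system`, ready for [solve_system()].
#' @export
apply_boundary_and_loads <- function(system, fixation, loads) {
  stopifnot(inherits(system, "fe_system"))
  if (fixation$k_axial <= 0 || fixation$k_shear <= 0) {
    stop("fixation spring stiffness must be positive.", call. = FALSE)
  }
  m <- system$model$master_idx
  f <- numeric(system$model$n_red)
  f[m["tz"]] <- -loads$F_axial
  f[m["tx"]] <- loads$F_shear
  system$f_red <- f
  system$springs <- c(tx = fixation$k_shear, tz = fixation$k_axial)
  system$locked_master <- m[c("rx", "ry", "rz")]
  system
}

#' Solve a constrained finite-element system
#'
#' Sparse Cholesky solve of the reduced system; degrees of freedom without
#' stiffness (nodes only attached to void/excluded elements) are dropped.
#' The relative residual is checked against `1e-8`.
#'
#' @param system An `fe_system` from [apply_boundary_and_loads()] (or from
#'   [assemble_system()] with a manually supplied `f_red`).
#' @return An `fe_solution`: list with the full nodal displacement matrix
#'   `u` (n_nodes x 3, mm), the reduced solution `u_red`, and the master
#'   end-plate displacement `master`.
#' @export
solve_system <- function(system) {
  stopifnot(inherits(system, "fe_system"))
  model <- system$model
  K <- system$K_red
  if (!is.null(system$springs)) {
    m <- model$master_idx
    sp <- Matrix::sparseMatrix(
      i = m[c("tx", "tz")], j = m[c("tx", "tz")],
      x = as.numeric(system$springs[c("tx", "tz")]),
      dims = dim(K), symmetric = TRUE)
    K <- K + sp
  }
  f <- system$f_red
  if (is.null(f)) stop("no loads applied; call apply_boundary_and_loads().",
                       call. = FALSE)
  keep <- which(Matrix::diag(K) > 0)
  keep <- setdiff(keep, system$locked_master)
  Kk <- K[keep, keep, drop = FALSE]
  fk <- f[keep]
  u_red <- numeric(model$n_red)
  ch <- tryCatch(Matrix::Cholesky(Kk, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop("singular stiffness system (floating fragment or ",
                        "zero-stiffness connection): ", conditionMessage(e),
                        call. = FALSE)
                 })
  uk <- as.numeric(Matrix::solve(ch, fk, system = "A"))
  res <- norm(Kk %*% uk - fk, "2") / max(norm(fk, "2"), 1e-300)
  if (is.finite(res) && res > 1e-8 && norm(fk, "2") > 0) {
    stop(sprintf("solver residual %.3e exceeds tolerance 1e-8", res),
         call. = FALSE)
  }
  u_red[keep] <- uk
  u_full <- as.numeric(model$T %*% u_red)
  structure(list(
    u = matrix(u_full, ncol = 3, byrow = TRUE),
    u_full = u_full, u_red = u_red,
    master = u_red[model$master_idx]
  ), class = "fe_solution")
}

#' Per-element strain invariants at element centroids
#'
#' Evaluates the small-strain tensor at each element centroid and returns
#' the two mechanoregulatory stimuli: the octahedral shear (distortional)
#' strain and the dilatational strain (trace; negative in compression).
#'
#' @param solution An [solve_system()] result (or a full displacement
#'   vector).
#' @param model The [fe_model()].
#' @return A data.frame with columns `gamma` (octahedral shear strain,
#'   >= 0), `eps_vol` (dilatational strain, signed) and the six engineering
#'   strain components.
#' @export
element_strains <- function(solution, model) {
  u_full <- if (inherits(solution, "fe_solution")) solution$u_full
            else as.numeric(solution)
  Ue <- matrix(u_full[t(model$gdof)], nrow = model$nel, byrow = TRUE)
  eps <- matrix(0, model$nel, 6)
  for (cc in seq_len(6)) {
    Bc <- model$B0[, seq(cc, 144, by = 6), drop = FALSE]
    eps[, cc] <- rowSums(Bc * Ue)
  }
  eps_vol <- eps[, 1] + eps[, 2] + eps[, 3]
  em <- eps_vol / 3
  # deviatoric tensor invariant; engineering shear -> tensor shear = /2
  tr_e2 <- (eps[, 1] - em)^2 + (eps[, 2] - em)^2 + (eps[, 3] - em)^2 +
    2 * ((eps[, 4] / 2)^2 + (eps[, 5] / 2)^2 + (eps[, 6] / 2)^2)
  gamma <- (2 / 3) * sqrt(3 * tr_e2)
  out <- data.frame(gamma = gamma, eps_vol = eps_vol,
                    exx = eps[, 1], eyy = eps[, 2], ezz = eps[, 3],
                    gxy = eps[, 4], gyz = eps[, 5], gxz = eps[, 6])
  out
}

#' Interfragmentary movement from a displacement field
#'
#' Relative displacement between the centroids of the two opposing cortical
#' fracture faces, decomposed along the bone axis (axial; positive = gap
#' closing) and the shear-load direction (x).
#'
#' @param solution An [solve_system()] result.
#' @param model The [fe_model()].
#' @return Named numeric vector `c(axial = , shear = )` in mm.
#' @export
interfragmentary_movement <- function(solution, model) {
  u <- solution$u
  ns <- model$mesh$node_sets
  up <- colMeans(u[ns$FRACTURE_FACE_PROX, , drop = FALSE])
  ud <- colMeans(u[ns$FRACTURE_FACE_DIST, , drop = FALSE])
  c(axial = -(up[3] - ud[3]), shear = up[1] - ud[1])
}

#' Virtual cantilever bending test
#'
#' Clamps the distal end, imposes a small transverse displacement `u_bend`
#' (x direction) on the proximal rigid end plate with free end-plate
#' rotations, recovers the reaction force and reports the flexural rigidity
#' `k_bend = F_bend * L^3 / (3 * u_bend)` (the tip-loaded cantilever
#' identity), with `L` the overall model length.  Fixation springs are
#' detached for the test.  If `k_intact` is supplied the result also
#' carries the stiffness as a percentage of that intact-bone reference.
#'
#' @param model An [fe_model()].
#' @param E,nu Per-element material properties (vectors of length
#'   `model$nel`; `E = 0` excludes an element).
#' @param u_bend Applied tip displacement, mm (default 0.1).
#' @param k_intact Optional intact-bone flexural rigidity (N mm^2) from
#'   [intact_bending_reference()].
#' @return List with `k_bend` (N mm^2), `F_bend` (N), `u_bend`, `L`, and
#'   `k_bend_rel` (percent of intact; `NA` if no reference given).
#' @export
bending_stiffness <- function(model, E, nu, u_bend = 0.1, k_intact = NULL) {
  stopifnot(u_bend > 0)
  E <- rep_len(E, model$nel); nu <- rep_len(nu, model$nel)
  E[!is.finite(E) | E < 0] <- 0
  lc <- lame_constants(E, nu)
  K <- reduce_stiffness(model, lc$lambda, lc$mu)
  m <- model$master_idx
  keep <- which(Matrix::diag(K) > 0)
  p <- m[["tx"]]
  fidx <- setdiff(keep, p)
  Kff <- K[fidx, fidx, drop = FALSE]
  Kfp <- K[fidx, p, drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop("bending test: singular system: ",
                        conditionMessage(e), call. = FALSE)
                 })
  uf <- as.numeric(Matrix::solve(ch, -as.numeric(Kfp) * u_bend,
                                 system = "A"))
  F_bend <- sum(as.numeric(Kfp) * uf) + as.numeric(K[p, p]) * u_bend
  k_bend <- F_bend * model$L^3 / (3 * u_bend)
  list(k_bend = k_bend, F_bend = F_bend, u_bend = u_bend, L = model$L,
       k_bend_rel = if (is.null(k_intact)) NA_real_ else
         100 * k_bend / k_intact)
}

#' Intact-bone bending reference
#'
#' Runs the same virtual cantilever protocol on the no-osteotomy model:
#' the cortical fragments plus the gap column restored to cortical bone,
#' with the extracortical healing domain and endosteal void excluded.  The
#' healed construct's bending stiffness is reported relative to this
#' computed reference (same mesh, same protocol), which cancels
#' discretization bias in the ratio.
#'
#' @param model An [fe_model()] built on a [generate_mesh()] mesh.
#' @param materials A [material_table()].
#' @param u_bend Applied tip displacement, mm.
#' @return Intact flexural rigidity `k_bend` in N mm^2.
#' @export
intact_bending_reference <- function(model, materials = material_table(),
                                     u_bend = 0.1) {
  mesh <- model$mesh
  cort <- materials[materials$tissue == "cortical", ]
  E <- numeric(model$nel)
  nu <- rep(cort$nu, model$nel)
  solid <- mesh$region == "CORTEX" | mesh$intercortical
  E[solid] <- cort$E
  bending_stiffness(model, E, nu, u_bend = u_bend)$k_bend
}

#' Fixation stiffness configuration
#'
#' @param k_axial Axial fixation stiffness, N/mm (> 0).
#' @param k_shear Translational shear fixation stiffness, N/mm (> 0).
#' @return A `fixation_config` object.
#' @export
fixation_config <- function(k_axial, k_shear) {
  if (!is.numeric(k_axial) || k_axial <= 0 || !is.numeric(k_shear) ||
      k_shear <= 0) {
    stop("fixation stiffness values must be positive (N/mm).", call. = FALSE)
  }
  structure(list(k_axial = k_axial, k_shear = k_shear),
            class = "fixation_config")
}

#' Physiological load case
#'
#' Averaged superimposed physiological loading of the ovine tibia during
#' gait: axial compression plus translational shear, applied at the
#' proximal end plate.
#'
#' @param F_axial Axial compressive force, N (default 840).
#' @param F_shear Translational shear force, N (default 200).
#' @param bodyweight_kg Metadata: animal bodyweight the loads correspond to
#'   (default 63).
#' @return A `load_case` object.
#' @export
load_case <- function(F_axial = 840, F_shear = 200, bodyweight_kg = 63) {
  if (F_axial < 0 || F_shear < 0) {
    stop("loads must be non-negative.", call. = FALSE)
  }
  structure(list(F_axial = F_axial, F_shear = F_shear,
                 bodyweight_kg = bodyweight_kg), class = "load_case")
}
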