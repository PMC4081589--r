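# Shared fixtures: small meshes for unit tests, memoised full-scale
# healing runs shared between acceptance blocks.

small_geom <- function(gap = 3) {
  osteotomy_geometry(gap_size = gap, fragment_length = 30,
                     callus_radial_extent = 9, callus_axial_extent = 9)
}

small_mesh <- function(gap = 3, resolution = NULL) {
  generate_mesh(small_geom(gap), resolution = resolution, n_theta = 8)
}

small_config <- function(ka = 1500, ks = 400, gap = 3, horizon = 84,
                         report_times = c(21, 42, 63, 84), ...) {
  simulation_config(
    geometry = small_geom(gap),
    fixation = fixation_config(ka, ks),
    horizon = horizon,
    report_times = report_times[report_times <= horizon],
    n_theta = 8, ...)
}

# box mesh wrapped with the node sets fe_model() needs
box_model <- function(lx = 10, ly = 10, lz = 100, nx = 4, ny = 4,
                      nz = 40, centered = TRUE) {
  box <- callusmap:::hex_box_mesh(lx, ly, lz, nx, ny, nz)
  if (centered) {
    box$nodes[, 1] <- box$nodes[, 1] - lx / 2
    box$nodes[, 2] <- box$nodes[, 2] - ly / 2
  }
  mesh <- list(nodes = box$nodes, elems = box$elems,
               node_sets = list(
                 DISTAL_END = which(box$nodes[, 3] == 0),
                 PROXIMAL_END = which(box$nodes[, 3] == lz)))
  list(mesh = mesh, model = fe_model(mesh))
}

# memoised full-scale healing runs (defaults; shared across test blocks)
.heal_runs <- new.env(parent = emptyenv())
cached_run <- function(ka, ks, gap = 3) {
  key <- paste(ka, ks, gap, sep = "_")
  if (is.null(.heal_runs[[key]])) {
    cfg <- simulation_config(
      geometry = osteotomy_geometry(gap_size = gap),
      fixation = fixation_config(ka, ks))
    .heal_runs[[key]] <- run_healing(cfg)
  }
  .heal_runs[[key]]
}

report_at <- function(tc, day) tc$report[tc$report$day == day, ]
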