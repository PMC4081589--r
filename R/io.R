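#' Write a simulation configuration to YAML
#'
#' Serializes every tunable of a [simulation_config()] (geometry, fixation,
#' loads, material table, rule parameters, maturation curve, time stepping,
#' mesh controls) into a YAML file that [read_config()] restores.
#'
#' @param config A [simulation_config()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "simulation_config"))
  x <- list(
    geometry = unclass(config$geometry)[c(
      "periosteal_diameter", "endosteal_diameter", "gap_size",
      "fragment_length", "callus_radial_extent", "callus_axial_extent")],
    fixation = unclass(config$fixation),
    loads = unclass(config$loads),
    materials = as.list(setNames(
      lapply(seq_len(nrow(config$materials)), function(i)
        c(config$materials$E[i], config$materials$nu[i])),
      config$materials$tissue)),
    rules = unclass(config$rules),
    maturation = unclass(config$maturation),
    horizon = config$horizon,
    report_times = config$report_times,
    resolution = config$resolution,
    n_theta = config$n_theta,
    bend_every_step = config$bend_every_step
  )
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a simulation configuration from YAML
#'
#' Counterpart of [write_config()].  Missing sections fall back to the
#' package defaults.
#'
#' @param file Path to a YAML configuration.
#' @return A [simulation_config()].
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  geom <- do.call(osteotomy_geometry, x$geometry %||% list())
  fix <- if (is.null(x$fixation)) fixation_config(1500, 400) else
    do.call(fixation_config, x$fixation)
  loads <- do.call(load_case, x$loads %||% list())
  mats <- if (is.null(x$materials)) material_table() else
    do.call(material_table, lapply(x$materials, as.numeric))
  rules <- do.call(rule_parameters, x$rules %||% list())
  mat <- do.call(maturation_curve, x$maturation %||% list())
  simulation_config(
    geometry = geom, fixation = fix, loads = loads, materials = mats,
    rules = rules, maturation = mat,
    horizon = x$horizon %||% 84,
    report_times = as.numeric(x$report_times %||% c(21, 42, 63, 84)),
    resolution = x$resolution,
    n_theta = x$n_theta %||% 16,
    bend_every_step = isTRUE(x$bend_every_step))
}

#' Export a healing timecourse
#'
#' Writes the report table and the per-step traces as CSV, a JSON summary,
#' and per-report-time VTK tissue fields.
#'
#' @param timecourse A [run_healing()] result.
#' @param dir Output directory (created if missing).
#' @param vtk Also write a VTK file of the final tissue field.
#' @return `dir`, invisibly.
#' @export
export_timecourse <- function(timecourse, dir, vtk = TRUE) {
  stopifnot(inherits(timecourse, "healing_timecourse"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(timecourse$report, file.path(dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(timecourse$traces, file.path(dir, "traces.csv"),
                   row.names = FALSE)
  last <- timecourse$report[nrow(timecourse$report), ]
  jsonlite::write_json(
    list(config = list(
      gap_size = timecourse$config$geometry$gap_size,
      k_axial = timecourse$config$fixation$k_axial,
      k_shear = timecourse$config$fixation$k_shear,
      horizon = timecourse$config$horizon),
      k_intact = timecourse$k_intact,
      final = as.list(last)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (vtk) {
    s <- timecourse$state
    write_vtk(timecourse$mesh, file.path(dir, "tissue_final.vtk"),
              cell_data = list(c_conn = s$c_conn, c_cart = s$c_cart,
                               c_bone = s$c_bone, vascularity = s$v))
  }
  invisible(dir)
}
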