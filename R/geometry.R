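#' Idealized mid-diaphyseal osteotomy geometry
#'
#' Parametric description of an idealized, transverse, mid-diaphyseal
#' osteotomy in a long-bone diaphysis (hollow cylinder) together with the
#' healing domain in which callus tissue may form.  All lengths are in mm;
#' the model uses a consistent N/mm/MPa unit system with the bone axis along
#' z, the shear-load direction along x, and the origin at the gap center.
#'
#' The healing domain consists of (i) the interfragmentary gap between the
#' two cortical fragment ends and (ii) a periosteal (extracortical) cuff of
#' radial thickness `callus_radial_extent` reaching `callus_axial_extent`
#' along each fragment.  The endosteal (intramedullary) canal is excluded
#' from healing, mirroring fractures stabilized by intramedullary devices.
#'
#' @param periosteal_diameter Outer (periosteal) cortex diameter in mm.
#' @param endosteal_diameter Inner (endosteal) cortex diameter in mm.
#' @param gap_size Osteotomy gap in mm.
#' @param fragment_length Length of each bone fragment along the axis in mm.
#' @param callus_radial_extent Maximal radial growth of the healing domain
#'   beyond the periosteal surface, mm.
#' @param callus_axial_extent Axial reach of the periosteal healing domain
#'   along each fragment, mm.
#'
#' @return An object of class `osteotomy_geometry`: a list with the input
#'   fields plus derived quantities `length` (overall model length
#'   `2 * fragment_length + gap_size`), `cortical_area` (cortical
#'   cross-section area, mm^2) and `cortical_inertia` (second moment of area
#'   of the hollow section, mm^4).
#'
#' The default fragment length (75 mm per fragment, model length 153 mm for
#' a 3 mm gap) approximates the mid-diaphyseal span of an adult ovine tibia;
#' it keeps end effects away from the gap and sets the lever arm of the
#' virtual bending test, to which the relative bending stiffness is mildly
#' sensitive.
#'
#' @examples
#' geom <- osteotomy_geometry(gap_size = 3)
#' geom$cortical_area    # pi/4 * (20^2 - 13^2)
#' geom$length           # 2 * 75 + 3
#' @export
osteotomy_geometry <- function(periosteal_diameter = 20,
                               endosteal_diameter = 13,
                               gap_size = 3,
                               fragment_length = 75,
                               callus_radial_extent = 15,
                               callus_axial_extent = 15) {
  check_positive <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", name, "` must be a single positive finite number, got ",
           deparse(substitute(x)), " = ", format(x), call. = FALSE)
    }
  }
  check_positive(periosteal_diameter, "periosteal_diameter")
  check_positive(endosteal_diameter, "endosteal_diameter")
  check_positive(gap_size, "gap_size")
  check_positive(fragment_length, "fragment_length")
  check_positive(callus_radial_extent, "callus_radial_extent")
  check_positive(callus_axial_extent, "callus_axial_extent")
  if (endosteal_diameter >= periosteal_diameter) {
    stop("`endosteal_diameter` (", endosteal_diameter,
         ") must be smaller than `periosteal_diameter` (",
         periosteal_diameter, "): the cortical wall would vanish.",
         call. = FALSE)
  }

  geom <- list(
    periosteal_diameter  = periosteal_diameter,
    endosteal_diameter   = endosteal_diameter,
    gap_size             = gap_size,
    fragment_length      = fragment_length,
    callus_radial_extent = callus_radial_extent,
    callus_axial_extent  = callus_axial_extent
  )
  geom$length <- 2 * fragment_length + gap_size
  geom$cortical_area <- pi / 4 * (periosteal_diameter^2 - endosteal_diameter^2)
  geom$cortical_inertia <- pi / 64 *
    (periosteal_diameter^4 - endosteal_diameter^4)
  class(geom) <- "osteotomy_geometry"
  geom
}

#' @export
print.osteotomy_geometry <- function(x, ...) {
  cat("Osteotomy geometry (mm):\n")
  cat(sprintf("  periosteal/endosteal diameter: %g / %g\n",
              x$periosteal_diameter, x$endosteal_diameter))
  cat(sprintf("  gap: %g, fragment length: %g (model length %g)\n",
              x$gap_size, x$fragment_length, x$length))
  cat(sprintf("  callus extent: %g radial, %g axial\n",
              x$callus_radial_extent, x$callus_axial_extent))
  cat(sprintf("  cortical area %.1f mm^2, I %.0f mm^4\n",
              x$cortical_area, x$cortical_inertia))
  invisible(x)
}

#' Analytic volume of the meshed model domain
#'
#' Closed-form volume of the domain that [generate_mesh()] discretizes:
#' cortical hollow cylinders of both fragments, the interfragmentary gap
#' annulus, the extracortical healing cuff, and the (void) endosteal gap
#' column between `void_inner_radius` and the endosteal radius.  Used as the
#' oracle for mesh volume conservation.
#'
#' @param geom An [osteotomy_geometry()].
#' @param void_inner_radius Inner radius of the meshed endosteal void
#'   annulus in the gap column, mm (default: half the endosteal radius,
#'   matching [generate_mesh()]).
#' @return Named list with components `cortex`, `gap_annulus`,
#'   `extracortical`, `void` and `total` (mm^3).
#' @export
analytic_model_volume <- function(geom, void_inner_radius = NULL) {
  rp <- geom$periosteal_diameter / 2
  re <- geom$endosteal_diameter / 2
  if (is.null(void_inner_radius)) void_inner_radius <- re / 2
  g  <- geom$gap_size
  lf <- geom$fragment_length
  rc <- rp + geom$callus_radial_extent
  za <- geom$callus_axial_extent
  cortex <- pi * (rp^2 - re^2) * 2 * lf
  gap_annulus <- pi * (rp^2 - re^2) * g
  extracortical <- pi * (rc^2 - rp^2) * (g + 2 * za)
  void <- pi * (re^2 - void_inner_radius^2) * g
  list(cortex = cortex, gap_annulus = gap_annulus,
       extracortical = extracortical, void = void,
       total = cortex + gap_annulus + extracortical + void)
}
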