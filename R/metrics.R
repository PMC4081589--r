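#' Extracortical bony callus volume fraction
#'
#' Percentage of the extracortical healing region (the periosteal cuff,
#' centroid radius beyond the periosteal surface) occupied by ossified
#' elements.  The interfragmentary gap column between the cortical ends is
#' excluded from both numerator and denominator, so purely intercortical
#' bridging scores near 0%.
#'
#' @param state A `tissue_state`.
#' @param mesh The mesh.
#' @param bone_threshold Bone fraction at which an element counts as bony
#'   callus (default 0.5).
#' @return Volume percentage in `[0, 100]`.
#' @export
callus_volume_fraction <- function(state, mesh, bone_threshold = 0.5) {
  ex <- mesh$extracortical
  denom <- sum(mesh$volumes[ex])
  if (denom <= 0) return(0)
  bony <- ex & state$c_bone >= bone_threshold
  100 * sum(mesh$volumes[bony]) / denom
}

#' Callus index
#'
#' Ratio of the maximal callus diameter to the periosteal (cortex)
#' diameter: `CI = diam_callus / diam_cortex`.  The callus diameter is
#' twice the largest radial centroid coordinate over all ossified elements
#' anywhere in the model; with no extracortical bone the callus diameter
#' equals the cortex diameter and `CI = 1`.
#'
#' @inheritParams callus_volume_fraction
#' @return CI >= 1 (dimensionless).
#' @export
callus_index <- function(state, mesh, bone_threshold = 0.5) {
  bony <- mesh$region == "HEALING" & state$c_bone >= bone_threshold
  diam_cortex <- mesh$geom$periosteal_diameter
  if (!any(bony)) return(1)
  diam_callus <- 2 * max(mesh$r_cent[bony])
  max(1, diam_callus / diam_cortex)
}

#' Detect bony bridging of the fracture gap
#'
#' Breadth-first search over the element face-adjacency graph restricted to
#' ossified elements (cortex, or healing elements with bone fraction at or
#' above `bone_threshold`): the gap is bridged when a face-connected bony
#' path links the distal and the proximal cortical fragment.  Exact
#' threshold ties count as ossified; an exactly-threshold path therefore
#' bridges, while any fraction below does not.
#'
#' @inheritParams callus_volume_fraction
#' @return `TRUE` if bridged.
#' @export
detect_bridging <- function(state, mesh, bone_threshold = 0.5) {
  cortex <- mesh$region == "CORTEX"
  allowed <- cortex | (mesh$region == "HEALING" &
                         state$c_bone >= bone_threshold)
  zc <- mesh$centroids[, 3]
  start <- which(cortex & zc < 0)
  target <- cortex & zc > 0
  if (!length(start) || !any(target)) return(FALSE)
  visited <- logical(length(allowed))
  visited[start] <- TRUE
  frontier <- start
  nb <- mesh$neighbors
  while (length(frontier)) {
    cand <- unique(as.integer(nb[frontier, ]))
    cand <- cand[cand > 0L]
    cand <- cand[allowed[cand] & !visited[cand]]
    if (!length(cand)) break
    visited[cand] <- TRUE
    if (any(target[cand])) return(TRUE)
    frontier <- cand
  }
  any(visited & target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
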