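#' Parameters of the tissue-differentiation rule engine
#'
#' Deterministic, crisp-threshold reconstruction of the fuzzy-logic
#' mechanoregulation controller: per-element distortional strain (octahedral
#' shear, `gamma`) and dilatational strain (`eps_vol`) select one of five
#' differentiation signals per day, following the strain/pressure windows of
#' the Claes-Heigele mechanoregulation hypothesis.  All thresholds and rates
#' are exposed for recalibration.
#'
#' Windows (checked in order, half-open, on clamped stimuli):
#' \enumerate{
#'   \item `DESTRUCTION` if `gamma > gamma_max` or `|eps_vol| > eps_max`;
#'   \item `NONE` (quiescent) if `gamma < resting_strain` and
#'     `|eps_vol| < resting_strain` — insufficient stimulation for
#'     periosteal callus formation.  This activation threshold applies to
#'     the extracortical (periosteal) healing domain only, and only while
#'     an element is uncommitted (cartilage + bone fraction below
#'     `commit_fraction`): callus formation must be mechanically initiated,
#'     but committed callus continues to differentiate as strains fall —
#'     endochondral ossification is precisely the low-strain completion of
#'     that program.  The interfragmentary gap is never gated: it ossifies
#'     even under near-zero strain, the primary/direct gap-healing mode of
#'     absolutely stable fixation, which produces intercortical bridging
#'     with minimal external callus;
#'   \item `INTRAMEMBRANOUS` if `gamma <= gamma_low` and
#'     `|eps_vol| <= eps_low` — direct bone apposition;
#'   \item `ENDOCHONDRAL` if `eps_vol < 0` (compression-dominated),
#'     `gamma <= gamma_eo` and `|eps_vol| <= eps_mid` — cartilage forms and
#'     ossifies at the vascularized bone front;
#'   \item `CHONDROGENESIS` if `eps_vol < 0`, `gamma <= gamma_mid` and
#'     `|eps_vol| <= eps_mid`;
#'   \item otherwise `NONE`.
#' }
#'
#' @param resting_strain Periosteal activation threshold (strain,
#'   absolute): below it no new callus is initiated in the extracortical
#'   domain.
#' @param commit_fraction Cartilage-plus-bone fraction above which a
#'   periosteal element counts as committed callus and is no longer
#'   subject to the activation threshold.
#' @param gamma_low,eps_low Upper window bounds for intramembranous
#'   ossification (strain).
#' @param gamma_eo Upper distortional bound of the endochondral route.
#' @param gamma_mid,eps_mid Upper bounds of the chondrogenic window.
#' @param gamma_max,eps_max Destruction thresholds.
#' @param r_io,r_ch,r_eo,r_destr Daily transformation rates
#'   (fraction/day) for intramembranous ossification, chondrogenesis,
#'   endochondral ossification and tissue destruction.
#' @param destruction_resets_age Logical; if `TRUE` a destroyed element's
#'   maturation age restarts from zero.  The default `FALSE` ties the
#'   connective-tissue maturation to the healing time (the fracture
#'   hematoma organizes and stiffens with time whether or not local
#'   overstraining keeps reverting differentiated tissue).
#' @param vascular_speed Vascular front speed, element layers/day.
#' @param vascular_threshold Minimum vascularity for ossification.
#' @param ossification_requires_vascularity Logical; bone formation only in
#'   vascularized elements.
#' @param appositional Logical; bone formation only in elements adjacent to
#'   cortex or existing bone (surface-bound, appositional growth).
#' @param bone_threshold Bone fraction at which an element counts as
#'   ossified (apposition surface, bridging, callus metrics).
#' @param strain_clamp Stimuli are clamped to this absolute value before
#'   classification (very soft early callus under flexible fixation yields
#'   unphysically large linear strains; the clamp routes them into the
#'   destruction regime deterministically).
#' @return A `rule_parameters` object.
#' @export
rule_parameters <- function(resting_strain = 0.03,
                            commit_fraction = 0.1,
                            gamma_low = 0.05, eps_low = 0.05,
                            gamma_eo = 0.10,
                            gamma_mid = 0.15, eps_mid = 0.15,
                            gamma_max = 0.50, eps_max = 0.50,
                            r_io = 0.12, r_ch = 0.12, r_eo = 0.15,
                            r_destr = 0.5,
                            destruction_resets_age = FALSE,
                            vascular_speed = 1,
                            vascular_threshold = 0.5,
                            ossification_requires_vascularity = TRUE,
                            appositional = TRUE,
                            bone_threshold = 0.5,
                            strain_clamp = 1.0) {
  p <- list(resting_strain = resting_strain,
            commit_fraction = commit_fraction,
            gamma_low = gamma_low, eps_low = eps_low,
            gamma_eo = gamma_eo, gamma_mid = gamma_mid, eps_mid = eps_mid,
            gamma_max = gamma_max, eps_max = eps_max,
            r_io = r_io, r_ch = r_ch, r_eo = r_eo, r_destr = r_destr,
            destruction_resets_age = destruction_resets_age,
            vascular_speed = vascular_speed,
            vascular_threshold = vascular_threshold,
            ossification_requires_vascularity =
              ossification_requires_vascularity,
            appositional = appositional,
            bone_threshold = bone_threshold,
            strain_clamp = strain_clamp)
  if (!(0 < p$resting_strain && p$resting_strain < p$gamma_low &&
        p$gamma_low < p$gamma_eo && p$gamma_eo <= p$gamma_mid &&
        p$gamma_mid < p$gamma_max)) {
    stop("rule windows must be ordered: 0 < resting_strain < gamma_low < ",
         "gamma_eo <= gamma_mid < gamma_max.", call. = FALSE)
  }
  rates <- c(p$r_io, p$r_ch, p$r_eo, p$r_destr)
  if (any(rates < 0) || any(rates > 1)) {
    stop("transformation rates must lie in [0, 1] per day.", call. = FALSE)
  }
  class(p) <- "rule_parameters"
  p
}

rule_signals <- c("NONE", "INTRAMEMBRANOUS", "CHONDROGENESIS",
                  "ENDOCHONDRAL", "DESTRUCTION")

#' Classify mechanical stimuli into differentiation signals
#'
#' @param gamma Octahedral shear (distortional) strain, >= 0; vectorized.
#' @param eps_vol Dilatational strain, signed (negative = compression).
#' @param params A [rule_parameters()].
#' @param periosteal Logical (recycled): elements subject to the
#'   `resting_strain` activation threshold (the extracortical, periosteal
#'   healing domain).  Interfragmentary gap elements are passed as `FALSE`
#'   so that direct gap healing proceeds under absolute stability.
#' @return Character vector of signals (one per element), each one of
#'   `"NONE"`, `"INTRAMEMBRANOUS"`, `"CHONDROGENESIS"`, `"ENDOCHONDRAL"`,
#'   `"DESTRUCTION"`.  The windows partition the stimulus plane: exactly
#'   one signal per input.
#' @export
classify_stimulus <- function(gamma, eps_vol, params = rule_parameters(),
                              periosteal = TRUE) {
  if (any(!is.finite(gamma)) || any(!is.finite(eps_vol)) || any(gamma < 0)) {
    stop("stimuli must be finite and gamma >= 0.", call. = FALSE)
  }
  g <- pmin(gamma, params$strain_clamp)
  ev <- pmax(pmin(eps_vol, params$strain_clamp), -params$strain_clamp)
  aev <- abs(ev)
  out <- rep("NONE", length(g))
  chon <- ev < 0 & g <= params$gamma_mid & aev <= params$eps_mid
  out[chon] <- "CHONDROGENESIS"
  eo <- ev < 0 & g <= params$gamma_eo & aev <= params$eps_mid
  out[eo] <- "ENDOCHONDRAL"
  im <- g <= params$gamma_low & aev <= params$eps_low
  out[im] <- "INTRAMEMBRANOUS"
  peri <- rep_len(as.logical(periosteal), length(g))
  out[peri & g < params$resting_strain & aev < params$resting_strain] <-
    "NONE"
  out[g > params$gamma_max | aev > params$eps_max] <- "DESTRUCTION"
  out
}

#' Initial tissue state of the healing domain
#'
#' Healing elements start as pure connective tissue (fracture hematoma,
#' age 0).  Vascularity is 1 on the healing elements that border the
#' periosteal surface or the surrounding soft tissue (the free hull of the
#' healing domain) and 0 elsewhere; cortical bone is treated as vascular.
#'
#' @param mesh A [generate_mesh()] mesh.
#' @return A `tissue_state` list with per-element vectors `c_conn`,
#'   `c_cart`, `c_bone`, `v` (vascularity) and `t_age` (days).
#' @export
initial_tissue_state <- function(mesh) {
  nel <- nrow(mesh$elems)
  healing <- mesh$region == "HEALING"
  v <- numeric(nel)
  v[mesh$region == "CORTEX"] <- 1
  v[mesh$source_elements] <- 1
  state <- list(
    c_conn = as.numeric(healing),
    c_cart = numeric(nel),
    c_bone = as.numeric(mesh$region == "CORTEX"),
    v = v,
    t_age = numeric(nel)
  )
  class(state) <- "tissue_state"
  state
}

#' Advance the vascular front
#'
#' Vascularity propagates by face adjacency from fully vascular elements
#' (cortex and the periosteal/soft-tissue sources) into the healing domain
#' at `vascular_speed` element layers per day; an element at graph distance
#' `d` from the sources becomes fully vascular after `ceiling(d / speed)`
#' days.  Destroyed elements lose their vascularity in the same step,
#' overriding growth.
#'
#' @param state A `tissue_state`.
#' @param mesh The mesh (provides the face-neighbor table).
#' @param params A [rule_parameters()].
#' @param destruction Logical per-element mask of elements destroyed this
#'   step (optional).
#' @param dt Time step, days.
#' @return The updated `tissue_state`.
#' @export
update_vascularity <- function(state, mesh, params = rule_parameters(),
                               destruction = NULL, dt = 1) {
  nel <- length(state$v)
  vascular <- state$v >= 1 | mesh$region == "CORTEX"
  nb <- mesh$neighbors
  has_vasc_nb <- rowSums(matrix(vascular[ifelse(nb == 0L, NA, nb)],
                                nel, 6), na.rm = TRUE) > 0
  grow <- mesh$region == "HEALING" & !vascular & has_vasc_nb
  v <- state$v
  v[grow] <- pmin(1, v[grow] + params$vascular_speed * dt)
  v[mesh$source_elements] <- 1
  if (!is.null(destruction)) v[destruction] <- 0
  state$v <- v
  state
}

#' Apply differentiation signals to the tissue composition
#'
#' One explicit-Euler day of tissue transformation:
#' \itemize{
#'   \item `INTRAMEMBRANOUS`: connective -> bone at `r_io` (vascularity and,
#'     if `appositional`, adjacency to bone/cortex required); any remaining
#'     cartilage in the low-strain window ossifies at `r_eo` (endochondral
#'     completion).
#'   \item `CHONDROGENESIS`: connective -> cartilage at `r_ch`.
#'   \item `ENDOCHONDRAL`: cartilage -> bone at `r_eo` (vascular,
#'     appositional) while connective -> cartilage continues at `r_ch`
#'     ahead of the ossification front.
#'   \item `DESTRUCTION`: bone and cartilage revert to connective tissue at
#'     `r_destr`; the maturation age resets to 0 only if
#'     `destruction_resets_age` is set (by default the hematoma maturation
#'     follows the healing time).
#' }
#' Fractions are transfers, so they remain in `[0, 1]` and sum to 1; a
#' final renormalization removes floating-point drift.  Tissue age advances
#' by `dt` for all healing elements except those destroyed.
#'
#' @param state A `tissue_state`.
#' @param signal Character vector of signals from [classify_stimulus()].
#' @param mesh The mesh.
#' @param params A [rule_parameters()].
#' @param dt Time step, days.
#' @return The updated `tissue_state`.
#' @export
update_composition <- function(state, signal, mesh,
                               params = rule_parameters(), dt = 1) {
  s <- state
  nel <- length(s$c_conn)
  if (length(signal) != nel) {
    stop("`signal` must have one entry per element.", call. = FALSE)
  }
  tot <- s$c_conn + s$c_cart + s$c_bone
  healing <- mesh$region == "HEALING"
  if (any(abs(tot[healing] - 1) > 1e-6)) {
    stop("invalid composition: fractions do not sum to 1.", call. = FALSE)
  }

  vasc_ok <- if (params$ossification_requires_vascularity) {
    s$v >= params$vascular_threshold
  } else rep(TRUE, nel)
  appo_ok <- if (params$appositional) {
    ossified <- s$c_bone >= params$bone_threshold |
      mesh$region == "CORTEX"
    nb <- mesh$neighbors
    rowSums(matrix(ossified[ifelse(nb == 0L, NA, nb)], nel, 6),
            na.rm = TRUE) > 0
  } else rep(TRUE, nel)

  rate <- function(r) min(1, r * dt)

  im <- healing & signal == "INTRAMEMBRANOUS" & vasc_ok & appo_ok
  d <- rate(params$r_io) * s$c_conn[im]
  s$c_conn[im] <- s$c_conn[im] - d
  s$c_bone[im] <- s$c_bone[im] + d
  im2 <- healing & signal == "INTRAMEMBRANOUS" & vasc_ok
  d <- rate(params$r_eo) * s$c_cart[im2]
  s$c_cart[im2] <- s$c_cart[im2] - d
  s$c_bone[im2] <- s$c_bone[im2] + d

  ch <- healing & (signal == "CHONDROGENESIS" |
                     signal == "ENDOCHONDRAL")
  d <- rate(params$r_ch) * s$c_conn[ch]
  s$c_conn[ch] <- s$c_conn[ch] - d
  s$c_cart[ch] <- s$c_cart[ch] + d

  eo <- healing & signal == "ENDOCHONDRAL" & vasc_ok & appo_ok
  d <- rate(params$r_eo) * s$c_cart[eo]
  s$c_cart[eo] <- s$c_cart[eo] - d
  s$c_bone[eo] <- s$c_bone[eo] + d

  de <- healing & signal == "DESTRUCTION"
  d <- rate(params$r_destr)
  back <- d * (s$c_cart[de] + s$c_bone[de])
  s$c_conn[de] <- s$c_conn[de] + back
  s$c_cart[de] <- s$c_cart[de] * (1 - d)
  s$c_bone[de] <- s$c_bone[de] * (1 - d)

  # renormalize healing fractions (guard against fp drift)
  tot <- s$c_conn + s$c_cart + s$c_bone
  h <- healing & tot > 0
  s$c_conn[h] <- s$c_conn[h] / tot[h]
  s$c_cart[h] <- s$c_cart[h] / tot[h]
  s$c_bone[h] <- s$c_bone[h] / tot[h]

  s$t_age[healing] <- s$t_age[healing] + dt
  if (params$destruction_resets_age) s$t_age[de] <- 0
  s
}
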