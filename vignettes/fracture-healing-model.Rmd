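---
title: "A mechanoregulated finite-element model of secondary fracture healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanoregulated finite-element model of secondary fracture healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(callusmap)
```

## Scope and idea

`callusmap` simulates secondary (callus) healing of an idealized,
transverse, mid-diaphyseal osteotomy of an ovine tibia under a chosen
fixation stiffness, and sweeps fixation-stiffness grids into
characteristic maps of healing outcome. The mechanical environment in the
fracture — summarized by the interfragmentary movement (IFM) — is set
jointly by the physiological load and by the stiffness of the fixation
device in the axial and translational-shear directions. The model asks:
for which (axial, shear) stiffness pairs does the fracture heal quickly
with a moderate callus, where does it drift into delayed healing or
hypertrophic non-union, and where does over-rigid fixation suppress the
callus altogether?

## The mechanical model

**Geometry and mesh.** A hollow cylinder (periosteal diameter 20 mm,
endosteal 13 mm) with a transverse gap of 1 or 3 mm, plus a predefined
healing domain: the interfragmentary gap annulus and a periosteal cuff
extending 15 mm radially and 15 mm axially along each fragment. The
endosteal canal is excluded from healing, representing intramedullary
fixation. The mesh is a structured, deterministic hexahedral grid in
cylindrical layout; radial node positions are scaled by
`sqrt(h/sin(h))` (`h` the sector angle) so every polygonal ring has the
exact annulus area, which makes the summed element volume equal the
analytic model volume to machine precision. The default discretization
uses 16 angular sectors, two element layers through the cortical wall,
~3 mm callus layers, and gap layers of at most half the gap size
(≈ 2300–2700 elements). Mirror symmetry about the load plane is exact by
construction.

**Fragment length.** Each fragment defaults to 75 mm (model length
153 mm for a 3 mm gap), approximating an ovine tibial mid-diaphysis. The
relative bending stiffness of a healed construct depends on this lever
arm, because the gap's flexibility is weighed against the rest of the
span: with very short fragments even a fully ossified (woven-bone) gap
could not exceed ~75% of the intact stiffness, which would contradict the
healed-state plateaus (>80–95%) this model is meant to reproduce. End
effects from the clamped and loaded ends stay far from the healing zone.

**Elasticity.** All tissues are linear elastic and isotropic (cortical
bone 15750 MPa / 0.325; woven bone 538 / 0.33; fibrocartilage 28 / 0.3;
connective tissue maturing 0.1 → 1.4 MPa / 0.33). Trilinear hexahedra
with 2×2×2 Gauss integration; element stiffness separates into
`lambda`- and `mu`-weighted geometric parts, so daily reassembly under
evolving tissue modules is a vectorized triplet update and the sparse
supernodal Cholesky analysis is reused across days. The distal end is
clamped; the proximal end is tied to a rigid plate with six master
degrees of freedom. The fixation device is idealized as two uncoupled
ground springs at that plate (axial, shear); plate rotations are locked
under the physiological load case — the device is treated as rigid in
bending and torsion, its compliance fully described by the two stiffness
numbers. Loads: 840 N axial compression plus 200 N translational shear,
held constant through healing.

**Stimuli.** Per element, at the centroid: octahedral shear strain
`gamma = (2/3) * sqrt(3 tr(e_dev^2))` and dilatational strain
`eps_vol = tr(eps)` (negative in compression). With near-rigid callus
absent and very soft springs the linear model produces unphysical strain
magnitudes; stimuli are clamped at 100% strain before classification,
which routes them deterministically into the destruction regime.

**Virtual bending test.** Distal end clamped, transverse displacement
`u_bend = 0.1 mm` imposed on the proximal plate with rotations free,
fixator springs detached; `k_Bend = F_bend L^3 / (3 u_bend)`, the
tip-loaded cantilever identity. The intact reference is computed with the
same mesh and protocol on the no-osteotomy model (gap restored to
cortical bone, callus domain removed), so discretization bias largely
cancels in the reported percentage. On a slender intact tube the test
reproduces the Euler–Bernoulli closed form `E·pi/64·(D^4 − d^4)` within
5%; at the default (stockier) geometry only the ratio is used.

## The differentiation rule engine

The published fuzzy-logic controller (20 linguistic rules implementing
intramembranous ossification, chondrogenesis, endochondral ossification,
revascularization and tissue destruction) is reconstructed as a crisp,
configurable threshold ruleset. Every threshold and rate is a
`rule_parameters()` field. Defaults, in strain:

| window | condition | action (per day) |
|---|---|---|
| destruction | `gamma > 50%` or `|eps_vol| > 50%` | bone/cartilage → connective at 0.5 |
| quiescent | periosteal, uncommitted, both stimuli < 3% | none |
| intramembranous | `gamma ≤ 5%`, `|eps_vol| ≤ 5%` | connective → bone at 0.12 (+ leftover cartilage → bone at 0.15) |
| endochondral | compressive, `gamma ≤ 10%` | cartilage → bone at 0.15, connective → cartilage at 0.12 |
| chondrogenic | compressive, `gamma ≤ 15%` | connective → cartilage at 0.12 |

The 5/15% window bounds follow the classical strain-range hypothesis for
intramembranous versus endochondral bone formation. Four reconstruction
choices deserve explanation:

* **Periosteal activation threshold (3%), gap exempt.** External callus
  is a mechanically induced structure: below a resting stimulus no new
  periosteal callus is initiated. The interfragmentary gap is exempt —
  under near-zero strain it heals by the direct/primary mode, producing
  the early intercortical bridging with minimal external callus that
  characterizes overly rigid fixation. Without this split, rigid
  fixations grow the same callus cuff as optimal ones and the
  low-callus/low-stiffness signature of over-rigid constructs is lost.
* **Commitment.** The activation threshold applies only while an element
  is uncommitted (cartilage + bone < 10%). Once callus tissue has formed,
  falling strain must not freeze it: endochondral ossification is
  precisely the low-strain completion of the program.
* **Coupled endochondral route.** In the endochondral window both steps
  of the route run (connective → cartilage behind the front,
  cartilage → bone at the vascularized front); in the intramembranous
  window leftover cartilage also ossifies. A strictly
  one-transformation-per-window engine stalls: cartilage formed in the
  chondrogenic window could never ossify as the callus stiffens and
  strains fall through the windows.
* **Destruction threshold at 50%.** The chondrogenic window already ends
  at 15%; between 15% and 50% tissue persists as (maturing) connective
  tissue. This band is what separates a hypertrophic non-union from
  delayed healing: a 3 mm gap on an extremely flexible fixation strains
  its whole healing domain beyond 50% and destroys tissue perpetually,
  while a small 1 mm gap on a flexible fixation retains surviving outer
  cuff tissue whose maturation starts the stabilization cascade.

**Maturation.** The initial connective tissue (fracture hematoma,
0.1 MPa) stiffens along a symmetric logistic to 1.4 MPa within 8 weeks
(midpoint 28 d, steepness 0.25/d, endpoints matched within 2%). The
clock is the healing time: local destruction reverts composition but does
not reset the organization of the hematoma (a flag restores the
alternative). This maturation is load-bearing for the flexible-fixation
cases: it is what first reduces the IFM enough for cartilage to appear.

**Revascularization.** Vascularity enters from the periosteal/soft-tissue
boundary of the healing domain and from the cortex and advances one
face-neighbor layer per day (configurable); an element at graph distance
`d` from the sources becomes vascular after `ceiling(d/speed)` days.
Ossification requires vascularity ≥ 0.5; destruction devascularizes.
Bone formation is appositional: only elements adjacent to cortex or to
ossified elements convert, which produces front-like periosteal and
interfragmentary growth rather than uniform interior ossification.

**Time stepping.** Explicit daily updates to a 12-week horizon (84
steps): mix materials → solve → classify clamped stimuli → advance
vascularity → update composition. Bending tests and callus metrics run at
report times (default weeks 3/6/9/12; per-step testing is a flag).
Everything is deterministic — there is no randomness anywhere in the
engine — and identical configurations give identical timecourses.

## Outcome metrics

* `k_bend_rel`: virtual bending stiffness as % of the intact reference.
* `v_bo`: ossified (bone fraction ≥ 0.5) share of the *extracortical*
  healing volume; the interfragmentary column is excluded on both sides
  of the ratio, so purely intercortical bridging scores ≈ 0%.
* `ci`: callus index, twice the largest radial centroid coordinate of any
  ossified element over the periosteal diameter, floored at 1. CI tracks
  only the largest diameter, not volume — the model reproduces the
  classical caveat that a large early CI does not predict union.
* `bridged`: face-connected path of ossified elements linking the two
  cortical fragments (threshold 0.5, ties ossified).

## Map pipeline

`sweep_map()` runs one simulation per grid point (96 combinations per gap
size at the default 12 × 8 grid; a 4 × 3 coarse preset serves test-scale
work), caches per-point results keyed by a configuration hash, and
tolerates per-point solver failures. `interpolate_map()` builds a
bilinear surface in log10-stiffness space — node-exact, no extrapolation.
`classify_regions()` applies the qualitative region semantics (non-union;
slightly delayed with large or moderate callus; optimal; suboptimal and
unfavorable over-rigid; delayed) with verbal callus sizes mapped to
`v_bo` < 10% (small), 10–40% (moderate), > 40% (large) — declared
thresholds, config-exposed. `corroborate()` evaluates the week-9 surface
at the stiffness coordinates of packaged literature records (14 ovine
experiments; estimated shear stiffness carries a ±20% band; out-of-grid
records are clamped and flagged).

## Calibration and what the defaults reproduce

The four per-day rates, the activation threshold and the destruction
threshold were calibrated once against the qualitative anchors of the
healing-outcome literature for this loading: an optimal fixation
(1500/400 N/mm, 3 mm gap) bridges between weeks 3 and 6 with ~86%
relative bending stiffness and a moderate callus (CI 1.74, `v_bo` 15%);
a very rigid fixation (7500/600) bridges intercortically with `v_bo`
≈ 2%; an extremely flexible fixation (1/1, 3 mm) forms a large callus
(CI 2.3) but never bridges; a flexible 1 mm gap (50/100) heals delayed
(bridged by week 9, ~98% at week 12). These are the same quantities the
acceptance script recomputes; the vignette states no number the code does
not produce.

## Numerical choices, degenerate inputs, limitations

* Sparse supernodal Cholesky with cached symbolic analysis; solver
  residual checked at 1e-8; singular systems (floating fragments) abort
  with a diagnostic.
* Degenerate geometry (zero cortical wall, non-positive lengths) and
  resolutions placing fewer than two element layers across the gap are
  rejected at construction.
* Unbridged soft constructs return a small positive bending stiffness,
  not an error; ossification ties at the bone-fraction threshold count as
  ossified, and bridging ties break toward unbridged only below the
  threshold.
* Small-strain linear kinematics throughout; no cortical contact, no
  bending/torsion load components, no poro-/viscoelasticity, no
  remodeling after bridging, and no stochastic inter-animal variability —
  the synthetic study conditions emulate an idealized standardized
  osteotomy, not the variance of real cohorts. Passing tests therefore
  demonstrate reproduction of map-level model behavior, not prediction of
  any individual animal.
* The strain clamp (100%) plus destruction regime is a deterministic
  stand-in for the mechanically chaotic early phase under gross
  instability; within the clamp the linear solver remains well posed
  because tissue moduli never drop below the hematoma value.
* Simulation scale: default runs use ~2500–2700 hexahedra and 84 daily
  steps (≈ half a minute each on one CPU core), the problem size at which
  the full acceptance recomputation stays in the minutes range.
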