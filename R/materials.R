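#' Tissue material table
#'
#' Linear-elastic, isotropic material properties of the tissues involved in
#' secondary fracture healing.  The connective-tissue modulus listed here
#' is the mature value; early granulation tissue starts near the fracture
#' hematoma modulus and matures towards it (see [maturation_curve()]).
#'
#' @param cortical,woven,fibrocartilage,connective Optional length-2
#'   numeric vectors `c(E, nu)` overriding the defaults (MPa, -).
#' @return A data.frame with columns `tissue`, `E` (MPa), `nu`.
#' @examples
#' material_table()
#' @export
material_table <- function(cortical = c(15750, 0.325),
                           woven = c(538, 0.33),
                           fibrocartilage = c(28, 0.3),
                           connective = c(1.4, 0.33)) {
  tab <- data.frame(
    tissue = c("cortical", "woven", "fibrocartilage", "connective"),
    E  = c(cortical[1], woven[1], fibrocartilage[1], connective[1]),
    nu = c(cortical[2], woven[2], fibrocartilage[2], connective[2])
  )
  if (any(tab$E <= 0) || any(tab$nu <= 0) || any(tab$nu >= 0.5)) {
    stop("material table requires E > 0 and 0 < nu < 0.5.", call. = FALSE)
  }
  tab
}

#' Connective-tissue maturation curve
#'
#' Sigmoidal stiffening of the initial soft callus tissue: from the
#' fracture-hematoma modulus to the mature connective-tissue modulus within
#' eight weeks.  The default is a symmetric logistic with midpoint at half
#' the maturation span; its steepness is chosen so the curve is within 2%
#' of both endpoints at age 0 and at `duration`.
#'
#' @param E_start Hematoma modulus, MPa (default 0.1).
#' @param E_end Mature connective-tissue modulus, MPa (default 1.4).
#' @param duration Maturation span, days (default 56 = 8 weeks).
#' @param steepness Logistic steepness, 1/day (default 0.25).
#' @return A `maturation_curve` object.
#' @export
maturation_curve <- function(E_start = 0.1, E_end = 1.4, duration = 56,
                             steepness = 0.25) {
  stopifnot(E_start > 0, E_end >= E_start, duration > 0, steepness > 0)
  structure(list(E_start = E_start, E_end = E_end, duration = duration,
                 steepness = steepness), class = "maturation_curve")
}

#' Maturing connective-tissue modulus
#'
#' @param t_age Tissue age(s), days (>= 0); vectorized.
#' @param curve A [maturation_curve()].
#' @return Young's modulus (MPa) of connective tissue at the given age(s);
#'   monotone non-decreasing, bounded by the curve endpoints.
#' @examples
#' maturation_modulus(c(0, 28, 56), maturation_curve())
#' @export
maturation_modulus <- function(t_age, curve = maturation_curve()) {
  if (any(!is.finite(t_age)) || any(t_age < 0)) {
    stop("`t_age` must be finite and non-negative (days).", call. = FALSE)
  }
  curve$E_start + (curve$E_end - curve$E_start) /
    (1 + exp(-curve$steepness * (t_age - curve$duration / 2)))
}

#' Rule-of-mixtures element material
#'
#' Per-element effective Young's modulus and Poisson's ratio as the
#' composition-weighted average of the tissue table, with the connective
#' fraction evaluated at its maturation age.  Pure tissues reproduce the
#' table values exactly (pure connective tissue reproduces the maturation
#' curve).
#'
#' @param composition A data.frame (or list) with numeric fields `c_conn`,
#'   `c_cart`, `c_bone` summing to 1 per element.
#' @param table A [material_table()].
#' @param t_age Tissue age(s), days, recycled across elements.
#' @param curve A [maturation_curve()].
#' @return List with vectors `E` (MPa) and `nu`.
#' @examples
#' mix_materials(list(c_conn = 0, c_cart = 0, c_bone = 1), t_age = 0)
#' @export
mix_materials <- function(composition, table = material_table(), t_age = 0,
                          curve = maturation_curve()) {
  cc <- composition$c_conn; ca <- composition$c_cart; cb <- composition$c_bone
  s <- cc + ca + cb
  if (any(!is.finite(s)) || any(abs(s - 1) > 1e-6)) {
    stop("tissue fractions must be finite and sum to 1.", call. = FALSE)
  }
  row <- function(t) table[table$tissue == t, ]
  E_conn <- maturation_modulus(rep_len(t_age, length(cc)), curve)
  E  <- cc * E_conn + ca * row("fibrocartilage")$E + cb * row("woven")$E
  nu <- cc * row("connective")$nu + ca * row("fibrocartilage")$nu +
    cb * row("woven")$nu
  list(E = E, nu = nu)
}
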