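# Pointwise myocardial constitutive law: Guccione transversely isotropic
# passive stress and the sarcomere active-contraction model.
#
# Stresses in Pa, lengths in um (sarcomere scale), times in ms.

#' Guccione passive material parameters
#'
#' Fung-type transversely isotropic strain energy
#' `W = C/2 (exp(Q) - 1)` with
#' `Q = b_ff E_ff^2 + b_xx (E_ss^2 + E_nn^2 + E_sn^2 + E_ns^2) +
#'  b_fx (E_fn^2 + E_nf^2 + E_fs^2 + E_sf^2)` in fiber (f), sheet (s),
#' sheet-normal (n) coordinates.  The stress scale defaults are the baseline
#' values (`C` = 280 Pa for the LV free wall + septum, 170 Pa for the RV free
#' wall); the exponents are a common literature set, configurable, and not
#' from the source parameter table.
#'
#' @param C Stress scale, Pa.
#' @param b_ff,b_xx,b_fx Dimensionless exponents.
#' @return Object of class `guccione_params`.
#' @export
guccione_params <- function(C = 280, b_ff = 29.9, b_xx = 13.3, b_fx = 26.6) {
  stopifnot(C > 0, b_ff > 0, b_xx > 0, b_fx > 0)
  structure(list(C = C, b_ff = b_ff, b_xx = b_xx, b_fx = b_fx),
            class = "guccione_params")
}

#' Active contraction parameters
#'
#' Sarcomere-level active stress: a series elastic element of stiffness
#' `E_a` links the contractile element length `l_c` to the sarcomere length
#' `l_s`; the developed stress is scaled by an isometric tension curve
#' `f_iso(l_c)` and a twitch function `f_twitch(t, l_s)` whose duration grows
#' with sarcomere length at slope `b`.
#'
#' Defaults: `T_0`, `t_r`, `t_d` are the baseline values (LV 2000 kPa
#' expressed here in Pa).  `a_6`, `a_7`, `E_a`, `v_0`, `l_d`, `l_s0` follow
#' the contraction-model lineage and are not from the source parameter table.
#' The printed duration slope (0.17 ms/um) yields sub-millisecond twitches at
#' physiologic sarcomere lengths, so the shipped default is `b` = 170 ms/um
#' (the lineage unit), configurable.
#'
#' `iso_variant` selects the branch orientation of `f_iso`: `"printed"`
#' develops tension for `l_c < a_7` exactly as printed; `"ascending"`
#' develops tension for `l_c > a_7` (the physiologic ascending limb, needed
#' for contraction at operating lengths 1.8-2.2 um).
#'
#' @param T_0 Tension scale, Pa.
#' @param t_r,t_d Twitch rise / decay time constants, ms.
#' @param b Twitch duration vs sarcomere length slope, ms/um.
#' @param l_d Sarcomere length at zero twitch duration, um.
#' @param a_6 Steepness of the isometric curve, 1/um.
#' @param a_7 Threshold length of the isometric curve, um.
#' @param E_a Series-element stiffness, 1/um.
#' @param v_0 Unloaded shortening velocity, um/ms.
#' @param l_s0 Relaxed sarcomere length, um.
#' @param iso_variant `"printed"` or `"ascending"`.
#' @return Object of class `active_params`.
#' @export
active_params <- function(T_0 = 2000e3, t_r = 280, t_d = 80, b = 170,
                          l_d = -0.4, a_6 = 2.0, a_7 = 1.5, E_a = 20,
                          v_0 = 0.0075, l_s0 = 1.9,
                          iso_variant = c("printed", "ascending")) {
  iso_variant <- match.arg(iso_variant)
  stopifnot(T_0 >= 0, t_r > 0, t_d > 0, l_s0 > 0)
  structure(list(T_0 = T_0, t_r = t_r, t_d = t_d, b = b, l_d = l_d,
                 a_6 = a_6, a_7 = a_7, E_a = E_a, v_0 = v_0, l_s0 = l_s0,
                 iso_variant = iso_variant),
            class = "active_params")
}

#' Sarcomere state at one material point
#'
#' @param l_s Sarcomere length, um.
#' @param l_c Contractile element length, um.
#' @param t_act Time since activation, ms.
#' @return Object of class `sarcomere_state`.
#' @export
sarcomere_state <- function(l_s, l_c, t_act) {
  stopifnot(l_s > 0, l_c > 0)
  structure(list(l_s = l_s, l_c = l_c, t_act = t_act),
            class = "sarcomere_state")
}

#' Orthonormal fiber basis
#'
#' Myofiber, sheet, sheet-normal unit vectors in the reference
#' configuration.  Validated orthonormal to 1e-10.
#'
#' @param e_f0,e_s0,e_n0 Length-3 numeric vectors.
#' @return Object of class `fiber_basis`; a 3x3 matrix with the vectors as
#'   columns (f, s, n).
#' @export
fiber_basis <- function(e_f0, e_s0, e_n0) {
  Q <- cbind(f = e_f0, s = e_s0, n = e_n0)
  if (max(abs(crossprod(Q) - diag(3))) > 1e-10)
    stop("fiber basis is not orthonormal", call. = FALSE)
  structure(Q, class = c("fiber_basis", "matrix"))
}

#' Green-Lagrange strain from a deformation gradient
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @return Symmetric strain tensor `E = (t(F) F - I)/2`.
#' @export
green_lagrange <- function(F) {
  if (det(F) <= 0) stop("deformation gradient must have positive determinant",
                        call. = FALSE)
  (crossprod(F) - diag(3)) / 2
}

# quadratic form Q(E) and its derivative dQ/dE in fiber coordinates
.guccione_Q <- function(Ef, p) {
  p$b_ff * Ef[1, 1]^2 +
    p$b_xx * (Ef[2, 2]^2 + Ef[3, 3]^2 + Ef[2, 3]^2 + Ef[3, 2]^2) +
    p$b_fx * (Ef[1, 3]^2 + Ef[3, 1]^2 + Ef[1, 2]^2 + Ef[2, 1]^2)
}

.guccione_dQ <- function(Ef, p) {
  B <- matrix(c(p$b_ff, p$b_fx, p$b_fx,
                p$b_fx, p$b_xx, p$b_xx,
                p$b_fx, p$b_xx, p$b_xx), 3, 3, byrow = TRUE)
  2 * B * Ef
}

#' Guccione passive strain-energy density
#'
#' @param E Green-Lagrange strain expressed in the (f, s, n) basis.
#' @param p [guccione_params()].
#' @return Energy density `C/2 (exp(Q) - 1)`, Pa; zero iff `Q = 0`.
#' @export
passive_energy <- function(E, p) {
  p$C / 2 * expm1(.guccione_Q(E, p))
}

#' Passive first Piola-Kirchhoff stress
#'
#' Exact gradient of [passive_energy()] composed with [green_lagrange()]:
#' `P = F S` with second Piola-Kirchhoff `S = C/2 exp(Q) dQ/dE` rotated from
#' the fiber basis.
#'
#' @param F 3x3 deformation gradient.
#' @param basis A [fiber_basis()] (columns f, s, n).
#' @param p [guccione_params()].
#' @return 3x3 first Piola-Kirchhoff stress tensor, Pa.
#' @export
passive_pk1 <- function(F, basis, p) {
  E <- green_lagrange(F)
  Q <- unclass(basis)
  Ef <- t(Q) %*% E %*% Q                       # strain in fiber coords
  Sf <- p$C / 2 * exp(.guccione_Q(Ef, p)) * .guccione_dQ(Ef, p)
  S <- Q %*% Sf %*% t(Q)
  F %*% S
}

#' Isometric tension-length relation of the contractile element
#'
#' `T_0 tanh^2(a_6 (l_c - a_7))` on the active branch, zero on the other
#' side of the threshold `a_7`.  With `iso_variant = "printed"` the active
#' branch is `l_c < a_7` (as printed); with `"ascending"` it is `l_c > a_7`.
#'
#' @param l_c Contractile element length, um (vectorised).
#' @param p [active_params()].
#' @return Tension in Pa, in [0, T_0].
#' @export
f_iso <- function(l_c, p) {
  active <- if (p$iso_variant == "printed") l_c < p$a_7 else l_c > p$a_7
  ifelse(active, p$T_0 * tanh(p$a_6 * (l_c - p$a_7))^2, 0)
}

#' Twitch time course of active tension
#'
#' `tanh^2(t/t_r) tanh^2((t_max - t)/t_d)` for `0 < t < t_max` with
#' `t_max = b (l_s - l_d)`; zero before activation and after the twitch
#' ends.  Value in [0, 1].
#'
#' @param t Time since activation, ms (vectorised).
#' @param l_s Sarcomere length, um.
#' @param p [active_params()].
#' @return Dimensionless twitch amplitude.
#' @export
f_twitch <- function(t, l_s, p) {
  t_max <- p$b * (l_s - p$l_d)
  inside <- t > 0 & t < t_max
  out <- numeric(length(t))
  out[inside] <- tanh(t[inside] / p$t_r)^2 *
    tanh((t_max - t[inside]) / p$t_d)^2
  out
}

#' Magnitude of the active fiber stress
#'
#' `P_a = (l_s/l_s0) f_iso(l_c) f_twitch(t, l_s) (l_s - l_c) E_a`.
#' Non-negative whenever `l_s >= l_c`.
#'
#' @param s A [sarcomere_state()].
#' @param p [active_params()].
#' @return Active stress magnitude, Pa.
#' @export
active_stress_magnitude <- function(s, p) {
  (s$l_s / p$l_s0) * f_iso(s$l_c, p) * f_twitch(s$t_act, s$l_s, p) *
    (s$l_s - s$l_c) * p$E_a
}

#' Rate of change of the contractile element length
#'
#' `dl_c/dt = (E_a (l_s - l_c) - 1) v_0`; at the isotonic equilibrium
#' `E_a (l_s - l_c) = 1` the rate vanishes.
#'
#' @param s A [sarcomere_state()].
#' @param p [active_params()].
#' @return Rate in um/ms.
#' @export
lc_rate <- function(s, p) {
  (p$E_a * (s$l_s - s$l_c) - 1) * p$v_0
}

#' Myofiber stretch and sarcomere length from a deformation gradient
#'
#' @param F 3x3 deformation gradient.
#' @param e_f0 Reference unit fiber vector.
#' @param l_s0 Relaxed sarcomere length, um.
#' @return List with `lambda = sqrt(e_f0 . t(F) F e_f0)` and
#'   `l_s = lambda * l_s0`.
#' @export
myofiber_stretch <- function(F, e_f0, l_s0) {
  if (abs(sum(e_f0^2) - 1) > 1e-8)
    stop("e_f0 must be a unit vector", call. = FALSE)
  lambda <- sqrt(drop(t(e_f0) %*% crossprod(F) %*% e_f0))
  list(lambda = lambda, l_s = lambda * l_s0)
}

#' Total first Piola-Kirchhoff stress (passive + active)
#'
#' `P = P_passive + P_a (e_f x e_f0)` with the current fiber direction
#' `e_f = F e_f0 / |F e_f0|`.
#'
#' @param F 3x3 deformation gradient.
#' @param basis A [fiber_basis()].
#' @param s A [sarcomere_state()] (its `l_s` should be consistent with `F`).
#' @param gp [guccione_params()].
#' @param ap [active_params()].
#' @return 3x3 stress tensor, Pa.
#' @export
total_pk1 <- function(F, basis, s, gp, ap) {
  Pp <- passive_pk1(F, basis, gp)
  e_f0 <- unclass(basis)[, 1]
  v <- drop(F %*% e_f0)
  e_f <- v / sqrt(sum(v^2))
  Pa <- active_stress_magnitude(s, ap)
  Pp + Pa * (e_f %o% e_f0)
}
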