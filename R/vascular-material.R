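# Constituent-based artery wall energy: elastin-dominated matrix, four
# collagen fiber families (longitudinal, circumferential, +/- alpha) and
# circumferential smooth muscle, each weighted by its mass per unit volume.
#
# Energies per unit reference volume, Pa (= J/m^3); stretches dimensionless.

#' Artery wall material (constrained-mixture membrane)
#'
#' Mass fractions must sum to one; 10% of the collagen mass sits in each of
#' the longitudinal and circumferential families and 40% in each diagonal
#' family by default.  Every energy term is proportional to the tissue mass
#' density `rho`, so `rho` and the `c` stiffnesses only enter as products;
#' `rho` defaults to 1050 kg/m^3 and the stiffness values absorb any rescale.
#' Wall thickness is not part of the printed parameter set; defaults are
#' 2.0 mm (aorta) and 1.5 mm (pulmonary artery), configurable.
#'
#' @param c_1 Elastin stiffness, Pa.
#' @param c_2,c_3 Collagen stiffness scale (Pa) and dimensionless exponent.
#' @param c_4,c_5 Smooth-muscle stiffness scale (Pa) and exponent.
#' @param phi_e,phi_m,phi_c Mass fractions of elastin, SMC, total collagen.
#' @param split Within-collagen fractions of the four families
#'   (longitudinal, circumferential, +alpha, -alpha); sums to 1.
#' @param alpha Diagonal family angle from the longitudinal axis, degrees.
#' @param rho Tissue mass density (kept dimensionless-normalised at 1 by
#'   default so that `M * c` products carry the stiffness; see Details).
#' @param h Membrane thickness, mm.
#' @return Object of class `vessel_wall_material`.
#' @details With `rho = 1` the constituent "mass densities" returned by
#'   [constituent_masses()] are simply the mass fractions and each energy
#'   term has the magnitude `phi * c`, which is how the printed stiffnesses
#'   (e.g. elastin 120 kPa for the aorta) are calibrated.  Supplying a true
#'   density rescales all stresses uniformly.
#' @export
vessel_wall_material <- function(c_1, c_2, c_3, c_4, c_5,
                                 phi_e, phi_m, phi_c,
                                 split = c(0.1, 0.1, 0.4, 0.4),
                                 alpha = 45, rho = 1, h = 1.5) {
  if (abs(phi_e + phi_m + phi_c - 1) > 1e-9)
    stop("mass fractions phi_e + phi_m + phi_c must sum to 1", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-9)
    stop("collagen split fractions must sum to 1", call. = FALSE)
  fr <- c(phi_e, phi_m, phi_c, split)
  if (any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  stopifnot(h > 0, rho > 0)
  structure(list(c_1 = c_1, c_2 = c_2, c_3 = c_3, c_4 = c_4, c_5 = c_5,
                 phi_e = phi_e, phi_m = phi_m, phi_c = phi_c,
                 split = split, alpha = alpha, rho = rho, h = h),
            class = "vessel_wall_material")
}

#' Baseline aorta / pulmonary-artery wall materials
#'
#' Baseline constituent parameters: aorta `c_1` = 120 kPa, collagen
#' (0.2 kPa, 8.0), SMC (0.08 kPa, 3.5), fractions (0.35, 0.45, 0.20);
#' pulmonary artery `c_1` = 45 kPa, collagen (100 kPa, 3.0), SMC
#' (5 kPa, 3.5), fractions (0.35, 0.23, 0.42).
#'
#' @param ... Overrides passed to [vessel_wall_material()].
#' @return A `vessel_wall_material`.
#' @export
aorta_material <- function(...) {
  args <- utils::modifyList(
    list(c_1 = 120e3, c_2 = 0.2e3, c_3 = 8.0, c_4 = 0.08e3, c_5 = 3.5,
         phi_e = 0.35, phi_m = 0.45, phi_c = 0.20, h = 2.0),
    list(...))
  do.call(vessel_wall_material, args)
}

#' @rdname aorta_material
#' @export
pa_material <- function(...) {
  args <- utils::modifyList(
    list(c_1 = 45e3, c_2 = 100e3, c_3 = 3.0, c_4 = 5e3, c_5 = 3.5,
         phi_e = 0.35, phi_m = 0.23, phi_c = 0.42, h = 1.5),
    list(...))
  do.call(vessel_wall_material, args)
}

#' Per-constituent mass densities
#'
#' `M_e = phi_e rho`, `M_m = phi_m rho`, and per collagen family
#' `M_i = split_i phi_c rho` (the within-collagen split applied to the total
#' collagen fraction, matching the parenthetical family definitions of the
#' parameter table).  The masses sum to `rho`.
#'
#' @param m A [vessel_wall_material()].
#' @return List with `M_e`, `M_m`, `M_c` (length 4).
#' @export
constituent_masses <- function(m) {
  list(M_e = m$phi_e * m$rho,
       M_m = m$phi_m * m$rho,
       M_c = m$split * m$phi_c * m$rho)
}

#' Elastin (neo-Hookean matrix) energy density
#'
#' `W = M_e (c_1/2)(tr(C) - 3)` where `tr(C)` includes the thickness stretch
#' determined by incompressibility, `lambda_t^2 = 1/det(C2)` for an in-plane
#' right Cauchy-Green tensor `C2`.
#'
#' @param C2 2x2 in-plane right Cauchy-Green tensor.
#' @param M_e Elastin mass density.
#' @param c_1 Elastin stiffness, Pa.
#' @return Energy density, Pa; zero at identity.
#' @export
elastin_energy <- function(C2, M_e, c_1) {
  trC <- C2[1, 1] + C2[2, 2] + 1 / (C2[1, 1] * C2[2, 2] - C2[1, 2] * C2[2, 1])
  M_e * c_1 / 2 * (trC - 3)
}

#' Stretch of a fiber family
#'
#' @param C2 2x2 in-plane right Cauchy-Green tensor.
#' @param e_0 In-plane unit vector of the family (length 2).
#' @return `lambda = sqrt(e_0 . C2 e_0)`.
#' @export
fiber_stretch <- function(C2, e_0) {
  if (abs(sum(e_0^2) - 1) > 1e-8)
    stop("fiber direction must be a unit vector", call. = FALSE)
  sqrt(drop(t(e_0) %*% C2 %*% e_0))
}

#' Collagen fiber family energy density
#'
#' `W = M_i c_2/(4 c_3) (exp(c_3 (lambda^2 - 1)^2) - 1)`; zero at
#' `lambda = 1` and, as printed, symmetric in `(lambda^2 - 1)` so compressed
#' fibers store energy too (a tension-only variant can be had by zeroing the
#' contribution for `lambda < 1` before summation; the default follows the
#' printed form).
#'
#' @param lambda Fiber stretch.
#' @param M_i Family mass density.
#' @param c_2,c_3 Stiffness scale (Pa) and exponent.
#' @return Energy density, Pa.
#' @export
collagen_family_energy <- function(lambda, M_i, c_2, c_3) {
  M_i * c_2 / (4 * c_3) * expm1(c_3 * (lambda^2 - 1)^2)
}

#' Smooth-muscle energy density
#'
#' Same functional form as [collagen_family_energy()] with parameters
#' `(c_4, c_5)`; the SMC direction is circumferential.
#'
#' @param lambda_m SMC stretch.
#' @param M_m SMC mass density.
#' @param c_4,c_5 Stiffness scale (Pa) and exponent.
#' @return Energy density, Pa.
#' @export
smc_energy <- function(lambda_m, M_m, c_4, c_5) {
  collagen_family_energy(lambda_m, M_m, c_4, c_5)
}

#' In-plane unit vectors of the four fiber families and the SMC
#'
#' Family order: longitudinal (0 deg), circumferential (90 deg), +alpha,
#' -alpha, measured from the longitudinal axis; the first local coordinate
#' is longitudinal, the second circumferential.
#'
#' @param alpha Diagonal angle in degrees.
#' @return 2x5 matrix of unit vectors (columns: four families then SMC).
#' @export
family_directions <- function(alpha = 45) {
  a <- alpha * pi / 180
  cbind(long = c(1, 0), circ = c(0, 1),
        plus = c(cos(a), sin(a)), minus = c(cos(a), -sin(a)),
        smc = c(0, 1))
}

#' Total wall energy density of the constrained-mixture membrane
#'
#' Sum of elastin, the four collagen families and SMC energies at the given
#' in-plane deformation.
#'
#' @param C2 2x2 in-plane right Cauchy-Green tensor (symmetric positive
#'   definite), expressed in the (longitudinal, circumferential) frame.
#' @param m A [vessel_wall_material()].
#' @return Energy density, Pa; zero at identity.
#' @export
wall_energy <- function(C2, m) {
  M <- constituent_masses(m)
  dirs <- family_directions(m$alpha)
  W <- elastin_energy(C2, M$M_e, m$c_1)
  for (i in 1:4) {
    lam <- fiber_stretch(C2, dirs[, i])
    W <- W + collagen_family_energy(lam, M$M_c[i], m$c_2, m$c_3)
  }
  lam_m <- fiber_stretch(C2, dirs[, 5])
  W + smc_energy(lam_m, M$M_m, m$c_4, m$c_5)
}

#' In-plane second Piola-Kirchhoff membrane stress
#'
#' Analytic derivative `S = 2 dW/dC2` of [wall_energy()]; used by the
#' membrane finite elements and by stiffness post-processing.
#'
#' @inheritParams wall_energy
#' @return 2x2 symmetric stress tensor, Pa.
#' @export
wall_pk2 <- function(C2, m) {
  M <- constituent_masses(m)
  dirs <- family_directions(m$alpha)
  d <- C2[1, 1] * C2[2, 2] - C2[1, 2] * C2[2, 1]
  C2inv <- matrix(c(C2[2, 2], -C2[1, 2], -C2[2, 1], C2[1, 1]), 2, 2) / d
  # elastin: W_e = M c1/2 (tr C2 + 1/det C2 - 3)
  S <- M$M_e * m$c_1 * (diag(2) - C2inv / d)
  cc <- cbind(c(m$c_2, m$c_3), c(m$c_2, m$c_3), c(m$c_2, m$c_3),
              c(m$c_2, m$c_3), c(m$c_4, m$c_5))
  Mi <- c(M$M_c, M$M_m)
  for (i in 1:5) {
    e0 <- dirs[, i]
    lam2 <- drop(t(e0) %*% C2 %*% e0)
    dWdl2 <- Mi[i] * cc[1, i] / 2 * (lam2 - 1) * exp(cc[2, i] * (lam2 - 1)^2)
    S <- S + 2 * dWdl2 * (e0 %o% e0)
  }
  S
}
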