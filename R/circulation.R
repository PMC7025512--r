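# Eight-compartment closed-loop lumped circulation.
#
# Internal unit system: pressure Pa, volume ml, time ms, flow ml/ms,
# resistance Pa*ms/ml, compliance ml/Pa.  mmHg appears only in reports
# (1 mmHg = 133.322 Pa).

#' Compartment and flow names of the closed loop
#'
#' The eight compartments are, in loop order: left ventricle (LV), systemic
#' arteries (sa), systemic veins (sv), right atrium (RA), right ventricle
#' (RV), pulmonary arteries (pa), pulmonary veins (pv), left atrium (LA).
#' The eight segmental flows are mv, av, sa, sv, tv, pvv, pa, pv; flow `mv`
#' feeds the LV from the LA, and each flow `x` drains the compartment it is
#' named after (or the chamber upstream of the named valve).
#'
#' @return Character vectors of compartment / flow names.
#' @export
compartment_names <- function() c("LV", "sa", "sv", "RA", "RV", "pa", "pv", "LA")

#' @rdname compartment_names
#' @export
flow_names <- function() c("mv", "av", "sa", "sv", "tv", "pvv", "pa", "pv")

#' Parameters of the lumped circulation
#'
#' Valve and vessel resistances, venous compliances and venous resting
#' volumes.  Defaults follow the baseline parameterization (resistances in
#' Pa·ms/ml: e.g. `R_sa` = 125 kPa·ms/ml).  Note: the source table prints the
#' venous compliances with an inconsistent unit; here `C_sv`, `C_pv` are true
#' compliances in ml/Pa and the shipped defaults are chosen so venous
#' pressures stay physiological (a few mmHg) at the default total blood
#' volume.
#'
#' @param R_mv,R_av,R_tv,R_pvv Valve resistances (mitral, aortic, tricuspid,
#'   pulmonary), Pa·ms/ml.
#' @param R_sa,R_sv,R_pa,R_pv Vessel resistances, Pa·ms/ml.
#' @param C_sv,C_pv Venous compliances, ml/Pa.
#' @param V_sv0,V_pv0 Venous resting volumes, ml.
#' @return An object of class `circulation_params`.
#' @export
circulation_params <- function(R_mv = 900, R_av = 3200, R_tv = 400,
                               R_pvv = 2000, R_sa = 125000, R_sv = 2000,
                               R_pa = 75000, R_pv = 2000,
                               C_sv = 0.6, C_pv = 0.15,
                               V_sv0 = 3570, V_pv0 = 485) {
  p <- list(R_mv = R_mv, R_av = R_av, R_tv = R_tv, R_pvv = R_pvv,
            R_sa = R_sa, R_sv = R_sv, R_pa = R_pa, R_pv = R_pv,
            C_sv = C_sv, C_pv = C_pv, V_sv0 = V_sv0, V_pv0 = V_pv0)
  rs <- unlist(p[grep("^R_", names(p))])
  if (any(!is.finite(rs)) || any(rs <= 0))
    stop("all resistances must be positive and finite", call. = FALSE)
  if (C_sv <= 0 || C_pv <= 0)
    stop("venous compliances must be positive", call. = FALSE)
  if (V_sv0 < 0 || V_pv0 < 0)
    stop("venous resting volumes must be non-negative", call. = FALSE)
  structure(p, class = "circulation_params")
}

#' Atrial time-varying elastance parameters
#'
#' The atrium pressure interpolates between an end-systolic linear PV
#' relation `E_es * (V - V_0)` and an exponential end-diastolic relation
#' `A * (exp(B (V - V_0)) - 1)`, weighted by the driving function
#' [activation_e()].
#'
#' @param E_es End-systolic elastance, Pa/ml.
#' @param V_0 Volume intercept, ml.
#' @param A EDPVR scale, Pa.
#' @param B EDPVR exponent, 1/ml.
#' @param t_max Time of maximal elastance, ms.
#' @param tau Relaxation time constant, ms.
#' @param onset Activation onset within the cycle, ms (time-shift applied by
#'   the caller mapping cycle time to activation time).
#' @return An object of class `elastance_params`.
#' @export
atrial_elastance_params <- function(E_es = 60, V_0 = 10, A = 58.67,
                                    B = 0.049, t_max = 135, tau = 50,
                                    onset = 0) {
  stopifnot(E_es > 0, B > 0, t_max > 0, tau > 0)
  structure(list(E_es = E_es, V_0 = V_0, A = A, B = B,
                 t_max = t_max, tau = tau, onset = onset),
            class = "elastance_params")
}

#' Flow across a valve (one-way resistive element)
#'
#' A diode-resistor: flow is `(P_up - P_down)/R` when the gradient is
#' forward, zero when the valve is closed.  Never negative.
#'
#' @param P_up,P_down Upstream / downstream pressures, Pa.
#' @param R Valve resistance, Pa·ms/ml; must be positive.
#' @return Flow in ml/ms.
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("valve resistance must be positive", call. = FALSE)
  ifelse(P_up >= P_down, (P_up - P_down) / R, 0)
}

#' Flow across a linear resistance (no valve)
#'
#' `(P_up - P_down)/R`; may be negative.
#'
#' @inheritParams valve_flow
#' @return Flow in ml/ms.
#' @export
resistive_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("resistance must be positive", call. = FALSE)
  (P_up - P_down) / R
}

#' Venous pressure from a linear compliance
#'
#' @param V Compartment volume, ml.
#' @param params A [circulation_params()] object.
#' @param bed `"systemic"` or `"pulmonary"`.
#' @return Pressure in Pa, `(V - V_0)/C` for the selected bed.
#' @export
venous_pressure <- function(V, params, bed = c("systemic", "pulmonary")) {
  bed <- match.arg(bed)
  if (bed == "systemic") (V - params$V_sv0) / params$C_sv
  else (V - params$V_pv0) / params$C_pv
}

#' Elastance driving function
#'
#' Piecewise activation: a half-sine rise/fall
#' `0.5 (sin(pi t / t_max - pi/2) + 1)` for `0 < t <= 3 t_max / 2`, then
#' exponential relaxation `0.5 exp(-(t - 3 t_max/2)/tau)`.  Continuous at the
#' switch, zero at `t = 0`, one at `t = t_max`; always in [0, 1].  Negative
#' times (before activation onset) give 0.
#'
#' @param t Time since activation onset, ms (vectorised).
#' @param params An [atrial_elastance_params()] object.
#' @return Dimensionless activation in [0, 1].
#' @export
activation_e <- function(t, params) {
  tm <- params$t_max; tau <- params$tau
  out <- numeric(length(t))
  rise <- t > 0 & t <= 1.5 * tm
  decay <- t > 1.5 * tm
  out[rise] <- 0.5 * (sin(pi * t[rise] / tm - pi / 2) + 1)
  out[decay] <- 0.5 * exp(-(t[decay] - 1.5 * tm) / tau)
  out
}

#' Atrial pressure from the time-varying elastance model
#'
#' @param V Atrial volume, ml.
#' @param t Time since atrial activation onset, ms.
#' @param params An [atrial_elastance_params()] object.
#' @return Pressure in Pa:
#'   `e(t) E_es (V - V_0) + (1 - e(t)) A (exp(B (V - V_0)) - 1)`.
#' @export
atrial_pressure <- function(V, t, params) {
  e <- activation_e(t, params)
  dv <- V - params$V_0
  e * params$E_es * dv + (1 - e) * params$A * (expm1(params$B * dv))
}

#' Construct a circulation state
#'
#' @param t Time since cycle start, ms.
#' @param V Named numeric of 8 compartment volumes (ml), names
#'   [compartment_names()].
#' @param P Named numeric of 8 compartment pressures (Pa); may be NA before
#'   the first pressure update.
#' @param q Named numeric of 8 segmental flows (ml/ms).
#' @return An object of class `circulation_state`.
#' @export
circulation_state <- function(t, V, P = NULL, q = NULL) {
  cn <- compartment_names(); fn <- flow_names()
  V <- V[cn]
  if (anyNA(V) || any(V <= 0))
    stop("all 8 compartment volumes must be given and positive", call. = FALSE)
  if (is.null(P)) P <- stats::setNames(rep(NA_real_, 8), cn) else P <- P[cn]
  if (is.null(q)) q <- stats::setNames(rep(0, 8), fn) else q <- q[fn]
  structure(list(t = t, V = V, P = P, q = q), class = "circulation_state")
}

#' Segmental flows from compartment pressures
#'
#' Applies the valve law to the four valves (mv, av, tv, pvv) and Ohm's law
#' to the four vessel segments (sa, sv, pa, pv).
#'
#' @param P Named pressures (Pa) for the 8 compartments.
#' @param params [circulation_params()].
#' @return Named flows, ml/ms.
#' @export
segment_flows <- function(P, params) {
  c(mv = valve_flow(P[["LA"]], P[["LV"]], params$R_mv),
    av = valve_flow(P[["LV"]], P[["sa"]], params$R_av),
    sa = resistive_flow(P[["sa"]], P[["sv"]], params$R_sa),
    sv = resistive_flow(P[["sv"]], P[["RA"]], params$R_sv),
    tv = valve_flow(P[["RA"]], P[["RV"]], params$R_tv),
    pvv = valve_flow(P[["RV"]], P[["pa"]], params$R_pvv),
    pa = resistive_flow(P[["pa"]], P[["pv"]], params$R_pa),
    pv = resistive_flow(P[["pv"]], P[["LA"]], params$R_pv))
}

#' Advance compartment volumes one explicit step
#'
#' Forward-Euler mass balance: each segmental flow leaves one compartment and
#' enters the next, so the total blood volume is conserved to machine
#' precision.
#'
#' @param state A [circulation_state()] whose flows were computed from its
#'   pressures.
#' @param dt Time step, ms.
#' @return A new `circulation_state` at `t + dt` with updated volumes
#'   (pressures unset, flows carried over for inspection).
#' @export
advance_volumes <- function(state, dt) {
  stopifnot(dt > 0)
  q <- state$q
  dV <- c(LV = q[["mv"]] - q[["av"]],
          sa = q[["av"]] - q[["sa"]],
          sv = q[["sa"]] - q[["sv"]],
          RA = q[["sv"]] - q[["tv"]],
          RV = q[["tv"]] - q[["pvv"]],
          pa = q[["pvv"]] - q[["pa"]],
          pv = q[["pa"]] - q[["pv"]],
          LA = q[["pv"]] - q[["mv"]])
  Vn <- state$V + dt * dV[compartment_names()]
  if (any(Vn <= 0)) {
    bad <- compartment_names()[which(Vn <= 0)]
    stop(sprintf(paste0("compartment volume driven non-positive in '%s' ",
                        "(explicit step unstable; reduce dt)"),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  circulation_state(state$t + dt, Vn, q = q)
}
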