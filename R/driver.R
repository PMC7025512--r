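# Closed-loop driver: explicit coupling of the eight-compartment lumped
# circulation with chamber/vessel models (time-varying elastance surrogates
# or finite-element models), scenario definitions and periodicity detection.
#
# Update order per step (explicit scheme): compartment volumes from the
# previous flows -> compartment pressures from the new volumes (elastance /
# venous / atrial relations, or FE solves at prescribed volumes) -> segment
# flows from the new pressures.

#' Unit conversion helpers
#'
#' @param x Pressure values.
#' @return Converted pressure (1 mmHg = 133.322 Pa).
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' @rdname pa_to_mmhg
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' Ventricular elastance surrogate parameters
#'
#' Same time-varying elastance form as the atria with ventricular defaults
#' (stiffer end-systolic elastance, slower activation).  Used when a
#' ventricle is simulated in `"elastance"` mode.
#'
#' @inheritParams atrial_elastance_params
#' @return An `elastance_params` object.
#' @export
ventricular_elastance_params <- function(E_es = 600, V_0 = 5, A = 60,
                                         B = 0.045, t_max = 250, tau = 45,
                                         onset = 0) {
  atrial_elastance_params(E_es = E_es, V_0 = V_0, A = A, B = B,
                          t_max = t_max, tau = tau, onset = onset)
}

#' Elastance-model pressure (shared atrial/ventricular form)
#'
#' @param V Volume, ml.
#' @param t Time since activation onset, ms.
#' @param params An `elastance_params` object.
#' @return Pressure, Pa.
#' @export
elastance_pressure <- function(V, t, params) atrial_pressure(V, t, params)

#' Default cardiac FE materials (LV free wall + septum vs RV free wall)
#'
#' Passive stress scales 280 / 170 Pa and contractilities 2000 / 1800 kPa
#' for the left/right groups; the active model runs on the ascending-limb
#' tension-length branch so that tension develops at operating sarcomere
#' lengths.
#'
#' @param T0_scale_rv Multiplier on the RV contractility (scenario hook).
#' @return Named list of material groups for [fe_chamber()].
#' @export
default_cardiac_materials <- function(T0_scale_rv = 1) {
  list(LV = list(passive = guccione_params(C = 280),
                 active = active_params(T_0 = 2000e3,
                                        iso_variant = "ascending")),
       RV = list(passive = guccione_params(C = 170),
                 active = active_params(T_0 = 1800e3 * T0_scale_rv,
                                        iso_variant = "ascending")))
}

#' Simulation configuration
#'
#' Assembles every parameter of the closed loop: cycle timing, the lumped
#' circulation, atrial elastances, the ventricle model (elastance surrogate
#' or FE biventricle) and the artery models (elastance surrogate, FE
#' response curve, or per-step FE solves).
#'
#' @param T_cyc Cycle length, ms (690 ms at the 87 bpm acquisition rate).
#' @param dt Time step, ms.
#' @param max_cycles Maximum cycles to run.
#' @param min_cycles Minimum cycles before periodicity can stop the run.
#' @param periodicity_tol Max absolute volume difference between
#'   consecutive cycles, ml.
#' @param circ [circulation_params()].
#' @param atria List with `LA`, `RA` [atrial_elastance_params()].
#' @param ventricle_mode `"elastance"` or `"fe"`.
#' @param ventricles List with `LV`, `RV` elastance surrogates.
#' @param bv List: `spec` ([bv_spec()]) or `mesh`, `materials`.
#' @param artery_mode `"elastance"`, `"fe_curve"` or `"fe_direct"`.
#' @param arteries List with `sa`, `pa` surrogate elastances
#'   (`C` ml/Pa, `V0` ml).
#' @param vessels List with `ao`, `pa`: each `spec` ([vessel_spec()]) or
#'   `mesh`, plus `material`.
#' @param total_volume Total blood volume, ml.
#' @param init_volumes Optional named vector of initial compartment volumes.
#' @param seed RNG seed recorded with the run (the loop itself is
#'   deterministic).
#' @return A `sim_config` object.
#' @export
sim_config <- function(T_cyc = 690, dt = 0.5, max_cycles = 40,
                       min_cycles = 3, periodicity_tol = 0.1,
                       circ = circulation_params(),
                       atria = list(LA = atrial_elastance_params(),
                                    RA = atrial_elastance_params()),
                       ventricle_mode = c("elastance", "fe"),
                       ventricles = list(
                         LV = ventricular_elastance_params(),
                         RV = ventricular_elastance_params(E_es = 380,
                                                           A = 50,
                                                           B = 0.042)),
                       bv = list(spec = bv_spec_coarse(),
                                 materials = default_cardiac_materials()),
                       artery_mode = c("elastance", "fe_curve", "fe_direct"),
                       arteries = list(sa = list(C = 0.012, V0 = 70),
                                       pa = list(C = 0.008, V0 = 40)),
                       vessels = list(
                         ao = list(spec = vessel_spec("cylinder",
                                                      radius = 12,
                                                      length = 120,
                                                      h = 2.0, n_theta = 16,
                                                      n_z = 8),
                                   material = aorta_material(h = 2.0)),
                         pa = list(spec = vessel_spec("cylinder",
                                                      radius = 13,
                                                      length = 100,
                                                      h = 1.5, n_theta = 16,
                                                      n_z = 8),
                                   material = pa_material(h = 1.5))),
                       total_volume = 5200, init_volumes = NULL, seed = 1L) {
  ventricle_mode <- match.arg(ventricle_mode)
  artery_mode <- match.arg(artery_mode)
  stopifnot(T_cyc > 0, dt > 0, max_cycles >= 1)
  steps <- round(T_cyc / dt)
  if (abs(steps * dt - T_cyc) > dt)
    stop("dt must divide the cycle length to within one step", call. = FALSE)
  structure(list(T_cyc = T_cyc, dt = dt, max_cycles = max_cycles,
                 min_cycles = min_cycles, periodicity_tol = periodicity_tol,
                 circ = circ, atria = atria,
                 ventricle_mode = ventricle_mode, ventricles = ventricles,
                 bv = bv, artery_mode = artery_mode, arteries = arteries,
                 vessels = vessels, total_volume = total_volume,
                 init_volumes = init_volumes, seed = as.integer(seed)),
            class = "sim_config")
}

#' Apply a PAH-progression scenario to a configuration
#'
#' * `collagen_increase`: PA collagen mass fraction 0.42 -> 0.70, elastin
#'   0.35 -> 0.15, SMC 0.23 -> 0.15 (fractions still sum to 1).
#' * `contractility_decrease`: RV contractility halved (1800 -> 900 kPa in
#'   the FE materials; the RV elastance surrogate is scaled by the same
#'   factor so the surrogate mode reproduces the sign of the effect).
#' * `resistance_increase`: pulmonary arterial resistance `R_pa` x 1.5.
#'
#' @param config A [sim_config()].
#' @param scenario One of `"none"`, `"collagen_increase"`,
#'   `"contractility_decrease"`, `"resistance_increase"`.
#' @return The modified configuration.
#' @export
apply_scenario <- function(config,
                           scenario = c("none", "collagen_increase",
                                        "contractility_decrease",
                                        "resistance_increase")) {
  scenario <- match.arg(scenario)
  if (scenario == "collagen_increase") {
    m <- config$vessels$pa$material
    config$vessels$pa$material <-
      vessel_wall_material(c_1 = m$c_1, c_2 = m$c_2, c_3 = m$c_3,
                           c_4 = m$c_4, c_5 = m$c_5,
                           phi_e = 0.15, phi_m = 0.15, phi_c = 0.70,
                           split = m$split, alpha = m$alpha, rho = m$rho,
                           h = m$h)
  } else if (scenario == "contractility_decrease") {
    a <- config$bv$materials$RV$active
    a$T_0 <- a$T_0 * 0.5
    config$bv$materials$RV$active <- a
    config$ventricles$RV$E_es <- config$ventricles$RV$E_es * 0.5
  } else if (scenario == "resistance_increase") {
    config$circ$R_pa <- config$circ$R_pa * 1.5
  }
  config$scenario <- scenario
  config
}

# default initial volume distribution
.init_volumes <- function(config, models) {
  if (!is.null(config$init_volumes)) return(config$init_volumes[compartment_names()])
  vLV <- 72; vRV <- 77
  if (config$ventricle_mode == "fe") {
    vLV <- models$bv_model$mesh$cavity_volumes[["LV"]]
    vRV <- models$bv_model$mesh$cavity_volumes[["RV"]]
  }
  if (config$artery_mode == "elastance") {
    vsa <- config$arteries$sa$V0 + 8000 * config$arteries$sa$C
    vpa <- config$arteries$pa$V0 + 4000 * config$arteries$pa$C
  } else if (config$artery_mode == "fe_curve") {
    # start each artery near a physiologic diastolic pressure on its curve
    vat <- function(curve, Ptgt) {
      rng <- curve$V_range
      if (curve$P(rng[2]) < Ptgt) return(rng[2])
      stats::uniroot(function(v) curve$P(v) - Ptgt, rng)$root
    }
    vsa <- vat(models$ao_curve, 8000)
    vpa <- vat(models$pa_curve, 5000)
  } else {
    vsa <- models$ao_ref * 1.25
    vpa <- models$pa_ref * 1.25
  }
  vpv <- config$circ$V_pv0 + 800 * config$circ$C_pv
  vLA <- 60; vRA <- 60
  vsv <- config$total_volume - (vLV + vRV + vLA + vRA + vsa + vpa + vpv)
  if (vsv <= 0) stop("total blood volume too small for the configured ",
                     "compartments", call. = FALSE)
  c(LV = vLV, sa = vsa, sv = vsv, RA = vRA, RV = vRV, pa = vpa, pv = vpv,
    LA = vLA)
}

# build runtime models from a config
.build_models <- function(config) {
  models <- list()
  if (config$ventricle_mode == "fe") {
    mesh <- config$bv$mesh
    if (is.null(mesh)) mesh <- make_biventricle(config$bv$spec)
    models$bv_model <- fe_chamber(mesh, config$bv$materials)
    models$bv_state <- .chamber_state0(models$bv_model)
    models$bv_cache <- new.env(parent = emptyenv())
  }
  if (config$artery_mode %in% c("fe_curve", "fe_direct")) {
    for (vn in c("ao", "pa")) {
      vs <- config$vessels[[vn]]
      mesh <- vs$mesh
      if (is.null(mesh)) mesh <- make_vessel(vs$spec)
      mdl <- fe_vessel(mesh, vs$material)
      models[[paste0(vn, "_model")]] <- mdl
      models[[paste0(vn, "_ref")]] <- mesh$ref_volume
      if (config$artery_mode == "fe_curve")
        models[[paste0(vn, "_curve")]] <-
          if (!is.null(vs$curve)) vs$curve else vessel_pv_curve(mdl)
      else
        models[[paste0(vn, "_state")]] <- .vessel_state0(mdl)
    }
  }
  models
}

# evaluate a monotone curve with linear extrapolation outside the ramp
.curve_eval <- function(curve, fn, V) {
  lo <- curve$V_range[1]; hi <- curve$V_range[2]
  if (V >= lo && V <= hi) return(fn(V))
  if (V > hi) {
    d <- (fn(hi) - fn(hi - 1e-3)) / 1e-3
    return(fn(hi) + d * (V - hi))
  }
  d <- (fn(lo + 1e-3) - fn(lo)) / 1e-3
  fn(lo) + d * (V - lo)
}

#' Run the closed-loop simulation
#'
#' Executes the explicit coupling loop until cycle-to-cycle periodicity of
#' all compartment volumes (or `max_cycles`).  Total blood volume is
#' conserved to machine precision by construction of the volume update.
#'
#' @param config A [sim_config()].
#' @param progress Print a per-cycle summary line.
#' @return A `simulation_record`: a tibble with one row per step (times in
#'   ms, volumes ml, pressures Pa, flows ml/ms, plus model-derived columns)
#'   with attributes `cycles` (per-cycle summary tibble), `config`,
#'   `converged`.
#' @export
run_closed_loop <- function(config, progress = FALSE) {
  set.seed(config$seed)
  models <- .build_models(config)
  V <- .init_volumes(config, models)
  steps <- round(config$T_cyc / config$dt)
  dt <- config$dt
  circ <- config$circ
  fe_vent <- config$ventricle_mode == "fe"
  amode <- config$artery_mode

  extras <- c("diam_pa", "diam_ao", "vm_pa_avg", "vm_pa_max", "vm_ao_avg",
              "vm_ao_max", "fs_lv", "fs_rv")
  nrec_cols <- 1 + 8 + 8 + 8 + length(extras) + 1
  rec <- vector("list", config$max_cycles)

  pressures <- function(V, t_cyc) {
    P <- stats::setNames(numeric(8), compartment_names())
    P[["sv"]] <- venous_pressure(V[["sv"]], circ, "systemic")
    P[["pv"]] <- venous_pressure(V[["pv"]], circ, "pulmonary")
    P[["LA"]] <- atrial_pressure(V[["LA"]], t_cyc - config$atria$LA$onset,
                                 config$atria$LA)
    P[["RA"]] <- atrial_pressure(V[["RA"]], t_cyc - config$atria$RA$onset,
                                 config$atria$RA)
    ex <- stats::setNames(rep(NA_real_, length(extras)), extras)
    if (fe_vent) {
      res <- solve_chamber_pressures(
        models$bv_model, c(LV = V[["LV"]], RV = V[["RV"]]), t_act = t_cyc,
        state = models$bv_state,
        control = list(cache = models$bv_cache, lagged_iters = 1000,
                       rtol = 1e-7, floor = 0.5, maxit = 80))
      # advance the contractile-element lengths with the explicit step
      st <- res$state
      act <- models$bv_model$act[models$bv_model$matid + 1, , drop = FALSE]
      st$lc <- st$lc + dt * ((act[, 8] * (res$ls - st$lc) - 1) * act[, 9])
      models$bv_state <<- st
      P[["LV"]] <- res$P[["LV"]]; P[["RV"]] <- res$P[["RV"]]
      fs <- fiber_stress_field(res, models$bv_model)
      ex["fs_lv"] <- fs$averages[["LV"]]; ex["fs_rv"] <- fs$averages[["RV"]]
    } else {
      P[["LV"]] <- elastance_pressure(V[["LV"]], t_cyc, config$ventricles$LV)
      P[["RV"]] <- elastance_pressure(V[["RV"]], t_cyc, config$ventricles$RV)
    }
    if (amode == "elastance") {
      P[["sa"]] <- (V[["sa"]] - config$arteries$sa$V0) / config$arteries$sa$C
      P[["pa"]] <- (V[["pa"]] - config$arteries$pa$V0) / config$arteries$pa$C
    } else if (amode == "fe_curve") {
      cv_ao <- models$ao_curve; cv_pa <- models$pa_curve
      P[["sa"]] <- .curve_eval(cv_ao, cv_ao$P, V[["sa"]])
      P[["pa"]] <- .curve_eval(cv_pa, cv_pa$P, V[["pa"]])
      ex["diam_ao"] <- .curve_eval(cv_ao, cv_ao$diam[[1]], V[["sa"]])
      ex["diam_pa"] <- .curve_eval(cv_pa, cv_pa$diam[[1]], V[["pa"]])
      ex["vm_ao_avg"] <- .curve_eval(cv_ao, cv_ao$vm_avg, V[["sa"]])
      ex["vm_pa_avg"] <- .curve_eval(cv_pa, cv_pa$vm_avg, V[["pa"]])
      ex["vm_ao_max"] <- .curve_eval(cv_ao, cv_ao$vm_max, V[["sa"]])
      ex["vm_pa_max"] <- .curve_eval(cv_pa, cv_pa$vm_max, V[["pa"]])
    } else {
      for (vn in c("ao", "pa")) {
        comp <- if (vn == "ao") "sa" else "pa"
        res <- solve_vessel_pressure(models[[paste0(vn, "_model")]],
                                     V[[comp]],
                                     state = models[[paste0(vn, "_state")]])
        models[[paste0(vn, "_state")]] <<- res$state
        P[[comp]] <- res$P
        vmf <- von_mises_field(res, models[[paste0(vn, "_model")]])
        ex[paste0("vm_", vn, "_avg")] <- vmf$average
        ex[paste0("vm_", vn, "_max")] <- vmf$max
        ex[paste0("diam_", vn)] <-
          diameter_at_slice(models[[paste0(vn, "_model")]]$mesh, res$u, 1)
      }
    }
    list(P = P, ex = ex)
  }

  pe <- pressures(V, 0)
  q <- segment_flows(pe$P, circ)
  state <- circulation_state(0, V, pe$P, q)
  total0 <- sum(V)

  cycles <- list()
  prev_cycle_V <- NULL
  converged <- FALSE
  t_abs <- 0
  for (cyc in seq_len(config$max_cycles)) {
    mat <- matrix(NA_real_, steps, nrec_cols)
    Vtrace <- matrix(NA_real_, steps, 8)
    for (s in seq_len(steps)) {
      t_cyc <- (s - 1) * dt
      state <- advance_volumes(state, dt)
      pe <- pressures(state$V, t_cyc)
      state$P <- pe$P[compartment_names()]
      state$q <- segment_flows(state$P, circ)
      t_abs <- t_abs + dt
      mat[s, ] <- c(t_abs, state$V, state$P, state$q, pe$ex, cyc)
      Vtrace[s, ] <- state$V
    }
    rec[[cyc]] <- mat
    # cycle summary
    Vlv <- Vtrace[, 1]; Vrv <- Vtrace[, 5]
    delta <- if (is.null(prev_cycle_V)) NA_real_
    else max(abs(Vtrace - prev_cycle_V))
    cycles[[cyc]] <- tibble::tibble(
      cycle = cyc, LVEDV = max(Vlv), LVESV = min(Vlv), RVEDV = max(Vrv),
      RVESV = min(Vrv),
      LVEF = (max(Vlv) - min(Vlv)) / max(Vlv) * 100,
      RVEF = (max(Vrv) - min(Vrv)) / max(Vrv) * 100,
      max_delta_ml = delta,
      total_volume_drift = abs(sum(Vtrace[steps, ]) - total0) / total0)
    if (progress)
      message(sprintf("cycle %d: LVEF %.1f%% RVEF %.1f%% delta %.3f ml",
                      cyc, cycles[[cyc]]$LVEF, cycles[[cyc]]$RVEF, delta))
    if (!is.null(prev_cycle_V) && cyc >= config$min_cycles &&
        is.finite(delta) && delta < config$periodicity_tol) {
      converged <- TRUE
      prev_cycle_V <- Vtrace
      break
    }
    prev_cycle_V <- Vtrace
  }

  used <- which(!vapply(rec, is.null, logical(1)))
  big <- do.call(rbind, rec[used])
  colnames(big) <- c("time_ms", paste0("V_", compartment_names()),
                     paste0("P_", compartment_names()),
                     paste0("q_", flow_names()), extras, "cycle")
  out <- tibble::as_tibble(big)
  drop_na_cols <- extras[vapply(extras, function(cn) all(is.na(out[[cn]])),
                                logical(1))]
  out <- out[, setdiff(names(out), drop_na_cols)]
  attr(out, "cycles") <- dplyr::bind_rows(cycles)
  attr(out, "config") <- config
  attr(out, "converged") <- converged
  attr(out, "total_volume0") <- total0
  class(out) <- c("simulation_record", class(out))
  out
}

#' Cycle-to-cycle periodicity check
#'
#' Maximum absolute difference of each compartment volume trace between the
#' two last complete cycles.
#'
#' @param record A `simulation_record` with at least 2 cycles.
#' @param tol Convergence tolerance, ml.
#' @return List with `converged` and the named per-compartment `deltas`
#'   (ml).
#' @export
check_periodicity <- function(record, tol = 0.1) {
  cyc <- record$cycle
  last <- max(cyc)
  if (last < 2) stop("need at least two completed cycles", call. = FALSE)
  vcols <- paste0("V_", compartment_names())
  a <- as.matrix(record[cyc == last - 1, vcols])
  b <- as.matrix(record[cyc == last, vcols])
  n <- min(nrow(a), nrow(b))
  deltas <- apply(abs(a[seq_len(n), ] - b[seq_len(n), ]), 2, max)
  names(deltas) <- compartment_names()
  list(converged = all(deltas < tol), deltas = deltas)
}

#' Percent diameter change equivalent to a resistance ratio (Poiseuille)
#'
#' With resistance scaling as the inverse fourth power of lumen diameter,
#' a resistance ratio r corresponds to a `(1 - r^(-1/4)) * 100` percent
#' reduction in diameter (about 10% for a 1.5x resistance increase).
#'
#' @param resistance_ratio New/old resistance ratio (> 0).
#' @return Percent diameter reduction.
#' @export
poiseuille_diameter_equivalent <- function(resistance_ratio) {
  stopifnot(resistance_ratio > 0)
  (1 - resistance_ratio^(-1 / 4)) * 100
}

#' @export
#' @method print simulation_record
print.simulation_record <- function(x, ...) {
  cyc <- attr(x, "cycles")
  cat(sprintf("Closed-loop simulation: %d cycles, %s\n", max(x$cycle),
              if (isTRUE(attr(x, "converged"))) "periodic" else
                "not yet periodic"))
  last <- cyc[nrow(cyc), ]
  cat(sprintf("  last cycle: LVEF %.1f%%, RVEF %.1f%%, max delta %.3f ml\n",
              last$LVEF, last$RVEF, last$max_delta_ml))
  NextMethod()
}
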