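# Structured configuration files (JSON or YAML) with explicit unit strings
# validated at load time.  Keys mirror the model parameter names
# (R_sa, C_pv, E_es, T_0, c_1, phi_c, ...).

.unit_table <- c(
  R_mv = "Pa.ms/ml", R_av = "Pa.ms/ml", R_tv = "Pa.ms/ml",
  R_pvv = "Pa.ms/ml", R_sa = "Pa.ms/ml", R_sv = "Pa.ms/ml",
  R_pa = "Pa.ms/ml", R_pv = "Pa.ms/ml",
  C_sv = "ml/Pa", C_pv = "ml/Pa", V_sv0 = "ml", V_pv0 = "ml",
  E_es = "Pa/ml", V_0 = "ml", A = "Pa", B = "1/ml", t_max = "ms",
  tau = "ms", onset = "ms",
  C = "Pa", b_ff = "1", b_xx = "1", b_fx = "1",
  T_0 = "Pa", t_r = "ms", t_d = "ms", b = "ms/um", l_d = "um",
  a_6 = "1/um", a_7 = "um", E_a = "1/um", v_0 = "um/ms", l_s0 = "um",
  c_1 = "Pa", c_2 = "Pa", c_3 = "1", c_4 = "Pa", c_5 = "1",
  phi_e = "1", phi_m = "1", phi_c = "1", alpha = "deg", rho = "1",
  h = "mm", T_cyc = "ms", dt = "ms", total_volume = "ml")

.read_cfg_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# a parameter entry is either a bare number (assumed internal units) or a
# list/record with `value` and `unit`; the unit string must match the table
.cfg_value <- function(entry, key) {
  if (is.numeric(entry) && length(entry) == 1) return(entry)
  if (is.list(entry) && !is.null(entry$value)) {
    exp_unit <- .unit_table[[key]]
    if (!is.null(entry$unit) && !is.null(exp_unit) &&
        !identical(entry$unit, exp_unit))
      stop(sprintf("parameter '%s' has unit '%s'; expected '%s'", key,
                   entry$unit, exp_unit), call. = FALSE)
    return(entry$value)
  }
  stop(sprintf("cannot parse parameter '%s'", key), call. = FALSE)
}

.cfg_section <- function(section, keys) {
  vals <- list()
  for (k in intersect(names(section), keys))
    vals[[k]] <- .cfg_value(section[[k]], k)
  vals
}

#' Read a simulation configuration file
#'
#' JSON or YAML (by extension).  Recognized sections: `sim` (T_cyc, dt,
#' max_cycles, total_volume, ventricle_mode, artery_mode, scenario),
#' `circulation`, `left_atrium` / `right_atrium`,
#' `lv_freewall_septum` / `rv_freewall` (each with `passive` and `active`
#' blocks), `aorta` / `pulmonary_artery` (wall constituents).  Numeric
#' entries may be bare (internal units: Pa, ml, ms) or
#' `{value: ..., unit: "..."}` with the unit validated.
#'
#' @param path Configuration file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- .read_cfg_file(path)
  args <- list()
  if (!is.null(raw$sim)) {
    s <- raw$sim
    for (k in c("T_cyc", "dt", "max_cycles", "periodicity_tol",
                "total_volume", "seed"))
      if (!is.null(s[[k]])) args[[k]] <- .cfg_value(s[[k]], k)
    if (!is.null(s$ventricle_mode)) args$ventricle_mode <- s$ventricle_mode
    if (!is.null(s$artery_mode)) args$artery_mode <- s$artery_mode
  }
  if (!is.null(raw$circulation))
    args$circ <- do.call(circulation_params,
                         .cfg_section(raw$circulation, names(formals(
                           circulation_params))))
  at <- list(LA = atrial_elastance_params(), RA = atrial_elastance_params())
  for (nm in c("left_atrium", "right_atrium")) {
    if (!is.null(raw[[nm]])) {
      key <- if (nm == "left_atrium") "LA" else "RA"
      at[[key]] <- do.call(atrial_elastance_params,
                           .cfg_section(raw[[nm]], names(formals(
                             atrial_elastance_params))))
    }
  }
  args$atria <- at
  mats <- default_cardiac_materials()
  for (nm in c("lv_freewall_septum", "rv_freewall")) {
    if (!is.null(raw[[nm]])) {
      key <- if (nm == "lv_freewall_septum") "LV" else "RV"
      blk <- raw[[nm]]
      if (!is.null(blk$passive))
        mats[[key]]$passive <- do.call(guccione_params,
                                       .cfg_section(blk$passive,
                                                    names(formals(
                                                      guccione_params))))
      if (!is.null(blk$active)) {
        aa <- .cfg_section(blk$active, names(formals(active_params)))
        if (!is.null(blk$active$iso_variant))
          aa$iso_variant <- blk$active$iso_variant
        mats[[key]]$active <- do.call(active_params, aa)
      }
    }
  }
  vess <- NULL
  for (nm in c("aorta", "pulmonary_artery")) {
    if (!is.null(raw[[nm]])) {
      key <- if (nm == "aorta") "ao" else "pa"
      wk <- .cfg_section(raw[[nm]], names(formals(vessel_wall_material)))
      base <- if (key == "ao") aorta_material else pa_material
      if (is.null(vess)) vess <- formals(sim_config)$vessels
      vess <- eval(vess)
      vess[[key]]$material <- do.call(base, wk)
    }
  }
  cfg <- do.call(sim_config, args)
  cfg$bv$materials <- mats
  if (!is.null(vess)) cfg$vessels <- vess
  if (!is.null(raw$sim$scenario))
    cfg <- apply_scenario(cfg, raw$sim$scenario)
  cfg
}

#' Write a simulation configuration file
#'
#' Writes the scalar parameter sections of a configuration (with unit
#' strings) as JSON or YAML by extension.
#'
#' @param config A [sim_config()].
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  wrap <- function(vals) {
    out <- list()
    for (k in names(vals)) {
      if (!is.numeric(vals[[k]]) || length(vals[[k]]) != 1) next
      u <- .unit_table[[k]]
      out[[k]] <- if (is.null(u)) vals[[k]] else
        list(value = unclass(vals[[k]]), unit = u)
    }
    out
  }
  obj <- list(
    sim = list(T_cyc = list(value = config$T_cyc, unit = "ms"),
               dt = list(value = config$dt, unit = "ms"),
               max_cycles = config$max_cycles,
               total_volume = list(value = config$total_volume, unit = "ml"),
               ventricle_mode = config$ventricle_mode,
               artery_mode = config$artery_mode),
    circulation = wrap(unclass(config$circ)),
    left_atrium = wrap(unclass(config$atria$LA)),
    right_atrium = wrap(unclass(config$atria$RA)),
    lv_freewall_septum = list(
      passive = wrap(unclass(config$bv$materials$LV$passive)),
      active = wrap(unclass(config$bv$materials$LV$active))),
    rv_freewall = list(
      passive = wrap(unclass(config$bv$materials$RV$passive)),
      active = wrap(unclass(config$bv$materials$RV$active))),
    aorta = wrap(unclass(config$vessels$ao$material)),
    pulmonary_artery = wrap(unclass(config$vessels$pa$material)))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}
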