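# Hemodynamic metrics, PAH classification and tidy/glance methods.

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param edv,esv Volumes (same units).
#' @return EF in percent, `(EDV - ESV)/EDV * 100`.
#' @export
ef_percent <- function(edv, esv) {
  stopifnot(edv > 0, esv >= 0, esv <= edv)
  (edv - esv) / edv * 100
}

#' Coefficient of determination of a simulated series against a reference
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the simulated series linearly
#' interpolated onto the reference time points.
#'
#' @param t_sim,y_sim Simulated time (ms) and values.
#' @param t_ref,y_ref Reference time and values.
#' @return R-squared (can be negative for a poor fit).
#' @export
r_squared <- function(t_sim, y_sim, t_ref, y_ref) {
  yi <- stats::approx(t_sim, y_sim, xout = t_ref, rule = 2)$y
  1 - sum((yi - y_ref)^2) / sum((y_ref - mean(y_ref))^2)
}

#' Hemodynamic metrics of a periodic cycle
#'
#' Computes, from the last complete cycle of a simulation record: EDV, ESV,
#' SV and EF per ventricle; systolic/diastolic/mean/pulse pressures per
#' artery (mmHg); mPAP; cardiac output; and the PAH classification triad
#' (mPAP >= 20 mmHg, PCWP <= 15 mmHg, PVR >= 3 WU).  PCWP defaults to the
#' mean pulmonary venous pressure of the cycle; PVR is
#' `(mPAP - PCWP) / CO` in Wood units unless supplied.
#'
#' @param record A `simulation_record`.
#' @param reference Optional list with `t`, `V_LV`, `P_LV`, ... series to
#'   compute R-squared values against.
#' @param pcwp Optional measured wedge pressure, mmHg.
#' @param pvr Optional measured pulmonary vascular resistance, WU.
#' @return A `metrics_report` (list; see [tidy.metrics_report()]).
#' @export
hemodynamic_metrics <- function(record, reference = NULL, pcwp = NULL,
                                pvr = NULL) {
  cyc <- record$cycle
  last <- record[cyc == max(cyc), ]
  T_cyc <- attr(record, "config")$T_cyc
  mm <- function(x) pa_to_mmhg(x)
  vent <- function(v) {
    edv <- max(v); esv <- min(v)
    c(EDV = edv, ESV = esv, SV = edv - esv, EF = ef_percent(edv, esv))
  }
  art <- function(p) {
    c(sys = mm(max(p)), dia = mm(min(p)), mean = mm(mean(p)),
      pulse = mm(max(p) - min(p)))
  }
  lv <- vent(last$V_LV); rv <- vent(last$V_RV)
  lv_psys <- mm(max(last$P_LV)); rv_psys <- mm(max(last$P_RV))
  ao <- art(last$P_sa); pa <- art(last$P_pa)
  mpap <- pa[["mean"]]
  co <- rv[["SV"]] * (60000 / T_cyc) / 1000    # L/min
  pcwp_v <- if (is.null(pcwp)) mm(mean(last$P_pv)) else pcwp
  pvr_v <- if (is.null(pvr)) (mpap - pcwp_v) / co else pvr
  flags <- c(mpap_ge_20 = mpap >= 20, pcwp_le_15 = pcwp_v <= 15,
             pvr_ge_3 = pvr_v >= 3)
  r2 <- NULL
  if (!is.null(reference)) {
    r2 <- vapply(setdiff(names(reference), "t"), function(nm)
      r_squared(last$time_ms - min(last$time_ms), last[[nm]],
                reference$t, reference[[nm]]), numeric(1))
  }
  structure(list(LV = lv, RV = rv, LV_Psys = lv_psys, RV_Psys = rv_psys,
                 AO = ao, PA = pa, mPAP = mpap, CO = co,
                 PCWP = pcwp_v, PVR = pvr_v, pah_flags = flags,
                 pah = all(flags), r_squared = r2,
                 rv_lv_edv_ratio = rv[["EDV"]] / lv[["EDV"]]),
            class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  cat("Hemodynamic metrics (last cycle)\n")
  cat(sprintf("  LV: EDV %.1f ml ESV %.1f ml EF %.1f%%\n",
              x$LV["EDV"], x$LV["ESV"], x$LV["EF"]))
  cat(sprintf("  RV: EDV %.1f ml ESV %.1f ml EF %.1f%%\n",
              x$RV["EDV"], x$RV["ESV"], x$RV["EF"]))
  cat(sprintf("  peak pressures: LV %.0f mmHg, RV %.0f mmHg\n",
              x$LV_Psys, x$RV_Psys))
  cat(sprintf("  AO: %.0f/%.0f mmHg (pulse %.0f)\n", x$AO["sys"],
              x$AO["dia"], x$AO["pulse"]))
  cat(sprintf("  PA: %.0f/%.0f mmHg (pulse %.0f), mPAP %.0f mmHg\n",
              x$PA["sys"], x$PA["dia"], x$PA["pulse"], x$mPAP))
  cat(sprintf("  CO %.2f L/min, PCWP %.1f mmHg, PVR %.1f WU -> %s\n",
              x$CO, x$PCWP, x$PVR,
              if (x$pah) "meets PAH criteria" else "below PAH criteria"))
  invisible(x)
}

#' Tidy a metrics report into a long tibble
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with columns `quantity`, `value`, `unit`.
#' @export
tidy.metrics_report <- function(x, ...) {
  rows <- list(
    tibble::tibble(quantity = paste0("LV_", names(x$LV)), value = unname(x$LV),
                   unit = c("ml", "ml", "ml", "%")),
    tibble::tibble(quantity = paste0("RV_", names(x$RV)), value = unname(x$RV),
                   unit = c("ml", "ml", "ml", "%")),
    tibble::tibble(quantity = paste0("AO_", names(x$AO)), value = unname(x$AO),
                   unit = "mmHg"),
    tibble::tibble(quantity = paste0("PA_", names(x$PA)), value = unname(x$PA),
                   unit = "mmHg"),
    tibble::tibble(quantity = c("LV_Psys", "RV_Psys", "mPAP", "CO", "PCWP",
                                "PVR", "RVEDV_LVEDV"),
                   value = c(x$LV_Psys, x$RV_Psys, x$mPAP, x$CO, x$PCWP,
                             x$PVR, x$rv_lv_edv_ratio),
                   unit = c("mmHg", "mmHg", "mmHg", "L/min", "mmHg", "WU",
                            "")))
  if (!is.null(x$r_squared))
    rows <- c(rows, list(tibble::tibble(
      quantity = paste0("R2_", names(x$r_squared)),
      value = unname(x$r_squared), unit = "")))
  dplyr::bind_rows(rows)
}

#' One-row summary of a metrics report
#'
#' @inheritParams tidy.metrics_report
#' @return One-row tibble with the headline quantities.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(LVEF = x$LV[["EF"]], RVEF = x$RV[["EF"]],
                 AO_sys = x$AO[["sys"]], PA_sys = x$PA[["sys"]],
                 PA_pulse = x$PA[["pulse"]], mPAP = x$mPAP, CO = x$CO,
                 PVR = x$PVR, pah = x$pah)
}

#' Tidy a simulation record into long format
#'
#' @param x A `simulation_record`.
#' @param ... Unused.
#' @return Long tibble with `time_ms`, `cycle`, `variable`, `value`.
#' @export
tidy.simulation_record <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = -c("time_ms", "cycle"),
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a simulation record
#'
#' @inheritParams tidy.simulation_record
#' @return One-row tibble (cycles run, periodicity, last-cycle EFs).
#' @export
glance.simulation_record <- function(x, ...) {
  cyc <- attr(x, "cycles")
  last <- cyc[nrow(cyc), ]
  tibble::tibble(cycles = max(x$cycle),
                 converged = isTRUE(attr(x, "converged")),
                 LVEF = last$LVEF, RVEF = last$RVEF,
                 max_delta_ml = last$max_delta_ml,
                 volume_drift = last$total_volume_drift)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
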