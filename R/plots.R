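# ggplot2 visualization of simulation records, vessel response curves and
# metric comparisons.

#' Plot a simulation record
#'
#' @param object A `simulation_record`.
#' @param type One of `"pressures"`, `"volumes"`, `"flows"`, `"pv"`
#'   (pressure-volume loops of the ventricles), `"diameters"`,
#'   `"stresses"`.
#' @param last_cycle Restrict to the final cycle (default TRUE except for
#'   `"volumes"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_record <- function(object,
                                       type = c("pressures", "volumes",
                                                "flows", "pv", "diameters",
                                                "stresses"),
                                       last_cycle = NULL, ...) {
  type <- match.arg(type)
  if (is.null(last_cycle)) last_cycle <- type != "volumes"
  d <- tibble::as_tibble(object)
  if (last_cycle) d <- d[d$cycle == max(d$cycle), ]
  d$t <- d$time_ms - min(d$time_ms)
  mm <- 133.322
  if (type == "pv") {
    pv <- dplyr::bind_rows(
      tibble::tibble(chamber = "LV", V = d$V_LV, P = d$P_LV / mm),
      tibble::tibble(chamber = "RV", V = d$V_RV, P = d$P_RV / mm))
    return(ggplot2::ggplot(pv, ggplot2::aes(.data$V, .data$P,
                                            colour = .data$chamber)) +
             ggplot2::geom_path() +
             ggplot2::labs(x = "Volume (ml)", y = "Pressure (mmHg)",
                           colour = NULL, title = "Ventricular PV loops") +
             ggplot2::theme_minimal())
  }
  sel <- switch(type,
                pressures = grep("^P_", names(d), value = TRUE),
                volumes = grep("^V_", names(d), value = TRUE),
                flows = grep("^q_", names(d), value = TRUE),
                diameters = grep("^diam_", names(d), value = TRUE),
                stresses = grep("^(vm|fs)_", names(d), value = TRUE))
  if (length(sel) == 0) stop("record has no '", type, "' columns",
                             call. = FALSE)
  long <- tidyr::pivot_longer(d[, c("t", sel)], -"t",
                              names_to = "variable", values_to = "value")
  ylab <- switch(type, pressures = "Pressure (mmHg)",
                 volumes = "Volume (ml)", flows = "Flow (ml/ms)",
                 diameters = "Diameter (mm)", stresses = "Stress (kPa)")
  if (type == "pressures") long$value <- long$value / mm
  if (type == "stresses") long$value <- long$value / 1000
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time in cycle (ms)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a vessel pressure-volume response curve
#'
#' @param object A `vessel_pv_curve`.
#' @param ... Unused.
#' @return A ggplot object (pressure in mmHg vs volume).
#' @export
autoplot.vessel_pv_curve <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(.data$V, .data$P / 133.322)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Cavity volume (ml)", y = "Pressure (mmHg)",
                  title = "Vessel FE inflation response") +
    ggplot2::theme_minimal()
}

#' Ventricular pressure-volume loop plot
#'
#' Convenience wrapper around [autoplot.simulation_record()] with
#' `type = "pv"`.
#'
#' @param record A `simulation_record`.
#' @return A ggplot object.
#' @export
plot_pv_loops <- function(record) {
  autoplot.simulation_record(record, type = "pv")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
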