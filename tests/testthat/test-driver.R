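# Closed-loop driver: periodicity, conservation, step-size robustness,
# scenarios, metrics and reproducibility.

test_that("the surrogate loop reaches cycle-to-cycle periodicity", {
  rec <- baseline_surrogate_run()
  expect_true(attr(rec, "converged"))
  expect_lte(max(rec$cycle), 30)
  cp <- check_periodicity(rec, tol = 0.1)
  expect_true(cp$converged)
  expect_named(cp$deltas, compartment_names())
  # periodicity deltas shrink monotonically once the transient dies out
  d <- attr(rec, "cycles")$max_delta_ml
  d <- d[-(1:3)]
  expect_true(all(diff(d) < 0))
})

test_that("total blood volume is conserved through the whole run", {
  rec <- baseline_surrogate_run()
  expect_gte(max(rec$cycle), 10)
  vcols <- paste0("V_", compartment_names())
  tot <- rowSums(as.matrix(tibble::as_tibble(rec)[, vcols]))
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
})

test_that("halving the time step barely changes the stroke volume", {
  run_sv <- function(dt) {
    cfg <- sim_config(dt = dt, max_cycles = 6, min_cycles = 6)
    rec <- run_closed_loop(cfg)
    cyc <- attr(rec, "cycles")
    cyc$LVEDV[6] - cyc$LVESV[6]
  }
  sv1 <- run_sv(0.5)
  sv2 <- run_sv(0.25)
  expect_lt(abs(sv1 - sv2) / sv1, 0.01)
})

test_that("periodicity check flags identical and perturbed cycles", {
  cn <- compartment_names()
  base <- tibble::tibble(time_ms = seq_len(20), cycle = rep(1:2, each = 10))
  for (k in seq_along(cn)) base[[paste0("V_", cn[k])]] <- rep(50 + k, 20)
  rec <- structure(base, class = c("simulation_record", class(base)))
  attr(rec, "config") <- list(T_cyc = 10)
  cp <- check_periodicity(rec, tol = 0.1)
  expect_true(cp$converged)
  expect_equal(unname(cp$deltas), rep(0, 8))
  rec2 <- rec
  rec2$V_sv[rec2$cycle == 2] <- rec2$V_sv[rec2$cycle == 2] + 1
  expect_false(check_periodicity(rec2, tol = 0.1)$converged)
  expect_error(check_periodicity(rec[rec$cycle == 1, ]), "two completed")
})

test_that("scenarios modify exactly the advertised parameters", {
  cfg <- sim_config()
  expect_identical(apply_scenario(cfg, "none")$circ, cfg$circ)
  c1 <- apply_scenario(cfg, "collagen_increase")
  m <- c1$vessels$pa$material
  expect_equal(m$phi_c, 0.70)
  expect_equal(m$phi_e, 0.15)
  expect_equal(m$phi_m, 0.15)
  expect_equal(m$phi_e + m$phi_m + m$phi_c, 1)
  expect_identical(c1$circ, cfg$circ)
  c2 <- apply_scenario(cfg, "contractility_decrease")
  expect_equal(c2$bv$materials$RV$active$T_0, 900e3)
  expect_equal(c2$bv$materials$LV$active$T_0, cfg$bv$materials$LV$active$T_0)
  c3 <- apply_scenario(cfg, "resistance_increase")
  expect_equal(c3$circ$R_pa, cfg$circ$R_pa * 1.5)
  expect_identical(c3$vessels, cfg$vessels)
})

test_that("hemodynamic metrics reproduce the textbook definitions", {
  # synthetic two-cycle record with a known EDV/ESV and flat PA pressure
  n <- 101      # odd count puts the volume minimum exactly on the grid
  v_lv <- 25 + (72 - 25) * (1 + cos(seq(0, 2 * pi, length.out = n))) / 2
  v_rv <- 30 + (77 - 30) * (1 + cos(seq(0, 2 * pi, length.out = n))) / 2
  d <- tibble::tibble(time_ms = seq_len(n), cycle = 1,
                      V_LV = v_lv, V_RV = v_rv,
                      P_LV = 10000 * sin(seq(0, pi, length.out = n)),
                      P_RV = 8000 * sin(seq(0, pi, length.out = n)),
                      P_sa = 12000, P_pa = mmhg_to_pa(59),
                      P_pv = mmhg_to_pa(6),
                      V_sa = 100, V_sv = 4000, V_RA = 50, V_pa = 80,
                      V_pv = 600, V_LA = 50)
  rec <- structure(d, class = c("simulation_record", class(d)))
  attr(rec, "config") <- list(T_cyc = 690)
  m <- hemodynamic_metrics(rec, pcwp = 6)
  expect_equal(m$LV[["EF"]], ef_percent(72, 25), tolerance = 1e-6)
  expect_equal(m$RV[["EF"]], ef_percent(77, 30), tolerance = 1e-6)
  expect_equal(m$PA[["pulse"]], 0)       # constant PA trace
  expect_equal(m$mPAP, 59, tolerance = 1e-9)
  expect_true(m$pah_flags[["mpap_ge_20"]])
  expect_true(m$pah_flags[["pcwp_le_15"]])
  expect_true(m$pah)                     # PVR = (59-6)/CO >= 3 WU here
  expect_equal(m$rv_lv_edv_ratio, 77 / 72, tolerance = 1e-6)
  td <- tidy(m)
  expect_true(all(c("quantity", "value", "unit") %in% names(td)))
  expect_equal(td$value[td$quantity == "LV_EF"], ef_percent(72, 25),
               tolerance = 1e-6)
})

test_that("identical configurations give bit-identical records", {
  cfg <- sim_config(max_cycles = 4, min_cycles = 4)
  r1 <- run_closed_loop(cfg)
  r2 <- run_closed_loop(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("R-squared against a reference series behaves sanely", {
  t <- seq(0, 690, by = 5)
  y <- sin(t / 100)
  expect_equal(r_squared(t, y, t, y), 1)
  expect_lt(r_squared(t, y, t, rev(y)), 1)
})

test_that("per-step vessel FE solves can replace the response curve", {
  # a short run exercising the fe_direct path end to end
  cfg <- sim_config(T_cyc = 30, dt = 5, max_cycles = 1, min_cycles = 1,
                    artery_mode = "fe_direct",
                    vessels = list(
                      ao = list(spec = vessel_spec("cylinder", radius = 12,
                                                   length = 120, h = 2.0,
                                                   n_theta = 12, n_z = 4),
                                material = aorta_material(h = 2.0)),
                      pa = list(spec = vessel_spec("cylinder", radius = 13,
                                                   length = 100, h = 1.5,
                                                   n_theta = 12, n_z = 4),
                                material = pa_material(h = 1.5))))
  rec <- run_closed_loop(cfg)
  expect_true(all(is.finite(rec$P_sa)))
  expect_true(all(c("vm_pa_avg", "diam_pa") %in% names(rec)))
  expect_true(all(rec$diam_pa > 0))
})

test_that("autoplot and tidy methods return the expected structures", {
  rec <- baseline_surrogate_run()
  expect_s3_class(autoplot(rec, "pressures"), "ggplot")
  expect_s3_class(autoplot(rec, "pv"), "ggplot")
  expect_s3_class(plot_pv_loops(rec), "ggplot")
  long <- tidy(rec)
  expect_true(all(c("time_ms", "cycle", "variable", "value") %in%
                    names(long)))
  g <- glance(rec)
  expect_equal(nrow(g), 1)
  expect_true(g$converged)
})

test_that("configuration files round-trip with validated units", {
  cfg <- sim_config()
  f <- tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$circ, cfg$circ)
  expect_equal(cfg2$atria$LA$E_es, cfg$atria$LA$E_es)
  expect_equal(cfg2$bv$materials$RV$active$T_0,
               cfg$bv$materials$RV$active$T_0)
  # wrong unit string is rejected
  raw <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  raw$circulation$R_sa$unit <- "dyn.s/cm5"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, f2, auto_unbox = TRUE)
  expect_error(read_sim_config(f2), "unit")
  unlink(c(f, f2))
  # YAML path
  fy <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, fy)
  expect_equal(read_sim_config(fy)$circ$R_pa, cfg$circ$R_pa)
  unlink(fy)
})
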