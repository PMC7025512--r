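# Lumped-circulation elements: valves, resistances, venous compliances,
# atrial elastance, explicit volume update.

test_that("valve flow behaves as a diode resistor", {
  expect_equal(valve_flow(100, 200, 1000), 0)          # reverse gradient
  expect_equal(valve_flow(150, 150, 1000), 0)          # zero gradient
  # 900 Pa across 0.9 kPa*ms/ml -> 1 ml/ms
  expect_equal(valve_flow(1900, 1000, 900), 1)
  expect_error(valve_flow(1, 0, 0), "positive")
  expect_error(valve_flow(1, 0, -2), "positive")
  # never negative over random pressure pairs
  set.seed(1)
  p1 <- rnorm(100, 0, 1e4); p2 <- rnorm(100, 0, 1e4)
  expect_true(all(valve_flow(p1, p2, 500) >= 0))
})

test_that("resistive flow is linear and signed", {
  # 12.5 kPa over R_sa = 125 kPa*ms/ml -> 0.1 ml/ms
  expect_equal(resistive_flow(12500 + 100, 100, 125000), 0.1)
  expect_equal(resistive_flow(5, 5, 10), 0)
  expect_equal(resistive_flow(0, 1000, 2000), -0.5)
  expect_error(resistive_flow(1, 0, 0), "positive")
})

test_that("venous pressure is linear in volume", {
  p <- circulation_params(C_sv = 25, V_sv0 = 3570, C_pv = 0.15, V_pv0 = 485)
  expect_equal(venous_pressure(3570, p, "systemic"), 0)
  expect_equal(venous_pressure(3620, p, "systemic"), 2)   # 50 ml / 25 ml/Pa
  expect_equal(venous_pressure(3670, p, "systemic"),
               2 * venous_pressure(3620, p, "systemic"))
  expect_equal(venous_pressure(485 + 30, p, "pulmonary"), 30 / 0.15)
})

test_that("activation function matches its closed form and is continuous", {
  ap <- atrial_elastance_params(t_max = 135, tau = 50)
  expect_equal(activation_e(0, ap), 0)
  expect_equal(activation_e(135, ap), 1)
  # both branches at the switch give 1/2; decay one tau later gives e^-1/2
  expect_equal(activation_e(202.5, ap), 0.5)
  expect_equal(activation_e(252.5, ap), 0.5 * exp(-1), tolerance = 1e-12)
  eps <- 1e-9
  expect_lt(abs(activation_e(202.5 - eps, ap) -
                  activation_e(202.5 + eps, ap)), 1e-7)
  tt <- seq(0, 2000, by = 0.25)
  ee <- activation_e(tt, ap)
  expect_true(all(ee >= 0 & ee <= 1))
})

test_that("atrial pressure combines ESPVR and EDPVR branches", {
  ap <- atrial_elastance_params(E_es = 60, V_0 = 10, A = 58.67, B = 0.049,
                                t_max = 135, tau = 50)
  for (tt in c(0, 60, 135, 300))
    expect_equal(atrial_pressure(10, tt, ap), 0)
  # at peak activation e = 1: pure ESPVR
  expect_equal(atrial_pressure(30, 135, ap), 60 * 20)
  # at t = 0 e = 0: pure EDPVR
  expect_equal(atrial_pressure(30, 0, ap), 58.67 * (exp(0.049 * 20) - 1),
               tolerance = 1e-12)
})

test_that("explicit volume update conserves total blood volume", {
  cn <- compartment_names()
  V0 <- stats::setNames(c(72, 160, 4000, 60, 77, 80, 600, 60), cn)
  st <- circulation_state(0, V0)
  # all flows zero -> unchanged
  expect_equal(advance_volumes(st, 1)$V, V0)
  # single mitral flow moves volume LA -> LV
  st$q[] <- 0; st$q[["mv"]] <- 1
  st2 <- advance_volumes(st, 1)
  expect_equal(st2$V[["LV"]], V0[["LV"]] + 1)
  expect_equal(st2$V[["LA"]], V0[["LA"]] - 1)
  expect_equal(st2$V[setdiff(cn, c("LV", "LA"))],
               V0[setdiff(cn, c("LV", "LA"))])
  # conservation for arbitrary flows over many steps
  set.seed(7)
  st <- circulation_state(0, V0)
  for (k in 1:200) {
    st$q <- stats::setNames(rnorm(8, 0, 0.2), flow_names())
    st <- advance_volumes(st, 0.5)
  }
  expect_lt(abs(sum(st$V) - sum(V0)), 1e-9 * sum(V0))
})

test_that("a volume driven non-positive names the compartment", {
  V0 <- stats::setNames(c(1, 160, 4000, 60, 77, 80, 600, 60),
                        compartment_names())
  st <- circulation_state(0, V0)
  st$q[["av"]] <- 5   # drains the LV
  expect_error(advance_volumes(st, 1), "LV")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(circulation_params(R_sa = -1), "positive")
  expect_error(circulation_params(C_sv = 0), "positive")
  expect_error(circulation_params(V_sv0 = -5), "non-negative")
  expect_error(atrial_elastance_params(E_es = -1))
})

test_that("explicit loop agrees with a stiff ODE integration of the same RHS",
{
  skip_if_not_installed("deSolve")
  # all four chambers as linear elastances -> smooth RHS
  circ <- circulation_params()
  E <- c(LV = 300, RA = 60, RV = 200, LA = 60)
  V0c <- c(LV = 10, RA = 10, RV = 10, LA = 10)
  Csa <- 0.012; Cpa <- 0.008; V0sa <- 70; V0pa <- 40
  pressures_of <- function(V) {
    c(LV = E[["LV"]] * (V[["LV"]] - V0c[["LV"]]),
      sa = (V[["sa"]] - V0sa) / Csa,
      sv = venous_pressure(V[["sv"]], circ, "systemic"),
      RA = E[["RA"]] * (V[["RA"]] - V0c[["RA"]]),
      RV = E[["RV"]] * (V[["RV"]] - V0c[["RV"]]),
      pa = (V[["pa"]] - V0pa) / Cpa,
      pv = venous_pressure(V[["pv"]], circ, "pulmonary"),
      LA = E[["LA"]] * (V[["LA"]] - V0c[["LA"]]))
  }
  rhs_of <- function(V) {
    q <- segment_flows(pressures_of(V), circ)
    c(q[["mv"]] - q[["av"]], q[["av"]] - q[["sa"]], q[["sa"]] - q[["sv"]],
      q[["sv"]] - q[["tv"]], q[["tv"]] - q[["pvv"]], q[["pvv"]] - q[["pa"]],
      q[["pa"]] - q[["pv"]], q[["pv"]] - q[["mv"]])
  }
  V <- stats::setNames(c(80, 160, 4000, 60, 80, 80, 600, 60),
                       compartment_names())
  # explicit loop at small dt
  dt <- 0.05
  st <- circulation_state(0, V, pressures_of(V), segment_flows(pressures_of(V),
                                                               circ))
  for (k in seq_len(round(200 / dt))) {
    st <- advance_volumes(st, dt)
    st$P <- pressures_of(st$V)
    st$q <- segment_flows(st$P, circ)
  }
  # lsoda on the same right-hand side
  ode_rhs <- function(t, y, parms) {
    names(y) <- compartment_names()
    list(rhs_of(y))
  }
  sol <- deSolve::lsoda(y = V, times = c(0, 200), func = ode_rhs,
                        rtol = 1e-9, atol = 1e-9)
  yf <- sol[2, 1 + seq_len(8)]
  expect_lt(max(abs(st$V - yf) / pmax(abs(yf), 1)), 0.01)
})
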