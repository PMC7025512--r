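# Shared fixtures, built once per test run and memoised in this
# environment.  All geometries are generated in code; nothing is read from
# disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# isotropic-exponent Guccione material (spherically symmetric behavior)
iso_gucc_materials <- function(C = 280, b = 10) {
  list(LV = list(passive = guccione_params(C = C, b_ff = b, b_xx = b,
                                           b_fx = b),
                 active = active_params(T_0 = 0)))
}

# coarse spherical shell + chamber model for oracle tests
sphere_fixture <- function() {
  fixture("sphere", function() {
    mesh <- make_sphere_shell(20, 4, n_theta = 12, n_s = 6, n_xi = 2)
    list(mesh = mesh, model = fe_chamber(mesh, iso_gucc_materials()))
  })
}

# 1D incompressible thick-shell inflation pressure for the isotropic
# Guccione law (independent quadrature oracle)
thick_shell_oracle <- function(V_ml, A, B, C = 280, b = 10, n = 600) {
  a <- (3 * V_ml * 1000 / (4 * pi))^(1 / 3)
  W <- function(l) {
    Er <- (l^-4 - 1) / 2; Et <- (l^2 - 1) / 2
    C / 2 * (exp(b * (Er^2 + 2 * Et^2)) - 1)
  }
  dW <- function(l) (W(l + 1e-6) - W(l - 1e-6)) / 2e-6
  R <- seq(A, B, length.out = n)
  r <- (R^3 + a^3 - A^3)^(1 / 3)
  lam <- r / R
  ig <- lam * dW(lam) / r * (R^2 / r^2)
  sum((ig[-1] + ig[-length(R)]) / 2 * diff(R))
}

# effective (discrete) shell radii matching the mesh volumes
sphere_radii <- function(mesh) {
  Vref <- mesh$cavity_volumes[["LV"]]
  Vwall <- sum(vacoupler:::.tet_vol6(mesh$nodes, mesh$tets)) / 6
  A <- (3 * Vref * 1000 / (4 * pi))^(1 / 3)
  B <- (A^3 + 3 * Vwall / (4 * pi))^(1 / 3)
  c(A = A, B = B, Vref = Vref)
}

# PA cylinder membrane fixture
pa_cylinder_fixture <- function() {
  fixture("pa_cyl", function() {
    mesh <- make_cylinder(radius = 13, length = 100, h = 1.2, n_theta = 16,
                          n_z = 8)
    list(mesh = mesh, material = pa_material(h = 1.2),
         model = fe_vessel(mesh, pa_material(h = 1.2)))
  })
}

# 1D equilibrium oracle for cylinder membrane inflation (fixed length):
# root of  P - h W'(lam_theta) / r  at the volume-implied stretch
cylinder_oracle <- function(V_ml, mesh, material) {
  R <- mesh$dims$radius; L <- mesh$dims$length
  Reff <- sqrt(mesh$ref_volume * 1000 / (pi * L))
  r <- sqrt(V_ml * 1000 / (pi * L))
  lam <- r / Reff
  Wl <- function(l) wall_energy(matrix(c(1, 0, 0, l^2), 2, 2), material)
  dW <- (Wl(lam + 1e-6) - Wl(lam - 1e-6)) / (2e-6)
  mesh$h * dW / r
}

# coarse biventricle + FE model for coupled tests
coarse_bv_fixture <- function() {
  fixture("coarse_bv", function() {
    spec <- bv_spec_coarse(n_theta = 10, n_s = 5,
                           rv_theta = c(0.25 * pi, 1.75 * pi),
                           rv_s_frac = 0.2)
    mesh <- make_biventricle(spec)
    list(spec = spec, mesh = mesh,
         model = fe_chamber(mesh, default_cardiac_materials()))
  })
}

# baseline surrogate-mode periodic run (shared across driver tests)
baseline_surrogate_run <- function() {
  fixture("base_run", function() run_closed_loop(sim_config(max_cycles = 30)))
}

random_spd_c2 <- function(ev_range = c(0.8, 1.5)) {
  th <- stats::runif(1, 0, pi)
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ev <- stats::runif(2, ev_range[1], ev_range[2])
  Q %*% diag(ev) %*% t(Q)
}

random_rotation3 <- function() {
  A <- matrix(stats::rnorm(9), 3)
  qr_d <- qr(A)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# FE-ventricle closed-loop runs at desk-scale coarse resolution: a 10-cycle
# baseline (also used for the FE conservation check) and a 3-cycle halved-
# contractility run compared against the matched baseline cycle.
fe_loop_runs <- function() {
  fixture("fe_runs", function() {
    mesh <- coarse_bv_fixture()$mesh
    cfg <- sim_config(ventricle_mode = "fe", dt = 1, max_cycles = 10,
                      min_cycles = 10,
                      bv = list(mesh = mesh,
                                materials = default_cardiac_materials()))
    base <- run_closed_loop(cfg)
    cfg2 <- apply_scenario(cfg, "contractility_decrease")
    cfg2$max_cycles <- 2; cfg2$min_cycles <- 2
    lowT0 <- run_closed_loop(cfg2)
    list(base = base, lowT0 = lowT0)
  })
}

# hybrid runs (elastance ventricles + FE artery response curves) for the
# collagen-accumulation scenario; the aorta curve is shared between runs
hybrid_runs <- function() {
  fixture("hybrid", function() {
    cfg <- sim_config(artery_mode = "fe_curve", max_cycles = 40, dt = 1)
    cfg$vessels$ao$spec$n_theta <- 12; cfg$vessels$ao$spec$n_z <- 6
    cfg$vessels$pa$spec$n_theta <- 12; cfg$vessels$pa$spec$n_z <- 6
    ao_mesh <- make_vessel(cfg$vessels$ao$spec)
    cfg$vessels$ao$mesh <- ao_mesh
    cfg$vessels$ao$curve <-
      vessel_pv_curve(fe_vessel(ao_mesh, cfg$vessels$ao$material))
    base <- hemodynamic_metrics(run_closed_loop(cfg))
    coll <- hemodynamic_metrics(
      run_closed_loop(apply_scenario(cfg, "collagen_increase")))
    list(base = base, collagen = coll)
  })
}
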