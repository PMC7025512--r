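# Chamber finite-element solver: reference consistency, the independent
# thick-shell oracle, incompressibility, multiplier duality and the
# thin-shell (Laplace) limit.

test_that("the reference configuration is stress-free", {
  fx <- sphere_fixture()
  res <- solve_chamber_pressures(fx$model,
                                 c(LV = fx$mesh$cavity_volumes[["LV"]]))
  expect_true(res$converged)
  expect_lt(abs(res$P[["LV"]]), 1)            # Pa
  expect_lt(max(abs(res$u)), 1e-6)
})

test_that("passive inflation matches the 1D thick-shell quadrature oracle", {
  fx <- sphere_fixture()
  rad <- sphere_radii(fx$mesh)
  state <- NULL
  prev_P <- 0
  for (fac in c(1.1, 1.2)) {
    res <- solve_chamber_pressures(fx$model, c(LV = rad[["Vref"]] * fac),
                                   state = state)
    state <- res$state
    P1d <- thick_shell_oracle(rad[["Vref"]] * fac, rad[["A"]], rad[["B"]])
    expect_lt(abs(res$P[["LV"]] - P1d) / P1d, 0.05)
    expect_gt(res$P[["LV"]], prev_P)          # monotone inflation
    prev_P <- res$P[["LV"]]
  }
  .fixture_env$sphere_state_12 <- state       # reused by later tests
})

test_that("cavity-volume multiplier equals the energy derivative (duality)", {
  fx <- sphere_fixture()
  rad <- sphere_radii(fx$mesh)
  V0 <- rad[["Vref"]] * 1.15
  dV <- 0.2
  state <- .fixture_env$sphere_state_12
  rp <- solve_chamber_pressures(fx$model, c(LV = V0 + dV), state = state)
  r0 <- solve_chamber_pressures(fx$model, c(LV = V0), state = rp$state)
  rm <- solve_chamber_pressures(fx$model, c(LV = V0 - dV), state = r0$state)
  dEdV <- (rp$energy - rm$energy) / (2 * dV * 1000)   # energy per mm^3
  expect_lt(abs(dEdV - r0$P[["LV"]]) / r0$P[["LV"]], 0.01)
})

test_that("incompressibility holds at convergence and improves with the mesh",
{
  jerr <- function(nt, ns, nx) {
    mesh <- make_sphere_shell(20, 4, n_theta = nt, n_s = ns, n_xi = nx)
    model <- fe_chamber(mesh, iso_gucc_materials())
    res <- solve_chamber_pressures(model,
                                   c(LV = mesh$cavity_volumes[["LV"]] * 1.03))
    expect_true(res$converged)
    res$avg_absJm1
  }
  coarse <- jerr(12, 6, 2)
  fine <- jerr(16, 8, 3)
  expect_lt(fine, coarse)
  expect_lt(fine, 1e-3)
})

test_that("a thin shell reproduces the Laplace law within 10%", {
  mesh <- make_sphere_shell(20, 1, n_theta = 16, n_s = 8, n_xi = 1)
  model <- fe_chamber(mesh, iso_gucc_materials())
  Vref <- mesh$cavity_volumes[["LV"]]
  res <- solve_chamber_pressures(model, c(LV = Vref * 1.1))
  fs <- fiber_stress_field(res, model)
  # mean tangential Cauchy stress from the stress tensor components
  cells <- fs$cells
  cent <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
             mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  rhat <- cent / sqrt(rowSums(cent^2))
  srr <- rhat[, 1]^2 * cells$s11 + rhat[, 2]^2 * cells$s22 +
    rhat[, 3]^2 * cells$s33 + 2 * (rhat[, 1] * rhat[, 2] * cells$s12 +
                                     rhat[, 1] * rhat[, 3] * cells$s13 +
                                     rhat[, 2] * rhat[, 3] * cells$s23)
  sig_t <- (cells$s11 + cells$s22 + cells$s33 - srr) / 2
  sig_mean <- sum(sig_t * cells$vol) / sum(cells$vol)
  lam <- (1.1)^(1 / 3)
  r_cur <- 20.5 * lam                      # mid-surface radius, deformed
  h_cur <- 1 / lam^2                       # incompressible thinning
  P_laplace <- 2 * h_cur * sig_mean / r_cur
  expect_lt(abs(res$P[["LV"]] - P_laplace) / res$P[["LV"]], 0.10)
})

test_that("the biventricle solves both cavities with in-plane basal motion", {
  fx <- coarse_bv_fixture()
  v0 <- fx$mesh$cavity_volumes
  res <- solve_chamber_pressures(fx$model,
                                 c(LV = v0[["LV"]] * 1.05,
                                   RV = v0[["RV"]] * 1.05))
  expect_true(res$converged)
  expect_equal(unname(res$volumes), unname(v0 * 1.05), tolerance = 1e-4)
  expect_gt(res$P[["LV"]], 0)
  expect_gt(res$P[["RV"]], 0)
  # basal plane: z-displacements of basal nodes are identically zero
  um <- matrix(res$u, ncol = 3, byrow = TRUE)
  base <- which(abs(fx$model$coords[, 3]) < 1e-8)
  expect_equal(max(abs(um[base, 3])), 0)
  # rigid-body constraints: zero mean displacement
  expect_lt(max(abs(colSums(fx$model$w0 * um))) /
              max(abs(um)) / sum(fx$model$w0), 1e-6)
  .fixture_env$bv_passive_state <- res$state
})

test_that("active stress raises cavity pressure at fixed volumes", {
  fx <- coarse_bv_fixture()
  v0 <- fx$mesh$cavity_volumes
  st <- .fixture_env$bv_passive_state
  res_p <- solve_chamber_pressures(fx$model,
                                   c(LV = v0[["LV"]] * 1.05,
                                     RV = v0[["RV"]] * 1.05),
                                   t_act = -1, state = st)
  # ramp the activation time the way the coupled loop would
  st <- res_p$state
  for (tt in seq(10, 60, by = 10)) {
    res_a <- solve_chamber_pressures(fx$model,
                                     c(LV = v0[["LV"]] * 1.05,
                                       RV = v0[["RV"]] * 1.05),
                                     t_act = tt, state = st)
    st <- res_a$state
  }
  expect_gt(res_a$P[["LV"]], 10 * max(res_p$P[["LV"]], 1))
  expect_gt(res_a$P[["RV"]], res_p$P[["RV"]])
  # fiber stress averages positive and larger in systole
  fs_a <- fiber_stress_field(res_a, fx$model)
  fs_p <- fiber_stress_field(res_p, fx$model)
  expect_gt(fs_a$averages[["LV"]], fs_p$averages[["LV"]])
  expect_gt(fs_a$averages[["RV"]], 0)
})

test_that("solver converges from a perturbed admissible start to the same state",
{
  fx <- sphere_fixture()
  rad <- sphere_radii(fx$mesh)
  tgt <- c(LV = rad[["Vref"]] * 1.1)
  r1 <- solve_chamber_pressures(fx$model, tgt)
  st <- r1$state
  set.seed(42)
  st$u <- st$u + rnorm(length(st$u), 0, 0.02)
  r2 <- solve_chamber_pressures(fx$model, tgt, state = st)
  expect_true(r2$converged)
  expect_lt(abs(r2$P[["LV"]] - r1$P[["LV"]]) / r1$P[["LV"]], 1e-3)
})
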