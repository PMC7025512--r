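# Constrained-mixture artery wall: constituent masses, energies, stresses.

test_that("constituent masses follow the collagen split rule", {
  m <- pa_material()   # phi_e 0.35, phi_m 0.23, phi_c 0.42, split .1/.1/.4/.4
  cm <- constituent_masses(m)
  expect_equal(cm$M_c, c(0.042, 0.042, 0.168, 0.168))
  expect_equal(cm$M_e + cm$M_m + sum(cm$M_c), m$rho)
  expect_equal(m$phi_e + m$phi_m + m$phi_c, 1)
  m2 <- pa_material(rho = 1050)
  expect_equal(constituent_masses(m2)$M_e, 367.5)
  expect_error(vessel_wall_material(1, 1, 1, 1, 1, phi_e = 0.5, phi_m = 0.5,
                                    phi_c = 0.2), "sum to 1")
  expect_error(pa_material(split = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("elastin energy uses the incompressible thickness stretch", {
  expect_equal(elastin_energy(diag(2), 1, 120e3), 0)
  # equibiaxial 1.2: tr C = 2*1.44 + 1/1.2^4
  lam <- 1.2
  C2 <- diag(c(lam^2, lam^2))
  W <- elastin_energy(C2, 0.35, 120e3)
  expect_equal(W, 0.35 * 120e3 / 2 * (2 * 1.44 + lam^-4 - 3))
  expect_equal(W / (0.35 * 120e3), 0.18113, tolerance = 1e-4)
  # in-plane rotation invariance
  th <- 0.7; Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  C2r <- Q %*% C2 %*% t(Q)
  expect_equal(elastin_energy(C2r, 0.35, 120e3), W)
})

test_that("fiber stretch is the quadratic form of the family direction", {
  expect_equal(fiber_stretch(diag(2), c(1, 0)), 1)
  expect_equal(fiber_stretch(diag(c(1.44, 1.44)), c(0.6, 0.8)), 1.2)
  e45 <- c(1, 1) / sqrt(2)
  expect_equal(fiber_stretch(diag(c(1.21, 1)), e45), sqrt(1.105))
  expect_equal(fiber_stretch(diag(c(1.21, 1)), e45), 1.0512, tolerance = 1e-4)
  expect_error(fiber_stretch(diag(2), c(1, 1)), "unit")
})

test_that("collagen and SMC energies share the exponential form", {
  expect_equal(collagen_family_energy(1, 0.1, 100e3, 3), 0)
  w <- collagen_family_energy(1.1, 1, 100e3, 3.0)
  expect_equal(w, 100e3 / 12 * (exp(3 * (1.1^2 - 1)^2) - 1))
  expect_equal(w / 1e3, 1.1787, tolerance = 1e-3)
  ws <- smc_energy(1.1, 1, 5e3, 3.5)
  expect_equal(ws, 5e3 / 14 * (exp(3.5 * 0.21^2) - 1))
  expect_equal(ws / 1e3, 0.0596, tolerance = 2e-3)
  expect_equal(smc_energy(1.07, 0.3, 7e3, 4),
               collagen_family_energy(1.07, 0.3, 7e3, 4))
  lam <- seq(1, 1.5, by = 0.01)
  expect_true(all(diff(collagen_family_energy(lam, 1, 100e3, 3)) > 0))
})

test_that("wall energy sums constituents and respects symmetries", {
  m <- pa_material()
  expect_equal(wall_energy(diag(2), m), 0)
  # additivity against independently evaluated terms on a random C2
  set.seed(5)
  C2 <- random_spd_c2()
  cm <- constituent_masses(m)
  dirs <- family_directions(m$alpha)
  W_terms <- elastin_energy(C2, cm$M_e, m$c_1)
  for (i in 1:4)
    W_terms <- W_terms + collagen_family_energy(
      fiber_stretch(C2, dirs[, i]), cm$M_c[i], m$c_2, m$c_3)
  W_terms <- W_terms + smc_energy(fiber_stretch(C2, dirs[, 5]), cm$M_m,
                                  m$c_4, m$c_5)
  expect_equal(wall_energy(C2, m), W_terms)
  # reflection about the longitudinal axis swaps the +/- alpha families
  R <- diag(c(1, -1))
  expect_equal(wall_energy(R %*% C2 %*% R, m), wall_energy(C2, m))
  # pure longitudinal family at lambda = 1 contributes nothing under pure
  # circumferential stretch
  Cc <- diag(c(1, 1.3))
  expect_equal(fiber_stretch(Cc, dirs[, 1]), 1)
})

test_that("wall energy is non-negative on tested SPD deformations", {
  m <- pa_material()
  set.seed(9)
  for (k in 1:50) {
    C2 <- random_spd_c2(c(0.8, 1.5))
    expect_gte(wall_energy(C2, m), -1e-12)
  }
})

test_that("membrane stress is the exact derivative of the wall energy", {
  m <- pa_material()
  set.seed(13)
  for (k in 1:10) {
    C2 <- random_spd_c2(c(0.9, 1.4))
    S <- wall_pk2(C2, m)
    expect_equal(S, t(S))
    h <- 1e-7
    for (idx in list(c(1, 1), c(2, 2), c(1, 2))) {
      Cp <- C2; Cp[idx[1], idx[2]] <- Cp[idx[1], idx[2]] + h
      Cm <- C2; Cm[idx[1], idx[2]] <- Cm[idx[1], idx[2]] - h
      if (idx[1] != idx[2]) { # keep symmetry of the perturbation
        Cp[idx[2], idx[1]] <- Cp[idx[2], idx[1]] + h
        Cm[idx[2], idx[1]] <- Cm[idx[2], idx[1]] - h
      }
      g <- (wall_energy(Cp, m) - wall_energy(Cm, m)) / (2 * h)
      # S = 2 dW/dC: a diagonal probe sees S_ii/2, a symmetric off-diagonal
      # probe sees S_ij
      expected <- if (idx[1] == idx[2]) S[idx[1], idx[2]] / 2
      else S[idx[1], idx[2]]
      expect_equal(expected, g, tolerance = 1e-5 * max(1, abs(g)))
    }
  }
})

test_that("raising the collagen fraction stiffens the circumferential response",
{
  lam <- 1.2
  dC <- 1e-4
  stiff <- function(mat) {
    C2a <- diag(c(1, (lam - dC)^2)); C2b <- diag(c(1, (lam + dC)^2))
    (wall_pk2(C2b, mat)[2, 2] - wall_pk2(C2a, mat)[2, 2]) / (2 * dC)
  }
  base <- pa_material()
  coll <- pa_material(phi_e = 0.15, phi_m = 0.15, phi_c = 0.70)
  expect_gt(stiff(coll), stiff(base))
})
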