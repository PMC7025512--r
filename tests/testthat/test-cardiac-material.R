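# Guccione passive law and the sarcomere active-contraction model.

test_that("Green-Lagrange strain is exact and symmetric", {
  expect_equal(green_lagrange(diag(3)), matrix(0, 3, 3))
  F <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  E <- green_lagrange(F)
  expect_equal(E[1, 1], (1.21 - 1) / 2)
  set.seed(3)
  for (k in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    if (det(F) <= 0) next
    E <- green_lagrange(F)
    expect_equal(E, t(E))
  }
  expect_error(green_lagrange(diag(c(1, 1, -1))), "determinant")
})

test_that("passive energy is transversely isotropic and matches closed form", {
  p <- guccione_params(C = 280, b_ff = 29.9, b_xx = 13.3, b_fx = 26.6)
  expect_equal(passive_energy(matrix(0, 3, 3), p), 0)
  # swapping sheet and sheet-normal strains leaves W unchanged
  E <- diag(c(0.05, 0.08, 0.03))
  Esw <- diag(c(0.05, 0.03, 0.08))
  expect_equal(passive_energy(E, p), passive_energy(Esw, p))
  # fiber-only strain: W = C/2 (exp(b_ff E_ff^2) - 1)
  Ef <- diag(c(0.1, 0, 0))
  expect_equal(passive_energy(Ef, p), 140 * (exp(29.9 * 0.01) - 1))
  expect_equal(passive_energy(Ef, p), 48.79, tolerance = 1e-3)
})

test_that("passive PK1 is the exact gradient of the energy", {
  p <- guccione_params(C = 280)
  basis <- fiber_basis(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(passive_pk1(diag(3), basis, p), matrix(0, 3, 3))
  # finite-difference oracle on random states near identity
  set.seed(11)
  wfun <- function(F) passive_energy(
    t(unclass(basis)) %*% green_lagrange(F) %*% unclass(basis), p)
  for (k in 1:20) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
    if (det(F) < 0.5) next
    P <- passive_pk1(F, basis, p)
    h <- 1e-6
    for (idx in list(c(1, 1), c(2, 3), c(3, 1))) {
      Fp <- F; Fp[idx[1], idx[2]] <- Fp[idx[1], idx[2]] + h
      Fm <- F; Fm[idx[1], idx[2]] <- Fm[idx[1], idx[2]] - h
      g <- (wfun(Fp) - wfun(Fm)) / (2 * h)
      expect_equal(P[idx[1], idx[2]], g,
                   tolerance = 1e-6 * max(1, abs(g)))
    }
  }
  # frame indifference: P(RF) = R P(F)
  for (k in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
    R <- random_rotation3()
    expect_equal(passive_pk1(R %*% F, basis, p), R %*% passive_pk1(F, basis, p),
                 tolerance = 1e-10)
  }
})

test_that("isometric tension curve follows the printed branches", {
  p <- active_params(T_0 = 2000e3, a_6 = 2.0, a_7 = 1.5,
                     iso_variant = "printed")
  expect_equal(f_iso(1.6, p), 0)          # zero branch above the threshold
  expect_equal(f_iso(1.5, p), 0)          # tanh(0) at the threshold
  # active branch (printed: below a_7) half a micron from the threshold
  expect_equal(f_iso(1.0, p), 2000e3 * tanh(1)^2)
  expect_equal(f_iso(1.0, p) / 1e3, 1160.05, tolerance = 1e-4)
  # ascending-limb variant mirrors the branch orientation
  pa <- active_params(T_0 = 2000e3, a_6 = 2.0, a_7 = 1.5,
                      iso_variant = "ascending")
  expect_equal(f_iso(2.0, pa), 2000e3 * tanh(1)^2)
  expect_equal(f_iso(1.4, pa), 0)
  # bounded by T_0
  lc <- seq(0.5, 3, by = 0.01)
  expect_true(all(f_iso(lc, p) >= 0 & f_iso(lc, p) <= p$T_0))
})

test_that("twitch function is causal, bounded and length-modulated", {
  p <- active_params(b = 170, l_d = -0.4, t_r = 280, t_d = 80)
  expect_equal(f_twitch(-1, 2.0, p), 0)
  expect_equal(f_twitch(0, 2.0, p), 0)
  expect_lt(f_twitch(1e-9, 2.0, p), 1e-12)
  # twitch vanishes entirely when l_s = l_d (zero duration)
  expect_true(all(f_twitch(seq(0, 500, 10), p$l_d, p) == 0))
  tt <- seq(-50, 1000, by = 1)
  ft <- f_twitch(tt, 2.0, p)
  expect_true(all(ft >= 0 & ft <= 1))
  # duration grows with sarcomere length
  t_end_short <- max(tt[f_twitch(tt, 1.8, p) > 0])
  t_end_long <- max(tt[f_twitch(tt, 2.2, p) > 0])
  expect_gt(t_end_long, t_end_short)
})

test_that("active stress magnitude is the product of its factors", {
  p <- active_params(T_0 = 1800e3, iso_variant = "ascending")
  s0 <- sarcomere_state(l_s = 2.0, l_c = 2.0, t_act = 100)
  expect_equal(active_stress_magnitude(s0, p), 0)     # unstretched series el.
  s1 <- sarcomere_state(l_s = 2.0, l_c = 1.9, t_act = -5)
  expect_equal(active_stress_magnitude(s1, p), 0)     # before activation
  s2 <- sarcomere_state(l_s = 2.05, l_c = 1.92, t_act = 120)
  expected <- (2.05 / p$l_s0) * f_iso(1.92, p) * f_twitch(120, 2.05, p) *
    (2.05 - 1.92) * p$E_a
  expect_equal(active_stress_magnitude(s2, p), expected)
  expect_gt(expected, 0)
})

test_that("contractile element rate has the isotonic equilibrium", {
  p <- active_params(E_a = 20, v_0 = 0.0075)
  leq <- 2.0 - 1 / 20
  expect_equal(lc_rate(sarcomere_state(2.0, leq, 0), p), 0)
  expect_equal(lc_rate(sarcomere_state(2.0, 2.0, 0), p), -p$v_0)
  # explicit Euler relaxation at fixed l_s matches the analytic exponential
  ls <- 2.0; lc <- 1.8; dt <- 0.5
  lc_euler <- lc
  nst <- 400
  for (k in seq_len(nst))
    lc_euler <- lc_euler + dt * lc_rate(sarcomere_state(ls, lc_euler, 0), p)
  k_rate <- p$E_a * p$v_0
  lc_exact <- leq + (lc - leq) * exp(-k_rate * nst * dt)
  expect_equal(lc_euler, lc_exact, tolerance = 0.01)
})

test_that("myofiber stretch maps deformation to sarcomere length", {
  r <- myofiber_stretch(diag(3), c(1, 0, 0), 1.9)
  expect_equal(r$lambda, 1); expect_equal(r$l_s, 1.9)
  r <- myofiber_stretch(diag(c(1.1, 1, 1)), c(1, 0, 0), 1.9)
  expect_equal(r$lambda, 1.1)
  expect_equal(r$l_s, 2.09)
  expect_error(myofiber_stretch(diag(3), c(1, 1, 0), 1.9), "unit")
})

test_that("total stress adds a rank-one active term to the passive stress", {
  gp <- guccione_params(C = 280)
  basis <- fiber_basis(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ap0 <- active_params(T_0 = 0)
  F <- diag(3) + matrix(c(0, 0.02, 0, 0, 0.01, 0, 0, 0, -0.01), 3)
  s <- sarcomere_state(2.0, 1.9, 100)
  # T_0 = 0 reduces bit-identically to the passive law
  expect_identical(total_pk1(F, basis, s, gp, ap0),
                   passive_pk1(F, basis, gp))
  # zero passive strain: rank-one active stress along e_f x e_f0
  ap <- active_params(T_0 = 1800e3, iso_variant = "ascending")
  P <- total_pk1(diag(3), basis, s, gp, ap)
  expect_equal(qr(P)$rank, 1)
  expect_equal(P, P[1, 1] * (c(1, 0, 0) %o% c(1, 0, 0)))
  # additivity on a random state
  Pa <- active_stress_magnitude(s, ap)
  v <- drop(F %*% c(1, 0, 0)); ef <- v / sqrt(sum(v^2))
  expect_equal(total_pk1(F, basis, s, gp, ap),
               passive_pk1(F, basis, gp) + Pa * (ef %o% c(1, 0, 0)))
})

test_that("passive fiber stress rises monotonically under uniaxial stretch", {
  p <- guccione_params(C = 280)
  basis <- fiber_basis(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  lams <- seq(1.01, 1.3, by = 0.01)
  sig <- vapply(lams, function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))   # incompressible uniaxial
    P <- passive_pk1(F, basis, p)
    # Cauchy fiber stress minus transverse reaction (deviatoric part)
    S <- (P %*% t(F))
    S[1, 1] - S[2, 2]
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})
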