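test_that("Lame conversion reproduces the worked values", {
  lam <- lame_from_modulus(0.11, 0.45)
  expect_equal(lam$lambda_lame, 0.341379, tolerance = 1e-6)
  expect_equal(lam$mu_lame, 0.0379310, tolerance = 1e-6)
  l2 <- lame_from_modulus(1, 0.25)
  expect_equal(l2$lambda_lame, 0.4)
  expect_equal(l2$mu_lame, 0.4)
  l0 <- lame_from_modulus(2, 0)
  expect_equal(l0$lambda_lame, 0)
  expect_equal(l0$mu_lame, 1)
  expect_error(lame_from_modulus(1, 0.5 - 1e-12), "overflow|0.5")
})

test_that("presets carry the published parameter values", {
  ilt <- material_preset("ilt_linear")
  expect_equal(c(ilt$E, ilt$nu), c(0.11, 0.45))
  hgo <- material_preset("wall_hgo_niestrawska")
  expect_equal(c(hgo$c, hgo$k1, hgo$k2, hgo$kappa, hgo$alpha),
               c(0.30055, 0.01632, 1768.15, 0.1010, 5.6))
  mr <- material_preset("wall_mooney_rivlin")
  expect_equal(c(mr$c1, mr$c2), c(0.174, 1.881))
})

test_that("energies vanish at the identity and SVK matches hand arithmetic", {
  fb <- test_fibers()
  for (m in all_materials()) {
    expect_equal(strain_energy(m, diag(3), fb), 0, tolerance = 1e-14)
    expect_equal(max(abs(cauchy_stress(m, diag(3), fb))), 0,
                 tolerance = 1e-12)
  }
  # SVK with the thrombus parameters at E_green = diag(0.01, 0, 0):
  # W = lambda/2 * 1e-4 + mu * 1e-4
  F <- diag(c(sqrt(1.02), 1, 1))
  W <- strain_energy(material_linear_elastic(0.11, 0.45, form = "svk"), F)
  expect_equal(W, 0.5 * 0.341379 * 1e-4 + 0.0379310 * 1e-4,
               tolerance = 1e-5)
})

test_that("dispersed fiber strain follows its closed form", {
  expect_equal(fiber_strain(3, 1, 0.2), 0)
  expect_equal(fiber_strain(3.05, 1.02, 0.1010), 0.018990, tolerance = 1e-12)
  # isotropic limit: independent of I4
  expect_equal(fiber_strain(3.3, 1.5, 1 / 3), fiber_strain(3.3, 9, 1 / 3))
})

test_that("compressed fibers carry no load (Macaulay rule)", {
  hgo <- material_hgo(kappa = 0, bulk_modulus = 30, invariants = "full")
  ground <- material_hgo(k1 = 1e-30, kappa = 0, bulk_modulus = 30,
                         invariants = "full")
  fb <- list(M4 = c(1, 0, 0), M6 = c(1, 0, 0))
  F <- diag(c(0.97, 1.01, 1.01))  # fiber direction compressed
  expect_equal(strain_energy(hgo, F, fb), strain_energy(ground, F, fb),
               tolerance = 1e-12)
  # tension engages the fiber term
  Ft <- diag(c(1.03, 0.99, 0.99))
  expect_gt(strain_energy(hgo, Ft, fb), strain_energy(ground, Ft, fb))
})

test_that("analytic Cauchy stress matches central differences of the energy", {
  set.seed(3)
  fb <- test_fibers()
  for (m in all_materials()) {
    for (k in 1:25) {
      F <- random_small_F()
      sig <- cauchy_stress(m, F, fb)
      fd <- aaamech:::fd_cauchy_from_energy(m, F, fb)
      expect_lt(max(abs(sig - fd)) / max(abs(sig)), 1e-6)
    }
  }
})

test_that("material tangent matches finite differences of the PK2 stress", {
  set.seed(4)
  fb <- test_fibers()
  h <- 1e-6
  for (m in all_materials()) {
    F <- random_small_F(0.02)
    C <- t(F) %*% F
    A <- material_tangent(m, F, fb)
    Afd <- array(0, c(3, 3, 3, 3))
    for (k in 1:3) for (l in 1:3) {
      dC <- matrix(0, 3, 3)
      dC[k, l] <- dC[k, l] + h
      dC[l, k] <- dC[l, k] + h
      Sp <- pk2_stress(m, chol(C + dC), fb)
      Sm <- pk2_stress(m, chol(C - dC), fb)
      Afd[, , k, l] <- as.matrix(Sp - Sm) / (2 * h)
    }
    expect_lt(max(abs(A - Afd)) / max(abs(A)), 1e-4)
    # major symmetry
    Apq <- aperm(A, c(3, 4, 1, 2))
    expect_lt(max(abs(A - Apq)) / max(abs(A)), 1e-10)
  }
})

test_that("SVK tangent at the identity is the isotropic elasticity tensor", {
  m <- material_linear_elastic(0.11, 0.45)
  A <- material_tangent(m, diag(3))
  lam <- m$lambda_lame
  mu <- m$mu_lame
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    expect_equal(A[i, j, k, l],
                 lam * (i == j) * (k == l) +
                   mu * ((i == k) * (j == l) + (i == l) * (j == k)),
                 tolerance = 1e-10)
  }
})

test_that("energies are frame indifferent and symmetric in the fiber pair", {
  set.seed(5)
  fb <- test_fibers(0.35)
  for (m in all_materials()) {
    for (k in 1:10) {
      F <- random_small_F()
      Q <- random_rotation()
      expect_equal(strain_energy(m, Q %*% F, fb), strain_energy(m, F, fb),
                   tolerance = 1e-10)
    }
  }
  hgo <- material_preset("wall_hgo_niestrawska")
  F <- random_small_F()
  swapped <- list(M4 = fb$M6, M6 = fb$M4)
  expect_equal(strain_energy(hgo, F, fb), strain_energy(hgo, F, swapped),
               tolerance = 1e-14)
})

test_that("HGO uniaxial stress stiffens monotonically and convexly", {
  hgo <- material_preset("wall_hgo_niestrawska")
  fb <- list(M4 = c(1, 0, 0), M6 = c(1, 0, 0))
  lams <- seq(1.005, 1.06, length.out = 12)
  s11 <- vapply(lams, function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    cauchy_stress(hgo, F, fb)[1, 1]
  }, numeric(1))
  expect_true(all(diff(s11) > 0))
  expect_true(all(diff(diff(s11)) > 0))
})

test_that("isotropic dispersion makes the energy fiber-rotation invariant", {
  hgo <- material_hgo(kappa = 1 / 3, bulk_modulus = 30)
  F <- random_small_F()
  w <- vapply(seq(0, pi, length.out = 7), function(a) {
    strain_energy(hgo, F, list(M4 = c(cos(a), sin(a), 0),
                               M6 = c(cos(a), -sin(a), 0)))
  }, numeric(1))
  expect_lt(diff(range(w)), 1e-14)
})

test_that("invalid deformation states are rejected", {
  expect_error(deformation_state(diag(c(-1, 1, 1))), "positive")
  expect_error(strain_energy(material_preset("ilt_linear"),
                             diag(c(0, 1, 1))), "positive")
  st <- deformation_state(diag(3), M4 = c(1, 0, 0))
  expect_equal(st$I1, 3)
  expect_equal(st$I4_4, 1)
  expect_equal(st$E_green, matrix(0, 3, 3))
})
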