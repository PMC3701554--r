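test_that("Cartesian moments match the direct-sum oracle and trivial cases", {
  # point charge at the expansion center: all higher moments vanish
  cs1 <- charge_set(data.frame(x = 0, y = 0, z = 0, q = 1))
  cm1 <- cartesian_moments(cs1)
  expect_equal(cm1$M, 1)
  expect_equal(cm1$p, c(0, 0, 0))
  expect_equal(cm1$Theta, matrix(0, 3, 3))
  expect_equal(max(abs(cm1$Omega)), 0)

  # symmetric physical dipole: M = 0, p = (0,0,1), Theta = 0
  cs2 <- charge_set(data.frame(x = 0, y = 0, z = c(0.5, -0.5), q = c(1, -1)))
  cm2 <- cartesian_moments(cs2)
  expect_equal(cm2$M, 0)
  expect_equal(cm2$p, c(0, 0, 1))
  expect_equal(max(abs(cm2$Theta)), 0)

  # random 12-charge set vs the independent loop oracle
  set.seed(7)
  cs <- charge_set(cbind(matrix(runif(36, -2, 2), 12, 3), runif(12, -1, 1)))
  for (origin in list(c(0, 0, 0), c(0.7, -0.3, 0.2))) {
    cm <- cartesian_moments(cs, origin)
    oc <- oracle_moments(cs, origin)
    expect_equal(cm$M, oc$M, tolerance = 1e-12)
    expect_equal(cm$p, oc$p, tolerance = 1e-12)
    expect_equal(cm$Theta, oc$Theta, tolerance = 1e-12)
    expect_equal(cm$Omega, oc$Omega, tolerance = 1e-12)
  }
})

test_that("quadrupole and octupole are symmetric and traceless on random sets", {
  for (s in 1:60) {
    cs <- random_charge_set(synth_spec(
      n_charges = c(3, 15), net_charge = sample(c(-1, 0, 1), 1), seed = s
    ))
    cm <- cartesian_moments(cs, origin = rnorm(3))
    nrmT <- sqrt(sum(cm$Theta^2)) + 1e-30
    expect_lt(abs(sum(diag(cm$Theta))) / nrmT, 1e-10)
    expect_equal(cm$Theta, t(cm$Theta))
    nrmO <- sqrt(sum(cm$Omega^2)) + 1e-30
    for (g in 1:3) {
      expect_lt(abs(sum(vapply(1:3, function(a) cm$Omega[a, a, g], 1))) / nrmO, 1e-10)
    }
    # full permutation symmetry
    expect_equal(cm$Omega, aperm(cm$Omega, c(2, 1, 3)))
    expect_equal(cm$Omega, aperm(cm$Omega, c(3, 2, 1)))
  }
})

test_that("the lowest non-vanishing multipole is origin independent", {
  for (s in 1:25) {
    cs <- neutral_set(s)
    p0 <- cartesian_moments(cs, c(0, 0, 0), 1)$p
    shift <- rnorm(3, sd = 3)
    p1 <- cartesian_moments(cs, shift, 1)$p
    expect_lt(max(abs(p1 - p0)) / (sqrt(sum(p0^2)) + 1e-12), 1e-10)
  }
  # M = 0 and p = 0: quadrupole becomes origin independent
  sq <- degenerate_fixtures()$zero_dipole_quadrupole
  T0 <- cartesian_moments(sq, c(0, 0, 0), 2)$Theta
  T1 <- cartesian_moments(sq, c(1.3, -0.4, 2.2), 2)$Theta
  expect_equal(T0, T1, tolerance = 1e-10)
})

test_that("shift_origin recomputes correctly", {
  cs <- charged_set(3)
  m0 <- cartesian_moments(cs, c(0, 0, 0))
  m1 <- shift_origin(cs, c(1, 2, 3))
  # dipole transforms as p' = p - M d for a charged set
  expect_equal(m1$p, m0$p - m0$M * c(1, 2, 3), tolerance = 1e-10)
  m2 <- shift_origin(cs, c(0, 0, 0))
  expect_equal(m2$p, m0$p)
  expect_equal(m2$Theta, m0$Theta)
})

test_that("spherical moments: conjugation symmetry, rotation invariance, cross-path", {
  # single charge at the origin: only the l = 0 channel survives
  cs0 <- charge_set(data.frame(x = 0, y = 0, z = 0, q = 2))
  sm0 <- spherical_moments(cs0, l_max = 3)
  expect_equal(Re(sm0$coeffs[[1]][["0"]]), 2 / sqrt(4 * pi))
  for (l in 1:3) expect_lt(max(Mod(sm0$coeffs[[l + 1]])), 1e-14)

  for (s in 1:10) {
    cs <- neutral_set(s)
    sm <- spherical_moments(cs, c(0, 0, 0), 4)
    # q_{l,-m} = (-1)^m conj(q_lm)
    for (l in 0:4) {
      q <- sm$coeffs[[l + 1]]
      for (m in 0:l) {
        expect_equal(q[[as.character(-m)]], (-1)^m * Conj(q[[as.character(m)]]),
          tolerance = 1e-10
        )
      }
    }
    # rigid rotation about the origin preserves the per-l norm
    R <- oracle_rotation(100 + s)
    smr <- spherical_moments(transform_charge_set(cs, rotation = R), c(0, 0, 0), 4)
    for (l in 0:4) {
      n0 <- sum(Mod(sm$coeffs[[l + 1]])^2)
      expect_equal(sum(Mod(smr$coeffs[[l + 1]])^2), n0, tolerance = 1e-9)
    }
    # cross-path: cart_to_spherical agrees with the direct sums for l <= 3
    s2 <- cart_to_spherical(cartesian_moments(cs, c(0.3, 0.1, -0.2)))
    smd <- spherical_moments(cs, c(0.3, 0.1, -0.2), 3)
    for (l in 0:3) {
      scale <- sqrt(sum(Mod(smd$coeffs[[l + 1]])^2)) + 1 # floor for zero channels
      expect_lt(max(Mod(s2$coeffs[[l + 1]] - smd$coeffs[[l + 1]])) / scale, 1e-9)
    }
  }
})

test_that("cart_to_spherical handles pure monopole and axial dipole", {
  cm <- cartesian_moments(charge_set(data.frame(x = 0, y = 0, z = 0, q = 1)))
  sm <- cart_to_spherical(cm)
  expect_gt(Mod(sm$coeffs[[1]][["0"]]), 0)
  for (l in 1:3) expect_lt(max(Mod(sm$coeffs[[l + 1]])), 1e-14)

  cs <- charge_set(data.frame(x = 0, y = 0, z = c(0.5, -0.5), q = c(1, -1)))
  sm1 <- cart_to_spherical(cartesian_moments(cs))
  q1 <- sm1$coeffs[[2]]
  expect_gt(Mod(q1[["0"]]), 0)
  expect_lt(Mod(q1[["1"]]), 1e-14)
})

test_that("centers of geometry/charge and the extent behave as defined", {
  cs <- charge_set(data.frame(x = c(1, -1), y = 0, z = 0, q = c(1, 1)))
  expect_equal(center_of_charge(cs), c(0, 0, 0))
  cs2 <- charge_set(data.frame(x = c(1, -2), y = 0, z = 0, q = c(2, 1)))
  expect_equal(center_of_charge(cs2), c(0, 0, 0))
  expect_equal(charge_extent(cs2), 1.5) # center of geometry at (-0.5, 0, 0)
  neutral <- charge_set(data.frame(x = c(1, -1), y = 0, z = 0, q = c(1, -1)))
  expect_error(center_of_charge(neutral), "neutral")
})

test_that("center of dipole: symmetry, translation covariance, optimizer oracle", {
  pair <- charge_set(data.frame(x = 0, y = 0, z = c(0.5, -0.5), q = c(1, -1)))
  expect_equal(center_of_dipole(pair), c(0, 0, 0), tolerance = 1e-12)
  moved <- transform_charge_set(pair, shift = c(1, 2, 3))
  expect_equal(center_of_dipole(moved), c(1, 2, 3), tolerance = 1e-12)

  # closed form vs brute-force minimization of the l = 2 channel norm of
  # the residual quadrupole over candidate expansion centers
  for (s in 1:6) {
    cs <- neutral_set(s)
    cod <- center_of_dipole(cs)
    obj <- function(r0) {
      sm <- spherical_moments(cs, r0, 2)
      sum(Mod(sm$coeffs[[3]])^2)
    }
    fit <- optim(center_of_geometry(cs), obj, method = "BFGS",
      control = list(reltol = 1e-15, maxit = 500)
    )
    expect_lt(sqrt(sum((fit$par - cod)^2)), 1e-6)
  }

  expect_error(
    center_of_dipole(degenerate_fixtures()$zero_dipole_quadrupole),
    "zero"
  )
})

test_that("quadrupole principal axes are ordered, deterministic and reconstruct", {
  pq <- quadrupole_principal_axes(diag(c(2, -1, -1)))
  expect_equal(pq$values[1], 2)
  expect_equal(abs(pq$vectors[, 1]), c(1, 0, 0), tolerance = 1e-12)
  expect_gt(pq$vectors[which.max(abs(pq$vectors[, 1])), 1], 0)

  pq0 <- quadrupole_principal_axes(matrix(0, 3, 3))
  expect_true(pq0$degenerate)
  expect_equal(pq0$values, c(0, 0, 0))

  for (s in 1:10) {
    Th <- cartesian_moments(charged_set(s), center_of_charge(charged_set(s)), 2)$Theta
    pq <- quadrupole_principal_axes(Th)
    expect_true(all(diff(abs(pq$values)) <= 1e-12))
    expect_equal(
      pq$vectors %*% diag(pq$values) %*% t(pq$vectors), Th,
      tolerance = 1e-9
    )
    expect_equal(crossprod(pq$vectors), diag(3), tolerance = 1e-10)
    expect_lt(abs(sum(pq$values)) / (max(abs(pq$values)) + 1e-30), 1e-9)
  }
})

test_that("published water octupole satisfies the trace identity within print rounding", {
  w <- water_qm_moments()
  expect_lt(abs(w$Omega_zzz + w$Omega_xxz + w$Omega_yyz), 0.015)
  expect_lt(abs(w$Theta_zz + w$Theta_xx + w$Theta_yy), 0.015)
  # after unit conversion the package-facing tensors are exactly traceless
  cm <- c2v_target_moments(w)
  expect_lt(abs(sum(diag(cm$Theta))), 1e-12)
  for (g in 1:3) {
    expect_lt(abs(sum(vapply(1:3, function(a) cm$Omega[a, a, g], 1))), 1e-12)
  }
})
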