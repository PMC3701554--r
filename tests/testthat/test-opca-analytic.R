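test_that("one-charge solution: trivial cases and moment identities", {
  single <- charge_set(data.frame(x = 1, y = -1, z = 2, q = 0.5))
  r <- opca1(single)
  expect_equal(as.data.frame(r$approx), as.data.frame(single),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_gte(r$matched_order, 1)

  two <- charge_set(data.frame(x = c(1, -2), y = 0, z = 0, q = c(2, 1)))
  r2 <- opca1(two)
  expect_equal(r2$approx$q, 3)
  expect_equal(unlist(r2$approx[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))

  # the dipole of the result matches the original about any origin
  for (s in 1:10) {
    cs <- charged_set(s)
    r <- opca1(cs)
    o <- rnorm(3)
    expect_equal(
      cartesian_moments(r$approx, o, 1)$p,
      cartesian_moments(cs, o, 1)$p,
      tolerance = 1e-9
    )
  }
  expect_error(opca1(neutral_set(1)), "net charge")
})

test_that("two-charge neutral solution: construction identities", {
  # an exact physical dipole is its own two-charge optimum
  pair <- charge_set(data.frame(x = 0, y = 0, z = c(0.2, -0.2), q = c(1, -1)))
  r <- opca2_neutral(pair)
  got <- as.matrix(r$approx[order(r$approx$q), c("x", "y", "z", "q")])
  want <- as.matrix(pair[order(pair$q), c("x", "y", "z", "q")])
  expect_equal(got, want, tolerance = 1e-8)

  for (s in c(1, 2, 3)) {
    cs <- neutral_set(s)
    r <- opca2_neutral(cs)
    expect_equal(sum(r$approx$q), 0, tolerance = 1e-12)
    expect_equal(
      cartesian_moments(r$approx, c(0, 0, 0), 1)$p,
      cartesian_moments(cs, c(0, 0, 0), 1)$p,
      tolerance = 1e-10
    )
    # the pair has no quadrupole about the center of dipole
    cod <- center_of_dipole(cs)
    expect_lt(max(abs(cartesian_moments(r$approx, cod, 2)$Theta)), 1e-10)
  }
})

test_that("practical neutral pair: fixed separation, preserved moments, bound shift", {
  cfg <- ppca_config()
  for (s in c(1, 5)) {
    cs <- neutral_set(s)
    r <- ppca2_neutral(cs, cfg)
    expect_equal(sum(r$approx$q), 0, tolerance = 1e-12)
    expect_equal(
      cartesian_moments(r$approx, c(0, 0, 0), 1)$p,
      cartesian_moments(cs, c(0, 0, 0), 1)$p,
      tolerance = 1e-12
    )
    pos <- as.matrix(r$approx[, c("x", "y", "z")])
    expect_equal(sqrt(sum((pos[1, ] - pos[2, ])^2)), cfg$d_sep, tolerance = 1e-12)
    if (r$fallback == "none") {
      expect_equal(unname(colMeans(pos)), center_of_dipole(cs), tolerance = 1e-10)
    }
  }

  # a weak dipole on a strong quadrupole puts the center of dipole far
  # outside; step (iv) must pull the pair back within 1.5 a
  fx <- degenerate_fixtures()$cod_outside
  a <- charge_extent(fx)
  g <- center_of_geometry(fx)
  expect_gt(sqrt(sum((center_of_dipole(fx) - g)^2)), 1.5 * a)
  r <- ppca2_neutral(fx)
  expect_equal(r$fallback, "bound_shift")
  pos <- as.matrix(r$approx[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(pos, 2, g)^2))
  expect_true(all(d <= 1.5 * a + 1e-9))
})

test_that("imaginary closed-form charge triggers the small-separation fallback", {
  fx <- degenerate_fixtures()$imaginary_charge
  # verify the criterion directly: octupole contraction along the dipole
  # direction (about the center of dipole) is negative
  p <- cartesian_moments(fx, c(0, 0, 0), 1)$p
  phat <- p / sqrt(sum(p^2))
  Om <- cartesian_moments(fx, center_of_dipole(fx), 3)$Omega
  ohat <- 0
  for (a in 1:3) {
    for (b in 1:3) for (g in 1:3) ohat <- ohat + Om[a, b, g] * phat[a] * phat[b] * phat[g]
  }
  expect_lt(ohat, 0)
  r <- opca2_neutral(fx)
  expect_equal(r$fallback, "small_separation")
  pos <- as.matrix(r$approx[, c("x", "y", "z")])
  expect_equal(sqrt(sum((pos[1, ] - pos[2, ])^2)), ppca_config()$d_sep,
    tolerance = 1e-12
  )
})

test_that("neutral zero-dipole input raises the documented degenerate error", {
  sq <- degenerate_fixtures()$zero_dipole_quadrupole
  expect_error(opca2_neutral(sq), "zero dipole")
  expect_error(ppca2_neutral(sq), "zero dipole")
})

test_that("charged pair: monopole, center of charge and principal quadrupole match", {
  for (s in 1:8) {
    cs <- charged_set(s)
    r <- ppca2_charged(cs)
    expect_equal(sum(r$approx$q), sum(cs$q), tolerance = 1e-12)
    coc <- center_of_charge(cs)
    expect_equal(center_of_charge(r$approx), coc, tolerance = 1e-10)
    pq <- quadrupole_principal_axes(cartesian_moments(cs, coc, 2)$Theta)
    v1 <- pq$vectors[, 1]
    Tp <- cartesian_moments(r$approx, coc, 2)$Theta
    expect_equal(drop(t(v1) %*% Tp %*% v1), pq$values[1], tolerance = 1e-9)
    # both charges lie on the principal axis through the center of charge
    rel <- sweep(as.matrix(r$approx[, c("x", "y", "z")]), 2, coc)
    off_axis <- rel - outer(drop(rel %*% v1), v1)
    expect_lt(max(abs(off_axis)), 1e-9)
  }
})

test_that("charged pair with the configured distance ratio reproduces itself", {
  k <- ppca_config()$kappa
  t <- 0.6
  cs <- charge_set(data.frame(
    x = c(-k * t, t), y = c(0, 0), z = c(0, 0),
    q = c(1 / (1 + k), k / (1 + k))
  ))
  r <- ppca2_charged(cs)
  got <- as.matrix(r$approx[order(r$approx$q), c("x", "y", "z", "q")])
  want <- as.matrix(cs[order(cs$q), c("x", "y", "z", "q")])
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("charged branch handles degenerate and opposite-sign quadrupole cases", {
  # spherically symmetric charge arrangement: quadrupole vanishes
  shell <- charge_set(data.frame(
    x = c(1, -1, 0, 0, 0, 0), y = c(0, 0, 1, -1, 0, 0),
    z = c(0, 0, 0, 0, 1, -1), q = rep(1 / 6, 6)
  ))
  r <- ppca2_charged(shell)
  expect_equal(r$fallback, "degenerate")
  expect_equal(sum(r$approx$q), 1, tolerance = 1e-12)

  # sign(lambda1) != sign(M): an opposite-sign pair still matches lambda1
  cs <- charge_set(data.frame(
    x = c(2, -2, 0.1), y = c(0, 0, 0), z = c(0.3, 0.3, -0.1),
    q = c(-1, -1, 3)
  ))
  coc <- center_of_charge(cs)
  pq <- quadrupole_principal_axes(cartesian_moments(cs, coc, 2)$Theta)
  expect_lt(pq$values[1] / sum(cs$q), 0)
  r2 <- ppca2_charged(cs)
  Tp <- cartesian_moments(r2$approx, coc, 2)$Theta
  v1 <- pq$vectors[, 1]
  expect_equal(drop(t(v1) %*% Tp %*% v1), pq$values[1], tolerance = 1e-9)
  expect_lt(min(r2$approx$q) * max(r2$approx$q), 0)
})

test_that("the two-charge dispatcher routes by net charge with the boundary neutral", {
  expect_equal(ppca2(neutral_set(1))$method, "ppca2_neutral")
  expect_equal(ppca2(charged_set(1))$method, "ppca2_charged")
  almost <- neutral_set(2)
  almost$q[1] <- almost$q[1] + ppca_config()$neutral_tol / 2
  expect_equal(ppca2(almost)$method, "ppca2_neutral")
})

test_that("error vs separation shows the documented small-separation trends", {
  rms_at_sep <- function(cs, d) {
    r <- ppca2_neutral(cs, ppca_config(d_sep = d))
    a <- charge_extent(cs)
    g <- sphere_grid(center_of_geometry(cs), 2 * a, 400)
    rms_error(coulomb_potential(cs, g), coulomb_potential(r$approx, g))
  }
  seps <- c(1.6, 0.8, 0.4, 0.2, 0.1, 0.05)
  # negative octupole contraction: shrinking the separation never hurts
  fx <- degenerate_fixtures()$imaginary_charge
  errs <- vapply(seps, function(d) rms_at_sep(fx, d), 1)
  expect_true(all(diff(errs) <= 1e-6))
  # positive contraction: the optimal separation is interior, so the curve
  # through the closed-form optimum beats both a tiny and a huge separation
  cs <- neutral_set(1)
  ropt <- opca2_neutral(cs)
  expect_equal(ropt$fallback, "none")
  d_opt <- {
    pos <- as.matrix(ropt$approx[, c("x", "y", "z")])
    sqrt(sum((pos[1, ] - pos[2, ])^2))
  }
  a <- charge_extent(cs)
  g <- sphere_grid(center_of_geometry(cs), 2 * a, 400)
  e_opt <- rms_error(coulomb_potential(cs, g), coulomb_potential(ropt$approx, g))
  expect_lt(e_opt, rms_at_sep(cs, d_opt / 12))
  expect_lt(e_opt, rms_at_sep(cs, d_opt * 3))
})
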