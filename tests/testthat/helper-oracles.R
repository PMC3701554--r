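# Independent oracles, deliberately written as plain loops so they share no
# code with the vectorized implementation paths they check.

# direct-sum Cartesian moments (Buckingham 1/2-prefactor convention)
oracle_moments <- function(cs, origin = c(0, 0, 0)) {
  M <- 0
  p <- c(0, 0, 0)
  Theta <- matrix(0, 3, 3)
  Omega <- array(0, c(3, 3, 3))
  for (i in seq_len(nrow(cs))) {
    q <- cs$q[i]
    r <- c(cs$x[i], cs$y[i], cs$z[i]) - origin
    r2 <- sum(r * r)
    M <- M + q
    p <- p + q * r
    for (a in 1:3) {
      for (b in 1:3) {
        Theta[a, b] <- Theta[a, b] + 0.5 * q * (3 * r[a] * r[b] - r2 * (a == b))
        for (cc in 1:3) {
          Omega[a, b, cc] <- Omega[a, b, cc] + 0.5 * q *
            (5 * r[a] * r[b] * r[cc] -
              r2 * (r[a] * (b == cc) + r[b] * (a == cc) + r[cc] * (a == b)))
        }
      }
    }
  }
  list(M = M, p = p, Theta = Theta, Omega = Omega)
}

# naive double-loop Coulomb sum
oracle_coulomb <- function(cs, pts) {
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    s <- 0
    for (i in seq_len(nrow(cs))) {
      d <- sqrt((pts[k, 1] - cs$x[i])^2 + (pts[k, 2] - cs$y[i])^2 +
        (pts[k, 3] - cs$z[i])^2)
      s <- s + cs$q[i] / d
    }
    out[k] <- s
  }
  out
}

# random rotation matrix from a seed (QR of a Gaussian matrix, det +1)
oracle_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

neutral_set <- function(seed, n = 8, radius = 3) {
  random_charge_set(synth_spec(n_charges = n, radius = radius, net_charge = 0, seed = seed))
}

charged_set <- function(seed, n = 10, radius = 3, net = 1) {
  random_charge_set(synth_spec(n_charges = n, radius = radius, net_charge = net, seed = seed))
}

# sum over m of |q_lm|^2 channel difference at one order
channel_diff <- function(cs_a, cs_b, origin, l) {
  sa <- spherical_moments(cs_a, origin, l)
  sb <- spherical_moments(cs_b, origin, l)
  sum(Mod(sa$coeffs[[l + 1]] - sb$coeffs[[l + 1]])^2)
}
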