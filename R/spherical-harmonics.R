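# Orthonormal complex spherical harmonics built on the associated Legendre
# functions of pracma::legendre (MATLAB convention, Condon-Shortley phase
# included). All error metrics in the package use this single convention.

.convention <- "buckingham-traceless; orthonormal complex Ylm (Condon-Shortley); e, Angstrom"

# Y_lm(theta, phi) for m = -l..l at a vector of angles.
# Returns a complex matrix, length(theta) x (2l+1), columns named by m.
.ylm <- function(l, theta, phi) {
  n <- length(theta)
  if (l == 0) {
    out <- matrix(complex(real = rep(1 / sqrt(4 * pi), n)), ncol = 1)
    colnames(out) <- "0"
    return(out)
  }
  x <- cos(theta)
  if (l <= 3) {
    # explicit associated Legendre values (Condon-Shortley phase), much
    # faster than the generic routine in the hot path of the solvers
    s <- sin(theta)
    P <- switch(l,
      rbind(x, -s),
      rbind((3 * x^2 - 1) / 2, -3 * s * x, 3 * s^2),
      rbind(
        (5 * x^3 - 3 * x) / 2, -1.5 * (5 * x^2 - 1) * s,
        15 * s^2 * x, -15 * s^3
      )
    )
  } else {
    P <- pracma::legendre(l, x) # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  }
  out <- matrix(complex(real = 0), nrow = n, ncol = 2 * l + 1)
  colnames(out) <- as.character(-l:l)
  for (m in 0:l) {
    norm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    ylm <- norm * P[m + 1, ] * exp(1i * m * phi)
    out[, as.character(m)] <- ylm
    if (m > 0) out[, as.character(-m)] <- (-1)^m * Conj(ylm)
  }
  out
}

# Spherical coordinates of rows of a position matrix about an origin.
# Points at (numerically) zero radius get theta = phi = 0; they contribute
# nothing to moments with l >= 1 because of the r^l factor.
.sph_coords <- function(pos, origin) {
  rel <- sweep(pos, 2, origin)
  r <- sqrt(rowSums(rel^2))
  safe <- pmax(r, .Machine$double.eps)
  theta <- acos(pmin(1, pmax(-1, rel[, 3] / safe)))
  theta[r < 1e-300] <- 0
  phi <- atan2(rel[, 2], rel[, 1])
  list(r = r, theta = theta, phi = phi)
}
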