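#' Cartesian multipole moments of a charge set
#'
#' Computes the monopole `M = sum(q_i)`, dipole `p = sum(q_i r_i)`, traceless
#' quadrupole `Theta` and traceless octupole `Omega` about a stated origin,
#' in the Buckingham (1/2-prefactor) convention:
#' \deqn{\Theta_{ab} = \tfrac12 \sum_i q_i (3 r_a r_b - r^2 \delta_{ab})}
#' \deqn{\Omega_{abc} = \tfrac12 \sum_i q_i \{5 r_a r_b r_c -
#'   r^2 (r_a \delta_{bc} + r_b \delta_{ac} + r_c \delta_{ab})\}}
#' Units are e, e·Å, e·Å² and e·Å³. Both tensors are fully symmetric and all
#' single-index contractions vanish, which makes the lowest non-vanishing
#' moment independent of the choice of origin.
#'
#' @inheritParams center_of_geometry
#' @param origin Expansion origin (3-vector, Angstrom).
#' @param order Highest order to compute: 0 (monopole) to 3 (octupole).
#' @return An object of class `cart_moments`: a list with `origin`, `M`,
#'   `p`, `Theta` (3x3), `Omega` (3x3x3), `order` and the `convention`
#'   string.
#' @examples
#' cs <- charge_set(data.frame(x = 0, y = 0, z = c(0.5, -0.5), q = c(1, -1)))
#' cartesian_moments(cs)$p
#' @export
cartesian_moments <- function(cs, origin = c(0, 0, 0), order = 3) {
  cs <- as_charge_set(cs)
  origin <- .as_point(origin)
  stopifnot(length(order) == 1, order %in% 0:3)
  rel <- sweep(.positions(cs), 2, origin)
  q <- cs$q
  M <- sum(q)
  p <- c(0, 0, 0)
  Theta <- matrix(0, 3, 3)
  Omega <- array(0, c(3, 3, 3))
  if (order >= 1) p <- unname(colSums(q * rel))
  r2 <- rowSums(rel^2)
  if (order >= 2) {
    for (a in 1:3) {
      for (b in a:3) {
        v <- 0.5 * sum(q * (3 * rel[, a] * rel[, b] - r2 * (a == b)))
        Theta[a, b] <- v
        Theta[b, a] <- v
      }
    }
  }
  if (order >= 3) {
    for (a in 1:3) {
      for (b in a:3) {
        for (cc in b:3) {
          v <- 0.5 * sum(q * (5 * rel[, a] * rel[, b] * rel[, cc] -
            r2 * (rel[, a] * (b == cc) + rel[, b] * (a == cc) + rel[, cc] * (a == b))))
          for (perm in list(
            c(a, b, cc), c(a, cc, b), c(b, a, cc),
            c(b, cc, a), c(cc, a, b), c(cc, b, a)
          )) {
            Omega[perm[1], perm[2], perm[3]] <- v
          }
        }
      }
    }
  }
  structure(
    list(
      origin = origin, M = M, p = p, Theta = Theta, Omega = Omega,
      order = order, convention = .convention
    ),
    class = "cart_moments"
  )
}

#' @export
print.cart_moments <- function(x, ...) {
  cat(sprintf(
    "<cart_moments> order %d about (%.3f, %.3f, %.3f) A\n",
    x$order, x$origin[1], x$origin[2], x$origin[3]
  ))
  cat(sprintf("  M = %.6g e\n", x$M))
  if (x$order >= 1) cat(sprintf("  p = (%.6g, %.6g, %.6g) e.A\n", x$p[1], x$p[2], x$p[3]))
  if (x$order >= 2) cat(sprintf("  |Theta|_F = %.6g e.A^2\n", sqrt(sum(x$Theta^2))))
  if (x$order >= 3) cat(sprintf("  |Omega|_F = %.6g e.A^3\n", sqrt(sum(x$Omega^2))))
  invisible(x)
}

#' Spherical multipole moments of a charge set
#'
#' Complex coefficients `q_lm = sum(q_i r_i^l conj(Y_lm(theta_i, phi_i)))`
#' for `0 <= l <= l_max`, with orthonormal complex spherical harmonics. For
#' a real charge distribution `q_{l,-m} = (-1)^m conj(q_lm)`.
#'
#' @inheritParams cartesian_moments
#' @param l_max Highest multipole order (any non-negative integer).
#' @return An object of class `sph_moments`: list with `origin`, `l_max`,
#'   `coeffs` (a list indexed by `l + 1`; each element a complex vector
#'   named by `m = -l..l`) and the `convention` string.
#' @export
spherical_moments <- function(cs, origin = c(0, 0, 0), l_max = 3) {
  cs <- as_charge_set(cs)
  origin <- .as_point(origin)
  stopifnot(l_max >= 0)
  sc <- .sph_coords(.positions(cs), origin)
  coeffs <- purrr::map(0:l_max, function(l) {
    Y <- .ylm(l, sc$theta, sc$phi)
    drop(t(Conj(Y)) %*% (cs$q * sc$r^l))
  })
  structure(
    list(origin = origin, l_max = l_max, coeffs = coeffs, convention = .convention),
    class = "sph_moments"
  )
}

#' @export
print.sph_moments <- function(x, ...) {
  cat(sprintf(
    "<sph_moments> l_max %d about (%.3f, %.3f, %.3f) A\n",
    x$l_max, x$origin[1], x$origin[2], x$origin[3]
  ))
  for (l in 0:x$l_max) {
    cat(sprintf("  l=%d: |q_l.|^2 = %.6g\n", l, sum(Mod(x$coeffs[[l + 1]])^2)))
  }
  invisible(x)
}

# sum over m of |q_lm|^2 for one l (rotationally invariant per-order norm)
.sph_l2 <- function(sm, l) sum(Mod(sm$coeffs[[l + 1]])^2)

#' Convert Cartesian moments to spherical moments
#'
#' Exact linear map for `l <= 3` between the Buckingham traceless Cartesian
#' tensors and the orthonormal complex spherical coefficients.
#'
#' @param cm A `cart_moments` object from [cartesian_moments()].
#' @return A `sph_moments` object with `l_max = cm$order`.
#' @export
cart_to_spherical <- function(cm) {
  stopifnot(inherits(cm, "cart_moments"))
  coeffs <- vector("list", cm$order + 1)
  named <- function(v, l) {
    names(v) <- as.character(-l:l)
    v
  }
  with_conj <- function(pos, l) {
    # fill m < 0 channels from q_{l,-m} = (-1)^m conj(q_lm)
    v <- complex(real = rep(0, 2 * l + 1))
    v[(l + 1):(2 * l + 1)] <- pos
    if (l > 0) {
      for (m in 1:l) v[l + 1 - m] <- (-1)^m * Conj(pos[m + 1])
    }
    named(v, l)
  }
  coeffs[[1]] <- named(complex(real = cm$M / sqrt(4 * pi)), 0)
  if (cm$order >= 1) {
    p <- cm$p
    q10 <- complex(real = sqrt(3 / (4 * pi)) * p[3])
    q11 <- -sqrt(3 / (8 * pi)) * complex(real = p[1], imaginary = -p[2])
    coeffs[[2]] <- with_conj(c(q10, q11), 1)
  }
  if (cm$order >= 2) {
    Th <- cm$Theta
    q20 <- complex(real = sqrt(5 / (16 * pi)) * 2 * Th[3, 3])
    q21 <- -sqrt(15 / (8 * pi)) * (2 / 3) *
      complex(real = Th[1, 3], imaginary = -Th[2, 3])
    q22 <- sqrt(15 / (32 * pi)) * (2 / 3) *
      complex(real = Th[1, 1] - Th[2, 2], imaginary = -2 * Th[1, 2])
    coeffs[[3]] <- with_conj(c(q20, q21, q22), 2)
  }
  if (cm$order >= 3) {
    Om <- cm$Omega
    q30 <- complex(real = sqrt(7 / (16 * pi)) * 2 * Om[3, 3, 3])
    q31 <- -sqrt(21 / (64 * pi)) * 2 *
      complex(real = Om[1, 3, 3], imaginary = -Om[2, 3, 3])
    q32 <- sqrt(105 / (32 * pi)) * (2 / 5) *
      complex(real = Om[1, 1, 3] - Om[2, 2, 3], imaginary = -2 * Om[1, 2, 3])
    q33 <- -sqrt(35 / (64 * pi)) * (2 / 5) *
      complex(
        real = Om[1, 1, 1] - 3 * Om[1, 2, 2],
        imaginary = -(3 * Om[1, 1, 2] - Om[2, 2, 2])
      )
    coeffs[[4]] <- with_conj(c(q30, q31, q32, q33), 3)
  }
  structure(
    list(
      origin = cm$origin, l_max = cm$order, coeffs = coeffs,
      convention = cm$convention
    ),
    class = "sph_moments"
  )
}

#' Recompute moments about a new origin
#'
#' Recomputes the Cartesian moments of a charge set about a different
#' origin. Translation is done by recomputation from the charges rather
#' than by tensor translation theorems, which keeps the result convention
#' independent.
#'
#' @inheritParams cartesian_moments
#' @param new_origin The new expansion origin.
#' @return A `cart_moments` object about `new_origin`.
#' @export
shift_origin <- function(cs, new_origin, order = 3) {
  cartesian_moments(cs, origin = new_origin, order = order)
}

#' Center of dipole of a neutral charge set
#'
#' The expansion center `R0` at which the quadrupole-order term of the
#' moment-discrepancy expansion is minimized for a dipole-matched two-charge
#' pair centered at `R0`. Because a symmetric pair has no quadrupole about
#' its own center, `R0` is equivalently the point minimizing the Frobenius
#' norm of the distribution's traceless quadrupole. For a neutral set with
#' dipole `p` and quadrupole `Theta` about any origin, the closed form is
#' \deqn{R_0 = \frac{2\,\Theta p}{3 |p|^2} -
#'   \frac{(p^T \Theta p)\, p}{6 |p|^4}}
#' relative to that origin. This is the optimal expansion center for the
#' point-dipole approximation of a neutral distribution.
#'
#' @inheritParams center_of_geometry
#' @return A 3-vector in Angstrom.
#' @export
center_of_dipole <- function(cs) {
  cs <- as_charge_set(cs)
  if (!is_neutral(cs)) {
    stop("center of dipole requires a neutral set; use center_of_charge()",
      call. = FALSE
    )
  }
  cm <- cartesian_moments(cs, origin = c(0, 0, 0), order = 2)
  p <- cm$p
  p2 <- sum(p^2)
  if (sqrt(p2) <= .dipole_tol) {
    stop("center of dipole undefined: |p| is (numerically) zero", call. = FALSE)
  }
  Tp <- drop(cm$Theta %*% p)
  as.numeric(2 * Tp / (3 * p2) - sum(p * Tp) * p / (6 * p2^2))
}

#' Principal axes of a quadrupole tensor
#'
#' Eigendecomposition of the symmetric traceless quadrupole, with
#' eigenvalues ordered by decreasing magnitude. Output is made
#' deterministic: each eigenvector is flipped so that its
#' largest-magnitude component is positive; magnitude ties (within 1e-12)
#' are broken by descending signed eigenvalue, then lexicographically by
#' eigenvector.
#'
#' @param Theta A symmetric 3x3 matrix (e·Å²), e.g. `cartesian_moments(cs)$Theta`.
#' @return A list of class `principal_quadrupole` with `values` (length-3,
#'   `|l1| >= |l2| >= |l3|`), `vectors` (3x3, columns are the axes) and
#'   `degenerate` (TRUE when all eigenvalues are numerically zero).
#' @export
quadrupole_principal_axes <- function(Theta) {
  stopifnot(is.matrix(Theta), all(dim(Theta) == c(3, 3)))
  if (max(abs(Theta - t(Theta))) > 1e-8 * max(1, max(abs(Theta)))) {
    stop("Theta must be symmetric", call. = FALSE)
  }
  e <- eigen((Theta + t(Theta)) / 2, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors
  # deterministic ordering: |lambda| desc, ties by signed lambda desc then
  # lexicographic eigenvector
  fix_sign <- function(v) {
    i <- which.max(abs(v))
    if (v[i] < 0) -v else v
  }
  vecs <- apply(vecs, 2, fix_sign)
  key <- order(-abs(vals), -vals, apply(vecs, 2, paste, collapse = ","))
  # treat |lambda| within 1e-12 as tied for the magnitude key
  mag <- abs(vals)
  grp <- round(mag / 1e-12)
  key <- order(-grp, -vals, apply(round(vecs, 9), 2, paste, collapse = ","))
  vals <- vals[key]
  vecs <- vecs[, key, drop = FALSE]
  structure(
    list(
      values = vals, vectors = vecs,
      degenerate = all(abs(vals) < 1e-12)
    ),
    class = "principal_quadrupole"
  )
}
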