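# Debye conversion: 1 debye = 0.2082 e.Angstrom
.debye <- 0.2082

#' Gas-phase multipole moments of the water molecule
#'
#' The dipole, traceless quadrupole and traceless octupole of an ab initio
#' (coupled-cluster) gas-phase charge density of a single water molecule,
#' in the standard molecular frame: origin at the oxygen nucleus, molecule
#' in the y-z plane, z axis bisecting the H-O-H angle (hydrogens on the
#' positive z side). Units are debye (dipole), debye-Angstrom (quadrupole)
#' and debye-Angstrom squared (octupole); `1 D = 0.2082 e*Angstrom`. By the
#' C2v symmetry of the molecule the only independent components are `p_z`,
#' the quadrupole diagonal and `O_zzz`, `O_xxz`, `O_yyz`; tracelessness ties
#' each diagonal set together.
#'
#' @return A list of class `c2v_target` with fields `p_z`, `Theta_zz`,
#'   `Theta_xx`, `Theta_yy`, `Omega_zzz`, `Omega_xxz`, `Omega_yyz` and a
#'   `frame` descriptor.
#' @export
water_qm_moments <- function() {
  structure(
    list(
      p_z = 1.81,
      Theta_zz = 0.08, Theta_xx = -2.53, Theta_yy = 2.45,
      Omega_zzz = -1.35, Omega_xxz = -1.25, Omega_yyz = 2.61,
      frame = "origin at O; molecule in y-z plane; z bisects the hydrogens"
    ),
    class = "c2v_target"
  )
}

#' @export
print.c2v_target <- function(x, ...) {
  cat("<c2v_target>", x$frame, "\n")
  cat(sprintf("  p_z = %.2f D\n", x$p_z))
  cat(sprintf(
    "  Theta (D.A): zz %.2f, xx %.2f, yy %.2f\n",
    x$Theta_zz, x$Theta_xx, x$Theta_yy
  ))
  cat(sprintf(
    "  Omega (D.A^2): zzz %.2f, xxz %.2f, yyz %.2f\n",
    x$Omega_zzz, x$Omega_xxz, x$Omega_yyz
  ))
  invisible(x)
}

# Target components in e/Angstrom units. Printed moment tables are rounded,
# so the quadrupole/octupole components may fail tracelessness by a last
# digit; physical traceless tensors are restored by projecting out the
# trace part (for the octupole: subtract (3, 1, 1)/5 * trace from the
# (zzz, xxz, yyz) components). Without this projection the rounding defect
# -- not the physics -- would pick the solution on the one-parameter family.
.c2v_target_atomic <- function(target) {
  stopifnot(inherits(target, "c2v_target"))
  tg <- lapply(
    target[c(
      "p_z", "Theta_zz", "Theta_xx", "Theta_yy",
      "Omega_zzz", "Omega_xxz", "Omega_yyz"
    )],
    function(v) v * .debye
  )
  trq <- tg$Theta_zz + tg$Theta_xx + tg$Theta_yy
  tg$Theta_zz <- tg$Theta_zz - trq / 3
  tg$Theta_xx <- tg$Theta_xx - trq / 3
  tg$Theta_yy <- tg$Theta_yy - trq / 3
  tro <- tg$Omega_zzz + tg$Omega_xxz + tg$Omega_yyz
  tg$Omega_zzz <- tg$Omega_zzz - 3 * tro / 5
  tg$Omega_xxz <- tg$Omega_xxz - tro / 5
  tg$Omega_yyz <- tg$Omega_yyz - tro / 5
  tg
}

# Closed-form family of C2v 3-charge sets matching monopole (zero), dipole
# and quadrupole of the target exactly, parameterized by the on-axis charge
# position z3. Derivation (charges q1 at (0, +/-y, z1), q3 = -2 q1 at
# (0, 0, z3), Buckingham convention):
#   q1 y^2            = (Theta_yy - Theta_xx) / 3
#   q1 (z1^2 - z3^2)  = -(2 Theta_xx + Theta_yy) / 3
#   2 q1 (z1 - z3)    = p_z
# so z1 + z3 = S with S = -2 (2 Theta_xx + Theta_yy) / (3 p_z), and for a
# trial z3: z1 = S - z3, q1 = p_z / (2 (S - 2 z3)), y = sqrt(...) when the
# sign of q1 allows it.
.c2v_family <- function(tg) {
  S <- -2 * (2 * tg$Theta_xx + tg$Theta_yy) / (3 * tg$p_z)
  qy2 <- (tg$Theta_yy - tg$Theta_xx) / 3
  function(z3) {
    den <- S - 2 * z3
    if (abs(den) < 1e-12) {
      return(NULL)
    }
    q1 <- tg$p_z / (2 * den)
    y2 <- qy2 / q1
    if (y2 < -1e-14) {
      return(NULL)
    }
    list(q1 = q1, y = sqrt(max(0, y2)), z1 = S - z3, z3 = z3, q3 = -2 * q1)
  }
}

# octupole components of the C2v family member about the frame origin
.c2v_octupole <- function(sol) {
  with(sol, list(
    zzz = q1 * (2 * z1^3 - 3 * y^2 * z1 - 2 * z3^3),
    xxz = q1 * (z3^3 - (y^2 + z1^2) * z1),
    yyz = q1 * (4 * y^2 * z1 - z1^3 + z3^3)
  ))
}

#' Symmetric three-charge optimal approximation of a C2v target
#'
#' Solves for three point charges respecting C2v symmetry -- a mirror pair
#' `q_pair` at `(0, +/-y_off, z_pair)` and a central charge `q_central =
#' -2 q_pair` on the symmetry axis at `(0, 0, z_central)` -- whose monopole
#' is zero and whose dipole and traceless quadrupole equal the target
#' exactly. Those constraints leave one free parameter; following the
#' error-expansion procedure it is fixed by minimizing the octupole-order
#' term of the moment discrepancy. The search runs over `z_central` on a
#' bounded bracket (grid scan plus golden-section refinement), restricted
#' to the branch where the mirror-pair offset is real.
#'
#' @param target A `c2v_target` (printed-moment units, debye-based), e.g.
#'   [water_qm_moments()].
#' @param objective `"spherical"` (default) minimizes the order-3 term of
#'   the spherical moment discrepancy, i.e. the rotationally invariant
#'   contraction of the traceless octupole difference; `"cartesian"` is a
#'   plain sum of squares of the three independent octupole components,
#'   provided for sensitivity analysis (it weights the components
#'   differently and is not rotationally invariant).
#' @param bracket Search interval for `z_central` in Angstrom.
#' @param tol Convergence tolerance of the one-dimensional search (Angstrom).
#' @return A list of class `c2v_solution`: `q_pair`, `y_off`, `z_pair`,
#'   `q_central`, `z_central`, the solution `charge_set`, achieved octupole
#'   components in both unit systems, and the objective value at the
#'   optimum.
#' @export
solve_water_c2v <- function(target = water_qm_moments(),
                            objective = c("spherical", "cartesian"),
                            bracket = c(0, 1.2), tol = 1e-9) {
  objective <- match.arg(objective)
  tg <- .c2v_target_atomic(target)
  fam <- .c2v_family(tg)
  # invariant octupole contraction for fully symmetric traceless rank-3
  # tensors with C2v sparsity: d_zzz^2 + 3 d_xxz^2 + 3 d_yyz^2 (proportional
  # to the l = 3 spherical channel norm)
  obj <- function(z3) {
    sol <- fam(z3)
    if (is.null(sol)) {
      return(Inf)
    }
    om <- .c2v_octupole(sol)
    dz <- om$zzz - tg$Omega_zzz
    dx <- om$xxz - tg$Omega_xxz
    dy <- om$yyz - tg$Omega_yyz
    if (objective == "spherical") dz^2 + 3 * dx^2 + 3 * dy^2 else dz^2 + dx^2 + dy^2
  }
  grid <- seq(bracket[1], bracket[2], length.out = 4801)
  vals <- vapply(grid, obj, numeric(1))
  if (!any(is.finite(vals))) {
    stop("no feasible C2v solution in the bracket (quadrupole pattern infeasible)",
      call. = FALSE
    )
  }
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = tol)
  sol <- fam(opt$minimum)
  om <- .c2v_octupole(sol)
  cs <- charge_set(
    tibble::tibble(
      x = c(0, 0, 0),
      y = c(-sol$y, sol$y, 0),
      z = c(sol$z1, sol$z1, sol$z3),
      q = c(sol$q1, sol$q1, sol$q3)
    ),
    label = "c2v 3-charge OPCA"
  )
  structure(
    list(
      q_pair = sol$q1, y_off = sol$y, z_pair = sol$z1,
      q_central = sol$q3, z_central = sol$z3,
      charge_set = cs,
      octupole_eA3 = unlist(om),
      octupole_DA2 = unlist(om) / .debye,
      objective = objective, objective_value = opt$objective,
      target = target
    ),
    class = "c2v_solution"
  )
}

#' @export
print.c2v_solution <- function(x, ...) {
  cat("<c2v_solution> three-charge C2v optimal point charge approximation\n")
  cat(sprintf(
    "  pair:    q = %+.4f e at (0, %+.4f, %.4f) and (0, %+.4f, %.4f) A\n",
    x$q_pair, -x$y_off, x$z_pair, x$y_off, x$z_pair
  ))
  cat(sprintf(
    "  central: q = %+.4f e at (0, 0, %.4f) A\n",
    x$q_central, x$z_central
  ))
  cat(sprintf(
    "  octupole (D.A^2): zzz %.2f, xxz %.2f, yyz %.2f\n",
    x$octupole_DA2[["zzz"]], x$octupole_DA2[["xxz"]], x$octupole_DA2[["yyz"]]
  ))
  invisible(x)
}

#' Atom-centered three-charge baseline for water
#'
#' The commonly used alternative construction: charges fixed at the three
#' atom centers, magnitudes set so the net charge is zero and the dipole
#' matches the target. The quadrupole is then whatever the geometry gives
#' -- this is the comparison baseline, not an optimized model.
#'
#' @param target A `c2v_target`; only its dipole is used.
#' @param r_oh O-H bond length in Angstrom (default 0.9572, gas-phase
#'   experimental geometry).
#' @param hoh_deg H-O-H angle in degrees (default 104.52).
#' @return A [charge_set()] with oxygen at the origin and the hydrogens in
#'   the y-z plane on the positive z side.
#' @export
water_atom_centered <- function(target = water_qm_moments(), r_oh = 0.9572,
                                hoh_deg = 104.52) {
  p <- target$p_z * .debye
  half <- hoh_deg / 2 * pi / 180
  zh <- r_oh * cos(half)
  yh <- r_oh * sin(half)
  if (abs(zh) < 1e-12) stop("degenerate (collinear) geometry", call. = FALSE)
  qh <- p / (2 * zh)
  charge_set(
    tibble::tibble(
      x = c(0, 0, 0), y = c(0, -yh, yh), z = c(0, zh, zh),
      q = c(-2 * qh, qh, qh)
    ),
    label = "water atom-centered"
  )
}

#' Symmetry specification of the C2v three-charge model
#'
#' Parameterization used with [solve_opca_constrained()]: parameters
#' `(q_pair, q_central, y_off, z_pair, z_central)` expand to the mirror
#' pair plus on-axis charge. The monopole is not hardwired, so the solver's
#' first stage must discover `q_central = -2 q_pair`.
#'
#' @return A symmetry specification list.
#' @export
c2v_symmetry <- function() {
  list(
    n_par = 5,
    expand = function(par) {
      charge_set(tibble::tibble(
        x = c(0, 0, 0),
        y = c(-abs(par[3]), abs(par[3]), 0),
        z = c(par[4], par[4], par[5]),
        q = c(par[1], par[1], par[2])
      ))
    },
    init = function() c(5, -10, 0.2, 0.5, 0.4)
  )
}

#' Cartesian moments of a C2v target in atomic units
#'
#' Expands the printed debye-based components of a [water_qm_moments()]
#' style target into full `cart_moments` tensors (e, Angstrom units) about
#' the frame origin, applying the C2v symmetry relations.
#'
#' @param target A `c2v_target`.
#' @return A `cart_moments` object (order 3, zero monopole).
#' @export
c2v_target_moments <- function(target) {
  tg <- .c2v_target_atomic(target)
  Theta <- diag(c(tg$Theta_xx, tg$Theta_yy, tg$Theta_zz))
  Omega <- array(0, c(3, 3, 3))
  put <- function(idx, v) {
    for (perm in list(
      idx, idx[c(1, 3, 2)], idx[c(2, 1, 3)],
      idx[c(2, 3, 1)], idx[c(3, 1, 2)], idx[c(3, 2, 1)]
    )) {
      Omega[perm[1], perm[2], perm[3]] <<- v
    }
  }
  put(c(3, 3, 3), tg$Omega_zzz)
  put(c(1, 1, 3), tg$Omega_xxz)
  put(c(2, 2, 3), tg$Omega_yyz)
  structure(
    list(
      origin = c(0, 0, 0), M = 0, p = c(0, 0, tg$p_z), Theta = Theta,
      Omega = Omega, order = 3, convention = .convention
    ),
    class = "cart_moments"
  )
}
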