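# Tolerances shared across the package. A force-field charge set is "neutral"
# when |M| falls below .neutral_tol (partial charges are rounded, so exact
# zero tests are brittle); a dipole below .dipole_tol is treated as absent.
.neutral_tol <- 1e-8 # e
.dipole_tol <- 1e-10 # e Angstrom

#' Create a charge set
#'
#' A charge set is the universal currency of the package: a tibble with one
#' row per point charge and columns `x`, `y`, `z` (Angstrom) and `q`
#' (elementary charges, e). Any data frame with those columns can be used
#' directly; `charge_set()` validates and attaches a label.
#'
#' @param x A data frame with numeric columns `x`, `y`, `z`, `q`, or a
#'   numeric matrix with 4 columns in that order.
#' @param label Free-text label carried along for printing and reports.
#'
#' @return A tibble of class `charge_set` with columns `x`, `y`, `z`, `q`.
#' @examples
#' cs <- charge_set(data.frame(x = 0, y = 0, z = c(0.5, -0.5), q = c(1, -1)))
#' center_of_geometry(cs)
#' @export
charge_set <- function(x, label = "") {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 4)
    x <- tibble::as_tibble(as.data.frame(x))
    names(x) <- c("x", "y", "z", "q")
  }
  stopifnot(is.data.frame(x))
  need <- c("x", "y", "z", "q")
  if (!all(need %in% names(x))) {
    stop("charge set needs columns x, y, z, q", call. = FALSE)
  }
  cs <- tibble::as_tibble(x[, need])
  if (nrow(cs) < 1) stop("charge set must contain at least one charge", call. = FALSE)
  vals <- as.matrix(cs)
  if (!all(is.finite(vals))) stop("charge set contains non-finite values", call. = FALSE)
  class(cs) <- c("charge_set", class(tibble::tibble()))
  attr(cs, "label") <- label
  cs
}

#' @rdname charge_set
#' @export
as_charge_set <- function(x, label = "") {
  if (inherits(x, "charge_set")) x else charge_set(x, label = label)
}

#' @export
print.charge_set <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf(
    "<charge_set> %d charges, net %.6g e%s\n",
    nrow(x), sum(x$q), if (nzchar(lbl %||% "")) paste0("  [", lbl, "]") else ""
  ))
  NextMethod()
}

.positions <- function(cs) as.matrix(cs[, c("x", "y", "z")])

.as_point <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3, all(is.finite(p)))
  p
}

#' Geometric descriptors of a charge set
#'
#' `center_of_geometry()` is the unweighted mean position;
#' `center_of_charge()` is the charge-weighted mean, `sum(q_i r_i) / M`,
#' defined only for sets whose net charge `M` exceeds the neutrality
#' tolerance; `charge_extent()` is the distance `a` from a center (the
#' center of geometry by default) to the outermost charge. The extent sets
#' the natural length scale of the distribution: "mid-field" means
#' evaluation distances around `2a`, "far-field" means much greater than `a`.
#'
#' @param cs A [charge_set()] (or a data frame coercible to one).
#' @param center Point from which the extent is measured (default: center of
#'   geometry).
#' @return A numeric 3-vector (centers) or a single non-negative number
#'   (extent), all in Angstrom.
#' @export
center_of_geometry <- function(cs) {
  cs <- as_charge_set(cs)
  unname(colMeans(.positions(cs)))
}

#' @rdname center_of_geometry
#' @export
center_of_charge <- function(cs) {
  cs <- as_charge_set(cs)
  M <- sum(cs$q)
  if (abs(M) <= .neutral_tol) {
    stop(
      "center of charge is undefined for a (numerically) neutral set; ",
      "use center_of_dipole() or center_of_geometry()",
      call. = FALSE
    )
  }
  unname(colSums(cs$q * .positions(cs)) / M)
}

#' @rdname center_of_geometry
#' @export
charge_extent <- function(cs, center = center_of_geometry(cs)) {
  cs <- as_charge_set(cs)
  center <- .as_point(center)
  max(sqrt(rowSums(sweep(.positions(cs), 2, center)^2)))
}

#' Is a charge set neutral?
#'
#' Net charge within `1e-8` e of zero counts as neutral; sets exactly at the
#' boundary are treated as neutral.
#'
#' @inheritParams center_of_geometry
#' @return Logical scalar.
#' @export
is_neutral <- function(cs) {
  cs <- as_charge_set(cs)
  abs(sum(cs$q)) < .neutral_tol
}

#' Rigidly transform a charge set
#'
#' Helper used throughout tests and examples: rotate by an orthogonal matrix
#' about a center and/or translate.
#'
#' @inheritParams center_of_geometry
#' @param rotation 3x3 orthogonal matrix (default identity).
#' @param shift Translation 3-vector in Angstrom.
#' @param about Center of rotation.
#' @return A transformed `charge_set`.
#' @export
transform_charge_set <- function(cs, rotation = diag(3), shift = c(0, 0, 0),
                                 about = c(0, 0, 0)) {
  cs <- as_charge_set(cs)
  about <- .as_point(about)
  shift <- .as_point(shift)
  pos <- sweep(.positions(cs), 2, about)
  pos <- pos %*% t(rotation)
  pos <- sweep(pos, 2, about + shift, "+")
  out <- cs
  out$x <- pos[, 1]
  out$y <- pos[, 2]
  out$z <- pos[, 3]
  out
}
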