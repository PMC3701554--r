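#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an OPCA result
#'
#' `tidy()` returns one row per approximating charge; `glance()` returns a
#' one-row summary with the matched order, fallback flag and the per-order
#' residuals of the error expansion.
#'
#' @param x An `opca_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.opca_result <- function(x, ...) {
  out <- tibble::as_tibble(x$approx)
  out$charge <- seq_len(nrow(out))
  out[, c("charge", "x", "y", "z", "q")]
}

#' @rdname tidy.opca_result
#' @export
glance.opca_result <- function(x, ...) {
  res <- as.list(x$residual_per_order)
  names(res) <- paste0("residual_l", names(x$residual_per_order))
  tibble::as_tibble(c(
    list(
      n = nrow(x$approx), matched_order = x$matched_order,
      fallback = x$fallback, method = x$method
    ),
    res
  ))
}

#' @rdname tidy.opca_result
#' @export
tidy.c2v_solution <- function(x, ...) {
  out <- tibble::as_tibble(x$charge_set)
  out$charge <- c("pair", "pair", "central")
  out[, c("charge", "x", "y", "z", "q")]
}

#' @rdname tidy.opca_result
#' @export
glance.c2v_solution <- function(x, ...) {
  tibble::tibble(
    q_pair = x$q_pair, y_off = x$y_off, z_pair = x$z_pair,
    q_central = x$q_central, z_central = x$z_central,
    octupole_zzz_DA2 = x$octupole_DA2[["zzz"]],
    octupole_xxz_DA2 = x$octupole_DA2[["xxz"]],
    octupole_yyz_DA2 = x$octupole_DA2[["yyz"]],
    objective = x$objective, objective_value = x$objective_value
  )
}

#' Tidy Cartesian moments into a long tibble
#'
#' One row per independent tensor component, with the order (0 to 3), the
#' component label and the value in e-Angstrom^order units.
#'
#' @param x A `cart_moments` object.
#' @param ... Unused.
#' @return A tibble with columns `order`, `component`, `value`.
#' @export
tidy.cart_moments <- function(x, ...) {
  ax <- c("x", "y", "z")
  rows <- list(tibble::tibble(order = 0L, component = "M", value = x$M))
  if (x$order >= 1) {
    rows <- c(rows, list(tibble::tibble(
      order = 1L, component = paste0("p_", ax), value = x$p
    )))
  }
  if (x$order >= 2) {
    idx <- which(upper.tri(matrix(0, 3, 3), diag = TRUE), arr.ind = TRUE)
    rows <- c(rows, list(tibble::tibble(
      order = 2L,
      component = paste0("Theta_", ax[idx[, 1]], ax[idx[, 2]]),
      value = x$Theta[idx]
    )))
  }
  if (x$order >= 3) {
    combs <- list()
    for (a in 1:3) {
      for (b in a:3) for (cc in b:3) combs <- c(combs, list(c(a, b, cc)))
    }
    rows <- c(rows, list(tibble::tibble(
      order = 3L,
      component = vapply(combs, function(i) paste0("Omega_", paste(ax[i], collapse = "")), ""),
      value = vapply(combs, function(i) x$Omega[i[1], i[2], i[3]], numeric(1))
    )))
  }
  dplyr::bind_rows(rows)
}

#' Plot an OPCA result
#'
#' Projects the original and approximating charges onto a coordinate plane;
#' point area scales with charge magnitude, color with sign.
#'
#' @param object An `opca_result`.
#' @param original Optionally, the original [charge_set()] to overlay.
#' @param plane Two coordinate names, e.g. `c("y", "z")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opca_result <- function(object, original = NULL, plane = c("y", "z"), ...) {
  stopifnot(length(plane) == 2, all(plane %in% c("x", "y", "z")))
  df <- tibble::as_tibble(object$approx)
  df$set <- "approximation"
  if (!is.null(original)) {
    d0 <- tibble::as_tibble(as_charge_set(original))
    d0$set <- "original"
    df <- dplyr::bind_rows(d0, df)
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data[[plane[1]]], y = .data[[plane[2]]],
      size = abs(.data$q), color = factor(sign(.data$q)), shape = .data$set
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(
      values = c("-1" = "#C0392B", "0" = "grey60", "1" = "#2471A3"),
      name = "sign(q)"
    ) +
    ggplot2::scale_size_area(name = "|q| (e)") +
    ggplot2::labs(
      x = paste0(plane[1], " (A)"), y = paste0(plane[2], " (A)"),
      title = "Point charge approximation"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' RMS potential error as a function of evaluation radius
#'
#' Evaluates the exact potential of the original and an approximating set
#' on spheres of increasing radius (centered at the center of geometry by
#' default) and returns the RMS error per radius -- the standard accuracy
#' profile for point-charge approximations. `autoplot()` on the result
#' draws the log-log error curve.
#'
#' @param cs Original [charge_set()].
#' @param approx Approximating [charge_set()] (e.g. `result$approx`).
#' @param radii Radii in Angstrom.
#' @param center Sphere center.
#' @param n_grid Grid points per sphere.
#' @return A tibble of class `rms_profile` with columns `R` and `rms`.
#' @export
rms_profile <- function(cs, approx, radii, center = center_of_geometry(cs),
                        n_grid = 500) {
  cs <- as_charge_set(cs)
  approx <- as_charge_set(approx)
  out <- purrr::map_dfr(radii, function(R) {
    g <- sphere_grid(center, R, n_grid)
    tibble::tibble(
      R = R,
      rms = rms_error(coulomb_potential(cs, g), coulomb_potential(approx, g))
    )
  })
  class(out) <- c("rms_profile", class(out))
  out
}

#' @rdname rms_profile
#' @param object An `rms_profile` tibble.
#' @param ... Unused.
#' @export
autoplot.rms_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$R, y = .data$rms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "evaluation radius R (A)", y = "RMS potential error (e/A)",
      title = "Far-field decay of the approximation error"
    ) +
    ggplot2::theme_minimal()
}
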