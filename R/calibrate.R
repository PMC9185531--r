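# Least-squares calibration of total spectral energy against glucose
# concentration, concentration extrapolation from measured energy, and the
# power-cycle drift diagnostic showing why one session's line cannot
# calibrate another session.

#' Least-squares line through energy-concentration points
#'
#' Closed-form simple linear regression,
#' `k = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)`, `b = ybar - k xbar`.
#' This is the calibration statistic of the pipeline and is implemented
#' directly from the normal equations (and cross-checked against
#' [stats::lm()] in the test suite).
#'
#' @param xs Concentrations (mg/mL), at least two distinct values.
#' @param ys Energies (a.u.^2), same length.
#' @return An object of class `linear_fit`: `slope`, `intercept`, `x_mean`,
#'   `y_mean`, `r_squared`, `n`.
#' @examples
#' fit <- linear_fit(c(1, 2, 3), c(3.1, 5.0, 6.9))
#' tidy(fit)
#' @export
linear_fit <- function(xs, ys) {
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length")
  if (length(xs) < 2L || length(unique(xs)) < 2L) {
    abort("degenerate design: need at least two distinct x values")
  }
  xbar <- mean(xs)
  ybar <- mean(ys)
  sxx <- sum((xs - xbar)^2)
  sxy <- sum((xs - xbar) * (ys - ybar))
  k <- sxy / sxx
  b <- ybar - k * xbar
  ss_res <- sum((ys - (k * xs + b))^2)
  ss_tot <- sum((ys - ybar)^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = k, intercept = b, x_mean = xbar, y_mean = ybar,
         r_squared = max(0, min(1, r2)), n = length(xs)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> E = %.6g * c + %.6g  (r² = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n,
                 x_mean = x$x_mean, y_mean = x$y_mean)
}

#' Fit the energy-versus-concentration calibration line
#'
#' Fits [linear_fit()] to per-record spectral features. By default each
#' concentration class is first collapsed to its mean energy over replicates
#' (the bench protocol measures each solution several times); set
#' `per_class_mean = FALSE` to fit the raw replicates.
#'
#' @param features Tibble with `concentration` and `total_energy` columns
#'   (see [spectral_features()]).
#' @param per_class_mean Average replicate energies per concentration before
#'   fitting (default `TRUE`).
#' @return A `linear_fit`.
#' @export
energy_calibration <- function(features, per_class_mean = TRUE) {
  if (!all(c("concentration", "total_energy") %in% names(features))) {
    abort("`features` must contain `concentration` and `total_energy`")
  }
  df <- if (isTRUE(per_class_mean)) {
    dplyr::summarise(
      dplyr::group_by(features, .data$concentration),
      total_energy = mean(.data$total_energy), .groups = "drop"
    )
  } else {
    features
  }
  linear_fit(df$concentration, df$total_energy)
}

#' Extrapolate concentration from measured energy
#'
#' Inverts the calibration line: `c = (E - b) / k`.
#'
#' @param energy Measured total energy (a.u.^2), vectorized.
#' @param fit A `linear_fit`.
#' @return Concentration estimate(s) in mg/mL.
#' @export
predict_concentration <- function(energy, fit) {
  if (!inherits(fit, "linear_fit")) abort("`fit` must be a linear_fit")
  if (abs(fit$slope) < .Machine$double.eps) {
    abort("zero slope: the calibration line cannot be inverted")
  }
  (energy - fit$intercept) / fit$slope
}

#' Power-cycle drift diagnostic
#'
#' Compares the calibration lines of two power-on sessions and quantifies
#' the error committed by carrying session A's line over to session B:
#' slope/intercept deltas, the within-session mean absolute concentration
#' error of each session's own line, and the cross-session error of
#' predicting session B's concentrations with session A's line.
#'
#' @param features Per-record spectral features with `power_cycle_id`,
#'   `concentration`, `total_energy`.
#' @param session_a,session_b Power-cycle ids of the two sessions.
#' @param per_class_mean Passed to [energy_calibration()].
#' @return One-row tibble with `slope_a`, `slope_b`, `delta_slope`,
#'   `intercept_a`, `intercept_b`, `delta_intercept`, `mae_within_a`,
#'   `mae_within_b`, `mae_cross_ab`.
#' @export
drift_report <- function(features, session_a, session_b,
                         per_class_mean = TRUE) {
  fa <- dplyr::filter(features, .data$power_cycle_id == session_a)
  fb <- dplyr::filter(features, .data$power_cycle_id == session_b)
  if (nrow(fa) == 0L || nrow(fb) == 0L) {
    abort("both sessions must contribute at least one record")
  }
  fit_a <- energy_calibration(fa, per_class_mean)
  fit_b <- energy_calibration(fb, per_class_mean)
  mae <- function(df, fit) {
    mean(abs(predict_concentration(df$total_energy, fit) - df$concentration))
  }
  tibble::tibble(
    slope_a = fit_a$slope, slope_b = fit_b$slope,
    delta_slope = fit_b$slope - fit_a$slope,
    intercept_a = fit_a$intercept, intercept_b = fit_b$intercept,
    delta_intercept = fit_b$intercept - fit_a$intercept,
    mae_within_a = mae(fa, fit_a),
    mae_within_b = mae(fb, fit_b),
    mae_cross_ab = mae(fb, fit_a)
  )
}

#' Plot a calibration line over its data
#'
#' @param object A `linear_fit`.
#' @param features Optional features tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot linear_fit
#' @export
autoplot.linear_fit <- function(object, features = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#d95f02") +
    ggplot2::labs(
      x = "glucose concentration (mg/mL)", y = "total energy (a.u.²)",
      title = sprintf("E = %.3g c + %.3g (r² = %.3f)",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    p <- p + ggplot2::geom_point(
      data = features,
      ggplot2::aes(.data$concentration, .data$total_energy),
      alpha = 0.6
    )
  }
  p
}
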