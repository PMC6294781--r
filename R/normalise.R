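#' Mean MoS of the final steps of each walking trial
#'
#' For the stability-normalised speed procedure, each constant-speed trial
#' contributes the mean anteroposterior MoS at foot touchdown of its final
#' `window` steps (10 by default).
#'
#' @param steps_by_speed Named list mapping speed (names coercible to
#'   numeric, m/s) to `step_records` data.frames (or anything with a `mos`
#'   column in touchdown order).
#' @param window Number of final steps to average (default 10).
#' @return data.frame with columns `speed`, `mean_mos`, `n`.
#' @export
mean_mos_per_speed <- function(steps_by_speed, window = 10) {
  speeds <- as.numeric(names(steps_by_speed))
  if (any(is.na(speeds)))
    stop("steps_by_speed must be a named list with numeric speeds as names")
  out <- data.frame(speed = speeds, mean_mos = NA_real_, n = NA_integer_)
  for (i in seq_along(steps_by_speed)) {
    s <- steps_by_speed[[i]]
    mos <- s$mos[order(s$touchdown_time %||% seq_along(s$mos))]
    if (length(mos) < window)
      stop("trial at speed ", format(speeds[i]), " m/s has only ",
           length(mos), " steps; ", window, " required")
    out$mean_mos[i] <- mean(tail(mos, window))
    out$n[i] <- window
  }
  out[order(out$speed), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the quadratic MoS-versus-speed curve
#'
#' Least-squares fit of `mos(v) = a0 + a1 v + a2 v^2` to per-speed mean MoS
#' values (unweighted; each point is the mean of the same number of steps).
#' With exactly three distinct speeds the quadratic interpolates exactly.
#'
#' @param points data.frame with columns `speed` and `mean_mos` (e.g. from
#'   [mean_mos_per_speed()]), at least 3 distinct speeds.
#' @param target_mos Target MoS in m recorded with the curve (default 0.05).
#' @return An object of class `speed_mos_curve`: coefficients `a0`, `a1`,
#'   `a2`, the input points, `r_squared`, `target_mos`, and `solved_speed`
#'   (`NA` until [solve_normalised_speed()] is called).
#' @seealso [solve_normalised_speed()], [normalised_speed_from_trials()]
#' @export
#' @examples
#' v <- seq(0.4, 1.8, by = 0.2)
#' fit <- fit_mos_speed_curve(data.frame(speed = v,
#'                                       mean_mos = 0.2 - 0.15 * v + 0.025 * v^2))
#' coef(fit)
fit_mos_speed_curve <- function(points, target_mos = 0.05) {
  stopifnot(is.data.frame(points))
  pts <- .check_table(points, c("speed", "mean_mos"), "points")
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (length(unique(pts$speed)) < 3)
    stop("quadratic fit needs at least 3 distinct speeds, got ",
         length(unique(pts$speed)))
  fit <- lm(mean_mos ~ speed + I(speed^2), data = pts)
  cf <- unname(coef(fit))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pts$mean_mos - mean(pts$mean_mos))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(coefficients = c(a0 = cf[1], a1 = cf[2], a2 = cf[3]),
         points = pts, r_squared = r2,
         target_mos = target_mos, solved_speed = NA_real_),
    class = "speed_mos_curve"
  )
}

#' Solve the stability-normalised walking speed
#'
#' Inverts the fitted quadratic: finds the real root of
#' `a0 + a1 v + a2 v^2 = target_mos` inside `speed_range`. If both roots
#' fall in range the one closer to the range midpoint is returned with a
#' warning. With `a2` numerically zero the linear solution is used.
#'
#' @param curve A `speed_mos_curve` from [fit_mos_speed_curve()].
#' @param target_mos Target MoS in m (default: the curve's target).
#' @param speed_range Admissible speed interval in m/s (default
#'   `range(curve$points$speed)`).
#' @return The curve with `solved_speed` (m/s) and `target_mos` filled in.
#'   The fitted quadratic evaluated at `solved_speed` equals `target_mos`
#'   to numerical precision.
#' @export
solve_normalised_speed <- function(curve, target_mos = NULL, speed_range = NULL) {
  stopifnot(inherits(curve, "speed_mos_curve"))
  if (is.null(target_mos)) target_mos <- curve$target_mos
  if (is.null(speed_range)) speed_range <- range(curve$points$speed)
  a <- curve$coefficients
  scale <- max(abs(a), abs(target_mos), .Machine$double.eps)
  roots <- if (abs(a[["a2"]]) < 1e-12 * scale) {
    if (abs(a[["a1"]]) < 1e-12 * scale)
      stop("degenerate curve: both speed coefficients are zero")
    (target_mos - a[["a0"]]) / a[["a1"]]
  } else {
    disc <- a[["a1"]]^2 - 4 * a[["a2"]] * (a[["a0"]] - target_mos)
    if (disc < 0) {
      extremum <- a[["a0"]] - a[["a1"]]^2 / (4 * a[["a2"]])
      stop(sprintf(
        "no real solution: the fitted curve never reaches MoS %.4g m (extremum %.4g m at %.3g m/s)",
        target_mos, extremum, -a[["a1"]] / (2 * a[["a2"]])))
    }
    (-a[["a1"]] + c(-1, 1) * sqrt(disc)) / (2 * a[["a2"]])
  }
  in_range <- roots[roots >= speed_range[1] - 1e-12 &
                      roots <= speed_range[2] + 1e-12]
  if (length(in_range) == 0) {
    vx <- if (abs(a[["a2"]]) > 0) -a[["a1"]] / (2 * a[["a2"]]) else NA_real_
    ex <- if (is.finite(vx)) a[["a0"]] + a[["a1"]] * vx + a[["a2"]] * vx^2 else NA_real_
    stop(sprintf(
      "no root in [%.3g, %.3g] m/s for target MoS %.4g m (curve extremum %.4g m at %.3g m/s)",
      speed_range[1], speed_range[2], target_mos, ex, vx))
  }
  if (length(in_range) > 1) {
    warning("two admissible roots (", paste(format(in_range), collapse = ", "),
            "); returning the one closer to the range midpoint")
    in_range <- in_range[which.min(abs(in_range - mean(speed_range)))]
  }
  curve$solved_speed <- unname(in_range)
  curve$target_mos <- target_mos
  curve
}

#' Evaluate a fitted MoS-speed curve
#'
#' @param object A `speed_mos_curve`.
#' @param speed Speeds (m/s) at which to evaluate; default: the fitted points.
#' @param ... Unused.
#' @return Predicted mean MoS values in m.
#' @export
predict.speed_mos_curve <- function(object, speed = NULL, ...) {
  if (is.null(speed)) speed <- object$points$speed
  a <- object$coefficients
  unname(a[["a0"]] + a[["a1"]] * speed + a[["a2"]] * speed^2)
}

#' @export
coef.speed_mos_curve <- function(object, ...) object$coefficients

#' @export
print.speed_mos_curve <- function(x, ...) {
  a <- x$coefficients
  cat(sprintf("<speed_mos_curve> mos(v) = %.4g %+.4g v %+.4g v^2  (R^2 = %.4f)\n",
              a[["a0"]], a[["a1"]], a[["a2"]], x$r_squared))
  if (is.finite(x$solved_speed))
    cat(sprintf("  stability-normalised speed: %.4f m/s at target MoS %.3f m\n",
                x$solved_speed, x$target_mos))
  else
    cat(sprintf("  not yet solved (target MoS %.3f m)\n", x$target_mos))
  invisible(x)
}

#' @export
plot.speed_mos_curve <- function(x, ...) {
  v <- seq(min(x$points$speed), max(x$points$speed), length.out = 200)
  plot(x$points$speed, x$points$mean_mos, xlab = "walking speed (m/s)",
       ylab = "mean MoS (m)", pch = 19, ...)
  lines(v, predict(x, v))
  if (is.finite(x$solved_speed)) {
    abline(h = x$target_mos, lty = 2)
    abline(v = x$solved_speed, lty = 2)
    points(x$solved_speed, x$target_mos, pch = 4, cex = 1.5)
  }
  invisible(x)
}

#' Stability-normalised walking speed from raw constant-speed trials
#'
#' End-to-end convenience wrapper: filters each trial, detects and corrects
#' gait events, computes per-touchdown MoS, averages the final 10 steps per
#' speed, fits the quadratic and solves it at the target MoS.
#'
#' @param trials Named list (names = speed in m/s) of [trial_recording()]s.
#' @param config A [run_config()].
#' @return A solved `speed_mos_curve`.
#' @export
normalised_speed_from_trials <- function(trials, config = run_config()) {
  steps_by_speed <- lapply(trials, function(tr) {
    ft <- filter_trial(tr, config)
    ev <- detect_gait_events(ft, config)
    compute_step_records(ft, ev$events)
  })
  pts <- mean_mos_per_speed(steps_by_speed, window = 10)
  curve <- fit_mos_speed_curve(pts, target_mos = config$target_mos)
  solve_normalised_speed(curve, speed_range = range(config$speed_grid))
}
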