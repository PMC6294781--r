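#' Analysis run configuration
#'
#' Collects every tunable of the processing pipeline in one validated list.
#' Defaults follow common practice for treadmill perturbation studies with a
#' reduced kinematic model: 12 Hz zero-phase second-order Butterworth
#' filtering, a 50 N vertical-force threshold for force-plate events, a
#' 0.05 m target MoS for speed normalisation over a 0.4-1.8 m/s speed grid,
#' and unilateral belt accelerations of 3 m/s^2 up to 180% of the
#' stability-normalised speed.
#'
#' @param filter_cutoff Low-pass cut-off frequency in Hz.
#' @param filter_order Butterworth filter order (applied twice, zero phase).
#' @param force_threshold Vertical force threshold in N defining force-plate
#'   touchdown/toe-off.
#' @param target_mos Target anteroposterior MoS in m for the
#'   stability-normalised walking speed.
#' @param speed_grid Treadmill speeds (m/s) of the unperturbed walking trials.
#' @param perturbation_accel Belt acceleration magnitude in m/s^2.
#' @param perturbation_factor Peak belt speed as a multiple of the base speed.
#' @param baseline_window Number of steps in the pre-perturbation baseline
#'   window (the 11th-to-2nd-last steps before each perturbation: 10 steps).
#' @param n_post_steps Number of recovery steps labelled after each
#'   perturbation.
#' @param event_match_window Matching window in s when pairing marker and
#'   force events for the event correction.
#' @param debounce Minimum separation in s between marker velocity sign
#'   switches; closer switch pairs are treated as chatter and merged.
#' @param alpha Significance level for the statistical reductions.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class `run_config` (a named list).
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$target_mos
run_config <- function(filter_cutoff = 12,
                       filter_order = 2,
                       force_threshold = 50,
                       target_mos = 0.05,
                       speed_grid = seq(0.4, 1.8, by = 0.2),
                       perturbation_accel = 3,
                       perturbation_factor = 1.8,
                       baseline_window = 10,
                       n_post_steps = 8,
                       event_match_window = 0.05,
                       debounce = 0.1,
                       alpha = 0.05,
                       rng_seed = NULL) {
  stopifnot(
    filter_cutoff > 0, filter_order >= 1,
    force_threshold > 0, target_mos > 0,
    length(speed_grid) >= 3, all(speed_grid > 0),
    perturbation_accel > 0, perturbation_factor > 1,
    baseline_window >= 1, n_post_steps >= 1,
    event_match_window > 0, debounce >= 0,
    alpha > 0, alpha < 1
  )
  structure(
    list(
      filter_cutoff = filter_cutoff,
      filter_order = filter_order,
      force_threshold = force_threshold,
      target_mos = target_mos,
      speed_grid = speed_grid,
      perturbation_accel = perturbation_accel,
      perturbation_factor = perturbation_factor,
      baseline_window = baseline_window,
      n_post_steps = n_post_steps,
      event_match_window = event_match_window,
      debounce = debounce,
      alpha = alpha,
      rng_seed = rng_seed
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Subject parameters for the reduced-model MoS equation
#'
#' The extrapolated centre of mass scales centre-of-mass velocity by
#' `sqrt(g / l_ref)`, the eigenfrequency of an inverted pendulum of length
#' `l_ref`. The reference leg length has no universally agreed measurement
#' protocol; trochanter height in standing is the conventional choice and
#' must be supplied explicitly.
#'
#' @param l_ref Reference leg length in m (> 0).
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @param height Stature in m (metadata only).
#' @param mass Body mass in kg (metadata; also scales synthetic force bursts).
#' @return An object of class `subject_params`.
#' @export
#' @examples
#' subject_params(l_ref = 0.9)
subject_params <- function(l_ref, g = 9.81, height = NA_real_, mass = NA_real_) {
  if (!is.numeric(l_ref) || length(l_ref) != 1 || !is.finite(l_ref) || l_ref <= 0)
    stop("l_ref must be a positive number (reference leg length in m)")
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g <= 0)
    stop("g must be a positive number")
  structure(list(l_ref = l_ref, g = g, height = height, mass = mass),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params> l_ref = %.3f m, g = %.2f m/s^2", x$l_ref, x$g))
  if (is.finite(x$height)) cat(sprintf(", height = %.2f m", x$height))
  if (is.finite(x$mass)) cat(sprintf(", mass = %.1f kg", x$mass))
  cat("\n")
  invisible(x)
}
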