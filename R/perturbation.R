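#' A single belt-acceleration perturbation specification
#'
#' One unilateral treadmill belt acceleration: the target belt accelerates
#' at `acceleration` m/s^2 from the base walking speed up to
#' `speed_factor` times that speed, and decelerates (same slope magnitude)
#' when the perturbed limb's toe-off is detected.
#'
#' @param target_limb `"left"` or `"right"`.
#' @param acceleration Belt acceleration in m/s^2 (default 3).
#' @param speed_factor Peak speed as a multiple of base speed (default 1.8).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target_limb = c("left", "right"),
                              acceleration = 3, speed_factor = 1.8) {
  target_limb <- match.arg(target_limb)
  stopifnot(acceleration > 0, speed_factor > 1)
  structure(list(target_limb = target_limb, acceleration = acceleration,
                 speed_factor = speed_factor),
            class = "perturbation_spec")
}

#' Build the perturbation session protocol
#'
#' The default session applies ten unilateral belt accelerations: the first
#' and last to the right leg and eight in between to the left leg, with
#' unannounced inter-perturbation intervals drawn uniformly between 30 and
#' 90 s of unperturbed walking. Interval draws are reproducible from `seed`.
#'
#' @param config A [run_config()] supplying acceleration and speed factor.
#' @param seed Integer seed for the interval draws.
#' @param limbs Character vector of perturbed limbs in order (default
#'   `c("right", rep("left", 8), "right")`).
#' @param interval_bounds Inter-perturbation interval bounds in s
#'   (default `c(30, 90)`).
#' @return An object of class `perturbation_protocol`: a data.frame with
#'   columns `id`, `limb`, `acceleration`, `speed_factor`, `interval` (s of
#'   unperturbed walking preceding each perturbation).
#' @export
#' @examples
#' p <- build_protocol(seed = 1)
#' table(p$limb)
build_protocol <- function(config = run_config(), seed = 1,
                           limbs = c("right", rep("left", 8), "right"),
                           interval_bounds = c(30, 90)) {
  stopifnot(inherits(config, "run_config"),
            all(limbs %in% c("left", "right")),
            length(interval_bounds) == 2,
            interval_bounds[1] > 0, diff(interval_bounds) >= 0)
  intervals <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    runif(length(limbs), interval_bounds[1], interval_bounds[2])
  })
  structure(
    data.frame(id = seq_along(limbs), limb = limbs,
               acceleration = config$perturbation_accel,
               speed_factor = config$perturbation_factor,
               interval = intervals, stringsAsFactors = FALSE),
    class = c("perturbation_protocol", "data.frame"),
    interval_bounds = interval_bounds, seed = seed
  )
}

#' @export
print.perturbation_protocol <- function(x, ...) {
  cat(sprintf(
    "<perturbation_protocol> %d perturbations (%d left / %d right), intervals %.0f-%.0f s\n",
    nrow(x), sum(x$limb == "left"), sum(x$limb == "right"),
    attr(x, "interval_bounds")[1], attr(x, "interval_bounds")[2]))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Write / read a perturbation protocol as JSON
#'
#' @param protocol A [build_protocol()] object.
#' @param path File path.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "perturbation_protocol"))
  jsonlite::write_json(
    list(interval_bounds = attr(protocol, "interval_bounds"),
         seed = attr(protocol, "seed"),
         perturbations = as.data.frame(protocol)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x$perturbations,
            class = c("perturbation_protocol", "data.frame"),
            interval_bounds = x$interval_bounds, seed = x$seed)
}

#' Detect the perturbation trigger from hallux positions
#'
#' The belt acceleration is triggered, once armed, at the first instant the
#' to-be-perturbed limb's hallux marker becomes anterior to the stance
#' limb's hallux marker in the sagittal plane (an upward crossing of the
#' anteroposterior position difference through zero). The comparison is
#' inclusive at the arming sample: a crossing completing exactly at
#' `arm_time` triggers there.
#'
#' @param hallux_ap_target,hallux_ap_other Anteroposterior hallux positions
#'   (m) of the to-be-perturbed and contralateral limbs, on a common clock.
#' @param time Time stamps (s) for both streams.
#' @param arm_time Earliest admissible trigger time in s.
#' @return Trigger time in s (linearly interpolated between samples).
#' @export
detect_trigger <- function(hallux_ap_target, hallux_ap_other, time, arm_time) {
  n <- length(time)
  stopifnot(length(hallux_ap_target) == n, length(hallux_ap_other) == n)
  if (arm_time < time[1] || arm_time > time[n])
    stop("arm_time lies outside the recorded data")
  d <- hallux_ap_target - hallux_ap_other
  cand <- which(d[-n] <= 0 & d[-1] > 0)  # crossing completes at sample i+1
  cand <- cand[time[cand + 1L] >= arm_time]
  if (length(cand) == 0)
    stop("the target-limb hallux never passes the stance-limb hallux after ",
         format(arm_time), " s")
  i <- cand[1]
  if (d[i + 1L] == d[i]) return(time[i + 1L])
  t_cross <- time[i] + (0 - d[i]) / (d[i + 1L] - d[i]) * (time[i + 1L] - time[i])
  max(t_cross, arm_time)
}

#' Belt-velocity profile of one perturbation
#'
#' Piecewise-linear belt speed: a ramp at slope `acceleration` starting at
#' `trigger_time`, a plateau at `speed_factor * base_speed`, and a
#' deceleration of the same slope magnitude back to `base_speed` beginning
#' at `toeoff_time`. If the plateau is not reached before `toeoff_time`
#' (very short stance) the profile peaks below the target speed and a
#' warning is issued.
#'
#' @param base_speed Base (stability-normalised) walking speed in m/s.
#' @param spec A [perturbation_spec()].
#' @param trigger_time,toeoff_time Trigger and perturbed-limb toe-off times, s.
#' @param rate Sampling rate of the returned profile in Hz.
#' @return data.frame (`time`, `v`) covering the whole deviation from
#'   trigger to the end of the deceleration. The attribute `"fun"` holds
#'   the continuous-time velocity function used to sample it.
#' @export
#' @examples
#' pr <- generate_belt_profile(1.33, perturbation_spec("left"), 10, 10.7, 1000)
#' max(pr$v) / 1.33  # 1.8
generate_belt_profile <- function(base_speed, spec, trigger_time, toeoff_time,
                                  rate = 1000) {
  stopifnot(inherits(spec, "perturbation_spec"),
            base_speed > 0, toeoff_time > trigger_time)
  f <- belt_profile_fun(base_speed, spec, trigger_time, toeoff_time)
  dv_peak <- attr(f, "peak") - base_speed
  t_end <- toeoff_time + dv_peak / spec$acceleration
  tt <- seq(trigger_time, t_end + 2 / rate, by = 1 / rate)
  structure(data.frame(time = tt, v = f(tt)), fun = f)
}

#' @rdname generate_belt_profile
#' @export
belt_profile_fun <- function(base_speed, spec, trigger_time, toeoff_time) {
  a <- spec$acceleration
  dv <- (spec$speed_factor - 1) * base_speed
  peak <- min(dv, a * (toeoff_time - trigger_time))
  if (peak < dv)
    warning(sprintf(
      "plateau not reached: belt peaks at %.3f m/s (target %.3f m/s)",
      base_speed + peak, base_speed + dv))
  f <- function(t) {
    excess <- pmin(a * (t - trigger_time), dv, peak - a * (t - toeoff_time))
    base_speed + pmax(0, excess)
  }
  attr(f, "peak") <- base_speed + peak
  f
}
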