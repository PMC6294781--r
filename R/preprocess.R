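#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter forward and backward (two passes),
#' cancelling the phase shift. Edge transients are controlled by reflective
#' padding of at least three filter settling lengths before filtering; the
#' padding is discarded so the output has the same length as the input. The
#' effective two-pass magnitude response is the squared single-pass
#' magnitude, i.e. approximately `(1 + (f/fc)^(2*order))^-1` away from the
#' Nyquist frequency.
#'
#' @param x Uniformly sampled numeric signal.
#' @param rate Sampling rate in Hz (must exceed twice the cut-off).
#' @param cutoff Cut-off frequency in Hz.
#' @param order Filter order per pass (default 2).
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' y <- lowpass_zero_phase(sin(2 * pi * 2 * t), rate = 100, cutoff = 12)
lowpass_zero_phase <- function(x, rate, cutoff, order = 2) {
  if (cutoff >= rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)")
  if (cutoff <= 0 || order < 1) stop("cutoff and order must be positive")
  n <- length(x)
  settle <- ceiling(rate / cutoff)
  pad <- min(n - 1, 3 * settle)
  if (n <= 3 * settle && n < 10)
    stop("signal too short to filter reliably (need more than ",
         3 * settle, " samples)")
  flt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # reflect about the end points so the padded signal is continuous in value
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Differentiate a uniformly sampled signal
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param x Numeric signal (at least 3 samples).
#' @param rate Sampling rate in Hz.
#' @return Numeric derivative, same length as `x`, in units of `x` per second.
#' @export
#' @examples
#' differentiate(1.3 * seq(0, 1, by = 0.01), rate = 100)[1:3]
differentiate <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("differentiate needs at least 3 samples, got ", n)
  dt <- 1 / rate
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

#' Filter a trial recording and compute marker velocities
#'
#' Low-pass filters every marker coordinate (zero phase) and differentiates
#' the filtered anteroposterior coordinates to marker velocities, in that
#' order (filter, then differentiate). The belt-velocity signal is a
#' commanded, piecewise-smooth profile and is used as recorded. Force
#' signals are only thresholded downstream and are not filtered.
#'
#' @param trial A [trial_recording()].
#' @param config A [run_config()] supplying `filter_cutoff` and `filter_order`.
#' @return A `filtered_trial`: the trial with filtered marker coordinates,
#'   a `velocities` data.frame (`time`, `marker`, `v_ap`) and a `provenance`
#'   record of the filter settings.
#' @export
filter_trial <- function(trial, config = run_config()) {
  stopifnot(inherits(trial, "trial_recording"), inherits(config, "run_config"))
  out <- trial
  tt <- marker_time(trial)
  vel <- vector("list", length(MARKER_NAMES))
  mk <- trial$markers
  for (i in seq_along(MARKER_NAMES)) {
    m <- MARKER_NAMES[i]
    sel <- which(mk$marker == m)
    sel <- sel[order(mk$time[sel])]
    for (comp in c("x_ap", "x_ml", "x_vert")) {
      out$markers[[comp]][sel] <- lowpass_zero_phase(
        mk[[comp]][sel], trial$marker_rate,
        config$filter_cutoff, config$filter_order)
    }
    vel[[i]] <- data.frame(
      time = tt, marker = m,
      v_ap = differentiate(out$markers$x_ap[sel], trial$marker_rate),
      stringsAsFactors = FALSE)
  }
  out$velocities <- do.call(rbind, vel)
  out$provenance <- list(filter_cutoff = config$filter_cutoff,
                         filter_order = config$filter_order,
                         zero_phase = TRUE)
  class(out) <- c("filtered_trial", class(trial))
  out
}

#' @rdname marker_signal
#' @export
marker_velocity <- function(trial, marker) {
  if (is.null(trial$velocities))
    stop("trial has no velocities; run filter_trial() first")
  marker <- match.arg(marker, MARKER_NAMES)
  sel <- trial$velocities$marker == marker
  trial$velocities$v_ap[sel][order(trial$velocities$time[sel])]
}
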