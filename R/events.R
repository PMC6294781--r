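.gait_events <- function(kind = character(), limb = character(),
                         time = numeric(), frame = integer(),
                         source = character()) {
  structure(data.frame(kind = kind, limb = limb, time = time,
                       frame = frame, source = source,
                       stringsAsFactors = FALSE),
            class = c("gait_events", "data.frame"))
}

#' Detect gait events from hallux anteroposterior velocity
#'
#' On a treadmill the hallux moves backward with the belt during stance
#' (negative anteroposterior velocity) and forward during swing (positive).
#' Touchdown is the frame in which the filtered marker velocity switches
#' from positive to non-positive; toe-off the frame of the opposite switch.
#' Sign-switch pairs closer together than `debounce` seconds (an impossibly
#' short stance or swing) are treated as chatter and removed.
#'
#' @param v_ap Filtered hallux anteroposterior velocity (m/s) for one limb.
#' @param rate Sampling rate in Hz.
#' @param limb `"left"` or `"right"`.
#' @param time Optional time stamps (defaults to `(0:(n-1))/rate`).
#' @param debounce Chatter-merging window in s (default 0.1).
#' @return A `gait_events` data.frame (`kind`, `limb`, `time`, `frame`,
#'   `source = "marker"`), time-ordered and alternating. Empty (with a
#'   warning) if no sign switch is found.
#' @export
detect_events_marker <- function(v_ap, rate, limb = c("left", "right"),
                                 time = NULL, debounce = 0.1) {
  limb <- match.arg(limb)
  n <- length(v_ap)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  pos <- v_ap > 0
  td_frames <- which(pos[-n] & !pos[-1]) + 1L   # + -> - switch
  to_frames <- which(!pos[-n] & pos[-1]) + 1L   # - -> + switch
  ev <- data.frame(
    kind = c(rep("touchdown", length(td_frames)),
             rep("toeoff", length(to_frames))),
    frame = c(td_frames, to_frames)
  )
  if (nrow(ev) == 0) {
    warning("no velocity sign switches found for ", limb, " hallux")
    return(.gait_events())
  }
  ev <- ev[order(ev$frame), , drop = FALSE]
  ev$time <- time[ev$frame]
  # debounce: drop pairs of adjacent opposite switches closer than the window
  repeat {
    if (nrow(ev) < 2) break
    gaps <- diff(ev$time)
    short <- which(gaps < debounce)
    if (length(short) == 0) break
    ev <- ev[-c(short[1], short[1] + 1L), , drop = FALSE]
  }
  if (nrow(ev) == 0) {
    warning("all velocity sign switches for ", limb,
            " hallux removed as chatter")
    return(.gait_events())
  }
  .gait_events(kind = ev$kind, limb = limb, time = ev$time,
               frame = as.integer(ev$frame), source = "marker")
}

#' Detect gait events from vertical ground-reaction force
#'
#' Touchdown at the upward crossing of the force threshold, toe-off at the
#' downward crossing, with linear interpolation between samples for
#' sub-sample event times.
#'
#' @param fz Vertical force signal (N) for one belt's force plate.
#' @param rate Sampling rate in Hz.
#' @param threshold Force threshold in N (default 50).
#' @param limb Limb walking on this belt (`"left"` or `"right"`).
#' @param time Optional time stamps.
#' @return A `gait_events` data.frame with `source = "force"`.
#' @export
detect_events_force <- function(fz, rate, threshold = 50,
                                limb = c("left", "right"), time = NULL) {
  limb <- match.arg(limb)
  if (is.null(fz) || length(fz) == 0)
    stop("force stream absent; use marker-only event detection")
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(fz)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  above <- fz >= threshold
  up <- which(!above[-n] & above[-1])     # crossing in (i, i+1]
  down <- which(above[-n] & !above[-1])
  cross_time <- function(i) {
    time[i] + (threshold - fz[i]) / (fz[i + 1L] - fz[i]) * (time[i + 1L] - time[i])
  }
  ev <- rbind(
    if (length(up)) data.frame(kind = "touchdown", frame = up + 1L,
                               time = vapply(up, cross_time, numeric(1))),
    if (length(down)) data.frame(kind = "toeoff", frame = down + 1L,
                                 time = vapply(down, cross_time, numeric(1)))
  )
  if (is.null(ev) || nrow(ev) == 0) return(.gait_events())
  ev <- ev[order(ev$time), , drop = FALSE]
  .gait_events(kind = ev$kind, limb = limb, time = ev$time,
               frame = as.integer(ev$frame), source = "force")
}

#' Correct marker events by the mean force-plate discrepancy
#'
#' Marker-velocity events are frame-quantized and can be systematically
#' offset from the mechanical contact; force-plate events are precise but
#' unreliable when a foot straddles the treadmill centre and loads both
#' plates. The hybrid correction estimates, separately for touchdown and
#' toe-off, the mean discrepancy (force minus marker) over all steps that
#' contacted exactly one force plate, and adds that constant offset to every
#' marker event of that kind (including steps that loaded both plates).
#'
#' A marker step is "single-plate" when exactly one belt shows a force
#' touchdown within `window` s of the marker touchdown and the same single
#' belt shows a force toe-off within `window` s of the marker toe-off.
#'
#' @param marker_events `gait_events` from [detect_events_marker()] (both
#'   limbs may be concatenated).
#' @param force_events `gait_events` from [detect_events_force()] for both
#'   belts; the `limb` column identifies the belt side.
#' @param window Matching window in s (default 0.05).
#' @return A list: `events` (corrected `gait_events`, `source =
#'   "corrected"`, continuous times), `offsets` (named vector, s),
#'   `n_matched` (named count of single-plate steps per event kind).
#' @export
correct_marker_events <- function(marker_events, force_events, window = 0.05) {
  stopifnot(inherits(marker_events, "data.frame"),
            inherits(force_events, "data.frame"))
  disc <- list(touchdown = numeric(), toeoff = numeric())
  for (lb in unique(marker_events$limb)) {
    me <- marker_events[marker_events$limb == lb, , drop = FALSE]
    me <- me[order(me$time), , drop = FALSE]
    td_i <- which(me$kind == "touchdown")
    for (i in td_i) {
      j <- i + 1L
      if (j > nrow(me) || me$kind[j] != "toeoff") next
      td_t <- me$time[i]; to_t <- me$time[j]
      belts_td <- unique(force_events$limb[
        force_events$kind == "touchdown" &
          abs(force_events$time - td_t) <= window])
      belts_to <- unique(force_events$limb[
        force_events$kind == "toeoff" &
          abs(force_events$time - to_t) <= window])
      if (length(belts_td) == 1 && identical(belts_td, belts_to)) {
        b <- belts_td
        f_td <- force_events$time[force_events$kind == "touchdown" &
                                    force_events$limb == b]
        f_to <- force_events$time[force_events$kind == "toeoff" &
                                    force_events$limb == b]
        f_td <- f_td[which.min(abs(f_td - td_t))]
        f_to <- f_to[which.min(abs(f_to - to_t))]
        disc$touchdown <- c(disc$touchdown, f_td - td_t)
        disc$toeoff <- c(disc$toeoff, f_to - to_t)
      }
    }
  }
  if (length(disc$touchdown) == 0 || length(disc$toeoff) == 0)
    stop("no single-plate steps matched between marker and force events; ",
         "fall back to marker-only events")
  offsets <- c(touchdown = mean(disc$touchdown), toeoff = mean(disc$toeoff))
  corrected <- marker_events
  corrected$time <- corrected$time + offsets[corrected$kind]
  corrected$source <- "corrected"
  corrected <- corrected[order(corrected$time), , drop = FALSE]
  class(corrected) <- c("gait_events", "data.frame")
  list(events = corrected, offsets = offsets,
       n_matched = c(touchdown = length(disc$touchdown),
                     toeoff = length(disc$toeoff)))
}

#' Detect and correct gait events for a whole trial
#'
#' Convenience wrapper: marker events from both hallux velocities, force
#' events from both belts, then the force-based correction. Falls back to
#' the uncorrected marker events (with a warning) when no single-plate
#' steps can be matched.
#'
#' @param ftrial A `filtered_trial` from [filter_trial()].
#' @param config A [run_config()].
#' @return A list as in [correct_marker_events()] plus `marker_events` and
#'   `force_events`.
#' @export
detect_gait_events <- function(ftrial, config = run_config()) {
  stopifnot(inherits(ftrial, "filtered_trial"))
  tt <- marker_time(ftrial)
  me <- rbind(
    detect_events_marker(marker_velocity(ftrial, "HalL"), ftrial$marker_rate,
                         limb = "left", time = tt, debounce = config$debounce),
    detect_events_marker(marker_velocity(ftrial, "HalR"), ftrial$marker_rate,
                         limb = "right", time = tt, debounce = config$debounce)
  )
  me <- me[order(me$time), , drop = FALSE]
  class(me) <- c("gait_events", "data.frame")
  fe <- do.call(rbind, lapply(BELT_NAMES, function(b) {
    sig <- .belt_signal(ftrial$forces, b, "fz")
    detect_events_force(sig$value, ftrial$force_rate,
                        threshold = config$force_threshold,
                        limb = b, time = sig$time)
  }))
  fe <- fe[order(fe$time), , drop = FALSE]
  class(fe) <- c("gait_events", "data.frame")
  res <- tryCatch(
    correct_marker_events(me, fe, window = config$event_match_window),
    error = function(e) {
      warning("event correction failed (", conditionMessage(e),
              "); using uncorrected marker events")
      list(events = me, offsets = c(touchdown = 0, toeoff = 0),
           n_matched = c(touchdown = 0L, toeoff = 0L))
    })
  res$marker_events <- me
  res$force_events <- fe
  res
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d events (%d touchdowns) from source(s): %s\n",
              nrow(x), sum(x$kind == "touchdown"),
              paste(unique(x$source), collapse = ", ")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}
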