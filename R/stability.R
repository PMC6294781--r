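#' Extrapolated centre of mass of the reduced five-marker model
#'
#' The anteroposterior extrapolated centre of mass (XCoM) of the reduced
#' model, expressed relative to the rearmost hallux marker:
#' the centre-of-mass position proxy is the trochanter midpoint minus the
#' rearmost hallux position, and the centre-of-mass velocity proxy is
#' `0.5 * ((v_troL + v_troR)/2 + v_c7) + |v_belt|`, scaled by the inverted-
#' pendulum eigenfrequency `sqrt(g / l_ref)`:
#'
#' `xcom = (p_troL + p_troR)/2 - p_halluxP +
#'         (0.5 * ((v_troL + v_troR)/2 + v_c7) + |v_belt|) / sqrt(g / l_ref)`
#'
#' The belt term enters because, in the treadmill frame, the body moves
#' backward relative to the support surface at the belt speed.
#'
#' @param p_troL,p_troR Anteroposterior trochanter positions (m).
#' @param p_halluxP Anteroposterior position of the rearmost (posterior)
#'   hallux marker (m).
#' @param v_troL,v_troR,v_c7 Anteroposterior marker velocities (m/s).
#' @param v_belt Treadmill belt velocity (m/s); its absolute value is used.
#' @param subject A [subject_params()] supplying `g` and `l_ref`.
#' @return XCoM in m (vectorized over the inputs).
#' @export
#' @examples
#' s <- subject_params(l_ref = 0.9)
#' compute_xcom(0.5, 0.5, 0, 0, 0, 0, v_belt = 1, subject = s) # ~0.8029
compute_xcom <- function(p_troL, p_troR, p_halluxP,
                         v_troL, v_troR, v_c7, v_belt, subject) {
  stopifnot(inherits(subject, "subject_params"))
  omega <- sqrt(subject$g / subject$l_ref)
  (p_troL + p_troR) / 2 - p_halluxP +
    (0.5 * ((v_troL + v_troR) / 2 + v_c7) + abs(v_belt)) / omega
}

#' Per-touchdown base of support, XCoM and margin of stability
#'
#' For every corrected touchdown, samples the filtered marker positions and
#' velocities at the touchdown instant (linear interpolation between marker
#' frames) and computes:
#'
#' * `bos`: the anteroposterior distance between the two hallux markers;
#' * `xcom`: the extrapolated centre of mass relative to the rearmost
#'   hallux, via [compute_xcom()]. The rearmost hallux is resolved per
#'   frame (whichever hallux has the smaller anteroposterior coordinate at
#'   that instant);
#' * `mos = bos - xcom`: the anteroposterior margin of stability. Positive
#'   values mean the XCoM lies within the base of support, i.e. stability
#'   against a forward loss of balance.
#'
#' The belt velocity entering the XCoM is that of the belt under the landing
#' limb (during a unilateral perturbation this is the perturbed belt when
#' the touchdown lands on it, and the unperturbed belt otherwise).
#'
#' @param ftrial A `filtered_trial` from [filter_trial()].
#' @param events A `gait_events` data.frame (typically the corrected events
#'   from [detect_gait_events()]); only touchdowns are used.
#' @param subject A [subject_params()]; defaults to the trial's subject.
#' @return A `step_records` data.frame: `touchdown_time`, `limb`, `bos`,
#'   `xcom`, `v_com` (the centre-of-mass velocity proxy, m/s), `mos`,
#'   `label` (initially `"unlabelled"`), `pert_id` (initially `NA`).
#'   Touchdowns outside the marker data range are skipped with a warning.
#' @export
compute_step_records <- function(ftrial, events, subject = NULL) {
  stopifnot(inherits(ftrial, "filtered_trial"))
  if (is.null(subject)) subject <- ftrial$subject
  stopifnot(inherits(subject, "subject_params"))
  td <- events[events$kind == "touchdown", , drop = FALSE]
  td <- td[order(td$time), , drop = FALSE]
  if (nrow(td) == 0) stop("no touchdowns in events")
  tt <- marker_time(ftrial)
  inside <- td$time >= tt[1] & td$time <= tt[length(tt)]
  if (any(!inside)) {
    warning(sum(!inside), " touchdown(s) outside the marker data range; skipped")
    td <- td[inside, , drop = FALSE]
  }
  at <- function(x) approx(tt, x, xout = td$time)$y
  hal_l <- at(marker_signal(ftrial, "HalL"))
  hal_r <- at(marker_signal(ftrial, "HalR"))
  p_troL <- at(marker_signal(ftrial, "TroL"))
  p_troR <- at(marker_signal(ftrial, "TroR"))
  v_troL <- at(marker_velocity(ftrial, "TroL"))
  v_troR <- at(marker_velocity(ftrial, "TroR"))
  v_c7 <- at(marker_velocity(ftrial, "C7"))
  belt_of_limb <- function(limb) {
    sig <- .belt_signal(ftrial$belt_velocity, limb, "v")
    approx(sig$time, sig$value, xout = td$time, rule = 2)$y
  }
  v_belt_by <- list(left = belt_of_limb("left"), right = belt_of_limb("right"))
  v_belt <- ifelse(td$limb == "left", v_belt_by$left, v_belt_by$right)
  p_halluxP <- pmin(hal_l, hal_r)
  bos <- abs(hal_l - hal_r)
  xcom <- compute_xcom(p_troL, p_troR, p_halluxP,
                       v_troL, v_troR, v_c7, v_belt, subject)
  v_com <- 0.5 * ((v_troL + v_troR) / 2 + v_c7) + abs(v_belt)
  structure(
    data.frame(touchdown_time = td$time, limb = td$limb,
               bos = bos, xcom = xcom, v_com = v_com, mos = bos - xcom,
               label = "unlabelled", pert_id = NA_integer_,
               stringsAsFactors = FALSE),
    class = c("step_records", "data.frame")
  )
}

#' Label steps relative to perturbations
#'
#' For each perturbation (in chronological order), labels:
#'
#' * `Pre`: the final touchdown before the trigger;
#' * `Post1..PostN`: the first `n_post_steps` touchdowns after the trigger
#'   (`Post1` is the perturbed limb's landing on the accelerating belt,
#'   since the trigger fires during its swing);
#' * `Base`: the 11th-to-2nd-last touchdowns before the perturbation (a
#'   window of `baseline_window` = 10 steps, excluding `Pre`); the per-
#'   perturbation baseline MoS is the mean over that window.
#'
#' When fewer than 8 post-steps or fewer than 11 pre-steps are available
#' the labels are truncated with a warning.
#'
#' @param steps A `step_records` data.frame from [compute_step_records()].
#' @param perturbations A data.frame of perturbation records with at least
#'   `trigger_time` (s) and optionally `id`; e.g. the realized records from
#'   [simulate_session()] or the protocol controller's log.
#' @param config A [run_config()].
#' @return The `step_records` with `label`/`pert_id` filled in, plus an
#'   attribute `"base"`: a data.frame (`pert_id`, `base_mos`, `n_base`).
#' @export
label_steps <- function(steps, perturbations, config = run_config()) {
  stopifnot(inherits(steps, "data.frame"), inherits(perturbations, "data.frame"))
  trig <- perturbations$trigger_time
  if (is.unsorted(trig, strictly = TRUE))
    stop("perturbations must be in strictly increasing chronological order")
  ids <- if (!is.null(perturbations$id)) perturbations$id
         else seq_along(trig)
  ord <- order(steps$touchdown_time)
  steps <- steps[ord, , drop = FALSE]
  n <- nrow(steps)
  base_tab <- data.frame(pert_id = ids, base_mos = NA_real_, n_base = NA_integer_)
  for (k in seq_along(trig)) {
    before <- which(steps$touchdown_time < trig[k])
    after <- which(steps$touchdown_time > trig[k])
    if (length(before) == 0) {
      warning("perturbation ", ids[k], ": no steps precede the trigger; skipped")
      next
    }
    pre_i <- before[length(before)]
    steps$label[pre_i] <- "Pre"
    steps$pert_id[pre_i] <- ids[k]
    # Base window: 11th-to-2nd-last step before the perturbation
    win <- before[before < pre_i]
    win <- tail(win, config$baseline_window)
    if (length(win) < config$baseline_window)
      warning("perturbation ", ids[k], ": only ", length(win),
              " baseline steps available (", config$baseline_window,
              " requested)")
    if (length(win)) {
      steps$label[win] <- "Base"
      steps$pert_id[win] <- ids[k]
      base_tab$base_mos[k] <- mean(steps$mos[win])
      base_tab$n_base[k] <- length(win)
    }
    n_post <- min(config$n_post_steps, length(after))
    if (n_post < config$n_post_steps)
      warning("perturbation ", ids[k], ": only ", n_post,
              " post-perturbation steps available; labels truncated")
    if (n_post > 0) {
      post_i <- after[seq_len(n_post)]
      steps$label[post_i] <- paste0("Post", seq_len(n_post))
      steps$pert_id[post_i] <- ids[k]
    }
  }
  attr(steps, "base") <- base_tab
  class(steps) <- c("step_records", "data.frame")
  steps
}

#' @export
print.step_records <- function(x, ...) {
  cat(sprintf("<step_records> %d touchdowns, MoS %.3f to %.3f m\n",
              nrow(x), min(x$mos), max(x$mos)))
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}
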