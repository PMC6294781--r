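# Base hallux waveform: one stride of anteroposterior foot motion as a
# two-harmonic periodic function of stride phase. Using exactly two
# harmonics keeps the trajectory band-limited far below the 12 Hz analysis
# cut-off while giving a realistic ~62% stance fraction, and makes the
# velocity zero crossings (the gait events) transversal and analytically
# known.
.g_wave <- function(phi) sin(2 * pi * phi) + 0.25 * sin(4 * pi * phi)
.g_prime <- function(phi) 2 * pi * cos(2 * pi * phi) + pi * cos(4 * pi * phi)
# velocity sign switches: cos(u) + 0.5*cos(2u) = 0 -> cos(u) = (sqrt(3)-1)/2
.PHI_TD <- acos((sqrt(3) - 1) / 2) / (2 * pi)    # ~0.1903: swing -> stance
.PHI_TO <- 1 - .PHI_TD                           # ~0.8097: stance -> swing
.STANCE_FRAC <- .PHI_TO - .PHI_TD                # ~0.619 of the stride

# quintic smoothstep: C2 at both ends
.smooth5 <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

#' Synthetic walker model
#'
#' Parametrizes the synthetic treadmill gait generator. Trajectories are
#' built by construction (prescribed marker paths satisfying a target
#' per-step MoS exactly), not by forward dynamics: the generator's job is
#' to provide controlled ground truth for the measurement pipeline, so the
#' true per-step MoS, event times and perturbation responses are known to
#' machine precision before any noise is added.
#'
#' @param step_frequency_fn Function speed (m/s) -> step cadence (steps/s).
#'   Default `v / step_length_fn(v)`.
#' @param step_length_fn Function speed -> step length (m). Default
#'   `0.35 + 0.25 * v`, a typical linear step-length/speed relationship.
#' @param mos_curve_true Coefficients `c(a0, a1, a2)` of the true mean
#'   MoS-versus-speed quadratic (m). The default
#'   `c(0.20, -0.15, 0.025)` yields a stability-normalised speed of
#'   ~1.27 m/s at a 0.05 m target, inside the 1.2-1.5 m/s range typical of
#'   healthy adults.
#' @param mos_noise_sd Step-to-step MoS variability (m, default 0.01).
#' @param marker_noise_sd White measurement noise added to every marker
#'   coordinate (m, default 5e-4, i.e. 0.5 mm of optical capture noise).
#' @param perturbation_response List with `drop` (m), `recovery` (per-step
#'   recovery fraction in (0,1)) and `adaptation` (fractional shrinkage of
#'   the drop per repeated same-limb perturbation). The true MoS deficit of
#'   recovery step k after the j-th perturbation of a limb is
#'   `drop * (1 - adaptation)^(j-1) * recovery^k`.
#' @param trunk_sway Anteroposterior sway amplitude of the trochanter
#'   midpoint and C7 markers (m, default 0.01).
#' @param force_noise_sd White noise on the vertical force signals (N).
#' @param seed Default seed used when the simulation functions are called
#'   without one.
#' @return An object of class `walker_model`.
#' @export
walker_model <- function(step_frequency_fn = NULL,
                         step_length_fn = function(v) 0.35 + 0.25 * v,
                         mos_curve_true = c(0.20, -0.15, 0.025),
                         mos_noise_sd = 0.01,
                         marker_noise_sd = 5e-4,
                         perturbation_response = list(drop = 0.45,
                                                      recovery = 0.5,
                                                      adaptation = 0.1),
                         trunk_sway = 0.01,
                         force_noise_sd = 2,
                         seed = 1L) {
  if (is.null(step_frequency_fn))
    step_frequency_fn <- function(v) v / step_length_fn(v)
  stopifnot(is.function(step_frequency_fn), is.function(step_length_fn),
            length(mos_curve_true) == 3,
            mos_noise_sd >= 0, marker_noise_sd >= 0, trunk_sway >= 0,
            force_noise_sd >= 0)
  pr <- perturbation_response
  stopifnot(pr$recovery > 0, pr$recovery < 1, pr$drop >= 0,
            pr$adaptation >= 0, pr$adaptation < 1)
  grid <- seq(0.4, 1.8, by = 0.2)
  if (any(step_frequency_fn(grid) <= 0) || any(step_length_fn(grid) <= 0))
    stop("cadence and step length must be positive over 0.4-1.8 m/s")
  structure(
    list(step_frequency_fn = step_frequency_fn,
         step_length_fn = step_length_fn,
         mos_curve_true = mos_curve_true,
         mos_noise_sd = mos_noise_sd,
         marker_noise_sd = marker_noise_sd,
         perturbation_response = pr,
         trunk_sway = trunk_sway,
         force_noise_sd = force_noise_sd,
         seed = seed),
    class = "walker_model"
  )
}

#' @export
print.walker_model <- function(x, ...) {
  a <- x$mos_curve_true
  cat(sprintf(
    "<walker_model> true MoS(v) = %.3g %+.3g v %+.3g v^2, noise sd %.3g m\n",
    a[1], a[2], a[3], x$mos_noise_sd))
  cat(sprintf("  perturbation: drop %.3g m, recovery %.2f/step, adaptation %.2f\n",
              x$perturbation_response$drop, x$perturbation_response$recovery,
              x$perturbation_response$adaptation))
  invisible(x)
}

#' Evaluate the model's true mean MoS at a speed
#' @param model A [walker_model()].
#' @param speed Speed(s) in m/s.
#' @return True mean MoS in m.
#' @export
true_mos <- function(model, speed) {
  a <- model$mos_curve_true
  a[1] + a[2] * speed + a[3] * speed^2
}

# Internal generator core shared by simulate_walking_trial / simulate_session.
# pert_plan: NULL or data.frame(id, limb, acceleration, speed_factor,
#            arm_time). Returns list(trial, truth, perturbations).
.synth_build <- function(model, speed, duration, subject, pert_plan = NULL,
                         marker_rate = 100, force_rate = 1000) {
  f_step <- model$step_frequency_fn(speed)
  T_step <- 1 / f_step
  T_str <- 2 * T_step
  R <- speed * .STANCE_FRAC * T_str / (2 * .g_wave(.PHI_TD))
  omega <- sqrt(subject$g / subject$l_ref)
  a_true <- model$mos_curve_true
  mos0 <- a_true[1] + a_true[2] * speed + a_true[3] * speed^2
  t0 <- c(right = 0, left = T_step)          # stride phase origins per limb

  # --- touchdown / toe-off schedule (ground truth) ----------------------
  sched <- function(limb, phi) {
    k <- -1:ceiling(duration / T_str + 2)
    tt <- t0[[limb]] + (k + phi) * T_str
    tt[tt > 0 & tt <= duration]
  }
  td <- rbind(
    data.frame(limb = "right", time = sched("right", .PHI_TD)),
    data.frame(limb = "left", time = sched("left", .PHI_TD))
  )
  td <- td[order(td$time), , drop = FALSE]
  rownames(td) <- NULL
  to <- rbind(
    data.frame(limb = "right", time = sched("right", .PHI_TO)),
    data.frame(limb = "left", time = sched("left", .PHI_TO))
  )
  to <- to[order(to$time), , drop = FALSE]
  n_steps <- nrow(td)

  # --- perturbation timing and belt profiles ----------------------------
  pert_rec <- NULL
  belt_fun <- list(left = function(t) rep(speed, length(t)),
                   right = function(t) rep(speed, length(t)))
  if (!is.null(pert_plan) && nrow(pert_plan) > 0) {
    pert_rec <- pert_plan
    pert_rec$trigger_time <- NA_real_
    pert_rec$touchdown_time <- NA_real_
    pert_rec$toeoff_time <- NA_real_
    profs <- list(left = list(), right = list())
    for (j in seq_len(nrow(pert_plan))) {
      lb <- pert_plan$limb[j]
      # the swinging target hallux passes the stance hallux at stride phase 0
      m <- ceiling((pert_plan$arm_time[j] - t0[[lb]]) / T_str)
      trig <- t0[[lb]] + m * T_str
      td_j <- trig + .PHI_TD * T_str
      to_j <- trig + .PHI_TO * T_str
      if (to_j + 2 > duration)
        stop("session too short: perturbation ", pert_plan$id[j],
             " would end after the recording")
      spec <- perturbation_spec(lb, pert_plan$acceleration[j],
                                pert_plan$speed_factor[j])
      profs[[lb]] <- c(profs[[lb]],
                       list(belt_profile_fun(speed, spec, trig, to_j)))
      pert_rec$trigger_time[j] <- trig
      pert_rec$touchdown_time[j] <- td_j
      pert_rec$toeoff_time[j] <- to_j
    }
    mk_belt <- function(fl) {
      if (length(fl) == 0) return(function(t) rep(speed, length(t)))
      function(t) {
        v <- rep(speed, length(t))
        for (f in fl) v <- v + (f(t) - speed)
        v
      }
    }
    belt_fun <- list(left = mk_belt(profs$left), right = mk_belt(profs$right))
  }

  # --- per-step true MoS targets ---------------------------------------
  mos_true <- mos0 + rnorm(n_steps, 0, model$mos_noise_sd)
  label_true <- rep("unlabelled", n_steps)
  pert_of <- rep(NA_integer_, n_steps)
  if (!is.null(pert_rec)) {
    reps <- c(left = 0L, right = 0L)
    pr <- model$perturbation_response
    for (j in seq_len(nrow(pert_rec))) {
      lb <- pert_rec$limb[j]
      reps[[lb]] <- reps[[lb]] + 1L
      drop_j <- pr$drop * (1 - pr$adaptation)^(reps[[lb]] - 1L)
      post <- which(td$time > pert_rec$trigger_time[j])
      pre <- which(td$time < pert_rec$trigger_time[j])
      if (length(pre)) {
        label_true[pre[length(pre)]] <- "Pre"
        pert_of[pre[length(pre)]] <- pert_rec$id[j]
      }
      kk <- seq_len(min(8, length(post)))
      mos_true[post[kk]] <- mos_true[post[kk]] - drop_j * pr$recovery^kk
      label_true[post[kk]] <- paste0("Post", kk)
      pert_of[post[kk]] <- pert_rec$id[j]
    }
  }

  # --- trunk and C7 kinematics (analytic) ------------------------------
  t_ref <- .PHI_TD * T_str                    # a touchdown instant: sway
  A <- model$trunk_sway                       # velocity vanishes at events
  p_tm <- function(t) A * cos(2 * pi * (t - t_ref) / T_str)
  v_tm <- function(t) -A * (2 * pi / T_str) * sin(2 * pi * (t - t_ref) / T_str)

  # --- foot placement offsets achieving the target MoS -----------------
  # At touchdown the MoS reduces to  x_front - p_tm - vel_term  (the
  # rearmost hallux cancels between BoS and XCoM), so the landing position
  # needed for a target MoS is known in closed form.
  d_of <- list()
  td_of <- list()
  c_limb <- speed / omega + mos0 - R * .g_wave(.PHI_TD)
  for (lb in c("left", "right")) {
    sel <- td$limb == lb
    tk <- td$time[sel]
    vel_term <- (0.5 * (v_tm(tk) + v_tm(tk)) + abs(belt_fun[[lb]](tk))) / omega
    x_need <- p_tm(tk) + vel_term + mos_true[sel]
    d_of[[lb]] <- x_need - (c_limb + R * .g_wave(.PHI_TD))
    td_of[[lb]] <- tk
  }

  # --- marker streams ---------------------------------------------------
  n_fr <- floor(duration * marker_rate) + 1L
  tm <- (seq_len(n_fr) - 1) / marker_rate
  noise <- function() rnorm(n_fr, 0, model$marker_noise_sd)

  hallux_ap <- function(lb) {
    phi_tot <- (tm - t0[[lb]]) / T_str
    s <- phi_tot - .PHI_TD
    k <- floor(s)
    psi <- s - k
    d <- d_of[[lb]]
    K <- length(d)
    idx <- pmin(pmax(k + 1L, 1L), K)          # stride k starts at touchdown k
    nxt <- pmin(pmax(k + 2L, 1L), K)          # clamp: constant before/after data
    sw <- 1 - .STANCE_FRAC
    m1 <- 0.1 * sw
    u <- (psi - .STANCE_FRAC - m1) / (sw - 2 * m1)
    blend <- ifelse(psi < .STANCE_FRAC, 0, .smooth5(u))
    D <- d[idx] + (d[nxt] - d[idx]) * blend
    list(ap = c_limb + R * .g_wave(phi_tot - floor(phi_tot)) + D,
         psi = psi)
  }
  swing_lift <- function(psi) {
    u <- (psi - .STANCE_FRAC) / (1 - .STANCE_FRAC)
    0.03 + 0.07 * ifelse(psi < .STANCE_FRAC, 0, sin(pi * pmin(pmax(u, 0), 1))^2)
  }
  hl <- hallux_ap("left"); hr <- hallux_ap("right")
  pelvis_rot <- 0.03 * sin(2 * pi * (tm - t_ref) / T_str)  # cancels in midpoint
  mk <- function(name, ap, ml, vert) {
    data.frame(time = tm, marker = name, x_ap = ap + noise(),
               x_ml = ml + noise(), x_vert = vert + noise(),
               stringsAsFactors = FALSE)
  }
  markers <- rbind(
    mk("C7", p_tm(tm), 0, subject$l_ref + 0.55),
    mk("TroL", p_tm(tm) + pelvis_rot, -0.12, subject$l_ref),
    mk("TroR", p_tm(tm) - pelvis_rot, 0.12, subject$l_ref),
    mk("HalL", hl$ap, -0.10, swing_lift(hl$psi)),
    mk("HalR", hr$ap, 0.10, swing_lift(hr$psi))
  )

  # --- force and belt streams ------------------------------------------
  n_ff <- floor(duration * force_rate) + 1L
  tf <- (seq_len(n_ff) - 1) / force_rate
  mass <- if (is.finite(subject$mass)) subject$mass else 75
  f_peak <- 1.1 * mass * subject$g
  stance_force <- function(lb) {
    psi <- ((tf - t0[[lb]]) / T_str - .PHI_TD) %% 1
    tau <- psi / .STANCE_FRAC
    f <- ifelse(psi < .STANCE_FRAC,
                f_peak * pmin(1, sin(pi * tau) / 0.2), 0)
    pmax(0, f + rnorm(n_ff, 0, model$force_noise_sd) * (f > 0))
  }
  forces <- rbind(
    data.frame(time = tf, belt = "left", fz = stance_force("left")),
    data.frame(time = tf, belt = "right", fz = stance_force("right"))
  )
  belt <- rbind(
    data.frame(time = tf, belt = "left", v = belt_fun$left(tf)),
    data.frame(time = tf, belt = "right", v = belt_fun$right(tf))
  )

  events <- rbind(
    data.frame(kind = "touchdown", limb = td$limb, time = td$time),
    data.frame(kind = "toeoff", limb = to$limb, time = to$time)
  )
  events <- events[order(events$time), , drop = FALSE]
  truth <- list(
    events = events,
    steps = data.frame(step = seq_len(n_steps), touchdown_time = td$time,
                       limb = td$limb, mos_true = mos_true,
                       label_true = label_true, pert_id = pert_of,
                       stringsAsFactors = FALSE),
    mos_mean_true = mos0, step_period = T_step
  )
  trial <- trial_recording(markers, forces, belt,
                           commanded_speed = speed, subject = subject,
                           marker_rate = marker_rate, force_rate = force_rate,
                           truth = truth)
  list(trial = trial, truth = truth, perturbations = pert_rec)
}

#' Simulate one constant-speed treadmill walking trial
#'
#' Generates a [trial_recording()] with periodic hallux trajectories
#' (backward motion during stance at approximately belt speed, forward
#' swing), trochanter and C7 sway, per-belt vertical force bursts peaking
#' near body weight, and a constant belt velocity. Ground-truth event times
#' and per-step MoS are attached as the `truth` element. Identical seeds
#' give bit-identical recordings.
#'
#' @param model A [walker_model()].
#' @param speed Commanded belt speed in m/s.
#' @param duration Trial length in s; must accommodate at least 12 steps.
#' @param subject A [subject_params()].
#' @param seed Integer seed (default: the model's seed).
#' @return A `trial_recording` with `truth = list(events, steps, ...)`.
#' @export
#' @examples
#' s <- subject_params(l_ref = 0.9, mass = 75)
#' tr <- simulate_walking_trial(walker_model(), 1.2, 20, s, seed = 1)
#' head(tr$truth$steps)
simulate_walking_trial <- function(model, speed, duration, subject,
                                   seed = model$seed) {
  stopifnot(inherits(model, "walker_model"), inherits(subject, "subject_params"),
            speed > 0)
  f_step <- model$step_frequency_fn(speed)
  min_dur <- (12 + 1) / f_step
  if (duration < min_dur)
    stop(sprintf(
      "duration %.1f s too short: at least 12 steps (~%.1f s at %.2f steps/s) required",
      duration, min_dur, f_step))
  res <- .with_seed(seed, .synth_build(model, speed, duration, subject))
  res$trial
}

#' Simulate a full perturbation session
#'
#' Simulates treadmill walking at the (stability-normalised) base speed with
#' the protocol's belt-acceleration perturbations embedded in the belt
#' velocity stream. Each perturbation is triggered at the instant the
#' to-be-perturbed hallux passes the stance hallux, ramps the perturbed
#' belt at the specified acceleration to `speed_factor` times the base
#' speed, and decelerates at the perturbed limb's toe-off. The true MoS of
#' recovery step k drops by `drop * (1-adaptation)^(j-1) * recovery^k`
#' below baseline for the j-th same-limb perturbation.
#'
#' @param model A [walker_model()].
#' @param protocol A [build_protocol()] object.
#' @param subject A [subject_params()].
#' @param speed Base walking speed in m/s; by default the model's true
#'   stability-normalised speed at a 0.05 m target.
#' @param lead_in Unperturbed walking before the first perturbation
#'   interval starts (s, default 60).
#' @param tail Unperturbed walking after the last perturbation (s, default 20).
#' @param seed Integer seed (default: the model's seed).
#' @return A list of class `perturbation_session`: `trial` (the recording,
#'   with truth attached), `perturbations` (realized records: trigger,
#'   perturbed touchdown and toe-off times per perturbation) and `truth`
#'   (ground-truth events and labelled per-step MoS).
#' @export
simulate_session <- function(model, protocol = build_protocol(), subject,
                             speed = NULL, lead_in = 60, tail = 20,
                             seed = model$seed) {
  stopifnot(inherits(model, "walker_model"),
            inherits(protocol, "perturbation_protocol"),
            inherits(subject, "subject_params"))
  if (is.null(speed)) {
    a <- model$mos_curve_true
    curve <- structure(
      list(coefficients = c(a0 = a[1], a1 = a[2], a2 = a[3]),
           points = data.frame(speed = seq(0.4, 1.8, 0.2),
                               mean_mos = true_mos(model, seq(0.4, 1.8, 0.2))),
           r_squared = 1, target_mos = 0.05, solved_speed = NA_real_),
      class = "speed_mos_curve")
    speed <- solve_normalised_speed(curve)$solved_speed
  }
  arm <- lead_in + cumsum(protocol$interval)
  plan <- data.frame(id = protocol$id, limb = protocol$limb,
                     acceleration = protocol$acceleration,
                     speed_factor = protocol$speed_factor,
                     arm_time = arm, stringsAsFactors = FALSE)
  duration <- max(arm) + tail
  res <- .with_seed(seed, .synth_build(model, speed, duration, subject,
                                       pert_plan = plan))
  structure(list(trial = res$trial, perturbations = res$perturbations,
                 truth = res$truth, speed = speed, protocol = protocol),
            class = "perturbation_session")
}

#' @export
print.perturbation_session <- function(x, ...) {
  cat(sprintf(
    "<perturbation_session> %d perturbations at %.3f m/s, %.0f s, %d steps\n",
    nrow(x$perturbations), x$speed,
    max(x$trial$markers$time), nrow(x$truth$steps)))
  invisible(x)
}
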