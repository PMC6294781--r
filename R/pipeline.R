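#' Process a trial end to end: filter, detect events, compute step records
#'
#' @param trial A [trial_recording()].
#' @param config A [run_config()].
#' @return A list: `steps` (`step_records`), `events` (event detection
#'   result from [detect_gait_events()]) and `ftrial` (the filtered trial).
#' @export
process_trial <- function(trial, config = run_config()) {
  ftrial <- filter_trial(trial, config)
  ev <- detect_gait_events(ftrial, config)
  steps <- compute_step_records(ftrial, ev$events)
  list(steps = steps, events = ev, ftrial = ftrial)
}

#' Analyse a perturbation session
#'
#' Runs the full measurement chain on a session recording: filtering,
#' hybrid event detection, per-touchdown MoS, step labelling relative to
#' the supplied perturbation records, and per-perturbation recovery
#' metrics.
#'
#' @param trial A session [trial_recording()] (e.g. from
#'   [simulate_session()], `$trial`).
#' @param perturbations data.frame of perturbation records with
#'   `trigger_time` and `id` (the protocol controller's log; for synthetic
#'   sessions, `session$perturbations`).
#' @param config A [run_config()].
#' @return A list: `metrics` ([recovery_metrics()]), `steps` (labelled
#'   `step_records` with the `"base"` attribute) and `events`.
#' @export
analyse_session <- function(trial, perturbations, config = run_config()) {
  pr <- process_trial(trial, config)
  labelled <- label_steps(pr$steps, perturbations, config)
  metrics <- recovery_metrics(labelled, n_post = config$n_post_steps)
  list(metrics = metrics, steps = labelled, events = pr$events)
}
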