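MARKER_NAMES <- c("C7", "TroL", "TroR", "HalL", "HalR")
BELT_NAMES <- c("left", "right")

#' A synchronized treadmill walking recording
#'
#' Container for one walking bout: five-marker 3-D trajectories (anterior-
#' posterior, mediolateral and vertical components, at `marker_rate` Hz),
#' per-belt vertical ground-reaction force (at `force_rate` Hz) and per-belt
#' velocity. The anteroposterior axis points in the walking direction and is
#' fixed to the treadmill chassis. All quantities are SI (m, N, m/s, s).
#'
#' @param markers data.frame with columns `time`, `marker` (one of C7, TroL,
#'   TroR, HalL, HalR), `x_ap`, `x_ml`, `x_vert`; every marker present at
#'   every frame.
#' @param forces data.frame with columns `time`, `belt` ("left"/"right"),
#'   `fz` (vertical force, N).
#' @param belt_velocity data.frame with columns `time`, `belt`, `v` (m/s,
#'   non-negative).
#' @param commanded_speed Commanded treadmill speed in m/s.
#' @param subject A [subject_params()] object.
#' @param marker_rate,force_rate Sampling rates in Hz.
#' @param truth Optional list of generator ground truth (see
#'   [simulate_walking_trial()]); `NULL` for measured data.
#'
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(markers, forces, belt_velocity, commanded_speed,
                            subject, marker_rate = 100, force_rate = 1000,
                            truth = NULL) {
  stopifnot(inherits(subject, "subject_params"))
  if (!is.numeric(marker_rate) || marker_rate <= 0) stop("marker_rate must be > 0")
  if (!is.numeric(force_rate) || force_rate <= 0) stop("force_rate must be > 0")
  markers <- .check_table(markers, c("time", "marker", "x_ap", "x_ml", "x_vert"),
                          "markers")
  forces <- .check_table(forces, c("time", "belt", "fz"), "forces")
  belt_velocity <- .check_table(belt_velocity, c("time", "belt", "v"),
                                "belt_velocity")
  missing_markers <- setdiff(MARKER_NAMES, unique(markers$marker))
  if (length(missing_markers))
    stop("marker stream is missing marker(s): ",
         paste(missing_markers, collapse = ", "))
  n_per_marker <- table(markers$marker)[MARKER_NAMES]
  if (length(unique(n_per_marker)) != 1)
    stop("all five markers must be present for every marker frame")
  for (m in MARKER_NAMES) .check_time(markers$time[markers$marker == m],
                                      paste0("markers/", m))
  for (b in unique(forces$belt)) .check_time(forces$time[forces$belt == b],
                                             paste0("forces/", b))
  for (b in unique(belt_velocity$belt))
    .check_time(belt_velocity$time[belt_velocity$belt == b],
                paste0("belt_velocity/", b))
  if (any(belt_velocity$v < 0)) stop("belt velocity must be non-negative")
  structure(
    list(markers = markers, forces = forces, belt_velocity = belt_velocity,
         commanded_speed = commanded_speed, subject = subject,
         marker_rate = marker_rate, force_rate = force_rate, truth = truth),
    class = "trial_recording"
  )
}

.check_table <- function(x, cols, what) {
  if (!is.data.frame(x)) stop(what, " must be a data.frame")
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  x[cols]
}

.check_time <- function(tt, what) {
  if (length(tt) < 2) return(invisible())
  bad <- which(diff(tt) <= 0)
  if (length(bad))
    stop("time must be strictly increasing in ", what,
         "; first offending row: ", bad[1] + 1)
  invisible()
}

#' @export
print.trial_recording <- function(x, ...) {
  nfr <- sum(x$markers$marker == "C7")
  cat(sprintf(
    "<trial_recording> %.1f s at %g Hz markers / %g Hz force, speed %.2f m/s\n",
    nfr / x$marker_rate, x$marker_rate, x$force_rate, x$commanded_speed))
  cat(sprintf("  markers: %d frames x 5; force samples: %d; truth: %s\n",
              nfr, nrow(x$forces),
              if (is.null(x$truth)) "none" else "attached"))
  invisible(x)
}

#' Extract one marker component as a numeric vector
#'
#' @param trial A `trial_recording` (or `filtered_trial`).
#' @param marker Marker name (C7, TroL, TroR, HalL, HalR).
#' @param component One of `"x_ap"`, `"x_ml"`, `"x_vert"`.
#' @return Numeric vector, one value per marker frame (time order).
#' @export
marker_signal <- function(trial, marker, component = "x_ap") {
  marker <- match.arg(marker, MARKER_NAMES)
  component <- match.arg(component, c("x_ap", "x_ml", "x_vert"))
  sel <- trial$markers$marker == marker
  trial$markers[[component]][sel][order(trial$markers$time[sel])]
}

#' @rdname marker_signal
#' @export
marker_time <- function(trial) {
  sel <- trial$markers$marker == "C7"
  sort(trial$markers$time[sel])
}

# per-belt vectors on the force/belt clock
.belt_signal <- function(tab, belt, value_col) {
  sel <- tab$belt == belt
  ord <- order(tab$time[sel])
  list(time = tab$time[sel][ord], value = tab[[value_col]][sel][ord])
}

#' Write / read a trial recording on disk
#'
#' A trial is stored as a directory of plain-text files: `markers.csv`,
#' `forces.csv`, `belt_velocity.csv` (long format, one header row, comma
#' separated, UTF-8) and `meta.json` (rates, commanded speed, subject
#' parameters). The layout round-trips losslessly: `read_trial(write_trial(x))`
#' equals `x` up to float formatting (full precision is written).
#'
#' @param trial A [trial_recording()].
#' @param path Directory to create/read.
#' @param config Optional [run_config()] (unused by the reader beyond
#'   validation; accepted for interface symmetry).
#' @return `write_trial` returns `path` invisibly; `read_trial` returns a
#'   validated `trial_recording`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_csv_full(trial$markers, file.path(path, "markers.csv"))
  .write_csv_full(trial$forces, file.path(path, "forces.csv"))
  .write_csv_full(trial$belt_velocity, file.path(path, "belt_velocity.csv"))
  meta <- list(commanded_speed = trial$commanded_speed,
               marker_rate = trial$marker_rate,
               force_rate = trial$force_rate,
               subject = unclass(trial$subject))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(path)) stop("trial directory not found: ", path)
  need <- c("markers.csv", "forces.csv", "belt_velocity.csv", "meta.json")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss)) stop("trial directory is missing: ", paste(miss, collapse = ", "))
  markers <- read.csv(file.path(path, "markers.csv"), stringsAsFactors = FALSE)
  forces <- read.csv(file.path(path, "forces.csv"), stringsAsFactors = FALSE)
  belt <- read.csv(file.path(path, "belt_velocity.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  subj <- do.call(subject_params, as.list(meta$subject))
  trial_recording(markers, forces, belt,
                  commanded_speed = meta$commanded_speed, subject = subj,
                  marker_rate = meta$marker_rate, force_rate = meta$force_rate)
}

.write_csv_full <- function(df, path) {
  df_out <- df
  num <- vapply(df_out, is.numeric, logical(1))
  df_out[num] <- lapply(df_out[num], function(x) sprintf("%.12g", x))
  write.csv(df_out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read tabular results (step records, recovery metrics, ...)
#'
#' Tab-delimited text with a single header row; numeric columns are written
#' at full precision so the round trip is lossless to ~1e-12 relative.
#'
#' @param records A non-empty data.frame (e.g. step records from
#'   [compute_step_records()] or metrics from [recovery_metrics()]).
#' @param path Output file.
#' @return `write_results` returns `path` invisibly; `read_results` returns
#'   a data.frame.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0) stop("records must be non-empty")
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  tryCatch(
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  read.csv(path, sep = "\t", stringsAsFactors = FALSE)
}
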