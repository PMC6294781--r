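test_that("marker events sit at the velocity sign-switch frames", {
  # square-wave velocity alternating +1/-1 every 0.5 s over 5 s
  rate <- 100
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  v <- ifelse(floor(t * 2) %% 2 == 0, 1, -1)
  ev <- detect_events_marker(v, rate, limb = "left")
  expect_equal(sum(ev$kind == "touchdown"), 5)
  expect_equal(sum(ev$kind == "toeoff"), 4)  # ends mid-stance: last switch is a td
  expect_equal(ev$time[ev$kind == "touchdown"], c(0.5, 1.5, 2.5, 3.5, 4.5))
  expect_equal(ev$time[ev$kind == "toeoff"], c(1.0, 2.0, 3.0, 4.0))

  # all-positive velocity: no stance, empty result with a warning
  expect_warning(ev0 <- detect_events_marker(rep(1, 100), rate), "no velocity")
  expect_equal(nrow(ev0), 0)
})

test_that("debouncing removes chatter switch pairs", {
  rate <- 100
  t <- seq(0, 3 - 1 / rate, by = 1 / rate)
  v <- ifelse(floor(t) %% 2 == 0, 1, -1)      # true switches at 1 s, 2 s
  v[151:153] <- 1                              # 30 ms blip inside stance
  ev <- detect_events_marker(v, rate, limb = "right", debounce = 0.1)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$time, c(1.0, 2.0))
  # with debouncing off the blip survives
  ev2 <- detect_events_marker(v, rate, limb = "right", debounce = 0)
  expect_equal(nrow(ev2), 4)
})

test_that("force events interpolate the threshold crossing analytically", {
  rate <- 1000
  t <- seq(0, 1, by = 1 / rate)
  ev <- detect_events_force(100 * t, rate, threshold = 50, limb = "left")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "touchdown")
  expect_equal(ev$time, 0.5, tolerance = 1e-9)

  expect_equal(nrow(detect_events_force(rep(0, 100), rate, 50)), 0)
  expect_equal(nrow(detect_events_force(rep(500, 100), rate, 50)), 0)
  expect_error(detect_events_force(numeric(0), rate, 50), "absent")
  expect_error(detect_events_force(rep(1, 10), rate, threshold = -5), "> 0")
})

test_that("a constant marker-to-force lag is recovered exactly", {
  # marker events uniformly 30 ms earlier than force events
  td_m <- seq(1, 9, by = 1); to_m <- td_m + 0.6
  mk <- rbind(
    data.frame(kind = "touchdown", limb = "left", time = td_m,
               frame = NA_integer_, source = "marker"),
    data.frame(kind = "toeoff", limb = "left", time = to_m,
               frame = NA_integer_, source = "marker"))
  fr <- mk
  fr$time <- fr$time + 0.030
  fr$source <- "force"
  res <- correct_marker_events(mk, fr, window = 0.05)
  expect_equal(unname(res$offsets), c(0.030, 0.030), tolerance = 1e-12)
  got <- res$events$time[order(res$events$time)]
  expect_equal(got, sort(fr$time), tolerance = 1e-12)
})

test_that("a jittered lag is recovered to sample-mean accuracy", {
  set.seed(11)
  n <- 40
  td_m <- seq_len(n); to_m <- td_m + 0.6
  jit_td <- runif(n, -0.005, 0.005); jit_to <- runif(n, -0.005, 0.005)
  mk <- rbind(
    data.frame(kind = "touchdown", limb = "left", time = td_m,
               frame = NA_integer_, source = "marker"),
    data.frame(kind = "toeoff", limb = "left", time = to_m,
               frame = NA_integer_, source = "marker"))
  fr <- rbind(
    data.frame(kind = "touchdown", limb = "left", time = td_m + 0.020 + jit_td,
               frame = NA_integer_, source = "force"),
    data.frame(kind = "toeoff", limb = "left", time = to_m + 0.020 + jit_to,
               frame = NA_integer_, source = "force"))
  res <- correct_marker_events(mk, fr, window = 0.05)
  expect_lt(abs(res$offsets[["touchdown"]] - 0.020), 0.005 / sqrt(n) * 3)
  expect_lt(abs(res$offsets[["toeoff"]] - 0.020), 0.005 / sqrt(n) * 3)
})

test_that("correction errors out with no matched single-plate steps", {
  mk <- data.frame(kind = c("touchdown", "toeoff"), limb = "left",
                   time = c(1, 1.6), frame = NA_integer_, source = "marker")
  fr <- data.frame(kind = c("touchdown", "toeoff"), limb = "left",
                   time = c(5, 5.6), frame = NA_integer_, source = "force")
  expect_error(correct_marker_events(mk, fr, window = 0.05), "single-plate")
})

test_that("detected events match generator ground truth within 2 frames", {
  s <- test_subject()
  tr <- simulate_walking_trial(quiet_model(), 1.2, 20, s, seed = 5)
  ft <- filter_trial(tr)
  ev <- detect_gait_events(ft)
  truth <- tr$truth$events
  two_frames <- 2 / tr$marker_rate
  for (kind in c("touchdown", "toeoff")) {
    for (lb in c("left", "right")) {
      got <- ev$events$time[ev$events$kind == kind & ev$events$limb == lb]
      want <- truth$time[truth$kind == kind & truth$limb == lb]
      nearest <- match_truth(got, want)
      expect_lt(max(abs(got - nearest)), two_frames)
    }
  }
})

test_that("corrected events alternate with positive stance durations and
           beat raw marker events against ground truth", {
  s <- test_subject()
  tr <- simulate_walking_trial(quiet_model(), 1.0, 20, s, seed = 9)
  ft <- filter_trial(tr)
  ev <- detect_gait_events(ft)
  truth <- tr$truth$events
  for (lb in c("left", "right")) {
    e <- ev$events[ev$events$limb == lb, ]
    e <- e[order(e$time), ]
    expect_true(all(e$kind[seq(1, nrow(e) - 1, by = 2)] !=
                      e$kind[seq(2, nrow(e), by = 2)]))
    expect_true(all(diff(e$time) > 0))
  }
  mae <- function(events) {
    got <- events$time
    mean(abs(got - match_truth(got, truth$time)))
  }
  expect_lte(mae(ev$events), mae(ev$marker_events))
})
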