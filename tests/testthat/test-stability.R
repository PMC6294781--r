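test_that("XCoM reproduces hand-evaluated cases of the reduced-model equation", {
  s <- subject_params(l_ref = 0.9, g = 9.81)
  # null configuration: everything at the rear hallux, at rest
  expect_equal(compute_xcom(0, 0, 0, 0, 0, 0, 0, s), 0, tolerance = 1e-12)
  # hand evaluation: 0.5 + 1.0 / sqrt(9.81 / 0.9) = 0.80289...
  expect_equal(compute_xcom(0.5, 0.5, 0, 0, 0, 0, v_belt = 1.0, subject = s),
               0.5 + 1.0 / sqrt(9.81 / 0.9), tolerance = 1e-12)
  expect_equal(compute_xcom(0.5, 0.5, 0, 0, 0, 0, 1.0, s), 0.8029,
               tolerance = 1e-4)
})

test_that("XCoM is monotone in leg length and belt speed as the equation
           dictates", {
  s1 <- subject_params(l_ref = 0.9)
  s2 <- subject_params(l_ref = 1.8)
  x1 <- compute_xcom(0.3, 0.3, 0, 0.1, 0.1, 0.1, 1.2, s1)
  x2 <- compute_xcom(0.3, 0.3, 0, 0.1, 0.1, 0.1, 1.2, s2)
  expect_gt(x2, x1)  # doubling l_ref increases xcom at fixed velocity
  # mos strictly decreasing in v_belt, all else fixed
  vb <- seq(0, 2, by = 0.25)
  mos <- 0.4 - compute_xcom(0.3, 0.3, 0, 0, 0, 0, vb, s1)
  expect_true(all(diff(mos) < 0))
})

test_that("static double stance degenerates to the static margin", {
  # zero velocities, zero belt: mos = bos - (trochanter midpoint - rear hallux)
  s <- test_subject()
  tm <- seq(0, 20, by = 0.01)
  mk <- rbind(
    data.frame(time = tm, marker = "C7", x_ap = 0.1, x_ml = 0, x_vert = 1.45),
    data.frame(time = tm, marker = "TroL", x_ap = 0.1, x_ml = -0.1, x_vert = 0.9),
    data.frame(time = tm, marker = "TroR", x_ap = 0.1, x_ml = 0.1, x_vert = 0.9),
    data.frame(time = tm, marker = "HalL", x_ap = 0.0, x_ml = -0.1, x_vert = 0.03),
    data.frame(time = tm, marker = "HalR", x_ap = 0.3, x_ml = 0.1, x_vert = 0.03))
  tf <- seq(0, 20, by = 0.001)
  forces <- rbind(data.frame(time = tf, belt = "left", fz = 400),
                  data.frame(time = tf, belt = "right", fz = 400))
  belt <- rbind(data.frame(time = tf, belt = "left", v = 0),
                data.frame(time = tf, belt = "right", v = 0))
  tr <- trial_recording(mk, forces, belt, 0, s)
  ft <- filter_trial(tr)
  ev <- data.frame(kind = "touchdown", limb = "right", time = 10,
                   frame = 1000L, source = "corrected")
  st <- compute_step_records(ft, ev)
  expect_equal(st$bos, 0.3, tolerance = 1e-6)
  expect_equal(st$mos, 0.3 - 0.1, tolerance = 1e-6)
  # negative mos when the halluces coincide and the XCoM is ahead
  mk2 <- mk
  mk2$x_ap[mk2$marker == "HalR"] <- 0.0
  tr2 <- trial_recording(mk2, forces, belt, 0, s)
  st2 <- compute_step_records(filter_trial(tr2), ev)
  expect_equal(st2$bos, 0, tolerance = 1e-6)
  expect_lt(st2$mos, 0)
})

test_that("per-step MoS matches generator ground truth on noiseless data", {
  s <- test_subject()
  tr <- simulate_walking_trial(quiet_model(), 1.3, 20, s, seed = 2)
  pr <- process_trial(tr)
  truth <- tr$truth$steps
  i <- vapply(pr$steps$touchdown_time,
              function(t) which.min(abs(truth$touchdown_time - t)), integer(1))
  expect_equal(nrow(pr$steps), nrow(truth))
  expect_lt(max(abs(pr$steps$mos - truth$mos_true[i])), 0.01)
  # invariant: mos = bos - xcom exactly
  expect_equal(pr$steps$mos, pr$steps$bos - pr$steps$xcom, tolerance = 1e-12)
})

test_that("step labelling implements the Base/Pre/Post window definitions", {
  # 20 pre-perturbation steps with MoS = index/100, perturbation after step 20
  n <- 30
  steps <- structure(
    data.frame(touchdown_time = seq_len(n), limb = rep(c("left", "right"), 15),
               bos = 0.5, xcom = 0.4, v_com = 1,
               mos = c(seq_len(20) / 100, rep(0.07, 10)),
               label = "unlabelled", pert_id = NA_integer_,
               stringsAsFactors = FALSE),
    class = c("step_records", "data.frame"))
  pert <- data.frame(id = 1L, trigger_time = 20.5)
  lab <- label_steps(steps, pert)
  base <- attr(lab, "base")
  # Base = mean MoS of the 11th-to-2nd-last pre-perturbation steps (10..19)
  expect_equal(base$base_mos, mean((10:19) / 100), tolerance = 1e-12)
  expect_equal(base$base_mos, 0.145, tolerance = 1e-12)
  expect_equal(base$n_base, 10L)
  expect_equal(lab$label[20], "Pre")
  expect_equal(lab$label[21:28], paste0("Post", 1:8))
  expect_equal(sum(lab$label == "Base"), 10)
  expect_true(all(is.na(lab$pert_id[29:30])))

  # constant pre-steps give a constant baseline
  steps$mos <- 0.07
  expect_equal(attr(label_steps(steps, pert), "base")$base_mos, 0.07)

  # truncation when fewer than 8 post steps remain
  pert_late <- data.frame(id = 1L, trigger_time = 24.5)
  expect_warning(lab2 <- label_steps(steps, pert_late), "only 6")
  expect_equal(sum(grepl("^Post", lab2$label)), 6)
  expect_equal(lab2$label[30], "Post6")

  # perturbations must be chronological
  pert2 <- data.frame(id = 1:2, trigger_time = c(20.5, 15.5))
  expect_error(label_steps(steps, pert2), "chronological")
})

test_that("label counts per perturbation follow the window sizes", {
  s <- test_subject()
  m <- walker_model()
  ses <- simulate_session(m, build_protocol(seed = 3), s, seed = 3)
  res <- analyse_session(ses$trial, ses$perturbations)
  lab <- res$steps
  for (id in ses$perturbations$id) {
    sel <- !is.na(lab$pert_id) & lab$pert_id == id
    expect_equal(sum(lab$label[sel] == "Pre"), 1)
    expect_equal(sum(grepl("^Post", lab$label[sel])), 8)
    expect_equal(sum(lab$label[sel] == "Base"), 10)
  }
})
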