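test_that("too-short trials are rejected with the minimum step count", {
  s <- test_subject()
  expect_error(simulate_walking_trial(walker_model(), 0.4, 5, s),
               "12 steps")
})

test_that("identical seeds give bit-identical recordings", {
  s <- test_subject()
  m <- walker_model()
  a <- simulate_walking_trial(m, 1.2, 15, s, seed = 4)
  b <- simulate_walking_trial(m, 1.2, 15, s, seed = 4)
  expect_identical(a$markers, b$markers)
  expect_identical(a$forces, b$forces)
  expect_identical(a$truth$steps, b$truth$steps)
  c <- simulate_walking_trial(m, 1.2, 15, s, seed = 5)
  expect_false(identical(a$markers$x_ap, c$markers$x_ap))
})

test_that("ground-truth MoS of the final 10 steps tracks the model's curve", {
  s <- test_subject()
  m <- walker_model()  # mos_noise_sd = 0.01
  for (v in c(0.6, 1.2, 1.8)) {
    tr <- simulate_walking_trial(m, v, 20, s, seed = round(100 * v))
    mos10 <- tail(tr$truth$steps$mos_true, 10)
    expect_lt(abs(mean(mos10) - true_mos(m, v)),
              3 * m$mos_noise_sd / sqrt(10))
  }
})

test_that("noiseless mean MoS versus speed is quadratic to R^2 > 0.99", {
  s <- test_subject()
  m <- quiet_model()
  grid <- seq(0.4, 1.8, by = 0.2)
  means <- vapply(grid, function(v) {
    tr <- simulate_walking_trial(m, v, 16, s, seed = 1)
    mean(tail(tr$truth$steps$mos_true, 10))
  }, numeric(1))
  fit <- fit_mos_speed_curve(data.frame(speed = grid, mean_mos = means))
  expect_gt(fit$r_squared, 0.99)
})

test_that("stance hallux velocity is negative and near belt speed", {
  s <- test_subject()
  tr <- simulate_walking_trial(quiet_model(), 1.0, 15, s, seed = 6)
  ft <- filter_trial(tr)
  v <- marker_velocity(ft, "HalL")
  tt <- marker_time(ft)
  truth <- tr$truth$events
  td <- truth$time[truth$kind == "touchdown" & truth$limb == "left"]
  to <- truth$time[truth$kind == "toeoff" & truth$limb == "left"]
  # mid-stance instants of a few full steps
  mid <- vapply(td[2:5], function(x) (x + min(to[to > x])) / 2, numeric(1))
  vmid <- approx(tt, v, xout = mid)$y
  expect_true(all(vmid < 0))
  expect_true(all(abs(-vmid - 1.0) < 0.5))
})

test_that("per-step perturbation deficits follow the closed-form schedule", {
  s <- test_subject()
  m <- walker_model(mos_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0,
                    perturbation_response = list(drop = 0.16, recovery = 0.5,
                                                 adaptation = 0))
  proto <- build_protocol(seed = 2, limbs = c("left", "left"),
                          interval_bounds = c(30, 40))
  ses <- simulate_session(m, proto, s, speed = 1.3, seed = 2)
  tru <- ses$truth$steps
  base <- true_mos(m, 1.3)
  for (id in 1:2) {
    post <- tru[!is.na(tru$pert_id) & tru$pert_id == id &
                  grepl("^Post", tru$label_true), ]
    post <- post[order(post$touchdown_time), ]
    defs <- base - post$mos_true
    # deficit of Post-k is drop * recovery^k; Post3: 0.16 * 0.5^3 = 0.02
    expect_equal(defs, 0.16 * 0.5^(1:8), tolerance = 1e-12)
    expect_equal(defs[3], 0.02, tolerance = 1e-12)
  }
})

test_that("zero adaptation gain gives identical drops; nonzero shrinks them", {
  s <- test_subject()
  m2 <- walker_model(mos_noise_sd = 0, marker_noise_sd = 0,
                     perturbation_response = list(drop = 0.3, recovery = 0.5,
                                                  adaptation = 0.2))
  proto <- build_protocol(seed = 2, limbs = c("left", "left", "left"),
                          interval_bounds = c(30, 40))
  ses <- simulate_session(m2, proto, s, speed = 1.3, seed = 2)
  tru <- ses$truth$steps
  base <- true_mos(m2, 1.3)
  p1 <- tru$mos_true[!is.na(tru$pert_id) & tru$pert_id == 1 &
                       tru$label_true == "Post1"]
  p3 <- tru$mos_true[!is.na(tru$pert_id) & tru$pert_id == 3 &
                       tru$label_true == "Post1"]
  expect_equal(base - p1, 0.3 * 0.5, tolerance = 1e-12)
  expect_equal(base - p3, 0.3 * 0.8^2 * 0.5, tolerance = 1e-12)
})

test_that("a 10-perturbation session embeds exactly 10 belt ramps", {
  s <- test_subject()
  ses <- simulate_session(walker_model(), build_protocol(seed = 8), s, seed = 8)
  bv <- ses$trial$belt_velocity
  n_ramps <- 0
  for (b in c("left", "right")) {
    v <- bv$v[bv$belt == b][order(bv$time[bv$belt == b])]
    dev <- v > ses$speed + 1e-9
    n_ramps <- n_ramps + sum(diff(c(FALSE, dev)) == 1)
  }
  expect_equal(n_ramps, 10)
  # trigger strictly precedes the perturbed limb's touchdown
  expect_true(all(ses$perturbations$trigger_time <
                    ses$perturbations$touchdown_time))
  expect_true(all(ses$perturbations$toeoff_time >
                    ses$perturbations$touchdown_time))
})
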