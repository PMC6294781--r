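test_that("steps to consistently positive MoS follows the terminal-run rule", {
  expect_equal(as.integer(steps_to_positive(
    c(-0.10, -0.05, 0.02, 0.04, 0.06, 0.07, 0.07, 0.07))), 3L)
  # isolated positive step does not count: positivity must be consistent
  expect_equal(as.integer(steps_to_positive(
    c(0.02, -0.01, 0.03, 0.04, 0.05, 0.05, 0.05, 0.05))), 3L)
  # all positive: minimum one step is always required
  expect_equal(as.integer(steps_to_positive(rep(0.05, 8))), 1L)
  # zero counts as non-negative
  expect_equal(as.integer(steps_to_positive(c(-0.1, 0, 0.1))), 2L)
  # still negative at the last analysed step: undetermined, K + 1
  res <- steps_to_positive(c(-0.1, -0.05, -0.01))
  expect_equal(as.integer(res), 4L)
  expect_true(attr(res, "undetermined"))
  expect_error(steps_to_positive(numeric(0)), "no post")
})

test_that("steps_to_positive ignores steps after the terminal run begins", {
  base <- c(-0.1, -0.02, 0.01, 0.02)
  extended <- c(base, rep(0.05, 10))
  expect_equal(as.integer(steps_to_positive(base)),
               as.integer(steps_to_positive(extended)))
})

test_that("recovery metrics reduce labelled sessions to per-perturbation rows", {
  s <- test_subject()
  m <- walker_model()
  ses <- simulate_session(m, build_protocol(seed = 12), s, seed = 12)
  res <- analyse_session(ses$trial, ses$perturbations)
  expect_s3_class(res$metrics, "recovery_metrics")
  expect_equal(nrow(res$metrics), 10)
  expect_equal(res$metrics$n_post, rep(8L, 10))
  expect_true(all(res$metrics$steps_to_positive >= 1))
  expect_true(all(res$metrics$steps_to_positive <= 9))
  # Post1 lands on the perturbed limb (the trigger fires during its swing)
  expect_equal(res$metrics$limb, ses$perturbations$limb)
  # deficits are negative early in recovery
  expect_true(all(res$metrics$deficit_post1 < 0))
})

test_that("group-level steps to baseline detects a constructed 3-step deficit", {
  set.seed(21)
  n <- 18
  mk_group <- function(deficits, sd = 0.02) {
    steps <- c("Base", paste0("Post", seq_along(deficits)))
    do.call(rbind, lapply(seq_len(n), function(s) {
      data.frame(subject = s, step = steps,
                 mos = c(mean(rnorm(10, 0.05, sd / sqrt(10))),
                         0.05 - deficits + rnorm(length(deficits), 0, sd)))
    }))
  }
  g <- mk_group(c(0.15, 0.15, 0.15, 0, 0, 0, 0, 0))
  expect_equal(as.integer(steps_to_baseline(g)), 3L)
  # deficit shrinking below noise after Post2
  g2 <- mk_group(c(0.15, 0.12, 0.001, 0.001, 0, 0, 0, 0))
  expect_equal(as.integer(steps_to_baseline(g2)), 2L)
  # unbalanced designs are rejected
  expect_error(steps_to_baseline(g[-1, ]), "unbalanced")
})

test_that("under the null, steps to baseline is almost always zero", {
  set.seed(31)
  n_rep <- 200
  zeros <- 0
  for (r in seq_len(n_rep)) {
    g <- do.call(rbind, lapply(1:18, function(s) {
      data.frame(subject = s, step = c("Base", paste0("Post", 1:8)),
                 mos = rnorm(9, 0.05, 0.02))
    }))
    if (steps_to_baseline(g) == 0L) zeros <- zeros + 1
  }
  # familywise bound: P(any false positive) <= 8 * alpha unadjusted;
  # with Bonferroni it is <= alpha, so well above 1 - 8 * 0.05
  expect_gt(zeros / n_rep, 1 - 8 * 0.05)
  expect_gt(zeros / n_rep, 0.9)
})

test_that("steps to baseline recovers the detectable deficit count under the
           generator's perturbation response", {
  # drop 0.16, recovery 0.5 per step, per-measurement noise 0.01, n = 18:
  # deficits 0.08, 0.04, 0.02, 0.01, 0.005, ... against a Bonferroni paired-t
  # detectability threshold of ~0.007 m -> expected count 4, with Post4 only
  # ~1.4x the threshold, so exact recovery cannot be certain in every seed.
  set.seed(41)
  drop <- 0.16; rec <- 0.5; sdn <- 0.01; n <- 18
  deficits <- drop * rec^(1:8)
  thresh <- qt(1 - 0.05 / 8 / 2, df = n - 1) * sdn * sqrt(1 + 1 / 10) / sqrt(n)
  expected <- max(which(deficits > thresh))
  expect_equal(expected, 4L)
  counts <- replicate(100, {
    g <- do.call(rbind, lapply(seq_len(n), function(s) {
      data.frame(subject = s, step = c("Base", paste0("Post", 1:8)),
                 mos = c(mean(rnorm(10, 0.05, sdn)),
                         0.05 - deficits + rnorm(8, 0, sdn)))
    }))
    as.integer(steps_to_baseline(g))
  })
  expect_gt(mean(counts == expected), 0.5)       # exact match in the majority
  expect_gte(mean(abs(counts - expected) <= 1), 0.95)  # within one step almost always
})
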