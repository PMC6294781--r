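# Shared fixtures: everything is generated in code at test time.

test_subject <- function() subject_params(l_ref = 0.9, g = 9.81,
                                          height = 1.75, mass = 75)

# noise-free walker for oracle-equivalence tests
quiet_model <- function(...) {
  walker_model(mos_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0, ...)
}

# a tiny hand-made trial: 2 s of 5-marker data at 100 Hz, flat forces
tiny_trial <- function(duration = 2, marker_rate = 100, force_rate = 1000) {
  tm <- seq(0, duration, by = 1 / marker_rate)
  tf <- seq(0, duration, by = 1 / force_rate)
  mk <- do.call(rbind, lapply(c("C7", "TroL", "TroR", "HalL", "HalR"),
    function(m) data.frame(time = tm, marker = m, x_ap = sin(tm),
                           x_ml = 0, x_vert = 1, stringsAsFactors = FALSE)))
  fz <- rbind(data.frame(time = tf, belt = "left", fz = 0),
              data.frame(time = tf, belt = "right", fz = 0))
  bv <- rbind(data.frame(time = tf, belt = "left", v = 1),
              data.frame(time = tf, belt = "right", v = 1))
  trial_recording(mk, fz, bv, commanded_speed = 1, subject = test_subject(),
                  marker_rate = marker_rate, force_rate = force_rate)
}

# match measured touchdowns to ground-truth touchdowns by nearest time
match_truth <- function(measured_times, truth_times) {
  vapply(measured_times,
         function(t) truth_times[which.min(abs(truth_times - t))],
         numeric(1))
}

# ground-truth steps-to-positive count for one perturbation of a session
truth_count <- function(session, id, n_post = 8) {
  tru <- session$truth$steps
  post <- tru[!is.na(tru$pert_id) & tru$pert_id == id &
                grepl("^Post", tru$label_true), , drop = FALSE]
  post <- post[order(post$touchdown_time), , drop = FALSE]
  as.integer(steps_to_positive(post$mos_true[seq_len(min(n_post, nrow(post)))]))
}

# brute-force sums-of-squares two-way repeated-measures ANOVA (oracle,
# independent of aov): balanced subject x A x B, one value per cell
rm_anova_bruteforce <- function(d) {
  s <- factor(d$subject); A <- factor(d$A); B <- factor(d$B); y <- d$value
  ns <- nlevels(s); na <- nlevels(A); nb <- nlevels(B)
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_sa <- tapply(y, list(s, A), mean); m_sb <- tapply(y, list(s, B), mean)
  m_ab <- tapply(y, list(A, B), mean)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
  ss_as <- nb * sum((m_sa - outer(m_s - gm, m_a - gm, "+") - gm)^2)
  ss_bs <- na * sum((m_sb - outer(m_s - gm, m_b - gm, "+") - gm)^2)
  resid <- y
  for (i in seq_along(y)) {
    resid[i] <- y[i] - m_sa[s[i], A[i]] - m_sb[s[i], B[i]] - m_ab[A[i], B[i]] +
      m_s[s[i]] + m_a[A[i]] + m_b[B[i]] - gm
  }
  ss_abs <- sum(resid^2)
  f_a <- (ss_a / (na - 1)) / (ss_as / ((na - 1) * (ns - 1)))
  f_b <- (ss_b / (nb - 1)) / (ss_bs / ((nb - 1) * (ns - 1)))
  f_ab <- (ss_ab / ((na - 1) * (nb - 1))) /
    (ss_abs / ((na - 1) * (nb - 1) * (ns - 1)))
  c(A = f_a, B = f_b, `A:B` = f_ab)
}
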