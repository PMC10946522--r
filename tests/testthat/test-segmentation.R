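test_that("local velocity is the forward difference over dt", {
  expect_equal(local_velocity(c(0, 0.2, 0.4), 0.2), c(1, 1))
  expect_equal(local_velocity(rep(0.7, 5), 0.2), rep(0, 4))
  expect_equal(local_velocity(c(0, -0.22), 0.2), -1.1)
  m <- local_velocity(rbind(c(0, 0.2, 0.4), c(0, 0, 0)), 0.2)
  expect_equal(m, rbind(c(1, 1), c(0, 0)))
  expect_error(local_velocity(c(0, 1), times = c(0, 0.2, 0.5), dt = 0.2),
               "irregular")
  expect_error(local_velocity(numeric(1), 0.2), "2 samples")
})

test_that("bilateral filter matches a direct stencil-formula oracle", {
  fp <- filter_params()
  set.seed(61)
  for (rep in 1:3) {
    v <- rnorm(80, 0, 0.3) + rep(c(0, 1, 0, -1.1), each = 20)
    expect_equal(bilateral_filter(v, fp), bilateral_reference(v, fp),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # matrix and vector paths agree row by row
  V <- rbind(v, rev(v))
  out <- bilateral_filter(V, fp)
  expect_equal(out[1, ], bilateral_filter(v, fp), ignore_attr = TRUE)
  expect_equal(out[2, ], bilateral_filter(rev(v), fp), ignore_attr = TRUE)
})

test_that("constant velocity series is a fixed point reached in one pass", {
  vs <- bilateral_filter(rep(0.8, 40))
  expect_equal(vs, rep(0.8, 40), ignore_attr = TRUE)
  expect_equal(unique(attr(vs, "iterations")), 1L)
})

test_that("a smoothing configuration denoises a step and keeps both plateaus", {
  fp <- filter_params(sigma_s_init = 2, sigma_v_init = 0.5)
  set.seed(62)
  v <- c(rep(0, 40), rep(1, 40)) + rnorm(80, 0, 0.05)
  vs <- bilateral_filter(v, fp)
  expect_lt(max(abs(vs[8:33])), 0.1)
  expect_lt(max(abs(vs[48:73] - 1)), 0.1)
})

test_that("a smoothing configuration attenuates an isolated spike; the default does not", {
  v <- rep(0, 60)
  v[30] <- 1
  fp <- filter_params(sigma_s_init = 2, sigma_v_init = 0.5)
  expect_lt(max(abs(bilateral_filter(v, fp))), 0.3)
  # the default schedule is conservative: a clean profile whose first-pass
  # update is below the stopping tolerance passes through nearly unchanged
  expect_gt(max(abs(bilateral_filter(v))), 0.9)
})

test_that("thresholding produces the documented segment boundaries", {
  # velocity labels r,r,R,R,R,r at dt = 0.2 -> durations 0.4, 0.6, 0.2
  v <- c(0, 0, 1, 1, 1, 0)
  x <- c(0, 0, 0, 0.2, 0.4, 0.6, 0.6)
  s <- segment_phases(v, x, 0.2)
  expect_equal(s$kind, c("rest", "run", "rest"))
  expect_equal(s$duration, c(0.4, 0.6, 0.2))
  expect_equal(s$v_run, c(NA, 1, NA))
  expect_equal(s$left_censored, c(TRUE, FALSE, FALSE))
  expect_equal(s$right_censored, c(FALSE, FALSE, TRUE))

  # all below threshold: one both-censored rest
  s2 <- segment_phases(rep(0.1, 10), seq(0, 0.2, length.out = 11), 0.2)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$kind, "rest")
  expect_true(s2$left_censored & s2$right_censored)

  # uniform run: v_run equals total displacement over total duration
  x3 <- seq(0, by = 0.2, length.out = 11)
  s3 <- segment_phases(rep(1, 10), x3, 0.2)
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$v_run, (x3[11] - x3[1]) / s3$duration)
  expect_error(segment_phases(numeric(0), numeric(0), 0.2), "empty")
})

test_that("segment durations always sum to the sampled span", {
  set.seed(63)
  ens <- simulate_trajectories(levy_walk_params(), 40, aging_time = 20,
                               noise = noise_white(0.05))
  segs <- segment_ensemble(ens)
  sums <- as.numeric(tapply(segs$duration, segs$particle_id, sum))
  expect_equal(sums, rep((length(ens$times) - 1) * ens$dt, 40))
  # consecutive segments alternate kind
  for (pid in unique(segs$particle_id)) {
    k <- segs$kind[segs$particle_id == pid]
    if (length(k) > 1) expect_true(all(k[-1] != k[-length(k)]))
  }
})

test_that("segmentation recovers true run intervals on noiseless data", {
  set.seed(64)
  ens <- simulate_trajectories(levy_walk_params(), 300, aging_time = 0,
                               ground_truth = TRUE)
  segs <- segment_ensemble(ens)
  tr <- ens$true_segments
  n_checked <- 0
  n_good <- 0
  for (pid in unique(tr$particle_id)) {
    t_runs <- tr[tr$particle_id == pid & tr$kind == "run" &
                   tr$duration > 7 * ens$dt, ]
    s_runs <- segs[segs$particle_id == pid & segs$kind == "run", ]
    for (i in seq_len(nrow(t_runs))) {
      n_checked <- n_checked + 1
      if (nrow(s_runs) == 0) next
      ov <- pmin(s_runs$t_end, t_runs$t_end[i]) -
        pmax(s_runs$t_start, t_runs$t_start[i])
      j <- which.max(ov)
      if (ov[j] > 0 &&
          abs(s_runs$t_start[j] - t_runs$t_start[i]) <= 3 * ens$dt &&
          abs(s_runs$t_end[j] - t_runs$t_end[i]) <= 3 * ens$dt)
        n_good <- n_good + 1
    }
  }
  expect_gt(n_checked, 200)
  expect_gte(n_good / n_checked, 0.9)
})

test_that("run statistics summarize velocities and directional bias", {
  segs <- data.frame(
    particle_id = c(1, 1, 2),
    kind = "run",
    v_run = c(1.0, -1.1, 1.0),
    left_censored = FALSE, right_censored = FALSE
  )
  rs <- run_statistics(segs)
  expect_equal(rs$v_antero_mean, 1.0)
  expect_equal(rs$v_retro_mean, -1.1)
  expect_equal(rs$antero_fraction, 2 / 3)

  only_rest <- data.frame(particle_id = 1, kind = "rest", v_run = NA,
                          left_censored = TRUE, right_censored = TRUE)
  rs2 <- run_statistics(only_rest)
  expect_true(is.na(rs2$v_antero_mean))
  expect_true(is.nan(rs2$antero_fraction))
  expect_equal(rs2$no_run_fraction, 1)
  expect_error(run_statistics(segs[0, ]), "empty")
})

test_that("segmenting simulated anterograde-biased data recovers the bias", {
  set.seed(65)
  p <- mrnp_preset("arc")
  ens <- simulate_trajectories(p, 800, aging_time = 0)
  segs <- segment_ensemble(ens)
  rs <- run_statistics(segs)
  expect_equal(rs$antero_fraction, p$p_antero, tolerance = 0.05)
  expect_equal(rs$v_antero_mean, p$v_antero, tolerance = 0.12)
  expect_equal(rs$v_retro_mean, p$v_retro, tolerance = 0.12)
})

test_that("filter parameter validation enforces the tolerance ordering", {
  expect_error(filter_params(stop_tol = 0.5, v_threshold = 0.3), "stop_tol")
  expect_error(filter_params(sigma_v_init = -1), "positive")
})
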