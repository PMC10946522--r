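test_that("rest-time sampler inverts the survival function exactly", {
  # S(3) = (3+1)^-1 = 1/4 for alpha = 1
  expect_equal(sample_rest_time(1, 0.25), 3)
  # frozen value: bisection of (t+1)^-0.24 = 0.5 gives 2^(1/0.24) - 1
  oracle <- uniroot(function(t) (t + 1)^(-0.24) - 0.5, c(1, 100),
                    tol = 1e-12)$root
  expect_equal(sample_rest_time(0.24, 0.5), 16.9594, tolerance = 1e-4)
  expect_equal(sample_rest_time(0.24, 0.5), oracle, tolerance = 1e-9)
  # u -> 1 limit gives vanishing rests
  expect_lt(sample_rest_time(0.24, 1 - 1e-12), 1e-8)
  expect_error(sample_rest_time(0, 0.5), "alpha_rest")
  expect_error(sample_rest_time(0.24, 0), "strictly inside")
  expect_error(sample_rest_time(0.24, 1), "strictly inside")
})

test_that("empirical CDF of rest draws matches the analytic law (KS)", {
  set.seed(11)
  draws <- sample_rest_time(0.24, runif(1e4))
  ks <- suppressWarnings(
    ks.test(draws, function(q) 1 - (q + 1)^(-0.24)))
  expect_gt(ks$p.value, 0.01)
})

test_that("run-time rejection sampler reproduces the truncated power law", {
  set.seed(12)
  draws <- sample_run_time(2e5, 0.18, 12.6)
  # mean against quadrature of t * psi_run(t)
  mean_oracle <- integrate(function(t) t * run_pdf(t, 0.18, 12.6),
                           0, Inf, rel.tol = 1e-10)$value
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean_oracle), 4 * se)
  # acceptance probability of one proposal equals eta * N (quadrature)
  set.seed(13)
  prop <- runif(2e5)^(-1 / 0.18) - 1
  acc_rate <- mean(exp(-prop / 12.6))
  expect_equal(acc_rate, 0.18 * run_pdf_norm(0.18, 12.6), tolerance = 0.01)
  # tau -> infinity limit collapses onto the pure power law
  set.seed(14)
  lim <- sample_run_time(2e4, 0.18, 1e12)
  pure <- sample_rest_time(0.18, runif(2e4))
  expect_gt(suppressWarnings(ks.test(lim, pure))$p.value, 0.01)
  expect_error(sample_run_time(10, -1, 5), "eta_run")
  expect_error(sample_run_time(10, 0.2, 0), "tau_r")
})

test_that("simulated trajectories are ballistic while the first run lasts", {
  p <- levy_walk_params(alpha_rest = 0.24, eta_run = 0.1, tau_r = 1e5,
                        v_antero = 1.3, p_antero = 1)
  set.seed(21)
  ens <- simulate_trajectories(p, 200, aging_time = 0, ground_truth = TRUE)
  first_run <- ens$true_segments[!duplicated(ens$true_segments$particle_id), ]
  covers <- first_run$particle_id[first_run$kind == "run" &
                                    first_run$t_end >= ens$window]
  expect_gt(length(covers), 20)
  X <- ens$positions[covers, , drop = FALSE]
  expect_equal(X, outer(rep(1, length(covers)), 1.3 * ens$times),
               tolerance = 1e-10, ignore_attr = TRUE)
  # and EA MSD of the ballistic subset is exactly v^2 dt^2
  sub <- ens
  sub$positions <- X
  ea <- ea_msd(sub, lags = c(1, 5, 20))
  expect_equal(ea$msd, (1.3 * ea$lag)^2, tolerance = 1e-10)
})

test_that("a trajectory resting through the window never moves", {
  set.seed(22)
  ens <- simulate_trajectories(levy_walk_params(), 400, aging_time = 50,
                               ground_truth = TRUE)
  tr <- ens$true_segments
  rest_cover <- tr$particle_id[tr$kind == "rest" & tr$t_start == 0 &
                                 tr$t_end == ens$window]
  expect_gt(length(rest_cover), 100)
  expect_equal(max(abs(ens$positions[rest_cover, ])), 0)
  # and their per-sample labels are all rest
  expect_equal(max(ens$labels[rest_cover, ]), 0L)
})

test_that("state occupancy at the aging time matches a scalar event-loop oracle", {
  p <- levy_walk_params()
  ta <- 10
  set.seed(31)
  ens <- simulate_trajectories(p, 4000, aging_time = ta)
  frac_run_pkg <- mean(ens$labels[, 1])
  set.seed(32)
  frac_run_oracle <- mean(vapply(1:4000, function(i)
    walk_state_at(p, ta) == "run", logical(1)))
  se <- sqrt(2 * 0.25 / 4000)
  expect_lt(abs(frac_run_pkg - frac_run_oracle), 5 * se)
})

test_that("no-run fraction is zero at ta = 0 and increases with aging", {
  set.seed(41)
  curve <- no_run_fraction_curve(levy_walk_params(), c(0, 5, 50, 500),
                                 n_traj = 20000)
  expect_equal(curve$fraction[1], 0)
  expect_true(all(diff(curve$fraction) >= 0))
  expect_error(no_run_fraction_curve(levy_walk_params(), numeric(0)),
               "non-empty")
})

test_that("identical seeds give bit-identical ensembles", {
  p <- mrnp_preset("arc")
  set.seed(7)
  a <- simulate_trajectories(p, 50, aging_time = 30,
                             noise = noise_white(0.05))
  set.seed(7)
  b <- simulate_trajectories(p, 50, aging_time = 30,
                             noise = noise_white(0.05))
  expect_identical(a$positions, b$positions)
  expect_identical(a$labels, b$labels)
})

test_that("noise models behave as specified", {
  set.seed(51)
  ens <- simulate_trajectories(levy_walk_params(), 50, aging_time = 100)
  clean <- ens$positions
  same <- add_noise(ens, noise_white(0))
  expect_identical(same$positions, clean)
  set.seed(52)
  noisy <- add_noise(ens, noise_white(0.05))
  expect_equal(var(as.vector(noisy$positions - clean)), 0.0025,
               tolerance = 0.05)
  # white-noise TA MSD plateau on an all-rest trajectory: 2 sigma^2
  flat <- ens
  flat$positions <- matrix(0, 200, ncol(clean))
  set.seed(53)
  flat <- add_noise(flat, noise_white(0.05))
  tam <- ta_msd(flat, lags = c(2, 10, 25))
  expect_equal(tam$msd, rep(2 * 0.05^2, 3), tolerance = 0.05)
  # AR(1) marginal variance
  set.seed(54)
  ar <- add_noise(ens, noise_ar1(0.05, 0.6))
  expect_equal(var(as.vector(ar$positions - clean)), 0.0025, tolerance = 0.1)
  # library noise shorter than the window errors
  expect_error(add_noise(ens, noise_library(matrix(0, 3, 10))), "shorter")
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(levy_walk_params(alpha_rest = -1), "alpha_rest")
  expect_error(levy_walk_params(v_retro = 0.5), "v_retro")
  expect_error(levy_walk_params(p_antero = 1.5), "p_antero")
  expect_error(simulate_trajectories(levy_walk_params(), 5, aging_time = -1),
               "aging_time")
})
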