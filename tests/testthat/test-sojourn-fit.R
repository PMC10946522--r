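test_that("sojourn densities match their closed forms and normalize", {
  expect_equal(rest_pdf(0, 0.24), 0.24)
  expect_equal(rest_pdf(1, 1), 0.25)
  expect_equal(integrate(rest_pdf, 0, Inf, alpha_rest = 0.24,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-7)
  # quadrature of the truncated law with the incomplete-gamma normalization
  expect_equal(integrate(function(t) run_pdf(t, 0.18, 12.6), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  expect_equal(run_pdf(0, 0.18, 12.6), 1 / run_pdf_norm(0.18, 12.6))
  # tau -> infinity limit approaches the pure power law; the normalization
  # converges only like tau^-eta, so compare the density shape (ratios)
  t <- c(0.5, 2, 20, 200)
  expect_equal(run_pdf(t, 0.18, 1e9) / run_pdf(0, 0.18, 1e9),
               rest_pdf(t, 0.18) / rest_pdf(0, 0.18), tolerance = 1e-6)
  expect_error(rest_pdf(-1, 0.24), ">= 0")
  expect_error(run_pdf(-1, 0.18, 12.6), ">= 0")
})

test_that("observation correction truncates, vanishes at the cutoff, and normalizes", {
  corr <- correction_params()   # Tw = 57.4, r = 7, dt = 0.2
  f <- apply_observation_correction(function(t) rest_pdf(t, 0.24), corr)
  expect_equal(f(c(0, 1, 1.3999)), c(0, 0, 0))
  expect_equal(f(57.4), 0)
  expect_equal(f(60), 0)
  expect_gt(f(10), 0)
  expect_equal(integrate(f, 1.4, 57.4, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # identity limit: wide window, no resolution cut. A light-tailed law is
  # needed here -- for heavy tails the window bias vanishes only like
  # Tw^-alpha, which is the very point of the correction.
  wide <- correction_params(window_param = 1e4, resolution = 0L)
  g <- apply_observation_correction(function(t) run_pdf(t, 0.18, 12.6), wide)
  t <- c(0.1, 1, 10, 50)
  expect_equal(g(t), run_pdf(t, 0.18, 12.6), tolerance = 1e-3)
  expect_error(correction_params(window_param = 1, resolution = 7, dt = 0.2),
               "exceed")
})

test_that("corrected mean matches Monte Carlo draws from the corrected law", {
  corr <- correction_params()
  f <- apply_observation_correction(function(t) rest_pdf(t, 0.24), corr,
                                    censor_exponent = 0.24)
  mean_quad <- integrate(function(t) t * f(t), 1.4, 57.4,
                         rel.tol = 1e-9)$value
  set.seed(71)
  draws <- draw_corrected_rest(2e4, 0.24, corr)
  expect_equal(mean(draws), mean_quad,
               tolerance = 4 * sd(draws) / sqrt(2e4) / mean_quad)
})

test_that("fits recover parameters from draws of the corrected laws", {
  corr <- correction_params()
  set.seed(72)
  d_rest <- draw_corrected_rest(1e4, 0.5, corr)
  # continuous draws: skip the first lattice bin (only half covered by the
  # corrected support)
  fr <- fit_rest(d_rest, corr, fit_range = c(1.5, 45.9))
  expect_equal(fr$estimates[["alpha_rest"]], 0.5, tolerance = 0.05 / 0.5)

  set.seed(73)
  d_run <- draw_corrected_run(1e4, 0.18, 12.6, corr, gamma = 0.24)
  fu <- fit_run(d_run, corr, fit_range = c(1.5, 45.9), rest_exponent = 0.24)
  expect_lt(abs(fu$estimates[["eta_run"]] - 0.18), 0.06)
  expect_lt(abs(fu$estimates[["tau_r"]] - 12.6), 0.25 * 12.6)
})

test_that("fit is scale-consistent: quadrupling n roughly halves the spread", {
  corr <- correction_params()
  est <- function(n, seed) {
    set.seed(seed)
    fit_rest(draw_corrected_rest(n, 0.4, corr),
             fit_range = c(1.5, 45.9))$estimates[["alpha_rest"]]
  }
  small <- vapply(1:10, function(s) est(1000, s), numeric(1))
  large <- vapply(1:10, function(s) est(9000, 100 + s), numeric(1))
  ratio <- sd(small) / sd(large)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 6)
})

test_that("including censored durations flattens the rest fit", {
  set.seed(74)
  ens <- simulate_trajectories(levy_walk_params(), 2500, aging_time = 0,
                               ground_truth = TRUE)
  tr <- ens$true_segments
  rests <- tr[tr$kind == "rest", ]
  unc <- rests$duration[!rests$left_censored & !rests$right_censored]
  a_excl <- fit_rest(unc)$estimates[["alpha_rest"]]
  a_incl <- fit_rest(rests$duration)$estimates[["alpha_rest"]]
  # censored rests are clipped long phases: treating them as complete adds
  # probability mass at long durations and lowers the fitted exponent
  expect_lt(a_incl, a_excl)
})

test_that("degenerate inputs fail loudly", {
  expect_error(fit_rest(rep(0.1, 50)), "censored")
  expect_error(fit_rest(c(2, 3)), "censored|fewer")
})
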