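#' Infer aging time from the stationary-trajectory fraction
#'
#' The fraction of trajectories with no run during the observation window
#' grows with aging time. Inverting the simulated curve F(ta) at the
#' observed stationary fraction therefore estimates the mean aging time: the
#' curve is computed by Monte Carlo on a log-spaced grid, made monotone by
#' isotonic regression in log(ta), and the crossing located by piecewise
#' linear interpolation of log(ta) versus F. The Monte-Carlo binomial error
#' of F is propagated to a confidence interval on ta by inverting
#' F +/- 1.96 SE.
#'
#' @param observed_fraction Observed stationary fraction, strictly in (0, 1).
#' @param params A [levy_walk_params()] object.
#' @param window Observation window in seconds.
#' @param ta_grid Aging-time grid in seconds (default log-spaced 1 to 1e4).
#' @param n_traj Trajectories per grid point.
#' @param curve Optional precomputed [no_run_fraction_curve()] (reused when
#'   inverting several observed fractions).
#' @return An object of class `aging_estimate`: `ta_hat` (s), `ci` (s),
#'   `observed_fraction`, and the simulated `curve`.
#' @export
#' @examples
#' set.seed(1)
#' est <- estimate_aging_time(0.82, levy_walk_params(), n_traj = 5000,
#'                            ta_grid = 10^seq(0, 3, length.out = 13))
#' est$ta_hat
estimate_aging_time <- function(observed_fraction, params, window = 60,
                                ta_grid = 10^seq(0, 4, length.out = 25),
                                n_traj = 20000, curve = NULL) {
  if (!is.numeric(observed_fraction) || length(observed_fraction) != 1L ||
      observed_fraction <= 0 || observed_fraction >= 1)
    stop("'observed_fraction' must lie strictly in (0, 1)")
  if (is.null(curve))
    curve <- no_run_fraction_curve(params, ta_grid, window, n_traj)
  lta <- log(curve$ta)
  if (any(curve$ta <= 0))
    stop("aging-time grid must be strictly positive for log interpolation")
  iso <- stats::isoreg(lta, curve$fraction)
  invert <- function(f) {
    if (f < min(iso$yf) || f > max(iso$yf)) return(NA_real_)
    exp(stats::approx(iso$yf, lta, xout = f, ties = mean)$y)
  }
  ta_hat <- invert(observed_fraction)
  if (is.na(ta_hat))
    stop("bracket not found: the simulated curve never crosses the observed ",
         "fraction inside the aging-time grid")
  se_at <- stats::approx(lta, curve$se, xout = log(ta_hat), rule = 2)$y
  ci <- c(lower = invert(observed_fraction - 1.96 * se_at),
          upper = invert(observed_fraction + 1.96 * se_at))
  structure(list(ta_hat = ta_hat, ci = ci,
                 observed_fraction = observed_fraction, curve = curve),
            class = "aging_estimate")
}

#' @export
print.aging_estimate <- function(x, ...) {
  cat(sprintf("Aging-time estimate: ta = %.3g s (observed stationary fraction %.3g)\n",
              x$ta_hat, x$observed_fraction))
  if (all(is.finite(x$ci)))
    cat(sprintf("  Monte-Carlo 95%% interval: [%.3g, %.3g] s\n",
                x$ci[["lower"]], x$ci[["upper"]]))
  invisible(x)
}

#' Simulate a two-population aging mixture
#'
#' Mixes trajectories from two aging times: a newly generated population
#' (weight `w_new`, aging time `ta_new`) and a pre-existing population
#' (weight `1 - w_new`, aging time `ta_old`). `floor(w_new * n_traj)`
#' trajectories are simulated at `ta_new` and the remainder at `ta_old`.
#'
#' @param params A [levy_walk_params()] object.
#' @param w_new Weight of the new population, in \[0, 1\].
#' @param ta_new Aging time of the new population (s); default 30 s.
#' @param ta_old Aging time of the pre-existing population (s); default
#'   660 s (11 min).
#' @param n_traj Total number of trajectories.
#' @param window Observation window (s).
#' @param noise Optional noise model applied to the mixed ensemble.
#' @param keep_labels Keep per-sample phase labels.
#' @return An `mrnp_ensemble` whose `aging_time` is `c(new =, old =)` and
#'   which carries the mixture weight in `$mixture`.
#' @export
simulate_mixture <- function(params, w_new, ta_new = 30, ta_old = 660,
                             n_traj, window = 60, noise = NULL,
                             keep_labels = FALSE) {
  if (!is.numeric(w_new) || length(w_new) != 1L || w_new < 0 || w_new > 1)
    stop("'w_new' must be a single weight in [0, 1]")
  n_new <- floor(w_new * n_traj)
  n_old <- n_traj - n_new
  parts <- list()
  if (n_new > 0)
    parts$new <- simulate_trajectories(params, n_new, ta_new, window,
                                       keep_labels = keep_labels)
  if (n_old > 0)
    parts$old <- simulate_trajectories(params, n_old, ta_old, window,
                                       keep_labels = keep_labels)
  base <- parts[[1L]]
  ens <- structure(
    list(times = base$times,
         positions = do.call(rbind, lapply(parts, `[[`, "positions")),
         labels = if (keep_labels)
           do.call(rbind, lapply(parts, `[[`, "labels")) else NULL,
         params = params,
         aging_time = c(new = ta_new, old = ta_old),
         window = window, dt = params$dt, noise = NULL,
         true_segments = NULL, mixture = c(w_new = w_new)),
    class = "mrnp_ensemble"
  )
  if (!is.null(noise)) ens <- add_noise(ens, noise)
  ens
}

#' Diagnostic statistics of an ensemble for mixture comparison
#'
#' Computes the four statistics used to compare simulated mixtures against
#' observed data: EA MSD, ensemble-mean TA MSD, the aged displacement
#' distribution and the TA MSD amplitude scatter. When a `template` (an
#' earlier result) is given, the same lags and bin breaks are reused so the
#' statistics are directly comparable.
#'
#' @param ens An `mrnp_ensemble`.
#' @param lags Lag times (s) for both MSD curves; default log-spaced over
#'   one decade up to half the window.
#' @param delta_t Elapsed time (s) for the aged displacement distribution.
#' @param scatter_lag Lag (s) for the amplitude scatter.
#' @param n_bins Bins for the two distributions.
#' @param template Optional `mixture_stats` result providing the supports.
#' @return An object of class `mixture_stats`: list with `ea`, `ta`,
#'   `aged`, `scatter` and the settings used.
#' @export
mixture_stats <- function(ens, lags = NULL, delta_t = 30, scatter_lag = 2,
                          n_bins = 61, template = NULL) {
  if (!is.null(template)) {
    stopifnot(inherits(template, "mixture_stats"))
    lags <- template$lags
    delta_t <- template$delta_t
    scatter_lag <- template$scatter_lag
    aged_breaks <- attr(template$aged, "breaks")
    sc_breaks <- attr(template$scatter, "breaks")
  } else {
    if (is.null(lags)) {
      m <- length(ens$times)
      kmax <- (m - 1) %/% 2
      ks <- unique(round(exp(seq(log(1), log(kmax), length.out = 20))))
      lags <- ks * ens$dt
    }
    aged_breaks <- NULL
    sc_breaks <- NULL
  }
  structure(list(
    ea = ea_msd(ens, lags),
    ta = ta_msd(ens, lags),
    aged = aged_displacement_pdf(ens, delta_t, n_bins, breaks = aged_breaks),
    scatter = amplitude_scatter(ens, scatter_lag, n_bins, breaks = sc_breaks),
    lags = lags, delta_t = delta_t, scatter_lag = scatter_lag
  ), class = "mixture_stats")
}

#' Discrepancy score between two sets of ensemble statistics
#'
#' Per-statistic discrepancies: mean squared log-residual for the two MSD
#' curves (their values span decades) and L2 distance between the binned
#' densities for the aged displacement distribution and amplitude scatter.
#' The total is a weighted sum, equal weights by default.
#'
#' @param observed,simulated `mixture_stats` objects on identical supports.
#' @param weights Length-4 weights for (EA MSD, TA MSD, aged PDF, scatter).
#' @return A list with the four component scores and `total`.
#' @export
score_mixture <- function(observed, simulated, weights = c(1, 1, 1, 1)) {
  stopifnot(inherits(observed, "mixture_stats"),
            inherits(simulated, "mixture_stats"), length(weights) == 4L)
  if (!isTRUE(all.equal(observed$lags, simulated$lags)) ||
      !isTRUE(all.equal(attr(observed$aged, "breaks"),
                        attr(simulated$aged, "breaks"))) ||
      !isTRUE(all.equal(attr(observed$scatter, "breaks"),
                        attr(simulated$scatter, "breaks"))))
    stop("statistics were not computed on identical supports")
  msd_score <- function(a, b) {
    ok <- a$msd > 0 & b$msd > 0
    mean((log(a$msd[ok]) - log(b$msd[ok]))^2)
  }
  l2_score <- function(a, b) {
    w <- diff(attr(a, "breaks"))
    sqrt(sum((a$density - b$density)^2 * w))
  }
  s <- c(ea = msd_score(observed$ea, simulated$ea),
         ta = msd_score(observed$ta, simulated$ta),
         aged = l2_score(observed$aged, simulated$aged),
         scatter = l2_score(observed$scatter, simulated$scatter))
  c(as.list(s), list(total = sum(weights * s)))
}

#' Select the mixture ratio best matching observed statistics
#'
#' Simulates the two-population mixture at each candidate weight and selects
#' the one minimizing the total discrepancy of [score_mixture()]. The default
#' candidate grid is new:old = 1:9, 3:7, 5:5 and 7:3.
#'
#' @param observed A `mixture_stats` object for the observed data.
#' @param params A [levy_walk_params()] object.
#' @param ratios Candidate new-population weights.
#' @param ta_new,ta_old Aging times (s) of the two populations.
#' @param n_traj Trajectories per candidate simulation.
#' @param window Observation window (s).
#' @param noise Optional noise model matching the observed data.
#' @param weights Score weights, see [score_mixture()].
#' @return An object of class `mixture_estimate`: a score table (one row per
#'   candidate), the selected `w_new`, and the settings.
#' @export
select_ratio <- function(observed, params, ratios = c(0.1, 0.3, 0.5, 0.7),
                         ta_new = 30, ta_old = 660, n_traj = 10000,
                         window = 60, noise = NULL, weights = c(1, 1, 1, 1)) {
  stopifnot(inherits(observed, "mixture_stats"))
  rows <- lapply(ratios, function(w) {
    sim <- simulate_mixture(params, w, ta_new, ta_old, n_traj, window, noise)
    st <- mixture_stats(sim, template = observed)
    sc <- score_mixture(observed, st, weights)
    data.frame(w_new = w, score_ea = sc$ea, score_ta = sc$ta,
               score_aged = sc$aged, score_scatter = sc$scatter,
               total = sc$total)
  })
  tab <- do.call(rbind, rows)
  structure(list(scores = tab, w_new = tab$w_new[which.min(tab$total)],
                 ta_new = ta_new, ta_old = ta_old, n_traj = n_traj),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("Two-population mixture selection (ta_new = %g s, ta_old = %g s)\n",
              x$ta_new, x$ta_old))
  print(x$scores, row.names = FALSE, digits = 4)
  cat(sprintf("selected: w_new = %g (new:old = %g:%g)\n",
              x$w_new, 10 * x$w_new, 10 * (1 - x$w_new)))
  invisible(x)
}
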