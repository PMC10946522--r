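#' Sojourn-time probability densities
#'
#' `rest_pdf()` is the normalized power law
#' \eqn{\psi_{rest}(t) = \alpha (t+1)^{-1-\alpha}} governing rest durations.
#' `run_pdf()` is the exponentially truncated power law
#' \eqn{\psi_{run}(t) = N^{-1} e^{-t/\tau_r} (t+1)^{-1-\eta}} governing run
#' durations, with normalization
#' \eqn{N = e^{1/\tau_r}\,\Gamma(-\eta, 1/\tau_r)\,/\,\tau_r^{\eta}}
#' (upper incomplete gamma function), computed by `run_pdf_norm()`.
#'
#' @param t Durations in seconds (>= 0).
#' @param alpha_rest Rest power-law exponent (> 0).
#' @param eta_run Run power-law exponent (> 0).
#' @param tau_r Characteristic run time in seconds (> 0).
#' @return Density values (1/s); `run_pdf_norm()` returns the scalar N.
#' @name sojourn_pdfs
#' @export
#' @examples
#' rest_pdf(0, 0.24)        # = alpha at t = 0
#' run_pdf(0, 0.18, 12.6)   # = 1/N at t = 0
rest_pdf <- function(t, alpha_rest) {
  if (any(t < 0)) stop("durations must be >= 0")
  if (alpha_rest <= 0) stop("'alpha_rest' must be > 0")
  alpha_rest * (t + 1)^(-1 - alpha_rest)
}

#' @rdname sojourn_pdfs
#' @export
run_pdf_norm <- function(eta_run, tau_r) {
  if (eta_run <= 0 || tau_r <= 0) stop("'eta_run' and 'tau_r' must be > 0")
  # upper incomplete gamma with negative shape, Gamma(-eta, 1/tau):
  # finite because the lower limit is positive. For tiny 1/tau the integrand
  # is steep near the origin, so that part is integrated after substituting
  # u = s^-eta (which flattens it onto [1, x^-eta]).
  x <- 1 / tau_r
  tail_part <- stats::integrate(function(s) s^(-eta_run - 1) * exp(-s),
                                lower = max(1, x), upper = Inf,
                                rel.tol = 1e-12, abs.tol = 0)$value
  head_part <- if (x < 1) {
    stats::integrate(function(u) exp(-u^(-1 / eta_run)) / eta_run,
                     lower = 1, upper = x^(-eta_run),
                     rel.tol = 1e-12, abs.tol = 0)$value
  } else 0
  exp(x) * (head_part + tail_part) / tau_r^eta_run
}

#' @rdname sojourn_pdfs
#' @export
run_pdf <- function(t, eta_run, tau_r) {
  if (any(t < 0)) stop("durations must be >= 0")
  N <- run_pdf_norm(eta_run, tau_r)
  exp(-t / tau_r) * (t + 1)^(-1 - eta_run) / N
}

#' Observation-window and resolution correction parameters
#'
#' The sojourn times measured from a finite recording differ from the
#' underlying laws: a phase of length t can only be observed in full if it
#' starts early enough to fit inside the effective window (length
#' `window_param`), and phases shorter than the temporal resolution
#' (`resolution` sampling steps) cannot be classified at all.
#'
#' @param window_param Effective time-window parameter T_w in seconds.
#' @param resolution Resolution in data points (a phase must span at least
#'   this many steps to be detected).
#' @param dt Sampling interval in seconds.
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(window_param = 57.4, resolution = 7L, dt = 0.2) {
  stopifnot(window_param > 0, resolution >= 0, dt > 0)
  if (window_param <= resolution * dt)
    stop("'window_param' must exceed resolution * dt")
  structure(list(window_param = window_param,
                 resolution = as.integer(resolution), dt = dt),
            class = "correction_params")
}

#' Apply the observation correction to a sojourn-time density
#'
#' Maps an underlying sojourn density \eqn{\psi(t)} to the density of
#' durations observed in full within the recording:
#' \deqn{\psi_{ext}(t) \propto (T_w - t)^{\gamma}\,\psi(t), \quad
#'   r\,dt \le t \le T_w,}
#' zero elsewhere, renormalized over the support. The left truncation at
#' \eqn{r\,dt} encodes the classification resolution. The censoring weight
#' counts the opportunities for a phase of length t to start and still fit
#' inside the window: with independent phases this is proportional to the
#' expected number of phase entries in the remaining time \eqn{T_w - t}.
#' `censor_exponent = 1` gives the elementary uniform-start weight; because
#' the run/rest cycle time is heavy tailed with index \eqn{\alpha < 1}, the
#' renewal function actually grows sublinearly, \eqn{m(u) \sim u^{\alpha}},
#' and \eqn{\gamma = \alpha} is the appropriate weight for data produced by
#' the alternating process (used by [fit_rest()] and [fit_run()]).
#'
#' @param pdf A vectorized density function of one argument (s -> 1/s).
#' @param corr A [correction_params()] object.
#' @param censor_exponent Exponent \eqn{\gamma} of the censoring weight.
#' @return A vectorized corrected density function with attributes `support`
#'   (the interval `c(r * dt, T_w)`) and `norm_const` (the normalization
#'   integral of the weighted density).
#' @export
#' @examples
#' corr <- correction_params()
#' f <- apply_observation_correction(function(t) rest_pdf(t, 0.24), corr)
#' f(c(1, 2, 60))   # zero below 1.4 s and above 57.4 s
apply_observation_correction <- function(pdf, corr, censor_exponent = 1) {
  stopifnot(is.function(pdf), inherits(corr, "correction_params"),
            censor_exponent >= 0)
  a <- corr$resolution * corr$dt
  b <- corr$window_param
  w <- function(t) (b - t)^censor_exponent * pdf(t)
  Z <- stats::integrate(w, lower = a, upper = b, rel.tol = 1e-10,
                        abs.tol = 0, subdivisions = 500L)$value
  f <- function(t) ifelse(t >= a & t <= b, (b - t)^censor_exponent * pdf(t) / Z, 0)
  attr(f, "support") <- c(a, b)
  attr(f, "norm_const") <- Z
  f
}

# Logarithmically spaced histogram breaks snapped to the duration lattice.
# Durations measured from sampled trajectories are multiples of dt; bins
# narrower than dt would alias against that lattice (alternating over- and
# under-filled bins), so every break sits halfway between lattice points and
# consecutive breaks differ by at least one lattice step.
lattice_breaks <- function(corr, bins_per_decade = 20) {
  r <- max(corr$resolution, 1L)
  dt <- corr$dt
  b <- corr$window_param
  k_max <- floor(b / dt - 0.5)
  ks <- r
  repeat {
    k <- ks[length(ks)]
    if (k >= k_max) break
    ks <- c(ks, min(k_max, max(k + 1, round(k * 10^(1 / bins_per_decade)))))
  }
  (c(ks, k_max + 1L) - 0.5) * dt
}

# Histogram of durations on the lattice-aligned log bins.
bin_durations <- function(durations, corr, bins_per_decade = 20) {
  breaks <- lattice_breaks(corr, bins_per_decade)
  d <- durations[durations >= breaks[1] &
                   durations < breaks[length(breaks)]]
  if (length(d) < 10L)
    stop("fewer than 10 observed durations inside the correction support; ",
         "cannot fit (all durations censored or out of range?)")
  cnt <- graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  width <- diff(breaks)
  data.frame(
    lower = breaks[-length(breaks)], upper = breaks[-1L],
    center = (breaks[-length(breaks)] + breaks[-1L]) / 2,
    count = cnt, density = cnt / (length(d) * width)
  )
}

# Least-squares engine shared by fit_rest()/fit_run(). Minimizes the
# count-weighted sum of squared log residuals between the binned empirical
# density and the bin-averaged corrected model density, with the amplitude
# profiled out (the fit is a pure shape fit: the censoring weight is only
# known up to a constant, and the weighted model normalization cancels).
fit_sojourn_ls <- function(durations, model_pdf, censor_exp_fun, par_grid,
                           corr, bins_per_decade, fit_range) {
  bins <- bin_durations(durations, corr, bins_per_decade)
  b <- corr$window_param
  if (is.null(fit_range))
    fit_range <- c((corr$resolution - 0.5) * corr$dt, 0.8 * b)
  use <- bins$count > 0 & bins$lower >= fit_range[1] - 1e-9 &
    bins$upper <= fit_range[2]
  if (sum(use) < 4L)
    stop("fewer than 4 usable bins inside the fit range")
  n_empty <- sum(bins$count == 0 & bins$lower >= fit_range[1] &
                   bins$upper <= fit_range[2])
  if (n_empty > 0)
    warning(sprintf("dropping %d empty bins from the least-squares fit", n_empty))
  lo <- bins$lower[use]; up <- bins$upper[use]; ce <- bins$center[use]
  wt <- bins$count[use]
  ldens <- log(bins$density[use])
  objective <- function(par) {
    g <- censor_exp_fun(par)
    f <- function(t) (b - t)^g * model_pdf(t, par)
    mod <- (f(lo) + 4 * f(ce) + f(up)) / 6   # Simpson bin average
    if (any(!is.finite(mod)) || any(mod <= 0)) return(Inf)
    r <- ldens - log(mod)
    r <- r - sum(wt * r) / sum(wt)           # profiled amplitude
    sum(wt * r^2) / sum(wt)
  }
  scores <- vapply(par_grid, objective, numeric(1))
  best_i <- which.min(scores)
  best <- par_grid[[best_i]]
  if (length(best) == 1L) {
    lo_p <- par_grid[[max(1L, best_i - 1L)]]
    hi_p <- par_grid[[min(length(par_grid), best_i + 1L)]]
    opt <- stats::optimize(objective, lower = lo_p * 0.8, upper = hi_p * 1.25)
    est <- opt$minimum
    val <- opt$objective
  } else {
    opt <- stats::optim(log(best), function(lp) objective(exp(lp)),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    est <- exp(opt$par)
    val <- opt$value
  }
  list(estimates = est, sse = val * sum(use), bins = bins,
       fit_range = fit_range, n_bins_used = sum(use))
}

#' Fit the rest-time law to observed durations
#'
#' Least-squares fit of the window- and resolution-corrected rest law to the
#' binned empirical density of fully observed rest durations. Residuals are
#' taken in log space on logarithmic bins snapped to the duration lattice
#' k dt (bins narrower than the sampling step would alias against the
#' discrete measured durations), weighted by bin counts, with the overall
#' amplitude profiled out; the censoring-weight exponent is tied
#' self-consistently to the candidate rest exponent (see
#' [apply_observation_correction()]). Censored
#' segments (phases touching the window edge) must be excluded by the
#' caller; durations outside the correction support are ignored.
#'
#' @param durations Uncensored rest durations in seconds.
#' @param corr A [correction_params()] object.
#' @param bins_per_decade Logarithmic binning density (default 20).
#' @param fit_range Duration interval (s) whose bins enter the fit. The
#'   default runs from the resolution limit up to 80% of the window
#'   parameter, keeping the fit away from the hard cutoff where the
#'   approximate censoring weight matters most.
#' @return An object of class `sojourn_fit` with `estimates`
#'   (`alpha_rest`), `sse` (sum of squared log residuals over the used
#'   bins), the bin table, fit range and the correction used.
#' @export
fit_rest <- function(durations, corr = correction_params(),
                     bins_per_decade = 20, fit_range = NULL) {
  grid <- as.list(exp(seq(log(0.02), log(2.5), length.out = 40)))
  res <- fit_sojourn_ls(durations, function(t, par) rest_pdf(t, par),
                        function(par) par, grid, corr, bins_per_decade,
                        fit_range)
  structure(list(state = "rest",
                 estimates = c(alpha_rest = unname(res$estimates)),
                 sse = res$sse, bins = res$bins, fit_range = res$fit_range,
                 n_bins_used = res$n_bins_used, corr = corr,
                 n = length(durations)),
            class = "sojourn_fit")
}

#' Fit the run-time law to observed durations
#'
#' As [fit_rest()], for the exponentially truncated run-time law: a coarse
#' grid over (`eta_run`, `tau_r`) refined by Nelder-Mead in log space. The
#' censoring-weight exponent is the tail index of the run/rest cycle time,
#' i.e. the rest exponent (`rest_exponent`, default 0.24).
#'
#' @inheritParams fit_rest
#' @param durations Uncensored run durations in seconds.
#' @param rest_exponent Rest power-law exponent governing the censoring
#'   weight (take it from [fit_rest()] when fitting both states).
#' @return An object of class `sojourn_fit` with `estimates`
#'   (`eta_run`, `tau_r`), `sse`, the bin table, fit range and correction.
#' @export
fit_run <- function(durations, corr = correction_params(),
                    bins_per_decade = 20, fit_range = NULL,
                    rest_exponent = 0.24) {
  etas <- exp(seq(log(0.05), log(0.8), length.out = 12))
  taus <- exp(seq(log(4), log(60), length.out = 12))
  grid <- unlist(lapply(etas, function(e) lapply(taus, function(tr) c(e, tr))),
                 recursive = FALSE)
  res <- fit_sojourn_ls(durations,
                        function(t, par) exp(-t / par[2]) * (t + 1)^(-1 - par[1]),
                        function(par) rest_exponent, grid, corr,
                        bins_per_decade, fit_range)
  structure(list(state = "run",
                 estimates = c(eta_run = unname(res$estimates[1]),
                               tau_r = unname(res$estimates[2])),
                 sse = res$sse, bins = res$bins, fit_range = res$fit_range,
                 n_bins_used = res$n_bins_used, corr = corr,
                 n = length(durations)),
            class = "sojourn_fit")
}

#' @export
print.sojourn_fit <- function(x, ...) {
  cat(sprintf("Corrected %s-time least-squares fit (n = %d durations)\n",
              x$state, x$n))
  for (nm in names(x$estimates))
    cat(sprintf("  %-10s %.4g\n", nm, x$estimates[[nm]]))
  cat(sprintf("  weighted SSE (log residuals): %.4g over %d bins in [%.3g, %.3g] s\n",
              x$sse, x$n_bins_used, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}
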