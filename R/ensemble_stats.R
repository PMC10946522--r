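#' Time-averaged mean squared displacement
#'
#' For a single trajectory the TA MSD at lag \eqn{\tau} is the moving average
#' of squared displacements over all start times,
#' \eqn{\overline{x^2}(\tau) = \langle (x(\tau_0+\tau) - x(\tau_0))^2
#' \rangle_{\tau_0}}; the discrete estimator averages over all overlapping
#' sample pairs at that lag. For an ensemble the per-particle curves are
#' averaged pointwise (one weight per trajectory).
#'
#' @param ens An `mrnp_ensemble`, or a numeric position matrix (one
#'   trajectory per row) with `dt` supplied.
#' @param lags Lag times in seconds (multiples of `dt`, smaller than the
#'   window). Default: every lag up to half the window.
#' @param by_particle If `TRUE`, return the matrix of per-particle TA MSD
#'   values (trajectories x lags) instead of the ensemble mean.
#' @param dt Sampling interval, required for a bare matrix.
#' @return A data frame (`lag`, `msd`, `n`) of class `msd_curve`, or a
#'   matrix when `by_particle = TRUE`.
#' @export
#' @examples
#' x <- matrix(c(0, 1, 0), 1)   # 3-sample series
#' ta_msd(x, dt = 0.2, lags = c(0.2, 0.4))
ta_msd <- function(ens, lags = NULL, by_particle = FALSE, dt = NULL) {
  X <- ensemble_positions(ens)
  dt <- ensemble_dt(ens, dt)
  m <- ncol(X)
  ks <- lag_indices(lags, dt, m, default_max = (m - 1) %/% 2)
  M <- matrix(NA_real_, nrow(X), length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    D <- X[, (1 + k):m, drop = FALSE] - X[, 1:(m - k), drop = FALSE]
    M[, j] <- rowMeans(D * D)
  }
  colnames(M) <- as.character(ks * dt)
  if (by_particle) {
    attr(M, "lags") <- ks * dt
    return(M)
  }
  out <- data.frame(lag = ks * dt, msd = colMeans(M), n = nrow(X))
  attr(out, "kind") <- "TA-ensemble-mean"
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Ensemble-averaged mean squared displacement
#'
#' EA MSD at elapsed time \eqn{\Delta t} is the average over particles of the
#' squared displacement from the initial recorded position,
#' \eqn{\langle x^2(\Delta t)\rangle = N^{-1}\sum_i (x_i(\Delta t) -
#' x_i(0))^2}.
#'
#' @inheritParams ta_msd
#' @return A data frame (`lag`, `msd`, `n`) of class `msd_curve`.
#' @export
ea_msd <- function(ens, lags = NULL, dt = NULL) {
  X <- ensemble_positions(ens)
  dt <- ensemble_dt(ens, dt)
  m <- ncol(X)
  ks <- lag_indices(lags, dt, m, default_max = m - 1)
  D <- X[, ks + 1L, drop = FALSE] - X[, 1L]
  out <- data.frame(lag = ks * dt, msd = colMeans(D * D), n = nrow(X))
  attr(out, "kind") <- "EA"
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Anomalous diffusion exponent of an MSD curve
#'
#' Least-squares slope of log(MSD) versus log(lag) over a lag range: the
#' exponent \eqn{\beta} in \eqn{MSD \sim \tau^\beta}. \eqn{\beta > 1}
#' indicates superdiffusion, \eqn{\beta = 1} Brownian scaling,
#' \eqn{\beta < 1} subdiffusion.
#'
#' @param curve An `msd_curve` data frame (columns `lag`, `msd`).
#' @param lag_range Length-2 numeric: inclusive lag interval in seconds.
#' @return The fitted exponent (scalar).
#' @export
msd_exponent <- function(curve, lag_range) {
  stopifnot(is.data.frame(curve), all(c("lag", "msd") %in% names(curve)),
            length(lag_range) == 2L)
  s <- curve$lag >= lag_range[1] & curve$lag <= lag_range[2]
  if (sum(s) < 4L) stop("need at least 4 lags inside 'lag_range'")
  if (any(curve$msd[s] <= 0))
    stop("MSD values in the fit range must be positive")
  unname(stats::coef(stats::lm(log(curve$msd[s]) ~ log(curve$lag[s])))[2])
}

#' Aged displacement distribution
#'
#' Binned density of the displacement \eqn{X = x(\Delta t) - x(0)} across the
#' ensemble, where positions are relative to the measurement start. For an
#' aged ensemble the distribution develops a heavy central peak (particles
#' resting through the whole interval) flanked by ballistic excursions.
#'
#' @inheritParams ta_msd
#' @param delta_t Elapsed time in seconds (multiple of `dt`, below the
#'   window).
#' @param n_bins Number of uniform bins, symmetric about zero (default 61).
#' @param breaks Optional explicit bin breaks (overrides `n_bins`); use to
#'   evaluate several ensembles on one common support.
#' @return A data frame (`center`, `density`, `n`) of class `dist_curve`,
#'   with the bin `breaks` as an attribute.
#' @export
aged_displacement_pdf <- function(ens, delta_t = 30, n_bins = 61,
                                  breaks = NULL, dt = NULL) {
  X <- ensemble_positions(ens)
  dt <- ensemble_dt(ens, dt)
  if (nrow(X) == 0L) stop("empty ensemble")
  k <- round(delta_t / dt)
  if (k < 1L || k > ncol(X) - 1L)
    stop("'delta_t' must be positive and below the observation window")
  disp <- X[, k + 1L] - X[, 1L]
  if (is.null(breaks)) {
    half <- max(abs(disp), dt / 2)  # degenerate all-zero case keeps a finite bin
    breaks <- seq(-half, half, length.out = n_bins + 1L)
  }
  binned_density(disp, breaks, kind = "aged-displacement")
}

#' Amplitude scatter of the time-averaged MSD
#'
#' Distribution of the normalized TA MSD amplitude
#' \eqn{\xi_i = \overline{x_i^2}(\tau) / \langle \overline{x^2}(\tau)\rangle}
#' across particles at a fixed lag. Its spread quantifies ergodicity
#' breaking: a delta peak at 1 for ergodic dynamics, mass near 0 from
#' trajectories that rest through the window.
#'
#' @inheritParams aged_displacement_pdf
#' @param lag Lag time in seconds at which the per-particle TA MSD is taken.
#' @param n_bins Number of uniform bins on `[0, max(xi)]` (default 40).
#' @return A data frame (`center`, `density`, `n`) of class `dist_curve`,
#'   with attributes `breaks` and `xi_mean` (equal to 1 by construction).
#' @export
amplitude_scatter <- function(ens, lag = 2, n_bins = 40, breaks = NULL,
                              dt = NULL) {
  M <- ta_msd(ens, lags = lag, by_particle = TRUE, dt = dt)
  amp <- M[, 1L]
  mu <- mean(amp)
  if (mu <= 0) stop("ensemble-mean TA MSD at this lag is zero")
  xi <- amp / mu
  if (is.null(breaks))
    breaks <- seq(0, max(xi, 1) * (1 + 1e-9), length.out = n_bins + 1L)
  out <- binned_density(xi, breaks, kind = "amplitude-scatter")
  attr(out, "xi_mean") <- mean(xi)
  out
}

# --- internal helpers -------------------------------------------------------

ensemble_positions <- function(ens) {
  if (inherits(ens, "mrnp_ensemble")) ens$positions
  else if (is.matrix(ens)) ens
  else stop("expected an 'mrnp_ensemble' or a position matrix")
}

ensemble_dt <- function(ens, dt) {
  if (inherits(ens, "mrnp_ensemble")) ens$dt
  else if (!is.null(dt)) dt
  else stop("'dt' is required for a bare position matrix")
}

lag_indices <- function(lags, dt, m, default_max) {
  if (is.null(lags)) {
    ks <- seq_len(max(default_max, 1L))
  } else {
    ks <- round(lags / dt)
    if (any(abs(ks * dt - lags) > 1e-6 * dt))
      stop("lags must be multiples of dt")
    if (any(ks < 1L) || any(ks > m - 1L))
      stop("lags must be positive and smaller than the observation window")
  }
  ks
}

binned_density <- function(x, breaks, kind) {
  inside <- x >= breaks[1] & x <= breaks[length(breaks)]
  h <- graphics::hist(x[inside], breaks = breaks, plot = FALSE)
  out <- data.frame(center = h$mids,
                    density = h$counts / (length(x) * diff(breaks)),
                    n = length(x))
  attr(out, "breaks") <- breaks
  attr(out, "kind") <- kind
  class(out) <- c("dist_curve", "data.frame")
  out
}
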