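#' Draw rest durations by inverse-transform sampling
#'
#' The rest-time law \eqn{\psi_{rest}(t) = \alpha (t+1)^{-1-\alpha}} has
#' survival function \eqn{S(t) = (t+1)^{-\alpha}}, whose inverse gives the
#' exact sampler \eqn{t = u^{-1/\alpha} - 1} for a uniform variate `u`.
#'
#' @param alpha_rest Rest-time power-law exponent (> 0).
#' @param u Uniform variates in (0, 1). Supply `stats::runif(n)` to draw `n`
#'   rests under the session RNG.
#' @return Rest durations in seconds, same length as `u`.
#' @export
#' @examples
#' sample_rest_time(1, 0.25)   # survival (t+1)^-1 = 1/4  =>  t = 3
#' set.seed(1); sample_rest_time(0.24, runif(5))
sample_rest_time <- function(alpha_rest, u) {
  if (!is.numeric(alpha_rest) || length(alpha_rest) != 1L || alpha_rest <= 0)
    stop("'alpha_rest' must be a single value > 0")
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1)")
  u^(-1 / alpha_rest) - 1
}

#' Draw run durations from the truncated power law
#'
#' Samples \eqn{\psi_{run}(t) \propto e^{-t/\tau_r} (t+1)^{-1-\eta}} by
#' rejection: proposals come from the pure power law with exponent `eta_run`
#' (inverse transform, as in [sample_rest_time()]) and are accepted with
#' probability \eqn{e^{-t/\tau_r}}, which bounds the target/proposal ratio.
#' The truncated law has no closed-form quantile function.
#'
#' @param n Number of durations to draw.
#' @param eta_run Run-time power-law exponent (> 0).
#' @param tau_r Characteristic run time in seconds (> 0).
#' @param max_rounds Safety cap on rejection rounds (each round proposes for
#'   every still-unfilled draw).
#' @return `n` run durations in seconds.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_run_time(1e4, 0.18, 12.6))
sample_run_time <- function(n, eta_run, tau_r, max_rounds = 1e6) {
  if (!is.numeric(eta_run) || length(eta_run) != 1L || eta_run <= 0)
    stop("'eta_run' must be a single value > 0")
  if (!is.numeric(tau_r) || length(tau_r) != 1L || tau_r <= 0)
    stop("'tau_r' must be a single value > 0")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  need <- seq_len(n)
  rounds <- 0L
  while (length(need)) {
    m <- length(need)
    t_prop <- stats::runif(m)^(-1 / eta_run) - 1
    acc <- stats::runif(m) < exp(-t_prop / tau_r)
    out[need[acc]] <- t_prop[acc]
    need <- need[!acc]
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("rejection sampler failed to accept within 'max_rounds' rounds")
  }
  out
}

# Event-level simulation of the alternating run/rest process.
#
# Every trajectory starts at t = 0 with a run; each phase duration is drawn
# from its sojourn law at phase entry; phases are generated until the
# trajectory's elapsed time exceeds t_max. Returns one row per phase with
# absolute start/end times and the run velocity (NA during rests).
simulate_phases <- function(params, n_traj, t_max) {
  stopifnot(inherits(params, "levy_walk_params"), n_traj >= 1, t_max > 0)
  n_traj <- as.integer(n_traj)
  rec <- vector("list", 64L)
  k <- 0L
  active <- seq_len(n_traj)
  t_now <- numeric(n_traj)
  while (length(active)) {
    m <- length(active)
    v <- ifelse(stats::runif(m) < params$p_antero, params$v_antero, params$v_retro)
    d_run <- sample_run_time(m, params$eta_run, params$tau_r)
    d_rest <- sample_rest_time(params$alpha_rest, stats::runif(m))
    k <- k + 1L
    if (k > length(rec)) rec <- c(rec, vector("list", length(rec)))
    rec[[k]] <- list(id = active, t0 = t_now[active],
                     d_run = d_run, d_rest = d_rest, v = v)
    t_now[active] <- t_now[active] + d_run + d_rest
    active <- active[t_now[active] <= t_max]
  }
  rec <- rec[seq_len(k)]
  id <- unlist(lapply(rec, `[[`, "id"), use.names = FALSE)
  t0 <- unlist(lapply(rec, `[[`, "t0"), use.names = FALSE)
  d_run <- unlist(lapply(rec, `[[`, "d_run"), use.names = FALSE)
  d_rest <- unlist(lapply(rec, `[[`, "d_rest"), use.names = FALSE)
  v <- unlist(lapply(rec, `[[`, "v"), use.names = FALSE)
  # interleave run and rest rows, ordered by trajectory then time
  o <- order(id, t0)
  id <- id[o]; t0 <- t0[o]; d_run <- d_run[o]; d_rest <- d_rest[o]; v <- v[o]
  n_pairs <- length(id)
  idx <- rep(seq_len(n_pairs), each = 2L)
  kind <- rep(c("run", "rest"), n_pairs)
  t_start <- as.vector(rbind(t0, t0 + d_run))
  t_end <- as.vector(rbind(t0 + d_run, t0 + d_run + d_rest))
  data.frame(
    id = id[idx],
    kind = kind,
    t_start = t_start,
    t_end = t_end,
    v = ifelse(kind == "run", v[idx], NA_real_)
  )
}

#' Simulate an ensemble of aging Levy walk trajectories
#'
#' Generates `n_traj` independent trajectories of the run/rest model. Each
#' trajectory starts from x = 0 at t = 0 with a run; sojourn durations are
#' drawn from their laws at phase entry and the position advances at the run's
#' constant signed velocity during runs (static during rests). The position is
#' then recorded on the regular grid `t in [aging_time, aging_time + window]`
#' at step `params$dt` and re-zeroed at the first recorded sample, emulating a
#' measurement that starts `aging_time` seconds after transport initiation.
#'
#' @param params A [levy_walk_params()] object.
#' @param n_traj Number of trajectories.
#' @param aging_time Aging time \eqn{t_a} in seconds (>= 0): elapsed time
#'   between transport initiation and the start of the recording.
#' @param window Observation window T in seconds (> 0).
#' @param noise Optional noise model ([noise_white()], [noise_ar1()] or
#'   [noise_library()]) superposed on the recorded positions.
#' @param keep_labels Keep per-sample run/rest phase labels (`TRUE` by
#'   default; the label of a sample on a phase boundary is the newly entered
#'   phase).
#' @param ground_truth Also attach the true phase intervals clipped to the
#'   observation window (a segment table with censoring flags), for
#'   benchmarking segmentation.
#' @return An object of class `mrnp_ensemble`: a list with elements `times`
#'   (window-relative sample times), `positions` (`n_traj` x `n_times`
#'   matrix, um), `labels` (0 = rest, 1 = run, or NULL), `params`,
#'   `aging_time`, `window`, `dt`, and optionally `true_segments`.
#' @export
#' @examples
#' set.seed(1)
#' ens <- simulate_trajectories(mrnp_preset("arc"), 50, aging_time = 30)
#' ens
simulate_trajectories <- function(params, n_traj, aging_time, window = 60,
                                  noise = NULL, keep_labels = TRUE,
                                  ground_truth = FALSE) {
  stopifnot(inherits(params, "levy_walk_params"))
  if (!is.numeric(aging_time) || length(aging_time) != 1L || aging_time < 0)
    stop("'aging_time' must be a single value >= 0")
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("'window' must be a single value > 0")
  n_traj <- as.integer(n_traj)
  dt <- params$dt
  n_steps <- round(window / dt)
  tt <- aging_time + dt * (0:n_steps)
  ph <- simulate_phases(params, n_traj, aging_time + window)
  # piecewise-linear position through phase boundaries; exact on the grid
  X <- matrix(0, n_traj, n_steps + 1L)
  L <- if (keep_labels) matrix(0L, n_traj, n_steps + 1L) else NULL
  rows <- split(seq_len(nrow(ph)), ph$id)
  dx_all <- ifelse(ph$kind == "run", (ph$t_end - ph$t_start) * ph$v, 0)
  for (i in seq_len(n_traj)) {
    j <- rows[[i]]
    keep <- ph$t_end[j] > ph$t_start[j]  # guard against zero-length phases
    j <- j[keep]
    node_t <- c(0, ph$t_end[j])
    node_x <- c(0, cumsum(dx_all[j]))
    X[i, ] <- stats::approx(node_t, node_x, xout = tt, rule = 2)$y
    if (keep_labels) {
      # sample at a boundary belongs to the newly entered phase
      idx <- findInterval(tt, ph$t_start[j])
      L[i, ] <- as.integer(ph$kind[j][pmax(idx, 1L)] == "run")
    }
  }
  X <- X - X[, 1L]
  ens <- structure(
    list(times = tt - aging_time, positions = X, labels = L,
         params = params, aging_time = aging_time, window = window, dt = dt,
         noise = NULL, true_segments = NULL),
    class = "mrnp_ensemble"
  )
  if (ground_truth)
    ens$true_segments <- clip_segments(ph, aging_time, window)
  if (!is.null(noise)) ens <- add_noise(ens, noise)
  ens
}

# Clip the event table to the observation window and express times relative
# to the window start; phases touching the window edge are flagged censored.
clip_segments <- function(ph, aging_time, window) {
  t0 <- aging_time
  t1 <- aging_time + window
  sel <- ph$t_end > t0 & ph$t_start < t1
  ph <- ph[sel, , drop = FALSE]
  left <- ph$t_start < t0
  right <- ph$t_end > t1
  out <- data.frame(
    particle_id = ph$id,
    kind = ph$kind,
    t_start = pmax(ph$t_start, t0) - t0,
    t_end = pmin(ph$t_end, t1) - t0,
    v_run = ph$v,
    left_censored = left,
    right_censored = right
  )
  out$duration <- out$t_end - out$t_start
  out$dx <- ifelse(out$kind == "run", out$duration * out$v_run, 0)
  rownames(out) <- NULL
  out[, c("particle_id", "kind", "t_start", "t_end", "duration", "dx",
          "v_run", "left_censored", "right_censored")]
}

#' @export
print.mrnp_ensemble <- function(x, ...) {
  cat(sprintf("mrnp_ensemble: %d trajectories, window %g s at dt = %g s\n",
              nrow(x$positions), x$window, x$dt))
  if (length(x$aging_time) == 1L) {
    cat(sprintf("  aging time: %g s\n", x$aging_time))
  } else {
    cat(sprintf("  aging mixture: w_new = %g (ta = %g s), w_old = %g (ta = %g s)\n",
                x$mixture["w_new"], x$aging_time[["new"]],
                1 - x$mixture["w_new"], x$aging_time[["old"]]))
  }
  if (!is.null(x$noise)) cat(sprintf("  noise: %s\n", x$noise$type))
  invisible(x)
}

#' Fraction of trajectories with no run during the observation window
#'
#' For each aging time on `ta_grid`, simulates the run/rest process and
#' reports the fraction of trajectories with no run interval overlapping the
#' window `[ta, ta + window]` - equivalently, the fraction whose window lies
#' entirely inside a single rest. This is the stationary fraction used to
#' infer aging times; it is computed at the event level so that runs shorter
#' than the sampling step are not missed. A single event ensemble (simulated
#' out to `max(ta_grid) + window`) is shared across all grid points.
#'
#' @param params A [levy_walk_params()] object.
#' @param ta_grid Aging times in seconds (non-empty, >= 0).
#' @param window Observation window in seconds.
#' @param n_traj Number of trajectories (>= 1000 recommended for stable
#'   estimates).
#' @param phases Optional precomputed event table from an earlier call
#'   (internal reuse).
#' @return A data frame of class `no_run_curve` with columns `ta`,
#'   `fraction`, `n_no_run`, `n_traj` and the binomial standard error `se`.
#' @export
#' @examples
#' set.seed(1)
#' no_run_fraction_curve(levy_walk_params(), c(10, 100), n_traj = 2000)
no_run_fraction_curve <- function(params, ta_grid, window = 60,
                                  n_traj = 20000, phases = NULL) {
  if (length(ta_grid) == 0L) stop("'ta_grid' must be non-empty")
  if (any(ta_grid < 0)) stop("aging times must be >= 0")
  if (n_traj < 1000)
    warning("fewer than 1000 trajectories; the fraction estimate will be noisy")
  if (is.null(phases))
    phases <- simulate_phases(params, n_traj, max(ta_grid) + window + params$dt)
  rest <- phases[phases$kind == "rest", , drop = FALSE]
  cnt <- vapply(ta_grid, function(ta) {
    sum(rest$t_start <= ta & rest$t_end >= ta + window)
  }, numeric(1))
  f <- cnt / n_traj
  out <- data.frame(ta = ta_grid, fraction = f, n_no_run = cnt,
                    n_traj = n_traj, se = sqrt(pmax(f * (1 - f), 0) / n_traj))
  class(out) <- c("no_run_curve", "data.frame")
  out
}
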