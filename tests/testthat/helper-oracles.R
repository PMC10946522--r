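# Independent reference implementations used as oracles. These deliberately
# use the most transparent (brute-force) formulation of each quantity and
# share no code with the package internals.

# TA MSD by explicit double loop over lags and start indices.
ta_msd_bruteforce <- function(x, dt, lags) {
  vapply(lags, function(lag) {
    k <- round(lag / dt)
    n <- length(x)
    s <- 0
    for (i in seq_len(n - k)) s <- s + (x[i + k] - x[i])^2
    s / (n - k)
  }, numeric(1))
}

# Iterative bilateral filter evaluated sample by sample from the weight
# formula on the 13-point stencil.
bilateral_reference <- function(v, fp) {
  vhat <- v
  m <- length(v)
  sig_s <- fp$sigma_s_init
  sig_v <- fp$sigma_v_init
  for (it in seq_len(fp$max_iter)) {
    if (it > 1) {
      sig_s <- sig_s + fp$sigma_s_growth * it^2
      sig_v <- fp$sigma_v_floor + (sig_v - fp$sigma_v_floor) * it^(-fp$sigma_v_decay)
    }
    new <- numeric(m)
    for (i in seq_len(m)) {
      num <- 0
      den <- 0
      for (j in -fp$half_width:fp$half_width) {
        k <- i - j
        if (k >= 1 && k <= m) {
          w <- exp(-j^2 / (2 * sig_s)) *
            exp(-(v[k] - v[i])^2 / (2 * sig_v))
          num <- num + w * vhat[k]
          den <- den + w
        }
      }
      new[i] <- num / den
    }
    converged <- max(abs(new - vhat)) < fp$stop_tol
    vhat <- new
    if (converged) break
  }
  vhat
}

# Scalar event-loop walk: returns the state occupied at time t_query for a
# single trajectory (run at t = 0, alternating states, durations drawn at
# state entry). Kept entirely separate from the package's vectorized
# generator.
walk_state_at <- function(params, t_query) {
  t <- 0
  state <- "run"
  repeat {
    d <- if (state == "run") {
      repeat {
        cand <- runif(1)^(-1 / params$eta_run) - 1
        if (runif(1) < exp(-cand / params$tau_r)) break
      }
      cand
    } else {
      runif(1)^(-1 / params$alpha_rest) - 1
    }
    if (t + d > t_query) return(state)
    t <- t + d
    state <- if (state == "run") "rest" else "run"
  }
}

# Rejection samplers for the window- and resolution-corrected sojourn laws
# (density prop. to (Tw - t)^gamma * psi(t) on [r dt, Tw]).
draw_corrected_rest <- function(n, alpha, corr, gamma = alpha) {
  a <- corr$resolution * corr$dt
  b <- corr$window_param
  s_a <- (a + 1)^(-alpha)
  s_b <- (b + 1)^(-alpha)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u <- runif(m, s_b, s_a)
    t <- u^(-1 / alpha) - 1
    out <- c(out, t[runif(m) < ((b - t) / b)^gamma])
  }
  out
}

draw_corrected_run <- function(n, eta, tau, corr, gamma) {
  a <- corr$resolution * corr$dt
  b <- corr$window_param
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    t <- runif(m)^(-1 / eta) - 1
    t <- t[t >= a & t <= b]
    t <- t[runif(length(t)) < exp(-t / tau) * ((b - t) / b)^gamma]
    out <- c(out, t)
  }
  out[seq_len(n)]
}

# Uncensored durations of one kind from a segment table.
uncensored_durations <- function(segments, kind) {
  s <- segments[segments$kind == kind &
                  !segments$left_censored & !segments$right_censored, ]
  s$duration
}

# Brute-force nearest-neighbor distances (per dendrite, all pairs).
nn_bruteforce <- function(query, reference) {
  d <- rep(NA_real_, nrow(query))
  for (i in seq_len(nrow(query))) {
    ri <- which(reference$dendrite_id == query$dendrite_id[i])
    if (!length(ri)) next
    dx <- reference$x_um[ri] - query$x_um[i]
    dy <- reference$y_um[ri] - query$y_um[i]
    dz <- reference$z_um[ri] - query$z_um[i]
    d[i] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  d
}
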