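#' Localization noise models
#'
#' Constructors for the noise superposed on recorded positions.
#' `noise_white()` adds independent zero-mean Gaussian localization error of
#' standard deviation `sigma` (um) to every sample. `noise_ar1()` adds a
#' stationary first-order autoregressive process with marginal standard
#' deviation `sigma` and lag-one correlation `phi`, a simple surrogate for
#' temporally correlated fluidic noise. `noise_library()` superposes a
#' randomly chosen, mean-subtracted empirical trace (rows of `positions`),
#' mirroring the practice of re-using all-rest experimental trajectories as a
#' noise library.
#'
#' @param sigma Marginal standard deviation in um (>= 0).
#' @param phi AR(1) lag-one correlation, in (-1, 1).
#' @param positions Numeric matrix of library traces (one row per trace),
#'   each at least as long as the target window.
#' @return A noise model object of class `mrnp_noise`.
#' @name noise_models
#' @export
noise_white <- function(sigma = 0.05) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(type = "white", sigma = sigma), class = "mrnp_noise")
}

#' @rdname noise_models
#' @export
noise_ar1 <- function(sigma = 0.05, phi = 0.5) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(phi), length(phi) == 1L, abs(phi) < 1)
  structure(list(type = "ar1", sigma = sigma, phi = phi), class = "mrnp_noise")
}

#' @rdname noise_models
#' @export
noise_library <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(is.numeric(positions), nrow(positions) >= 1)
  structure(list(type = "library", positions = positions), class = "mrnp_noise")
}

#' Superpose localization noise on an ensemble
#'
#' Adds zero-mean stationary noise to the recorded positions of every
#' trajectory in the ensemble. See [noise_models] for the available models.
#'
#' @param ens An `mrnp_ensemble` from [simulate_trajectories()].
#' @param noise A noise model object.
#' @return The ensemble with noisy positions; the `noise` field records the
#'   model applied.
#' @export
#' @examples
#' set.seed(1)
#' ens <- simulate_trajectories(levy_walk_params(), 10, aging_time = 0)
#' noisy <- add_noise(ens, noise_white(0.05))
add_noise <- function(ens, noise = noise_white()) {
  stopifnot(inherits(ens, "mrnp_ensemble"), inherits(noise, "mrnp_noise"))
  n <- nrow(ens$positions)
  m <- ncol(ens$positions)
  eps <- switch(noise$type,
    white = matrix(stats::rnorm(n * m, 0, noise$sigma), n, m),
    ar1 = {
      innov_sd <- noise$sigma * sqrt(1 - noise$phi^2)
      e <- matrix(0, n, m)
      e[, 1] <- stats::rnorm(n, 0, noise$sigma)
      for (j in 2:m)
        e[, j] <- noise$phi * e[, j - 1] + stats::rnorm(n, 0, innov_sd)
      e
    },
    library = {
      lib <- noise$positions
      if (ncol(lib) < m)
        stop("noise library traces are shorter than the observation window")
      pick <- sample.int(nrow(lib), n, replace = TRUE)
      tr <- lib[pick, seq_len(m), drop = FALSE]
      tr - rowMeans(tr)
    },
    stop("unknown noise type")
  )
  ens$positions <- ens$positions + eps
  ens$noise <- noise[setdiff(names(noise), "positions")]
  ens
}
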