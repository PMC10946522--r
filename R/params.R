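#' Kinetic parameters of the aging Levy walk with rests
#'
#' Bundles the sojourn-law and velocity parameters of the transport model:
#' rests are drawn from the power law \eqn{\psi_{rest}(t) = \alpha (t+1)^{-1-\alpha}}
#' and runs from the exponentially truncated power law
#' \eqn{\psi_{run}(t) \propto e^{-t/\tau_r} (t+1)^{-1-\eta}}. During a run the
#' particle moves at a constant signed velocity, anterograde (`v_antero`) with
#' probability `p_antero` or retrograde (`v_retro`) otherwise; during a rest it
#' is static.
#'
#' @param alpha_rest Power-law exponent of the rest-time distribution
#'   (dimensionless, > 0).
#' @param eta_run Power-law exponent of the run-time distribution
#'   (dimensionless, > 0).
#' @param tau_r Characteristic (cutoff) run time in seconds (> 0).
#' @param v_antero Anterograde run speed in micrometres per second (> 0).
#' @param v_retro Retrograde run speed in micrometres per second (< 0).
#' @param p_antero Probability that a run is anterograde, in \[0, 1\].
#' @param dt Sampling interval of the recording in seconds (> 0).
#'
#' @return An object of class `levy_walk_params` (a validated list).
#' @seealso [mrnp_preset()] for the species presets,
#'   [simulate_trajectories()] for the simulator.
#' @export
#' @examples
#' p <- levy_walk_params()
#' p
levy_walk_params <- function(alpha_rest = 0.24, eta_run = 0.18, tau_r = 12.6,
                             v_antero = 1.0, v_retro = -1.1, p_antero = 0.5,
                             dt = 0.2) {
  stopifnot(
    is.numeric(alpha_rest), length(alpha_rest) == 1L, is.finite(alpha_rest),
    is.numeric(eta_run), length(eta_run) == 1L, is.finite(eta_run),
    is.numeric(tau_r), length(tau_r) == 1L,
    is.numeric(v_antero), length(v_antero) == 1L, is.finite(v_antero),
    is.numeric(v_retro), length(v_retro) == 1L, is.finite(v_retro),
    is.numeric(p_antero), length(p_antero) == 1L,
    is.numeric(dt), length(dt) == 1L, is.finite(dt)
  )
  if (alpha_rest <= 0) stop("'alpha_rest' must be > 0")
  if (eta_run <= 0) stop("'eta_run' must be > 0")
  if (tau_r <= 0) stop("'tau_r' must be > 0")
  if (!(v_antero > 0)) stop("'v_antero' must be > 0")
  if (!(v_retro < 0)) stop("'v_retro' must be < 0")
  if (p_antero < 0 || p_antero > 1) stop("'p_antero' must be in [0, 1]")
  if (dt <= 0) stop("'dt' must be > 0")
  structure(
    list(alpha_rest = alpha_rest, eta_run = eta_run, tau_r = tau_r,
         v_antero = v_antero, v_retro = v_retro, p_antero = p_antero,
         dt = dt),
    class = "levy_walk_params"
  )
}

#' Species presets for the transport model
#'
#' Returns the `levy_walk_params` describing the two mRNP species studied in
#' proximal dendrites. Both share the same sojourn-time laws
#' (`alpha_rest = 0.24`, `eta_run = 0.18`, `tau_r = 12.6` s); they differ in
#' run velocities and directional bias: beta-actin mRNP runs at +1.0 / -1.1
#' um/s with no directional preference, Arc mRNP at +1.3 / -1.1 um/s with a
#' 54% anterograde bias.
#'
#' @param species `"beta_actin"` or `"arc"`.
#' @param ... Overrides passed on to [levy_walk_params()].
#' @return A `levy_walk_params` object.
#' @export
#' @examples
#' mrnp_preset("arc")
mrnp_preset <- function(species = c("beta_actin", "arc"), ...) {
  species <- match.arg(species)
  defaults <- switch(species,
    beta_actin = list(v_antero = 1.0, v_retro = -1.1, p_antero = 0.5),
    arc        = list(v_antero = 1.3, v_retro = -1.1, p_antero = 0.54)
  )
  args <- utils::modifyList(defaults, list(...))
  p <- do.call(levy_walk_params, args)
  attr(p, "species") <- species
  p
}

#' @export
print.levy_walk_params <- function(x, ...) {
  sp <- attr(x, "species")
  cat("Aging Levy walk parameters",
      if (!is.null(sp)) sprintf(" (%s preset)", sp), "\n", sep = "")
  cat(sprintf("  rest law : alpha_rest = %g\n", x$alpha_rest))
  cat(sprintf("  run law  : eta_run = %g, tau_r = %g s\n", x$eta_run, x$tau_r))
  cat(sprintf("  velocity : %+g / %+g um/s, P(anterograde) = %g\n",
              x$v_antero, x$v_retro, x$p_antero))
  cat(sprintf("  sampling : dt = %g s\n", x$dt))
  invisible(x)
}
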