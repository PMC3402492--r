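#' Logistic transfer function
#'
#' Maps a neuron's local input to an activity in (0, 1):
#' \eqn{f(h) = 1 / (1 + e^{-h/T})}. `T` is the neuronal gain (Table-level
#' default 0.05 for both layers); smaller `T` makes the neuron more nearly
#' binary.
#'
#' @param h Local input (vector).
#' @param T Neuronal gain.
#' @return Activity values in (0, 1).
#' @export
transfer <- function(h, T = 0.05) {
  1 / (1 + exp(-h / T))
}

#' Thresholded (rectified-shift) external input
#'
#' External drive influences a neuron only when it exceeds the constant
#' external threshold: \eqn{g(I) = \max(I - \theta_{ext}, 0)}. Inputs are
#' always excitatory, so `I >= 0` is expected.
#'
#' @param I_ext External drive (vector).
#' @param theta_ext External-input threshold.
#' @return Gated drive.
#' @export
gate_external <- function(I_ext, theta_ext) {
  pmax(I_ext - theta_ext, 0)
}

#' One step of temporally correlated Gaussian noise
#'
#' Exact AR(1) discretization of an Ornstein-Uhlenbeck process:
#' \eqn{\eta(t+dt) = a\,\eta(t) + \eta_{amp}\sqrt{1-a^2}\,\varepsilon},
#' \eqn{a = e^{-dt/\tau_{corr}}}. The stationary process has standard
#' deviation `eta_amp` and autocorrelation \eqn{e^{-\tau/\tau_{corr}}} at lag
#' \eqn{\tau}, i.e. white noise passed through a first-order low-pass filter.
#'
#' @param eta Current noise values (vector).
#' @param eta_amp Stationary standard deviation.
#' @param tau_corr Correlation time (ms).
#' @param dt Time step (ms).
#' @return Updated noise vector (draws from the current RNG stream).
#' @export
noise_step <- function(eta, eta_amp, tau_corr, dt) {
  if (eta_amp == 0) return(rep(0, length(eta)))
  a <- exp(-dt / tau_corr)
  a * eta + eta_amp * sqrt(1 - a^2) * stats::rnorm(length(eta))
}

#' Pearson correlation of an activity vector with a stored pattern
#'
#' The convergence measure of the simulations: a network is converged on
#' pattern \eqn{\mu} when this correlation reaches 0.95 while staying below
#' 0.5 for every other pattern.
#'
#' @param x Activity vector.
#' @param xi Binary pattern (same length).
#' @return Correlation in \[-1, 1\], or `NA` when either vector has zero
#'   variance (reported as not-converged).
#' @export
pattern_correlation <- function(x, xi) {
  if (stats::sd(x) == 0 || stats::sd(xi) == 0) return(NA_real_)
  stats::cor(as.numeric(x), as.numeric(xi))
}

#' One forward-Euler step of a single recurrent network (reference path)
#'
#' Base-R reference implementation of the local-input dynamics
#' \deqn{\tau_n \dot h_i = -h_i + \sum_j J^{eff}_{ij} x_j
#'   - \lambda(\langle x\rangle - c\,p) - \theta + g(I^{ext}_i) + \eta_i}
#' followed by \eqn{x = f(h)}. The regulation term penalizes deviations of
#' the mean activity from a set point `c * p` (`c = params$reg_frac`: 0.55 for
#' the semantic layer, 1 for the lexical layer); together with the
#' constant threshold \eqn{\theta} it acts as global inhibition and mediates
#' winner-take-all competition between patterns. `J_eff` must already include
#' any depression scaling (see [effective_weights()]). This path is dense and
#' unoptimized; the trial simulator uses a compiled equivalent, and the two
#' are cross-checked in the test suite.
#'
#' @param state List with `h` (local inputs) and `x` (activities).
#' @param J_eff Effective weight matrix (N x N).
#' @param I_ext Raw external drive per neuron (gated internally).
#' @param params A `network_params` object.
#' @param dt Time step (ms).
#' @param eta Noise vector (default zero).
#' @return Updated state list (`h`, `x`).
#' @export
network_step <- function(state, J_eff, I_ext, params, dt, eta = 0) {
  if (!all(is.finite(state$h)))
    stop("non-finite local input: parameter misconfiguration?", call. = FALSE)
  drive <- as.numeric(J_eff %*% state$x)
  reg <- params$lambda * (mean(state$x) - params$reg_frac * params$p)
  dh <- (-state$h + drive - reg - params$theta +
           gate_external(I_ext, params$theta_ext) + eta) / params$tau_n
  h <- state$h + dt * dh
  list(h = h, x = transfer(h, params$T))
}
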