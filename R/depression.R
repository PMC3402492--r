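#' One Euler step of short-term synaptic depression
#'
#' Rate-based Tsodyks-Markram resource dynamics, tracked per presynaptic
#' neuron (the rule depends only on presynaptic activity, so one resource
#' pool per neuron is mathematically identical to one per synapse):
#' \deqn{\dot r_j = \frac{1 - r_j}{\tau_r} - U\, x_{max}\, x_j\, r_j}
#' Each presynaptic spike consumes a fraction `U` of the available resources;
#' the synapse recovers with time constant `tau_r`. The effective outgoing
#' weight of neuron j is its static weight times `r_j`, applied to excitatory
#' and inhibitory connections alike.
#'
#' `U` is per spike and `x` is a normalized rate in \[0, 1\], so the depletion
#' rate uses the maximal firing rate `x_max` (spikes/s, converted internally
#' to spikes/ms) to restore physical units.
#'
#' @param r Resource fractions in \[0, 1\] (one per presynaptic neuron).
#' @param x_pre Presynaptic activities in \[0, 1\].
#' @param U Utilization per spike.
#' @param tau_r Recovery time constant (ms).
#' @param x_max Maximal firing rate (spikes/s).
#' @param dt Time step (ms).
#' @return Updated resource vector.
#' @export
depression_step <- function(r, x_pre, U, tau_r, x_max, dt) {
  r + dt * ((1 - r) / tau_r - U * (x_max / 1000) * x_pre * r)
}

#' Steady-state resource level under sustained presynaptic drive
#'
#' Closed form for a presynaptic neuron held at full activity (x = 1):
#' \eqn{r^* = 1 / (1 + U\, x_{max}\, \tau_r)}. At the semantic-network
#' defaults this gives about 0.343 for the control condition and about 0.291
#' for the elevated-utilization condition, whose resources therefore deplete
#' faster and further at every point in time.
#'
#' @param U Utilization per spike.
#' @param tau_r Recovery time (ms).
#' @param x_max Maximal firing rate (spikes/s).
#' @return The plateau resource fraction.
#' @export
depression_plateau <- function(U, tau_r, x_max = 100) {
  1 / (1 + U * (x_max / 1000) * tau_r)
}

#' Scale static weights by presynaptic resources
#'
#' Column j of the static matrix is multiplied by the resource fraction of
#' presynaptic neuron j.
#'
#' @param J_static Static weight matrix.
#' @param r Resource vector (length = ncol(J_static)).
#' @return The effective weight matrix.
#' @export
effective_weights <- function(J_static, r) {
  stopifnot(length(r) == ncol(J_static))
  sweep(J_static, 2, r, `*`)
}
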