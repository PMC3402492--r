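#' Default parameters for the semantic network
#'
#' Returns the parameter set of the semantic (concept) layer: a 500-neuron
#' recurrent attractor network with sparse binary patterns (sparseness 0.06),
#' logistic rate dynamics and short-term synaptic depression on all recurrent
#' synapses. The `condition` switch changes only the synaptic utilization
#' `U` (0.206 for control, 0.2615 for the elevated-utilization
#' "schizophrenic" condition, about a 25% increase); every other parameter is
#' identical between conditions.
#'
#' @param condition `"control"` or `"schizophrenic"`.
#' @return An object of class `network_params`: a list with fields
#'   `N` (neurons), `p` (sparseness), `T` (neuronal gain of the logistic
#'   transfer), `tau_n` (neuron time constant, ms), `theta` (activation
#'   threshold / global inhibition), `lambda` (mean-activity regulation),
#'   `reg_frac` (regulation set point as a fraction of `p`: the regulation
#'   term is \eqn{\lambda(\langle x\rangle - reg\_frac \cdot p)}; 0.55 for the
#'   semantic layer, whose overlapping patterns need standing inhibition at
#'   convergence to suppress mixture states, and 1 for the lexical layer,
#'   whose disjoint word patterns must remain ignitable by the thresholded
#'   external input),
#'   `x_max` (maximal firing rate, spikes/s), `U` (utilization per spike of
#'   recurrent synapses), `tau_r` (recovery time of recurrent synapses, ms),
#'   `theta_ext` (external-input threshold), `eta_amp` (noise standard
#'   deviation), `eta_amp_low` (reduced-noise value, exposed but unused by the
#'   standard experiments), `tau_corr` (noise correlation time, ms).
#' @export
semantic_params <- function(condition = c("control", "schizophrenic")) {
  condition <- match.arg(condition)
  structure(list(
    name      = "semantic",
    N         = 500L,
    p         = 0.06,
    T         = 0.05,
    tau_n     = 7,
    theta     = 0.02,
    lambda    = 14.75,
    reg_frac  = 0.55,
    x_max     = 100,
    U         = if (condition == "control") 0.206 else 0.2615,
    tau_r     = 93,
    theta_ext = 1,
    eta_amp   = 0.05,
    eta_amp_low = 0.02,
    tau_corr  = 17
  ), class = "network_params")
}

#' Default parameters for the lexical network
#'
#' The lexical (word-form) layer: same size and transfer function as the
#' semantic layer but sparser patterns (0.04), slower neurons, a higher
#' activation threshold, and crucially no recurrent synaptic depression
#' (`U = 0`), so its attractors are indefinitely stable and the layer shows no
#' latching. Identical in both conditions.
#'
#' @return A `network_params` object (see [semantic_params()]).
#' @export
lexical_params <- function() {
  structure(list(
    name      = "lexical",
    N         = 500L,
    p         = 0.04,
    T         = 0.05,
    tau_n     = 13,
    theta     = 0.17,
    lambda    = 27.75,
    reg_frac  = 1,
    x_max     = 100,
    U         = 0,
    tau_r     = 93,
    theta_ext = 0.25,
    eta_amp   = 0.025,
    eta_amp_low = 0.025,
    tau_corr  = 17
  ), class = "network_params")
}

#' Inter-network coupling parameters
#'
#' Lexical-to-semantic projections are strong (raw gain 2, normalized by the
#' number of active presynaptic neurons in a word pattern) and depress with a
#' slow recovery time (1333 ms), so a recognized word gives the semantic layer
#' a fast but short-lived push. Semantic-to-lexical feedback is weak (raw gain
#' 0.21) and does not depress, providing the slow top-down facilitation that
#' produces priming. The condition switch changes only the bottom-up
#' utilization (0.087 control, 0.1104 schizophrenic).
#'
#' @param condition `"control"` or `"schizophrenic"`.
#' @return A list with fields `gain_ls`, `gain_sl` (raw projection gains),
#'   `U_ls`, `tau_r_ls` (depression of the lexical-to-semantic projection),
#'   `U_sl` (always 0: feedback does not depress), and `external_gain`
#'   (strength of the visual word input to the lexical layer, 0.56).
#' @export
coupling_params <- function(condition = c("control", "schizophrenic")) {
  condition <- match.arg(condition)
  list(
    gain_ls       = 2,
    gain_sl       = 0.21,
    U_ls          = if (condition == "control") 0.087 else 0.1104,
    tau_r_ls      = 1333,
    U_sl          = 0,
    external_gain = 0.56
  )
}

validate_network_params <- function(p) {
  stopifnot(
    p$N >= 2, p$p > 0, p$p < 1, p$T > 0, p$tau_n > 0, p$tau_r > 0,
    p$eta_amp >= 0, p$U >= 0, p$tau_corr > 0, p$x_max > 0,
    p$reg_frac >= 0, p$reg_frac <= 1
  )
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params: %s>\n", x$name))
  flds <- setdiff(names(x), "name")
  for (f in flds) cat(sprintf("  %-10s %s\n", f, format(x[[f]])))
  invisible(x)
}
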