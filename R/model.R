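#' Dense inter-network projection matrices
#'
#' Each active neuron of word pattern \eqn{\mu} in one layer sends an
#' excitatory connection to every active neuron of concept pattern \eqn{\mu}
#' in the other layer. Per-connection weights are the raw gain normalized by
#' the number of active presynaptic neurons in the pattern (2/20 bottom-up,
#' 0.21/30 top-down at the defaults), summed when a presynaptic neuron serves
#' several patterns. The baseline patterns carry no inter-network
#' connections.
#'
#' The trial simulator uses an equivalent low-rank factorization of these
#' matrices; this dense constructor is the reference form.
#'
#' @param lexical,semantic `pattern_set` objects with matching pattern
#'   indexing.
#' @param gain_ls Raw lexical-to-semantic gain.
#' @param gain_sl Raw semantic-to-lexical gain.
#' @return List with `W_ls` (N_sem x N_lex) and `W_sl` (N_lex x N_sem),
#'   both nonnegative.
#' @export
build_projections <- function(lexical, semantic, gain_ls = 2, gain_sl = 0.21) {
  if (nrow(lexical$patterns) != nrow(semantic$patterns))
    stop("pattern index mismatch between the lexical and semantic sets")
  if (lexical$baseline_index != semantic$baseline_index)
    stop("baseline index mismatch between the lexical and semantic sets")
  keep <- setdiff(seq_len(nrow(lexical$patterns)), lexical$baseline_index)
  Xl <- lexical$patterns[keep, , drop = FALSE]
  Xs <- semantic$patterns[keep, , drop = FALSE]
  W_ls <- (gain_ls / lexical$n_active) * crossprod(Xs, Xl)  # N_sem x N_lex
  W_sl <- (gain_sl / semantic$n_active) * crossprod(Xl, Xs) # N_lex x N_sem
  list(W_ls = W_ls, W_sl = W_sl)
}

#' Assemble the two-layer coupled model
#'
#' Builds lexical and semantic pattern sets (from one seed, so a model is
#' fully reproducible), attaches the Table-level parameters of the requested
#' condition, and the coupling parameters. The condition switch changes only
#' the synaptic utilization values (recurrent semantic and bottom-up); all
#' other parameters are identical between conditions.
#'
#' @param condition `"control"` or `"schizophrenic"`.
#' @param seed Integer seed for pattern construction.
#' @param semantic,lexical Optional pre-built `pattern_set`s (e.g. a reduced
#'   fixture); when supplied, `seed` only affects whichever set is missing.
#' @param sem_params,lex_params,coupling Optional parameter overrides.
#' @return An object of class `coupled_model`.
#' @export
build_coupled_model <- function(condition = c("control", "schizophrenic"),
                                seed = 1L,
                                semantic = NULL, lexical = NULL,
                                sem_params = NULL, lex_params = NULL,
                                coupling = NULL) {
  condition <- match.arg(condition)
  sp <- if (is.null(sem_params)) semantic_params(condition) else sem_params
  lp <- if (is.null(lex_params)) lexical_params() else lex_params
  cp <- if (is.null(coupling)) coupling_params(condition) else coupling
  validate_network_params(sp)
  validate_network_params(lp)
  if (is.null(semantic))
    semantic <- make_semantic_patterns(N = sp$N, p = sp$p, seed = seed)
  if (is.null(lexical))
    lexical <- make_lexical_patterns(N = lp$N, p = lp$p,
                                     n_patterns = nrow(semantic$patterns),
                                     seed = seed + 1L)
  if (nrow(semantic$patterns) != nrow(lexical$patterns))
    stop("pattern index mismatch between the lexical and semantic sets")
  structure(list(
    condition = condition,
    semantic = list(params = sp, patterns = semantic),
    lexical  = list(params = lp, patterns = lexical),
    coupling = cp,
    graph = semantic$graph
  ), class = "coupled_model")
}

#' @export
print.coupled_model <- function(x, ...) {
  cat(sprintf("<coupled_model: %s condition>\n", x$condition))
  cat(sprintf("  semantic: %d neurons, %d patterns (p = %g), U = %g\n",
              x$semantic$params$N, nrow(x$semantic$patterns$patterns),
              x$semantic$params$p, x$semantic$params$U))
  cat(sprintf("  lexical:  %d neurons, %d patterns (p = %g), U = %g\n",
              x$lexical$params$N, nrow(x$lexical$patterns$patterns),
              x$lexical$params$p, x$lexical$params$U))
  cat(sprintf("  coupling: gain %g down / %g up, bottom-up U = %g\n",
              x$coupling$gain_ls, x$coupling$gain_sl, x$coupling$U_ls))
  invisible(x)
}
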