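#' Specify one priming trial
#'
#' @param relatedness `"related"`, `"indirect"`, or `"unrelated"`.
#' @param soa Stimulus onset asynchrony in ms (200 short, 950 long).
#' @param prime_type `"I"`, `"II"`, or `NA` (unrelated trials; ignored when
#'   `prime`/`target` are given explicitly).
#' @param prime,target Pattern indices; `NA` to sample them from the model's
#'   relation graph inside the trial's own RNG stream.
#' @param seed Integer seed for the trial (noise and pair sampling).
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(relatedness = c("related", "indirect", "unrelated"),
                       soa = 200, prime_type = NA, prime = NA, target = NA,
                       seed = NULL) {
  relatedness <- match.arg(relatedness)
  stopifnot(soa > 0)
  structure(list(relatedness = relatedness, soa = soa,
                 prime_type = prime_type, prime = prime, target = target,
                 seed = seed),
            class = "trial_spec")
}

# draw a (prime, target) pair for the given relatedness/prime type from the
# canonical pair lists, using the current RNG stream
sample_pair <- function(graph, relatedness, prime_type = NA) {
  if (relatedness == "unrelated") {
    nbp <- graph$unrelated_neighborhood_pairs[[
      sample.int(length(graph$unrelated_neighborhood_pairs), 1L)]]
    if (stats::runif(1) < 0.5) nbp <- rev(nbp)
    prime <- sample(graph$neighborhoods[[nbp[1]]], 1L)
    target <- sample(graph$neighborhoods[[nbp[2]]], 1L)
    return(c(prime = prime, target = target))
  }
  pairs <- switch(paste0(relatedness, prime_type),
    relatedI   = graph$typeI_direct_pairs,
    relatedII  = graph$typeII_direct_pairs,
    indirectI  = graph$typeI_indirect_pairs,
    indirectII = graph$typeII_indirect_pairs,
    stop("prime_type must be 'I' or 'II' for related/indirect trials")
  )
  pr <- pairs[[sample.int(length(pairs), 1L)]]
  c(prime = pr[1], target = pr[2])
}

#' Run one simulated priming trial
#'
#' Protocol: both networks start clamped on their baseline patterns for a
#' 50 ms burn-in (resources at 1, local inputs settled at the baseline fixed
#' point). At t = 0 the prime word drives the lexical network for 100 ms,
#' followed by a blank interval; the target word comes on at `soa` and stays
#' on until the trial ends. The reaction time is the latency from target
#' onset to the lexical network's convergence on the target attractor
#' (correlation >= 0.95 with the target and < 0.5 with every other pattern,
#' checked every step). Semantic convergence events are logged with the same
#' criterion throughout the trial.
#'
#' @param model A `coupled_model`.
#' @param spec A `trial_spec`.
#' @param dt Integration step (ms).
#' @param burn_in Baseline clamp duration before prime onset (ms).
#' @param prime_dur Prime presentation time (ms).
#' @param timeout Maximum time after target onset before the trial is marked
#'   not-converged (ms).
#' @param noise,depression Logical switches for the noise process and the
#'   synaptic depression (both on for the standard experiments; turning them
#'   off gives the stable-attractor limit).
#' @param record_every Record the correlation trajectory every this many
#'   steps (0 = no recording).
#' @return An object of class `trial_record`: the spec (with the sampled
#'   prime/target filled in), `rt` (ms, `NA` if not converged), `converged`,
#'   `n_transitions` (semantic attractor transitions between prime onset and
#'   lexical target convergence, not counting the two stimulus-driven
#'   convergences; see [count_transitions()]), event tables for both
#'   networks, and optionally the trajectory.
#' @export
run_trial <- function(model, spec, dt = 0.66, burn_in = 50, prime_dur = 100,
                      timeout = 1000, noise = TRUE, depression = TRUE,
                      record_every = 0L) {
  stopifnot(inherits(model, "coupled_model"), inherits(spec, "trial_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.na(spec$prime) || is.na(spec$target)) {
    pr <- sample_pair(model$graph, spec$relatedness, spec$prime_type)
    spec$prime <- unname(pr["prime"])
    spec$target <- unname(pr["target"])
  }
  sem <- model$semantic
  lex <- model$lexical
  res <- .sim_trial_cpp(
    sem$patterns$patterns, lex$patterns$patterns,
    unclass(sem$params), unclass(lex$params), model$coupling,
    sem$patterns$baseline_index, lex$patterns$baseline_index,
    sem$patterns$baseline_index, lex$patterns$baseline_index,
    as.integer(spec$prime), as.integer(spec$target),
    prime_dur, spec$soa, timeout, burn_in, dt,
    0.95, 0.5, noise, depression,
    as.integer(record_every), spec$soa + timeout)
  sem_events <- data.frame(time = res$sem_event_t, pattern = res$sem_event_id)
  lex_events <- data.frame(time = res$lex_event_t, pattern = res$lex_event_id)
  rec <- structure(list(
    spec = spec, condition = model$condition,
    rt = res$rt, converged = res$converged,
    semantic_events = sem_events, lexical_events = lex_events,
    baseline_index = sem$patterns$baseline_index,
    t_end = res$t_end
  ), class = "trial_record")
  rec$n_transitions <- count_transitions(rec)
  if (record_every > 0) {
    rec$traj <- list(time = res$traj_t, semantic = res$traj_sem,
                     lexical = res$traj_lex)
  }
  rec
}

#' Count semantic attractor transitions in a trial
#'
#' The number of changes of converged semantic pattern identity between prime
#' onset and the lexical network's convergence on the target. Two
#' stimulus-driven convergences are not transitions and are excluded: the
#' initial convergence out of the baseline state (baseline to prime), and a
#' final convergence onto the target's own semantic pattern occurring after
#' target onset (the recognition response itself). A jump onto the target
#' pattern *before* target onset is spontaneous latching and does count.
#'
#' @param record A `trial_record`, or a plain integer vector of converged
#'   pattern identities in temporal order (in which case leading baseline
#'   entries are identified by the `baseline` argument and the target-onset
#'   exclusion requires `target`, `soa`, and `times`).
#' @param baseline Baseline pattern index (taken from the record when one is
#'   supplied).
#' @param target,soa,times Target pattern index, target onset time (ms), and
#'   event times parallel to the id vector; only used for a bare id vector,
#'   and the final-event exclusion is skipped when any is `NULL`.
#' @return Integer transition count.
#' @export
count_transitions <- function(record, baseline = NULL, target = NULL,
                              soa = NULL, times = NULL) {
  if (inherits(record, "trial_record")) {
    ids <- record$semantic_events$pattern
    times <- record$semantic_events$time
    baseline <- record$baseline_index
    target <- record$spec$target
    soa <- record$spec$soa
  } else {
    ids <- as.integer(record)
    if (is.null(baseline)) stop("baseline index required for a bare id vector")
  }
  while (length(ids) > 0 && ids[1] == baseline) {
    ids <- ids[-1]
    if (!is.null(times)) times <- times[-1]
  }
  n <- length(ids)
  if (n > 0 && !is.null(target) && !is.null(soa) && !is.null(times) &&
      !is.na(target) && ids[n] == target && times[n] >= soa) {
    ids <- ids[-n]
  }
  max(length(ids) - 1L, 0L)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record: %s %s prime %s -> target %s, SOA %g ms>\n",
              x$condition, x$spec$relatedness, x$spec$prime, x$spec$target,
              x$spec$soa))
  if (x$converged) cat(sprintf("  RT %.2f ms, %d semantic transition(s)\n",
                               x$rt, x$n_transitions))
  else cat("  not converged\n")
  invisible(x)
}

#' Run a full experimental session
#'
#' Crosses condition, relatedness, and Type-I prime ratio, running
#' `trials_per_cell` trials in each cell. Within related and indirect cells
#' the number of Type-I-prime trials is exactly `round(ratio *
#' trials_per_cell)` (deterministic allocation); unrelated pairs are drawn
#' from mutually uncorrelated neighborhoods. Every trial gets its own RNG
#' stream seeded `base_seed + trial index`, so the session is reproducible
#' and order-independent.
#'
#' @param soa SOA in ms for every trial of the session.
#' @param relatedness Character vector of relatedness conditions to cross.
#' @param conditions Character vector of network conditions.
#' @param ratios Type-I prime ratios to cross.
#' @param trials_per_cell Trials per (condition, relatedness, ratio) cell.
#' @param base_seed Base seed; also (plus one offset) the pattern seed used
#'   when `models` is not supplied.
#' @param models Optional named list of pre-built `coupled_model`s (names =
#'   conditions); both conditions should share one pattern seed so they
#'   differ only in utilization.
#' @param progress Print per-cell progress to stderr.
#' @param ... Passed to [run_trial()] (`dt`, `timeout`, ...).
#' @return A data.frame with one row per trial: `condition`, `soa`,
#'   `relatedness`, `ratio`, `prime_type`, `prime`, `target`, `seed`, `rt`,
#'   `n_transitions`, `converged`.
#' @export
run_session <- function(soa = 200,
                        relatedness = c("related", "indirect", "unrelated"),
                        conditions = c("control", "schizophrenic"),
                        ratios = c(0, 0.25, 0.5, 0.75, 1),
                        trials_per_cell = 300,
                        base_seed = 1L,
                        models = NULL,
                        progress = FALSE, ...) {
  if (is.null(models)) {
    models <- lapply(conditions, function(cond)
      build_coupled_model(cond, seed = base_seed))
    names(models) <- conditions
  }
  out <- list()
  ctr <- 0L
  for (cond in conditions) {
    model <- models[[cond]]
    for (rel in relatedness) {
      for (ratio in ratios) {
        n <- trials_per_cell
        n_typeI <- round(ratio * n)
        if (progress)
          message(sprintf("cell: %s / %s / ratio %g", cond, rel, ratio))
        for (i in seq_len(n)) {
          ctr <- ctr + 1L
          ptype <- if (rel == "unrelated") NA_character_
                   else if (i <= n_typeI) "I" else "II"
          spec <- trial_spec(relatedness = rel, soa = soa,
                             prime_type = ptype, seed = base_seed + ctr)
          rec <- run_trial(model, spec, ...)
          out[[ctr]] <- data.frame(
            condition = cond, soa = soa, relatedness = rel, ratio = ratio,
            prime_type = ifelse(is.na(ptype), NA_character_, ptype),
            prime = rec$spec$prime, target = rec$spec$target,
            seed = base_seed + ctr,
            rt = rec$rt, n_transitions = rec$n_transitions,
            converged = rec$converged,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Simulated experiment 1: short stimulus onset asynchrony
#'
#' Related, indirectly related, and unrelated pairs at a 200 ms SOA (100 ms
#' prime, 100 ms blank), crossed with five Type-I prime ratios and both
#' network conditions. At the full 300 trials per cell this is the 9000-trial
#' design.
#'
#' @inheritParams run_session
#' @param ... Passed to [run_session()].
#' @return The trial data.frame (see [run_session()]).
#' @export
simulate_sim1 <- function(trials_per_cell = 300, base_seed = 1L, ...) {
  run_session(soa = 200,
              relatedness = c("related", "indirect", "unrelated"),
              trials_per_cell = trials_per_cell, base_seed = base_seed, ...)
}

#' Simulated experiment 2: long stimulus onset asynchrony
#'
#' As experiment 1 but with a 950 ms SOA and no indirectly related pairs
#' (6000 trials at 300 per cell).
#'
#' @inheritParams run_session
#' @param ... Passed to [run_session()].
#' @return The trial data.frame.
#' @export
simulate_sim2 <- function(trials_per_cell = 300, base_seed = 1L, ...) {
  run_session(soa = 950,
              relatedness = c("related", "unrelated"),
              trials_per_cell = trials_per_cell, base_seed = base_seed, ...)
}
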