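#' Priming effects from a trial table
#'
#' The direct priming effect in a (condition, SOA, ratio) cell is
#' mean(unrelated RT) minus mean(related RT); indirect priming substitutes
#' the indirectly related cell. Non-converged trials are excluded from the
#' means but counted. Standard errors are propagated from the trial-level RT
#' variances of the two cells.
#'
#' @param trials A trial data.frame from [run_session()] (or several
#'   rbind-ed together). Must contain matched unrelated cells for every
#'   related/indirect cell.
#' @return An object of class `priming_summary`: list with
#'   `cells` (per-cell mean/sd/n of RT), `by_ratio` (direct and, when
#'   available, indirect priming per condition x SOA x ratio, with standard
#'   errors), `by_condition` (averages across ratios), and
#'   `n_not_converged`.
#' @export
priming_effects <- function(trials) {
  stopifnot(all(c("condition", "soa", "relatedness", "ratio", "rt") %in%
                  names(trials)))
  conv <- trials[trials$converged & !is.na(trials$rt), ]
  cells <- stats::aggregate(rt ~ condition + soa + relatedness + ratio,
                            data = conv,
                            FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                                n = length(v)))
  cells <- cbind(cells[, 1:4], as.data.frame(cells$rt))

  get_cell <- function(cond, soa, rel, ratio) {
    r <- cells[cells$condition == cond & cells$soa == soa &
                 cells$relatedness == rel & cells$ratio == ratio, ]
    if (nrow(r) == 0)
      stop(sprintf("missing cell: %s / soa %g / %s / ratio %g",
                   cond, soa, rel, ratio))
    r
  }

  combos <- unique(conv[conv$relatedness != "unrelated",
                        c("condition", "soa", "relatedness", "ratio")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    cc <- combos[k, ]
    rel_cell <- get_cell(cc$condition, cc$soa, cc$relatedness, cc$ratio)
    unr_cell <- get_cell(cc$condition, cc$soa, "unrelated", cc$ratio)
    eff <- unr_cell$mean - rel_cell$mean
    se <- sqrt(unr_cell$sd^2 / unr_cell$n + rel_cell$sd^2 / rel_cell$n)
    data.frame(condition = cc$condition, soa = cc$soa,
               type = ifelse(cc$relatedness == "related", "direct", "indirect"),
               ratio = cc$ratio, priming = eff, se = se,
               stringsAsFactors = FALSE)
  })
  by_ratio <- do.call(rbind, rows)
  by_condition <- stats::aggregate(priming ~ condition + soa + type,
                                   data = by_ratio, FUN = mean)
  structure(list(
    cells = cells, by_ratio = by_ratio, by_condition = by_condition,
    n_not_converged = sum(!trials$converged)
  ), class = "priming_summary")
}

#' @export
print.priming_summary <- function(x, ...) {
  cat("<priming_summary>\n")
  cat("priming (ms), averaged across Type-I prime ratios:\n")
  print(x$by_condition, row.names = FALSE)
  if (x$n_not_converged > 0)
    cat(sprintf("%d trial(s) did not converge (excluded from means)\n",
                x$n_not_converged))
  invisible(x)
}

#' Summary aggregates of short- and long-SOA priming
#'
#' Condition-level summary mirroring the headline comparisons: indirect and
#' long-SOA direct priming averaged across all Type-I ratios, and short-SOA
#' direct priming averaged separately over the high ratios (0.75 and 1,
#' Type-I-dominated stimulus lists) and the low ratios (0 and 0.25,
#' Type-II-dominated lists).
#'
#' @param trials_short Trial table of the short-SOA experiment.
#' @param trials_long Trial table of the long-SOA experiment (optional).
#' @return A data.frame with columns `condition`, `measure`, `priming`.
#' @export
priming_overview <- function(trials_short, trials_long = NULL) {
  ps <- priming_effects(trials_short)
  out <- list()
  dir_short <- ps$by_ratio[ps$by_ratio$type == "direct", ]
  for (cond in unique(dir_short$condition)) {
    d <- dir_short[dir_short$condition == cond, ]
    out[[length(out) + 1]] <- data.frame(
      condition = cond, measure = "direct_short_highI",
      priming = mean(d$priming[d$ratio >= 0.75]))
    out[[length(out) + 1]] <- data.frame(
      condition = cond, measure = "direct_short_lowI",
      priming = mean(d$priming[d$ratio <= 0.25]))
  }
  ind <- ps$by_condition[ps$by_condition$type == "indirect", ]
  if (nrow(ind) > 0)
    out[[length(out) + 1]] <- data.frame(condition = ind$condition,
                                         measure = "indirect_short",
                                         priming = ind$priming)
  if (!is.null(trials_long)) {
    pl <- priming_effects(trials_long)
    dl <- pl$by_condition[pl$by_condition$type == "direct", ]
    out[[length(out) + 1]] <- data.frame(condition = dl$condition,
                                         measure = "direct_long",
                                         priming = dl$priming)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distribution of semantic transition counts
#'
#' Normalized histogram of the number of semantic attractor transitions per
#' trial (before lexical target convergence), per grouping cell.
#'
#' @param trials A trial data.frame.
#' @param by Grouping columns (default condition and SOA).
#' @return A data.frame with the grouping columns, `n_transitions`, `count`,
#'   and `proportion` (within each group).
#' @export
transition_histogram <- function(trials, by = c("condition", "soa")) {
  stopifnot("n_transitions" %in% names(trials))
  tab <- stats::aggregate(list(count = trials$n_transitions),
                          by = c(trials[by],
                                 list(n_transitions = trials$n_transitions)),
                          FUN = length)
  grp <- do.call(paste, tab[by])
  tab$proportion <- tab$count / stats::ave(tab$count, grp, FUN = sum)
  tab[order(grp, tab$n_transitions), ]
}

#' Modal transition count per group
#'
#' @param trials A trial data.frame.
#' @param by Grouping columns.
#' @return A data.frame with the grouping columns and `mode_transitions`.
#' @export
transition_mode <- function(trials, by = c("condition", "soa")) {
  h <- transition_histogram(trials, by)
  grp <- do.call(paste, h[by])
  picks <- unlist(lapply(split(seq_len(nrow(h)), grp), function(idx)
    idx[which.max(h$count[idx])]))
  out <- h[picks, c(by, "n_transitions")]
  names(out)[names(out) == "n_transitions"] <- "mode_transitions"
  rownames(out) <- NULL
  out
}

#' Statistical spreading-activation wave
#'
#' Runs related short-SOA trials with a fixed prime (pattern 1, target its
#' strongly related pattern 2 — the pure Type-I cell) while recording the
#' semantic network's correlation trajectory, and averages across trials the
#' correlation with probe patterns at increasing semantic distance from the
#' prime (the prime itself, its strongly related concept, an indirectly
#' related concept, an unrelated concept) at fixed probe times after prime
#' onset. Faster latching spreads this wave further at any given time.
#'
#' @param model A `coupled_model`.
#' @param n_trials Number of trials to average.
#' @param base_seed Base seed (trial i uses `base_seed + i`).
#' @param probe_patterns Semantic pattern indices probed (default 1, 2, 9, 16).
#' @param probe_times Times after prime onset, ms (default 150 and 200).
#' @param prime,target Prime/target word indices (default 1 and 2).
#' @param soa Trial SOA (the default 200 keeps the probe window inside the
#'   prime-target interval).
#' @param ... Passed to [run_trial()].
#' @return A matrix (probe pattern x probe time) of mean correlations, with
#'   dimnames; attribute `n_trials`.
#' @export
spreading_wave <- function(model, n_trials = 100, base_seed = 1L,
                           probe_patterns = c(1, 2, 9, 16),
                           probe_times = c(150, 200),
                           prime = 1, target = 2, soa = 200, ...) {
  acc <- matrix(0, length(probe_patterns), length(probe_times),
                dimnames = list(pattern = probe_patterns,
                                time_ms = probe_times))
  for (i in seq_len(n_trials)) {
    spec <- trial_spec("related", soa = soa, prime = prime, target = target,
                       seed = base_seed + i)
    rec <- run_trial(model, spec, record_every = 1L, ...)
    idx <- vapply(probe_times, function(tt) which.min(abs(rec$traj$time - tt)),
                  integer(1))
    acc <- acc + t(rec$traj$semantic[idx, probe_patterns, drop = FALSE])
  }
  out <- acc / n_trials
  attr(out, "n_trials") <- n_trials
  out
}
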