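default_run_config <- function() {
  list(
    condition = "control",
    soa = 200,
    relatedness = c("related", "indirect", "unrelated"),
    ratios = c(0, 0.25, 0.5, 0.75, 1),
    trials_per_cell = 300,
    base_seed = 1L,
    dt = 0.66,
    timeout = 1000,
    prime_dur = 100,
    burn_in = 50,
    smoke = FALSE,
    semantic = unclass(semantic_params("control"))[-1],  # drop name field
    lexical  = unclass(lexical_params())[-1],
    coupling = coupling_params("control")
  )
}

apply_condition <- function(cfg) {
  if (cfg$condition == "schizophrenic") {
    sp <- semantic_params("schizophrenic")
    cp <- coupling_params("schizophrenic")
    cfg$semantic$U <- sp$U
    cfg$coupling$U_ls <- cp$U_ls
  }
  cfg
}

validate_run_config <- function(cfg) {
  check_pos <- function(key, val) {
    if (!is.numeric(val) || any(val <= 0))
      stop(sprintf("config key '%s' must be positive", key), call. = FALSE)
  }
  if (!cfg$condition %in% c("control", "schizophrenic"))
    stop("config key 'condition' must be 'control' or 'schizophrenic'",
         call. = FALSE)
  for (k in c("soa", "trials_per_cell", "dt", "timeout", "prime_dur"))
    check_pos(k, cfg[[k]])
  if (cfg$burn_in < 0) stop("config key 'burn_in' must be >= 0", call. = FALSE)
  if (!all(cfg$ratios >= 0 & cfg$ratios <= 1))
    stop("config key 'ratios' must lie in [0, 1]", call. = FALSE)
  if (!all(cfg$relatedness %in% c("related", "indirect", "unrelated")))
    stop("config key 'relatedness' has unknown levels", call. = FALSE)
  for (nw in c("semantic", "lexical")) {
    if (cfg[[nw]]$p <= 0 || cfg[[nw]]$p >= 1)
      stop(sprintf("config key '%s.p' must lie in (0, 1)", nw), call. = FALSE)
    for (k in c("T", "tau_n", "tau_r", "tau_corr", "x_max"))
      check_pos(paste0(nw, ".", k), cfg[[nw]][[k]])
    if (cfg[[nw]]$eta_amp < 0 || cfg[[nw]]$U < 0)
      stop(sprintf("config keys '%s.eta_amp'/'%s.U' must be >= 0", nw, nw),
           call. = FALSE)
  }
  invisible(cfg)
}

#' Build a fully resolved run configuration
#'
#' Defaults reproduce the standard parameter table exactly; the condition
#' switch changes only the two utilization values (recurrent semantic and
#' bottom-up lexical-to-semantic). Supplied values override defaults;
#' unknown keys are rejected.
#'
#' @param ... Named overrides of the default fields (`condition`, `soa`,
#'   `relatedness`, `ratios`, `trials_per_cell`, `base_seed`, `dt`,
#'   `timeout`, `prime_dur`, `burn_in`, `smoke`, and the nested `semantic`,
#'   `lexical`, `coupling` parameter lists, which are merged key-wise).
#' @return A validated list of class `run_config`.
#' @export
make_config <- function(...) {
  over <- list(...)
  cfg <- default_run_config()
  nested <- c("semantic", "lexical", "coupling")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # condition first, so explicit U overrides still win
  if (!is.null(over$condition)) cfg$condition <- over$condition
  validate_run_config(cfg)  # catches a bad condition before applying it
  cfg <- apply_condition(cfg)
  for (k in setdiff(names(over), "condition")) {
    if (k %in% nested) {
      bad <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(bad) > 0)
        stop(sprintf("unknown config key(s) under '%s': %s", k,
                     paste(bad, collapse = ", ")), call. = FALSE)
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Missing keys are filled with the defaults (an empty file yields the full
#' default control configuration); unknown or out-of-range keys raise an
#' error naming the key. The resolved configuration is suitable for
#' [save_config()], and `save(load(x))` is idempotent.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(make_config, raw)
}

#' Write a resolved run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the experiment described by a configuration
#'
#' Builds the model for the configured condition and runs the session grid.
#' In smoke mode the trial count per cell is reduced to 10.
#'
#' @param cfg A `run_config`.
#' @param progress Print per-cell progress.
#' @return A trial data.frame (see [run_session()]).
#' @export
run_config <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  sp <- structure(c(list(name = "semantic"), cfg$semantic),
                  class = "network_params")
  lp <- structure(c(list(name = "lexical"), cfg$lexical),
                  class = "network_params")
  model <- build_coupled_model(cfg$condition, seed = cfg$base_seed,
                               sem_params = sp, lex_params = lp,
                               coupling = cfg$coupling)
  run_session(soa = cfg$soa, relatedness = cfg$relatedness,
              conditions = cfg$condition, ratios = cfg$ratios,
              trials_per_cell = if (isTRUE(cfg$smoke)) 10L else cfg$trials_per_cell,
              base_seed = cfg$base_seed,
              models = stats::setNames(list(model), cfg$condition),
              progress = progress,
              dt = cfg$dt, timeout = cfg$timeout,
              prime_dur = cfg$prime_dur, burn_in = cfg$burn_in)
}

#' Build a test fixture (pattern sets, parameters, configuration)
#'
#' `"paper"` is the full standard setup (two 500-neuron networks, 17
#' patterns). `"tiny"` is a 50-neuron, 3-pattern miniature (one strongly
#' related pair plus a baseline) with sparseness raised so that active-set
#' and overlap counts stay meaningful integers (6 active semantic neurons,
#' overlap 1; 4 active lexical neurons); it exercises every invariant and
#' runs a trial in well under a second, for unit tests.
#'
#' @param scale `"tiny"` or `"paper"`.
#' @param seed Pattern seed.
#' @return A list with `semantic` and `lexical` pattern sets, `sem_params`,
#'   `lex_params`, `coupling`, and `config`.
#' @export
make_fixture <- function(scale = c("tiny", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    sp <- semantic_params()
    lp <- lexical_params()
    return(list(
      semantic = make_semantic_patterns(N = sp$N, p = sp$p, seed = seed),
      lexical = make_lexical_patterns(N = lp$N, p = lp$p, n_patterns = 17,
                                      seed = seed + 1L),
      sem_params = sp, lex_params = lp, coupling = coupling_params(),
      config = make_config()
    ))
  }
  g <- tiny_graph()
  sp <- semantic_params()
  sp$N <- 50L; sp$p <- 0.12
  lp <- lexical_params()
  lp$N <- 50L; lp$p <- 0.08
  sem <- make_semantic_patterns(N = sp$N, p = sp$p, graph = g, seed = seed)
  lex <- make_lexical_patterns(N = lp$N, p = lp$p, n_patterns = 3,
                               seed = seed + 1L)
  cfg <- make_config(trials_per_cell = 10L,
                     relatedness = c("related", "unrelated"),
                     semantic = list(N = sp$N, p = sp$p),
                     lexical = list(N = lp$N, p = lp$p))
  list(semantic = sem, lexical = lex, sem_params = sp, lex_params = lp,
       coupling = coupling_params(), config = cfg)
}

# miniature relation graph: patterns 1 and 2 strongly related, 3 = baseline
tiny_graph <- function() {
  structure(list(
    n_patterns = 3L,
    baseline_index = 3L,
    neighborhoods = list(1:2),
    strong_within_pairs = list(c(1L, 2L)),
    strong_cross_pairs = list(),
    typeI_direct_pairs = list(c(1L, 2L)),
    typeII_direct_pairs = list(),
    typeI_indirect_pairs = list(),
    typeII_indirect_pairs = list(),
    unrelated_neighborhood_pairs = list(),
    typical_within_pairs = list()
  ), class = "relation_graph")
}

#' Build a coupled model from a fixture
#'
#' @param fix A fixture from [make_fixture()].
#' @param condition `"control"` or `"schizophrenic"`.
#' @return A `coupled_model`.
#' @export
fixture_model <- function(fix, condition = c("control", "schizophrenic")) {
  condition <- match.arg(condition)
  sp <- fix$sem_params
  cp <- fix$coupling
  if (condition == "schizophrenic") {
    sp$U <- semantic_params("schizophrenic")$U
    cp$U_ls <- coupling_params("schizophrenic")$U_ls
  }
  build_coupled_model(condition, semantic = fix$semantic, lexical = fix$lexical,
                      sem_params = sp, lex_params = fix$lex_params,
                      coupling = cp)
}
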