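test_that("default parameters match the printed table", {
  sp <- semantic_params("control")
  expect_equal(sp$N, 500L); expect_equal(sp$p, 0.06)
  expect_equal(sp$T, 0.05); expect_equal(sp$tau_n, 7)
  expect_equal(sp$theta, 0.02); expect_equal(sp$lambda, 14.75)
  expect_equal(sp$U, 0.206); expect_equal(sp$tau_r, 93)
  expect_equal(sp$theta_ext, 1); expect_equal(sp$eta_amp, 0.05)
  expect_equal(sp$tau_corr, 17); expect_equal(sp$x_max, 100)
  expect_equal(semantic_params("schizophrenic")$U, 0.2615)
  # conditions differ only in U
  a <- unclass(semantic_params("control")); a$U <- NULL
  b <- unclass(semantic_params("schizophrenic")); b$U <- NULL
  expect_identical(a, b)

  lp <- lexical_params()
  expect_equal(lp$p, 0.04); expect_equal(lp$tau_n, 13)
  expect_equal(lp$theta, 0.17); expect_equal(lp$lambda, 27.75)
  expect_equal(lp$U, 0); expect_equal(lp$theta_ext, 0.25)
  expect_equal(lp$eta_amp, 0.025)

  cp <- coupling_params("control")
  expect_equal(cp$gain_ls, 2); expect_equal(cp$gain_sl, 0.21)
  expect_equal(cp$U_ls, 0.087); expect_equal(cp$tau_r_ls, 1333)
  expect_equal(cp$U_sl, 0); expect_equal(cp$external_gain, 0.56)
  expect_equal(coupling_params("schizophrenic")$U_ls, 0.1104)
})

test_that("projection matrices have the declared sparsity and gains", {
  sem <- make_semantic_patterns(seed = 2)
  lex <- make_lexical_patterns(seed = 3)
  pr <- build_projections(lex, sem)
  expect_identical(dim(pr$W_ls), c(500L, 500L))
  expect_identical(dim(pr$W_sl), c(500L, 500L))
  expect_true(all(pr$W_ls >= 0) && all(pr$W_sl >= 0))
  # single-connection weights: gain / n_active_presynaptic
  mu <- 4
  i_s <- which(sem$patterns[mu, ] == 1)[1]
  j_l <- which(lex$patterns[mu, ] == 1)[1]
  expect_equal(pr$W_ls[i_s, j_l], 2 / 20)
  expect_equal(pr$W_sl[j_l, i_s], 0.21 / 30)
  # connections only between corresponding patterns: a lexical neuron of
  # word mu projects exactly to the active set of concept mu
  targets <- which(pr$W_ls[, j_l] > 0)
  expect_setequal(targets, which(sem$patterns[mu, ] == 1))
  # baseline patterns carry no inter-network connections
  b_l <- which(lex$patterns[17, ] == 1)
  b_s <- which(sem$patterns[17, ] == 1)
  expect_true(all(pr$W_ls[, b_l] == 0))
  expect_true(all(pr$W_sl[, b_s] == 0))
  expect_true(all(pr$W_ls[b_s, ] == 0))
  expect_true(all(pr$W_sl[b_l, ] == 0))
  # a semantic neuron shared by two patterns sums both contributions
  shared <- which(colSums(sem$patterns[c(1, 2), ]) == 2)[1]
  j1 <- which(lex$patterns[1, ] == 1)[1]
  j2 <- which(lex$patterns[2, ] == 1)[1]
  expect_equal(pr$W_ls[shared, j1], 2 / 20)
  expect_equal(pr$W_ls[shared, j2], 2 / 20)
})

test_that("build_projections validates index compatibility", {
  sem <- make_semantic_patterns(seed = 2)
  lex <- make_lexical_patterns(n_patterns = 5, seed = 3)
  expect_error(build_projections(lex, sem), "mismatch")
})

test_that("coupled model assembly is reproducible and condition-aware", {
  m1 <- build_coupled_model("control", seed = 9)
  m2 <- build_coupled_model("control", seed = 9)
  ms <- build_coupled_model("schizophrenic", seed = 9)
  expect_identical(m1$semantic$patterns$patterns, m2$semantic$patterns$patterns)
  expect_identical(m1$lexical$patterns$patterns, ms$lexical$patterns$patterns)
  # condition changes exactly the two utilizations
  expect_equal(m1$semantic$params$U, 0.206)
  expect_equal(ms$semantic$params$U, 0.2615)
  expect_equal(m1$coupling$U_ls, 0.087)
  expect_equal(ms$coupling$U_ls, 0.1104)
  expect_equal(m1$lexical$params, ms$lexical$params)
  expect_identical(m1$graph, relation_graph())
})

test_that("lexical network stays on baseline without input but recognizes a word", {
  # simulation oracles for the coupled stepping system (full-size model)
  m <- build_coupled_model("control", seed = 1)
  # no visual input: baseline holds for >= 1 s
  set.seed(101)
  res0 <- latchnet:::.sim_trial_cpp(
    m$semantic$patterns$patterns, m$lexical$patterns$patterns,
    unclass(m$semantic$params), unclass(m$lexical$params), m$coupling,
    17L, 17L, 17L, 17L, 0L, 0L, 100, 200, 1000, 50, 0.66, 0.95, 0.5,
    TRUE, TRUE, 0L, 1000)
  expect_identical(res0$lex_event_id[length(res0$lex_event_id)], 17L)
  # visual input = word 1 for 100 ms: lexical converges on word 1 and
  # remains converged after offset
  set.seed(102)
  res1 <- latchnet:::.sim_trial_cpp(
    m$semantic$patterns$patterns, m$lexical$patterns$patterns,
    unclass(m$semantic$params), unclass(m$lexical$params), m$coupling,
    17L, 17L, 17L, 17L, 1L, 0L, 100, 200, 1000, 50, 0.66, 0.95, 0.5,
    TRUE, TRUE, 0L, 400)
  expect_identical(res1$lex_event_id, c(17L, 1L))
  expect_lt(res1$lex_event_t[2], 150)
})

test_that("word recognition triggers semantic convergence on the concept", {
  # Fig 2C chain of events: lexical prime convergence followed by semantic
  # convergence on the corresponding concept in > 90% of control trials
  m <- build_coupled_model("control", seed = 1)
  ok <- 0L; n <- 20L
  for (i in seq_len(n)) {
    spec <- trial_spec("related", soa = 200, prime_type = "I",
                       prime = 1, target = 2, seed = 300 + i)
    rec <- run_trial(m, spec)
    sem <- rec$semantic_events$pattern
    lex <- rec$lexical_events$pattern
    if (length(lex) >= 2 && lex[2] == 1L && 1L %in% sem) ok <- ok + 1L
  }
  expect_gt(ok / n, 0.9)
})

test_that("top-down feedback ablation removes priming", {
  # with gain_sl = 0 related and unrelated mean RTs are equal within
  # sampling error (the feedback is the priming mechanism)
  m <- build_coupled_model("control", seed = 1)
  m$coupling$gain_sl <- 0
  rts <- function(rel, prime, target, n = 15) {
    vapply(seq_len(n), function(i) {
      rec <- run_trial(m, trial_spec(rel, soa = 200, prime = prime,
                                     target = target, seed = 500 + i))
      if (rec$converged) rec$rt else NA_real_
    }, numeric(1))
  }
  related <- rts("related", 1, 2)
  unrelated <- rts("unrelated", 1, 9)
  expect_true(sum(!is.na(related)) > 10 && sum(!is.na(unrelated)) > 10)
  expect_lt(abs(mean(related, na.rm = TRUE) - mean(unrelated, na.rm = TRUE)),
            3 * sqrt(var(related, na.rm = TRUE) / sum(!is.na(related)) +
                     var(unrelated, na.rm = TRUE) / sum(!is.na(unrelated))) + 1)
})
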