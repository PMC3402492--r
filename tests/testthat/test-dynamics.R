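test_that("transfer function is a logistic in h/T", {
  expect_equal(transfer(0, 0.05), 0.5)
  expect_equal(transfer(c(-1e3, 1e3), 0.05), c(0, 1))
  expect_equal(transfer(0.05, 0.05), 1 / (1 + exp(-1)))
  # monotone
  h <- seq(-1, 1, length.out = 101)
  expect_true(all(diff(transfer(h, 0.05)) > 0))
})

test_that("external gating is a rectified shift", {
  expect_equal(gate_external(c(0, 0.2, 0.25, 1), 0.25), c(0, 0, 0, 0.75))
  expect_true(all(gate_external(runif(100), 0.3) >= 0))
})

test_that("noise process matches its stationary moments", {
  set.seed(1)
  n <- 20000
  dt <- 0.66; tau <- 17; amp <- 0.05
  eta <- rnorm(n, 0, amp)  # start in the stationary distribution
  steps <- 40
  tr <- matrix(0, steps, n)
  for (k in seq_len(steps)) {
    eta <- noise_step(eta, amp, tau, dt)
    tr[k, ] <- eta
  }
  # stationary sd = amp (Monte-Carlo tolerance)
  expect_equal(sd(tr[steps, ]), amp, tolerance = 0.03)
  # lag tau_corr autocorrelation = exp(-1)
  lag <- round(tau / dt)
  ac <- cor(tr[steps - lag, ], tr[steps, ])
  expect_equal(ac, exp(-1), tolerance = 0.05)
  # zero amplitude returns exact zeros
  expect_identical(noise_step(rnorm(5), 0, tau, dt), rep(0, 5))
})

test_that("pattern correlation matches stats::cor and handles flat input", {
  xi <- c(1, 1, 0, 0, 1, 0)
  x <- c(0.9, 0.8, 0.1, 0.2, 0.95, 0.05)
  expect_equal(pattern_correlation(x, xi), cor(x, xi))
  expect_true(is.na(pattern_correlation(rep(0.5, 6), xi)))
  expect_true(is.na(pattern_correlation(x, rep(1, 6))))
  expect_equal(pattern_correlation(xi, xi), 1)
})

test_that("stored patterns are fixed points without noise/depression", {
  # single-network invariant, checked through the reference stepper at the
  # full size and sparseness (the inhibition balance depends on both)
  ps <- make_semantic_patterns(seed = 4)
  J <- hopfield_weights(ps)
  par <- semantic_params("control")
  x0 <- as.numeric(ps$patterns[1, ])
  state <- list(h = (2 * x0 - 1) * 0.5, x = x0)
  for (k in seq_len(round(300 / 0.66)))
    state <- network_step(state, J, 0, par, 0.66)
  expect_gt(pattern_correlation(state$x, ps$patterns[1, ]), 0.95)
  expect_lt(abs(pattern_correlation(state$x, ps$patterns[2, ])), 0.5)
  # converged activities are near-binary
  expect_true(all(state$x[x0 == 1] > 0.9))
  expect_true(all(state$x[x0 == 0] < 0.1))
})

test_that("network_step rejects non-finite state", {
  fix <- make_fixture("tiny")
  J <- hopfield_weights(fix$semantic)
  st <- list(h = c(NaN, rep(0, 49)), x = rep(0, 50))
  expect_error(network_step(st, J, 0, fix$sem_params, 0.66), "non-finite")
})

test_that("compiled kernel agrees with the base-R reference stepper", {
  # dual-route check: replicate the kernel's deterministic main loop
  # (noise off, depression on) in plain R on the tiny fixture and compare
  # correlation trajectories step by step
  fix <- make_fixture("tiny")
  model <- fixture_model(fix, "control")
  sem <- model$semantic; lex <- model$lexical
  dt <- 0.66; burn_in <- 50; prime <- 1L; target <- 2L
  prime_dur <- 100; soa <- 200
  n_steps <- 280

  res <- latchnet:::.sim_trial_cpp(
    sem$patterns$patterns, lex$patterns$patterns,
    unclass(sem$params), unclass(lex$params), model$coupling,
    sem$patterns$baseline_index, lex$patterns$baseline_index,
    sem$patterns$baseline_index, lex$patterns$baseline_index,
    prime, 0L, prime_dur, soa, 1000, burn_in, dt, 0.95, 0.5,
    FALSE, TRUE, 1L, n_steps * dt)

  # --- R reference path (dense matrices, exported building blocks) ---
  Js <- hopfield_weights(sem$patterns)
  Jl <- hopfield_weights(lex$patterns)
  pr <- build_projections(lex$patterns, sem$patterns,
                          gain_ls = model$coupling$gain_ls,
                          gain_sl = model$coupling$gain_sl)
  sp <- sem$params; lp <- lex$params; cp <- model$coupling
  Ns <- sp$N; Nl <- lp$N
  x_s <- as.numeric(sem$patterns$patterns[sem$patterns$baseline_index, ])
  x_l <- as.numeric(lex$patterns$patterns[lex$patterns$baseline_index, ])
  h_s <- (2 * x_s - 1) * 0.5
  h_l <- (2 * x_l - 1) * 0.5
  r_s <- rep(1, Ns); r_ls <- rep(1, Nl)
  # burn-in: x clamped, resources frozen
  st_s <- list(h = h_s, x = x_s); st_l <- list(h = h_l, x = x_l)
  for (k in seq_len(round(burn_in / dt))) {
    es <- as.numeric(pr$W_ls %*% x_l)
    el <- as.numeric(pr$W_sl %*% x_s)
    st_s <- network_step(list(h = st_s$h, x = x_s), Js, es, sp, dt)
    st_l <- network_step(list(h = st_l$h, x = x_l), Jl, el, lp, dt)
  }
  h_s <- st_s$h; h_l <- st_l$h
  cors <- function(x, Xi) apply(Xi, 1, function(xi) pattern_correlation(x, xi))
  ref_s <- matrix(NA_real_, n_steps, 3)
  ref_l <- matrix(NA_real_, n_steps, 3)
  for (k in seq_len(n_steps)) {
    tk <- (k - 1) * dt
    word <- if (tk < prime_dur - 1e-9) prime else 0L
    rx_s <- r_s * x_s
    rx_l <- r_ls * x_l
    es <- as.numeric(pr$W_ls %*% rx_l)
    el <- as.numeric(pr$W_sl %*% x_s)
    if (word > 0) el <- el + cp$external_gain * lex$patterns$patterns[word, ]
    r_s <- depression_step(r_s, x_s, sp$U, sp$tau_r, sp$x_max, dt)
    r_ls <- depression_step(r_ls, x_l, cp$U_ls, cp$tau_r_ls, lp$x_max, dt)
    # J (r ∘ x) equals the resource-scaled effective weights acting on x
    drive_s <- as.numeric(Js %*% rx_s)
    reg_s <- sp$lambda * (mean(x_s) - sp$reg_frac * sp$p)
    h_s <- h_s + dt * (-h_s + drive_s - reg_s - sp$theta +
                         gate_external(es, sp$theta_ext)) / sp$tau_n
    drive_l <- as.numeric(Jl %*% x_l)
    reg_l <- lp$lambda * (mean(x_l) - lp$reg_frac * lp$p)
    h_l <- h_l + dt * (-h_l + drive_l - reg_l - lp$theta +
                         gate_external(el, lp$theta_ext)) / lp$tau_n
    x_s <- transfer(h_s, sp$T)
    x_l <- transfer(h_l, lp$T)
    ref_s[k, ] <- cors(x_s, sem$patterns$patterns)
    ref_l[k, ] <- cors(x_l, lex$patterns$patterns)
  }
  expect_equal(res$traj_sem, ref_s, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$traj_lex, ref_l, tolerance = 1e-8, ignore_attr = TRUE)
})
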