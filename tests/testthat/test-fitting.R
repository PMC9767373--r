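test_that("BIC formula and identity", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(100, 5, 588), 200 + 5 * log(588), tolerance = 1e-12)
  # one extra parameter at equal NLL costs exactly log(n)
  expect_equal(bic(50, 6, 588) - bic(50, 5, 588), log(588), tolerance = 1e-12)
})

test_that("session NLL matches hand-computable cases", {
  # two probe trials with go responses at p = 0.5: values never update
  sess <- tibble::tibble(
    trial = 0:1, stimulus_id = c(0L, 1L),
    stimulus_class = c("go", "nogo"), block_type = "probe",
    probe_block_id = 1L, response = "go", outcome = 0
  )
  p <- param_set(tau_R = 1, b_R = 0, Q0 = 0, theta = 1)
  expect_equal(session_nll(sess, p), 2 * log(2), tolerance = 1e-12)

  # near-deterministic agent choosing its own preferred responses: NLL ~ 0
  pd <- param_set(tau_R = 1e-4, b_R = 0, Q0 = 0.5, theta = 1)
  sd_sess <- simulate_session(default_sched, pd, seed = 5)
  expect_lt(session_nll(sd_sess, pd), 1e-6)
})

test_that("session NLL equals the naive trial-loop oracle on random sessions", {
  for (seed in 1:50) {
    sess <- random_small_session(seed)
    p <- random_params(seed + 31)
    expect_equal(session_nll(sess, p), oracle_session_nll(sess, p),
                 tolerance = 1e-10)
  }
})

test_that("fitting respects nesting: richer models never fit worse", {
  tol <- 1e-6
  for (seed in c(1, 2)) {
    sess <- simulate_session(default_sched, random_params(seed), seed = seed)
    nll <- vapply(c("baseline", "temperature", "bias", "full"), function(m) {
      fit_session(sess, m, n_starts = 25, seed = seed)$nll
    }, numeric(1))
    expect_lte(nll["temperature"], nll["baseline"] + tol)
    expect_lte(nll["bias"], nll["baseline"] + tol)
    expect_lte(nll["full"], nll["temperature"] + tol)
    expect_lte(nll["full"], nll["bias"] + tol)
  }
})

test_that("more starts never worsen the best NLL (prefix start sampling)", {
  sess <- simulate_session(default_sched, ref_params, seed = 13)
  nlls <- vapply(c(1, 10, 50), function(ns) {
    fit_session(sess, "bias", n_starts = ns, seed = 99)$nll
  }, numeric(1))
  expect_true(all(diff(nlls) <= 1e-12))
})

test_that("a fit started from the truth cannot end above the truth's NLL", {
  p <- param_set(tau_R = 1e-3, b_R = 0.2, b_P = 0.1, Q0 = 0.5, theta = 0.98)
  sess <- simulate_session(default_sched, p, seed = 7)
  f <- fit_session(sess, "bias", n_starts = 1, seed = 1, init = p)
  expect_lte(f$nll, session_nll(sess, p) + 1e-9)
})

test_that("fit results carry a consistent BIC and tidy/glance methods", {
  sess <- simulate_session(default_sched, ref_params, seed = 3)
  f <- fit_session(sess, "bias", n_starts = 10, seed = 2)
  expect_equal(f$bic, 2 * f$nll + 5 * log(588), tolerance = 1e-12)
  td <- generics::tidy(f)
  expect_equal(td$parameter, c("tau", "b_R", "b_P", "Q0", "theta"))
  gl <- generics::glance(f)
  expect_equal(gl$bic, f$bic)
  expect_equal(gl$n_free_params, 5)
})

test_that("single-session single-model comparison is the trivial table", {
  sess <- simulate_session(default_sched, ref_params, seed = 8, participant = 1L)
  cmp <- compare_models(sess, models = "bias", n_starts = 10, seed = 4)
  expect_equal(nrow(cmp$fits), 1)
  expect_equal(cmp$winner, "bias")
  expect_equal(cmp$summary$bic_summary, cmp$fits$bic)
})

test_that("the learning-rate grid is six values log-spaced on [0.01, 0.20]", {
  a <- alpha_sweep()
  expect_length(a, 6)
  expect_equal(a[1], 0.01)
  expect_equal(a[6], 0.20)
  expect_equal(diff(log(a)), rep(diff(log(c(0.01, 0.2))) / 5, 5), tolerance = 1e-12)
  expect_error(learning_rate_sweep(NULL, alphas = c(0, 0.1)),
               class = "gng_config_error")
})

test_that("a single-alpha sweep reduces to a plain model comparison", {
  sessions <- dplyr::bind_rows(
    simulate_session(default_sched, ref_params, seed = 31, participant = 1L),
    simulate_session(default_sched, ref_params, seed = 32, participant = 2L)
  )
  sw <- learning_rate_sweep(sessions, alphas = 0.06,
                            models = c("baseline", "bias"),
                            n_starts = 10, seed = 6)
  direct <- compare_models(sessions, models = c("baseline", "bias"),
                           alpha = 0.06, n_starts = 10,
                           seed = probegng:::derive_seed(6, round(1e6 * 0.06)))
  expect_equal(sw$winners$winner, direct$winner)
  expect_equal(sw$comparisons[[1]]$summary, direct$summary)
  expect_true(sw$stable)
})
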