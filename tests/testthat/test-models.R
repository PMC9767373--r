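test_that("model specifications count free parameters correctly", {
  expect_equal(model_spec("baseline")$n_free_params, 4)
  expect_equal(model_spec("temperature")$n_free_params, 5)
  expect_equal(model_spec("bias")$n_free_params, 5)
  expect_equal(model_spec("full")$n_free_params, 6)
  expect_equal(model_spec("bias")$free, c("tau", "b_R", "b_P", "Q0", "theta"))
  expect_error(
    validate_params(param_set(tau_R = 0.3, b_R = 0.3, b_P = 0.1),
                    model_spec("baseline")),
    class = "gng_param_error"
  )
})

test_that("delta-rule update moves values toward the outcome", {
  expect_equal(update_value(0, 0.06, 1), 0.06)
  expect_equal(update_value(0.73, 0, -1), 0.73)
  expect_equal(update_value(0.5, 0.06, -1), 0.41)
  # result always between q and r
  for (q in c(-1, -0.2, 0, 0.9)) {
    u <- update_value(q, 0.3, 1)
    expect_true(u >= min(q, 1) && u <= max(q, 1))
  }
  expect_error(update_value(0, 1.5, 1), class = "gng_param_error")
})

test_that("decay shrinks values toward zero, preserving sign", {
  expect_equal(decay_value(0, 0.9), 0)
  expect_equal(decay_value(0.5, 1), 0.5)
  expect_equal(decay_value(-0.2, 0.95), -0.19)
  expect_error(decay_value(0.5, 1.2), class = "gng_param_error")
})

test_that("biased softmax is a shifted, scaled logistic", {
  expect_equal(go_probability(0.4, -0.4, 0.7), 0.5)
  expect_equal(go_probability(0.37, 0, 1), 1 / (1 + exp(-0.37)), tolerance = 1e-12)
  expect_gt(go_probability(0.1, 0, 1e-8), 1 - 1e-6)  # deterministic limit
  expect_error(go_probability(0, 0, 0), class = "gng_param_error")
  # strictly increasing in q and bias
  qs <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(go_probability(qs, 0.2, 0.5)) > 0))
  expect_true(all(diff(go_probability(0.1, qs, 0.5)) > 0))
})

test_that("step_values applies the trial-type-dependent dynamics", {
  p <- param_set(alpha = 0.06, tau_R = 0.3, b_R = 0.3, Q0 = 0.2, theta = 0.9)
  v <- c(0.1, -0.4, 0.7)

  out <- step_values(v, list(stimulus_id = 2L, block_type = "reinforced"),
                     "go", 1, p)
  expect_equal(out, c(0.1, -0.4, 0.7 + 0.06 * (1 - 0.7)))

  out <- step_values(v, list(stimulus_id = 0L, block_type = "probe"), "go", NA, p)
  expect_identical(out, v)

  out <- step_values(v, list(stimulus_id = 1L, block_type = "probe"), "nogo", NA, p)
  expect_equal(out, c(0.1, -0.4 * 0.9, 0.7))

  expect_error(
    step_values(v, list(stimulus_id = 1L, block_type = "probe"), "go", 1, p),
    class = "gng_data_error"
  )
  expect_error(
    step_values(v, list(stimulus_id = 1L, block_type = "reinforced"), "nogo", -1, p),
    class = "gng_data_error"
  )
})

test_that("simulated sessions are reproducible and respect the outcome rule", {
  s1 <- simulate_session(default_sched, ref_params, seed = 42)
  s2 <- simulate_session(default_sched, ref_params, seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_session(default_sched, ref_params, seed = 43)
  expect_false(identical(s1$response, s3$response))

  # outcomes: +1 go response to go stimulus, -1 to no-go, 0 otherwise, 0 on probe
  go_resp <- s1$response == "go"
  reinf <- s1$block_type == "reinforced"
  expect_true(all(s1$outcome[go_resp & reinf & s1$stimulus_class == "go"] == 1))
  expect_true(all(s1$outcome[go_resp & reinf & s1$stimulus_class == "nogo"] == -1))
  expect_true(all(s1$outcome[!go_resp | !reinf] == 0))
})

test_that("near-deterministic agent with positive Q0 always goes on first presentations", {
  p <- param_set(tau_R = 1e-6, b_R = 0, Q0 = 0.5, theta = 1)
  sess <- simulate_session(default_sched, p, seed = 9)
  first_pres <- !duplicated(sess$stimulus_id)
  expect_true(all(sess$response[first_pres] == "go"))
})

test_that("without learning or decay the go probability is constant", {
  p <- param_set(alpha = 0, tau_R = 0.5, b_R = 0.2, Q0 = 0.3, theta = 1)
  sess <- simulate_session(default_sched, p, model = model_spec("baseline"), seed = 17)
  target <- plogis((0.3 + 0.2) / 0.5)
  expect_true(all(abs(sess$p_go - target) < 1e-12))
  # empirical rate within Monte-Carlo error (3 sigma) of the closed form
  mc_sd <- sqrt(target * (1 - target) / nrow(sess))
  expect_lt(abs(mean(sess$response == "go") - target), 3 * mc_sd)
})

test_that("value estimates stay inside the contraction bounds", {
  for (seed in 1:5) {
    p <- random_params(seed)
    sess <- simulate_session(default_sched, p, seed = seed, keep_trace = TRUE)
    tr <- attr(sess, "q_trace")
    expect_true(all(tr >= min(-1, p$Q0) - 1e-12))
    expect_true(all(tr <= max(1, p$Q0) + 1e-12))
  }
})

test_that("k consecutive rewarded go responses follow the geometric closed form", {
  alpha <- 0.06
  for (Q0 in c(-0.3, 0, 0.4)) {
    q <- Q0
    for (k in 1:6) {
      q <- update_value(q, alpha, 1)
      expect_equal(q, 1 - (1 - alpha)^k * (1 - Q0), tolerance = 1e-12)
    }
  }
})

test_that("sessions round-trip through the CSV dialect", {
  sess <- simulate_session(default_sched, ref_params, seed = 4, participant = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(sess, path)
  back <- read_sessions(path)
  expect_equal(back$response, sess$response)
  expect_equal(back$outcome, sess$outcome)
  expect_equal(back$participant, sess$participant)
})

test_that("parameter sets round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_params(ref_params, path)
  back <- read_params(path)
  expect_equal(unclass(back), unclass(ref_params), tolerance = 1e-12)
})
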