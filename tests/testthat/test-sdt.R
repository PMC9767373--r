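test_that("rate correction is identity inside and pulls perfect counts inward", {
  expect_equal(corrected_rate(18, 36), 0.5)
  expect_equal(corrected_rate(36, 36), 1 - 1 / 72)
  expect_equal(corrected_rate(0, 36), 1 / 72)
  for (n in c(1, 2, 5, 36, 200)) {
    expect_gt(corrected_rate(0, n), 0)
    expect_lt(corrected_rate(n, n), 1)
    ks <- 1:(max(n - 1, 1))
    ks <- ks[ks < n]
    if (length(ks)) expect_equal(corrected_rate(ks, n), ks / n)
  }
  expect_error(corrected_rate(1, 0), class = "gng_rate_error")
  expect_error(corrected_rate(-1, 10), class = "gng_rate_error")
})

test_that("d-prime and criterion match their probit definitions", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(pnorm(1), pnorm(-1)), 2, tolerance = 1e-10)
  expect_equal(dprime(0.8413, 0.1587), 2, tolerance = 1e-3)
  expect_equal(dprime(0.1587, 0.8413), -2, tolerance = 1e-3)
  expect_equal(criterion(0.8413, 0.1587), 0, tolerance = 1e-3)
  expect_equal(criterion(0.9, 0.9), qnorm(0.9), tolerance = 1e-10)
  expect_equal(criterion(0.5, 0.5), 0)
  expect_error(dprime(1, 0.5), class = "gng_rate_error")

  # antisymmetry / symmetry and monotonicity over a grid
  grid <- seq(0.05, 0.95, by = 0.15)
  for (h in grid) for (f in grid) {
    expect_equal(dprime(h, f), -dprime(f, h), tolerance = 1e-12)
    expect_equal(criterion(h, f), criterion(f, h), tolerance = 1e-12)
  }
  expect_true(all(diff(dprime(grid, 0.3)) > 0))
  expect_true(all(diff(dprime(0.7, grid)) < 0))
})

test_that("sliding curves agree with a naive window oracle", {
  for (seed in c(2, 8)) {
    sess <- simulate_session(default_sched, random_params(seed), seed = seed)
    for (metric in c("dprime", "criterion", "p_go_go", "p_go_nogo")) {
      for (w in c(5, 21)) {
        got <- sliding_curve(sess, metric, w)$value
        expect_equal(got, oracle_sliding(sess, metric, w), tolerance = 1e-12)
      }
    }
  }
})

test_that("sliding curve handles edges, degenerate responding and bad windows", {
  sess <- simulate_session(default_sched, ref_params, seed = 3)
  got <- sliding_curve(sess, "dprime", 21)
  expect_equal(nrow(got), 588)
  expect_true(all(is.na(got$value[1:10])))
  expect_true(all(is.na(got$value[579:588])))
  expect_true(all(!is.na(got$value[11:578])))

  # hand-built alternating session with a perfectly correct agent
  alt <- tibble::tibble(
    trial = 0:19,
    stimulus_id = rep(c(0L, 1L), 10),
    stimulus_class = rep(c("go", "nogo"), 10),
    block_type = "reinforced",
    probe_block_id = NA_integer_,
    response = rep(c("go", "nogo"), 10),
    outcome = rep(c(1, 0), 10)
  )
  expect_true(all(sliding_curve(alt, "p_go_go", 5)$value[3:18] == 1))
  expect_true(all(sliding_curve(alt, "p_go_nogo", 5)$value[3:18] == 0))

  expect_error(sliding_curve(sess, "dprime", 20), class = "gng_config_error")
})

test_that("probe contrasts use matched flanking windows and flag shortfalls", {
  sess <- simulate_session(default_sched, ref_params, seed = 21)
  bc <- block_contrast(sess)
  expect_equal(bc$probe_block_id, 1:5)
  expect_equal(bc$delta_d_prime, bc$d_prime_probe - bc$d_prime_pre)
  expect_equal(bc$delta_FAR_post, bc$FAR_probe - bc$FAR_post)

  # probe block too close to session start -> window shortfall
  sched2 <- gng_schedule(n_stimuli = 4, presentations = 30, n_probe_blocks = 1,
                         probe_block_length = 8, probe_onsets = 4L, seed = 2)
  sess2 <- simulate_session(sched2, ref_params, seed = 2)
  expect_error(block_contrast(sess2, window = 8), class = "gng_window_error")
})

test_that("block-independent parameters give no systematic probe contrast", {
  p <- param_set(alpha = 0, tau_R = 0.4, b_R = 0.1, Q0 = 0.2, theta = 1)
  deltas <- vapply(1:40, function(s) {
    sess <- simulate_session(default_sched, p, seed = 100 + s)
    mean(block_contrast(sess)$delta_d_prime, na.rm = TRUE)
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 4 * se + 0.05)
})

test_that("group test matches the textbook one-sample t formulas", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  got <- group_test(x)
  m <- mean(x); s <- sd(x); n <- length(x)
  t_hand <- m / (s / sqrt(n))
  expect_equal(got$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$dof, n - 1)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-12)
  expect_equal(got$cohens_d, m / s, tolerance = 1e-12)

  sym <- group_test(c(1, -1))
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$cohens_d, 0)

  expect_error(group_test(c(0, 0, 0)), class = "gng_test_error")
  expect_error(group_test(0.5), class = "gng_test_error")
})
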