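# Independent oracles and small fixtures used across the suite.
# The oracles deliberately avoid the package's computational paths: the NLL
# oracle is a naive trial loop over a literal per-stimulus value table, the
# window oracle recomputes every sliding window by explicit subsetting.

# Naive negative log-likelihood: literal per-stimulus table, explicit loop.
oracle_session_nll <- function(session, params, lik_floor = 1e-12) {
  n_stim <- max(session$stimulus_id) + 1L
  q <- rep(params$Q0, n_stim)
  nll <- 0
  for (t in seq_len(nrow(session))) {
    s <- session$stimulus_id[t] + 1L
    probe <- session$block_type[t] == "probe"
    tau <- if (probe) params$tau_P else params$tau_R
    b <- if (probe) params$b_P else params$b_R
    p <- 1 / (1 + exp(-(q[s] + b) / tau))
    go <- session$response[t] == "go"
    lik <- if (go) p else 1 - p
    nll <- nll - log(max(lik, lik_floor))
    if (go) {
      if (!probe) q[s] <- q[s] + params$alpha * (session$outcome[t] - q[s])
    } else {
      q[s] <- params$theta * q[s]
    }
  }
  nll
}

# Naive sliding-window metric: explicit subsetting per centre position.
oracle_sliding <- function(session, metric, window) {
  h <- (window - 1) / 2
  n <- nrow(session)
  vapply(seq_len(n), function(t) {
    if (t - h < 1 || t + h > n) return(NA_real_)
    w <- session[(t - h):(t + h), ]
    go <- w$stimulus_class == "go"
    rg <- w$response == "go"
    if (metric == "p_go_go") {
      if (!any(go)) return(NA_real_)
      return(sum(rg & go) / sum(go))
    }
    if (metric == "p_go_nogo") {
      if (!any(!go)) return(NA_real_)
      return(sum(rg & !go) / sum(!go))
    }
    if (!any(go) || !any(!go)) return(NA_real_)
    HR <- corrected_rate(sum(rg & go), sum(go))
    FAR <- corrected_rate(sum(rg & !go), sum(!go))
    if (metric == "dprime") qnorm(HR) - qnorm(FAR) else (qnorm(HR) + qnorm(FAR)) / 2
  }, numeric(1))
}

# Random small session for oracle-equivalence checks.
random_small_session <- function(seed) {
  set.seed(seed)
  sched <- gng_schedule(
    n_stimuli = 4, presentations = 9, n_probe_blocks = 1,
    probe_block_length = 6, probe_onsets = 18L, seed = seed
  )
  p <- random_params(seed + 1000)
  simulate_session(sched, p, seed = seed + 2000)
}

random_params <- function(seed) {
  set.seed(seed)
  param_set(
    alpha = 0.06,
    tau_R = exp(runif(1, log(0.05), log(2))),
    tau_P = exp(runif(1, log(0.05), log(2))),
    b_R = runif(1, -1.5, 1.5),
    b_P = runif(1, -1.5, 1.5),
    Q0 = runif(1, -1.5, 1.5),
    theta = runif(1, 0.5, 0.999)
  )
}

# Default 588-trial schedule shared by the slower tests (built once).
default_sched <- gng_schedule(seed = 1)

# Reference bias-model parameters at the published group scale.
ref_params <- param_set(tau_R = 0.3, b_R = 0.3, b_P = 0.13, Q0 = 0.37, theta = 0.95)
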