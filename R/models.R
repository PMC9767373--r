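#' Model specification for the biased-softmax Q-learning family
#'
#' The four model variants share the same value dynamics (delta-rule update on
#' reinforced go trials, no update on probe go trials, passive decay on no-go
#' trials) and differ only in which softmax parameters are allowed to change
#' between reinforced and probe blocks:
#'
#' * `baseline`: one temperature, one action bias (4 free parameters:
#'   tau, b, Q0, theta);
#' * `temperature`: block-specific temperatures tau_R/tau_P (5);
#' * `bias`: block-specific action biases b_R/b_P (5);
#' * `full`: both split (6).
#'
#' The learning rate alpha is never a free parameter (it is fixed, by default
#' at 0.06, because temperature and learning rate are not jointly identifiable
#' under deterministic reinforcement).
#'
#' @param name One of `"baseline"`, `"temperature"`, `"bias"`, `"full"`.
#' @return An object of class `gng_model`: a list with `name`,
#'   `split_temperature`, `split_bias`, `n_free_params` and `free` (names of
#'   the free parameters, in fitting order).
#' @examples
#' model_spec("bias")$n_free_params  # 5
#' @export
model_spec <- function(name = c("baseline", "temperature", "bias", "full")) {
  name <- match.arg(name)
  split_tau <- name %in% c("temperature", "full")
  split_b <- name %in% c("bias", "full")
  free <- c(
    if (split_tau) c("tau_R", "tau_P") else "tau",
    if (split_b) c("b_R", "b_P") else "b",
    "Q0", "theta"
  )
  structure(
    list(
      name = name,
      split_temperature = split_tau,
      split_bias = split_b,
      n_free_params = 4L + split_tau + split_b,
      free = free
    ),
    class = "gng_model"
  )
}

#' @export
print.gng_model <- function(x, ...) {
  cat(sprintf("<gng_model: %s> %d free parameters (%s); alpha fixed\n",
              x$name, x$n_free_params, paste(x$free, collapse = ", ")))
  invisible(x)
}

#' Create a parameter set for a go/no-go learning agent
#'
#' @param alpha Learning rate in \[0, 1\] (fixed during fitting; default 0.06).
#' @param tau_R,tau_P Softmax temperatures (> 0) for reinforced and probe
#'   blocks. `tau_P` defaults to `tau_R` (shared temperature).
#' @param b_R,b_P Additive action biases for reinforced and probe blocks;
#'   `b_P` defaults to `b_R` (shared bias).
#' @param Q0 Initial value estimate, one scalar shared by all stimuli.
#' @param theta Decay (passive-forgetting) factor in \[0, 1\] applied to the
#'   displayed stimulus on no-go-response trials.
#' @return An object of class `gng_params` (named list).
#' @examples
#' param_set(tau_R = 0.3, b_R = 0.3, b_P = 0.13, Q0 = 0.37, theta = 0.95)
#' @export
param_set <- function(alpha = 0.06, tau_R, tau_P = tau_R,
                      b_R = 0, b_P = b_R, Q0 = 0, theta = 1) {
  p <- list(alpha = alpha, tau_R = tau_R, tau_P = tau_P,
            b_R = b_R, b_P = b_P, Q0 = Q0, theta = theta)
  for (nm in names(p)) {
    if (length(p[[nm]]) != 1 || !is.finite(p[[nm]])) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "gng_param_error")
    }
  }
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "gng_param_error")
  }
  if (tau_R <= 0 || tau_P <= 0) {
    abort("Temperatures must be strictly positive.", class = "gng_param_error")
  }
  if (theta < 0 || theta > 1) {
    abort("`theta` must lie in [0, 1].", class = "gng_param_error")
  }
  structure(p, class = "gng_params")
}

#' @export
print.gng_params <- function(x, ...) {
  cat("<gng_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.data.frame.gng_params <- function(x, ...) as.data.frame(unclass(x), ...)

# Assert that a parameter set honours a model's tying constraints.
validate_params <- function(params, model) {
  if (!inherits(params, "gng_params")) {
    params <- do.call(param_set, as.list(params))
  }
  if (!model$split_temperature && params$tau_R != params$tau_P) {
    abort(sprintf("Model '%s' ties tau_R = tau_P.", model$name),
          class = "gng_param_error")
  }
  if (!model$split_bias && params$b_R != params$b_P) {
    abort(sprintf("Model '%s' ties b_R = b_P.", model$name),
          class = "gng_param_error")
  }
  params
}

# Map between a model's free-parameter vector and a full gng_params object.
free_to_params <- function(free, model, alpha) {
  v <- as.list(free)
  names(v) <- model$free
  tau_R <- if (model$split_temperature) v$tau_R else v$tau
  tau_P <- if (model$split_temperature) v$tau_P else v$tau
  b_R <- if (model$split_bias) v$b_R else v$b
  b_P <- if (model$split_bias) v$b_P else v$b
  param_set(alpha = alpha, tau_R = tau_R, tau_P = tau_P,
            b_R = b_R, b_P = b_P, Q0 = v$Q0, theta = v$theta)
}

params_to_free <- function(params, model) {
  v <- c(
    if (model$split_temperature) c(tau_R = params$tau_R, tau_P = params$tau_P)
    else c(tau = params$tau_R),
    if (model$split_bias) c(b_R = params$b_R, b_P = params$b_P)
    else c(b = params$b_R),
    Q0 = params$Q0, theta = params$theta
  )
  v[model$free]
}

#' Delta-rule value update
#'
#' `Q <- Q + alpha * (r - Q)`: moves the value estimate a fraction `alpha` of
#' the way toward the obtained outcome. Vectorized over `q` and `r`.
#'
#' @param q Current value estimate(s).
#' @param alpha Learning rate in \[0, 1\].
#' @param r Outcome, +1 (reward) or -1 (punishment).
#' @return Updated value(s), lying between `q` and `r`.
#' @export
update_value <- function(q, alpha, r) {
  if (any(alpha < 0 | alpha > 1)) {
    abort("`alpha` must lie in [0, 1].", class = "gng_param_error")
  }
  q + alpha * (r - q)
}

#' Passive forgetting (value decay)
#'
#' `Q <- theta * Q`: multiplicative shrinkage of a value estimate toward zero,
#' applied to the displayed stimulus on trials without a go response.
#'
#' @param q Current value estimate(s).
#' @param theta Decay factor in \[0, 1\]; 1 disables forgetting.
#' @return Decayed value(s).
#' @export
decay_value <- function(q, theta) {
  if (any(theta < 0 | theta > 1)) {
    abort("`theta` must lie in [0, 1].", class = "gng_param_error")
  }
  theta * q
}

#' Biased softmax go-response probability
#'
#' Probability of a go response to a stimulus with value `q`:
#' `1 / (1 + exp(-(q + bias) / tau))`. The additive `bias` shifts the overall
#' propensity to respond independent of learnt value; `tau` scales how
#' sensitive the choice is to value (higher temperature, more stochastic
#' choice).
#'
#' @param q Stimulus value(s).
#' @param bias Action bias (unbounded real).
#' @param tau Temperature, strictly positive.
#' @return Probability strictly in (0, 1), increasing in both `q` and `bias`.
#' @examples
#' go_probability(0, 0, 1)      # 0.5
#' go_probability(0.37, 0, 1)   # plogis(0.37)
#' @export
go_probability <- function(q, bias, tau) {
  if (any(tau <= 0)) {
    abort("`tau` must be strictly positive.", class = "gng_param_error")
  }
  plogis((q + bias) / tau)
}

#' Advance the per-stimulus value vector by one trial
#'
#' Applies the trial-type-dependent value dynamics to a full vector of
#' per-stimulus values: reinforced go-response trials update the displayed
#' stimulus by the delta rule; probe go-response trials leave all values
#' unchanged; no-go-response trials (either block type) decay the displayed
#' stimulus by `theta`. Non-displayed stimuli are never touched.
#'
#' @param values Numeric vector of per-stimulus values.
#' @param trial A single schedule row (list or one-row data frame) with
#'   `stimulus_id` (0-based) and `block_type`.
#' @param response `"go"` or `"nogo"`.
#' @param outcome Obtained outcome, +1/-1 on reinforced go-response trials and
#'   `NA` (or 0) otherwise; a nonzero outcome on a probe or no-go-response
#'   trial is a data-consistency error.
#' @param params A [param_set()].
#' @return The updated value vector.
#' @export
step_values <- function(values, trial, response, outcome, params) {
  s <- trial$stimulus_id + 1L
  stopifnot(s >= 1, s <= length(values))
  probe <- trial$block_type == "probe"
  go <- response == "go"
  has_outcome <- !is.na(outcome) && outcome != 0
  if (has_outcome && (probe || !go)) {
    abort("Nonzero outcome recorded on a probe or no-go-response trial.",
          class = "gng_data_error")
  }
  if (go && !probe) {
    if (!has_outcome) {
      abort("Reinforced go-response trial without an outcome.",
            class = "gng_data_error")
    }
    values[s] <- update_value(values[s], params$alpha, outcome)
  } else if (!go) {
    values[s] <- decay_value(values[s], params$theta)
  }
  values
}

#' Simulate one agent's session on a task schedule
#'
#' Plays a parameterized agent through a schedule: on each trial a go response
#' is drawn with the biased-softmax probability using the block-appropriate
#' temperature and bias, outcomes follow the deterministic reinforcement rule
#' (+1 for go responses to go stimuli, -1 for go responses to no-go stimuli,
#' nothing otherwise and nothing on probe trials), and values evolve as in
#' [step_values()].
#'
#' @param schedule A [gng_schedule()] (or data frame with its columns).
#' @param params A [param_set()].
#' @param model Optional [model_spec()]; when given, `params` is checked
#'   against the model's tying constraints.
#' @param seed Integer seed; identical seeds reproduce the session exactly.
#' @param participant Participant id recorded in the output.
#' @param keep_trace If `TRUE`, attach the pre-choice per-stimulus value
#'   matrix (trials x stimuli) as attribute `q_trace`.
#' @return A tibble with the schedule columns plus `participant`, `response`
#'   (`"go"`/`"nogo"`), `outcome` (+1/-1/0) and `p_go` (the model's
#'   go-probability on each trial).
#' @examples
#' sched <- gng_schedule(seed = 1)
#' sess <- simulate_session(sched, param_set(tau_R = 0.3, b_R = 0.3,
#'                                           Q0 = 0.37, theta = 0.95), seed = 7)
#' mean(sess$response == "go")
#' @export
simulate_session <- function(schedule, params, model = NULL, seed = 1L,
                             participant = 1L, keep_trace = FALSE) {
  if (!is.null(model)) params <- validate_params(params, model)
  n_stimuli <- attr(schedule, "n_stimuli") %||% length(unique(schedule$stimulus_id))
  sim <- with_seed(seed, {
    cpp_simulate_session(
      as.integer(schedule$stimulus_id),
      as.integer(schedule$stimulus_class == "go"),
      as.integer(schedule$block_type == "probe"),
      n_stimuli,
      params$alpha, params$tau_R, params$tau_P,
      params$b_R, params$b_P, params$Q0, params$theta,
      keep_trace
    )
  })
  out <- tibble::tibble(
    participant = as.integer(participant),
    trial = schedule$trial,
    stimulus_id = schedule$stimulus_id,
    stimulus_class = schedule$stimulus_class,
    block_type = schedule$block_type,
    probe_block_id = schedule$probe_block_id,
    response = ifelse(sim$response == 1L, "go", "nogo"),
    outcome = sim$outcome,
    p_go = sim$p_go
  )
  if (keep_trace) attr(out, "q_trace") <- sim$q_trace
  out
}
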