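#' Negative log-likelihood of a session under a model
#'
#' Replays the value dynamics deterministically from the recorded responses
#' and outcomes and accumulates `-sum(log p_t)`, where `p_t` is the model's
#' probability of the response actually given on trial `t` (the
#' biased-softmax go-probability for go responses, its complement for no-go
#' responses, with the block-appropriate temperature and bias). Per-trial
#' probabilities are floored at `lik_floor` before the log, so extreme
#' parameter values encountered during optimization cannot produce infinities.
#'
#' @param session A session tibble (one participant).
#' @param params A [param_set()].
#' @param model Optional [model_spec()] used to check tying constraints.
#' @param lik_floor Floor on per-trial probabilities.
#' @return Non-negative scalar NLL.
#' @export
session_nll <- function(session, params, model = NULL, lik_floor = 1e-12) {
  if (!is.null(model)) params <- validate_params(params, model)
  n_stimuli <- length(unique(session$stimulus_id))
  n_stimuli <- max(n_stimuli, max(session$stimulus_id) + 1L)
  cpp_session_nll(
    as.integer(session$stimulus_id),
    as.integer(session$block_type == "probe"),
    as.integer(session$response == "go"),
    as.numeric(session$outcome),
    n_stimuli,
    params$alpha, params$tau_R, params$tau_P,
    params$b_R, params$b_P, params$Q0, params$theta,
    lik_floor
  )
}

#' Bayesian information criterion
#'
#' `BIC = 2 * NLL + k * log(n)`; lower is better.
#'
#' @param nll Negative log-likelihood.
#' @param n_free_params Number of free parameters `k`.
#' @param n_trials Number of trials `n`.
#' @return BIC value.
#' @export
bic <- function(nll, n_free_params, n_trials) {
  if (any(n_trials < 1)) abort("`n_trials` must be >= 1.")
  2 * nll + n_free_params * log(n_trials)
}

# --- transform layer: free parameters <-> unconstrained optimizer space ----
# tau: log (positivity); theta: logit (unit interval); b, Q0: identity.
free_to_unconstrained <- function(free, model) {
  u <- free
  tau_names <- intersect(model$free, c("tau", "tau_R", "tau_P"))
  u[tau_names] <- log(free[tau_names])
  u["theta"] <- qlogis(min(max(free["theta"], 1e-9), 1 - 1e-9))
  u
}

unconstrained_to_free <- function(u, model) {
  free <- u
  tau_names <- intersect(model$free, c("tau", "tau_R", "tau_P"))
  # clamp keeps degenerate tau -> 0 / tau -> Inf optima representable
  free[tau_names] <- pmin(pmax(exp(u[tau_names]), 1e-12), 1e12)
  free["theta"] <- plogis(u["theta"])
  free
}

# Random start point in unconstrained space: tau ~ logU[0.05, 2],
# b and Q0 ~ U[-1.5, 1.5], theta ~ U[0.5, 0.999] (then logit).
sample_start <- function(model) {
  u <- numeric(length(model$free))
  names(u) <- model$free
  for (nm in model$free) {
    u[nm] <- switch(
      substr(nm, 1, 2),
      "ta" = runif(1, log(0.05), log(2)),
      "b_" = runif(1, -1.5, 1.5),
      "b"  = runif(1, -1.5, 1.5),
      "Q0" = runif(1, -1.5, 1.5),
      "th" = qlogis(runif(1, 0.5, 0.999))
    )
  }
  u
}

#' Fit one model to one session by multi-start maximum likelihood
#'
#' Minimizes [session_nll()] over the model's free parameters using BFGS in a
#' transformed, unconstrained space (log temperature, logit decay), started
#' from `n_starts` random initializations; the learning rate is held fixed.
#' The best converged solution (lowest NLL; ties broken by start index) is
#' returned.
#'
#' @param session A session tibble (one participant).
#' @param model A [model_spec()] or model name.
#' @param alpha Fixed learning rate.
#' @param n_starts Number of random starting points. 1000 is the conventional
#'   choice for this model class; smaller values (25-50) are routinely
#'   sufficient for this likelihood and are used throughout the package's own
#'   harnesses.
#' @param seed Integer seed governing start-point sampling.
#' @param init Optional [param_set()] used as an additional (first) starting
#'   point, e.g. the generating truth in recovery studies.
#' @param lik_floor Per-trial probability floor, as in [session_nll()].
#' @return An object of class `gng_fit`: `model`, fitted `params`
#'   ([param_set()]), `nll`, `bic`, `n_starts`, `n_converged`, `best_start`,
#'   `n_trials`. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_session <- function(session, model, alpha = 0.06, n_starts = 50,
                        seed = 1L, init = NULL, lik_floor = 1e-12) {
  if (is.character(model)) model <- model_spec(model)
  n_starts <- check_count(n_starts, "n_starts")
  n_stimuli <- max(session$stimulus_id) + 1L
  stim <- as.integer(session$stimulus_id)
  blk <- as.integer(session$block_type == "probe")
  resp <- as.integer(session$response == "go")
  outc <- as.numeric(session$outcome)
  split_tau <- model$split_temperature
  split_b <- model$split_bias

  # objective over unconstrained parameters, avoiding per-call tibble work
  obj <- function(u) {
    tau_R <- exp(u[1])
    tau_P <- if (split_tau) exp(u[2]) else tau_R
    i <- if (split_tau) 3L else 2L
    b_R <- u[i]
    b_P <- if (split_b) u[i + 1L] else b_R
    j <- i + 1L + split_b
    val <- cpp_session_nll(stim, blk, resp, outc, n_stimuli,
                           alpha, tau_R, tau_P, b_R, b_P,
                           u[j], plogis(u[j + 1L]), lik_floor)
    if (!is.finite(val)) 1e10 else val  # line searches can wander to Inf-Inf
  }

  starts <- with_seed(seed, purrr::map(seq_len(n_starts), ~ sample_start(model)))
  if (!is.null(init)) {
    init <- validate_params(init, model)
    u0 <- free_to_unconstrained(params_to_free(init, model), model)
    starts <- c(list(stats::setNames(u0, model$free)), starts)
  }
  best <- NULL
  n_converged <- 0L
  for (k in seq_along(starts)) {
    res <- tryCatch(
      optim(starts[[k]], obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(res) || any(!is.finite(res$par))) next
    if (res$convergence == 0) n_converged <- n_converged + 1L
    if (is.null(best) || res$value < best$value - 1e-12) {
      best <- res
      best$start <- k
    }
  }
  if (is.null(best)) {
    abort("Optimization failed from every starting point.",
          class = "gng_fit_error")
  }
  free <- unconstrained_to_free(stats::setNames(best$par, model$free), model)
  params <- free_to_params(free, model, alpha)
  structure(
    list(
      model = model,
      params = params,
      nll = best$value,
      bic = bic(best$value, model$n_free_params, nrow(session)),
      n_starts = n_starts,
      n_converged = n_converged,
      best_start = best$start,
      n_trials = nrow(session)
    ),
    class = "gng_fit"
  )
}

#' @export
print.gng_fit <- function(x, ...) {
  cat(sprintf("<gng_fit: %s> NLL %.2f, BIC %.2f (%d/%d starts converged)\n",
              x$model$name, x$nll, x$bic, x$n_converged, x$n_starts))
  print(round(unlist(unclass(x$params)), 4))
  invisible(x)
}

#' Fit all models to all sessions and compare by BIC
#'
#' Fits each model in `models` to every participant's session and summarises
#' the per-participant BICs per model (median with an SEM computed as
#' sd/sqrt(n), and the median-BIC difference from the baseline model). The
#' winner is the model with the lowest group summary (median by default).
#'
#' @param sessions Long tibble of sessions with a `participant` column.
#' @param models Character vector of model names to compare.
#' @param alpha Fixed learning rate shared by all fits.
#' @param n_starts Random starts per fit.
#' @param seed Master seed; per-(participant, model) seeds are derived from
#'   it.
#' @param summary_stat `"median"` (default) or `"mean"` group summary used to
#'   declare the winner.
#' @return An object of class `gng_comparison`: `fits` (one row per
#'   participant x model with NLL, BIC and fitted parameters), `summary` (one
#'   row per model), `winner`, `summary_stat`, `alpha`.
#' @export
compare_models <- function(sessions,
                           models = c("baseline", "temperature", "bias", "full"),
                           alpha = 0.06, n_starts = 50, seed = 1L,
                           summary_stat = c("median", "mean")) {
  summary_stat <- match.arg(summary_stat)
  by_pid <- split(sessions, sessions$participant)
  fits <- purrr::imap(by_pid, function(sess, pid) {
    purrr::map(models, function(m) {
      f <- fit_session(sess, m, alpha = alpha, n_starts = n_starts,
                       seed = derive_seed(seed, as.integer(pid), match(m, models)))
      tibble::tibble(
        participant = as.integer(pid), model = m,
        nll = f$nll, bic = f$bic,
        n_converged = f$n_converged,
        tau_R = f$params$tau_R, tau_P = f$params$tau_P,
        b_R = f$params$b_R, b_P = f$params$b_P,
        Q0 = f$params$Q0, theta = f$params$theta
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  stat_fun <- if (summary_stat == "median") median else mean
  summ <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      bic_summary = stat_fun(.data$bic),
      bic_sem = sd(.data$bic) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ref <- if ("baseline" %in% summ$model) {
    summ$bic_summary[summ$model == "baseline"]
  } else {
    summ$bic_summary[1]
  }
  summ$delta_bic_vs_baseline <- summ$bic_summary - ref
  summ <- summ[order(match(summ$model, models)), ]
  structure(
    list(
      fits = fits,
      summary = summ,
      winner = summ$model[which.min(summ$bic_summary)],
      summary_stat = summary_stat,
      alpha = alpha
    ),
    class = "gng_comparison"
  )
}

#' @export
print.gng_comparison <- function(x, ...) {
  cat(sprintf("<gng_comparison> alpha = %g, winner: %s (%s BIC)\n",
              x$alpha, x$winner, x$summary_stat))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Log-spaced learning-rate grid
#'
#' @param n Number of values.
#' @param from,to Range endpoints (inclusive).
#' @return Numeric vector, evenly spaced on the log scale.
#' @examples
#' alpha_sweep()  # 6 values from 0.01 to 0.20
#' @export
alpha_sweep <- function(n = 6, from = 0.01, to = 0.20) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Model comparison across a grid of fixed learning rates
#'
#' Repeats [compare_models()] at each learning rate in `alphas` and reports
#' whether the winning model is stable across the grid — the check that the
#' model-selection conclusion does not hinge on the particular fixed alpha.
#'
#' @inheritParams compare_models
#' @param alphas Learning-rate grid; defaults to [alpha_sweep()].
#' @return An object of class `gng_sweep`: `winners` (tibble of alpha and
#'   winning model), `comparisons` (list of `gng_comparison`), `stable`
#'   (logical: one winner across all alphas).
#' @export
learning_rate_sweep <- function(sessions, alphas = alpha_sweep(),
                                models = c("baseline", "temperature", "bias", "full"),
                                n_starts = 50, seed = 1L,
                                summary_stat = "median") {
  if (any(alphas <= 0 | alphas > 1)) {
    abort("All learning rates must lie in (0, 1].", class = "gng_config_error")
  }
  comparisons <- purrr::imap(
    stats::setNames(as.list(alphas), sprintf("alpha_%g", alphas)),
    function(a, nm) {
      compare_models(sessions, models = models, alpha = a,
                     n_starts = n_starts,
                     seed = derive_seed(seed, round(1e6 * a)),
                     summary_stat = summary_stat)
    }
  )
  winners <- tibble::tibble(
    alpha = alphas,
    winner = unname(purrr::map_chr(comparisons, "winner"))
  )
  structure(
    list(winners = winners, comparisons = comparisons,
         stable = length(unique(winners$winner)) == 1),
    class = "gng_sweep"
  )
}

#' @export
print.gng_sweep <- function(x, ...) {
  cat("<gng_sweep>", if (x$stable) "stable winner:" else "winner varies:",
      paste(unique(x$winners$winner), collapse = ", "), "\n")
  print(as.data.frame(x$winners), row.names = FALSE)
  invisible(x)
}
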