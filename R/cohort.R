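#' Configuration for a synthetic cohort
#'
#' Describes the population from which synthetic participants' true parameters
#' are drawn, and the inclusion rule applied to their simulated behaviour. The
#' defaults emulate a 60-participant cohort performing the default 588-trial
#' task, with behaviour generated by the bias model: initial values centred on
#' Q0 = 0.37 (SD 0.58), a probe-minus-reinforced bias difference centred on
#' -0.17 (SD 0.12), fixed learning rate 0.06, and an inclusion criterion of
#' d-prime >= 1 on the reinforced trials of the second session half.
#' Temperature, reinforced bias and decay have no published group values; the
#' defaults (tau log-normal around 0.3, b_R ~ N(0.3, 0.3),
#' theta ~ N(0.95, 0.05) clipped to \[0, 1\]) are documented stand-ins chosen
#' to produce realistic learning curves.
#'
#' @param n_participants Cohort size.
#' @param Q0_mean,Q0_sd Normal distribution of initial values.
#' @param db_mean,db_sd Normal distribution of the bias difference
#'   `b_P - b_R`.
#' @param alpha Fixed learning rate (not sampled).
#' @param tau_meanlog,tau_sdlog Log-normal distribution of the shared
#'   temperature.
#' @param b_R_mean,b_R_sd Normal distribution of the reinforced-block bias.
#' @param theta_mean,theta_sd Normal distribution of the decay factor,
#'   clipped to \[0, 1\].
#' @param inclusion_dprime d-prime threshold on second-half reinforced trials;
#'   `-Inf` includes everyone.
#' @param master_seed Master seed from which all per-participant seeds are
#'   derived.
#' @return An object of class `gng_cohort_config`.
#' @export
cohort_config <- function(n_participants = 60,
                          Q0_mean = 0.37, Q0_sd = 0.58,
                          db_mean = -0.17, db_sd = 0.12,
                          alpha = 0.06,
                          tau_meanlog = log(0.3), tau_sdlog = 0.2,
                          b_R_mean = 0.3, b_R_sd = 0.3,
                          theta_mean = 0.95, theta_sd = 0.05,
                          inclusion_dprime = 1,
                          master_seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants"),
    Q0_mean = Q0_mean, Q0_sd = Q0_sd,
    db_mean = db_mean, db_sd = db_sd,
    alpha = alpha,
    tau_meanlog = tau_meanlog, tau_sdlog = tau_sdlog,
    b_R_mean = b_R_mean, b_R_sd = b_R_sd,
    theta_mean = theta_mean, theta_sd = theta_sd,
    inclusion_dprime = inclusion_dprime,
    master_seed = as.integer(master_seed)
  )
  if (any(c(Q0_sd, db_sd, tau_sdlog, b_R_sd, theta_sd) < 0)) {
    abort("Distribution scales must be non-negative.", class = "gng_config_error")
  }
  structure(cfg, class = "gng_cohort_config")
}

#' Draw one participant's true parameters
#'
#' Samples a bias-model parameter set from the population described by a
#' [cohort_config()]: `tau` log-normal (shared across blocks), `b_R` normal,
#' `b_P = b_R + db` with `db` normal, `Q0` normal, `theta` normal clipped to
#' \[0, 1\]. Draws violating a hard domain constraint are resampled, up to a
#' bounded retry budget.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for this draw.
#' @param max_retries Retry budget for domain violations.
#' @return A [param_set()] for the bias model (`tau_R = tau_P`).
#' @export
sample_parameters <- function(config, seed = 1L, max_retries = 100L) {
  with_seed(seed, {
    for (i in seq_len(max_retries)) {
      tau <- rlnorm(1, config$tau_meanlog, config$tau_sdlog)
      b_R <- rnorm(1, config$b_R_mean, config$b_R_sd)
      b_P <- b_R + rnorm(1, config$db_mean, config$db_sd)
      Q0 <- rnorm(1, config$Q0_mean, config$Q0_sd)
      theta <- min(1, max(0, rnorm(1, config$theta_mean, config$theta_sd)))
      if (tau > 0) {
        return(param_set(alpha = config$alpha, tau_R = tau, tau_P = tau,
                         b_R = b_R, b_P = b_P, Q0 = Q0, theta = theta))
      }
    }
    abort("Could not draw domain-valid parameters within the retry budget.",
          class = "gng_config_error")
  })
}

#' Generate a synthetic cohort of simulated participants
#'
#' Samples true parameters per participant, simulates each one's session on a
#' common schedule, and applies the inclusion criterion (d-prime on the
#' reinforced trials of the second half of the session). Excluded participants
#' are retained with `included = FALSE` so exclusion behaviour itself can be
#' studied. Fully deterministic given `config$master_seed`.
#'
#' @param config A [cohort_config()].
#' @param schedule A [gng_schedule()] shared by all participants.
#' @param model A [model_spec()]; defaults to the bias model. Models that tie
#'   the bias force `b_P = b_R` on the sampled parameters (and likewise for
#'   the temperature), so the same population machinery can generate
#'   baseline-model cohorts.
#' @return An object of class `gng_cohort`: a list with `participants` (one
#'   row per participant: true parameters, second-half d-prime, `included`)
#'   and `sessions` (long per-trial tibble over all participants), plus the
#'   `config`, `schedule` and `model` used.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_participants = 4),
#'                           gng_schedule(seed = 1))
#' cohort$participants
#' }
#' @export
generate_cohort <- function(config, schedule, model = model_spec("bias")) {
  half_start <- floor(nrow(schedule) / 2)
  res <- purrr::map(seq_len(config$n_participants), function(pid) {
    p <- sample_parameters(config, seed = derive_seed(config$master_seed, pid, 1L))
    if (!model$split_bias) p$b_P <- p$b_R
    if (!model$split_temperature) p$tau_P <- p$tau_R
    sess <- simulate_session(schedule, p, model = model,
                             seed = derive_seed(config$master_seed, pid, 2L),
                             participant = pid)
    second_half <- sess[sess$trial >= half_start & sess$block_type == "reinforced", ]
    dp <- sdt_window(second_half)$d_prime
    list(
      row = tibble::tibble(
        participant = pid,
        alpha = p$alpha, tau_R = p$tau_R, tau_P = p$tau_P,
        b_R = p$b_R, b_P = p$b_P, Q0 = p$Q0, theta = p$theta,
        d_prime_second_half = dp,
        included = is.finite(dp) && dp >= config$inclusion_dprime
      ),
      sess = sess
    )
  })
  structure(
    list(
      participants = dplyr::bind_rows(purrr::map(res, "row")),
      sessions = dplyr::bind_rows(purrr::map(res, "sess")),
      config = config,
      schedule = schedule,
      model = model
    ),
    class = "gng_cohort"
  )
}

#' @export
print.gng_cohort <- function(x, ...) {
  cat(sprintf(
    "<gng_cohort> %d participants (%d included), %d trials each, model '%s'\n",
    nrow(x$participants), sum(x$participants$included),
    nrow(x$schedule), x$model$name
  ))
  invisible(x)
}

#' True parameter sets of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param included_only Restrict to participants passing the inclusion
#'   criterion.
#' @return A list of [param_set()] objects.
#' @export
cohort_params <- function(cohort, included_only = FALSE) {
  pt <- cohort$participants
  if (included_only) pt <- pt[pt$included, ]
  purrr::pmap(
    pt[, c("alpha", "tau_R", "tau_P", "b_R", "b_P", "Q0", "theta")],
    param_set
  )
}
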