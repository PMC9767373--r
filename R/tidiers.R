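#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted model
#'
#' @param x A `gng_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `parameter`, `estimate`.
#' @method tidy gng_fit
#' @export
tidy.gng_fit <- function(x, ...) {
  free <- params_to_free(x$params, x$model)
  tibble::tibble(parameter = names(free), estimate = unname(free))
}

#' @rdname tidy.gng_fit
#' @method glance gng_fit
#' @export
glance.gng_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    n_free_params = x$model$n_free_params,
    nll = x$nll,
    bic = x$bic,
    n_trials = x$n_trials,
    n_starts = x$n_starts,
    n_converged = x$n_converged
  )
}

#' Tidy a model comparison
#'
#' @param x A `gng_comparison`.
#' @param ... Unused.
#' @return `tidy()`: per-participant, per-model fit table. `glance()`: one
#'   row per model with the group BIC summary and the winner flagged.
#' @method tidy gng_comparison
#' @export
tidy.gng_comparison <- function(x, ...) x$fits

#' @rdname tidy.gng_comparison
#' @method glance gng_comparison
#' @export
glance.gng_comparison <- function(x, ...) {
  dplyr::mutate(x$summary, winner = .data$model == x$winner)
}

#' Tidy a parameter-recovery report
#'
#' @param x A `gng_recovery`.
#' @param ... Unused.
#' @return `tidy()`: per-parameter correlations, bias and RMSE. `glance()`:
#'   one row with the minimum correlations across parameters and run sizes.
#' @method tidy gng_recovery
#' @export
tidy.gng_recovery <- function(x, ...) x$summary

#' @rdname tidy.gng_recovery
#' @method glance gng_recovery
#' @export
glance.gng_recovery <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    min_pearson = min(x$summary$pearson),
    min_spearman = min(x$summary$spearman),
    n_sets = length(unique(x$draws$set)),
    n_datasets = x$n_datasets,
    n_starts = x$n_starts,
    n_failed = x$n_failed
  )
}
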