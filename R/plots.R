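#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_ribbon geom_hline geom_abline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a participant's sliding-window learning curve
#'
#' Overlays the windowed d-prime (or another metric) on the session timeline,
#' shading probe blocks so the probe-versus-reinforced pattern is visible.
#'
#' @param session A session tibble (one participant).
#' @param metric Metric passed to [sliding_curve()].
#' @param window Window width.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(session, metric = "dprime", window = 21) {
  curve <- sliding_curve(session, metric, window)
  curve$block_type <- session$block_type
  ggplot(curve, aes(x = .data$trial, y = .data$value,
                    colour = .data$block_type, group = 1)) +
    geom_line(na.rm = TRUE) +
    labs(x = "Trial", y = metric, colour = "Block") +
    theme_minimal()
}

#' @describeIn validation_curves Plot simulated go-probability curves per
#'   model, go and no-go stimuli separately, probe trials highlighted.
#' @param object A `gng_curves` tibble.
#' @param ... Unused.
#' @method autoplot gng_curves
#' @export
autoplot.gng_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$trial, y = .data$p_go,
                     colour = .data$stimulus_class,
                     alpha = .data$block_type, group = .data$stimulus_class)) +
    geom_ribbon(aes(ymin = .data$p_go - .data$sem,
                    ymax = .data$p_go + .data$sem,
                    fill = .data$stimulus_class),
                colour = NA, alpha = 0.2, na.rm = TRUE) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~model) +
    labs(x = "Trial", y = "P(Go)", colour = "Stimulus class") +
    theme_minimal()
}

#' @describeIn compare_models Plot the group BIC of each model relative to
#'   the baseline model (negative bars fit better than baseline).
#' @param object A `gng_comparison`.
#' @param ... Unused.
#' @method autoplot gng_comparison
#' @export
autoplot.gng_comparison <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$model, y = .data$delta_bic_vs_baseline,
             fill = .data$model == object$winner)) +
    geom_col(show.legend = FALSE) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = NULL, y = sprintf("%s BIC - baseline", object$summary_stat)) +
    theme_minimal()
}

#' @describeIn parameter_recovery Scatter generating against recovered
#'   values, one facet per free parameter, identity line overlaid.
#' @param object A `gng_recovery`.
#' @param ... Unused.
#' @method autoplot gng_recovery
#' @export
autoplot.gng_recovery <- function(object, ...) {
  ggplot(object$draws, aes(x = .data$generating, y = .data$recovered)) +
    geom_point(alpha = 0.3, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    facet_wrap(~parameter, scales = "free") +
    labs(x = "Generating value", y = "Recovered value") +
    theme_minimal()
}

#' @describeIn mechanism_demo Plot the reinforced and probe choice curves and
#'   their gap across stimulus value.
#' @param object A tibble from [mechanism_demo()].
#' @param ... Unused.
#' @export
plot_mechanism <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("value", "p_reinforced", "p_probe")],
                              -"value", names_to = "block",
                              names_prefix = "p_", values_to = "p_go")
  ggplot(long, aes(x = .data$value, y = .data$p_go, colour = .data$block)) +
    geom_line() +
    labs(x = "Stimulus value Q", y = "P(Go)", colour = NULL) +
    theme_minimal()
}
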